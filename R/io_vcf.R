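#' GRCh37 pseudoautosomal regions of chromosome X
#'
#' PAR1 and PAR2 intervals (1-based inclusive, GRCh37). X positions inside
#' these intervals are diploid in both sexes and are classified as
#' `chrom_class = "other"`.
#'
#' @return A `data.frame` with `start` and `end`.
#' @export
grch37_par_regions <- function() {
  data.frame(start = c(60001, 154931044), end = c(2699520, 155260560))
}

#' Chromosome class of a locus
#'
#' @param chrom Chromosome names (with or without a `chr` prefix).
#' @param pos 1-based positions.
#' @param par_regions Pseudoautosomal intervals on X; see
#'   [grch37_par_regions()].
#' @return `"autosome"`, `"X_nonPAR"` or `"other"` (pseudoautosomal X, Y,
#'   MT, unplaced).
#' @export
chrom_class_of <- function(chrom, pos, par_regions = grch37_par_regions()) {
  chrom <- sub("^chr", "", as.character(chrom))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.numeric(pos), n)
  out <- rep("other", n)
  out[chrom %in% as.character(1:22)] <- "autosome"
  on_x <- chrom == "X"
  in_par <- rep(FALSE, n)
  for (i in seq_len(nrow(par_regions))) {
    in_par <- in_par | (pos >= par_regions$start[i] &
                          pos <= par_regions$end[i])
  }
  out[on_x & !in_par] <- "X_nonPAR"
  out
}

#' Read a six-column PED pedigree file
#'
#' Whitespace-delimited, no header: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, 0 = unknown), phenotype. The trio
#' `role` of each sample is derived from the pedigree structure: an
#' individual listed as someone's mother/father gets that role; an
#' individual with at least one named parent is a proband.
#'
#' @param path PED file.
#' @return A `data.frame` with `family`, `id`, `father`, `mother`, `sex`
#'   (decoded to male/female/unknown), `phenotype`, `role`.
#' @export
read_ped <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ped) < 6L) stop("PED file must have 6 columns: ", path)
  ped <- ped[, 1:6]
  names(ped) <- c("family", "id", "father", "mother", "sex", "phenotype")
  if (anyDuplicated(ped$id)) {
    stop("duplicate sample id(s) in PED: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  ped$sex <- c("1" = "male", "2" = "female", "0" = "unknown")[ped$sex]
  ped$sex[is.na(ped$sex)] <- "unknown"
  role <- rep("unrelated", nrow(ped))
  role[ped$father != "0" | ped$mother != "0"] <- "proband"
  role[ped$id %in% ped$mother[ped$mother != "0"]] <- "mother"
  role[ped$id %in% ped$father[ped$father != "0"]] <- "father"
  ped$role <- role
  ped
}

#' Read per-sample variant observations from a VCF
#'
#' Parses a VCF 4.2 with per-sample `AD` (allele depths) using
#' `VariantAnnotation::readVcf()` and emits one observation per sample and
#' alternate allele. Multi-allelic sites are decomposed: each alternate
#' yields its own observation with that alternate's AD as `alt_reads`, while
#' `total_reads` is the site total (the sample's `DP` when present and
#' consistent, otherwise the sum over all allele depths). Sites where a
#' sample's AD is missing are skipped with a log line. When AD is absent at
#' a site but `DP` and a single-ALT `AF` FORMAT field are present,
#' observations are reconstructed as `round(AF * DP)` and logged as
#' inferred. Coordinates are 1-based inclusive throughout.
#'
#' @param vcf_path VCF file (plain text or bgzipped).
#' @param ped_path Optional PED file; when given, every PED sample must be
#'   present in the VCF (fatal error listing offenders) and sex, family and
#'   trio role are attached to each observation.
#' @param par_regions Pseudoautosomal intervals for [chrom_class_of()].
#' @return A `data.frame`: `sample`, `family`, `role`, `sex`, `chrom`,
#'   `pos`, `ref`, `alt`, `alt_index`, `alt_reads`, `total_reads`,
#'   `chrom_class`.
#' @export
read_vcf_observations <- function(vcf_path, ped_path = NULL,
                                  par_regions = grch37_par_regions()) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  samples <- colnames(vcf)
  ped <- NULL
  if (!is.null(ped_path)) {
    ped <- read_ped(ped_path)
    missing <- setdiff(ped$id, samples)
    if (length(missing) > 0L) {
      stop("PED sample(s) absent from VCF: ",
           paste(missing, collapse = ", "))
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list),
                    function(i) as.character(alt_list[[i]]))
  geno <- VariantAnnotation::geno(vcf)
  has_ad <- "AD" %in% names(geno)
  ad <- if (has_ad) geno$AD else NULL
  dp <- if ("DP" %in% names(geno)) geno$DP else NULL
  af <- if ("AF" %in% names(geno)) geno$AF else NULL

  rows <- vector("list", length(chrom) * length(samples))
  k <- 0L
  for (i in seq_along(chrom)) {
    alts <- alt_chr[[i]]
    for (s in seq_along(samples)) {
      ad_i <- if (has_ad) ad[i, s][[1]] else NULL
      if (is.null(ad_i) || length(ad_i) == 0L || all(is.na(ad_i))) {
        # AD-absent fallback: reconstruct from AF * DP for single-ALT sites
        dp_i <- if (!is.null(dp)) dp[i, s] else NA
        af_i <- if (!is.null(af)) unlist(af[i, s]) else NA
        if (length(alts) == 1L && !is.na(dp_i) && length(af_i) == 1L &&
            !is.na(af_i)) {
          .msg("AD missing at ", chrom[i], ":", pos[i], " sample ",
               samples[s], "; inferred alt reads as round(AF*DP)")
          ad_i <- c(dp_i - round(af_i * dp_i), round(af_i * dp_i))
        } else {
          .msg("AD missing at ", chrom[i], ":", pos[i], " sample ",
               samples[s], "; observation skipped")
          next
        }
      }
      if (length(ad_i) != length(alts) + 1L) {
        .msg("AD length mismatch at ", chrom[i], ":", pos[i], " sample ",
             samples[s], "; observation skipped")
        next
      }
      total <- sum(ad_i)
      dp_i <- if (!is.null(dp)) dp[i, s] else NA
      if (!is.na(dp_i) && dp_i >= total) total <- dp_i
      for (a in seq_along(alts)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample = samples[s], chrom = chrom[i], pos = pos[i],
          ref = ref[i], alt = alts[a], alt_index = a,
          alt_reads = ad_i[a + 1L], total_reads = total,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
    data.frame(sample = character(0), chrom = character(0),
               pos = numeric(0), ref = character(0), alt = character(0),
               alt_index = integer(0), alt_reads = integer(0),
               total_reads = integer(0), stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    idx <- match(out$sample, ped$id)
    out$family <- ped$family[idx]
    out$role <- ped$role[idx]
    out$sex <- ped$sex[idx]
  } else {
    out$family <- NA_character_
    out$role <- NA_character_
    out$sex <- "unknown"
  }
  out$chrom_class <- chrom_class_of(out$chrom, out$pos, par_regions)
  out[, c("sample", "family", "role", "sex", "chrom", "pos", "ref", "alt",
          "alt_index", "alt_reads", "total_reads", "chrom_class")]
}

#' Write a summary report to JSON or TSV
#'
#' The JSON form round-trips: [read_report()] on the written file
#' reproduces the report. The TSV form is a flat two-column key/value
#' rendering for spreadsheet use.
#'
#' @param report A `summary_report` from [summarize_cohort()].
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "summary_report"))
  if (format == "json") {
    # named atomic vectors must become named lists or jsonlite drops names
    jsonify <- function(x) {
      if (is.list(x)) lapply(x, jsonify)
      else if (length(x) > 0L && !is.null(names(x))) as.list(x)
      else x
    }
    jsonlite::write_json(jsonify(unclass(report)), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    flat <- unlist(unclass(report))
    write.table(
      data.frame(key = names(flat), value = unname(flat)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON summary report written by [write_report()]
#'
#' @param path JSON file.
#' @return A `summary_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$mean_aaf_by_group <- lapply(x$mean_aaf_by_group, unlist)
  for (nm in c("counts_by_inheritance", "counts_by_classification",
               "counts_by_classification_proband", "counts_by_consequence",
               "recurrent_genes", "pathway_burden", "rates")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  x$excluded_from_means <- as.character(unlist(x$excluded_from_means))
  x$n_cpg <- if (is.null(x$n_cpg)) NA_real_ else as.numeric(x$n_cpg)
  class(x) <- "summary_report"
  x
}

#' Write mosaic calls to TSV
#'
#' @param calls A `data.frame` of calls (e.g. from [trio_pipeline()] or a
#'   classified observation table).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
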
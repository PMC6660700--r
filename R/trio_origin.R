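#' Assign the inheritance origin of a proband variant from trio read counts
#'
#' A variant absent from both available parents (fewer than
#' `presence_min_reads` alternate reads each) is de novo when both parents
#' were tested, and `incomplete_trio` when one or both parental samples are
#' unavailable and the available parent (if any) is negative. A variant
#' present in one parent is inherited when that parent classifies as a
#' consistent heterozygote/hemizygote, and parental-mosaic when the parent
#' classifies as a mosaic candidate; presence in both parents (or a parent
#' observation that cannot be classified) yields `ambiguous` with an
#' explanatory note. Every input maps to an origin; no case errors.
#'
#' The published criteria never quantify "absence of the variant in parental
#' DNA" for Sanger-screened parents; the read-count rule used here (default
#' 3 alternate reads) is a configurable stand-in.
#'
#' @param proband Named list or vector with `alt_reads` and `total_reads`.
#' @param mother,father Same shape as `proband`, or `NULL` when the sample
#'   is unavailable.
#' @param policy A [threshold_policy()] used to classify parental
#'   observations.
#' @param presence_min_reads Minimum alternate reads for a parent to count
#'   as carrying the variant (default 3).
#' @param chrom_class Chromosome class of the locus (shared by the trio).
#' @return An object of class `origin_call`: list with `origin`,
#'   `upd_suspicion` (always `FALSE` here; see [flag_aaf_inconsistency()]),
#'   `notes`, and per-parent AAFs/statuses (`NA` when unavailable).
#' @examples
#' assign_origin(list(alt_reads = 24, total_reads = 130),
#'               mother = list(alt_reads = 0, total_reads = 60),
#'               father = list(alt_reads = 0, total_reads = 55))$origin
#' @export
assign_origin <- function(proband, mother = NULL, father = NULL,
                          policy = threshold_policy(),
                          presence_min_reads = 3L,
                          chrom_class = "autosome") {
  stopifnot(inherits(policy, "threshold_policy"))
  pro <- .as_counts(proband, "proband")
  if (pro$total_reads < policy$min_depth) {
    stop("proband observation below minimum depth (",
         pro$total_reads, " < ", policy$min_depth, ")")
  }

  side <- function(obs, parent_sex) {
    if (is.null(obs)) {
      return(list(available = FALSE, present = FALSE, aaf = NA_real_,
                  status = NA_character_))
    }
    obs <- .as_counts(obs, "parent")
    cls <- classify_observation(obs$alt_reads, obs$total_reads,
                                sex = parent_sex, chrom_class = chrom_class,
                                policy = policy)
    list(available = TRUE,
         present = obs$alt_reads >= presence_min_reads,
         aaf = cls$aaf, status = cls$status)
  }
  mo <- side(mother, "female")
  fa <- side(father, "male")

  notes <- character(0)
  n_avail <- mo$available + fa$available
  present_in <- c(mother = mo$present, father = fa$present)

  if (!any(present_in)) {
    if (n_avail == 2L) {
      origin <- "de_novo"
    } else {
      origin <- "incomplete_trio"
      notes <- c(notes, sprintf(
        "%d parental sample(s) unavailable; variant absent in available parent(s)",
        2L - n_avail))
    }
  } else if (all(present_in)) {
    origin <- "ambiguous"
    notes <- c(notes, "variant present in both parents")
  } else {
    p <- if (mo$present) mo else fa
    label <- if (mo$present) "maternal" else "paternal"
    if (isTRUE(p$status %in% c("consistent_het", "consistent_hemi"))) {
      origin <- paste0("inherited_", label)
    } else if (is_mosaic_candidate(p$status)) {
      origin <- paste0("parental_mosaic_", label)
    } else {
      origin <- "ambiguous"
      notes <- c(notes, sprintf(
        "variant present in %s but parental status is %s", label, p$status))
    }
  }

  structure(
    list(origin = origin, upd_suspicion = FALSE,
         notes = paste(notes, collapse = "; "),
         proband_aaf = pro$alt_reads / pro$total_reads,
         mother_aaf = mo$aaf, father_aaf = fa$aaf,
         mother_status = mo$status, father_status = fa$status),
    class = "origin_call"
  )
}

.as_counts <- function(x, what) {
  x <- as.list(x)
  if (is.null(x$alt_reads) || is.null(x$total_reads)) {
    stop(what, " observation needs alt_reads and total_reads")
  }
  a <- as.numeric(x$alt_reads); t <- as.numeric(x$total_reads)
  if (is.na(a) || is.na(t) || t < 1 || a < 0 || a > t) {
    stop("invalid ", what, " read counts")
  }
  list(alt_reads = a, total_reads = t)
}

#' Flag an AAF-inconsistent inherited variant (suspected UPD/AOH)
#'
#' An inherited variant is expected at a heterozygous-consistent AAF in the
#' proband. When the inheritance origin is `inherited_*` but the proband's
#' own call is a diploid mosaic candidate (AAF below the heterozygote floor
#' or above its ceiling), the call is flagged for orthogonal review: such
#' discrepancies have revealed segmental uniparental disomy / absence of
#' heterozygosity covering the inherited allele.
#'
#' @param proband_status The proband's classification status (a row of
#'   [classify_observation()] output, or its `status` string).
#' @param origin An `origin_call` from [assign_origin()].
#' @return The `origin_call` with `upd_suspicion` set and a review note
#'   appended when triggered.
#' @export
flag_aaf_inconsistency <- function(proband_status, origin) {
  stopifnot(inherits(origin, "origin_call"))
  status <- if (is.data.frame(proband_status)) proband_status$status
            else as.character(proband_status)
  stopifnot(length(status) == 1L)
  inherited <- origin$origin %in% c("inherited_maternal", "inherited_paternal")
  if (inherited &&
      status %in% c("candidate_mosaic_low", "candidate_mosaic_high")) {
    origin$upd_suspicion <- TRUE
    origin$notes <- paste(
      c(if (nzchar(origin$notes)) origin$notes,
        "proband AAF inconsistent with inherited heterozygote; recommend SNP-array AOH/UPD review"),
      collapse = "; ")
  }
  origin
}

#' @export
print.origin_call <- function(x, ...) {
  cat("<origin_call> ", x$origin,
      if (x$upd_suspicion) " [UPD suspicion]" else "", "\n", sep = "")
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Run the call + origin pipeline over a trio VCF
#'
#' Reads per-sample observations from a multi-sample VCF and a PED file,
#' classifies each proband observation against `policy`, assigns an
#' inheritance origin from the parental read counts at the same site, and
#' applies the AAF-inconsistency (UPD suspicion) flag.
#'
#' @param vcf_path,ped_path Input files; see [read_vcf_observations()].
#' @param policy A [threshold_policy()].
#' @param presence_min_reads Parental presence cutoff; see [assign_origin()].
#' @param par_regions Pseudoautosomal intervals used to treat X positions as
#'   diploid; see [chrom_class_of()].
#' @return A `data.frame`, one row per proband observation: locus, proband
#'   AAF and status, parental AAFs, `origin`, `upd_suspicion`, `notes`.
#' @export
trio_pipeline <- function(vcf_path, ped_path, policy = threshold_policy(),
                          presence_min_reads = 3L,
                          par_regions = grch37_par_regions()) {
  obs <- read_vcf_observations(vcf_path, ped_path, par_regions = par_regions)
  pro <- obs[obs$role == "proband", , drop = FALSE]
  if (nrow(pro) == 0L) stop("no proband observations found in ", vcf_path)
  key <- function(d) paste(d$family, d$chrom, d$pos, d$ref, d$alt, sep = ":")
  mo <- obs[obs$role == "mother", , drop = FALSE]
  fa <- obs[obs$role == "father", , drop = FALSE]
  mo_idx <- match(key(pro), key(mo))
  fa_idx <- match(key(pro), key(fa))

  pro_cls <- classify_observation(pro$alt_reads, pro$total_reads,
                                  sex = pro$sex,
                                  chrom_class = pro$chrom_class,
                                  policy = policy)
  res <- lapply(seq_len(nrow(pro)), function(i) {
    as_parent <- function(d, j) {
      if (is.na(j)) NULL
      else list(alt_reads = d$alt_reads[j], total_reads = d$total_reads[j])
    }
    if (pro_cls$status[i] == "insufficient_depth") {
      return(data.frame(
        family = pro$family[i], sample = pro$sample[i],
        chrom = pro$chrom[i], pos = pro$pos[i],
        ref = pro$ref[i], alt = pro$alt[i],
        proband_aaf = pro_cls$aaf[i], proband_status = pro_cls$status[i],
        mother_aaf = NA_real_, father_aaf = NA_real_,
        origin = NA_character_, upd_suspicion = FALSE,
        notes = "proband below minimum depth; origin not assigned",
        stringsAsFactors = FALSE))
    }
    oc <- assign_origin(
      list(alt_reads = pro$alt_reads[i], total_reads = pro$total_reads[i]),
      mother = as_parent(mo, mo_idx[i]),
      father = as_parent(fa, fa_idx[i]),
      policy = policy, presence_min_reads = presence_min_reads,
      chrom_class = pro$chrom_class[i])
    oc <- flag_aaf_inconsistency(pro_cls$status[i], oc)
    data.frame(
      family = pro$family[i], sample = pro$sample[i],
      chrom = pro$chrom[i], pos = pro$pos[i],
      ref = pro$ref[i], alt = pro$alt[i],
      proband_aaf = pro_cls$aaf[i], proband_status = pro_cls$status[i],
      mother_aaf = oc$mother_aaf, father_aaf = oc$father_aaf,
      origin = oc$origin, upd_suspicion = oc$upd_suspicion,
      notes = oc$notes, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
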
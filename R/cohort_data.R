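#' Path to the bundled mosaic cohort table
#'
#' Returns the installed location of `mosaic_cohort.tsv`, a machine-readable
#' reconstruction of the 120 reported mosaic variants of a ~12,000-sample
#' diagnostic exome cohort: 80 detected in probands and 40 in parental or
#' grandparental samples. One parental row of the published rendition is not
#' recoverable; it is represented by a reconstructed placeholder record
#' (`record_id` `"106-PLACEHOLDER"`, sentinel gene symbol `UNKNOWN106`) whose
#' category, classification and consequence class are forced by the published
#' aggregate counts and whose AAF is left absent (`aaf_method` `unavailable`)
#' so that no group mean is contaminated.
#'
#' @return Path to the TSV file.
#' @export
mosascan_fixture_path <- function() {
  system.file("extdata", "mosaic_cohort.tsv", package = "mosascan",
              mustWork = TRUE)
}

.cohort_columns <- c(
  "record_id", "table", "carrier", "carrier_sex", "inheritance_category",
  "gene", "transcript", "cdna_hgvs", "protein_hgvs", "classification",
  "aaf_percent", "aaf_method"
)

.enums <- list(
  table = c("proband", "parental"),
  carrier = c("proband", "mother", "father", "grandmother"),
  carrier_sex = c("male", "female", "unknown"),
  inheritance_category = c("AD", "AD_AR", "AD_somatic", "AR", "XL",
                           "somatic_only"),
  classification = c("pathogenic", "likely_pathogenic", "VOUS"),
  aaf_method = c("exome", "amplicon", "sanger_only", "unavailable")
)

#' Load a mosaic cohort record table
#'
#' Reads a TSV of cohort records (one row per reported mosaic variant) and
#' validates it: column schema, enum values, AAF range, uniqueness of record
#' ids. The bundled fixture (the default) holds exactly 120 records, 80 with
#' `carrier = "proband"`.
#'
#' @param path TSV file; defaults to the bundled fixture.
#' @return A `data.frame` of class `cohort_records`. `aaf_percent` is numeric
#'   in (0, 100] with `NA` where no AAF was reported; `protein_hgvs` is `NA`
#'   where absent.
#' @examples
#' rec <- load_cohort_fixture()
#' nrow(rec)                       # 120
#' sum(rec$carrier == "proband")   # 80
#' @export
load_cohort_fixture <- function(path = mosascan_fixture_path()) {
  if (!file.exists(path)) stop("cohort fixture not found: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nfields != length(.cohort_columns))
  if (length(bad) > 0L) {
    stop("malformed cohort row(s) at line ", paste(bad, collapse = ", "),
         ": expected ", length(.cohort_columns), " tab-separated fields")
  }
  x <- read.delim(path, colClasses = "character", quote = "",
                  check.names = FALSE)
  if (!identical(names(x), .cohort_columns)) {
    stop("cohort fixture columns must be exactly: ",
         paste(.cohort_columns, collapse = ", "))
  }
  if (anyDuplicated(x$record_id)) {
    stop("duplicate record_id in cohort table: ",
         paste(unique(x$record_id[duplicated(x$record_id)]), collapse = ", "))
  }
  for (col in names(.enums)) {
    bad <- !(x[[col]] %in% .enums[[col]])
    if (any(bad)) {
      stop("invalid ", col, " value(s) in row(s) ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(x[[col]][bad]), collapse = ", "))
    }
  }
  aaf <- suppressWarnings(as.numeric(x$aaf_percent))
  unparsed <- nzchar(x$aaf_percent) & is.na(aaf)
  if (any(unparsed)) {
    stop("non-numeric aaf_percent in row(s) ",
         paste(which(unparsed), collapse = ", "))
  }
  if (any(!is.na(aaf) & (aaf <= 0 | aaf > 100))) {
    stop("aaf_percent out of (0, 100] in row(s) ",
         paste(which(!is.na(aaf) & (aaf <= 0 | aaf > 100)), collapse = ", "))
  }
  x$aaf_percent <- aaf
  x$protein_hgvs[!nzchar(x$protein_hgvs)] <- NA_character_
  if (!all((x$carrier == "proband") == (x$table == "proband"))) {
    stop("carrier 'proband' must coincide with table 'proband'")
  }
  class(x) <- c("cohort_records", "data.frame")
  x
}

#' Parse proband sex from a cohort record id
#'
#' Proband record ids end in F (female), M (male) or U (unknown, e.g. a
#' fetus); parental ids carry a `-Mo`/`-Fa`/`-PGM` suffix naming the carrier.
#'
#' @param record_id Character vector of record ids.
#' @return Character vector: `"female"`, `"male"` or `"unknown"`.
#' @export
proband_sex_from_id <- function(record_id) {
  suffix <- sub("^[0-9]+\\s*([FMU]).*$", "\\1", record_id)
  out <- rep("unknown", length(record_id))
  out[suffix == "F"] <- "female"
  out[suffix == "M"] <- "male"
  out
}

#' Classify the molecular consequence of an HGVS-described variant
#'
#' Maps cDNA/protein HGVS notation to one of `missense`, `nonsense`,
#' `frameshift`, `inframe_indel`, `splice`, `other`. Protein notation takes
#' precedence over cDNA notation, and a frameshift marker takes precedence
#' over del/dup/delins: `fs` -> frameshift; a terminating change (`*`/`Ter`)
#' -> nonsense; a single-residue substitution -> missense; del/dup/delins
#' without `fs` -> inframe_indel. Without protein notation, an intronic
#' position offset (e.g. `c.67+2T>G`) maps to splice, and a cDNA del/dup is
#' resolved in-frame/frameshift by whether its span is divisible by three.
#' Unparseable notation yields `other` with a warning, never an error.
#'
#' @param cdna_hgvs Character vector of cDNA HGVS strings (`c.` notation).
#' @param protein_hgvs Character vector of protein HGVS strings (`p.`
#'   notation) or `NA` where absent. Recycled if length 1.
#' @return Character vector of consequence classes.
#' @examples
#' classify_consequence("c.1447C>T", "p.R483*")   # nonsense
#' classify_consequence("c.67+2T>G", NA)          # splice
#' @export
classify_consequence <- function(cdna_hgvs, protein_hgvs = NA_character_) {
  n <- max(length(cdna_hgvs), length(protein_hgvs))
  cdna <- rep_len(as.character(cdna_hgvs), n)
  prot <- rep_len(as.character(protein_hgvs), n)
  prot[!is.na(prot) & (prot %in% c("", "N/A", "NA", "."))] <- NA_character_
  vapply(seq_len(n), function(i) {
    .classify_consequence_one(cdna[i], prot[i])
  }, character(1))
}

.classify_consequence_one <- function(cdna, prot) {
  if (!is.na(prot)) {
    body <- sub("^p\\.", "", sub("^p\\.\\((.*)\\)$", "p.\\1", prot))
    if (grepl("fs", body)) return("frameshift")
    if (grepl("(\\*|Ter)$", body)) return("nonsense")
    if (grepl("^[A-Z]([a-z]{2})?[0-9]+[A-Z]([a-z]{2})?$", body)) {
      return("missense")
    }
    if (grepl("(del|dup|delins)", body)) return("inframe_indel")
    warning("unparseable protein HGVS: ", prot, call. = FALSE)
    return("other")
  }
  if (is.na(cdna) || !grepl("^c\\.", cdna)) {
    warning("unparseable cDNA HGVS: ", cdna, call. = FALSE)
    return("other")
  }
  # intronic / splice-site position offset with no protein change
  if (grepl("^c\\.[-*]?[0-9]+([_+-]|$)", cdna) &&
      grepl("[0-9]+[+-][0-9]+", cdna)) {
    return("splice")
  }
  span <- .cdna_indel_span(cdna)
  if (!is.na(span)) {
    return(if (span %% 3L == 0L) "inframe_indel" else "frameshift")
  }
  warning("cDNA HGVS without resolvable consequence: ", cdna, call. = FALSE)
  "other"
}

# span (in nucleotides) of a coding del/dup without protein annotation;
# NA when the notation is not a plain del/dup
.cdna_indel_span <- function(cdna) {
  m <- regmatches(cdna,
    regexec("^c\\.([0-9]+)(?:_([0-9]+))?(del|dup)[ACGT]*$", cdna))[[1]]
  if (length(m) == 0L) return(NA_integer_)
  from <- as.integer(m[2])
  to <- if (nzchar(m[3])) as.integer(m[3]) else from
  to - from + 1L
}

#' Is a cDNA HGVS string a single-nucleotide substitution?
#'
#' `TRUE` for `X>Y` notation, including intronic/splice-site substitutions
#' with position offsets (`c.291+2T>G`). Indels, duplications and delins are
#' `FALSE`. Non-HGVS input yields `FALSE` with a warning.
#'
#' @param cdna_hgvs Character vector of cDNA HGVS strings.
#' @return Logical vector.
#' @export
is_substitution <- function(cdna_hgvs) {
  cdna <- as.character(cdna_hgvs)
  bad <- is.na(cdna) | !grepl("^c\\.", cdna)
  if (any(bad)) {
    warning("unparseable cDNA HGVS: ",
            paste(unique(cdna[bad]), collapse = ", "), call. = FALSE)
  }
  !bad & grepl("^c\\.[-*]?[0-9]+([+-][0-9]+)?[ACGT]>[ACGT]$", cdna)
}

#' Is a substitution at a CpG dinucleotide?
#'
#' A substitution involves a CpG site when the reference base is C followed
#' by G on the 3' side, or G preceded by C on the 5' side (the reverse-strand
#' case). Sequence context is supplied by the caller; the package performs no
#' reference-genome lookup.
#'
#' @param ref_base,five_prime,three_prime Single reference bases (A/C/G/T),
#'   vectorized.
#' @param alt_base Alternate base; validated but not used by the CpG
#'   definition itself.
#' @return Logical vector.
#' @export
is_cpg_site <- function(ref_base, five_prime, three_prime, alt_base = "N") {
  check <- function(b, what, allow_n = FALSE) {
    b <- toupper(as.character(b))
    ok <- b %in% c("A", "C", "G", "T", if (allow_n) "N")
    if (!all(ok)) {
      stop("invalid ", what, " base(s): ",
           paste(unique(b[!ok]), collapse = ", "))
    }
    b
  }
  ref <- check(ref_base, "reference")
  fp <- check(five_prime, "five-prime")
  tp <- check(three_prime, "three-prime")
  check(alt_base, "alternate", allow_n = TRUE)
  (ref == "C" & tp == "G") | (ref == "G" & fp == "C")
}

#' @export
print.cohort_records <- function(x, ...) {
  cat("<cohort_records> ", nrow(x), " mosaic variant records (",
      sum(x$table == "proband"), " proband, ",
      sum(x$table == "parental"), " parental/grandparental)\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
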
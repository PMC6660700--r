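#' Mosaic calling threshold policy
#'
#' Bundles the AAF cutoffs of the reporting criteria. In a diploid context a
#' variant is a mosaic candidate when AAF < `het_lower` or AAF > `het_upper`
#' (strict inequalities: an AAF of exactly 0.36 is consistent with a
#' heterozygote). In a hemizygous context (non-pseudoautosomal X in a male)
#' an AAF in `[hemi_min, hemi_upper]` is a mosaic candidate; the published
#' criteria state only the 10% floor, and the 0.90 ceiling default is the
#' smallest round value above every reported hemizygous mosaic call (85%).
#' Observations below `min_depth` total reads are not classified.
#'
#' With `mode = "depth_adaptive"`, the fixed heterozygote cutoffs are
#' replaced per site by [derive_het_thresholds()] at level `alpha` using the
#' exact binomial method.
#'
#' @param het_lower,het_upper Diploid AAF cutoffs (defaults 0.36 / 0.64).
#' @param hemi_min,hemi_upper Hemizygous AAF window (defaults 0.10 / 0.90).
#' @param min_depth Minimum total reads to classify (default 20).
#' @param alpha Significance level for confidence intervals and for
#'   depth-adaptive thresholds (default 0.05).
#' @param mode `"fixed"` or `"depth_adaptive"`.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(het_lower = 0.36, het_upper = 0.64,
                             hemi_min = 0.10, hemi_upper = 0.90,
                             min_depth = 20L, alpha = 0.05,
                             mode = c("fixed", "depth_adaptive")) {
  mode <- match.arg(mode)
  stopifnot(
    het_lower > 0, het_lower < 0.5, het_upper > 0.5, het_upper < 1,
    hemi_min < hemi_upper, hemi_min >= 0, hemi_upper <= 1,
    min_depth >= 1, alpha > 0, alpha < 1
  )
  structure(
    list(het_lower = het_lower, het_upper = het_upper,
         hemi_min = hemi_min, hemi_upper = hemi_upper,
         min_depth = as.integer(min_depth), alpha = alpha, mode = mode),
    class = "threshold_policy"
  )
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf(
    "<threshold_policy mode=%s> diploid (%.3g, %.3g), hemizygous [%.3g, %.3g], min depth %d, alpha %.3g\n",
    x$mode, x$het_lower, x$het_upper, x$hemi_min, x$hemi_upper,
    x$min_depth, x$alpha))
  invisible(x)
}

#' Alternate allele fraction with exact binomial confidence interval
#'
#' AAF is the exact ratio of alternate-supporting reads to total reads at a
#' site. The confidence interval is the exact Clopper-Pearson interval at
#' level `1 - alpha`, computed from beta quantiles.
#'
#' @param alt_reads,total_reads Non-negative integer vectors,
#'   `alt_reads <= total_reads`, `total_reads >= 1`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param method Provenance label for the estimate: `"exome"` or
#'   `"amplicon"`.
#' @return A `data.frame` of class `aaf_estimate` with columns `alt_reads`,
#'   `total_reads`, `value`, `ci_low`, `ci_high`, `method`.
#' @examples
#' compute_aaf(18, 100)$value    # 0.18
#' compute_aaf(65, 130)[, c("ci_low", "ci_high")]  # contains 0.5
#' @export
compute_aaf <- function(alt_reads, total_reads, alpha = 0.05,
                        method = c("exome", "amplicon")) {
  method <- match.arg(method)
  x <- as.numeric(alt_reads)
  n <- as.numeric(total_reads)
  if (length(n) == 1L) n <- rep_len(n, length(x))
  if (length(x) != length(n)) stop("alt_reads and total_reads lengths differ")
  if (any(is.na(x)) || any(is.na(n))) stop("read counts must not be NA")
  if (any(n < 1)) stop("total_reads must be >= 1")
  if (any(x < 0)) stop("alt_reads must be >= 0")
  if (any(x > n)) stop("alt_reads must not exceed total_reads")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ci_low <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  ci_high <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  out <- data.frame(
    alt_reads = as.integer(x), total_reads = as.integer(n),
    value = x / n, ci_low = ci_low, ci_high = ci_high,
    method = method, stringsAsFactors = FALSE
  )
  class(out) <- c("aaf_estimate", "data.frame")
  out
}

#' Depth-dependent heterozygote AAF thresholds
#'
#' An ideal diploid heterozygote yields alternate reads distributed
#' Binomial(depth, 0.5); the thresholds returned here bound the interval,
#' symmetric about 0.5, outside which such an observation falls with total
#' probability at most `alpha`.
#'
#' * `method = "normal"`: closed form `0.5 +/- z(1 - alpha/2) * 0.5 /
#'   sqrt(depth)`. At depth 48 and alpha 0.05 this gives (0.359, 0.641) -
#'   essentially the fixed 36%/64% reporting cutoffs.
#' * `method = "exact"`: the widest symmetric pair of binomial tail cutoffs
#'   `( (k+1)/depth, (depth-k-1)/depth )` with
#'   `2 * P(X <= k) <= alpha`, `X ~ Binomial(depth, 0.5)`. Flagging a true
#'   heterozygote (AAF strictly below the lower or strictly above the upper
#'   threshold) then has probability at most `alpha`.
#'
#' @param depth Integer vector of total read depths (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param method `"normal"` or `"exact"`.
#' @return A `data.frame` with columns `depth`, `lower`, `upper`.
#' @examples
#' derive_het_thresholds(48, 0.05, "normal")   # ~ (0.359, 0.641)
#' @export
derive_het_thresholds <- function(depth, alpha = 0.05,
                                  method = c("normal", "exact")) {
  method <- match.arg(method)
  depth <- as.integer(depth)
  if (any(is.na(depth)) || any(depth < 1)) stop("depth must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (method == "normal") {
    half <- qnorm(1 - alpha / 2) * 0.5 / sqrt(depth)
    lower <- pmax(0, 0.5 - half)
  } else {
    lower <- vapply(depth, function(d) {
      k <- qbinom(alpha / 2, d, 0.5)  # first k with P(X <= k) >= alpha/2
      while (k >= 0L && 2 * pbinom(k, d, 0.5) > alpha) k <- k - 1L
      (k + 1) / d
    }, numeric(1))
  }
  data.frame(depth = depth, lower = lower, upper = 1 - lower)
}

.chrom_classes <- c("autosome", "X_nonPAR", "other")
.mosaic_statuses <- c("consistent_het", "candidate_mosaic_low",
                      "candidate_mosaic_high", "candidate_mosaic_hemi",
                      "consistent_hemi", "below_detection",
                      "insufficient_depth", "uncallable")
.candidate_statuses <- c("candidate_mosaic_low", "candidate_mosaic_high",
                         "candidate_mosaic_hemi")

#' Classify a read-count observation against a threshold policy
#'
#' Applies the mosaic reporting criteria to per-sample allele depths.
#' Observations with fewer than `min_depth` total reads get status
#' `insufficient_depth`. In a diploid context (autosome, or X in a female)
#' the status is `candidate_mosaic_low` / `candidate_mosaic_high` /
#' `consistent_het` by strict comparison of the AAF with the heterozygote
#' cutoffs. In a hemizygous context (non-pseudoautosomal X in a male) an AAF
#' below `hemi_min` is `below_detection`, within `[hemi_min, hemi_upper]` a
#' `candidate_mosaic_hemi`, and above `hemi_upper` `consistent_hemi`. A
#' non-pseudoautosomal X observation with unknown sex is `uncallable` rather
#' than guessed.
#'
#' All arguments are vectorized and recycled to the longest length;
#' classification is pure and deterministic.
#'
#' @param alt_reads,total_reads Read counts.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param chrom_class `"autosome"`, `"X_nonPAR"` or `"other"` (treated as
#'   diploid, e.g. pseudoautosomal X).
#' @param policy A [threshold_policy()].
#' @return A `data.frame` of class `mosaic_calls`: read counts, `aaf`,
#'   `ci_low`, `ci_high`, `ploidy_context`, `status`.
#' @examples
#' classify_observation(175, 1000, "female", "autosome")$status
#' @export
classify_observation <- function(alt_reads, total_reads, sex = "unknown",
                                 chrom_class = "autosome",
                                 policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  n <- max(length(alt_reads), length(total_reads), length(sex),
           length(chrom_class))
  est <- compute_aaf(rep_len(alt_reads, n), rep_len(total_reads, n),
                     alpha = policy$alpha)
  sex <- rep_len(as.character(sex), n)
  chrom_class <- rep_len(as.character(chrom_class), n)
  if (!all(chrom_class %in% .chrom_classes)) {
    stop("chrom_class must be one of: ", paste(.chrom_classes, collapse = ", "))
  }
  if (!all(sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male, female or unknown")
  }
  hemi <- chrom_class == "X_nonPAR" & sex == "male"
  unknown_x <- chrom_class == "X_nonPAR" & sex == "unknown"
  ploidy <- ifelse(hemi, "hemizygous", "diploid")
  ploidy[unknown_x] <- NA_character_

  aaf <- est$value
  depth <- est$total_reads
  if (policy$mode == "depth_adaptive") {
    thr <- derive_het_thresholds(depth, policy$alpha, method = "exact")
    lo <- thr$lower
    hi <- thr$upper
  } else {
    lo <- rep_len(policy$het_lower, n)
    hi <- rep_len(policy$het_upper, n)
  }

  status <- character(n)
  dip <- !hemi & !unknown_x
  status[dip] <- ifelse(aaf[dip] < lo[dip], "candidate_mosaic_low",
                 ifelse(aaf[dip] > hi[dip], "candidate_mosaic_high",
                        "consistent_het"))
  status[hemi] <- ifelse(aaf[hemi] < policy$hemi_min, "below_detection",
                  ifelse(aaf[hemi] > policy$hemi_upper, "consistent_hemi",
                         "candidate_mosaic_hemi"))
  status[unknown_x] <- "uncallable"
  status[depth < policy$min_depth] <- "insufficient_depth"

  out <- data.frame(
    alt_reads = est$alt_reads, total_reads = est$total_reads,
    aaf = aaf, ci_low = est$ci_low, ci_high = est$ci_high,
    ploidy_context = ploidy, status = status, stringsAsFactors = FALSE
  )
  class(out) <- c("mosaic_calls", "data.frame")
  out
}

#' Is a call status a mosaic candidate?
#'
#' @param status Character vector of statuses from [classify_observation()].
#' @return Logical vector, `TRUE` for `candidate_mosaic_low/high/hemi`.
#' @export
is_mosaic_candidate <- function(status) {
  status %in% .candidate_statuses
}

#' Rank correlation between paired AAF estimates
#'
#' Spearman rank correlation (mid-ranks for ties) between AAFs measured by
#' two assays on the same variants, e.g. exome NGS versus Sanger peak-height
#' quantification.
#'
#' @param aaf_primary,aaf_orthogonal Equal-length numeric vectors, n >= 3.
#' @return Spearman rho in [-1, 1].
#' @export
aaf_concordance <- function(aaf_primary, aaf_orthogonal) {
  if (length(aaf_primary) != length(aaf_orthogonal)) {
    stop("paired AAF vectors must have equal length")
  }
  if (length(aaf_primary) < 3L) stop("need at least 3 paired AAFs")
  cor(aaf_primary, aaf_orthogonal, method = "spearman")
}

#' Remove common polymorphisms from a variant stream
#'
#' Drops records whose population allele frequency is at or above
#' `threshold`. Records absent from the frequency map are kept and their
#' loci logged.
#'
#' @param records A `data.frame` with a `locus` column (any unique key).
#' @param population_af Named numeric vector mapping locus to population
#'   frequency.
#' @param threshold Frequency cutoff in (0, 1); default 0.01.
#' @return A list with `kept` and `removed` data frames and counts `n_in`,
#'   `n_kept`, `n_removed`.
#' @export
filter_common <- function(records, population_af, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  stopifnot(is.data.frame(records), "locus" %in% names(records))
  af <- population_af[records$locus]
  missing <- is.na(af)
  if (any(missing)) {
    .msg("no population frequency for ",
         paste(records$locus[missing], collapse = ", "), "; kept")
  }
  drop <- !missing & af >= threshold
  list(kept = records[!drop, , drop = FALSE],
       removed = records[drop, , drop = FALSE],
       n_in = nrow(records), n_kept = sum(!drop), n_removed = sum(drop))
}
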
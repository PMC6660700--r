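#' Ras / PI3K-AKT-mTOR pathway gene set
#'
#' The six Ras- and PI3K-AKT-mTOR-pathway disease genes used for the
#' proband pathway-burden statistic.
#'
#' @return Character vector of HGNC symbols.
#' @export
ras_pathway_genes <- function() {
  c("BRAF", "NF1", "HRAS", "KRAS", "PIK3CA", "MTOR")
}

#' Summarize a mosaic variant cohort
#'
#' Computes every cohort-level aggregate from a table of cohort records:
#' record and gene counts, counts by inheritance category, by ACMG
#' classification (overall and per carrier group), by molecular consequence
#' (via [classify_consequence()]), substitution and optional CpG counts,
#' recurrent genes, group AAF means, Ras-pathway burden and
#' diagnosis-attribution rates.
#'
#' AAF group definitions follow the published table labels: `male_X` pools
#' records with a male carrier and inheritance category XL (both carriers and
#' probands); everything else with a reported AAF forms the diploid group,
#' split by carrier. Records lacking an AAF are excluded from all means and
#' their ids logged via `message()`.
#'
#' @param records A `cohort_records` table from [load_cohort_fixture()].
#' @param contexts Optional `data.frame` with columns `record_id`,
#'   `ref_base`, `five_prime`, `three_prime`, `alt_base` supplying sequence
#'   context for substitution records; enables the CpG count.
#' @param cohort_size,diagnostic_yield Passed to [attribution_rates()].
#' @return An object of class `summary_report` (a named list; see
#'   [write_report()] for serialization).
#' @examples
#' rep <- summarize_cohort(load_cohort_fixture())
#' rep$n_total    # 120
#' rep$n_genes    # 107
#' @export
summarize_cohort <- function(records, contexts = NULL,
                             cohort_size = 11992, diagnostic_yield = 0.25) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  counts_of <- function(values, levels) {
    tab <- table(factor(values, levels = levels))
    setNames(as.numeric(tab), levels)
  }
  n_total <- nrow(records)
  proband <- records$table == "proband"
  csq <- classify_consequence(records$cdna_hgvs, records$protein_hgvs)
  subst <- is_substitution(records$cdna_hgvs)

  n_cpg <- NA_real_
  if (!is.null(contexts)) {
    stopifnot(all(c("record_id", "ref_base", "five_prime", "three_prime",
                    "alt_base") %in% names(contexts)))
    idx <- match(records$record_id[subst], contexts$record_id)
    if (anyNA(idx)) {
      .msg("no sequence context for ",
           sum(is.na(idx)), " substitution record(s); excluded from CpG count")
    }
    ctx <- contexts[idx[!is.na(idx)], , drop = FALSE]
    n_cpg <- sum(is_cpg_site(ctx$ref_base, ctx$five_prime, ctx$three_prime,
                             ctx$alt_base))
  }

  no_aaf <- is.na(records$aaf_percent)
  if (any(no_aaf)) {
    .msg("excluded from AAF means (no reported AAF): ",
         paste(records$record_id[no_aaf], collapse = ", "))
  }
  male_x <- records$carrier_sex == "male" &
    records$inheritance_category == "XL"
  grp_stats <- function(sel) {
    v <- records$aaf_percent[sel & !no_aaf]
    if (length(v) == 0L) {
      return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
               max = NA_real_, n = 0))
    }
    c(mean = mean(v), sd = sd(v), min = min(v), max = max(v),
      n = length(v))
  }
  mean_aaf_by_group <- list(
    male_X = grp_stats(male_x),
    male_X_proband = grp_stats(male_x & proband),
    diploid = grp_stats(!male_x),
    diploid_proband = grp_stats(!male_x & proband),
    diploid_parental = grp_stats(!male_x & !proband),
    diploid_maternal = grp_stats(!male_x & records$carrier %in%
                                   c("mother", "grandmother"))
  )

  rec <- recurrent_genes(records)
  burden <- pathway_burden(records, ras_pathway_genes(), group = "proband")
  rates <- attribution_rates(records, cohort_size = cohort_size,
                             diagnostic_yield = diagnostic_yield)

  plp <- c("pathogenic", "likely_pathogenic")
  report <- list(
    n_total = n_total,
    n_proband = sum(proband),
    n_parental = sum(!proband),
    n_genes = length(unique(records$gene)),
    counts_by_inheritance = counts_of(records$inheritance_category,
                                      .enums$inheritance_category),
    counts_by_classification = counts_of(records$classification,
                                         .enums$classification),
    counts_by_classification_proband = counts_of(
      records$classification[proband], .enums$classification),
    n_p_lp = sum(records$classification %in% plp),
    n_p_lp_proband = sum(proband & records$classification %in% plp),
    n_p_lp_parental = sum(!proband & records$classification %in% plp),
    counts_by_consequence = counts_of(
      csq, c("missense", "nonsense", "frameshift", "inframe_indel",
             "splice", "other")),
    n_substitutions = sum(subst),
    n_cpg = n_cpg,
    recurrent_genes = rec$genes,
    n_recurrent_genes = rec$n_genes,
    n_recurrent_variants = rec$n_variants,
    mean_aaf_by_group = mean_aaf_by_group,
    excluded_from_means = records$record_id[no_aaf],
    pathway_burden = c(hits = burden$hits, denominator = burden$denominator,
                       fraction = burden$fraction),
    rates = rates
  )
  class(report) <- "summary_report"
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  cat(sprintf("  %d variants in %d genes (%d proband, %d parental)\n",
              x$n_total, x$n_genes, x$n_proband, x$n_parental))
  cat("  inheritance:",
      paste(names(x$counts_by_inheritance), x$counts_by_inheritance,
            sep = "=", collapse = " "), "\n")
  cat("  classification:",
      paste(names(x$counts_by_classification), x$counts_by_classification,
            sep = "=", collapse = " "), "\n")
  cat("  consequence:",
      paste(names(x$counts_by_consequence), x$counts_by_consequence,
            sep = "=", collapse = " "), "\n")
  g <- x$mean_aaf_by_group
  cat(sprintf("  mean AAF%%: male X %.1f (n=%d), diploid proband %.1f (n=%d), diploid parental %.1f (n=%d)\n",
              g$male_X["mean"], as.integer(g$male_X["n"]),
              g$diploid_proband["mean"], as.integer(g$diploid_proband["n"]),
              g$diploid_parental["mean"],
              as.integer(g$diploid_parental["n"])))
  invisible(x)
}

#' Genes with recurrent mosaic events
#'
#' @param records A cohort record table.
#' @return List with `genes` (named count vector, genes appearing at least
#'   twice, sorted alphabetically), `n_genes`, and `n_variants` (total
#'   variants in those genes).
#' @export
recurrent_genes <- function(records) {
  tab <- table(records$gene)
  tab <- tab[tab >= 2L]
  genes <- setNames(as.numeric(tab), names(tab))
  genes <- genes[order(names(genes))]
  list(genes = genes, n_genes = length(genes),
       n_variants = sum(genes))
}

#' Pathway burden of mosaic variants
#'
#' Fraction of records in a carrier group whose gene belongs to a pathway
#' gene set.
#'
#' @param records Cohort record table.
#' @param gene_set Non-empty character vector of gene symbols; defaults to
#'   [ras_pathway_genes()].
#' @param group `"proband"`, `"parental"` or `"all"`.
#' @return List with `hits`, `denominator`, `fraction`.
#' @export
pathway_burden <- function(records, gene_set = ras_pathway_genes(),
                           group = c("proband", "parental", "all")) {
  group <- match.arg(group)
  if (length(gene_set) == 0L) stop("gene_set must be non-empty")
  sel <- switch(group,
                proband = records$table == "proband",
                parental = records$table == "parental",
                all = rep(TRUE, nrow(records)))
  denom <- sum(sel)
  if (denom == 0L) stop("empty denominator group: ", group)
  hits <- sum(sel & records$gene %in% gene_set)
  list(hits = hits, denominator = denom, fraction = hits / denom)
}

#' Two-sample comparison of AAF groups
#'
#' Two-sided two-sample t test of group means; Welch (unequal variances) by
#' default, Student available.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param method `"welch"` or `"student"`.
#' @return An object of class `group_comparison`: group means, t statistic,
#'   two-sided p value, method.
#' @export
compare_groups <- function(a, b, method = c("welch", "student")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (sd(a) == 0) stop("group_a has zero variance; t test is degenerate")
  if (sd(b) == 0) stop("group_b has zero variance; t test is degenerate")
  tt <- t.test(a, b, var.equal = (method == "student"))
  structure(
    list(group_a_mean = mean(a), group_b_mean = mean(b),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         method = method),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison %s> means %.3f vs %.3f, t = %.3f, p = %.4g\n",
              x$method, x$group_a_mean, x$group_b_mean, x$statistic,
              x$p_value))
  invisible(x)
}

#' Diagnosis-attribution rates for mosaic findings
#'
#' `parental_rate` is the fraction of all families analyzed in which a
#' parental mosaic variant was identified; `diagnosis_fraction` is the
#' fraction of all molecular diagnoses attributable to a mosaic
#' pathogenic/likely-pathogenic variant detected in the proband, assuming a
#' cohort-wide diagnostic yield.
#'
#' @param records Cohort record table (may have zero rows).
#' @param cohort_size Number of families analyzed (default 11,992).
#' @param diagnostic_yield Fraction of patients with a molecular diagnosis
#'   (default 0.25).
#' @return Named numeric vector with `parental_rate` and
#'   `diagnosis_fraction`.
#' @export
attribution_rates <- function(records, cohort_size = 11992,
                              diagnostic_yield = 0.25) {
  if (cohort_size < 1) stop("cohort_size must be >= 1")
  if (diagnostic_yield <= 0 || diagnostic_yield > 1) {
    stop("diagnostic_yield must be in (0, 1]")
  }
  if (nrow(records) == 0L) {
    return(c(parental_rate = 0, diagnosis_fraction = 0))
  }
  plp <- c("pathogenic", "likely_pathogenic")
  n_parental <- sum(records$table == "parental")
  n_proband_plp <- sum(records$table == "proband" &
                         records$classification %in% plp)
  c(parental_rate = n_parental / cohort_size,
    diagnosis_fraction = n_proband_plp / (diagnostic_yield * cohort_size))
}
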
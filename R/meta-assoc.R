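# Cross-cohort meta-analysis: sample-size weighted Z for variants and the
# binomial count test for genes.

#' Sample-size weighted Z meta-analysis for one variant
#'
#' Converts each cohort's two-sided p-value to a signed Z
#' (`z_i = qnorm(1 - p_i/2) * direction_i`), combines them weighted by the
#' square root of the per-cohort sample size, and returns the two-sided meta
#' p-value. Cohorts with unknown direction (0) are excluded; `n_total`
#' reflects the included cohorts only.
#'
#' @param pvalue,direction,n Equal-length vectors, one entry per cohort:
#'   two-sided p-values in (0, 1), direction in \{-1, 0, +1\}, per-variant
#'   sample size.
#' @return One-row tibble: `z`, `pvalue`, `n_total`, `n_cohorts`.
#' @export
stouffer_meta <- function(pvalue, direction, n) {
  stopifnot(length(pvalue) == length(direction), length(pvalue) == length(n))
  keep <- direction != 0L
  if (!any(keep)) abort("unsigned meta undefined: all directions are 0")
  p <- pvalue[keep]; d <- direction[keep]; w <- n[keep]
  if (any(p <= 0) || any(p >= 1)) abort("meta-analysis requires p-values in (0, 1)")
  z_i <- qnorm(1 - p / 2) * d
  z <- sum(sqrt(w) * z_i) / sqrt(sum(w))
  tibble(z = z, pvalue = 2 * pnorm(-abs(z)),
         n_total = sum(w), n_cohorts = length(p))
}

#' Meta-analyze variants across cohorts
#'
#' Applies [stouffer_meta()] per variant id over a stacked multi-cohort
#' summary-statistics table. Cohorts lacking a variant simply do not
#' contribute to it.
#'
#' @param gwas_all Tibble of per-variant rows from several cohorts (a
#'   `bind_rows()` of [read_summary_stats()] outputs) with columns `vid`,
#'   `chrom`, `pos`, `pvalue`, `direction`, `n`.
#' @return Tibble with one row per variant: `vid`, `chrom`, `pos`, `z`,
#'   `pvalue`, `n_total`, `n_cohorts`.
#' @export
meta_variants <- function(gwas_all) {
  gwas_all |>
    filter(.data$direction != 0L) |>
    group_by(.data$vid, .data$chrom, .data$pos) |>
    summarise(stouffer_meta(.data$pvalue, .data$direction, .data$n),
              .groups = "drop")
}

#' Upper-tail binomial probability
#'
#' `P(X >= m)` for `X ~ Binomial(n, p0)`, the meta-analysis p-value for
#' observing at least `m` of `n` cohorts significant when each is
#' independently significant with probability `p0` under the null. Since the
#' U-score is uniform under the null, `p0 = 0.05` is exact for the call
#' `U <= 0.05`.
#'
#' @param m Successes, `0 <= m <= n` (vectorized).
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @return Upper-tail probability; `m = 0` gives 1.
#' @export
binomial_tail <- function(m, n, p0 = 0.05) {
  if (any(p0 <= 0) || any(p0 >= 1)) abort("p0 must lie in (0, 1)")
  if (any(m < 0) || any(m > n)) abort("m must satisfy 0 <= m <= n")
  pbinom(m - 1, n, p0, lower.tail = FALSE)
}

#' Binomial gene-level meta-analysis across cohorts
#'
#' For every gene, counts the cohorts in which its U-score is at or below
#' `alpha` among the cohorts that scored it, and converts the count to an
#' upper-tail binomial p-value (`gene_p`). A gene is flagged significant when
#' `gene_p <= alpha / bonferroni_n` (default threshold 1E-06 = 0.05/50,000).
#'
#' @param u_tables Long tibble of per-cohort gene scores (a `bind_rows()` of
#'   [gene_association_scores()] outputs) with columns `cohort_id`,
#'   `gene_id`, `u_score`.
#' @param alpha Per-cohort significance call on the U-score (default 0.05,
#'   also the binomial null probability).
#' @param bonferroni_n Number of genes assumed for the Bonferroni threshold
#'   (default 50,000).
#' @return Tibble with one row per gene: `gene_id`, `m_sig`, `n_cohorts`,
#'   `gene_p`, `significant`.
#' @export
binomial_gene_meta <- function(u_tables, alpha = 0.05, bonferroni_n = 50000) {
  if (n_distinct(u_tables$cohort_id) < 2) abort("need at least 2 cohorts")
  u_tables |>
    group_by(.data$gene_id) |>
    summarise(
      m_sig = sum(.data$u_score <= alpha),
      n_cohorts = n_distinct(.data$cohort_id),
      .groups = "drop"
    ) |>
    mutate(
      gene_p = binomial_tail(.data$m_sig, .data$n_cohorts, alpha),
      significant = .data$gene_p <= alpha / bonferroni_n
    )
}
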
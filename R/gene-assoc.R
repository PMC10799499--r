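# Gene-level association scoring for one cohort: SNP -> gene mapping,
# greedy LD clumping, Simes combination p-value, and the rank uniform score.

#' Map SNPs to genes by flanked transcription bounds
#'
#' A SNP maps to every gene whose interval
#' `[tx_start - flank, tx_end + flank]` (1-based inclusive) contains its
#' position; SNPs inside overlapping genes appear under each of them. Genes
#' with no mapped SNP are absent from the result and are therefore excluded
#' from gene scoring.
#'
#' @param gwas Per-variant tibble (see [read_summary_stats()]).
#' @param genes Gene-model tibble (see [read_gene_models()]); each model
#'   carries its own `flank`.
#' @return Tibble of (gene, variant) pairs: gene columns `gene_id`, `symbol`
#'   followed by the variant columns of `gwas`.
#' @export
map_snps_to_genes <- function(gwas, genes) {
  windows <- mutate(genes,
                    lo = .data$tx_start - .data$flank,
                    hi = .data$tx_end + .data$flank)
  inner_join(
    select(windows, "gene_id", "symbol", "chrom", "lo", "hi"),
    gwas,
    by = join_by("chrom", between(y$pos, x$lo, x$hi))
  ) |>
    select(-"lo", -"hi")
}

#' Greedy LD clumping of a SNP list
#'
#' Iteratively selects the SNP with the smallest p-value and removes all
#' remaining SNPs correlated with it above `r2_max` (strictly greater; a SNP
#' at exactly `r2_max` is retained), until none remain. Ties on p-value break
#' by ascending (pos, vid) so the output is deterministic and invariant to
#' input order. SNPs absent from the panel (or with undefined r-squared) are
#' treated as independent and a note reports how many.
#'
#' @param snps Tibble of variants on one chromosome with columns `vid`,
#'   `pos`, `pvalue`.
#' @param panel A [reference_panel()].
#' @param r2_max LD pruning threshold (default 0.2).
#' @return The retained (independent) SNP rows, in selection order.
#' @export
clump_snps <- function(snps, panel, r2_max = 0.2) {
  if (nrow(snps) == 0) abort("no SNPs to clump")
  if (n_distinct(snps$chrom %||% "1") > 1) abort("all SNPs must share one chromosome")
  check_pvalues(snps$pvalue)
  ord <- order(snps$pvalue, snps$pos, snps$vid)
  snps <- snps[ord, ]
  r2 <- ld_r2_matrix(panel, snps$vid)
  n_unknown <- sum(!snps$vid %in% panel$variants$vid)
  if (n_unknown > 0) {
    inform(sprintf("%d SNP(s) absent from panel; treated as independent", n_unknown))
  }
  remaining <- seq_len(nrow(snps))
  keep <- integer(0)
  while (length(remaining) > 0) {
    lead <- remaining[1]
    keep <- c(keep, lead)
    rest <- remaining[-1]
    if (length(rest) == 0) break
    r2_lead <- r2[lead, rest]
    drop <- !is.na(r2_lead) & r2_lead > r2_max
    remaining <- rest[!drop]
  }
  snps[keep, ]
}

#' Simes combination p-value
#'
#' `M = min_i k * p_(i) / i` over the sorted p-values of a gene's `k`
#' independent SNPs, capped at 1 so it remains a probability. A valid
#' gene-level p-value under independence of the clumped SNPs.
#'
#' @param pvalues Numeric vector of p-values in (0, 1], nonempty.
#' @return The combination p-value `M` in (0, 1].
#' @export
simes_p <- function(pvalues) {
  check_pvalues(pvalues)
  k <- length(pvalues)
  min(1, min(k * sort(pvalues) / seq_len(k)))
}

#' Gene uniform scores from combination p-values
#'
#' The U-score of a gene is its mid-rank among all scored genes divided by
#' the gene count: `U = (#\{M_j < M\} + 0.5 * #\{M_j = M\}) / L`, where the
#' tie term includes the gene itself. U estimates the proportion of genes
#' with a stronger association; it is strictly inside (0, 1) and averages
#' exactly 0.5 over any input. Genes with `U <= 0.05` are called
#' phenotype-associated.
#'
#' @param m Numeric vector of per-gene combination p-values (optionally
#'   named by gene).
#' @return Numeric vector of U-scores, same length and names as `m`.
#' @export
u_scores <- function(m) {
  if (length(m) < 1) abort("need at least one gene")
  (rank(m, ties.method = "average") - 0.5) / length(m)
}

#' Score one cohort's GWAS at the gene level
#'
#' Runs the full per-cohort gene pipeline: map SNPs to flanked gene bounds,
#' clump each gene's SNPs in the reference panel, combine the independent
#' p-values with Simes' method, and convert the combination p-values to
#' uniform scores over the `L` scored genes (genes with zero mapped SNPs are
#' excluded from `L`).
#'
#' @param gwas Per-variant tibble for one cohort.
#' @param genes Gene-model tibble.
#' @param panel A [reference_panel()].
#' @param r2_clump Clumping threshold (default 0.2).
#' @return Tibble with one row per scored gene: `cohort_id`, `phenotype`,
#'   `gene_id`, `k` (independent SNPs), `simes_m`, `u_score`, `L`.
#' @export
gene_association_scores <- function(gwas, genes, panel, r2_clump = 0.2) {
  mapped <- map_snps_to_genes(gwas, genes)
  if (nrow(mapped) == 0) abort("no SNP maps to any gene")
  per_gene <- mapped |>
    group_by(.data$gene_id) |>
    dplyr::group_map(function(df, key) {
      ind <- suppressMessages(clump_snps(df, panel, r2_max = r2_clump))
      tibble(gene_id = key$gene_id, k = nrow(ind), simes_m = simes_p(ind$pvalue))
    }) |>
    list_rbind()
  per_gene$u_score <- u_scores(per_gene$simes_m)
  tibble(
    cohort_id = gwas$cohort_id[1] %||% NA_character_,
    phenotype = gwas$phenotype[1] %||% NA_character_,
    per_gene,
    L = nrow(per_gene)
  )
}
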
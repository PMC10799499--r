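# Uniform-score gene-set analysis (USGSA) and its two cross-cohort
# meta-analysis approaches:
#   Approach 1 - meta-analyze per-cohort enrichment effects (random-effects
#     model) and per-cohort significance counts (binomial test);
#   Approach 2 - enrichment of the cross-cohort meta-significant genes.

# Shared enrichment engine. For each set Omega: n_omega = |Omega ∩ universe|,
# x = |Omega ∩ Phi|, p_hat = x / n_omega, effect E = p_hat - p0,
# SE = sqrt(p0 (1 - p0) / n_omega), exact upper-tail hypergeometric p.
enrich_sets <- function(universe, phi, gene_sets, p0) {
  L <- length(universe)
  n_phi <- length(phi)
  in_universe <- filter(gene_sets, .data$gene %in% universe)
  dropped <- setdiff(unique(gene_sets$set_name), unique(in_universe$set_name))
  if (length(dropped)) {
    warn(sprintf("%d gene set(s) with no gene in the universe omitted", length(dropped)))
  }
  out <- in_universe |>
    group_by(.data$set_name) |>
    summarise(
      n_omega = n_distinct(.data$gene),
      x_overlap = sum(unique(.data$gene) %in% phi),
      .groups = "drop"
    ) |>
    mutate(
      p_hat = .data$x_overlap / .data$n_omega,
      p0 = p0,
      effect = .data$p_hat - p0,
      se = sqrt(p0 * (1 - p0) / .data$n_omega),
      p_exact = phyper(.data$x_overlap - 1, n_phi, L - n_phi, .data$n_omega,
                       lower.tail = FALSE)
    )
  attr(out, "L") <- L
  attr(out, "n_phi") <- n_phi
  class(out) <- c("vdm_enrichment", class(out))
  out
}

#' Uniform-score gene-set analysis (USGSA) for one cohort
#'
#' Tests whether a gene set is enriched for the cohort's associated genes
#' Phi = \{genes with U-score <= alpha\}. For a set Omega the enrichment
#' effect is `E = p_hat - p0` where `p_hat` is the fraction of Omega's
#' in-universe genes that fall in Phi and `p0` (default `alpha`) is the null
#' probability of a random gene falling in Phi; the standard error is the
#' binomial `sqrt(p0 (1 - p0) / |Omega|)` and the exact p-value comes from
#' the upper tail of the hypergeometric distribution. Sets with no gene in
#' the scored universe are omitted with a warning.
#'
#' @param u_table Per-gene scores with columns `gene_id`, `u_score`.
#' @param gene_sets Long tibble with columns `set_name`, `gene`.
#' @param alpha U-score cut defining Phi (default 0.05).
#' @param p0 Null membership probability (default `alpha`).
#' @return Tibble of class `vdm_enrichment`, one row per retained set:
#'   `set_name`, `n_omega`, `x_overlap`, `p_hat`, `p0`, `effect`, `se`,
#'   `p_exact`; attributes `L` and `n_phi`.
#' @export
usgsa <- function(u_table, gene_sets, alpha = 0.05, p0 = alpha) {
  universe <- unique(u_table$gene_id)
  phi <- unique(u_table$gene_id[u_table$u_score <= alpha])
  enrich_sets(universe, phi, gene_sets, p0)
}

# Min-p permutation adjustment of exact enrichment p-values over a
# collection. Pseudo-Phi sets of the observed size are drawn uniformly from
# the universe (equivalent to permuting significance labels over genes),
# which preserves the between-set gene overlaps exactly.
perm_adjust_enrichment <- function(observed, universe, gene_sets, n_perm, seed,
                                   chunk = 500L) {
  L <- attr(observed, "L")
  n_phi <- attr(observed, "n_phi")
  sets <- observed$set_name
  in_universe <- filter(gene_sets, .data$set_name %in% sets,
                        .data$gene %in% universe) |>
    distinct(.data$set_name, .data$gene)
  M <- matrix(0, nrow = length(sets), ncol = L,
              dimnames = list(sets, universe))
  M[cbind(match(in_universe$set_name, sets),
          match(in_universe$gene, universe))] <- 1
  n_omega <- observed$n_omega
  min_p <- numeric(n_perm)
  with_local_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      ind <- matrix(0, nrow = L, ncol = b)
      for (j in seq_len(b)) ind[sample.int(L, n_phi), j] <- 1
      counts <- M %*% ind
      pmat <- phyper(counts - 1, n_phi, L - n_phi,
                     matrix(n_omega, nrow = length(n_omega), ncol = b),
                     lower.tail = FALSE)
      min_p[done + seq_len(b)] <- apply(pmat, 2, min)
      done <- done + b
    }
  })
  map_dbl(observed$p_exact, function(p) (1 + sum(min_p <= p)) / (n_perm + 1))
}

#' USGSA with permutation multiplicity adjustment
#'
#' Runs [usgsa()] over a collection and adjusts each set's exact p-value for
#' multiple testing and for correlations induced by genes belonging to
#' multiple sets: every permutation draws a uniformly random pseudo-Phi of
#' the observed size from the universe, recomputes each set's exact p, and
#' records the collection-wide minimum; the adjusted p-value is
#' `(1 + #\{min-p <= p_exact\}) / (n_perm + 1)`.
#'
#' @inheritParams usgsa
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return The [usgsa()] tibble with an extra `p_adj` column.
#' @export
usgsa_perm_adjust <- function(u_table, gene_sets, alpha = 0.05, p0 = alpha,
                              n_perm = 10000, seed = NULL) {
  observed <- usgsa(u_table, gene_sets, alpha = alpha, p0 = p0)
  universe <- unique(u_table$gene_id)
  observed$p_adj <- perm_adjust_enrichment(observed, universe, gene_sets,
                                           n_perm, seed)
  observed
}

#' Random-effects meta-analysis of enrichment effects
#'
#' DerSimonian-Laird random-effects pooling of per-cohort enrichment effects
#' weighted by inverse variance (via `metafor::rma(method = "DL")`):
#' method-of-moments between-cohort variance `tau2` (truncated at 0),
#' weights `1 / (SE_i^2 + tau2)`, and a two-sided normal test of the pooled
#' effect. With a single cohort the effect passes through unchanged with a
#' warning.
#'
#' @param effects Per-cohort enrichment effects `E`.
#' @param ses Per-cohort standard errors (finite, positive).
#' @return One-row tibble: `re_effect`, `re_se`, `tau2`, `re_p`,
#'   `n_cohorts`.
#' @export
re_meta <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  if (!all(is.finite(ses)) || any(ses <= 0)) abort("SEs must be finite and > 0")
  if (length(effects) < 2) {
    warn("single cohort: fixed-effect passthrough")
    return(tibble(re_effect = effects, re_se = ses, tau2 = 0,
                  re_p = 2 * pnorm(-abs(effects / ses)), n_cohorts = 1L))
  }
  fit <- metafor::rma(yi = effects, sei = ses, method = "DL")
  tibble(re_effect = as.numeric(fit$beta), re_se = fit$se, tau2 = fit$tau2,
         re_p = fit$pval, n_cohorts = length(effects))
}

#' Approach 1, per set: random-effects meta over cohorts
#'
#' Applies [re_meta()] to every gene set of a stacked per-cohort enrichment
#' table.
#'
#' @param enrichments Long tibble with columns `set_name`, `cohort_id`,
#'   `effect`, `se` (per-cohort [usgsa()] rows).
#' @return Tibble with one row per set: `set_name` plus the [re_meta()]
#'   columns.
#' @export
pathway_re_meta <- function(enrichments) {
  enrichments |>
    group_by(.data$set_name) |>
    summarise(re_meta(.data$effect, .data$se), .groups = "drop")
}

#' Approach 1, per set: binomial meta of per-cohort significance
#'
#' Counts the cohorts in which the pathway p-value is significant and
#' converts the count to an upper-tail binomial probability. Discovery and
#' joint analyses use the permutation-adjusted per-cohort p-values at
#' `alpha`; for replication alone pass the exact per-cohort p-values and
#' `n_tests` to apply a Bonferroni threshold `alpha / n_tests`.
#'
#' @param path_p Per-cohort pathway p-values for one set.
#' @param alpha Per-cohort significance level (default 0.05).
#' @param p0 Null per-cohort significance probability (default 0.05).
#' @param n_tests Optional Bonferroni divisor for the per-cohort calls.
#' @return One-row tibble: `n_sig_cohorts`, `n_cohorts`, `bin_p`.
#' @export
binomial_pathway_meta <- function(path_p, alpha = 0.05, p0 = 0.05,
                                  n_tests = NULL) {
  thr <- if (is.null(n_tests)) alpha else alpha / n_tests
  m <- sum(path_p <= thr)
  tibble(n_sig_cohorts = m, n_cohorts = length(path_p),
         bin_p = binomial_tail(m, length(path_p), p0))
}

#' Approach 2: enrichment of cross-cohort meta-significant genes
#'
#' Tests gene sets for over-representation of the genes found significant by
#' the cross-cohort binomial gene meta-analysis (`Gene_p <= 1E-06`). The
#' machinery is [usgsa()]'s, but Phi is the meta-significant gene list and
#' the null probability is `p0 = |Phi| / L` - the chance that a random
#' universe gene is meta-significant - rather than the per-cohort 0.05.
#' Multiplicity adjustment draws pseudo-Phi sets of size `|Phi|`.
#'
#' @param sig_genes Character vector of meta-significant gene ids (nonempty).
#' @param gene_sets Long tibble with columns `set_name`, `gene`.
#' @param universe Character vector of all scored gene ids (genes scored in
#'   at least one contributing cohort).
#' @param n_perm Permutations for the adjustment (default 10,000).
#' @param seed Integer seed.
#' @return A `vdm_enrichment` tibble with `p_adj`, as in
#'   [usgsa_perm_adjust()].
#' @export
candidate_enrichment <- function(sig_genes, gene_sets, universe,
                                 n_perm = 10000, seed = NULL) {
  phi <- intersect(unique(sig_genes), unique(universe))
  if (length(phi) == 0) abort("no significant genes")
  universe <- unique(universe)
  p0 <- length(phi) / length(universe)
  observed <- enrich_sets(universe, phi, gene_sets, p0)
  observed$p_adj <- perm_adjust_enrichment(observed, universe, gene_sets,
                                           n_perm, seed)
  observed
}

#' Infer integer overlaps and a common universe size from reported effects
#'
#' Consistency solver for reported candidate-gene enrichment results: given
#' per-set effects `E = x / n_omega - |Phi| / L` with known set sizes
#' `n_omega` and significant-gene counts `|Phi|` but unknown integer
#' overlaps `x` and universe size `L`, scans `L` over a range and returns
#' the `L` whose implied overlaps are closest to integers across all rows,
#' together with those overlaps and the implied binomial standard errors.
#'
#' @param effects Tibble with columns `set_name`, `size` (n_omega), `effect`
#'   (proportion scale), `phi_size` (|Phi| for that row's phenotype).
#' @param L_range Integer candidates for the universe size.
#' @return List with elements `L`, `max_residual` (worst distance of an
#'   implied overlap from its integer), and `overlaps` - the input tibble
#'   plus `overlap` (rounded integer), `residual` and `implied_se`.
#' @export
infer_enrichment_overlaps <- function(effects, L_range = 32000:34000) {
  need <- c("set_name", "size", "effect", "phi_size")
  if (!all(need %in% names(effects))) {
    abort(sprintf("effects needs columns: %s", paste(need, collapse = ", ")))
  }
  score <- vapply(L_range, function(L) {
    x <- effects$size * (effects$effect + effects$phi_size / L)
    max(abs(x - round(x)))
  }, numeric(1))
  L <- L_range[which.min(score)]
  x <- effects$size * (effects$effect + effects$phi_size / L)
  p0 <- effects$phi_size / L
  overlaps <- mutate(effects,
                     overlap = as.integer(round(x)),
                     residual = x - round(x),
                     implied_se = sqrt(p0 * (1 - p0) / .data$size))
  list(L = L, max_residual = min(score), overlaps = overlaps)
}
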
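# Differential expression of pathway component genes across ordered
# cognitive-status groups: quantile normalization, moderated linear
# contrasts (limma), trend contrasts, and the mean-rank permutation
# gene-set test.

#' Quantile-normalize an expression matrix
#'
#' Replaces each sample's sorted values by the cross-sample rank means so
#' that every sample shares one empirical distribution (ties receive the
#' mean of their target quantiles). Idempotent: a second application changes
#' nothing.
#'
#' @param mat Numeric gene x sample matrix with at least 2 samples.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) abort("need at least 2 samples")
  if (!all(is.finite(mat))) abort("expression values must be finite")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Linear trend contrast over ordered groups
#'
#' Centered, unit-spaced coefficients over the ordered groups; with
#' `include_reference = FALSE` the first (reference) group is dropped from
#' the trend - its coefficient is 0 - and the remaining coefficients are
#' recentered. Coefficients always sum to zero.
#'
#' @param n_groups Number of ordered groups (>= 2; >= 3 when the reference
#'   is excluded).
#' @param include_reference Include the first group in the trend (TRUE gives
#'   the full trend; FALSE the trend over the non-reference groups).
#' @return Numeric contrast vector of length `n_groups`.
#' @export
trend_contrast <- function(n_groups, include_reference = TRUE) {
  if (n_groups < 2) abort("need at least 2 groups")
  if (include_reference) {
    seq_len(n_groups) - (n_groups + 1) / 2
  } else {
    if (n_groups < 3) abort("excluding the reference needs at least 3 groups")
    c(0, seq_len(n_groups - 1) - n_groups / 2)
  }
}

#' Moderated per-gene contrast test
#'
#' Fits a group-means linear model per gene, forms the requested contrast,
#' and moderates the residual variances by empirical-Bayes shrinkage toward
#' a common prior (limma's `lmFit`/`contrasts.fit`/`eBayes`), yielding a
#' moderated F statistic (the squared moderated t for a single contrast)
#' and p-value with augmented degrees of freedom.
#'
#' @param mat Numeric gene x sample matrix (typically quantile-normalized).
#' @param groups Group label per sample (character or factor).
#' @param contrast Contrast coefficients over the group levels; must sum
#'   to 0.
#' @param group_levels Declared group order; defaults to first appearance.
#' @param contrast_name Label stored on the result.
#' @param study_id Study label stored on the result.
#' @return Tibble with one row per gene: `gene_id`, `f_stat`, `p_value`,
#'   `study_id`, `contrast`.
#' @export
moderated_fit <- function(mat, groups, contrast, group_levels = NULL,
                          contrast_name = "contrast", study_id = "study") {
  group_levels <- group_levels %||% unique(as.character(groups))
  g <- factor(as.character(groups), levels = group_levels)
  if (anyNA(g)) abort("groups contain labels not in group_levels")
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    abort("need >= 2 groups each with >= 1 sample")
  }
  if (length(contrast) != nlevels(g)) {
    abort("contrast length must equal the number of groups")
  }
  if (abs(sum(contrast)) > 1e-8) abort("contrast coefficients must sum to 0")
  if (ncol(mat) <= nlevels(g)) abort("zero residual degrees of freedom")
  design <- model.matrix(~ 0 + g)
  colnames(design) <- levels(g)
  fit <- limma::lmFit(mat, design)
  cf <- limma::contrasts.fit(fit, contrasts = matrix(contrast, ncol = 1))
  eb <- limma::eBayes(cf)
  tibble(
    gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    f_stat = as.numeric(eb$t[, 1])^2,
    p_value = as.numeric(eb$p.value[, 1]),
    study_id = study_id,
    contrast = contrast_name
  )
}

#' Mean-rank permutation gene-set test
#'
#' Competitive set-level test: ranks all scored genes by their statistic
#' (rank 1 = largest, i.e. most differentially expressed), takes the mean
#' rank of the set's genes, and compares it against `n_perm` random
#' same-size gene subsets. One-sided toward enrichment: the p-value is
#' `(1 + #\{draws with mean rank <= observed\}) / (n_perm + 1)`, so its
#' attainable minimum is `1/(n_perm + 1)`.
#'
#' @param gene_stats Tibble with columns `gene_id`, `f_stat` (one row per
#'   scored gene).
#' @param set_genes Character vector of set gene ids; at least one must be
#'   scored (an error lists the missing ones otherwise).
#' @param n_perm Number of random subsets (default 10,000).
#' @param seed Integer seed; fixed seed gives bit-identical p-values.
#' @return One-row tibble of class `set_de_result`: `n_genes` (set genes
#'   scored), `n_universe`, `mean_rank`, `p_perm`, `n_perm`.
#' @export
mean_rank_set_test <- function(gene_stats, set_genes, n_perm = 10000,
                               seed = NULL) {
  set_genes <- unique(set_genes)
  present <- set_genes %in% gene_stats$gene_id
  if (!any(present)) {
    abort(sprintf("no set gene has a measured statistic; missing: %s",
                  paste(set_genes, collapse = ", ")))
  }
  r <- rank(-gene_stats$f_stat, ties.method = "average")
  idx <- match(set_genes[present], gene_stats$gene_id)
  obs <- mean(r[idx])
  m <- length(idx)
  perm_means <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) mean(r[sample.int(length(r), m)]),
           numeric(1))
  })
  out <- tibble(
    n_genes = m, n_universe = length(r), mean_rank = obs,
    p_perm = (1 + sum(perm_means <= obs)) / (n_perm + 1),
    n_perm = n_perm
  )
  class(out) <- c("set_de_result", class(out))
  out
}

#' Map gene symbols through a homolog table
#'
#' One-to-one mapping of (human) symbols to model-organism homologs via a
#' user-supplied table; unmapped symbols are reported, and when two input
#' symbols collapse onto the same homolog only the first is kept, with a
#' warning.
#'
#' @param symbols Character vector of symbols to map.
#' @param homolog_table Tibble with columns `symbol`, `homolog`.
#' @return Tibble with columns `symbol`, `homolog` for the mapped symbols;
#'   attribute `unmapped` holds the rest.
#' @export
map_homologs <- function(symbols, homolog_table) {
  if (!all(c("symbol", "homolog") %in% names(homolog_table))) {
    abort("homolog table needs columns symbol, homolog")
  }
  tbl <- distinct(homolog_table, .data$symbol, .keep_all = TRUE)
  hit <- match(symbols, tbl$symbol)
  mapped <- tibble(symbol = symbols[!is.na(hit)],
                   homolog = tbl$homolog[hit[!is.na(hit)]])
  dup <- duplicated(mapped$homolog)
  if (any(dup)) {
    warn(sprintf("%d symbol(s) collapsed onto an already-used homolog; dropped",
                 sum(dup)))
    mapped <- mapped[!dup, ]
  }
  attr(mapped, "unmapped") <- symbols[is.na(hit)]
  mapped
}

#' Set-level differential expression across cognitive statuses
#'
#' Full set-level pipeline for one study: quantile normalization, moderated
#' trend-contrast fit over the ordered groups, then the mean-rank
#' permutation test of the pathway component genes.
#'
#' @param ds An [expression_dataset()].
#' @param set_genes Character vector of component gene ids (already
#'   homolog-mapped for model organisms).
#' @param include_reference Include the first (reference) group in the trend
#'   (the two standard contrasts: with and without the control group).
#' @param n_perm Permutations for the set test (default 10,000).
#' @param seed Integer seed.
#' @return The [mean_rank_set_test()] row, with `study_id` and `contrast`
#'   columns added.
#' @export
set_de_test <- function(ds, set_genes, include_reference = TRUE,
                        n_perm = 10000, seed = NULL) {
  mat <- quantile_normalize(ds$values)
  contrast <- trend_contrast(length(ds$group_levels), include_reference)
  cname <- if (include_reference) "trend-with-reference" else "trend-without-reference"
  stats <- moderated_fit(mat, ds$samples$group, contrast,
                         group_levels = ds$group_levels,
                         contrast_name = cname, study_id = ds$study_id)
  res <- mean_rank_set_test(stats, set_genes, n_perm = n_perm, seed = seed)
  mutate(res, study_id = ds$study_id, contrast = cname)
}
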
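# Multi-omics function analysis: does association strength predict
# functional annotation? Variant level: LD with eQTL/meQTL records.
# Gene level: high expression, regulon membership, immune annotation.

#' Annotate independent SNPs with LD-to-annotation status
#'
#' For each independent SNP, status is 1 iff some annotation record (eQTL or
#' meQTL) on the same chromosome lies within `window_bp` and has
#' `r^2 >= r2_min` with the SNP in the reference panel; a SNP that is itself
#' an annotation record (matched by variant id or by chromosome+position)
#' gets status 1. Undefined r-squared (variant missing from the panel or
#' monomorphic) counts as not-in-LD.
#'
#' @param snps Tibble of genome-wide independent SNPs with columns `vid`,
#'   `chrom`, `pos`, `pvalue` (meta-analysis p).
#' @param annotation Annotation tibble (see [read_annotation_table()]).
#' @param panel A [reference_panel()].
#' @param r2_min High-LD threshold (default 0.8; the boundary value counts
#'   as in LD).
#' @param window_bp Search window around the SNP (default 1 Mb).
#' @return Tibble with columns `vid`, `chrom`, `pos`, `neglog10_p`, `status`,
#'   `tissue`.
#' @export
annotate_ld_status <- function(snps, annotation, panel, r2_min = 0.8,
                               window_bp = 1e6) {
  tissue <- if (nrow(annotation) > 0) annotation$tissue[1] else NA_character_
  out <- tibble(
    vid = snps$vid, chrom = snps$chrom, pos = snps$pos,
    neglog10_p = -log10(snps$pvalue),
    status = 0L, tissue = tissue
  )
  if (nrow(annotation) == 0) {
    warn("annotation table is empty; all LD statuses are 0")
    return(out)
  }
  ann <- distinct(annotation, .data$chrom, .data$pos, .data$vid)
  pairs <- inner_join(
    select(out, "vid", "chrom", snp_pos = "pos"),
    select(ann, "chrom", ann_pos = "pos", ann_vid = "vid"),
    by = join_by("chrom"), relationship = "many-to-many"
  ) |>
    filter(abs(.data$snp_pos - .data$ann_pos) <= window_bp)
  if (nrow(pairs) == 0) return(out)
  self_hit <- pairs |>
    filter(.data$vid == .data$ann_vid | .data$snp_pos == .data$ann_pos) |>
    pull("vid") |>
    unique()
  todo <- filter(pairs, !.data$vid %in% self_hit)
  ld_hit <- character(0)
  if (nrow(todo) > 0) {
    for (snp in unique(todo$vid)) {
      cand <- unique(todo$ann_vid[todo$vid == snp])
      r2 <- ld_r2_matrix(panel, c(snp, cand))[1, -1]
      if (any(!is.na(r2) & r2 >= r2_min)) ld_hit <- c(ld_hit, snp)
    }
  }
  out$status <- as.integer(out$vid %in% c(self_hit, ld_hit))
  out
}

#' Top-5% expression status
#'
#' Flags the genes whose expression value is at or above the empirical 95th
#' percentile for a tissue; ties spanning the cut are all included (so the
#' realized fraction can exceed the nominal one, which is reported). Being
#' rank-based, the flagged set is invariant under monotone transformations
#' of the values.
#'
#' @param expr Tibble with columns `gene_id`, `value` (e.g. RPKM), at least
#'   20 genes.
#' @param prop Top fraction to flag (default 0.05).
#' @return Tibble with columns `gene_id`, `status` (0/1).
#' @export
top_expression_status <- function(expr, prop = 0.05) {
  if (nrow(expr) < 20) abort("need at least 20 genes")
  v <- expr$value
  if (!all(is.finite(v))) abort("expression values must be finite")
  if (diff(range(v)) == 0) abort("no expression gradient: all values equal")
  cut <- quantile(v, 1 - prop, names = FALSE)
  status <- as.integer(v >= cut)
  inform(sprintf("flagged %d/%d genes (%.1f%%) as highly expressed",
                 sum(status), length(v), 100 * mean(status)))
  tibble(gene_id = expr$gene_id, status = status)
}

#' Filter regulons by minimum target count in the scored universe
#'
#' Keeps regulators (TFs or microRNAs) whose regulon contains at least
#' `min_targets` genes of the scored-gene universe; targets outside the
#' universe do not count.
#'
#' @param regulons Long tibble with columns `regulator`, `target`.
#' @param universe Character vector of scored gene ids.
#' @param min_targets Minimum in-universe regulon size (default 10).
#' @return The filtered long tibble (possibly empty).
#' @export
filter_regulons <- function(regulons, universe, min_targets = 10) {
  regulons |>
    filter(.data$target %in% universe) |>
    group_by(.data$regulator) |>
    filter(n() >= min_targets) |>
    ungroup()
}

#' Logistic regression of binary gene status on association strength
#'
#' Fits, for every unit in a family (each tissue's high-expression call,
#' each regulator's regulon membership, or the single immune annotation), a
#' logistic regression of the gene status on `-log10(U)` and calibrates the
#' family with [permutation_family_adjust()]. An adjusted p-value at or
#' below 0.05 is considered significant.
#'
#' @param u_table Per-gene scores with columns `gene_id`, `u_score` (one
#'   cohort's table or a meta summary).
#' @param status Tibble with columns `unit`, `gene_id`, `status` (0/1); one
#'   block of rows per family member covering the same genes.
#' @param scope Label describing the family, e.g. `"gene-expression"`,
#'   `"gene-TF"`, `"gene-immune"`.
#' @param n_perm Permutations for the family adjustment (default 1,000 at
#'   the gene level).
#' @param seed Integer seed.
#' @return Tibble with one row per unit: `scope`, `unit`, `beta`,
#'   `or_per_unit`, `ci_lo`, `ci_hi`, `wald_p`, `p_perm`, `n_perm`; class
#'   `vdm_fun_regression` for [autoplot()].
#' @export
gene_function_regression <- function(u_table, status, scope = "gene-function",
                                     n_perm = 1000, seed = NULL) {
  x_tbl <- tibble(gene_id = u_table$gene_id,
                  x = -log10(u_table$u_score))
  units <- unique(status$unit)
  ys <- list(); xs <- list(); fits <- list()
  for (u in units) {
    joined <- inner_join(x_tbl, filter(status, .data$unit == u),
                         by = "gene_id")
    if (nrow(joined) == 0) abort(sprintf("no genes in common for unit '%s'", u))
    ys[[u]] <- joined$status
    xs[[u]] <- joined$x
    fits[[u]] <- fit_binary_logistic(joined$status, joined$x)
  }
  adj <- permutation_family_adjust(ys, xs, n_perm = n_perm, seed = seed)
  out <- tibble(
    scope = scope,
    unit = units,
    beta = map_dbl(fits, "beta"),
    or_per_unit = map_dbl(fits, "or"),
    ci_lo = map_dbl(fits, function(f) f$ci95[1]),
    ci_hi = map_dbl(fits, function(f) f$ci95[2]),
    wald_p = adj$wald_p,
    p_perm = adj$p_perm,
    n_perm = n_perm
  )
  class(out) <- c("vdm_fun_regression", class(out))
  out
}

#' Logistic regression of variant LD status on association strength
#'
#' The variant-level analogue of [gene_function_regression()]: regresses the
#' high-LD status of genome-wide independent SNPs on `-log10` of their
#' meta-analysis p-values, per tissue plus an `"all"` unit in which a SNP
#' counts as in LD if any tissue annotates it. The family (all tissues plus
#' `"all"`) is permutation-calibrated jointly.
#'
#' @param ld_tbl Stacked [annotate_ld_status()] outputs with columns
#'   `tissue`, `vid`, `neglog10_p`, `status`.
#' @param n_perm Permutations (default 10,000 at the variant level).
#' @param seed Integer seed.
#' @param include_all Add the combined `"all"` unit (default TRUE).
#' @return Same shape as [gene_function_regression()], with
#'   `scope = "variant-LD"`.
#' @export
ld_function_regression <- function(ld_tbl, n_perm = 10000, seed = NULL,
                                   include_all = TRUE) {
  status <- select(ld_tbl, unit = "tissue", gene_id = "vid", "status")
  x_per_snp <- distinct(ld_tbl, .data$vid, .data$neglog10_p)
  if (include_all && n_distinct(ld_tbl$tissue) > 1) {
    all_status <- ld_tbl |>
      group_by(.data$vid) |>
      summarise(status = as.integer(any(.data$status == 1L)), .groups = "drop") |>
      mutate(unit = "all") |>
      select("unit", gene_id = "vid", "status")
    status <- bind_rows(status, all_status)
  }
  u_table <- tibble(gene_id = x_per_snp$vid,
                    u_score = 10^(-x_per_snp$neglog10_p))
  out <- gene_function_regression(u_table, status, scope = "variant-LD",
                                  n_perm = n_perm, seed = seed)
  out
}
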
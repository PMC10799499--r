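# Shared in-code fixtures: tiny deterministic panels and GWAS tables.

# A reference panel built directly from a dosage matrix; variants named by
# the matrix columns, all on one chromosome at 10 kb spacing unless given.
make_panel <- function(dosage, chrom = "1", pos = NULL) {
  vids <- colnames(dosage)
  pos <- pos %||% (10000L + (seq_along(vids) - 1L) * 10000L)
  reference_panel(dosage, tibble::tibble(
    chrom = rep_len(chrom, length(vids)), pos = as.integer(pos), vid = vids,
    ref = "A", alt = "G"
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A minimal per-variant summary-statistics tibble.
make_gwas <- function(vid, pos, pvalue, chrom = "1", direction = 1L,
                      n = 1000, cohort_id = "c1", phenotype = "PAR-dr",
                      role = "discovery") {
  tibble::tibble(
    cohort_id = cohort_id, phenotype = phenotype, role = role,
    chrom = rep_len(chrom, length(vid)), pos = as.integer(pos), vid = vid,
    effect_allele = "G", other_allele = "A",
    pvalue = pvalue, direction = rep_len(as.integer(direction), length(vid)),
    n = rep_len(n, length(vid))
  )
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability that a uniformly random size-k subset of L genes, n_phi of
# which are "significant", contains at least x significant genes.
enum_hyper_tail <- function(x, n_phi, L, k) {
  sig <- seq_len(n_phi)
  subsets <- utils::combn(L, k)
  mean(apply(subsets, 2, function(s) sum(s %in% sig) >= x))
}

# Exhaustive-enumeration oracle for the binomial upper tail over all 2^n
# outcome vectors.
enum_binom_tail <- function(m, n, p0) {
  grid <- expand.grid(rep(list(c(0, 1)), n))
  probs <- apply(grid, 1, function(g) prod(ifelse(g == 1, p0, 1 - p0)))
  sum(probs[rowSums(grid) >= m])
}

# Small simulated study used by several tests: strong desk-scale signal
# (per-SNP h2 ~1% at n=2000) over a reduced gene map.
small_config <- function(seed = 11, ...) {
  sim_config(
    seed = seed, n_individuals = 2000, n_panel = 300, n_genes = 120,
    genes_per_chromosome = 60, snps_per_gene = 5, n_causal_genes = 6,
    pathway_size = 12, n_gene_sets = 40, set_size_range = c(8, 25),
    n_tissues = 3, n_regulators = 6, ...
  )
}
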
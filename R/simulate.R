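# Synthetic multi-cohort study generator. Emulates the statistical structure
# the pipeline assumes - block LD, planted causal genes and pathway, planted
# annotation enrichment among associated genes, group-shifted expression -
# so every stage runs end-to-end without consortium data.

#' Simulation configuration
#'
#' Bundles the generator's knobs with desk-scale defaults: 8 discovery and 8
#' replication cohorts for the paragraph-recall trait (15 discovery for the
#' word-list trait), 2,000 individuals per cohort, 1,000 genes tiling LD
#' blocks of 10 SNPs with within-block haplotype correlation 0.8, 20 planted
#' causal genes each carrying one causal SNP explaining about 1% of trait
#' variance, a planted pathway of 40 genes, annotation enrichment log-odds
#' 0.6, and expression depressed by one standard deviation per planted gene.
#'
#' @param seed Master seed; every generator op derives its own stream from
#'   it.
#' @param n_cohorts_discovery,n_cohorts_replication Cohort counts (8/8 for
#'   paragraph recall; use 15 discovery for word-list recall).
#' @param n_individuals Individuals per cohort.
#' @param n_panel Individuals in the reference panel.
#' @param n_genes,genes_per_chromosome,snps_per_gene Gene/variant layout;
#'   each gene spans one LD block.
#' @param block_rho Within-block haplotype autocorrelation, in \[0, 1).
#' @param maf_range Minor-allele-frequency range (uniform).
#' @param n_causal_genes,snp_h2 Planted causal genes and the per-SNP trait
#'   variance fraction of each causal SNP.
#' @param pathway_size Size of the planted gene set (causal genes plus
#'   fillers).
#' @param n_gene_sets,set_size_range Collection size and null-set sizes.
#' @param annotation_log_or Planted enrichment log-odds linking association
#'   strength to annotation membership.
#' @param annotation_base_rate,immune_base_rate,regulon_base_rate Baseline
#'   membership rates.
#' @param n_tissues Number of pseudo-tissues for eQTL and expression tables.
#' @param n_regulators Number of regulators (TFs/microRNAs).
#' @param expression_shift Mean shift (in residual SDs) per ordered group
#'   step for planted genes in expression studies, and the log-scale
#'   depression of planted genes' expression levels.
#' @param n_expression_groups,samples_per_group Expression-study design.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_cohorts_discovery = 8,
                       n_cohorts_replication = 8,
                       n_individuals = 2000,
                       n_panel = 500,
                       n_genes = 1000,
                       genes_per_chromosome = 50,
                       snps_per_gene = 10,
                       block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_causal_genes = 20,
                       snp_h2 = 0.01,
                       pathway_size = 40,
                       n_gene_sets = 200,
                       set_size_range = c(20, 100),
                       annotation_log_or = 0.6,
                       annotation_base_rate = 0.05,
                       immune_base_rate = 0.1,
                       regulon_base_rate = 0.05,
                       n_tissues = 4,
                       n_regulators = 12,
                       expression_shift = 1,
                       n_expression_groups = 4,
                       samples_per_group = 10) {
  cfg <- as.list(environment())
  counts <- setdiff(grep("^n_", names(cfg), value = TRUE), "n_causal_genes")
  stopifnot(cfg$block_rho >= 0, cfg$block_rho < 1,
            all(unlist(cfg[counts]) >= 1), cfg$n_causal_genes >= 0,
            cfg$snp_h2 > 0, cfg$snp_h2 < 1)
  structure(cfg, class = "sim_config")
}

# One LD block of dosages: two haplotypes per individual, each from a
# latent Gaussian AR(1) thresholded at the per-SNP allele frequency.
draw_block_dosages <- function(n, mafs, rho) {
  m <- length(mafs)
  draw_hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho > 0) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    sweep(z, 2, qnorm(mafs), `<`) * 1
  }
  draw_hap() + draw_hap()
}

#' Simulate a reference panel with gene models and planted causal SNPs
#'
#' Lays `n_genes` LD blocks of `snps_per_gene` SNPs (1 kb spacing, blocks
#' 100 kb apart so flanked gene windows never cross blocks), draws panel
#' haplotypes with block-autoregressive allele correlation and independence
#' across blocks, and plants `n_causal_genes` causal genes whose middle SNP
#' carries an effect sized from `snp_h2`.
#'
#' @param config A [sim_config()].
#' @param seed Stream seed; defaults to a child of `config$seed`.
#' @return List of class `panel_sim`: `panel` ([reference_panel()] with a
#'   `maf` column on the variant index), `genes` (gene models), `causal`
#'   (tibble `gene_id`, `vid`, `beta`), `config`.
#' @export
simulate_panel <- function(config, seed = child_seed(config$seed, "panel")) {
  m <- config$snps_per_gene
  block <- (seq_len(config$n_genes) - 1L) %% config$genes_per_chromosome
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    symbol = sprintf("G%04d", seq_len(config$n_genes)),
    chrom = as.character(ceiling(seq_len(config$n_genes) / config$genes_per_chromosome)),
    tx_start = 10000L + block * 100000L,
    tx_end = 10000L + block * 100000L + (m - 1L) * 1000L,
    flank = 2000L
  )
  variants <- with_local_seed(seed, {
    v <- tidyr::crossing(gene_id = genes$gene_id, snp = seq_len(m) - 1L) |>
      left_join(select(genes, "gene_id", "chrom", "tx_start"), by = "gene_id") |>
      mutate(
        pos = .data$tx_start + .data$snp * 1000L,
        vid = sprintf("%s_S%02d", .data$gene_id, .data$snp + 1L),
        maf = runif(n(), config$maf_range[1], config$maf_range[2]),
        ref = sample(c("A", "C", "G", "T"), n(), replace = TRUE),
        alt = "X"
      )
    v$alt <- vapply(v$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                    character(1))
    v
  })
  dosage <- with_local_seed(child_seed(seed, "dosage"), {
    blocks <- map(split(variants$maf, variants$gene_id)[unique(variants$gene_id)],
                  function(mafs) draw_block_dosages(config$n_panel, mafs, config$block_rho))
    do.call(cbind, blocks)
  })
  panel <- reference_panel(
    dosage,
    select(variants, "chrom", "pos", "vid", "ref", "alt", "maf")
  )
  causal <- with_local_seed(child_seed(seed, "causal"), {
    cg <- sort(sample(genes$gene_id, config$n_causal_genes))
    mid <- ceiling(m / 2)
    cv <- variants |>
      filter(.data$gene_id %in% cg, .data$snp == mid - 1L)
    var_g <- 2 * cv$maf * (1 - cv$maf)
    tibble(gene_id = cv$gene_id, vid = cv$vid,
           beta = sqrt(config$snp_h2 / (1 - config$snp_h2) / var_g))
  })
  structure(list(panel = panel, genes = genes, causal = causal, config = config),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat(sprintf("<panel_sim> %d genes x %d SNPs, %d causal gene(s)\n",
              nrow(x$genes), nrow(x$panel$variants), nrow(x$causal)))
  invisible(x)
}

#' Simulate one cohort's GWAS summary statistics
#'
#' Draws a fresh cohort from the panel's population (same allele frequencies
#' and block LD), builds the phenotype as the sum of planted SNP effects
#' plus standard normal noise, and computes a per-SNP marginal regression
#' p-value and effect direction - so null SNPs yield uniform p-values and
#' LD-induced p-value correlation within blocks is real, not sampled.
#'
#' @param panel_sim A [simulate_panel()] result.
#' @param cohort_id Cohort label.
#' @param phenotype,role Metadata stored on the rows.
#' @param n_individuals Cohort size; defaults to the configured value.
#' @param seed Stream seed; defaults to a child of the master seed and the
#'   cohort id, so each cohort is distinct but reproducible.
#' @return A per-variant tibble in the shape of [read_summary_stats()].
#' @export
simulate_cohort_gwas <- function(panel_sim, cohort_id,
                                 phenotype = "PAR-dr", role = "discovery",
                                 n_individuals = panel_sim$config$n_individuals,
                                 seed = child_seed(panel_sim$config$seed, cohort_id)) {
  cfg <- panel_sim$config
  v <- panel_sim$panel$variants
  with_local_seed(seed, {
    blocks <- map(split(v$maf, sub("_S[0-9]+$", "", v$vid))[unique(sub("_S[0-9]+$", "", v$vid))],
                  function(mafs) draw_block_dosages(n_individuals, mafs, cfg$block_rho))
    G <- do.call(cbind, blocks)
    colnames(G) <- v$vid
    idx <- match(panel_sim$causal$vid, v$vid)
    y <- as.numeric(G[, idx, drop = FALSE] %*% panel_sim$causal$beta) +
      rnorm(n_individuals)
    r <- suppressWarnings(as.numeric(cor(G, y)))
    tstat <- r * sqrt((n_individuals - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tstat), df = n_individuals - 2)
    bad <- !is.finite(p)
    p[bad] <- 1
    p <- pmin(pmax(p, 1e-300), 1)
    direction <- as.integer(sign(r))
    direction[bad | direction == 0] <- 0L
    tibble(
      cohort_id = cohort_id, phenotype = phenotype, role = role,
      chrom = v$chrom, pos = v$pos, vid = v$vid,
      effect_allele = v$alt, other_allele = v$ref,
      pvalue = p, direction = direction, n = n_individuals
    )
  })
}

#' Simulate multi-omics annotation inputs
#'
#' Generates the functional-annotation side of the study with planted
#' enrichment. Variant-level eQTL/meQTL records are drawn per pseudo-tissue
#' with membership odds elevated by `annotation_log_or` for variants inside
#' planted causal blocks (hence in LD with causal SNPs). Gene-level immune
#' and regulon membership is drawn from a logistic model on
#' `-log10(U-score)` with slope `annotation_log_or`, so the downstream
#' logistic regressions estimate exactly the planted coefficient. Expression
#' levels are log-normal with planted genes depressed by `expression_shift`
#' on the log scale.
#'
#' @param panel_sim A [simulate_panel()] result.
#' @param u_table Per-gene association scores (columns `gene_id`,
#'   `u_score`), e.g. one cohort's [gene_association_scores()] output.
#' @param seed Stream seed.
#' @return List with elements `eqtl` (tibble across pseudo-tissues),
#'   `meqtl` (one hippocampus-like tissue), `immune` (character vector),
#'   `regulons` (long tibble), `rpkm` (tibble `tissue`, `gene_id`,
#'   `value`).
#' @export
simulate_annotations <- function(panel_sim, u_table,
                                 seed = child_seed(panel_sim$config$seed, "annot")) {
  cfg <- panel_sim$config
  v <- panel_sim$panel$variants
  block_gene <- sub("_S[0-9]+$", "", v$vid)
  in_causal <- block_gene %in% panel_sim$causal$gene_id
  draw_variant_table <- function(kind, tissue) {
    pr <- plogis(qlogis(cfg$annotation_base_rate) + cfg$annotation_log_or * in_causal)
    hit <- rbinom(length(pr), 1, pr) == 1
    tibble(kind = kind, tissue = tissue,
           chrom = v$chrom[hit], pos = v$pos[hit], vid = v$vid[hit],
           target = block_gene[hit])
  }
  x <- -log10(u_table$u_score)
  draw_gene_status <- function(base_rate) {
    pr <- plogis(qlogis(base_rate) - cfg$annotation_log_or * mean(x) +
                   cfg$annotation_log_or * x)
    rbinom(length(pr), 1, pr)
  }
  with_local_seed(seed, {
    eqtl <- list_rbind(map(seq_len(cfg$n_tissues), function(i) {
      draw_variant_table("eQTL", sprintf("tissue%02d", i))
    }))
    meqtl <- draw_variant_table("meQTL", "hippocampus")
    immune <- u_table$gene_id[draw_gene_status(cfg$immune_base_rate) == 1]
    regulons <- list_rbind(map(seq_len(cfg$n_regulators), function(i) {
      hit <- draw_gene_status(cfg$regulon_base_rate) == 1
      tibble(regulator = sprintf("REG%02d", i), target = u_table$gene_id[hit])
    }))
    rpkm <- list_rbind(map(seq_len(cfg$n_tissues), function(i) {
      planted <- panel_sim$genes$gene_id %in% panel_sim$causal$gene_id
      tibble(tissue = sprintf("tissue%02d", i),
             gene_id = panel_sim$genes$gene_id,
             value = exp(rnorm(nrow(panel_sim$genes),
                               mean = 2 - cfg$expression_shift * planted, sd = 1)))
    }))
    list(eqtl = eqtl, meqtl = meqtl, immune = immune,
         regulons = regulons, rpkm = rpkm)
  })
}

#' Simulate a gene-set collection with one planted pathway
#'
#' The planted set (`"planted_pathway"`) contains the causal genes plus
#' random fillers up to `pathway_size`; the remaining sets are uniform draws
#' from the gene universe with sizes in `set_size_range`.
#'
#' @param panel_sim A [simulate_panel()] result.
#' @param seed Stream seed.
#' @return Long tibble with columns `set_name`, `gene`.
#' @export
simulate_gene_sets <- function(panel_sim,
                               seed = child_seed(panel_sim$config$seed, "sets")) {
  cfg <- panel_sim$config
  universe <- panel_sim$genes$gene_id
  with_local_seed(seed, {
    filler <- sample(setdiff(universe, panel_sim$causal$gene_id),
                     max(0, cfg$pathway_size - nrow(panel_sim$causal)))
    planted <- tibble(set_name = "planted_pathway",
                      gene = c(panel_sim$causal$gene_id, filler))
    nulls <- list_rbind(map(seq_len(cfg$n_gene_sets - 1), function(i) {
      sz <- sample(cfg$set_size_range[1]:cfg$set_size_range[2], 1)
      tibble(set_name = sprintf("set%03d", i), gene = sample(universe, sz))
    }))
    bind_rows(planted, nulls)
  })
}

#' Simulate an expression study with ordered groups
#'
#' Builds a gene x sample matrix over ordered cognitive-status groups with
#' standard-normal noise; each planted gene's mean increases by
#' `expression_shift` residual SDs per group step (set `trend_sd = 0` for a
#' null study).
#'
#' @param panel_sim A [simulate_panel()] result (supplies the gene universe
#'   and configuration).
#' @param planted_genes Genes receiving the trend; defaults to the causal
#'   genes.
#' @param trend_sd Per-group-step mean shift; defaults to the configured
#'   `expression_shift`.
#' @param study_id Study label.
#' @param seed Stream seed.
#' @return An [expression_dataset()].
#' @export
simulate_expression_study <- function(panel_sim,
                                      planted_genes = panel_sim$causal$gene_id,
                                      trend_sd = panel_sim$config$expression_shift,
                                      study_id = "simulated-study",
                                      seed = child_seed(panel_sim$config$seed, study_id)) {
  cfg <- panel_sim$config
  genes <- panel_sim$genes$gene_id
  k <- cfg$n_expression_groups
  npg <- cfg$samples_per_group
  group_levels <- sprintf("status%d", seq_len(k))
  samples <- tibble(
    sample = sprintf("S%03d", seq_len(k * npg)),
    group = rep(group_levels, each = npg)
  )
  with_local_seed(seed, {
    values <- matrix(rnorm(length(genes) * k * npg), nrow = length(genes),
                     dimnames = list(genes, samples$sample))
    step <- rep(seq_len(k) - 1, each = npg)
    planted <- genes %in% planted_genes
    values[planted, ] <- values[planted, , drop = FALSE] +
      matrix(rep(trend_sd * step, each = sum(planted)), nrow = sum(planted))
    expression_dataset(values, samples, group_levels = group_levels,
                       study_id = study_id)
  })
}
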
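# The synthetic-study generator: determinism, LD structure, calibration and
# signal propagation.

test_that("fixed seeds give bit-identical panels, cohorts and VCF bytes", {
  cfg <- sim_config(seed = 33, n_individuals = 200, n_panel = 80, n_genes = 30,
                    genes_per_chromosome = 15, snps_per_gene = 4,
                    n_causal_genes = 2)
  ps1 <- simulate_panel(cfg)
  ps2 <- simulate_panel(cfg)
  expect_identical(ps1$panel$dosage, ps2$panel$dosage)
  expect_identical(ps1$causal, ps2$causal)

  g1 <- simulate_cohort_gwas(ps1, "c1")
  g2 <- simulate_cohort_gwas(ps2, "c1")
  expect_identical(g1, g2)
  # distinct cohorts draw distinct samples
  expect_false(identical(g1$pvalue, simulate_cohort_gwas(ps1, "c2")$pvalue))

  v1 <- withr::local_tempfile(fileext = ".vcf")
  v2 <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(ps1$panel, v1)
  write_panel_vcf(ps2$panel, v2)
  expect_identical(readLines(v1), readLines(v2))
})

test_that("within-block LD tracks the haplotype autocorrelation", {
  base <- list(n_panel = 400, n_genes = 24, genes_per_chromosome = 12,
               snps_per_gene = 10, n_causal_genes = 2)
  ps0 <- simulate_panel(do.call(sim_config, c(base, list(seed = 41, block_rho = 0))))
  ps9 <- simulate_panel(do.call(sim_config, c(base, list(seed = 41, block_rho = 0.95))))
  block_r2 <- function(ps) {
    g <- sub("_S[0-9]+$", "", ps$panel$variants$vid)
    unlist(lapply(unique(g), function(gg) {
      r2 <- suppressWarnings(cor(ps$panel$dosage[, g == gg]))^2
      r2[upper.tri(r2)]
    }))
  }
  r2_null <- block_r2(ps0)
  r2_ld <- block_r2(ps9)
  # independent sites: mean r2 near the finite-sample floor 1/(n-1)
  expect_lt(mean(r2_null, na.rm = TRUE), 3 / 400)
  # strong autocorrelation: dichotomized haplotypes retain substantial LD
  # (Monte-Carlo-derived level; thresholding attenuates the latent 0.95)
  expect_gt(median(r2_ld, na.rm = TRUE), 0.2)
  expect_gt(median(r2_ld, na.rm = TRUE), 10 * median(r2_null, na.rm = TRUE))
})

test_that("a null cohort yields uniform p-values", {
  cfg <- sim_config(seed = 57, n_individuals = 500, n_panel = 100,
                    n_genes = 80, genes_per_chromosome = 40,
                    snps_per_gene = 5, n_causal_genes = 0)
  ps <- simulate_panel(cfg)
  expect_equal(nrow(ps$causal), 0)
  gwas <- simulate_cohort_gwas(ps, "null1")
  ks <- suppressWarnings(stats::ks.test(gwas$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and no gene reaches a extreme uniform score by construction
  tab <- gene_association_scores(gwas, ps$genes, ps$panel)
  expect_equal(mean(tab$u_score <= 0.05), 0.05, tolerance = 0.5)
})

test_that("a planted gene with ~1% per-SNP h2 is recovered in most cohorts", {
  cfg <- small_config(seed = 47)
  ps <- simulate_panel(cfg)
  hit_rate <- purrr::map_dbl(1:4, function(i) {
    gwas <- simulate_cohort_gwas(ps, paste0("c", i))
    tab <- gene_association_scores(gwas, ps$genes, ps$panel)
    mean(tab$u_score[match(ps$causal$gene_id, tab$gene_id)] <= 0.05,
         na.rm = TRUE)
  })
  expect_gt(mean(hit_rate), 0.5)
})

test_that("generated files parse back through the readers without warnings", {
  cfg <- sim_config(seed = 71, n_individuals = 150, n_panel = 60, n_genes = 20,
                    genes_per_chromosome = 10, snps_per_gene = 3,
                    n_causal_genes = 2, n_gene_sets = 5,
                    set_size_range = c(3, 8), pathway_size = 4)
  ps <- simulate_panel(cfg)
  gwas <- simulate_cohort_gwas(ps, "c1")
  td <- withr::local_tempdir()

  f_gwas <- file.path(td, "c1.tsv")
  write_summary_stats(gwas, f_gwas)
  expect_no_warning(read_summary_stats(f_gwas, "c1", "PAR-dr", "discovery"))

  f_vcf <- file.path(td, "panel.vcf")
  write_panel_vcf(ps$panel, f_vcf)
  expect_no_warning(read_reference_panel(f_vcf))

  f_bed <- file.path(td, "genes.bed")
  write_gene_models_bed(ps$genes, f_bed)
  models <- read_gene_models(f_bed, flank = 2000)
  expect_equal(models$tx_start, ps$genes$tx_start)
  expect_equal(models$tx_end, ps$genes$tx_end)

  f_gmt <- file.path(td, "sets.gmt")
  write_gmt(simulate_gene_sets(ps), f_gmt)
  expect_no_warning(read_gmt(f_gmt))
})

test_that("planted annotations elevate membership among associated genes", {
  cfg <- sim_config(seed = 53, n_individuals = 100, n_panel = 60,
                    n_genes = 800, genes_per_chromosome = 100,
                    snps_per_gene = 2, n_causal_genes = 40)
  ps <- simulate_panel(cfg)
  u_tbl <- tibble::tibble(
    gene_id = ps$genes$gene_id,
    u_score = ifelse(ps$genes$gene_id %in% ps$causal$gene_id,
                     runif(nrow(ps$genes), 0, 0.05), runif(nrow(ps$genes)))
  )
  ann <- simulate_annotations(ps, u_tbl, seed = 13)
  # variant-level: eQTL rate higher inside causal blocks
  blocks <- sub("_S[0-9]+$", "", ps$panel$variants$vid)
  rate_in <- mean(ps$panel$variants$vid[blocks %in% ps$causal$gene_id] %in%
                    ann$eqtl$vid)
  rate_out <- mean(ps$panel$variants$vid[!blocks %in% ps$causal$gene_id] %in%
                     ann$eqtl$vid)
  expect_gt(rate_in, rate_out)
  # gene-level: immune membership enriched among low-U genes
  expect_gt(mean(ps$causal$gene_id %in% ann$immune),
            mean(u_tbl$gene_id[u_tbl$u_score > 0.5] %in% ann$immune))
  # expression depressed for planted genes
  rp <- ann$rpkm[ann$rpkm$tissue == "tissue01", ]
  expect_lt(mean(log(rp$value[rp$gene_id %in% ps$causal$gene_id])),
            mean(log(rp$value[!rp$gene_id %in% ps$causal$gene_id])))
})
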
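# SNP -> gene mapping, clumping, Simes combination and uniform scores.

test_that("SNP mapping respects flanked inclusive bounds and overlaps", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), symbol = c("gA", "gB"), chrom = "1",
    tx_start = c(10000L, 11000L), tx_end = c(12000L, 13000L),
    flank = c(2000L, 2000L)
  )
  gwas <- make_gwas(c("in_edge", "out_edge", "shared"),
                    c(8000, 7999, 11500), c(0.1, 0.2, 0.3))
  mapped <- map_snps_to_genes(gwas, genes)
  expect_true("in_edge" %in% mapped$vid[mapped$gene_id == "gA"])
  expect_false("out_edge" %in% mapped$vid)
  expect_equal(sum(mapped$vid == "shared"), 2)  # both overlapping genes

  genes0 <- dplyr::mutate(genes[1, ], flank = 0L)
  at_end <- make_gwas("end", 12000, 0.5)
  expect_equal(nrow(map_snps_to_genes(at_end, genes0)), 1)
})

test_that("greedy clumping drops correlated SNPs and keeps order-invariance", {
  # dosages chosen so that r2(A,B) > 0.2 while r2(A,C) <= 0.2
  d <- cbind(A = c(0, 0, 0, 2, 2, 2, 1, 1),
             B = c(0, 0, 2, 2, 2, 2, 1, 0),
             C = c(2, 0, 1, 0, 2, 0, 1, 2))
  panel <- make_panel(d)
  stopifnot(ld_r2(panel, "A", "B") > 0.2, ld_r2(panel, "A", "C") <= 0.2)
  snps <- make_gwas(c("A", "B", "C"), c(10000, 20000, 30000),
                    c(1e-8, 1e-5, 1e-3))
  kept <- clump_snps(snps, panel)
  expect_equal(kept$vid, c("A", "C"))

  shuffled <- snps[c(3, 1, 2), ]
  expect_equal(clump_snps(shuffled, panel)$vid, c("A", "C"))

  # all pairwise r2 <= r2_max: everything is retained
  expect_equal(nrow(clump_snps(snps, panel, r2_max = 1)), 3)
})

test_that("equal p-values break ties by ascending (pos, vid)", {
  d <- cbind(x1 = c(0, 1, 2, 1, 0, 2), x2 = c(0, 1, 2, 1, 0, 2))
  panel <- make_panel(d)
  snps <- make_gwas(c("x2", "x1"), c(20000, 10000), c(0.01, 0.01))
  kept <- clump_snps(snps, panel)
  expect_equal(nrow(kept), 1)  # either choice gives k = 1 ...
  expect_equal(kept$vid, "x1") # ... and the tie rule picks the smaller pos
})

test_that("SNPs absent from the panel are treated as independent", {
  d <- cbind(a = c(0, 1, 2, 1, 0, 2))
  panel <- make_panel(d)
  snps <- make_gwas(c("a", "ghost"), c(10000, 20000), c(1e-4, 1e-2))
  expect_message(kept <- clump_snps(snps, panel), "absent from panel")
  expect_equal(sort(kept$vid), c("a", "ghost"))
})

test_that("Simes combination follows the sorted-minimum formula", {
  expect_equal(simes_p(c(0.01, 0.04, 0.9)), 0.03)
  expect_equal(simes_p(0.2), 0.2)
  expect_equal(simes_p(rep(1, 4)), 1)  # capped at 1
  expect_error(simes_p(numeric(0)), "empty")
  expect_error(simes_p(c(0.5, 0)), "\\(0, 1\\]")

  # monotone: increasing any input p never decreases M
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(simes_p(p2), simes_p(p))
  }
})

test_that("Simes p-value is valid for independent uniforms (Monte Carlo)", {
  set.seed(2024)
  k <- 5
  p <- matrix(runif(1e5 * k), ncol = k)
  m <- apply(p, 1, simes_p)
  # Pr(M <= alpha) <= alpha, with 3 MC standard errors of slack
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(m <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 1e5))
  }
})

test_that("uniform scores use the self-inclusive mid-rank and average 0.5", {
  u <- u_scores(c(g1 = 0.01, g2 = 0.02, g3 = 0.02, g4 = 0.5))
  expect_equal(unname(u), c(0.125, 0.5, 0.5, 0.875))

  m <- c(0.3, 0.1, 0.7, 0.2)
  expect_equal(sort(u_scores(m)), (seq_along(m) - 0.5) / length(m))

  set.seed(9)
  for (i in 1:20) {
    m <- sample(round(runif(50), 2), 50, replace = TRUE)  # heavy ties
    expect_equal(mean(u_scores(m)), 0.5, tolerance = 1e-12)
    u <- u_scores(m)
    expect_true(all(u > 0 & u < 1))
  }
})

test_that("cohort gene scoring yields a coherent table", {
  cfg <- small_config(seed = 21)
  ps <- simulate_panel(cfg)
  gwas <- simulate_cohort_gwas(ps, "c1")
  tab <- gene_association_scores(gwas, ps$genes, ps$panel)
  expect_equal(tab$L[1], nrow(tab))
  expect_equal(mean(tab$u_score), 0.5, tolerance = 1e-12)
  expect_true(all(tab$k >= 1))
  # Simes M is at least the smallest clumped SNP p of the gene
  mapped <- map_snps_to_genes(gwas, ps$genes)
  minp <- dplyr::summarise(dplyr::group_by(mapped, gene_id),
                           mp = min(pvalue), .groups = "drop")
  joined <- dplyr::inner_join(tab, minp, by = "gene_id")
  expect_true(all(joined$simes_m >= joined$mp - 1e-15))
})
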
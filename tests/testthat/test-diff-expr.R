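# Quantile normalization, trend contrasts, moderated fits and the
# mean-rank permutation set test.

test_that("quantile normalization matches the rank-mean hand example", {
  m <- cbind(s1 = c(1, 2), s2 = c(4, 3))
  rownames(m) <- c("g1", "g2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2, 3), c(3, 2)))

  # idempotent, and every column shares one sorted vector afterwards
  set.seed(3)
  big <- matrix(rnorm(200), ncol = 4)
  qn1 <- quantile_normalize(big)
  expect_equal(quantile_normalize(qn1), qn1)
  sorted <- apply(qn1, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  same <- cbind(a = c(1, 5, 9), b = c(9, 1, 5))
  expect_equal(quantile_normalize(same), same)  # identical distributions
})

test_that("trend contrasts are centered and unit-spaced", {
  expect_equal(trend_contrast(4), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(trend_contrast(3), c(-1, 0, 1))
  expect_equal(trend_contrast(4, include_reference = FALSE), c(0, -1, 0, 1))
  for (k in 2:6) expect_equal(sum(trend_contrast(k)), 0)
  expect_error(trend_contrast(1), "at least 2")
  expect_error(trend_contrast(2, include_reference = FALSE), "at least 3")
})

test_that("moderated contrast fit validates design and is shift-invariant", {
  set.seed(17)
  mat <- matrix(rnorm(50 * 12), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  groups <- rep(c("a", "b", "c"), each = 4)
  ct <- trend_contrast(3)
  res <- moderated_fit(mat, groups, ct, group_levels = c("a", "b", "c"))
  expect_equal(nrow(res), 50)
  expect_true(all(res$f_stat >= 0))

  shifted <- mat
  shifted[1, ] <- shifted[1, ] + 100
  res2 <- moderated_fit(shifted, groups, ct, group_levels = c("a", "b", "c"))
  expect_equal(res2$f_stat[1], res$f_stat[1], tolerance = 1e-8)

  expect_error(moderated_fit(mat, groups, c(1, 1, 1)), "sum to 0")
  expect_error(moderated_fit(mat, groups, c(1, -1)), "length")
  expect_error(moderated_fit(mat[, 1:3], rep(c("a", "b", "c")), ct),
               "zero residual")
})

test_that("genes with a planted trend dominate the moderated ranking", {
  set.seed(19)
  n_genes <- 300
  groups <- rep(paste0("st", 1:4), each = 6)
  mat <- matrix(rnorm(n_genes * 24), nrow = n_genes,
                dimnames = list(paste0("g", 1:n_genes), NULL))
  shifted <- 1:30
  step <- rep(0:3, each = 6)
  mat[shifted, ] <- mat[shifted, ] + rep(step, each = 30) * 1.0
  res <- moderated_fit(mat, groups, trend_contrast(4),
                       group_levels = paste0("st", 1:4))
  ranks <- rank(-res$f_stat)
  expect_lt(median(ranks[shifted]), n_genes / 10)
})

test_that("mean-rank set test matches its enumeration oracle", {
  stats5 <- tibble::tibble(gene_id = paste0("g", 1:5), f_stat = c(9, 7, 5, 3, 1))
  # set = the two top-ranked genes; exact p over C(5,2) subsets is 1/10
  res <- mean_rank_set_test(stats5, c("g1", "g2"), n_perm = 4000, seed = 2)
  expect_equal(res$mean_rank, 1.5)
  expect_equal(res$p_perm, 0.1, tolerance = 0.25)

  # extreme case: the attainable minimum is 1/(n_perm+1)
  stats100 <- tibble::tibble(gene_id = paste0("g", 1:100), f_stat = 100:1)
  extreme <- mean_rank_set_test(stats100, paste0("g", 1:5), n_perm = 500, seed = 1)
  expect_equal(extreme$p_perm, 1 / 501)

  again <- mean_rank_set_test(stats100, paste0("g", 1:5), n_perm = 500, seed = 1)
  expect_identical(extreme$p_perm, again$p_perm)

  expect_error(mean_rank_set_test(stats5, c("zz", "yy")), "no set gene.*zz")
})

test_that("homolog mapping reports unmapped symbols and collapses duplicates", {
  tbl <- tibble::tibble(symbol = c("HLA-A", "HLA-B", "PSMD4"),
                        homolog = c("H2-K1", "H2-K1", "Psmd4"))
  expect_warning(mapped <- map_homologs(c("HLA-A", "HLA-B", "PSMD4", "NOPE"), tbl),
                 "collapsed")
  expect_equal(mapped$homolog, c("H2-K1", "Psmd4"))
  expect_equal(attr(mapped, "unmapped"), "NOPE")
})

test_that("set-level pipeline detects a planted expression trend", {
  cfg <- small_config(seed = 23)
  ps <- simulate_panel(cfg)
  planted <- simulate_expression_study(ps, study_id = "planted", seed = 5)
  res <- suppressMessages(set_de_test(planted, ps$causal$gene_id,
                                      n_perm = 1000, seed = 6))
  expect_lte(res$p_perm, 0.05)

  null_ds <- simulate_expression_study(ps, trend_sd = 0, study_id = "null",
                                       seed = 7)
  res0 <- suppressMessages(set_de_test(null_ds, ps$causal$gene_id,
                                       n_perm = 1000, seed = 8))
  expect_gte(res0$p_perm, 0.05)
})
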
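# USGSA enrichment, permutation adjustment, and both meta-analysis
# approaches.

toy_u_table <- function() {
  # 10-gene universe, Phi = {A, B, C}
  tibble::tibble(
    gene_id = LETTERS[1:10],
    u_score = c(0.01, 0.02, 0.03, seq(0.2, 0.9, length.out = 7))
  )
}

test_that("USGSA effect, SE and exact hypergeometric p match hand values", {
  sets <- tibble::tibble(set_name = "S", gene = c("A", "B", "D", "E"))
  res <- usgsa(toy_u_table(), sets)
  expect_equal(res$n_omega, 4)
  expect_equal(res$x_overlap, 2)
  expect_equal(res$p_hat, 0.5)
  expect_equal(res$p_exact, 70 / 210, tolerance = 1e-12)  # exhaustive count
  expect_equal(res$effect + res$p0, res$x_overlap / res$n_omega)  # identity

  se44 <- usgsa(tibble::tibble(gene_id = paste0("g", 1:44), u_score = 0.5),
                tibble::tibble(set_name = "S", gene = paste0("g", 1:44)))
  expect_equal(se44$se, sqrt(0.05 * 0.95 / 44), tolerance = 1e-9)
  expect_equal(se44$se, 0.03286, tolerance = 1e-3)
})

test_that("null identity and saturation behave as expected", {
  u <- tibble::tibble(gene_id = paste0("g", 1:100),
                      u_score = (1:100 - 0.5) / 100)  # Phi = 5 genes
  sets <- tibble::tibble(set_name = "S", gene = paste0("g", seq(1, 100, by = 5)))
  res <- usgsa(u, sets)  # overlap 1 of 20 = p0 * n_omega exactly
  expect_equal(res$effect, 0)

  sat <- candidate_enrichment(u$gene_id, sets, u$gene_id, n_perm = 100, seed = 1)
  expect_equal(sat$p_hat, 1)
})

test_that("exact p agrees with subset enumeration on small universes", {
  set.seed(14)
  for (i in 1:5) {
    L <- sample(8:12, 1)
    n_phi <- sample(2:4, 1)
    k <- sample(3:6, 1)
    u <- tibble::tibble(gene_id = paste0("g", 1:L),
                        u_score = c(rep(0.01, n_phi), rep(0.5, L - n_phi)))
    members <- sample(u$gene_id, k)
    res <- usgsa(u, tibble::tibble(set_name = "S", gene = members),
                 alpha = 0.02)
    x <- res$x_overlap
    expect_equal(res$p_exact, enum_hyper_tail(x, n_phi, L, k),
                 tolerance = 1e-12)
  }
})

test_that("sets with no universe gene are omitted with a warning", {
  sets <- tibble::tibble(set_name = c("in", "out"),
                         gene = c("A", "ZZZ"))
  expect_warning(res <- usgsa(toy_u_table(), sets), "omitted")
  expect_equal(res$set_name, "in")
})

test_that("permutation adjustment is symmetric, reproducible and calibrated", {
  u <- toy_u_table()
  one <- tibble::tibble(set_name = "S", gene = c("A", "B", "D", "E"))
  single <- usgsa_perm_adjust(u, one, n_perm = 2000, seed = 9)
  expect_lt(abs(single$p_adj - single$p_exact), 0.06)

  dup <- dplyr::bind_rows(one, dplyr::mutate(one, set_name = "S-copy"))
  both <- usgsa_perm_adjust(u, dup, n_perm = 300, seed = 9)
  expect_equal(both$p_adj[1], both$p_adj[2])

  again <- usgsa_perm_adjust(u, dup, n_perm = 300, seed = 9)
  expect_identical(both$p_adj, again$p_adj)
  expect_true(all(both$p_adj >= 1 / 301))
})

test_that("random-effects meta reproduces the DerSimonian-Laird hand example", {
  hom <- re_meta(rep(0.1, 3), rep(0.02, 3))
  expect_equal(hom$re_effect, 0.1, tolerance = 1e-10)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$re_se, 0.02 / sqrt(3), tolerance = 1e-10)

  dl <- re_meta(c(0, 0.2), c(0.1, 0.1))
  expect_equal(dl$tau2, 0.01, tolerance = 1e-10)
  expect_equal(dl$re_effect, 0.1, tolerance = 1e-10)
  expect_equal(dl$re_se, 0.1, tolerance = 1e-10)

  perm <- re_meta(c(0.2, 0), c(0.1, 0.1))
  expect_equal(perm[c("re_effect", "re_se", "tau2", "re_p")],
               dl[c("re_effect", "re_se", "tau2", "re_p")])

  expect_warning(single <- re_meta(0.1, 0.05), "single cohort")
  expect_equal(single$re_effect, 0.1)
})

test_that("binomial pathway meta counts cohorts and applies Bonferroni", {
  none <- binomial_pathway_meta(rep(0.5, 8))
  expect_equal(none$bin_p, 1)
  five <- binomial_pathway_meta(c(rep(0.01, 5), rep(0.5, 3)))
  expect_equal(five$n_sig_cohorts, 5L)
  expect_equal(five$bin_p, 1.54e-5, tolerance = 5e-3)
  # replication stage with 6 pathways: threshold 0.05/6
  repl <- binomial_pathway_meta(c(0.008, 0.02, 0.5), n_tests = 6)
  expect_equal(repl$n_sig_cohorts, 1L)
  # invariant to which cohorts are significant
  a <- binomial_pathway_meta(c(0.01, 0.5, 0.5))
  b <- binomial_pathway_meta(c(0.5, 0.5, 0.01))
  expect_equal(a$bin_p, b$bin_p)
})

test_that("candidate enrichment uses p0 = |Phi|/L and rejects empty Phi", {
  u <- tibble::tibble(gene_id = paste0("g", 1:200), u_score = 0.5)
  sets <- tibble::tibble(set_name = "S", gene = paste0("g", 1:10))
  res <- candidate_enrichment(paste0("g", 101:110), sets, u$gene_id,
                              n_perm = 100, seed = 2)
  expect_equal(res$p0, 10 / 200)
  expect_equal(res$x_overlap, 0)
  expect_equal(res$effect, -res$p0)
  expect_gt(res$p_exact, 0.5)
  expect_error(candidate_enrichment(character(0), sets, u$gene_id),
               "no significant genes")
})

test_that("the overlap/universe solver inverts a known construction", {
  L_true <- 5000
  truth <- tibble::tibble(
    set_name = c("s1", "s2", "s3"), size = c(40, 70, 25),
    phi_size = 60, overlap = c(5, 9, 2)
  )
  effects <- dplyr::mutate(truth, effect = overlap / size - phi_size / L_true)
  sol <- infer_enrichment_overlaps(effects, L_range = 4000:6000)
  expect_equal(sol$L, L_true)
  expect_equal(sol$overlaps$overlap, truth$overlap)
  expect_lt(sol$max_residual, 1e-8)
})
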
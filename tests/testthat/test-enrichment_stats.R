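# Propagated-score fixtures are built directly: the cascade only requires the
# provenance flag and a named non-negative vector.
prop_scores <- function(v, genes = sprintf("g%02d", seq_along(v))) {
  gene_scores(v, genes, provenance = "propagated")
}

test_that("K-S pathway test detects upper-tail enrichment and handles ties", {
  v <- seq_len(100) / 10
  gs <- prop_scores(v)
  top <- names(gs)[order(-v)][1:20]
  expect_lt(ks_pathway_test(gs, top), 1e-8)
  # members in the lower tail: one-sided 'greater' test should not fire
  bottom <- names(gs)[order(v)][1:20]
  expect_gt(ks_pathway_test(gs, bottom), 0.5)
  # all values identical: D = 0, p = 1
  expect_equal(ks_pathway_test(prop_scores(rep(1, 30)),
                               sprintf("g%02d", 1:5)), 1)
  expect_error(ks_pathway_test(gs, "g01"), "fewer than 2")
})

test_that("K-S and MW p-values are near-uniform under the null", {
  set.seed(71)
  v <- rnorm(400)^2
  gs <- prop_scores(v, sprintf("g%03d", 1:400))
  ks_p <- mw_p <- numeric(300)
  for (r in 1:300) {
    members <- sample(names(gs), 25)
    ks_p[r] <- ks_pathway_test(gs, members)
    mw_p[r] <- mw_pathway_test(gs, members)
  }
  # type-I rate at 0.05 within a generous binomial window (n = 300)
  expect_gt(mean(ks_p <= 0.05), 0.01)
  expect_lt(mean(ks_p <= 0.05), 0.10)
  expect_gt(mean(mw_p <= 0.05), 0.01)
  expect_lt(mean(mw_p <= 0.05), 0.10)
  # gross uniformity of the whole distribution
  expect_gt(suppressWarnings(ks.test(ks_p, "punif")$p.value), 1e-4)
})

test_that("MW pathway test matches exact enumeration on a tiny universe", {
  v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  gs <- prop_scores(v, letters[1:10])
  # enumeration oracle: P(random 3-subset has rank sum >= observed)
  obs <- sum(rank(v)[1:3])
  subsets <- combn(10, 3)
  null_sums <- apply(subsets, 2, function(ix) sum(rank(v)[ix]))
  p_exact <- mean(null_sums >= obs)
  expect_equal(p_exact, 1 / choose(10, 3))
  expect_equal(mw_pathway_test(gs, letters[1:3]), p_exact, tolerance = 1e-12)
  # all tied values carry no rank information
  expect_equal(mw_pathway_test(prop_scores(rep(2, 20)),
                               sprintf("g%02d", 1:4)), 1)
})

test_that("permutation p-values use the add-one estimator", {
  set.seed(5)
  v <- sort(runif(50), decreasing = TRUE)
  gs <- prop_scores(v)
  top <- names(gs)[1:5]   # maximal possible mean
  out <- permutation_test(gs, top, n_perm = 2000, seed = 9)
  expect_equal(out$observed, mean(v[1:5]))
  expect_equal(out$p, (1 + sum(out$null >= out$observed)) / 2001)
  expect_lte(out$p, (1 + sum(out$null == out$observed)) / 2001)
  expect_gt(out$p, 0)

  # constant scores: every null mean ties the observed mean
  const <- prop_scores(rep(3, 30))
  expect_equal(permutation_test(const, sprintf("g%02d", 1:4),
                                n_perm = 100, seed = 1)$p, 1)
})

test_that("permutation p converges to the exhaustive enumeration", {
  v <- c(5, 4, 3.5, 2, 1.5, 1)
  gs <- prop_scores(v, letters[1:6])
  members <- c("a", "c")
  obs <- mean(v[c(1, 3)])
  null_exact <- apply(combn(6, 2), 2, function(ix) mean(v[ix]))
  p_exact <- mean(null_exact >= obs)   # 15 equally likely subsets
  out <- permutation_test(gs, members, n_perm = 20000, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(out$p - p_exact), 3 * se + 2 / 20001)
})

test_that("permutation draws are reproducible and order-independent via child seeds", {
  gs <- prop_scores(runif(40))
  m <- names(gs)[c(3, 7, 9, 22)]
  a <- permutation_test(gs, m, n_perm = 500, seed = 42)
  b <- permutation_test(gs, m, n_perm = 500, seed = 42)
  expect_identical(a$null, b$null)
  expect_identical(child_seed(42, "PW_A"), child_seed(42, "PW_A"))
  expect_false(child_seed(42, "PW_A") == child_seed(42, "PW_B"))
  expect_false(child_seed(42, "PW_A") == child_seed(43, "PW_A"))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  set.seed(88)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("cascade gates stages, calls significance, and ranks deterministically", {
  set.seed(31)
  n <- 300
  v <- abs(rnorm(n))
  genes <- sprintf("g%03d", 1:n)
  # plant one pathway in the upper tail
  planted <- order(-v)[1:20]
  sets <- list(PLANTED = genes[planted])
  for (k in 1:15) sets[[sprintf("DECOY_%02d", k)]] <- sample(genes, 20)
  col <- pathway_collection(sets)
  gs <- prop_scores(v, genes)

  res <- run_cascade(gs, col, threshold = 0.05, n_perm = 500, seed = 7)
  expect_setequal(res$pathway, names(sets))
  expect_true(all(res$rank == seq_len(nrow(res))))
  planted_row <- res[res$pathway == "PLANTED", ]
  expect_true(planted_row$significant)
  expect_equal(planted_row$rank, 1L)
  # stage gating: MW only where ks_fdr passed, permutation only where mw_fdr passed
  expect_true(all(is.na(res$mw_p[res$ks_fdr > 0.05])))
  expect_true(all(!is.na(res$mw_p[res$ks_fdr <= 0.05])))
  expect_true(all(is.na(res$perm_p[is.na(res$mw_fdr) | res$mw_fdr > 0.05])))
  expect_true(all(res$significant ==
                    (res$ks_fdr <= 0.05 & !is.na(res$mw_fdr) & res$mw_fdr <= 0.05)))

  # threshold 1: every pathway reaches all three stages
  res_all <- run_cascade(gs, col, threshold = 1, n_perm = 200, seed = 7)
  expect_true(all(!is.na(res_all$mw_p)))
  expect_true(all(!is.na(res_all$perm_p)))

  # cascade monotonicity: raising the threshold never drops a later stage
  res_lo <- run_cascade(gs, col, threshold = 0.01, n_perm = 200, seed = 7)
  reached_mw_lo <- res_lo$pathway[!is.na(res_lo$mw_p)]
  reached_mw_hi <- res_all$pathway[!is.na(res_all$mw_p)]
  expect_true(all(reached_mw_lo %in% reached_mw_hi))

  # determinism: identical inputs give byte-identical tables
  res2 <- run_cascade(gs, col, threshold = 0.05, n_perm = 500, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_results(res, f1); write_results(res2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # propagated provenance is required
  expect_error(run_cascade(gene_scores(v, genes), col), "propagated")
})

test_that("cascade with no K-S hit computes no later stages", {
  set.seed(99)
  v <- abs(rnorm(200))
  genes <- sprintf("g%03d", 1:200)
  sets <- lapply(1:10, function(k) sample(genes, 15))
  names(sets) <- sprintf("PW_%02d", 1:10)
  res <- run_cascade(prop_scores(v, genes), pathway_collection(sets),
                     threshold = 1e-6, n_perm = 100, seed = 3)
  expect_true(all(is.na(res$mw_p)))
  expect_true(all(is.na(res$perm_p)))
  expect_equal(sum(res$significant), 0L)
})

test_that("untestable pathways are skipped with a recorded reason", {
  v <- abs(rnorm(50))
  genes <- sprintf("g%02d", 1:50)
  col <- pathway_collection(list(OK = genes[1:10], TINY = c(genes[1], "zzz"),
                                 ALIEN = c("q1", "q2")))
  res <- run_cascade(prop_scores(v, genes), col, n_perm = 100, seed = 1)
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$pathway, c("TINY", "ALIEN"))
  expect_match(skipped$reason[skipped$pathway == "TINY"], "effective size 1")
  expect_equal(res$pathway, "OK")
})
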
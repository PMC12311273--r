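test_that("neighbor-averaging transform reproduces hand cases", {
  # gene with |x| = 2 and neighbor magnitudes {1, 3}: NS = 2 + 2 = 4
  net <- ppi_network(c("A", "A"), c("B", "C"))
  gs <- suppressMessages(intersect_with_network(
    gene_scores(c(A = -2, B = 1, C = -3)), net))
  ns <- ngsea_transform(gs, net)
  expect_equal(ns[["A"]], 4)
  expect_equal(provenance(ns), "ngsea")
  # neighbors of B = {A}: NS_B = 1 + 2
  expect_equal(ns[["B"]], 3)

  # isolated gene keeps its absolute score
  net2 <- ppi_network("A", "B", nodes = c("A", "B", "Z"))
  gs2 <- suppressMessages(intersect_with_network(
    gene_scores(c(A = 1, B = 1, Z = 5)), net2))
  expect_equal(ngsea_transform(gs2, net2)[["Z"]], 5)

  # star center, unit neighbors, center score 0: average of identical values
  star <- ppi_network(rep("HUB", 4), sprintf("S%d", 1:4))
  gs3 <- suppressMessages(intersect_with_network(
    gene_scores(c(HUB = 0, S1 = 1, S2 = -1, S3 = 1, S4 = -1)), star))
  expect_equal(ngsea_transform(gs3, star)[["HUB"]], 1)

  # neighbor-averaged scores dominate the absolute scores elementwise
  net4 <- random_net(60, 0.08, seed = 2)
  set.seed(3)
  gs4 <- gene_scores(rnorm(60), net4$nodes)
  expect_true(all(as.numeric(ngsea_transform(gs4, net4)) >=
                    abs(as.numeric(gs4)) - 1e-12))

  expect_error(ngsea_transform(gene_scores(c(X = 1, Y = 2)), net), "aligned")
})

test_that("abs transform mirrors to_absolute", {
  gs <- gene_scores(c(a = -1, b = 2))
  expect_equal(unname(as.numeric(abs_transform(gs))), c(1, 2))
  gs2 <- gene_scores(c(a = -1, b = -2))
  expect_equal(unname(as.numeric(abs_transform(gs2))), c(1, 2))
  expect_equal(unname(as.numeric(abs_transform(gene_scores(c(z = 0))))), 0)
})

test_that("running-sum ES hits the exact extremes and stays in [-1, 1]", {
  set.seed(17)
  v <- rnorm(60)
  genes <- sprintf("g%02d", 1:60)
  gs <- gene_scores(v, genes)
  ranked <- genes[order(-v, genes)]

  # top-m pathway: all increments before any decrement, ES = +1 exactly
  col_top <- pathway_collection(list(TOP = ranked[1:8]))
  res <- prerank_enrichment(gs, col_top, n_perm = 50, seed = 1)
  expect_equal(res$ES, 1)
  res0 <- prerank_enrichment(gs, col_top, n_perm = 50, weight = 0, seed = 1)
  expect_equal(res0$ES, 1)

  # bottom-m pathway: most extreme deviation is negative
  col_bot <- pathway_collection(list(BOT = ranked[53:60]))
  expect_lt(prerank_enrichment(gs, col_bot, n_perm = 50, seed = 1)$ES, 0)

  # random pathways stay within bounds
  for (r in 1:40) {
    m <- sample(2:20, 1)
    col_r <- pathway_collection(list(R = sample(genes, m)))
    es <- prerank_enrichment(gs, col_r, n_perm = 10, seed = r)$ES
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("ES agrees with an independent brute-force running-sum walk", {
  set.seed(23)
  v <- rnorm(40)
  genes <- sprintf("g%02d", 1:40)
  gs <- gene_scores(v, genes)
  ord <- order(-v, genes)
  ranked_scores <- v[ord]
  ranked_genes <- genes[ord]
  for (r in 1:25) {
    m <- sample(1:15, 1)
    members <- sample(genes, m)
    for (wt in c(0, 1, 1.5)) {
      res <- prerank_enrichment(gs, pathway_collection(list(P = members)),
                                n_perm = 5, weight = wt, seed = r)
      expect_equal(res$ES,
                   es_oracle(ranked_scores, ranked_genes %in% members, wt),
                   tolerance = 1e-12,
                   label = sprintf("rep %d weight %.1f", r, wt))
    }
  }
  # single-member pathway at a known rank, weight 0: closed form
  # ES = max over the walk = 1 - (r - 1)/(N - 1) at the hit
  members <- ranked_genes[10]
  res <- prerank_enrichment(gs, pathway_collection(list(S = members)),
                            n_perm = 5, weight = 0, seed = 1)
  expect_equal(res$ES, 1 - 9 / 39, tolerance = 1e-12)
})

test_that("ES matches fgsea's statistic on random cases", {
  skip_if_not_installed("fgsea")
  set.seed(29)
  v <- rnorm(80)
  genes <- sprintf("g%02d", 1:80)
  gs <- gene_scores(v, genes)
  ord <- order(-v, genes)
  for (r in 1:10) {
    members <- sample(genes, sample(3:20, 1))
    res <- prerank_enrichment(gs, pathway_collection(list(P = members)),
                              n_perm = 5, weight = 1, seed = r)
    ref <- fgsea::calcGseaStat(stats = v[ord],
                               selectedStats = which(genes[ord] %in% members),
                               gseaParam = 1, scoreType = "std")
    expect_equal(res$ES, ref, tolerance = 1e-10)
  }
})

test_that("rank-only statistic is shift invariant; weighted is not", {
  set.seed(37)
  v <- rnorm(50)
  genes <- sprintf("g%02d", 1:50)
  members <- sample(genes, 10)
  col <- pathway_collection(list(P = members))
  es_w0 <- prerank_enrichment(gene_scores(v, genes), col, n_perm = 5,
                              weight = 0, seed = 1)$ES
  es_w0_shift <- prerank_enrichment(gene_scores(v + 5, genes), col, n_perm = 5,
                                    weight = 0, seed = 1)$ES
  expect_equal(es_w0, es_w0_shift, tolerance = 1e-12)
  es_w1 <- prerank_enrichment(gene_scores(v, genes), col, n_perm = 5,
                              weight = 1, seed = 1)$ES
  es_w1_shift <- prerank_enrichment(gene_scores(v + 5, genes), col, n_perm = 5,
                                    weight = 1, seed = 1)$ES
  expect_false(isTRUE(all.equal(es_w1, es_w1_shift, tolerance = 1e-6)))
})

test_that("baseline dispatch applies the right transform", {
  set.seed(41)
  net <- random_net(80, 0.06, seed = 41)
  v <- rnorm(80)
  gs <- gene_scores(v, net$nodes)
  sets <- lapply(1:6, function(k) sample(net$nodes, 12))
  names(sets) <- sprintf("PW_%d", 1:6)
  col <- pathway_collection(sets)

  # gsea is the identity transform
  a <- run_baseline("gsea", gs, col = col, n_perm = 100, seed = 5)
  b <- prerank_enrichment(gs, col, n_perm = 100, seed = 5)
  expect_equal(a$ES, b$ES)
  expect_equal(a$fdr_q, b$fdr_q)

  # abs_gsea on an all-positive list equals gsea
  gsp <- gene_scores(abs(v) + 0.1, net$nodes)
  expect_equal(run_baseline("abs_gsea", gsp, col = col, n_perm = 50, seed = 5)$ES,
               run_baseline("gsea", gsp, col = col, n_perm = 50, seed = 5)$ES)

  # ngsea on an edgeless network degenerates to abs_gsea
  edgeless <- ppi_network(nodes = net$nodes)
  expect_equal(
    suppressMessages(run_baseline("ngsea", gs, net = edgeless, col = col,
                                  n_perm = 50, seed = 5))$ES,
    suppressMessages(run_baseline("abs_gsea", gs, net = edgeless, col = col,
                                  n_perm = 50, seed = 5,
                                  restrict_to_network = TRUE))$ES)

  expect_error(run_baseline("ngsea", gs, col = col), "network")

  # pathways with no effective members are skipped, not scored
  col2 <- pathway_collection(c(sets, list(ALIEN = c("x1", "x2"))))
  res <- run_baseline("gsea", gs, col = col2, n_perm = 20, seed = 1)
  expect_false("ALIEN" %in% res$pathway)
  expect_true("ALIEN" %in% attr(res, "skipped")$pathway)
})
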
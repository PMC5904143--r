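test_that("archetype orthogonalization matches a least-squares oracle", {
  set.seed(51)
  A <- matrix(rnorm(10 * 3), 10, 3)
  Ap <- pmax(A, 0)
  for (i in 1:3) {
    res <- orthogonalize_archetype(A, i)
    oracle <- residuals(lm(Ap[, i] ~ 0 + Ap[, -i]))
    expect_equal(unname(res), unname(oracle), tolerance = 1e-10)
    dots <- abs(crossprod(Ap[, -i, drop = FALSE], res))
    norms <- sqrt(colSums(Ap[, -i, drop = FALSE]^2)) * sqrt(sum(res^2))
    expect_true(all(dots <= 1e-8 * pmax(norms, 1e-300)))
  }
})

test_that("disjoint positive supports leave the archetype unchanged", {
  A <- cbind(c(2, 3, 0, 0, -1), c(-1, 0, 1, 4, 0))
  expect_equal(orthogonalize_archetype(A, 1), pmax(A[, 1], 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a duplicated archetype has zero residual via the pseudoinverse", {
  a <- c(1, 2, 0, 3)
  A <- cbind(a, a, c(0, 1, 2, 0))
  expect_equal(max(abs(orthogonalize_archetype(A, 1))), 0, tolerance = 1e-8)
})

test_that("gene ranking is descending with lexicographic ties", {
  expect_equal(rank_genes(c(0.1, 0.9, 0.5), c("g1", "g2", "g3")),
               c("g2", "g3", "g1"))
  expect_equal(rank_genes(c(1, 1, 1), c("b", "c", "a")), c("a", "b", "c"))
  set.seed(52)
  v <- rnorm(50)
  ids <- sprintf("g%02d", 1:50)
  expect_equal(rank_genes(v, ids), ids[order(-v)])
})

test_that("mHG score equals the per-cut hypergeometric minimum", {
  # both targets at the top of 5: tail at l=2 is 1/C(5,2)
  sc <- mhg_score(c(1, 1, 0, 0, 0))
  expect_equal(sc$score, 1 / choose(5, 2))
  expect_equal(sc$l_best, 2L)
  # empty target set
  expect_equal(mhg_score(rep(0, 6)), list(score = 1, l_best = 0L,
                                          r = 0L, m = 6L))
  # brute-force per-cut oracle
  lam <- c(1, 0, 1, 0, 0, 1, 0, 0)
  r <- sum(lam); m <- length(lam)
  tails <- sapply(seq_len(m), function(l) {
    k <- sum(lam[1:l])
    sum(dhyper(k:min(l, r), r, m - r, l))
  })
  sc2 <- mhg_score(lam)
  expect_equal(sc2$score, min(tails), tolerance = 1e-12)
  expect_equal(sc2$l_best, which.min(tails))
})

test_that("adding a target at rank 1 never increases the mHG score", {
  set.seed(53)
  for (rep in 1:20) {
    lam <- as.integer(runif(12) < 0.3)
    expect_lte(mhg_score(c(1L, lam))$score, mhg_score(lam)$score + 1e-15)
  }
})

test_that("DP p-value matches exhaustive enumeration on a grid", {
  for (m in c(4, 6, 8)) {
    for (r in 0:m) {
      set.seed(100 * m + r)
      lam <- integer(m)
      if (r > 0) lam[sample(m, r)] <- 1L
      sc <- mhg_score(lam)
      expect_equal(mhg_pvalue_dp(sc$score, m, r),
                   mhg_pvalue_enum(sc$score, m, r), tolerance = 1e-12)
    }
  }
})

test_that("DP p-value respects its analytic bounds", {
  expect_equal(mhg_pvalue_dp(1, 7, 0), 1)
  set.seed(54)
  for (rep in 1:20) {
    m <- sample(5:40, 1); r <- sample(1:m, 1)
    lam <- integer(m); lam[sample(m, r)] <- 1L
    sc <- mhg_score(lam)
    p <- mhg_pvalue_dp(sc$score, m, r)
    expect_gte(p, sc$score - 1e-12)
    expect_lte(p, min(1, m * sc$score) + 1e-12)
  }
})

test_that("p-value is stable for long rankings (rescaled path counts)", {
  set.seed(56)
  lam <- integer(2000); lam[c(1:15, sample(16:2000, 5))] <- 1L
  sc <- mhg_score(lam)
  p <- mhg_pvalue_dp(sc$score, sc$m, sc$r)
  expect_true(is.finite(p) && p > 0 && p <= 1)
  expect_lt(p, 1e-10)   # 15 of 20 targets at the very top is extreme
})

test_that("regulon reader parses, dedups, and rejects malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ATF1\tCDK4\tActivation\t12345",
               "ATF1\tCDK4\tActivation\t99999",
               "ATF1\tMYC\tRepression\t1",
               "E2F1\tCCNE1\tActivation\t2",
               "E2F1\tCDK4\tUnknown\t3",
               "E2F1\tCCNE1\tActivation\t4"), tmp)
  reg <- read_regulons(tmp)
  expect_s3_class(reg, "regulon_set")
  expect_length(reg, 2)
  expect_setequal(reg$ATF1, c("CDK4", "MYC"))
  expect_setequal(reg$E2F1, c("CCNE1", "CDK4"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ATF1\tCDK4\tx\t1", "orphan"), bad)
  expect_error(read_regulons(bad), "line 2")
  # header auto-detection
  hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF\ttarget\tmode\tref", "ATF1\tCDK4\tActivation\t1"), hdr)
  expect_length(read_regulons(hdr), 1)
})

test_that("TRN keeps only significant TFs and their above-cut targets", {
  # hand-built archetypes: archetype 1 strongly expresses genes 1..10
  set.seed(55)
  m <- 60
  genes <- sprintf("g%02d", 1:m)
  A <- matrix(abs(rnorm(m * 2, sd = 0.05)), m, 2,
              dimnames = list(genes, NULL))
  A[1:10, 1] <- 5 + runif(10)
  A[31:40, 2] <- 5 + runif(10)
  reg <- regulon_set(list(
    hitTF = genes[1:8],                  # all near the top of archetype 1
    nullTF = genes[seq(5, 60, by = 6)])) # scattered
  trn <- build_trn(A, reg, alpha = 0.05)
  tt <- trn$tf_table
  hit1 <- tt[tt$archetype == 1 & tt$tf == "hitTF", ]
  expect_true(hit1$significant)
  # all its r targets precede the cut -> exactly r edges
  e1 <- trn$edges[trn$edges$archetype == 1 & trn$edges$tf == "hitTF", ]
  expect_equal(nrow(e1), hit1$r)
  expect_true(all(e1$target %in% genes[1:8]))
  # a TRN with an impossible threshold is empty
  trn0 <- build_trn(A, reg, alpha = 1e-30)
  expect_equal(nrow(trn0$edges), 0)
})

test_that("planted regulon is detected and a random one is not", {
  ok_hit <- 0; ok_null <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    ds <- small_dataset(seed = seed)
    reg <- plant_regulons(ds, focal_type = 1, n_targets = 20,
                          overlap = 15, n_decoy_tfs = 1, seed = seed)
    dec <- suppressWarnings(action_decompose(ds$X, k = 5))
    # find the archetype dominated by type 1
    arch <- as.integer(names(which.max(table(dec$labels[ds$labels == 1]))))
    trn <- build_trn(dec, reg, alpha = 0.05)
    tt <- trn$tf_table
    pa <- tt$p_value[tt$archetype == arch & tt$tf == "TF_A"]
    pb <- tt$p_value[tt$archetype == arch & tt$tf == "TF_B"]
    if (length(pa) == 1 && pa <= 1e-3) ok_hit <- ok_hit + 1
    if (length(pb) == 1 && pb > 0.05) ok_null <- ok_null + 1
  }
  expect_gte(ok_hit, 9)
  expect_gte(ok_null, 9)
})

test_that("TRN export writers produce SIF and GraphML", {
  genes <- sprintf("g%02d", 1:30)
  A <- matrix(abs(rnorm(60, sd = 0.05)), 30, 2,
              dimnames = list(genes, NULL))
  A[1:6, 1] <- 4
  A[21:26, 2] <- 4
  trn <- build_trn(A, regulon_set(list(tfX = genes[1:6],
                                       decoy = genes[7:20])), alpha = 0.05)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_trn_sif(trn, sif)
  expect_true(any(grepl("tfX\tregulates\t", readLines(sif), fixed = TRUE)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_trn_graphml(trn, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(trn$edges))
  expect_true("TF" %in% igraph::V(g)$type)
})
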
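test_that("two-step normalization follows the row-then-column rule", {
  expect_equal(normalizeRelation(matrix(c(3, 4), 1, 2)),
               matrix(c(1, 1), 1, 2))
  expect_equal(normalizeRelation(diag(4)), diag(4))
  set.seed(2)
  m <- matrix(runif(20), 5, 4)
  expect_equal(normalizeRelation(m), oracle_two_step_norm(m))
  # zero rows and columns are preserved, not dropped
  m0 <- m; m0[2, ] <- 0
  out <- normalizeRelation(m0)
  expect_equal(out[2, ], rep(0, 4))
  expect_identical(dim(out), dim(m0))
  expect_error(normalizeRelation(matrix(c(-1, 2), 1, 2)), "nonnegative")
})

test_that("an exact low-rank relation is reconstructed within 1%", {
  set.seed(9)
  G0 <- matrix(runif(24), 12, 2); S0 <- matrix(runif(4), 2, 2)
  H0 <- matrix(runif(16), 8, 2)
  R <- G0 %*% S0 %*% t(H0)
  dimnames(R) <- list(paste0("a", 1:12), paste0("b", 1:8))
  gr <- FusionGraph(list(A = rownames(R), B = colnames(R)),
                    list(rel = list(rows = "A", cols = "B", data = R)))
  sys <- fitFusion(gr, ranks = c(A = 2, B = 2), seed = 4, maxit = 2000,
                   tol = 1e-10)
  Rn <- normalizeRelation(R)
  rec <- reconstruct(sys, "rel")
  expect_lt(sqrt(sum((Rn - rec)^2) / sum(Rn^2)), 0.01)
  expect_identical(dim(rec), dim(R))
  expect_true(all(rec >= 0))
  expect_error(reconstruct(sys, "nope"), "unknown relation")
})

test_that("the objective trace never increases", {
  set.seed(4)
  cfg <- generatorConfig(fusionNoiseSd = 0.3, seed = 10)
  fg <- simulateFusionGraph(cfg)
  sys <- fitFusion(fg$graph, ranks = c(gene = 3, substrate = 2), seed = 2)
  expect_true(all(diff(objectiveTrace(sys)) <= 1e-12))
  # and on an arbitrary random graph
  R1 <- matrix(runif(35), 7, 5, dimnames = list(paste0("x", 1:7),
                                                paste0("y", 1:5)))
  R2 <- matrix(runif(49), 7, 7, dimnames = list(paste0("x", 1:7),
                                                paste0("x", 1:7)))
  gr <- FusionGraph(list(X = rownames(R1), Y = colnames(R1)),
                    list(a = list(rows = "X", cols = "Y", data = R1),
                         b = list(rows = "X", cols = "X", data = R2)))
  sys2 <- fitFusion(gr, ranks = c(X = 2, Y = 2), seed = 6)
  expect_true(all(diff(objectiveTrace(sys2)) <= 1e-12))
})

test_that("shared factors carry block structure across relations", {
  cfg <- generatorConfig(fusionNoiseSd = 0, seed = 15)
  fg <- simulateFusionGraph(cfg)
  sys <- fitFusion(fg$graph, ranks = c(gene = 2, substrate = 2), seed = 1)
  # one factor matrix per type, reused by every relation touching it
  expect_named(latentFactors(sys), c("gene", "substrate"))
  blocks <- plantedBlocks(fg$truth)$gene
  d <- cosineDistances(latentFactors(sys)$gene)
  same <- outer(blocks, blocks, `==`); diag(same) <- NA
  expect_lt(mean(d[same & !is.na(same)]), mean(d[!same & !is.na(same)]))
})

test_that("planted blocks are recovered through the full profile pipeline", {
  cfg <- generatorConfig(seed = 11)  # margin 5x the noise SD
  fg <- simulateFusionGraph(cfg)
  sys <- fitFusion(fg$graph, ranks = c(gene = 2, substrate = 2), seed = 1)
  cl <- clusterProfiles(profileDistances(sys, "gene"), k = 2)
  expect_equal(adjustedRand(cl$labels, plantedBlocks(fg$truth)$gene), 1)
})

test_that("profile distances average per-relation cosine distances", {
  cfg <- generatorConfig(seed = 3)
  fg <- simulateFusionGraph(cfg)
  sys <- fitFusion(fg$graph, ranks = c(gene = 2, substrate = 2), seed = 1)
  pd <- profileDistances(sys, "gene")
  expect_setequal(pd@relations, c("activity", "interaction", "binding"))
  manual <- Reduce(`+`, pd@perRelation) / length(pd@perRelation)
  expect_equal(averageDistance(pd), manual)
  d <- averageDistance(pd)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0 & d <= 2))
  expect_error(profileDistances(sys, "nope"), "touches")
})

test_that("cosine distance hits its landmark values", {
  m <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  d <- cosineDistances(m)
  expect_equal(d["a", "b"], 0)  # identical direction
  expect_equal(d["a", "c"], 1)  # orthogonal
  expect_equal(d["a", "d"], 2)  # antiparallel
  expect_warning(dz <- cosineDistances(rbind(a = c(1, 0), z = c(0, 0))),
                 "zero-vector")
  expect_equal(dz["a", "z"], 1)
})

test_that("profile clustering is invariant to input label order", {
  set.seed(8)
  n <- 7
  d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
  rownames(d) <- colnames(d) <- paste0("o", 1:n)
  c1 <- clusterProfiles(d, k = 3)
  perm <- sample(n)
  c2 <- clusterProfiles(d[perm, perm], k = 3)
  expect_equal(adjustedRand(c1$labels, c2$labels), 1)
  expect_identical(c1$order, c2$order)
  # n = 2: a single merge at the pairwise distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  c3 <- clusterProfiles(d2)
  expect_equal(c3$hclust$height, 0.7)
  expect_error(clusterProfiles(d2, k = 5), "cannot cut")
})

test_that("a single square relation reduces to plain tri-factorization", {
  set.seed(12)
  G0 <- matrix(runif(20, 0.1, 1), 10, 2)
  S0 <- matrix(runif(4, 0.1, 1), 2, 2)
  R <- G0 %*% S0 %*% t(G0)
  dimnames(R) <- list(paste0("x", 1:10), paste0("x", 1:10))
  gr <- FusionGraph(list(X = rownames(R)),
                    list(r1 = list(rows = "X", cols = "X", data = R),
                         r2 = list(rows = "X", cols = "X", data = R)))
  # fit only the first relation; the duplicate keeps the >=1-relation graph
  sys <- fitFusion(FusionGraph(list(X = rownames(R)),
                               list(r1 = list(rows = "X", cols = "X",
                                              data = R))),
                   ranks = c(X = 2), seed = 5, maxit = 3000, tol = 1e-12,
                   normalize = FALSE)
  objFit <- sum((R - reconstruct(sys, "r1"))^2)
  oracle <- oracle_nmtf(R, 2, seed = 5, maxit = 3000)
  denom <- sum(R^2)
  expect_lt(abs(objFit - oracle$objective) / denom, 0.01)
})

test_that("degenerate fusion inputs error or warn as promised", {
  R <- matrix(runif(12), 4, 3, dimnames = list(paste0("x", 1:4),
                                               paste0("y", 1:3)))
  gr <- FusionGraph(list(X = rownames(R), Y = colnames(R)),
                    list(a = list(rows = "X", cols = "Y", data = R)))
  expect_error(fitFusion(gr, ranks = c(X = 4, Y = 2), seed = 1), "rank")
  Z <- matrix(0, 4, 3, dimnames = dimnames(R))
  gr2 <- FusionGraph(list(X = rownames(R), Y = colnames(R)),
                     list(a = list(rows = "X", cols = "Y", data = R),
                          z = list(rows = "X", cols = "Y", data = Z)))
  expect_warning(fitFusion(gr2, ranks = c(X = 2, Y = 2), seed = 1),
                 "all-zero")
  expect_error(FusionGraph(list(X = rownames(R)),
                           list(a = list(rows = "X", cols = "Q", data = R))),
               "unknown object type")
})

test_that("held-out rank selection rejects underfitting ranks", {
  set.seed(21)
  G0 <- matrix(runif(24, 0.1, 1), 12, 2); H0 <- matrix(runif(20, 0.1, 1), 10, 2)
  S0 <- matrix(runif(4, 0.1, 1), 2, 2)
  R <- G0 %*% S0 %*% t(H0)
  dimnames(R) <- list(paste0("a", 1:12), paste0("b", 1:10))
  gr <- FusionGraph(list(A = rownames(R), B = colnames(R)),
                    list(rel = list(rows = "A", cols = "B", data = R)))
  # ranks beyond the planted one all explain the held-out entries to noise
  # level; the contract is that a too-small rank is never selected
  ranks <- selectFusionRanks(gr, grid = 1:4, seed = 2, maxit = 800)
  expect_gte(unname(ranks[["A"]]), 2)
  expect_identical(unname(ranks[["A"]]), unname(ranks[["B"]]))
})
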
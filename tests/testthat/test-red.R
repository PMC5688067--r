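test_that("a planted rank-1 logistic landscape is recovered", {
  set.seed(5)
  n <- 8
  g <- sprintf("g%02d", 1:n)
  u <- runif(n, 0.2, 1)
  Z <- outer(u, u)  # symmetric rank-1 latent landscape
  G <- 1.1 * stats::plogis(1.5 * (Z - 0.4))
  dimnames(G) <- list(g, g); diag(G) <- NA
  S <- stats::setNames(rep(0.8, n), g)
  inp <- redInputs(G, S = S)
  fit <- fitLatentModel(inp, rankGrid = 1, seed = 3)
  expect_lt(nrmseByRank(fit)[["1"]], 1e-3)
  expect_identical(selectedRank(fit), 1L)
})

test_that("a constant landscape needs only rank 1", {
  n <- 6; g <- sprintf("g%02d", 1:n)
  G <- matrix(0.5, n, n, dimnames = list(g, g)); diag(G) <- NA
  inp <- redInputs(G, S = stats::setNames(rep(0.7, n), g))
  fit <- fitLatentModel(inp, rankGrid = c(1, 2), seed = 1)
  expect_lt(nrmseByRank(fit)[["1"]], 1e-4)
  expect_identical(selectedRank(fit), 1L)
})

test_that("fits are deterministic and NRMSE is nonincreasing in rank", {
  cfg <- generatorConfig(nGenes = 8, seed = 14)
  sim <- simulateKnockdownPanel(cfg)
  inp <- redInputs(sim$panel)
  f1 <- fitLatentModel(inp, rankGrid = c(1, 2, 4), seed = 9, maxit = 800)
  f2 <- fitLatentModel(inp, rankGrid = c(1, 2, 4), seed = 9, maxit = 800)
  expect_identical(f1@U, f2@U)
  expect_identical(f1@V, f2@V)
  expect_true(all(diff(nrmseByRank(f1)) <= 1e-12))
  expect_true(all(diff(objectiveTrace(f1)) <= 0))
  # the denoised landscape is symmetric
  expect_equal(denoisedViability(f1), t(denoisedViability(f1)))
})

test_that("exact-hypothesis pairs get their hypothesis the top score", {
  g <- c("u1", "v1")
  S <- stats::setNames(c(0.5, 0.9), g)
  mkModel <- function(val) {
    G <- matrix(c(NA, val, val, NA), 2, 2, dimnames = list(g, g))
    new("RedModel", U = matrix(0, 2, 1), V = matrix(0, 2, 1),
        mapParams = c(x0 = 0, k = 1, ceiling = 1), rank = 1,
        nrmseByRank = c("1" = 0), denoised = G, converged = TRUE,
        objTrace = 0)
  }
  mkInputs <- function(val) {
    G <- matrix(c(NA, val, val, NA), 2, 2, dimnames = list(g, g))
    new("RedInputs", G = G, S = S, H = outer(S, S), sigma = 0.02)
  }
  # double equals the product (and differs from both singles): parallel wins
  pr <- resultTable(scoreRelationships(mkModel(0.45), mkInputs(0.45)))
  expect_identical(pr$bestClass, "parallel")
  # double equals the u single: the u-masks-v orientation wins
  pr2 <- resultTable(scoreRelationships(mkModel(0.5), mkInputs(0.5)))
  expect_identical(pr2$bestClass, "u_masks_v")
  expect_gt(pr2$pUMasksV, pr2$pVMasksU)
  # swapping the genes' phenotypes moves the mass to the other orientation
  S2 <- stats::setNames(c(0.9, 0.5), g)
  m3 <- mkModel(0.5); i3 <- mkInputs(0.5); i3@S <- S2; i3@H <- outer(S2, S2)
  pr3 <- resultTable(scoreRelationships(m3, i3))
  expect_identical(pr3$bestClass, "v_masks_u")
  expect_equal(pr3$pVMasksU, pr2$pUMasksV)
  expect_equal(pr3$pUMasksV, pr2$pVMasksU)
})

test_that("relationship probabilities match the direct likelihood oracle", {
  set.seed(31)
  n <- 6; g <- sprintf("g%02d", 1:n)
  S <- stats::setNames(runif(n, 0.4, 0.9), g)
  G <- matrix(runif(n * n, 0.2, 0.9), n, n, dimnames = list(g, g))
  G <- (G + t(G)) / 2; diag(G) <- NA
  model <- new("RedModel", U = matrix(0, n, 1), V = matrix(0, n, 1),
               mapParams = c(x0 = 0, k = 1, ceiling = 1), rank = 1,
               nrmseByRank = c("1" = 0), denoised = G, converged = TRUE,
               objTrace = 0)
  inp <- new("RedInputs", G = G, S = S, H = outer(S, S), sigma = 0.05)
  tb <- resultTable(scoreRelationships(model, inp, sigmaFloor = 0.02))
  for (i in seq_len(nrow(tb))) {
    o <- oracle_relationship_probs(G[tb$geneU[i], tb$geneV[i]],
                                   S[tb$geneU[i]], S[tb$geneV[i]],
                                   sigma = 0.05)
    expect_equal(unname(unlist(tb[i, c("pUMasksV", "pVMasksU", "pParallel",
                                       "pPartial")])), o, tolerance = 1e-12)
  }
  # 4-vectors sum to one (validity enforces it too)
  expect_equal(tb$pUMasksV + tb$pVMasksU + tb$pParallel + tb$pPartial,
               rep(1, nrow(tb)))
})

test_that("noise-free four-way classification recovers every hypothesis", {
  set.seed(77)
  n <- 12; g <- sprintf("g%02d", 1:n)
  S <- stats::setNames(runif(n, 0.4, 0.9), g)
  classes <- rep(c("u_masks_v", "v_masks_u", "parallel", "partial"),
                 length.out = choose(n, 2))
  G <- make_hypothesis_G(S, classes)
  inp <- redInputs(G, S = S)
  fit <- fitLatentModel(inp, rankGrid = c(2, 4, 6, 8, 10, 11), seed = 1)
  suppressMessages(pr <- scoreRelationships(fit, inp))
  acc <- mean(resultTable(pr)$bestClass == classes)
  expect_gte(acc, 0.95)
})

test_that("network construction respects class, orientation and threshold", {
  tb <- data.frame(
    geneU = c("a", "a", "b", "c"), geneV = c("b", "c", "c", "d"),
    pUMasksV = c(0.9, 0.1, 0.2, 0.3), pVMasksU = c(0.05, 0.8, 0.2, 0.3),
    pParallel = c(0.03, 0.05, 0.55, 0.2), pPartial = c(0.02, 0.05, 0.05, 0.2),
    lambda = 0.5, bestClass = "x", stringsAsFactors = FALSE)
  probs <- new("RelationshipProbs", table = tb, sigma = 0.02, penalty = 1)
  net <- inferNetwork(probs, edgeThreshold = 0.5)
  expect_identical(nrow(net), 2L)
  # a masks b: directed edge a -> b; c masks a: directed edge c -> a
  expect_identical(net$from, c("a", "c"))
  expect_identical(net$to, c("b", "a"))
  expect_identical(net$type, c("directed", "directed"))
  # dominant parallel pairs contribute no edge at any threshold
  expect_false(any(net$from == "b" & net$to == "c"))
  # monotone in the threshold
  net3 <- inferNetwork(probs, edgeThreshold = 0.7)
  expect_true(all(paste(net3$from, net3$to) %in% paste(net$from, net$to)))
  # all-parallel input gives an empty network
  tbP <- tb; tbP$pParallel <- 0.97
  tbP$pUMasksV <- tbP$pVMasksU <- tbP$pPartial <- 0.01
  expect_identical(nrow(inferNetwork(new("RelationshipProbs", table = tbP,
                                         sigma = 0.02, penalty = 1))), 0L)
})

test_that("stability classes follow the 40%/20% rule exactly", {
  expect_identical(classifyStability(c(0.45, 0.25, 0.10)),
                   c("solid", "dashed", "absent"))
  expect_identical(classifyStability(c(0.40, 0.399999, 0.20, 0.199999, 0, 1)),
                   c("solid", "dashed", "dashed", "absent", "absent", "solid"))
})

test_that("negligible noise keeps a strong linear pair solid", {
  set.seed(55)
  n <- 8; g <- sprintf("g%02d", 1:n)
  S <- stats::setNames(runif(n, 0.4, 0.9), g)
  classes <- rep("parallel", choose(n, 2))
  pairs <- enumeratePairs(g)
  planted <- which(pairs[, 1] == "g01" & pairs[, 2] == "g02")
  classes[planted] <- "u_masks_v"
  # make the masking unmistakable: g01 weak, g02 strong
  S["g01"] <- 0.45; S["g02"] <- 0.95
  G <- make_hypothesis_G(S, classes)
  inp <- redInputs(G, S = S)
  rep1 <- stabilityAnalysis(inp, rankGrid = c(2, 4, 7), M = 5,
                            noiseGrid = 1e-6, seed = 8, maxit = 1500)
  row <- rep1@perLevel[rep1@perLevel$from == "g01" &
                         rep1@perLevel$to == "g02" &
                         rep1@perLevel$type == "directed", ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$fraction, 1)
  expect_identical(row$class, "solid")
  # M = 1 can only yield fractions 0 or 1
  rep2 <- stabilityAnalysis(inp, rankGrid = 4, M = 1, noiseGrid = 1e-6,
                            seed = 8, maxit = 500)
  expect_true(all(rep2@perLevel$fraction %in% c(0, 1)))
})

test_that("inputs built from a panel satisfy the (G, S, H) contract", {
  cfg <- generatorConfig(nGenes = 6, seed = 17)
  sim <- simulateKnockdownPanel(cfg)
  inp <- redInputs(sim$panel)
  expect_equal(inp@H, outer(inp@S, inp@S))
  expect_true(all(is.na(diag(inp@G))))
  expect_equal(inp@G, t(inp@G))
  expect_gt(inp@sigma, 0)
  key <- pairKeys(sim$panel)[1]
  gs <- strsplit(key, "|", fixed = TRUE)[[1]]
  expect_equal(inp@G[gs[1], gs[2]], unname(rowMeans(doubleViab(sim$panel))[key]))
})
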
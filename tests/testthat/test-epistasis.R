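test_that("batch normalization divides by each batch's control mean", {
  raw <- data.frame(
    batch = c(1, 1, 1, 2, 2, 2),
    geneA = c("scrambled", "gA", "gB", "scrambled", "gC", "gA"),
    geneB = c("", "", "", "", "", "gB"),
    replicate_1 = c(2.0, 1.0, 2.0, 4.0, 1.0, 2.0),
    replicate_2 = c(2.0, 1.0, 2.0, 4.0, 1.0, 2.0),
    stringsAsFactors = FALSE)
  panel <- normalizeToControls(raw, "scrambled")
  expect_equal(unname(singleViab(panel)["gA", ]), c(0.5, 0.5))
  expect_equal(unname(singleViab(panel)["gB", ]), c(1.0, 1.0))  # == control
  expect_equal(unname(singleViab(panel)["gC", ]), c(0.25, 0.25))
  expect_equal(unname(doubleViab(panel)["gA|gB", ]), c(0.5, 0.5))
  expect_equal(mean(panel@controlViab), 1)

  rawBad <- raw; rawBad$replicate_1[1] <- -2; rawBad$replicate_2[1] <- 0
  expect_error(normalizeToControls(rawBad, "scrambled"), "batch '1'")
})

test_that("epsilon is the departure of the double from the product", {
  panel <- make_panel(
    singles = list(gA = c(0.8, 0.8), gB = c(0.5, 0.5),
                   gC = c(1.0, 1.0), gD = c(0.9, 0.9)),
    doubles = list("gA|gB" = c(0.4, 0.4), "gC|gD" = c(0.7, 0.7),
                   "gA|gD" = c(0.95, 0.95)))
  res <- computeEpistasis(panel)
  eps <- epsilonScores(res)
  tb <- resultTable(res)
  expect_equal(unname(tb$expected[match("gA|gB", pairKey(tb$geneA, tb$geneB))]), 0.40)
  expect_equal(unname(eps[["gA|gB"]]), 0)
  expect_equal(unname(eps[["gC|gD"]]), 0.7 - 0.9, tolerance = 1e-12)
  expect_equal(unname(eps[["gA|gD"]]), 0.95 - 0.72, tolerance = 1e-12)
})

test_that("scores are invariant to the order genes appear in a pair", {
  sv <- rbind(gX = c(0.6, 0.62, 0.58), gY = c(0.9, 0.88, 0.92),
              gZ = c(0.7, 0.7, 0.7))
  dv <- rbind(c(0.50, 0.52, 0.48), c(0.61, 0.60, 0.62))
  p1 <- KnockdownPanel(sv, rbind(c("gX", "gY"), c("gY", "gZ")), dv)
  p2 <- KnockdownPanel(sv, rbind(c("gY", "gX"), c("gZ", "gY")), dv)
  r1 <- callInteractions(computeEpistasis(p1), p1)
  r2 <- callInteractions(computeEpistasis(p2), p2)
  expect_identical(resultTable(r1), resultTable(r2))
})

test_that("the Z-test matches a direct independent computation", {
  panel <- make_panel(
    singles = list(gA = c(0.8, 0.8, 0.8), gB = c(0.9, 0.9, 0.9)),
    doubles = list("gA|gB" = c(0.40, 0.42, 0.38)))
  res <- callInteractions(computeEpistasis(panel), panel, alpha = 0.05,
                          seMethod = "replicate")
  tb <- resultTable(res)
  # independent route: the difference 0.40 - 0.72 with only the double's
  # replicate scatter contributing (singles are exactly constant)
  seOracle <- sqrt(stats::var(c(0.40, 0.42, 0.38)) / 3)
  zOracle <- (0.40 - 0.72) / seOracle
  expect_equal(tb$z, zOracle)
  expect_equal(tb$p, 2 * stats::pnorm(-abs(zOracle)))
  expect_identical(tb$call, "aggravating")

  # pooled variance route agrees with the explicit pooled formula
  resP <- callInteractions(computeEpistasis(panel), panel, alpha = 0.05,
                           seMethod = "pooled")
  s2 <- (sum((c(0.40, 0.42, 0.38) - 0.40)^2)) / (3 * 2)  # only nonzero SS
  seP <- sqrt(s2 / 3 + 0.9^2 * s2 / 3 + 0.8^2 * s2 / 3)
  expect_equal(resultTable(resP)$z, (0.4 - 0.72) / seP)
})

test_that("identical observed and expected means give z = 0, p = 1", {
  panel <- make_panel(
    singles = list(gA = c(0.8, 0.9, 1.0), gB = c(0.5, 0.6, 0.7)),
    doubles = list("gA|gB" = c(0.53, 0.54, 0.55)))
  # mean double = 0.54 = 0.9 * 0.6 exactly
  res <- callInteractions(computeEpistasis(panel), panel)
  expect_equal(resultTable(res)$z, 0)
  expect_equal(resultTable(res)$p, 1)
  expect_identical(resultTable(res)$call, "none")
})

test_that("zero-variance nonzero-epsilon pairs are flagged, not infinite", {
  panel <- make_panel(
    singles = list(gA = c(0.8, 0.8), gB = c(0.5, 0.5)),
    doubles = list("gA|gB" = c(0.2, 0.2)))
  expect_warning(res <- callInteractions(computeEpistasis(panel), panel),
                 "degenerate")
  tb <- resultTable(res)
  expect_true(tb$degenerate)
  expect_identical(tb$call, "aggravating")
  expect_false(is.infinite(tb$z) %in% TRUE)
})

test_that("density calling equals the brute-force percentile oracle", {
  set.seed(42)
  eps <- stats::rnorm(100)
  genesA <- sprintf("a%03d", 1:100); genesB <- sprintf("b%03d", 1:100)
  tb <- data.frame(geneA = genesA, geneB = genesB,
                   observed = eps, expected = 0, epsilon = eps,
                   se = NA_real_, z = NA_real_, p = NA_real_,
                   call = "none", degenerate = FALSE, stringsAsFactors = FALSE)
  res <- new("EpistasisResult", table = tb, alpha = NA_real_, method = "",
             coverage = NA_real_, cellLine = "x")
  called <- callInteractions(res, method = "density", coverage = 0.90)
  expect_identical(unname(interactionCalls(called) != "none"),
                   unname(oracle_density_outside(eps, 0.90)))
  called95 <- callInteractions(res, method = "density", coverage = 0.95)
  # the strict set nests inside the loose set
  expect_true(all(significantPairs(called95) %in% significantPairs(called)))
})

test_that("null panels with noise are called at the nominal rate", {
  panel <- simulateNullScreen(1000, seed = 19)
  res <- computeEpistasis(panel)
  for (a in c(0.05, 0.1)) {
    rate <- mean(interactionCalls(callInteractions(res, panel, alpha = a))
                 != "none")
    expect_lt(abs(rate - a), 3 * sqrt(a * (1 - a) / 1000))
  }
})

test_that("equal-width bins follow the declared boundary rule", {
  eps <- c(-0.5, -0.31, -0.3, -0.1, 0.1, 0.3, 0.5, 0.0, 0.25, -0.05)
  tb <- data.frame(geneA = sprintf("a%02d", 1:10), geneB = sprintf("b%02d", 1:10),
                   observed = eps, expected = 0, epsilon = eps,
                   se = NA_real_, z = NA_real_, p = NA_real_,
                   call = "none", degenerate = FALSE, stringsAsFactors = FALSE)
  res <- new("EpistasisResult", table = tb, alpha = NA_real_, method = "",
             coverage = NA_real_, cellLine = "x")
  b <- binScores(res, nBins = 5)
  expect_equal(b$edges, seq(-0.5, 0.5, by = 0.2))
  k <- stats::setNames(b$bins, NULL)
  expect_identical(k[1], 1L)            # minimum in bin 1
  expect_identical(k[7], 5L)            # maximum in bin 5
  expect_identical(k[3], 1L)            # -0.3 sits on the right edge of bin 1
  expect_identical(k[2], 1L)
  expect_identical(sum(b$counts), 10L)  # partition
  # constant scores collapse to one degenerate bin
  tb$epsilon <- tb$observed <- rep(0.2, 10)
  resC <- new("EpistasisResult", table = tb, alpha = NA_real_, method = "",
              coverage = NA_real_, cellLine = "x")
  expect_warning(bC <- binScores(resC), "degenerate")
  expect_true(all(bC$bins == 1L))
})

test_that("per-bin covariate summaries match the declared quantile rule", {
  bins <- stats::setNames(c(1L, 1L, 1L, 2L, 2L), paste0("p", 1:5))
  vals <- stats::setNames(c(1, 2, 3, 7, 7), paste0("p", 1:5))
  s <- compareBins(bins, vals)
  expect_equal(s$median, c(2, 7))
  expect_equal(s$q1[1], stats::quantile(1:3, 0.25, type = 7, names = FALSE))
  expect_equal(s$n, c(3L, 2L))
  # constant covariate: every bin median equals the constant
  s2 <- compareBins(bins, stats::setNames(rep(3, 5), paste0("p", 1:5)))
  expect_true(all(s2$median == 3))
  # empty bins are reported with n = 0 and no summary
  bins3 <- stats::setNames(c(1L, 3L), c("p1", "p2"))
  s3 <- compareBins(bins3, stats::setNames(c(1, 2), c("p1", "p2")))
  expect_identical(s3$n[2], 0L)
  expect_true(is.na(s3$median[2]))
})

test_that("cross-line Spearman matches the rank-then-Pearson oracle", {
  set.seed(11)
  eps1 <- stats::rnorm(50)
  eps2 <- eps1^3 + stats::rnorm(50, 0, 0.3)  # noisy monotone transform
  mk <- function(e) {
    tb <- data.frame(geneA = sprintf("a%02d", 1:50), geneB = sprintf("b%02d", 1:50),
                     observed = e, expected = 0, epsilon = e,
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     call = "none", degenerate = FALSE, stringsAsFactors = FALSE)
    new("EpistasisResult", table = tb, alpha = NA_real_, method = "",
        coverage = NA_real_, cellLine = "x")
  }
  rho <- pairwiseSpearman(list(A = mk(eps1), B = mk(eps2), C = mk(-eps1)))
  expect_equal(diag(rho), c(A = 1, B = 1, C = 1))
  expect_equal(rho, t(rho))
  expect_equal(rho["A", "B"], oracle_spearman(eps1, eps2))
  expect_equal(rho["A", "C"], -1)
})

test_that("Venn region counts equal exhaustive enumeration", {
  expect_equal(
    as.list(overlapCounts(list(X = c("AB", "BC"), Y = c("BC", "CD")))),
    list(X = 1L, Y = 1L, `X&Y` = 1L))
  s4 <- c("p1", "p2", "p3", "p4")
  tri <- overlapCounts(list(A = s4, B = s4, C = s4))
  expect_equal(unname(tri[["A&B&C"]]), 4L)
  expect_true(all(tri[names(tri) != "A&B&C"] == 0L))
  set.seed(3)
  universe <- sprintf("e%02d", 1:30)
  sets <- list(A = sample(universe, 12), B = sample(universe, 9),
               C = sample(universe, 15))
  got <- overlapCounts(sets)
  want <- oracle_venn(sets)
  for (nm in names(want)) expect_equal(unname(got[[nm]]), want[[nm]])
  expect_equal(sum(got), length(unique(unlist(sets))))
})

test_that("network export produces nested two-tier edge sets", {
  panel <- simulateNullScreen(30, noiseSd = 0.02, seed = 23)
  res <- callInteractions(computeEpistasis(panel), panel, alpha = 0.05)
  net <- exportNetwork(res)
  tb <- resultTable(res)
  strictKeys <- pairKey(tb$geneA, tb$geneB)[tb$p < 0.05]
  looseKeys <- pairKey(tb$geneA, tb$geneB)[tb$p < 0.1]
  edgeKeys <- pairKey(net$edges$geneA, net$edges$geneB)
  expect_setequal(edgeKeys, looseKeys)
  expect_setequal(edgeKeys[net$edges$tier == "strict"], strictKeys)
  expect_true(all(net$edges$geneA %in% net$nodes &
                    net$edges$geneB %in% net$nodes))
  # no significant pairs -> empty edge set, full node set
  panel0 <- simulateNullScreen(25, noiseSd = 0, seed = 2)
  res0 <- callInteractions(computeEpistasis(panel0), panel0)
  net0 <- exportNetwork(res0)
  expect_identical(nrow(net0$edges), 0L)
  expect_length(net0$nodes, 50)
  # files are written where asked
  f <- tempfile(fileext = ".tsv"); g <- tempfile(fileext = ".graphml")
  exportNetwork(res, file = f, graphmlFile = g)
  expect_true(file.exists(f) && file.exists(g))
  expect_equal(nrow(utils::read.delim(f)), nrow(net$edges))
})
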
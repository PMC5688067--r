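## Synthetic screen generator: every input the pipeline consumes, with
## planted ground truth, so downstream recovery is testable without the
## original screens.

#' Generator configuration for the synthetic screen suite
#'
#' Bundles every tunable of the synthetic generators with validation. One
#' master `seed` drives all generators; each draws from a deterministic
#' substream so components are independently reproducible.
#'
#' @param nGenes number of knockdown targets (>= 3).
#' @param nReplicates technical replicates per measurement (>= 2).
#' @param noiseSd Gaussian replicate noise SD on the viability scale.
#' @param singleRange interval (within (0, 1.2]) the single-knockdown mean
#'   viabilities are drawn from.
#' @param nAggravating,nAlleviating planted interacting pairs per class.
#' @param effectSize absolute planted epistasis effect |eps*|.
#' @param phases ordered cell-cycle phase labels.
#' @param phaseControl control phase-fraction vector (must sum to 1).
#' @param phaseNoiseSd log-ratio noise SD for phase fractions.
#' @param phaseEffect planted per-phase deviation for interacting pairs.
#' @param fusionSpec named list, one entry per object type:
#'   `list(n = objects, blocks = planted blocks)`.
#' @param fusionRelations list of `list(name, rows, cols)` describing which
#'   types each synthetic relation links.
#' @param blockBase,blockMargin between-block mean and within-block margin of
#'   the planted block matrices.
#' @param fusionNoiseSd Gaussian noise SD on relation entries.
#' @param nLeaves leaves of the synthetic phylogeny (2..nGenes).
#' @param nNormal,nTumor expression samples per condition.
#' @param nDeGenes,deLfc planted differentially expressed genes and their
#'   log2 fold change.
#' @param exprNoiseSd per-sample log2 expression noise SD.
#' @param activityGain,activityNoiseSd fold gain of active enzyme/substrate
#'   combinations and absorbance noise SD.
#' @param seed master integer seed.
#' @return a validated `GeneratorConfig` (list subclass).
#' @export
generatorConfig <- function(nGenes = 24, nReplicates = 3, noiseSd = 0.05,
                            singleRange = c(0.4, 1.0),
                            nAggravating = 3, nAlleviating = 3,
                            effectSize = 0.3,
                            phases = c("sub-G0/G1", "G1", "S", "G2/M", ">4N"),
                            phaseControl = c(0.05, 0.40, 0.20, 0.30, 0.05),
                            phaseNoiseSd = 0.05, phaseEffect = 0.1,
                            fusionSpec = list(
                              gene = list(n = 12, blocks = 2),
                              substrate = list(n = 8, blocks = 2)),
                            fusionRelations = NULL,
                            blockBase = 0.5, blockMargin = 0.5,
                            fusionNoiseSd = 0.1,
                            nLeaves = min(nGenes, 10),
                            nNormal = 6, nTumor = 6,
                            nDeGenes = 5, deLfc = 2, exprNoiseSd = 0.3,
                            activityGain = 2, activityNoiseSd = 0.02,
                            seed = 1L) {
  stopifnot(nGenes >= 3, nReplicates >= 2, noiseSd >= 0,
            length(singleRange) == 2, singleRange[1] < singleRange[2],
            singleRange[1] > 0, singleRange[2] <= 1.2,
            nAggravating >= 0, nAlleviating >= 0, effectSize >= 0,
            length(phases) >= 1, length(phaseControl) == length(phases),
            all(phaseControl > 0), abs(sum(phaseControl) - 1) < 1e-9,
            phaseNoiseSd >= 0, phaseEffect >= 0,
            blockMargin >= 0, fusionNoiseSd >= 0,
            nLeaves >= 2, nNormal >= 2, nTumor >= 2,
            nDeGenes >= 0, exprNoiseSd >= 0, activityGain > 0)
  if (is.null(fusionRelations)) {
    tn <- names(fusionSpec)
    if (length(tn) < 2) stop("fusionSpec needs at least two object types")
    fusionRelations <- list(
      list(name = "activity", rows = tn[1], cols = tn[2]),
      list(name = "interaction", rows = tn[1], cols = tn[1]),
      list(name = "binding", rows = tn[1], cols = tn[2]))
  }
  for (rel in fusionRelations)
    if (!all(c(rel$rows, rel$cols) %in% names(fusionSpec)))
      stop("fusion relation '", rel$name, "' names a type absent from fusionSpec")
  cfg <- list(nGenes = nGenes, nReplicates = nReplicates, noiseSd = noiseSd,
              singleRange = singleRange, nAggravating = nAggravating,
              nAlleviating = nAlleviating, effectSize = effectSize,
              phases = phases, phaseControl = phaseControl,
              phaseNoiseSd = phaseNoiseSd, phaseEffect = phaseEffect,
              fusionSpec = fusionSpec, fusionRelations = fusionRelations,
              blockBase = blockBase, blockMargin = blockMargin,
              fusionNoiseSd = fusionNoiseSd, nLeaves = nLeaves,
              nNormal = nNormal, nTumor = nTumor, nDeGenes = nDeGenes,
              deLfc = deLfc, exprNoiseSd = exprNoiseSd,
              activityGain = activityGain, activityNoiseSd = activityNoiseSd,
              seed = as.integer(seed))
  class(cfg) <- c("GeneratorConfig", "list")
  cfg
}

.geneNames <- function(cfg) sprintf("g%02d", seq_len(cfg$nGenes))

# Gaussian replicate draws around `means`, truncated at 0 by resampling.
.replicateDraws <- function(means, nRep, sd) {
  m <- matrix(rep(means, nRep), nrow = length(means)) +
    matrix(stats::rnorm(length(means) * nRep, 0, sd), nrow = length(means))
  while (any(m < 0)) {
    neg <- which(m < 0)
    m[neg] <- rep(means, nRep)[neg] + stats::rnorm(length(neg), 0, sd)
  }
  m
}

#' Simulate a pairwise knockdown viability panel with planted interactions
#'
#' Single-knockdown mean viabilities are drawn uniformly from
#' `cfg$singleRange`; every non-planted pair's mean is exactly the product of
#' its single means (the multiplicative null) and planted pairs deviate from
#' the product by their effect size (negative for aggravating, positive for
#' alleviating). Each measurement receives `cfg$nReplicates` Gaussian
#' replicate draws (SD `cfg$noiseSd`, truncated at 0 by resampling). The
#' negative control has mean exactly 1.
#'
#' Aggravating pairs are planted only on pairs whose product of single means
#' supports the full effect without crossing 0; if no such pair exists the
#' configuration is rejected.
#'
#' @param cfg a [generatorConfig()].
#' @return `list(panel = KnockdownPanel, truth = TruthSet)`.
#' @export
simulateKnockdownPanel <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(.substream(cfg$seed, 1))
  g <- .geneNames(cfg)
  singleMeans <- stats::setNames(
    stats::runif(cfg$nGenes, cfg$singleRange[1], cfg$singleRange[2]), g)
  pairs <- enumeratePairs(g)
  pairMeans <- singleMeans[pairs[, 1]] * singleMeans[pairs[, 2]]

  nPlant <- cfg$nAggravating + cfg$nAlleviating
  if (nPlant > nrow(pairs))
    stop("more planted pairs requested than pairs available")
  effects <- numeric(nrow(pairs))
  classes <- character(0); plantedIdx <- integer(0)
  if (cfg$nAggravating > 0) {
    eligible <- which(pairMeans - cfg$effectSize >= 0)
    if (length(eligible) < cfg$nAggravating)
      stop("configuration error: effect size ", cfg$effectSize,
           " pushes aggravating double-knockdown means below 0 for all ",
           "candidate pairs; reduce effectSize or raise singleRange")
    idx <- sample(eligible, cfg$nAggravating)
    effects[idx] <- -cfg$effectSize
    plantedIdx <- idx; classes <- rep("aggravating", cfg$nAggravating)
  }
  if (cfg$nAlleviating > 0) {
    idx <- sample(setdiff(seq_len(nrow(pairs)), plantedIdx), cfg$nAlleviating)
    effects[idx] <- cfg$effectSize
    plantedIdx <- c(plantedIdx, idx)
    classes <- c(classes, rep("alleviating", cfg$nAlleviating))
  }
  pairMeans <- pairMeans + effects

  singleViab <- .replicateDraws(singleMeans, cfg$nReplicates, cfg$noiseSd)
  rownames(singleViab) <- g
  colnames(singleViab) <- paste0("replicate_", seq_len(cfg$nReplicates))
  doubleViab <- .replicateDraws(pairMeans, cfg$nReplicates, cfg$noiseSd)
  colnames(doubleViab) <- colnames(singleViab)
  ctrl <- 1 + stats::rnorm(cfg$nReplicates, 0, cfg$noiseSd)
  while (any(ctrl <= 0)) ctrl[ctrl <= 0] <- 1 + stats::rnorm(sum(ctrl <= 0), 0, cfg$noiseSd)
  ctrl <- ctrl / mean(ctrl)  # per-batch normalization fixes the control mean at 1

  panel <- KnockdownPanel(singleViab, pairs, doubleViab, controlViab = ctrl)
  truth <- new("TruthSet",
               interactions = data.frame(
                 geneA = pairs[plantedIdx, 1], geneB = pairs[plantedIdx, 2],
                 class = classes, effect = effects[plantedIdx],
                 stringsAsFactors = FALSE),
               blocks = list(), deGenes = data.frame(gene = character(),
                                                     lfc = numeric()),
               seed = cfg$seed)
  list(panel = panel, truth = truth)
}

#' Simulate many independent null gene pairs
#'
#' A calibration panel: `nPairs` disjoint gene pairs, each with its own two
#' single knockdowns and a double knockdown whose mean is exactly the
#' product of the single means (no interaction anywhere).
#'
#' @param nPairs number of non-interacting pairs.
#' @param nReplicates,noiseSd,singleRange,seed as in [generatorConfig()].
#' @return a [KnockdownPanel-class].
#' @export
simulateNullScreen <- function(nPairs, nReplicates = 3, noiseSd = 0.05,
                               singleRange = c(0.4, 1.0), seed = 1L) {
  stopifnot(nPairs >= 1, nReplicates >= 2, noiseSd >= 0)
  set.seed(.substream(seed, 11))
  gA <- sprintf("p%05d_a", seq_len(nPairs))
  gB <- sprintf("p%05d_b", seq_len(nPairs))
  mA <- stats::runif(nPairs, singleRange[1], singleRange[2])
  mB <- stats::runif(nPairs, singleRange[1], singleRange[2])
  singleMeans <- stats::setNames(c(mA, mB), c(gA, gB))
  ord <- order(names(singleMeans))
  singleViab <- .replicateDraws(singleMeans[ord], nReplicates, noiseSd)
  rownames(singleViab) <- names(singleMeans)[ord]
  colnames(singleViab) <- paste0("replicate_", seq_len(nReplicates))
  doubleViab <- .replicateDraws(mA * mB, nReplicates, noiseSd)
  colnames(doubleViab) <- colnames(singleViab)
  KnockdownPanel(singleViab, cbind(gA, gB), doubleViab)
}

#' Simulate a cell-cycle phase-fraction table under the per-phase null
#'
#' The control fraction vector is a fixed simplex point
#' (`cfg$phaseControl`). Single knockdowns perturb the control through
#' log-ratio noise and renormalization (keeping vectors on the simplex);
#' each double knockdown follows the per-phase multiplicative null on
#' control-relative ratios, with a planted deviation of `cfg$phaseEffect`
#' for the pairs recorded in `truth` (aggravating pairs gain sub-G0/G1
#' fraction, emulating increased cell death; alleviating pairs gain fraction
#' in the second phase, emulating arrest) before renormalization.
#'
#' @param cfg a [generatorConfig()].
#' @param truth the [TruthSet-class] from [simulateKnockdownPanel()].
#' @return a [CellCycleTable-class] with replicate fraction matrices.
#' @export
simulateCellCycleTable <- function(cfg, truth) {
  stopifnot(inherits(cfg, "GeneratorConfig"), is(truth, "TruthSet"))
  set.seed(.substream(cfg$seed, 2))
  g <- .geneNames(cfg)
  nP <- length(cfg$phases)
  F0 <- cfg$phaseControl

  perturb <- function(f) {
    v <- f * exp(stats::rnorm(nP, 0, cfg$phaseNoiseSd))
    v / sum(v)
  }
  singles <- t(vapply(g, function(.) perturb(F0), numeric(nP)))

  pairs <- enumeratePairs(g)
  keys <- pairKey(pairs[, 1], pairs[, 2])
  planted <- plantedInteractions(truth)
  plantedKeys <- if (nrow(planted)) pairKey(planted$geneA, planted$geneB) else character()

  doubles <- matrix(0, nrow(pairs), nP, dimnames = list(keys, cfg$phases))
  clipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    rA <- singles[pairs[i, 1], ] / F0
    rB <- singles[pairs[i, 2], ] / F0
    e <- rA * rB * F0
    e <- e / sum(e)  # compositional closure of the null expectation
    j <- match(keys[i], plantedKeys)
    if (!is.na(j)) {
      k <- if (planted$class[j] == "aggravating") 1L else min(2L, nP)
      e[k] <- e[k] + cfg$phaseEffect
    }
    if (any(e < 0)) { e[e < 0] <- 0; clipped <- clipped + 1L }
    doubles[i, ] <- e / sum(e)
  }
  if (clipped > 0)
    message(clipped, " double-knockdown vector(s) had negative intermediate ",
            "fractions; renormalized after clipping")

  truthMat <- rbind(control = F0, singles, doubles)
  colnames(truthMat) <- cfg$phases
  reps <- lapply(seq_len(cfg$nReplicates), function(.) {
    t(apply(truthMat, 1, perturb))
  })
  fr <- Reduce(`+`, reps) / length(reps)
  fr <- fr / rowSums(fr)
  CellCycleTable(fr, controlLabel = "control", replicates = reps)
}

#' Simulate a multi-relational fusion-graph collection with planted blocks
#'
#' Each relation matrix is a planted block matrix: entries have mean
#' `blockBase`, raised by `blockMargin` when the row and column objects
#' carry the same block label, plus Gaussian noise clipped at 0.
#'
#' @param cfg a [generatorConfig()].
#' @return `list(graph = FusionGraph, truth = TruthSet)` where the truth
#'   records the block label of every object of every type.
#' @export
simulateFusionGraph <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (length(cfg$fusionSpec) < 2 || length(cfg$fusionRelations) < 2)
    stop("fusion generation needs >= 2 object types and >= 2 relations")
  set.seed(.substream(cfg$seed, 3))
  objectTypes <- list(); blocks <- list()
  for (tn in names(cfg$fusionSpec)) {
    sp <- cfg$fusionSpec[[tn]]
    objs <- sprintf("%s%02d", tn, seq_len(sp$n))
    objectTypes[[tn]] <- objs
    blocks[[tn]] <- stats::setNames(
      sprintf("B%d", rep_len(seq_len(sp$blocks), sp$n)), objs)
  }
  relations <- list()
  for (rel in cfg$fusionRelations) {
    bi <- blocks[[rel$rows]]; bj <- blocks[[rel$cols]]
    same <- outer(bi, bj, `==`)
    m <- cfg$blockBase + cfg$blockMargin * same +
      matrix(stats::rnorm(length(same), 0, cfg$fusionNoiseSd),
             nrow = nrow(same))
    m[m < 0] <- 0
    dimnames(m) <- list(objectTypes[[rel$rows]], objectTypes[[rel$cols]])
    relations[[rel$name]] <- list(rows = rel$rows, cols = rel$cols, data = m)
  }
  graph <- FusionGraph(objectTypes, relations)
  truth <- new("TruthSet", interactions = data.frame(
    geneA = character(), geneB = character(), class = character(),
    effect = numeric()), blocks = blocks,
    deGenes = data.frame(gene = character(), lfc = numeric()),
    seed = cfg$seed)
  list(graph = graph, truth = truth)
}

#' Simulate a random phylogeny over the panel genes
#'
#' @param cfg a [generatorConfig()]; uses `cfg$nLeaves` leaves labelled with
#'   the first panel gene names.
#' @return newick text with positive branch lengths.
#' @export
simulateTree <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (cfg$nLeaves > cfg$nGenes)
    stop("nLeaves cannot exceed nGenes (leaf labels reuse panel gene names)")
  set.seed(.substream(cfg$seed, 4))
  tr <- ape::rtree(cfg$nLeaves, tip.label = .geneNames(cfg)[seq_len(cfg$nLeaves)])
  ape::write.tree(tr)
}

#' Simulate raw enzyme-activity absorbances and a matched expression pair
#'
#' The activity table mimics a coupled-enzyme absorbance plate: one signal
#' column and one no-coupling-enzyme control column per substrate, with
#' group-structured activity (enzyme group b is active on substrate group b,
#' multiplying the control level by `1 + activityGain`). The expression pair
#' carries planted log2 fold changes on `cfg$nDeGenes` genes.
#'
#' @param cfg a [generatorConfig()].
#' @return list with `activityRaw` (enzymes x columns matrix),
#'   `controlMap` (named vector: signal column -> control column),
#'   `expression` ([ExpressionPair-class]) and `truth` ([TruthSet-class]
#'   recording DE genes and activity group labels).
#' @export
simulateActivityExpression <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(.substream(cfg$seed, 5))
  enzymes <- .geneNames(cfg)
  nSub <- cfg$fusionSpec[[min(2, length(cfg$fusionSpec))]]$n
  substrates <- sprintf("sub%02d", seq_len(nSub))
  nGroups <- 3L
  eGroup <- stats::setNames(rep_len(seq_len(nGroups), length(enzymes)), enzymes)
  sGroup <- stats::setNames(rep_len(seq_len(nGroups), nSub), substrates)

  raw <- matrix(0, length(enzymes), 2 * nSub,
                dimnames = list(enzymes,
                                as.vector(rbind(substrates,
                                                paste0(substrates, "_ctrl")))))
  for (s in substrates) {
    ctrl <- pmax(0.3 + stats::rnorm(length(enzymes), 0, cfg$activityNoiseSd), 1e-3)
    active <- eGroup == sGroup[s]
    sig <- pmax(ctrl * (1 + cfg$activityGain * active) +
                  stats::rnorm(length(enzymes), 0, cfg$activityNoiseSd), 0)
    raw[, s] <- sig
    raw[, paste0(s, "_ctrl")] <- ctrl
  }
  controlMap <- stats::setNames(paste0(substrates, "_ctrl"), substrates)

  deIdx <- if (cfg$nDeGenes > 0) sample(length(enzymes), cfg$nDeGenes) else integer()
  lfc <- numeric(length(enzymes))
  lfc[deIdx] <- cfg$deLfc
  base <- stats::runif(length(enzymes), 3, 8)
  normal <- matrix(base, length(enzymes), cfg$nNormal) +
    matrix(stats::rnorm(length(enzymes) * cfg$nNormal, 0, cfg$exprNoiseSd),
           length(enzymes))
  tumor <- matrix(base + lfc, length(enzymes), cfg$nTumor) +
    matrix(stats::rnorm(length(enzymes) * cfg$nTumor, 0, cfg$exprNoiseSd),
           length(enzymes))
  dimnames(normal) <- list(enzymes, paste0("N", seq_len(cfg$nNormal)))
  dimnames(tumor) <- list(enzymes, paste0("T", seq_len(cfg$nTumor)))

  truth <- new("TruthSet", interactions = data.frame(
    geneA = character(), geneB = character(), class = character(),
    effect = numeric()),
    blocks = list(enzyme = stats::setNames(sprintf("B%d", eGroup), enzymes),
                  substrate = stats::setNames(sprintf("B%d", sGroup), substrates)),
    deGenes = data.frame(gene = enzymes[deIdx], lfc = rep(cfg$deLfc,
                                                          length(deIdx))),
    seed = cfg$seed)
  list(activityRaw = raw, controlMap = controlMap,
       expression = ExpressionPair(normal, tumor), truth = truth)
}

#' Precision/recall of an interaction caller against planted truth
#'
#' @param truth a [TruthSet-class] with planted interactions.
#' @param result a called [EpistasisResult-class].
#' @return list with `precision`, `recall`, `signAccuracy` (fraction of
#'   recovered planted pairs whose called class matches the planted class)
#'   and the counts behind them.
#' @export
truthRecovery <- function(truth, result) {
  planted <- plantedInteractions(truth)
  tb <- resultTable(result)
  calledKeys <- pairKey(tb$geneA, tb$geneB)[tb$call != "none"]
  calledClass <- stats::setNames(tb$call, pairKey(tb$geneA, tb$geneB))
  plantedKeys <- pairKey(planted$geneA, planted$geneB)
  tp <- intersect(calledKeys, plantedKeys)
  precision <- if (length(calledKeys)) length(tp) / length(calledKeys) else NA_real_
  recall <- if (length(plantedKeys)) length(tp) / length(plantedKeys) else NA_real_
  signAcc <- if (length(tp)) {
    mean(calledClass[tp] == planted$class[match(tp, plantedKeys)])
  } else NA_real_
  list(precision = precision, recall = recall, signAccuracy = signAcc,
       nCalled = length(calledKeys), nPlanted = length(plantedKeys),
       nRecovered = length(tp))
}
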
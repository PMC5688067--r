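#' @import methods
NULL

## ---------------------------------------------------------------------------
## KnockdownPanel: replicate single/double knockdown viabilities
## ---------------------------------------------------------------------------

#' KnockdownPanel: control-normalized single and double knockdown viabilities
#'
#' Container for a pairwise knockdown screen. Viabilities are unitless,
#' normalized to the negative (non-targeting) control, with technical
#' replicates in columns. Double knockdowns are keyed by canonical unordered
#' pairs; not every pair needs to be measured.
#'
#' @slot genes character vector of knocked-down gene identifiers.
#' @slot singleViab numeric matrix, genes x replicates.
#' @slot pairGenes character matrix, measured pairs x 2 (canonical order).
#' @slot doubleViab numeric matrix, measured pairs x replicates; rownames are
#'   [pairKey()] keys.
#' @slot controlViab numeric vector of negative-control replicates (mean 1
#'   after normalization); may be empty.
#' @slot controlLabel,cellLine single-character annotations.
#' @export
setClass("KnockdownPanel", representation(
  genes = "character",
  singleViab = "matrix",
  pairGenes = "matrix",
  doubleViab = "matrix",
  controlViab = "numeric",
  controlLabel = "character",
  cellLine = "character"
))

setValidity("KnockdownPanel", function(object) {
  msg <- character()
  g <- object@genes
  if (anyDuplicated(g)) msg <- c(msg, "gene identifiers must be unique")
  if (!identical(rownames(object@singleViab), g))
    msg <- c(msg, "singleViab rownames must equal genes")
  if (any(object@singleViab < 0) || any(object@doubleViab < 0) ||
      any(object@controlViab < 0))
    msg <- c(msg, "viabilities must be nonnegative")
  if (nrow(object@doubleViab) != nrow(object@pairGenes))
    msg <- c(msg, "doubleViab and pairGenes must have matching rows")
  if (nrow(object@pairGenes) > 0) {
    if (!all(object@pairGenes %in% g))
      msg <- c(msg, "every measured pair's genes must appear in genes")
    if (any(object@pairGenes[, 1] == object@pairGenes[, 2]))
      msg <- c(msg, "self-pairs are not allowed")
    keys <- pairKey(object@pairGenes[, 1], object@pairGenes[, 2])
    if (!identical(rownames(object@doubleViab), keys))
      msg <- c(msg, "doubleViab rownames must be the canonical pair keys")
    if (anyDuplicated(keys)) msg <- c(msg, "duplicate pair measurements")
  }
  if (length(object@controlViab) > 0 &&
      abs(mean(object@controlViab) - 1) > 1e-6)
    msg <- c(msg, "negative-control replicates must average 1 after normalization")
  if (length(msg)) msg else TRUE
})

#' Construct a KnockdownPanel
#'
#' @param singleViab numeric matrix of single-knockdown viabilities
#'   (genes x replicates, rownames = gene identifiers).
#' @param pairGenes two-column character matrix of measured gene pairs.
#' @param doubleViab numeric matrix of double-knockdown viabilities, one row
#'   per row of `pairGenes`.
#' @param controlViab optional numeric vector of normalized negative-control
#'   replicates (mean 1).
#' @param controlLabel,cellLine annotation strings.
#' @return a [KnockdownPanel-class] object.
#' @export
KnockdownPanel <- function(singleViab, pairGenes, doubleViab,
                           controlViab = numeric(),
                           controlLabel = "scrambled", cellLine = "synthetic") {
  singleViab <- as.matrix(singleViab)
  pairGenes <- as.matrix(pairGenes)
  doubleViab <- as.matrix(doubleViab)
  storage.mode(pairGenes) <- "character"
  if (nrow(pairGenes) > 0) {
    swap <- pairGenes[, 1] > pairGenes[, 2]
    pairGenes[swap, ] <- pairGenes[swap, 2:1]
    rownames(doubleViab) <- pairKey(pairGenes[, 1], pairGenes[, 2])
    colnames(pairGenes) <- c("geneA", "geneB")
  }
  new("KnockdownPanel", genes = rownames(singleViab),
      singleViab = singleViab, pairGenes = pairGenes,
      doubleViab = doubleViab, controlViab = as.numeric(controlViab),
      controlLabel = controlLabel, cellLine = cellLine)
}

## ---------------------------------------------------------------------------
## EpistasisResult
## ---------------------------------------------------------------------------

#' EpistasisResult: multiplicative-null scores and interaction calls
#'
#' One row per measured pair with the expected viability under the
#' multiplicative null, the epistasis score epsilon = mean(W_ab) - E(W_ab),
#' and (after [callInteractions()]) the test statistic, p-value and call.
#'
#' @slot table data.frame with columns geneA, geneB, observed, expected,
#'   epsilon, se, z, p, call, degenerate.
#' @slot alpha significance level used for calling (NA before calling).
#' @slot method "ztest" or "density" (empty before calling).
#' @slot coverage central-region coverage for the density method.
#' @slot cellLine annotation string.
#' @export
setClass("EpistasisResult", representation(
  table = "data.frame", alpha = "numeric", method = "character",
  coverage = "numeric", cellLine = "character"
))

setValidity("EpistasisResult", function(object) {
  tb <- object@table
  need <- c("geneA", "geneB", "observed", "expected", "epsilon", "call")
  if (!all(need %in% names(tb))) return("result table is missing columns")
  msg <- character()
  if (any(abs(tb$epsilon - (tb$observed - tb$expected)) > 1e-9))
    msg <- c(msg, "epsilon must equal observed - expected")
  if ("p" %in% names(tb)) {
    p <- tb$p[!is.na(tb$p)]
    if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  }
  bad <- (tb$call == "aggravating" & tb$epsilon >= 0) |
         (tb$call == "alleviating" & tb$epsilon <= 0)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "call sign must match the sign of epsilon")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CellCycleTable
## ---------------------------------------------------------------------------

#' CellCycleTable: per-knockdown cell-cycle phase fractions
#'
#' Compositional phase-fraction vectors (rows sum to 1) for a control, the
#' single knockdowns and the double knockdowns of a screen. Row names use
#' gene identifiers for singles and [pairKey()] keys for doubles; the control
#' row is named by `controlLabel`.
#'
#' @slot phases ordered character vector of phase labels.
#' @slot fractions numeric matrix, knockdowns x phases.
#' @slot replicates optional list of replicate fraction matrices (same shape
#'   as `fractions`), one per technical replicate.
#' @slot controlLabel row name of the control vector.
#' @export
setClass("CellCycleTable", representation(
  phases = "character", fractions = "matrix",
  replicates = "list", controlLabel = "character"
))

setValidity("CellCycleTable", function(object) {
  msg <- character()
  if (!identical(colnames(object@fractions), object@phases))
    msg <- c(msg, "fraction columns must match the phase labels")
  if (any(object@fractions < 0)) msg <- c(msg, "fractions must be nonnegative")
  if (any(abs(rowSums(object@fractions) - 1) > 1e-6))
    msg <- c(msg, "each fraction vector must sum to 1")
  if (!object@controlLabel %in% rownames(object@fractions))
    msg <- c(msg, "control row missing from the table")
  if (length(msg)) msg else TRUE
})

#' Construct a CellCycleTable
#' @param fractions knockdowns x phases matrix of fractions (rows sum to 1).
#' @param controlLabel row name of the control vector.
#' @param replicates optional list of per-replicate fraction matrices.
#' @return a [CellCycleTable-class] object.
#' @export
CellCycleTable <- function(fractions, controlLabel = "control",
                           replicates = list()) {
  fractions <- as.matrix(fractions)
  new("CellCycleTable", phases = colnames(fractions), fractions = fractions,
      replicates = replicates, controlLabel = controlLabel)
}

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' TruthSet: planted ground truth of the synthetic generators
#'
#' Records everything needed to score downstream recovery: planted
#' interactions with their class and effect size, planted block labels per
#' object type, planted differentially expressed genes, and the master seed.
#'
#' @slot interactions data.frame(geneA, geneB, class, effect); aggravating
#'   effects are negative, alleviating positive.
#' @slot blocks named list: object type -> named vector of block labels.
#' @slot deGenes data.frame(gene, lfc) of planted log2 fold changes.
#' @slot seed master seed the outputs were generated from.
#' @export
setClass("TruthSet", representation(
  interactions = "data.frame", blocks = "list",
  deGenes = "data.frame", seed = "numeric"
))

setValidity("TruthSet", function(object) {
  tb <- object@interactions
  msg <- character()
  if (nrow(tb)) {
    if (any(tb$effect[tb$class == "aggravating"] >= 0))
      msg <- c(msg, "aggravating effects must be negative")
    if (any(tb$effect[tb$class == "alleviating"] <= 0))
      msg <- c(msg, "alleviating effects must be positive")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Latent-factor network inference
## ---------------------------------------------------------------------------

#' RedInputs: inputs to latent-factor gene network inference
#'
#' @slot G symmetric gene x gene matrix of averaged double-knockdown
#'   viabilities (diagonal NA / unobserved).
#' @slot S named vector of averaged single-knockdown viabilities.
#' @slot H gene x gene matrix of expected viabilities under the
#'   multiplicative null, `H[a, b] = S[a] * S[b]`.
#' @slot sigma replicate-scatter noise scale for the probabilistic scoring
#'   (NA when replicates were unavailable).
#' @export
setClass("RedInputs", representation(
  G = "matrix", S = "numeric", H = "matrix", sigma = "numeric"
))

setValidity("RedInputs", function(object) {
  msg <- character()
  g <- names(object@S)
  if (!identical(rownames(object@G), g) || !identical(colnames(object@G), g))
    msg <- c(msg, "G dimnames must match names(S)")
  off <- object@G[upper.tri(object@G)]
  offT <- t(object@G)[upper.tri(object@G)]
  obs <- !is.na(off) & !is.na(offT)
  if (any(abs(off[obs] - offT[obs]) > 1e-9))
    msg <- c(msg, "G must be symmetric where observed")
  if (any(object@G < 0, na.rm = TRUE) || any(object@S < 0))
    msg <- c(msg, "viabilities must be nonnegative")
  if (any(abs(object@H - outer(object@S, object@S)) > 1e-9))
    msg <- c(msg, "H must equal the outer product of S")
  if (length(msg)) msg else TRUE
})

#' RedModel: fitted latent-factor model with a logistic output map
#'
#' The denoised viability landscape is `Ghat = logistic(U V')` symmetrized,
#' with `logistic(x) = ceiling / (1 + exp(-k (x - x0)))`.
#'
#' @slot U,V gene x rank latent matrices.
#' @slot mapParams named vector (x0, k, ceiling) of the logistic map.
#' @slot rank selected factorization rank.
#' @slot nrmseByRank named vector: rank -> normalized root-mean-square
#'   reconstruction error on the observed entries.
#' @slot denoised symmetrized denoised gene x gene matrix.
#' @slot converged logical convergence flag at the selected rank.
#' @slot objTrace objective value per accepted iteration at the selected rank.
#' @export
setClass("RedModel", representation(
  U = "matrix", V = "matrix", mapParams = "numeric", rank = "numeric",
  nrmseByRank = "numeric", denoised = "matrix", converged = "logical",
  objTrace = "numeric"
))

#' RelationshipProbs: four-way pairwise relationship probabilities
#'
#' One row per unordered pair (canonical order) with the probabilities of
#' the four pathway hypotheses: `pUMasksV` (linear pathway, the double
#' resembles the u single: u's knockdown phenotype masks v's), `pVMasksU`
#' (the mirror orientation), `pParallel` (independent action, multiplicative
#' double) and `pPartial` (partial interdependence, an interpolation between
#' the nearest single and the product). Rows sum to 1.
#'
#' @slot table data.frame(geneU, geneV, pUMasksV, pVMasksU, pParallel,
#'   pPartial, lambda, bestClass).
#' @slot sigma noise scale used in the Gaussian likelihoods.
#' @slot penalty log-likelihood penalty applied to the partial hypothesis.
#' @export
setClass("RelationshipProbs", representation(
  table = "data.frame", sigma = "numeric", penalty = "numeric"
))

setValidity("RelationshipProbs", function(object) {
  tb <- object@table
  s <- tb$pUMasksV + tb$pVMasksU + tb$pParallel + tb$pPartial
  if (any(abs(s - 1) > 1e-9)) return("probability 4-vectors must sum to 1")
  TRUE
})

#' StabilityReport: edge appearance fractions under data perturbation
#'
#' @slot perLevel data.frame(noiseSd, edge, from, to, type, fraction, class)
#'   with one row per candidate edge and noise level.
#' @slot pooled data.frame(edge, from, to, type, fraction, class) pooled over
#'   all levels and runs.
#' @slot M number of perturbation runs per noise level.
#' @slot noiseGrid noise standard deviations used.
#' @export
setClass("StabilityReport", representation(
  perLevel = "data.frame", pooled = "data.frame",
  M = "numeric", noiseGrid = "numeric"
))

## ---------------------------------------------------------------------------
## Fusion
## ---------------------------------------------------------------------------

#' FusionGraph: typed object sets and the relation matrices linking them
#'
#' @slot objectTypes named list: type name -> ordered character vector of
#'   object identifiers.
#' @slot relations named list: relation name -> list(rows = row type,
#'   cols = column type, data = numeric matrix).
#' @export
setClass("FusionGraph", representation(
  objectTypes = "list", relations = "list"
))

setValidity("FusionGraph", function(object) {
  msg <- character()
  if (is.null(names(object@relations)) || anyDuplicated(names(object@relations)))
    msg <- c(msg, "relation names must be unique")
  for (nm in names(object@relations)) {
    rel <- object@relations[[nm]]
    if (!all(c(rel$rows, rel$cols) %in% names(object@objectTypes))) {
      msg <- c(msg, sprintf("relation '%s' names an unknown object type", nm))
      next
    }
    if (!identical(dim(rel$data),
                   c(length(object@objectTypes[[rel$rows]]),
                     length(object@objectTypes[[rel$cols]]))))
      msg <- c(msg, sprintf("relation '%s' dimensions do not match its types", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FusionGraph
#' @param objectTypes named list of object identifier vectors, one per type.
#' @param relations named list of `list(rows, cols, data)` relation entries.
#' @return a [FusionGraph-class] object.
#' @export
FusionGraph <- function(objectTypes, relations) {
  relations <- lapply(relations, function(rel) {
    rel$data <- as.matrix(rel$data)
    rel
  })
  new("FusionGraph", objectTypes = objectTypes, relations = relations)
}

#' LatentSystem: shared per-type factors and per-relation cores
#'
#' Fitted collective tri-factorization: every relation `R_ij` is
#' approximated by `G_i S_ij G_j'` with one shared nonnegative factor matrix
#' per object type.
#'
#' @slot factors named list: type -> nonnegative n_i x k_i matrix.
#' @slot cores named list: relation -> k_i x k_j core matrix.
#' @slot ranks named numeric vector of per-type ranks.
#' @slot objTrace squared reconstruction error per accepted sweep.
#' @slot graph the (normalized) FusionGraph the system was fitted to.
#' @export
setClass("LatentSystem", representation(
  factors = "list", cores = "list", ranks = "numeric",
  objTrace = "numeric", graph = "FusionGraph"
))

setValidity("LatentSystem", function(object) {
  msg <- character()
  if (any(vapply(object@factors, function(g) any(g < 0), logical(1))))
    msg <- c(msg, "factor entries must be nonnegative")
  if (any(diff(object@objTrace) > 1e-8 * max(1, object@objTrace[1])))
    msg <- c(msg, "objective trace must be nonincreasing")
  if (length(msg)) msg else TRUE
})

#' ProfileDistances: cosine distances between reconstructed profiles
#'
#' @slot perRelation named list of gene x gene cosine-distance matrices, one
#'   per contributing relation.
#' @slot average unweighted (or weighted) mean distance matrix.
#' @slot relations names of the contributing relations.
#' @slot targetType the object type the profiles describe.
#' @export
setClass("ProfileDistances", representation(
  perRelation = "list", average = "matrix",
  relations = "character", targetType = "character"
))

setValidity("ProfileDistances", function(object) {
  d <- object@average
  msg <- character()
  if (any(d < -1e-9) || any(d > 2 + 1e-9)) msg <- c(msg, "distances must lie in [0, 2]")
  if (any(abs(diag(d)) > 1e-9)) msg <- c(msg, "diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-9)) msg <- c(msg, "distance matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Profiles module containers
## ---------------------------------------------------------------------------

#' ActivityMatrix: control-normalized enzyme activity ratios
#'
#' @slot ratios enzymes x conditions matrix of absorbance ratios relative to
#'   the matched no-coupling-enzyme control (NA where the control was
#'   unusable).
#' @slot active logical matrix flagging ratios above the fold threshold.
#' @slot threshold fold-change threshold defining activity.
#' @export
setClass("ActivityMatrix", representation(
  ratios = "matrix", active = "matrix", threshold = "numeric"
))

setValidity("ActivityMatrix", function(object) {
  if (any(object@ratios < 0, na.rm = TRUE)) return("ratios must be nonnegative")
  if (!identical(dim(object@ratios), dim(object@active)))
    return("ratios and active flags must align")
  TRUE
})

#' ExpressionPair: matched log2 expression for two conditions
#'
#' @slot normal,tumor genes x samples matrices of log2 expression with
#'   identical rownames.
#' @export
setClass("ExpressionPair", representation(
  normal = "matrix", tumor = "matrix"
))

setValidity("ExpressionPair", function(object) {
  if (!identical(rownames(object@normal), rownames(object@tumor)))
    return("normal and tumor matrices must share gene rownames")
  TRUE
})

#' ExpressionPair constructor
#' @param normal,tumor genes x samples log2 expression matrices.
#' @return an [ExpressionPair-class] object.
#' @export
ExpressionPair <- function(normal, tumor) {
  new("ExpressionPair", normal = as.matrix(normal), tumor = as.matrix(tumor))
}

#' TreeDistances: patristic distance matrix of a phylogenetic tree
#'
#' @slot labels leaf labels.
#' @slot distances symmetric patristic-distance matrix (zero diagonal).
#' @slot newick the source newick text.
#' @export
setClass("TreeDistances", representation(
  labels = "character", distances = "matrix", newick = "character"
))

setValidity("TreeDistances", function(object) {
  d <- object@distances
  if (any(abs(d - t(d)) > 1e-9)) return("patristic matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) return("patristic diagonal must be zero")
  TRUE
})
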
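## Generics -----------------------------------------------------------------

#' @rdname KnockdownPanel-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname KnockdownPanel-class
#' @export
setGeneric("singleViab", function(object) standardGeneric("singleViab"))

#' @rdname KnockdownPanel-class
#' @export
setGeneric("doubleViab", function(object) standardGeneric("doubleViab"))

#' @rdname KnockdownPanel-class
#' @export
setGeneric("pairKeys", function(object) standardGeneric("pairKeys"))

#' @rdname EpistasisResult-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname EpistasisResult-class
#' @export
setGeneric("epsilonScores", function(object) standardGeneric("epsilonScores"))

#' @rdname EpistasisResult-class
#' @export
setGeneric("interactionCalls", function(object) standardGeneric("interactionCalls"))

#' @rdname CellCycleTable-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("phases", function(object) standardGeneric("phases"))

#' @rdname CellCycleTable-class
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname RedModel-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("denoisedViability", function(object) standardGeneric("denoisedViability"))

#' @rdname RedModel-class
#' @export
setGeneric("selectedRank", function(object) standardGeneric("selectedRank"))

#' @rdname RedModel-class
#' @export
setGeneric("nrmseByRank", function(object) standardGeneric("nrmseByRank"))

#' @rdname LatentSystem-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("latentFactors", function(object) standardGeneric("latentFactors"))

#' @rdname LatentSystem-class
#' @export
setGeneric("coreMatrices", function(object) standardGeneric("coreMatrices"))

#' @rdname LatentSystem-class
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname ProfileDistances-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("averageDistance", function(object) standardGeneric("averageDistance"))

#' @rdname TruthSet-class
#' @param object an epifuse S4 object.
#' @export
setGeneric("plantedInteractions", function(object) standardGeneric("plantedInteractions"))

#' @rdname TruthSet-class
#' @export
setGeneric("plantedBlocks", function(object) standardGeneric("plantedBlocks"))

## Methods ------------------------------------------------------------------

#' @rdname KnockdownPanel-class
#' @export
setMethod("genes", "KnockdownPanel", function(object) object@genes)
#' @rdname KnockdownPanel-class
#' @export
setMethod("singleViab", "KnockdownPanel", function(object) object@singleViab)
#' @rdname KnockdownPanel-class
#' @export
setMethod("doubleViab", "KnockdownPanel", function(object) object@doubleViab)
#' @rdname KnockdownPanel-class
#' @export
setMethod("pairKeys", "KnockdownPanel",
          function(object) rownames(object@doubleViab))

#' @rdname EpistasisResult-class
#' @export
setMethod("resultTable", "EpistasisResult", function(object) object@table)
#' @rdname EpistasisResult-class
#' @export
setMethod("epsilonScores", "EpistasisResult", function(object) {
  stats::setNames(object@table$epsilon,
                  pairKey(object@table$geneA, object@table$geneB))
})
#' @rdname EpistasisResult-class
#' @export
setMethod("interactionCalls", "EpistasisResult", function(object) {
  stats::setNames(object@table$call,
                  pairKey(object@table$geneA, object@table$geneB))
})

#' @rdname CellCycleTable-class
#' @export
setMethod("phases", "CellCycleTable", function(object) object@phases)
#' @rdname CellCycleTable-class
#' @export
setMethod("fractions", "CellCycleTable", function(object) object@fractions)

#' @rdname RedModel-class
#' @export
setMethod("denoisedViability", "RedModel", function(object) object@denoised)
#' @rdname RedModel-class
#' @export
setMethod("selectedRank", "RedModel", function(object) object@rank)
#' @rdname RedModel-class
#' @export
setMethod("nrmseByRank", "RedModel", function(object) object@nrmseByRank)

#' @rdname RelationshipProbs-class
#' @param object an epifuse S4 object.
#' @export
setMethod("resultTable", "RelationshipProbs", function(object) object@table)

#' @rdname LatentSystem-class
#' @export
setMethod("latentFactors", "LatentSystem", function(object) object@factors)
#' @rdname LatentSystem-class
#' @export
setMethod("coreMatrices", "LatentSystem", function(object) object@cores)
#' @rdname LatentSystem-class
#' @export
setMethod("objectiveTrace", "LatentSystem", function(object) object@objTrace)
#' @rdname RedModel-class
#' @export
setMethod("objectiveTrace", "RedModel", function(object) object@objTrace)

#' @rdname ProfileDistances-class
#' @export
setMethod("averageDistance", "ProfileDistances", function(object) object@average)

#' @rdname TruthSet-class
#' @export
setMethod("plantedInteractions", "TruthSet", function(object) object@interactions)
#' @rdname TruthSet-class
#' @export
setMethod("plantedBlocks", "TruthSet", function(object) object@blocks)

## show ---------------------------------------------------------------------

setMethod("show", "KnockdownPanel", function(object) {
  cat("KnockdownPanel:", length(object@genes), "genes,",
      nrow(object@doubleViab), "measured pairs,",
      ncol(object@singleViab), "replicates",
      sprintf("(cell line: %s)\n", object@cellLine))
})

setMethod("show", "EpistasisResult", function(object) {
  tb <- object@table
  called <- sum(tb$call != "none", na.rm = TRUE)
  cat("EpistasisResult:", nrow(tb), "pairs")
  if (length(object@method) && nzchar(object@method))
    cat(sprintf("; %d significant (%s, alpha = %s)",
                called, object@method,
                format(object@alpha)))
  cat("\n")
})

setMethod("show", "CellCycleTable", function(object) {
  cat("CellCycleTable:", nrow(object@fractions), "knockdowns x",
      length(object@phases), "phases;",
      length(object@replicates), "replicate set(s)\n")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@interactions), "planted interactions,",
      length(object@blocks), "typed block labelings,",
      nrow(object@deGenes), "planted DE genes (seed",
      format(object@seed), ")\n")
})

setMethod("show", "RedModel", function(object) {
  cat("RedModel: rank", object@rank,
      sprintf("(NRMSE %.4g)", object@nrmseByRank[as.character(object@rank)]),
      if (object@converged) "converged" else "iteration cap reached", "\n")
})

setMethod("show", "RelationshipProbs", function(object) {
  cat("RelationshipProbs:", nrow(object@table), "pairs; dominant classes:\n")
  print(table(object@table$bestClass))
})

setMethod("show", "FusionGraph", function(object) {
  cat("FusionGraph:", length(object@objectTypes), "object types,",
      length(object@relations), "relations\n")
  for (nm in names(object@relations)) {
    rel <- object@relations[[nm]]
    cat(sprintf("  %s: %s (%d) x %s (%d)\n", nm, rel$rows, nrow(rel$data),
                rel$cols, ncol(rel$data)))
  }
})

setMethod("show", "LatentSystem", function(object) {
  cat("LatentSystem: ranks",
      paste(sprintf("%s=%d", names(object@ranks), object@ranks), collapse = ", "),
      sprintf("; final objective %.6g after %d sweeps\n",
              utils::tail(object@objTrace, 1), length(object@objTrace)))
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport:", object@M, "runs x", length(object@noiseGrid),
      "noise levels;", sum(object@pooled$class == "solid"), "solid /",
      sum(object@pooled$class == "dashed"), "dashed edges (pooled)\n")
})

setMethod("show", "ProfileDistances", function(object) {
  cat("ProfileDistances over type", object@targetType, "from",
      length(object@relations), "relations;", nrow(object@average),
      "objects\n")
})
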
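## Plain-text interchange: TSV tables and JSON manifests for every
## container the pipeline consumes or produces.

#' Write a knockdown panel as a viability TSV
#'
#' One row per knockdown (control, singles, doubles) with columns `id`,
#' `gene_a`, `gene_b` (empty for singles and the control) and
#' `replicate_1..n`.
#'
#' @param panel a [KnockdownPanel-class].
#' @param file output path.
#' @export
writePanelTSV <- function(panel, file) {
  nRep <- ncol(panel@singleViab)
  rows <- list()
  if (length(panel@controlViab) == nRep) {
    cv <- matrix(panel@controlViab, nrow = 1,
                 dimnames = list(NULL, colnames(panel@singleViab)))
    rows[[1]] <- data.frame(id = panel@controlLabel,
                            gene_a = panel@controlLabel, gene_b = "", cv)
  }
  singles <- data.frame(id = rownames(panel@singleViab),
                        gene_a = rownames(panel@singleViab), gene_b = "",
                        panel@singleViab, row.names = NULL)
  doubles <- data.frame(id = rownames(panel@doubleViab),
                        gene_a = panel@pairGenes[, 1],
                        gene_b = panel@pairGenes[, 2],
                        panel@doubleViab, row.names = NULL)
  out <- do.call(rbind, c(rows, list(singles, doubles)))
  names(out) <- c("id", "gene_a", "gene_b", paste0("replicate_", seq_len(nRep)))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a viability TSV back into a KnockdownPanel
#'
#' @param file path written by [writePanelTSV()].
#' @param controlLabel id of the control row (dropped into `controlViab`).
#' @param cellLine annotation.
#' @return a [KnockdownPanel-class].
#' @export
readPanelTSV <- function(file, controlLabel = "scrambled",
                         cellLine = "unknown") {
  tb <- utils::read.delim(file, stringsAsFactors = FALSE)
  tb$gene_b[is.na(tb$gene_b)] <- ""
  repCols <- grep("^replicate_", names(tb), value = TRUE)
  vals <- as.matrix(tb[, repCols, drop = FALSE])
  isCtrl <- tb$gene_a == controlLabel & tb$gene_b == ""
  isSingle <- !isCtrl & tb$gene_b == ""
  singles <- vals[isSingle, , drop = FALSE]
  rownames(singles) <- tb$gene_a[isSingle]
  ord <- order(rownames(singles))
  doubles <- vals[tb$gene_b != "", , drop = FALSE]
  KnockdownPanel(singles[ord, , drop = FALSE],
                 cbind(tb$gene_a[tb$gene_b != ""], tb$gene_b[tb$gene_b != ""]),
                 doubles,
                 controlViab = as.vector(vals[isCtrl, , drop = FALSE]),
                 controlLabel = controlLabel, cellLine = cellLine)
}

#' Write phase fractions as a TSV (knockdown id x phase)
#' @param table a [CellCycleTable-class].
#' @param file output path.
#' @export
writeCellCycleTSV <- function(table, file) {
  out <- data.frame(id = rownames(fractions(table)), fractions(table),
                    check.names = FALSE, row.names = NULL)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a phase-fraction TSV
#' @param file path written by [writeCellCycleTSV()].
#' @param controlLabel control row id.
#' @return a [CellCycleTable-class] (no replicate matrices).
#' @export
readCellCycleTSV <- function(file, controlLabel = "control") {
  tb <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$id
  m <- m / rowSums(m)  # absorb round-off from the text representation
  CellCycleTable(m, controlLabel = controlLabel)
}

#' Write a fusion graph as a JSON manifest plus one TSV per relation
#'
#' @param graph a [FusionGraph-class].
#' @param dir output directory (created if needed).
#' @export
writeFusionGraph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    objectTypes = graph@objectTypes,
    relations = lapply(names(graph@relations), function(nm) {
      rel <- graph@relations[[nm]]
      list(name = nm, rows = rel$rows, cols = rel$cols,
           file = paste0(nm, ".tsv"))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(graph@relations)) {
    m <- graph@relations[[nm]]$data
    out <- data.frame(id = rownames(m), m, check.names = FALSE,
                      row.names = NULL)
    utils::write.table(out, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a fusion graph from a manifest directory
#' @param dir directory written by [writeFusionGraph()].
#' @return a [FusionGraph-class].
#' @export
readFusionGraph <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  objectTypes <- as.list(manifest$objectTypes)
  rels <- manifest$relations
  relations <- list()
  for (i in seq_len(nrow(rels))) {
    tb <- utils::read.delim(file.path(dir, rels$file[i]),
                            stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tb[, -1, drop = FALSE])
    rownames(m) <- tb$id
    relations[[rels$name[i]]] <- list(rows = rels$rows[i], cols = rels$cols[i],
                                      data = m)
  }
  FusionGraph(objectTypes, relations)
}

#' Write planted truth as JSON
#' @param truth a [TruthSet-class].
#' @param file output path.
#' @export
writeTruthJSON <- function(truth, file) {
  jsonlite::write_json(list(interactions = plantedInteractions(truth),
                            blocks = lapply(plantedBlocks(truth), as.list),
                            deGenes = truth@deGenes, seed = truth@seed),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write an epistasis result table as TSV
#' @param result an [EpistasisResult-class].
#' @param file output path.
#' @param bins optional output of [binScores()] to append a bin column.
#' @export
writeResultTSV <- function(result, file, bins = NULL) {
  tb <- resultTable(result)
  if (!is.null(bins)) {
    if (is.list(bins) && !is.null(bins$bins)) bins <- bins$bins
    tb$bin <- bins[pairKey(tb$geneA, tb$geneB)]
  }
  utils::write.table(tb, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write Venn region counts as JSON
#' @param counts output of [overlapCounts()].
#' @param file output path.
#' @export
writeOverlapJSON <- function(counts, file) {
  jsonlite::write_json(as.list(counts), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
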
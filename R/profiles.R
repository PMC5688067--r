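## Stand-alone profile computations around the core pipeline: substrate
## activity, cluster co-assignment, differential expression, patristic
## distances.

#' Normalize raw activity absorbances to their no-coupling-enzyme controls
#'
#' Every signal cell is divided by its matched control cell (same enzyme
#' row, mapped control column); ratios above `threshold` are flagged
#' active. Ratios are scale-equivariant: multiplying a signal and its
#' control by the same constant leaves them unchanged.
#'
#' @param raw enzymes x columns matrix of absorbances containing both
#'   signal and control columns.
#' @param controlMap named character vector mapping each signal column to
#'   its control column.
#' @param threshold fold-change ratio above which a cell counts as active
#'   (default 1.5).
#' @return an [ActivityMatrix-class] over the signal columns; cells whose
#'   control is not positive are set NA with a warning.
#' @export
normalizeActivity <- function(raw, controlMap, threshold = 1.5) {
  raw <- as.matrix(raw)
  miss <- setdiff(c(names(controlMap), unname(controlMap)), colnames(raw))
  if (length(miss))
    stop("columns missing from the raw table: ", paste(miss, collapse = ", "))
  sig <- raw[, names(controlMap), drop = FALSE]
  ctrl <- raw[, unname(controlMap), drop = FALSE]
  bad <- ctrl <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with non-positive control; marked missing")
    ctrl[bad] <- NA_real_
  }
  ratios <- sig / ctrl
  active <- !is.na(ratios) & ratios > threshold
  new("ActivityMatrix", ratios = ratios, active = active,
      threshold = threshold)
}

#' Hierarchical clustering of active enzyme profiles
#'
#' Enzymes and conditions without a single active cell are removed before
#' clustering (they carry no signal); the remaining activity ratios are
#' clustered agglomeratively on correlation distance (`1 - Pearson r`),
#' with rows sorted by label first for deterministic tie-breaking.
#'
#' @param am an [ActivityMatrix-class].
#' @param dropInactive remove all-inactive rows/columns first (default).
#' @param linkage agglomeration method.
#' @param k optional number of flat clusters.
#' @return as [clusterProfiles()]: list(hclust, labels, order).
#' @export
clusterActivity <- function(am, dropInactive = TRUE, linkage = "average",
                            k = NULL) {
  stopifnot(is(am, "ActivityMatrix"))
  m <- am@ratios
  if (dropInactive) {
    keepR <- rowSums(am@active, na.rm = TRUE) > 0
    keepC <- colSums(am@active, na.rm = TRUE) > 0
    if (!any(keepR)) stop("nothing to cluster: no enzyme shows activity")
    m <- m[keepR, keepC, drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least two enzymes with activity to cluster")
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  d <- 1 - stats::cor(t(m), use = "pairwise.complete.obs")
  d[is.na(d)] <- 1  # constant profiles carry no correlation signal
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels, order = rownames(m)[hc$order])
}

#' Cluster co-assignment matrix and agreement score
#'
#' Compares two flat clusterings of the same objects pair by pair: each
#' unordered object pair is coded by whether it is co-clustered under each
#' labeling (`"both"`, `"only_a"`, `"only_b"`, `"neither"`). The agreement
#' score is the fraction of pairs with concordant co-membership (`both` or
#' `neither`); it equals 1 iff the labelings induce identical pair
#' partitions.
#'
#' @param labelsA,labelsB named label vectors over a shared object set.
#' @return list with `matrix` (character co-assignment matrix, diagonal
#'   `"self"`), `agreement`, and per-category pair counts.
#' @export
coAssignment <- function(labelsA, labelsB) {
  if (is.null(names(labelsA)) || is.null(names(labelsB)))
    stop("labelings must be named by object")
  common <- intersect(names(labelsA), names(labelsB))
  if (length(common) == 0) stop("labelings share no objects")
  common <- sort(common)
  a <- labelsA[common]; b <- labelsB[common]
  coA <- outer(a, a, `==`)
  coB <- outer(b, b, `==`)
  m <- matrix("neither", length(common), length(common),
              dimnames = list(common, common))
  m[coA & coB] <- "both"
  m[coA & !coB] <- "only_a"
  m[!coA & coB] <- "only_b"
  diag(m) <- "self"
  ut <- upper.tri(m)
  counts <- table(factor(m[ut], levels = c("both", "only_a", "only_b",
                                           "neither")))
  agreement <- (counts[["both"]] + counts[["neither"]]) / sum(counts)
  list(matrix = m, agreement = agreement, counts = counts)
}

#' Differential expression between matched conditions
#'
#' Per-gene Welch two-sample t-tests on log2 expression (tumor vs normal),
#' Benjamini-Hochberg adjustment across genes, and a significance flag at
#' the given FDR level. The log2 fold change is the tumor mean minus the
#' normal mean. Degenerate genes (zero variance in both groups) get p = 1
#' when the means are equal, p = 0 otherwise, with a `degenerate` flag.
#'
#' @param pair an [ExpressionPair-class].
#' @param fdr FDR level for the significance flag (default 0.05).
#' @return data.frame(gene, lfc, t, p, padj, significant, direction,
#'   degenerate).
#' @export
diffExpression <- function(pair, fdr = 0.05) {
  stopifnot(is(pair, "ExpressionPair"))
  if (ncol(pair@normal) < 2 || ncol(pair@tumor) < 2)
    stop("need >= 2 samples per condition")
  g <- rownames(pair@normal)
  res <- t(vapply(seq_along(g), function(i) {
    x <- pair@tumor[i, ]; y <- pair@normal[i, ]
    lfc <- mean(x) - mean(y)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (lfc == 0) c(lfc, 0, 1, 1) else c(lfc, Inf * sign(lfc), 0, 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      c(lfc, unname(tt$statistic), tt$p.value, 0)
    }
  }, numeric(4)))
  out <- data.frame(gene = g, lfc = res[, 1], t = res[, 2], p = res[, 3],
                    padj = stats::p.adjust(res[, 3], method = "BH"),
                    degenerate = res[, 4] == 1, stringsAsFactors = FALSE)
  out$significant <- out$padj < fdr
  out$direction <- ifelse(out$lfc > 0, "up", ifelse(out$lfc < 0, "down",
                                                    "none"))
  rownames(out) <- NULL
  out
}

#' Bubble radius for expression plots
#'
#' The plotting rule for expression bubbles: the radius is proportional to
#' the square root of the expression level.
#'
#' @param expression nonnegative expression levels (linear scale).
#' @return `sqrt(expression)`.
#' @export
bubbleSize <- function(expression) {
  stopifnot(all(expression >= 0, na.rm = TRUE))
  sqrt(expression)
}

#' Patristic distances between the leaves of a phylogeny
#'
#' The distance between two leaves is the sum of branch lengths along the
#' unique path connecting them.
#'
#' @param newick newick text (or a path handled by `ape::read.tree` when
#'   `isFile = TRUE`).
#' @param isFile treat `newick` as a file path.
#' @return a [TreeDistances-class].
#' @export
patristicDistances <- function(newick, isFile = FALSE) {
  tr <- if (isFile) ape::read.tree(newick) else ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree has edges without branch lengths")
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  d <- d[ord, ord]
  new("TreeDistances", labels = ord, distances = d,
      newick = if (isFile) ape::write.tree(tr) else newick)
}

#' Spearman similarity of enzyme activity profiles
#'
#' Pairwise Spearman rank correlation of the activity ratio profiles
#' (rows) of an [ActivityMatrix-class]; feeds [compareBins()] as a per-pair
#' covariate. Constant profiles have undefined rank correlation and are
#' reported NA.
#'
#' @param am an [ActivityMatrix-class] with >= 3 conditions.
#' @return symmetric enzyme x enzyme correlation matrix with unit diagonal.
#' @export
activitySimilarity <- function(am) {
  stopifnot(is(am, "ActivityMatrix"))
  if (ncol(am@ratios) < 3) stop("need >= 3 shared conditions")
  constant <- apply(am@ratios, 1, function(x) stats::var(x, na.rm = TRUE)) == 0
  rho <- suppressWarnings(
    stats::cor(t(am@ratios), method = "spearman",
               use = "pairwise.complete.obs"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  if (any(constant))
    warning("constant activity profile(s): correlation undefined for ",
            paste(rownames(am@ratios)[constant], collapse = ", "))
  rho
}
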
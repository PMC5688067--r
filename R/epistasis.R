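## Multiplicative-null epistasis scoring of pairwise knockdown screens.

#' Normalize a raw plate table to its negative controls, per batch
#'
#' Each batch's values are divided by the mean of that batch's negative
#' control wells. Replicate structure is preserved; when a knockdown was
#' measured in several batches, its normalized replicates are concatenated.
#' Averaging across experiments happens only at scoring time.
#'
#' @param raw data.frame with columns `batch`, `geneA`, `geneB` (empty or NA
#'   for single knockdowns; `geneA == controlLabel` marks control wells) and
#'   one `replicate_*` column per technical replicate.
#' @param controlLabel identifier of the negative control.
#' @param cellLine annotation passed to the panel.
#' @return a [KnockdownPanel-class].
#' @export
normalizeToControls <- function(raw, controlLabel = "scrambled",
                                cellLine = "unknown") {
  repCols <- grep("^replicate_", names(raw), value = TRUE)
  if (length(repCols) == 0) stop("no replicate_* columns found")
  raw$geneB[is.na(raw$geneB)] <- ""
  vals <- as.matrix(raw[, repCols, drop = FALSE])
  for (b in unique(raw$batch)) {
    inb <- raw$batch == b
    ctrl <- inb & raw$geneA == controlLabel & raw$geneB == ""
    if (!any(ctrl))
      stop("batch '", b, "' has no control wells labelled '", controlLabel, "'")
    cm <- mean(vals[ctrl, ])
    if (!is.finite(cm) || cm <= 0)
      stop("control mean is not positive in batch '", b, "'")
    vals[inb, ] <- vals[inb, ] / cm
  }
  isCtrl <- raw$geneA == controlLabel & raw$geneB == ""
  isSingle <- !isCtrl & raw$geneB == ""
  isDouble <- raw$geneB != ""

  gatherRows <- function(keys) {
    split(seq_along(keys), keys)
  }
  stackReplicates <- function(rows) {
    grp <- gatherRows(rows$key)
    n <- lengths(grp) * length(repCols)
    if (length(unique(n)) > 1)
      stop("unequal replicate counts across knockdowns after batch merging")
    m <- t(vapply(grp, function(i) as.vector(t(vals[rows$idx[i], , drop = FALSE])),
                  numeric(n[1])))
    colnames(m) <- paste0("replicate_", seq_len(ncol(m)))
    m
  }
  singles <- stackReplicates(list(key = raw$geneA[isSingle],
                                  idx = which(isSingle)))
  singles <- singles[order(rownames(singles)), , drop = FALSE]
  pg <- cbind(pmin(raw$geneA[isDouble], raw$geneB[isDouble]),
              pmax(raw$geneA[isDouble], raw$geneB[isDouble]))
  keys <- pairKey(pg[, 1], pg[, 2])
  doubles <- stackReplicates(list(key = keys, idx = which(isDouble)))
  pgU <- do.call(rbind, strsplit(rownames(doubles), "|", fixed = TRUE))
  ctrlViab <- as.vector(vals[isCtrl, , drop = FALSE])
  ctrlViab <- ctrlViab / mean(ctrlViab)
  KnockdownPanel(singles, pgU, doubles, controlViab = ctrlViab,
                 controlLabel = controlLabel, cellLine = cellLine)
}

#' Epistasis scores under the multiplicative null
#'
#' For every measured pair (a, b) computes the expected double-knockdown
#' viability `E(W_ab) = mean(W_a) * mean(W_b)` and the epistasis score
#' `epsilon = mean(W_ab) - E(W_ab)`. Scores are symmetric in the pair order
#' by construction (pairs are canonicalized).
#'
#' @param panel a [KnockdownPanel-class].
#' @return an [EpistasisResult-class] with expected values and epsilon;
#'   tests and calls are filled by [callInteractions()].
#' @export
computeEpistasis <- function(panel) {
  stopifnot(is(panel, "KnockdownPanel"))
  pg <- panel@pairGenes
  missing <- setdiff(unique(as.vector(pg)), rownames(panel@singleViab))
  if (length(missing))
    stop("pairs reference genes without single-knockdown measurements: ",
         paste(missing, collapse = ", "))
  sMean <- rowMeans(panel@singleViab)
  obs <- rowMeans(panel@doubleViab)
  expd <- unname(sMean[pg[, 1]] * sMean[pg[, 2]])
  tb <- data.frame(geneA = pg[, 1], geneB = pg[, 2],
                   observed = unname(obs), expected = expd,
                   epsilon = unname(obs) - expd,
                   se = NA_real_, z = NA_real_, p = NA_real_,
                   call = "none", degenerate = FALSE,
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("EpistasisResult", table = tb, alpha = NA_real_, method = "",
      coverage = NA_real_, cellLine = panel@cellLine)
}

# Pooled replicate variance: sum of squares / sum of df over every
# measurement in the panel (singles, doubles, control).
.pooledVariance <- function(panel) {
  ss <- function(m) sum((m - rowMeans(m))^2)
  s <- ss(panel@singleViab) + ss(panel@doubleViab)
  df <- (ncol(panel@singleViab) - 1) * nrow(panel@singleViab) +
    (ncol(panel@doubleViab) - 1) * nrow(panel@doubleViab)
  if (length(panel@controlViab) > 1) {
    s <- s + sum((panel@controlViab - mean(panel@controlViab))^2)
    df <- df + length(panel@controlViab) - 1
  }
  if (df == 0) return(0)
  s / df
}

#' Call significant aggravating and alleviating interactions
#'
#' Two callers share the sign convention (negative epsilon = aggravating,
#' positive = alleviating):
#'
#' * `method = "ztest"`: `z = epsilon / SE` where `SE^2` combines the
#'   standard error of the double-knockdown mean with the delta-method error
#'   of the product of the two single means
#'   (`SE^2 = s^2/n_ab + mB^2 s^2/n_a + mA^2 s^2/n_b`). By default the
#'   replicate variance `s^2` is pooled across all measurements of the panel
#'   (`seMethod = "pooled"`), which keeps the standard-normal reference of a
#'   Z-test honest for triplicate screens; `seMethod = "replicate"` uses each
#'   measurement's own variance instead. Two-tailed p from the standard
#'   normal (`refDist = "t"` substitutes a t reference on the pooled df).
#'   Significant iff `p < alpha`.
#' * `method = "density"`: a pair is significant iff its epsilon lies
#'   strictly outside the central empirical-probability region of all
#'   pairwise epsilon scores of the panel, at the given `coverage`
#'   (symmetric percentiles, midpoint interpolation). 0.90 corresponds to
#'   the looser (dotted-line) tier, 0.95 to the strict tier.
#'
#' Zero-variance measurements with a non-negligible epsilon cannot produce a
#' finite z; they are flagged `degenerate` and called by the sign of epsilon.
#'
#' @param result an [EpistasisResult-class] from [computeEpistasis()].
#' @param panel the [KnockdownPanel-class] the result was computed from
#'   (required for `method = "ztest"`).
#' @param alpha two-tailed significance level for the Z-test.
#' @param method "ztest" or "density".
#' @param coverage central-region coverage for the density method.
#' @param seMethod "pooled" or "replicate" variance estimation.
#' @param refDist "normal" (Z-test) or "t".
#' @return the result with z, p and calls filled.
#' @export
callInteractions <- function(result, panel = NULL, alpha = 0.05,
                             method = c("ztest", "density"), coverage = 0.90,
                             seMethod = c("pooled", "replicate"),
                             refDist = c("normal", "t")) {
  method <- match.arg(method)
  seMethod <- match.arg(seMethod)
  refDist <- match.arg(refDist)
  tb <- resultTable(result)
  eps <- tb$epsilon

  if (method == "ztest") {
    if (is.null(panel)) stop("the ztest method needs the panel replicates")
    nS <- ncol(panel@singleViab); nD <- ncol(panel@doubleViab)
    if (nS < 2 || nD < 2) stop("ztest needs >= 2 replicates per measurement")
    singleMeans <- rowMeans(panel@singleViab)
    mA <- singleMeans[tb$geneA]; mB <- singleMeans[tb$geneB]
    if (seMethod == "pooled") {
      s2 <- .pooledVariance(panel)
      vD <- rep(s2, nrow(tb)); vA <- rep(s2, nrow(tb)); vB <- vA
      df <- (nS - 1) * nrow(panel@singleViab) + (nD - 1) * nrow(panel@doubleViab)
    } else {
      vS <- apply(panel@singleViab, 1, stats::var)
      vD <- apply(panel@doubleViab, 1, stats::var)
      vA <- vS[tb$geneA]; vB <- vS[tb$geneB]
      df <- NA_real_
    }
    se2 <- vD / nD + mB^2 * vA / nS + mA^2 * vB / nS
    se <- sqrt(se2)
    z <- ifelse(se > 0, eps / se, NA_real_)
    if (refDist == "normal") {
      p <- 2 * stats::pnorm(-abs(z))
    } else {
      if (seMethod == "replicate") {
        # Welch-Satterthwaite df over the three variance components
        num <- se2^2
        den <- (vD / nD)^2 / (nD - 1) +
          (mB^2 * vA / nS)^2 / (nS - 1) + (mA^2 * vB / nS)^2 / (nS - 1)
        df <- ifelse(den > 0, num / den, Inf)
      }
      p <- 2 * stats::pt(-abs(z), df = df)
    }
    degenerate <- se == 0 & abs(eps) > 1e-10
    if (any(degenerate))
      warning(sum(degenerate),
              " pair(s) with zero variance and nonzero epsilon: ",
              "flagged degenerate, called by sign")
    exactNull <- se == 0 & !degenerate
    z[exactNull] <- 0; p[exactNull] <- 1
    sig <- (!is.na(p) & p < alpha) | degenerate
    tb$se <- unname(se); tb$z <- unname(z); tb$p <- unname(p)
    tb$degenerate <- unname(degenerate)
  } else {
    if (length(eps) < 20)
      stop("the density method needs >= 20 pairs to estimate the region")
    region <- .centralRegion(eps, coverage)
    sig <- eps < region[1] | eps > region[2]
    tb$se <- NA_real_; tb$z <- NA_real_; tb$p <- NA_real_
    tb$degenerate <- FALSE
  }
  tb$call <- ifelse(sig & eps < 0, "aggravating",
                    ifelse(sig & eps > 0, "alleviating", "none"))
  new("EpistasisResult", table = tb, alpha = alpha, method = method,
      coverage = if (method == "density") coverage else NA_real_,
      cellLine = result@cellLine)
}

#' Assign epistasis scores to equal-width bins
#'
#' Bins span the observed epsilon range with equal widths; an interior right
#' edge belongs to the lower bin's upper neighbour (bins are
#' `(e_{i-1}, e_i]`, with the minimum included in bin 1).
#'
#' @param result an [EpistasisResult-class].
#' @param nBins number of bins (default 5).
#' @return list with `bins` (named integer vector per pair key), `edges`
#'   (length `nBins + 1`) and `counts`.
#' @export
binScores <- function(result, nBins = 5) {
  eps <- epsilonScores(result)
  lo <- min(eps); hi <- max(eps)
  if (hi == lo) {
    warning("constant epsilon: single degenerate bin")
    bins <- stats::setNames(rep(1L, length(eps)), names(eps))
    return(list(bins = bins, edges = rep(lo, nBins + 1),
                counts = c(length(eps), rep(0L, nBins - 1))))
  }
  edges <- seq(lo, hi, length.out = nBins + 1)
  w <- (hi - lo) / nBins
  idx <- pmin(pmax(ceiling((eps - lo) / w), 1L), nBins)
  bins <- stats::setNames(as.integer(idx), names(eps))
  list(bins = bins, edges = edges,
       counts = as.integer(tabulate(bins, nBins)))
}

#' Per-bin summaries of a per-pair covariate
#'
#' Summarizes any per-pair covariate (log2 expression change, patristic
#' distance, activity Spearman rho, ...) within epistasis-score bins:
#' median and quartiles (linear interpolation) plus the bin size. A pair may
#' contribute several values (e.g. one per member gene).
#'
#' @param bins the `bins` element of [binScores()] (named by pair key), or
#'   the full [binScores()] list.
#' @param values named numeric vector or named list of numeric vectors,
#'   keyed by pair key.
#' @return data.frame(bin, n, median, q1, q3).
#' @export
compareBins <- function(bins, values) {
  if (is.list(bins) && !is.null(bins$bins)) bins <- bins$bins
  if (!is.list(values)) values <- as.list(values)
  miss <- setdiff(names(bins), names(values))
  if (length(miss))
    stop("pairs without covariate values: ", paste(utils::head(miss, 5),
                                                   collapse = ", "))
  nb <- max(bins)
  out <- data.frame(bin = seq_len(nb), n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_)
  for (b in seq_len(nb)) {
    v <- unlist(values[names(bins)[bins == b]], use.names = FALSE)
    out$n[b] <- length(v)
    if (length(v)) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out$q1[b] <- q[1]; out$median[b] <- q[2]; out$q3[b] <- q[3]
    }
  }
  out
}

#' Spearman correlation of epistasis scores across cell lines
#'
#' @param results named list of [EpistasisResult-class] objects (>= 2) over
#'   comparable pair sets; mismatched sets are intersected with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwiseSpearman <- function(results) {
  stopifnot(length(results) >= 2)
  epsList <- lapply(results, epsilonScores)
  common <- Reduce(intersect, lapply(epsList, names))
  if (length(common) == 0) stop("result sets share no pairs")
  if (any(vapply(epsList, length, 1L) != length(common)))
    warning("pair sets differ across results; intersecting to ",
            length(common), " shared pairs")
  m <- vapply(epsList, function(e) e[common], numeric(length(common)))
  rho <- stats::cor(m, method = "spearman")
  dimnames(rho) <- list(names(results), names(results))
  rho
}

#' Keys of significantly interacting pairs
#' @param result a called [EpistasisResult-class].
#' @return character vector of pair keys with a non-"none" call.
#' @export
significantPairs <- function(result) {
  tb <- resultTable(result)
  pairKey(tb$geneA, tb$geneB)[tb$call != "none"]
}

#' Venn region counts of significant-pair sets
#'
#' Counts every region of the Venn partition of the given sets: for each
#' nonempty combination of set names, the number of elements belonging to
#' exactly those sets. Region names join member set names with `"&"`.
#'
#' @param sets named list of character vectors (e.g. significant pair keys
#'   per cell line).
#' @return named integer vector of region counts; the counts sum to the size
#'   of the union.
#' @export
overlapCounts <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  u <- unique(unlist(sets, use.names = FALSE))
  if (length(u) == 0) return(stats::setNames(integer(0), character(0)))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  nm <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(nm)), nm)
  tt <- table(sig)
  counts[names(tt)] <- as.integer(tt)
  counts
}

#' Export a two-tier interaction network
#'
#' Builds an edge list from a called result at a strict and a loose tier.
#' For Z-test results the tiers are significance levels (defaults 0.05 and
#' 0.1); for density results they are central-region coverages (defaults
#' 0.95 and 0.90). Edges significant at the strict tier are labelled
#' `"strict"` (they belong to the loose set too); edges significant only at
#' the loose tier are labelled `"loose"`. Node and edge order is
#' deterministic (sorted by gene name).
#'
#' @param result a called [EpistasisResult-class], or one per-phase
#'   data.frame from [phaseInteractions()].
#' @param strictAlpha,looseAlpha Z-test tier levels.
#' @param strictCoverage,looseCoverage density tier coverages.
#' @param phase label stored on the edges ("viability" for survival screens).
#' @param file optional path for an edge-list TSV.
#' @param graphmlFile optional path for a GraphML export (via igraph).
#' @return invisible list with `nodes` (character) and `edges` (data.frame:
#'   geneA, geneB, sign, weight, tier, phase).
#' @export
exportNetwork <- function(result, strictAlpha = 0.05, looseAlpha = 0.1,
                          strictCoverage = 0.95, looseCoverage = 0.90,
                          phase = "viability", file = NULL,
                          graphmlFile = NULL) {
  if (is(result, "EpistasisResult")) {
    tb <- resultTable(result)
    method <- result@method
  } else {
    tb <- result
    method <- "ztest"
  }
  if (identical(method, "density")) {
    strictR <- .centralRegion(tb$epsilon, strictCoverage)
    looseR <- .centralRegion(tb$epsilon, looseCoverage)
    strict <- tb$epsilon < strictR[1] | tb$epsilon > strictR[2]
    loose <- tb$epsilon < looseR[1] | tb$epsilon > looseR[2]
  } else {
    if (all(is.na(tb$p))) stop("result has no p-values; call interactions first")
    strict <- !is.na(tb$p) & tb$p < strictAlpha
    loose <- !is.na(tb$p) & tb$p < looseAlpha
    if ("degenerate" %in% names(tb)) {
      strict <- strict | tb$degenerate
      loose <- loose | tb$degenerate
    }
  }
  loose <- loose | strict  # tiers are nested by construction
  weight <- if ("epsilon" %in% names(tb)) tb$epsilon else tb$score
  keep <- loose
  edges <- data.frame(geneA = tb$geneA[keep], geneB = tb$geneB[keep],
                      sign = ifelse(weight[keep] < 0, "-", "+"),
                      weight = weight[keep],
                      tier = ifelse(strict[keep], "strict", "loose"),
                      phase = rep(phase, sum(keep)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(tb$geneA, tb$geneB)))
  net <- list(nodes = nodes, edges = edges)
  if (!is.null(file))
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphmlFile)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::write_graph(g, graphmlFile, format = "graphml")
  }
  invisible(net)
}
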
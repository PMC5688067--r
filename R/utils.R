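#' Canonical key for an unordered gene pair
#'
#' Pairs are keyed by the lexicographically sorted gene names joined with
#' `"|"`, so that `(a, b)` and `(b, a)` always map to the same key.
#'
#' @param a,b character vectors of gene identifiers (recycled).
#' @return character vector of canonical pair keys.
#' @examples
#' pairKey("NUDT5", "NUDT1")  # "NUDT1|NUDT5"
#' @export
pairKey <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "|")
}

#' Enumerate all unordered, non-self gene pairs
#'
#' @param genes character vector of unique gene identifiers.
#' @return two-column character matrix (`geneA`, `geneB`) with one row per
#'   unordered pair, in canonical (sorted-within-pair) order.
#' @examples
#' nrow(enumeratePairs(paste0("g", 1:24)))  # 276 pairwise combinations
#' @export
enumeratePairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (length(genes) < 2L) stop("need at least two genes to form pairs")
  idx <- utils::combn(length(genes), 2L)
  m <- cbind(geneA = pmin(genes[idx[1L, ]], genes[idx[2L, ]]),
             geneB = pmax(genes[idx[1L, ]], genes[idx[2L, ]]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# Deterministic per-generator seed stream derived from one master seed.
# Keeps derived seeds in [0, 2^31) so set.seed() always accepts them.
.substream <- function(seed, id) {
  s <- (as.numeric(seed) %% 65521) * 31397 + as.numeric(id) * 7919 + 1
  as.integer(s %% 2147483647)
}

# Central empirical-probability interval of a score vector.
# Symmetric-in-probability percentiles with midpoint interpolation
# (stats::quantile type 2).
.centralRegion <- function(x, coverage) {
  stopifnot(coverage > 0, coverage < 1)
  a <- (1 - coverage) / 2
  # snap the tail probabilities so (1 - 0.9)/2 is exactly 0.05 and the
  # order statistics picked by the midpoint rule are well defined
  probs <- signif(c(a, 1 - a), 10)
  stats::quantile(x, probs = probs, type = 2, names = FALSE)
}

#' Pairwise cosine distances between matrix rows
#'
#' Distance is `1 - cos(angle)`, in `[0, 2]` for signed profiles and
#' `[0, 1]` for nonnegative ones. The distance from an all-zero profile to
#' any other profile is defined as 1 (flagged with a warning).
#'
#' @param m numeric matrix; profiles in rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
cosineDistances <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero-vector profile(s); distances to them set to 1")
    nrm[zero] <- 1
  }
  sim <- tcrossprod(m / nrm)
  sim[zero, ] <- 0
  sim[, zero] <- 0
  d <- 1 - sim
  diag(d) <- 0
  d[d < 0] <- 0  # clip tiny negative round-off
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two flat clusterings of the same
#' objects; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors over the same objects (matched by name when both
#'   are named, by position otherwise).
#' @return scalar adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) stop("labelings share no object names")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("labelings must cover the same objects")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxi - expected)
}

# Shared guard: finite numeric matrix
.checkMatrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m)) stop(what, " must be a numeric matrix")
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
  invisible(m)
}
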
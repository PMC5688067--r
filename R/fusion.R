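## Collective matrix tri-factorization over a fusion graph with shared
## nonnegative per-type factors; profile distances and clustering.

#' Two-step L2 normalization of a relation matrix
#'
#' Each nonzero row is divided by its Euclidean norm, then each nonzero
#' column of the result is divided by its Euclidean norm. Zero rows and
#' columns are left untouched (object indexing is preserved).
#'
#' @param m nonnegative numeric matrix.
#' @return the normalized matrix.
#' @export
normalizeRelation <- function(m) {
  m <- .checkMatrix(as.matrix(m), "relation")
  if (any(m < 0)) stop("normalization assumes a nonnegative relation matrix")
  rn <- sqrt(rowSums(m^2))
  m <- m / ifelse(rn == 0, 1, rn)
  cn <- sqrt(colSums(m^2))
  sweep(m, 2, ifelse(cn == 0, 1, cn), `/`)
}

.relObjective <- function(rels, factors, cores, masks) {
  s <- 0
  for (nm in names(rels)) {
    rel <- rels[[nm]]
    R <- rel$data
    Rec <- factors[[rel$rows]] %*% cores[[nm]] %*% t(factors[[rel$cols]])
    d <- (R - Rec)[masks[[nm]]]
    s <- s + sum(d^2)
  }
  s
}

#' Fit a collective tri-factorization to a fusion graph
#'
#' Jointly co-factorizes every relation matrix as
#' `R_ij ~ G_i S_ij G_j'` with one shared nonnegative factor matrix per
#' object type, minimizing the total squared reconstruction error by
#' multiplicative updates. Information flows between relations through the
#' shared factors. Each individual update is accepted only if it does not
#' increase the objective, so the per-sweep objective trace is
#' nonincreasing by construction.
#'
#' @param graph a [FusionGraph-class].
#' @param ranks named vector of per-type ranks (each `< n_type`).
#' @param seed seed for the uniform(0, 1) initialization.
#' @param maxit sweep cap.
#' @param tol relative objective-change stopping tolerance.
#' @param normalize apply [normalizeRelation()] to every relation first.
#' @param masks optional named list of logical matrices (TRUE = fit this
#'   entry); used for held-out rank selection.
#' @param nStarts random restarts; the system with the lowest final
#'   objective is kept (multiplicative updates only find local optima).
#' @return a [LatentSystem-class].
#' @export
fitFusion <- function(graph, ranks, seed = 1L, maxit = 500, tol = 1e-6,
                      normalize = TRUE, masks = NULL, nStarts = 5) {
  stopifnot(is(graph, "FusionGraph"))
  types <- names(graph@objectTypes)
  if (!all(types %in% names(ranks)))
    stop("ranks must name every object type")
  for (tn in types)
    if (ranks[[tn]] >= length(graph@objectTypes[[tn]]))
      stop("rank for type '", tn, "' must be smaller than its object count")

  rels <- graph@relations
  drop <- vapply(rels, function(rel) all(rel$data == 0), logical(1))
  if (any(drop)) {
    warning("skipping all-zero relation(s): ",
            paste(names(rels)[drop], collapse = ", "))
    rels <- rels[!drop]
  }
  if (length(rels) == 0) stop("no non-empty relations to fit")
  if (normalize)
    rels <- lapply(rels, function(rel) {
      rel$data <- normalizeRelation(rel$data); rel
    })
  if (is.null(masks))
    masks <- lapply(rels, function(rel)
      matrix(TRUE, nrow(rel$data), ncol(rel$data)))
  masks <- masks[names(rels)]

  # zero out held-out entries; with W in {0,1} the weighted updates reduce
  # to masking R and the reconstruction
  Rw <- lapply(names(rels), function(nm) rels[[nm]]$data * masks[[nm]])
  names(Rw) <- names(rels)

  best <- NULL
  for (start in seq_len(nStarts)) {
    run <- .fitFusionOnce(graph, rels, Rw, masks, ranks, types,
                          seed = .substream(seed, 31 + start),
                          maxit = maxit, tol = tol)
    if (is.null(best) || utils::tail(run$trace, 1) < utils::tail(best$trace, 1))
      best <- run
  }
  graphOut <- FusionGraph(graph@objectTypes, rels)
  new("LatentSystem", factors = best$factors, cores = best$cores,
      ranks = vapply(types, function(tn) as.numeric(ranks[[tn]]), 1),
      objTrace = best$trace, graph = graphOut)
}

.fitFusionOnce <- function(graph, rels, Rw, masks, ranks, types, seed,
                           maxit, tol) {
  set.seed(seed)
  eps <- 1e-12
  factors <- lapply(types, function(tn) {
    n <- length(graph@objectTypes[[tn]])
    m <- matrix(stats::runif(n * ranks[[tn]], 0.1, 1), n, ranks[[tn]])
    rownames(m) <- graph@objectTypes[[tn]]
    m
  })
  names(factors) <- types
  cores <- lapply(rels, function(rel)
    matrix(stats::runif(ranks[[rel$rows]] * ranks[[rel$cols]], 0.1, 1),
           ranks[[rel$rows]], ranks[[rel$cols]]))

  obj <- .relObjective(rels, factors, cores, masks)
  trace <- obj
  for (sweepIt in seq_len(maxit)) {
    # core updates
    for (nm in names(rels)) {
      rel <- rels[[nm]]
      Gi <- factors[[rel$rows]]; Gj <- factors[[rel$cols]]
      Rec <- (Gi %*% cores[[nm]] %*% t(Gj)) * masks[[nm]]
      num <- t(Gi) %*% Rw[[nm]] %*% Gj
      den <- t(Gi) %*% Rec %*% Gj
      cand <- cores[[nm]] * num / (den + eps)
      old <- cores[[nm]]; cores[[nm]] <- cand
      obj2 <- .relObjective(rels, factors, cores, masks)
      if (obj2 <= obj) obj <- obj2 else cores[[nm]] <- old
    }
    # shared factor updates
    for (tn in types) {
      Gi <- factors[[tn]]
      num <- matrix(0, nrow(Gi), ncol(Gi))
      den <- matrix(0, nrow(Gi), ncol(Gi))
      touched <- FALSE
      for (nm in names(rels)) {
        rel <- rels[[nm]]
        S <- cores[[nm]]
        if (rel$rows == tn) {
          Gj <- factors[[rel$cols]]
          Rec <- (factors[[rel$rows]] %*% S %*% t(Gj)) * masks[[nm]]
          num <- num + Rw[[nm]] %*% Gj %*% t(S)
          den <- den + Rec %*% Gj %*% t(S)
          touched <- TRUE
        }
        if (rel$cols == tn) {
          Gp <- factors[[rel$rows]]
          Rec <- (Gp %*% S %*% t(factors[[rel$cols]])) * masks[[nm]]
          num <- num + t(Rw[[nm]]) %*% Gp %*% S
          den <- den + t(Rec) %*% Gp %*% S
          touched <- TRUE
        }
      }
      if (!touched) next
      cand <- Gi * num / (den + eps)
      factors[[tn]] <- cand
      obj2 <- .relObjective(rels, factors, cores, masks)
      if (obj2 <= obj) obj <- obj2 else factors[[tn]] <- Gi
    }
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if ((prev - obj) / max(prev, 1e-30) < tol) break
  }
  list(factors = factors, cores = cores, trace = trace)
}

#' Select per-type ranks by held-out reconstruction error
#'
#' Grid search over a shared candidate rank: for each candidate, 10% of
#' each relation's entries are masked, the system is fitted on the rest and
#' scored on the masked entries; the smallest rank within 1% of the optimum
#' is kept (per type, capped at `n_type - 1`).
#'
#' @param graph a [FusionGraph-class].
#' @param grid candidate ranks.
#' @param holdout fraction of entries to mask.
#' @param seed seed for masking and fits.
#' @param ... passed to [fitFusion()].
#' @return named vector of selected per-type ranks.
#' @export
selectFusionRanks <- function(graph, grid = 1:4, holdout = 0.1, seed = 1L,
                              ...) {
  types <- names(graph@objectTypes)
  set.seed(.substream(seed, 32))
  masks <- lapply(graph@relations, function(rel) {
    m <- matrix(stats::runif(length(rel$data)) > holdout,
                nrow(rel$data), ncol(rel$data))
    m
  })
  err <- stats::setNames(numeric(length(grid)), grid)
  for (i in seq_along(grid)) {
    ranks <- stats::setNames(
      pmin(grid[i], lengths(graph@objectTypes) - 1), types)
    sys <- fitFusion(graph, ranks, seed = seed, masks = masks, ...)
    e <- 0
    for (nm in names(sys@graph@relations)) {
      R <- sys@graph@relations[[nm]]$data
      Rec <- reconstruct(sys, nm)
      held <- !masks[[nm]]
      e <- e + sum((R[held] - Rec[held])^2)
    }
    err[i] <- e
  }
  best <- min(err)
  sel <- grid[which(err <= best * 1.01)[1]]
  stats::setNames(pmin(sel, lengths(graph@objectTypes) - 1), types)
}

#' Reconstruct a relation from the fitted latent system
#'
#' @param system a [LatentSystem-class].
#' @param relation relation name.
#' @return the dense reconstruction `G_i S_ij G_j'` with the relation's
#'   dimnames.
#' @export
reconstruct <- function(system, relation) {
  stopifnot(is(system, "LatentSystem"))
  rel <- system@graph@relations[[relation]]
  if (is.null(rel)) stop("unknown relation '", relation, "'")
  out <- system@factors[[rel$rows]] %*% system@cores[[relation]] %*%
    t(system@factors[[rel$cols]])
  dimnames(out) <- dimnames(rel$data)
  out
}

#' Cosine profile distances for a target object type
#'
#' For every relation touching the target type, the reconstructed matrix is
#' oriented so the target objects index the rows, and pairwise cosine
#' distances between those profile rows are computed; the per-relation
#' matrices are then averaged (unweighted by default).
#'
#' @param system a [LatentSystem-class].
#' @param targetType object type to profile.
#' @param weights optional per-relation weights for the average.
#' @return a [ProfileDistances-class].
#' @export
profileDistances <- function(system, targetType, weights = NULL) {
  stopifnot(is(system, "LatentSystem"))
  rels <- system@graph@relations
  touching <- names(rels)[vapply(rels, function(rel)
    rel$rows == targetType || rel$cols == targetType, logical(1))]
  if (length(touching) == 0)
    stop("no relation touches type '", targetType, "'")
  perRel <- list()
  for (nm in touching) {
    rel <- rels[[nm]]
    M <- reconstruct(system, nm)
    if (rel$rows != targetType) M <- t(M)
    perRel[[nm]] <- cosineDistances(M)
  }
  if (is.null(weights)) weights <- rep(1, length(perRel))
  weights <- weights / sum(weights)
  avg <- Reduce(`+`, Map(`*`, perRel, weights))
  new("ProfileDistances", perRelation = perRel, average = avg,
      relations = touching, targetType = targetType)
}

#' Hierarchical clustering of averaged profile distances
#'
#' Agglomerative clustering of the averaged cosine-distance matrix. Objects
#' are sorted by label before clustering, so the output is invariant to the
#' input label order (ties broken deterministically by label).
#'
#' @param distances a [ProfileDistances-class] or a symmetric distance
#'   matrix.
#' @param linkage agglomeration method (default "average").
#' @param k number of flat clusters, or `NULL`.
#' @param h cut height alternative to `k`.
#' @return list with `hclust` (the merge tree), `labels` (named flat cluster
#'   assignment, when `k` or `h` given) and `order` (heat-map permutation of
#'   object names).
#' @export
clusterProfiles <- function(distances, linkage = "average", k = NULL,
                            h = NULL) {
  d <- if (is(distances, "ProfileDistances")) averageDistance(distances)
       else as.matrix(distances)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  if (!is.null(k) && k > nrow(d))
    stop("cannot cut ", nrow(d), " objects into ", k, " clusters")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- NULL
  if (!is.null(k) || !is.null(h))
    labels <- stats::cutree(hc, k = k, h = h)
  list(hclust = hc, labels = labels, order = rownames(d)[hc$order])
}
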
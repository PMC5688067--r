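## Latent-factor gene network inference from single/double knockdown
## phenotypes: logistic-map factorization, probabilistic four-way
## relationship scoring, and stability-filtered network construction.

#' Assemble network-inference inputs
#'
#' Builds the (G, S, H) triple: the symmetric gene x gene matrix of
#' averaged double-knockdown viabilities (diagonal unobserved), the vector
#' of averaged single-knockdown viabilities, and the expected-viability
#' matrix `H = S S'` under the multiplicative null. When built from a
#' panel, the noise scale `sigma` is estimated from replicate scatter as
#' the pooled standard error of a double-knockdown mean.
#'
#' @param x a [KnockdownPanel-class], or a symmetric numeric matrix G with
#'   gene dimnames.
#' @param S single-knockdown viability vector (required when `x` is a
#'   matrix), named by gene.
#' @param sigma optional noise scale override.
#' @return a [RedInputs-class].
#' @export
redInputs <- function(x, S = NULL, sigma = NA_real_) {
  if (is(x, "KnockdownPanel")) {
    g <- sort(genes(x))
    G <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
    pg <- x@pairGenes
    obs <- rowMeans(x@doubleViab)
    G[cbind(pg[, 1], pg[, 2])] <- obs
    G[cbind(pg[, 2], pg[, 1])] <- obs
    S <- rowMeans(x@singleViab)[g]
    if (is.na(sigma)) {
      v <- .pooledVariance(x)
      sigma <- sqrt(v / ncol(x@doubleViab))
    }
  } else {
    G <- as.matrix(x)
    if (is.null(S)) stop("S is required when G is given directly")
    S <- S[rownames(G)]
  }
  diag(G) <- NA_real_
  new("RedInputs", G = G, S = S, H = outer(S, S), sigma = sigma)
}

# logistic output map and its building blocks
.logisticMap <- function(Z, par) par["ceiling"] * stats::plogis(par["k"] * (Z - par["x0"]))

.redObjective <- function(G, mask, U, V, par) {
  Ghat <- .logisticMap(U %*% t(V), par)
  sum((Ghat[mask] - G[mask])^2)
}

# Spectral initialization: invert the logistic map on the observed entries
# (diagonal and gaps imputed with row means) and take the leading
# eigenpairs of the logit-scale matrix. Lands close to the optimum for
# ranks near n and gives the descent a strong, deterministic starting
# point.
.spectralInit <- function(G, mask, par, r) {
  X <- G
  X[!mask] <- NA
  P <- pmin(pmax(X / par["ceiling"], 1e-6), 1 - 1e-6)
  L <- par["x0"] + stats::qlogis(P) / par["k"]
  rm <- rowMeans(L, na.rm = TRUE)
  rm[is.nan(rm)] <- mean(L, na.rm = TRUE)
  miss <- which(is.na(L), arr.ind = TRUE)
  L[miss] <- (rm[miss[, 1]] + rm[miss[, 2]]) / 2
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  idx <- order(abs(e$values), decreasing = TRUE)[seq_len(r)]
  list(U = e$vectors[, idx, drop = FALSE] %*% diag(e$values[idx], r),
       V = e$vectors[, idx, drop = FALSE])
}

# Monotone alternating gradient descent over the blocks U, V and the map
# parameters, each with its own adaptive step size (backtracking per
# block). Returns the updated state and the achieved objective.
.redDescend <- function(G, mask, U, V, par, maxit, tol, cMin) {
  obj <- .redObjective(G, mask, U, V, par)
  trace <- obj
  eta <- c(U = 1e-2, V = 1e-2, par = 1e-2)
  grads <- function() {
    Z <- U %*% t(V)
    P <- stats::plogis(par["k"] * (Z - par["x0"]))
    R <- matrix(0, nrow(G), ncol(G))
    R[mask] <- (par["ceiling"] * P)[mask] - G[mask]
    W <- 2 * R * (par["ceiling"] * par["k"] * P * (1 - P))
    list(gU = W %*% V, gV = t(W) %*% U,
         gpar = c(x0 = -sum(W[mask]),
                  k = sum(2 * R[mask] *
                            (par["ceiling"] * P * (1 - P) * (Z - par["x0"]))[mask]),
                  ceiling = sum(2 * R[mask] * P[mask])))
  }
  tryStep <- function(block, grad) {
    gn <- sqrt(sum(grad^2))
    if (gn == 0) return(FALSE)
    for (bt in seq_len(30)) {
      s <- eta[block] / gn
      if (block == "U") {
        cand <- U - s * grad
        obj2 <- .redObjective(G, mask, cand, V, par)
      } else if (block == "V") {
        cand <- V - s * grad
        obj2 <- .redObjective(G, mask, U, cand, par)
      } else {
        cand <- par - s * grad
        cand["k"] <- max(1e-3, cand["k"])
        cand["ceiling"] <- max(cMin, cand["ceiling"])
        obj2 <- .redObjective(G, mask, U, V, cand)
      }
      if (obj2 <= obj) {
        if (block == "U") U <<- cand else if (block == "V") V <<- cand
        else par <<- cand
        obj <<- obj2
        eta[block] <<- min(eta[block] * 1.5, 1e3)
        return(TRUE)
      }
      eta[block] <<- eta[block] / 2
    }
    FALSE
  }
  for (it in seq_len(maxit)) {
    prev <- obj
    g <- grads()
    movedU <- tryStep("U", g$gU)
    g <- grads()
    movedV <- tryStep("V", g$gV)
    g <- grads()
    movedP <- tryStep("par", g$gpar)
    trace <- c(trace, obj)
    if (!movedU && !movedV && !movedP)
      return(list(U = U, V = V, par = par, obj = obj, trace = trace,
                  converged = TRUE))
    if ((prev - obj) / max(prev, 1e-30) < tol)
      return(list(U = U, V = V, par = par, obj = obj, trace = trace,
                  converged = TRUE))
  }
  list(U = U, V = V, par = par, obj = obj, trace = trace, converged = FALSE)
}

#' Fit the latent-factor viability model over a rank grid
#'
#' Minimizes the squared reconstruction error of the observed entries of G
#' under `Ghat = logistic(U V')` by monotone alternating gradient descent,
#' jointly fitting the logistic map (midpoint, steepness, ceiling). Ranks
#' are fitted in increasing order with warm starts (the new factor column of
#' U initialized at zero), which makes the training NRMSE nonincreasing in
#' rank by construction. The selected rank is the smallest whose NRMSE is
#' within 1% of the grid minimum.
#'
#' @param inputs a [RedInputs-class].
#' @param rankGrid candidate factorization ranks (within `[1, n - 1]`).
#' @param seed integer seed for the uniform(0, 1) initialization.
#' @param maxit iteration cap per rank.
#' @param tol relative objective-change tolerance.
#' @return a [RedModel-class] at the selected rank.
#' @export
fitLatentModel <- function(inputs, rankGrid = NULL, seed = 1L, maxit = 5000,
                           tol = 1e-8) {
  stopifnot(is(inputs, "RedInputs"))
  G <- inputs@G
  n <- nrow(G)
  if (n < 4) stop("need at least 4 genes to factorize")
  if (is.null(rankGrid)) rankGrid <- unique(pmin(c(1, 2, 4, 8, n - 1), n - 1))
  rankGrid <- sort(unique(as.integer(rankGrid)))
  if (any(rankGrid < 1 | rankGrid > n - 1))
    stop("rankGrid must lie within [1, n - 1]")
  mask <- !is.na(G)
  diag(mask) <- FALSE
  gObs <- G[mask]
  denom <- diff(range(gObs))
  if (denom == 0) denom <- max(abs(gObs), 1)
  cMin <- max(gObs) * 1.0001 + 1e-9

  set.seed(.substream(seed, 21))
  fits <- list()
  nrmse <- stats::setNames(numeric(length(rankGrid)), rankGrid)
  par0 <- c(x0 = 0.5, k = 2, ceiling = max(gObs) * 1.05)
  U <- NULL; V <- NULL; par <- NULL
  for (i in seq_along(rankGrid)) {
    r <- rankGrid[i]
    # candidate A: spectral start in logit space
    sp <- .spectralInit(G, mask, par0, r)
    fitA <- .redDescend(G, mask, sp$U, sp$V, par0, maxit = maxit, tol = tol,
                        cMin = cMin)
    # candidate B: warm start from the previous rank (zero-padded U keeps
    # the starting objective equal to the previous optimum, which makes
    # the NRMSE-by-rank curve nonincreasing by construction)
    if (i == 1) {
      Uw <- matrix(stats::runif(n * r), n, r)
      Vw <- matrix(stats::runif(n * r), n, r)
      parW <- par0
    } else {
      extra <- r - ncol(U)
      Uw <- cbind(U, matrix(0, n, extra))
      Vw <- cbind(V, matrix(stats::runif(n * extra), n, extra))
      parW <- par
    }
    fitB <- .redDescend(G, mask, Uw, Vw, parW, maxit = maxit, tol = tol,
                        cMin = cMin)
    fit <- if (fitA$obj <= fitB$obj) fitA else fitB
    U <- fit$U; V <- fit$V; par <- fit$par
    nrmse[i] <- sqrt(fit$obj / sum(mask)) / denom
    fits[[i]] <- fit
  }
  best <- min(nrmse)
  sel <- which(nrmse <= best + max(1e-12, 0.01 * best))[1]
  fit <- fits[[sel]]
  Ghat <- .logisticMap(fit$U %*% t(fit$V), fit$par)
  Ghat <- (Ghat + t(Ghat)) / 2
  dimnames(Ghat) <- dimnames(G)
  rownames(fit$U) <- rownames(G); rownames(fit$V) <- rownames(G)
  new("RedModel", U = fit$U, V = fit$V, mapParams = fit$par,
      rank = rankGrid[sel], nrmseByRank = nrmse, denoised = Ghat,
      converged = fit$converged, objTrace = fit$trace)
}

#' Probabilistic scoring of the four pairwise pathway relationships
#'
#' For each gene pair (u, v) the denoised double-knockdown viability
#' `ghat_uv` is compared against the four hypothesis predictions: the u
#' single alone (`u` masks `v`: linear pathway), the v single alone, the
#' product of singles (parallel/independent action), and a penalized
#' interpolation `lambda * nearest_single + (1 - lambda) * product` with
#' `lambda` in (0, 1) (partial interdependence). Residuals are converted to
#' probabilities through a Gaussian likelihood with noise scale `sigma`
#' (replicate scatter, floored), the interpolation hypothesis carrying a
#' log-likelihood penalty for its extra parameter; the four likelihoods are
#' normalized to sum 1. Scoring (u, v) and (v, u) differ only by swapping
#' the two linear components.
#'
#' @param model a fitted [RedModel-class].
#' @param inputs the [RedInputs-class] the model was fitted on.
#' @param sigmaFloor lower bound on the noise scale (used, with a message,
#'   when replicate scatter is zero or unavailable).
#' @param penalty log-likelihood penalty on the interpolation hypothesis.
#' @param lambdaRange closed interval the interpolation weight is clamped to.
#' @return a [RelationshipProbs-class].
#' @export
scoreRelationships <- function(model, inputs, sigmaFloor = 0.02,
                               penalty = 1, lambdaRange = c(0.05, 0.95)) {
  stopifnot(is(model, "RedModel"), is(inputs, "RedInputs"))
  S <- inputs@S
  g <- names(S)
  Ghat <- denoisedViability(model)
  sigma <- inputs@sigma
  if (!is.finite(sigma) || sigma < sigmaFloor) {
    if (!is.finite(sigma) || sigma == 0)
      message("replicate noise scale unavailable or zero; using the floor ",
              sigmaFloor)
    sigma <- sigmaFloor
  }
  pairs <- enumeratePairs(g)
  u <- pairs[, 1]; v <- pairs[, 2]
  ghat <- Ghat[cbind(u, v)]
  su <- unname(S[u]); sv <- unname(S[v])
  prod <- su * sv

  nearU <- abs(ghat - su) <= abs(ghat - sv)
  snear <- ifelse(nearU, su, sv)
  den <- snear - prod
  lambda <- ifelse(den == 0, mean(lambdaRange),
                   pmin(pmax((ghat - prod) / ifelse(den == 0, 1, den),
                             lambdaRange[1]), lambdaRange[2]))
  pred4 <- lambda * snear + (1 - lambda) * prod

  ll <- cbind(uMasksV = -(ghat - su)^2, vMasksU = -(ghat - sv)^2,
              parallel = -(ghat - prod)^2, partial = -(ghat - pred4)^2)
  ll <- ll / (2 * sigma^2)
  ll[, "partial"] <- ll[, "partial"] - penalty
  m <- apply(ll, 1, max)
  w <- exp(ll - m)
  probs <- w / rowSums(w)

  cls <- c("u_masks_v", "v_masks_u", "parallel", "partial")
  best <- cls[max.col(probs, ties.method = "first")]
  tb <- data.frame(geneU = u, geneV = v,
                   pUMasksV = probs[, "uMasksV"],
                   pVMasksU = probs[, "vMasksU"],
                   pParallel = probs[, "parallel"],
                   pPartial = probs[, "partial"],
                   lambda = lambda, bestClass = best,
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("RelationshipProbs", table = tb, sigma = sigma, penalty = penalty)
}

#' Construct a directed gene network from relationship probabilities
#'
#' A pair contributes an edge when its dominant relationship class exceeds
#' `edgeThreshold`: a directed edge from the masking gene to the masked gene
#' for the linear-pathway classes, an undirected edge for partial
#' interdependence, and no edge when parallel action dominates. Output order
#' is deterministic (sorted by endpoints).
#'
#' @param probs a [RelationshipProbs-class].
#' @param edgeThreshold probability threshold (default 0.5).
#' @return data.frame(from, to, type, prob, class); `type` is "directed" or
#'   "undirected".
#' @export
inferNetwork <- function(probs, edgeThreshold = 0.5) {
  tb <- resultTable(probs)
  p <- as.matrix(tb[, c("pUMasksV", "pVMasksU", "pParallel", "pPartial")])
  top <- max.col(p, ties.method = "first")
  pmaxv <- p[cbind(seq_len(nrow(p)), top)]
  keep <- pmaxv > edgeThreshold & top != 3L
  from <- ifelse(top == 1L, tb$geneU, ifelse(top == 2L, tb$geneV, tb$geneU))
  to <- ifelse(top == 1L, tb$geneV, ifelse(top == 2L, tb$geneU, tb$geneV))
  type <- ifelse(top == 4L, "undirected", "directed")
  cls <- c("u_masks_v", "v_masks_u", "parallel", "partial")[top]
  edges <- data.frame(from = from[keep], to = to[keep], type = type[keep],
                      prob = pmaxv[keep], class = cls[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Classify edge stability from appearance fractions
#'
#' Edges appearing in at least 40% of perturbation runs are "solid", edges
#' appearing in 20% to 40% (right-open) are "dashed", the rest "absent".
#'
#' @param fraction numeric vector of appearance fractions in `[0, 1]`.
#' @return character vector of classes.
#' @export
classifyStability <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction >= 0.40, "solid",
         ifelse(fraction >= 0.20, "dashed", "absent"))
}

#' Network stability under independent Gaussian data perturbation
#'
#' For each noise level, `M` perturbed copies of G (independent normal
#' noise added symmetrically, clipped at 0) are refitted at the selected
#' rank, rescored, and re-thresholded into networks. Per-edge appearance
#' fractions are aggregated per level and pooled across all runs, and
#' classified by the 40%/20% rule ([classifyStability()]).
#'
#' @param inputs a [RedInputs-class].
#' @param rankGrid rank grid for the initial fit (the perturbation runs
#'   reuse the selected rank).
#' @param M runs per noise level (default 100).
#' @param noiseGrid noise SDs; defaults to three levels spanning `1e-6` to
#'   `sd(G)/3` (the grid must stay within that interval).
#' @param seed master seed.
#' @param edgeThreshold passed to [inferNetwork()].
#' @param maxit iteration cap per perturbation refit.
#' @param ... passed to [scoreRelationships()].
#' @return a [StabilityReport-class].
#' @export
stabilityAnalysis <- function(inputs, rankGrid = NULL, M = 100,
                              noiseGrid = NULL, seed = 1L,
                              edgeThreshold = 0.5, maxit = 500, ...) {
  stopifnot(is(inputs, "RedInputs"), M >= 1)
  G <- inputs@G
  sdG <- stats::sd(G[!is.na(G)])
  if (is.null(noiseGrid)) noiseGrid <- c(1e-6, sdG / 6, sdG / 3)
  if (any(noiseGrid < 1e-6 - 1e-12 | noiseGrid > sdG / 3 + 1e-12))
    stop("noise grid must lie within [1e-6, sd(G)/3]")

  base <- fitLatentModel(inputs, rankGrid = rankGrid, seed = seed,
                         maxit = maxit)
  r <- selectedRank(base)
  n <- nrow(G)
  ut <- upper.tri(G)

  edgeId <- function(edges)
    paste(edges$from, edges$to, edges$type, sep = ":")
  runsPerLevel <- list()
  for (li in seq_along(noiseGrid)) {
    sdLevel <- noiseGrid[li]
    ids <- vector("list", M)
    for (m in seq_len(M)) {
      set.seed(.substream(seed, 100000 + li * 1000 + m))
      E <- matrix(0, n, n)
      E[ut] <- stats::rnorm(sum(ut), 0, sdLevel)
      E <- E + t(E)
      Gp <- pmax(G + E, 0)
      diag(Gp) <- NA_real_
      dimnames(Gp) <- dimnames(G)
      inp <- new("RedInputs", G = Gp, S = inputs@S,
                 H = inputs@H, sigma = inputs@sigma)
      fit <- fitLatentModel(inp, rankGrid = r,
                            seed = .substream(seed, 200000 + li * 1000 + m),
                            maxit = maxit)
      net <- inferNetwork(scoreRelationships(fit, inp, ...), edgeThreshold)
      ids[[m]] <- unique(edgeId(net))
    }
    runsPerLevel[[li]] <- ids
  }
  allEdges <- sort(unique(unlist(runsPerLevel)))
  splitId <- function(id) strsplit(id, ":", fixed = TRUE)[[1]]
  perLevel <- do.call(rbind, lapply(seq_along(noiseGrid), function(li) {
    fr <- vapply(allEdges, function(e)
      mean(vapply(runsPerLevel[[li]], function(s) e %in% s, logical(1))),
      numeric(1))
    parts <- t(vapply(allEdges, splitId, character(3)))
    data.frame(noiseSd = noiseGrid[li], edge = allEdges,
               from = parts[, 1], to = parts[, 2], type = parts[, 3],
               fraction = unname(fr), class = classifyStability(unname(fr)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  allRuns <- unlist(runsPerLevel, recursive = FALSE)
  frPooled <- vapply(allEdges, function(e)
    mean(vapply(allRuns, function(s) e %in% s, logical(1))), numeric(1))
  parts <- if (length(allEdges)) t(vapply(allEdges, splitId, character(3)))
           else matrix(character(), 0, 3)
  pooled <- data.frame(edge = allEdges, from = parts[, 1], to = parts[, 2],
                       type = parts[, 3], fraction = unname(frPooled),
                       class = classifyStability(unname(frPooled)),
                       stringsAsFactors = FALSE, row.names = NULL)
  new("StabilityReport", perLevel = perLevel, pooled = pooled, M = M,
      noiseGrid = noiseGrid)
}
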
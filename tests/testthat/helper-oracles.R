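# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and, where possible, the same base helpers) so that each
# check is a genuine dual-route computation.

# Empirical percentile with midpoint interpolation (the declared rule):
# h = n * p; average the two order statistics when h is an integer.
oracle_quantile_mid <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- n * pp
    if (abs(h - round(h)) < 1e-9) {
      h <- round(h)
      if (h <= 0) s[1] else if (h >= n) s[n] else (s[h] + s[h + 1]) / 2
    } else s[min(n, max(1, ceiling(h)))]
  }, numeric(1))
}

# Density-region calling by brute-force sorting
oracle_density_outside <- function(eps, coverage) {
  a <- (1 - coverage) / 2
  q <- oracle_quantile_mid(eps, c(a, 1 - a))
  eps < q[1] | eps > q[2]
}

# Spearman rho as rank-then-Pearson, with the Pearson formula written out
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Venn region counts by per-element membership enumeration
oracle_venn <- function(sets) {
  u <- unique(unlist(sets))
  out <- list()
  for (el in u) {
    members <- names(sets)[vapply(sets, function(s) el %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Co-assignment agreement by explicit pair loops
oracle_coassignment <- function(a, b) {
  objs <- sort(intersect(names(a), names(b)))
  agree <- 0L; total <- 0L
  cats <- c(both = 0L, only_a = 0L, only_b = 0L, neither = 0L)
  for (i in seq_along(objs)) for (j in seq_along(objs)) {
    if (j <= i) next
    ca <- a[objs[i]] == a[objs[j]]
    cb <- b[objs[i]] == b[objs[j]]
    total <- total + 1L
    if (ca == cb) agree <- agree + 1L
    key <- if (ca && cb) "both" else if (ca) "only_a" else if (cb) "only_b" else "neither"
    cats[key] <- cats[key] + 1L
  }
  list(agreement = agree / total, counts = cats)
}

# Benjamini-Hochberg from the definition (step-up)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Patristic distances as shortest paths on the tree graph (igraph)
oracle_patristic <- function(newick) {
  tr <- ape::read.tree(text = newick)
  nTips <- length(tr$tip.label)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tr$edge.length
  d <- igraph::distances(g, v = as.character(seq_len(nTips)),
                         to = as.character(seq_len(nTips)))
  dimnames(d) <- list(tr$tip.label, tr$tip.label)
  ord <- sort(tr$tip.label)
  d[ord, ord]
}

# Two-step L2 normalization entry by entry
oracle_two_step_norm <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    nrm <- sqrt(sum(m[i, ]^2))
    if (nrm > 0) out[i, ] <- m[i, ] / nrm
  }
  for (j in seq_len(ncol(m))) {
    nrm <- sqrt(sum(out[, j]^2))
    if (nrm > 0) out[, j] <- out[, j] / nrm
  }
  out
}

# Per-phase multiplicative-null expectation, written independently
oracle_phase_expected <- function(F0, Fa, Fb) {
  e <- numeric(length(F0))
  for (k in seq_along(F0)) {
    e[k] <- (Fa[k] / F0[k]) * (Fb[k] / F0[k]) * F0[k]
  }
  e / sum(e)
}

# Direct evaluation of the four relationship likelihoods
oracle_relationship_probs <- function(ghat, su, sv, sigma, penalty = 1,
                                      lrange = c(0.05, 0.95)) {
  prod <- su * sv
  snear <- if (abs(ghat - su) <= abs(ghat - sv)) su else sv
  lambda <- if (snear == prod) mean(lrange) else
    min(max((ghat - prod) / (snear - prod), lrange[1]), lrange[2])
  pred <- unname(c(su, sv, prod, lambda * snear + (1 - lambda) * prod))
  ll <- -(ghat - pred)^2 / (2 * sigma^2)
  ll[4] <- ll[4] - penalty
  w <- exp(ll - max(ll))
  w / sum(w)
}

# Welch t statistic and two-sided p from the textbook formulas
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Plain single-matrix nonnegative tri-factorization (independent solver:
# straight multiplicative updates, no safeguards, own code path)
oracle_nmtf <- function(R, k, seed = 1, maxit = 2000) {
  set.seed(seed)
  n <- nrow(R); m <- ncol(R)
  G <- matrix(runif(n * k, 0.1, 1), n, k)
  S <- matrix(runif(k * k, 0.1, 1), k, k)
  H <- matrix(runif(m * k, 0.1, 1), m, k)
  eps <- 1e-12
  for (it in seq_len(maxit)) {
    Rec <- G %*% S %*% t(H)
    G <- G * (R %*% H %*% t(S)) / (Rec %*% H %*% t(S) + eps)
    Rec <- G %*% S %*% t(H)
    H <- H * (t(R) %*% G %*% S) / (t(Rec) %*% G %*% S + eps)
    Rec <- G %*% S %*% t(H)
    S <- S * (t(G) %*% R %*% H) / (t(G) %*% Rec %*% H + eps)
  }
  Rec <- G %*% S %*% t(H)
  list(reconstruction = Rec, objective = sum((R - Rec)^2))
}

# small helpers shared by tests ------------------------------------------

# panel with explicitly chosen replicate vectors
make_panel <- function(singles, doubles) {
  sv <- do.call(rbind, singles)
  rownames(sv) <- names(singles)
  pg <- do.call(rbind, strsplit(names(doubles), "|", fixed = TRUE))
  dv <- do.call(rbind, doubles)
  KnockdownPanel(sv, pg, dv)
}

# RedInputs straight from a (G, S) pair
make_red_inputs <- function(G, S, sigma = NA_real_) {
  redInputs(G, S = S, sigma = sigma)
}

# noise-free G whose pairs follow chosen hypotheses exactly
make_hypothesis_G <- function(S, classes, lambda = 0.5) {
  g <- names(S)
  pairs <- enumeratePairs(g)
  G <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_len(nrow(pairs))) {
    u <- pairs[i, 1]; v <- pairs[i, 2]
    pr <- S[u] * S[v]
    val <- switch(classes[i],
                  u_masks_v = S[u],
                  v_masks_u = S[v],
                  parallel = pr,
                  partial = lambda * min(S[u], S[v]) + (1 - lambda) * pr)
    G[u, v] <- val; G[v, u] <- val
  }
  G
}
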
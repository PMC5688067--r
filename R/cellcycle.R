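## Per-phase interaction scoring of cell-cycle phase fractions under the
## multiplicative null on control-relative ratios.

#' Per-phase interaction scores for double knockdowns
#'
#' For each cell-cycle phase k, the expected double-knockdown fraction
#' under the multiplicative null is formed from control-relative ratios:
#' `r_ab,k = (F_a,k / F_0,k) * (F_b,k / F_0,k)`, expected raw fraction
#' `r_ab,k * F_0,k`, then renormalized across phases to sum 1 (compositional
#' closure). The per-phase score is the observed minus the expected
#' fraction: positive scores mean an increased cell fraction in that phase
#' ("increase", rendered cyan/blue in phase networks), negative a decrease
#' ("brown").
#'
#' Significance per phase:
#' * `"ztest"` (needs replicate fraction matrices): `z = score / SE` with a
#'   per-phase replicate SD pooled across knockdowns; two-tailed normal p,
#'   significant iff `p < alpha`.
#' * `"density"`: a score is significant iff it lies outside the central
#'   region (coverage `1 - alpha`) of all scores in that phase.
#'
#' Phases with a zero control fraction are excluded with a warning.
#'
#' @param table a [CellCycleTable-class] containing the control, every
#'   single and every double knockdown.
#' @param pairs optional two-column matrix restricting the scored pairs;
#'   defaults to every double-knockdown row of the table.
#' @param alpha two-tailed significance level (default 0.1, the loose tier
#'   used for phase networks).
#' @param method "ztest" or "density"; defaults to "ztest" when replicate
#'   fractions are available.
#' @return named list (one element per retained phase) of data.frames with
#'   columns geneA, geneB, observed, expected, score, z, p, call
#'   (increase / decrease / none).
#' @export
phaseInteractions <- function(table, pairs = NULL, alpha = 0.1,
                              method = NULL) {
  stopifnot(is(table, "CellCycleTable"))
  fr <- fractions(table)
  ph <- phases(table)
  F0 <- fr[table@controlLabel, ]
  if (is.null(method))
    method <- if (length(table@replicates) >= 2) "ztest" else "density"
  method <- match.arg(method, c("ztest", "density"))

  doubleRows <- grep("|", rownames(fr), fixed = TRUE, value = TRUE)
  if (is.null(pairs)) {
    pairs <- do.call(rbind, strsplit(doubleRows, "|", fixed = TRUE))
  } else {
    pairs <- as.matrix(pairs)
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
  }
  keys <- pairKey(pairs[, 1], pairs[, 2])
  need <- c(table@controlLabel, unique(as.vector(pairs)), keys)
  miss <- setdiff(need, rownames(fr))
  if (length(miss))
    stop("table is missing knockdowns: ", paste(utils::head(miss, 5),
                                                collapse = ", "))

  keep <- F0 > 0
  if (!all(keep))
    warning("excluding phase(s) with zero control fraction: ",
            paste(ph[!keep], collapse = ", "))

  rA <- sweep(fr[pairs[, 1], , drop = FALSE], 2, F0, `/`)
  rB <- sweep(fr[pairs[, 2], , drop = FALSE], 2, F0, `/`)
  expRaw <- sweep(rA * rB, 2, F0, `*`)
  expRaw[, !keep] <- 0
  expected <- expRaw / rowSums(expRaw[, keep, drop = FALSE])
  observed <- fr[keys, , drop = FALSE]
  score <- observed - expected

  if (method == "ztest") {
    if (length(table@replicates) < 2)
      stop("ztest on phase fractions needs replicate fraction matrices")
    reps <- table@replicates
    nRep <- length(reps)
    # per-phase replicate variance pooled over knockdowns
    arr <- vapply(reps, function(r) r[keys, , drop = FALSE],
                  matrix(0, length(keys), length(ph)))
    s2k <- colMeans(apply(arr, c(1, 2), stats::var))
    se <- sqrt(s2k / nRep)
  }

  out <- list()
  for (k in which(keep)) {
    df <- data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                     observed = unname(observed[, k]),
                     expected = unname(expected[, k]),
                     score = unname(score[, k]),
                     z = NA_real_, p = NA_real_, call = "none",
                     stringsAsFactors = FALSE)
    if (method == "ztest") {
      if (se[k] > 0) {
        df$z <- df$score / se[k]
        df$p <- 2 * stats::pnorm(-abs(df$z))
        sig <- df$p < alpha
      } else {
        df$z <- ifelse(abs(df$score) <= 1e-10, 0, NA_real_)
        df$p <- ifelse(abs(df$score) <= 1e-10, 1, NA_real_)
        sig <- abs(df$score) > 1e-10
      }
    } else {
      region <- .centralRegion(df$score, 1 - alpha)
      sig <- df$score < region[1] | df$score > region[2]
    }
    df$call <- ifelse(sig & df$score > 0, "increase",
                      ifelse(sig & df$score < 0, "decrease", "none"))
    out[[ph[k]]] <- df
  }
  out
}

#' Export one network per cell-cycle phase
#'
#' Thin wrapper over [exportNetwork()]: per-phase results produce one
#' two-tier network each, with the phase label carried on the edges.
#'
#' @param phaseResults output of [phaseInteractions()] (ztest mode).
#' @param strictAlpha,looseAlpha tier significance levels.
#' @param dir optional directory; one edge-list TSV per phase is written.
#' @return named list of networks (see [exportNetwork()]).
#' @export
exportPhaseNetworks <- function(phaseResults, strictAlpha = 0.05,
                                looseAlpha = 0.1, dir = NULL) {
  nets <- list()
  for (ph in names(phaseResults)) {
    tb <- phaseResults[[ph]]
    file <- if (!is.null(dir))
      file.path(dir, paste0("network_", gsub("[^A-Za-z0-9]+", "_", ph), ".tsv"))
    nets[[ph]] <- exportNetwork(tb, strictAlpha = strictAlpha,
                                looseAlpha = looseAlpha, phase = ph,
                                file = file)
  }
  nets
}
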
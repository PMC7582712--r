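#' Gene-wise cell means and pooled residual variance
#'
#' Fits the group-means parameterization of the 2x2 design: one mean
#' per genotype x treatment cell per probe, with a pooled residual
#' variance on `n_arrays - 4` degrees of freedom.
#'
#' @param m log2 matrix (probes x arrays).
#' @param cell factor of design cells per array (levels in canonical
#'   order; see [designCells()]).
#' @return `list(means, s2, df)`: probes x 4 cell-mean matrix, residual
#'   variances and their (scalar) degrees of freedom.
#' @examples
#' m <- matrix(c(1, 3, 2, 2, 5, 5, 0, 0), 1)
#' cell <- factor(rep(c("WT.control", "WT.drought", "Fld.control",
#'                      "Fld.drought"), each = 2),
#'                levels = c("WT.control", "WT.drought", "Fld.control",
#'                           "Fld.drought"))
#' fitCellMeans(m, cell)
#' @export
fitCellMeans <- function(m, cell) {
  m <- as.matrix(m)
  cell <- factor(cell, levels = .CELLS)
  if (anyNA(cell)) stop("unknown design cells")
  if (any(table(cell) == 0)) stop("every design cell needs >= 1 array")
  df <- ncol(m) - 4L
  if (df <= 0) stop("no residual degrees of freedom: need > 4 arrays")
  means <- .cellMeans(m, cell)
  fitted <- means[, as.character(cell), drop = FALSE]
  s2 <- rowSums((m - fitted)^2) / df
  list(means = means, s2 = s2, df = df)
}

#' Invert the trigamma function
#'
#' Monotone Newton iteration for `x` with `trigamma(x) = y`, `y > 0`.
#'
#' @param y positive numeric.
#' @return numeric solution (Inf for y <= 0).
#' @keywords internal
.trigammaInverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- (tri - y) / psigamma(x, deriv = 2)
    x <- x - dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Moment estimation of the variance-prior hyperparameters
#'
#' Matches the mean and variance of the log residual variances to their
#' expectations under a scaled inverse chi-square prior: for
#' `s2 ~ s0sq * (d0/chisq_d0) * (chisq_df/df)`,
#' `Var(log s2) = trigamma(df/2) + trigamma(d0/2)` and
#' `E(log s2) = log s0sq + digamma(df/2) - log(df/2) - digamma(d0/2) +
#' log(d0/2)`. The trigamma equation is solved by Newton iteration.
#' `d0 = Inf` is returned when the empirical spread of log variances
#' does not exceed that implied by the residual degrees of freedom
#' alone; in the fully degenerate case of identical variances the
#' common value is returned as `s0sq`.
#'
#' @param s2 positive residual variances (>= 100 values for a stable
#'   estimate; fewer are allowed but warned about).
#' @param df residual degrees of freedom of each `s2`.
#' @return `list(d0, s0sq)`.
#' @examples
#' set.seed(1)
#' s2 <- 0.05 * 4 / rchisq(10000, 4) * rchisq(10000, 4) / 4
#' estimatePrior(s2, df = 4)
#' @export
estimatePrior <- function(s2, df) {
  s2 <- as.numeric(s2)
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("variances must be finite and strictly positive")
  if (length(s2) < 100)
    warning("fewer than 100 variances; prior estimate will be unstable")
  e <- log(s2)
  emean <- mean(e)
  evar <- stats::var(e)
  if (evar < 1e-12)
    return(list(d0 = Inf, s0sq = exp(emean)))
  y <- evar - trigamma(df / 2)
  if (y <= 0) {
    d0 <- Inf
    s0sq <- exp(emean - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * .trigammaInverse(y)
    s0sq <- exp(emean - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Posterior (moderated) variance
#'
#' `s2Post = (d0 * s0sq + df * s2) / (d0 + df)`; equals `s0sq` at
#' `d0 = Inf` and `s2` at `d0 = 0`.
#'
#' @param s2 residual variances; `df` their degrees of freedom.
#' @param d0,s0sq prior degrees of freedom and variance.
#' @return moderated variances.
#' @export
squeezeVariance <- function(s2, df, d0, s0sq) {
  if (is.infinite(d0)) rep(s0sq, length(s2))
  else (d0 * s0sq + df * s2) / (d0 + df)
}

#' Moderated t-statistics for one contrast
#'
#' `t = beta / sqrt(s2Post * varFactor)` with two-sided p-values from a
#' t distribution on `d0 + df` degrees of freedom (standard normal when
#' `d0 = Inf`). Probes with zero moderated variance get `NA` with an
#' error flag.
#'
#' @param beta contrast log2 fold-changes.
#' @param s2Post moderated variances from [squeezeVariance()].
#' @param varFactor unscaled variance factor of the contrast (sum of
#'   1/n over its two cells).
#' @param df residual degrees of freedom; `d0` prior degrees of freedom.
#' @return `list(t, p, error)` (`error`: logical flag per probe).
#' @export
moderatedT <- function(beta, s2Post, varFactor, df, d0) {
  bad <- s2Post <= 0
  se <- sqrt(s2Post * varFactor)
  t <- ifelse(bad, NA_real_, beta / se)
  p <- 2 * stats::pt(-abs(t), df = d0 + df)
  list(t = t, p = p, error = bad)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p p-values in [0, 1].
#' @return q-values (monotone step-up adjustment, capped at 1).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ternary expression-state call
#'
#' `U` iff fold-change strictly exceeds `up` and `q < alpha`; `D` iff
#' fold-change is strictly below `down` and `q < alpha`; otherwise `N`.
#'
#' @param beta log2 fold-changes; `q` BH-adjusted p-values.
#' @param up,down fold-change thresholds (default 2 and 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @return character vector over \{"U", "D", "N"\}.
#' @examples
#' callState(beta = log2(c(2.5, 2, 0.4)), q = c(0.01, 0.001, 0.2))
#' @export
callState <- function(beta, q, up = 2, down = 0.5, alpha = 0.05) {
  stopifnot(up > 1, down < 1, down > 0, alpha > 0)
  fc <- 2^beta
  out <- rep("N", length(beta))
  out[fc > up & q < alpha] <- "U"
  out[fc < down & q < alpha] <- "D"
  out
}

#' Empirical-Bayes moderated fit of the four factorial contrasts
#'
#' Runs the full differential-expression stage on a log2-scale
#' experiment: cell means and pooled residual variances, prior
#' hyperparameter estimation by moment matching on log variances,
#' variance moderation, per-contrast moderated t-statistics, two-sided
#' p-values, per-contrast BH FDR control, and ternary state calls at
#' the fold-change / FDR thresholds.
#'
#' @param x log2-scale [FactorialArrayExperiment-class] (typically the
#'   filtered output of [preprocessArrays()]).
#' @param fcUp,fcDown,alpha state-call thresholds (defaults: induced at
#'   FC > 2, repressed at FC < 0.5, FDR < 0.05).
#' @param d0,s0sq optional fixed prior parameters overriding estimation
#'   (useful for limiting-case analyses).
#' @return A [ModeratedFit-class] object.
#' @examples
#' cfg <- simulationConfig(nProbes = 600, seed = 5)
#' pre <- preprocessArrays(simulateExpression(cfg))
#' fit <- moderatedFit(pre$experiment)
#' fit
#' @export
moderatedFit <- function(x, fcUp = 2, fcDown = 0.5, alpha = 0.05,
                         d0 = NULL, s0sq = NULL) {
  stopifnot(is(x, "FactorialArrayExperiment"),
            intensityScale(x) == "log2")
  m <- assay(x, "intensity")
  cell <- designCells(x)
  fit <- fitCellMeans(m, cell)
  if (is.null(d0) || is.null(s0sq)) {
    prior <- estimatePrior(fit$s2, fit$df)
    d0 <- prior$d0; s0sq <- prior$s0sq
  }
  s2Post <- squeezeVariance(fit$s2, fit$df, d0, s0sq)
  nPer <- table(cell)
  contrasts <- .CONTRAST_CELLS
  nc <- length(contrasts)
  n <- nrow(m)
  beta <- tmat <- pmat <- qmat <- matrix(
    NA_real_, n, nc, dimnames = list(rownames(m), names(contrasts)))
  states <- matrix("N", n, nc, dimnames = dimnames(beta))
  varFactor <- numeric(nc)
  for (k in seq_len(nc)) {
    cc <- contrasts[[k]]
    beta[, k] <- fit$means[, cc["plus"]] - fit$means[, cc["minus"]]
    varFactor[k] <- 1 / nPer[[cc["plus"]]] + 1 / nPer[[cc["minus"]]]
    mt <- moderatedT(beta[, k], s2Post, varFactor[k], fit$df, d0)
    tmat[, k] <- mt$t
    pmat[, k] <- mt$p
    qmat[, k] <- bhFdr(mt$p)
    states[, k] <- callState(beta[, k], qmat[, k], fcUp, fcDown, alpha)
  }
  names(varFactor) <- names(contrasts)
  new("ModeratedFit", cellMeans = fit$means, coefficients = beta,
      s2 = fit$s2, df = as.numeric(fit$df), d0 = d0, s0sq = s0sq,
      s2Post = s2Post, varFactor = varFactor,
      t = tmat, p = pmat, q = qmat, states = states,
      thresholds = list(fcUp = fcUp, fcDown = fcDown, alpha = alpha))
}

#' Accessors for ModeratedFit
#'
#' `logFoldChanges`, `pValues`, `qValues`, `contrastStates` return the
#' probes x 4 matrices of the fit; `contrastNames` the canonical
#' contrast names; `priorParameters` the estimated `(d0, s0sq)`.
#'
#' @param x a [ModeratedFit-class].
#' @name ModeratedFit-accessors
NULL

#' @rdname ModeratedFit-accessors
#' @export
setMethod("contrastNames", "ModeratedFit",
          function(x) colnames(x@coefficients))

#' @rdname ModeratedFit-accessors
#' @export
setMethod("logFoldChanges", "ModeratedFit", function(x) x@coefficients)

#' @rdname ModeratedFit-accessors
#' @export
setMethod("pValues", "ModeratedFit", function(x) x@p)

#' @rdname ModeratedFit-accessors
#' @export
setMethod("qValues", "ModeratedFit", function(x) x@q)

#' @rdname ModeratedFit-accessors
#' @export
setMethod("contrastStates", "ModeratedFit", function(x) x@states)

#' @rdname ModeratedFit-accessors
#' @export
setMethod("priorParameters", "ModeratedFit",
          function(x) list(d0 = x@d0, s0sq = x@s0sq))

setMethod("show", "ModeratedFit", function(object) {
  cat(sprintf("ModeratedFit: %d probes, 4 contrasts, df = %g\n",
              nrow(object@coefficients), object@df))
  cat(sprintf("  prior: d0 = %.3g, s0sq = %.4g\n", object@d0, object@s0sq))
  th <- object@thresholds
  cat(sprintf("  state calls at FC > %g / < %g, FDR < %g:\n",
              th$fcUp, th$fcDown, th$alpha))
  print(apply(object@states, 2, function(s) table(factor(s, c("U", "D", "N")))))
  invisible(NULL)
})

#' Per-contrast DE result table
#'
#' @param fit a [ModeratedFit-class].
#' @param contrast contrast name or index.
#' @return `data.frame(probe_id, log2FC, t, p, q, state)`.
#' @export
contrastTable <- function(fit, contrast) {
  stopifnot(is(fit, "ModeratedFit"))
  k <- if (is.character(contrast)) match(contrast, contrastNames(fit))
       else as.integer(contrast)
  if (is.na(k) || k < 1 || k > 4) stop("unknown contrast")
  data.frame(probe_id = rownames(fit@coefficients),
             log2FC = fit@coefficients[, k], t = fit@t[, k],
             p = fit@p[, k], q = fit@q[, k], state = fit@states[, k],
             row.names = NULL)
}
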
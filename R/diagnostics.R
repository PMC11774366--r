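#' Moran's I global spatial autocorrelation
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} \tilde w_{ij} (x_i-\bar x)(x_j-\bar x)}
#'                        {\sum_i (x_i-\bar x)^2},\qquad S_0=\sum_{ij}\tilde w_{ij},}
#' with \eqn{\tilde w} the binary neighbour indicator (`style = "B"`) or its
#' row-standardised form (`style = "W"`, the default, under which values
#' typically fall in \eqn{[-1, 1]}).  Positive values mean neighbouring
#' areas carry similar values.  Isolated areas contribute nothing to the
#' statistic and are excluded with a warning.
#'
#' @param x per-area numeric vector, aligned with `adjacency`.
#' @param adjacency a [build_adjacency()] object.
#' @param style `"W"` (row-standardised) or `"B"` (binary).
#' @return The Moran's I scalar.
#' @export
morans_i <- function(x, adjacency, style = c("W", "B")) {
  style <- match.arg(style)
  prep <- .moran_prep(x, adjacency, style)
  .moran_stat(prep$z, prep)
}

.moran_prep <- function(x, adjacency, style) {
  if (length(x) != adjacency$n) stop("x misaligned with adjacency")
  if (any(!is.finite(x))) stop("x must be finite")
  keep <- seq_len(adjacency$n)
  if (length(adjacency$isolated)) {
    warning(sprintf("excluding %d isolated area(s) from Moran's I",
                    length(adjacency$isolated)))
    keep <- setdiff(keep, adjacency$isolated)
  }
  if (length(keep) < 3L) stop("need at least 3 connected areas")
  x <- x[keep]
  if (var(x) == 0) stop("constant x: Moran's I undefined")
  W <- adjacency$W[keep, keep, drop = FALSE]
  if (style == "W") W <- W / Matrix::rowSums(W)
  list(z = x - mean(x), W = W, n = length(keep), S0 = sum(W))
}

.moran_stat <- function(z, prep) {
  # z must already be centred; works column-wise when z is a matrix
  if (is.matrix(z)) {
    num <- colSums(as.matrix(prep$W %*% z) * z)
    den <- colSums(z * z)
  } else {
    num <- sum(as.vector(prep$W %*% z) * z)
    den <- sum(z * z)
  }
  (prep$n / prep$S0) * num / den
}

#' Moran's I permutation test
#'
#' One-sided test against positive spatial autocorrelation.  The null
#' distribution is generated by randomly relabelling `x` across areas;
#' the p-value is `(1 + #{I_perm >= I_obs}) / (1 + n_permutations)`, so its
#' smallest attainable value is `1/(n_permutations + 1)`.
#'
#' @inheritParams morans_i
#' @param n_permutations number of random relabellings (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `moran_result`: list with `statistic`,
#'   `p_value`, `n_permutations`, `weight_style`, `perm_mean`, `perm_sd`.
#' @export
morans_i_test <- function(x, adjacency, style = c("W", "B"),
                          n_permutations = 999L, seed = NULL) {
  style <- match.arg(style)
  if (n_permutations < 99L) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  prep <- .moran_prep(x, adjacency, style)
  obs <- .moran_stat(prep$z, prep)
  Z <- vapply(seq_len(n_permutations), function(b) sample(prep$z),
              numeric(prep$n))
  perm <- .moran_stat(Z, prep)
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  structure(list(statistic = obs, p_value = p,
                 n_permutations = as.integer(n_permutations),
                 weight_style = style,
                 perm_mean = mean(perm), perm_sd = sd(perm)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f, one-sided permutation p = %.4g (%d perms, style %s)\n",
              x$statistic, x$p_value, x$n_permutations, x$weight_style))
  invisible(x)
}

#' Residuals from a fitted BYM model
#'
#' Fitted counts are `E_i * fitted_sir_i` with the fitted SIR the per-area
#' posterior median of `exp(mu_i)`.  Pearson residuals
#' `(y_i - fit_i)/sqrt(fit_i)` are the default; `kind = "response"` gives
#' raw differences.
#'
#' @param outcome an outcome table (`area_id`, `y`, `E`, ...) restricted to
#'   the modelled areas.
#' @param summary a [summary.bym_chain()] object with `$fitted_sir`.
#' @param kind `"pearson"` (default) or `"response"`.
#' @return Named numeric vector of residuals.
#' @export
model_residuals <- function(outcome, summary, kind = c("pearson", "response")) {
  kind <- match.arg(kind)
  fs <- summary$fitted_sir
  m <- match(outcome$area_id, fs$area_id)
  if (anyNA(m)) stop("fitted values missing for some areas")
  fit <- outcome$E * fs$fitted_sir[m]
  if (any(fit == 0)) stop("zero fitted count")
  r <- switch(kind,
              pearson = (outcome$y - fit) / sqrt(fit),
              response = outcome$y - fit)
  stats::setNames(r, outcome$area_id)
}

#' Geweke convergence z-score for a chain
#'
#' Compares the mean of the first `frac1` of retained draws against the
#' mean of the last `frac2`, standardised by spectral-density-at-zero
#' variance estimates from an autoregressive approximation fitted to each
#' segment (so autocorrelation within segments is accounted for).  For a
#' converged chain the score is approximately standard normal.
#'
#' @param x numeric vector of ordered draws (>= 200).
#' @param frac1 fraction forming the early window (default 0.1).
#' @param frac2 fraction forming the late window (default 0.5).
#' @return The z-score (scalar).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 200L) stop("need at least 200 draws")
  if (frac1 <= 0 || frac2 <= 0 || frac1 + frac2 > 1) {
    stop("windows must be positive, non-overlapping fractions")
  }
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  if (var(a) == 0 || var(b) == 0) stop("constant segment: variance is zero")
  (mean(a) - mean(b)) / sqrt(.spectrum0(a) / length(a) +
                             .spectrum0(b) / length(b))
}

# spectral density at frequency zero via a Yule-Walker AR fit with
# AIC-selected order: sigma^2 / (1 - sum(phi))^2
.spectrum0 <- function(z) {
  ord_max <- min(20L, length(z) - 1L, floor(10 * log10(length(z))))
  fit <- tryCatch(
    ar(z, aic = TRUE, order.max = ord_max, method = "yule-walker"),
    error = function(e) NULL)
  if (is.null(fit)) return(var(z))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke diagnostics for every scalar parameter of a chain
#'
#' @param chain a [fit_bym()] result.
#' @param frac1,frac2 windows as in [geweke_z()].
#' @return Named numeric vector of z-scores (alpha, betas, sigma2_u,
#'   sigma2_v).
#' @export
geweke_diagnostics <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  d <- .chain_param_matrix(chain)
  apply(d, 2L, function(col) {
    tryCatch(geweke_z(col, frac1, frac2), error = function(e) NA_real_)
  })
}
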
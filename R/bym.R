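#' Configuration for the BYM sampler
#'
#' Defaults follow common disease-mapping practice: essentially flat
#' Gaussian priors on the intercept and covariate effects (variance 10^6)
#' and Inverse-Gamma(1, 0.01) hyperpriors on both random-effect variances.
#' Chain defaults are desk scale (60,000 iterations, 10,000 burn-in,
#' thinning 5, leaving 10,000 draws); `full_scale = TRUE` switches to the
#' production schedule of 1,500,000 iterations with 500,000 burn-in and
#' thinning 100.
#'
#' @param prior_var_alpha,prior_var_beta Gaussian prior variances for the
#'   intercept and each covariate coefficient.
#' @param ig_shape,ig_scale Inverse-Gamma hyperparameters (a, b) shared by
#'   the structured and unstructured variance components.
#' @param n_iter,n_burnin,thin chain controls; `n_burnin < n_iter`,
#'   `thin >= 1`.
#' @param seed integer RNG seed used by [fit_bym()].
#' @param include_covariate fit the quintile covariate if one is supplied.
#' @param count_policy `"round"` (default: fractional disaggregated counts
#'   are rounded to the nearest integer before the Poisson fit, and the
#'   total discrepancy recorded) or `"fractional"` (gamma-function form of
#'   the likelihood on the fractional counts).
#' @param full_scale use the production chain schedule.
#' @return An object of class `bym_config` (a validated list).
#' @export
bym_config <- function(prior_var_alpha = 1e6, prior_var_beta = 1e6,
                       ig_shape = 1, ig_scale = 0.01,
                       n_iter = 60000L, n_burnin = 10000L, thin = 5L,
                       seed = 1L, include_covariate = TRUE,
                       count_policy = c("round", "fractional"),
                       full_scale = FALSE) {
  if (full_scale) { n_iter <- 1500000L; n_burnin <- 500000L; thin <- 100L }
  count_policy <- match.arg(count_policy)
  stopifnot(prior_var_alpha > 0, prior_var_beta > 0,
            ig_shape > 0, ig_scale > 0,
            n_burnin < n_iter, thin >= 1, is.finite(seed))
  structure(list(prior_var_alpha = prior_var_alpha,
                 prior_var_beta = prior_var_beta,
                 ig_shape = ig_shape, ig_scale = ig_scale,
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 include_covariate = isTRUE(include_covariate),
                 count_policy = count_policy),
            class = "bym_config")
}

#' BYM Poisson log-likelihood
#'
#' `sum_i [ y_i (log E_i + mu_i) - E_i e^{mu_i} - log Gamma(y_i + 1) ]`
#' with `mu_i = alpha + x_i' beta + u_i + v_i`.  Written in the gamma
#' form so fractional counts are admissible.
#'
#' @param y observed counts (>= 0).
#' @param E expected counts (> 0).
#' @param mu linear predictor per area, or supply the pieces via `alpha`,
#'   `X`, `beta`, `u`, `v`.
#' @param alpha,beta,u,v,X optional model components used when `mu` is
#'   missing; `X` is the n-by-p dummy matrix.
#' @return Scalar log-likelihood.
#' @export
log_likelihood_bym <- function(y, E, mu = NULL, alpha = 0, beta = NULL,
                               u = NULL, v = NULL, X = NULL) {
  if (is.null(mu)) {
    mu <- rep(alpha, length(y))
    if (!is.null(X) && !is.null(beta)) mu <- mu + drop(as.matrix(X) %*% beta)
    if (!is.null(u)) mu <- mu + u
    if (!is.null(v)) mu <- mu + v
  }
  if (any(!is.finite(mu))) stop("non-finite linear predictor")
  if (any(E <= 0)) stop("E must be positive for modelled areas")
  if (any(y < 0)) stop("negative counts")
  sum(y * (log(E) + mu) - E * exp(mu) - lgamma(y + 1))
}

#' Full conditional of one intrinsic-CAR effect
#'
#' For area `i` with at least one neighbour, the CAR prior gives
#' `u_i | u_{-i} ~ N( sum_j w_ij u_j / sum_j w_ij, sigma2_u / sum_j w_ij )`.
#'
#' @param u current vector of structured effects.
#' @param i area index.
#' @param adjacency a [build_adjacency()] object.
#' @param sigma2_u conditional variance parameter.
#' @return List with `mean` and `variance`.
#' @export
car_conditional <- function(u, i, adjacency, sigma2_u) {
  nb <- adjacency$nb[[i]]
  if (!length(nb)) stop("area ", i, " is isolated: CAR conditional undefined")
  list(mean = mean(u[nb]), variance = sigma2_u / length(nb))
}

#' Conjugate Gibbs draws for the variance components
#'
#' `gibbs_update_sigma2_v` draws from the exact conditional
#' Inverse-Gamma(a + n/2, b + sum(v^2)/2) of the unstructured variance.
#' `gibbs_update_sigma2_u` draws the structured variance from
#' Inverse-Gamma with shape `a + (sum over multi-area components of
#' (size - 1) + n_isolated)/2` — the rank of the intrinsic CAR precision
#' plus one per isolated area (which carries a proper N(0, sigma2_u)
#' prior) — and scale `b + sum_{i<j} w_ij (u_i - u_j)^2 / 2 +
#' sum_isolated u_i^2 / 2`.  On a graph without isolated areas the shape
#' reduces to `a + (n - c)/2` with `c` the number of connected components.
#'
#' @param v,u current random-effect vectors.
#' @param a,b Inverse-Gamma shape and scale hyperparameters.
#' @param adjacency a [build_adjacency()] object.
#' @return A single draw (scalar), using the current RNG state.
#' @export
gibbs_update_sigma2_v <- function(v, a, b) {
  1 / rgamma(1L, shape = a + length(v) / 2, rate = b + sum(v^2) / 2)
}

#' @rdname gibbs_update_sigma2_v
#' @export
gibbs_update_sigma2_u <- function(u, adjacency, a, b) {
  par <- .car_ig_params(u, adjacency, a, b)
  1 / rgamma(1L, shape = par$shape, rate = par$rate)
}

.car_ig_params <- function(u, adjacency, a, b) {
  iso <- adjacency$isolated
  comp <- adjacency$components
  sizes <- tabulate(comp)
  multi <- sizes[sizes >= 2L]
  n_eff <- sum(multi - 1L) + length(iso)
  pair <- 0
  for (i in seq_len(adjacency$n)) {
    nb <- adjacency$nb[[i]]
    nb <- nb[nb > i]
    if (length(nb)) pair <- pair + sum((u[i] - u[nb])^2)
  }
  rate <- b + pair / 2 + if (length(iso)) sum(u[iso]^2) / 2 else 0
  list(shape = a + n_eff / 2, rate = rate)
}

#' Fit the BYM model by Metropolis-within-Gibbs MCMC
#'
#' Model: `y_i ~ Poisson(E_i e^{mu_i})`,
#' `mu_i = alpha + x_i' beta + u_i + v_i`, with `u` an intrinsic CAR
#' structured effect, `v` iid `N(0, sigma2_v)`, flat-ish Gaussian priors on
#' `alpha` and `beta`, and Inverse-Gamma hyperpriors on both variances.
#' The sampler performs random-walk Metropolis updates for `alpha`, each
#' `beta_j`, each `u_i` (CAR full conditional as prior times the area's
#' Poisson likelihood) and each `v_i`, then conjugate Gibbs draws for the
#' two variances.  `u` is mean-centred within every multi-area connected
#' component after each iteration (sum-to-zero identifiability); isolated
#' areas keep a proper `N(0, sigma2_u)` prior and are not centred.
#' Proposal scales adapt during burn-in towards 40–50% acceptance and are
#' frozen afterwards.  Runs are fully reproducible given `config$seed`.
#'
#' @param outcome outcome table (`area_id`, `y`, `E`) — areas with
#'   `E = 0` must already be excluded (they are dropped with a warning).
#' @param covariate optional covariate table (`area_id`, `quintile`); the
#'   first quintile is the reference, so coefficients `beta2..beta5`
#'   correspond to quintiles 2–5.
#' @param adjacency a [build_adjacency()] object aligned with `outcome`
#'   after exclusions.
#' @param config a [bym_config()].
#' @param keep_effects store per-draw `u` and `v` matrices (memory heavy;
#'   used by tests).
#' @param fix_variances optional list(sigma2_u=, sigma2_v=) freezing the
#'   variance components (no Gibbs updates).
#' @param update_u,update_v enable the random-effect updates (both `TRUE`
#'   by default; disabling yields reduced models for checking).
#' @return An object of class `bym_chain` with per-draw parameter vectors,
#'   the per-draw empirical variances of `u` and `v`, the matrix of
#'   retained linear predictors `mu` (areas x draws), acceptance rates and
#'   metadata.
#' @export
fit_bym <- function(outcome, covariate = NULL, adjacency, config = bym_config(),
                    keep_effects = FALSE, fix_variances = NULL,
                    update_u = TRUE, update_v = TRUE) {
  stopifnot(inherits(config, "bym_config"))
  y <- outcome$y; E <- outcome$E; ids <- as.character(outcome$area_id)
  if (length(y) != adjacency$n) stop("outcome and adjacency misaligned")
  if (any(E == 0)) {
    keep <- which(E > 0)
    warning(sprintf("dropping %d area(s) with E = 0 before fitting",
                    sum(E == 0)))
    sub <- .subset_adjacency(adjacency, keep)
    out2 <- outcome[keep, , drop = FALSE]
    cov2 <- if (!is.null(covariate)) {
      covariate[match(out2$area_id, covariate$area_id), , drop = FALSE]
    }
    return(fit_bym(out2, cov2, sub, config, keep_effects, fix_variances,
                   update_u, update_v))
  }
  rounding_discrepancy <- 0
  if (config$count_policy == "round" && any(y != round(y))) {
    rounding_discrepancy <- sum(round(y)) - sum(y)
    y <- round(y)
  }
  X <- matrix(numeric(), length(y), 0L)
  if (config$include_covariate && !is.null(covariate)) {
    q <- covariate$quintile[match(ids, covariate$area_id)]
    if (anyNA(q)) stop("covariate missing for some modelled areas")
    X <- .quintile_dummies(q)
  }
  if (length(adjacency$isolated) == adjacency$n) {
    stop("all areas are isolated: no spatial structure to fit")
  }
  fix <- !is.null(fix_variances)
  set.seed(config$seed)
  res <- bym_mcmc_cpp(
    y = as.numeric(y), E = as.numeric(E), X = X,
    nb = adjacency$nb, comp = adjacency$components,
    prior_var_alpha = config$prior_var_alpha,
    prior_var_beta = config$prior_var_beta,
    a = config$ig_shape, b = config$ig_scale,
    n_iter = config$n_iter, n_burnin = config$n_burnin, thin = config$thin,
    keep_effects = keep_effects,
    fix_variances = fix,
    sigma2_u_fix = if (fix) fix_variances$sigma2_u else 0,
    sigma2_v_fix = if (fix) fix_variances$sigma2_v else 0,
    update_u = update_u, update_v = update_v)
  res$area_ids <- ids
  res$beta_names <- colnames(X)
  res$config <- config
  res$rounding_discrepancy <- rounding_discrepancy
  res$n <- length(y)
  class(res) <- "bym_chain"
  res
}

.quintile_dummies <- function(q) {
  if (!all(q %in% 1:5)) stop("quintiles must lie in 1..5")
  X <- vapply(2:5, function(k) as.numeric(q == k), numeric(length(q)))
  colnames(X) <- paste0("beta_q", 2:5)
  X
}

.subset_adjacency <- function(adjacency, keep) {
  ids <- adjacency$ids[keep]
  trip <- .triplets(adjacency$W[keep, keep, drop = FALSE])
  edges <- cbind(trip$i, trip$j)[trip$i < trip$j, , drop = FALSE]
  if (!nrow(edges)) edges <- matrix(integer(), 0, 2)
  new_adjacency(ids, edges)
}

#' @export
print.bym_chain <- function(x, ...) {
  cat(sprintf("bym_chain: %d areas, %d retained draws, %s covariates\n",
              x$n, length(x$alpha),
              if (length(x$beta_names)) length(x$beta_names) else "no"))
  cat(sprintf("  acceptance: alpha %.2f, u %.2f, v %.2f\n",
              x$accept_alpha, x$accept_u, x$accept_v))
  invisible(x)
}

# retained scalar parameters as a draws x p matrix
.chain_param_matrix <- function(chain) {
  d <- cbind(alpha = chain$alpha)
  if (length(chain$beta_names)) {
    b <- chain$beta
    colnames(b) <- chain$beta_names
    d <- cbind(d, b)
  }
  cbind(d, sigma2_u = chain$sigma2_u, sigma2_v = chain$sigma2_v)
}

#' Posterior summary of a BYM chain
#'
#' Reports, for every scalar parameter, the posterior median and equal-
#' tailed 95% credible interval (2.5/97.5 empirical percentiles) plus the
#' Geweke z-score; the fraction of spatial variation, defined as the
#' posterior median across draws of `var(u) / (var(u) + var(v))` with
#' variances taken empirically across areas; and the per-area fitted SIR,
#' the posterior median of `exp(mu_i)`.
#'
#' @param object a [fit_bym()] chain (>= 100 retained draws).
#' @param ... unused.
#' @return An object of class `bym_summary`: list with `parameters` (data
#'   frame: parameter, median, ci_low, ci_high, geweke_z),
#'   `fraction_spatial_variation`, and `fitted_sir` (data frame: area_id,
#'   fitted_sir, sd).
#' @export
summary.bym_chain <- function(object, ...) {
  if (length(object$alpha) < 100L) stop("need at least 100 retained draws")
  d <- .chain_param_matrix(object)
  qs <- t(apply(d, 2L, quantile, probs = c(.5, .025, .975), names = FALSE))
  gz <- geweke_diagnostics(object)
  parameters <- data.frame(parameter = colnames(d),
                           median = qs[, 1], ci_low = qs[, 2],
                           ci_high = qs[, 3], geweke_z = as.numeric(gz),
                           row.names = NULL)
  ratio <- object$empvar_u / (object$empvar_u + object$empvar_v)
  frac <- median(ratio[is.finite(ratio)])
  fit <- exp(object$mu)
  fitted_sir <- data.frame(
    area_id = object$area_ids,
    fitted_sir = apply(fit, 1L, median),
    sd = apply(fit, 1L, sd), row.names = NULL)
  structure(list(parameters = parameters,
                 fraction_spatial_variation = frac,
                 fitted_sir = fitted_sir,
                 accept = c(alpha = object$accept_alpha,
                            beta = object$accept_beta,
                            u = object$accept_u, v = object$accept_v)),
            class = "bym_summary")
}

#' @export
print.bym_summary <- function(x, ...) {
  df <- x$parameters
  cat("Posterior summary (median [95% CI], Geweke z):\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s %8.4f [%8.4f, %8.4f]  z = %5.2f\n",
                df$parameter[i], df$median[i], df$ci_low[i], df$ci_high[i],
                df$geweke_z[i]))
  }
  cat(sprintf("Fraction of spatial variation: %.2f\n",
              x$fraction_spatial_variation))
  invisible(x)
}
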
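#' Scenario configuration for the synthetic five-level geography
#'
#' The default scenario is a desk-scale emulation of a state-wide
#' five-level statistical geography: 4096 finest-level cells (mesh-block
#' analogue) nesting into 1024, 64, 16 and 4 progressively coarser levels,
#' mirroring the strongly decreasing area counts of real hierarchies.
#' Populations are drawn log-normal with median about 82 persons per
#' finest cell (right-skewed, as observed for mesh blocks) and split over
#' `K = 18` five-year age strata.  Counts are generated at the third-finest
#' level (the SA2 analogue, where such data are realistically available)
#' from the BYM data model itself — a spatially structured field plus
#' unstructured noise on the log relative risk — and then moved to every
#' other level by population-weighted correspondences.  The default
#' expected state total of 1229 cases keeps the finest level in the sparse
#' regime of about 0.3 cases per area.
#'
#' @param nesting integer vector of per-level area counts, fine to coarse;
#'   each level must be a square grid that coarsens evenly into the next.
#' @param level_names names for the levels (defaults to
#'   mesh/sa1/sa2/sa3/sa4 when five levels are given).
#' @param K number of age strata (default 18 five-year groups, 0-4 .. 85+).
#' @param total_cases_target expected state-wide case count before
#'   relative-risk effects.
#' @param alpha_true,beta_true generative intercept and quintile effects
#'   (quintiles 2-5 against quintile 1); the default effect sizes are
#'   typical of area-level socio-economic gradients in cancer incidence.
#' @param sigma2_u_true empirical variance of the structured spatial field.
#' @param sigma2_v_true variance of the unstructured effects.
#' @param rho spatial-dependence parameter of the generative proper-CAR
#'   field, in `[0, 1)`.
#' @param zero_pop_frac fraction of finest areas given zero population, to
#'   exercise the exclusion rule.
#' @param generative_level level index (from finest) at which counts are
#'   simulated; default 3 (SA2 analogue).
#' @param seed integer seed driving all simulation randomness.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(nesting = c(4096L, 1024L, 64L, 16L, 4L),
                            level_names = NULL, K = 18L,
                            total_cases_target = 1229,
                            alpha_true = 0,
                            beta_true = c(-0.13, -0.23, -0.29, -0.46),
                            sigma2_u_true = 0.05, sigma2_v_true = 0.005,
                            rho = 0.95, zero_pop_frac = 0.02,
                            generative_level = 3L, seed = 1L) {
  nesting <- as.integer(nesting)
  if (any(diff(nesting) >= 0)) stop("nesting must be strictly decreasing")
  sides <- sqrt(nesting)
  if (any(sides != round(sides))) stop("each level must be a square grid")
  if (any(sides[-length(sides)] %% sides[-1] != 0)) {
    stop("each level's grid side must divide the finer level's side")
  }
  if (is.null(level_names)) {
    level_names <- if (length(nesting) == 5L) {
      c("mesh", "sa1", "sa2", "sa3", "sa4")
    } else paste0("level", seq_along(nesting))
  }
  stopifnot(length(level_names) == length(nesting),
            K >= 1, total_cases_target > 0, rho >= 0, rho < 1,
            length(beta_true) == 4L, zero_pop_frac >= 0, zero_pop_frac < 1,
            generative_level >= 1, generative_level <= length(nesting))
  structure(list(nesting = nesting, level_names = level_names,
                 K = as.integer(K), total_cases_target = total_cases_target,
                 alpha_true = alpha_true, beta_true = beta_true,
                 sigma2_u_true = sigma2_u_true, sigma2_v_true = sigma2_v_true,
                 rho = rho, zero_pop_frac = zero_pop_frac,
                 generative_level = as.integer(generative_level),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Build the synthetic nested hierarchy with adjacency and geometry
#'
#' The finest level is a unit-square grid; every coarser level merges
#' equal square blocks of children.  Queen adjacency is built per level,
#' and each area carries its rectangle polygon so maps can be exported as
#' GeoJSON.
#'
#' @param config a [scenario_config()].
#' @return An [area_hierarchy()] with `$adjacency` and `$geometry` filled.
#' @export
make_synthetic_hierarchy <- function(config) {
  sides <- as.integer(sqrt(config$nesting))
  lv <- config$level_names
  ids <- list(); membership <- list(); adjacency <- list(); geometry <- list()
  cell <- sides[1L] / sides                      # cell width per level
  for (k in seq_along(lv)) {
    s <- sides[k]
    id <- sprintf("%s_%04d", lv[k], seq_len(s * s))
    ids[[lv[k]]] <- id
    adjacency[[lv[k]]] <- grid_adjacency(s, s, "queen", ids = id)
    w <- cell[k]
    r <- rep(seq_len(s), each = s); c <- rep(seq_len(s), s)  # row-major
    geometry[[lv[k]]] <- lapply(seq_len(s * s), function(i) {
      x0 <- (c[i] - 1) * w; y0 <- (r[i] - 1) * w
      cbind(x = c(x0, x0 + w, x0 + w, x0, x0),
            y = c(y0, y0, y0 + w, y0 + w, y0))
    })
    if (k > 1L) {
      b <- sides[k - 1L] / s
      rc <- sides[k - 1L]
      rr <- rep(seq_len(rc), each = rc); cc <- rep(seq_len(rc), rc)
      parent_idx <- (ceiling(rr / b) - 1L) * s + ceiling(cc / b)
      membership[[lv[k - 1L]]] <- stats::setNames(id[parent_idx],
                                                  ids[[lv[k - 1L]]])
    }
  }
  area_hierarchy(lv, ids, membership, adjacency = adjacency,
                 geometry = geometry)
}

# fixed stylised age distribution over 18 five-year strata (0-4 .. 85+),
# summing to 1
.age_distribution <- function(K) {
  base <- c(6.2, 6.2, 6.0, 6.0, 6.6, 7.0, 7.0, 6.8, 6.6, 6.5, 6.3, 6.0,
            5.6, 5.0, 4.2, 3.2, 2.4, 2.4) / 100
  if (K == 18L) return(base)
  # other K: interpolate the same shape
  p <- stats::approx(seq_len(18L), base, n = K)$y
  p / sum(p)
}

# stylised increasing-with-age incidence schedule (relative rates)
.incidence_schedule <- function(K) {
  exp(seq(-4, 2, length.out = K))
}

#' Simulate age-stratified populations at the finest level
#'
#' Per-area totals are log-normal (median about 82, right-skewed); a
#' configurable fraction of areas receives zero population.  Totals are
#' split across the age strata multinomially around a fixed age
#' distribution, so stratum counts sum exactly to each area's total.
#'
#' @param hierarchy from [make_synthetic_hierarchy()].
#' @param config a [scenario_config()].
#' @return The hierarchy with populations attached at every level (see
#'   [set_population()]).
#' @export
simulate_population <- function(hierarchy, config) {
  finest <- hierarchy$levels[1L]
  ids <- hierarchy$ids[[finest]]
  n <- length(ids)
  tot <- pmax(round(rlnorm(n, meanlog = log(82), sdlog = 0.5)), 1)
  n_zero <- floor(config$zero_pop_frac * n)
  if (n_zero > 0) tot[sample.int(n, n_zero)] <- 0
  p_age <- .age_distribution(config$K)
  pop <- matrix(0, n, config$K, dimnames = list(ids, NULL))
  nz <- which(tot > 0)
  pop[nz, ] <- t(vapply(nz, function(i) rmultinom(1L, tot[i], p_age)[, 1L],
                        numeric(config$K)))
  set_population(hierarchy, pop)
}

# draw one centred realisation of a proper-CAR field on an adjacency,
# rescaled to a target empirical variance
.car_field <- function(adjacency, rho, target_var) {
  n <- adjacency$n
  D <- Matrix::Diagonal(n, pmax(lengths(adjacency$nb), 1))
  Q <- as.matrix(D - rho * adjacency$W)
  R <- chol(Q)                       # Q = R'R  =>  u = R^{-1} z ~ N(0, Q^{-1})
  u <- backsolve(R, rnorm(n))
  u <- u - mean(u)
  u * sqrt(target_var) / sd(u)
}

#' Simulate a smooth deprivation-style covariate
#'
#' At the generative level the score is a broad spatial gradient plus a
#' CAR-correlated field — a smooth surface like an area-level
#' socio-economic index (scores around 1000, lower = more disadvantaged).
#' The score is then disaggregated (copied) to finer levels and aggregated
#' (population-weighted mean) to coarser ones, and population-weighted
#' quintiles are assigned per level.
#'
#' @param hierarchy hierarchy with populations set.
#' @param config a [scenario_config()].
#' @return Named list per level of covariate tables
#'   (`area_id`, `score`, `quintile`).
#' @export
simulate_covariate <- function(hierarchy, config) {
  lv <- hierarchy$levels
  native <- lv[config$generative_level]
  adj <- hierarchy$adjacency[[native]]
  n <- adj$n
  s <- as.integer(sqrt(n))
  r <- rep(seq_len(s), each = s); c <- rep(seq_len(s), s)
  grad <- scale((r + c) / 2)[, 1L]
  field <- .car_field(adj, config$rho, 1)
  score <- 1000 + 40 * grad + 40 * field
  names(score) <- hierarchy$ids[[native]]
  out <- list()
  for (lev in lv) {
    if (lev == native) {
      sc <- score
    } else {
      corr <- membership_to_correspondence(hierarchy, native, lev)
      sc <- transfer_score(score, corr,
                           populations = level_population(hierarchy, native))
    }
    pop <- level_population(hierarchy, lev)
    out[[lev]] <- data.frame(area_id = names(sc), score = as.numeric(sc),
                             quintile = assign_quintiles(sc, pop),
                             row.names = NULL)
  }
  out
}

#' Simulate sparse spatially-correlated counts and move them across levels
#'
#' At the generative level, expected counts `E` are formed by applying a
#' stylised increasing-with-age incidence schedule to each area's age
#' structure, scaled so the state-wide total equals
#' `total_cases_target`.  Log relative risks are
#' `mu_i = alpha + x_i'beta + u_i + v_i` with `u` a centred proper-CAR
#' field (the proper stand-in for the intrinsic prior, which cannot be
#' sampled directly) and `v` iid normal; counts are
#' `y_i ~ Poisson(E_i e^{mu_i})` and are allocated to age strata in
#' proportion to expected stratum risk.  The state-wide strata reference is
#' then rebuilt from the *simulated* counts — as an analyst would — so the
#' expected counts used downstream satisfy `sum(E) = sum(y)` exactly, and
#' outcome tables (y, E, SIR) are produced at every level: exact summation
#' upward, population-share disaggregation downward (fractional by
#' default).
#'
#' @param hierarchy hierarchy with populations set.
#' @param covariate output of [simulate_covariate()].
#' @param config a [scenario_config()].
#' @return List with `outcome_by_level` (named list of outcome tables),
#'   `reference` (the [build_strata_reference()] built from the simulated
#'   counts), `generative_level`, and `truth` (u, v, mu and the generative
#'   parameters).
#' @export
simulate_counts <- function(hierarchy, covariate, config) {
  lv <- hierarchy$levels
  native <- lv[config$generative_level]
  pop_g <- hierarchy$pop[[native]]
  rate0 <- .incidence_schedule(config$K)
  E0 <- drop(pop_g %*% rate0)
  E0 <- E0 * config$total_cases_target / sum(E0)

  adj <- hierarchy$adjacency[[native]]
  keep <- which(E0 > 0)
  u <- numeric(length(E0)); v <- numeric(length(E0))
  if (config$sigma2_u_true > 0) u <- .car_field(adj, config$rho,
                                                config$sigma2_u_true)
  if (config$sigma2_v_true > 0) v <- rnorm(length(E0), 0,
                                           sqrt(config$sigma2_v_true))
  q <- covariate[[native]]$quintile[match(hierarchy$ids[[native]],
                                          covariate[[native]]$area_id)]
  X <- .quintile_dummies(q)
  mu <- config$alpha_true + drop(X %*% config$beta_true) + u + v
  y <- rpois(length(E0), E0 * exp(mu))

  # allocate each area's count over strata by expected stratum risk
  y_ik <- matrix(0, nrow(pop_g), config$K,
                 dimnames = list(rownames(pop_g), NULL))
  for (i in seq_len(nrow(pop_g))) {
    if (y[i] == 0) next
    w <- pop_g[i, ] * rate0
    y_ik[i, ] <- rmultinom(1L, y[i], w / sum(w))[, 1L]
  }
  reference <- build_strata_reference(y_ik, hierarchy$pop[[lv[1L]]])

  # expected counts: computed at the finest level, aggregated upward
  E_fine <- expected_counts(hierarchy$pop[[lv[1L]]], reference)
  names(E_fine) <- hierarchy$ids[[lv[1L]]]
  E_by_level <- list(); E_by_level[[lv[1L]]] <- E_fine
  for (k in seq.int(2L, length(lv))) {
    corr <- membership_to_correspondence(hierarchy, lv[1L], lv[k])
    E_by_level[[lv[k]]] <- transfer_counts(E_fine, corr)
  }

  # counts: exact aggregation up, population-share disaggregation down
  y_native <- stats::setNames(as.numeric(y), hierarchy$ids[[native]])
  y_by_level <- list(); y_by_level[[native]] <- y_native
  for (lev in setdiff(lv, native)) {
    corr <- membership_to_correspondence(hierarchy, native, lev)
    y_by_level[[lev]] <- transfer_counts(y_native, corr)
  }

  outcome_by_level <- lapply(stats::setNames(lv, lv), function(lev) {
    compute_sir(y_by_level[[lev]], E_by_level[[lev]],
                area_id = hierarchy$ids[[lev]])
  })
  list(outcome_by_level = outcome_by_level,
       reference = reference,
       generative_level = native,
       truth = list(u = u, v = v, mu = mu,
                    alpha = config$alpha_true, beta = config$beta_true,
                    keep = keep))
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: builds the hierarchy, simulates populations,
#' covariate and counts under `config$seed`, and returns everything the
#' pipeline needs.  Identical configs (and seeds) give byte-identical
#' output.
#'
#' @param config a [scenario_config()].
#' @return List with `hierarchy`, `covariate_by_level`, `outcome_by_level`,
#'   `reference`, `truth`, `generative_level`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  set.seed(config$seed)
  h <- make_synthetic_hierarchy(config)
  h <- simulate_population(h, config)
  covariate <- simulate_covariate(h, config)
  counts <- simulate_counts(h, covariate, config)
  c(list(hierarchy = h, covariate_by_level = covariate, config = config),
    counts)
}
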
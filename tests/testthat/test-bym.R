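test_that("log-likelihood equals an independent Poisson log-pmf oracle", {
  # single area, y = 2, E = 1, mu = 0: log(e^-1 / 2) = -1 - log 2
  expect_equal(log_likelihood_bym(y = 2, E = 1, mu = 0), -1 - log(2),
               tolerance = 1e-12)
  # closed form at y = E, mu = 0
  y <- c(3, 1, 4)
  expect_equal(log_likelihood_bym(y, y, mu = rep(0, 3)),
               sum(y * log(y) - y - lgamma(y + 1)), tolerance = 1e-12)
  # random states vs dpois oracle
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    y <- rpois(n, 5); E <- rgamma(n, 2, 0.5) + 0.1
    X <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
    alpha <- rnorm(1); beta <- rnorm(4, 0, 0.3)
    u <- rnorm(n, 0, 0.5); v <- rnorm(n, 0, 0.2)
    mu <- alpha + drop(X %*% beta) + u + v
    oracle <- sum(dpois(y, E * exp(mu), log = TRUE))
    expect_equal(log_likelihood_bym(y, E, alpha = alpha, beta = beta,
                                    u = u, v = v, X = X),
                 oracle, tolerance = 1e-10)
  }
  expect_error(log_likelihood_bym(1, 1, mu = Inf), "non-finite")
})

test_that("CAR full conditional matches its formula and a dense oracle", {
  adj <- build_adjacency(ids = c("i", "a", "b"),
                         edge_list = rbind(c("i", "a"), c("i", "b")))
  got <- car_conditional(c(0, 1, 1), 1, adj, sigma2_u = 2)
  expect_equal(got$mean, 1)
  expect_equal(got$variance, 1)

  adj3 <- build_adjacency(ids = c("i", "a", "b", "c"),
                          edge_list = rbind(c("i", "a"), c("i", "b"),
                                            c("i", "c")))
  got3 <- car_conditional(c(9, 0, 0, 0), 1, adj3, sigma2_u = 3)
  expect_equal(got3$mean, 0)
  expect_equal(got3$variance, 1)

  set.seed(77)
  adj6 <- random_graph_adjacency(6)
  u <- rnorm(6)
  for (i in 1:6) {
    expect_equal(car_conditional(u, i, adj6, 1.3),
                 car_conditional_oracle(u, i, adj6, 1.3), tolerance = 1e-12)
  }
  iso <- build_adjacency(ids = c("a", "b", "c"),
                         edge_list = rbind(c("a", "b")))
  expect_error(car_conditional(rnorm(3), 3, iso, 1), "isolated")
})

test_that("sigma2_v Gibbs draw follows the conjugate Inverse-Gamma", {
  # v = 0, n = 10, a = 1, b = 0.01: IG(6, 0.01) with mean 0.002
  set.seed(1)
  draws <- replicate(20000, gibbs_update_sigma2_v(rep(0, 10), 1, 0.01))
  expect_equal(mean(draws), 0.01 / 5, tolerance = 0.05)
  # distributional check: 1/draws ~ Gamma(6, rate 0.01)
  ks <- ks.test(1 / draws, pgamma, shape = 6, rate = 0.01)
  expect_gt(ks$p.value, 0.01)
  # fixed seed reproduces the draw
  set.seed(99); d1 <- gibbs_update_sigma2_v(rnorm(5), 1, 0.01)
  set.seed(99); d2 <- gibbs_update_sigma2_v(rnorm(5), 1, 0.01)
  expect_identical(d1, d2)
})

test_that("sigma2_u Gibbs update uses pairwise differences and CAR rank", {
  path <- build_adjacency(ids = c("a", "b", "c"),
                          edge_list = rbind(c("a", "b"), c("b", "c")))
  # u = (-1, 0, 1): pairwise sum = 2, so scale = b + 1
  par <- maupbym:::.car_ig_params(c(-1, 0, 1), path, a = 1, b = 0.01)
  expect_equal(par$rate, 0.01 + 1)
  expect_equal(par$shape, 1 + (3 - 1) / 2)
  # u constant within each component: scale stays b
  two <- build_adjacency(ids = letters[1:5],
                         edge_list = rbind(c("a", "b"), c("b", "c"),
                                           c("d", "e")))
  par2 <- maupbym:::.car_ig_params(c(4, 4, 4, -2, -2), two, 1, 0.01)
  expect_equal(par2$rate, 0.01)
  expect_equal(par2$shape, 1 + (5 - 2) / 2)  # a + (n - c)/2, c = 2
  # distributional check on the path graph
  set.seed(2)
  draws <- replicate(20000, gibbs_update_sigma2_u(c(-1, 0, 1), path, 1, 0.01))
  ks <- ks.test(1 / draws, pgamma, shape = 2, rate = 1.01)
  expect_gt(ks$p.value, 0.01)
})

test_that("same seed gives identical chains; config is validated", {
  set.seed(50)
  adj <- grid_adjacency(5, 8)
  dat <- simulate_bym_data(adj, beta_true = c(-0.1, -0.2, -0.3, -0.45))
  cfg <- bym_config(n_iter = 3000, n_burnin = 1000, thin = 2, seed = 123)
  f1 <- fit_bym(dat$outcome, dat$covariate, adj, cfg)
  f2 <- fit_bym(dat$outcome, dat$covariate, adj, cfg)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$mu, f2$mu)
  expect_error(bym_config(n_iter = 100, n_burnin = 200), "n_burnin")
  expect_true(bym_config(full_scale = TRUE)$n_iter == 1500000L)
})

test_that("intercept-only fit with random effects off recovers sum(y)/sum(E)", {
  set.seed(60)
  adj <- grid_adjacency(6, 6)
  E <- rgamma(36, 20, 1)
  y <- rpois(36, E * 1.4)
  out <- data.frame(area_id = adj$ids, y = y, E = E)
  cfg <- bym_config(n_iter = 20000, n_burnin = 5000, thin = 5, seed = 4,
                    include_covariate = FALSE)
  fit <- fit_bym(out, NULL, adj, cfg,
                 fix_variances = list(sigma2_u = 1e-8, sigma2_v = 1e-8),
                 update_u = FALSE, update_v = FALSE)
  post_mean <- mean(exp(fit$alpha))
  glm_hat <- sum(y) / sum(E)
  mc_se <- sd(exp(fit$alpha)) / sqrt(200)  # generous ESS allowance
  expect_lt(abs(post_mean - glm_hat), 4 * mc_se + 0.02 * glm_hat)
})

test_that("u respects the per-component sum-to-zero constraint every draw", {
  set.seed(61)
  adj <- grid_adjacency(4, 5)
  dat <- simulate_bym_data(adj, beta_true = rep(0, 4))
  cfg <- bym_config(n_iter = 2000, n_burnin = 500, thin = 1, seed = 9,
                    include_covariate = FALSE)
  fit <- fit_bym(dat$outcome, NULL, adj, cfg, keep_effects = TRUE)
  expect_lt(max(abs(rowSums(fit$u_draws))), 1e-10)
})

test_that("with variances pinned near zero, fitted SIRs shrink to sum(y)/sum(E)", {
  set.seed(62)
  adj <- grid_adjacency(5, 5)
  E <- rgamma(25, 30, 1)
  y <- rpois(25, E * runif(25, 0.3, 3))   # strong heterogeneity
  out <- data.frame(area_id = adj$ids, y = y, E = E)
  cfg <- bym_config(n_iter = 15000, n_burnin = 5000, thin = 5, seed = 10,
                    include_covariate = FALSE)
  fit <- fit_bym(out, NULL, adj, cfg,
                 fix_variances = list(sigma2_u = 1e-9, sigma2_v = 1e-9))
  sm <- summary(fit)
  expect_lt(max(abs(sm$fitted_sir$fitted_sir - sum(y) / sum(E))), 0.02)
})

test_that("zero-expected-count areas are dropped before fitting", {
  set.seed(63)
  adj <- grid_adjacency(3, 3)
  out <- data.frame(area_id = adj$ids, y = c(rpois(8, 5), 0),
                    E = c(rgamma(8, 5, 1), 0))
  cfg <- bym_config(n_iter = 1000, n_burnin = 200, thin = 1, seed = 2,
                    include_covariate = FALSE)
  expect_warning(fit <- fit_bym(out, NULL, adj, cfg), "E = 0")
  expect_equal(fit$n, 8L)
})

test_that("posterior summary reports percentiles, spatial fraction, Geweke", {
  # hand-built chain object: percentiles vs a sorted-array oracle
  set.seed(70)
  nkeep <- 500; n <- 6
  draws <- rnorm(nkeep)
  chain <- structure(list(
    alpha = draws, beta = matrix(numeric(), nkeep, 0),
    sigma2_u = rgamma(nkeep, 2), sigma2_v = rgamma(nkeep, 2),
    empvar_u = rep(9, nkeep), empvar_v = rep(1, nkeep),
    mu = matrix(rep(log(2), n * nkeep), n),
    area_ids = paste0("a", 1:n), beta_names = character(),
    accept_alpha = .45, accept_beta = NA, accept_u = .45, accept_v = .45,
    n = n), class = "bym_chain")
  sm <- summary(chain)
  sorted <- sort(draws)
  oracle_q <- quantile(sorted, c(.5, .025, .975), names = FALSE)
  row <- sm$parameters[sm$parameters$parameter == "alpha", ]
  expect_equal(c(row$median, row$ci_low, row$ci_high), oracle_q)
  expect_true(all(sm$parameters$ci_low <= sm$parameters$median &
                  sm$parameters$median <= sm$parameters$ci_high))
  expect_equal(sm$fraction_spatial_variation, 0.9)
  expect_equal(sm$fitted_sir$fitted_sir, rep(2, n))
  # degenerate constant chain: zero-width interval
  chain$alpha <- rep(1.5, nkeep)
  sm2 <- summary(chain)
  row2 <- sm2$parameters[sm2$parameters$parameter == "alpha", ]
  expect_equal(row2$ci_high - row2$ci_low, 0)
  chain$alpha <- draws[1:50]
  expect_error(summary(chain), "100")
})

test_that("posterior covers generative quintile effects at desk scale", {
  set.seed(80)
  adj <- grid_adjacency(10, 20)
  dat <- simulate_bym_data(adj, beta_true = c(-0.1, -0.2, -0.3, -0.45))
  cfg <- bym_config(n_iter = 20000, n_burnin = 5000, thin = 5, seed = 17)
  fit <- fit_bym(dat$outcome, dat$covariate, adj, cfg)
  sm <- summary(fit)
  b <- sm$parameters[grepl("beta", sm$parameters$parameter), ]
  expect_equal(b$median, c(-0.1, -0.2, -0.3, -0.45), tolerance = 0.6)
  covered <- b$ci_low <= c(-0.1, -0.2, -0.3, -0.45) &
             c(-0.1, -0.2, -0.3, -0.45) <= b$ci_high
  expect_gte(sum(covered), 3)
})
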
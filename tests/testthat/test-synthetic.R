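test_that("grid hierarchy nests 16 -> 4 -> 1 with conserved populations", {
  tiny <- tiny_hierarchy()
  h <- tiny$h
  expect_equal(lengths(h$ids), c(cell = 16L, block = 4L, root = 1L))
  expect_true(all(table(h$membership$cell) == 4))
  expect_true(all(table(h$membership$block) == 4))
  expect_true(validate_hierarchy(h))
  expect_equal(sum(h$pop$root), sum(tiny$pop))
})

test_that("coarsened-level adjacency equals polygon-derived adjacency", {
  tiny <- tiny_hierarchy()
  h <- tiny$h
  adj_geom <- build_adjacency(ids = h$ids$block,
                              polygons = h$geometry$block)
  expect_equal(as.matrix(adj_geom$W), as.matrix(h$adjacency$block$W))
  # and via the GeoJSON round trip
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(h, "block", path = path)
  gj <- read_geojson(path)
  adj_gj <- build_adjacency(ids = gj$ids, polygons = gj$polygons)
  expect_equal(as.matrix(adj_gj$W[h$ids$block, h$ids$block]),
               as.matrix(h$adjacency$block$W))
})

test_that("invalid nestings are rejected", {
  expect_error(scenario_config(nesting = c(15, 4, 1)), "square")
  expect_error(scenario_config(nesting = c(16, 9, 1)), "divide")
  expect_error(scenario_config(nesting = c(16, 16, 1)), "decreasing")
})

test_that("simulated populations have realistic scale and exact strata", {
  cfg <- scenario_config(nesting = c(4096L, 1024L, 64L, 16L, 4L), seed = 5)
  set.seed(cfg$seed)
  h <- make_synthetic_hierarchy(cfg)
  h <- simulate_population(h, cfg)
  tot <- level_population(h, "mesh")
  expect_equal(median(tot[tot > 0]), 82, tolerance = 13 / 82)  # in [70, 95]
  expect_gt(max(tot), 5 * median(tot[tot > 0]))                # right skew
  expect_equal(sum(tot == 0), floor(cfg$zero_pop_frac * 4096))
  expect_true(all(rowSums(h$pop$mesh) == tot))                 # multinomial exact
  expect_true(validate_hierarchy(h))
})

test_that("covariate is smooth, population-balanced across quintiles", {
  cfg <- scenario_config(seed = 6)
  set.seed(cfg$seed)
  h <- make_synthetic_hierarchy(cfg)
  h <- simulate_population(h, cfg)
  cov <- simulate_covariate(h, cfg)
  native <- cfg$level_names[cfg$generative_level]
  tab <- cov[[native]]
  pop <- level_population(h, native)
  shares <- tapply(pop[tab$area_id], tab$quintile, sum) / sum(pop)
  expect_true(all(abs(shares - 0.2) < 0.02))
  mo <- morans_i_test(tab$score, h$adjacency[[native]],
                      n_permutations = 999, seed = 1)
  expect_lte(mo$p_value, 0.01)
  # disaggregated scores are inherited unchanged from the ancestor
  anc <- maupbym:::.ancestor_map(h, "mesh", native)
  mesh_scores <- cov$mesh$score[match(names(anc), cov$mesh$area_id)]
  expect_equal(mesh_scores,
               tab$score[match(unname(anc), tab$area_id)])
})

test_that("counts follow the generative Poisson model and conserve totals", {
  # beta = 0, variances 0: sum(y)/sum(E0) ~ e^alpha within 3 Poisson se
  cfg0 <- scenario_config(nesting = c(256L, 64L, 16L), K = 5L,
                          level_names = c("fine", "mid", "coarse"),
                          total_cases_target = 600, alpha_true = 0.3,
                          beta_true = rep(0, 4), sigma2_u_true = 0,
                          sigma2_v_true = 0, zero_pop_frac = 0,
                          generative_level = 2L, seed = 7)
  sim0 <- simulate_scenario(cfg0)
  lam <- cfg0$total_cases_target * exp(cfg0$alpha_true)
  total <- sum(sim0$outcome_by_level$mid$y)
  expect_lt(abs(total - lam), 3 * sqrt(lam))

  # default scenario: sparse finest level and autocorrelated structured field
  cfg <- scenario_config(seed = 8)
  sim <- simulate_scenario(cfg)
  mesh_mean <- mean(sim$outcome_by_level$mesh$y)
  expect_equal(mesh_mean, cfg$total_cases_target / 4096, tolerance = 0.35)
  mo_u <- morans_i_test(sim$truth$u, sim$hierarchy$adjacency$sa2,
                        n_permutations = 999, seed = 2)
  expect_lte(mo_u$p_value, 0.01)

  # totals conserved at every level; E sums to y total (mean SIR 1)
  totals_y <- vapply(sim$outcome_by_level, function(o) sum(o$y), 0)
  expect_true(all(abs(totals_y - totals_y[1]) < 1e-9))
  totals_E <- vapply(sim$outcome_by_level, function(o) sum(o$E), 0)
  expect_true(all(abs(totals_E - totals_y[1]) < 1e-9))
})

test_that("identical config and seed give byte-identical scenarios", {
  cfg <- scenario_config(nesting = c(64L, 16L, 4L), K = 3L,
                         level_names = c("a", "b", "c"),
                         total_cases_target = 80, generative_level = 2L,
                         seed = 33)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$outcome_by_level, s2$outcome_by_level)
  expect_identical(s1$covariate_by_level, s2$covariate_by_level)
  expect_identical(s1$hierarchy$pop, s2$hierarchy$pop)
})
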
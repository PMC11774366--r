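# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (dense double loops, closed forms)
# and independent of the package's implementations.

# unit-square polygon with lower-left corner (x0, y0) and width w
square_poly <- function(x0, y0, w = 1) {
  cbind(x = c(x0, x0 + w, x0 + w, x0, x0),
        y = c(y0, y0, y0 + w, y0 + w, y0))
}

# list of polygons for an nr x nc grid of unit squares, row-major
grid_polygons <- function(nr, nc, w = 1) {
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- k + 1L
    out[[k]] <- square_poly((c - 1) * w, (r - 1) * w, w)
  }
  out
}

# random connected-ish graph on n nodes: spanning path plus extra edges
random_graph_adjacency <- function(n, extra = n) {
  edges <- cbind(1:(n - 1), 2:n)
  if (extra > 0) {
    more <- cbind(sample.int(n, extra, replace = TRUE),
                  sample.int(n, extra, replace = TRUE))
    more <- more[more[, 1] != more[, 2], , drop = FALSE]
    if (nrow(more) > 0) {
      edges <- rbind(edges, cbind(pmin(more[, 1], more[, 2]),
                                  pmax(more[, 1], more[, 2])))
    }
  }
  new_adjacency(paste0("a", seq_len(n)), unique(edges))
}

# dense O(n^2) Moran's I oracle
moran_oracle <- function(x, adjacency, style = "W") {
  W <- as.matrix(adjacency$W)
  keep <- rowSums(W) > 0
  W <- W[keep, keep, drop = FALSE]
  x <- x[keep]
  if (style == "W") W <- sweep(W, 1, rowSums(W), "/")
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# dense evaluation of the CAR full conditional
car_conditional_oracle <- function(u, i, adjacency, sigma2_u) {
  w <- as.matrix(adjacency$W)[i, ]
  list(mean = sum(w * u) / sum(w), variance = sigma2_u / sum(w))
}

# a tiny three-level hierarchy: 16 cells -> 4 blocks -> 1 root, with
# deterministic populations and two age strata
tiny_hierarchy <- function() {
  cfg <- scenario_config(nesting = c(16L, 4L, 1L),
                         level_names = c("cell", "block", "root"),
                         K = 2L, total_cases_target = 40,
                         zero_pop_frac = 0, generative_level = 2L)
  h <- make_synthetic_hierarchy(cfg)
  ids <- h$ids$cell
  pop <- cbind(seq(10, 160, by = 10), seq(20, 320, by = 20))
  rownames(pop) <- ids
  list(h = set_population(h, pop), cfg = cfg, pop = pop)
}

# simulate y, E, covariate at a given adjacency from the BYM data model
# (proper-CAR structured field), for parameter-recovery experiments
simulate_bym_data <- function(adjacency, beta_true, alpha_true = 0,
                              E_mean = 30, sigma2_u = 0.02, sigma2_v = 0.01,
                              rho = 0.9) {
  n <- adjacency$n
  q <- rep_len(1:5, n)[sample.int(n)]
  X <- vapply(2:5, function(k) as.numeric(q == k), numeric(n))
  D <- diag(pmax(lengths(adjacency$nb), 1))
  Q <- D - rho * as.matrix(adjacency$W)
  u <- backsolve(chol(Q), rnorm(n))
  u <- (u - mean(u))
  u <- u * sqrt(sigma2_u) / sd(u)
  v <- rnorm(n, 0, sqrt(sigma2_v))
  E <- E_mean * exp(rnorm(n, 0, 0.2))
  mu <- alpha_true + drop(X %*% beta_true) + u + v
  y <- rpois(n, E * exp(mu))
  list(outcome = data.frame(area_id = adjacency$ids, y = y, E = E,
                            sir = y / E),
       covariate = data.frame(area_id = adjacency$ids, score = q,
                              quintile = q),
       truth = list(alpha = alpha_true, beta = beta_true, u = u, v = v))
}
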
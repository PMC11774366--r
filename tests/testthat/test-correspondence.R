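make_two_level <- function(pops = c(300, 100)) {
  h <- area_hierarchy(
    levels = c("child", "parent"),
    ids = list(child = c("c1", "c2"), parent = "P"),
    membership = list(child = c(c1 = "P", c2 = "P")))
  pop <- matrix(pops, 2, 1, dimnames = list(c("c1", "c2"), NULL))
  set_population(h, pop)
}

test_that("disaggregation weights are population shares; aggregation is exact", {
  h <- make_two_level()
  down <- membership_to_correspondence(h, "parent", "child")
  expect_equal(as.numeric(down$W["P", ]), c(0.75, 0.25))
  up <- membership_to_correspondence(h, "child", "parent")
  expect_equal(as.numeric(up$W[, "P"]), c(1, 1))
  expect_equal(Matrix::rowSums(up$W), c(c1 = 1, c2 = 1))
})

test_that("zero-population source area makes disaggregation shares undefined", {
  h <- make_two_level(c(0, 0))
  expect_error(membership_to_correspondence(h, "parent", "child"),
               "zero total population")
})

test_that("composed correspondences across three levels equal the direct one", {
  tiny <- tiny_hierarchy()
  h <- tiny$h
  direct <- membership_to_correspondence(h, "cell", "root")
  step1 <- membership_to_correspondence(h, "cell", "block")
  step2 <- membership_to_correspondence(h, "block", "root")
  expect_equal(as.matrix(step1$W %*% step2$W), as.matrix(direct$W))
  # and downward: root -> cell equals the product root->block @ block->cell
  d_direct <- membership_to_correspondence(h, "root", "cell")
  d1 <- membership_to_correspondence(h, "root", "block")
  d2 <- membership_to_correspondence(h, "block", "cell")
  expect_equal(as.matrix(d1$W %*% d2$W), as.matrix(d_direct$W))
})

test_that("transfer_counts splits, conserves, and integerises correctly", {
  h <- make_two_level()
  down <- membership_to_correspondence(h, "parent", "child")
  expect_equal(unname(transfer_counts(c(P = 4), down)), c(3, 1))

  # conservation on random share matrices
  set.seed(42)
  for (rep in 1:20) {
    ns <- sample(3:8, 1); nt <- sample(2:6, 1)
    W <- matrix(rgamma(ns * nt, 1), ns)
    W <- W / rowSums(W)
    corr <- structure(list(source_ids = paste0("s", 1:ns),
                           target_ids = paste0("t", 1:nt),
                           direction = "disaggregate",
                           W = Matrix::Matrix(W, sparse = TRUE)),
                      class = "correspondence")
    x <- rpois(ns, 10)
    expect_equal(sum(transfer_counts(x, corr)), sum(x), tolerance = 1e-12)
  }

  # multinomial integerisation: child-1 mean ~ n * p = 3 over 10,000 draws
  set.seed(7)
  draws <- replicate(10000, transfer_counts(c(P = 4), down,
                                            integerise = TRUE)[1])
  expect_true(all(draws == round(draws)))
  expect_equal(mean(draws), 3, tolerance = 0.05 / 3)

  expect_error(transfer_counts(c(P = -1), down), ">= 0")
  expect_error(transfer_counts(c(1, 2, 3), down), "length")
})

test_that("round trip coarse<-fine on population-proportional counts is identity", {
  tiny <- tiny_hierarchy()
  h <- tiny$h
  up <- membership_to_correspondence(h, "cell", "block")
  down <- membership_to_correspondence(h, "block", "cell")
  y_block <- c(5, 10, 2, 8)
  names(y_block) <- h$ids$block
  back <- transfer_counts(transfer_counts(y_block, down), up)
  expect_equal(back, y_block, tolerance = 1e-12)
})

test_that("transfer_score aggregates by population weight and copies downward", {
  h <- make_two_level()
  up <- membership_to_correspondence(h, "child", "parent")
  got <- transfer_score(c(c1 = 900, c2 = 1100), up,
                        populations = level_population(h, "child"))
  expect_equal(unname(got), 950)
  down <- membership_to_correspondence(h, "parent", "child")
  expect_equal(unname(transfer_score(c(P = 1000), down)), c(1000, 1000))
  # round trip on uniform scores is the identity
  expect_equal(unname(transfer_score(transfer_score(c(P = 77), down), up,
                                     populations = level_population(h, "child"))),
               77)
})

test_that("population-weighted quintiles respect cumulative population", {
  expect_equal(unname(assign_quintiles(c(10, 20, 30, 40, 50), rep(1, 5))),
               1:5)
  expect_equal(unname(table(assign_quintiles(1:10, rep(1, 10)))),
               rep(2L, 5), ignore_attr = TRUE)
  # hand-computed cumulative shares: pops (50,50,400,100,200,200), sorted
  # scores; cut points fall inside the heavy third area
  q <- assign_quintiles(scores = 1:6,
                        populations = c(50, 50, 400, 100, 200, 200))
  expect_equal(unname(q), c(1, 1, 1, 3, 4, 5))
  # ties share the first tied element's quintile
  q2 <- assign_quintiles(c(1, 2, 2, 2, 3, 4, 5, 6, 7, 8), rep(1, 10))
  expect_equal(unname(q2[2:4]), rep(q2[[2]], 3))
  expect_error(assign_quintiles(rep(5, 6), rep(1, 6)), "degenerate")
})

test_that("correspondence CSV round trip preserves weights", {
  tiny <- tiny_hierarchy()
  corr <- membership_to_correspondence(tiny$h, "block", "cell")
  path <- withr::local_tempfile(fileext = ".csv")
  write_correspondence(corr, path)
  back <- read_correspondence(path, "block", "cell")
  expect_equal(back$direction, "disaggregate")
  expect_equal(as.matrix(back$W[corr$source_ids, corr$target_ids]),
               as.matrix(corr$W))
})
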
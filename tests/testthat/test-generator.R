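test_that("study sizes are uniform over the inclusive range", {
  set.seed(1)
  expect_equal(draw_study_sizes(7, 90, 90), rep(90L, 7))
  s <- draw_study_sizes(10)
  expect_length(s, 10)
  expect_true(all(s >= 90 & s <= 1238))
  big <- draw_study_sizes(4000)
  expect_equal(mean(big), (90 + 1238) / 2, tolerance = 0.05)
})

test_that("generation is bit-identical under the same seed", {
  a <- simulate_meta_dataset(get_scenario("S2"), k = 6, seed = 99,
                             n_min = 20, n_max = 40)
  b <- simulate_meta_dataset(get_scenario("S2"), k = 6, seed = 99,
                             n_min = 20, n_max = 40)
  expect_identical(a, b)
  s <- child_seed(1, 12345, 7)
  expect_identical(s, child_seed(1, 12345, 7))
  expect_true(s >= 1 && s <= .Machine$integer.max)
})

test_that("variable-level missingness masks exactly half the studies", {
  set.seed(5)
  ds <- simulate_meta_dataset(get_scenario("S1"), k = 10, n_min = 10,
                              n_max = 20, missing = TRUE)
  masked <- vapply(ds$studies, function(s) !all(s$observed), logical(1))
  expect_equal(sum(masked), 5)
  for (s in ds$studies[masked]) {
    expect_equal(colnames(s$Y), c("ATT", "SN", "PBC", "INT"))
    expect_equal(nrow(s$Y), s$n)       # masking is variable-level only
  }
  ds2 <- simulate_meta_dataset(get_scenario("S1"), k = 9, n_min = 10,
                               n_max = 20)
  expect_error(apply_missingness(ds2), "even number")
  set.seed(3); m1 <- apply_missingness(ds)
  set.seed(3); m2 <- apply_missingness(ds)
  expect_identical(m1, m2)
})

test_that("study-mean centering zeroes study means and is idempotent", {
  set.seed(8)
  ds <- simulate_meta_dataset(get_scenario("S3"), k = 6, n_min = 15,
                              n_max = 30, missing = TRUE)
  cds <- center_within(ds)
  for (s in cds$studies) expect_lt(max(abs(colMeans(s$Y))), 1e-12)
  expect_equal(center_within(cds), cds)
})

test_that("IPD collections round-trip through the long-format CSV", {
  set.seed(21)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 6, n_min = 8,
                              n_max = 15, missing = TRUE)
  f <- tempfile(fileext = ".csv")
  write_ipd_csv(ds, f)
  back <- read_ipd_csv(f)
  expect_equal(length(back$studies), 6)
  for (j in 1:6) {
    expect_equal(back$studies[[j]]$observed, ds$studies[[j]]$observed)
    expect_equal(back$studies[[j]]$Y, ds$studies[[j]]$Y,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  unlink(f)
})

test_that("generated moments recover the population covariances", {
  pop <- get_scenario("S3")
  set.seed(77)
  ds <- simulate_meta_dataset(pop, k = 400, n_min = 90, n_max = 400)
  ybar <- t(vapply(ds$studies, function(s) colMeans(s$Y), numeric(5)))
  # between: covariance of study means ~ Sigma_B + Sigma_W * E(1/n)
  corr <- pop$sigma_w * mean(1 / vapply(ds$studies, `[[`, integer(1), "n"))
  expect_lt(max(abs(cov(ybar) - corr - pop$sigma_b)), 0.25)
  # within: pooled within-study covariance ~ Sigma_W
  sw <- matrix(0, 5, 5); dfw <- 0
  for (s in ds$studies) {
    sw <- sw + crossprod(scale(s$Y, scale = FALSE)); dfw <- dfw + s$n - 1
  }
  expect_lt(max(abs(sw / dfw - pop$sigma_w)), 0.02)
})

test_that("equal structures yield sample intraclass correlations near one half", {
  set.seed(123)
  ds <- simulate_meta_dataset(get_scenario("S4"), k = 200, n_min = 100,
                              n_max = 100)
  # balanced one-way ANOVA decomposition per variable
  for (v in c("ATT", "BEH")) {
    y <- lapply(ds$studies, function(s) s$Y[, v])
    n <- 100
    gm <- mean(unlist(y))
    msb <- n * sum((vapply(y, mean, 1) - gm)^2) / (length(y) - 1)
    msw <- sum(vapply(y, function(x) sum((x - mean(x))^2), 1)) /
      (length(y) * (n - 1))
    icc <- (msb - msw) / (msb + (n - 1) * msw)
    expect_equal(icc, 0.5, tolerance = 0.06)
  }
})

test_that("a degenerate between level gives vanishing study-mean spread", {
  pop <- get_scenario("S4")
  tiny <- two_level_population(pop$within,
                               path_model_matrices(0 * pop$between$B,
                                                   1e-16 * pop$between$Psi))
  set.seed(4)
  ds <- simulate_meta_dataset(tiny, k = 5, n_min = 50, n_max = 50)
  mns <- t(vapply(ds$studies, function(s) colMeans(s$Y), numeric(5)))
  # study means differ from zero only through within-level sampling error
  expect_lt(max(abs(mns)), 5 / sqrt(50))
})
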
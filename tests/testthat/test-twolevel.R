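test_that("two-level likelihood matches the dense-matrix oracle", {
  for (masked in c(FALSE, TRUE)) {
    ds <- make_toy_dataset(seed = 10 + masked, masked = masked)
    pop <- get_scenario("S4")
    set.seed(100 + masked)
    for (i in 1:25) {
      SW <- pop$sigma_w * exp(rnorm(1, 0, 0.2)) + random_pd(5) * 0.1
      SB <- random_pd(5) * runif(1, 0.05, 0.5)
      dimnames(SW) <- dimnames(SB) <- list(tpb_variables(), tpb_variables())
      mu <- rnorm(5, 0, 0.3)
      expect_equal(twolevel_loglik(ds, SW, SB, mu),
                   oracle_dense_loglik(ds, SW, SB, mu), tolerance = 1e-8)
    }
  }
})

test_that("a vanishing between level reduces to the pooled i.i.d. likelihood", {
  ds <- make_toy_dataset(seed = 4)
  pop <- get_scenario("S4")
  SW <- pop$sigma_w
  mu <- rep(0.1, 5)
  ll <- twolevel_loglik(ds, SW, diag(1e-14, 5), mu)
  Y <- do.call(rbind, lapply(ds$studies, function(s) s$Y))
  R <- chol(SW)
  z <- backsolve(R, t(sweep(Y, 2, mu)), transpose = TRUE)
  ll_iid <- -0.5 * (length(Y) * log(2 * pi) + 2 * nrow(Y) * sum(log(diag(R))) +
                      sum(z^2))
  expect_equal(ll, ll_iid, tolerance = 1e-6)
})

test_that("the likelihood is invariant to permuting participants in a cluster", {
  ds <- make_toy_dataset(seed = 6)
  pop <- get_scenario("S4")
  ll1 <- twolevel_loglik(ds, pop$sigma_w, pop$sigma_b, rep(0, 5))
  set.seed(1)
  ds$studies[[2]]$Y <- ds$studies[[2]]$Y[sample(ds$studies[[2]]$n), ]
  expect_equal(twolevel_loglik(ds, pop$sigma_w, pop$sigma_b, rep(0, 5)), ll1)
})

test_that("the saturated fit matches a brute-force dense optimizer", {
  set.seed(71)
  ds <- simulate_meta_dataset(get_scenario("S4"), k = 6, n_min = 8, n_max = 8)
  fit <- fit_saturated_twolevel(ds)
  orc <- oracle_saturated_fit(ds)
  expect_true(fit$converged)
  expect_equal(fit$loglik, orc$loglik, tolerance = 1e-5)
})

test_that("log-likelihoods nest: saturated >= partially saturated >= two-level", {
  spec <- tpb_spec()
  for (seed in c(1, 2)) {
    set.seed(seed)
    ds <- simulate_meta_dataset(get_scenario("S2"), k = 20, n_min = 30,
                                n_max = 80, missing = seed == 2)
    sat <- fit_saturated_twolevel(ds)
    ps <- fit_partially_saturated(ds, spec, se = FALSE, saturated = sat)
    tl <- fit_twolevel(ds, spec, spec, se = FALSE, saturated = sat)
    expect_true(all(c(sat$converged, ps$converged, tl$converged)))
    expect_gte(sat$loglik + 1e-6, ps$loglik)
    expect_gte(ps$loglik + 1e-6, tl$loglik)
    expect_identical(ps$df, 2)
    expect_identical(tl$df, 4)
  }
})

test_that("partially saturated and two-level within estimates agree", {
  # with a correctly specified between model the within-level estimates of
  # the two parameterizations coincide
  spec <- tpb_spec()
  set.seed(14)
  diffs <- replicate(3, {
    ds <- simulate_meta_dataset(get_scenario("S3"), k = 30)
    sat <- fit_saturated_twolevel(ds)
    ps <- fit_partially_saturated(ds, spec, se = FALSE, saturated = sat)
    tl <- fit_twolevel(ds, spec, spec, se = FALSE, saturated = sat)
    max(abs(ps$estimates - tl$estimates))
  })
  expect_lt(mean(diffs), 0.005)
})

test_that("two-level fits report between-level paths where modeled", {
  set.seed(40)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 50)
  tl <- fit_twolevel(ds, tpb_spec())
  expect_named(tl$between_estimates,
               c("INT~ATT", "INT~SN", "INT~PBC", "BEH~PBC", "BEH~INT"))
  # between-level behavior-on-intention is far from its within value (0.07)
  expect_gt(tl$between_estimates[["BEH~INT"]], 0.4)
})
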
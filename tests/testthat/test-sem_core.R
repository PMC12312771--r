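test_that("fitting the population covariance recovers the population paths", {
  pop <- get_scenario("S1")
  fit <- fit_path_model_ml(pop$sigma_w, 1000, tpb_spec())
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), c(0.43, 0.16, 0.31, 0.53, 0.07),
               tolerance = 1e-5)
  expect_lt(fit$chi2, 1e-6)
  expect_identical(fit$df, 2)
})

test_that("degrees of freedom follow the free-parameter count", {
  S <- random_pd(5, seed = 3)
  dimnames(S) <- list(tpb_variables(), tpb_variables())
  expect_identical(fit_path_model_ml(S, 500, tpb_spec(), se = FALSE)$df, 2)
  # a just-identified model reproduces any covariance matrix exactly
  sat <- path_model_spec(tpb_variables(),
                         rbind(c("INT", "ATT"), c("INT", "SN"), c("INT", "PBC"),
                               c("BEH", "ATT"), c("BEH", "SN"), c("BEH", "PBC"),
                               c("BEH", "INT")))
  fs <- fit_path_model_ml(S, 500, sat, se = FALSE)
  expect_identical(fs$df, 0)
  expect_lt(fs$chi2, 1e-6)
  # reduced four-variable model is saturated as well
  expect_identical(tpb_spec(FALSE)$npar, 10)
  expect_identical(tpb_spec(FALSE)$df, 0)
})

test_that("ML path estimates equal ordered-regression closed forms", {
  set.seed(9)
  for (i in 1:20) {
    S <- random_pd(5)
    dimnames(S) <- list(tpb_variables(), tpb_variables())
    fit <- fit_path_model_ml(S, 300, tpb_spec(), se = FALSE)
    orc <- oracle_regression_paths(S, tpb_outcomes())
    expect_equal(unname(fit$estimates),
                 unname(c(orc$INT, orc$BEH)), tolerance = 1e-6)
  }
})

test_that("fit measures truncate at zero and flag undefined cases", {
  expect_equal(fit_measures(1.2, 2, 500)$rmsea, 0)
  fm <- fit_measures(2, 2, 10000)
  expect_gt(fm$rmsea_close_p, 0.5)
  expect_true(is.na(fit_measures(3, 0, 500)$rmsea))
})

test_that("cluster-robust point estimates are identical to naive pooling", {
  set.seed(31)
  ds <- simulate_meta_dataset(get_scenario("S3"), k = 12, n_min = 40,
                              n_max = 120)
  np <- fit_naive_pooling(ds, tpb_spec())
  cr <- fit_cluster_robust(ds, tpb_spec())
  expect_identical(cr$estimates, np$estimates)
  expect_identical(cr$chi2 * cr$scaling, np$chi2)
  # clustering inflates the standard errors here (high ICC)
  expect_true(all(cr$se > np$se))
  one <- ds; one$studies <- one$studies[1]
  expect_error(fit_cluster_robust(one, tpb_spec()), "at least 2")
})

test_that("with size-one clusters the sandwich is the observation-level sandwich", {
  set.seed(17)
  pop <- get_scenario("S4")
  Y <- MASS::mvrnorm(600, rep(0, 5), pop$sigma_w)
  colnames(Y) <- tpb_variables()
  ds <- structure(list(studies = lapply(seq_len(nrow(Y)), function(i)
    list(id = i, n = 1L, Y = Y[i, , drop = FALSE],
         observed = setNames(rep(TRUE, 5), tpb_variables()))),
    variables = tpb_variables(), missing = FALSE), class = "meta_dataset")
  cr <- fit_cluster_robust(ds, tpb_spec())
  # independent observation-level computation of the same sandwich
  base <- fit_naive_pooling(ds, tpb_spec())
  Sigma <- base$Sigma_hat
  Siginv <- solve(Sigma)
  J <- base$J
  D <- ipdmasem:::dup_matrix(5)
  Z <- sweep(Y, 2, colMeans(Y))
  Bm <- matrix(0, length(base$theta), length(base$theta))
  for (i in seq_len(nrow(Z))) {
    M <- Siginv %*% (tcrossprod(Z[i, ]) - Sigma) %*% Siginv
    g <- 0.5 * crossprod(D %*% J, as.vector(M))
    Bm <- Bm + tcrossprod(g)
  }
  W <- 0.5 * t(D) %*% (Siginv %x% Siginv) %*% D
  A <- (nrow(Y) - 1) * t(J) %*% W %*% J
  se_obs <- sqrt(diag(solve(A) %*% Bm %*% solve(A)))[1:5]
  expect_equal(unname(cr$se), se_obs, tolerance = 1e-8)
  # i.i.d. data, size-one clusters: the scaling factor approaches one
  expect_equal(cr$scaling, 1, tolerance = 0.25)
})

test_that("exact-fit rejection is nominal for independent model-true data", {
  pop <- get_scenario("S4")
  tiny <- two_level_population(pop$within,
                               path_model_matrices(0 * pop$between$B,
                                                   1e-14 * pop$between$Psi))
  set.seed(2024)
  rej <- 0; reps <- 200
  for (r in seq_len(reps)) {
    ds <- simulate_meta_dataset(tiny, k = 5, n_min = 300, n_max = 300)
    fit <- fit_naive_pooling(ds, tpb_spec(), se = FALSE)
    rej <- rej + (fit$chi2_p < 0.05)
  }
  # binomial Monte Carlo band around 5% at 200 replications
  expect_gt(rej / reps, 0.013)
  expect_lt(rej / reps, 0.095)
})

test_that("masked variables are rejected or dropped per the caller's choice", {
  set.seed(12)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 6, n_min = 30,
                              n_max = 60, missing = TRUE)
  expect_error(fit_naive_pooling(ds, tpb_spec(), on_missing = "error"),
               "masked|observed")
  fit <- fit_naive_pooling(ds, tpb_spec(), on_missing = "common")
  expect_named(fit$estimates, c("INT~ATT", "INT~SN", "INT~PBC"))
})

test_that("single-level estimates drift toward the between-level value", {
  # behavior-on-intention: within 0.07, between 0.91 in the medium scenario
  set.seed(55)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 30)
  np <- fit_naive_pooling(ds, tpb_spec(), se = FALSE)
  est <- np$estimates[["BEH~INT"]]
  expect_gt(est, 0.15)
  expect_lt(est, 0.91)
})
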
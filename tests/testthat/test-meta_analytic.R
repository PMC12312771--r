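test_that("per-study fits recover population paths in a large study", {
  pop <- get_scenario("S1")
  set.seed(61)
  Y <- MASS::mvrnorm(1e5, rep(0, 5), pop$sigma_w)
  colnames(Y) <- tpb_variables()
  ds <- structure(list(studies = list(list(id = 1L, n = nrow(Y), Y = Y,
                                           observed = setNames(rep(TRUE, 5),
                                                               tpb_variables()))),
                       variables = tpb_variables(), missing = FALSE),
                  class = "meta_dataset")
  eff <- fit_per_study(ds)
  expect_equal(unname(eff[[1]]$beta), c(0.43, 0.16, 0.31, 0.53, 0.07),
               tolerance = 0.02)
  # information scaling: the sampling covariance shrinks as 1/n
  S <- cov(Y)
  f1 <- fit_path_model_ml(S, 1000, tpb_spec())
  f2 <- fit_path_model_ml(S, 2000, tpb_spec())
  expect_equal(f1$acov[1:5, 1:5] / f2$acov[1:5, 1:5],
               matrix(1999 / 999, 5, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("behavior-masked studies contribute three path coefficients", {
  set.seed(62)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 6, n_min = 60,
                              n_max = 90, missing = TRUE)
  eff <- fit_per_study(ds)
  lens <- vapply(eff, function(e) length(e$beta), integer(1))
  expect_setequal(lens, c(3L, 5L))
  expect_equal(sum(lens == 3), 3)
  short <- eff[[which(lens == 3)[1]]]
  expect_named(short$beta, c("INT~ATT", "INT~SN", "INT~PBC"))
})

test_that("fixed-effects pooling reduces to means and respects ordering", {
  e1 <- list(id = 1, beta = c(a = 1, b = 3), V = diag(2), converged = TRUE)
  e2 <- list(id = 2, beta = c(a = 2, b = 5), V = diag(2), converged = TRUE)
  pooled <- mvma_fixed(list(e1, e2), c("a", "b"))
  expect_equal(pooled$beta, c(a = 1.5, b = 4))
  expect_equal(pooled$acov, 0.5 * diag(2), ignore_attr = TRUE)
  single <- mvma_fixed(list(e1), c("a", "b"))
  expect_equal(single$beta, e1$beta)
  expect_equal(unname(single$acov), e1$V)
  # order invariance
  expect_equal(mvma_fixed(list(e2, e1), c("a", "b"))$beta, pooled$beta)
  # a study with (near) infinite variance contributes nothing
  e3 <- list(id = 3, beta = c(a = 50, b = -50), V = 1e10 * diag(2),
             converged = TRUE)
  expect_equal(mvma_fixed(list(e1, e2, e3), c("a", "b"))$beta, pooled$beta,
               tolerance = 1e-6)
  # an effect observed by no study fails loudly
  expect_error(mvma_fixed(list(e1), c("a", "b", "zz")), "zz")
})

test_that("fixed-effects pooling agrees with metafor's GLS", {
  set.seed(63)
  ds <- simulate_meta_dataset(get_scenario("S4"), k = 8, n_min = 100,
                              n_max = 200, missing = TRUE)
  eff <- Filter(function(e) e$converged, fit_per_study(ds))
  pooled <- mvma_fixed(eff, tpb_spec()$path_names)
  yi <- unlist(lapply(eff, function(e) e$beta))
  V <- matrix(0, length(yi), length(yi))
  off <- 0
  for (e in eff) {
    ix <- off + seq_along(e$beta)
    V[ix, ix] <- e$V
    off <- off + length(e$beta)
  }
  lab <- factor(unlist(lapply(eff, function(e) names(e$beta))),
                levels = tpb_spec()$path_names)
  mf <- metafor::rma.mv(yi, V, mods = ~ lab - 1, method = "FE")
  expect_equal(unname(pooled$beta), as.vector(mf$beta), tolerance = 1e-6)
  expect_equal(unname(pooled$se), mf$se, tolerance = 1e-6)
})

test_that("correlation sampling variances follow the classical formula", {
  set.seed(64)
  Y <- MASS::mvrnorm(150, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  colnames(Y) <- c("X1", "X2")
  ds <- structure(list(studies = list(list(id = 1L, n = 150L, Y = Y,
                                           observed = c(X1 = TRUE, X2 = TRUE))),
                       variables = c("X1", "X2"), missing = FALSE),
                  class = "meta_dataset")
  sc <- study_correlations(ds)[[1]]
  r <- cor(Y)[2, 1]
  expect_equal(unname(sc$r), r)
  expect_equal(unname(drop(sc$V)), (1 - r^2)^2 / 150)
})

test_that("correlation vectors have 10 entries, or 6 when behavior is masked", {
  set.seed(65)
  ds <- simulate_meta_dataset(get_scenario("S2"), k = 4, n_min = 40,
                              n_max = 60, missing = TRUE)
  cors <- study_correlations(ds)
  lens <- vapply(cors, function(s) length(s$r), integer(1))
  expect_setequal(lens, c(6L, 10L))
  short <- cors[[which(lens == 6)[1]]]
  expect_false(any(grepl("BEH", names(short$r))))
})

test_that("one-stage MASEM recovers the model from its own correlations", {
  pop <- get_scenario("S1")
  Rho <- cov2cor(pop$sigma_w)
  fake <- lapply(1:2, function(i)
    list(id = i, r = vechs(Rho), V = ipdmasem:::nt_cor_cov(Rho, 500), n = 500L))
  fit <- fit_osmasem(cors = fake)
  expect_true(fit$converged)
  # the correlation metric standardizes the paths: b * sd(pred) / sd(outcome)
  sds <- sqrt(diag(pop$sigma_w))
  Bstd <- diag(1 / sds) %*% pop$within$B %*% diag(sds)
  dimnames(Bstd) <- dimnames(pop$within$B)
  expect_equal(unname(fit$estimates), unname(Bstd[tpb_spec()$edges]),
               tolerance = 1e-4)
  # population variances are near one, so raw paths are reproduced closely
  expect_equal(unname(fit$estimates), c(0.43, 0.16, 0.31, 0.53, 0.07),
               tolerance = 0.01)
  expect_lt(fit$chi2, 1e-6)
  expect_identical(fit$df, 2)
})

test_that("the two-stage, one-stage, and two-level estimates agree", {
  set.seed(66)
  ds <- simulate_meta_dataset(get_scenario("S1"), k = 30, n_min = 200,
                              n_max = 500)
  ps <- fit_partially_saturated(ds, tpb_spec(), se = FALSE)
  mv <- fit_mvma(ds)
  os <- fit_osmasem(ds)
  expect_lt(max(abs(ps$estimates - mv$estimates)), 0.02)
  expect_lt(max(abs(ps$estimates - os$estimates)), 0.02)
})
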
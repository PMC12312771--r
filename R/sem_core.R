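# Single-level path-model estimation: normal-theory ML, naive and
# cluster-robust standard errors, naive and mean-scaled chi-square.

vech <- function(M) M[lower.tri(M, diag = TRUE)]

dup_matrix <- function(p) {
  # duplication matrix: vec(M) = D %*% vech(M) for symmetric M
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

.fml_value <- function(S, Sigma, logdetS, p) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R))) + sum(chol2inv(R) * S) - logdetS - p
}

.vech_jacobian <- function(theta, spec, h = 1e-6) {
  f <- function(th) vech(implied_sigma(spec_build(th, spec)$B,
                                       spec_build(th, spec)$Psi))
  d <- length(theta)
  J <- matrix(0, spec$p * (spec$p + 1) / 2, d)
  for (i in seq_len(d)) {
    hi <- h * (1 + abs(theta[i]))
    tp <- tm <- theta
    tp[i] <- theta[i] + hi; tm[i] <- theta[i] - hi
    J[, i] <- (f(tp) - f(tm)) / (2 * hi)
  }
  J
}

.masem_fit <- function(method, estimates, se, chi2, df, chi2_p, scaling = 1,
                       rmsea = NA_real_, rmsea_close_p = NA_real_,
                       loglik = NA_real_, converged = TRUE,
                       N_effective = NA_real_, extra = list()) {
  structure(c(list(method = method, estimates = estimates, se = se,
                   chi2 = chi2, df = df, chi2_p = chi2_p, scaling = scaling,
                   rmsea = rmsea, rmsea_close_p = rmsea_close_p,
                   loglik = loglik, converged = converged,
                   N_effective = N_effective), extra),
            class = "masem_fit")
}

#' @export
print.masem_fit <- function(x, ...) {
  cat("MASEM fit (", x$method, ")",
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  if (length(x$estimates)) {
    tab <- cbind(estimate = x$estimates,
                 se = if (length(x$se)) x$se[names(x$estimates)] else NA)
    print(round(tab, 4))
  }
  if (is.finite(x$chi2))
    cat(sprintf("chi2(%d) = %.3f, p = %.4f, RMSEA = %.4f, close-fit p = %.4f\n",
                x$df, x$chi2, x$chi2_p, x$rmsea, x$rmsea_close_p))
  invisible(x)
}

#' RMSEA and close-fit test from a chi-square statistic
#'
#' The root mean square error of approximation is
#' \eqn{\sqrt{\max(\chi^2 - df, 0) / (df (N-1))}}.  The close-fit null
#' hypothesis RMSEA < .05 is tested against the noncentral chi-square
#' distribution with noncentrality \eqn{0.05^2 \, df \, (N-1)}; close fit is
#' rejected when the returned p-value falls below the chosen alpha.
#'
#' @param chi2 Chi-square test statistic.
#' @param df Model degrees of freedom (must be at least 1 for a defined
#'   RMSEA; `df = 0` returns `NA` values).
#' @param N Sample size used for scaling.
#'
#' @return List with elements `rmsea` and `rmsea_close_p`.
#' @export
fit_measures <- function(chi2, df, N) {
  if (is.na(chi2) || df < 1 || is.na(N))
    return(list(rmsea = NA_real_, rmsea_close_p = NA_real_))
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (N - 1)))
  ncp <- 0.05^2 * df * (N - 1)
  list(rmsea = rmsea,
       rmsea_close_p = 1 - pchisq(chi2, df, ncp = ncp))
}

#' Fit a path model to a covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \deqn{F(\theta) = \log|\Sigma(\theta)| + tr(S \Sigma(\theta)^{-1})
#'   - \log|S| - p}
#' over the free parameters of a recursive path model, with
#' \eqn{\Sigma(\theta) = (I-B)^{-1}\Psi(I-B)^{-T}}.  The chi-square
#' statistic is \eqn{(N-1) F(\hat\theta)}; standard errors come from the
#' inverse expected information of the discrepancy.
#'
#' @param S Sample covariance matrix (divisor `N - 1`).
#' @param N Number of observations behind `S`.
#' @param spec A [path_model_spec()].
#' @param se Logical; compute standard errors.
#'
#' @return A `"masem_fit"` object; `estimates` holds the path coefficients.
#' @export
fit_path_model_ml <- function(S, N, spec, se = TRUE) {
  v <- spec$variables
  S <- S[v, v, drop = FALSE]
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  if (N <= spec$p) stop("N must exceed the number of variables")
  Rs <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(Rs)) stop("S must be positive definite")
  logdetS <- 2 * sum(log(diag(Rs)))

  theta0 <- tryCatch(spec_start(S, spec), error = function(e) NULL)
  if (is.null(theta0))
    return(.masem_fit("ML", setNames(rep(NA_real_, spec$n_edges),
                                     spec$path_names),
                      numeric(0), NA, spec$df, NA, converged = FALSE,
                      N_effective = N))
  obj <- function(th) {
    m <- spec_build(th, spec)
    f <- .fml_value(S, implied_sigma(m$B, m$Psi), logdetS, spec$p)
    if (!is.finite(f)) 1e10 else f
  }
  opt <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    hi <- 1e-6 * (1 + abs(theta[i]))
    tp <- tm <- theta; tp[i] <- theta[i] + hi; tm[i] <- theta[i] - hi
    g[i] <- (obj(tp) - obj(tm)) / (2 * hi)
  }
  converged <- opt$convergence == 0 && max(abs(g)) < 1e-6
  m <- spec_build(theta, spec)
  Sigma_hat <- implied_sigma(m$B, m$Psi)
  Fmin <- max(opt$value, 0)
  chi2 <- (N - 1) * Fmin
  df <- spec$df
  chi2_p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  fm <- fit_measures(chi2, df, N)
  estimates <- setNames(theta[seq_len(spec$n_edges)], spec$path_names)

  se_vec <- numeric(0); acov <- NULL; J <- NULL
  if (se) {
    J <- .vech_jacobian(theta, spec)
    Siginv <- chol2inv(chol(Sigma_hat))
    D <- dup_matrix(spec$p)
    W <- 0.5 * t(D) %*% (Siginv %x% Siginv) %*% D
    info <- t(J) %*% W %*% J
    acov <- tryCatch(solve(info) / (N - 1), error = function(e) NULL)
    if (is.null(acov)) converged <- FALSE
    else se_vec <- setNames(sqrt(pmax(diag(acov)[seq_len(spec$n_edges)], 0)),
                            spec$path_names)
  }
  ll <- -0.5 * (N - 1) * (Fmin + logdetS + spec$p)
  .masem_fit("ML", estimates, se_vec, chi2, df, chi2_p, 1,
             fm$rmsea, fm$rmsea_close_p, ll, converged, N,
             extra = list(theta = theta, spec = spec, Sigma_hat = Sigma_hat,
                          S = S, J = J, acov = acov))
}

# restrict a spec to a subset of variables (drops edges touching removed ones)
spec_restrict <- function(spec, variables) {
  keep <- spec$variables[spec$variables %in% variables]
  edges <- spec$edges[spec$edges[, 1] %in% keep & spec$edges[, 2] %in% keep, ,
                      drop = FALSE]
  path_model_spec(keep, edges)
}

.pooled_rows <- function(ds, variables) {
  bad <- vapply(ds$studies, function(s)
    !all(variables %in% colnames(s$Y)[s$observed]), logical(1))
  if (any(bad))
    stop("variable(s) masked in ", sum(bad), " studies; use on_missing = ",
         "\"common\" to restrict the model to commonly observed variables")
  do.call(rbind, lapply(ds$studies, function(s) s$Y[, variables, drop = FALSE]))
}

.common_spec <- function(ds, spec, on_missing) {
  obs <- Reduce(intersect, lapply(ds$studies, function(s)
    colnames(s$Y)[s$observed]))
  if (all(spec$variables %in% obs)) return(spec)
  if (on_missing == "error")
    stop("not all model variables are observed in every study")
  spec_restrict(spec, obs)
}

#' Naive-pooling single-level path model fit
#'
#' Stacks every participant from every study into one sample, ignoring the
#' clustering, and fits the path model to the pooled covariance matrix.
#'
#' @param ds A meta-analytic IPD collection (see [simulate_meta_dataset()]).
#' @param spec A [path_model_spec()].
#' @param se Logical; compute (information-based) standard errors.
#' @param on_missing `"error"` to fail when a model variable is masked in
#'   some study, `"common"` to restrict the model to the commonly observed
#'   variables.
#'
#' @return A `"masem_fit"` object with method tag `"NP"`.
#' @export
fit_naive_pooling <- function(ds, spec, se = TRUE,
                              on_missing = c("error", "common")) {
  on_missing <- match.arg(on_missing)
  spec <- .common_spec(ds, spec, on_missing)
  Y <- .pooled_rows(ds, spec$variables)
  fit <- fit_path_model_ml(cov(Y), nrow(Y), spec, se = se)
  fit$method <- "NP"
  fit$n_studies <- length(ds$studies)
  fit
}

#' Cluster-robust single-level path model fit
#'
#' Point estimates are identical to [fit_naive_pooling()]; standard errors
#' are replaced by the cluster (study) sandwich estimator
#' \eqn{A^{-1} B A^{-1}} with `A` the expected information and `B` the sum
#' of outer products of per-study score contributions, and the chi-square
#' statistic is divided by a mean scaling factor
#' \eqn{c = tr(U\Gamma)/df} computed from the cluster-level covariance of
#' the sample moments.
#'
#' @inheritParams fit_naive_pooling
#'
#' @return A `"masem_fit"` object with method tag `"CR"`; `scaling` holds
#'   the chi-square scaling factor.
#' @export
fit_cluster_robust <- function(ds, spec, se = TRUE,
                               on_missing = c("error", "common")) {
  on_missing <- match.arg(on_missing)
  if (length(ds$studies) < 2) stop("cluster-robust fit needs at least 2 studies")
  base <- fit_naive_pooling(ds, spec, se = TRUE, on_missing = on_missing)
  base$method <- "CR"
  if (!base$converged) return(base)
  uspec <- base$spec
  v <- uspec$variables
  p <- uspec$p
  N <- base$N_effective
  Sigma <- base$Sigma_hat
  Siginv <- chol2inv(chol(Sigma))
  J <- base$J                       # d vech(Sigma) / d theta
  D <- dup_matrix(p)
  W <- 0.5 * t(D) %*% (Siginv %x% Siginv) %*% D
  gbar <- colMeans(.pooled_rows(ds, v))

  # per-study scatter about the pooled mean, scores, and moment deviations
  Cs <- lapply(ds$studies, function(s) {
    Z <- sweep(s$Y[, v, drop = FALSE], 2, gbar)
    list(C = crossprod(Z), n = nrow(Z))
  })
  Ctot <- Reduce(`+`, lapply(Cs, `[[`, "C"))
  Jv <- D %*% J                     # d vec(Sigma) / d theta
  d <- ncol(J)
  Bmat <- matrix(0, d, d)
  ns <- p * (p + 1) / 2
  Gamma <- matrix(0, ns, ns)
  for (s in Cs) {
    M <- Siginv %*% (s$C - s$n * Sigma) %*% Siginv
    gj <- 0.5 * crossprod(Jv, as.vector(M))
    Bmat <- Bmat + tcrossprod(gj)
    uj <- vech(s$C) - s$n * vech(Ctot) / N
    Gamma <- Gamma + tcrossprod(uj)
  }
  Gamma <- Gamma / N
  A <- (N - 1) * (t(J) %*% W %*% J)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    base$converged <- FALSE
    return(base)
  }
  acov_cr <- Ainv %*% Bmat %*% Ainv
  base$se <- setNames(sqrt(pmax(diag(acov_cr)[seq_len(uspec$n_edges)], 0)),
                      uspec$path_names)
  base$acov <- acov_cr
  if (uspec$df > 0) {
    WJ <- W %*% J
    U <- W - WJ %*% solve(t(J) %*% WJ, t(WJ))
    cfac <- sum(U * Gamma) / uspec$df
    base$scaling <- cfac
    base$chi2 <- base$chi2 / cfac
    base$chi2_p <- pchisq(base$chi2, uspec$df, lower.tail = FALSE)
    fm <- fit_measures(base$chi2, uspec$df, N)
    base$rmsea <- fm$rmsea
    base$rmsea_close_p <- fm$rmsea_close_p
  }
  base
}
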
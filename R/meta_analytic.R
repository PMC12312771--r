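# Two-stage estimators: per-study path-model fits pooled by fixed-effects
# multivariate meta-analysis, and fixed-effects one-stage MASEM on study
# correlation vectors.

#' Strict half-vectorization
#'
#' Stacks the below-diagonal elements of a symmetric matrix into a vector,
#' column-major over the strict lower triangle.  This ordering convention is
#' fixed project-wide (correlation vectors, their sampling covariances, and
#' model-implied correlation structures all use it).
#'
#' @param M Symmetric matrix.
#'
#' @return Numeric vector of length `p(p-1)/2`, named `"a:b"` per pair.
#' @export
vechs <- function(M) {
  lt <- lower.tri(M)
  out <- M[lt]
  if (!is.null(rownames(M))) {
    idx <- which(lt, arr.ind = TRUE)
    names(out) <- paste0(rownames(M)[idx[, 1]], ":", colnames(M)[idx[, 2]])
  }
  out
}

vechs_names <- function(variables) {
  p <- length(variables)
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  paste0(variables[idx[, 1]], ":", variables[idx[, 2]])
}

#' Per-study path-model estimates for multivariate meta-analysis
#'
#' Fits the path model separately in every primary study by maximum
#' likelihood.  Studies with the behavior variable masked are fitted with
#' the reduced (three-path) model, so they contribute three path
#' coefficients instead of five.  The sampling covariance `V` of each
#' study's coefficients is the path block of the inverse expected
#' information.
#'
#' @param ds A `"meta_dataset"`.
#' @param spec Full-model [path_model_spec()].
#'
#' @return List of study effects: `id`, `beta` (named), `V`, `n`,
#'   `converged`.  Non-converged studies carry `converged = FALSE` and are
#'   dropped by [mvma_fixed()].
#' @export
fit_per_study <- function(ds, spec = tpb_spec()) {
  lapply(ds$studies, function(s) {
    vs <- intersect(spec$variables, colnames(s$Y))
    sspec <- if (length(vs) == length(spec$variables)) spec
             else spec_restrict(spec, vs)
    fit <- tryCatch(fit_path_model_ml(cov(s$Y[, sspec$variables, drop = FALSE]),
                                      s$n, sspec, se = TRUE),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(list(id = s$id, beta = NULL, V = NULL, n = s$n, converged = FALSE))
    ix <- seq_len(sspec$n_edges)
    list(id = s$id, beta = fit$estimates,
         V = fit$acov[ix, ix, drop = FALSE], n = s$n, converged = TRUE)
  })
}

#' Fixed-effects multivariate meta-analysis of study effects
#'
#' GLS pooling with between-study heterogeneity fixed at zero:
#' \deqn{\hat\beta = (\sum_j X_j' V_j^{-1} X_j)^{-1}
#'       \sum_j X_j' V_j^{-1} \hat\beta_j,}
#' where the selection matrix \eqn{X_j} picks the effects observed by study
#' `j` (studies may contribute unequal numbers of effects).
#'
#' @param effects List of study effects as returned by [fit_per_study()].
#' @param effect_names Names of the full effect vector; defaults to the
#'   union over studies, in first-seen order.
#'
#' @return List with `beta` (pooled estimates), `acov`, `se`, `Q`
#'   (heterogeneity statistic, reported but unused under fixed effects),
#'   `k_used`, and `T2` (identically zero).
#' @export
mvma_fixed <- function(effects, effect_names = NULL) {
  effects <- Filter(function(e) isTRUE(e$converged), effects)
  if (length(effects) < 1) stop("no converged study effects to pool")
  if (is.null(effect_names))
    effect_names <- unique(unlist(lapply(effects, function(e) names(e$beta))))
  q <- length(effect_names)
  A <- matrix(0, q, q, dimnames = list(effect_names, effect_names))
  rhs <- setNames(numeric(q), effect_names)
  for (e in effects) {
    ix <- match(names(e$beta), effect_names)
    if (anyNA(ix)) stop("study effect name not in effect_names")
    Wj <- solve(e$V)
    A[ix, ix] <- A[ix, ix] + Wj
    rhs[ix] <- rhs[ix] + Wj %*% e$beta
  }
  counts <- rowSums(vapply(effects, function(e)
    effect_names %in% names(e$beta), logical(q)))
  if (any(counts == 0))
    stop("effect observed by no study: ",
         paste(effect_names[counts == 0], collapse = ", "))
  acov <- solve(A)
  beta <- drop(acov %*% rhs)
  names(beta) <- effect_names
  Q <- 0
  for (e in effects) {
    d <- e$beta - beta[names(e$beta)]
    Q <- Q + drop(t(d) %*% solve(e$V, d))
  }
  list(beta = beta, acov = acov,
       se = setNames(sqrt(diag(acov)), effect_names),
       Q = Q, Q_df = sum(vapply(effects, function(e) length(e$beta),
                                integer(1))) - q,
       k_used = length(effects), T2 = matrix(0, q, q))
}

#' Multivariate meta-analysis of path coefficients (two-stage estimator)
#'
#' Convenience wrapper: per-study fits ([fit_per_study()]) pooled by
#' [mvma_fixed()].  The meta-analytic path model itself has no chi-square
#' fit statistic.
#'
#' @inheritParams fit_per_study
#'
#' @return A `"masem_fit"` with method tag `"MVMA"` (fit statistics `NA`).
#' @export
fit_mvma <- function(ds, spec = tpb_spec()) {
  effects <- fit_per_study(ds, spec)
  pooled <- tryCatch(mvma_fixed(effects, spec$path_names),
                     error = function(e) NULL)
  if (is.null(pooled))
    return(.masem_fit("MVMA", setNames(rep(NA_real_, spec$n_edges),
                                       spec$path_names), numeric(0),
                      NA_real_, NA_integer_, NA_real_, converged = FALSE))
  .masem_fit("MVMA", pooled$beta, pooled$se, NA_real_, NA_integer_, NA_real_,
             loglik = NA_real_, converged = TRUE,
             N_effective = sum(vapply(ds$studies, `[[`, integer(1), "n")),
             extra = list(acov = pooled$acov, Q = pooled$Q,
                          k_used = pooled$k_used))
}

# normal-theory (Olkin-Siotani) asymptotic covariance of sample correlations;
# vectorized over all pairs of correlation entries
nt_cor_cov <- function(R, n) {
  idx <- which(lower.tri(R), arr.ind = TRUE)
  I <- idx[, 1]; J <- idx[, 2]
  r <- R[idx]                       # r_a = R[i_a, j_a]
  Rik <- R[I, I, drop = FALSE]      # entry (a,b) = R[i_a, i_b]
  Ril <- R[I, J, drop = FALSE]
  Rjk <- R[J, I, drop = FALSE]
  Rjl <- R[J, J, drop = FALSE]
  rr <- tcrossprod(r)               # r_a * r_b
  ra <- matrix(r, length(r), length(r))
  V <- 0.5 * rr * (Rik^2 + Ril^2 + Rjk^2 + Rjl^2) +
    Rik * Rjl + Ril * Rjk -
    (ra * (Rik * Ril + Rjk * Rjl) + t(ra) * (Rik * Rjk + Ril * Rjl))
  V <- (V + t(V)) / (2 * n)
  nm <- vechs_names(rownames(R))
  dimnames(V) <- list(nm, nm)
  V
}

#' Study correlation vectors with sampling covariances
#'
#' For each study, computes the strict half-vectorization of its sample
#' correlation matrix and the normal-theory asymptotic sampling covariance
#' of those correlations (evaluated at the sample values, scaled by
#' `1/n_j`).  Studies with a masked variable contribute the correlations of
#' their observed variables only.
#'
#' @param ds A `"meta_dataset"`.
#'
#' @return List of per-study records: `id`, `r` (named), `V`, `n`.
#'   Studies with a degenerate variance are dropped.
#' @export
study_correlations <- function(ds) {
  out <- lapply(ds$studies, function(s) {
    if (any(apply(s$Y, 2, sd) <= 0)) return(NULL)
    R <- cor(s$Y)
    list(id = s$id, r = vechs(R), V = nt_cor_cov(R, s$n), n = s$n)
  })
  Filter(Negate(is.null), out)
}

# GLS pooling of correlation vectors with subset selection for masked studies
pool_correlations <- function(cors, pair_names) {
  q <- length(pair_names)
  A <- matrix(0, q, q, dimnames = list(pair_names, pair_names))
  rhs <- setNames(numeric(q), pair_names)
  for (s in cors) {
    ix <- match(names(s$r), pair_names)
    if (anyNA(ix)) stop("correlation pair not in pair_names")
    Wj <- solve(s$V)
    A[ix, ix] <- A[ix, ix] + Wj
    rhs[ix] <- rhs[ix] + Wj %*% s$r
  }
  acov <- solve(A)
  list(rbar = drop(acov %*% rhs), W = A, acov = acov)
}

# implied correlation vector of the standardized path model: exogenous block
# parameterized as correlations, residual variances solved for unit diagonals
osmasem_rho <- function(theta, spec) {
  v <- spec$variables
  p <- spec$p
  nx <- spec$nexog
  B <- matrix(0, p, p, dimnames = list(v, v))
  B[spec$edges] <- theta[seq_len(spec$n_edges)]
  C <- diag(nx)
  C[lower.tri(C)] <- theta[spec$n_edges + seq_len(nx * (nx - 1) / 2)]
  C[upper.tri(C)] <- t(C)[upper.tri(C)]
  Sigma <- matrix(NA_real_, p, p, dimnames = list(v, v))
  Sigma[seq_len(nx), seq_len(nx)] <- C
  # recursive construction in variable order; each endogenous variable gets
  # the residual variance that brings its implied variance to one
  for (m in (nx + 1):p) {
    out <- v[m]
    pred <- spec$edges[spec$edges[, "outcome"] == out, "predictor"]
    b <- B[out, pred]
    prev <- v[seq_len(m - 1)]
    cov_prev <- drop(Sigma[prev, pred, drop = FALSE] %*% b)
    var_struct <- drop(t(b) %*% Sigma[pred, pred] %*% b)
    psi <- 1 - var_struct
    if (psi <= 0) return(NULL)       # unit-diagonal constraint infeasible
    Sigma[prev, out] <- Sigma[out, prev] <- cov_prev
    Sigma[out, out] <- 1
  }
  vechs(Sigma)
}

osmasem_start <- function(rbar, spec) {
  p <- spec$p
  R <- diag(p)
  dimnames(R) <- list(spec$variables, spec$variables)
  R[lower.tri(R)] <- rbar
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  cf <- spec_closed_form(R, spec)
  nx <- spec$nexog
  c(cf$B[spec$edges], cf$exog[lower.tri(cf$exog)])
}

#' One-stage MASEM on pooled study correlations (fixed effects)
#'
#' Pools the study correlation vectors by inverse-variance GLS (with subset
#' selection for studies missing the behavior variable) and minimizes the
#' GLS discrepancy \eqn{(\bar\rho - \rho(\theta))' W (\bar\rho -
#' \rho(\theta))} with `W` the pooled precision.  The model-implied
#' correlation structure is
#' \eqn{\rho(\theta) = vechs((I-B)^{-1}\Psi(I-B)^{-T})} under the
#' standardization constraint of unit diagonals: exogenous variances and
#' covariances are parameterized as correlations and residual variances are
#' solved to keep every implied variance at one.  The minimized discrepancy
#' is the chi-square statistic (df = 2 for the planned-behavior model).
#'
#' @param ds A `"meta_dataset"` (or a precomputed [study_correlations()]
#'   list via the `cors` argument).
#' @param spec Full-model [path_model_spec()].
#' @param cors Optional precomputed correlation records.
#'
#' @return A `"masem_fit"` with method tag `"OSMASEM"`; `estimates` holds
#'   the (within-study level) path coefficients.
#' @export
fit_osmasem <- function(ds, spec = tpb_spec(), cors = NULL) {
  if (is.null(cors)) cors <- study_correlations(ds)
  if (length(cors) < 2) stop("one-stage MASEM needs at least 2 studies")
  pair_names <- vechs_names(spec$variables)
  pooled <- pool_correlations(cors, pair_names)
  rbar <- pooled$rbar
  W <- pooled$W
  npar <- spec$n_edges + spec$nexog * (spec$nexog - 1) / 2
  df <- length(pair_names) - npar
  na_fit <- function() .masem_fit("OSMASEM",
                                  setNames(rep(NA_real_, spec$n_edges),
                                           spec$path_names), numeric(0),
                                  NA_real_, df, NA_real_, converged = FALSE)
  theta0 <- tryCatch(osmasem_start(rbar, spec), error = function(e) NULL)
  if (is.null(theta0)) return(na_fit())
  obj <- function(th) {
    rho <- osmasem_rho(th, spec)
    if (is.null(rho)) return(1e10)
    e <- rbar - rho
    drop(t(e) %*% W %*% e)
  }
  opt <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  theta <- opt$par
  if (is.null(osmasem_rho(theta, spec)) || opt$value >= 1e10) return(na_fit())
  # numeric Jacobian of the implied correlations
  d <- length(theta)
  Delta <- matrix(0, length(pair_names), d)
  for (i in seq_len(d)) {
    hi <- 1e-6 * (1 + abs(theta[i]))
    tp <- tm <- theta; tp[i] <- theta[i] + hi; tm[i] <- theta[i] - hi
    rp <- osmasem_rho(tp, spec); rm <- osmasem_rho(tm, spec)
    if (is.null(rp) || is.null(rm)) return(na_fit())
    Delta[, i] <- (rp - rm) / (2 * hi)
  }
  acov <- tryCatch(solve(t(Delta) %*% W %*% Delta), error = function(e) NULL)
  if (is.null(acov)) return(na_fit())
  chi2 <- max(opt$value, 0)
  chi2_p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  N <- sum(vapply(cors, `[[`, numeric(1), "n"))
  fm <- fit_measures(chi2, df, N)
  est <- setNames(theta[seq_len(spec$n_edges)], spec$path_names)
  se <- setNames(sqrt(pmax(diag(acov)[seq_len(spec$n_edges)], 0)),
                 spec$path_names)
  .masem_fit("OSMASEM", est, se, chi2, df, chi2_p, 1,
             fm$rmsea, fm$rmsea_close_p, NA_real_,
             opt$convergence == 0, N,
             extra = list(theta = theta, rbar = rbar, acov = acov))
}
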
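# Two-level path-model estimation by direct full-information maximum
# likelihood on unbalanced clusters.  The likelihood is evaluated from
# per-cluster sufficient statistics in compiled code; grand means are
# profiled out analytically at every evaluation.

# ---- sufficient statistics -------------------------------------------------

tl_stats <- function(ds, variables = ds$variables) {
  p <- length(variables)
  pat <- vapply(ds$studies, function(s)
    paste(which(variables %in% colnames(s$Y)), collapse = ","), character(1))
  groups <- lapply(split(seq_along(ds$studies), pat), function(ix) {
    obs <- which(variables %in% colnames(ds$studies[[ix[1]]]$Y))
    vs <- variables[obs]
    ybar <- t(vapply(ix, function(j) colMeans(ds$studies[[j]]$Y[, vs, drop = FALSE]),
                     numeric(length(vs))))
    n <- vapply(ix, function(j) ds$studies[[j]]$n, integer(1))
    spool <- matrix(0, length(vs), length(vs))
    for (j in ix) {
      Y <- ds$studies[[j]]$Y[, vs, drop = FALSE]
      spool <- spool + crossprod(scale(Y, center = TRUE, scale = FALSE))
    }
    list(obs = obs - 1L, ybar = ybar, n = as.numeric(n), spool = spool,
         dfw = sum(n - 1))
  })
  names(groups) <- NULL
  const_term <- sum(vapply(ds$studies, function(s)
    s$n * sum(s$observed[variables]) * log(2 * pi), numeric(1)))
  list(groups = groups, const_term = const_term, p = as.integer(p),
       N = sum(vapply(ds$studies, `[[`, integer(1), "n")),
       k = length(ds$studies), variables = variables)
}

# ---- model encodings -------------------------------------------------------

# level types for the compiled likelihood: 0 structured, 1 saturated
.tl_level_encoding <- function(spec_or_sat, variables) {
  p <- length(variables)
  if (identical(spec_or_sat, "saturated")) {
    list(type = 1L, edges = matrix(0L, 0, 2), npar = p * (p + 1) / 2,
         names = {
           lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
           paste0("chol.", variables[lt[, 1]], ".", variables[lt[, 2]])
         })
  } else {
    spec <- spec_or_sat
    stopifnot(inherits(spec, "path_model_spec"),
              identical(spec$variables, variables))
    edges <- cbind(match(spec$edges[, 1], variables),
                   match(spec$edges[, 2], variables)) - 1L
    list(type = 0L, edges = edges, npar = spec$npar,
         names = spec_theta_names(spec), spec = spec)
  }
}

tl_encode <- function(within, between, variables) {
  w <- .tl_level_encoding(within, variables)
  b <- .tl_level_encoding(between, variables)
  nexog <- if (w$type == 0L) w$spec$nexog else if (b$type == 0L) b$spec$nexog
           else length(variables) - 2L
  list(p = length(variables), nexog = as.integer(nexog),
       w_type = w$type, b_type = b$type,
       edges_w = w$edges, edges_b = b$edges,
       npar_w = as.integer(w$npar), npar_b = as.integer(b$npar),
       theta_names = c(paste0("w.", w$names), paste0("b.", b$names)),
       within = within, between = between)
}

# number of covariance-structure parameters + p means
tl_npar <- function(enc) enc$npar_w + enc$npar_b + enc$p

#' Exact two-level multivariate-normal log-likelihood
#'
#' Evaluates the log-likelihood of a meta-analytic IPD collection under a
#' two-level normal model with within-study covariance `sigma_w`,
#' between-study covariance `sigma_b`, and grand mean `mu`.  Within-cluster
#' deviations contribute `n_j - 1` degrees of freedom on `sigma_w`; each
#' cluster mean contributes one observation with covariance
#' `sigma_b + sigma_w / n_j`.  Studies with masked variables contribute the
#' corresponding multivariate-normal marginal.
#'
#' @param ds A `"meta_dataset"`.
#' @param sigma_w Within-study covariance matrix (positive definite).
#' @param sigma_b Between-study covariance matrix (positive semi-definite).
#' @param mu Grand mean vector; `NULL` profiles it out by GLS.
#'
#' @return The log-likelihood (scalar).
#' @export
twolevel_loglik <- function(ds, sigma_w, sigma_b, mu = NULL) {
  stats <- tl_stats(ds)
  m2 <- cpp_tl_m2ll_mats(as.matrix(sigma_w), as.matrix(sigma_b),
                         if (is.null(mu)) numeric(0) else as.numeric(mu),
                         stats)
  if (m2 >= 1e12) stop("likelihood not defined (covariance not PD?)")
  -m2 / 2
}

# ---- start values ----------------------------------------------------------

tl_start <- function(enc, stats) {
  p <- enc$p
  # use the complete-pattern group (largest observed set) for moment starts
  sizes <- vapply(stats$groups, function(g) length(g$obs), integer(1))
  g <- stats$groups[[which.max(sizes)]]
  if (length(g$obs) < p)
    stop("no study observes all model variables; cannot form start values")
  SW0 <- g$spool / g$dfw
  ybar <- g$ybar
  SB0 <- cov(ybar) - SW0 * mean(1 / g$n)
  ev <- eigen((SB0 + t(SB0)) / 2, symmetric = TRUE)
  SB0 <- ev$vectors %*% diag(pmax(ev$values, 0.01), p) %*% t(ev$vectors)
  level_start <- function(S, type, spec) {
    if (type == 1L) .chol_pack(S) else spec_start(S, spec)
  }
  vnames <- colnames(ybar)
  dimnames(SW0) <- dimnames(SB0) <- list(vnames, vnames)
  c(level_start(SW0, enc$w_type, enc$within),
    level_start(SB0, enc$b_type, enc$between))
}

# ---- driver ----------------------------------------------------------------

tl_optimize <- function(enc, stats, se = FALSE) {
  theta0 <- tryCatch(unname(tl_start(enc, stats)), error = function(e) NULL)
  fail <- function() list(converged = FALSE, theta = NULL, loglik = NA_real_,
                          m2ll = NA_real_, acov = NULL, enc = enc)
  if (is.null(theta0)) return(fail())
  spec_list <- enc[c("p", "nexog", "w_type", "b_type", "edges_w", "edges_b",
                     "npar_w", "npar_b")]
  fn <- function(th) cpp_tl_m2ll(th, spec_list, stats)
  gr <- function(th) cpp_tl_grad(th, spec_list, stats, 1e-6, FALSE)
  grc <- function(th) cpp_tl_grad(th, spec_list, stats, 1e-5, TRUE)
  if (!is.finite(fn(theta0)) || fn(theta0) >= 1e12) return(fail())
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  g <- grc(opt$par)
  if (max(abs(g)) > 0.5) {   # one polishing restart with central differences
    opt2 <- optim(opt$par, fn, grc, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    g <- grc(opt$par)
  }
  # a gradient max-norm of 1 on the -2logL scale perturbs the chi-square by
  # ~1e-4 at these sample sizes; beyond that the fit is treated as failed
  converged <- opt$value < 1e12 && max(abs(g)) < 1
  acov <- NULL
  if (se && converged) {
    H <- tryCatch(optimHess(opt$par, fn, grc), error = function(e) NULL)
    if (!is.null(H))
      acov <- tryCatch(2 * solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(acov)) converged <- FALSE
  }
  list(converged = converged, theta = setNames(opt$par, enc$theta_names),
       loglik = -opt$value / 2, m2ll = opt$value, acov = acov, enc = enc,
       grad_norm = max(abs(g)))
}

.tl_extract_paths <- function(res, which_level = c("w", "b")) {
  which_level <- match.arg(which_level)
  spec <- if (which_level == "w") res$enc$within else res$enc$between
  if (!inherits(spec, "path_model_spec")) return(NULL)
  offset <- if (which_level == "w") 0L else res$enc$npar_w
  idx <- offset + seq_len(spec$n_edges)
  est <- setNames(res$theta[idx], spec$path_names)
  se <- if (!is.null(res$acov))
    setNames(sqrt(pmax(diag(res$acov)[idx], 0)), spec$path_names)
  else numeric(0)
  list(est = est, se = se)
}

#' Saturated-saturated two-level baseline fit
#'
#' Fits unstructured covariance matrices at both levels; its maximized
#' log-likelihood is the reference for likelihood-ratio chi-square tests of
#' the structured two-level models.
#'
#' @param ds A `"meta_dataset"`.
#'
#' @return List with `loglik`, `m2ll`, `theta`, and `converged`.
#' @export
fit_saturated_twolevel <- function(ds) {
  stats <- tl_stats(ds)
  enc <- tl_encode("saturated", "saturated", ds$variables)
  tl_optimize(enc, stats, se = FALSE)
}

#' Partially saturated (maximum) two-level model fit
#'
#' The hypothesized path model is specified at the within-study level while
#' the between-study level is saturated, so the between-level covariance
#' matrix is reproduced freely.  The chi-square statistic is the likelihood
#' ratio against the saturated-saturated baseline (df = 2 for the
#' five-variable planned-behavior model).
#'
#' @param ds A `"meta_dataset"`.
#' @param spec Within-level [path_model_spec()].
#' @param se Logical; compute standard errors from the observed information.
#' @param saturated Optional precomputed [fit_saturated_twolevel()] result
#'   for the same dataset (avoids refitting when several structured models
#'   share the baseline).
#'
#' @return A `"masem_fit"` object with method tag `"PS"`; `estimates` holds
#'   the within-level path coefficients.
#' @export
fit_partially_saturated <- function(ds, spec = tpb_spec(), se = TRUE,
                                    saturated = NULL) {
  stats <- tl_stats(ds)
  enc <- tl_encode(spec, "saturated", ds$variables)
  res <- tl_optimize(enc, stats, se = se)
  if (is.null(saturated)) saturated <- fit_saturated_twolevel(ds)
  .tl_fit_result("PS", res, saturated, stats, df = spec$df)
}

#' Structured two-level path model fit
#'
#' Hypothesized path structures at both levels.  Within-level path
#' coefficients are the primary estimates; between-level coefficients are
#' reported separately.  The chi-square statistic is the likelihood ratio
#' against the saturated-saturated baseline (df = 4 for the five-variable
#' planned-behavior model at both levels).
#'
#' @param ds A `"meta_dataset"`.
#' @param within_spec,between_spec [path_model_spec()] objects for the two
#'   levels (the between level defaults to the within structure).
#' @inheritParams fit_partially_saturated
#'
#' @return A `"masem_fit"` object with method tag `"2L"`; `estimates` holds
#'   the within-level paths, `between_estimates` the between-level paths.
#' @export
fit_twolevel <- function(ds, within_spec = tpb_spec(),
                         between_spec = within_spec, se = TRUE,
                         saturated = NULL) {
  stats <- tl_stats(ds)
  enc <- tl_encode(within_spec, between_spec, ds$variables)
  res <- tl_optimize(enc, stats, se = se)
  if (is.null(saturated)) saturated <- fit_saturated_twolevel(ds)
  fit <- .tl_fit_result("2L", res, saturated, stats,
                        df = within_spec$df + between_spec$df)
  if (fit$converged) {
    bp <- .tl_extract_paths(res, "b")
    fit$between_estimates <- bp$est
    fit$between_se <- bp$se
  }
  fit
}

.tl_fit_result <- function(method, res, saturated, stats, df) {
  enc <- res$enc
  wspec <- enc$within
  na_est <- setNames(rep(NA_real_, wspec$n_edges), wspec$path_names)
  if (!res$converged || !saturated$converged) {
    return(.masem_fit(method, na_est, numeric(0), NA_real_, df, NA_real_,
                      converged = FALSE, N_effective = stats$N,
                      extra = list(theta = res$theta, loglik_sat = saturated$loglik)))
  }
  wp <- .tl_extract_paths(res, "w")
  chi2 <- max(res$m2ll - saturated$m2ll, 0)
  chi2_p <- pchisq(chi2, df, lower.tail = FALSE)
  fm <- fit_measures(chi2, df, stats$N)
  .masem_fit(method, wp$est, wp$se, chi2, df, chi2_p, 1,
             fm$rmsea, fm$rmsea_close_p, res$loglik, TRUE, stats$N,
             extra = list(theta = res$theta, acov = res$acov,
                          loglik_sat = saturated$loglik, enc = enc))
}
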
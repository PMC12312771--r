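#' Path-model specification for estimation
#'
#' Describes the free parameters of a recursive path model: directed edges,
#' a saturated covariance block among the exogenous variables, and one
#' residual variance per endogenous variable.
#'
#' @param variables Character vector of variable labels, in the fixed
#'   modeling order (exogenous variables first).
#' @param edges Two-column character matrix of directed edges; column 1 is
#'   the outcome, column 2 the predictor.
#'
#' @return An object of class `"path_model_spec"`.
#' @export
path_model_spec <- function(variables, edges) {
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("outcome", "predictor")))
  if (!all(edges %in% variables)) stop("edges refer to unknown variables")
  endo <- unique(edges[, "outcome"])
  exog <- setdiff(variables, endo)
  if (!identical(variables, c(exog, endo)))
    stop("variables must be ordered with the exogenous block first")
  p <- length(variables)
  ne <- nrow(edges)
  nexog <- length(exog)
  # acyclicity via topological check on the edge list
  B0 <- matrix(0, p, p, dimnames = list(variables, variables))
  B0[edges] <- 1
  Bk <- B0
  for (i in seq_len(p)) Bk <- Bk %*% B0
  if (max(Bk) > 0) stop("edge list contains a cycle")
  npar <- ne + nexog * (nexog + 1) / 2 + length(endo)
  df <- p * (p + 1) / 2 - npar
  path_names <- paste0(edges[, "outcome"], "~", edges[, "predictor"])
  structure(list(variables = variables, edges = edges, exog = exog,
                 endo = endo, p = p, n_edges = ne, nexog = nexog,
                 npar = npar, df = df, path_names = path_names),
            class = "path_model_spec")
}

#' Planned-behavior path model specification
#'
#' The five-variable model has edges INT~ATT, INT~SN, INT~PBC, BEH~PBC and
#' BEH~INT (13 free parameters, 2 degrees of freedom).  The reduced
#' four-variable model used when behavior is unobserved drops BEH and its
#' two incoming paths (10 free parameters, saturated).
#'
#' @param include_behavior Logical; `FALSE` gives the reduced model.
#'
#' @return A [path_model_spec()].
#' @export
tpb_spec <- function(include_behavior = TRUE) {
  if (include_behavior) {
    path_model_spec(tpb_variables(),
                    rbind(c("INT", "ATT"), c("INT", "SN"), c("INT", "PBC"),
                          c("BEH", "PBC"), c("BEH", "INT")))
  } else {
    path_model_spec(setdiff(tpb_variables(), "BEH"),
                    rbind(c("INT", "ATT"), c("INT", "SN"), c("INT", "PBC")))
  }
}

# ---- parameter packing -----------------------------------------------------
# theta layout for a structured level:
#   [path coefficients (edge order)]
#   [log-Cholesky of the exogenous covariance block, column-major lower
#    triangle, log on the diagonal]
#   [log residual variances (endogenous order)]

.chol_pack <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

.chol_unpack <- function(theta, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

spec_build <- function(theta, spec) {
  p <- spec$p; v <- spec$variables
  B <- matrix(0, p, p, dimnames = list(v, v))
  if (spec$n_edges > 0) B[spec$edges] <- theta[seq_len(spec$n_edges)]
  Psi <- matrix(0, p, p, dimnames = list(v, v))
  nx <- spec$nexog
  ix <- spec$n_edges + seq_len(nx * (nx + 1) / 2)
  Psi[seq_len(nx), seq_len(nx)] <- .chol_unpack(theta[ix], nx)
  ir <- spec$n_edges + nx * (nx + 1) / 2 + seq_along(spec$endo)
  diag(Psi)[match(spec$endo, v)] <- exp(theta[ir])
  list(B = B, Psi = Psi)
}

# Closed-form ML solution for a recursive model with independent residuals:
# each outcome's coefficients solve the normal equations on its predictors,
# the exogenous block is copied from S.
spec_closed_form <- function(S, spec) {
  v <- spec$variables
  S <- S[v, v, drop = FALSE]
  B <- matrix(0, spec$p, spec$p, dimnames = list(v, v))
  resid <- setNames(numeric(length(spec$endo)), spec$endo)
  for (out in spec$endo) {
    pred <- spec$edges[spec$edges[, "outcome"] == out, "predictor"]
    b <- solve(S[pred, pred, drop = FALSE], S[pred, out])
    B[out, pred] <- b
    resid[out] <- S[out, out] - sum(b * S[pred, out])
  }
  if (any(resid <= 0)) stop("closed-form residual variance is not positive")
  list(B = B, resid = resid, exog = S[spec$exog, spec$exog, drop = FALSE])
}

spec_start <- function(S, spec) {
  cf <- spec_closed_form(S, spec)
  theta <- c(cf$B[spec$edges], .chol_pack(cf$exog), log(cf$resid))
  names(theta) <- spec_theta_names(spec)
  theta
}

spec_theta_names <- function(spec) {
  nx <- spec$nexog
  lt <- which(lower.tri(diag(nx), diag = TRUE), arr.ind = TRUE)
  chn <- paste0("chol.", spec$exog[lt[, 1]], ".", spec$exog[lt[, 2]])
  c(spec$path_names, chn, paste0("logvar.", spec$endo))
}
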
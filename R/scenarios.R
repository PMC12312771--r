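#' Variables of the planned-behavior path model
#'
#' Ordered variable labels used throughout the package: attitudes (ATT),
#' subjective norms (SN), perceived behavioral control (PBC), intentions
#' (INT), and behavior (BEH).  The path coefficient matrix of the
#' planned-behavior model is strictly lower triangular under this ordering.
#'
#' @return Character vector of length five.
#' @export
tpb_variables <- function() c("ATT", "SN", "PBC", "INT", "BEH")

#' Path-model population matrices
#'
#' Bundles a path coefficient matrix `B` (rows index outcomes, columns index
#' predictors) with a residual variance-covariance matrix `Psi` for one level
#' of a path model.
#'
#' @param B Square numeric matrix of path coefficients; must encode an
#'   acyclic structure (`B` nilpotent).
#' @param Psi Symmetric numeric matrix of residual variances and covariances
#'   with strictly positive diagonal.
#' @param variables Optional character vector of variable labels; defaults to
#'   the dimnames of `B`.
#'
#' @return An object of class `"path_model_matrices"` with elements
#'   `variables`, `B`, `Psi`, and `p`.
#' @export
path_model_matrices <- function(B, Psi, variables = colnames(B)) {
  B <- as.matrix(B); Psi <- as.matrix(Psi)
  p <- nrow(B)
  if (ncol(B) != p || !all(dim(Psi) == p))
    stop("B and Psi must be square matrices of the same order")
  if (is.null(variables)) variables <- paste0("V", seq_len(p))
  if (max(abs(Psi - t(Psi))) > 1e-8) stop("Psi must be symmetric")
  if (any(diag(Psi) <= 0)) stop("Psi must have a strictly positive diagonal")
  # acyclicity: B is nilpotent iff the path diagram has no cycles
  Bk <- abs(B)
  for (i in seq_len(p)) Bk <- Bk %*% abs(B)
  if (max(Bk) > 1e-10) stop("B does not encode an acyclic path structure")
  dimnames(B) <- dimnames(Psi) <- list(variables, variables)
  structure(list(variables = variables, B = B, Psi = Psi, p = p),
            class = "path_model_matrices")
}

#' Model-implied covariance matrix of a path model
#'
#' Computes the reduced-form covariance matrix
#' \deqn{\Sigma = (I - B)^{-1} \Psi (I - B)^{-T}}
#' of a linear path model with coefficient matrix `B` and residual
#' covariance matrix `Psi`.
#'
#' @param x A [path_model_matrices()] object, or the `B` matrix itself.
#' @param Psi Residual covariance matrix; required when `x` is a matrix.
#'
#' @return The implied covariance matrix (symmetric, `p` by `p`).
#' @export
#' @examples
#' m <- get_scenario("S4")$within
#' implied_sigma(m)["ATT", "INT"]
implied_sigma <- function(x, Psi = NULL) {
  if (inherits(x, "path_model_matrices")) {
    B <- x$B; Psi <- x$Psi
  } else {
    B <- as.matrix(x)
    if (is.null(Psi)) stop("Psi is required when x is not a path_model_matrices object")
  }
  p <- nrow(B)
  IB <- diag(p) - B
  A <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(A)) stop("(I - B) is singular; the path model has no reduced form")
  S <- A %*% Psi %*% t(A)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(B)
  S
}

#' Two-level path-model population
#'
#' Combines within-study and between-study level path-model matrices into a
#' two-level population.  The total covariance matrix decomposes as
#' \eqn{\Sigma_T = \Sigma_W + \Sigma_B}, and the intraclass correlation of
#' each variable is the between-study share of its total variance.
#'
#' @param within,between [path_model_matrices()] objects for the two levels,
#'   with identical variable sets.
#'
#' @return An object of class `"two_level_population"` with elements
#'   `within`, `between`, `sigma_w`, `sigma_b`, `sigma_t`, and `icc`.
#' @export
two_level_population <- function(within, between) {
  stopifnot(inherits(within, "path_model_matrices"),
            inherits(between, "path_model_matrices"))
  if (!identical(within$variables, between$variables))
    stop("within and between levels must share the same variables")
  sw <- implied_sigma(within)
  sb <- implied_sigma(between)
  st <- sw + sb
  pop <- structure(list(within = within, between = between,
                        sigma_w = sw, sigma_b = sb, sigma_t = st,
                        icc = NULL),
                   class = "two_level_population")
  pop$icc <- icc_profile(pop)
  pop
}

#' Per-variable intraclass correlations of a two-level population
#'
#' @param pop A [two_level_population()] object.
#'
#' @return Named numeric vector; entry `v` equals
#'   \eqn{\sigma_B[v,v] / (\sigma_W[v,v] + \sigma_B[v,v])}.
#' @export
icc_profile <- function(pop) {
  stopifnot(inherits(pop, "two_level_population"))
  tot <- diag(pop$sigma_w) + diag(pop$sigma_b)
  if (any(tot <= 0)) stop("total variance is zero for at least one variable")
  setNames(diag(pop$sigma_b) / tot, pop$within$variables)
}

#' Scenario identifiers of the simulation design
#'
#' @return Character vector of the four population scenario identifiers:
#'   unequal structures with low, medium, and high intraclass correlation,
#'   and equal structures (high intraclass correlation).
#' @export
scenario_ids <- function() {
  c("S1_low_unequal", "S2_medium_unequal", "S3_high_unequal", "S4_high_equal")
}

.normalize_scenario <- function(id) {
  ids <- scenario_ids()
  if (id %in% ids) return(id)
  short <- match(id, c("S1", "S2", "S3", "S4"))
  if (!is.na(short)) return(ids[short])
  stop("unknown scenario id: ", id,
       " (expected one of ", paste(ids, collapse = ", "), ")")
}

.read_scenario_block <- function(tab, level, block, variables) {
  rows <- tab$level == level & tab$block == block
  M <- as.matrix(tab[rows, variables])
  rownames(M) <- tab$row[rows]
  M[variables, variables, drop = FALSE]
}

#' Retrieve a population scenario
#'
#' Loads the population `B` and `Psi` matrices of one of the four simulation
#' scenarios from the tabular fixtures shipped with the package, computes the
#' implied covariance matrices, and cross-checks them against the tabulated
#' (rounded) covariance values.
#'
#' @param id Scenario identifier (see [scenario_ids()]); the short forms
#'   `"S1"`..`"S4"` are also accepted.
#'
#' @return A [two_level_population()] object.
#' @export
#' @examples
#' pop <- get_scenario("S4_high_equal")
#' round(pop$icc, 2)
get_scenario <- function(id) {
  id <- .normalize_scenario(id)
  cache <- .ipdmasem_env
  if (!is.null(cache$scenarios[[id]])) return(cache$scenarios[[id]])
  path <- system.file("extdata", paste0("scenario_", id, ".csv"),
                      package = "ipdmasem", mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE)
  v <- tpb_variables()
  within <- path_model_matrices(.read_scenario_block(tab, "within", "B", v),
                                .read_scenario_block(tab, "within", "Psi", v), v)
  between <- path_model_matrices(.read_scenario_block(tab, "between", "B", v),
                                 .read_scenario_block(tab, "between", "Psi", v), v)
  pop <- two_level_population(within, between)
  # the tabulated Sigma blocks are rounded to 2 decimals; propagated rounding
  # of B and Psi can exceed half a unit in the last place
  for (lv in c("within", "between")) {
    printed <- .read_scenario_block(tab, lv, "Sigma", v)
    implied <- if (lv == "within") pop$sigma_w else pop$sigma_b
    dev <- max(abs(printed - implied))
    if (dev > 0.015)
      stop("scenario ", id, ": implied ", lv, "-level covariance deviates ",
           "from its tabulated values by ", format(dev))
  }
  if (is.null(cache$scenarios)) cache$scenarios <- list()
  cache$scenarios[[id]] <- pop
  pop
}

#' @export
print.path_model_matrices <- function(x, ...) {
  cat("Path model matrices (", x$p, " variables: ",
      paste(x$variables, collapse = ", "), ")\n", sep = "")
  cat("B (paths):\n"); print(round(x$B, 3))
  cat("Psi (residual covariances):\n"); print(round(x$Psi, 3))
  invisible(x)
}

#' @export
print.two_level_population <- function(x, ...) {
  cat("Two-level path-model population\n")
  cat("ICC:", paste(sprintf("%s=%.3f", x$within$variables, x$icc),
                    collapse = ", "), "\n")
  invisible(x)
}
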
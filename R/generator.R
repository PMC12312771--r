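# Simulation of meta-analytic IPD collections from a two-level population.

#' Condition specification for the simulation study
#'
#' @param scenario Scenario identifier (see [scenario_ids()]).
#' @param k Number of primary studies.
#' @param missing Logical; mask the behavior variable in half the studies.
#' @param n_min,n_max Bounds of the study sample sizes (drawn uniformly with
#'   replacement from the integers in this range).
#' @param reps Number of replications.
#' @param master_seed Master seed of the condition.
#'
#' @return An object of class `"condition_spec"`.
#' @export
condition_spec <- function(scenario, k, missing = FALSE,
                           n_min = 90, n_max = 1238,
                           reps = 1, master_seed = 1L) {
  scenario <- .normalize_scenario(scenario)
  stopifnot(k >= 2, n_min <= n_max, n_min >= 1, reps >= 1)
  structure(list(scenario = scenario, k = as.integer(k),
                 missing = isTRUE(missing), n_min = as.integer(n_min),
                 n_max = as.integer(n_max), reps = as.integer(reps),
                 master_seed = as.integer(master_seed)),
            class = "condition_spec")
}

#' Deterministic child seed for one replication of one condition
#'
#' Counter-based spawning: replications and conditions can be generated in
#' any order (or in parallel) with identical results.  The returned seed is
#' always a valid 32-bit integer.
#'
#' @param master Master seed (integer).
#' @param condition_code Integer code of the condition (any stable coding).
#' @param rep Replication index.
#'
#' @return A single integer seed.
#' @export
child_seed <- function(master, condition_code, rep) {
  x <- (as.double(master) * 1000003 + as.double(condition_code) * 10007 +
          as.double(rep) * 7919) %% 2147483629
  as.integer(x + 1)
}

.condition_code <- function(scenario, k, missing) {
  match(.normalize_scenario(scenario), scenario_ids()) * 10000 +
    as.integer(k) * 2 + as.integer(isTRUE(missing))
}

#' Draw study sample sizes
#'
#' Sizes are drawn independently and uniformly (with replacement) from the
#' integers in `[n_min, n_max]`, using the current RNG state.
#'
#' @param k Number of studies.
#' @param n_min,n_max Inclusive bounds.
#'
#' @return Integer vector of length `k`.
#' @export
draw_study_sizes <- function(k, n_min = 90, n_max = 1238) {
  stopifnot(k >= 1, n_min <= n_max)
  if (n_min == n_max) return(rep(as.integer(n_min), k))
  sample(seq.int(n_min, n_max), k, replace = TRUE)
}

#' Simulate a meta-analytic IPD collection
#'
#' Two-stage multivariate-normal generation: study means are drawn i.i.d.
#' from \eqn{N_p(0, \Sigma_B)}, and the observations of study `j` are drawn
#' i.i.d. from \eqn{N_p(\mu_j, \Sigma_W)}.  Grand means are fixed at zero.
#'
#' @param pop A [two_level_population()] object (or scenario id).
#' @param k Number of studies.
#' @param n_min,n_max Study-size bounds (see [draw_study_sizes()]).
#' @param missing Logical; if `TRUE`, [apply_missingness()] masks the last
#'   variable (behavior) in exactly half of the studies.
#' @param seed Optional integer seed set before generation.
#'
#' @return An object of class `"meta_dataset"`: a list with element
#'   `studies` (each study holding `id`, `n`, the `n` by `p` observation
#'   matrix `Y`, and a per-variable `observed` flag) plus provenance fields.
#' @export
simulate_meta_dataset <- function(pop, k, n_min = 90, n_max = 1238,
                                  missing = FALSE, seed = NULL) {
  if (is.character(pop)) pop <- get_scenario(pop)
  stopifnot(inherits(pop, "two_level_population"))
  v <- pop$within$variables
  p <- length(v)
  for (nm in c("sigma_w", "sigma_b")) {
    ev <- eigen(pop[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= if (nm == "sigma_w") 1e-10 else -1e-10)
      stop(nm, " is not positive (semi-)definite; cannot simulate")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sizes <- draw_study_sizes(k, n_min, n_max)
  mu <- MASS::mvrnorm(k, rep(0, p), pop$sigma_b)
  if (k == 1) mu <- matrix(mu, 1)
  N <- sum(sizes)
  E <- MASS::mvrnorm(N, rep(0, p), pop$sigma_w)
  idx <- rep(seq_len(k), sizes)
  studies <- vector("list", k)
  off <- c(0L, cumsum(sizes))
  for (j in seq_len(k)) {
    Y <- E[(off[j] + 1):off[j + 1], , drop = FALSE]
    Y <- sweep(Y, 2, mu[j, ], `+`)
    colnames(Y) <- v
    studies[[j]] <- list(id = j, n = sizes[j], Y = Y,
                         observed = setNames(rep(TRUE, p), v))
  }
  ds <- structure(list(studies = studies, variables = v,
                       scenario = NULL, seed = seed, missing = FALSE),
                  class = "meta_dataset")
  if (missing) ds <- apply_missingness(ds)
  ds
}

#' Mask the behavior variable in half of the studies
#'
#' Selects exactly `k/2` studies uniformly at random (without replacement)
#' and removes the last model variable (behavior) from them entirely.
#' Masking is at the variable level; the remaining variables keep all rows.
#'
#' @param ds A `"meta_dataset"`.
#' @param variable Variable to mask; defaults to the last one.
#'
#' @return The dataset with masked studies.
#' @export
apply_missingness <- function(ds, variable = NULL) {
  k <- length(ds$studies)
  if (k %% 2 != 0) stop("missingness design requires an even number of studies")
  if (is.null(variable)) variable <- ds$variables[length(ds$variables)]
  pick <- sample(seq_len(k), k / 2)
  for (j in pick) {
    s <- ds$studies[[j]]
    keep <- setdiff(colnames(s$Y), variable)
    s$Y <- s$Y[, keep, drop = FALSE]
    s$observed <- setNames(ds$variables %in% keep, ds$variables)
    ds$studies[[j]] <- s
  }
  ds$missing <- TRUE
  ds
}

#' Center every variable at its study mean
#'
#' Subtracts the per-study mean from each observed variable, removing all
#' between-study mean differences.  Fitting a single-level model to centered
#' data targets the within-study level parameters.
#'
#' @param ds A `"meta_dataset"`.
#'
#' @return The centered dataset.
#' @export
center_within <- function(ds) {
  ds$studies <- lapply(ds$studies, function(s) {
    s$Y <- scale(s$Y, center = TRUE, scale = FALSE)
    attr(s$Y, "scaled:center") <- NULL
    s
  })
  ds
}

#' Write / read an IPD collection as a long-format CSV
#'
#' Columns: `study_id`, `participant_id`, then one column per variable
#' (empty cells for masked variables).
#'
#' @param ds A `"meta_dataset"`.
#' @param path File path.
#'
#' @return `write_ipd_csv` returns `path` invisibly; `read_ipd_csv` returns
#'   a `"meta_dataset"`.
#' @export
write_ipd_csv <- function(ds, path) {
  rows <- lapply(ds$studies, function(s) {
    out <- matrix(NA_real_, s$n, length(ds$variables),
                  dimnames = list(NULL, ds$variables))
    out[, colnames(s$Y)] <- s$Y
    data.frame(study_id = s$id, participant_id = seq_len(s$n), out)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  tab <- read.csv(path)
  v <- setdiff(colnames(tab), c("study_id", "participant_id"))
  studies <- lapply(split(tab, tab$study_id), function(d) {
    Y <- as.matrix(d[, v, drop = FALSE])
    obs <- setNames(colSums(is.na(Y)) == 0, v)
    list(id = d$study_id[1], n = nrow(Y),
         Y = Y[, obs, drop = FALSE], observed = obs)
  })
  names(studies) <- NULL
  structure(list(studies = studies, variables = v, scenario = NULL,
                 seed = NULL, missing = any(!vapply(studies, function(s)
                   all(s$observed), logical(1)))),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  k <- length(x$studies)
  n <- vapply(x$studies, `[[`, integer(1), "n")
  masked <- sum(!vapply(x$studies, function(s) all(s$observed), logical(1)))
  cat("Meta-analytic IPD collection: ", k, " studies, N = ", sum(n),
      " (n_j ", min(n), "-", max(n), "), ", masked,
      " studies with masked variables\n", sep = "")
  invisible(x)
}
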
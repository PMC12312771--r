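# Orchestration of the replication study and the evaluation criteria:
# convergence rates, mean estimates, RMSE, relative SE bias, and exact- and
# close-fit rejection rates.

.path_keys <- function() c("INT~ATT", "INT~SN", "INT~PBC", "BEH~PBC", "BEH~INT")

.methods_all <- function() c("NP", "CR", "PS", "2L", "MVMA", "OSMASEM",
                             "CR-centered")

.record_row <- function(cond, rep, method, fit) {
  keys <- .path_keys()
  est <- setNames(rep(NA_real_, length(keys)), keys)
  se <- est
  if (!is.null(fit) && length(fit$estimates)) {
    common <- intersect(names(fit$estimates), keys)
    est[common] <- fit$estimates[common]
    if (length(fit$se)) se[common] <- fit$se[common]
  }
  out <- data.frame(scenario = cond$scenario, k = cond$k,
                    missing = cond$missing, rep = rep, method = method,
                    converged = !is.null(fit) && isTRUE(fit$converged),
                    chi2 = if (is.null(fit)) NA_real_ else fit$chi2,
                    df = if (is.null(fit)) NA_real_ else as.numeric(fit$df),
                    chi2_p = if (is.null(fit)) NA_real_ else fit$chi2_p,
                    rmsea = if (is.null(fit)) NA_real_ else fit$rmsea,
                    close_p = if (is.null(fit)) NA_real_ else fit$rmsea_close_p,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    out[[paste0("est.", keys[i])]] <- est[i]
    out[[paste0("se.", keys[i])]] <- se[i]
  }
  out
}

#' Run all replications of one simulation condition
#'
#' For each replication a fresh IPD collection is generated (deterministic
#' child seed from the master seed), and every requested method is fitted to
#' the same collection.  Per-fit failures are recorded as non-converged
#' replications, never raised.
#'
#' @param cond A [condition_spec()].
#' @param methods Subset of `"NP"`, `"CR"`, `"PS"`, `"2L"`, `"MVMA"`,
#'   `"OSMASEM"`, `"CR-centered"`.
#' @param se Logical; compute standard errors (needed for SE-bias
#'   evaluation; skipping them speeds up fit-rate studies).
#' @param progress Logical; print a dot per replication.
#'
#' @return A data frame with one row per (replication, method).
#' @export
run_condition <- function(cond, methods = c("NP", "CR", "PS", "2L",
                                            "MVMA", "OSMASEM"),
                          se = TRUE, progress = FALSE) {
  stopifnot(inherits(cond, "condition_spec"))
  methods <- match.arg(methods, .methods_all(), several.ok = TRUE)
  pop <- get_scenario(cond$scenario)
  code <- .condition_code(cond$scenario, cond$k, cond$missing)
  spec <- tpb_spec()
  out <- vector("list", cond$reps * length(methods))
  ri <- 0
  for (r in seq_len(cond$reps)) {
    ds <- simulate_meta_dataset(pop, cond$k, cond$n_min, cond$n_max,
                                missing = cond$missing,
                                seed = child_seed(cond$master_seed, code, r))
    sat <- NULL
    if (any(c("PS", "2L") %in% methods))
      sat <- tryCatch(fit_saturated_twolevel(ds), error = function(e)
        list(converged = FALSE, loglik = NA_real_, m2ll = NA_real_))
    cds <- if ("CR-centered" %in% methods) center_within(ds) else NULL
    for (m in methods) {
      fit <- tryCatch(switch(m,
        "NP" = fit_naive_pooling(ds, spec, se = se, on_missing = "common"),
        "CR" = fit_cluster_robust(ds, spec, se = se, on_missing = "common"),
        "CR-centered" = fit_cluster_robust(cds, spec, se = se,
                                           on_missing = "common"),
        "PS" = fit_partially_saturated(ds, spec, se = se, saturated = sat),
        "2L" = fit_twolevel(ds, spec, spec, se = se, saturated = sat),
        "MVMA" = fit_mvma(ds, spec),
        "OSMASEM" = fit_osmasem(ds, spec)),
        error = function(e) NULL)
      ri <- ri + 1
      out[[ri]] <- .record_row(cond, r, m, fit)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, out)
}

#' Root mean square error of a set of estimates
#'
#' @param estimates Numeric vector of estimates across replications.
#' @param beta_true True parameter value.
#'
#' @return \eqn{\sqrt{mean((\hat\beta_i - \beta)^2)}}.
#' @export
rmse <- function(estimates, beta_true) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates)) return(NA_real_)
  sqrt(mean((estimates - beta_true)^2))
}

#' Percentage relative bias of a standard error
#'
#' `100 * (mean_se - empirical_sd) / empirical_sd`; values beyond 10 in
#' magnitude are conventionally considered unacceptable.
#'
#' @param mean_se Mean estimated standard error across replications.
#' @param empirical_sd Empirical standard deviation of the estimates.
#'
#' @return Percentage relative bias (scalar).
#' @export
se_bias_pct <- function(mean_se, empirical_sd) {
  if (is.na(empirical_sd) || empirical_sd <= 0) return(NA_real_)
  100 * (mean_se - empirical_sd) / empirical_sd
}

#' Exact-fit and close-fit rejection rates
#'
#' @param records Data frame of replication records (converged rows are
#'   used).
#' @param alpha Significance level.
#'
#' @return Named vector with `exact` and `close` rejection percentages.
#' @export
rejection_rates <- function(records, alpha = 0.05) {
  rec <- records[records$converged, , drop = FALSE]
  c(exact = 100 * mean(rec$chi2_p < alpha, na.rm = TRUE),
    close = 100 * mean(rec$close_p < alpha, na.rm = TRUE))
}

#' Monte Carlo interval around a nominal rejection rate
#'
#' @param alpha Nominal rate.
#' @param reps Number of replications.
#'
#' @return Two-element vector (percent, 1 decimal):
#'   \eqn{100(\alpha \pm 1.96\sqrt{\alpha(1-\alpha)/reps})}.
#' @export
mc_interval <- function(alpha = 0.05, reps = 1000) {
  half <- 1.96 * sqrt(alpha * (1 - alpha) / reps)
  round(100 * c(low = alpha - half, high = alpha + half), 1)
}

#' Summarize replication records per condition and method
#'
#' Summaries are computed over converged replications only.  Conditions
#' with convergence below 50% are flagged (`low_convergence`); their
#' summaries should not be interpreted or compared.
#'
#' @param records Data frame from [run_condition()] (possibly row-bound
#'   over conditions).
#' @param alpha Significance level for the rejection rates.
#'
#' @return Data frame with one row per (scenario, k, missing, method):
#'   convergence rate (%), mean estimate / RMSE / SE bias (%) per path, and
#'   exact- and close-fit rejection rates (%).
#' @export
summarize_replications <- function(records, alpha = 0.05) {
  keys <- .path_keys()
  groups <- split(records, list(records$scenario, records$k,
                                records$missing, records$method),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    pop <- get_scenario(g$scenario[1])
    truth <- setNames(pop$within$B[tpb_spec()$edges], keys)
    conv <- 100 * mean(g$converged)
    cg <- g[g$converged, , drop = FALSE]
    row <- data.frame(scenario = g$scenario[1], k = g$k[1],
                      missing = g$missing[1], method = g$method[1],
                      convergence_pct = conv,
                      low_convergence = conv < 50,
                      stringsAsFactors = FALSE)
    for (key in keys) {
      est <- cg[[paste0("est.", key)]]
      ses <- cg[[paste0("se.", key)]]
      row[[paste0("mean.", key)]] <- if (nrow(cg)) mean(est, na.rm = TRUE) else NA
      row[[paste0("rmse.", key)]] <- rmse(est, truth[key])
      row[[paste0("sebias.", key)]] <-
        if (nrow(cg)) se_bias_pct(mean(ses, na.rm = TRUE), sd(est, na.rm = TRUE))
        else NA_real_
    }
    rr <- rejection_rates(cg, alpha)
    row$exact_fit_pct <- rr["exact"]
    row$close_fit_pct <- rr["close"]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$missing, out$scenario, out$k, out$method), ]
}

#' Run a grid of simulation conditions
#'
#' @param scenarios,ks,missing Vectors spanning the condition grid.
#' @param reps Replications per condition.
#' @param master_seed Master seed (each condition/replication derives its
#'   own child seed, so the grid order does not matter).
#' @param methods,se,progress Passed to [run_condition()].
#'
#' @return Row-bound data frame of replication records.
#' @export
run_grid <- function(scenarios = scenario_ids(), ks = c(10, 30, 50),
                     missing = c(FALSE, TRUE), reps = 200, master_seed = 1,
                     methods = c("NP", "CR", "PS", "2L", "MVMA", "OSMASEM"),
                     se = TRUE, progress = FALSE) {
  grid <- expand.grid(scenario = scenarios, k = ks, missing = missing,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- condition_spec(grid$scenario[i], grid$k[i], grid$missing[i],
                           reps = reps, master_seed = master_seed)
    run_condition(cond, methods = methods, se = se, progress = progress)
  })
  do.call(rbind, out)
}

#' Write evaluation tables (and optional figures) to disk
#'
#' Emits one CSV per evaluation criterion, with rows spanning
#' (missingness, scenario, k) and columns spanning methods, mirroring the
#' layout of the study's result tables.  Cells of methods whose convergence
#' rate fell below 50% in a condition are left empty.
#'
#' @param summaries Data frame from [summarize_replications()].
#' @param dir Output directory (created if needed).
#' @param figures Logical; additionally write mean-estimate and RMSE plots
#'   per path (requires ggplot2).
#'
#' @return Invisibly, the paths of the files written.
#' @export
report <- function(summaries, dir, figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  methods <- unique(summaries$method)
  base <- unique(summaries[, c("missing", "scenario", "k")])
  base <- base[order(base$missing, base$scenario, base$k), , drop = FALSE]
  wide <- function(col, blank_low = TRUE) {
    out <- base
    for (m in methods) {
      vals <- rep(NA_real_, nrow(base))
      sub <- summaries[summaries$method == m, , drop = FALSE]
      ix <- match(paste(base$missing, base$scenario, base$k),
                  paste(sub$missing, sub$scenario, sub$k))
      vals <- sub[[col]][ix]
      if (blank_low) vals[sub$low_convergence[ix]] <- NA_real_
      out[[m]] <- round(vals, 2)
    }
    out
  }
  files <- character(0)
  tabs <- list(convergence = wide("convergence_pct", blank_low = FALSE),
               exact_fit = wide("exact_fit_pct"),
               close_fit = wide("close_fit_pct"))
  for (key in .path_keys()) {
    tabs[[paste0("se_bias_", gsub("~", "_", key))]] <-
      wide(paste0("sebias.", key))
    tabs[[paste0("mean_est_", gsub("~", "_", key))]] <-
      wide(paste0("mean.", key))
    tabs[[paste0("rmse_", gsub("~", "_", key))]] <- wide(paste0("rmse.", key))
  }
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  if (figures && requireNamespace("ggplot2", quietly = TRUE))
    files <- c(files, .report_figures(summaries, dir))
  invisible(files)
}

.report_figures <- function(summaries, dir) {
  files <- character(0)
  for (key in c("BEH~INT", "BEH~PBC")) {
    long <- summaries[!summaries$low_convergence, ]
    long$value <- long[[paste0("mean.", key)]]
    refs <- do.call(rbind, lapply(unique(long$scenario), function(s) {
      pop <- get_scenario(s)
      out <- strsplit(key, "~")[[1]][1]
      prd <- strsplit(key, "~")[[1]][2]
      data.frame(scenario = s, within = pop$within$B[out, prd],
                 between = pop$between$B[out, prd])
    }))
    gg <- ggplot2::ggplot(long, ggplot2::aes(x = factor(k), y = value,
                                             color = method, group = method)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::geom_hline(data = refs,
                          ggplot2::aes(yintercept = within),
                          linetype = "dashed", color = "red") +
      ggplot2::geom_hline(data = refs,
                          ggplot2::aes(yintercept = between),
                          linetype = "dotted", color = "blue") +
      ggplot2::facet_grid(missing ~ scenario) +
      ggplot2::labs(x = "number of studies",
                    y = paste("mean estimate,", key))
    f <- file.path(dir, paste0("mean_est_", gsub("~", "_", key), ".pdf"))
    ggplot2::ggsave(f, gg, width = 9, height = 5)
    files <- c(files, f)
  }
  files
}
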
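#' Run configuration
#'
#' Flat named-list configuration for the end-to-end pipeline
#' (simulate -> preprocess -> fit -> infer -> probe -> report), with one
#' seed funnelling every source of randomness. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, out_dir = "diaryreact-run",
              data_csv = NULL,
              design = "negative_affect", quadratic_stress = FALSE,
              chains = 4L, warmup = 1000L, iter = 1000L,
              adapt_delta = 0.8, convergence_check = "error",
              rope = 0.05, rope_relaxed = 0.025,
              probe_unit = "column_sd")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ",
                            paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a flat key: value config file
#'
#' @param path file path; lines are `key: value`, `#` comments allowed.
#' @return [read_run_config()] returns a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = ":"))
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^-?[0-9.]+$", v)) as.numeric(v)
    else v
  })
  names(vals) <- trimws(vapply(kv, `[`, character(1), 1))
  do.call(run_config, vals)
}

#' @param config a `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  keys <- setdiff(names(config), "data_csv")
  if (!is.null(config$data_csv)) keys <- names(config)
  writeLines(vapply(keys, function(k) {
    sprintf("%s: %s", k, format(config[[k]]))
  }, character(1)), path)
  invisible(path)
}

run_info <- function(config, stage, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  info <- c(list(stage = stage, seed = config$seed,
                 config_hash = unname(tools::md5sum(tmp))), extra)
  paste(names(info), vapply(info, function(v) paste(format(v), collapse = ","),
                            character(1)), sep = "=")
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1fs)", stage,
                  paste(..., collapse = "; "),
                  proc.time()[["elapsed"]] - t0))
}

#' Simulate a dataset to disk
#'
#' Writes `data.csv` (long-form diary table), `truth.csv` (flat ground
#' truth: coefficient vector, SDs, shape and censoring setup per
#' outcome model) and `run_info.txt` (seed + config hash) into
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param generator a [generator_config()] (seeded from the run config).
#' @return invisibly, the simulated dataset list.
#' @export
run_simulate <- function(config = run_config(),
                         generator = generator_config(seed = config$seed)) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(generator, seed = config$seed)
  write_long_csv(sim$table, file.path(config$out_dir, "data.csv"))
  rows <- do.call(rbind, lapply(names(sim$truth$outcomes), function(nm) {
    tp <- sim$truth$outcomes[[nm]]
    rbind(data.frame(outcome = nm, parameter = names(tp$beta),
                     value = unname(tp$beta)),
          data.frame(outcome = nm,
                     parameter = c("tau", "sigma", "alpha",
                                   "bound_lower", "bound_upper",
                                   "outcome_mean", "outcome_sd"),
                     value = c(tp$tau, tp$sigma, tp$alpha,
                               tp$bounds_raw, tp$outcome_mean,
                               tp$outcome_sd)))
  }))
  utils::write.csv(rows, file.path(config$out_dir, "truth.csv"),
                   row.names = FALSE)
  writeLines(run_info(config, "simulate",
                      list(rows = nrow(sim$table),
                           persons = length(unique(sim$table$person_id)))),
             file.path(config$out_dir, "run_info.txt"))
  stage_log("simulate", t0, sprintf("%d rows, %d persons", nrow(sim$table),
                                    length(unique(sim$table$person_id))))
  invisible(sim)
}

#' Fit a configured design and write coefficient tables
#'
#' Reads the dataset (defaults to the one [run_simulate()] wrote),
#' builds the model frame for the configured design, fits it, and
#' writes pooled posterior draws of the reported parameters
#' (`draws.csv`), the dual-ROPE coefficient summary (`summary.csv` and
#' an aligned text rendering `summary.txt`), and convergence
#' diagnostics (`diagnostics.csv`). Non-convergence raises an error
#' naming the offending parameters.
#'
#' @param config a [run_config()].
#' @return the `diary_fit`, invisibly.
#' @export
run_fit <- function(config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  path <- config$data_csv %||% file.path(config$out_dir, "data.csv")
  tab <- read_long_csv(path)
  spec <- design_spec(config$design,
                      quadratic_stress = isTRUE(config$quadratic_stress))
  frame <- build_model_frame(tab, spec)
  fit <- fit_hierarchical(frame, chains = config$chains,
                          warmup = config$warmup, iter = config$iter,
                          seed = config$seed,
                          adapt_delta = config$adapt_delta,
                          check = config$convergence_check)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(config$design,
                if (isTRUE(config$quadratic_stress)) "_quadratic" else "")
  dr <- posterior_draws(fit)
  utils::write.csv(as.data.frame(dr),
                   file.path(config$out_dir, paste0("draws_", tag, ".csv")),
                   row.names = FALSE)
  st <- summary_table(fit, c(config$rope, config$rope_relaxed))
  utils::write.csv(as.data.frame(st),
                   file.path(config$out_dir, paste0("summary_", tag, ".csv")),
                   row.names = FALSE)
  writeLines(c(run_info(config, "fit"),
               utils::capture.output(print(st))),
             file.path(config$out_dir, paste0("summary_", tag, ".txt")))
  utils::write.csv(fit$diagnostics,
                   file.path(config$out_dir,
                             paste0("diagnostics_", tag, ".csv")),
                   row.names = FALSE)
  stage_log("fit", t0, sprintf("%s on %d rows", tag, length(frame$y)))
  invisible(fit)
}

#' Probe a fitted model and write report tables
#'
#' Writes the reactivity-slope grid, slope differences with the
#' difference-of-differences summary (including the algebraic
#' `4 * b_3way` identity check), descriptive statistics of the analysed
#' dataset, and (for quadratic designs) the quadratic stress curves at
#' +/-1 SD WP AARC-losses.
#'
#' @param fit a [fit_hierarchical()] result.
#' @param config a [run_config()].
#' @return invisibly, the list of written paths.
#' @export
run_report <- function(fit, config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  unit <- config$probe_unit
  if ("wp_gains:wp_losses:wp_stress" %in% colnames(fit$frame$X)) {
    sg <- slope_grid(fit, unit = unit)
    p <- file.path(config$out_dir, "slope_grid.csv")
    utils::write.csv(sg, p, row.names = FALSE)
    paths <- c(paths, p)
    sd_draws <- slope_differences(fit, unit = unit)
    b3 <- posterior_draws(fit, "wp_gains:wp_losses:wp_stress")[, 1]
    sc <- moderator_scale(fit, unit)
    identity_gap <- max(abs(sd_draws$diff_of_diffs -
                              4 * sc["wp_gains"] * sc["wp_losses"] * b3))
    sums <- data.frame(
      quantity = c("diff_low_losses", "diff_high_losses", "diff_of_diffs"),
      est = vapply(sd_draws, mean, numeric(1)),
      hdi_low = vapply(sd_draws, function(v) hdi(v)[["low"]], numeric(1)),
      hdi_high = vapply(sd_draws, function(v) hdi(v)[["high"]], numeric(1)))
    sums$identity_check_4b3way <- c(NA, NA, identity_gap)
    p <- file.path(config$out_dir, "slope_differences.csv")
    utils::write.csv(sums, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (isTRUE(config$quadratic_stress) &&
      "wp_stress2" %in% colnames(fit$frame$X)) {
    qc <- rbind(cbind(losses = -1, quadratic_curve(fit, -1, unit = unit)),
                cbind(losses = +1, quadratic_curve(fit, +1, unit = unit)))
    p <- file.path(config$out_dir, "quadratic_curves.csv")
    utils::write.csv(qc, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  path <- config$data_csv %||% file.path(config$out_dir, "data.csv")
  if (file.exists(path)) {
    de <- descriptives(read_long_csv(path))
    p <- file.path(config$out_dir, "descriptives.csv")
    utils::write.csv(de$summary, p, row.names = FALSE)
    utils::write.csv(de$correlations,
                     file.path(config$out_dir, "correlations.csv"))
    paths <- c(paths, p)
  }
  writeLines(run_info(config, "report"),
             file.path(config$out_dir, "report_info.txt"))
  stage_log("report", t0, sprintf("%d artifact(s)", length(paths)))
  invisible(paths)
}

#' Compare two fitted models by PSIS-LOO elpd
#'
#' @param fit_reference,fit_challenger `diary_fit` objects on the same
#'   observations.
#' @param config a [run_config()] (for the output directory).
#' @return invisibly, a list with both `elpd_result`s and the
#'   difference.
#' @export
run_compare <- function(fit_reference, fit_challenger,
                        config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  ea <- elpd_loo(pointwise_loglik(fit_reference))
  eb <- elpd_loo(pointwise_loglik(fit_challenger))
  d <- elpd_difference(ea, eb)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(model = c("reference", "challenger", "difference"),
                    elpd = c(ea$elpd, eb$elpd, d$difference),
                    se = c(ea$se, eb$se, d$se))
  utils::write.csv(tab, file.path(config$out_dir, "elpd_comparison.csv"),
                   row.names = FALSE)
  writeLines(c(run_info(config, "compare"),
               utils::capture.output(print(tab, row.names = FALSE))),
             file.path(config$out_dir, "elpd_comparison.txt"))
  stage_log("compare", t0, sprintf("elpd diff %.1f (SE %.1f)",
                                   d$difference, d$se))
  invisible(list(reference = ea, challenger = eb, difference = d))
}

#' Descriptive statistics of a diary table
#'
#' Day-1 means and SDs, long-form observed ranges, and long-form
#' pairwise correlations of the key study variables.
#'
#' @param table a [diary_table()].
#' @return list with `summary` (per-variable day-1 M/SD and long-form
#'   range) and `correlations` (long-form correlation matrix).
#' @export
descriptives <- function(table) {
  tab <- as.data.frame(table)
  tab$female <- as.numeric(tab$gender == "female")
  tab$not_in_labor_force <- 1 - tab$in_labor_force
  vars <- c("age", "female", "tertiary_educated", "not_in_labor_force",
            "physical_functioning", "aarc_gains", "aarc_losses",
            "negative_affect", "vitality", "stress_severity")
  day1 <- tab[tab$day_index == min(tab$day_index), ]
  summ <- do.call(rbind, lapply(vars, function(v) {
    data.frame(variable = v,
               day1_mean = mean(day1[[v]], na.rm = TRUE),
               day1_sd = stats::sd(day1[[v]], na.rm = TRUE),
               min = min(tab[[v]], na.rm = TRUE),
               max = max(tab[[v]], na.rm = TRUE))
  }))
  corr <- stats::cor(tab[, vars], use = "pairwise.complete.obs")
  list(summary = summ, correlations = round(corr, 3))
}
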
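#' Descriptive statistics across aggregation levels
#'
#' For every level, reports the number of areas with non-zero population
#' and — for per-area total population and per-area counts — the mean,
#' sample standard deviation (denominator n-1), minimum, median, IQR
#' (75th minus 25th percentile) and maximum, computed over the included
#' areas.  This is the machine-readable analogue of the usual
#' "population and diagnoses by level" descriptive table.
#'
#' @param hierarchy hierarchy with populations set.
#' @param outcome_by_level named list of outcome tables per level.
#' @return Data frame with one row per level and variable
#'   (`variable` is `"population"` or `"count"`).
#' @export
descriptives <- function(hierarchy, outcome_by_level) {
  rows <- list()
  for (lev in hierarchy$levels) {
    pop <- level_population(hierarchy, lev)
    keep <- pop > 0
    if (!any(keep)) stop("empty level: ", lev)
    out <- outcome_by_level[[lev]]
    y <- out$y[match(names(pop), out$area_id)]
    for (vn in c("population", "count")) {
      x <- if (vn == "population") pop[keep] else y[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, variable = vn, n_areas = sum(keep),
        mean = mean(x), sd = if (sum(keep) > 1L) sd(x) else NA_real_,
        min = min(x), median = median(x),
        iqr = unname(diff(quantile(x, c(.25, .75)))), max = max(x),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Run the full cross-level MAUP experiment
#'
#' Executes, for a synthetic scenario (or pre-simulated data of the same
#' shape): descriptive statistics per level; Moran's I permutation tests on
#' observed counts per level; BYM fits without and with the covariate at
#' every selected level; Moran's I on the Pearson residuals of both fits;
#' and posterior summaries including the fraction of spatial variation.
#' Model seeds are derived deterministically from `config$seed` and the
#' level, so the whole experiment is reproducible end to end.
#'
#' @param scenario a [scenario_config()], or a pre-built
#'   [simulate_scenario()] result.
#' @param config a [bym_config()]; its `seed` drives the model fits.
#' @param levels level names to fit (default: all).
#' @param include_finest fit the finest level too (it is the heaviest and
#'   noisiest; set `FALSE` to skip while keeping its descriptives and
#'   Moran's I).
#' @param n_permutations permutations for every Moran test.
#' @param residual_kind residual type fed to the residual Moran tests.
#' @param moran_style Moran weight style (`"W"` row-standardised default).
#' @param out_dir optional directory: writes `table1.csv`, `table2.csv`,
#'   `posterior_summary_nocov.csv`, `posterior_summary_cov.csv`,
#'   `maps_<level>.geojson` and `run.log`.
#' @param verbose print progress lines.
#' @return An object of class `maup_experiment`: list with `table1`,
#'   `table2`, `posterior_nocov`, `posterior_cov`, `summaries` (per level,
#'   per model), `fits_run`, `scenario`, `config`, `log`.
#' @export
run_experiment <- function(scenario = scenario_config(),
                           config = bym_config(),
                           levels = NULL, include_finest = TRUE,
                           n_permutations = 999L,
                           residual_kind = "pearson",
                           moran_style = "W",
                           out_dir = NULL, verbose = FALSE) {
  sim <- if (inherits(scenario, "scenario_config")) {
    simulate_scenario(scenario)
  } else scenario
  h <- sim$hierarchy
  all_levels <- h$levels
  fit_levels <- levels %||% all_levels
  if (!include_finest) fit_levels <- setdiff(fit_levels, all_levels[1L])
  log_lines <- c(sprintf("scenario seed %d; model seed %d; chain %d/%d/%d",
                         sim$config$seed, config$seed, config$n_iter,
                         config$n_burnin, config$thin))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  table1 <- descriptives(h, sim$outcome_by_level)

  moran_rows <- list(); post_rows <- list(); summaries <- list()
  fits_run <- 0L
  for (lev in all_levels) {
    out <- sim$outcome_by_level[[lev]]
    keep <- which(out$E > 0)
    out_k <- out[keep, , drop = FALSE]
    adj_k <- if (length(keep) < h$adjacency[[lev]]$n) {
      .subset_adjacency(h$adjacency[[lev]], keep)
    } else h$adjacency[[lev]]

    # derived seeds stay inside 32-bit integer range for any base seed
    seed_lev <- as.integer((as.numeric(config$seed) * 1000 +
                              match(lev, all_levels)) %% 2147000000)
    mo <- morans_i_test(out_k$y, adj_k, style = moran_style,
                        n_permutations = n_permutations, seed = seed_lev)
    moran_rows[[length(moran_rows) + 1L]] <- data.frame(
      level = lev, target = "observed", statistic = mo$statistic,
      p_value = mo$p_value, row.names = NULL)
    say("moran observed %-5s I = %.3f p = %.4g", lev, mo$statistic, mo$p_value)

    if (!lev %in% fit_levels) next
    for (spec in c("nocov", "cov")) {
      cfg <- config
      cfg$seed <- as.integer((as.numeric(seed_lev) +
                                if (spec == "cov") 500000 else 0) %% 2147000000)
      cov_tab <- if (spec == "cov") sim$covariate_by_level[[lev]] else NULL
      fit <- fit_bym(out_k, cov_tab, adj_k, cfg)
      fits_run <- fits_run + 1L
      sm <- summary(fit)
      summaries[[lev]][[spec]] <- sm
      bad <- sm$parameters$parameter[
        !is.na(sm$parameters$geweke_z) & abs(sm$parameters$geweke_z) > 3]
      say("fit %-5s %-5s accept(a/u/v) %.2f/%.2f/%.2f frac_spatial %.2f%s",
          lev, spec, fit$accept_alpha, fit$accept_u, fit$accept_v,
          sm$fraction_spatial_variation,
          if (length(bad)) paste0(" GEWEKE FLAG: ", paste(bad, collapse = ","))
          else "")
      res <- model_residuals(out_k, sm, kind = residual_kind)
      mo_r <- morans_i_test(res, adj_k, style = moran_style,
                            n_permutations = n_permutations,
                            seed = cfg$seed + 1L)
      moran_rows[[length(moran_rows) + 1L]] <- data.frame(
        level = lev, target = paste0("resid_", spec),
        statistic = mo_r$statistic, p_value = mo_r$p_value, row.names = NULL)
      post_rows[[length(post_rows) + 1L]] <- cbind(
        data.frame(level = lev, model = spec), sm$parameters,
        fraction_spatial_variation = sm$fraction_spatial_variation)
    }
  }
  table2 <- do.call(rbind, moran_rows)
  posterior <- do.call(rbind, post_rows)
  result <- structure(list(
    table1 = table1, table2 = table2,
    posterior_nocov = posterior[posterior$model == "nocov", , drop = FALSE],
    posterior_cov = posterior[posterior$model == "cov", , drop = FALSE],
    summaries = summaries, fits_run = fits_run,
    scenario = sim, config = config, log = log_lines),
    class = "maup_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.maup_experiment <- function(x, ...) {
  cat(sprintf("maup_experiment: %d levels, %d model fits\n",
              length(unique(x$table1$level)), x$fits_run))
  cat("\nMoran's I (observed counts):\n")
  print(x$table2[x$table2$target == "observed", ], row.names = FALSE)
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Emits `table1.csv` (descriptives), `table2.csv` (Moran's I of observed
#' counts and residuals), `posterior_summary_nocov.csv`,
#' `posterior_summary_cov.csv`, one `maps_<level>.geojson` per level with
#' observed and fitted SIRs as feature attributes, and `run.log`.
#'
#' @param result a [run_experiment()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table1, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$table2, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(result$posterior_nocov,
                   file.path(dir, "posterior_summary_nocov.csv"),
                   row.names = FALSE)
  utils::write.csv(result$posterior_cov,
                   file.path(dir, "posterior_summary_cov.csv"),
                   row.names = FALSE)
  sim <- result$scenario
  for (lev in sim$hierarchy$levels) {
    vals <- sim$outcome_by_level[[lev]][, c("area_id", "sir")]
    names(vals)[2] <- "observed_sir"
    for (spec in c("nocov", "cov")) {
      sm <- result$summaries[[lev]][[spec]]
      if (!is.null(sm)) {
        fs <- sm$fitted_sir[, c("area_id", "fitted_sir")]
        names(fs)[2] <- paste0("fitted_sir_", spec)
        vals <- merge(vals, fs, by = "area_id", all.x = TRUE, sort = FALSE)
      }
    }
    write_geojson(sim$hierarchy, lev, vals,
                  file.path(dir, paste0("maps_", lev, ".geojson")))
  }
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}
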
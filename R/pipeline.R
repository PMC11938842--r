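# End-to-end pipeline: minute averaging -> surrogate -> coalesce -> both
# decompositions -> z-score outliers -> summaries -> distribution fit ->
# cumulative Agr.Ops -> stability GLM, with tidy CSV outputs and a manifest.

#' Pipeline configuration
#'
#' @param sensor_log Path to a sensor CSV (`timestamp,sensor_id,value_c`),
#'   or `NULL` to simulate with `sim` instead.
#' @param event_log Path to an event CSV (`timestamp,channel,state`), or
#'   `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()] used when `sensor_log` is `NULL`.
#' @param outlier An [outlier_config()].
#' @param fit_method `"mle"` or `"mge_cvm"` for [fit_distributions()].
#' @param weights Agr.Ops weights, `c(person = 1, door = 0)`.
#' @param fit_sensors Sensors pooled for distribution fitting and the
#'   stability GLM; defaults to every sensor except `"Reference"` (the
#'   independent logger is excluded from model fitting).
#' @param trials Trial plan when reading from files; defaults to the `sim`
#'   plan.
#' @param seed Master seed (also forwarded into `sim`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sensor_log = NULL, event_log = NULL,
                            out_dir = "chamberqc-out",
                            sim = sim_config(seed = seed),
                            outlier = outlier_config(),
                            fit_method = "mle",
                            weights = c(person = 1, door = 0),
                            fit_sensors = NULL,
                            trials = NULL,
                            seed = 1L) {
  structure(
    list(sensor_log = sensor_log, event_log = event_log, out_dir = out_dir,
         sim = sim, outlier = outlier, fit_method = fit_method,
         weights = weights, fit_sensors = fit_sensors,
         trials = if (is.null(trials)) sim$trials else trials,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either on-disk logs or a fresh simulation, writes
#' `decomposition.csv`, `outliers.csv`, `summary.csv`, `raw_summary.csv`,
#' `distfit.csv`, `agrops.csv`, `regression.csv` and `manifest.json` into
#' `cfg$out_dir`, and returns the in-memory bundle. Residual analysis is
#' restricted to each trial's analysis window. Identical config and seed
#' give byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-stage objects (`series`,
#'   `surrogates`, `decompositions`, `outliers`, `summary`, `distfit`,
#'   `agrops`, `regression`, `truth`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  labels <- NULL
  if (is.null(cfg$sensor_log)) {
    sim <- stage("simulate", simulate_chamber(cfg$sim))
    series <- sim$series
    events <- sim$events
    labels <- sim$labels
  } else {
    series <- list()
    events <- list()
    for (tr in cfg$trials) {
      got <- stage("read", read_sensor_log(cfg$sensor_log,
                                           window = tr$window,
                                           trial_id = tr$trial_id))
      for (s in got) series[[paste(s$sensor_id, tr$trial_id, sep = "/")]] <- s
      events[[tr$trial_id]] <- if (is.null(cfg$event_log)) {
        stats::setNames(lapply(event_channels(), function(ch)
          event_log(ch, as_naive_time(character(0)), integer(0))),
          event_channels())
      } else stage("read", read_event_log(cfg$event_log))
    }
  }

  # restrict each series to its trial's analysis window
  series <- lapply(series, function(s) {
    tr <- cfg$trials[[s$trial_id]]
    keep <- s$timestamps >= tr$analysis_window[1L] &
      s$timestamps < tr$analysis_window[2L]
    sensor_series(s$sensor_id, s$trial_id, s$timestamps[keep],
                  s$values[keep])
  })

  surrogates <- stage("surrogate", lapply(series, build_surrogate))
  decomps <- stage("decompose", lapply(names(series), function(k) {
    co <- coalesce(series[[k]], surrogates[[k]])
    list(alternative = alt_decompose(co),
         standard = standard_additive_decompose(co))
  }))
  names(decomps) <- names(series)

  tables <- stage("outliers", {
    tb <- list()
    for (k in names(decomps)) {
      tb[[paste0(k, "/alternative")]] <-
        zscore_outliers(decomps[[k]]$alternative, cfg$outlier, degenerate = "zero")
      tb[[paste0(k, "/standard")]] <-
        zscore_outliers(decomps[[k]]$standard, cfg$outlier, degenerate = "zero")
    }
    tb
  })

  summary_df <- stage("summarize", summarize_residuals(tables, series))
  raw_df <- stage("summarize", summarize_raw(series))

  fit_sensors <- cfg$fit_sensors
  if (is.null(fit_sensors)) {
    all_sensors <- unique(vapply(series, `[[`, character(1), "sensor_id"))
    fit_sensors <- setdiff(all_sensors, "Reference")
  }
  alt_tables <- tables[grepl("/alternative$", names(tables))]
  fit_tables <- Filter(function(tb) tb$sensor_id[1L] %in% fit_sensors,
                       alt_tables)
  abs_z <- unlist(lapply(fit_tables, function(tb) abs(tb$z[tb$is_outlier])),
                  use.names = FALSE)
  distfit <- if (length(abs_z) >= 10L) {
    stage("fitdist", fit_distributions(abs_z, method = cfg$fit_method))
  } else NULL

  agrops <- stage("agrops", {
    out <- list()
    for (tid in names(events)) {
      tr <- cfg$trials[[tid]]
      am <- events_to_minutes(events[[tid]], tr$analysis_window)
      out[[tid]] <- cumulative_agr_ops(am, cfg$weights)
    }
    out
  })

  reg_in <- stage("regress", regression_input(fit_tables, agrops))
  regression <- if (nrow(reg_in) >= 3L &&
                    length(unique(reg_in$agr_ops)) >= 2L) {
    stage("regress", fit_stability_glm(reg_in))
  } else NULL

  truth <- if (!is.null(labels)) {
    stage("truth", labels_to_truth(labels, alt_tables))
  } else NULL

  stage("write", {
    decomp_df <- do.call(rbind, lapply(decomps, function(d) {
      a <- as.data.frame(d$alternative)
      a$method <- "alternative"
      s <- as.data.frame(d$standard)
      s$method <- "standard_additive"
      rbind(a, s)
    }))
    rownames(decomp_df) <- NULL
    utils::write.csv(decomp_df, file.path(cfg$out_dir, "decomposition.csv"),
                     row.names = FALSE)
    out_df <- do.call(rbind, lapply(names(tables), function(k) {
      tb <- tables[[k]]
      data.frame(timestamp = format_ts(tb$timestamp),
                 sensor_id = tb$sensor_id, trial_id = tb$trial_id,
                 method = attr(tb, "method"), residual = tb$residual,
                 z = tb$z, is_outlier = tb$is_outlier, filled = tb$filled,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(out_df, file.path(cfg$out_dir, "outliers.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(raw_df, file.path(cfg$out_dir, "raw_summary.csv"),
                     row.names = FALSE)
    if (!is.null(distfit)) {
      utils::write.csv(as.data.frame(distfit),
                       file.path(cfg$out_dir, "distfit.csv"),
                       row.names = FALSE)
    }
    ag_df <- do.call(rbind, lapply(names(agrops), function(tid) {
      a <- as.data.frame(agrops[[tid]])
      a$timestamp <- format_ts(a$timestamp)
      cbind(trial_id = tid, a)
    }))
    utils::write.csv(ag_df, file.path(cfg$out_dir, "agrops.csv"),
                     row.names = FALSE)
    if (!is.null(regression)) {
      write_regression(regression, file.path(cfg$out_dir, "regression.csv"))
    }
    manifest <- list(
      seed = cfg$seed,
      alpha = cfg$outlier$alpha,
      threshold = cfg$outlier$threshold,
      fit_method = cfg$fit_method,
      weights = as.list(cfg$weights),
      config_hash = config_hash(cfg),
      n_series = length(series),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      package_version = as.character(utils::packageVersion("chamberqc")))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(series = series, surrogates = surrogates,
                 decompositions = decomps, outliers = tables,
                 summary = summary_df, raw_summary = raw_df,
                 distfit = distfit, agrops = agrops,
                 regression = regression, truth = truth))
}

# stable content hash of the config (no external digest dependency)
config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
               collapse = "\n")
  # polynomial rolling hash over the printed structure (stays in double
  # precision integer range)
  h <- 0
  for (b in utf8ToInt(txt)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
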
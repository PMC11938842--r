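# Log-normal stability regression: outlier severity |z| against cumulative
# Agr.Ops, with sensor main effects and interactions.

#' Assemble the regression input from outlier tables and the Agr.Ops series
#'
#' Keeps the flagged rows only (the model is fitted on outliers: non-outlier
#' rows, over 97% of the data, would swamp it) and joins each to the
#' cumulative Agr.Ops value at its own minute.
#'
#' @param tables A single `outlier_table` or list of them.
#' @param agrops An `agrops_series` with `cumulative` filled in (see
#'   [cumulative_agr_ops()]), or a named list of them keyed by trial_id when
#'   tables span several trials.
#' @return A data.frame with columns `abs_z, agr_ops, sensor_id, trial_id`.
#' @export
regression_input <- function(tables, agrops) {
  if (inherits(tables, "outlier_table")) tables <- list(tables)
  single <- inherits(agrops, "agrops_series")
  rows <- lapply(tables, function(tb) {
    out <- tb[tb$is_outlier, , drop = FALSE]
    if (nrow(out) == 0L) return(NULL)
    a <- if (single) agrops else agrops[[out$trial_id[1L]]]
    if (is.null(a)) stop("no agrops series for trial ", out$trial_id[1L])
    pos <- match(as.numeric(out$timestamp), as.numeric(a$timestamp))
    if (anyNA(pos)) stop("outlier timestamp missing from agrops grid")
    data.frame(abs_z = abs(out$z), agr_ops = a$cumulative[pos],
               sensor_id = out$sensor_id, trial_id = out$trial_id,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(abs_z = numeric(0), agr_ops = numeric(0),
                      sensor_id = character(0), trial_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Fit the stability GLM of log outlier severity on cumulative Agr.Ops
#'
#' "Log-normal regression" realized as a Gaussian-family identity-link GLM
#' on the log scale: `log(abs_z) ~ agr_ops * sensor_id` with treatment
#' coding (first sensor alphabetically as baseline). With a single sensor
#' level the model reduces to simple linear regression of `log(abs_z)` on
#' `agr_ops`. If a sensor level (or, per trial, a trial-sensor cell) has
#' fewer than `min_cell` outliers, the interaction is dropped with a warning
#' to avoid singular fits. A Gamma family with log link is available behind
#' `family = "gamma_log"`.
#'
#' @param data A data.frame from [regression_input()] (columns `abs_z`,
#'   `agr_ops`, `sensor_id`, and `trial_id` when `per_trial = TRUE`); all
#'   `abs_z` must be positive.
#' @param per_trial If `TRUE`, fit one model per trial plus the combined
#'   model; returns a named list (`T1`, ..., `combined`).
#' @param family `"lognormal"` (Gaussian on log(abs_z), default) or
#'   `"gamma_log"` (Gamma GLM, log link, on abs_z).
#' @param min_cell Minimum outliers per sensor cell before the interaction
#'   (or sensor term) is retained; default 10.
#' @return A `stability_fit` (or named list of them): coefficient table
#'   `data.frame(term, estimate, std_error, t_value, p_value)` with metadata
#'   attributes `formula`, `family`, `n`, `baseline`.
#' @export
fit_stability_glm <- function(data, per_trial = FALSE,
                              family = c("lognormal", "gamma_log"),
                              min_cell = 10L) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data),
            all(c("abs_z", "agr_ops", "sensor_id") %in% names(data)))
  if (any(data$abs_z <= 0)) stop("abs_z must be positive")
  if (per_trial) {
    stopifnot("trial_id" %in% names(data))
    fits <- lapply(split(data, data$trial_id), fit_stability_glm,
                   per_trial = FALSE, family = family, min_cell = min_cell)
    fits$combined <- fit_stability_glm(data, per_trial = FALSE,
                                       family = family, min_cell = min_cell)
    return(fits)
  }
  if (length(unique(data$agr_ops)) < 2L) {
    stop("need at least 2 distinct cumulative Agr.Ops values")
  }
  data$sensor_id <- factor(data$sensor_id, levels = sort(unique(data$sensor_id)))
  cells <- table(data$sensor_id)
  multi <- nlevels(data$sensor_id) > 1L
  use_interaction <- multi && all(cells >= min_cell)
  if (multi && !use_interaction) {
    warning("sensor cell with < ", min_cell,
            " outliers: dropping Agr.Ops x sensor interaction")
  }
  rhs <- if (!multi) "agr_ops"
         else if (use_interaction) "agr_ops * sensor_id"
         else "agr_ops + sensor_id"
  if (family == "lognormal") {
    fml <- stats::as.formula(paste("log(abs_z) ~", rhs))
    fit <- stats::glm(fml, data = data, family = stats::gaussian())
  } else {
    fml <- stats::as.formula(paste("abs_z ~", rhs))
    fit <- stats::glm(fml, data = data,
                      family = stats::Gamma(link = "log"))
  }
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                    std_error = sm[, 2L], t_value = sm[, 3L],
                    p_value = sm[, 4L], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(tab,
            formula = deparse(fml), family = family, n = nrow(data),
            baseline = if (multi) levels(data$sensor_id)[1L] else
              as.character(data$sensor_id[1L]),
            model = fit,
            class = c("stability_fit", "data.frame"))
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("<stability_fit> %s (family %s, n = %d, baseline %s)\n",
              attr(x, "formula"), attr(x, "family"), attr(x, "n"),
              attr(x, "baseline")))
  print.data.frame(cbind(x, signif. = stars(x$p_value)), digits = 6)
  invisible(x)
}

stars <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""))
}

#' Write a coefficient table to CSV
#'
#' Columns: `term, estimate, std_error, t_value, p_value, significance`.
#'
#' @param fit A `stability_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regression <- function(fit, path) {
  df <- as.data.frame(fit)
  df$significance <- as.character(stars(df$p_value))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
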
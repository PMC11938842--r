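# Candidate-distribution fitting for outlier |z| severities with AIC/BIC
# model selection. Candidates: normal, lognormal, gamma, weibull, logistic,
# cauchy. Default estimation is maximum likelihood; maximum goodness-of-fit
# (Cramer-von Mises distance) is available as `mge_cvm`. Every candidate has
# two parameters, so AIC = 4 - 2*loglik and BIC = 2*log(n) - 2*loglik.

dist_families <- function() {
  list(
    normal = list(
      dens = stats::dnorm, cdf = stats::pnorm,
      names = c("mean", "sd"),
      init = function(x) c(mean(x), stats::sd(x)),
      positive = c(FALSE, TRUE),
      closed_mle = function(x) c(mean(x), sqrt(mean((x - mean(x))^2)))
    ),
    lognormal = list(
      dens = stats::dlnorm, cdf = stats::plnorm,
      names = c("meanlog", "sdlog"),
      init = function(x) c(mean(log(x)), stats::sd(log(x))),
      positive = c(FALSE, TRUE), needs_positive_data = TRUE,
      closed_mle = function(x) {
        lx <- log(x)
        c(mean(lx), sqrt(mean((lx - mean(lx))^2)))
      }
    ),
    gamma = list(
      dens = stats::dgamma, cdf = stats::pgamma,
      names = c("shape", "rate"),
      init = function(x) {
        m <- mean(x); v <- stats::var(x)
        c(m^2 / v, m / v)  # method of moments
      },
      positive = c(TRUE, TRUE), needs_positive_data = TRUE
    ),
    weibull = list(
      dens = stats::dweibull, cdf = stats::pweibull,
      names = c("shape", "scale"),
      init = function(x) {
        # regression on log(-log(1-F)) vs log(x) would be tidier; a moment
        # start is robust enough for Nelder-Mead
        cv <- stats::sd(x) / mean(x)
        shape <- max(0.1, cv^(-1.086))
        c(shape, mean(x) / gamma(1 + 1 / shape))
      },
      positive = c(TRUE, TRUE), needs_positive_data = TRUE
    ),
    logistic = list(
      dens = stats::dlogis, cdf = stats::plogis,
      names = c("location", "scale"),
      init = function(x) c(mean(x), stats::sd(x) * sqrt(3) / pi),
      positive = c(FALSE, TRUE)
    ),
    cauchy = list(
      dens = stats::dcauchy, cdf = stats::pcauchy,
      names = c("location", "scale"),
      init = function(x) c(stats::median(x), stats::IQR(x) / 2),
      positive = c(FALSE, TRUE)
    )
  )
}

#' Fit candidate distributions to outlier severities
#'
#' Fits all six candidate families (normal, lognormal, gamma, weibull,
#' logistic, cauchy) to positive values -- typically the `|z|` of flagged
#' outliers -- and ranks them by AIC. Estimation is maximum likelihood by
#' default (closed form where available, Nelder-Mead otherwise); method
#' `"mge_cvm"` instead minimizes the Cramer-von Mises distance between the
#' empirical and model CDFs, with log-likelihood, AIC and BIC still evaluated
#' at the fitted parameters. A candidate that cannot be fitted (e.g. a
#' log-family on non-positive data, or a failed optimizer) is returned as
#' failed with a message rather than aborting the others.
#'
#' The candidates are unconditional families even though flagged `|z|`
#' values are truncated below at the threshold; no truncation correction is
#' applied (see the package vignette).
#'
#' @param abs_z Numeric vector of values to fit; `n >= 10`.
#' @param method `"mle"` (default) or `"mge_cvm"`.
#' @return An object of class `distfit_results`: a list of per-family fits
#'   (`distribution`, `params`, `loglik`, `aic`, `bic`, `n`, `fit_method`,
#'   `converged`, `message`), sorted ascending by AIC with failures last.
#'   Use [as.data.frame()] for a flat ranked table.
#' @export
fit_distributions <- function(abs_z, method = c("mle", "mge_cvm")) {
  method <- match.arg(method)
  x <- as.numeric(abs_z)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite input")
  n <- length(x)
  if (n < 10L) stop("need at least 10 values")
  fams <- dist_families()
  fits <- lapply(names(fams), function(fam_name) {
    fam <- fams[[fam_name]]
    if (isTRUE(fam$needs_positive_data) && any(x <= 0)) {
      return(failed_fit(fam_name, n, method,
                        "non-positive data for a positive-support family"))
    }
    est <- tryCatch(
      if (method == "mle") fit_mle(x, fam) else fit_mge_cvm(x, fam),
      error = function(e) conditionMessage(e))
    if (is.character(est)) return(failed_fit(fam_name, n, method, est))
    ll <- sum(do.call(fam$dens, c(list(x), as.list(est), log = TRUE)))
    if (!is.finite(ll)) {
      return(failed_fit(fam_name, n, method, "non-finite log-likelihood"))
    }
    k <- length(est)
    list(distribution = fam_name,
         params = stats::setNames(est, fam$names),
         loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
         n = n, fit_method = method, converged = TRUE, message = "")
  })
  ok <- vapply(fits, `[[`, logical(1), "converged")
  aics <- vapply(fits, function(f) if (f$converged) f$aic else Inf, numeric(1))
  fits <- fits[order(!ok, aics)]
  structure(fits, class = "distfit_results")
}

failed_fit <- function(name, n, method, msg) {
  list(distribution = name, params = numeric(0),
       loglik = NA_real_, aic = NA_real_, bic = NA_real_,
       n = n, fit_method = method, converged = FALSE, message = msg)
}

# Maximum-likelihood fit of one two-parameter family; closed form when the
# family provides one, Nelder-Mead on log-transformed positive parameters
# otherwise.
fit_mle <- function(x, fam) {
  if (!is.null(fam$closed_mle)) return(fam$closed_mle(x))
  optimize_family(x, fam, function(par) {
    -sum(do.call(fam$dens, c(list(x), as.list(par), log = TRUE)))
  })
}

# Maximum goodness-of-fit: minimize the Cramer-von Mises statistic
# 1/(12n) + sum_i (F(x_(i)) - (2i-1)/(2n))^2.
fit_mge_cvm <- function(x, fam) {
  xs <- sort(x)
  n <- length(xs)
  ui <- (2 * seq_len(n) - 1) / (2 * n)
  optimize_family(x, fam, function(par) {
    p <- do.call(fam$cdf, c(list(xs), as.list(par)))
    1 / (12 * n) + sum((p - ui)^2)
  })
}

optimize_family <- function(x, fam, objective) {
  init <- fam$init(x)
  pos <- fam$positive
  to_par <- function(theta) ifelse(pos, exp(theta), theta)
  theta0 <- ifelse(pos, log(pmax(init, 1e-8)), init)
  fn <- function(theta) {
    val <- objective(to_par(theta))
    if (!is.finite(val)) 1e300 else val
  }
  opt <- stats::optim(theta0, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) stop("optimizer did not converge")
  unname(to_par(opt$par))
}

#' @export
print.distfit_results <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Ranked distribution-fit table
#'
#' @param x A `distfit_results` object.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return A data.frame with columns `rank, distribution, param1, estimate1,
#'   param2, estimate2, loglik, aic, bic, n, fit_method, converged, message`.
#' @export
as.data.frame.distfit_results <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  rows <- lapply(seq_along(x), function(i) {
    f <- x[[i]]
    p <- f$params
    data.frame(
      rank = i, distribution = f$distribution,
      param1 = if (length(p) >= 1L) names(p)[1L] else NA_character_,
      estimate1 = if (length(p) >= 1L) unname(p[1L]) else NA_real_,
      param2 = if (length(p) >= 2L) names(p)[2L] else NA_character_,
      estimate2 = if (length(p) >= 2L) unname(p[2L]) else NA_real_,
      loglik = f$loglik, aic = f$aic, bic = f$bic, n = f$n,
      fit_method = f$fit_method, converged = f$converged,
      message = f$message, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
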
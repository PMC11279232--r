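# Growth-curve modelling.
#
# Spot biomass is estimated as size x opacity and log2-transformed; growth is
# modelled with the standard three-parameter Gompertz curve
#
#     y(t) = A * exp(-exp(-k * (t - t_i)))
#
# where A is the asymptote (log2-biomass units), k the growth-rate parameter
# (1/h) and t_i the inflection time (h); y(t_i) = A/e. Fits are screened by
# per-parameter significance (two-sided Wald test; the square of the Wald z
# is chi-square(1)) and by an automated residual check standing in for the
# visual curation of aberrant curves.

#' Log2 biomass from spot size and opacity
#'
#' Biomass is estimated as the product of the spot's size and opacity,
#' floored at 1 before the log2 transform so that an undetected/empty spot
#' maps to biomass 0.
#'
#' @param size,opacity Non-negative measurements in arbitrary image units.
#' @return `log2(pmax(size * opacity, 1))`.
#' @export
compute_biomass <- function(size, opacity) {
  if (any(size < 0, na.rm = TRUE) || any(opacity < 0, na.rm = TRUE)) {
    stop("size and opacity must be non-negative")
  }
  log2(pmax(size * opacity, 1))
}

#' Quality-control filter for a spot time series
#'
#' Spots with fewer than `min_points` timepoints with defined biomass are
#' excluded; series longer than `max_points` are truncated to the first
#' `max_points` timepoints.
#'
#' @param times Hours, strictly increasing.
#' @param biomass Log2 biomass at each timepoint.
#' @param min_points,max_points Retention bounds (defaults 5 and 20).
#' @return List with `pass` (logical), `reason` (`NA` or `"too_few_points"`),
#'   and the (possibly truncated) `times` and `biomass`.
#' @export
qc_filter <- function(times, biomass, min_points = 5L, max_points = 20L) {
  stopifnot(length(times) == length(biomass))
  keep <- is.finite(times) & is.finite(biomass)
  times <- times[keep]
  biomass <- biomass[keep]
  o <- order(times)
  times <- times[o]
  biomass <- biomass[o]
  if (anyDuplicated(times)) stop("duplicated timepoints in series")
  if (length(times) < min_points) {
    return(list(pass = FALSE, reason = "too_few_points",
                times = times, biomass = biomass))
  }
  if (length(times) > max_points) {
    times <- times[seq_len(max_points)]
    biomass <- biomass[seq_len(max_points)]
  }
  list(pass = TRUE, reason = NA_character_, times = times, biomass = biomass)
}

#' Three-parameter Gompertz curve
#'
#' @param t Time (h).
#' @param A Asymptote (log2-biomass units).
#' @param k Growth-rate parameter (1/h).
#' @param t_i Inflection time (h); `gompertz(t_i, A, k, t_i) == A / exp(1)`.
#' @return `A * exp(-exp(-k * (t - t_i)))`.
#' @export
gompertz <- function(t, A, k, t_i) {
  A * exp(-exp(-k * (t - t_i)))
}

growth_fit <- function(A = NA_real_, k = NA_real_, t_i = NA_real_,
                       se = c(A = NA_real_, k = NA_real_, t_i = NA_real_),
                       p_A = NA_real_, p_k = NA_real_, p_ti = NA_real_,
                       status, converged = FALSE, sigma = NA_real_,
                       max_abs_z = NA_real_, n = NA_integer_,
                       times = numeric(0), biomass = numeric(0)) {
  structure(list(A = A, k = k, t_i = t_i, se = se, p_A = p_A, p_k = p_k,
                 p_ti = p_ti, status = status, converged = converged,
                 sigma = sigma, max_abs_z = max_abs_z, n = n,
                 times = times, biomass = biomass),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit %s: A=%.4g k=%.4g t_i=%.4g (p=%.3g/%.3g/%.3g), n=%d>\n",
              x$status, x$A, x$k, x$t_i, x$p_A, x$p_k, x$p_ti, x$n))
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, times = object$times, ...) {
  gompertz(times, object$A, object$k, object$t_i)
}

# Deterministic starting values: asymptote from the max observation,
# inflection near the steepest observed increase, rate from the max slope
# (the Gompertz slope at t_i is A*k/e).
gompertz_starts <- function(times, biomass) {
  A0 <- max(biomass)
  if (A0 <= 0) A0 <- 1e-3
  sl <- diff(biomass) / diff(times)
  i <- which.max(sl)
  ti0 <- (times[i] + times[i + 1L]) / 2
  k0 <- max(sl) * exp(1) / A0
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.1
  k0 <- min(max(k0, 0.01), 2)
  list(A = A0, k = k0, t_i = ti0)
}

#' Fit the three-parameter Gompertz model to one spot series
#'
#' Nonlinear least squares (port algorithm) with deterministic multi-start:
#' the data-driven start plus two fixed jittered variants are tried in order
#' until one converges. Per-parameter p-values are two-sided Wald tests
#' (estimate / standard error against the standard normal; the squared z is
#' chi-square with 1 df, matching a "Chi-square p" report). Nonconvergence or
#' a singular covariance yields a rejected fit, never an error. Fits whose
#' largest absolute standardized residual exceeds `max_resid_z` are rejected
#' as aberrant (automated stand-in for visual curation).
#'
#' @param times,biomass A series that passed [qc_filter()] (at least 5
#'   points; at most 20 are used).
#' @param alpha Per-parameter significance level (default 0.05).
#' @param max_resid_z Residual rejection threshold (default 4).
#' @return A `growth_fit` object with `status` in `accepted`,
#'   `rejected_significance`, `rejected_visual`.
#' @export
fit_gompertz <- function(times, biomass, alpha = 0.05, max_resid_z = 4) {
  qc <- qc_filter(times, biomass)
  if (!qc$pass) stop("series does not satisfy the QC preconditions (need >= 5 points)")
  times <- qc$times
  biomass <- qc$biomass
  n <- length(times)

  if (stats::sd(biomass) == 0) {
    # flat series: no growth signal, asymptote indistinguishable from the
    # baseline (a constant is fit perfectly by degenerate parameters)
    return(growth_fit(status = "rejected_significance", converged = FALSE,
                      n = n, times = times, biomass = biomass))
  }

  s0 <- gompertz_starts(times, biomass)
  starts <- list(
    s0,
    list(A = s0$A * 1.25, k = s0$k * 0.5, t_i = s0$t_i + 4),
    list(A = s0$A * 0.8, k = min(s0$k * 2, 5), t_i = max(s0$t_i - 4, min(times)))
  )
  dat <- data.frame(t = times, y = biomass)
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      stats::nls(y ~ A * exp(-exp(-k * (t - t_i))), data = dat,
                 start = st, algorithm = "port",
                 lower = c(A = 1e-8, k = 1e-4, t_i = min(times) - 200),
                 upper = c(A = 1e4, k = 20, t_i = max(times) + 500),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(cand) && isTRUE(cand$convInfo$isConv)) {
      fit <- cand
      break
    }
  }
  if (is.null(fit)) {
    return(growth_fit(status = "rejected_significance", converged = FALSE,
                      n = n, times = times, biomass = biomass))
  }

  est <- stats::coef(fit)
  fitted_y <- gompertz(times, est[["A"]], est[["k"]], est[["t_i"]])
  resid <- biomass - fitted_y
  sigma <- sqrt(sum(resid^2) / max(n - 3L, 1L))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  names(se) <- c("A", "k", "t_i")

  if (sigma < 1e-10 * max(1, abs(est[["A"]]))) {
    # numerically perfect fit: parameters exactly determined
    p <- c(0, 0, 0)
    max_abs_z <- 0
  } else {
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    max_abs_z <- max(abs(resid) / sigma)
  }
  names(p) <- c("A", "k", "t_i")

  out <- growth_fit(A = est[["A"]], k = est[["k"]], t_i = est[["t_i"]], se = se,
                    p_A = p[["A"]], p_k = p[["k"]], p_ti = p[["t_i"]],
                    status = "accepted", converged = TRUE, sigma = sigma,
                    max_abs_z = max_abs_z, n = n,
                    times = times, biomass = biomass)
  if (is.finite(max_abs_z) && max_abs_z > max_resid_z) {
    out$status <- "rejected_visual"
    return(out)
  }
  out$status <- validate_fit(out, alpha)
  out
}

#' Significance screen on a converged Gompertz fit
#'
#' A fit is accepted iff all three parameter p-values are below `alpha`
#' (strict) and the asymptote and rate are positive; undefined p-values
#' (singular covariance) reject.
#'
#' @param fit A `growth_fit`.
#' @param alpha Significance level (default 0.05).
#' @return `"accepted"` or `"rejected_significance"`.
#' @export
validate_fit <- function(fit, alpha = 0.05) {
  p <- c(fit$p_A, fit$p_k, fit$p_ti)
  ok <- all(is.finite(p)) && max(p) < alpha &&
    is.finite(fit$A) && fit$A > 0 && is.finite(fit$k) && fit$k > 0 &&
    is.finite(fit$t_i)
  if (isTRUE(ok)) "accepted" else "rejected_significance"
}

#' Fit growth curves for every spot of a tidy series table
#'
#' @param series data.frame with columns `plate_id`, `position`, `time_h`,
#'   and either `biomass` or both `size` and `opacity`.
#' @param alpha,max_resid_z Passed to [fit_gompertz()].
#' @param min_points,max_points Passed to [qc_filter()].
#' @return data.frame with one row per (plate, position): the fitted
#'   parameters, p-values, `status` (including `rejected_qc`), and
#'   `n_points`.
#' @export
fit_growth_table <- function(series, alpha = 0.05, max_resid_z = 4,
                             min_points = 5L, max_points = 20L) {
  stopifnot(all(c("plate_id", "position", "time_h") %in% names(series)))
  if (!"biomass" %in% names(series)) {
    series$biomass <- compute_biomass(series$size, series$opacity)
  }
  key <- paste(series$plate_id, series$position, sep = "\r")
  groups <- split(seq_len(nrow(series)), key)
  rows <- lapply(groups, function(idx) {
    plate <- series$plate_id[idx[1L]]
    pos <- series$position[idx[1L]]
    qc <- qc_filter(series$time_h[idx], series$biomass[idx],
                    min_points = min_points, max_points = max_points)
    if (!qc$pass) {
      return(data.frame(plate_id = plate, position = pos,
                        n_points = length(qc$times),
                        A = NA_real_, k = NA_real_, t_i = NA_real_,
                        p_A = NA_real_, p_k = NA_real_, p_ti = NA_real_,
                        sigma = NA_real_, status = "rejected_qc"))
    }
    f <- fit_gompertz(qc$times, qc$biomass, alpha = alpha,
                      max_resid_z = max_resid_z)
    data.frame(plate_id = plate, position = pos, n_points = f$n,
               A = f$A, k = f$k, t_i = f$t_i,
               p_A = f$p_A, p_k = f$p_k, p_ti = f$p_ti,
               sigma = f$sigma, status = f$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
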
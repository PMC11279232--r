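# Integrated fitness and the replicate-noise scale.
#
# A spot's scalar fitness proxy is the area under its fitted Gompertz curve
# from inoculation (t = 0) up to 72 h ("integrated fitness", IF, in
# log2-biomass x hours). Plates are normalized by subtracting a robust
# (Huber M-) location per plate to absorb plate-to-plate offsets. The noise
# scale used by the interaction classifier is the MSD: per isolate, the
# sample standard deviation of IF over its four replicate spots (border
# positions excluded); the MSD is the median of those SDs over the dataset.

#' Integrated fitness of a fitted Gompertz curve
#'
#' Numerical integral of `gompertz(t, A, k, t_i)` over `[0, t_max]` by
#' adaptive quadrature (absolute tolerance 1e-8). IF scales exactly linearly
#' in `A`.
#'
#' @param A,k,t_i Gompertz parameters (vectorized).
#' @param t_max Upper integration limit in hours (default 72; must be > 0).
#' @return Numeric vector of IF values (log2-biomass x hours).
#' @export
integrated_fitness <- function(A, k, t_i, t_max = 72) {
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) || t_max <= 0) {
    stop("t_max must be a positive number of hours")
  }
  mapply(function(a, kk, ti) {
    if (!is.finite(a) || !is.finite(kk) || !is.finite(ti)) return(NA_real_)
    if (a == 0) return(0)
    stats::integrate(gompertz, lower = 0, upper = t_max, A = a, k = kk,
                     t_i = ti, abs.tol = 1e-8, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }, A, k, t_i)
}

#' Huber M-estimate of location
#'
#' Iteratively reweighted mean with Huber's psi (tuning constant `k`,
#' default 1.345) and fixed MAD scale, iterated to `tol`. With zero MAD
#' (more than half the values tied) the median is returned.
#'
#' @param x Numeric; non-finite values are dropped.
#' @param k Tuning constant (1.345 gives 95% efficiency at the normal).
#' @param tol Convergence tolerance on the location update (default 1e-8).
#' @param max_iter Iteration cap.
#' @return The location estimate (length-1 numeric).
#' @export
huber_location <- function(x, k = 1.345, tol = 1e-8, max_iter = 500L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values")
  s <- stats::mad(x)
  mu <- stats::median(x)
  if (s <= 0) return(mu)
  for (i in seq_len(max_iter)) {
    r <- (x - mu) / s
    w <- pmin(1, k / abs(r))
    w[!is.finite(w)] <- 1
    mu_new <- sum(w * x) / sum(w)
    done <- abs(mu_new - mu) < tol
    mu <- mu_new
    if (done) break
  }
  mu
}

#' Robustly center the IF values of one plate
#'
#' Subtracts a robust location (Huber M-estimate by default, or the median)
#' from every IF value of the plate, absorbing plate-level offsets.
#' Translation-equivariant: adding a constant to all inputs leaves the output
#' unchanged.
#'
#' @param if_values IF values of one plate (NAs are carried through).
#' @param method `"huber"` (default) or `"median"`.
#' @param min_values Minimum number of finite values required (default 8).
#' @return Centered values, same length and order as the input.
#' @export
center_plate <- function(if_values, method = c("huber", "median"),
                         min_values = 8L) {
  method <- match.arg(method)
  finite <- is.finite(if_values)
  if (!any(finite)) stop("cannot center a plate with no finite IF values")
  if (sum(finite) < min_values) {
    stop("cannot center a plate with fewer than ", min_values,
         " finite IF values (got ", sum(finite), ")")
  }
  loc <- if (method == "huber") huber_location(if_values[finite])
         else stats::median(if_values[finite])
  if_values - loc
}

#' Median standard deviation (MSD) of replicate integrated fitness
#'
#' Per isolate, the sample SD (n-1 denominator) of IF over its non-border
#' replicate spots; replicate sets reduced below `min_replicates` usable
#' values are dropped. The MSD is the median of the per-isolate SDs.
#' Computed over the whole dataset by default (the replicate SD is
#' translation-invariant, so raw and plate-centered IF give the same MSD).
#'
#' @param if_values Numeric IF values (one per replicate spot).
#' @param isolate Isolate id per spot.
#' @param border Logical border flag per spot (border spots are excluded).
#' @param min_replicates Minimum usable replicates per isolate (default 2).
#' @param scope Dataset identifier stored in the result.
#' @return List with `msd`, `n_isolates_used`, `scope`.
#' @export
compute_msd <- function(if_values, isolate, border = FALSE,
                        min_replicates = 2L, scope = "dataset") {
  n <- length(if_values)
  stopifnot(length(isolate) == n)
  border <- rep_len(border, n)
  keep <- is.finite(if_values) & !border
  if (!any(keep)) stop("no usable (finite, non-border) replicate values")
  sds <- tapply(if_values[keep], isolate[keep], function(v) {
    if (length(v) >= min_replicates) stats::sd(v) else NA_real_
  })
  sds <- sds[is.finite(sds)]
  if (length(sds) == 0L) {
    stop("no isolate has >= ", min_replicates, " usable replicates")
  }
  list(msd = unname(stats::median(sds)), n_isolates_used = length(sds),
       scope = scope)
}
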
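# Intensity-uncertainty inflation models for integrated still data.
#
# Counting statistics alone (sigma_c) underestimate the true measurement
# error.  Two inflation treatments are provided: a per-image multiplicative
# factor estimated from the negative-intensity tail (Ha14-style), and a
# three-parameter model (SdFac, SdB, SdAdd) fitted so that normalized
# deviates of repeated measurements have unit variance (Ev11-style).

#' Ha14-style error model: negative-tail inflation factor
#'
#' Because still-shot prediction must overmodel mosaicity, many predicted
#' reflections contain no photons and integrate to pure noise; the
#' negative values of I/sigma_c are assumed to form the lower half of a
#' zero-mean Gaussian, whose standard deviation sigma_neg is the
#' root-mean-square of the negative normalized intensities.  sigma_neg is
#' then used as a constant multiplicative inflation of sigma_c.
#'
#' @param I intensities of one image's measurements.
#' @param sigma_c counting-statistics uncertainties (> 0).
#' @param min_neg minimum number of negative measurements required.
#' @param image_id identifier used in error messages.
#' @return `fit_ha14`: sigma_neg (dimensionless scalar).
#' @export
fit_ha14 <- function(I, sigma_c, min_neg = 10L, image_id = NULL) {
  stopifnot(length(I) == length(sigma_c), all(sigma_c > 0))
  z <- I / sigma_c
  neg <- z[z < 0]
  if (length(neg) < min_neg)
    stop("fit_ha14: only ", length(neg), " negative measurements",
         if (!is.null(image_id)) paste0(" on image ", image_id),
         " (need >= ", min_neg, ")")
  sqrt(mean(neg^2))   # zero-mean half-Gaussian estimator
}

#' @rdname fit_ha14
#' @param sigma_neg fitted inflation factor.
#' @return `apply_ha14`: inflated uncertainties `sigma_neg * sigma_c`.
#' @export
apply_ha14 <- function(sigma_c, sigma_neg) {
  stopifnot(sigma_neg >= 0)
  sigma_neg * sigma_c
}

# Adopted Ev11 variance form.  Isolated here so the algebra can be swapped:
# sigma^2 = SdFac^2 * ( sigma_c^2 + SdB * <I_h> + (SdAdd * <I_h>)^2 ).
ev11_variance <- function(sigma_c, Imean, sdfac, sdb, sdadd) {
  sdfac^2 * (sigma_c^2 + sdb * Imean + (sdadd * Imean)^2)
}

#' Ev11-style three-parameter error model
#'
#' Fits SdFac (multiplicative), SdB (proportional to the group mean
#' intensity) and SdAdd (its square) so that the normalized deviates
#' `delta_hl = (I_hl - <I_h>) / (sqrt(1 - 1/n_h) * sigma_Ev11)` have unit
#' variance within each mean-intensity bin.  The objective (sum of squared
#' deviations of the bin variances from 1) is minimized by derivative-free
#' Nelder-Mead from (1, 0, 0); the fit is deterministic given the input
#' order.  Groups with multiplicity < 2 are excluded and counted.
#'
#' @param group group (symmetry-unique reflection) identifier per
#'   measurement.
#' @param I measured intensities.
#' @param sigma_c counting uncertainties.
#' @param n_bins number of mean-intensity bins.
#' @return list with `sdfac`, `sdb`, `sdadd`, `n_groups`, `n_excluded`,
#'   `bin_variance` (per-bin deviate variances at the optimum).
#' @export
fit_ev11 <- function(group, I, sigma_c, n_bins = 10L) {
  stopifnot(length(group) == length(I), length(I) == length(sigma_c))
  cnt <- table(group)
  good <- names(cnt)[cnt >= 2L]
  n_excluded <- sum(cnt < 2L)
  keep <- group %in% good
  if (!any(keep)) stop("fit_ev11: no groups with multiplicity >= 2")
  group <- group[keep]; I <- I[keep]; sigma_c <- sigma_c[keep]
  gm <- tapply(I, group, mean)
  gn <- tapply(I, group, length)
  gi <- match(as.character(group), names(gm))
  Imean <- as.numeric(gm)[gi]
  nh <- as.numeric(gn)[gi]
  dev <- I - Imean
  bias <- sqrt(1 - 1 / nh)
  # mean-intensity bins with roughly equal occupancy
  qs <- unique(stats::quantile(Imean, seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  bin <- findInterval(Imean, qs, rightmost.closed = TRUE)
  obj <- function(p) {
    v <- ev11_variance(sigma_c, Imean, p[1], p[2], p[3])
    if (any(v <= 0) || p[1] <= 0) return(1e12)
    d <- dev / (bias * sqrt(v))
    bv <- tapply(d^2, bin, mean)
    sum((bv - 1)^2)
  }
  fit <- stats::optim(c(1, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- fit$par
  v <- ev11_variance(sigma_c, Imean, p[1], p[2], p[3])
  d <- dev / (bias * sqrt(v))
  list(sdfac = abs(p[1]), sdb = p[2], sdadd = abs(p[3]),
       n_groups = length(gm), n_excluded = n_excluded,
       bin_variance = as.numeric(tapply(d^2, bin, mean)))
}

#' @rdname fit_ev11
#' @param Imean group mean intensity `<I_h>` per measurement.
#' @param params a list with `sdfac`, `sdb`, `sdadd` (as from `fit_ev11`).
#' @return `apply_ev11`: corrected uncertainties sigma_Ev11 per
#'   measurement; for `<I_h>` = 0 this reduces to `sdfac * sigma_c`.
#' @export
apply_ev11 <- function(sigma_c, Imean, params) {
  sqrt(ev11_variance(sigma_c, Imean, params$sdfac, params$sdb, params$sdadd))
}

#' Overall and resolution-binned signal strength
#'
#' Mean of I/sigma over all measurements and per resolution bin
#' (equal-volume reciprocal-space bins).
#'
#' @param I intensities.
#' @param sigma uncertainties (after any error-model inflation).
#' @param inv_d optional reciprocal resolution 1/d per measurement; when
#'   given, per-bin means are reported.
#' @param n_bins number of resolution bins.
#' @return list with `overall` and optionally `binned` (data.frame).
#' @export
signal_summary <- function(I, sigma, inv_d = NULL, n_bins = 10L) {
  if (length(I) == 0L) stop("signal_summary: empty input")
  stopifnot(length(I) == length(sigma), all(sigma > 0))
  out <- list(overall = mean(I / sigma))
  if (!is.null(inv_d)) {
    b <- resolution_bins(inv_d, n_bins)
    out$binned <- data.frame(bin = sort(unique(b)),
                             signal = as.numeric(tapply(I / sigma, b, mean)),
                             n = as.numeric(table(b)))
  }
  out
}
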
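#' Photoresponse feature extraction
#'
#' The three features used to characterise flash responses are the rate
#' of the activation phase (time to peak), the light sensitivity (the
#' half-maximal flash strength I0 from a normalized stimulus-response
#' curve) and the speed of the recovery phase (time for the photocurrent
#' to re-establish its dark value).  Peaks are measured on |Delta J| so
#' the sign convention of the source model does not matter.
#'
#' @name photoresponse-features
NULL

peak_index <- function(resp) which.max(abs(resp$dJ))

#' Time to peak of a flash response
#'
#' Time needed to reach the maximum of |Delta J| after the delivery of
#' the flash (the clock starts at flash onset).
#'
#' @param resp a `photoresponse`.
#' @return time to peak in seconds (>= 0).
#' @export
time_to_peak <- function(resp) {
  if (max(abs(resp$dJ)) <= 0)
    stop("flat response (zero flash): time to peak is undefined")
  tp <- resp$time[peak_index(resp)]
  max(tp, 0)
}

#' Peak amplitude of a flash response
#'
#' @param resp a `photoresponse`.
#' @return max |Delta J|.
#' @export
peak_amplitude <- function(resp) max(abs(resp$dJ))

#' Recovery time of a flash response
#'
#' First time after the peak at which |Delta J| falls to within
#' `tolerance` x peak of the dark value and stays there for the rest of
#' the simulated window.  The dark value itself (Delta J = 0) is not
#' numerically attainable, hence the tolerance (default 1% of peak).
#'
#' @param resp a `photoresponse`.
#' @param tolerance recovery tolerance as a fraction of the peak.
#' @return recovery time in seconds, or `NA` with attribute `window` if
#'   the response has not recovered within the simulated window.
#' @export
recovery_time <- function(resp, tolerance = 0.01) {
  pk <- max(abs(resp$dJ))
  if (pk <= 0) return(0)
  ip <- peak_index(resp)
  below <- abs(resp$dJ) <= tolerance * pk
  n <- length(below)
  # stays below for the remainder
  ok <- rev(cumprod(rev(below))) == 1
  idx <- which(ok & seq_len(n) >= ip)
  if (!length(idx)) {
    out <- NA_real_
    attr(out, "window") <- resp$time[n]
    attr(out, "recovered") <- FALSE
    return(out)
  }
  resp$time[idx[1]]
}

#' Normalize a family of flash responses into a stimulus-response curve
#'
#' Peak amplitudes are normalized with respect to the maximum
#' photocurrent across the family, so the largest (saturating) response
#' maps to 1.0 and the ordering of amplitudes is preserved.
#'
#' @param responses list of `photoresponse` objects from the same model,
#'   at increasing flash intensities.
#' @return an object of class `stim_response_curve`: data.frame with
#'   columns `intensity` and `amplitude` (in \[0,1\]).
#' @export
normalize_family <- function(responses) {
  if (!length(responses)) stop("empty response family")
  intens <- vapply(responses, function(r) r$stimulus$intensity, numeric(1))
  peaks <- vapply(responses, peak_amplitude, numeric(1))
  o <- order(intens)
  intens <- intens[o]; peaks <- peaks[o]
  if (any(duplicated(intens))) stop("duplicate flash intensities in family")
  if (max(peaks) <= 0) stop("all responses are flat; cannot normalize")
  out <- data.frame(intensity = intens, amplitude = peaks / max(peaks))
  class(out) <- c("stim_response_curve", "data.frame")
  out
}

#' Half-maximal flash strength I0
#'
#' The flash strength that elicits a half-maximal normalized response,
#' obtained by interpolation between the two samples bracketing
#' amplitude 0.5.  Because flash families span several decades the
#' interpolation is linear in log10(intensity) by default; a fit of the
#' saturating function A(I) = I^n/(I^n + I0^n) is available as an
#' alternative.
#'
#' @param curve a `stim_response_curve` (see [normalize_family()]).
#' @param method "interpolate" (default) or "fit".
#' @return I0 in photons um^-2.
#' @export
half_max_intensity <- function(curve, method = c("interpolate", "fit")) {
  method <- match.arg(method)
  a <- curve$amplitude
  x <- curve$intensity
  if (method == "fit") {
    i0_start <- if (any(a <= 0.5) && any(a >= 0.5))
      half_max_intensity(curve, method = "interpolate")
    else stats::median(x)
    fit <- stats::nls(a ~ x^n / (x^n + i0^n),
                      start = list(i0 = i0_start, n = 1),
                      control = stats::nls.control(maxiter = 500,
                                                   warnOnly = TRUE))
    return(unname(stats::coef(fit)[["i0"]]))
  }
  if (all(a > 0.5) || all(a < 0.5))
    stop("amplitude 0.5 is not bracketed by the flash family; ",
         "simulate a wider range of intensities (",
         signif(min(x), 3), "..", signif(max(x), 3), " spans amplitudes ",
         signif(min(a), 3), "..", signif(max(a), 3), ")")
  # first bracketing interval on the increasing curve
  i <- which(a[-length(a)] <= 0.5 & a[-1] >= 0.5)[1]
  if (is.na(i)) i <- which.min(abs(a - 0.5))
  if (a[i] == 0.5) return(x[i])
  lx <- log10(x[c(i, i + 1)])
  10^(lx[1] + (0.5 - a[i]) / (a[i + 1] - a[i]) * (lx[2] - lx[1]))
}

#' Extract all photoresponse features for a flash family
#'
#' @param responses list of `photoresponse` objects (increasing flash
#'   strength; should bracket the half-maximal amplitude).
#' @param recovery_tolerance passed to [recovery_time()].
#' @return an object of class `response_features`: list with `I0`,
#'   `time_to_peak` (of the dimmest flash response, the conventional
#'   dim-flash kinetic readout), `per_flash` data.frame and the
#'   normalized curve.
#' @export
response_features <- function(responses, recovery_tolerance = 0.01) {
  curve <- normalize_family(responses)
  per <- data.frame(
    intensity = vapply(responses, function(r) r$stimulus$intensity, numeric(1)),
    peak = vapply(responses, peak_amplitude, numeric(1)),
    t_peak_s = vapply(responses, time_to_peak, numeric(1)),
    t_rec_s = vapply(responses, function(r)
      as.numeric(recovery_time(r, recovery_tolerance)), numeric(1)))
  per <- per[order(per$intensity), ]
  structure(list(I0 = half_max_intensity(curve),
                 time_to_peak = per$t_peak_s[which.min(per$intensity)],
                 per_flash = per, curve = curve),
            class = "response_features")
}

#' @export
print.response_features <- function(x, ...) {
  cat("Photoresponse features over", nrow(x$per_flash), "flashes\n")
  cat("  I0 (half-maximal flash):", signif(x$I0, 4), "photons/um^2\n")
  cat("  time to peak (dimmest flash):", signif(x$time_to_peak, 4), "s\n")
  invisible(x)
}

#' @export
plot.stim_response_curve <- function(x, ...) {
  graphics::plot(x$intensity, x$amplitude, log = "x", type = "b", pch = 16,
                 xlab = "flash strength (photons/um^2)",
                 ylab = "normalized response amplitude", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
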
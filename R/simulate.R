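#' Flash stimulus
#'
#' A rectangular photon-flux pulse.  The intensity is the total photon
#' density delivered (photons per square micron); during the pulse the
#' flux is intensity/duration.  Photoisomerizations are obtained through
#' the model's collecting-area convention (parameter `c_area`, square
#' microns, stored in the network).
#'
#' @param intensity photon density of the flash (photons um^-2), >= 0.
#' @param onset flash onset time (s).
#' @param duration pulse duration (s), > 0 (default 0.01 s).
#' @return an object of class `flash_stimulus`.
#' @export
flash_stimulus <- function(intensity, onset = 0, duration = 0.01) {
  if (intensity < 0) stop("intensity must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(intensity = intensity, onset = onset, duration = duration),
            class = "flash_stimulus")
}

#' @export
print.flash_stimulus <- function(x, ...) {
  cat("Flash:", x$intensity, "photons/um^2 at t =", x$onset,
      "s, duration", x$duration, "s\n")
  invisible(x)
}

#' Simulate the photoresponse to a light flash
#'
#' Pre-equilibrates the network to its dark steady state, then
#' integrates the mass-action system through the flash with a stiff
#' implicit solver and dense output, and returns the change in
#' photocurrent relative to the dark value, Delta J(t).  The integration
#' is split at the pulse edges so the discontinuous photon flux is
#' handled exactly; the result is deterministic for a fixed solver
#' configuration.
#'
#' @param net a [reaction_network()] with an output observable J.
#' @param stimulus a [flash_stimulus()].
#' @param t_end end of the simulated window, seconds after the flash
#'   onset (default 30).
#' @param dt output grid spacing (s), default 0.01.
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-12).
#' @param equilibrate pre-equilibration settings passed to
#'   [dark_steady_state()]; set to `FALSE` to start from `net$species`
#'   as-is.
#' @return an object of class `photoresponse`: a list with `time`
#'   (grid, s, 0 = flash onset), `dJ`, `J_dark`, `stimulus`, `state`
#'   (species trajectory matrix) and `normalized = FALSE`.
#' @export
simulate_flash <- function(net, stimulus, t_end = 30, dt = 0.01,
                           rtol = 1e-8, atol = 1e-12, equilibrate = TRUE) {
  if (is.null(net$output))
    stop("network has no output observable; set `output` when building it")
  if (isTRUE(equilibrate)) {
    y0 <- dark_steady_state(net, rtol = rtol, atol = atol)$state
  } else {
    y0 <- net$species
  }
  on <- stimulus$onset
  off <- stimulus$onset + stimulus$duration
  flux <- stimulus$intensity / stimulus$duration
  segs <- list(
    list(t = seq(0, on, by = dt), light = 0),
    list(t = unique(c(seq(on, off, by = min(dt, stimulus$duration / 10)), off)),
         light = flux),
    list(t = seq(off, on + t_end, by = dt), light = 0))
  segs <- Filter(function(s) length(s$t) >= 2, segs)

  rows <- list()
  y <- y0
  for (s in segs) {
    f <- ode_function(net, extra = list(light = function(t) s$light))
    out <- deSolve::lsoda(y, s$t, f, parms = NULL, rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop("integration failure near t = ", utils::tail(out[, 1], 1),
           " s (stiff segment; consider lowering tolerances)")
    y <- stats::setNames(as.numeric(out[nrow(out), -1]), names(y))
    rows <- c(rows, list(out[-nrow(out), , drop = FALSE]))
  }
  rows <- c(rows, list(matrix(c(utils::tail(segs, 1)[[1]]$t[length(utils::tail(segs, 1)[[1]]$t)], y),
                              nrow = 1, dimnames = list(NULL, c("time", names(y))))))
  traj <- do.call(rbind, rows)
  time <- traj[, 1]
  states <- traj[, -1, drop = FALSE]
  J <- eval_output(net, states)
  J_dark <- eval_output(net, matrix(y0, nrow = 1, dimnames = list(NULL, names(y0))))
  structure(list(time = time - on, dJ = J - J_dark, J_dark = J_dark,
                 stimulus = stimulus, state = states, normalized = FALSE),
            class = "photoresponse")
}

#' @export
print.photoresponse <- function(x, ...) {
  cat("Photoresponse: flash", x$stimulus$intensity, "photons/um^2,",
      length(x$time), "time points,",
      "peak |dJ| =", signif(max(abs(x$dJ)), 4), "\n")
  invisible(x)
}

#' @export
plot.photoresponse <- function(x, ...) {
  graphics::plot(x$time, x$dJ, type = "l", xlab = "time after flash (s)",
                 ylab = expression(Delta * J), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
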
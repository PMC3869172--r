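#' Stimulus protocols: steps and inhibitor events
#'
#' External perturbations enter the model through the stimulus `s = k0 +
#' input` (e.g. an osmotic-shock dose added at a given time) and through
#' inhibitor events that rescale a named rate constant from an event time
#' onward (e.g. a kinase inhibitor reducing `k5`).
#'
#' @param steps Data frame with columns `time` and `input`: from each `time`
#'   on, the external input added to `k0` (doses are cumulative with the most
#'   recent step's value in force, not summed).
#' @param inhibitors Data frame with columns `time`, `rate`, `factor`: from
#'   `time` on, parameter `rate` is multiplied by `factor` (`factor >= 0`).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(steps = data.frame(time = 0, input = 0.4))
#' @export
stimulus_protocol <- function(steps = NULL, inhibitors = NULL) {
  if (is.null(steps)) steps <- data.frame(time = numeric(), input = numeric())
  if (is.null(inhibitors))
    inhibitors <- data.frame(time = numeric(), rate = character(),
                             factor = numeric())
  steps <- as.data.frame(steps)
  inhibitors <- as.data.frame(inhibitors)
  stopifnot(all(c("time", "input") %in% names(steps)),
            all(c("time", "rate", "factor") %in% names(inhibitors)))
  if (is.unsorted(steps$time) || is.unsorted(inhibitors$time))
    stop("protocol event times must be non-decreasing")
  if (any(inhibitors$factor < 0)) stop("inhibitor multipliers must be >= 0")
  structure(list(steps = steps, inhibitors = inhibitors),
            class = "stimulus_protocol")
}

# Input level and effective parameters in force at time t (right-continuous).
protocol_at <- function(protocol, params, t) {
  input <- 0
  if (nrow(protocol$steps)) {
    on <- protocol$steps$time <= t
    if (any(on)) input <- protocol$steps$input[max(which(on))]
  }
  if (nrow(protocol$inhibitors)) {
    on <- which(protocol$inhibitors$time <= t)
    for (i in on) {
      r <- protocol$inhibitors$rate[i]
      params[[r]] <- params[[r]] * protocol$inhibitors$factor[i]
    }
  }
  list(input = input, params = params)
}

#' Integrate the model under a stimulus protocol
#'
#' Integrates piecewise between protocol events with a stiff-capable solver
#' (`deSolve::lsoda`, rtol `1e-8`, atol `1e-10`) using the analytic Jacobian.
#'
#' @inheritParams rhs
#' @param protocol A [stimulus_protocol()] (default: constant basal stimulus).
#' @param times Increasing numeric vector of output times.
#' @param init Initial state `c(x, y, z)`. Default: the pre-stimulus steady
#'   state (`pre_equilibrate = TRUE`) or a small positive state.
#' @param pre_equilibrate Start from the steady state at the basal stimulus.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time`, `x`, `y`, `z` and `stimulus`, of
#'   class `triloop_trajectory`.
#' @examples
#' spec <- model_spec("output_activation")
#' p <- default_params(spec)
#' tr <- simulate_model(spec, p, times = seq(0, 50, 1))
#' @export
simulate_model <- function(spec, params, protocol = stimulus_protocol(),
                           times, init = NULL, pre_equilibrate = is.null(init),
                           rtol = 1e-8, atol = 1e-10) {
  validate_model(spec, params)
  stopifnot(!is.unsorted(times), length(times) >= 2)
  if (is.null(init)) {
    if (pre_equilibrate) {
      eq <- steady_state(spec, params, params$k0)
      init <- if (eq$exists) c(eq$x, eq$y, eq$z) else c(0.01, 0.01, 0.01)
    } else init <- c(0.01, 0.01, 0.01)
  }
  init <- unname(init)
  ev_times <- sort(unique(c(protocol$steps$time, protocol$inhibitors$time)))
  ev_times <- ev_times[ev_times > times[1] & ev_times < times[length(times)]]
  # also treat events at exactly times[1] as already in force
  bounds <- c(times[1], ev_times, times[length(times)])
  out <- NULL
  state <- init
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    env <- protocol_at(protocol, params, t0)
    seg_times <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    fns <- model_functions(spec, env$params)
    stim <- env$params$k0 + env$input
    ode_fun <- function(t, y, parms) list(fns$rhs(y, stim))
    jac_fun <- function(t, y, parms) fns$jac(y, stim)
    sol <- deSolve::lsoda(y = state, times = seg_times, func = ode_fun,
                          parms = NULL, jacfunc = jac_fun, jactype = "fullusr",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure on interval [%g, %g]", t0, t1))
    sol <- as.data.frame(sol)
    names(sol) <- c("time", "x", "y", "z")
    sol$stimulus <- env$params$k0 + env$input
    state <- unname(unlist(sol[nrow(sol), c("x", "y", "z")]))
    keep <- sol$time %in% times & (is.null(out) | sol$time > t0 | t0 == times[1])
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  out <- out[!duplicated(out$time), , drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "spec") <- spec
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("triloop_trajectory", class(out))
  out
}

#' Detect sustained oscillations in a trajectory
#'
#' A limit cycle is declared when, after discarding an initial transient, the
#' peak-to-trough amplitude of the chosen component exceeds `1e-4` times its
#' mean level and successive peak amplitudes differ by less than 1% (i.e. the
#' oscillation is neither decaying nor growing). The period is estimated from
#' the mean spacing of peaks.
#'
#' @param traj A trajectory tibble from [simulate_model()] (or any data frame
#'   with a `time` column and the component column).
#' @param component Which state variable to analyse (default `"z"`).
#' @param transient Fraction of the time span discarded as transient.
#' @param rel_amplitude_min Relative amplitude threshold.
#' @param peak_rel_tol Maximum relative difference between successive peak
#'   heights for the oscillation to count as sustained.
#' @return A list with `oscillating` (logical), `amplitude`, `period`,
#'   `n_peaks` and `inconclusive` (TRUE when too few peaks are present to
#'   decide).
#' @export
detect_oscillation <- function(traj, component = "z", transient = 0.25,
                               rel_amplitude_min = 1e-4, peak_rel_tol = 0.01) {
  tt <- traj$time
  v <- traj[[component]]
  keep <- tt >= tt[1] + transient * (tt[length(tt)] - tt[1])
  tt <- tt[keep]; v <- v[keep]
  res <- list(oscillating = FALSE, amplitude = NA_real_, period = NA_real_,
              n_peaks = 0L, inconclusive = FALSE)
  if (length(v) < 10) { res$inconclusive <- TRUE; return(res) }
  dv <- diff(v)
  pk <- which(dv[-length(dv)] > 0 & dv[-1] <= 0) + 1L   # local maxima
  tr <- which(dv[-length(dv)] < 0 & dv[-1] >= 0) + 1L   # local minima
  res$n_peaks <- length(pk)
  if (length(pk) < 3 || length(tr) < 2) {
    # no repeated extrema: flat or monotone tail -> not oscillating
    amp <- max(v) - min(v)
    res$amplitude <- amp
    res$inconclusive <- length(pk) > 0 && amp > rel_amplitude_min * max(abs(mean(v)), 1e-12)
    return(res)
  }
  # amplitude of the final cycle, so decaying transients are not mistaken
  # for limit cycles
  amp <- v[pk[length(pk)]] - v[tr[length(tr)]]
  res$amplitude <- amp
  level <- max(abs(mean(v)), 1e-12)
  pk_h <- v[pk]
  last <- pk_h[length(pk_h)]; prev <- pk_h[length(pk_h) - 1]
  sustained <- abs(last - prev) < peak_rel_tol * max(abs(amp), 1e-12)
  res$period <- mean(diff(tt[pk]))
  res$oscillating <- amp > rel_amplitude_min * level && sustained
  res
}
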
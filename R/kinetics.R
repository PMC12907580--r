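#' Solve mono-exponential temperature kinetics from three printed time points
#'
#' The exercise temperature trajectory is modelled as a mono-exponential rise
#' to a plateau, `T(t) = T0 + dT_eq * (1 - exp(-t / tau))`. Given the values
#' at exercise start, 60 and 120 min, the time constant follows from the
#' identity `1 + exp(-60 / tau) = (T120 - T0) / (T60 - T0)` and the
#' asymptotic rise from `dT_eq = (T60 - T0) / (1 - exp(-60 / tau))`.
#'
#' When `t60 == t120` the trajectory has fully plateaued by 60 min; this is
#' represented by `tau = 0` (instantaneous rise in the model family limit)
#' with `dT_eq = t60 - t0`.
#'
#' @param t0,t60,t120 Temperature (degrees C) at exercise start, 60 and
#'   120 min; must satisfy `t0 < t60 <= t120` and
#'   `(t120 - t0) / (t60 - t0) < 2` for an exponential solution to exist.
#' @return A list with elements `tau` (min) and `deq` (degrees C).
#' @examples
#' solve_trec_kinetics(36.98, 38.12, 38.41) # tau ~ 43.8 min, deq ~ 1.53 C
#' @export
solve_trec_kinetics <- function(t0, t60, t120) {
  d60 <- t60 - t0
  d120 <- t120 - t0
  if (d60 <= 0) stop("t60 must exceed t0", call. = FALSE)
  if (d120 < d60) stop("t120 must be >= t60 for a rising trajectory",
                       call. = FALSE)
  r <- d120 / d60
  x <- r - 1
  if (x >= 1) {
    stop("(t120 - t0)/(t60 - t0) must be < 2: no exponential plateau fits",
         call. = FALSE)
  }
  if (x <= 0) {
    return(list(tau = 0, deq = d60))
  }
  tau <- -60 / log(x)
  list(tau = tau, deq = d60 / (1 - x))
}

#' Solve the two-phase heart-rate trajectory from three printed time points
#'
#' Heart rate is modelled as fast on-kinetics plus linear cardiovascular
#' drift, `HR(t) = HR0 + dHR_fast * (1 - exp(-t / tau_h)) + drift * t`, with
#' the on-kinetics time constant `tau_h` fixed (default 10 min). The fast
#' amplitude and drift slope are solved exactly from the 60- and 120-min
#' values.
#'
#' @param h0,h60,h120 Heart rate (bpm) at exercise start, 60 and 120 min.
#' @param tau_h On-kinetics time constant (min), > 0.
#' @return A list with elements `fast` (bpm) and `drift` (bpm per min).
#' @export
solve_hr_kinetics <- function(h0, h60, h120, tau_h = 10) {
  stopifnot(tau_h > 0)
  a1 <- 1 - exp(-60 / tau_h)
  a2 <- 1 - exp(-120 / tau_h)
  d60 <- h60 - h0
  d120 <- h120 - h0
  # [a1 60; a2 120] %*% c(fast, drift) = c(d60, d120)
  det <- a1 * 120 - a2 * 60
  fast <- (d60 * 120 - d120 * 60) / det
  drift <- (a1 * d120 - a2 * d60) / det
  list(fast = fast, drift = drift)
}

#' Noise-free model trajectories
#'
#' Evaluate the mono-exponential temperature model or the two-phase heart
#' rate model on a time grid. `tau = 0` denotes the fully-plateaued limit of
#' the temperature model (the asymptote is reached immediately after start).
#'
#' @param t Time grid (min).
#' @param t0 Value at exercise start.
#' @param deq Asymptotic rise (degrees C).
#' @param tau Rise time constant (min), >= 0.
#' @return Numeric vector of model values.
#' @export
trec_trajectory <- function(t, t0, deq, tau) {
  if (tau <= 0) {
    t0 + deq * as.numeric(t > 0)
  } else {
    t0 + deq * (1 - exp(-t / tau))
  }
}

#' @rdname trec_trajectory
#' @param h0 Heart rate at exercise start (bpm).
#' @param fast Fast on-kinetics amplitude (bpm).
#' @param drift Cardiovascular drift slope (bpm per min).
#' @param tau_h On-kinetics time constant (min).
#' @export
hr_trajectory <- function(t, h0, fast, drift, tau_h = 10) {
  h0 + fast * (1 - exp(-t / tau_h)) + drift * t
}
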
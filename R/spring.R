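#' Damped-harmonic-oscillator (spring) approximation
#'
#' The balanced network's transient dynamics are well approximated by a
#' damped spring, `R'' + 2 zeta omega0 R' + omega0^2 R = I(t)`: transient
#' imbalances between fast excitatory and slow inhibitory feedback act
#' like a first-derivative (friction) term. `zeta` is the damping
#' coefficient and `omega0` the angular frequency of the undamped
#' oscillation; negative `zeta` corresponds to an unstable network.
#'
#' @param omega0 Natural angular frequency (rad/s), positive.
#' @param zeta Damping coefficient (dimensionless; negative allowed).
#' @return An object of class `"spring_params"`.
#' @export
spring_params <- function(omega0, zeta) {
  if (!is.numeric(omega0) || length(omega0) != 1L || !is.finite(omega0) ||
      omega0 <= 0)
    stop("'omega0' must be a single positive number", call. = FALSE)
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta))
    stop("'zeta' must be a single finite number", call. = FALSE)
  structure(list(omega0 = omega0, zeta = zeta), class = "spring_params")
}

#' Natural frequency of the spring reduction
#'
#' In the one-population reduction with instantaneous AMPA the undamped
#' oscillation frequency is `omega0 = 1 / sqrt(tau_e * tau_nmda)` (rad/s)
#' -- about 3.56 Hz for the standard cortical values of a 20 ms membrane
#' and a 100 ms NMDA decay, which places the resonance squarely in the
#' delta band.
#'
#' @param tau_e Membrane time constant (s).
#' @param tau_nmda NMDA decay time (s).
#' @return A list with `omega0` (rad/s) and `hz` (`omega0 / 2 pi`).
#' @export
#' @examples
#' natural_frequency(0.02, 0.1)$hz   # ~3.56 Hz
natural_frequency <- function(tau_e, tau_nmda) {
  if (!is.numeric(tau_e) || tau_e <= 0 || !is.numeric(tau_nmda) ||
      tau_nmda <= 0)
    stop("time constants must be positive", call. = FALSE)
  omega0 <- 1 / sqrt(tau_e * tau_nmda)
  list(omega0 = omega0, hz = omega0 / (2 * pi))
}

#' Poles of the damped spring
#'
#' `-zeta omega0 +- omega0 sqrt(zeta^2 - 1)` (complex for `|zeta| < 1`).
#'
#' @param params A [spring_params()] object.
#' @return Complex vector of length 2 (1/s).
#' @export
spring_poles <- function(params) {
  stopifnot(inherits(params, "spring_params"))
  w0 <- params$omega0; z <- params$zeta
  disc <- sqrt(as.complex(z^2 - 1))
  w0 * c(-z + disc, -z - disc)
}

#' Simulate the spring equation
#'
#' Fixed-step Runge-Kutta integration of the second-order system written
#' as two first-order states (position and velocity), from rest.
#'
#' @param params A [spring_params()] object.
#' @param input An [make_input()] stimulus.
#' @param duration Simulated time (s).
#' @param dt Step (s).
#' @param bound Divergence guard for unstable springs.
#' @return A `rate_trajectory` with columns `time`, `r`, `drdt`.
#' @export
simulate_spring <- function(params, input, duration, dt = 1e-4, bound = 1e9) {
  stopifnot(inherits(params, "spring_params"), duration > 0)
  w0 <- params$omega0; z <- params$zeta
  A <- matrix(c(0, 1, -w0^2, -2 * z * w0), 2, 2, byrow = TRUE,
              dimnames = list(c("r", "drdt"), c("r", "drdt")))
  B <- c(0, 1)
  times <- seq(0, duration, by = dt)
  u <- sample_input(input, times)
  Y <- rk4_linear(A, B, u, c(0, 0), dt, bound = bound)
  new_rate_trajectory(times, Y, rownames(A), params, dt, input)
}

#' Closed-form unit-step response of the spring
#'
#' Analytic solution of the spring equation for `I(t) = amplitude` for
#' `t >= 0` from rest, covering the undamped, underdamped, critically
#' damped and overdamped cases. Steady state is
#' `amplitude / omega0^2`.
#'
#' @param params A [spring_params()] object.
#' @param times Evaluation times (s).
#' @param amplitude Step height.
#' @return Numeric vector of responses.
#' @export
spring_step_response <- function(params, times, amplitude = 1) {
  stopifnot(inherits(params, "spring_params"))
  w0 <- params$omega0; z <- params$zeta
  ss <- amplitude / w0^2
  t <- times
  if (abs(z) < 1e-12) {                       # undamped
    ss * (1 - cos(w0 * t))
  } else if (abs(z - 1) < 1e-9) {             # critically damped
    ss * (1 - (1 + w0 * t) * exp(-w0 * t))
  } else if (z < 1) {                         # underdamped (incl. unstable)
    wd <- w0 * sqrt(1 - z^2)
    ss * (1 - exp(-z * w0 * t) *
            (cos(wd * t) + z * w0 / wd * sin(wd * t)))
  } else {                                    # overdamped
    s1 <- w0 * (-z + sqrt(z^2 - 1))
    s2 <- w0 * (-z - sqrt(z^2 - 1))
    ss * (1 - (s2 * exp(s1 * t) - s1 * exp(s2 * t)) / (s2 - s1))
  }
}

#' Fit spring parameters from a dominant pole pair
#'
#' Maps a complex-conjugate pole pair `lambda = a +- b i` to the spring
#' with the same poles: `omega0 = |lambda|`, `zeta = -a / |lambda|`.
#' This is the numerical route from a network's dominant pair to its
#' spring approximation; feeding the result to [spring_poles()]
#' round-trips to the input pair.
#'
#' @param pair Complex vector: one member of the pair or both.
#' @return A [spring_params()] object.
#' @export
#' @examples
#' fit_spring_from_poles(complex(real = -1, imaginary = 1))
fit_spring_from_poles <- function(pair) {
  lam <- pair[1L]
  if (length(pair) == 2L &&
      abs(pair[2L] - Conj(pair[1L])) > 1e-8 * max(1, Mod(pair[1L])))
    stop("'pair' must be a complex-conjugate pair", call. = FALSE)
  if (abs(Im(lam)) < 1e-12 * max(1, abs(Re(lam))))
    stop("degenerate fit: poles are purely real, no oscillatory pair",
         call. = FALSE)
  spring_params(omega0 = Mod(lam), zeta = -Re(lam) / Mod(lam))
}

#' Damping-regime classification
#'
#' @param zeta Damping coefficient.
#' @param tol_undamped Tolerance around `zeta = 0`.
#' @param tol_critical Tolerance around `zeta = 1`.
#' @return One of `"unstable"`, `"undamped"`, `"underdamped"`,
#'   `"critical"`, `"overdamped"`.
#' @export
damping_regime <- function(zeta, tol_undamped = 1e-9, tol_critical = 1e-6) {
  if (abs(zeta) <= tol_undamped) return("undamped")
  if (zeta < 0) return("unstable")
  if (abs(zeta - 1) <= tol_critical) return("critical")
  if (zeta < 1) "underdamped" else "overdamped"
}
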
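#' Linear state-space representation of a network
#'
#' Holds the state matrix `A`, the input column `B` (driving the
#' excitatory rate equation), the output row `C` (reading out the
#' excitatory rate), the poles (the exact eigenvalues of `A`, in 1/s) and
#' the provenance of the system. The full two-population network has
#' eight states (the two rates and six synaptic activations); the reduced
#' one-population network has five.
#'
#' @param A Square state matrix (1/s).
#' @param B Input column vector.
#' @param C Output row vector.
#' @param params Optional [network_params()] provenance.
#' @param variant Label: `"full"`, `"reduced"`, `"spring"` or `"custom"`.
#' @param state_names Optional state labels.
#'
#' @return An object of class `"linear_system"` with elements `A`, `B`,
#'   `C`, `poles`, `params`, `variant`.
#' @export
linear_system <- function(A, B, C, params = NULL, variant = "custom",
                          state_names = NULL) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), length(B) == nrow(A), length(C) == nrow(A))
  if (is.null(state_names)) state_names <- rownames(A)
  structure(list(A = A, B = as.numeric(B), C = as.numeric(C),
                 poles = eigen(A, only.values = TRUE)$values,
                 params = params, variant = variant,
                 state_names = state_names),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat("Linear system (", x$variant, "), ", nrow(x$A), " states\n", sep = "")
  rep <- stability_report(x)
  print(rep)
  invisible(x)
}

# State matrix of the full 8-state network from explicit weights.
# States: re, ri, see_ampa, see_nmda, sie_ampa, sie_nmda, sei_gaba, sii_gaba.
assemble_full <- function(weights, taus) {
  te <- taus$tau_e; ti <- taus$tau_i
  ta <- taus$tau_ampa; tn <- taus$tau_nmda; tg <- taus$tau_gaba
  A <- matrix(0, 8, 8)
  A[1, ] <- c(-1, 0, weights$jee_ampa, weights$jee_nmda, 0, 0,
              -weights$jei, 0) / te
  A[2, ] <- c(0, -1, 0, 0, weights$jie_ampa, weights$jie_nmda, 0,
              -weights$jii) / ti
  A[3, c(1, 3)] <- c(1, -1) / ta
  A[4, c(1, 4)] <- c(1, -1) / tn
  A[5, c(1, 5)] <- c(1, -1) / ta
  A[6, c(1, 6)] <- c(1, -1) / tn
  A[7, c(2, 7)] <- c(1, -1) / tg
  A[8, c(2, 8)] <- c(1, -1) / tg
  nm <- c("re", "ri", "see_ampa", "see_nmda", "sie_ampa", "sie_nmda",
          "sei_gaba", "sii_gaba")
  dimnames(A) <- list(nm, nm)
  A
}

# State matrix of the reduced 5-state one-population network.
# States: r, sp_ampa, sp_nmda, sm_ampa, sm_nmda (+: excitatory feedback,
# -: inhibitory feedback).
assemble_reduced <- function(w, q, dq, taus) {
  te <- taus$tau_e; ta <- taus$tau_ampa; tn <- taus$tau_nmda
  A <- matrix(0, 5, 5)
  A[1, ] <- c(-1, w * (1 - q - dq), w * (q + dq), -w * (1 - q), -w * q) / te
  A[2, c(1, 2)] <- c(1, -1) / ta
  A[3, c(1, 3)] <- c(1, -1) / tn
  A[4, c(1, 4)] <- c(1, -1) / ta
  A[5, c(1, 5)] <- c(1, -1) / tn
  nm <- c("r", "sp_ampa", "sp_nmda", "sm_ampa", "sm_nmda")
  dimnames(A) <- list(nm, nm)
  A
}

#' Linearized network system
#'
#' Assembles the linear state-space system of the full two-population
#' network (8 states) or the reduced one-population network (5 states),
#' without rate rectification. Input drives the excitatory rate equation
#' (scaled by `1/tau_e`); output reads the excitatory rate. The poles are
#' the exact eigenvalues of the state matrix; for `w = 0` they are the
#' decoupled leak rates `-1/tau` of the individual states.
#'
#' @param params A [network_params()] object (for the reduced variant `k`
#'   is ignored).
#' @param variant `"full"` or `"reduced"`.
#' @return A [linear_system()] object.
#' @export
#' @examples
#' sys <- build_linear_system(network_params(30, 1.2, 0.3, 0.05))
#' stability_report(sys)
build_linear_system <- function(params, variant = c("full", "reduced")) {
  stopifnot(inherits(params, "network_params"))
  variant <- match.arg(variant)
  taus <- params$taus
  if (variant == "full") {
    A <- assemble_full(make_weights(params), taus)
  } else {
    A <- assemble_reduced(params$w, params$q, params$dq, taus)
  }
  B <- numeric(nrow(A)); B[1L] <- 1 / taus$tau_e
  C <- numeric(nrow(A)); C[1L] <- 1
  linear_system(A, B, C, params = params, variant = variant,
                state_names = rownames(A))
}

# Linear system built directly from a synaptic_weights object (used by
# the short-term-depression instantaneous linearization, where the
# effective weights leave the (w, k, q, dq) family's EE = IE constraint).
build_linear_system_weights <- function(weights, taus) {
  A <- assemble_full(weights, taus)
  B <- numeric(8L); B[1L] <- 1 / taus$tau_e
  C <- numeric(8L); C[1L] <- 1
  linear_system(A, B, C, variant = "full", state_names = rownames(A))
}

# Dominant pole: largest real part; ties (within tol) broken toward the
# member of a complex pair.
dominant_pole <- function(poles, tol = 1e-9) {
  mx <- max(Re(poles))
  cand <- poles[Re(poles) >= mx - tol * max(1, abs(mx))]
  cand[order(-abs(Im(cand)))][1L]
}

#' Stability verdict and derived time scales of a linear system
#'
#' @param sys A [linear_system()] object.
#' @param im_tol Threshold (rad/s) below which the dominant pole's
#'   imaginary part is treated as zero.
#' @return An object of class `"stability_report"`: `stable` (all poles
#'   in the open left half-plane), `dominant_pole`, `tau_n` (the network
#'   time constant `-1/Re(dominant)`, `NA` when unstable), `oscillatory`
#'   (dominant pole has nonzero imaginary part) and `resonant_freq`
#'   (`|Im(dominant)| / 2 pi` in Hz, `NA` when non-oscillatory).
#' @export
stability_report <- function(sys, im_tol = 1e-9) {
  stopifnot(inherits(sys, "linear_system"))
  dom <- dominant_pole(sys$poles)
  stable <- Re(dom) < 0
  oscillatory <- abs(Im(dom)) > im_tol
  structure(list(stable = stable,
                 dominant_pole = dom,
                 tau_n = if (stable) -1 / Re(dom) else NA_real_,
                 oscillatory = oscillatory,
                 resonant_freq = if (oscillatory) abs(Im(dom)) / (2 * pi)
                                 else NA_real_,
                 poles = sys$poles),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(if (x$stable) "stable" else "UNSTABLE",
      if (x$oscillatory) sprintf(", oscillatory (%.3g Hz)", x$resonant_freq)
      else ", non-oscillatory", "\n", sep = "")
  if (x$stable) cat("tau_n =", signif(x$tau_n, 4), "s\n")
  cat("dominant pole:", format(signif(x$dominant_pole, 6)), "1/s\n")
  invisible(x)
}

#' Analytic fixed point under constant input
#'
#' Steady state `-A^{-1} B u` of the linear system for a constant input
#' level `u`.
#'
#' @param sys A [linear_system()] object.
#' @param input_level Constant input amplitude.
#' @return Named numeric state vector.
#' @export
fixed_point <- function(sys, input_level = 1) {
  stopifnot(inherits(sys, "linear_system"))
  y <- solve(sys$A, -sys$B * input_level)
  names(y) <- sys$state_names
  y
}

# Analytic step response of the output variable on a time grid, via the
# eigendecomposition y(t) = yss + V exp(Lambda t) V^{-1} (y0 - yss).
# Falls back to RK4 integration when the eigenvector basis is
# ill-conditioned (near-defective matrix, e.g. exactly at critical
# damping).
step_response_output <- function(sys, times, amplitude = 1) {
  A <- sys$A
  yss <- solve(A, -sys$B * amplitude)
  ed <- eigen(A)
  kappa <- tryCatch(1 / rcond(ed$vectors), error = function(e) Inf)
  if (is.finite(kappa) && kappa < 1e10) {
    co <- solve(ed$vectors, -yss)           # y0 = 0
    cv <- (sys$C %*% ed$vectors) * co       # row of modal contributions
    out <- as.numeric(Re(cv %*% exp(outer(ed$values, times))))
    out + as.numeric(sys$C %*% yss)
  } else {
    dt <- min(-1 / Re(ed$values)) / 20
    n <- ceiling(max(times) / dt)
    tt <- seq(0, by = dt, length.out = n + 1L)
    Y <- rk4_linear(A, sys$B, rep(amplitude, n + 1L), numeric(nrow(A)), dt)
    stats::approx(tt, as.numeric(sys$C %*% Y), xout = times)$y
  }
}

#' Rise time of a step response
#'
#' Time between the first upward crossings of 10% and 90% of the
#' steady-state value, with linear interpolation between samples.
#' Overshoot in underdamped responses is ignored (first crossings only).
#' For a one-pole system this equals `ln(9) tau`.
#'
#' For a [linear_system()], the step response and its steady state
#' (`-A^{-1} B`) are computed analytically. For a simulated
#' [rate_trajectory], supply the analytic `steady_state`; the last sample
#' is never used as a stand-in.
#'
#' @param x A `linear_system` or `rate_trajectory`.
#' @param ... Passed to methods.
#' @return Rise time in seconds.
#' @export
rise_time <- function(x, ...) UseMethod("rise_time")

#' @rdname rise_time
#' @param amplitude Step amplitude (cancels in the 10-90% normalization).
#' @param n_grid Number of samples of the analytic response.
#' @export
rise_time.linear_system <- function(x, amplitude = 1, n_grid = 20000L, ...) {
  rep <- stability_report(x)
  if (!rep$stable)
    stop("rise time undefined: system is unstable", call. = FALSE)
  ss <- as.numeric(x$C %*% fixed_point(x, amplitude))
  if (abs(ss) < 1e-12)
    stop("rise time undefined: zero steady state", call. = FALSE)
  # Sample long enough to contain the 90% crossing, extending if needed.
  horizon <- 7 * rep$tau_n
  for (trial in 1:8) {
    times <- seq(0, horizon, length.out = n_grid)
    out <- step_response_output(x, times, amplitude) / ss   # normalized
    if (any(out >= 0.9)) break
    horizon <- horizon * 2
  }
  crossings_10_90(times, out)
}

#' @rdname rise_time
#' @param steady_state Analytic steady-state value of the response column
#'   (required for trajectories).
#' @param column Which trajectory column to use (default the excitatory
#'   rate).
#' @export
rise_time.rate_trajectory <- function(x, steady_state, column = NULL, ...) {
  if (missing(steady_state))
    stop("supply the analytic 'steady_state' for trajectory rise times",
         call. = FALSE)
  if (is.null(column)) column <- if ("re" %in% names(x)) "re" else "r"
  out <- x[[column]] / steady_state
  if (!any(out >= 0.9))
    stop("response does not reach 90% of steady state within the trajectory",
         call. = FALSE)
  crossings_10_90(x$time, out)
}

# First upward crossings of 0.1 and 0.9 of a normalized response.
crossings_10_90 <- function(times, out) {
  cross_at <- function(level) {
    i <- which(out >= level)[1L]
    if (is.na(i)) stop("response never reaches ", level, call. = FALSE)
    if (i == 1L) return(times[1L])
    t0 <- times[i - 1L]; t1 <- times[i]
    y0 <- out[i - 1L]; y1 <- out[i]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  cross_at(0.9) - cross_at(0.1)
}

#' Transfer-function magnitude of a stable linear system
#'
#' `|C (2 pi i f I - A)^{-1} B|` on a grid of frequencies. For an
#' underdamped system the peak sits near the dominant pole's frequency
#' `|Im(lambda)| / 2 pi`; as the network approaches the AMPA-dominated
#' instability the peak grows in the delta band, and near the
#' NMDA-dominated instability a gamma-band peak appears.
#'
#' @param sys A stable [linear_system()].
#' @param freqs Frequencies (Hz), non-negative.
#' @return A data frame with columns `freq_hz` and `magnitude`.
#' @export
transfer_magnitude <- function(sys, freqs) {
  stopifnot(inherits(sys, "linear_system"))
  if (!stability_report(sys)$stable)
    stop("transfer magnitude requires a stable system", call. = FALSE)
  n <- nrow(sys$A)
  mag <- vapply(freqs, function(f) {
    M <- 2i * pi * f * diag(n) - sys$A
    h <- tryCatch(solve(M, sys$B),
                  error = function(e)
                    stop("singular at ", f, " Hz (pole on the imaginary axis)",
                         call. = FALSE))
    Mod(sum(sys$C * h))
  }, numeric(1))
  data.frame(freq_hz = freqs, magnitude = mag)
}

max_real_part <- function(params) {
  max(Re(eigen(if (attr(params, "variant") == "full")
                 assemble_full(make_weights(params), params$taus)
               else
                 assemble_reduced(params$w, params$q, params$dq, params$taus),
               only.values = TRUE)$values))
}

with_dq <- function(params, dq, variant) {
  p <- network_params(params$w, params$k, params$q, dq, params$taus)
  attr(p, "variant") <- variant
  p
}

#' Critical dq at which poles cross the imaginary axis
#'
#' Searches, by bisection on the maximum real part of the poles, for the
#' value of `dq` at which the network loses stability. With
#' `direction = "decreasing_dq"` the search runs toward the AMPA-dominated
#' (delta-band) instability at negative `dq`; with `"increasing_dq"`
#' toward the NMDA-dominated (gamma-band) instability at positive `dq`.
#' The bracket is discovered by geometric expansion from `dq = 0` unless
#' supplied; if no sign change exists within the admissible `dq` range
#' an error is raised.
#'
#' @param params A [network_params()] template; its `dq` is ignored.
#' @param variant `"full"` or `"reduced"`.
#' @param direction `"decreasing_dq"` or `"increasing_dq"`.
#' @param bracket Optional length-2 numeric bracket for `dq`.
#' @param tol Bisection tolerance on `dq`.
#' @return A list with `dq` (critical value), `frequency_hz` (crossing
#'   frequency `|Im| / 2 pi` of the dominant pole at the crossing) and
#'   `poles`.
#' @export
#' @examples
#' p <- network_params(30, 1.5, 0.3)
#' find_imag_axis_crossing(p, "full", "decreasing_dq")$dq   # about -0.0226
find_imag_axis_crossing <- function(params, variant = c("full", "reduced"),
                                    direction = c("decreasing_dq",
                                                  "increasing_dq"),
                                    bracket = NULL, tol = 1e-6) {
  stopifnot(inherits(params, "network_params"))
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  f <- function(dq) max_real_part(with_dq(params, dq, variant))
  if (is.null(bracket)) {
    sgn <- if (direction == "decreasing_dq") -1 else 1
    lim <- if (direction == "decreasing_dq") -params$q else 1 - params$q
    lo <- 0; step <- 1e-3
    if (f(0) >= 0)
      stop("system already unstable at dq = 0; supply an explicit bracket",
           call. = FALSE)
    repeat {
      hi <- if (sgn < 0) max(sgn * step, lim) else min(sgn * step, lim)
      if (f(hi) > 0) break
      if (abs(hi) >= abs(lim))
        stop("no instability found for ", direction,
             " within the admissible dq range", call. = FALSE)
      lo <- hi; step <- step * 2
    }
    bracket <- c(lo, hi)
  } else {
    if (f(bracket[1]) * f(bracket[2]) > 0)
      stop("bracket does not straddle a stability change", call. = FALSE)
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  dq_c <- (lo + hi) / 2
  sys <- build_linear_system(with_dq(params, dq_c, variant), variant)
  dom <- dominant_pole(sys$poles)
  list(dq = dq_c, frequency_hz = abs(Im(dom)) / (2 * pi), poles = sys$poles)
}

#' Critical damping point: dq where the slow poles become complex
#'
#' As `dq` decreases from the overdamped regime toward the AMPA-side
#' instability, the two slowest real poles approach each other, merge,
#' and separate from the real line into a complex-conjugate pair -- the
#' onset of (damped) delta-band oscillations. Because other, fast pole
#' pairs can be complex throughout (and a decoupled real pole may remain
#' the dominant one for a while), the transition is detected as an
#' *increase in the number of complex poles* relative to the stable end
#' of the bracket, located by bisection. By default the bracket runs from
#' just inside the AMPA-side instability up to `dq = 0`.
#'
#' @inheritParams find_imag_axis_crossing
#' @param im_tol Imaginary-part threshold defining "complex", relative to
#'   the pole magnitude (guards against the spurious imaginary parts that
#'   numerically degenerate real eigenvalues can acquire).
#' @return The critical `dq` (scalar).
#' @export
find_critical_damping <- function(params, variant = c("full", "reduced"),
                                  bracket = NULL, tol = 1e-6, im_tol = 1e-5) {
  stopifnot(inherits(params, "network_params"))
  variant <- match.arg(variant)
  n_complex <- function(dq) {
    poles <- eigen(if (variant == "full")
        assemble_full(make_weights(with_dq(params, dq, variant)), params$taus)
      else assemble_reduced(params$w, params$q, dq, params$taus),
      only.values = TRUE)$values
    sum(abs(Im(poles)) > im_tol * (1 + Mod(poles)))
  }
  if (is.null(bracket)) {
    unst <- find_imag_axis_crossing(params, variant, "decreasing_dq",
                                    tol = tol)
    bracket <- c(unst$dq * (1 - 1e-3), 0)
  }
  lo <- bracket[1]; hi <- bracket[2]
  base <- n_complex(hi)
  if (n_complex(lo) <= base)
    stop("bracket does not contain the real-to-complex transition",
         call. = FALSE)
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (n_complex(mid) > base) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Parameter-sweep maps of stability and response-time statistics
#'
#' Evaluates one statistic on a two-parameter grid, one row per grid
#' point. Supported statistics:
#' \describe{
#'   \item{`critical_dq_unstable`}{`dq` at the AMPA-side (delta)
#'     imaginary-axis crossing.}
#'   \item{`critical_dq_oscillation`}{`dq` at the critical-damping point
#'     where delta oscillations first appear.}
#'   \item{`resonant_freq`}{Crossing frequency (Hz) at the AMPA-side
#'     instability.}
#'   \item{`critical_rise_time`}{Rise time (s) at the `dq` where delta
#'     oscillations appear or, when no such point exists (very small
#'     `q`), at the most negative admissible `dq = -q`.}
#'   \item{`overdamped_slope`}{Slope of the rise time per 0.01 change in
#'     `dq`, fitted on `dq` from 0 to 90% of the gamma-side instability.}
#' }
#' Grid points where the requested instability does not exist are
#' reported as `NA` (some networks are stable for every admissible `dq`).
#'
#' @param params A [network_params()] template.
#' @param sweep Named list of exactly two numeric vectors; names among
#'   `w`, `k`, `q`, `dq`, `tau_nmda`.
#' @param statistic One of the statistics above.
#' @param variant `"full"` or `"reduced"`.
#' @return A data frame: the two grid columns plus `value`.
#' @export
sweep_map <- function(params, sweep,
                      statistic = c("critical_dq_unstable",
                                    "critical_dq_oscillation",
                                    "resonant_freq",
                                    "critical_rise_time",
                                    "overdamped_slope"),
                      variant = c("full", "reduced")) {
  stopifnot(inherits(params, "network_params"), length(sweep) == 2L,
            !is.null(names(sweep)))
  statistic <- match.arg(statistic)
  variant <- match.arg(variant)
  ok <- c("w", "k", "q", "dq", "tau_nmda")
  if (!all(names(sweep) %in% ok))
    stop("sweep variables must be among: ", paste(ok, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  grid$value <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(sweep)) {
      v <- grid[[nm]][i]
      if (nm == "tau_nmda") {
        tc <- p$taus; tc$tau_nmda <- v
        p$taus <- do.call(time_constants, tc)
      } else p[[nm]] <- v
    }
    p <- network_params(p$w, p$k, p$q, p$dq, p$taus)
    tryCatch(sweep_statistic(p, statistic, variant),
             error = function(e) NA_real_)
  }, numeric(1))
  grid
}

sweep_statistic <- function(p, statistic, variant) {
  switch(statistic,
    critical_dq_unstable =
      find_imag_axis_crossing(p, variant, "decreasing_dq")$dq,
    critical_dq_oscillation = find_critical_damping(p, variant),
    resonant_freq =
      find_imag_axis_crossing(p, variant, "decreasing_dq")$frequency_hz,
    critical_rise_time = {
      dq_c <- tryCatch(find_critical_damping(p, variant),
                       error = function(e) -p$q)
      sys <- build_linear_system(with_dq(p, dq_c, variant), variant)
      rise_time(sys)
    },
    overdamped_slope = {
      dq_g <- find_imag_axis_crossing(p, variant, "increasing_dq")$dq
      dqs <- seq(0, 0.9 * dq_g, length.out = 8L)
      rts <- vapply(dqs, function(d)
        rise_time(build_linear_system(with_dq(p, d, variant), variant)),
        numeric(1))
      unname(stats::coef(stats::lm(rts ~ dqs))[2L]) * 0.01
    })
}
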
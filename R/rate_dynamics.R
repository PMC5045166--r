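#' @useDynLib eibalance, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed-step classical 4th-order Runge-Kutta for dy/dt = A y + B u(t),
# with optional post-step rectification (clipping) of selected states at
# zero and a divergence guard. `u` holds input samples at the grid
# points; the midpoint stage uses their average.
rk4_linear <- function(A, B, u, y0, dt, rectify_idx = NULL, bound = 1e9) {
  n <- length(u) - 1L
  m <- nrow(A)
  Y <- matrix(0, m, n + 1L)
  y <- y0
  Y[, 1L] <- y
  for (k in seq_len(n)) {
    u0 <- u[k]; u1 <- u[k + 1L]; um <- 0.5 * (u0 + u1)
    k1 <- A %*% y + B * u0
    k2 <- A %*% (y + 0.5 * dt * k1) + B * um
    k3 <- A %*% (y + 0.5 * dt * k2) + B * um
    k4 <- A %*% (y + dt * k3) + B * u1
    y <- y + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.null(rectify_idx)) {
      neg <- y[rectify_idx] < 0
      if (any(neg)) y[rectify_idx[neg]] <- 0
    }
    if (max(abs(y)) > bound)
      stop(structure(class = c("eibalance_unstable", "error", "condition"),
                     list(message = sprintf(
                       "unstable trajectory: state magnitude exceeded %g at t = %g s",
                       bound, k * dt), call = NULL)))
    Y[, k + 1L] <- y
  }
  Y
}

# General RK4 for dy/dt = f(t, y, u) (nonlinear systems, e.g. with STD).
rk4_general <- function(f, u, y0, dt, rectify_idx = NULL, bound = 1e9) {
  n <- length(u) - 1L
  Y <- matrix(0, length(y0), n + 1L)
  y <- y0
  Y[, 1L] <- y
  t <- 0
  for (k in seq_len(n)) {
    u0 <- u[k]; u1 <- u[k + 1L]; um <- 0.5 * (u0 + u1)
    k1 <- f(t, y, u0)
    k2 <- f(t + dt / 2, y + 0.5 * dt * k1, um)
    k3 <- f(t + dt / 2, y + 0.5 * dt * k2, um)
    k4 <- f(t + dt, y + dt * k3, u1)
    y <- y + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.null(rectify_idx)) {
      neg <- y[rectify_idx] < 0
      if (any(neg)) y[rectify_idx[neg]] <- 0
    }
    if (max(abs(y)) > bound)
      stop(structure(class = c("eibalance_unstable", "error", "condition"),
                     list(message = sprintf(
                       "unstable trajectory: state magnitude exceeded %g at t = %g s",
                       bound, t + dt), call = NULL)))
    Y[, k + 1L] <- y
    t <- t + dt
  }
  Y
}

new_rate_trajectory <- function(times, Y, state_names, params, dt, input) {
  df <- as.data.frame(t(Y))
  names(df) <- state_names
  df <- cbind(time = times, df)
  structure(df, class = c("rate_trajectory", "data.frame"),
            params = params, dt = dt, input = input)
}

#' Simulate the full two-population rate network
#'
#' Integrates the eight coupled ODEs of the excitatory/inhibitory rate
#' network (two rate equations plus six first-order synaptic activations)
#' with a fixed-step classical Runge-Kutta scheme. With `rectify = TRUE`
#' (the default, matching the simulated network) the rate variables are
#' clipped at zero after every step; turn it off to compare against the
#' linear analysis, for which the system is exactly linear and
#' superposition holds.
#'
#' @param params A [network_params()] object.
#' @param input An [make_input()] stimulus driving the excitatory
#'   population (Hz).
#' @param duration Simulated time (s).
#' @param dt Integration step (s); must satisfy `dt <= min(taus) / 10`.
#' @param rectify Clip `re` and `ri` at zero after each step.
#' @param init Initial state (default the zero state).
#' @param bound Divergence guard: integration aborts with an
#'   "unstable trajectory" error if any state exceeds this magnitude.
#'
#' @return A `rate_trajectory`: a data frame with columns `time`, `re`,
#'   `ri` and one column per synaptic activation, with the parameters,
#'   step and stimulus attached as attributes.
#' @export
#' @examples
#' p <- network_params(30, 1.2, 0.3, dq = 0.05)
#' traj <- simulate_full(p, make_input("step", 5), duration = 1, dt = 5e-4)
simulate_full <- function(params, input, duration, dt = 1e-4,
                          rectify = TRUE, init = NULL, bound = 1e9) {
  stopifnot(inherits(params, "network_params"), duration > 0)
  taus <- params$taus
  if (dt > min(unlist(taus)) / 10)
    stop("'dt' must be at most min(taus)/10 = ",
         min(unlist(taus)) / 10, " s", call. = FALSE)
  A <- assemble_full(make_weights(params), taus)
  B <- numeric(8L); B[1L] <- 1 / taus$tau_e
  times <- seq(0, duration, by = dt)
  u <- sample_input(input, times)
  if (is.null(init)) init <- numeric(8L)
  Y <- rk4_linear(A, B, u, init, dt,
                  rectify_idx = if (rectify) 1:2 else NULL, bound = bound)
  new_rate_trajectory(times, Y, rownames(A), params, dt, input)
}

#' Simulate the reduced one-population rate network
#'
#' Integrates the five ODEs of the single-population network whose
#' excitatory and inhibitory recurrent feedback each carry an AMPA and an
#' NMDA component of total strength `w`. At `dq = 0` the two feedback
#' pathways cancel exactly at all times and the response equals that of a
#' feedback-free leaky integrator. Rectification is off by default, as
#' this variant is used for linear-regime comparisons (an undamped
#' oscillation is only sustained in the linear system).
#'
#' @param w Recurrent strength of each feedback projection.
#' @param q NMDA fraction.
#' @param dq NMDA-fraction shift on the excitatory feedback.
#' @param taus A [time_constants()] object (`tau_i`, `tau_gaba` unused).
#' @inheritParams simulate_full
#' @return A `rate_trajectory` with columns `time`, `r`, `sp_ampa`,
#'   `sp_nmda`, `sm_ampa`, `sm_nmda`.
#' @export
simulate_reduced <- function(w, q, dq, taus = time_constants(), input,
                             duration, dt = 1e-4, rectify = FALSE,
                             init = NULL, bound = 1e9) {
  stopifnot(duration > 0)
  relevant <- c(taus$tau_e, taus$tau_ampa, taus$tau_nmda)
  if (dt > min(relevant) / 10)
    stop("'dt' must be at most min(taus)/10 = ", min(relevant) / 10, " s",
         call. = FALSE)
  if (q < 0 || q > 1 || q + dq < 0 || q + dq > 1)
    stop("'q' and 'q + dq' must lie in [0, 1]", call. = FALSE)
  A <- assemble_reduced(w, q, dq, taus)
  B <- numeric(5L); B[1L] <- 1 / taus$tau_e
  times <- seq(0, duration, by = dt)
  u <- sample_input(input, times)
  if (is.null(init)) init <- numeric(5L)
  Y <- rk4_linear(A, B, u, init, dt,
                  rectify_idx = if (rectify) 1L else NULL, bound = bound)
  params <- list(w = w, q = q, dq = dq, taus = taus)
  new_rate_trajectory(times, Y, rownames(A), params, dt, input)
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat("Rate trajectory: ", nrow(x), " samples over ",
      signif(max(x$time), 4), " s (dt = ", attr(x, "dt"), " s)\n", sep = "")
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Write a trajectory to CSV with a JSON provenance sidecar
#'
#' The CSV holds the time column and every state series; the sidecar
#' (`<path>.json`) records the parameters, integration step and stimulus
#' so the trajectory can be reproduced.
#'
#' @param traj A `rate_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rate_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  side <- list(params = unclass_deep(attr(traj, "params")),
               dt = attr(traj, "dt"),
               input = unclass_deep(attr(traj, "input")),
               n_samples = nrow(traj))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
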
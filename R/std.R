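#' Short-term depression parameters
#'
#' Tsodyks-Markram-style depression with receptor-specific usage rates
#' split symmetrically around the base rate `u`: a positive `du`
#' depresses the AMPA synapses of the EE projection harder
#' (`u_ampa = u + du`, `u_nmda = u - du`), transiently *raising* the
#' effective NMDA fraction of that projection, which slows the network
#' exactly as a positive static `dq` would; a negative `du` depresses
#' NMDA harder and pushes the network toward the AMPA-dominated
#' delta-band instability. The split therefore plays the same role as
#' `dq`, but in a time-dependent manner. Recovery has time constant
#' `tau_r` (shared by both receptor types).
#'
#' @param u Base usage rate (dimensionless).
#' @param du Usage-rate split; `u - |du| >= 0` and `u + |du| <= 1`.
#' @param tau_r Recovery time constant (s), positive.
#' @return An object of class `"std_params"`.
#' @export
#' @examples
#' std_params(u = 0.2, du = -0.03, tau_r = 0.5)
std_params <- function(u = 0.2, du = 0, tau_r = 0.5) {
  for (v in list(u = u, du = du, tau_r = tau_r))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("STD parameters must be single finite numbers", call. = FALSE)
  if (u - abs(du) < 0)
    stop("'u - |du|' must be non-negative", call. = FALSE)
  if (u + abs(du) > 1)
    stop("'u + |du|' must not exceed 1", call. = FALSE)
  if (tau_r <= 0) stop("'tau_r' must be positive", call. = FALSE)
  structure(list(u = u, du = du, tau_r = tau_r), class = "std_params")
}

#' Depression dynamics: time derivative of the synaptic efficacy
#'
#' `dx/dt = (1 - x) / tau_r - u x R(t)`: recovery toward full efficacy
#' with time constant `tau_r`, and usage-proportional depression driven
#' by the presynaptic rate `R`. The efficacy `x` stays in `[0, 1]` under
#' these dynamics for any non-negative rate.
#'
#' @param x Current efficacy in `[0, 1]` (vectorized).
#' @param u Usage rate.
#' @param tau_r Recovery time constant (s).
#' @param rate Presynaptic rate `R(t)` (Hz), non-negative.
#' @return `dx/dt` (1/s).
#' @export
std_derivative <- function(x, u, tau_r, rate) {
  (1 - x) / tau_r - u * x * rate
}

#' Fixed point of the depression dynamics under constant rate
#'
#' `x* = 1 / (1 + u tau_r R)`.
#'
#' @inheritParams std_derivative
#' @return The equilibrium efficacy.
#' @export
std_fixed_point <- function(u, tau_r, rate) {
  1 / (1 + u * tau_r * rate)
}

#' Effective projection strengths under depression
#'
#' With the NMDA fraction fixed at `q = 0.5`, depression scales the EE
#' components by their receptor-specific efficacies,
#' `jee_ampa = x_ampa w / 2` and `jee_nmda = x_nmda w / 2`, while both IE
#' components carry the mean depression,
#' `jie_ampa = jie_nmda = (x_ampa + x_nmda) w / 4`. This construction
#' keeps the strength balance condition exactly satisfied at all times --
#' the depression state moves the network only along the temporal-balance
#' axis (effective `dq`) and the overall-strength axis.
#'
#' @param x_ampa,x_nmda Efficacies in `[0, 1]`.
#' @param w Base synaptic strength.
#' @param k Inhibitory ratio (the GABA weights `k w` are undepressed).
#' @return A [synaptic_weights()] object.
#' @export
effective_weights <- function(x_ampa, x_nmda, w, k) {
  synaptic_weights(jee_ampa = x_ampa * w / 2,
                   jee_nmda = x_nmda * w / 2,
                   jie_ampa = (x_ampa + x_nmda) * w / 4,
                   jie_nmda = (x_ampa + x_nmda) * w / 4,
                   jei = k * w, jii = k * w)
}

#' Position of a depressed network in the (We, dq) plane
#'
#' Summarizes the instantaneous effective weights by the total excitatory
#' strength `We = (x_ampa + x_nmda) w / 2` (equal on EE and IE by
#' construction) and the effective NMDA-fraction shift
#' `dq_eff = x_nmda / (x_ampa + x_nmda) - 1/2`. The depression state thus
#' traces a trajectory through the same parameter plane in which the
#' static network's instability regions live.
#'
#' @inheritParams effective_weights
#' @return A list with `we` and `dq_eff`.
#' @export
effective_position <- function(x_ampa, x_nmda, w) {
  s <- x_ampa + x_nmda
  if (any(s <= 0))
    stop("effective position undefined: x_ampa + x_nmda must be positive",
         call. = FALSE)
  list(we = s * w / 2, dq_eff = x_nmda / s - 0.5)
}

#' Simulate the rate network with short-term depression
#'
#' Couples the two-population rate equations to the depression dynamics
#' of the EE efficacies `x_ampa` and `x_nmda` (driven by the excitatory
#' rate), with the IE projections carrying the mean depression so that
#' strength balance is preserved throughout. Requires `q = 0.5`, the
#' configuration in which depression moves only the effective `dq` and
#' overall strength. Efficacies start at 1 (fully recovered).
#'
#' @param params A [network_params()] with `q = 0.5`.
#' @param std An [std_params()] object.
#' @inheritParams simulate_full
#' @return A `rate_trajectory` with the usual columns plus `x_ampa`,
#'   `x_nmda`, `we` and `dq_eff`.
#' @export
#' @examples
#' p <- network_params(50, 1.2, 0.5)
#' s <- std_params(u = 0.2, du = 0.03, tau_r = 0.5)
#' traj <- simulate_rate_std(p, s, make_input("pulse", 10, 0.05, 1),
#'                           duration = 1.2, dt = 5e-4)
simulate_rate_std <- function(params, std, input, duration, dt = 1e-4,
                              rectify = TRUE, bound = 1e9) {
  stopifnot(inherits(params, "network_params"), inherits(std, "std_params"),
            duration > 0)
  if (abs(params$q - 0.5) > 1e-12)
    stop("the depressed network requires q = 0.5 (balance-preserving split)",
         call. = FALSE)
  taus <- params$taus
  if (dt > min(unlist(taus)) / 10)
    stop("'dt' must be at most min(taus)/10", call. = FALSE)
  w <- params$w; k <- params$k
  u_a <- std$u + std$du; u_n <- std$u - std$du; tr <- std$tau_r
  te <- taus$tau_e; ti <- taus$tau_i
  ta <- taus$tau_ampa; tn <- taus$tau_nmda; tg <- taus$tau_gaba
  kw <- k * w
  # State: re ri see_a see_n sie_a sie_n sei sii x_a x_n
  f <- function(t, y, uin) {
    re <- y[1]; ri <- y[2]
    x_a <- y[9]; x_n <- y[10]
    re_drive <- max(re, 0)
    c((-re + 0.5 * x_a * w * y[3] + 0.5 * x_n * w * y[4] - kw * y[7] + uin) / te,
      (-ri + 0.25 * (x_a + x_n) * w * (y[5] + y[6]) - kw * y[8]) / ti,
      (re - y[3]) / ta,
      (re - y[4]) / tn,
      (re - y[5]) / ta,
      (re - y[6]) / tn,
      (ri - y[7]) / tg,
      (ri - y[8]) / tg,
      (1 - x_a) / tr - u_a * x_a * re_drive,
      (1 - x_n) / tr - u_n * x_n * re_drive)
  }
  times <- seq(0, duration, by = dt)
  uu <- sample_input(input, times)
  y0 <- c(numeric(8L), 1, 1)
  Y <- rk4_general(f, uu, y0, dt,
                   rectify_idx = if (rectify) 1:2 else NULL, bound = bound)
  nm <- c("re", "ri", "see_ampa", "see_nmda", "sie_ampa", "sie_nmda",
          "sei_gaba", "sii_gaba", "x_ampa", "x_nmda")
  traj <- new_rate_trajectory(times, Y, nm, params, dt, input)
  pos <- effective_position(traj$x_ampa, traj$x_nmda, w)
  traj$we <- pos$we
  traj$dq_eff <- pos$dq_eff
  attr(traj, "std") <- std
  traj
}

#' Instantaneous linearization along a depressed trajectory
#'
#' At each (subsampled) time point, freezes the depression state, builds
#' the static linear network with the corresponding effective weights,
#' and reports the position in the `(We, dq_eff)` plane together with the
#' frozen system's stability verdict and rise time (`NA` while unstable).
#' When the frozen systems cross into the delta-band instability region,
#' the nonlinear depressed network starts oscillating at essentially the
#' same moment, which is what makes this static picture a useful map of
#' the time-varying dynamics.
#'
#' @param traj A trajectory from [simulate_rate_std()].
#' @param every Spacing (s) between analyzed time points.
#' @param rise_times Compute rise times (the slower part); set `FALSE`
#'   for stability flags only.
#' @return A data frame with columns `time`, `we`, `dq_eff`, `stable`,
#'   `rise_time`.
#' @export
instantaneous_linearization <- function(traj, every = 0.01,
                                        rise_times = TRUE) {
  stopifnot(inherits(traj, "rate_trajectory"),
            all(c("x_ampa", "x_nmda") %in% names(traj)))
  params <- attr(traj, "params")
  taus <- params$taus
  dt <- attr(traj, "dt")
  idx <- seq(1L, nrow(traj), by = max(1L, round(every / dt)))
  res <- lapply(idx, function(i) {
    ww <- effective_weights(traj$x_ampa[i], traj$x_nmda[i],
                            params$w, params$k)
    sys <- build_linear_system_weights(ww, taus)
    rep <- stability_report(sys)
    rt <- if (rise_times && rep$stable)
      tryCatch(rise_time(sys), error = function(e) NA_real_)
    else NA_real_
    data.frame(time = traj$time[i], we = traj$we[i],
               dq_eff = traj$dq_eff[i], stable = rep$stable,
               rise_time = rt)
  })
  do.call(rbind, res)
}
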
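#' Configuration of the leaky integrate-and-fire network
#'
#' Describes a randomly connected network of `n_e` excitatory and `n_i`
#' inhibitory LIF neurons (defaults 3,200 and 800) with connection
#' probability `p`, exponential AMPA/NMDA/GABA synapses, and
#' merged-Poisson background input. Individual synaptic strengths are
#' `w / (n_e p)` for excitatory and `k w / (n_i p)` for inhibitory
#' synapses, so `w` and `k` play the same roles as in the rate model; the
#' AMPA/NMDA split follows `q + dq` on EE and `q` on IE projections. The
#' AMPA decay default is 10 ms here (slower than the rate model's 5 ms),
#' which improves the spiking network's stability.
#'
#' Background: each neuron receives one merged Poisson stream representing
#' `bg_sources` upstream neurons firing at `bg_rate_e_hz` (excitatory
#' targets) or `bg_rate_i_hz` (inhibitory targets), each event kicking the
#' membrane voltage by `bg_event_mv` instantaneously (inhibitory neurons
#' receive kicks scaled by `tau_e / tau_i` so both populations see the
#' same mean background elevation, matching the intent that background
#' rates keep baseline firing equal across populations). The default
#' source rates of 4.2 and 4.0 Hz (ratio 1.05:1) are calibrated so that
#' the canonical network (`w = 5`, `k = 0.65`) sits in a stable,
#' fluctuation-driven regime with a baseline of a few Hz; see the methods
#' vignette for the reasoning.
#'
#' @param n_e,n_i Population sizes.
#' @param p Connection probability (Bernoulli per ordered pair, no
#'   self-connections).
#' @param w,k,q,dq Synaptic parameterization as in [network_params()].
#' @param tau_e,tau_i Membrane time constants (s).
#' @param tau_ampa,tau_nmda,tau_gaba Synaptic decay times (s).
#' @param e_l,v_thresh,v_reset Leak reversal, firing threshold and reset
#'   potential (mV).
#' @param t_ref_e,t_ref_i Absolute refractory periods (s). The defaults
#'   (4 ms excitatory, 1 ms fast-spiking inhibitory) ensure that during
#'   an extreme excursion inhibition saturates at a higher rate than
#'   excitation, so population bursts self-terminate instead of locking
#'   into a saturated runaway state.
#' @param bg_sources,bg_event_mv,bg_rate_e_hz,bg_rate_i_hz Background
#'   parameters (see above).
#' @param std Optional [std_params()]; when present the network runs with
#'   per-presynaptic-neuron short-term depression and an even AMPA/NMDA
#'   split (`q = 0.5`), with the sign of `du` reversed on IE projections.
#' @param seed Integer seed governing connectivity and background.
#' @return An object of class `"lif_config"`.
#' @export
lif_config <- function(n_e = 3200, n_i = 800, p = 0.2,
                       w = 5, k = 0.65, q = 0.3, dq = 0,
                       tau_e = 0.02, tau_i = 0.01,
                       tau_ampa = 0.01, tau_nmda = 0.1, tau_gaba = 0.01,
                       e_l = -60, v_thresh = -40, v_reset = -52,
                       t_ref_e = 0.004, t_ref_i = 0.001,
                       bg_sources = 1000, bg_event_mv = 0.2,
                       bg_rate_e_hz = 4.2, bg_rate_i_hz = 4.0,
                       std = NULL, seed = 1L) {
  stopifnot(n_e > 0, n_i > 0, p > 0, p <= 1, v_reset < v_thresh,
            w >= 0, k > 0, q >= 0, q <= 1, q + dq >= 0, q + dq <= 1)
  if (!is.null(std)) stopifnot(inherits(std, "std_params"))
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i), p = p,
                 w = w, k = k, q = q, dq = dq,
                 tau_e = tau_e, tau_i = tau_i, tau_ampa = tau_ampa,
                 tau_nmda = tau_nmda, tau_gaba = tau_gaba,
                 e_l = e_l, v_thresh = v_thresh, v_reset = v_reset,
                 t_ref_e = t_ref_e, t_ref_i = t_ref_i,
                 bg_sources = bg_sources, bg_event_mv = bg_event_mv,
                 bg_rate_e_hz = bg_rate_e_hz, bg_rate_i_hz = bg_rate_i_hz,
                 std = std, seed = as.integer(seed)),
            class = "lif_config")
}

#' Random connectivity table for the LIF network
#'
#' Draws a Bernoulli(`p`) connection for every ordered pair of neurons
#' (no self-connections), seeded by `config$seed` so that a fixed seed
#' gives an identical table. Stored in compressed sparse-row form by
#' source neuron.
#'
#' @param config An [lif_config()] object.
#' @return An object of class `"lif_connectivity"` with 0-based `targets`
#'   and `offsets`; convert with `as.data.frame()` for an edge list.
#' @export
build_connectivity <- function(config) {
  stopifnot(inherits(config, "lif_config"))
  n <- config$n_e + config$n_i
  set.seed(config$seed)
  tl <- vector("list", n)
  for (s in seq_len(n)) {
    tg <- which(stats::runif(n) < config$p)
    tl[[s]] <- tg[tg != s] - 1L
  }
  lens <- lengths(tl)
  structure(list(targets = as.integer(unlist(tl, use.names = FALSE)),
                 offsets = c(0L, as.integer(cumsum(lens))),
                 n_e = config$n_e, n_i = config$n_i),
            class = "lif_connectivity")
}

#' @export
as.data.frame.lif_connectivity <- function(x, ...) {
  lens <- diff(x$offsets)
  data.frame(source = rep(seq_along(lens) - 1L, lens), target = x$targets)
}

#' Simulate the LIF network
#'
#' Runs the spiking network: exponential-Euler membrane updates,
#' exact exponential decay of the synaptic drives, synaptic increments of
#' `1/tau` on presynaptic spikes (scaled by the per-synapse strength, in
#' mV), instantaneous background kicks, and threshold/reset firing with
#' absolute refractory periods. When `config$std` is present the network
#' uses an even AMPA/NMDA split per connection (`q = 0.5`) with event-
#' driven per-presynaptic-neuron depression: each spike transmits with
#' the current efficacy and then depresses it by its usage rate, with
#' continuous recovery toward 1 between spikes.
#'
#' Reproducibility: the RNG is seeded from `config$seed`, so identical
#' configurations give bit-identical rasters.
#'
#' @param config An [lif_config()] object.
#' @param input An [make_input()] stimulus (mV) applied to the excitatory
#'   population's membrane equation.
#' @param duration Simulated time (s).
#' @param dt Step (s), at most 0.1 ms.
#' @param record_traces Number of excitatory neurons whose recurrent
#'   glutamatergic input (AMPA + NMDA drive, mV) is recorded, or a vector
#'   of neuron ids (0-based).
#' @param trace_dt Sampling interval for traces (s).
#' @param connectivity Optional pre-built [build_connectivity()] table.
#' @param rate_cap Runaway guard: if the excitatory population rate in any
#'   100 ms window exceeds this (Hz), the result is flagged (attribute
#'   `runaway`), never silently truncated.
#' @return A list with `raster` (class `"spike_raster"`: data frame of
#'   `neuron` id and spike `time`, time-sorted, with population sizes and
#'   duration as attributes) and `traces` (class `"neuron_traces"`:
#'   matrix samples x neurons with sampling interval attribute), plus the
#'   runaway flag.
#' @export
simulate_lif <- function(config, input, duration, dt = 1e-4,
                         record_traces = 0, trace_dt = 1e-3,
                         connectivity = NULL, rate_cap = 500) {
  stopifnot(inherits(config, "lif_config"), duration > 0)
  if (dt > 1e-4 + 1e-12)
    stop("'dt' must be at most 0.1 ms", call. = FALSE)
  if (is.null(connectivity)) connectivity <- build_connectivity(config)
  # build_connectivity consumed the seed; background continues the stream.
  n_steps <- ceiling(duration / dt)
  times <- seq(0, by = dt, length.out = n_steps)
  u <- sample_input(input, times)

  use_std <- !is.null(config$std)
  # A presynaptic spike increments the activation by 1/tau of its
  # receptor, so each activation tracks the presynaptic rate in Hz and
  # (w, k, q, dq) keep the same quantitative meaning as in the rate
  # model (steady drive w * rate, split by receptor fraction).
  je <- config$w / (config$n_e * config$p)
  if (use_std) {
    # even AMPA/NMDA split per connection => q = 0.5 exactly
    j_ee_ampa <- je / 2 / config$tau_ampa
    j_ee_nmda <- je / 2 / config$tau_nmda
    j_ie_ampa <- je / 2 / config$tau_ampa
    j_ie_nmda <- je / 2 / config$tau_nmda
    std <- config$std
  } else {
    j_ee_ampa <- (1 - config$q - config$dq) * je / config$tau_ampa
    j_ee_nmda <- (config$q + config$dq) * je / config$tau_nmda
    j_ie_ampa <- (1 - config$q) * je / config$tau_ampa
    j_ie_nmda <- config$q * je / config$tau_nmda
    std <- list(u = 0, du = 0, tau_r = 1)
  }
  ji <- config$k * config$w / (config$n_i * config$p) / config$tau_gaba

  # a single number is a count (record the first N excitatory neurons);
  # a vector is taken as explicit 0-based ids
  rec_ids <- if (length(record_traces) == 1L)
    seq_len(min(record_traces, config$n_e)) - 1L
  else as.integer(record_traces)
  if (any(rec_ids >= config$n_e))
    stop("trace recording is limited to excitatory neurons", call. = FALSE)
  trace_every <- if (length(rec_ids)) max(1L, round(trace_dt / dt)) else 0L

  # membranes start uniformly between rest and threshold (seeded), which
  # avoids the artificial population-wide synchrony of identical initial
  # conditions
  v_init <- stats::runif(config$n_e + config$n_i, config$e_l,
                         config$v_thresh)
  out <- lif_simulate_cpp(connectivity$targets, connectivity$offsets,
                          config$n_e, config$n_i,
                          j_ee_ampa, j_ee_nmda, j_ie_ampa, j_ie_nmda,
                          ji, ji,
                          config$tau_e, config$tau_i,
                          config$tau_ampa, config$tau_nmda, config$tau_gaba,
                          config$e_l, config$v_thresh, config$v_reset,
                          config$bg_sources * config$bg_rate_e_hz,
                          config$bg_sources * config$bg_rate_i_hz,
                          config$bg_event_mv,
                          # equal mean background drive for both
                          # populations: a voltage kick's steady-state
                          # elevation is rate * size * tau_m, so the
                          # inhibitory kick is scaled by tau_e / tau_i
                          config$bg_event_mv * config$tau_e / config$tau_i,
                          u, dt,
                          use_std, std$u, std$du, std$tau_r,
                          rec_ids, trace_every, rate_cap, v_init,
                          config$t_ref_e, config$t_ref_i)

  raster <- structure(data.frame(neuron = out$spike_id,
                                 time = out$spike_time),
                      class = c("spike_raster", "data.frame"),
                      n_e = config$n_e, n_i = config$n_i,
                      duration = duration)
  traces <- NULL
  if (length(rec_ids)) {
    traces <- out$traces[seq_len(out$n_trace_samples), , drop = FALSE]
    colnames(traces) <- paste0("n", rec_ids)
    traces <- structure(traces, class = "neuron_traces",
                        dt = trace_every * dt, neuron_ids = rec_ids)
  }
  if (out$runaway)
    warning("runaway activity: excitatory population rate exceeded ",
            rate_cap, " Hz", call. = FALSE)
  list(raster = raster, traces = traces, runaway = out$runaway)
}

#' @rdname simulate_lif
#' @export
simulate_lif_std <- function(config, input, duration, dt = 1e-4,
                             record_traces = 0, trace_dt = 1e-3,
                             connectivity = NULL, rate_cap = 500) {
  if (is.null(config$std))
    stop("'config$std' must be set (see std_params)", call. = FALSE)
  simulate_lif(config, input, duration, dt, record_traces, trace_dt,
               connectivity, rate_cap)
}

#' Binned population firing rate from a spike raster
#'
#' Spike count per bin divided by bin width and population size.
#'
#' @param raster A `spike_raster`.
#' @param bin Bin width (s), positive.
#' @param population `"e"`, `"i"` or `"all"`.
#' @return A data frame with `time` (bin centers) and `rate` (Hz).
#' @export
population_rate <- function(raster, bin, population = c("e", "i", "all")) {
  stopifnot(inherits(raster, "spike_raster"), bin > 0)
  population <- match.arg(population)
  n_e <- attr(raster, "n_e"); n_i <- attr(raster, "n_i")
  duration <- attr(raster, "duration")
  sel <- switch(population,
                e = raster$neuron < n_e,
                i = raster$neuron >= n_e,
                all = rep(TRUE, nrow(raster)))
  n_pop <- switch(population, e = n_e, i = n_i, all = n_e + n_i)
  breaks <- seq(0, bin * ceiling(duration / bin), by = bin)
  counts <- if (any(sel))
    graphics::hist(raster$time[sel], breaks = breaks, plot = FALSE,
                   right = FALSE, include.lowest = TRUE)$counts
  else integer(length(breaks) - 1L)
  data.frame(time = breaks[-length(breaks)] + bin / 2,
             rate = counts / (bin * n_pop))
}

#' Write a spike raster as CSV with a JSON metadata sidecar
#'
#' @param raster A `spike_raster`.
#' @param path Output CSV path (columns `neuron_id`, `time_s`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(data.frame(neuron_id = raster$neuron,
                              time_s = raster$time),
                   path, row.names = FALSE)
  jsonlite::write_json(list(n_e = attr(raster, "n_e"),
                            n_i = attr(raster, "n_i"),
                            duration_s = attr(raster, "duration"),
                            n_spikes = nrow(raster)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-neuron frequency response from recorded glutamatergic input
#'
#' For each recorded neuron, takes a window of its recurrent
#' glutamatergic input, removes the mean, and computes the magnitude of
#' the discrete Fourier transform. The growing delta-band peak of this
#' spectrum as the network slides toward the AMPA-dominated instability
#' is the locally available signal a homeostatic controller could use.
#'
#' @param traces A `neuron_traces` object.
#' @param window Window length (s) taken from the end of the recording
#'   unless `start` is given; must fit inside the trace.
#' @param start Optional window start time (s).
#' @return An object of class `"frequency_response"`: list with `freqs`
#'   (Hz, ascending, up to Nyquist), `magnitude` (neurons x frequencies)
#'   and `n_runs` (1; see [average_responses()]).
#' @export
neuron_frequency_response <- function(traces, window, start = NULL) {
  stopifnot(inherits(traces, "neuron_traces"))
  dt <- attr(traces, "dt")
  total <- nrow(traces) * dt
  if (window > total + 1e-9)
    stop("window (", window, " s) longer than trace (", total, " s)",
         call. = FALSE)
  n_win <- floor(window / dt)
  i1 <- if (is.null(start)) nrow(traces) - n_win + 1L
        else max(1L, round(start / dt) + 1L)
  if (i1 + n_win - 1L > nrow(traces))
    stop("window extends past the end of the trace", call. = FALSE)
  seg <- traces[i1:(i1 + n_win - 1L), , drop = FALSE]
  seg <- sweep(seg, 2L, colMeans(seg))
  sp <- stats::mvfft(seg)
  n_half <- floor(n_win / 2) + 1L
  mag <- t(Mod(sp[seq_len(n_half), , drop = FALSE])) * (2 / n_win)
  freqs <- (seq_len(n_half) - 1L) / (n_win * dt)
  structure(list(freqs = freqs, magnitude = mag, n_runs = 1L),
            class = "frequency_response")
}

#' Average frequency responses across runs
#'
#' Arithmetic mean of the magnitude spectra of several runs (same
#' frequency grid and neuron count required).
#'
#' @param responses List of `frequency_response` objects.
#' @return A `frequency_response` with `n_runs` summed.
#' @export
average_responses <- function(responses) {
  stopifnot(length(responses) >= 1L)
  f0 <- responses[[1L]]$freqs
  for (r in responses) stopifnot(length(r$freqs) == length(f0))
  mag <- Reduce(`+`, lapply(responses, `[[`, "magnitude")) /
    length(responses)
  structure(list(freqs = f0, magnitude = mag,
                 n_runs = sum(vapply(responses, `[[`, integer(1), "n_runs"))),
            class = "frequency_response")
}

#' Band area of a frequency response, relative to a baseline
#'
#' Trapezoidal integral of each neuron's magnitude spectrum over a
#' frequency band, minus the same neuron's baseline integral (typically
#' the response of the balanced network at `dq = 0` or `du = 0`). The
#' delta band `[0.5, 5.5]` Hz is the relevant one for the AMPA-dominated
#' instability without depression; `[3, 8]` Hz for the depressed network.
#'
#' @param response A `frequency_response`.
#' @param band Numeric length 2, `c(lo, hi)` in Hz, inside the frequency
#'   grid.
#' @param baseline Optional `frequency_response` (same grid and neurons)
#'   or per-neuron numeric vector of baseline areas.
#' @return Per-neuron numeric vector of (baseline-subtracted) band areas.
#' @export
band_area <- function(response, band, baseline = NULL) {
  stopifnot(inherits(response, "frequency_response"), length(band) == 2L)
  if (band[1L] < min(response$freqs) || band[2L] > max(response$freqs))
    stop("band outside the frequency grid", call. = FALSE)
  area_of <- function(resp) {
    sel <- which(resp$freqs >= band[1L] & resp$freqs <= band[2L])
    f <- resp$freqs[sel]
    m <- resp$magnitude[, sel, drop = FALSE]
    as.numeric(m[, -1L, drop = FALSE] %*% diff(f) / 2 +
               m[, -length(sel), drop = FALSE] %*% diff(f) / 2)
  }
  a <- area_of(response)
  if (is.null(baseline)) return(a)
  b <- if (inherits(baseline, "frequency_response")) area_of(baseline)
       else as.numeric(baseline)
  a - b
}

#' Event-driven depression along a spike train
#'
#' The per-synapse depression rule used by the spiking simulator, exposed
#' for direct inspection: between spikes the efficacy recovers toward 1
#' with time constant `tau_r`; at each spike the synapse transmits with
#' its current efficacy and is then depressed to `x (1 - u)`. For a
#' regular train at rate `R` the transmitted efficacy converges to the
#' discrete-map fixed point
#' `x* = (1 - exp(-1/(R tau_r))) / (1 - (1 - u) exp(-1/(R tau_r)))`.
#'
#' @param u Usage rate.
#' @param tau_r Recovery time constant (s).
#' @param spike_times Ascending spike times (s).
#' @param x0 Initial efficacy.
#' @return Data frame with `time`, `x_before` (transmitted efficacy) and
#'   `x_after` (post-depression).
#' @export
std_event_train <- function(u, tau_r, spike_times, x0 = 1) {
  stopifnot(!is.unsorted(spike_times))
  x <- x0; t_last <- 0
  xb <- xa <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    x <- 1 - (1 - x) * exp(-(spike_times[i] - t_last) / tau_r)
    xb[i] <- x
    x <- x * (1 - u)
    xa[i] <- x
    t_last <- spike_times[i]
  }
  data.frame(time = spike_times, x_before = xb, x_after = xa)
}
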
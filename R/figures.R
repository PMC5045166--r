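#' Reproduce a standard figure's data and plot
#'
#' Regenerates the data tables (CSV), a plot (PDF) and a JSON manifest
#' for one of the package's standard analyses, with the canonical
#' parameters as defaults:
#' \describe{
#'   \item{`fig1d`}{Step responses of the spring, the reduced network and
#'     the full network across the four damping regimes.}
#'   \item{`fig2bd`}{Full-network step responses at three `dq` values and
#'     the rise-time-versus-`dq` curve with its instability edges.}
#'   \item{`fig2e`}{Transfer-function magnitude across `dq`, showing the
#'     delta- and gamma-band peaks near the two instabilities.}
#'   \item{`fig3`}{Maps over `(q, tau_nmda)` of the instability `dq`, its
#'     resonant frequency, the critically damped rise time and the
#'     overdamped slope.}
#'   \item{`fig4`}{Rate network with short-term depression: pulse
#'     responses for three `du` values and the instantaneous-
#'     linearization trajectories.}
#'   \item{`fig5`}{LIF per-neuron frequency responses and delta-band
#'     areas across `dq`, averaged over seeded runs.}
#' }
#' The heavier figures accept size knobs (`...`) so scaled-down versions
#' can be produced quickly; see the individual `fig_*` workers.
#'
#' @param name Figure name.
#' @param outdir Output directory (created if needed).
#' @param ... Passed to the figure worker (grid sizes, `n_e`, `n_runs`,
#'   `seed`, ...).
#' @return Invisibly, the list of files written.
#' @export
run_figure <- function(name = c("fig1d", "fig2bd", "fig2e", "fig3",
                                "fig4", "fig5"),
                       outdir = ".", ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown figure; valid names: fig1d, fig2bd, ",
                          "fig2e, fig3, fig4, fig5", call. = FALSE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  worker <- switch(name, fig1d = fig_regimes, fig2bd = fig_step_rise,
                   fig2e = fig_transfer, fig3 = fig_nmda_maps,
                   fig4 = fig_std, fig5 = fig_freq_response)
  files <- worker(outdir, ...)
  manifest <- list(figure = name, files = files,
                   package_version = as.character(utils::packageVersion("eibalance")),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(outdir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

fig_regimes <- function(outdir, duration = 3, dt = 2e-4) {
  taus <- time_constants()
  # spring row: zeta spanning the four regimes at the reduction's omega0
  w0 <- natural_frequency(taus$tau_e, taus$tau_nmda)$omega0
  zetas <- c(0, 0.35, 1, 2.5)
  # reduced and full rows: the published dq values for each regime
  dq_red <- c(-0.0425, -0.0340, -0.0095, 0.125)
  dq_full <- c(-0.0226, -0.0196, -0.0068, 0.05)
  step <- make_input("step", 1)
  rows <- list()
  for (i in seq_along(zetas)) {
    tr <- simulate_spring(spring_params(w0, zetas[i]), step, duration, dt)
    rows[[length(rows) + 1L]] <-
      data.frame(model = "spring", regime = i, time = tr$time, r = tr$r)
    tr <- simulate_reduced(30, 0.3, dq_red[i], taus, step, duration, dt)
    rows[[length(rows) + 1L]] <-
      data.frame(model = "reduced", regime = i, time = tr$time, r = tr$r)
    p <- network_params(30, 1.5, 0.3, dq_full[i], taus)
    tr <- simulate_full(p, step, duration, dt, rectify = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(model = "full", regime = i, time = tr$time, r = tr$re)
  }
  dat <- do.call(rbind, rows)
  csv <- file.path(outdir, "fig1d_responses.csv")
  utils::write.csv(dat, csv, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig1d.pdf")
  grDevices::pdf(pdf_f, width = 9, height = 6)
  graphics::par(mfrow = c(3, 4), mar = c(3, 3, 2, 1))
  for (m in c("spring", "reduced", "full"))
    for (i in 1:4) {
      d <- dat[dat$model == m & dat$regime == i, ]
      graphics::plot(d$time, d$r, type = "l", xlab = "time (s)",
                     ylab = "response", main = paste(m, i))
    }
  grDevices::dev.off()
  c(csv, pdf_f)
}

fig_step_rise <- function(outdir, dqs = c(-0.015, 0, 0.05),
                          duration = 3, dt = 2e-4, n_rise = 60) {
  taus <- time_constants()
  step <- make_input("step", 5, smoothing_sigma = 0.1, onset = 0.2)
  rows <- lapply(dqs, function(dq) {
    p <- network_params(30, 1.2, 0.3, dq, taus)
    tr <- simulate_full(p, step, duration, dt)
    data.frame(dq = dq, time = tr$time, re = tr$re)
  })
  dat <- do.call(rbind, rows)
  csv1 <- file.path(outdir, "fig2b_steps.csv")
  utils::write.csv(dat, csv1, row.names = FALSE)
  p0 <- network_params(30, 1.2, 0.3)
  lo <- find_imag_axis_crossing(p0, "full", "decreasing_dq")$dq
  hi <- find_imag_axis_crossing(p0, "full", "increasing_dq")$dq
  grid_dq <- seq(lo * 0.98, hi * 0.98, length.out = n_rise)
  rt <- vapply(grid_dq, function(dq)
    tryCatch(rise_time(build_linear_system(
      network_params(30, 1.2, 0.3, dq, taus), "full")),
      error = function(e) NA_real_), numeric(1))
  rdat <- data.frame(dq = grid_dq, rise_time = rt)
  csv2 <- file.path(outdir, "fig2d_rise.csv")
  utils::write.csv(rdat, csv2, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig2bd.pdf")
  grDevices::pdf(pdf_f, width = 8, height = 4)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  graphics::matplot(matrix(dat$time, ncol = length(dqs)),
                    matrix(dat$re, ncol = length(dqs)), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "Re (Hz)")
  graphics::legend("topright", legend = paste("dq =", dqs), lty = 1,
                   col = seq_along(dqs), cex = 0.7)
  graphics::plot(rdat$dq, rdat$rise_time, log = "y", type = "l",
                 xlab = "dq", ylab = "rise time (s)")
  graphics::abline(v = c(lo, hi), col = "red", lty = 2)
  grDevices::dev.off()
  c(csv1, csv2, pdf_f)
}

fig_transfer <- function(outdir, dqs = c(-0.015, -0.01, 0, 0.05, 0.1, 0.13),
                         freqs = c(seq(0.2, 12, by = 0.2),
                                   seq(13, 90, by = 1))) {
  rows <- lapply(dqs, function(dq) {
    sys <- build_linear_system(network_params(30, 1.2, 0.3, dq), "full")
    tm <- transfer_magnitude(sys, freqs)
    tm$dq <- dq
    tm
  })
  dat <- do.call(rbind, rows)
  csv <- file.path(outdir, "fig2e_transfer.csv")
  utils::write.csv(dat, csv, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig2e.pdf")
  grDevices::pdf(pdf_f, width = 6, height = 4.5)
  graphics::matplot(matrix(dat$freq_hz, ncol = length(dqs)),
                    matrix(dat$magnitude, ncol = length(dqs)),
                    type = "l", lty = 1, log = "xy",
                    xlab = "frequency (Hz)", ylab = "|H(f)|")
  graphics::legend("bottomleft", legend = paste("dq =", dqs), lty = 1,
                   col = seq_along(dqs), cex = 0.7)
  grDevices::dev.off()
  c(csv, pdf_f)
}

fig_nmda_maps <- function(outdir, q_grid = seq(0.05, 0.6, length.out = 6),
                          tau_nmda_grid = c(0.05, 0.1, 0.2, 0.4)) {
  p <- network_params(30, 1.2, 0.3)
  sweep <- list(q = q_grid, tau_nmda = tau_nmda_grid)
  stats_wanted <- c("critical_dq_unstable", "resonant_freq",
                    "critical_rise_time", "overdamped_slope")
  files <- character(0)
  pdf_f <- file.path(outdir, "fig3.pdf")
  grDevices::pdf(pdf_f, width = 9, height = 7)
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  for (st in stats_wanted) {
    m <- sweep_map(p, sweep, st, "full")
    csv <- file.path(outdir, paste0("fig3_", st, ".csv"))
    utils::write.csv(m, csv, row.names = FALSE)
    files <- c(files, csv)
    z <- matrix(m$value, nrow = length(q_grid))
    graphics::image(q_grid, tau_nmda_grid * 1e3, z, xlab = "q",
                    ylab = "tau_nmda (ms)", main = st)
    graphics::points(0.3, 100, pch = 3)
  }
  grDevices::dev.off()
  c(files, pdf_f)
}

fig_std <- function(outdir, dus = c(-0.03, 0, 0.03), duration = 2.5,
                    dt = 2e-4, every = 0.02) {
  pulse <- make_input("pulse", 10, onset = 0, offset = 1,
                      smoothing_sigma = 0.1)
  files <- character(0)
  traj_rows <- list(); lin_rows <- list()
  for (du in dus) {
    p <- network_params(50, 1.2, 0.5)
    s <- std_params(u = 0.2, du = du, tau_r = 0.5)
    tr <- tryCatch(simulate_rate_std(p, s, pulse, duration, dt),
                   error = function(e) NULL)
    if (is.null(tr)) next
    traj_rows[[length(traj_rows) + 1L]] <-
      data.frame(du = du, time = tr$time, re = tr$re,
                 x_ampa = tr$x_ampa, x_nmda = tr$x_nmda,
                 we = tr$we, dq_eff = tr$dq_eff)
    lin <- instantaneous_linearization(tr, every = every)
    lin$du <- du
    lin_rows[[length(lin_rows) + 1L]] <- lin
  }
  dat <- do.call(rbind, traj_rows)
  lin <- do.call(rbind, lin_rows)
  csv1 <- file.path(outdir, "fig4a_responses.csv")
  csv2 <- file.path(outdir, "fig4bc_linearization.csv")
  utils::write.csv(dat, csv1, row.names = FALSE)
  utils::write.csv(lin, csv2, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig4.pdf")
  grDevices::pdf(pdf_f, width = 9, height = 3.2)
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (du in unique(dat$du)) {
    d <- dat[dat$du == du, ]
    graphics::plot(d$time, d$re, type = "l", xlab = "time (s)",
                   ylab = "Re (Hz)", main = paste("du =", du))
  }
  grDevices::dev.off()
  c(csv1, csv2, pdf_f)
}

fig_freq_response <- function(outdir, dqs = c(0, -0.05, -0.1, -0.15),
                              n_e = 3200, n_i = 800, n_runs = 10,
                              seed = 1, settle = 4, window = 4,
                              n_record = 100, step_mv = 2) {
  resp <- lif_delta_band_protocol(dqs, n_e = n_e, n_i = n_i,
                                  n_runs = n_runs, seed = seed,
                                  settle = settle, window = window,
                                  n_record = n_record, step_mv = step_mv)
  csv1 <- file.path(outdir, "fig5a_spectra.csv")
  spect <- do.call(rbind, lapply(seq_along(dqs), function(i) {
    r <- resp$responses[[i]]
    data.frame(dq = dqs[i], freq_hz = r$freqs,
               magnitude = colMeans(r$magnitude))
  }))
  utils::write.csv(spect, csv1, row.names = FALSE)
  csv2 <- file.path(outdir, "fig5c_band_areas.csv")
  utils::write.csv(resp$areas, csv2, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig5.pdf")
  grDevices::pdf(pdf_f, width = 8, height = 4)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  graphics::matplot(matrix(spect$freq_hz, ncol = length(dqs)),
                    matrix(spect$magnitude, ncol = length(dqs)),
                    type = "l", lty = 1, xlim = c(0, 12),
                    xlab = "frequency (Hz)", ylab = "mean |DFT|")
  graphics::legend("topright", legend = paste("dq =", dqs), lty = 1,
                   col = seq_along(dqs), cex = 0.7)
  graphics::plot(resp$areas$dq, resp$areas$mean_area, type = "b",
                 xlab = "dq", ylab = "delta-band area (rel. dq = 0)")
  grDevices::dev.off()
  c(csv1, csv2, pdf_f)
}

#' Delta-band frequency-response protocol for the LIF network
#'
#' Runs the spiking network at each `dq` for `n_runs` seeds (`seed`,
#' `seed + 1`, ...), records the recurrent glutamatergic input of
#' `n_record` excitatory neurons, applies a Gaussian-smoothed voltage
#' step of `step_mv`, lets the network settle for `settle` seconds, and
#' computes per-neuron magnitude spectra over the following `window`
#' seconds, averaged across runs. Band areas in `[0.5, 5.5]` Hz are
#' reported relative to the `dq = 0` baseline.
#'
#' @param dqs The `dq` grid; must include 0 (the baseline).
#' @param n_e,n_i,w,k Network size and strength parameters.
#' @param n_runs Independent seeded runs per `dq`.
#' @param seed Base seed.
#' @param settle,window Settling and analysis durations (s).
#' @param n_record Number of recorded excitatory neurons.
#' @param step_mv Step amplitude (mV), smoothed with a 100 ms Gaussian.
#' @param band Analysis band (Hz).
#' @return List with `responses` (one averaged `frequency_response` per
#'   `dq`) and `areas` (data frame `dq`, `mean_area`, `sd_area`).
#' @export
lif_delta_band_protocol <- function(dqs, n_e = 3200, n_i = 800, w = 5,
                                    k = 0.65, n_runs = 10, seed = 1,
                                    settle = 4, window = 4,
                                    n_record = 100, step_mv = 2,
                                    band = c(0.5, 5.5)) {
  stopifnot(any(dqs == 0))
  input <- make_input("step", step_mv, onset = 0, smoothing_sigma = 0.1)
  duration <- settle + window
  responses <- lapply(dqs, function(dq) {
    runs <- lapply(seq_len(n_runs), function(r) {
      cfg <- lif_config(n_e = n_e, n_i = n_i, w = w, k = k, q = 0.3,
                        dq = dq, seed = seed + r - 1L)
      sim <- simulate_lif(cfg, input, duration,
                          record_traces = n_record)
      neuron_frequency_response(sim$traces, window)
    })
    average_responses(runs)
  })
  base <- band_area(responses[[which(dqs == 0)[1L]]], band)
  areas <- do.call(rbind, lapply(seq_along(dqs), function(i) {
    a <- band_area(responses[[i]], band, baseline = base)
    data.frame(dq = dqs[i], mean_area = mean(a), sd_area = stats::sd(a))
  }))
  list(responses = responses, areas = areas)
}
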
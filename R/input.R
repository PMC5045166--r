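#' Stimulus waveforms
#'
#' Describes the external input `I(t)` driving a simulation: an ideal
#' step, a finite pulse, an impulse (unit-integral delta approximated on
#' the simulation grid), the zero signal, or user-supplied samples.
#' An optional Gaussian smoothing kernel of standard deviation
#' `smoothing_sigma` (truncated at four standard deviations and
#' renormalized to unit area, so the integral of the signal is preserved)
#' reproduces the filtered steps used for the network simulations.
#'
#' @param kind One of `"step"`, `"pulse"`, `"impulse"`, `"zero"`,
#'   `"custom"`.
#' @param amplitude Signal amplitude; rate units (Hz) for the rate models,
#'   mV for the spiking model. For an impulse this is the integral of the
#'   signal.
#' @param onset Onset time (s).
#' @param offset End time (s) for a pulse; must exceed `onset`.
#' @param smoothing_sigma Standard deviation (s) of the Gaussian
#'   smoothing kernel, or `NULL` for no smoothing.
#' @param times,samples For `kind = "custom"`, the sample times and values
#'   (linearly interpolated onto the simulation grid, constant beyond the
#'   ends).
#'
#' @return An object of class `"input_signal"`.
#' @export
#' @examples
#' make_input("step", amplitude = 5, onset = 0, smoothing_sigma = 0.1)
#' make_input("pulse", amplitude = 10, onset = 0, offset = 1)
make_input <- function(kind = c("step", "pulse", "impulse", "zero", "custom"),
                       amplitude = 1, onset = 0, offset = NULL,
                       smoothing_sigma = NULL, times = NULL, samples = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude))
    stop("'amplitude' must be a single finite number", call. = FALSE)
  if (!is.null(smoothing_sigma)) {
    if (!is.numeric(smoothing_sigma) || length(smoothing_sigma) != 1L ||
        !is.finite(smoothing_sigma) || smoothing_sigma < 0)
      stop("'smoothing_sigma' must be a non-negative number", call. = FALSE)
    if (smoothing_sigma == 0) smoothing_sigma <- NULL
  }
  if (kind == "pulse") {
    if (is.null(offset)) stop("a pulse needs an 'offset'", call. = FALSE)
    if (offset <= onset) stop("'onset' must precede 'offset'", call. = FALSE)
  }
  if (kind == "custom") {
    if (is.null(times) || is.null(samples) || length(times) != length(samples))
      stop("custom input needs matching 'times' and 'samples'", call. = FALSE)
  }
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 offset = offset, smoothing_sigma = smoothing_sigma,
                 times = times, samples = samples),
            class = "input_signal")
}

#' Sample an input signal on a uniform time grid
#'
#' Returns `I(t)` evaluated at `times` (uniformly spaced). Impulses are
#' realized as a single sample of height `amplitude / dt` so that the
#' discrete integral equals `amplitude`. Smoothing convolves the sampled
#' signal with the discrete Gaussian kernel; the signal is extended by
#' its end values so a step smoothed at the boundary behaves as an
#' infinitely long step.
#'
#' @param input An [make_input()] object.
#' @param times Uniform, ascending time grid (s).
#' @return Numeric vector of samples, one per time point.
#' @export
sample_input <- function(input, times) {
  stopifnot(inherits(input, "input_signal"), length(times) >= 2L)
  dt <- times[2L] - times[1L]
  x <- switch(input$kind,
    zero = numeric(length(times)),
    step = input$amplitude * as.numeric(times >= input$onset),
    pulse = input$amplitude *
      as.numeric(times >= input$onset & times < input$offset),
    impulse = {
      v <- numeric(length(times))
      i <- which.min(abs(times - input$onset))
      v[i] <- input$amplitude / dt
      v
    },
    custom = stats::approx(input$times, input$samples, xout = times,
                           rule = 2)$y
  )
  if (!is.null(input$smoothing_sigma))
    x <- gaussian_smooth(x, dt, input$smoothing_sigma)
  x
}

# Discrete Gaussian smoothing, kernel truncated at +-4 sigma and
# renormalized to unit sum; edges padded with the end values.
gaussian_smooth <- function(x, dt, sigma) {
  half <- max(1L, ceiling(4 * sigma / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  out <- stats::filter(xp, kern, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}
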
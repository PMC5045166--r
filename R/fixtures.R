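#' Deterministic small test objects
#'
#' Builds tiny, fully deterministic datasets used by the test suite and
#' handy for experimentation:
#' \describe{
#'   \item{`toy-linear-system`}{A 2-state diagonal system with poles
#'     exactly \{-1, -10\} 1/s.}
#'   \item{`toy-raster`}{A seeded 100-event spike raster over 20 neurons
#'     and 1 s.}
#'   \item{`std-pulse`}{A constant 10 Hz drive, the configuration whose
#'     depression fixed point is `1 / (1 + u tau_r R)`.}
#' }
#'
#' @param kind One of the names above.
#' @param seed Integer seed (used by `toy-raster`).
#' @return The corresponding object.
#' @export
make_fixture <- function(kind = c("toy-linear-system", "toy-raster",
                                  "std-pulse"), seed = 0L) {
  kind <- match.arg(kind)
  switch(kind,
    "toy-linear-system" =
      linear_system(diag(c(-1, -10)), B = c(1, 1), C = c(1, 0),
                    variant = "custom", state_names = c("slow", "fast")),
    "toy-raster" = {
      set.seed(seed)
      structure(data.frame(neuron = sample.int(20L, 100L, replace = TRUE) - 1L,
                           time = sort(stats::runif(100L, 0, 1))),
                class = c("spike_raster", "data.frame"),
                n_e = 16L, n_i = 4L, duration = 1)
    },
    "std-pulse" = make_input("step", amplitude = 10, onset = 0)
  )
}
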
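# Shared builders for the canonical parameter sets.

canonical_taus <- function(...) time_constants(...)

canonical_params <- function(w = 30, k = 1.2, q = 0.3, dq = 0, ...) {
  network_params(w, k, q, dq, taus = canonical_taus(...))
}

# Random valid parameter draws for property-style tests.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    q <- runif(1, 0.05, 0.6)
    network_params(w = runif(1, 5, 40),
                   k = runif(1, 0.5, 2),
                   q = q,
                   dq = runif(1, -q / 2, min(1 - q, 0.3)))
  })
}

# Decay/growth rate of the envelope of a trajectory around its fixed
# point, estimated from log-amplitude regression: on oscillatory
# responses the local peaks of |x - ss| are used, otherwise all samples
# in the window. Independent of the eigenvalue route.
estimate_envelope_rate <- function(times, x, ss, t_from, t_to) {
  sel <- times >= t_from & times <= t_to
  t <- times[sel]
  d <- abs(x[sel] - ss)
  pk <- which(diff(sign(diff(d))) < 0) + 1L
  if (length(pk) >= 4L) {
    fit <- stats::lm(log(d[pk]) ~ t[pk])
  } else {
    keep <- d > max(d) * 1e-9
    fit <- stats::lm(log(d[keep]) ~ t[keep])
  }
  unname(stats::coef(fit)[2L])
}

# Hand-built state matrix of the full network (independent of the
# package's internal assembly) with the NMDA-fraction shift applied
# either by adding dq on the EE projection or by subtracting it from IE.
assemble_full_for_test <- function(w, k, q, dq, dq_on = c("ee", "ie"),
                                   taus = time_constants()) {
  dq_on <- match.arg(dq_on)
  if (dq_on == "ee") {
    jee_a <- (1 - q - dq) * w; jee_n <- (q + dq) * w
    jie_a <- (1 - q) * w;      jie_n <- q * w
  } else {
    jee_a <- (1 - q) * w;      jee_n <- q * w
    jie_a <- (1 - q + dq) * w; jie_n <- (q - dq) * w
  }
  jei <- jii <- k * w
  te <- taus$tau_e; ti <- taus$tau_i
  ta <- taus$tau_ampa; tn <- taus$tau_nmda; tg <- taus$tau_gaba
  A <- matrix(0, 8, 8)
  A[1, ] <- c(-1, 0, jee_a, jee_n, 0, 0, -jei, 0) / te
  A[2, ] <- c(0, -1, 0, 0, jie_a, jie_n, 0, -jii) / ti
  A[3, c(1, 3)] <- c(1, -1) / ta
  A[4, c(1, 4)] <- c(1, -1) / tn
  A[5, c(1, 5)] <- c(1, -1) / ta
  A[6, c(1, 6)] <- c(1, -1) / tn
  A[7, c(2, 7)] <- c(1, -1) / tg
  A[8, c(2, 8)] <- c(1, -1) / tg
  A
}

dominant_complex <- function(poles) {
  poles[order(-Re(poles), -abs(Im(poles)))][1L]
}
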
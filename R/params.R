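#' Membrane and synaptic time constants
#'
#' Bundle of the five time constants that govern the rate-based network:
#' the membrane time constants of the excitatory and inhibitory
#' populations and the decay times of the AMPA, NMDA and GABA synaptic
#' activations. All values are in seconds; the defaults are the standard
#' cortical values used throughout the package (20, 10, 5, 100 and 10 ms).
#'
#' @param tau_e Excitatory membrane time constant (s).
#' @param tau_i Inhibitory membrane time constant (s).
#' @param tau_ampa AMPA decay time (s); must be shorter than `tau_nmda`.
#' @param tau_nmda NMDA decay time (s).
#' @param tau_gaba GABA decay time (s).
#'
#' @return An object of class `"time_constants"`.
#' @export
#' @examples
#' time_constants()                       # cortical defaults
#' time_constants(tau_nmda = 0.4)        # slow NMDA variant
time_constants <- function(tau_e = 0.02, tau_i = 0.01, tau_ampa = 0.005,
                           tau_nmda = 0.1, tau_gaba = 0.01) {
  tc <- list(tau_e = tau_e, tau_i = tau_i, tau_ampa = tau_ampa,
             tau_nmda = tau_nmda, tau_gaba = tau_gaba)
  for (nm in names(tc)) {
    v <- tc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("time constant '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (tau_ampa >= tau_nmda)
    stop("'tau_ampa' must be strictly smaller than 'tau_nmda'", call. = FALSE)
  structure(tc, class = "time_constants")
}

#' @export
print.time_constants <- function(x, ...) {
  cat("Time constants (ms): tau_e =", x$tau_e * 1e3,
      " tau_i =", x$tau_i * 1e3,
      " tau_ampa =", x$tau_ampa * 1e3,
      " tau_nmda =", x$tau_nmda * 1e3,
      " tau_gaba =", x$tau_gaba * 1e3, "\n")
  invisible(x)
}

#' Network parameterization (w, k, q, dq)
#'
#' The four-parameter description of the two-population balanced network:
#' `w` is the base synaptic strength shared by the excitatory-to-excitatory
#' (EE) and excitatory-to-inhibitory (IE) projections, `k` scales the
#' inhibitory (GABA) projections relative to `w`, `q` is the fraction of
#' excitatory strength carried by NMDA receptors, and `dq` shifts the NMDA
#' fraction on the EE projection only. `dq` is the control parameter of the
#' temporal balance condition: `dq = 0` keeps positive and negative
#' feedback exactly matched in time as well as in strength.
#'
#' Validation is strict: values outside the admissible region raise an
#' error naming the offending field rather than being clamped, so that
#' parameter sweeps cannot silently leave the model's domain.
#'
#' @param w Base synaptic strength (rate units per unit synaptic
#'   activation); non-negative.
#' @param k Inhibitory-to-excitatory strength ratio; positive.
#' @param q NMDA fraction on excitatory projections, in `[0, 1]`.
#' @param dq NMDA-fraction shift applied to the EE projection, in
#'   `[-q, 1 - q]` so that `q + dq` stays in `[0, 1]`.
#' @param taus A [time_constants()] object.
#'
#' @return An object of class `"network_params"`.
#' @seealso [make_weights()], [balance_lhs()], [temporal_balance_lhs()]
#' @export
#' @examples
#' network_params(w = 30, k = 1.2, q = 0.3, dq = 0.05)
network_params <- function(w, k, q, dq = 0, taus = time_constants()) {
  stopifnot(inherits(taus, "time_constants"))
  chk_num <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  chk_num(w, "w"); chk_num(k, "k"); chk_num(q, "q"); chk_num(dq, "dq")
  if (w < 0) stop("'w' must be non-negative", call. = FALSE)
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (q < 0 || q > 1) stop("'q' must lie in [0, 1]", call. = FALSE)
  if (dq < -q || dq > 1 - q)
    stop("'dq' must lie in [-q, 1 - q]; got q + dq = ", q + dq, call. = FALSE)
  structure(list(w = w, k = k, q = q, dq = dq, taus = taus),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("Balanced-network parameters: w =", x$w, " k =", x$k,
      " q =", x$q, " dq =", x$dq, "\n")
  print(x$taus)
  invisible(x)
}

#' Projection strengths of the two-population network
#'
#' Container for the six synaptic strengths of the full network: the AMPA
#' and NMDA components of the EE and IE projections and the GABA strengths
#' of the EI and II projections. Use [make_weights()] to build them from a
#' [network_params()] object; this constructor also accepts free
#' (unparameterized) weights for evaluating the balance conditions on
#' arbitrary networks.
#'
#' @param jee_ampa,jee_nmda AMPA/NMDA strengths of the EE projection.
#' @param jie_ampa,jie_nmda AMPA/NMDA strengths of the IE projection.
#' @param jei,jii GABA strengths of the EI and II projections.
#'
#' @return An object of class `"synaptic_weights"`.
#' @export
synaptic_weights <- function(jee_ampa, jee_nmda, jie_ampa, jie_nmda, jei, jii) {
  ww <- list(jee_ampa = jee_ampa, jee_nmda = jee_nmda,
             jie_ampa = jie_ampa, jie_nmda = jie_nmda,
             jei = jei, jii = jii)
  for (nm in names(ww)) {
    v <- ww[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("weight '", nm, "' must be a single non-negative finite number",
           call. = FALSE)
  }
  structure(ww, class = "synaptic_weights")
}

#' @export
print.synaptic_weights <- function(x, ...) {
  cat("Synaptic weights:\n")
  cat("  EE: ampa =", x$jee_ampa, " nmda =", x$jee_nmda, "\n")
  cat("  IE: ampa =", x$jie_ampa, " nmda =", x$jie_nmda, "\n")
  cat("  EI =", x$jei, "  II =", x$jii, "\n")
  invisible(x)
}

#' Build projection strengths from the (w, k, q, dq) parameterization
#'
#' Expands the four-parameter description into the six projection
#' strengths: `jee_ampa = (1 - q - dq) w`, `jee_nmda = (q + dq) w`,
#' `jie_ampa = (1 - q) w`, `jie_nmda = q w` and `jei = jii = k w`. The
#' `dq` shift is applied to the EE projection only; shifting IE by `-dq`
#' instead produces the same network dynamics (see the methods vignette).
#'
#' @param params A [network_params()] object.
#' @return A [synaptic_weights()] object satisfying
#'   `jee_ampa + jee_nmda = jie_ampa + jie_nmda = w`.
#' @export
#' @examples
#' make_weights(network_params(w = 30, k = 1.2, q = 0.3, dq = 0.1))
make_weights <- function(params) {
  stopifnot(inherits(params, "network_params"))
  w <- params$w; q <- params$q; dq <- params$dq; k <- params$k
  synaptic_weights(jee_ampa = (1 - q - dq) * w,
                   jee_nmda = (q + dq) * w,
                   jie_ampa = (1 - q) * w,
                   jie_nmda = q * w,
                   jei = k * w, jii = k * w)
}

#' Recover (w, k, q, dq) from projection strengths
#'
#' Inverse of [make_weights()]. Fails if the weights do not come from the
#' parameterization (unequal EE and IE totals, or `jei != jii`).
#'
#' @param weights A [synaptic_weights()] object.
#' @param taus Time constants to attach to the result.
#' @param tol Relative tolerance for the consistency checks.
#' @return A [network_params()] object.
#' @export
weights_to_params <- function(weights, taus = time_constants(), tol = 1e-9) {
  stopifnot(inherits(weights, "synaptic_weights"))
  w_ee <- weights$jee_ampa + weights$jee_nmda
  w_ie <- weights$jie_ampa + weights$jie_nmda
  scale <- max(w_ee, w_ie, 1)
  if (abs(w_ee - w_ie) > tol * scale)
    stop("EE and IE totals differ; weights are not in the (w, k, q, dq) family",
         call. = FALSE)
  if (abs(weights$jei - weights$jii) > tol * max(weights$jei, 1))
    stop("'jei' and 'jii' differ; weights are not in the (w, k, q, dq) family",
         call. = FALSE)
  w <- w_ee
  network_params(w = w, k = weights$jei / w,
                 q = weights$jie_nmda / w,
                 dq = weights$jee_nmda / w - weights$jie_nmda / w,
                 taus = taus)
}

#' Balance condition diagnostic
#'
#' Left-hand side of the strength balance condition,
#' `jei (jie_ampa + jie_nmda) - jii (jee_ampa + jee_nmda)`. A positive
#' value means net recurrent inhibition dominates net recurrent
#' excitation (the classical stability requirement); under the
#' (w, k, q, dq) parameterization the terms cancel exactly and the value
#' is identically zero.
#'
#' @param weights A [synaptic_weights()] object.
#' @return A scalar in units of strength squared.
#' @export
balance_lhs <- function(weights) {
  stopifnot(inherits(weights, "synaptic_weights"))
  weights$jei * (weights$jie_ampa + weights$jie_nmda) -
    weights$jii * (weights$jee_ampa + weights$jee_nmda)
}

#' Temporal balance condition diagnostic
#'
#' Left-hand side of the temporal balance condition,
#' `jei (jie_ampa tau_nmda + jie_nmda tau_ampa) -
#'  jii (jee_ampa tau_nmda + jee_nmda tau_ampa)`:
#' each AMPA strength is weighted by the NMDA decay time and vice versa,
#' so the expression measures whether strength-weighted negative feedback
#' is fast enough to cancel positive feedback transients. Under the
#' (w, k, q, dq) parameterization it reduces to
#' `k w^2 dq (tau_nmda - tau_ampa)`: zero at `dq = 0`, negative (temporal
#' balance violated) for `dq < 0`.
#'
#' @param weights A [synaptic_weights()] object.
#' @param taus A [time_constants()] object supplying `tau_ampa` and
#'   `tau_nmda`.
#' @return A scalar in units of strength squared times time.
#' @export
temporal_balance_lhs <- function(weights, taus = time_constants()) {
  stopifnot(inherits(weights, "synaptic_weights"),
            inherits(taus, "time_constants"))
  ta <- taus$tau_ampa; tn <- taus$tau_nmda
  weights$jei * (weights$jie_ampa * tn + weights$jie_nmda * ta) -
    weights$jii * (weights$jee_ampa * tn + weights$jee_nmda * ta)
}

#' Read network parameters from a JSON or YAML config file
#'
#' The config uses milliseconds for all time constants (keys
#' `tau_e_ms`, `tau_i_ms`, `tau_ampa_ms`, `tau_nmda_ms`, `tau_gaba_ms`);
#' they are converted to seconds once here, at the boundary. Missing keys
#' fall back to the package defaults (`w = 30`, `k = 1.2`, `q = 0.3`,
#' `dq = 0`; 20, 10, 5, 100, 10 ms).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [network_params()] object.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(w = 30, k = 1.2, q = 0.3, dq = 0,
                   tau_e_ms = 20, tau_i_ms = 10, tau_ampa_ms = 5,
                   tau_nmda_ms = 100, tau_gaba_ms = 10)
  known <- names(defaults)
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg[intersect(names(cfg), known)])
  network_params(w = cfg$w, k = cfg$k, q = cfg$q, dq = cfg$dq,
                 taus = time_constants(tau_e = cfg$tau_e_ms / 1e3,
                                       tau_i = cfg$tau_i_ms / 1e3,
                                       tau_ampa = cfg$tau_ampa_ms / 1e3,
                                       tau_nmda = cfg$tau_nmda_ms / 1e3,
                                       tau_gaba = cfg$tau_gaba_ms / 1e3))
}
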
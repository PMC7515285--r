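#' Generate an i.i.d. Bernoulli spike train
#'
#' The presynaptic spike process is modeled as an i.i.d. Bernoulli process:
#' each bin carries a spike with probability `alpha` (the normalized input
#' spike rate).
#'
#' @param alpha Per-bin spike probability in `[0, 1]`.
#' @param n Number of bins (`>= 1`).
#' @param seed Optional integer seed; with a seed the train is reproducible
#'   bit-for-bit and the caller's RNG state is left untouched.
#' @param bin_width Optional bin width in ms, attached to the train.
#' @return A [binary_train()] with role `"input"`.
#' @export
generate_bernoulli_train <- function(alpha, n, seed = NULL,
                                     bin_width = NULL) {
  check_alpha(alpha)
  stopifnot(length(alpha) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  x <- with_seed(seed, rbinom(as.integer(n), 1L, alpha))
  binary_train(x, role = "input", bin_width = bin_width)
}

#' Generate a spike train from an inhomogeneous (sinusoidal) rate
#'
#' Discrete-time inhomogeneous Poisson generation: bin `i` carries a spike
#' with probability \eqn{\alpha(t_i)} given by the [rate_signal()], with
#' \eqn{t_i = i \cdot \mathrm{bin\_width}}; bins are independent given the
#' rate. The sinusoidal modulation induces temporal correlations in the
#' marginal spike train.
#'
#' @param signal A [rate_signal()].
#' @param seed Optional integer seed (see [generate_bernoulli_train()]).
#' @return A [binary_train()] with role `"input"` and the signal's
#'   `bin_width`.
#' @export
generate_inhomogeneous_train <- function(signal, seed = NULL) {
  alpha_t <- rate_profile(signal)
  x <- with_seed(seed, rbinom(length(alpha_t), 1L, alpha_t))
  binary_train(x, role = "input", bin_width = signal$bin_width)
}

#' Simulate release under the two-state facilitation model
#'
#' The channel state at bin `i` is set by the previous input: after a
#' quiet bin (`X[i-1] = 0`) the synapse is in the baseline state and
#' releases with probability `p1` (spike bin) or `q1` (quiet bin); after a
#' spike (`X[i-1] = 1`) it is facilitated and releases with `p2` or `q2`.
#' The first bin uses the baseline state (equivalent to assuming no spike
#' before the train started); this affects one symbol and no stationary
#' quantity.
#'
#' @param x Input [binary_train()] (role `"input"`).
#' @param params A [synapse_params()] object.
#' @param seed Optional integer seed.
#' @return A [binary_train()] with role `"output"`, same length and bin
#'   width as `x`.
#' @export
simulate_two_state_release <- function(x, params, seed = NULL) {
  assert_train(x, role = "input")
  stopifnot(inherits(params, "synapse_params"))
  fp <- facilitated_params(params)
  n <- length(x)
  xs <- unclass(x)
  facilitated <- c(0L, xs[-n]) == 1L  # state i is set by X[i-1]
  prob <- ifelse(xs == 1L,
                 ifelse(facilitated, fp[["p2"]], params$p1),
                 ifelse(facilitated, fp[["q2"]], params$q1))
  y <- with_seed(seed, rbinom(n, 1L, prob))
  binary_train(y, role = "output", bin_width = attr(x, "bin_width"))
}

#' Parameters of the general history-dependent facilitation model
#'
#' In the general model the instantaneous release probabilities `p` and
#' `q` relax exponentially (time constants `tau_L_p`, `tau_L_q`) toward
#' moving targets, the limit probabilities `p(L)` and `q(L)`. Each spike
#' increments the limit probabilities by `u * (pmax - p(L))` and
#' `v * (qmax - q(L))`; in quiescent bins they decay back to the
#' baselines `p1`, `q1` with the facilitation decay time constants
#' `tau_f_p`, `tau_f_q`. The two-state model is the fast-decay limit of
#' this model.
#'
#' @param base A [synapse_params()] object supplying `p1`, `q1`, `pmax`,
#'   `qmax`, `u`, `v`.
#' @param tau_L_p,tau_L_q Convergence time constants toward the limit
#'   probabilities, in ms.
#' @param tau_f_p,tau_f_q Facilitation decay time constants, in ms.
#' @param bin_width Simulation bin width in ms (default 1 ms, the
#'   conventional spike-train bin, which makes the per-bin `alpha`
#'   numerically equal to the rate in kHz).
#' @return An object of class `general_model_params`.
#' @export
general_model_params <- function(base, tau_L_p = 250, tau_L_q = 250,
                                 tau_f_p = 20, tau_f_q = 20,
                                 bin_width = 1) {
  stopifnot(inherits(base, "synapse_params"))
  for (nm in c("tau_L_p", "tau_L_q", "tau_f_p", "tau_f_q", "bin_width")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("'%s' must be a positive duration in ms", nm),
           call. = FALSE)
  }
  structure(list(base = base, tau_L_p = tau_L_p, tau_L_q = tau_L_q,
                 tau_f_p = tau_f_p, tau_f_q = tau_f_q,
                 bin_width = bin_width),
            class = "general_model_params")
}

#' Per-bin release probabilities of the general facilitation model
#'
#' Deterministically propagates the four state variables
#' (`p`, `p(L)`, `q`, `q(L)`) through an input spike train and returns the
#' instantaneous release probabilities that [simulate_general_release()]
#' draws from. Each bin is driven by the previous bin's input symbol,
#' mirroring the two-state channel: the limits jump after a spike and
#' decay toward baseline after a quiet bin, then `p` and `q` relax one
#' bin toward the updated limits. Exponential steps use the exact
#' per-bin factor `exp(-bin_width / tau)`, so the limit trajectory is
#' invariant to splitting a bin in two.
#'
#' @param x Input [binary_train()] whose `bin_width` matches `params`
#'   (a train without a bin width adopts the model's).
#' @param params A [general_model_params()] object.
#' @return A data frame with columns `p`, `q` (instantaneous release
#'   probabilities used for bin `i`) and `p_L`, `q_L` (limit
#'   probabilities governing bin `i`, after the jump or decay).
#' @export
general_release_probs <- function(x, params) {
  assert_train(x, role = "input")
  stopifnot(inherits(params, "general_model_params"))
  bw <- attr(x, "bin_width")
  if (!is.null(bw) && !isTRUE(all.equal(bw, params$bin_width)))
    stop("bin width of the train does not match the model's", call. = FALSE)
  b <- params$base
  st <- general_state_cpp(unclass(x), b$p1, b$q1, b$pmax, b$qmax, b$u, b$v,
                          params$bin_width, params$tau_L_p, params$tau_L_q,
                          params$tau_f_p, params$tau_f_q)
  data.frame(p = st$p, q = st$q, p_L = st$p_L, q_L = st$q_L)
}

#' Simulate release under the general facilitation model
#'
#' Computes the state trajectory with [general_release_probs()] and draws
#' each release as Bernoulli(`p[i]`) in spike bins and Bernoulli(`q[i]`)
#' in quiet bins.
#'
#' @inheritParams general_release_probs
#' @param seed Optional integer seed.
#' @return A [binary_train()] with role `"output"`.
#' @export
simulate_general_release <- function(x, params, seed = NULL) {
  st <- general_release_probs(x, params)
  prob <- ifelse(unclass(x) == 1L, st$p, st$q)
  y <- with_seed(seed, rbinom(length(x), 1L, prob))
  binary_train(y, role = "output", bin_width = params$bin_width)
}
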
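#' Synapse parameters for the two-state facilitation model
#'
#' Bundles the release probabilities of a facilitating synapse: baseline
#' synchronous (spike-evoked) release `p1`, baseline asynchronous release
#' `q1`, their ceilings `pmax` and `qmax`, and the facilitation coefficients
#' `u` (synchronous) and `v` (asynchronous). The facilitated-state
#' probabilities are always derived, never stored:
#' \deqn{p_2 = u (p_{max} - p_1) + p_1, \qquad q_2 = v (q_{max} - q_1) + q_1,}
#' so `p1 <= p2 <= pmax` and `q1 <= q2 <= qmax` hold by construction.
#'
#' @param p1,q1 Baseline synchronous and asynchronous release probabilities.
#' @param pmax,qmax Maximum release probabilities of the two release modes.
#' @param u,v Facilitation coefficients in `[0, 1]`.
#'
#' @return An object of class `synapse_params`: a named list with the six
#'   fields above.
#' @seealso [facilitated_probability()], [facilitated_params()],
#'   [bound_set()]
#' @examples
#' par <- synapse_params(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2,
#'                       u = 0.5, v = 0.5)
#' facilitated_params(par)
#' @export
synapse_params <- function(p1, q1, pmax, qmax, u, v) {
  for (nm in c("p1", "q1", "pmax", "qmax", "u", "v")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < 0 || val > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (p1 > pmax) stop("'p1' must not exceed 'pmax'", call. = FALSE)
  if (q1 > qmax) stop("'q1' must not exceed 'qmax'", call. = FALSE)
  structure(list(p1 = p1, q1 = q1, pmax = pmax, qmax = qmax, u = u, v = v),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  fp <- facilitated_params(x)
  cat("Two-state facilitating synapse\n")
  cat(sprintf("  synchronous : p1 = %g, p2 = %g, pmax = %g (u = %g)\n",
              x$p1, fp[["p2"]], x$pmax, x$u))
  cat(sprintf("  asynchronous: q1 = %g, q2 = %g, qmax = %g (v = %g)\n",
              x$q1, fp[["q2"]], x$qmax, x$v))
  invisible(x)
}

#' Facilitated release probability
#'
#' Linear interpolation between a baseline probability and its ceiling,
#' controlled by a facilitation coefficient: `coeff * (max - base) + base`.
#' The result is guaranteed to lie in `[base, max]`.
#'
#' @param base Baseline probability.
#' @param max Maximum (ceiling) probability, `base <= max`.
#' @param coeff Facilitation coefficient in `[0, 1]`.
#' @return The facilitated probability. Vectorized over all arguments.
#' @examples
#' facilitated_probability(0.05, 0.2, 0.5) # 0.125
#' @export
facilitated_probability <- function(base, max, coeff) {
  if (any(!is.finite(base)) || any(!is.finite(max)) || any(!is.finite(coeff)))
    stop("arguments must be finite numbers", call. = FALSE)
  if (any(base < 0) || any(max > 1) || any(base > max))
    stop("need 0 <= base <= max <= 1", call. = FALSE)
  if (any(coeff < 0) || any(coeff > 1))
    stop("'coeff' must lie in [0, 1]", call. = FALSE)
  coeff * (max - base) + base
}

#' Facilitated-state probabilities of a synapse
#'
#' @param params A [synapse_params()] object.
#' @return Named numeric vector with elements `p2` and `q2`.
#' @export
facilitated_params <- function(params) {
  stopifnot(inherits(params, "synapse_params"))
  c(p2 = facilitated_probability(params$p1, params$pmax, params$u),
    q2 = facilitated_probability(params$q1, params$qmax, params$v))
}

#' Binary entropy function
#'
#' \eqn{h(x) = -x \log_2 x - (1-x) \log_2 (1-x)} in bits, with the
#' convention \eqn{0 \log_2 0 = 0} enforced by explicit branching.
#'
#' @param x Probability (vectorized).
#' @return Entropy in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(0.5) # 1
#' binary_entropy(c(0, 1)) # both 0
#' @export
binary_entropy <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(x))
  inner <- x > 0 & x < 1
  xi <- x[inner]
  out[inner] <- -xi * log2(xi) - (1 - xi) * log2(1 - xi)
  out
}

#' Stationary release probability of the two-state model
#'
#' Long-run probability that the synapse releases in a given bin under
#' i.i.d. Bernoulli(`alpha`) input:
#' \deqn{P(Y_i = 1) = \bar\alpha (\alpha p_1 + \bar\alpha q_1) +
#'       \alpha (\alpha p_2 + \bar\alpha q_2),}
#' the mixture of the per-state release probabilities weighted by the
#' stationary state occupancies (\eqn{\bar\alpha} baseline, \eqn{\alpha}
#' facilitated). This is the denominator of the energy-normalized
#' information rates of the facilitated synapse.
#'
#' @param params A [synapse_params()] object.
#' @param alpha Normalized input spike rate, the per-bin spike probability.
#' @return Release probability in `[0, 1]`. Vectorized over `alpha`.
#' @export
stationary_release_probability <- function(params, alpha) {
  stopifnot(inherits(params, "synapse_params"))
  check_alpha(alpha)
  fp <- facilitated_params(params)
  ab <- 1 - alpha
  ab * (alpha * params$p1 + ab * params$q1) +
    alpha * (alpha * fp[["p2"]] + ab * fp[["q2"]])
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  invisible(alpha)
}
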
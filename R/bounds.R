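#' Mutual information rate of a single-state binary asymmetric channel
#'
#' For a memoryless binary asymmetric channel with spike-evoked release
#' probability `p`, asynchronous release probability `q` and i.i.d.
#' Bernoulli(`alpha`) input,
#' \deqn{R = h(\alpha p + \bar\alpha q) - \alpha h(p) - \bar\alpha h(q)}
#' bits per step, where \eqn{h} is [binary_entropy()].
#'
#' @param p Release probability given a spike (`P(Y=1 | X=1)`).
#' @param q Release probability given no spike (`P(Y=1 | X=0)`).
#' @param alpha Per-bin input spike probability.
#' @return Mutual information in bits/step, in `[0, 1]`. Vectorized.
#' @examples
#' single_state_rate(1, 0, 0.3)  # noiseless: h(0.3)
#' single_state_rate(0.4, 0.4, 0.7)  # output independent of input: 0
#' @export
single_state_rate <- function(p, q, alpha) {
  check_alpha(alpha)
  binary_entropy(alpha * p + (1 - alpha) * q) -
    alpha * binary_entropy(p) - (1 - alpha) * binary_entropy(q)
}

#' Lower bound on the information rate of a facilitating synapse
#'
#' The state-averaged rate
#' \deqn{R_{LB} = \bar\alpha R_1 + \alpha R_2,}
#' where \eqn{R_1} and \eqn{R_2} are the [single_state_rate()]s of the
#' baseline state `(p1, q1)` and the facilitated state `(p2, q2)`. This is
#' a provable lower bound on the true mutual information rate of the
#' two-state channel (for the analogous two-state model of short-term
#' depression the same expression is exact).
#'
#' @inheritParams stationary_release_probability
#' @return Lower bound in bits/step. Vectorized over `alpha`.
#' @export
lower_bound <- function(params, alpha) {
  stopifnot(inherits(params, "synapse_params"))
  check_alpha(alpha)
  fp <- facilitated_params(params)
  r1 <- single_state_rate(params$p1, params$q1, alpha)
  r2 <- single_state_rate(fp[["p2"]], fp[["q2"]], alpha)
  (1 - alpha) * r1 + alpha * r2
}

#' Upper bound on the information rate of a facilitating synapse
#'
#' Closed-form upper bound `RUB = u7 - u6` on the mutual information rate
#' of the two-state channel, built from the stationary joint law of
#' \eqn{(X_{i-1}, X_i, Y_i)}:
#' \deqn{u_1 = \bar\alpha(\alpha p_1 + \bar\alpha q_1), \quad
#'       u_2 = \bar\alpha q_1 + \alpha q_2, \quad
#'       u_3 = \alpha(\alpha p_2 + \bar\alpha q_2), \quad
#'       u_4 = \bar\alpha p_1 + \alpha p_2, \quad
#'       u_5 = u_1 + u_3,}
#' \deqn{u_6 = h(q_1)\bar\alpha^2 + (h(p_1) + h(q_2))\alpha\bar\alpha +
#'       h(p_2)\alpha^2,}
#' \deqn{u_7 = u_5\, h\!\left(\frac{u_1 u_2 + u_3 u_4}{u_5}\right) +
#'       \bar u_5\, h\!\left(\frac{u_1 \bar u_2 + u_3 \bar u_4}
#'       {\bar u_5}\right).}
#' Here `u6` is the conditional output entropy rate `H(Y | X)` and `u7`
#' upper-bounds the output entropy rate by conditioning on the previous
#' output only. Degenerate cases (`alpha` or `u5` in `{0, 1}`) are handled
#' by the `0 log 0 = 0` convention and give the corresponding limits; when
#' `u = v = 0` the bound collapses to [single_state_rate()] exactly.
#'
#' @inheritParams stationary_release_probability
#' @return Upper bound in bits/step. Vectorized over `alpha`.
#' @export
upper_bound <- function(params, alpha) {
  stopifnot(inherits(params, "synapse_params"))
  check_alpha(alpha)
  fp <- facilitated_params(params)
  p1 <- params$p1; q1 <- params$q1
  p2 <- fp[["p2"]]; q2 <- fp[["q2"]]
  ab <- 1 - alpha

  u1 <- ab * (alpha * p1 + ab * q1)
  u2 <- ab * q1 + alpha * q2
  u3 <- alpha * (alpha * p2 + ab * q2)
  u4 <- ab * p1 + alpha * p2
  u5 <- u1 + u3

  u6 <- binary_entropy(q1) * ab^2 +
    (binary_entropy(p1) + binary_entropy(q2)) * alpha * ab +
    binary_entropy(p2) * alpha^2

  # conditional arguments; 0/0 at degenerate u5 resolves to an arbitrary
  # probability since the h() term carries weight 0
  a_rel <- safe_ratio(u1 * u2 + u3 * u4, u5)
  a_norel <- safe_ratio(u1 * (1 - u2) + u3 * (1 - u4), 1 - u5)
  u7 <- u5 * binary_entropy(a_rel) + (1 - u5) * binary_entropy(a_norel)

  u7 - u6
}

# x/y clamped to [0,1]; y = 0 maps to 0 (weight on the term is then 0)
safe_ratio <- function(x, y) {
  r <- ifelse(y > 0, x / pmax(y, .Machine$double.xmin), 0)
  pmin(pmax(r, 0), 1)
}

#' Energy-normalized information rate
#'
#' Divides an information rate (bits/step) by a release probability to give
#' bits per release, a proxy for information per unit of metabolic cost.
#'
#' @param rate Information rate in bits/step.
#' @param release_prob Release probability per step, in `(0, 1]`.
#' @return Rate in bits per release.
#' @export
energy_normalized <- function(rate, release_prob) {
  if (any(!is.finite(release_prob)) || any(release_prob <= 0) ||
      any(release_prob > 1))
    stop("'release_prob' must lie in (0, 1]: bits-per-release is undefined ",
         "for a synapse that never releases", call. = FALSE)
  rate / release_prob
}

#' Full set of analytic rates and bounds at one parameter point
#'
#' Evaluates, at each value of `alpha`, the single-state rates `R1`
#' (baseline) and `R2` (facilitated), the lower and upper bounds `RLB` and
#' `RUB` on the facilitated synapse's mutual information rate, the
#' stationary release probability, and the energy-normalized variants:
#' `R1_E = R1 / (alpha p1 + (1-alpha) q1)` (static-synapse denominator)
#' and `RLB_E`, `RUB_E` (bounds divided by the two-state release
#' probability).
#'
#' @inheritParams stationary_release_probability
#' @return A data frame of class `bound_set` with one row per `alpha` and
#'   columns `alpha`, `R1`, `R2`, `RLB`, `RUB`, `release_prob`, `R1_E`,
#'   `RLB_E`, `RUB_E`. Energy-normalized columns are `NA` where the
#'   corresponding release probability is 0.
#' @examples
#' par <- synapse_params(0.5, 0.05, 1, 0.2, u = 0.5, v = 0.5)
#' bound_set(par, alpha = c(0.1, 0.3, 0.5))
#' @export
bound_set <- function(params, alpha) {
  stopifnot(inherits(params, "synapse_params"))
  check_alpha(alpha)
  fp <- facilitated_params(params)
  r1 <- single_state_rate(params$p1, params$q1, alpha)
  r2 <- single_state_rate(fp[["p2"]], fp[["q2"]], alpha)
  rlb <- (1 - alpha) * r1 + alpha * r2
  rub <- upper_bound(params, alpha)
  rel <- stationary_release_probability(params, alpha)
  rel1 <- alpha * params$p1 + (1 - alpha) * params$q1
  out <- data.frame(
    alpha = alpha, R1 = r1, R2 = r2, RLB = rlb, RUB = rub,
    release_prob = rel,
    R1_E = ifelse(rel1 > 0, r1 / rel1, NA_real_),
    RLB_E = ifelse(rel > 0, rlb / rel, NA_real_),
    RUB_E = ifelse(rel > 0, rub / rel, NA_real_)
  )
  class(out) <- c("bound_set", "data.frame")
  out
}

#' Classify the functional effect of short-term facilitation
#'
#' Compares the bounds on the facilitated synapse with the static-synapse
#' baseline. Facilitation provably *increases* the mutual information rate
#' when `RLB > R1`, provably *decreases* it when `RUB < R1`; when
#' `RLB <= R1 <= RUB` the bounds cannot discriminate and the effect is
#' *undetermined* (ties included). The energy-normalized effect is
#' classified the same way from `RLB_E`, `RUB_E` vs `R1_E`. Comparisons
#' use strict inequalities with a small numerical guard (`1e-12`): exact
#' ties — e.g. the `u = v = 0` collapse, where both bounds equal `R1` up
#' to rounding — are `undetermined`, since the bounds genuinely cannot
#' discriminate there.
#'
#' @inheritParams stationary_release_probability
#' @return A data frame with one row per `alpha` and factor columns
#'   `rate_effect` and `energy_effect`, each with levels
#'   `increases`, `decreases`, `undetermined`.
#' @export
classify_effect <- function(params, alpha) {
  b <- bound_set(params, alpha)
  lv <- c("increases", "decreases", "undetermined")
  tol <- 1e-12
  cls <- function(lb, ub, ref) {
    out <- rep("undetermined", length(ref))
    defined <- !is.na(lb) & !is.na(ub) & !is.na(ref)
    out[defined & lb > ref + tol] <- "increases"
    out[defined & ub < ref - tol] <- "decreases"
    factor(out, levels = lv)
  }
  data.frame(
    alpha = b$alpha,
    rate_effect = cls(b$RLB, b$RUB, b$R1),
    energy_effect = cls(b$RLB_E, b$RUB_E, b$R1_E)
  )
}
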
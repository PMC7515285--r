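#' Context-tree-weighting estimator configuration
#'
#' @param depth Maximum context length `D` (default 8; the two-state
#'   channel has one step of memory, the general model motivates larger
#'   depths).
#' @param alphabet_size 2 for single trains, 4 for joint (input, output)
#'   sequences.
#' @return An object of class `ctw_config`.
#' @export
ctw_config <- function(depth = 8, alphabet_size = 2) {
  stopifnot(is.numeric(depth), length(depth) == 1L, depth >= 1,
            alphabet_size %in% c(2, 4))
  structure(list(depth = as.integer(depth),
                 alphabet_size = as.integer(alphabet_size),
                 estimator = "KT"),
            class = "ctw_config")
}

#' CTW weighted codelength of a symbol sequence
#'
#' Sequential context-tree weighting over all tree sources of depth up to
#' `config$depth`, with the Krichevsky-Trofimov add-1/2 estimator at every
#' node and equal 1/2 weights between a node's own estimate and its
#' children's product. Computed in log domain; deterministic for fixed
#' input. The first `depth` symbols serve only as initial context and are
#' excluded from the codelength, which avoids start-of-sequence boundary
#' bias.
#'
#' @param seq A [binary_train()] or an integer vector of symbols in
#'   `{0, ..., alphabet_size - 1}`.
#' @param config A [ctw_config()]; its `alphabet_size` must cover the
#'   symbols present.
#' @return Codelength in bits (a single non-negative number) for symbols
#'   `depth + 1, ..., n`.
#' @export
ctw_codelength <- function(seq, config = ctw_config()) {
  stopifnot(inherits(config, "ctw_config"))
  s <- if (inherits(seq, "binary_train")) unclass(seq) else as.integer(seq)
  if (length(s) <= config$depth)
    stop("sequence must be longer than the context depth", call. = FALSE)
  ctw_codelength_cpp(s, config$depth, config$alphabet_size)
}

#' CTW entropy-rate estimate
#'
#' Normalized codelength `ctw_codelength(seq) / (n - depth)`, a consistent
#' estimator of the entropy rate of a stationary ergodic source (the KT
#' redundancy vanishes as `O(log n / n)`).
#'
#' @inheritParams ctw_codelength
#' @return Estimated entropy rate in bits/symbol.
#' @export
entropy_rate_estimate <- function(seq, config = ctw_config()) {
  s <- if (inherits(seq, "binary_train")) unclass(seq) else as.integer(seq)
  ctw_codelength(s, config) / (length(s) - config$depth)
}

#' CTW mutual-information-rate estimate for a train pair
#'
#' Estimates the mutual information rate between an input spike train and
#' an output release train as
#' \deqn{\hat I = \hat H(X) + \hat H(Y) - \hat H(X, Y),}
#' each term a CTW entropy-rate estimate; the joint term runs CTW on the
#' 4-symbol sequence \eqn{2 X_i + Y_i}. Estimates can be slightly
#' negative for independent finite samples and are reported unclipped
#' (clipping would bias bracketing checks against the analytic bounds).
#'
#' @param x Input [binary_train()] (role `"input"`).
#' @param y Output [binary_train()] (role `"output"`), same length as `x`.
#' @param config A [ctw_config()]; its `depth` is used for all three
#'   terms (the marginal terms use alphabet 2, the joint term alphabet 4).
#' @return Estimated mutual information rate in bits/step.
#' @export
mi_rate_estimate <- function(x, y, config = ctw_config()) {
  assert_train(x, role = "input")
  assert_train(y, role = "output")
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  stopifnot(inherits(config, "ctw_config"))
  d <- config$depth
  cfg2 <- ctw_config(depth = d, alphabet_size = 2)
  cfg4 <- ctw_config(depth = d, alphabet_size = 4)
  hx <- entropy_rate_estimate(unclass(x), cfg2)
  hy <- entropy_rate_estimate(unclass(y), cfg2)
  hxy <- entropy_rate_estimate(2L * unclass(x) + unclass(y), cfg4)
  hx + hy - hxy
}

#' CTW estimate of the energy-normalized information rate
#'
#' [mi_rate_estimate()] divided by the empirical release fraction of the
#' output train: estimated bits per release.
#'
#' @inheritParams mi_rate_estimate
#' @return Estimated energy-normalized information rate in bits/release.
#' @export
energy_normalized_estimate <- function(x, y, config = ctw_config()) {
  assert_train(y, role = "output")
  frac <- mean(unclass(y))
  if (frac == 0)
    stop("output train contains no releases: bits-per-release undefined",
         call. = FALSE)
  mi_rate_estimate(x, y, config) / frac
}
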
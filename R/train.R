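#' Binary spike or release train
#'
#' A finite 0/1 sequence on a fixed time grid, tagged as a presynaptic
#' spike train (`role = "input"`) or a release train (`role = "output"`).
#'
#' @param symbols Integer or logical vector of 0/1 symbols.
#' @param role `"input"` (spikes) or `"output"` (releases).
#' @param bin_width Optional bin width in milliseconds; required only for
#'   simulations of the general (time-constant) facilitation model.
#' @return An integer vector of class `binary_train` with attributes
#'   `role` and (optionally) `bin_width`.
#' @export
binary_train <- function(symbols, role = c("input", "output"),
                         bin_width = NULL) {
  role <- match.arg(role)
  symbols <- as.integer(symbols)
  if (length(symbols) < 1L)
    stop("a train must contain at least one symbol", call. = FALSE)
  if (anyNA(symbols) || any(symbols != 0L & symbols != 1L))
    stop("train symbols must all be 0 or 1", call. = FALSE)
  if (!is.null(bin_width)) {
    if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
      stop("'bin_width' must be a positive duration in ms", call. = FALSE)
  }
  structure(symbols, class = "binary_train", role = role,
            bin_width = bin_width)
}

#' @export
print.binary_train <- function(x, ...) {
  n <- length(x)
  bw <- attr(x, "bin_width")
  cat(sprintf("binary_train (%s): %d bins, %d ones (fraction %.4g)%s\n",
              attr(x, "role"), n, sum(x), mean(x),
              if (is.null(bw)) "" else sprintf(", bin width %g ms", bw)))
  head_n <- min(n, 40L)
  cat(" ", paste(unclass(x)[seq_len(head_n)], collapse = ""),
      if (n > head_n) "..." else "", "\n", sep = "")
  invisible(x)
}

train_role <- function(x) attr(x, "role")

assert_train <- function(x, role = NULL, arg = deparse(substitute(x))) {
  if (!inherits(x, "binary_train"))
    stop(sprintf("'%s' must be a binary_train", arg), call. = FALSE)
  if (!is.null(role) && !identical(train_role(x), role))
    stop(sprintf("'%s' must have role '%s' (got '%s')", arg, role,
                 train_role(x)), call. = FALSE)
  invisible(x)
}

#' Sinusoidal rate signal for inhomogeneous spike generation
#'
#' Describes the time-varying per-bin spike probability
#' \deqn{\alpha(t) = \mathrm{baseline} + \mathrm{amplitude}
#'   \cdot \sin(2\pi f t),}
#' clipped to `[0, 1]`, on a grid of `n_bins` bins of width `bin_width` ms.
#'
#' @param baseline Mean per-bin spike probability.
#' @param amplitude Amplitude of the sinusoidal modulation (per-bin
#'   probability units); `0` gives a homogeneous train.
#' @param frequency Modulation frequency in Hz.
#' @param bin_width Bin width in ms.
#' @param n_bins Number of bins.
#' @return An object of class `rate_signal`.
#' @export
rate_signal <- function(baseline, amplitude = 0, frequency = 1,
                        bin_width = 1, n_bins) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L, baseline >= 0,
            is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(frequency), length(frequency) == 1L, frequency >= 0,
            is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 1)
  structure(list(baseline = baseline, amplitude = amplitude,
                 frequency = frequency, bin_width = bin_width,
                 n_bins = as.integer(n_bins)),
            class = "rate_signal")
}

#' Instantaneous rate profile of a rate signal
#'
#' @param signal A [rate_signal()] object.
#' @return Numeric vector of per-bin spike probabilities, clipped to
#'   `[0, 1]`.
#' @export
rate_profile <- function(signal) {
  stopifnot(inherits(signal, "rate_signal"))
  t_s <- (seq_len(signal$n_bins) - 1L) * signal$bin_width / 1000
  a <- signal$baseline +
    signal$amplitude * sin(2 * pi * signal$frequency * t_s)
  pmin(pmax(a, 0), 1)
}

#' Write a binary train to a delimited text file
#'
#' The train is written as a single newline-terminated line of
#' space-separated 0/1 symbols. A structured-text sidecar
#' (`<path>.meta.yaml`) records the role, bin width and any generator
#' metadata, so a train round-trips through [read_train()].
#'
#' @param x A [binary_train()].
#' @param path Output file path.
#' @param metadata Optional named list of extra metadata (e.g. generator
#'   parameters and seed) stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_train <- function(x, path, metadata = list()) {
  assert_train(x)
  writeLines(paste(unclass(x), collapse = " "), path)
  meta <- c(list(role = train_role(x), length = length(x)), metadata)
  bw <- attr(x, "bin_width")
  if (!is.null(bw)) meta$bin_width <- bw
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a binary train written by [write_train()]
#'
#' @param path File path. Symbols may be separated by whitespace or
#'   commas. If a `<path>.meta.yaml` sidecar exists, its `role` and
#'   `bin_width` are applied.
#' @return A [binary_train()].
#' @export
read_train <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  syms <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
  role <- "input"; bw <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$role)) role <- meta$role
    if (!is.null(meta$bin_width)) bw <- meta$bin_width
  }
  binary_train(as.integer(syms), role = role, bin_width = bw)
}
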
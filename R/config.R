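#' Read a synapse parameter configuration file
#'
#' Loads a structured text (YAML) file with keys `p1`, `q1`, `pmax`,
#' `qmax`, `u`, `v` and optionally `alpha` (a scalar or list). `qmax` must
#' be given explicitly; no relation to `q1` is assumed.
#'
#' @param path Path to the config file.
#' @return A list with elements `params` (a [synapse_params()]) and
#'   `alpha` (numeric vector or `NULL`).
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("p1", "q1", "pmax", "qmax", "u", "v")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  params <- synapse_params(cfg$p1, cfg$q1, cfg$pmax, cfg$qmax, cfg$u, cfg$v)
  alpha <- if (!is.null(cfg$alpha)) unlist(cfg$alpha) else NULL
  if (!is.null(alpha)) check_alpha(alpha)
  list(params = params, alpha = alpha)
}

#' Write a synapse parameter configuration file
#'
#' @param params A [synapse_params()].
#' @param path Output path.
#' @param alpha Optional normalized spike rate(s) to store alongside.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path, alpha = NULL) {
  stopifnot(inherits(params, "synapse_params"))
  cfg <- unclass(params)
  if (!is.null(alpha)) {
    check_alpha(alpha)
    cfg$alpha <- alpha
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
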
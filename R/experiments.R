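#' Build a parameter sweep grid
#'
#' Crosses the supplied axes into a table of parameter points, filling the
#' remaining channel parameters from `fixed`. Every point must define a
#' complete, valid combination of `p1`, `q1`, `pmax`, `qmax`, `u`, `v`,
#' `alpha`; axes named in both `axes` and `fixed` are an error. Pass
#' `tie = c(v = "u")` (say) to slave one parameter to another instead of
#' crossing them, e.g. equal synchronous and asynchronous facilitation.
#'
#' @param axes Named list of numeric vectors to cross (names among the
#'   seven parameters above).
#' @param fixed Named list of held-constant parameters.
#' @param tie Optional named character vector mapping a parameter to the
#'   axis it copies.
#' @return A data frame of class `sweep_grid`, one row per grid point.
#' @examples
#' g <- sweep_grid(axes = list(alpha = c(0.1, 0.3), u = c(0.2, 0.8)),
#'                 fixed = list(p1 = 0.5, q1 = 0.05, pmax = 1, qmax = 0.2),
#'                 tie = c(v = "u"))
#' nrow(g) # 4
#' @export
sweep_grid <- function(axes, fixed = list(), tie = NULL) {
  all_names <- c("p1", "q1", "pmax", "qmax", "u", "v", "alpha")
  stopifnot(is.list(axes), length(axes) >= 1)
  bad <- setdiff(c(names(axes), names(fixed), names(tie)), all_names)
  if (length(bad) > 0)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(intersect(names(axes), names(fixed))) > 0)
    stop("a parameter cannot be both an axis and fixed", call. = FALSE)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  for (nm in names(fixed)) grid[[nm]] <- fixed[[nm]]
  for (nm in names(tie)) grid[[nm]] <- grid[[tie[[nm]]]]
  missing <- setdiff(all_names, names(grid))
  if (length(missing) > 0)
    stop("grid does not define: ", paste(missing, collapse = ", "),
         call. = FALSE)
  grid <- grid[all_names]
  class(grid) <- c("sweep_grid", "data.frame")
  grid
}

point_params <- function(grid, i) {
  tryCatch(
    synapse_params(grid$p1[i], grid$q1[i], grid$pmax[i], grid$qmax[i],
                   grid$u[i], grid$v[i]),
    error = function(e) stop(sprintf(
      "invalid grid point %d (p1=%g, q1=%g, pmax=%g, qmax=%g, u=%g, v=%g): %s",
      i, grid$p1[i], grid$q1[i], grid$pmax[i], grid$qmax[i], grid$u[i],
      grid$v[i], conditionMessage(e)), call. = FALSE))
}

#' Evaluate the analytic bounds over a sweep grid
#'
#' Computes the full [bound_set()] at every grid point. Deterministic;
#' one output row per grid point.
#'
#' @param grid A [sweep_grid()] (or data frame with the seven parameter
#'   columns).
#' @return A data frame: the grid columns followed by `R1`, `R2`, `RLB`,
#'   `RUB`, `release_prob`, `R1_E`, `RLB_E`, `RUB_E`.
#' @export
sweep_bounds <- function(grid) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b <- bound_set(point_params(grid, i), grid$alpha[i])
    b[, setdiff(names(b), "alpha")]
  })
  out <- cbind(as.data.frame(grid), do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Map the functional effect of facilitation over a sweep grid
#'
#' Classifies, at every grid point, whether facilitation provably
#' increases or decreases the mutual information rate and the
#' energy-normalized rate ([classify_effect()]), alongside the bound
#' values. Suitable for rendering three-color maps over (`u`, `p1`) or
#' (`v`, `q1`) planes.
#'
#' @inheritParams sweep_bounds
#' @return A data frame: grid columns, bound columns, and factor columns
#'   `rate_effect`, `energy_effect`.
#' @export
effect_map <- function(grid) {
  out <- sweep_bounds(grid)
  eff <- lapply(seq_len(nrow(grid)), function(i) {
    classify_effect(point_params(grid, i), grid$alpha[i])[, -1]
  })
  cbind(out, do.call(rbind, eff))
}

#' Trial-averaged rate profile (PSTH) of an inhomogeneous generator
#'
#' Generates `n_trials` spike trains from a [rate_signal()] and averages
#' them per bin, recovering the instantaneous rate estimate a
#' peri-stimulus time histogram provides.
#'
#' @param signal A [rate_signal()].
#' @param n_trials Number of independent trials.
#' @param seed Optional integer seed.
#' @return A data frame with columns `t` (ms), `alpha_true` (the clipped
#'   programmed rate) and `alpha_hat` (trial-averaged empirical rate).
#' @export
estimate_rate_profile <- function(signal, n_trials = 1000, seed = NULL) {
  stopifnot(inherits(signal, "rate_signal"), n_trials >= 1)
  alpha_t <- rate_profile(signal)
  counts <- with_seed(seed, {
    acc <- numeric(length(alpha_t))
    for (i in seq_len(n_trials))
      acc <- acc + rbinom(length(alpha_t), 1L, alpha_t)
    acc
  })
  data.frame(t = (seq_along(alpha_t) - 1L) * signal$bin_width,
             alpha_true = alpha_t, alpha_hat = counts / n_trials)
}

#' Correlated-input facilitation experiment
#'
#' Numerically classifies the functional effect of facilitation under
#' temporally correlated (sinusoidal-rate) input, where the analytic
#' bounds no longer apply. For each modulation amplitude and each
#' `(p1, u)` point, `n_trials` input trains are generated; each is passed
#' through the facilitated synapse and through the matched static synapse
#' (`u = v = 0`), and the CTW estimates of the mutual information rate
#' and energy-normalized rate are compared. An effect is declared only
#' when the mean paired difference exceeds `margin` times its standard
#' error across trials; otherwise it is `undetermined`.
#'
#' @param p1_values,u_values Numeric vectors defining the classification
#'   grid.
#' @param amplitudes Sinusoidal modulation amplitudes (per-bin probability
#'   units); `0` reproduces homogeneous input.
#' @param baseline Mean per-bin spike probability of the input.
#' @param frequency Modulation frequency in Hz.
#' @param q1,v,pmax,qmax Held-constant asynchronous/ceiling parameters.
#' @param n_bins Train length per trial.
#' @param n_trials Trials per grid point.
#' @param bin_width Bin width in ms.
#' @param config A [ctw_config()].
#' @param margin Multiple of the across-trial standard error a difference
#'   must exceed to be classified (default 2).
#' @param seed Optional integer seed.
#' @return A data frame with one row per (amplitude, p1, u): mean
#'   facilitated and static MI estimates, paired differences with
#'   standard errors, and factor columns `rate_effect`, `energy_effect`.
#' @export
correlated_input_experiment <- function(p1_values, u_values,
                                        amplitudes = c(0, 0.075, 0.15),
                                        baseline = 0.3, frequency = 1,
                                        q1 = 0.05, v = 0.5, pmax = 1,
                                        qmax = 0.2, n_bins = 1e5,
                                        n_trials = 10, bin_width = 1,
                                        config = ctw_config(),
                                        margin = 2, seed = NULL) {
  grid <- expand.grid(amplitude = amplitudes, p1 = p1_values,
                      u = u_values, KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      amp <- grid$amplitude[i]
      fac <- synapse_params(grid$p1[i], q1, pmax, qmax, grid$u[i], v)
      stat <- synapse_params(grid$p1[i], q1, pmax, qmax, 0, 0)
      sig <- rate_signal(baseline, amp, frequency, bin_width, n_bins)
      mi_f <- mi_s <- en_f <- en_s <- numeric(n_trials)
      for (k in seq_len(n_trials)) {
        x <- generate_inhomogeneous_train(sig)
        yf <- simulate_two_state_release(x, fac)
        ys <- simulate_two_state_release(x, stat)
        mi_f[k] <- mi_rate_estimate(x, yf, config)
        mi_s[k] <- mi_rate_estimate(x, ys, config)
        en_f[k] <- mi_f[k] / mean(unclass(yf))
        en_s[k] <- mi_s[k] / mean(unclass(ys))
      }
      cls <- function(diff) {
        m <- mean(diff)
        se <- stats::sd(diff) / sqrt(length(diff))
        if (is.na(se) || se == 0) se <- Inf
        if (m > margin * se) "increases"
        else if (m < -margin * se) "decreases"
        else "undetermined"
      }
      data.frame(
        amplitude = amp, p1 = grid$p1[i], u = grid$u[i],
        mi_facilitated = mean(mi_f), mi_static = mean(mi_s),
        rate_diff = mean(mi_f - mi_s),
        rate_se = stats::sd(mi_f - mi_s) / sqrt(n_trials),
        energy_diff = mean(en_f - en_s),
        energy_se = stats::sd(en_f - en_s) / sqrt(n_trials),
        rate_effect = cls(mi_f - mi_s),
        energy_effect = cls(en_f - en_s)
      )
    })
    out <- do.call(rbind, rows)
    lv <- c("increases", "decreases", "undetermined")
    out$rate_effect <- factor(out$rate_effect, levels = lv)
    out$energy_effect <- factor(out$energy_effect, levels = lv)
    out
  })
}

#' Compare the two-state and general facilitation models
#'
#' For each `(p1, alpha)` combination, simulates release under both the
#' two-state channel and the general time-constant model driven by the
#' same Bernoulli input, estimates both mutual information rates with
#' CTW, and tabulates them next to the analytic bounds of the two-state
#' model.
#'
#' @param p1_values Baseline synchronous release probabilities to sweep.
#' @param alpha_values Normalized input spike rates to sweep.
#' @param q1,u,v,pmax,qmax Remaining channel parameters.
#' @param tau_L,tau_f Convergence and facilitation-decay time constants
#'   (ms), applied to both release modes.
#' @param n Train length in bins.
#' @param bin_width Bin width in ms.
#' @param config A [ctw_config()].
#' @param seed Optional integer seed.
#' @return A data frame with one row per (p1, alpha): CTW estimates
#'   `mi_two_state`, `mi_general`, energy-normalized counterparts, and
#'   the analytic `RLB`, `RUB`, `release_prob` of the two-state model.
#' @export
compare_models <- function(p1_values, alpha_values, q1 = 0.05, u = 0.5,
                           v = 0.5, pmax = 1, qmax = 0.2, tau_L = 250,
                           tau_f = 20, n = 1e6, bin_width = 1,
                           config = ctw_config(), seed = NULL) {
  grid <- expand.grid(p1 = p1_values, alpha = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      params <- synapse_params(grid$p1[i], q1, pmax, qmax, u, v)
      gparams <- general_model_params(params, tau_L_p = tau_L,
                                      tau_L_q = tau_L, tau_f_p = tau_f,
                                      tau_f_q = tau_f,
                                      bin_width = bin_width)
      x <- generate_bernoulli_train(grid$alpha[i], n,
                                    bin_width = bin_width)
      y2 <- simulate_two_state_release(x, params)
      yg <- simulate_general_release(x, gparams)
      mi2 <- mi_rate_estimate(x, y2, config)
      mig <- mi_rate_estimate(x, yg, config)
      b <- bound_set(params, grid$alpha[i])
      data.frame(
        p1 = grid$p1[i], alpha = grid$alpha[i],
        mi_two_state = mi2, mi_general = mig,
        en_two_state = mi2 / mean(unclass(y2)),
        en_general = mig / mean(unclass(yg)),
        RLB = b$RLB, RUB = b$RUB, release_prob = b$release_prob
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
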
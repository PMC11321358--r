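# Virtual-electrode capture model: maps true site-to-nerve distance to an
# observed capture-threshold category under the clinical pacing protocol
# (50 mA / 2 ms screening, then differential pacing at 10/20/30 mA).

#' Capture-model parameters
#'
#' Generative strength-duration x strength-distance model. The threshold at
#' distance `d` and pulse width `w` is
#' `(rheobase + distance_coeff * d^2) * (1 + chronaxie / w)`:
#' Weiss-Lapicque strength-duration scaling around a quadratic far-field
#' strength-distance term. Observed thresholds carry multiplicative lognormal
#' noise (thresholds are positive and their dispersion grows with magnitude).
#'
#' @param rheobase_mA current needed at zero distance and infinite pulse
#'   width (mA), > 0.
#' @param chronaxie_ms pulse width at which the threshold doubles (ms), > 0;
#'   default 1.5 ms, the pulse width reported to reach the phrenic-nerve
#'   rheobase.
#' @param distance_coeff_mA_per_mm2 quadratic strength-distance coefficient
#'   (mA / mm^2), > 0.
#' @param threshold_noise_sd_log SD of the lognormal multiplicative noise on
#'   observed thresholds (log scale), >= 0.
#' @return object of class `capture_params`.
#' @export
capture_params <- function(rheobase_mA = 2, chronaxie_ms = 1.5,
                           distance_coeff_mA_per_mm2 = 0.12,
                           threshold_noise_sd_log = 0.5) {
  if (rheobase_mA <= 0 || chronaxie_ms <= 0 || distance_coeff_mA_per_mm2 <= 0) {
    stop("rheobase, chronaxie and distance coefficient must be > 0", call. = FALSE)
  }
  if (threshold_noise_sd_log < 0) stop("noise SD must be >= 0", call. = FALSE)
  structure(list(rheobase_mA = rheobase_mA, chronaxie_ms = chronaxie_ms,
                 distance_coeff_mA_per_mm2 = distance_coeff_mA_per_mm2,
                 threshold_noise_sd_log = threshold_noise_sd_log),
            class = "capture_params")
}

#' The clinical pacing protocol
#'
#' High-output screening at `max_output_mA` with pulse width `pulse_width_ms`,
#' then differential pacing at `test_levels_mA` to bracket the threshold.
#'
#' @param max_output_mA maximum deliverable output (mA).
#' @param pulse_width_ms pulse width (ms).
#' @param test_levels_mA differential pacing levels (mA), strictly increasing
#'   and below `max_output_mA`.
#' @return object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(max_output_mA = 50, pulse_width_ms = 2,
                            test_levels_mA = c(10, 20, 30)) {
  if (any(diff(test_levels_mA) <= 0) || any(test_levels_mA >= max_output_mA)) {
    stop("test levels must be strictly increasing and below max output", call. = FALSE)
  }
  structure(list(max_output_mA = max_output_mA, pulse_width_ms = pulse_width_ms,
                 test_levels_mA = test_levels_mA), class = "pacing_protocol")
}

#' Threshold-category labels and ordering
#'
#' The five exhaustive, mutually exclusive categories used throughout:
#' `<=10 mA`, `>10-<=20 mA`, `>20-<=30 mA`, `>30-<=50 mA`, and
#' `non-capture at 50 mA`. Boundary thresholds land in the lower-labelled
#' category (the labels are "<=").
#'
#' @return character vector of the five ordered labels.
#' @export
threshold_categories <- function() {
  c("<=10 mA", ">10-<=20 mA", ">20-<=30 mA", ">30-<=50 mA", "non-capture")
}

#' Classify a threshold into its protocol category
#'
#' @param threshold_mA numeric vector of (possibly noisy) thresholds (mA).
#' @param protocol a [pacing_protocol()].
#' @return ordered factor over [threshold_categories()].
#' @export
classify_threshold <- function(threshold_mA, protocol = pacing_protocol()) {
  breaks <- c(0, protocol$test_levels_mA, protocol$max_output_mA, Inf)
  i <- findInterval(threshold_mA, breaks, left.open = TRUE)  # (lo, hi] bins
  factor(threshold_categories()[i], levels = threshold_categories(), ordered = TRUE)
}

#' Noise-free capture threshold at a given distance
#'
#' Strictly increasing in distance and decreasing in pulse width.
#'
#' @param d_mm distance(s) from pacing site to nerve (mm), >= 0.
#' @param params a [capture_params()].
#' @param pulse_width_ms pulse width (ms).
#' @return threshold(s) in mA.
#' @export
threshold_from_distance <- function(d_mm, params = capture_params(),
                                    pulse_width_ms = 2) {
  if (any(d_mm < 0)) stop("distance must be >= 0", call. = FALSE)
  (params$rheobase_mA + params$distance_coeff_mA_per_mm2 * d_mm^2) *
    (1 + params$chronaxie_ms / pulse_width_ms)
}

#' Algebraic inverse of [threshold_from_distance()]
#'
#' @param threshold_mA noise-free threshold(s) (mA); must be at least the
#'   zero-distance threshold.
#' @param params a [capture_params()].
#' @param pulse_width_ms pulse width (ms).
#' @return distance(s) in mm.
#' @export
distance_from_threshold <- function(threshold_mA, params = capture_params(),
                                    pulse_width_ms = 2) {
  sd_factor <- 1 + params$chronaxie_ms / pulse_width_ms
  x <- threshold_mA / sd_factor - params$rheobase_mA
  if (any(x < -1e-12)) stop("threshold below the zero-distance threshold", call. = FALSE)
  sqrt(pmax(0, x) / params$distance_coeff_mA_per_mm2)
}

#' Simulate the observed threshold category for true thresholds
#'
#' Applies multiplicative lognormal noise, then classifies against the
#' protocol: no capture when the noisy threshold exceeds the maximum output,
#' otherwise the bracketing differential-pacing category, with boundaries
#' inclusive on the upper edge. Deterministic given the seed.
#'
#' @param true_threshold_mA numeric vector of noise-free thresholds (mA), > 0.
#' @param protocol a [pacing_protocol()].
#' @param noise_sd_log lognormal noise SD (log scale), >= 0.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return ordered factor of observed categories.
#' @export
simulate_observed_category <- function(true_threshold_mA,
                                       protocol = pacing_protocol(),
                                       noise_sd_log = 0, seed = NULL) {
  if (any(true_threshold_mA <= 0)) stop("thresholds must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
  }
  noisy <- true_threshold_mA *
    exp(stats::rnorm(length(true_threshold_mA), 0, noise_sd_log))
  classify_threshold(noisy, protocol)
}

#' Calibrate capture-model parameters against per-category distance means
#'
#' Fits the quadratic distance coefficient and the lognormal noise SD so that,
#' when the cohort's distance distribution is pushed through the capture
#' model and the protocol, the per-category mean distances approximate the
#' target summary. The distance pool is drawn from the target summary's own
#' truncated-normal mixture; the fit uses common random numbers and
#' Nelder-Mead over log-parameters.
#'
#' @param target_summary data.frame with columns `n`, `mean_mm`, `sd_mm`,
#'   `min_mm`, one row per category in protocol order (5 rows, n > 0).
#' @param seed integer seed.
#' @param n_pool size of the simulated distance pool.
#' @param protocol a [pacing_protocol()].
#' @param rheobase_mA rheobase (mA); its value is used as the fixed rheobase
#'   when `fit_rheobase = FALSE` and as a starting value otherwise.
#' @param chronaxie_ms fixed chronaxie (ms).
#' @param fit_rheobase also fit the rheobase (default TRUE; three free
#'   parameters give the model enough freedom to hit the observed
#'   per-category means, see the methods vignette).
#' @return list: `params` (a [capture_params()]), `objective` (achieved mean
#'   squared error in mm^2), `category_means` (simulated at the optimum).
#' @export
calibrate_capture_params <- function(target_summary, seed = 1L, n_pool = 20000L,
                                     protocol = pacing_protocol(),
                                     rheobase_mA = 2, chronaxie_ms = 1.5,
                                     fit_rheobase = TRUE) {
  stopifnot(nrow(target_summary) == 5L, all(target_summary$n > 0))
  if (any(diff(target_summary$mean_mm) <= 0)) {
    warning("target category means are not strictly increasing; best-effort fit")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  # distance pool from the summary's own truncated-normal mixture
  pool <- unlist(lapply(seq_len(nrow(target_summary)), function(i) {
    tn <- calibrate_truncated_normal(target_summary$mean_mm[i],
                                     target_summary$sd_mm[i],
                                     target_summary$min_mm[i])
    k <- round(n_pool * target_summary$n[i] / sum(target_summary$n))
    rtruncnorm(k, tn["mu"], tn["sigma"], target_summary$min_mm[i])
  }))
  z <- stats::rnorm(length(pool))  # common random numbers across evaluations
  target_means <- target_summary$mean_mm
  sim_means <- function(rheo, coeff, noise_sd) {
    par <- capture_params(rheo, chronaxie_ms, coeff, noise_sd)
    thr <- threshold_from_distance(pool, par, protocol$pulse_width_ms)
    cat_i <- as.integer(classify_threshold(thr * exp(noise_sd * z), protocol))
    vapply(1:5, function(k) if (any(cat_i == k)) mean(pool[cat_i == k]) else NA_real_,
           numeric(1))
  }
  penalise <- function(m) ifelse(is.na(m), 2 * max(target_means), m)
  if (fit_rheobase) {
    obj <- function(lp) {
      sum((penalise(sim_means(exp(lp[1]), exp(lp[2]), exp(lp[3]))) - target_means)^2)
    }
    starts <- list(log(c(rheobase_mA, 0.1, 0.4)), log(c(1, 0.05, 0.6)),
                   log(c(4, 0.2, 0.3)), log(c(0.5, 0.15, 0.8)))
  } else {
    obj <- function(lp) {
      sum((penalise(sim_means(rheobase_mA, exp(lp[1]), exp(lp[2]))) - target_means)^2)
    }
    starts <- list(log(c(0.1, 0.4)), log(c(0.05, 0.6)), log(c(0.2, 0.3)),
                   log(c(0.15, 0.8)))
  }
  fit <- NULL
  for (st in starts) {
    f <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-9))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  p <- exp(fit$par)
  best <- if (fit_rheobase) {
    capture_params(p[1], chronaxie_ms, p[2], p[3])
  } else {
    capture_params(rheobase_mA, chronaxie_ms, p[1], p[2])
  }
  list(params = best, objective = fit$value / 5,
       category_means = if (fit_rheobase) sim_means(p[1], p[2], p[3]) else
         sim_means(rheobase_mA, p[1], p[2]))
}

#' Serialize capture-model parameters to JSON
#' @param params a [capture_params()].
#' @param path file path.
#' @return [read_capture_params_json()] returns a [capture_params()].
#' @export
write_capture_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_capture_params_json
#' @export
read_capture_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  capture_params(x$rheobase_mA, x$chronaxie_ms, x$distance_coeff_mA_per_mm2,
                 x$threshold_noise_sd_log)
}
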
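# Cumulative-Gaussian psychometric fitting and the low-level 2AFC tasks used
# to measure cue reliability. The orientation task reports whether a briefly
# flashed Gabor is tilted clockwise of vertical; the position task whether it
# lies right of a reference axis. The fitted spread sigma of
# P(resp = 1 | x) = Phi((x - mu) / sigma) indexes the sensory noise of the cue
# and feeds the observer's integration weights.

MAX_ORI_OFFSET <- 20    # degrees, orientation-task offsets span at most +/-20
MAX_POS_OFFSET <- 0.67  # degrees, position-task offsets span at most +/-0.67

#' Construct a psychometric dataset
#'
#' @param offset Stimulus offsets (degrees; orientation or position).
#' @param response Binary responses (1 = clockwise / right).
#' @param kind `"orientation"` or `"position"` (metadata).
#' @return A `psychometric_dataset` (data.frame with attributes).
#' @export
psychometric_dataset <- function(offset, response, kind = "orientation") {
  if (length(offset) != length(response))
    df_stop("offset and response must have the same length", "dynform_invalid_input")
  if (!all(response %in% c(0, 1)))
    df_stop("responses must be binary 0/1", "dynform_invalid_input")
  if (length(unique(offset)) < 2 || min(offset) >= 0 || max(offset) <= 0)
    df_stop("offsets must span negative and positive values with >= 2 levels",
            "dynform_invalid_input")
  structure(data.frame(offset = offset, response = response),
            kind = kind, class = c("psychometric_dataset", "data.frame"))
}

#' Fit a two-parameter cumulative-Gaussian psychometric function
#'
#' Maximises the Bernoulli likelihood of `P(resp = 1 | x) = Phi((x - mu) /
#' sigma)` via probit regression (`glm` with a probit link: `mu = -b0 / b1`,
#' `sigma = 1 / b1`), which is exactly the two-parameter cumulative-Gaussian
#' MLE and is well defined with unequal trial counts per level. No lapse rate
#' is fitted. Degenerate data are flagged rather than silently fit: perfect
#' separation clamps sigma at the lower bound, non-positive or vanishing
#' slopes (e.g. responses independent of offset) clamp it at the upper bound.
#'
#' @param data A `psychometric_dataset` or data.frame with `offset` and
#'   `response`.
#' @param sigma_bounds Lower/upper clamp for sigma, in task units.
#' @return A `psychometric_fit` with `mu`, `sigma`, `reliability_index`
#'   (equal to sigma: larger = less reliable), `n`, `converged`, and a
#'   character vector `flags` (empty for a clean fit).
#' @examples
#' d <- simulate_orientation_task(2, seq(-6, 6, length.out = 8), 50, seed = 1)
#' fit_cumulative_gaussian(d)
#' @export
fit_cumulative_gaussian <- function(data, sigma_bounds = c(1e-3, 1e3)) {
  if (!all(c("offset", "response") %in% names(data)))
    df_stop("data needs offset and response columns", "dynform_invalid_input")
  if (!all(data$response %in% c(0, 1)))
    df_stop("responses must be binary 0/1", "dynform_invalid_input")
  if (nrow(data) < 16)
    df_stop("need at least 16 trials", "dynform_invalid_input")
  if (length(unique(data$offset)) < 2)
    df_stop("need at least 2 distinct offsets", "dynform_invalid_input")

  flags <- character(0)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(response ~ offset, family = stats::binomial("probit"), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- stats::coef(fit)
  slope <- unname(b[2])
  intercept <- unname(b[1])

  if (!is.finite(slope) || slope <= 0) {
    flags <- c(flags, "non_identifiable")
    sigma <- sigma_bounds[2]
    mu <- 0
  } else {
    sigma <- 1 / slope
    mu <- -intercept / slope
    if (separated || sigma < sigma_bounds[1]) {
      flags <- c(flags, if (separated) "separation")
      if (sigma < sigma_bounds[1]) {
        flags <- c(flags, "sigma_at_lower_bound")
        sigma <- sigma_bounds[1]
      }
    }
    if (sigma > sigma_bounds[2]) {
      flags <- c(flags, "sigma_at_upper_bound")
      sigma <- sigma_bounds[2]
    }
    rng <- range(data$offset)
    if (mu < rng[1] || mu > rng[2]) {
      flags <- c(flags, "mu_outside_range")
      mu <- min(max(mu, rng[1]), rng[2])
    }
  }
  structure(list(mu = mu, sigma = sigma, reliability_index = sigma,
                 n = nrow(data), converged = fit$converged,
                 flags = flags,
                 coefficients = c(intercept = intercept, slope = slope)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> mu=%.4g sigma=%.4g n=%d%s\n",
              x$mu, x$sigma, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# default 8-level symmetric offset grid adapted to the expected noise
default_offsets <- function(sigma, max_offset) {
  m <- min(2.5 * sigma, max_offset)
  seq(-m, m, length.out = 8)
}

simulate_2afc <- function(sigma, offsets, n_per_level, seed, kind, max_offset) {
  if (!is.finite(sigma) || sigma <= 0)
    df_stop("sigma must be > 0", "dynform_invalid_params")
  if (is.null(offsets)) offsets <- default_offsets(sigma, max_offset)
  if (any(abs(offsets) > max_offset + 1e-12))
    df_stop(sprintf("offsets must lie within +/-%g degrees", max_offset),
            "dynform_range_error")
  x <- rep(offsets, each = n_per_level)
  resp <- with_seed(seed, as.integer(x + stats::rnorm(length(x), 0, sigma) > 0))
  d <- psychometric_dataset(x, resp, kind = kind)
  attr(d, "sigma_true") <- sigma
  attr(d, "seed") <- seed
  d
}

#' Simulate the low-level orientation discrimination task
#'
#' Binary clockwise/counter-clockwise judgements of a Gabor tilted from
#' vertical: response = 1 iff `offset + N(0, sigma_theta^2) > 0`. Offsets
#' span eight levels within +/-20 degrees; by default they adapt to the
#' noise level (`+/- min(2.5 sigma, 20)`) so the psychometric function is
#' sampled over its full range.
#'
#' @param sigma_theta Orientation noise SD in degrees (> 0).
#' @param offsets Offset levels (degrees) or `NULL` for the adaptive default.
#' @param n_per_level Trials per offset level (default 24, the standard
#'   per-condition budget of the low-level tasks).
#' @param seed RNG seed.
#' @return A `psychometric_dataset`.
#' @export
simulate_orientation_task <- function(sigma_theta, offsets = NULL,
                                      n_per_level = 24, seed = 1) {
  simulate_2afc(sigma_theta, offsets, n_per_level, seed,
                "orientation", MAX_ORI_OFFSET)
}

#' Simulate the low-level position discrimination task
#'
#' Binary left/right judgements of a Gabor displaced from a reference axis;
#' offsets span eight levels within +/-0.67 degrees of visual angle (offsets
#' outside that range are rejected). `sigma_p` is in degrees here; convert
#' task-unit reliabilities with the position unit before simulating.
#'
#' @param sigma_p Position noise SD in degrees (> 0).
#' @param offsets Offset levels (degrees) or `NULL` for the adaptive default.
#' @param n_per_level Trials per offset level.
#' @param seed RNG seed.
#' @return A `psychometric_dataset`.
#' @export
simulate_position_task <- function(sigma_p, offsets = NULL,
                                   n_per_level = 24, seed = 1) {
  simulate_2afc(sigma_p, offsets, n_per_level, seed, "position", MAX_POS_OFFSET)
}

#' Construct a cue-reliability profile
#'
#' Maps stimulus conditions to sensory noise magnitudes: `sigma_theta` by
#' spatial-frequency level (degrees) and `sigma_p` by envelope-size level
#' (task units; multiply by the position unit for degrees). Orientation
#' bandwidth is equated across envelope sizes, so `sigma_theta` depends only
#' on the sf level.
#'
#' @param sigma_theta Named numeric vector of orientation noise by sf level.
#' @param sigma_p Named numeric vector of position noise by size level.
#' @param provenance `"fixture"` or `"fitted"`.
#' @return A `reliability_profile`.
#' @export
reliability_profile <- function(sigma_theta, sigma_p, provenance = "fixture") {
  if (is.null(names(sigma_theta)) || is.null(names(sigma_p)))
    df_stop("sigma vectors must be named by condition level", "dynform_invalid_input")
  if (any(!is.finite(sigma_theta)) || any(sigma_theta <= 0) ||
      any(!is.finite(sigma_p)) || any(sigma_p <= 0))
    df_stop("all reliability sigmas must be positive and finite",
            "dynform_invalid_input")
  structure(list(sigma_theta = sigma_theta, sigma_p = sigma_p,
                 provenance = provenance),
            class = "reliability_profile")
}

#' @export
print.reliability_profile <- function(x, ...) {
  cat(sprintf("<reliability_profile> (%s)\n", x$provenance))
  cat("  sigma_theta (deg):",
      paste(sprintf("%s=%.3g", names(x$sigma_theta), x$sigma_theta), collapse = " "), "\n")
  cat("  sigma_p (task units):",
      paste(sprintf("%s=%.3g", names(x$sigma_p), x$sigma_p), collapse = " "), "\n")
  invisible(x)
}

# Look up condition reliabilities; classed error listing any gaps.
profile_lookup <- function(profile, sf_level, size_level) {
  missing <- c(
    if (!sf_level %in% names(profile$sigma_theta))
      sprintf("sigma_theta['%s']", sf_level),
    if (!size_level %in% names(profile$sigma_p))
      sprintf("sigma_p['%s']", size_level)
  )
  if (length(missing))
    df_stop(paste("reliability profile is missing:", paste(missing, collapse = ", ")),
            "dynform_missing_reliability")
  c(sigma_theta = unname(profile$sigma_theta[[sf_level]]),
    sigma_p = unname(profile$sigma_p[[size_level]]))
}

#' Build a reliability profile from psychometric fits
#'
#' Orientation fits (one per sf level, in degrees) supply `sigma_theta`;
#' position fits (one per envelope-size level, fitted in degrees) supply
#' `sigma_p` after conversion back to task units. Half-size conditions reuse
#' the bandwidth-matched orientation sigma by construction, since the profile
#' is keyed by sf *level* rather than carrier frequency.
#'
#' @param orientation_fits Named list of `psychometric_fit`s by sf level.
#' @param position_fits Named list of `psychometric_fit`s by size level.
#' @param grid Optional condition grid; coverage of its `sf_level` and
#'   `size_level` values is checked and gaps raise a missing-reliability
#'   error.
#' @param position_unit Degrees per position task unit (default 0.05).
#' @return A `reliability_profile` with provenance `"fitted"`.
#' @export
build_reliability_profile <- function(orientation_fits, position_fits,
                                      grid = NULL, position_unit = 0.05) {
  sig <- function(f) if (inherits(f, "psychometric_fit")) f$sigma else as.numeric(f)
  st <- vapply(orientation_fits, sig, numeric(1))
  sp <- vapply(position_fits, sig, numeric(1)) / position_unit
  if (!is.null(grid)) {
    gaps <- c(
      vapply(setdiff(unique(grid$sf_level), names(st)),
             function(l) sprintf("sigma_theta['%s']", l), character(1)),
      vapply(setdiff(unique(grid$size_level), names(sp)),
             function(l) sprintf("sigma_p['%s']", l), character(1))
    )
    if (length(gaps))
      df_stop(paste("reliability profile is missing:", paste(gaps, collapse = ", ")),
              "dynform_missing_reliability")
  }
  flagged <- c(
    names(orientation_fits)[vapply(orientation_fits, function(f)
      inherits(f, "psychometric_fit") && length(f$flags) > 0, logical(1))],
    names(position_fits)[vapply(position_fits, function(f)
      inherits(f, "psychometric_fit") && length(f$flags) > 0, logical(1))]
  )
  if (length(flagged))
    warning("flagged psychometric fits used in profile: ",
            paste(flagged, collapse = ", "))
  reliability_profile(st, sp, provenance = "fitted")
}

#' Reference observer reliabilities and fitted biases
#'
#' Loads the packaged table of per-observer low-level discrimination spreads
#' (orientation sigma by sf level, position sigma by envelope size, seven
#' observers) together with their fitted position-bias parameters.
#'
#' @return A data.frame with one row per observer.
#' @export
fixture_observers <- function() {
  rel <- utils::read.csv(system.file("extdata", "observer_reliability.csv",
                                     package = "dynform"), stringsAsFactors = FALSE)
  bias <- utils::read.csv(system.file("extdata", "observer_bias.csv",
                                      package = "dynform"), stringsAsFactors = FALSE)
  merge(rel, bias, by = "observer")
}

#' Reliability profile of a reference observer
#'
#' @param observer Observer index 1-7, or `"mean"` for the column means of
#'   the reference table.
#' @return A `reliability_profile` keyed by the standard sf levels
#'   (`low`, `med-low`, `med-high`, `high`) and size levels
#'   (`large`, `small`).
#' @examples
#' fixture_profile(3)
#' @export
fixture_profile <- function(observer = 1) {
  tab <- fixture_observers()
  row <- if (identical(observer, "mean")) {
    as.list(colMeans(tab[, -1]))
  } else {
    as.list(tab[tab$observer == observer, ])
  }
  if (!length(row$sf_low)) df_stop("unknown observer", "dynform_invalid_input")
  reliability_profile(
    sigma_theta = c("low" = row$sf_low, "med-low" = row$sf_med_low,
                    "med-high" = row$sf_med_high, "high" = row$sf_high),
    sigma_p = c("large" = row$size_large, "small" = row$size_small),
    provenance = "fixture"
  )
}
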
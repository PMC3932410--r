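# Synthetic behavioral and low-level datasets with known ground truth.
# These generators define the study conditions for validation: observers with
# known reliabilities, bias and sequence selectivity produce per-condition
# binary direction responses (full observer pipeline per trial) and low-level
# 2AFC datasets, each accompanied by a sidecar recording every generating
# parameter so recovery analyses never rely on hard-coded constants.

#' Specify a synthetic observer
#'
#' @param profile A `reliability_profile` (e.g. [fixture_profile()]).
#' @param alpha Generating position-bias parameter.
#' @param sigma_s Sequence-weighting SD (index units).
#' @param prior Direction prior.
#' @param position_unit Degrees per position task unit.
#' @param n_trials Trials per condition.
#' @param seed Master seed; the whole dataset is a deterministic function of
#'   the spec.
#' @param grid Condition grid (default the 48-cell incongruent grid).
#' @return A `synthetic_observer_spec`.
#' @export
synthetic_observer <- function(profile, alpha, sigma_s = sqrt(3.6), prior = 0.5,
                               position_unit = 0.05, n_trials = 100, seed = 1,
                               grid = condition_grid(2)) {
  params <- observer_params(alpha = alpha, sigma_s = sigma_s, prior = prior,
                            position_unit = position_unit, seed = seed)
  structure(list(profile = profile, params = params, n_trials = n_trials,
                 seed = seed, grid = grid),
            class = "synthetic_observer_spec")
}

#' @export
print.synthetic_observer_spec <- function(x, ...) {
  cat(sprintf("<synthetic_observer_spec> alpha=%g sigma_s=%.3f %d cells x %d trials seed=%d\n",
              x$params$alpha, x$params$sigma_s, nrow(x$grid), x$n_trials, x$seed))
  invisible(x)
}

#' Generate a full synthetic behavioral dataset
#'
#' Runs the complete observer pipeline trial by trial over the spec's
#' condition grid: fresh limited-lifetime stimulus, encoding noise at the
#' condition's reliabilities, two-module decision at the spec's alpha.
#' Identical specs produce byte-identical outputs.
#'
#' @param spec A [synthetic_observer()] spec.
#' @param dir Optional output directory; writes `responses.csv`,
#'   `summary.csv` and `truth.json` (the ground-truth sidecar).
#' @return List with `responses` (one row per trial), `summary`
#'   (per-condition proportions, suitable for [fit_alpha()]), and `truth`
#'   (every generating parameter).
#' @export
generate_behavioral_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_observer_spec"))
  grid <- spec$grid
  cache <- new.env(parent = emptyenv())
  responses <- vector("list", nrow(grid))
  summary_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cond <- grid[i, ]
    cell <- simulate_cell(cond, spec$profile, spec$params, spec$n_trials,
                          derive_seed(spec$seed, 7000L + i), cache = cache)
    pc <- cell_decide(cell, spec$params$alpha, spec$params)
    hyp <- cell$hyp
    truth_lab <- ifelse(cell$truth, hyp[1], hyp[2])
    choice_lab <- ifelse(pc, truth_lab, vapply(truth_lab, opposite_direction, character(1)))
    responses[[i]] <- data.frame(
      cell = cond$cell %||% i, trial = seq_len(spec$n_trials),
      kind = cond$kind, orientation_condition = cond$orientation_condition,
      sf_level = cond$sf_level, n_elements = cond$n_elements,
      size_level = cond$size_level,
      truth = truth_lab, choice = choice_lab,
      position_consistent = as.integer(pc),
      stringsAsFactors = FALSE
    )
    p <- mean(pc)
    summary_rows[[i]] <- cbind(cond, data.frame(
      n_trials = spec$n_trials, prop_position_consistent = p,
      se = sqrt(p * (1 - p) / spec$n_trials)))
  }
  responses <- do.call(rbind, responses)
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  truth <- list(
    alpha = spec$params$alpha,
    sigma_s = spec$params$sigma_s,
    prior = spec$params$prior,
    position_unit = spec$params$position_unit,
    sigma_theta = as.list(spec$profile$sigma_theta),
    sigma_p = as.list(spec$profile$sigma_p),
    profile_provenance = spec$profile$provenance,
    n_trials = spec$n_trials,
    seed = spec$seed,
    n_conditions = nrow(grid)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(responses, file.path(dir, "responses.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(responses = responses, summary = summary, truth = truth)
}

#' Generate the low-level discrimination suite for a reliability profile
#'
#' One orientation 2AFC dataset per spatial-frequency level (noise
#' `sigma_theta` in degrees) and one position 2AFC dataset per envelope-size
#' level (noise `sigma_p` converted to degrees via the position unit, offsets
#' within the +/-0.67 deg task range).
#'
#' @param profile A `reliability_profile` (ground truth).
#' @param n_per_level Trials per offset level (default 24).
#' @param seed Master seed.
#' @param position_unit Degrees per position task unit.
#' @return List with named lists `orientation` and `position` of
#'   `psychometric_dataset`s.
#' @export
generate_lowlevel_suite <- function(profile, n_per_level = 24, seed = 1,
                                    position_unit = 0.05) {
  ori <- lapply(seq_along(profile$sigma_theta), function(i)
    simulate_orientation_task(profile$sigma_theta[[i]], NULL, n_per_level,
                              seed = derive_seed(seed, 100L + i)))
  names(ori) <- names(profile$sigma_theta)
  pos <- lapply(seq_along(profile$sigma_p), function(i)
    simulate_position_task(profile$sigma_p[[i]] * position_unit, NULL,
                           n_per_level, seed = derive_seed(seed, 200L + i)))
  names(pos) <- names(profile$sigma_p)
  list(orientation = ori, position = pos)
}

#' Fit a low-level suite and rebuild the reliability profile
#'
#' Closed-loop companion of [generate_lowlevel_suite()]: fits every dataset
#' with [fit_cumulative_gaussian()] and assembles the fitted profile.
#'
#' @param suite Output of [generate_lowlevel_suite()].
#' @param position_unit Degrees per position task unit.
#' @return A fitted `reliability_profile`.
#' @export
profile_from_suite <- function(suite, position_unit = 0.05) {
  build_reliability_profile(
    orientation_fits = lapply(suite$orientation, fit_cumulative_gaussian),
    position_fits = lapply(suite$position, fit_cumulative_gaussian),
    position_unit = position_unit
  )
}

#' Default synthetic cohort
#'
#' Seven synthetic observers mirroring the reference observers: each takes a
#' fixture reliability profile and that observer's fitted bias, so the
#' synthetic study is shaped like the behavioral one.
#'
#' @param n_trials Trials per condition per observer.
#' @param seed Master seed; observer i uses a derived seed.
#' @return List of `synthetic_observer_spec`s.
#' @export
synthetic_cohort <- function(n_trials = 100, seed = 1) {
  tab <- fixture_observers()
  lapply(seq_len(nrow(tab)), function(i)
    synthetic_observer(fixture_profile(tab$observer[i]), alpha = tab$alpha[i],
                       n_trials = n_trials,
                       seed = derive_seed(seed, 500L + i)))
}
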
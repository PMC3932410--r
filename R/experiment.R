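# Condition grids, batched observer simulation, and least-squares fitting of
# the position-bias parameter alpha to behavioral proportions.
#
# The key computational device: for a fixed seed, a condition's stimuli and
# the per-frame module evidence they generate do not depend on alpha — alpha
# enters only through the integration weights. fit_alpha() therefore
# simulates each condition once, caches the compact per-frame evidence, and
# evaluates the least-squares objective deterministically over the cache
# (common random numbers), which makes the stochastic objective smooth enough
# for least squares.

SF_LEVELS_EXP2 <- c("low", "med-low", "med-high", "high")
SF_CPD_LARGE <- c("low" = 0.2, "med-low" = 0.4, "med-high" = 0.8, "high" = 1.6)
SF_LEVELS_EXP1 <- c("low", "med", "high")
SF_CPD_EXP1 <- c("low" = 0.25, "med" = 0.75, "high" = 1.25)
ENVELOPE_SD <- c("large" = 0.84, "small" = 0.42)
N_ELEMENTS <- list(walker = c(2L, 4L, 6L), square = c(4L, 6L, 8L))

#' Experimental condition grid
#'
#' Experiment 2 style: 4 spatial frequencies x 3 element counts x 2 envelope
#' sizes x 2 stimulus kinds = 48 cells, all with incongruent cues (carrier
#' frequencies are doubled for the half-size envelope so orientation
#' bandwidth, hence sigma_theta, is equated across sizes). Experiment 1
#' style: 3 orientation conditions x 3 spatial frequencies x 3 element counts
#' = 27 cells for one stimulus kind at the large envelope.
#'
#' @param experiment 1 or 2.
#' @param kind For experiment 1, the stimulus kind (`"walker"` or
#'   `"square"`); ignored for experiment 2, which crosses both.
#' @return A data.frame with one row per condition (`cell`, `kind`,
#'   `orientation_condition`, `sf_level`, `sf_cyc_deg`, `n_elements`,
#'   `size_level`, `envelope_sd`).
#' @examples
#' nrow(condition_grid(2))  # 48
#' @export
condition_grid <- function(experiment = 2, kind = c("walker", "square")) {
  if (experiment == 2) {
    g <- expand.grid(elem_idx = 1:3, sf_level = SF_LEVELS_EXP2,
                     size_level = names(ENVELOPE_SD), kind = c("walker", "square"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$orientation_condition <- "incongruent"
    g$sf_cyc_deg <- SF_CPD_LARGE[g$sf_level] *
      ifelse(g$size_level == "small", 2, 1)
  } else if (experiment == 1) {
    kind <- match.arg(kind)
    g <- expand.grid(elem_idx = 1:3, sf_level = SF_LEVELS_EXP1,
                     orientation_condition = c("congruent", "incongruent", "random"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$kind <- kind
    g$size_level <- "large"
    g$sf_cyc_deg <- SF_CPD_EXP1[g$sf_level]
  } else df_stop("experiment must be 1 or 2", "dynform_invalid_input")
  g$envelope_sd <- ENVELOPE_SD[g$size_level]
  g$n_elements <- mapply(function(k, i) N_ELEMENTS[[k]][i], g$kind, g$elem_idx)
  g$elem_idx <- NULL
  g <- g[, c("kind", "orientation_condition", "sf_level", "sf_cyc_deg",
             "n_elements", "size_level", "envelope_sd")]
  g$cell <- seq_len(nrow(g))
  rownames(g) <- NULL
  g
}

# Shared stimulus machinery (sequences + template banks), built once per kind
# and reused across conditions.
stimulus_machinery <- function(kind, K = 8, cache = NULL, n_frames = 60) {
  key <- paste(kind, K, n_frames, sep = "_")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  m <- if (kind == "walker") {
    seq1 <- make_walker_sequence(n_frames = n_frames, direction = "left")
    seq2 <- opposite_sequence(seq1)
    list(kind = kind,
         seqs = list(left = seq1, right = seq2),
         banks = list(left = build_template_bank(seq1, K),
                      right = build_template_bank(seq2, K)))
  } else {
    seq1 <- make_square_sequence(n_frames = n_frames, direction = "cw")
    seq2 <- opposite_sequence(seq1)
    list(kind = kind,
         seqs = list(cw = seq1, ccw = seq2),
         banks = list(shared = build_template_bank(seq1, K)))
  }
  if (!is.null(cache)) cache[[key]] <- m
  m
}

# Simulate one condition's trials and reduce them to the compact evidence
# cache that decisions (at any alpha) can be computed from.
simulate_cell <- function(cond, profile, params, n_trials, seed,
                          machinery = NULL, cache = NULL) {
  if (n_trials < 1) df_stop("n_trials must be >= 1", "dynform_invalid_input")
  kind <- cond$kind
  m <- machinery %||% stimulus_machinery(kind, cache = cache)
  rel <- profile_lookup(profile, cond$sf_level, cond$size_level)
  sigma_theta <- rel[["sigma_theta"]]
  sigma_p_raw <- rel[["sigma_p"]]
  sigma_p_deg <- sigma_p_raw * params$position_unit
  T <- m$seqs[[1]]$n_frames
  K <- m$banks[[1]]$K

  truth <- with_seed(derive_seed(seed, .STREAMS[["truth"]]),
                     stats::runif(n_trials) < 0.5)  # TRUE = first hypothesis
  coin <- with_seed(derive_seed(seed, .STREAMS[["decision"]]),
                    stats::runif(n_trials))

  cell <- list(kind = kind, T = T, K = K, n = n_trials, truth = truth,
               coin = coin, sigma_theta = sigma_theta, sigma_p = sigma_p_raw,
               hyp = names(m$seqs))
  if (kind == "walker") {
    cell$s1 <- cell$s2 <- cell$o1 <- cell$o2 <- matrix(0, T, n_trials)
  } else {
    cell$Pp <- cell$Pt <- matrix(0, K, T * n_trials)
  }

  for (b in 1:2) {
    ids <- if (b == 1) which(truth) else which(!truth)
    if (!length(ids)) next
    seq_pos <- m$seqs[[b]]
    seq_opp <- m$seqs[[3 - b]]
    seeds <- stream_seeds(derive_seed(seed, b))
    el <- sample_stimulus_batch(seq_pos, seq_opp, cond$n_elements,
                                cond$orientation_condition, length(ids), seeds)
    nz <- with_seed(seeds[["noise"]],
                    list(dx = stats::rnorm(nrow(el)), dy = stats::rnorm(nrow(el)),
                         dth = stats::rnorm(nrow(el))))
    el$x_obs <- el$x + sigma_p_deg * nz$dx
    el$y_obs <- el$y + sigma_p_deg * nz$dy
    el$theta_obs <- (el$theta + sigma_theta * nz$dth) %% 180

    cols <- as.vector(outer(seq_len(T), (ids - 1L) * T, `+`))
    if (kind == "walker") {
      for (h in 1:2) {
        bank <- m$banks[[h]]
        v <- bank_variances(bank, sigma_p_deg, sigma_theta)
        sc <- kernel_scores(el$x_obs, el$y_obs, el$theta_obs, el$frame, el$trial,
                            T, length(ids), bank, v$var_p, v$var_t)
        s <- matrix(col_max(sc$pos), T, length(ids))
        o <- matrix(col_max(sc$ori), T, length(ids))
        if (h == 1) { cell$s1[, ids] <- s; cell$o1[, ids] <- o }
        else { cell$s2[, ids] <- s; cell$o2[, ids] <- o }
      }
    } else {
      bank <- m$banks$shared
      v <- bank_variances(bank, sigma_p_deg, sigma_theta)
      sc <- kernel_scores(el$x_obs, el$y_obs, el$theta_obs, el$frame, el$trial,
                          T, length(ids), bank, v$var_p, v$var_t)
      cell$Pp[, cols] <- col_softmax(sc$pos)
      cell$Pt[, cols] <- col_softmax(sc$ori)
    }
  }
  cell
}

# Position-consistent decisions for every cached trial at a given alpha.
cell_decide <- function(cell, alpha, params) {
  w <- integration_weights(list(alpha = alpha, sigma_p = cell$sigma_p,
                                sigma_theta = cell$sigma_theta))
  dec <- if (cell$kind == "walker") {
    walker_decision_core(cell$s1, cell$s2, cell$o1, cell$o2, w,
                         params$prior, cell$coin)
  } else {
    square_decision_core(cell$Pp, cell$Pt, cell$K, cell$T, cell$n, w,
                         params$sigma_s, cell$coin)
  }
  dec$first == cell$truth
}

#' Run the observer over one condition
#'
#' Builds `n_trials` fresh limited-lifetime stimuli (balanced random truth
#' directions), encodes them with the condition's reliabilities, runs the
#' two-module observer, and returns the proportion of position-consistent
#' responses.
#'
#' @param cond One row of a [condition_grid()] (or a list with the same
#'   fields).
#' @param observer An [observer_params()] (alpha, sigma_s, prior,
#'   position_unit).
#' @param profile A `reliability_profile` covering the condition.
#' @param n_trials Number of simulated trials (>= 1).
#' @param seed Simulation seed.
#' @return A one-row data.frame (`condition_result`): the condition columns
#'   plus `n_trials`, `prop_position_consistent`, and binomial `se`.
#' @export
run_condition <- function(cond, observer, profile, n_trials = 100,
                          seed = observer$seed %||% 1) {
  cell <- simulate_cell(cond, profile, observer, n_trials, seed)
  pc <- cell_decide(cell, observer$alpha, observer)
  p <- mean(pc)
  out <- data.frame(kind = cond$kind,
                    orientation_condition = cond$orientation_condition,
                    sf_level = cond$sf_level, n_elements = cond$n_elements,
                    size_level = cond$size_level, n_trials = n_trials,
                    prop_position_consistent = p,
                    se = sqrt(p * (1 - p) / n_trials),
                    stringsAsFactors = FALSE)
  class(out) <- c("condition_result", "data.frame")
  out
}

#' Run the observer over a whole condition grid
#'
#' @param grid A [condition_grid()].
#' @param observer An [observer_params()].
#' @param profile A `reliability_profile`.
#' @param n_trials Trials per condition.
#' @param seed Master seed; each cell derives its own.
#' @return A data.frame of per-condition results (`condition_results`).
#' @export
run_grid <- function(grid, observer, profile, n_trials = 100,
                     seed = observer$seed %||% 1) {
  cache <- new.env(parent = emptyenv())
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cond <- grid[i, ]
    cell <- simulate_cell(cond, profile, observer, n_trials,
                          derive_seed(seed, 7000L + i), cache = cache)
    pc <- cell_decide(cell, observer$alpha, observer)
    p <- mean(pc)
    cbind(cond, data.frame(n_trials = n_trials, prop_position_consistent = p,
                           se = sqrt(p * (1 - p) / n_trials)))
  }))
  rownames(out) <- NULL
  class(out) <- c("condition_results", "data.frame")
  out
}

#' Correlation and RMS error between model and observed proportions
#'
#' @param model,observed Equal-length numeric vectors of proportions (>= 3
#'   cells).
#' @return List with `r` (Pearson correlation; `NA` with a warning if either
#'   vector has zero variance) and `rms` (root-mean-squared discrepancy).
#' @export
fit_metrics <- function(model, observed) {
  if (length(model) != length(observed) || length(model) < 3)
    df_stop("need equal-length vectors with at least 3 cells", "dynform_invalid_input")
  r <- if (stats::sd(model) == 0 || stats::sd(observed) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else stats::cor(model, observed)
  list(r = r, rms = sqrt(mean((model - observed)^2)))
}

#' Fit the position-bias parameter alpha to behavioral proportions
#'
#' Least-squares fit of the model's single free parameter: the argmin over
#' alpha of the summed squared discrepancy between model and observed
#' position-consistent proportions across conditions. Model proportions are
#' simulated once per condition at a fixed derived seed and cached; alpha is
#' then searched on a log-spaced grid with local refinement over the cached
#' evidence, so the objective is deterministic (common random numbers).
#'
#' @param observed Data.frame of observed per-condition proportions: the
#'   condition columns of a [condition_grid()] plus
#'   `prop_position_consistent` (e.g. from [run_grid()] or the `summary`
#'   element of [generate_behavioral_dataset()]).
#' @param observer An [observer_params()]; its `alpha` is ignored.
#' @param profile A `reliability_profile` covering all conditions.
#' @param n_sim_trials Simulated trials per condition per objective
#'   evaluation (default 400).
#' @param alpha_grid Coarse search grid (default `2^seq(-2, 5, 0.5)`); a
#'   single-point grid skips the search and evaluates that point.
#' @param seed Simulation seed for the evidence cache.
#' @param refine Refine around the best grid point with `optimize()`.
#' @param keep_cache Keep the evidence cache in the returned object so
#'   `predict(fit, alpha = ...)` can re-evaluate at new alpha values
#'   (memory-heavy; default `FALSE`).
#' @return An object of class `alpha_fit` with components `alpha`, `rms`,
#'   `grid` (alpha/rms curve), `fitted` (per-condition observed and model
#'   proportions at the fitted alpha), and the call metadata. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' prof <- fixture_profile(3)
#' obs <- observer_params(alpha = 6)
#' grid <- condition_grid(2)[1:6, ]
#' dat <- run_grid(grid, obs, prof, n_trials = 50, seed = 2)
#' fit <- fit_alpha(dat, obs, prof, n_sim_trials = 50, seed = 3)
#' coef(fit)
#' }
#' @export
fit_alpha <- function(observed, observer, profile, n_sim_trials = 400,
                      alpha_grid = 2^seq(-2, 5, by = 0.5), seed = 1,
                      refine = TRUE, keep_cache = FALSE) {
  need <- c("kind", "orientation_condition", "sf_level", "n_elements",
            "size_level", "prop_position_consistent")
  if (!all(need %in% names(observed)))
    df_stop(paste("observed must contain columns:", paste(need, collapse = ", ")),
            "dynform_invalid_input")
  if (any(!is.finite(observed$prop_position_consistent)))
    df_stop("observed proportions must be finite", "dynform_optimizer_failure")

  mach_cache <- new.env(parent = emptyenv())
  cells <- lapply(seq_len(nrow(observed)), function(i) {
    simulate_cell(observed[i, ], profile, observer, n_sim_trials,
                  derive_seed(seed, 3000L + i), cache = mach_cache)
  })
  p_obs <- observed$prop_position_consistent

  model_props <- function(alpha)
    vapply(cells, function(cell) mean(cell_decide(cell, alpha, observer)),
           numeric(1))
  objective <- function(alpha) {
    v <- sum((model_props(alpha) - p_obs)^2)
    if (!is.finite(v))
      df_stop("non-finite least-squares objective", "dynform_optimizer_failure")
    v
  }

  sse_grid <- vapply(alpha_grid, objective, numeric(1))
  best <- which.min(sse_grid)
  alpha_hat <- alpha_grid[best]
  sse_hat <- sse_grid[best]
  if (refine && length(alpha_grid) > 1) {
    lo <- log2(alpha_grid[max(1, best - 1)])
    hi <- log2(alpha_grid[min(length(alpha_grid), best + 1)])
    opt <- stats::optimize(function(l) objective(2^l), c(lo, hi))
    if (opt$objective <= sse_hat) {
      alpha_hat <- 2^opt$minimum
      sse_hat <- opt$objective
    }
  }

  p_hat <- model_props(alpha_hat)
  fitted_tab <- cbind(
    observed[, intersect(names(observed),
                         c("cell", "kind", "orientation_condition", "sf_level",
                           "sf_cyc_deg", "n_elements", "size_level")),
             drop = FALSE],
    data.frame(observed = p_obs, predicted = p_hat)
  )
  structure(list(
    alpha = alpha_hat,
    rms = sqrt(sse_hat / length(p_obs)),
    grid = data.frame(alpha = alpha_grid, rms = sqrt(sse_grid / length(p_obs))),
    fitted = fitted_tab,
    n_conditions = length(p_obs),
    n_sim_trials = n_sim_trials,
    observer = observer,
    profile = profile,
    seed = seed,
    cache = if (keep_cache) cells else NULL,
    call = match.call()
  ), class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat("Position-bias fit (two-module Bayesian observer)\n")
  cat(sprintf("  alpha = %.4g   RMS = %.4f   (%d conditions, %d sim trials/cell)\n",
              x$alpha, x$rms, x$n_conditions, x$n_sim_trials))
  invisible(x)
}

#' @export
coef.alpha_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
fitted.alpha_fit <- function(object, ...) object$fitted$predicted

#' @export
residuals.alpha_fit <- function(object, ...)
  object$fitted$observed - object$fitted$predicted

#' @export
predict.alpha_fit <- function(object, alpha = NULL, ...) {
  if (is.null(alpha) || isTRUE(all.equal(alpha, object$alpha)))
    return(object$fitted$predicted)
  if (is.null(object$cache))
    df_stop("refit with keep_cache = TRUE to predict at a new alpha",
            "dynform_invalid_input")
  vapply(object$cache,
         function(cell) mean(cell_decide(cell, alpha, object$observer)),
         numeric(1))
}

#' @export
summary.alpha_fit <- function(object, ...) {
  m <- fit_metrics(object$fitted$predicted, object$fitted$observed)
  structure(list(fit = object, r = m$r, rms = m$rms,
                 by_kind = tapply(object$fitted$observed - object$fitted$predicted,
                                  object$fitted$kind,
                                  function(e) sqrt(mean(e^2)))),
            class = "summary.alpha_fit")
}

#' @export
print.summary.alpha_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  model-observed correlation r = %.3f\n", x$r))
  cat("  per-kind RMS:",
      paste(sprintf("%s=%.4f", names(x$by_kind), x$by_kind), collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.alpha_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$grid$alpha, x$grid$rms, log = "x", type = "b", pch = 16,
                 xlab = expression(alpha), ylab = "RMS",
                 main = "Least-squares objective")
  graphics::abline(v = x$alpha, lty = 2)
  graphics::plot(x$fitted$observed, x$fitted$predicted,
                 xlim = c(0, 1), ylim = c(0, 1),
                 pch = ifelse(x$fitted$kind == "walker", 16, 1),
                 xlab = "observed proportion", ylab = "model proportion",
                 main = sprintf("alpha = %.3g, RMS = %.3f", x$alpha, x$rms))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
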
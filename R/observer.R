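# Two-module Bayesian template-matching observer.
#
# The position module matches observed element positions to each hypothesis'
# probabilistic templates (Gaussian likelihood of the element-to-template
# distances); the orientation module matches observed orientations against
# the orientation of the positionally nearest template segment. Within each
# module and hypothesis the best template is selected per frame (MAP), the
# two hypotheses' MAP scores are turned into a posterior, and the two module
# posteriors are combined by Bayesian model averaging with weights built from
# cue reliabilities and a single position-bias parameter alpha. Walker
# decisions sum integrated posteriors over frames; square decisions weight
# each frame transition by how consistent the MAP template index step is with
# the hypothesised rotation order (Gaussian sequence weighting).

#' Observer parameter bundle
#'
#' @param alpha Position-module prior bias, the ratio of module prior
#'   probabilities (>= 0; `Inf` gives a pure position observer). This is the
#'   model's single free parameter and absorbs the unit mismatch between
#'   position reliabilities (task units) and orientation reliabilities
#'   (degrees).
#' @param sigma_p Position cue reliability in task units (optional here;
#'   usually supplied per condition via a reliability profile).
#' @param sigma_theta Orientation cue reliability in degrees.
#' @param sigma_s Sequence-weighting SD in template-index units; the default
#'   `sqrt(3.6)` is the group-level value for the rotating-square task.
#' @param prior Prior probability of the first hypothesis (leftward /
#'   matching the bank order), default 0.5.
#' @param position_unit Degrees of visual angle per position-reliability task
#'   unit; converts `sigma_p` to degrees for stimulus encoding and template
#'   matching (default 0.05 deg/unit, approximately one display pixel).
#' @param seed Seed for the observer's decision tie-break stream.
#' @return An `observer_params` object.
#' @export
observer_params <- function(alpha, sigma_p = NULL, sigma_theta = NULL,
                            sigma_s = sqrt(3.6), prior = 0.5,
                            position_unit = 0.05, seed = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha < 0)
    df_stop("alpha must be a single number >= 0 (Inf allowed)", "dynform_invalid_params")
  if (!is.finite(sigma_s) || sigma_s <= 0)
    df_stop("sigma_s must be > 0", "dynform_invalid_params")
  if (!is.finite(prior) || prior < 0 || prior > 1)
    df_stop("prior must be in [0, 1]", "dynform_invalid_params")
  if (!is.finite(position_unit) || position_unit <= 0)
    df_stop("position_unit must be > 0", "dynform_invalid_params")
  structure(list(alpha = alpha, sigma_p = sigma_p, sigma_theta = sigma_theta,
                 sigma_s = sigma_s, prior = prior,
                 position_unit = position_unit, seed = seed),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> alpha=%g sigma_s=%.3f prior=%.2f position_unit=%.3f\n",
              x$alpha, x$sigma_s, x$prior, x$position_unit))
  if (!is.null(x$sigma_p))
    cat(sprintf("  sigma_p=%g (task units), sigma_theta=%g deg\n",
                x$sigma_p, x$sigma_theta))
  invisible(x)
}

#' Module integration weights
#'
#' Inverse-variance (precision) weighting of the position and orientation
#' modules, with the bias alpha multiplying the position precision:
#' `w_p = alpha * sigma_p^-2 / (alpha * sigma_p^-2 + sigma_theta^-2)`.
#' Reliabilities enter in their native task units; alpha absorbs the scale.
#'
#' @param params An `observer_params` with `sigma_p` and `sigma_theta` set
#'   (or a list with fields `alpha`, `sigma_p`, `sigma_theta`).
#' @return Named numeric `c(w_p = , w_theta = )`, summing to 1.
#' @examples
#' integration_weights(observer_params(1, sigma_p = 2, sigma_theta = 2))
#' @export
integration_weights <- function(params) {
  sp <- params$sigma_p
  st <- params$sigma_theta
  a <- params$alpha
  if (is.null(sp) || is.null(st) || !is.finite(sp) || !is.finite(st) ||
      sp <= 0 || st <= 0)
    df_stop("sigma_p and sigma_theta must be positive and finite",
            "dynform_invalid_params")
  if (is.infinite(a)) return(c(w_p = 1, w_theta = 0))
  prec_p <- a / sp^2
  prec_t <- 1 / st^2
  if (prec_p + prec_t <= 0)
    df_stop("both module precisions are zero", "dynform_invalid_params")
  w <- prec_p / (prec_p + prec_t)
  c(w_p = w, w_theta = 1 - w)
}

# Combined matching variances (degrees^2) for a bank under given sensory noise.
bank_variances <- function(bank, sigma_p_deg, sigma_theta) {
  list(var_p = bank$sigma_tp^2 + sigma_p_deg^2,
       var_t = bank$sigma_ttheta^2 + sigma_theta^2)
}

kernel_scores <- function(px, py, ptheta, frame, trial, n_frames, n_trials,
                          bank, var_p, var_t) {
  bank_frame_scores(as.numeric(px), as.numeric(py), as.numeric(ptheta),
                    as.integer(frame), as.integer(trial),
                    as.integer(n_frames), as.integer(n_trials),
                    bank$seg$x0, bank$seg$y0, bank$seg$x1, bank$seg$y1,
                    bank$seg$theta, as.integer(bank$seg$template),
                    bank$K, var_p, var_t)
}

#' Position-module log-scores for one frame
#'
#' For each template k the score is the summed Gaussian log-density of the
#' minimum point-to-segment distances from every observed element to the
#' template's segments, with variance `sigma_Tp^2 + sigma_p^2`.
#'
#' @param observed_pos Two-column matrix (x, y) of observed element positions
#'   in degrees.
#' @param bank A `template_bank`.
#' @param sigma_p Position sensory noise SD in degrees.
#' @return List with `log_score` (length-K vector) and `map` (1-based index
#'   of the best template).
#' @export
position_frame_score <- function(observed_pos, bank, sigma_p) {
  observed_pos <- as.matrix(observed_pos)
  if (nrow(observed_pos) == 0)
    df_stop("no observed elements", "dynform_invalid_input")
  v <- bank_variances(bank, sigma_p, 0)
  sc <- kernel_scores(observed_pos[, 1], observed_pos[, 2],
                      rep(0, nrow(observed_pos)),
                      rep(1L, nrow(observed_pos)), rep(1L, nrow(observed_pos)),
                      1L, 1L, bank, v$var_p, max(v$var_t, 1))
  ls <- as.numeric(sc$pos)
  list(log_score = ls, map = which.max(ls))
}

#' Orientation-module log-scores for one frame
#'
#' Each element is associated to the positionally nearest segment of each
#' template; the score is the summed Gaussian log-density of the folded
#' circular differences between observed and template orientations, with
#' variance `sigma_Ttheta^2 + sigma_theta^2`. The module is therefore
#' sensitive to both the orientation and the relative position of elements.
#'
#' @param observed_pos Two-column matrix of observed positions (degrees).
#' @param observed_theta Observed orientations (degrees), same length.
#' @param bank A `template_bank`.
#' @param sigma_theta Orientation sensory noise SD in degrees.
#' @return List with `log_score` (length-K) and `map`.
#' @export
orientation_frame_score <- function(observed_pos, observed_theta, bank, sigma_theta) {
  observed_pos <- as.matrix(observed_pos)
  if (nrow(observed_pos) == 0)
    df_stop("no observed elements", "dynform_invalid_input")
  if (length(observed_theta) != nrow(observed_pos))
    df_stop("positions and orientations must have the same length",
            "dynform_invalid_input")
  v <- bank_variances(bank, 0, sigma_theta)
  sc <- kernel_scores(observed_pos[, 1], observed_pos[, 2], observed_theta,
                      rep(1L, nrow(observed_pos)), rep(1L, nrow(observed_pos)),
                      1L, 1L, bank, max(v$var_p, 1), v$var_t)
  ls <- as.numeric(sc$ori)
  list(log_score = ls, map = which.max(ls))
}

#' Posterior over two hypotheses from per-template log-scores
#'
#' Uses the MAP template within each hypothesis:
#' `P_A = prior * exp(s*_A) / (prior * exp(s*_A) + (1 - prior) * exp(s*_B))`,
#' computed stably in the log domain.
#'
#' @param scores_a,scores_b Per-template log-score vectors for the two
#'   hypotheses.
#' @param prior Prior probability of hypothesis A.
#' @return Numeric `c(P_A, P_B)` summing to 1.
#' @examples
#' module_posterior(log(9), 0, prior = 0.5)  # c(0.9, 0.1)
#' @export
module_posterior <- function(scores_a, scores_b, prior = 0.5) {
  if (!length(scores_a) || !length(scores_b))
    df_stop("score vectors must be non-empty", "dynform_invalid_input")
  if (prior <= 0) return(c(0, 1))
  if (prior >= 1) return(c(1, 0))
  pa <- stats::plogis(max(scores_a) - max(scores_b) + stats::qlogis(prior))
  c(pa, 1 - pa)
}

#' Integrate the two module posteriors
#'
#' Bayesian model averaging: `P_int = w_p * P_p + w_theta * P_theta`.
#'
#' @param p_pos,p_theta Length-2 posterior vectors (each summing to 1).
#' @param weights Weights from [integration_weights()].
#' @return Length-2 integrated posterior.
#' @export
integrate_frame <- function(p_pos, p_theta, weights) {
  weights[[1]] * p_pos + weights[[2]] * p_theta
}

#' Frame-by-frame module evidence for a whole trial
#'
#' Computes per-frame, per-template log-scores of both modules against one or
#' more template banks in a single pass.
#'
#' @param trial A `stimulus_trial` (after [encode_with_noise()] if noise is
#'   wanted).
#' @param banks A `template_bank` or named list of banks (one per hypothesis).
#' @param sigma_p Position sensory noise SD in **degrees**.
#' @param sigma_theta Orientation sensory noise SD in degrees.
#' @return A named list (one entry per bank) of lists with `pos` and `ori`
#'   K-by-T log-score matrices.
#' @export
trial_evidence <- function(trial, banks, sigma_p, sigma_theta) {
  if (inherits(banks, "template_bank")) {
    banks <- stats::setNames(list(banks), banks$hypothesis)
  }
  e <- trial$elements
  out <- lapply(banks, function(b) {
    v <- bank_variances(b, sigma_p, sigma_theta)
    kernel_scores(e$x_obs, e$y_obs, e$theta_obs, e$frame, rep(1L, nrow(e)),
                  trial$n_frames, 1L, b, v$var_p, v$var_t)
  })
  structure(out, class = "trial_evidence")
}

# column maxima of a K x n matrix
col_max <- function(m) {
  tm <- t(m)
  tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
}

# column-wise softmax of a K x n log-score matrix
col_softmax <- function(m) {
  mx <- col_max(m)
  em <- exp(sweep(m, 2, mx))
  sweep(em, 2, colSums(em), `/`)
}

# Shared decision arithmetic -------------------------------------------------

# Walker-style decision from per-frame MAP log-scores of the two hypotheses.
# s1/s2, o1/o2: T x n matrices (position / orientation module, hypothesis 1/2).
# Returns list(first = logical n, agg1, agg2, p_int = T x n).
walker_decision_core <- function(s1, s2, o1, o2, w, prior, coin) {
  T <- nrow(s1)
  lo <- stats::qlogis(prior)
  p_p <- stats::plogis(s1 - s2 + lo)
  p_t <- stats::plogis(o1 - o2 + lo)
  if (prior <= 0) { p_p[] <- 0; p_t[] <- 0 }
  if (prior >= 1) { p_p[] <- 1; p_t[] <- 1 }
  p_int <- w[[1]] * p_p + w[[2]] * p_t
  agg1 <- colSums(p_int)
  agg2 <- T - agg1
  first <- agg1 > agg2
  tie <- agg1 == agg2
  if (any(tie)) first[tie] <- coin[tie] < 0.5
  list(first = first, agg1 = agg1, agg2 = agg2, p_int = p_int,
       p_pos = p_p, p_theta = p_t)
}

# signed cyclic displacement folded into (-K/2, K/2]
wrap_steps <- function(x, K) {
  m <- x %% K
  ifelse(m > K / 2, m - K, m)
}

# Square-style decision from per-template integrated posteriors.
# Pp, Pt: K x (T*n) template-probability matrices. Ascending index order
# corresponds to hypothesis 1 (the bank's source direction). The sequence
# weight for each transition multiplies the mean of the two flanking frames'
# max integrated posteriors, which makes time reversal swap the aggregates
# exactly.
square_decision_core <- function(Pp, Pt, K, T, n, w, sigma_s, coin) {
  I <- w[[1]] * Pp + w[[2]] * Pt
  idx <- max.col(t(I), ties.method = "first")
  pmx <- I[cbind(idx, seq_along(idx))]
  idx <- matrix(idx, nrow = T, ncol = n)
  pmx <- matrix(pmx, nrow = T, ncol = n)
  d <- idx[-1, , drop = FALSE] - idx[-T, , drop = FALSE]
  mid <- (pmx[-1, , drop = FALSE] + pmx[-T, , drop = FALSE]) / 2
  d_asc <- wrap_steps(d - 1, K)
  d_desc <- wrap_steps(d + 1, K)
  g <- -1 / (2 * sigma_s^2)
  agg1 <- colSums(exp(g * d_asc^2) * mid)
  agg2 <- colSums(exp(g * d_desc^2) * mid)
  first <- agg1 > agg2
  tie <- agg1 == agg2
  if (any(tie)) first[tie] <- coin[tie] < 0.5
  list(first = first, agg1 = agg1, agg2 = agg2, index = idx, steps = d)
}

decision_coin <- function(trial_seed, params) {
  with_seed(derive_seed(trial_seed %||% 0L, params$seed %||% 0L,
                        .STREAMS[["decision"]]),
            stats::runif(1))
}

#' Decide the walking direction of a walker trial
#'
#' Per frame, both modules' posteriors over the two direction hypotheses are
#' computed from the MAP template within each bank, integrated with the
#' reliability weights, and the integrated posteriors are summed across
#' frames; the direction with the greater aggregate wins (exact ties are
#' broken by a fair coin from the observer's decision stream).
#'
#' @param trial A `stimulus_trial` of kind `"walker"`.
#' @param banks Named list of two `template_bank`s (e.g. left and right).
#' @param params An `observer_params` with condition reliabilities
#'   `sigma_p` (task units) and `sigma_theta` (degrees) set.
#' @param evidence Optional precomputed [trial_evidence()] for these banks.
#' @return List with `choice`, `aggregate` (named), `weights`, and per-frame
#'   posteriors in `frames`.
#' @export
decide_walker <- function(trial, banks, params, evidence = NULL) {
  if (trial$n_frames < 1) df_stop("trial has no frames", "dynform_invalid_input")
  stopifnot(length(banks) == 2)
  w <- integration_weights(params)
  if (is.null(evidence))
    evidence <- trial_evidence(trial, banks,
                               params$sigma_p * params$position_unit,
                               params$sigma_theta)
  hyp <- vapply(banks, function(b) b$hypothesis, character(1))
  s1 <- matrix(col_max(evidence[[1]]$pos), ncol = 1)
  s2 <- matrix(col_max(evidence[[2]]$pos), ncol = 1)
  o1 <- matrix(col_max(evidence[[1]]$ori), ncol = 1)
  o2 <- matrix(col_max(evidence[[2]]$ori), ncol = 1)
  dec <- walker_decision_core(s1, s2, o1, o2, w, params$prior,
                              decision_coin(trial$seed, params))
  list(choice = unname(if (dec$first) hyp[1] else hyp[2]),
       aggregate = stats::setNames(c(dec$agg1, dec$agg2), hyp),
       weights = w,
       frames = data.frame(p_pos = dec$p_pos[, 1], p_theta = dec$p_theta[, 1],
                           p_int = dec$p_int[, 1]))
}

#' Decide the rotation direction of a square trial
#'
#' Both rotation hypotheses share one template bank (the same key frames in
#' different temporal orders). Per frame the integrated max-posterior
#' template index is tracked; index steps are compared with the expected step
#' (+1 for the bank's source direction, -1 for the reverse) through a
#' Gaussian sequence weight `exp(-(step - expected)^2 / (2 sigma_s^2))`
#' using the signed shortest cyclic displacement. Each transition's weight
#' multiplies the mean of the flanking frames' max integrated posteriors and
#' the products are summed; the hypothesis with the greater aggregate wins.
#'
#' @param trial A `stimulus_trial` of kind `"square"` with at least 2 frames.
#' @param bank The shared `template_bank` (built from the forward-order
#'   sequence; ascending indices = its direction).
#' @param params An `observer_params` with condition reliabilities set.
#' @param evidence Optional precomputed [trial_evidence()].
#' @return List with `choice`, `aggregate` (named), `weights`, per-frame MAP
#'   `index`, and `steps`.
#' @export
decide_square <- function(trial, bank, params, evidence = NULL) {
  if (trial$n_frames < 2)
    df_stop("square decisions need at least 2 frames", "dynform_invalid_input")
  w <- integration_weights(params)
  if (is.null(evidence))
    evidence <- trial_evidence(trial, bank,
                               params$sigma_p * params$position_unit,
                               params$sigma_theta)
  ev <- evidence[[1]]
  dec <- square_decision_core(col_softmax(ev$pos), col_softmax(ev$ori),
                              bank$K, trial$n_frames, 1L, w, params$sigma_s,
                              decision_coin(trial$seed, params))
  hyp <- c(bank$hypothesis, opposite_direction(bank$hypothesis))
  list(choice = unname(if (dec$first) hyp[1] else hyp[2]),
       aggregate = stats::setNames(c(dec$agg1, dec$agg2), hyp),
       weights = w,
       index = dec$index[, 1], steps = dec$steps[, 1])
}
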
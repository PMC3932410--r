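# One-frame limited-lifetime sampling of a segment sequence into Gabor
# element frames. Element positions are drawn fresh on every frame, so local
# image motion carries no direction signal; element orientations are either
# congruent with the sampled segment, taken from the nearest segment of the
# opposite-motion stimulus (incongruent), or randomized with an independent
# uniform offset. Gabor carrier/envelope parameters (sf, envelope_sd) are
# carried as metadata only: they influence the observer solely through the
# measured cue reliabilities.

#' Sample element positions on one stimulus frame
#'
#' Walker frames sample `n` *distinct* limb segments (uniformly without
#' replacement), one uniform-random point along each; square frames sample `n`
#' independent edges with replacement, uniform along each edge.
#'
#' @param frame One frame of a `segment_sequence` (a data.frame of segments).
#' @param n Number of elements to sample.
#' @param kind `"walker"` or `"square"`.
#' @param seed Optional seed; `NULL` draws from the current RNG state.
#' @return A data.frame with columns `x`, `y`, `segment` (row index into the
#'   frame), `label`, `u` (arc-length fraction along the segment).
#' @export
sample_positions <- function(frame, n, kind = c("walker", "square"), seed = NULL) {
  kind <- match.arg(kind)
  s <- nrow(frame)
  if (n < 1) df_stop("n must be >= 1", "dynform_invalid_count")
  if (kind == "walker" && n > s)
    df_stop(sprintf("cannot sample %d distinct segments from %d limbs", n, s),
            "dynform_invalid_count")
  draw <- function() {
    seg <- if (kind == "walker") sample.int(s, n) else sample.int(s, n, replace = TRUE)
    u <- stats::runif(n)
    list(seg = seg, u = u)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  data.frame(
    x = frame$x0[d$seg] + d$u * (frame$x1[d$seg] - frame$x0[d$seg]),
    y = frame$y0[d$seg] + d$u * (frame$y1[d$seg] - frame$y0[d$seg]),
    segment = d$seg,
    label = frame$label[d$seg],
    u = d$u,
    stringsAsFactors = FALSE
  )
}

#' Assign element orientations under a cue condition
#'
#' Congruent elements take the orientation of their source segment;
#' incongruent elements take the orientation of the segment of the
#' opposite-motion sequence (same frame) nearest to the element's position
#' (ties broken by label order); randomized elements add an independent
#' uniform offset in `[0, 180)` to the congruent orientation.
#'
#' @param samples Data.frame from [sample_positions()] (needs `x`, `y`,
#'   `segment`).
#' @param seq The `segment_sequence` the samples were drawn from.
#' @param t Frame index (1-based).
#' @param condition `"congruent"`, `"incongruent"` or `"random"`.
#' @param seed Optional seed for the random-offset draw.
#' @return Numeric vector of orientations in `[0, 180)`.
#' @export
assign_orientation <- function(samples, seq, t,
                               condition = c("congruent", "incongruent", "random"),
                               seed = NULL) {
  condition <- match.arg(condition)
  fr <- seq$frames[[t]]
  theta0 <- fr$theta[samples$segment]
  if (condition == "congruent") return(theta0)
  if (condition == "random") {
    off <- if (is.null(seed)) stats::runif(nrow(samples), 0, 180)
           else with_seed(seed, stats::runif(nrow(samples), 0, 180))
    return((theta0 + off) %% 180)
  }
  opp <- opposite_sequence(seq)
  nn <- nearest_segment(samples$x, samples$y, opp$frames[[t]])
  opp$frames[[t]]$theta[nn$index]
}

# Vectorised batch construction of many trials of one condition. Returns the
# long element table with true and (identical, pre-noise) observed fields.
# Streams: element sampling, orientation offsets and encoding noise each draw
# from their own seed so element positions are identical across orientation
# conditions built from the same sampling stream.
sample_stimulus_batch <- function(seq, opp, n_elements, orientation_condition,
                                  n_trials, seeds) {
  T <- seq$n_frames
  S <- length(seq$labels)
  if (n_elements < 1) df_stop("n_elements must be >= 1", "dynform_invalid_count")
  if (seq$kind == "walker" && n_elements > S)
    df_stop(sprintf("cannot sample %d distinct segments from %d limbs", n_elements, S),
            "dynform_invalid_count")
  n_blocks <- n_trials * T
  N <- n_blocks * n_elements

  smp <- with_seed(seeds[["sampling"]], {
    seg <- if (seq$kind == "walker") {
      r <- stats::runif(n_blocks * S)
      o <- order(rep(seq_len(n_blocks), each = S), r)
      pick <- o[as.vector(outer(seq_len(n_elements), (seq_len(n_blocks) - 1L) * S, `+`))]
      (pick - 1L) %% S + 1L
    } else {
      sample.int(S, N, replace = TRUE)
    }
    list(seg = seg, u = stats::runif(N))
  })

  block <- rep(seq_len(n_blocks), each = n_elements)
  trial <- (block - 1L) %/% T + 1L
  frame <- (block - 1L) %% T + 1L
  arr <- seq$arrays
  ij <- cbind(frame, smp$seg)
  x <- arr$x0[ij] + smp$u * (arr$x1[ij] - arr$x0[ij])
  y <- arr$y0[ij] + smp$u * (arr$y1[ij] - arr$y0[ij])

  theta <- switch(orientation_condition,
    congruent = arr$theta[ij],
    random = {
      off <- with_seed(seeds[["orientation"]], stats::runif(N, 0, 180))
      (arr$theta[ij] + off) %% 180
    },
    incongruent = {
      oarr <- opp$arrays
      D <- matrix(0, nrow = N, ncol = S)
      for (s in seq_len(S)) {
        D[, s] <- point_segment_distance(x, y,
                                         oarr$x0[cbind(frame, s)], oarr$y0[cbind(frame, s)],
                                         oarr$x1[cbind(frame, s)], oarr$y1[cbind(frame, s)])
      }
      amin <- max.col(-D, ties.method = "first")
      oarr$theta[cbind(frame, amin)]
    },
    df_stop(paste("unknown orientation condition:", orientation_condition),
            "dynform_invalid_input")
  )

  data.frame(trial = trial, frame = frame, segment = smp$seg,
             label = seq$labels[smp$seg],
             x = x, y = y, theta = theta,
             x_obs = x, y_obs = y, theta_obs = theta,
             stringsAsFactors = FALSE)
}

#' Build a complete limited-lifetime stimulus trial
#'
#' Samples every frame of the cycle independently (one-frame lifetime) and
#' assigns orientations under the requested cue condition. The returned trial
#' carries identical true and observed fields; apply [encode_with_noise()] to
#' model sensory encoding.
#'
#' @param seq Position-defining `segment_sequence` (its direction is the
#'   position-defined truth).
#' @param n_elements Elements sampled per frame.
#' @param orientation_condition `"congruent"`, `"incongruent"` or `"random"`.
#' @param sf,envelope_sd Gabor carrier spatial frequency (cyc/deg) and
#'   envelope SD (deg); metadata only.
#' @param seed Trial seed; all internal streams derive from it.
#' @return A `stimulus_trial` object.
#' @examples
#' w <- make_walker_sequence(n_frames = 12)
#' tr <- make_stimulus_trial(w, 4, "incongruent", seed = 7)
#' head(tr$elements)
#' @export
make_stimulus_trial <- function(seq, n_elements,
                                orientation_condition = c("congruent", "incongruent", "random"),
                                sf = NA_real_, envelope_sd = NA_real_, seed = 1) {
  orientation_condition <- match.arg(orientation_condition)
  opp <- opposite_sequence(seq)
  seeds <- stream_seeds(seed)
  el <- sample_stimulus_batch(seq, opp, n_elements, orientation_condition, 1L, seeds)
  structure(list(
    elements = el,
    truth = seq$direction,
    kind = seq$kind,
    orientation_condition = orientation_condition,
    n_frames = seq$n_frames,
    n_elements = n_elements,
    sf = sf, envelope_sd = envelope_sd,
    seed = seed
  ), class = "stimulus_trial")
}

#' @export
print.stimulus_trial <- function(x, ...) {
  cat(sprintf("<stimulus_trial> %s/%s %s, %d frames x %d elements\n",
              x$kind, x$truth, x$orientation_condition, x$n_frames, x$n_elements))
  invisible(x)
}

#' Inject sensory encoding noise into a trial
#'
#' Observed positions are the true positions plus isotropic Gaussian noise of
#' SD `sigma_p` (degrees); observed orientations are the true orientations
#' plus Gaussian noise of SD `sigma_theta` (degrees), wrapped into
#' `[0, 180)`. True fields are untouched.
#'
#' @param trial A `stimulus_trial`.
#' @param sigma_p Position noise SD in degrees (>= 0).
#' @param sigma_theta Orientation noise SD in degrees (>= 0).
#' @param seed Optional seed; defaults to the trial's own noise stream.
#' @return The trial with updated `x_obs`, `y_obs`, `theta_obs`.
#' @export
encode_with_noise <- function(trial, sigma_p, sigma_theta, seed = NULL) {
  stopifnot(inherits(trial, "stimulus_trial"))
  if (sigma_p < 0 || sigma_theta < 0)
    df_stop("noise SDs must be >= 0", "dynform_invalid_params")
  if (is.null(seed)) seed <- stream_seeds(trial$seed)[["noise"]]
  n <- nrow(trial$elements)
  nz <- with_seed(seed, list(dx = stats::rnorm(n), dy = stats::rnorm(n),
                             dth = stats::rnorm(n)))
  trial$elements$x_obs <- trial$elements$x + sigma_p * nz$dx
  trial$elements$y_obs <- trial$elements$y + sigma_p * nz$dy
  trial$elements$theta_obs <- (trial$elements$theta + sigma_theta * nz$dth) %% 180
  trial$sigma_p <- sigma_p
  trial$sigma_theta <- sigma_theta
  trial
}

#' Mirror a trial across the vertical meridian
#'
#' Negates all x-coordinates and maps orientations to `180 - theta` (mod 180),
#' for both true and observed fields; the position-defined truth flips.
#'
#' @param trial A `stimulus_trial`.
#' @return The mirrored trial.
#' @export
mirror_trial <- function(trial) {
  e <- trial$elements
  e$x <- -e$x; e$x_obs <- -e$x_obs
  e$theta <- mirror_orientation(e$theta)
  e$theta_obs <- mirror_orientation(e$theta_obs)
  trial$elements <- e
  trial$truth <- opposite_direction(trial$truth)
  trial
}

#' Reverse the temporal order of a trial
#'
#' Frame indices are remapped `t -> T + 1 - t`. For a rotating square this
#' flips the position-defined rotation direction.
#'
#' @param trial A `stimulus_trial`.
#' @return The time-reversed trial.
#' @export
reverse_trial <- function(trial) {
  trial$elements$frame <- trial$n_frames + 1L - trial$elements$frame
  trial$truth <- opposite_direction(trial$truth)
  trial
}

#' Export a trial as a long-format CSV
#'
#' Columns: `trial_id`, `frame`, `element_id`, true and observed coordinates
#' and orientations, `source_label`, and the condition metadata.
#'
#' @param trial A `stimulus_trial`.
#' @param path Output file path.
#' @param trial_id Identifier written to the `trial_id` column.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, trial_id = 1L) {
  e <- trial$elements
  out <- data.frame(
    trial_id = trial_id, frame = e$frame,
    element_id = seq_len(nrow(e)),
    x_true = e$x, y_true = e$y, theta_true = e$theta,
    x_obs = e$x_obs, y_obs = e$y_obs, theta_obs = e$theta_obs,
    source_label = e$label,
    kind = trial$kind, truth = trial$truth,
    orientation_condition = trial$orientation_condition,
    n_elements = trial$n_elements, sf = trial$sf, envelope_sd = trial$envelope_sd,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
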
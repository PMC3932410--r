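# Probabilistic template banks: K equidistant snapshots of a cyclic segment
# sequence, together with data-driven spread parameters. The position spread
# sigma_Tp is the largest directed point-to-shape distance between cyclically
# neighbouring template frames (each frame densely sampled along its
# segments); the orientation spread sigma_Ttheta is the largest folded
# orientation change of same-label segments between neighbouring templates.
# Both reflect how distinct the stored key frames are, and both are convolved
# with the observer's sensory noise when templates are matched to stimuli.

#' Estimate template spread parameters from a set of template frames
#'
#' @param frames List of template frames (data.frames with `label`, `x0`,
#'   `y0`, `x1`, `y1`), treated as cyclically adjacent (the last neighbours
#'   the first).
#' @param n_points Number of points sampled per segment (endpoints included)
#'   for the closest-distance computation.
#' @param ori_period Period of the orientation fold in degrees: 180 for
#'   general segments; 90 for square edges, whose orientation multiset is
#'   invariant under quarter turns (label correspondence across the symmetry
#'   wrap is only defined modulo that symmetry).
#' @return Named numeric vector `c(sigma_tp = , sigma_ttheta = )` in degrees.
#'   Identical neighbouring frames give zeros; downstream code applies a
#'   positive floor.
#' @export
estimate_template_variances <- function(frames, n_points = 100, ori_period = 180) {
  K <- length(frames)
  if (K < 2) df_stop("need at least 2 template frames", "dynform_invalid_bank")
  tt <- seq(0, 1, length.out = n_points)
  max_dist <- 0
  max_dtheta <- 0
  for (k in seq_len(K)) {
    a <- frames[[k]]
    b <- frames[[if (k == K) 1L else k + 1L]]
    px <- as.vector(outer(tt, a$x1 - a$x0) + rep(a$x0, each = n_points))
    py <- as.vector(outer(tt, a$y1 - a$y0) + rep(a$y0, each = n_points))
    nn <- nearest_segment(px, py, b)
    max_dist <- max(max_dist, max(nn$distance))
    tha <- segment_orientation(a$x0, a$y0, a$x1, a$y1)
    thb <- segment_orientation(b$x0, b$y0, b$x1, b$y1)
    if (!identical(a$label, b$label)) {
      thb <- thb[match(a$label, b$label)]
      if (anyNA(thb)) df_stop("template frames must share segment labels",
                              "dynform_invalid_bank")
    }
    dth <- abs(tha - thb) %% ori_period
    max_dtheta <- max(max_dtheta, max(pmin(dth, ori_period - dth)))
  }
  c(sigma_tp = max_dist, sigma_ttheta = max_dtheta)
}

#' Build a probabilistic template bank from a segment sequence
#'
#' Takes `K` equidistant snapshots of the sequence's symmetry period (frame
#' indices `round(t * period / K)`, t = 0..K-1) and computes the bank's
#' spread parameters with [estimate_template_variances()]. For a walker the
#' period is the full gait cycle; for a square it is one quarter turn, since
#' rotations 90 degrees apart produce identical images — subsampling the full
#' rotation would store duplicate templates and make the MAP template index
#' ambiguous, destroying sequence selectivity. A positive floor guards the
#' degenerate case of identical neighbouring templates.
#'
#' @param seq A `segment_sequence`.
#' @param K Number of template frames (>= 2, <= the symmetry period).
#' @param sigma_floor Lower bound applied to both spreads (degrees).
#' @param n_points Sampling density for the distance computation.
#' @return A `template_bank` object with fields `hypothesis` (the source
#'   direction), `kind`, `K`, `frame_index` (0-based source frames), `frames`,
#'   `seg` (flattened segment table), `sigma_tp`, `sigma_ttheta`.
#' @examples
#' bank <- build_template_bank(make_square_sequence(6, 60, 9, "cw"), K = 8)
#' bank$sigma_ttheta
#' @export
build_template_bank <- function(seq, K = 8, sigma_floor = 1e-3, n_points = 100) {
  stopifnot(inherits(seq, "segment_sequence"))
  if (!is.numeric(K) || K != round(K) || K < 2)
    df_stop("K must be an integer >= 2", "dynform_invalid_bank")
  period <- seq$period_frames %||% seq$n_frames
  if (K > period)
    df_stop("K cannot exceed the sequence's symmetry period", "dynform_invalid_bank")
  idx0 <- floor((seq_len(K) - 1L) * period / K + 0.5)  # 0-based, round-half-up
  frames <- seq$frames[idx0 + 1L]
  sig <- estimate_template_variances(frames, n_points = n_points,
                                     ori_period = if (seq$kind == "square") 90 else 180)
  seg <- do.call(rbind, lapply(seq_len(K), function(k) {
    fr <- frames[[k]]
    data.frame(template = k, label = fr$label,
               x0 = fr$x0, y0 = fr$y0, x1 = fr$x1, y1 = fr$y1, theta = fr$theta,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    hypothesis = seq$direction,
    kind = seq$kind,
    K = as.integer(K),
    frame_index = as.integer(idx0),
    frames = frames,
    seg = seg,
    sigma_tp = max(unname(sig["sigma_tp"]), sigma_floor),
    sigma_ttheta = max(unname(sig["sigma_ttheta"]), sigma_floor),
    sigma_raw = sig
  ), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %s/%s K=%d sigma_Tp=%.3f deg sigma_Ttheta=%.2f deg\n",
              x$kind, x$hypothesis, x$K, x$sigma_tp, x$sigma_ttheta))
  invisible(x)
}
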
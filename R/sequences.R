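# Dynamic-form segment sequences: an articulated walker and a rigid rotating
# square, each represented frame-by-frame as a set of labelled 2-D line
# segments in degrees of visual angle (origin at the stimulus center,
# y upward). Both stimuli are cyclic: the walker spans one gait cycle and the
# square one unit of its rotational symmetry as configured.

WALKER_SEGMENT_LABELS <- c(
  "left-lower-arm", "left-lower-leg", "left-upper-arm", "left-upper-leg",
  "right-lower-arm", "right-lower-leg", "right-upper-arm", "right-upper-leg",
  "torso"
)

# Build a segment_sequence from a list of per-frame segment data.frames.
# period_frames is the length of the shortest sub-cycle after which the
# *image* repeats (the symmetry period): the full cycle for a walker, but one
# quarter turn for a square, whose 4-fold symmetry makes rotations 90 degrees
# apart indistinguishable. Template banks subsample one symmetry period so
# that no two templates are duplicate images.
new_segment_sequence <- function(frames, kind, direction, frame_rate = 60,
                                 period_frames = length(frames)) {
  frames <- lapply(frames, function(fr) {
    fr <- fr[order(fr$label), , drop = FALSE]
    rownames(fr) <- NULL
    if (anyDuplicated(fr$label))
      df_stop("segment labels must be unique within a frame", "dynform_invalid_geometry")
    if (any(fr$x0 == fr$x1 & fr$y0 == fr$y1))
      df_stop("degenerate segment (p0 == p1)", "dynform_invalid_geometry")
    fr$theta <- segment_orientation(fr$x0, fr$y0, fr$x1, fr$y1)
    fr
  })
  labs <- frames[[1]]$label
  for (fr in frames)
    if (!identical(fr$label, labs))
      df_stop("all frames must share the same segment labels", "dynform_invalid_geometry")
  seq <- list(
    frames = frames,
    frame_rate = frame_rate,
    cycle_frames = length(frames),
    n_frames = length(frames),
    period_frames = period_frames,
    kind = kind,
    direction = direction,
    labels = labs
  )
  seq$arrays <- sequence_arrays(frames)
  class(seq) <- "segment_sequence"
  seq
}

# Matrix view [n_frames x n_segments] of the frame list, for vectorised code.
sequence_arrays <- function(frames) {
  grab <- function(col) do.call(rbind, lapply(frames, function(fr) fr[[col]]))
  list(x0 = grab("x0"), y0 = grab("y0"), x1 = grab("x1"), y1 = grab("y1"),
       theta = grab("theta"))
}

#' @export
print.segment_sequence <- function(x, ...) {
  cat(sprintf("<segment_sequence> kind=%s direction=%s frames=%d segments=%d\n",
              x$kind, x$direction, x$n_frames, length(x$labels)))
  invisible(x)
}

#' Rotating-square segment sequence
#'
#' Four edge segments of a square centered at the origin, rotated by a fixed
#' increment on every frame. A clockwise (`cw`) sequence rotates clockwise in
#' screen coordinates (y upward); the counter-clockwise sequence is defined as
#' the clockwise sequence played in reverse frame order, so the two directions
#' are exact temporal mirrors of one another.
#'
#' @param rotation_increment_deg Rotation per frame in degrees (> 0). The
#'   default 6 degrees together with 60 frames spans one full rotation.
#' @param n_frames Number of frames (>= 1).
#' @param side_deg Side length of the square in degrees of visual angle; the
#'   unrotated square subtends this vertically.
#' @param direction `"cw"` or `"ccw"`.
#' @return A `segment_sequence` with 4 labelled edges per frame.
#' @examples
#' sq <- make_square_sequence(6, 60, 9, "cw")
#' sq$n_frames
#' @export
make_square_sequence <- function(rotation_increment_deg = 6, n_frames = 60,
                                 side_deg = 9, direction = c("cw", "ccw")) {
  direction <- match.arg(direction)
  if (!is.finite(side_deg) || side_deg <= 0)
    df_stop("side_deg must be positive", "dynform_invalid_geometry")
  if (!is.finite(rotation_increment_deg) || rotation_increment_deg <= 0)
    df_stop("rotation_increment_deg must be positive", "dynform_invalid_geometry")
  if (n_frames < 1) df_stop("n_frames must be >= 1", "dynform_invalid_geometry")

  r <- side_deg / sqrt(2)
  corner_base <- c(45, 135, 225, 315) * pi / 180
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    phi <- -rotation_increment_deg * t * pi / 180  # clockwise = negative math angle
    cx <- r * cos(corner_base + phi)
    cy <- r * sin(corner_base + phi)
    nxt <- c(2L, 3L, 4L, 1L)
    data.frame(
      label = paste0("edge-", 1:4),
      x0 = cx, y0 = cy, x1 = cx[nxt], y1 = cy[nxt],
      stringsAsFactors = FALSE
    )
  })
  if (direction == "ccw") frames <- rev(frames)
  # symmetry period: smallest frame count whose cumulative rotation is a
  # multiple of 90 degrees (4-fold square symmetry); full cycle if none.
  period <- n_frames
  for (m in seq_len(n_frames)) {
    if (abs((m * rotation_increment_deg) %% 90) < 1e-9 ||
        abs(90 - (m * rotation_increment_deg) %% 90) < 1e-9) {
      period <- m
      break
    }
  }
  new_segment_sequence(frames, kind = "square", direction = direction,
                       period_frames = period)
}

#' Default parametric gait
#'
#' A sinusoidal joint-angle model of human walking viewed in profile, used in
#' place of motion-capture data. Angles are measured from the downward
#' vertical, positive toward the facing direction; each joint angle is
#' `mean + amp * sin(2*pi*harmonic*phase01 + phase)` over one gait cycle, which
#' guarantees exact periodicity. Left and right limbs move in antiphase and
#' arms in antiphase with the ipsilateral leg. Segment lengths and trunk
#' geometry are in model units; `make_walker_sequence()` rescales the figure to
#' the requested vertical size.
#'
#' @param thigh_amp,arm_amp Swing amplitudes in degrees for thighs and upper
#'   arms.
#' @return A gait description list with components `lengths`, `trunk`, and
#'   `angles` (per-joint sinusoid parameters).
#' @export
default_gait <- function(thigh_amp = 28, arm_amp = 20) {
  ang <- function(mean, amp, phase, harmonic = 1L)
    list(mean = mean, amp = amp, phase = phase, harmonic = harmonic)
  list(
    lengths = c(thigh = 0.50, shank = 0.48, upper_arm = 0.30, forearm = 0.28),
    trunk = c(hip_y = 0, neck_y = 0.62, head_y = 0.80),
    angles = list(
      thigh_left     = ang(0, thigh_amp, 0),
      thigh_right    = ang(0, thigh_amp, pi),
      knee_left      = ang(20, 18, 2.2),        # flexion, bends shank backward
      knee_right     = ang(20, 18, 2.2 + pi),
      shoulder_left  = ang(0, arm_amp, pi),     # antiphase with left thigh
      shoulder_right = ang(0, arm_amp, 0),
      elbow_left     = ang(22, 12, pi + 0.6),   # flexion, bends forearm forward
      elbow_right    = ang(22, 12, 0.6)
    )
  )
}

validate_gait <- function(gait) {
  ok <- is.list(gait) && all(c("lengths", "trunk", "angles") %in% names(gait))
  if (!ok) df_stop("gait must have lengths, trunk and angles", "dynform_invalid_gait")
  need <- c("thigh_left", "thigh_right", "knee_left", "knee_right",
            "shoulder_left", "shoulder_right", "elbow_left", "elbow_right")
  if (!all(need %in% names(gait$angles)))
    df_stop(paste("gait$angles must define:", paste(need, collapse = ", ")),
            "dynform_invalid_gait")
  for (nm in names(gait$angles)) {
    a <- gait$angles[[nm]]
    if (!all(c("mean", "amp", "phase", "harmonic") %in% names(a)) ||
        !all(vapply(a[c("mean", "amp", "phase")], function(v) is.finite(v), logical(1))) ||
        a$amp < 0 ||
        !is.finite(a$harmonic) || a$harmonic != round(a$harmonic) || a$harmonic < 1)
      df_stop(sprintf("joint '%s': angles must be finite sinusoids with a positive integer harmonic (periodic over the cycle)", nm),
              "dynform_invalid_gait")
  }
  invisible(gait)
}

eval_joint_angle <- function(spec, phase01) {
  (spec$mean + spec$amp * sin(2 * pi * spec$harmonic * phase01 + spec$phase)) * pi / 180
}

#' Parametric walker segment sequence
#'
#' Builds one gait cycle of a stick-figure walker with nine limb segments
#' (upper and lower arms and legs, plus the mid-shoulder-to-head torso) from a
#' periodic joint-angle model. The walker steps in place: the hip stays at
#' x = 0, so there is no net horizontal translation. The figure is uniformly
#' scaled and vertically centered so its vertical extent over the cycle equals
#' `height_deg`. The rightward walker is the exact mirror (x to -x) of the
#' leftward walker.
#'
#' @param gait Gait description as returned by [default_gait()].
#' @param n_frames Number of frames spanning one cycle (>= 2).
#' @param direction `"left"` or `"right"` (facing/walking direction).
#' @param height_deg Target vertical extent in degrees of visual angle.
#' @return A `segment_sequence` with 9 labelled limb segments per frame.
#' @examples
#' w <- make_walker_sequence(default_gait(), 60, "left")
#' names(w$frames[[1]])
#' @export
make_walker_sequence <- function(gait = default_gait(), n_frames = 60,
                                 direction = c("left", "right"), height_deg = 9) {
  direction <- match.arg(direction)
  validate_gait(gait)
  if (n_frames < 2) df_stop("n_frames must be >= 2", "dynform_invalid_gait")

  L <- gait$lengths
  trunk <- gait$trunk
  fwd <- -1  # canonical build faces left (forward = -x)
  phase01 <- (seq_len(n_frames) - 1L) / n_frames

  limb_pt <- function(ox, oy, len, ang) {
    list(x = ox + len * fwd * sin(ang), y = oy - len * cos(ang))
  }

  frames <- lapply(seq_len(n_frames), function(i) {
    ph <- phase01[i]
    A <- lapply(gait$angles, eval_joint_angle, phase01 = ph)
    hip <- list(x = 0, y = trunk[["hip_y"]])
    neck <- list(x = 0, y = trunk[["neck_y"]])
    head <- list(x = 0, y = trunk[["head_y"]])
    knee_l <- limb_pt(hip$x, hip$y, L[["thigh"]], A$thigh_left)
    knee_r <- limb_pt(hip$x, hip$y, L[["thigh"]], A$thigh_right)
    foot_l <- limb_pt(knee_l$x, knee_l$y, L[["shank"]], A$thigh_left - A$knee_left)
    foot_r <- limb_pt(knee_r$x, knee_r$y, L[["shank"]], A$thigh_right - A$knee_right)
    elb_l <- limb_pt(neck$x, neck$y, L[["upper_arm"]], A$shoulder_left)
    elb_r <- limb_pt(neck$x, neck$y, L[["upper_arm"]], A$shoulder_right)
    wri_l <- limb_pt(elb_l$x, elb_l$y, L[["forearm"]], A$shoulder_left + A$elbow_left)
    wri_r <- limb_pt(elb_r$x, elb_r$y, L[["forearm"]], A$shoulder_right + A$elbow_right)
    seg <- function(label, a, b) data.frame(label = label, x0 = a$x, y0 = a$y,
                                            x1 = b$x, y1 = b$y,
                                            stringsAsFactors = FALSE)
    rbind(
      seg("torso", neck, head),
      seg("left-upper-arm", neck, elb_l),
      seg("left-lower-arm", elb_l, wri_l),
      seg("right-upper-arm", neck, elb_r),
      seg("right-lower-arm", elb_r, wri_r),
      seg("left-upper-leg", hip, knee_l),
      seg("left-lower-leg", knee_l, foot_l),
      seg("right-upper-leg", hip, knee_r),
      seg("right-lower-leg", knee_r, foot_r)
    )
  })

  # scale to the requested vertical extent and center vertically
  ys <- unlist(lapply(frames, function(fr) c(fr$y0, fr$y1)))
  sc <- height_deg / (max(ys) - min(ys))
  ymid <- (max(ys) + min(ys)) / 2
  frames <- lapply(frames, function(fr) {
    fr$x0 <- fr$x0 * sc; fr$x1 <- fr$x1 * sc
    fr$y0 <- (fr$y0 - ymid) * sc; fr$y1 <- (fr$y1 - ymid) * sc
    fr
  })

  out <- new_segment_sequence(frames, kind = "walker", direction = "left")
  if (direction == "right") out <- mirror_sequence(out) else out
}

# Reflect a sequence across the vertical meridian (x -> -x), flipping its
# direction label. Exact in floating point (pure sign changes).
mirror_sequence <- function(seq) {
  frames <- lapply(seq$frames, function(fr) {
    fr$x0 <- -fr$x0; fr$x1 <- -fr$x1
    fr$theta <- NULL
    fr
  })
  new_segment_sequence(frames, kind = seq$kind,
                       direction = opposite_direction(seq$direction),
                       frame_rate = seq$frame_rate)
}

#' Opposite direction label
#' @param direction One of `"left"`, `"right"`, `"cw"`, `"ccw"`.
#' @return The label of the opposite motion direction.
#' @export
opposite_direction <- function(direction) {
  switch(direction,
         left = "right", right = "left", cw = "ccw", ccw = "cw",
         df_stop(paste("unknown direction:", direction), "dynform_invalid_input"))
}

#' Opposite-motion counterpart of a sequence
#'
#' For a walker the opposite stimulus is the mirror image (frame indices
#' preserved); for a square it is the same frames in reverse temporal order.
#' The operation is an exact involution.
#'
#' @param seq A `segment_sequence`.
#' @return A `segment_sequence` moving in the opposite direction.
#' @export
opposite_sequence <- function(seq) {
  stopifnot(inherits(seq, "segment_sequence"))
  if (seq$kind == "walker") {
    mirror_sequence(seq)
  } else {
    new_segment_sequence(rev(seq$frames), kind = seq$kind,
                         direction = opposite_direction(seq$direction),
                         frame_rate = seq$frame_rate,
                         period_frames = seq$period_frames)
  }
}

#' Export a segment sequence as CSV
#'
#' Long format with one row per segment per frame: `frame` (0-based), `label`,
#' `x0`, `y0`, `x1`, `y1` in degrees.
#'
#' @param seq A `segment_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(seq, path) {
  rows <- do.call(rbind, lapply(seq_along(seq$frames), function(i) {
    fr <- seq$frames[[i]]
    data.frame(frame = i - 1L, label = fr$label,
               x0 = fr$x0, y0 = fr$y0, x1 = fr$x1, y1 = fr$y1,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Joint topology used when assembling a walker from a joint-trajectory table.
WALKER_TOPOLOGY <- data.frame(
  label = c("torso",
            "left-upper-arm", "left-lower-arm",
            "right-upper-arm", "right-lower-arm",
            "left-upper-leg", "left-lower-leg",
            "right-upper-leg", "right-lower-leg"),
  from = c("neck",
           "neck", "left-elbow",
           "neck", "right-elbow",
           "hip", "left-knee",
           "hip", "right-knee"),
  to = c("head",
         "left-elbow", "left-wrist",
         "right-elbow", "right-wrist",
         "left-knee", "left-foot",
         "right-knee", "right-foot"),
  stringsAsFactors = FALSE
)

#' Build a walker sequence from a joint-trajectory CSV
#'
#' Reads a table with columns `frame` (0-based), `joint`, `x_deg`, `y_deg`
#' (one row per joint per frame) and connects the joints into the standard
#' nine-segment stick figure. Required joints: head, neck, hip, left/right
#' elbow, wrist, knee, foot.
#'
#' @param path CSV file path.
#' @param direction Direction label to record (`"left"` or `"right"`).
#' @return A `segment_sequence` of kind `"walker"`.
#' @export
read_joint_trajectories <- function(path, direction = "left") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "x_deg", "y_deg")
  if (!all(need %in% names(tab)))
    df_stop("joint-trajectory CSV needs columns frame, joint, x_deg, y_deg",
            "dynform_invalid_input")
  joints <- unique(c(WALKER_TOPOLOGY$from, WALKER_TOPOLOGY$to))
  frames_id <- sort(unique(tab$frame))
  frames <- lapply(frames_id, function(f) {
    sub <- tab[tab$frame == f, ]
    missing <- setdiff(joints, sub$joint)
    if (length(missing))
      df_stop(paste("frame", f, "missing joints:", paste(missing, collapse = ", ")),
              "dynform_invalid_input")
    px <- stats::setNames(sub$x_deg, sub$joint)
    py <- stats::setNames(sub$y_deg, sub$joint)
    data.frame(label = WALKER_TOPOLOGY$label,
               x0 = unname(px[WALKER_TOPOLOGY$from]),
               y0 = unname(py[WALKER_TOPOLOGY$from]),
               x1 = unname(px[WALKER_TOPOLOGY$to]),
               y1 = unname(py[WALKER_TOPOLOGY$to]),
               stringsAsFactors = FALSE)
  })
  new_segment_sequence(frames, kind = "walker", direction = direction)
}
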
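test_that("square sequence completes one full rotation and respects symmetry", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  expect_equal(sq$n_frames, 60)
  expect_equal(sq$period_frames, 15)
  # frame t holds the frame-0 square rotated clockwise by 6t degrees
  rot <- function(fr, deg) {
    phi <- -deg * pi / 180
    data.frame(x0 = fr$x0 * cos(phi) - fr$y0 * sin(phi),
               y0 = fr$x0 * sin(phi) + fr$y0 * cos(phi),
               x1 = fr$x1 * cos(phi) - fr$y1 * sin(phi),
               y1 = fr$x1 * sin(phi) + fr$y1 * cos(phi))
  }
  f0 <- sq$frames[[1]]
  for (t in c(2, 31, 60)) {
    expect_equal(sq$frames[[t]][, c("x0", "y0", "x1", "y1")],
                 rot(f0, 6 * (t - 1)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # cumulative rotation after the last frame closes the cycle: one more
  # 6-degree step returns the frame-0 coordinates
  expect_equal(rot(sq$frames[[60]], 6)[, c("x0", "y0")],
               f0[, c("x0", "y0")], tolerance = 1e-9, ignore_attr = TRUE)

  # single-frame sequence is the unrotated square with 9-degree extent
  one <- make_square_sequence(6, 1, 9, "cw")
  expect_equal(length(one$frames), 1)
  expect_equal(max(one$frames[[1]]$y0) - min(one$frames[[1]]$y0), 9)
  expect_setequal(round(one$frames[[1]]$theta, 9), c(0, 90))

  # 90-degree increments: every frame's edge-orientation multiset identical
  s4 <- make_square_sequence(90, 4, 9, "cw")
  base <- sort(round(s4$frames[[1]]$theta, 6) %% 90)
  for (fr in s4$frames) expect_equal(sort(round(fr$theta, 6) %% 90), base)

  expect_error(make_square_sequence(6, 60, -1), class = "dynform_invalid_geometry")
  expect_error(make_square_sequence(0, 60, 9), class = "dynform_invalid_geometry")
})

test_that("ccw square is the cw sequence in reverse frame order", {
  cw <- make_square_sequence(6, 60, 9, "cw")
  ccw <- make_square_sequence(6, 60, 9, "ccw")
  for (t in c(1, 17, 60))
    expect_identical(ccw$frames[[t]][, 2:5], cw$frames[[61 - t]][, 2:5])
})

test_that("walker has nine labelled limb segments and the stated extent", {
  w <- make_walker_sequence(n_frames = 60, direction = "left")
  expect_equal(length(w$labels), 9)
  expect_true(all(c("torso", "left-upper-arm", "left-lower-leg",
                    "right-upper-leg", "right-lower-arm") %in% w$labels))
  ys <- unlist(lapply(w$frames, function(fr) c(fr$y0, fr$y1)))
  expect_equal(max(ys) - min(ys), 9, tolerance = 0.05)
})

test_that("rightward walker is the exact mirror of the leftward walker", {
  wl <- make_walker_sequence(n_frames = 60, direction = "left")
  wr <- make_walker_sequence(n_frames = 60, direction = "right")
  expect_identical(wr$arrays$x0, -wl$arrays$x0)
  expect_identical(wr$arrays$x1, -wl$arrays$x1)
  expect_identical(wr$arrays$y0, wl$arrays$y0)
  # orientations map theta -> 180 - theta (mod 180)
  expect_equal(wr$arrays$theta, (180 - wl$arrays$theta) %% 180, tolerance = 1e-9)
})

test_that("walker walks in place: hip mean x is zero over the cycle", {
  # the hip is the proximal endpoint of the upper legs; integrate its
  # trajectory over finely sampled phases as an independent check
  for (nf in c(60, 480)) {
    w <- make_walker_sequence(n_frames = nf, direction = "left")
    hip_x <- vapply(w$frames, function(fr) fr$x0[fr$label == "left-upper-leg"],
                    numeric(1))
    expect_lt(abs(mean(hip_x)), 1e-9)
  }
})

test_that("zero-amplitude gait yields a static figure", {
  g <- default_gait()
  for (nm in names(g$angles)) g$angles[[nm]]$amp <- 0
  w <- make_walker_sequence(g, 60, "right")
  for (t in 2:60) expect_identical(w$frames[[t]], w$frames[[1]])
})

test_that("non-periodic gait parameters are rejected", {
  g <- default_gait()
  g$angles$thigh_left$harmonic <- 0.5
  expect_error(make_walker_sequence(g), class = "dynform_invalid_gait")
  g2 <- default_gait()
  g2$angles$knee_left <- NULL
  expect_error(make_walker_sequence(g2), class = "dynform_invalid_gait")
  expect_error(make_walker_sequence(default_gait(), n_frames = 1),
               class = "dynform_invalid_gait")
})

test_that("opposite_sequence is an exact involution and maps frames correctly", {
  wl <- make_walker_sequence(n_frames = 30)
  expect_equal(opposite_sequence(opposite_sequence(wl)), wl)
  # walker: same frame index, mirrored coordinates
  opp <- opposite_sequence(wl)
  expect_identical(opp$frames[[10]]$x0, -wl$frames[[10]]$x0)
  expect_identical(opp$direction, "right")

  sq <- make_square_sequence(6, 60, 9, "cw")
  expect_equal(opposite_sequence(opposite_sequence(sq)), sq)
  # square: cw frame t equals ccw frame n_frames + 1 - t
  osq <- opposite_sequence(sq)
  for (t in c(1, 23, 60))
    expect_identical(osq$frames[[t]][, 2:5], sq$frames[[61 - t]][, 2:5])
})

test_that("joint-trajectory CSV loader reconstructs the walker", {
  w <- make_walker_sequence(n_frames = 8)
  # rebuild the joint table from the segment endpoints
  rows <- do.call(rbind, lapply(seq_along(w$frames), function(t) {
    fr <- w$frames[[t]]
    pt <- function(joint, lab, end) {
      data.frame(frame = t - 1L, joint = joint,
                 x_deg = fr[[paste0("x", end)]][fr$label == lab],
                 y_deg = fr[[paste0("y", end)]][fr$label == lab])
    }
    rbind(pt("hip", "left-upper-leg", 0), pt("neck", "torso", 0),
          pt("head", "torso", 1),
          pt("left-elbow", "left-upper-arm", 1), pt("left-wrist", "left-lower-arm", 1),
          pt("right-elbow", "right-upper-arm", 1), pt("right-wrist", "right-lower-arm", 1),
          pt("left-knee", "left-upper-leg", 1), pt("left-foot", "left-lower-leg", 1),
          pt("right-knee", "right-upper-leg", 1), pt("right-foot", "right-lower-leg", 1))
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  rebuilt <- read_joint_trajectories(path, direction = "left")
  for (t in seq_along(w$frames))
    expect_equal(rebuilt$frames[[t]], w$frames[[t]], tolerance = 1e-12)
  unlink(path)
})

test_that("sequence CSV export has the documented long format", {
  sq <- make_square_sequence(6, 5, 9, "cw")
  path <- tempfile(fileext = ".csv")
  write_sequence_csv(sq, path)
  tab <- utils::read.csv(path)
  expect_equal(names(tab), c("frame", "label", "x0", "y0", "x1", "y1"))
  expect_equal(nrow(tab), 5 * 4)
  expect_equal(range(tab$frame), c(0, 4))
  unlink(path)
})
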
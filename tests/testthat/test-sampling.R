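test_that("walker sampling exhausts all limbs at n = 9 and rejects n > 9", {
  w <- make_walker_sequence(n_frames = 12)
  s <- sample_positions(w$frames[[1]], 9, "walker", seed = 3)
  expect_setequal(s$label, w$labels)
  expect_error(sample_positions(w$frames[[1]], 10, "walker", seed = 3),
               class = "dynform_invalid_count")
  expect_error(sample_positions(w$frames[[1]], 0, "walker", seed = 3),
               class = "dynform_invalid_count")
})

test_that("square sampling places every element exactly on an edge", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  fr <- sq$frames[[7]]
  s <- sample_positions(fr, 8, "square", seed = 5)
  expect_equal(nrow(s), 8)
  for (i in 1:8) {
    dmin <- min(vapply(1:4, function(e)
      seg_dist_scalar(s$x[i], s$y[i], fr$x0[e], fr$y0[e], fr$x1[e], fr$y1[e]),
      numeric(1)))
    expect_lt(dmin, 1e-9)
  }
})

test_that("sampling is bit-reproducible under a fixed seed", {
  w <- make_walker_sequence(n_frames = 12)
  s1 <- sample_positions(w$frames[[3]], 6, "walker", seed = 42)
  s2 <- sample_positions(w$frames[[3]], 6, "walker", seed = 42)
  expect_identical(s1, s2)
  t1 <- make_stimulus_trial(w, 4, "incongruent", seed = 9)
  t2 <- make_stimulus_trial(w, 4, "incongruent", seed = 9)
  expect_identical(t1$elements, t2$elements)
})

test_that("element positions are identical across orientation conditions", {
  w <- make_walker_sequence(n_frames = 60)
  trials <- lapply(c("congruent", "incongruent", "random"), function(oc)
    make_stimulus_trial(w, 4, oc, seed = 17))
  for (i in 2:3) {
    expect_identical(trials[[i]]$elements$x, trials[[1]]$elements$x)
    expect_identical(trials[[i]]$elements$y, trials[[1]]$elements$y)
    expect_identical(trials[[i]]$elements$frame, trials[[1]]$elements$frame)
  }
})

test_that("congruent orientation returns the source segment orientation", {
  sq <- make_square_sequence(6, 1, 9, "cw")  # unrotated: edges vertical/horizontal
  fr <- sq$frames[[1]]
  s <- sample_positions(fr, 8, "square", seed = 2)
  th <- assign_orientation(s, sq, 1, "congruent")
  vertical <- orientation_diff(fr$theta[s$segment], 0) < 1e-9
  expect_true(any(vertical))
  expect_lt(max(orientation_diff(th[vertical], 0)), 1e-9)
  expect_equal(th, fr$theta[s$segment])
  # the convention itself: a vertical segment has orientation exactly 0
  expect_identical(segment_orientation(0, 0, 0, 1), 0)
})

test_that("incongruent walker orientations match a brute-force nearest-limb scan", {
  w <- make_walker_sequence(n_frames = 60)
  opp <- opposite_sequence(w)
  s <- sample_positions(w$frames[[1]], 6, "walker", seed = 8)
  th <- assign_orientation(s, w, 1, "incongruent")
  ofr <- opp$frames[[1]]
  for (i in seq_len(nrow(s))) {
    dmin <- Inf; best <- NA
    for (k in seq_len(nrow(ofr))) {
      d <- seg_dist_scalar(s$x[i], s$y[i],
                           ofr$x0[k], ofr$y0[k], ofr$x1[k], ofr$y1[k])
      if (d < dmin) { dmin <- d; best <- k }
    }
    expect_equal(th[i], ofr$theta[best])
  }
})

test_that("incongruent equals congruent at a fully symmetric square frame", {
  s4 <- make_square_sequence(90, 4, 9, "cw")  # every frame 4-fold symmetric
  s <- sample_positions(s4$frames[[2]], 6, "square", seed = 4)
  th_c <- assign_orientation(s, s4, 2, "congruent")
  th_i <- assign_orientation(s, s4, 2, "incongruent")
  expect_equal(orientation_diff(th_c, th_i), rep(0, 6), tolerance = 1e-9)
})

test_that("randomized orientations are congruent plus a uniform offset", {
  w <- make_walker_sequence(n_frames = 60)
  tc <- make_stimulus_trial(w, 6, "congruent", seed = 31)
  tr <- make_stimulus_trial(w, 6, "random", seed = 31)
  off <- (tr$elements$theta - tc$elements$theta) %% 180
  expect_true(all(off >= 0 & off < 180))
  # offsets should look uniform: mean near 90, spread near uniform SD
  expect_equal(mean(off), 90, tolerance = 5)
  expect_gt(stats::sd(off), 40)
})

test_that("encoding noise has the nominal magnitude and leaves truth untouched", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  tr <- make_stimulus_trial(sq, 170, "congruent", seed = 12)  # ~10^4 elements
  expect_gt(nrow(tr$elements), 10000)

  t0 <- encode_with_noise(tr, 0, 0)
  expect_identical(t0$elements$x_obs, t0$elements$x)
  expect_identical(t0$elements$theta_obs, t0$elements$theta)

  tn <- encode_with_noise(tr, 3.87, 1.82)
  expect_identical(tn$elements$x, tr$elements$x)  # truth untouched
  expect_equal(stats::sd(tn$elements$x_obs - tn$elements$x), 3.87, tolerance = 0.05 * 3.87)
  expect_equal(stats::sd(tn$elements$y_obs - tn$elements$y), 3.87, tolerance = 0.05 * 3.87)
  dth <- ((tn$elements$theta_obs - tn$elements$theta + 90) %% 180) - 90
  expect_equal(stats::sd(dth), 1.82, tolerance = 0.05 * 1.82)
  expect_true(all(tn$elements$theta_obs >= 0 & tn$elements$theta_obs < 180))
})

test_that("one-frame lifetime: consecutive-frame repeats match the independence null", {
  w <- make_walker_sequence(n_frames = 60)
  n_rep <- 0; n_tot <- 0
  for (s in 1:80) {
    tr <- make_stimulus_trial(w, 2, "congruent", seed = 1000 + s)
    sets <- split(tr$elements$segment, tr$elements$frame)
    for (t in 2:60) {
      n_tot <- n_tot + 1
      if (identical(sort(sets[[t]]), sort(sets[[t - 1]]))) n_rep <- n_rep + 1
    }
  }
  p0 <- 1 / choose(9, 2)  # independent resampling null
  se <- sqrt(p0 * (1 - p0) / n_tot)
  expect_lt(abs(n_rep / n_tot - p0), 4 * se)
})

test_that("mirror and reversal helpers are involutions", {
  w <- make_walker_sequence(n_frames = 20)
  tr <- encode_with_noise(make_stimulus_trial(w, 4, "incongruent", seed = 6), 0.2, 2)
  expect_equal(mirror_trial(mirror_trial(tr)), tr)
  sq <- make_square_sequence(6, 60, 9, "cw")
  ts <- make_stimulus_trial(sq, 6, "congruent", seed = 6)
  expect_identical(reverse_trial(reverse_trial(ts)), ts)
  expect_identical(reverse_trial(ts)$truth, "ccw")
})

test_that("trial CSV export carries true and observed fields", {
  w <- make_walker_sequence(n_frames = 10)
  tr <- encode_with_noise(make_stimulus_trial(w, 3, "random", seed = 2), 0.1, 1)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path, trial_id = 7)
  tab <- utils::read.csv(path)
  expect_true(all(c("trial_id", "frame", "element_id", "x_true", "y_true",
                    "theta_true", "x_obs", "y_obs", "theta_obs", "source_label",
                    "orientation_condition") %in% names(tab)))
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$trial_id == 7))
  unlink(path)
})
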
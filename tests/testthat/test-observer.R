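test_that("frame scores match brute-force enumeration on small instances", {
  for (case in 1:30) {
    set.seed(case)
    K <- sample(2:4, 1)
    S <- sample(2:4, 1)
    n <- sample(1:3, 1)
    bank <- random_toy_bank(K, S, seed = 100 + case)
    pos <- cbind(runif(n, -4, 4), runif(n, -4, 4))
    theta <- runif(n, 0, 180)
    sp <- runif(1, 0.1, 2)
    st <- runif(1, 0.5, 10)
    ps <- position_frame_score(pos, bank, sp)
    os <- orientation_frame_score(pos, theta, bank, st)
    expect_equal(ps$log_score, oracle_position_score(pos, bank, sp),
                 tolerance = 1e-12)
    expect_equal(os$log_score, oracle_orientation_score(pos, theta, bank, st),
                 tolerance = 1e-12)
    expect_equal(ps$map, which.max(ps$log_score))
  }
})

test_that("elements lying on a template's segments make it the MAP template", {
  bank <- random_toy_bank(4, 3, seed = 11)
  seg2 <- bank$seg[bank$seg$template == 2, ]
  pos <- cbind(c(seg2$x0, (seg2$x0 + seg2$x1) / 2),
               c(seg2$y0, (seg2$y0 + seg2$y1) / 2))
  sc <- position_frame_score(pos, bank, 0)
  expect_equal(sc$map, 2)
  th <- seg2$theta[c(1:3, 1:3)]
  so <- orientation_frame_score(pos, th, bank, 1e-6)
  expect_equal(so$map, 2)
})

test_that("larger sensory noise flattens the template scores", {
  bank <- random_toy_bank(4, 3, seed = 21)
  set.seed(33)
  pos <- cbind(runif(5, -3, 3), runif(5, -3, 3))
  gap <- vapply(c(0.5, 1, 2, 4), function(sp) {
    s <- position_frame_score(pos, bank, sp)$log_score
    max(s) - min(s)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})

test_that("module posterior has the stated closed forms", {
  expect_equal(module_posterior(c(1, 3), c(3, 1), 0.5), c(0.5, 0.5))
  expect_equal(module_posterior(log(9), 0, 0.5), c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(module_posterior(-50, 80, 1), c(1, 0))
  expect_equal(module_posterior(80, -50, 0), c(0, 1))
  p <- module_posterior(c(-3, 0.3), c(1.2, -1), 0.7)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # log-domain result equals the direct probability-domain computation
  direct <- 0.7 * exp(0.3) / (0.7 * exp(0.3) + 0.3 * exp(1.2))
  expect_equal(p[1], direct, tolerance = 1e-9)
  expect_error(module_posterior(numeric(0), 1), class = "dynform_invalid_input")
})

test_that("integration weights follow precision weighting with bias alpha", {
  expect_equal(integration_weights(observer_params(1, sigma_p = 2, sigma_theta = 2)),
               c(w_p = 0.5, w_theta = 0.5))
  # hand-computed reference: alpha 6, sigma_p 3.87, sigma_theta 1.82
  pp <- 6 / 3.87^2; pt <- 1 / 1.82^2
  w <- integration_weights(observer_params(6, sigma_p = 3.87, sigma_theta = 1.82))
  expect_equal(unname(w[1]), pp / (pp + pt), tolerance = 1e-12)
  # monotone approach to pure position weighting as alpha grows
  ws <- vapply(c(0.1, 1, 10, 100, 1e4), function(a)
    integration_weights(observer_params(a, sigma_p = 3, sigma_theta = 2))[[1]],
    numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_equal(integration_weights(observer_params(Inf, sigma_p = 3, sigma_theta = 2)),
               c(w_p = 1, w_theta = 0))
  expect_error(integration_weights(observer_params(1, sigma_p = -1, sigma_theta = 2)),
               class = "dynform_invalid_params")
})

test_that("frame integration is a convex combination of module posteriors", {
  w <- c(w_p = 0.5, w_theta = 0.5)
  expect_equal(integrate_frame(c(0.8, 0.2), c(0.8, 0.2), w), c(0.8, 0.2))
  expect_equal(integrate_frame(c(0.9, 0.1), c(0.1, 0.9), w), c(0.5, 0.5))
  expect_equal(integrate_frame(c(0.9, 0.1), c(0.1, 0.9), c(1, 0)), c(0.9, 0.1))
  expect_equal(sum(integrate_frame(c(0.7, 0.3), c(0.2, 0.8), c(0.3, 0.7))), 1)
})

test_that("congruent walker trials are decided correctly at low noise", {
  wl <- make_walker_sequence(n_frames = 60)
  banks <- list(left = build_template_bank(wl, 8),
                right = build_template_bank(opposite_sequence(wl), 8))
  params <- observer_params(1, sigma_p = 0.5, sigma_theta = 2)
  for (s in 1:15) {
    tr <- encode_with_noise(make_stimulus_trial(wl, 4, "congruent", seed = s),
                            0.5 * params$position_unit, 2)
    expect_equal(decide_walker(tr, banks, params)$choice, "left")
  }
})

test_that("orientation module places incongruent evidence in the opposite bank", {
  wl <- make_walker_sequence(n_frames = 60)
  wr <- opposite_sequence(wl)
  banks <- list(left = build_template_bank(wl, 8),
                right = build_template_bank(wr, 8))
  tr <- make_stimulus_trial(wl, 6, "incongruent", seed = 5)  # noiseless
  e <- tr$elements[tr$elements$frame == 1, ]
  sL <- orientation_frame_score(cbind(e$x, e$y), e$theta, banks$left, 0.5)
  sR <- orientation_frame_score(cbind(e$x, e$y), e$theta, banks$right, 0.5)
  # exhaustive over all 16 templates: the best match is a right-bank template
  expect_gt(max(sR$log_score), max(sL$log_score))
})

test_that("a single-frame trial reduces to the frame's integrated argmax", {
  wl <- make_walker_sequence(n_frames = 60)
  banks <- list(left = build_template_bank(wl, 8),
                right = build_template_bank(opposite_sequence(wl), 8))
  params <- observer_params(2, sigma_p = 1, sigma_theta = 3)
  tr <- encode_with_noise(make_stimulus_trial(wl, 5, "congruent", seed = 44), 0.05, 3)
  one <- tr
  one$elements <- tr$elements[tr$elements$frame == 1, ]
  one$n_frames <- 1L
  d <- decide_walker(one, banks, params)
  expect_equal(d$choice, names(which.max(d$aggregate)))
  expect_equal(d$frames$p_int, unname(d$aggregate["left"]))
})

test_that("noiseless congruent square steps ascend by one per frame", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  bank <- build_template_bank(sq, sq$period_frames)  # one template per period frame
  params <- observer_params(1, sigma_p = 0.1, sigma_theta = 0.5)
  tr <- make_stimulus_trial(sq, 8, "congruent", seed = 3)  # no encoding noise
  d <- decide_square(tr, bank, params)
  expect_true(all((d$steps - 1) %% bank$K == 0))  # +1 cyclically on every frame
  expect_equal(d$choice, "cw")
  expect_gt(d$aggregate[["cw"]], d$aggregate[["ccw"]])
})

test_that("time-reversing a square trial flips the choice and swaps aggregates", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  bank <- build_template_bank(sq, 8)
  params <- observer_params(3, sigma_p = 3, sigma_theta = 4)
  for (s in 1:10) {
    tr <- encode_with_noise(make_stimulus_trial(sq, 6, "incongruent", seed = 70 + s),
                            3 * params$position_unit, 4)
    d1 <- decide_square(tr, bank, params)
    d2 <- decide_square(reverse_trial(tr), bank, params)
    expect_equal(d2$aggregate[["cw"]], d1$aggregate[["ccw"]], tolerance = 1e-9)
    expect_equal(d2$aggregate[["ccw"]], d1$aggregate[["cw"]], tolerance = 1e-9)
    expect_equal(d2$choice, opposite_direction(d1$choice))
  }
})

test_that("sequence selectivity vanishes as sigma_s grows", {
  sq <- make_square_sequence(6, 60, 9, "cw")
  bank <- build_template_bank(sq, 8)
  tr <- encode_with_noise(make_stimulus_trial(sq, 6, "congruent", seed = 2), 0.1, 2)
  p1 <- observer_params(1, sigma_p = 2, sigma_theta = 2, sigma_s = sqrt(3.6))
  p2 <- observer_params(1, sigma_p = 2, sigma_theta = 2, sigma_s = 1e9)
  d1 <- decide_square(tr, bank, p1)
  d2 <- decide_square(tr, bank, p2)
  expect_gt(abs(d1$aggregate[[1]] - d1$aggregate[[2]]), 0)
  expect_equal(d2$aggregate[[1]], d2$aggregate[[2]])
})

test_that("mirroring a walker trial flips the decision", {
  wl <- make_walker_sequence(n_frames = 60)
  banks <- list(left = build_template_bank(wl, 8),
                right = build_template_bank(opposite_sequence(wl), 8))
  params <- observer_params(4, sigma_p = 4, sigma_theta = 3)
  for (s in 1:25) {
    tr <- encode_with_noise(make_stimulus_trial(wl, 4, "incongruent", seed = 300 + s),
                            4 * params$position_unit, 3)
    d1 <- decide_walker(tr, banks, params)
    d2 <- decide_walker(mirror_trial(tr), banks, params)
    expect_equal(d2$choice, opposite_direction(d1$choice))
  }
})

test_that("degenerate observer inputs are rejected", {
  bank <- random_toy_bank(3, 2, seed = 1)
  expect_error(position_frame_score(matrix(numeric(0), ncol = 2), bank, 1),
               class = "dynform_invalid_input")
  expect_error(orientation_frame_score(cbind(0, 0), c(10, 20), bank, 1),
               class = "dynform_invalid_input")
  sq <- make_square_sequence(6, 60, 9, "cw")
  b <- build_template_bank(sq, 8)
  tr <- make_stimulus_trial(sq, 4, "congruent", seed = 1)
  tr$elements <- tr$elements[tr$elements$frame == 1, ]
  tr$n_frames <- 1L
  expect_error(decide_square(tr, b, observer_params(1, sigma_p = 1, sigma_theta = 1)),
               class = "dynform_invalid_input")
  expect_error(observer_params(-1), class = "dynform_invalid_params")
  expect_error(observer_params(1, prior = 2), class = "dynform_invalid_params")
})
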
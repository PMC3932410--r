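# Independent brute-force oracles (plain nested loops, no vectorisation) and
# small fixtures used across the tests. These deliberately re-derive the
# arithmetic from first principles rather than calling package internals.

# scalar point-to-segment distance, written out longhand
seg_dist_scalar <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  t <- ((px - x0) * vx + (py - y0) * vy) / (vx^2 + vy^2)
  t <- min(max(t, 0), 1)
  sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
}

fold90 <- function(d) {
  d <- abs(d) %% 180
  if (d > 90) 180 - d else d
}

# brute-force position-module log-scores: loop templates, elements, segments
oracle_position_score <- function(pos, bank, sigma_p) {
  v <- bank$sigma_tp^2 + sigma_p^2
  out <- numeric(bank$K)
  for (k in seq_len(bank$K)) {
    segk <- bank$seg[bank$seg$template == k, ]
    tot <- 0
    for (i in seq_len(nrow(pos))) {
      dmin <- Inf
      for (s in seq_len(nrow(segk))) {
        d <- seg_dist_scalar(pos[i, 1], pos[i, 2],
                             segk$x0[s], segk$y0[s], segk$x1[s], segk$y1[s])
        if (d < dmin) dmin <- d
      }
      tot <- tot + stats::dnorm(dmin, 0, sqrt(v), log = TRUE)
    }
    out[k] <- tot
  }
  out
}

# brute-force orientation-module log-scores: nearest segment by position,
# folded circular difference of orientations
oracle_orientation_score <- function(pos, theta, bank, sigma_theta) {
  v <- bank$sigma_ttheta^2 + sigma_theta^2
  out <- numeric(bank$K)
  for (k in seq_len(bank$K)) {
    segk <- bank$seg[bank$seg$template == k, ]
    tot <- 0
    for (i in seq_len(nrow(pos))) {
      dmin <- Inf; best <- NA
      for (s in seq_len(nrow(segk))) {
        d <- seg_dist_scalar(pos[i, 1], pos[i, 2],
                             segk$x0[s], segk$y0[s], segk$x1[s], segk$y1[s])
        if (d < dmin) { dmin <- d; best <- s }
      }
      dth <- fold90(theta[i] - segk$theta[best])
      tot <- tot + stats::dnorm(dth, 0, sqrt(v), log = TRUE)
    }
    out[k] <- tot
  }
  out
}

# a random toy template bank with K templates of S segments each
random_toy_bank <- function(K, S, seed, sigma_tp = 0.8, sigma_ttheta = 15) {
  set.seed(seed)
  seg <- do.call(rbind, lapply(seq_len(K), function(k) {
    x0 <- runif(S, -4, 4); y0 <- runif(S, -4, 4)
    ang <- runif(S, 0, 2 * pi); len <- runif(S, 0.5, 3)
    data.frame(template = k, label = paste0("s", seq_len(S)),
               x0 = x0, y0 = y0, x1 = x0 + len * cos(ang), y1 = y0 + len * sin(ang),
               stringsAsFactors = FALSE)
  }))
  seg$theta <- segment_orientation(seg$x0, seg$y0, seg$x1, seg$y1)
  structure(list(hypothesis = "left", kind = "toy", K = K,
                 frame_index = seq_len(K) - 1L, frames = NULL, seg = seg,
                 sigma_tp = sigma_tp, sigma_ttheta = sigma_ttheta),
            class = "template_bank")
}

# 95% normal-approximation binomial CI
binom_ci <- function(p, n) {
  se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
  c(lo = max(0, p - 1.96 * se), hi = min(1, p + 1.96 * se))
}

ci_overlap <- function(p1, p2, n) {
  a <- binom_ci(p1, n); b <- binom_ci(p2, n)
  a["lo"] <= b["hi"] && b["lo"] <= a["hi"]
}

# a monotonicity check that tolerates comparisons whose binomial CIs overlap:
# ordered violations only count when the proportions are distinguishable
mono_ok <- function(props, n, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  for (i in seq_len(length(props) - 1)) {
    bad <- if (direction == "decreasing") props[i + 1] > props[i]
           else props[i + 1] < props[i]
    if (bad && !ci_overlap(props[i], props[i + 1], n)) return(FALSE)
  }
  TRUE
}
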
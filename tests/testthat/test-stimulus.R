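test_that("stimulation-range membership is an inclusive rectangle test", {
  stim <- stimulus_config("landmark")
  cc <- stim$center_cm
  expect_true(in_stimulation_range(cc[1], cc[2], stim))
  expect_false(in_stimulation_range(cc[1] - 9, cc[2], stim))
  expect_true(in_stimulation_range(cc[1] - 8, cc[2], stim))   # boundary
  expect_true(in_stimulation_range(cc[1], cc[2] + 5, stim))   # boundary
  expect_false(in_stimulation_range(cc[1], cc[2] + 5 + 1e-9, stim))
})

test_that("stimulation metrics handle the degenerate occupancy cases", {
  arena <- default_arena()
  stim <- stimulus_config("vibration", arena = arena)
  # parked at centre: one bout, 100% of time, zero speeds
  tr <- stationary_fish(180, sl = 8)
  k <- compute_kinematics(tr)
  m <- compute_stimulation_metrics(tr, k, stim, 8, 180)
  expect_equal(m$s_frequency, 1)
  expect_equal(m$s_time_pct, 100)
  expect_equal(m$s_speed_sl_s, 0)
  # never in the zone
  tr2 <- wall_hugger(60, sl = 8)
  k2 <- compute_kinematics(tr2)
  m2 <- compute_stimulation_metrics(tr2, k2, stim, 8, 60)
  expect_equal(m2$s_frequency, 0)
  expect_equal(m2$s_time_pct, 0)
  expect_equal(m2$s_max_speed_sl_s, 0)
})

test_that("stimulation metrics match the per-sample oracle on simulations", {
  arena <- default_arena()
  stim <- stimulus_config("vibration", arena = arena)
  for (seed in c(2, 9)) {
    sim <- random_sim_trial(seed, duration_s = 300)
    tr <- sim$traj
    k <- compute_kinematics(tr)
    m <- compute_stimulation_metrics(tr, k, stim, sim$sl, 300)
    o <- oracle_s_metrics(tr, stim, sim$sl, 300)
    for (col in names(o))
      expect_equal(m[[col]], o[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("approach angle follows vector geometry and is rotation invariant", {
  stim <- stimulus_config("landmark")
  cc <- stim$center_cm
  # heading due east, stimulus due east of the fish
  expect_equal(approach_angle(0, cc[1] - 5, cc[2], stim), 0)
  # stimulus perpendicular to heading
  expect_equal(approach_angle(pi / 2, cc[1] - 5, cc[2], stim), 90)
  # 45 degrees
  expect_equal(approach_angle(pi / 4, cc[1] - 5, cc[2], stim), 45)
  # rotating fish position and heading about the stimulus centre
  set.seed(1)
  for (i in 1:20) {
    px <- cc[1] + runif(1, -4, 4); py <- cc[2] + runif(1, -4, 4)
    hd <- runif(1, -pi, pi); phi <- runif(1, -pi, pi)
    rot <- function(x, y) c(cc[1] + cos(phi) * (x - cc[1]) - sin(phi) * (y - cc[2]),
                            cc[2] + sin(phi) * (x - cc[1]) + cos(phi) * (y - cc[2]))
    p2 <- rot(px, py)
    expect_equal(approach_angle(hd, px, py, stim),
                 approach_angle(hd + phi, p2[1], p2[2], stim),
                 tolerance = 1e-9)
  }
})

test_that("approach distance is the body-segment to boundary distance", {
  stim <- stimulus_config("landmark")  # radius 2.5
  cc <- stim$center_cm
  # centroid 10 cm from the centre, heading straight at it, SL 8:
  # nose at 6 cm from centre, minus radius -> 3.5 cm -> 0.4375 SL
  expect_equal(approach_distance(cc[1] - 10, cc[2], 0, 8, stim), 0.4375)
  # touching: centroid 4 cm away, nose overlaps the cylinder
  expect_equal(approach_distance(cc[1] - 4, cc[2], 0, 8, stim), 0)
  # numeric oracle: densely sampled body points, arbitrary pose
  set.seed(2)
  for (i in 1:25) {
    px <- cc[1] + runif(1, -12, 12); py <- cc[2] + runif(1, -8, 8)
    hd <- runif(1, -pi, pi); sl <- runif(1, 5, 10)
    s <- seq(-sl / 2, sl / 2, length.out = 4001)
    bx <- px + s * cos(hd); by <- py + s * sin(hd)
    brute <- max(0, min(sqrt((bx - cc[1])^2 + (by - cc[2])^2)) - 2.5) / sl
    expect_equal(approach_distance(px, py, hd, sl, stim), brute,
                 tolerance = 1e-6)
  }
  # monotone non-increasing under radial approach with fixed heading
  d <- sapply(seq(14, 3, by = -0.5), function(r)
    approach_distance(cc[1] - r, cc[2], pi / 3, 8, stim))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("only the first three approaches are kept, matching bout runs", {
  arena <- default_arena()
  stim <- stimulus_config("landmark", arena = arena)
  cc <- stim$center_cm
  # track oscillating in and out of the zone five times along x
  half <- stim$zone_length_cm / 2
  xwave <- cc[1] + (half + 4) * sin(seq(0, 5 * pi - 0.1, length.out = 2000))
  tr <- traj_from_xy(xwave, rep(cc[2], 2000), sl = 8)
  k <- compute_kinematics(tr)
  ap <- detect_approaches(tr, k, stim, 8)
  expect_equal(ap$order, 1:3)
  # bout boundaries agree with a run-length oracle on zone membership
  inz <- in_stimulation_range(tr$x_cm, tr$y_cm, stim)
  r <- rle(inz)
  starts <- (cumsum(r$lengths) - r$lengths + 1)[r$values]
  expect_gte(sum(r$values), 5)
  # each approach time falls inside its corresponding bout
  ends <- cumsum(r$lengths)[r$values]
  for (j in 1:3) {
    idx <- which(tr$time_s == ap$time_s[j])
    expect_true(idx >= starts[j] && idx <= ends[j])
  }
  # never entering the zone -> empty
  tr0 <- wall_hugger(30, sl = 8)
  k0 <- compute_kinematics(tr0)
  expect_equal(nrow(detect_approaches(tr0, k0, stim, 8)), 0)
})
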
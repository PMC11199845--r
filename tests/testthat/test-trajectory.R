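test_that("trajectory CSV round-trips and validates its contract", {
  arena <- default_arena()
  fish <- test_fish()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x_cm,y_cm",
               "0,0.00,1.0,1.0", "1,0.04,1.2,1.0", "2,0.08,1.4,1.0"), f)
  tr <- read_trajectory_csv(f, arena, fish)
  expect_s3_class(tr, "trajectory")
  expect_equal(nrow(tr), 3)
  expect_false(any(tr$gap_mask))
  expect_equal(tr$x_cm, c(1.0, 1.2, 1.4))

  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f2)
  tr2 <- read_trajectory_csv(f2, arena, fish)
  expect_equal(tr2$x_cm, tr$x_cm)
  expect_equal(tr2$time_s, tr$time_s)

  # missing column
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x", "0,0,1"), f3)
  expect_error(read_trajectory_csv(f3, arena, fish), "missing columns")

  # shuffled time
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x_cm,y_cm",
               "0,0.04,1,1", "1,0.00,2,1"), f4)
  expect_error(read_trajectory_csv(f4, arena, fish), "increasing")

  # far out of arena, offending rows listed
  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x_cm,y_cm",
               "0,0.00,1,1", "1,0.04,47.5,1"), f5)
  expect_error(read_trajectory_csv(f5, arena, fish), "rows: 2")

  # mild (<= 1 cm) overshoot is clamped, not fatal
  f6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x_cm,y_cm",
               "0,0.00,-0.4,1", "1,0.04,1,28.6"), f6)
  tr6 <- read_trajectory_csv(f6, arena, fish)
  expect_equal(tr6$x_cm[1], 0)
  expect_equal(tr6$y_cm[2], 28)

  # too many gaps -> quality error
  f7 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,x_cm,y_cm",
               "0,0.00,1,1", "1,0.04,,", "2,0.08,,", "3,0.12,,",
               "4,0.16,1,1"), f7)
  expect_error(read_trajectory_csv(f7, arena, fish), "quality")
})

test_that("fill_gaps interpolates short gaps linearly and is idempotent", {
  # 0.2 s gap between (0,0)-ish points at 25 Hz: 4 interior samples
  x <- c(0, rep(NA, 4), 1); y <- rep(0, 6); y[2:5] <- NA
  tr <- traj_from_xy(x, y)
  filled <- fill_gaps(tr, max_gap_s = 0.5)
  expect_equal(filled$x_cm, c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(filled$y_cm, rep(0, 6))
  expect_equal(filled$gap_mask, c(FALSE, rep(TRUE, 4), FALSE))
  expect_equal(unique(filled$segment), 1L)
  expect_identical(as.data.frame(fill_gaps(filled)), as.data.frame(filled))

  # no-gap input passes through unchanged
  tr0 <- traj_from_xy(c(1, 2, 3), c(1, 1, 1))
  expect_identical(as.data.frame(fill_gaps(tr0)), as.data.frame(tr0))
})

test_that("gaps longer than the limit split the trajectory into segments", {
  n_gap <- 50  # 2 s at 25 Hz
  x <- c(seq(0, 1, length.out = 10), rep(NA, n_gap), seq(5, 6, length.out = 10))
  y <- rep(1, length(x)); y[11:(10 + n_gap)] <- NA
  tr <- traj_from_xy(x, y)
  filled <- fill_gaps(tr, max_gap_s = 0.5)
  expect_equal(length(unique(filled$segment)), 2L)
  expect_equal(nrow(filled), 20)          # gap samples dropped
  expect_false(any(is.na(filled$x_cm)))
  # path length excludes the jump across the split
  expect_equal(path_length_cm(filled), 2, tolerance = 1e-12)
})

test_that("kinematics recover speed, resting and heading", {
  # constant-velocity track at 1 cm/s
  n <- 100
  tr <- traj_from_xy(seq(0, by = 0.04, length.out = n), rep(5, n))
  k <- compute_kinematics(tr)
  expect_equal(k$speed_cm_s, rep(1, n), tolerance = 1e-12)
  expect_false(any(k$resting_mask))
  expect_equal(k$heading_rad[3:(n - 2)], rep(0, n - 4), tolerance = 1e-12)

  # stationary track
  trs <- stationary_fish(4)
  ks <- compute_kinematics(trs)
  expect_equal(ks$speed_cm_s, rep(0, nrow(trs)))
  expect_true(all(ks$resting_mask))
  expect_true(all(is.na(ks$heading_rad)))

  # circular track: central-difference heading is tangent to the circle
  m <- 500; dt <- 0.04; r <- 5
  ang <- (seq_len(m) - 1) * dt * 0.5      # 0.5 rad/s
  trc <- traj_from_xy(22.5 + r * cos(ang), 14 + r * sin(ang))
  kc <- compute_kinematics(trc)
  interior <- 3:(m - 2)
  tangent <- ang[interior] + pi / 2
  err <- atan2(sin(kc$heading_rad[interior] - tangent),
               cos(kc$heading_rad[interior] - tangent))
  expect_lt(max(abs(err)) * 180 / pi, 2)

  # short trajectory: headings undefined, with a warning
  expect_warning(k3 <- compute_kinematics(traj_from_xy(c(1, 2, 3), c(1, 1, 1))),
                 "heading window")
  expect_true(all(is.na(k3$heading_rad)))
})

test_that("path length is translation invariant and bounds the chord", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 50
    x <- cumsum(rnorm(n, 0, 0.2)) + 20
    y <- cumsum(rnorm(n, 0, 0.2)) + 14
    tr <- traj_from_xy(x, y)
    shift <- traj_from_xy(x + 3, y - 2)
    expect_equal(path_length_cm(tr), path_length_cm(shift), tolerance = 1e-12)
    chord <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
    expect_gte(path_length_cm(tr) + 1e-12, chord)
  }
})
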
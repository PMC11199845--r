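# Independent brute-force recomputation of the indicators, written as a
# per-sample classifier with explicit loops: no code shared with the
# package's event segmentation.

oracle_wf_metrics <- function(t, arena, sl, testing_time_s,
                              rest_thresh = 0.2, belt_sl = 0.5,
                              event_min_sl = 2) {
  x <- t$x_cm; y <- t$y_cm; ts <- t$time_s; n <- length(x)
  b <- belt_sl * sl
  in_belt <- (x <= b) | (x >= arena$width_cm - b) |
             (y <= b) | (y >= arena$height_cm - b)
  # per-sample speed: preceding interval (first sample inherits interval 1)
  spd <- numeric(n)
  for (i in 2:n)
    spd[i] <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / (ts[i] - ts[i - 1])
  spd[1] <- spd[2]
  resting <- spd < rest_thresh
  # walk runs of belt membership manually
  tot_path <- 0; tot_dur <- 0; tot_mobile <- 0; freq <- 0
  i <- 1
  while (i <= n) {
    if (!in_belt[i]) { i <- i + 1; next }
    j <- i
    while (j < n && in_belt[j + 1]) j <- j + 1
    path <- 0; mobile <- 0
    if (j > i) for (q in (i + 1):j) {
      path <- path + sqrt((x[q] - x[q - 1])^2 + (y[q] - y[q - 1])^2)
      if (!resting[q]) mobile <- mobile + (ts[q] - ts[q - 1])
    }
    if (path >= event_min_sl * sl) {
      freq <- freq + 1
      tot_path <- tot_path + path
      tot_dur <- tot_dur + (ts[j] - ts[i])
      tot_mobile <- tot_mobile + mobile
    }
    i <- j + 1
  }
  rest_time <- 0
  for (i in 2:n) if (resting[i]) rest_time <- rest_time + (ts[i] - ts[i - 1])
  if (resting[1]) rest_time <- rest_time  # first sample carries no interval
  list(wf_distance_sl = tot_path / sl,
       wf_frequency = freq,
       wf_time_pct = 100 * tot_dur / testing_time_s,
       wf_resting_time_s = rest_time,
       wf_speed_sl_s = if (tot_mobile > 0) tot_path / tot_mobile / sl else 0,
       wf_max_speed_sl_s = max(spd) / sl)
}

oracle_s_metrics <- function(t, stimulus, sl, testing_time_s,
                             rest_thresh = 0.2) {
  x <- t$x_cm; y <- t$y_cm; ts <- t$time_s; n <- length(x)
  cx <- stimulus$center_cm[1]; cy <- stimulus$center_cm[2]
  inz <- abs(x - cx) <= stimulus$zone_length_cm / 2 &
         abs(y - cy) <= stimulus$zone_width_cm / 2
  spd <- numeric(n)
  for (i in 2:n)
    spd[i] <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / (ts[i] - ts[i - 1])
  spd[1] <- spd[2]
  resting <- spd < rest_thresh
  freq <- 0
  for (i in 1:n) if (inz[i] && (i == 1 || !inz[i - 1])) freq <- freq + 1
  zone_time <- 0
  for (i in 2:n) if (inz[i]) zone_time <- zone_time + (ts[i] - ts[i - 1])
  mob <- inz & !resting
  list(s_frequency = freq,
       s_time_pct = 100 * zone_time / testing_time_s,
       s_speed_sl_s = if (any(mob)) mean(spd[mob]) / sl else 0,
       s_max_speed_sl_s = if (any(inz)) max(spd[inz]) / sl else 0)
}

# direct (non-profiled) log-likelihood of the lambda model, built on
# solve() and determinant() rather than the package's Cholesky route
oracle_lambda_loglik <- function(lambda, tree, y) {
  C <- ape::vcv(tree)
  d <- diag(C); C <- C * lambda; diag(C) <- d
  y <- y[rownames(C)]
  n <- length(y)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  r <- y - mu
  s2 <- as.numeric(t(r) %*% Ci %*% r) / n
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  -n / 2 * log(2 * pi) - n / 2 * log(s2) - ld / 2 - n / 2
}

oracle_lambda_grid <- function(tree, y, npts = 1001) {
  grid <- seq(0, 1, length.out = npts)
  ll <- vapply(grid, oracle_lambda_loglik, 0, tree = tree, y = y)
  list(lambda = grid[which.max(ll)], loglik = max(ll))
}

# mixed-preset simulated trial used by oracle-equivalence tests
random_sim_trial <- function(seed, duration_s = 600) {
  morph <- .subset2(list("eyeless", "micro_eyed", "normal_eyed"),
                    (seed %% 3) + 1)
  sl <- 6 + (seed %% 5)
  ind <- individual_record(paste0("sim", seed), "S_test", morph, sl)
  cfg <- morph_preset(morph, duration_s = duration_s, seed = seed)
  list(traj = simulate_trajectory(cfg, default_arena(), ind), sl = sl,
       ind = ind)
}
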
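#' Swim simulator configuration
#'
#' Parameters of the boundary-attracted correlated random walk used to
#' generate synthetic trials. The fish alternates between a mobile and a
#' resting state via a two-state Markov chain; while mobile its heading
#' receives wrapped-normal turning noise, a wall-attraction torque inside
#' the wall sensing range, and an optional bias toward a stimulus; the
#' position advances along the heading with specular reflection at the
#' walls.
#'
#' @param duration_s Trial duration (s).
#' @param dt_s Time step (s), default 0.04 (25 Hz).
#' @param speed_mean_sl_s Arithmetic mean mobile speed, SL/s.
#' @param speed_sd Log-sd of the lognormal per-step speed draw.
#' @param turn_kappa Concentration of the wrapped-normal heading noise
#'   (per-step sd = 1/sqrt(kappa)), default 8.
#' @param wall_attraction Steering gain (per s) toward wall-parallel
#'   travel at the preferred offset, active inside the sensing range.
#' @param wall_sense_sl Wall sensing range in SL, default 1.
#' @param wall_offset_sl Preferred distance from the wall in SL while
#'   wall-following, default 0.25 (mid-belt).
#' @param stim_attraction Steering gain (per s) toward the stimulus.
#' @param rest_on_rate_hz Rate (per s) of entering the resting state.
#' @param rest_off_rate_hz Rate (per s) of leaving the resting state.
#' @param seed Integer RNG seed; trajectories are reproducible given it.
#' @return An object of class `swim_sim_config`.
#' @export
swim_sim_config <- function(duration_s = 600, dt_s = 0.04,
                            speed_mean_sl_s = 0.45, speed_sd = 0.35,
                            turn_kappa = 8,
                            wall_attraction = 0, wall_sense_sl = 1,
                            wall_offset_sl = 0.25,
                            stim_attraction = 0,
                            rest_on_rate_hz = 0.03, rest_off_rate_hz = 0.4,
                            seed = 1L) {
  stopifnot(dt_s > 0, duration_s > 0, speed_mean_sl_s > 0, turn_kappa > 0,
            wall_attraction >= 0, stim_attraction >= 0,
            rest_on_rate_hz >= 0, rest_off_rate_hz >= 0)
  structure(as.list(environment()), class = "swim_sim_config")
}

#' Eye-morph simulator presets
#'
#' Calibrated simulator configurations for the three eye morphs. Mean
#' mobile speeds are set to the observed per-morph wall-following speeds
#' (0.52, 0.45 and 0.36 SL/s for eyeless, micro-eyed and normal-eyed
#' fish); wall attraction decreases strictly from eyeless to normal-eyed,
#' and resting rates increase, so that simulated studies reproduce the
#' qualitative eyeless > micro-eyed > normal-eyed wall-following gradient.
#' Calibration constants are stored as data in an internal table.
#'
#' @param name `"eyeless"`, `"micro_eyed"` or `"normal_eyed"`.
#' @param duration_s Trial duration (s), default 600.
#' @param seed RNG seed for the resulting config.
#' @return A `swim_sim_config` with attribute `morph`.
#' @export
morph_preset <- function(name, duration_s = 600, seed = 1L) {
  name <- match.arg(name, .eye_morphs)
  p <- .morph_calibration[[name]]
  cfg <- swim_sim_config(duration_s = duration_s,
                         speed_mean_sl_s = p$target_speed_sl_s,
                         wall_attraction = p$wall_attraction,
                         rest_on_rate_hz = p$rest_on_rate_hz,
                         rest_off_rate_hz = p$rest_off_rate_hz,
                         seed = seed)
  attr(cfg, "morph") <- name
  cfg
}

# preset calibration constants (data, not code): speeds are the observed
# per-morph means in SL/s; attraction/rest rates grade the morphs.
.morph_calibration <- list(
  eyeless     = list(target_speed_sl_s = 0.52, wall_attraction = 5.0,
                     rest_on_rate_hz = 0.02, rest_off_rate_hz = 0.50),
  micro_eyed  = list(target_speed_sl_s = 0.45, wall_attraction = 2.5,
                     rest_on_rate_hz = 0.03, rest_off_rate_hz = 0.40),
  normal_eyed = list(target_speed_sl_s = 0.36, wall_attraction = 1.2,
                     rest_on_rate_hz = 0.05, rest_off_rate_hz = 0.30))

.wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Simulate one swimming trajectory
#'
#' Generates a synthetic centroid track obeying the trajectory-core
#' invariants: positions never leave the arena, times are strictly
#' increasing at the configured rate, and identical seeds give identical
#' tracks.
#'
#' @param cfg A [swim_sim_config()].
#' @param arena An [arena_config()].
#' @param individual An [individual_record()] (provides SL).
#' @param stimulus Optional [stimulus_config()]; with
#'   `cfg$stim_attraction > 0` the heading is biased toward its centre.
#' @param assay Assay label stored on the trajectory.
#' @return A gap-free `trajectory`.
#' @export
simulate_trajectory <- function(cfg, arena, individual, stimulus = NULL,
                                assay = "no_stimulation_10min") {
  sl <- individual$standard_length_cm
  n <- as.integer(round(cfg$duration_s / cfg$dt_s)) + 1L
  dt <- cfg$dt_s
  W <- arena$width_cm; H <- arena$height_cm
  sense <- cfg$wall_sense_sl * sl
  d0 <- cfg$wall_offset_sl * sl
  beta <- cfg$wall_attraction; gamma <- cfg$stim_attraction
  has_stim <- !is.null(stimulus) && gamma > 0
  if (has_stim) { sx <- stimulus$center_cm[1]; sy <- stimulus$center_cm[2] }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  # pre-drawn randomness; only the state recursion stays in the loop
  noise <- stats::rnorm(n, 0, 1 / sqrt(cfg$turn_kappa))
  meanlog <- log(cfg$speed_mean_sl_s * sl) - cfg$speed_sd^2 / 2
  speeds <- stats::rlnorm(n, meanlog, cfg$speed_sd)
  u_switch <- stats::runif(n)
  p_rest <- 1 - exp(-cfg$rest_on_rate_hz * dt)
  p_wake <- 1 - exp(-cfg$rest_off_rate_hz * dt)

  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, 0.05 * W, 0.95 * W)
  y[1] <- stats::runif(1, 0.05 * H, 0.95 * H)
  th <- stats::runif(1, -pi, pi)
  resting <- FALSE
  for (i in 2:n) {
    resting <- if (resting) u_switch[i] >= p_wake else u_switch[i] < p_rest
    if (resting) { x[i] <- x[i - 1]; y[i] <- y[i - 1]; next }
    xi <- x[i - 1]; yi <- y[i - 1]
    # wall attraction: align with the wall tangent while holding the
    # preferred offset d0 from the nearest wall
    d <- min(xi, W - xi, yi, H - yi)
    if (beta > 0 && d <= sense) {
      if (d == xi)          { nx <- 1;  ny <- 0 }   # left wall, normal points in
      else if (d == W - xi) { nx <- -1; ny <- 0 }
      else if (d == yi)     { nx <- 0;  ny <- 1 }
      else                  { nx <- 0;  ny <- -1 }
      # tangent direction closest to current travel
      tx <- -ny; ty <- nx
      if (cos(th) * tx + sin(th) * ty < 0) { tx <- -tx; ty <- -ty }
      err <- 2 * (d - d0) / sense                   # >0: too far from wall
      gx <- tx - err * nx; gy <- ty - err * ny
      th <- th + beta * dt * sin(atan2(gy, gx) - th)
    }
    if (has_stim)
      th <- th + gamma * dt * sin(atan2(sy - yi, sx - xi) - th)
    th <- .wrap_angle(th + noise[i])
    xn <- xi + speeds[i] * dt * cos(th)
    yn <- yi + speeds[i] * dt * sin(th)
    # specular reflection at the four walls
    if (xn < 0)      { xn <- -xn;         th <- .wrap_angle(pi - th) }
    else if (xn > W) { xn <- 2 * W - xn;  th <- .wrap_angle(pi - th) }
    if (yn < 0)      { yn <- -yn;         th <- -th }
    else if (yn > H) { yn <- 2 * H - yn;  th <- -th }
    x[i] <- xn; y[i] <- yn
  }
  trajectory(seq(0, by = dt, length.out = n), x, y, individual, arena,
             assay = assay, sample_rate_hz = 1 / dt, validate = FALSE)
}

#' Configuration for Brownian-motion trait simulation
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param sigma2 Brownian rate parameter (trait variance per unit branch
#'   length), >= 0.
#' @param lambda_true Pagel's lambda of the generating model, in \[0, 1\]:
#'   off-diagonal phylogenetic covariances are multiplied by this value.
#' @param root_value Trait value at the root.
#' @param seed RNG seed.
#' @return An object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(tree, sigma2 = 1, lambda_true = 1,
                             root_value = 0, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0,
            lambda_true >= 0, lambda_true <= 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  structure(list(tree = tree, sigma2 = sigma2, lambda_true = lambda_true,
                 root_value = root_value, seed = as.integer(seed)),
            class = "trait_sim_config")
}

#' Simulate species traits under lambda-transformed Brownian motion
#'
#' Draws one multivariate-normal trait vector with covariance
#' `sigma2 * C(lambda)`, where `C` is the shared-branch-length matrix of
#' the tree with off-diagonals scaled by `lambda_true`, centred on the
#' root value.
#'
#' @param cfg A [trait_sim_config()].
#' @param n_traits Number of independent replicate trait columns.
#' @return data.frame with `species` and trait columns `trait_1..n`.
#' @export
simulate_bm_traits <- function(cfg, n_traits = 1) {
  C <- bm_covariance(cfg$tree, cfg$lambda_true)
  ntip <- nrow(C)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (cfg$sigma2 == 0) {
    traits <- matrix(cfg$root_value, ntip, n_traits)
  } else {
    L <- chol(cfg$sigma2 * C + diag(1e-12, ntip))
    z <- matrix(stats::rnorm(ntip * n_traits), ntip, n_traits)
    traits <- cfg$root_value + crossprod(L, z)
  }
  out <- data.frame(species = rownames(C))
  for (j in seq_len(n_traits)) out[[paste0("trait_", j)]] <- traits[, j]
  out
}
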
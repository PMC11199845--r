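# shared builders for tests

default_arena <- function() arena_config()

test_fish <- function(sl = 8, morph = "eyeless", id = "f1") {
  individual_record(id, "S_test", morph, sl)
}

# trajectory from explicit coordinates at 25 Hz
traj_from_xy <- function(x, y, sl = 8, arena = default_arena(),
                         assay = "no_stimulation_10min", dt = 0.04,
                         morph = "eyeless") {
  trajectory(seq(0, by = dt, length.out = length(x)), x, y,
             test_fish(sl, morph), arena, assay = assay)
}

# wall-hugging swimmer: back and forth along the bottom wall at y = offset,
# exactly `step_cm` per 0.04 s sample, for `duration_s`
wall_hugger <- function(duration_s = 600, speed_cm_s = 4.5, sl = 9,
                        offset = 1, x0 = 1, span_steps = 230) {
  dt <- 0.04
  n <- as.integer(duration_s / dt) + 1L
  step <- speed_cm_s * dt
  pos <- seq_len(n) - 1L
  cycle <- pos %% (2L * span_steps)
  along <- ifelse(cycle <= span_steps, cycle, 2L * span_steps - cycle)
  traj_from_xy(x0 + along * step, rep(offset, n), sl = sl)
}

stationary_fish <- function(duration_s = 600, sl = 9, x = 22.5, y = 14) {
  dt <- 0.04
  n <- as.integer(duration_s / dt) + 1L
  traj_from_xy(rep(x, n), rep(y, n), sl = sl)
}

# balanced ultrametric tree with 2^k tips and unit branch lengths
balanced_tree <- function(k = 6) {
  tr <- ape::stree(2^k, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
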
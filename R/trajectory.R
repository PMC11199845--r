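#' Construct a trajectory object
#'
#' A trajectory is the time-stamped 2-D centroid track of one individual in
#' one trial. Positions are arena-frame cm. Samples whose position is `NA`
#' are tracking gaps; [fill_gaps()] interpolates short ones and splits the
#' track into independent segments at long ones.
#'
#' @param times_s Strictly increasing sample times (s).
#' @param x_cm,y_cm Centroid coordinates (cm); `NA` marks a tracking gap.
#' @param individual An [individual_record()].
#' @param arena An [arena_config()].
#' @param assay Assay type, one of `"no_stimulation_10min"`,
#'   `"landmark_5min"`, `"vibration_3min"`.
#' @param sample_rate_hz Nominal sampling rate (Hz), default 25.
#' @param gap_mask Logical, `TRUE` where the position was interpolated.
#' @param segment Integer segment id per sample (gaps longer than the
#'   interpolation limit split the track).
#' @param validate Check coordinates against the arena (default `TRUE`).
#' @return An object of class `trajectory`: a data.frame with columns
#'   `time_s, x_cm, y_cm, gap_mask, segment` and attributes `individual`,
#'   `arena`, `assay`, `sample_rate_hz`.
#' @export
trajectory <- function(times_s, x_cm, y_cm, individual, arena,
                       assay = "no_stimulation_10min",
                       sample_rate_hz = 25,
                       gap_mask = NULL, segment = NULL, validate = TRUE) {
  assay <- match.arg(assay, names(.assay_types))
  n <- length(times_s)
  stopifnot(length(x_cm) == n, length(y_cm) == n)
  if (n > 1 && any(diff(times_s) <= 0))
    stop("trajectory times must be strictly increasing")
  if (is.null(gap_mask)) gap_mask <- is.na(x_cm) | is.na(y_cm)
  if (is.null(segment)) segment <- rep.int(1L, n)
  df <- data.frame(time_s = as.numeric(times_s),
                   x_cm = as.numeric(x_cm), y_cm = as.numeric(y_cm),
                   gap_mask = as.logical(gap_mask),
                   segment = as.integer(segment))
  if (validate && n > 0) {
    ok <- is.na(df$x_cm) |
      (df$x_cm >= 0 & df$x_cm <= arena$width_cm &
       df$y_cm >= 0 & df$y_cm <= arena$height_cm)
    if (!all(ok)) {
      # tolerate up to 1 cm of tracking overshoot by clamping
      over <- pmax(-df$x_cm, df$x_cm - arena$width_cm,
                   -df$y_cm, df$y_cm - arena$height_cm)
      over[is.na(over)] <- 0
      bad <- which(over > 1)
      if (length(bad))
        stop("positions outside arena by > 1 cm at rows: ",
             paste(utils::head(bad, 10), collapse = ", "))
      df$x_cm <- pmin(pmax(df$x_cm, 0), arena$width_cm)
      df$y_cm <- pmin(pmax(df$y_cm, 0), arena$height_cm)
    }
  }
  structure(df, class = c("trajectory", "data.frame"),
            individual = individual, arena = arena, assay = assay,
            sample_rate_hz = sample_rate_hz)
}

#' @export
print.trajectory <- function(x, ...) {
  ind <- attr(x, "individual")
  cat(sprintf("<trajectory> %s (%s), %d samples, %.1f s, %d gap(s), %d segment(s)\n",
              ind$individual_id, attr(x, "assay"), nrow(x),
              if (nrow(x)) diff(range(x$time_s)) else 0,
              sum(x$gap_mask), length(unique(x$segment))))
  invisible(x)
}

#' Testing time of an assay type
#' @param assay Assay type string.
#' @return Duration in seconds (600, 300 or 180).
#' @export
assay_duration_s <- function(assay) {
  assay <- match.arg(assay, names(.assay_types))
  unname(.assay_types[assay])
}

#' Read a trajectory CSV export
#'
#' Reads a tracking export with header `frame,time_s,x_cm,y_cm`; blank
#' x/y cells are tracking gaps. The returned trajectory keeps gaps
#' unfilled (use [fill_gaps()]).
#'
#' @param path CSV path.
#' @param arena An [arena_config()].
#' @param individual An [individual_record()].
#' @param assay Assay type (see [trajectory()]).
#' @param max_gap_frac Maximum tolerated fraction of gap samples
#'   (default 0.5); above this the file is rejected as unanalysable.
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path, arena, individual,
                                assay = "no_stimulation_10min",
                                max_gap_frac = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "time_s", "x_cm", "y_cm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trajectory CSV missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop("trajectory CSV time_s is not strictly increasing")
  gap <- is.na(df$x_cm) | is.na(df$y_cm)
  if (nrow(df) > 0 && mean(gap) > max_gap_frac)
    stop(sprintf("trajectory quality too low: %.0f%% gap samples (limit %.0f%%)",
                 100 * mean(gap), 100 * max_gap_frac))
  trajectory(df$time_s, df$x_cm, df$y_cm, individual, arena, assay = assay)
}

#' Write a trajectory CSV
#' @param t A `trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(t, path) {
  out <- data.frame(frame = seq_len(nrow(t)) - 1L,
                    time_s = t$time_s, x_cm = t$x_cm, y_cm = t$y_cm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repair short tracking gaps and split at long ones
#'
#' Gaps no longer than `max_gap_s` are filled by linear interpolation
#' between the flanking tracked positions and flagged in `gap_mask`.
#' Longer gaps split the trajectory into independent segments: their
#' samples are dropped and downstream analyses treat segments separately,
#' so total analysed time excludes long gaps. Idempotent.
#'
#' @param t A `trajectory`.
#' @param max_gap_s Longest gap (s) to interpolate; default 0.5.
#' @return A gap-filled `trajectory` (possibly multi-segment).
#' @export
fill_gaps <- function(t, max_gap_s = 0.5) {
  stopifnot(max_gap_s > 0)
  if (nrow(t) == 0 || !any(t$gap_mask & is.na(t$x_cm))) return(t)
  time_s <- t$time_s; x <- t$x_cm; y <- t$y_cm
  gap <- is.na(x) | is.na(y)
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- !logical(length(x))
  segment <- rep.int(1L, length(x))
  seg_id <- 1L
  filled <- t$gap_mask
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    i0 <- starts[r]; i1 <- ends[r]
    prev <- i0 - 1L; nxt <- i1 + 1L
    # leading/trailing gaps cannot be interpolated: drop them
    if (prev < 1L || nxt > length(x)) { keep[i0:i1] <- FALSE; next }
    gap_len_s <- time_s[nxt] - time_s[prev]
    if (gap_len_s <= max_gap_s) {
      w <- (time_s[i0:i1] - time_s[prev]) / gap_len_s
      x[i0:i1] <- x[prev] + w * (x[nxt] - x[prev])
      y[i0:i1] <- y[prev] + w * (y[nxt] - y[prev])
      filled[i0:i1] <- TRUE
    } else {
      keep[i0:i1] <- FALSE
      seg_id <- seg_id + 1L
      segment[nxt:length(x)] <- seg_id
    }
  }
  trajectory(time_s[keep], x[keep], y[keep],
             attr(t, "individual"), attr(t, "arena"),
             assay = attr(t, "assay"),
             sample_rate_hz = attr(t, "sample_rate_hz"),
             gap_mask = filled[keep],
             segment = cumsum(c(1L, diff(segment[keep]) != 0)),
             validate = FALSE)
}

#' Derive per-sample kinematics from a gap-filled trajectory
#'
#' Speed at sample i is the displacement over the preceding inter-sample
#' interval divided by its duration (the first sample inherits the first
#' interval's speed). A sample is resting when its speed falls below
#' `resting_threshold_cm_s`. Heading is the direction of the
#' central-difference displacement over `heading_window` samples and is
#' undefined (`NA`) while resting or when the window displacement is zero.
#' All derivations respect segment boundaries.
#'
#' @param t A gap-filled `trajectory`.
#' @param resting_threshold_cm_s Immobility threshold (cm/s), default 0.2.
#' @param heading_window Central-difference window width in samples
#'   (odd, default 5).
#' @return An object of class `kinematics`: data.frame with columns
#'   `speed_cm_s`, `heading_rad`, `resting_mask`, aligned with `t`.
#' @export
compute_kinematics <- function(t, resting_threshold_cm_s = 0.2,
                               heading_window = 5) {
  n <- nrow(t)
  h <- max(1L, floor(heading_window / 2))
  speed <- numeric(n); heading <- rep(NA_real_, n)
  if (n > 0 && n < heading_window)
    warning("trajectory shorter than heading window; headings undefined")
  for (s in unique(t$segment)) {
    idx <- which(t$segment == s)
    m <- length(idx)
    if (m < 2) next
    xs <- t$x_cm[idx]; ys <- t$y_cm[idx]; ts <- t$time_s[idx]
    dd <- sqrt(diff(xs)^2 + diff(ys)^2) / diff(ts)
    speed[idx] <- c(dd[1], dd)
    if (m >= 2 * h + 1) {
      lo <- pmax(seq_len(m) - h, 1L)
      hi <- pmin(seq_len(m) + h, m)
      dx <- xs[hi] - xs[lo]; dy <- ys[hi] - ys[lo]
      hd <- atan2(dy, dx)
      hd[dx == 0 & dy == 0] <- NA_real_
      heading[idx] <- hd
    }
  }
  resting <- speed < resting_threshold_cm_s
  heading[resting] <- NA_real_
  structure(data.frame(speed_cm_s = speed, heading_rad = heading,
                       resting_mask = resting),
            class = c("kinematics", "data.frame"),
            resting_threshold_cm_s = resting_threshold_cm_s,
            heading_window = heading_window)
}

#' Total path length of a trajectory
#'
#' Sum of inter-sample displacements within segments (long gaps contribute
#' nothing).
#'
#' @param t A `trajectory`.
#' @return Path length in cm.
#' @export
path_length_cm <- function(t) {
  total <- 0
  for (s in unique(t$segment)) {
    idx <- which(t$segment == s)
    if (length(idx) < 2) next
    total <- total +
      sum(sqrt(diff(t$x_cm[idx])^2 + diff(t$y_cm[idx])^2))
  }
  total
}

# per-sample interval durations: dt attributed to each sample is the
# length of its preceding interval; the first sample of a segment gets the
# following interval's length so that segment dts sum to segment span plus
# one nominal interval is avoided -- the first sample carries 0.
.sample_dt <- function(t) {
  n <- nrow(t)
  dts <- numeric(n)
  for (s in unique(t$segment)) {
    idx <- which(t$segment == s)
    if (length(idx) < 2) next
    dts[idx] <- c(0, diff(t$time_s[idx]))
  }
  dts
}
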
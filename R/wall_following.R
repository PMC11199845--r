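#' Distance from a point to the nearest arena wall
#'
#' @param x,y Point coordinates (cm), inside the arena.
#' @param arena An [arena_config()].
#' @return Distance (cm) to the closest of the four walls. Vectorised.
#' @export
distance_to_nearest_wall <- function(x, y, arena) {
  if (any(x < 0 | x > arena$width_cm | y < 0 | y > arena$height_cm,
          na.rm = TRUE))
    stop("point outside arena")
  pmin(x, arena$width_cm - x, y, arena$height_cm - y)
}

#' Near-wall belt membership
#'
#' The near-wall belt is the rectangular annulus within 0.5 standard
#' lengths of any wall; membership uses a closed (inclusive) boundary so a
#' point exactly at the belt edge is in the belt.
#'
#' @param x,y Point coordinates (cm). Vectorised.
#' @param arena An [arena_config()].
#' @param sl_cm Standard length (cm) of the individual.
#' @param belt_sl Belt half-width in SL units (default 0.5).
#' @return Logical vector: `TRUE` where the point is in the belt.
#' @export
belt_membership <- function(x, y, arena, sl_cm, belt_sl = 0.5) {
  stopifnot(sl_cm > 0)
  distance_to_nearest_wall(x, y, arena) <= belt_sl * sl_cm
}

#' Segment wall-following events
#'
#' A candidate bout opens when the track enters the near-wall belt and
#' closes when it exits (or at a segment boundary). The in-belt path of a
#' bout is the summed displacement over intervals whose both endpoints are
#' in the belt. A bout qualifies as a wall-following event only when that
#' path reaches `event_min_sl` standard lengths; sub-threshold visits
#' contribute nothing to any indicator.
#'
#' @param t A gap-filled `trajectory`.
#' @param k Matching `kinematics` from [compute_kinematics()].
#' @param arena An [arena_config()].
#' @param sl_cm Standard length (cm).
#' @param belt_sl Belt half-width in SL (default 0.5).
#' @param event_min_sl Minimum in-belt path, in SL, for a bout to qualify
#'   (default 2).
#' @param all_entries If `TRUE`, every belt entry is returned (the
#'   permissive frequency reading) with a `qualifies` flag; default
#'   `FALSE` returns qualifying events only.
#' @return data.frame with one row per event: `start_index, end_index,
#'   in_belt_path_cm, duration_s, mobile_time_s, resting_time_s,
#'   qualifies`.
#' @export
segment_wf_events <- function(t, k, arena, sl_cm,
                              belt_sl = 0.5, event_min_sl = 2,
                              all_entries = FALSE) {
  n <- nrow(t)
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      in_belt_path_cm = numeric(), duration_s = numeric(),
                      mobile_time_s = numeric(), resting_time_s = numeric(),
                      qualifies = logical())
  if (n == 0) return(empty)
  in_belt <- belt_membership(t$x_cm, t$y_cm, arena, sl_cm, belt_sl)
  dts <- .sample_dt(t)
  out <- empty
  for (s in unique(t$segment)) {
    idx <- which(t$segment == s)
    memb <- in_belt[idx]
    if (!any(memb)) next
    runs <- rle(memb)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      i0 <- idx[starts[r]]; i1 <- idx[ends[r]]
      if (i1 > i0) {
        path <- sum(sqrt(diff(t$x_cm[i0:i1])^2 + diff(t$y_cm[i0:i1])^2))
        dur <- t$time_s[i1] - t$time_s[i0]
        # interval time is attributed to its terminal sample
        mobile <- sum(dts[(i0 + 1L):i1][!k$resting_mask[(i0 + 1L):i1]])
        resting <- dur - mobile
      } else {
        path <- 0; dur <- 0; mobile <- 0; resting <- 0
      }
      q <- path >= event_min_sl * sl_cm
      if (q || all_entries)
        out <- rbind(out, data.frame(
          start_index = i0, end_index = i1, in_belt_path_cm = path,
          duration_s = dur, mobile_time_s = mobile,
          resting_time_s = resting, qualifies = q))
    }
  }
  out
}

#' Six wall-following indicators for one trial
#'
#' Computes, over the qualifying events of one assay:
#' * `wf_distance_sl` — summed in-belt path of events, in SL;
#' * `wf_frequency` — number of qualifying events;
#' * `wf_time_pct` — summed event duration as a percentage of testing time;
#' * `wf_resting_time_s` — total resting time over the whole assay;
#' * `wf_speed_sl_s` — event path over event mobile time, in SL/s
#'   (0 when there are no events);
#' * `wf_max_speed_sl_s` — maximum per-interval speed over the whole
#'   assay, in SL/s.
#'
#' @param t A gap-filled `trajectory`.
#' @param k Matching `kinematics`.
#' @param events Output of [segment_wf_events()].
#' @param sl_cm Standard length (cm).
#' @param testing_time_s Assay duration (s): 600, 300 or 180.
#' @return A one-row data.frame of class `wf_metrics`.
#' @export
compute_wf_metrics <- function(t, k, events, sl_cm, testing_time_s) {
  if (testing_time_s <= 0) stop("testing_time_s must be positive")
  ev <- events[events$qualifies, , drop = FALSE]
  dts <- .sample_dt(t)
  resting_s <- sum(dts[k$resting_mask])
  path <- sum(ev$in_belt_path_cm)
  mobile <- sum(ev$mobile_time_s)
  structure(data.frame(
    wf_distance_sl = path / sl_cm,
    wf_frequency = nrow(ev),
    wf_time_pct = 100 * sum(ev$duration_s) / testing_time_s,
    wf_resting_time_s = resting_s,
    wf_speed_sl_s = if (mobile > 0) (path / mobile) / sl_cm else 0,
    wf_max_speed_sl_s = if (nrow(t) > 1) max(k$speed_cm_s) / sl_cm else 0),
    class = c("wf_metrics", "data.frame"))
}

#' Wall-following indicators for a trajectory in one call
#'
#' Convenience wrapper: gap-fills, derives kinematics, segments events and
#' returns the indicator row together with identifiers.
#'
#' @param t A `trajectory` (raw or gap-filled).
#' @param belt_sl,event_min_sl,resting_threshold_cm_s Analysis parameters
#'   (defaults 0.5 SL, 2 SL, 0.2 cm/s).
#' @param testing_time_s Assay duration; defaults to the assay type's
#'   nominal duration.
#' @return One-row data.frame: identifiers plus the six indicators.
#' @export
wf_metrics_for_trajectory <- function(t, belt_sl = 0.5, event_min_sl = 2,
                                      resting_threshold_cm_s = 0.2,
                                      testing_time_s = NULL) {
  ind <- attr(t, "individual"); arena <- attr(t, "arena")
  if (is.null(testing_time_s)) testing_time_s <- assay_duration_s(attr(t, "assay"))
  tf <- fill_gaps(t)
  k <- compute_kinematics(tf, resting_threshold_cm_s)
  ev <- segment_wf_events(tf, k, arena, ind$standard_length_cm,
                          belt_sl = belt_sl, event_min_sl = event_min_sl)
  m <- compute_wf_metrics(tf, k, ev, ind$standard_length_cm, testing_time_s)
  cbind(data.frame(individual_id = ind$individual_id,
                   species = ind$species, eye_morph = ind$eye_morph,
                   clade = ind$clade, assay = attr(t, "assay"),
                   standard_length_cm = ind$standard_length_cm,
                   stringsAsFactors = FALSE),
        as.data.frame(m))
}
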
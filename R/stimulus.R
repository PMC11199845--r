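#' Stimulation configuration
#'
#' Geometry of the landmark / vibration stimulation assays: the stimulus
#' sits at the arena centre by default and a 10 x 16 cm axis-aligned
#' rectangle around it is the stimulation range. The landmark is a 5 cm
#' diameter opaque cylinder; the vibration source (an aeration pump at
#' 40-50 Hz) defaults to the same footprint radius because its physical
#' size is assay-rig specific.
#'
#' @param kind `"none"`, `"landmark"` or `"vibration"`.
#' @param arena An [arena_config()] used for the default centre.
#' @param center_cm Length-2 numeric, stimulus centre (cm).
#' @param zone_width_cm Zone extent along y (cm), default 10.
#' @param zone_length_cm Zone extent along x (cm), default 16.
#' @param cylinder_diameter_cm Landmark cylinder diameter (cm), default 5.
#' @param source_radius_cm Physical stimulus footprint radius used for
#'   body-edge distances; defaults to the cylinder radius.
#' @param vibration_hz Informational vibration frequency range.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(kind = c("none", "landmark", "vibration"),
                            arena = arena_config(),
                            center_cm = c(arena$width_cm / 2, arena$height_cm / 2),
                            zone_width_cm = 10, zone_length_cm = 16,
                            cylinder_diameter_cm = 5,
                            source_radius_cm = cylinder_diameter_cm / 2,
                            vibration_hz = c(40, 50)) {
  kind <- match.arg(kind)
  stopifnot(length(center_cm) == 2, zone_width_cm > 0, zone_length_cm > 0)
  half_l <- zone_length_cm / 2; half_w <- zone_width_cm / 2
  if (center_cm[1] - half_l < 0 || center_cm[1] + half_l > arena$width_cm ||
      center_cm[2] - half_w < 0 || center_cm[2] + half_w > arena$height_cm)
    stop("stimulation zone extends outside the arena")
  if (source_radius_cm >= min(half_l, half_w))
    stop("stimulus footprint radius must be smaller than the zone half-extent")
  structure(list(kind = kind, center_cm = as.numeric(center_cm),
                 zone_width_cm = zone_width_cm, zone_length_cm = zone_length_cm,
                 cylinder_diameter_cm = cylinder_diameter_cm,
                 source_radius_cm = source_radius_cm,
                 vibration_hz = vibration_hz),
            class = "stimulus_config")
}

#' Stimulation-range membership
#'
#' Axis-aligned rectangle test with inclusive boundaries: the zone is
#' `zone_length_cm` wide in x and `zone_width_cm` in y, centred on the
#' stimulus.
#'
#' @param x,y Point coordinates (cm). Vectorised.
#' @param stimulus A [stimulus_config()].
#' @return Logical vector.
#' @export
in_stimulation_range <- function(x, y, stimulus) {
  abs(x - stimulus$center_cm[1]) <= stimulus$zone_length_cm / 2 &
  abs(y - stimulus$center_cm[2]) <= stimulus$zone_width_cm / 2
}

#' Stimulation-range indicators for one trial
#'
#' * `s_frequency` — number of zone-entry bouts (every entry counts);
#' * `s_time_pct` — time in the zone as a percentage of testing time;
#' * `s_speed_sl_s` — mean mobile speed inside the zone, in SL/s
#'   (0 if the fish is never mobile in the zone);
#' * `s_max_speed_sl_s` — maximum speed inside the zone, in SL/s.
#'
#' @param t A gap-filled `trajectory`.
#' @param k Matching `kinematics`.
#' @param stimulus A [stimulus_config()] with kind != "none".
#' @param sl_cm Standard length (cm).
#' @param testing_time_s Assay duration (s).
#' @return One-row data.frame of class `s_metrics`.
#' @export
compute_stimulation_metrics <- function(t, k, stimulus, sl_cm, testing_time_s) {
  if (stimulus$kind == "none") stop("assay has no stimulation")
  if (testing_time_s <= 0) stop("testing_time_s must be positive")
  n <- nrow(t)
  if (n == 0)
    return(structure(data.frame(s_frequency = 0L, s_time_pct = 0,
                                s_speed_sl_s = 0, s_max_speed_sl_s = 0),
                     class = c("s_metrics", "data.frame")))
  inz <- in_stimulation_range(t$x_cm, t$y_cm, stimulus)
  dts <- .sample_dt(t)
  freq <- 0L
  for (s in unique(t$segment)) {
    runs <- rle(inz[t$segment == s])
    freq <- freq + sum(runs$values)
  }
  zone_time <- sum(dts[inz])
  mobile_in <- inz & !k$resting_mask
  structure(data.frame(
    s_frequency = freq,
    s_time_pct = 100 * zone_time / testing_time_s,
    s_speed_sl_s = if (any(mobile_in)) mean(k$speed_cm_s[mobile_in]) / sl_cm else 0,
    s_max_speed_sl_s = if (any(inz)) max(k$speed_cm_s[inz]) / sl_cm else 0),
    class = c("s_metrics", "data.frame"))
}

#' Approach angle to the stimulus
#'
#' Unsigned angle, in degrees within \[0, 180\], between the fish's heading
#' (the smoothed motion direction standing in for the body midline) and
#' the bearing from the fish to the stimulus centre.
#'
#' @param heading_rad Heading angle (rad).
#' @param x,y Fish position (cm).
#' @param stimulus A [stimulus_config()].
#' @return Angle in degrees. Vectorised.
#' @export
approach_angle <- function(heading_rad, x, y, stimulus) {
  bearing <- atan2(stimulus$center_cm[2] - y, stimulus$center_cm[1] - x)
  d <- abs(atan2(sin(bearing - heading_rad), cos(bearing - heading_rad)))
  d * 180 / pi
}

#' Body-edge distance to the stimulus boundary
#'
#' The fish body is modelled as a 1-D segment of length SL centred on the
#' tracked centroid and aligned with the heading; the returned value is
#' the shortest distance from that segment to the stimulus boundary
#' (a circle of `source_radius_cm`), clamped at 0 on overlap, in SL units.
#'
#' @param x,y Centroid position (cm).
#' @param heading_rad Heading (rad).
#' @param sl_cm Standard length (cm).
#' @param stimulus A [stimulus_config()].
#' @return Distance in SL units (scalar).
#' @export
approach_distance <- function(x, y, heading_rad, sl_cm, stimulus) {
  cx <- stimulus$center_cm[1]; cy <- stimulus$center_cm[2]
  ux <- cos(heading_rad); uy <- sin(heading_rad)
  # closest point of the body segment [p - SL/2 u, p + SL/2 u] to the centre
  tproj <- (cx - x) * ux + (cy - y) * uy
  tproj <- pmin(pmax(tproj, -sl_cm / 2), sl_cm / 2)
  px <- x + tproj * ux; py <- y + tproj * uy
  d <- sqrt((cx - px)^2 + (cy - py)^2) - stimulus$source_radius_cm
  pmax(d, 0) / sl_cm
}

#' Detect the first three approaches to the stimulation
#'
#' An approach bout runs from zone entry to zone exit. Angle and distance
#' are measured, by default, at the bout's frame of minimal body-to-
#' stimulus distance among frames with a defined heading (`measure_at =
#' "closest"`); `measure_at = "entry"` instead measures at the first
#' frame of the bout. When no frame of the bout has a defined heading, the
#' nearest mobile frame in the trial is used and the record is flagged.
#'
#' @param t A gap-filled `trajectory`.
#' @param k Matching `kinematics`.
#' @param stimulus A [stimulus_config()] with kind != "none".
#' @param sl_cm Standard length (cm).
#' @param max_approaches Number of approaches kept (default 3).
#' @param measure_at `"closest"` (default) or `"entry"`.
#' @return data.frame with at most `max_approaches` rows:
#'   `order, angle_deg, distance_sl, time_s, heading_imputed`.
#' @export
detect_approaches <- function(t, k, stimulus, sl_cm,
                              max_approaches = 3,
                              measure_at = c("closest", "entry")) {
  measure_at <- match.arg(measure_at)
  if (stimulus$kind == "none") stop("assay has no stimulation")
  empty <- data.frame(order = integer(), angle_deg = numeric(),
                      distance_sl = numeric(), time_s = numeric(),
                      heading_imputed = logical())
  n <- nrow(t)
  if (n == 0) return(empty)
  inz <- in_stimulation_range(t$x_cm, t$y_cm, stimulus)
  out <- empty
  for (s in unique(t$segment)) {
    if (nrow(out) >= max_approaches) break
    idx <- which(t$segment == s)
    runs <- rle(inz[idx])
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      if (nrow(out) >= max_approaches) break
      bout <- idx[starts[r]:ends[r]]
      cand <- bout[!is.na(k$heading_rad[bout])]
      imputed <- FALSE
      if (measure_at == "entry" && length(cand) && cand[1] == bout[1]) {
        at <- bout[1]
      } else if (length(cand)) {
        dists <- approach_distance(t$x_cm[cand], t$y_cm[cand],
                                   k$heading_rad[cand], sl_cm, stimulus)
        at <- if (measure_at == "entry") cand[1] else cand[which.min(dists)]
      } else {
        mobile <- which(!is.na(k$heading_rad))
        if (!length(mobile)) next
        at <- mobile[which.min(abs(mobile - bout[1]))]
        imputed <- TRUE
      }
      out <- rbind(out, data.frame(
        order = nrow(out) + 1L,
        angle_deg = approach_angle(k$heading_rad[at], t$x_cm[at],
                                   t$y_cm[at], stimulus),
        distance_sl = approach_distance(t$x_cm[at], t$y_cm[at],
                                        k$heading_rad[at], sl_cm, stimulus),
        time_s = t$time_s[at],
        heading_imputed = imputed))
    }
  }
  out
}
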
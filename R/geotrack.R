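# Shore-based theodolite geometry: angle fixes -> planar positions -> tracks
# -> per-5-min movement speeds.

#' Station geometry for a shore-based theodolite
#'
#' Describes the observation platform: its height above the waterline, an
#' optional instrument height and tide offset, and the reference bearing from
#' which horizontal angles are measured. The effective height
#' `height_above_water + instrument_height - tide_offset` must be positive.
#'
#' @param height_above_water Height of the vantage point above the water
#'   surface, metres.
#' @param station_lat_lon Optional latitude/longitude of the station, decimal
#'   degrees (metadata only; positions are expressed in a local planar grid).
#' @param reference_bearing Bearing (degrees true) corresponding to a
#'   horizontal angle of zero.
#' @param instrument_height Height of the theodolite telescope above the
#'   platform, metres.
#' @param tide_offset Water-level offset above datum, metres; subtracted from
#'   the effective height.
#' @param curvature_correction Logical; apply an earth-curvature/refraction
#'   correction to the computed range (see [fix_to_position()]).
#' @return An object of class `station_geometry`.
#' @export
station_geometry <- function(height_above_water,
                             station_lat_lon = c(NA_real_, NA_real_),
                             reference_bearing = 0,
                             instrument_height = 0,
                             tide_offset = 0,
                             curvature_correction = FALSE) {
  h_eff <- height_above_water + instrument_height - tide_offset
  if (!is.finite(h_eff) || h_eff <= 0) {
    stop("effective station height must be positive", call. = FALSE)
  }
  structure(
    list(
      height_above_water = height_above_water,
      station_lat_lon = station_lat_lon,
      reference_bearing = reference_bearing,
      instrument_height = instrument_height,
      tide_offset = tide_offset,
      curvature_correction = isTRUE(curvature_correction),
      effective_height = h_eff
    ),
    class = "station_geometry"
  )
}

#' @export
print.station_geometry <- function(x, ...) {
  cat("Theodolite station: effective height", format(x$effective_height),
      "m, reference bearing", format(x$reference_bearing), "deg",
      if (x$curvature_correction) "(curvature corrected)" else "", "\n")
  invisible(x)
}

# refraction coefficient and earth radius used by the optional curvature fix
.curvature_k <- 0.13
.earth_radius_m <- 6371000

#' Convert theodolite angle fixes to planar positions
#'
#' Standard vantage-point trigonometry: the horizontal range to a target seen
#' at depression angle `v` from an effective height `h` is `r = h / tan(v)`;
#' the bearing is the station reference bearing plus the horizontal angle.
#' Positions are metres east/north of the station.
#'
#' When `station$curvature_correction` is `TRUE` the apparent drop is
#' augmented by `(1 - k) r^2 / (2 R)` with `k = 0.13`, `R = 6371` km, applied
#' iteratively (two passes), which matters only for ranges approaching a
#' kilometre or more.
#'
#' @param fixes Data frame with columns `timestamp` (seconds),
#'   `horizontal_angle` (degrees from the reference bearing) and
#'   `vertical_angle` (degrees of depression below the horizontal, in
#'   `(0, 90]`); additional columns (e.g. `target_id`) are carried through.
#' @param station A [station_geometry()].
#' @param max_range Positions farther than this from the station (metres) are
#'   rejected with an error; guards against near-horizon angle noise.
#' @return Data frame with `x_east`, `y_north` (metres) plus the input
#'   columns.
#' @export
fix_to_position <- function(fixes, station, max_range = 5000) {
  stopifnot(inherits(station, "station_geometry"))
  v <- fixes$vertical_angle
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("target at or above the horizon: vertical (depression) angle must be > 0",
         call. = FALSE)
  }
  if (any(v > 90)) stop("depression angle exceeds 90 degrees", call. = FALSE)
  h <- station$effective_height
  vr <- v * pi / 180
  r <- h / tan(vr)
  if (station$curvature_correction) {
    for (iter in 1:2) {
      drop <- h + (1 - .curvature_k) * r^2 / (2 * .earth_radius_m)
      r <- drop / tan(vr)
    }
  }
  if (any(r > max_range)) {
    stop("computed range exceeds max_range (", max_range, " m)", call. = FALSE)
  }
  bearing <- (station$reference_bearing + fixes$horizontal_angle) * pi / 180
  out <- fixes
  out$x_east <- r * sin(bearing)
  out$y_north <- r * cos(bearing)
  out
}

#' Convert planar positions back to theodolite angles
#'
#' Inverse of [fix_to_position()] with the curvature correction off; used by
#' the synthetic survey generator and for round-trip checks.
#'
#' @param positions Data frame with `x_east`, `y_north` (metres); other
#'   columns are carried through.
#' @param station A [station_geometry()].
#' @return Data frame with `horizontal_angle` and `vertical_angle` (degrees).
#' @export
position_to_fix <- function(positions, station) {
  stopifnot(inherits(station, "station_geometry"))
  r <- sqrt(positions$x_east^2 + positions$y_north^2)
  if (any(r <= 0)) stop("target at the station: range must be positive", call. = FALSE)
  bearing <- atan2(positions$x_east, positions$y_north) * 180 / pi
  out <- positions
  out$horizontal_angle <- (bearing - station$reference_bearing) %% 360
  out$vertical_angle <- atan2(station$effective_height, r) * 180 / pi
  out
}

#' Per-segment speeds along a track
#'
#' One speed per consecutive pair of positions: planar distance divided by
#' the time difference.
#'
#' @param track Data frame with `timestamp`, `x_east`, `y_north` for a single
#'   target, in time order.
#' @return Data frame with `t_start`, `t_end`, `t_mid`, `distance` (m) and
#'   `speed` (m/s), one row per segment.
#' @export
segment_speeds <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("need at least 2 positions to compute speeds", call. = FALSE)
  o <- order(track$timestamp)
  track <- track[o, ]
  dt <- diff(track$timestamp)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps in track", call. = FALSE)
  dist <- sqrt(diff(track$x_east)^2 + diff(track$y_north)^2)
  data.frame(
    t_start = track$timestamp[-n],
    t_end = track$timestamp[-1],
    t_mid = (track$timestamp[-n] + track$timestamp[-1]) / 2,
    distance = dist,
    speed = dist / dt
  )
}

#' Average speed of a track within one 5-min sample window
#'
#' Segments are assigned to the window containing their midpoint. Windows
#' with fewer than two fixes are excluded (returned as `NA`), enforcing the
#' minimum-two-measurements rule for reliable speed estimates.
#'
#' @param track Data frame with `timestamp`, `x_east`, `y_north`.
#' @param window_start Window start time, seconds; must be an integer
#'   multiple of `interval`.
#' @param interval Window length in seconds (default 300 = 5 min).
#' @return Mean segment speed in m/s, or `NA_real_` if fewer than two fixes
#'   fall inside the window.
#' @export
sample_average_speed <- function(track, window_start, interval = 300) {
  if (window_start %% interval != 0) {
    stop("window_start must be an integer multiple of the interval", call. = FALSE)
  }
  in_win <- track$timestamp >= window_start & track$timestamp < window_start + interval
  if (sum(in_win) < 2) return(NA_real_)
  seg <- segment_speeds(track)
  seg_in <- seg$t_mid >= window_start & seg$t_mid < window_start + interval
  if (!any(seg_in)) return(NA_real_)
  mean(seg$speed[seg_in])
}

#' Average speeds for all 5-min windows spanned by a track
#'
#' @param track Data frame with `timestamp`, `x_east`, `y_north` for one
#'   target.
#' @param interval Window length in seconds.
#' @return Data frame with `window_start`, `n_fixes` and `mean_speed`
#'   (`NA` where the two-fix rule excludes the window).
#' @export
track_sample_speeds <- function(track, interval = 300) {
  w0 <- floor(min(track$timestamp) / interval) * interval
  w1 <- floor(max(track$timestamp) / interval) * interval
  starts <- seq(w0, w1, by = interval)
  n_fixes <- vapply(starts, function(s) {
    sum(track$timestamp >= s & track$timestamp < s + interval)
  }, integer(1))
  speeds <- vapply(starts, function(s) sample_average_speed(track, s, interval),
                   numeric(1))
  data.frame(window_start = starts, n_fixes = n_fixes, mean_speed = speeds)
}

#' Build tracks and per-sample speeds from a table of fixes
#'
#' Converts every fix to a planar position, splits by target, and computes
#' per-5-min average speeds per target.
#'
#' @param fixes Data frame of fixes (see [fix_to_position()]) with a
#'   `target_id` column.
#' @param station A [station_geometry()].
#' @param interval Sample window length, seconds.
#' @param max_range Passed to [fix_to_position()].
#' @return List with `tracks` (positions plus segment speed per fix) and
#'   `sample_speeds` (`target_id`, `window_start`, `n_fixes`, `mean_speed`).
#' @export
build_tracks <- function(fixes, station, interval = 300, max_range = 5000) {
  pos <- fix_to_position(fixes, station, max_range = max_range)
  split_pos <- split(pos, pos$target_id)
  tracks <- lapply(split_pos, function(p) p[order(p$timestamp), ])
  sample_speeds <- do.call(rbind, lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    if (nrow(tr) < 2) {
      return(data.frame(target_id = id,
                        window_start = floor(min(tr$timestamp) / interval) * interval,
                        n_fixes = nrow(tr), mean_speed = NA_real_))
    }
    ss <- track_sample_speeds(tr, interval)
    cbind(target_id = id, ss)
  }))
  rownames(sample_speeds) <- NULL
  list(tracks = do.call(rbind, c(tracks, list(make.row.names = FALSE))),
       sample_speeds = sample_speeds)
}

#' Join per-5-min track speeds onto behavioural samples
#'
#' Builds tracks from the fixes, computes per-window mean speeds, and joins
#' them to the behavioural sample table by window start, classifying each
#' sample's vessel density as low or high. Samples excluded by the two-fix
#' rule carry `NA` speeds.
#'
#' @param fixes Theodolite fix table (see [fix_to_position()]).
#' @param samples Behavioural sample table with `sample_start`,
#'   `activity_state` and `vessel_count`.
#' @param station A [station_geometry()].
#' @param cutoff Vessel-density cutoff (default 3).
#' @param interval Window length, seconds.
#' @return Data frame with `sample_start`, `activity_state`,
#'   `vessel_density_class`, `n_fixes`, `mean_speed`.
#' @export
speed_sample_table <- function(fixes, samples, station, cutoff = 3,
                               interval = 300) {
  bt <- build_tracks(fixes, station, interval = interval)
  ss <- bt$sample_speeds
  # one burst per window in the synthetic surveys; with several targets per
  # window, average the per-target means weighted equally
  agg <- stats::aggregate(ss[, c("n_fixes", "mean_speed")],
                          by = list(window_start = ss$window_start),
                          FUN = mean, na.rm = TRUE)
  agg$mean_speed[!is.finite(agg$mean_speed)] <- NA_real_
  out <- merge(samples, agg, by.x = "sample_start", by.y = "window_start",
               all.x = TRUE)
  out$vessel_density_class <- vessel_density_class(out$vessel_count, cutoff)
  out[, c("sample_start", "activity_state", "vessel_density_class",
          "n_fixes", "mean_speed")]
}
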
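# Calibrated underwater noise metrics (broadband rms level and octave-band
# levels), whistle-contour feature extraction, and whistle-to-context
# pairing.

#' Hydrophone-to-digitiser calibration chain
#'
#' @param hydrophone_sensitivity Hydrophone sensitivity, dB re 1 uPa/V
#'   (negative; e.g. -202.8).
#' @param preamp_gain Pre-amplifier gain, dB.
#' @param adc_fullscale_volts Voltage corresponding to digital full scale.
#' @param highpass_hz High-pass cutoff of the recorder, Hz (metadata).
#' @param sample_rate Sampling frequency, Hz; must exceed twice the highest
#'   analysis frequency (48 kHz).
#' @return Object of class `calibration_chain`.
#' @export
calibration_chain <- function(hydrophone_sensitivity, preamp_gain,
                              adc_fullscale_volts = 1, highpass_hz = 8,
                              sample_rate = 96000) {
  for (f in c(hydrophone_sensitivity, preamp_gain, adc_fullscale_volts,
              sample_rate)) {
    if (!is.finite(f)) stop("calibration field missing or non-finite", call. = FALSE)
  }
  if (sample_rate < 2 * 48000) {
    stop("sample rate must be at least twice the 48 kHz analysis band edge",
         call. = FALSE)
  }
  structure(list(hydrophone_sensitivity = hydrophone_sensitivity,
                 preamp_gain = preamp_gain,
                 adc_fullscale_volts = adc_fullscale_volts,
                 highpass_hz = highpass_hz, sample_rate = sample_rate),
            class = "calibration_chain")
}

#' Convert raw digitiser samples to pressure in micro-Pascals
#'
#' Applies the calibration chain multiplicatively: normalised counts scale to
#' volts at the digitiser, the pre-amp gain is removed, and the hydrophone
#' sensitivity converts volts to micro-Pascals:
#' `p = v * 10^(-(sensitivity + gain)/20)`. With the printed sensitivity
#' -202.8 dB re 1 uPa/V and 20 dB gain, a 1 V rms input corresponds to
#' 182.8 dB re 1 uPa.
#'
#' @param samples Numeric vector: either normalised amplitudes in `[-1, 1]`
#'   or raw 16-bit integer counts (auto-detected when values exceed 1 in
#'   magnitude, divided by 32768).
#' @param chain A [calibration_chain()].
#' @return Pressure series in uPa.
#' @export
counts_to_pressure <- function(samples, chain) {
  stopifnot(inherits(chain, "calibration_chain"))
  if (max(abs(samples), na.rm = TRUE) > 1) samples <- samples / 32768
  volts <- samples * chain$adc_fullscale_volts
  volts * 10^(-(chain$hydrophone_sensitivity + chain$preamp_gain) / 20)
}

# FFT band mask: zero spectral content outside [f_lo, f_hi) and invert.
# Bin convention lo <= f < hi, applied to the positive-frequency image (and
# mirrored), so contiguous bands partition the spectrum exactly.
.band_mask_ms <- function(p, sr, f_lo, f_hi) {
  n <- length(p)
  X <- stats::fft(p)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f)  # folded (absolute) frequency of each bin
  keep <- f >= f_lo & f < f_hi
  sum(Mod(X[keep])^2) / n^2
}

.band_limit <- function(p, sr, f_lo, f_hi) {
  n <- length(p)
  X <- stats::fft(p)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f)
  X[!(f >= f_lo & f < f_hi)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Broadband rms sound pressure level
#'
#' Band-limits the pressure series to `band` (default 10 Hz - 48 kHz) by FFT
#' masking and returns `20 log10(rms)` in dB re 1 uPa. A zero (silent)
#' window returns `-Inf`.
#'
#' @param pressure Pressure series in uPa.
#' @param sr Sample rate, Hz.
#' @param band Two-element band edges in Hz.
#' @return Level in dB re 1 uPa rms.
#' @export
broadband_level <- function(pressure, sr, band = c(10, 48000)) {
  ms <- .band_mask_ms(pressure, sr, band[1], band[2])
  if (ms <= 0) return(-Inf)
  10 * log10(ms)
}

#' Octave-band centre frequencies
#'
#' Twelve octaves with centres `15.625 * 2^k`, k = 0..11 (16 Hz to 32 kHz),
#' covering the analysis band and including the 1, 16 and 32 kHz bands used
#' as noise covariates.
#' @return Numeric vector of 12 centre frequencies in Hz.
#' @export
octave_centres <- function() 15.625 * 2^(0:11)

#' Octave-band rms levels
#'
#' rms level in each octave band (edges `f_c / sqrt(2)` to `f_c * sqrt(2)`),
#' computed by FFT masking so adjacent bands partition the spectrum exactly
#' and band energies sum to the broadband energy over the combined span.
#'
#' @param pressure Pressure series in uPa.
#' @param sr Sample rate, Hz.
#' @param centres Band centre frequencies (default [octave_centres()]).
#' @return Named numeric vector of levels in dB re 1 uPa (`-Inf` for empty
#'   bands).
#' @export
octave_band_levels <- function(pressure, sr, centres = octave_centres()) {
  lv <- vapply(centres, function(fc) {
    ms <- .band_mask_ms(pressure, sr, fc / sqrt(2), fc * sqrt(2))
    if (ms <= 0) -Inf else 10 * log10(ms)
  }, numeric(1))
  names(lv) <- paste0("obl_", round(centres))
  lv
}

#' Is a time window inside a duty-cycle ON period?
#'
#' The logger records `on` seconds out of every `period` seconds (default
#' 10 min every 15 min). Noise windows overlapping an OFF gap cannot be
#' measured and the associated whistle is excluded.
#'
#' @param t_start,t_end Window boundaries in seconds from recording start.
#' @param period Duty-cycle period, seconds.
#' @param on ON duration at the start of each period, seconds.
#' @return Logical.
#' @export
in_duty_cycle <- function(t_start, t_end, period = 900, on = 600) {
  (t_start %% period) <= (t_end %% period) &
    (t_end %% period) <= on &
    (t_end - t_start) <= on
}

#' Extract shape characteristics from a whistle contour
#'
#' The contour (fundamental frequency vs time) is smoothed by a 5-point
#' running median followed by a 3-point mean, then characterised:
#' duration spans the whistle (`t_last - t_first`); minimum, maximum, start,
#' end and delta (max - min) frequencies are read off the raw contour;
#' extrema are interior local maxima/minima (sign changes of the smoothed
#' first difference, slopes within `slope_tol` of zero treated as flat);
#' inflection points are curvature sign changes (sign changes of the second
#' difference); breaks are inter-point gaps longer than `break_threshold`;
#' saddles are flat slope runs whose flanking slopes share a sign.
#'
#' @param contour Data frame with `time` (s, strictly increasing) and
#'   `frequency` (Hz, positive); at least 3 points.
#' @param slope_tol Slope magnitudes below this (Hz per step) count as zero.
#' @param curv_tol Second-difference magnitudes below this (Hz) are ignored
#'   when counting inflections.
#' @param break_threshold Gap length (s) above which a break is counted.
#' @param smooth Logical; apply the median/mean smoother before counting.
#' @return One-row data frame: `duration`, `freq_min`, `freq_max`,
#'   `freq_start`, `freq_end`, `freq_delta`, `inflections`, `extrema`,
#'   `breaks`, `saddles`.
#' @export
extract_features <- function(contour, slope_tol = 50, curv_tol = 2,
                             break_threshold = 0.05, smooth = TRUE) {
  if (nrow(contour) < 3) stop("contour needs at least 3 points", call. = FALSE)
  tt <- contour$time
  if (any(diff(tt) <= 0)) stop("contour times must be strictly increasing", call. = FALSE)
  ff <- contour$frequency
  if (any(ff <= 0)) stop("contour frequencies must be positive", call. = FALSE)
  fs <- ff
  if (smooth && length(ff) >= 5) {
    fs <- stats::runmed(ff, 5, endrule = "median")
    fs3 <- stats::filter(fs, rep(1 / 3, 3))
    fs[2:(length(fs) - 1)] <- fs3[2:(length(fs) - 1)]
  }
  d1 <- diff(fs)
  s1 <- ifelse(abs(d1) < slope_tol, 0L, as.integer(sign(d1)))
  s1nz <- s1[s1 != 0]
  extrema <- if (length(s1nz) > 1) sum(diff(s1nz) != 0) else 0L
  # saddles: interior zero-slope runs flanked by equal nonzero signs
  saddles <- 0L
  r <- rle(s1)
  if (length(r$lengths) >= 3) {
    for (k in 2:(length(r$values) - 1)) {
      if (r$values[k] == 0 && r$values[k - 1] != 0 &&
          r$values[k - 1] == r$values[k + 1]) {
        saddles <- saddles + 1L
      }
    }
  }
  d2 <- diff(d1)
  s2 <- sign(d2)
  s2[abs(d2) < curv_tol] <- 0L
  s2nz <- s2[s2 != 0]
  inflections <- if (length(s2nz) > 1) sum(diff(s2nz) != 0) else 0L
  data.frame(
    duration = tt[length(tt)] - tt[1],
    freq_min = min(ff), freq_max = max(ff),
    freq_start = ff[1], freq_end = ff[length(ff)],
    freq_delta = max(ff) - min(ff),
    inflections = inflections, extrema = extrema,
    breaks = sum(diff(tt) > break_threshold),
    saddles = saddles
  )
}

#' Extract features for a table of contours
#'
#' @param contours Data frame with `whistle_id`, `time`, `frequency`.
#' @param whistles Optional whistle metadata with `whistle_id`, `start_time`
#'   and a `harmonics` flag, joined onto the output.
#' @param ... Passed to [extract_features()].
#' @return Data frame, one row per whistle.
#' @export
extract_features_all <- function(contours, whistles = NULL, ...) {
  feats <- do.call(rbind, lapply(split(contours, contours$whistle_id),
                                 extract_features, ...))
  feats$whistle_id <- as.integer(rownames(feats))
  feats <- feats[order(feats$whistle_id), ]
  rownames(feats) <- NULL
  if (!is.null(whistles)) {
    keep <- intersect(c("whistle_id", "start_time", "harmonics"),
                      names(whistles))
    feats <- merge(whistles[, keep], feats, by = "whistle_id")
  }
  feats
}

#' Pair whistles with behavioural context and pre-whistle noise
#'
#' Each whistle is joined to the temporally closest behavioural observation
#' (activity state, group size, calf presence); whistles with no observation
#' within `max_gap` (10 min) are excluded with a reason. Ties between two
#' equidistant observations go to the earlier one. Broadband and octave-band
#' noise levels are averaged over the `noise_window` (2 s) immediately
#' before the whistle start; windows containing missing noise values (e.g.
#' duty-cycle gaps) exclude the whistle.
#'
#' @param whistles Data frame with `whistle_id`, `start_time` and optionally
#'   `harmonics`.
#' @param samples Data frame with `obs_time` (or `sample_start`),
#'   `activity_state`, `group_size`, `calf_present`.
#' @param noise Noise series from [simulate_noise_series()] or measured
#'   equivalently: `time`, `nl_bb`, `obl_*` columns.
#' @param max_gap Maximum observation gap, seconds (default 600).
#' @param noise_window Pre-whistle averaging window, seconds (default 2).
#' @return List with `records` (one row per retained whistle: whistle id,
#'   start time, context covariates, `nl_bb`, `obl_*`) and `excluded`
#'   (whistle_id, reason).
#' @export
pair_whistles <- function(whistles, samples, noise, max_gap = 600,
                          noise_window = 2) {
  obs_time <- if ("obs_time" %in% names(samples)) samples$obs_time else
    samples$sample_start
  ord <- order(obs_time)
  samples <- samples[ord, ]
  obs_time <- obs_time[ord]
  obl_cols <- grep("^obl_", names(noise), value = TRUE)
  noise <- noise[order(noise$time), ]
  t0 <- whistles$start_time
  # nearest observation: the last at or before t0 vs the first after;
  # an exact gap tie goes to the earlier observation
  jlo <- pmax(findInterval(t0, obs_time), 1L)
  jhi <- pmin(jlo + 1L, length(obs_time))
  j <- ifelse(abs(obs_time[jhi] - t0) < abs(obs_time[jlo] - t0), jhi, jlo)
  gap <- abs(obs_time[j] - t0)
  # pre-whistle noise window means via prefix sums over the regular series
  i0 <- findInterval(t0 - noise_window - 1e-9, noise$time) + 1L
  i1 <- findInterval(t0 - 1e-9, noise$time)
  n_win <- pmax(i1 - i0 + 1L, 0L)
  win_mean <- function(v) {
    na <- is.na(v)
    S <- c(0, cumsum(ifelse(na, 0, v)))
    Sna <- c(0L, cumsum(na))
    out <- (S[i1 + 1] - S[pmax(i0, 1L)]) / n_win
    out[n_win <= 0 | (Sna[i1 + 1] - Sna[pmax(i0, 1L)]) > 0] <- NA_real_
    out
  }
  nl_bb <- win_mean(noise$nl_bb)
  no_obs <- gap > max_gap
  no_noise <- !is.finite(nl_bb)
  keep <- !no_obs & !no_noise
  rec <- data.frame(
    whistle_id = whistles$whistle_id[keep], start_time = t0[keep],
    activity_state = samples$activity_state[j[keep]],
    group_size = samples$group_size[j[keep]],
    calf_present = samples$calf_present[j[keep]],
    nl_bb = nl_bb[keep]
  )
  for (cc in obl_cols) rec[[cc]] <- win_mean(noise[[cc]])[keep]
  if ("harmonics" %in% names(whistles)) rec$harmonics <- whistles$harmonics[keep]
  excl_id <- whistles$whistle_id[!keep]
  list(
    records = if (nrow(rec)) rec else NULL,
    excluded = data.frame(
      whistle_id = excl_id,
      reason = ifelse(no_obs[!keep], "no_observation_within_10min",
                      "noise_window_unavailable"))
  )
}

#' Read a 16-bit PCM RIFF/WAVE file
#'
#' Minimal mono/first-channel reader for uncompressed 16-bit PCM WAV, the
#' format written by the acoustic logger.
#'
#' @param path File path.
#' @return List with `samples` (normalised to `[-1, 1)`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (wave != "WAVE") stop("not a WAVE file", call. = FALSE)
  sr <- NULL; nchan <- 1L; bits <- 16L; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      nchan <- fmt[2]
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      blk <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      bits <- blk[2]
      if (fmt[1] != 1 || bits != 16) stop("only 16-bit PCM supported", call. = FALSE)
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      n <- sz %/% 2
      samples <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples) || is.null(sr)) stop("malformed WAV file", call. = FALSE)
  if (nchan > 1) samples <- samples[seq(1, length(samples), by = nchan)]
  list(samples = samples / 32768, sample_rate = sr)
}

#' Write a 16-bit PCM RIFF/WAVE file
#'
#' @param samples Numeric vector in `[-1, 1)`.
#' @param sample_rate Sampling frequency, Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_sz, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
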
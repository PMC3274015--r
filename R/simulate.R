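#' Recording protocol for the simulated study
#'
#' The session layout under which signals are acquired: each motion is
#' performed for `intervals_per_motion` intervals of `interval_s` seconds;
#' each interval's decimated signal is cut into `segments_per_interval`
#' non-overlapping windows of exactly `segment_len` samples per channel.
#' With the defaults (8 motions x 8 intervals x 6 segments x 2 channels)
#' this yields 768 single-channel segments, i.e. 384 two-channel patterns.
#'
#' @param n_motions Number of motion classes recorded.
#' @param intervals_per_motion Number of 72-second intervals per motion.
#' @param interval_s Duration of one interval (s).
#' @param segments_per_interval Number of windows cut from each interval.
#' @param segment_len Window length in (decimated) samples.
#' @param n_channels Number of gyroscope channels.
#' @return An object of class `recording_protocol` (a named list).
#' @examples
#' recording_protocol()
#' @export
recording_protocol <- function(n_motions = 8L, intervals_per_motion = 8L,
                               interval_s = 72, segments_per_interval = 6L,
                               segment_len = 1600L, n_channels = 2L) {
  p <- list(
    n_motions = as.integer(n_motions),
    intervals_per_motion = as.integer(intervals_per_motion),
    interval_s = interval_s,
    segments_per_interval = as.integer(segments_per_interval),
    segment_len = as.integer(segment_len),
    n_channels = as.integer(n_channels)
  )
  class(p) <- "recording_protocol"
  stopifnot(p$n_motions >= 1L, p$intervals_per_motion >= 1L,
            p$interval_s > 0, p$segments_per_interval >= 1L,
            p$segment_len >= 1L, p$n_channels %in% 1:2)
  p
}

channel_names <- function() c("above_knee", "below_knee")

# Unit-peak within-burst oscillation: harmonics of the fundamental swing
# (two cycles per repetition) under a raised-cosine envelope.
burst_waveform <- function(u, harmonics, phase = 0) {
  cycles <- 2
  osc <- 0
  for (k in seq_along(harmonics)) {
    osc <- osc + harmonics[k] * sin(2 * pi * k * cycles * u + phase)
  }
  env <- 0.5 * (1 - cos(2 * pi * u))
  w <- env * osc
  peak <- max(abs(w))
  if (peak > 0) w <- w / peak
  w
}

#' Simulate a two-channel gyroscope rate signal for one motion interval
#'
#' Generates the angular-rate time series the two leg-mounted gyroscopes
#' would measure while the subject repeats one motion. The repetition period
#' is drawn uniformly from 5--7 s (giving 10--14 repetitions per 72-second
#' interval); every repetition is a raised-cosine burst of the motion's
#' harmonic template with per-repetition amplitude and phase jitter, shared
#' between the two channels (both gyroscopes see the same limb movement).
#' Two disturbance components are added. A physiological tremor term --
#' a narrow-band oscillation around `tremor_hz` whose amplitude is a fixed
#' fraction of the channel's movement amplitude and which is gated by the
#' movement envelope -- gives the high-frequency wavelet sub-bands
#' motion-correlated content, as real limb recordings have. Independent
#' white Gaussian sensor noise is then added to every channel; its standard
#' deviation is a property of the sensor, not of the motion, and is set by
#' `snr_db` relative to a fixed nominal movement intensity of
#' `ref_rms` deg/s RMS (so all channels and classes, including the
#' motionless M1, receive the same noise level), with an absolute floor
#' `noise_floor`.
#'
#' @param motion_id Integer motion class in `1..8` (see [motion_classes()]).
#' @param duration_s Duration of the interval (s).
#' @param fs Sampling frequency (Hz).
#' @param seed Integer seed; the same call with the same seed reproduces the
#'   signal exactly.
#' @param snr_db Sensor signal-to-noise ratio (dB) relative to `ref_rms`.
#' @param noise_floor Minimum noise standard deviation (deg/s).
#' @param ref_rms Nominal movement intensity (deg/s RMS) that anchors the
#'   SNR scale.
#' @param tremor_hz Centre frequency of the physiological tremor band (Hz).
#' @param tremor_frac Tremor amplitude as a fraction of the channel's
#'   movement amplitude (0 disables it).
#' @return A tibble with columns `time` (s), `above_knee` and `below_knee`
#'   (deg/s), of `round(duration_s * fs)` rows.
#' @examples
#' x <- generate_rate_signal(4, duration_s = 12, fs = 133.4, seed = 1)
#' sapply(x[-1], sd)
#' @export
generate_rate_signal <- function(motion_id, duration_s, fs, seed,
                                 snr_db = 20, noise_floor = 1, ref_rms = 30,
                                 tremor_hz = 9, tremor_frac = 0.06) {
  if (length(motion_id) != 1L || is.na(motion_id) ||
      motion_id != round(motion_id) || motion_id < 1 || motion_id > 8) {
    abort("`motion_id` must be a single integer in 1..8.")
  }
  stopifnot(duration_s > 0, fs > 0)
  tmpl <- motion_template(motion_id)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  with_local_seed(derive_seed(seed, motion_id), {
    period <- runif(1, 5, 7)
    n_reps <- ceiling(duration_s / period)
    rep_amp <- pmin(pmax(rnorm(n_reps, 1, 0.05), 0.85), 1.15)
    rep_phase <- rnorm(n_reps, 0, 0.15)

    rep_idx <- pmin(floor(t / period), n_reps - 1)
    u <- t / period - rep_idx

    shape <- numeric(n)
    harmonics <- tmpl$harmonics[[1]]
    for (r in seq_len(n_reps) - 1L) {
      sel <- rep_idx == r
      if (!any(sel)) next
      shape[sel] <- rep_amp[r + 1] *
        burst_waveform(u[sel], harmonics, rep_phase[r + 1])
    }
    shape <- tmpl$direction * shape

    out <- list(time = t)
    amps <- c(above_knee = tmpl$amp_above, below_knee = tmpl$amp_below)
    for (ch in channel_names()) {
      sig <- amps[[ch]] * shape
      if (amps[[ch]] > 0 && tremor_frac > 0) {
        # ~1 Hz-wide line at tremor_hz via a random phase walk, gated by
        # the movement envelope and scaled with the movement amplitude
        walk <- cumsum(rnorm(n, 0, sqrt(2 * pi / fs)))
        sig <- sig + tremor_frac * amps[[ch]] * abs(shape) *
          sin(2 * pi * tremor_hz * t + walk)
      }
      sigma <- max(noise_floor, ref_rms * 10^(-snr_db / 20))
      out[[ch]] <- sig + rnorm(n, 0, sigma)
    }
    tibble::as_tibble(out)
  })
}

#' Simulate a full labeled gyroscope dataset
#'
#' Runs the complete acquisition chain for every motion, interval and
#' channel: rate signal synthesis at the raw sampling frequency, the affine
#' rate-to-voltage sensor characteristic with saturation, mid-tread A/D
#' quantization, decimation to the effective sampling rate, conversion back
#' to angular rate, and segmentation into fixed-length labeled windows.
#'
#' @param protocol A [recording_protocol()].
#' @param spec A [gyro_spec()].
#' @param seed Integer master seed; per-interval sub-streams are derived
#'   deterministically from it.
#' @param snr_db,noise_floor,... Passed to [generate_rate_signal()].
#' @return A tibble of single-channel segments with columns `motion_id`,
#'   `channel`, `interval_index`, `segment_index` and `samples` (list-column
#'   of numeric vectors of length `segment_len`, deg/s). The `protocol`,
#'   `spec`, `seed` and `snr_db` used are attached as attributes.
#' @examples
#' small <- recording_protocol(n_motions = 2, intervals_per_motion = 1,
#'                             segments_per_interval = 2)
#' d <- build_dataset(small, seed = 1)
#' dplyr::count(d, motion_id, channel)
#' @export
build_dataset <- function(protocol = recording_protocol(), spec = gyro_spec(),
                          seed = 1L, snr_db = 20, noise_floor = 1, ...) {
  validate_gyro_spec(spec)
  needed_raw <- protocol$segments_per_interval * protocol$segment_len *
    spec$downsample_factor
  avail_raw <- round(protocol$interval_s * spec$fs_raw)
  if (needed_raw > avail_raw * 1.01) {
    abort(sprintf(
      "interval too short: %d raw samples required for %d segments of %d samples (decimation %d), but only %d available.",
      needed_raw, protocol$segments_per_interval, protocol$segment_len,
      spec$downsample_factor, avail_raw
    ))
  }

  rows <- list()
  i <- 1L
  for (m in seq_len(protocol$n_motions)) {
    for (itv in seq_len(protocol$intervals_per_motion)) {
      raw <- generate_rate_signal(
        m, protocol$interval_s, spec$fs_raw,
        seed = derive_seed(seed, m, itv),
        snr_db = snr_db, noise_floor = noise_floor, ...
      )
      for (ch in channel_names()[seq_len(protocol$n_channels)]) {
        v <- rate_to_voltage(raw[[ch]], spec)
        v <- quantize_adc(v, spec)
        r <- voltage_to_rate(downsample_signal(v, spec$downsample_factor), spec)
        for (s in seq_len(protocol$segments_per_interval)) {
          idx <- ((s - 1L) * protocol$segment_len + 1L):(s * protocol$segment_len)
          rows[[i]] <- tibble::tibble(
            motion_id = m, channel = ch, interval_index = itv,
            segment_index = s, samples = list(r[idx])
          )
          i <- i + 1L
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "protocol") <- protocol
  attr(out, "spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  attr(out, "snr_db") <- snr_db
  out
}

#' Pair the two channels of a segment dataset into patterns
#'
#' Joins the above-knee and below-knee segments that share the same
#' `(motion_id, interval_index, segment_index)` triple into one two-channel
#' pattern, the unit on which features are computed and classification is
#' performed.
#'
#' @param dataset A segment tibble from [build_dataset()].
#' @return A tibble with one row per pattern: `pattern_id`, `motion_id`,
#'   `interval_index`, `segment_index`, `above_knee` and `below_knee`
#'   (list-columns of sample vectors).
#' @export
pair_patterns <- function(dataset) {
  wide <- tidyr::pivot_wider(
    dataset,
    id_cols = c("motion_id", "interval_index", "segment_index"),
    names_from = "channel", values_from = "samples"
  )
  if (!all(channel_names() %in% names(wide))) {
    abort("dataset must contain both an above_knee and a below_knee channel.")
  }
  wide <- dplyr::arrange(wide, .data$motion_id, .data$interval_index,
                         .data$segment_index)
  dplyr::mutate(wide, pattern_id = dplyr::row_number(), .before = 1)
}

#' Write or read a segment dataset as delimited text
#'
#' `write_dataset()` stores one row per single-channel segment
#' (`motion_id, channel, interval_index, segment_index, s1..sN`) in
#' `segments.csv` plus a `meta.json` sidecar holding the protocol, sensor
#' spec, seed and SNR. `read_dataset()` restores the tibble and its
#' attributes.
#'
#' @param dataset A segment tibble from [build_dataset()].
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the segment tibble.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat <- do.call(rbind, dataset$samples)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  flat <- dplyr::bind_cols(
    dataset[c("motion_id", "channel", "interval_index", "segment_index")],
    tibble::as_tibble(mat)
  )
  readr::write_csv(flat, file.path(dir, "segments.csv"))
  meta <- list(
    protocol = unclass(attr(dataset, "protocol")),
    spec = unclass(attr(dataset, "spec")),
    seed = attr(dataset, "seed"),
    snr_db = attr(dataset, "snr_db")
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  flat <- readr::read_csv(file.path(dir, "segments.csv"),
                          show_col_types = FALSE)
  key <- c("motion_id", "channel", "interval_index", "segment_index")
  sample_cols <- setdiff(names(flat), key)
  out <- flat[key]
  mat <- as.matrix(flat[sample_cols])
  out$samples <- lapply(seq_len(nrow(mat)), function(i) unname(mat[i, ]))
  out <- tibble::as_tibble(out)
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "protocol") <- do.call(recording_protocol, meta$protocol[
      c("n_motions", "intervals_per_motion", "interval_s",
        "segments_per_interval", "segment_len", "n_channels")
    ])
    attr(out, "spec") <- do.call(gyro_spec, meta$spec[
      c("rate_max", "v_zero", "v_min", "v_max", "adc_bits", "adc_range",
        "fs_raw", "downsample_factor")
    ])
    attr(out, "seed") <- meta$seed
    attr(out, "snr_db") <- meta$snr_db
  }
  out
}
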
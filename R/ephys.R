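#' Detector settings for band-pass event detection
#'
#' Mirrors the programmable parameters of an implanted responsive
#' neurostimulator's band-pass detector: frequency band, a minimum
#' amplitude expressed as a percentage of the channel's full-scale range
#' (here: the maximum absolute value over the recording), and a minimum
#' duration the envelope must stay above that amplitude.
#'
#' @param min_freq,max_freq band edges in Hz (0 < min < max).
#' @param min_amplitude_pct minimum envelope amplitude, percent of
#'   full-scale, in (0, 100].
#' @param min_duration_s minimum suprathreshold run length in seconds (> 0).
#' @param channel channel name the detector is programmed on (may be
#'   overridden per call).
#' @return A `detector_settings` object.
#' @export
detector_settings <- function(min_freq = 33.1, max_freq = 125,
                              min_amplitude_pct = 25, min_duration_s = 0.51,
                              channel = "CX 1-2") {
  if (!(min_freq > 0 && min_freq < max_freq)) {
    stop("need 0 < `min_freq` < `max_freq`")
  }
  if (!(min_amplitude_pct > 0 && min_amplitude_pct <= 100)) {
    stop("`min_amplitude_pct` must be in (0, 100]")
  }
  if (min_duration_s <= 0) stop("`min_duration_s` must be > 0")
  structure(list(min_freq = min_freq, max_freq = max_freq,
                 min_amplitude_pct = min_amplitude_pct,
                 min_duration_s = min_duration_s, channel = channel),
            class = "detector_settings")
}

#' Z-score every channel of a recording
#'
#' Per channel: subtract the mean and divide by the (sample) SD, yielding
#' similar amplitude scaling across channels (thalamic signals are much
#' smaller than cortical ones on the raw traces).
#'
#' @param rec an `event_recording`.
#' @return The recording with standardized traces.
#' @export
zscore_channels <- function(rec) {
  sds <- apply(rec$traces, 1, sd)
  if (any(sds < 1e-12)) {
    stop("degenerate input: channel(s) ",
         paste(rownames(rec$traces)[sds < 1e-12], collapse = ", "),
         " are flat")
  }
  rec$traces <- (rec$traces - rowMeans(rec$traces)) / sds
  rec
}

# band-limited rectified smoothed envelope of one channel; zero-phase
# 4th-order (2 x 2) Butterworth so onsets are not systematically delayed
channel_envelope <- function(x, fs, min_freq, max_freq,
                             smooth_s = 0.1) {
  nyq <- fs / 2
  if (min_freq >= nyq) stop("band outside Nyquist: `min_freq` >= fs/2")
  hi <- min(max_freq, 0.99 * nyq)
  bf <- signal::butter(2, c(min_freq, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  w <- max(1L, round(smooth_s * fs))
  env <- as.numeric(stats::filter(abs(y), rep(1 / w, w), sides = 2))
  # centred moving average leaves NAs at the edges; hold the nearest value
  first <- which(!is.na(env))[1]
  last <- max(which(!is.na(env)))
  env[seq_len(first - 1)] <- env[first]
  if (last < length(env)) env[(last + 1):length(env)] <- env[last]
  env
}

#' Band-pass envelope event detection on one channel
#'
#' Band-limits the named channel, computes a rectified envelope smoothed
#' with a 0.1-s moving average, and returns the maximal runs where the
#' envelope stays at or above `min_amplitude_pct` percent of the channel's
#' full-scale range (max absolute value over the recording) for at least
#' `min_duration_s`. The onset of a detection is the start of its run.
#'
#' @param rec an `event_recording`.
#' @param settings a `detector_settings`; its `channel` field names the
#'   channel unless `channel` is supplied.
#' @param channel optional channel name override.
#' @return `data.frame` with `start_s`, `end_s`, `channel`, plus attribute
#'   `suprathreshold_frac`, the fraction of the record above threshold.
#' @export
bandpass_detect <- function(rec, settings, channel = NULL) {
  ch <- if (is.null(channel)) settings$channel else channel
  if (!ch %in% rownames(rec$traces)) stop("unknown channel: ", ch)
  x <- rec$traces[ch, ]
  env <- channel_envelope(x, rec$fs, settings$min_freq, settings$max_freq)
  thr <- settings$min_amplitude_pct / 100 * max(abs(x))
  above <- env >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rec$fs >= settings$min_duration_s - 1e-9)
  out <- data.frame(start_s = (starts[keep] - 1L) / rec$fs,
                    end_s = ends[keep] / rec$fs,
                    channel = rep(ch, sum(keep)))
  attr(out, "suprathreshold_frac") <- mean(above)
  out
}

#' Per-lead onset estimation
#'
#' For each lead role (cortical, thalamic), runs the band-pass detector on
#' every channel of that role and takes the earliest detection start as the
#' lead's onset; absent if no channel detects anything. A recording is
#' flagged `undetermined` when the envelope criterion holds for more than
#' `undetermined_frac` of the record on both leads (continuously
#' epileptiform throughout).
#'
#' @param rec an `event_recording`.
#' @param cortical_settings,thalamic_settings `detector_settings` per role.
#' @param undetermined_frac suprathreshold fraction above which a lead
#'   counts as continuously epileptiform (default 0.9).
#' @return List with `cortical_onset_s`, `thalamic_onset_s` (NA if no
#'   detection) and logical `undetermined`.
#' @export
estimate_onsets <- function(rec, cortical_settings,
                            thalamic_settings = cortical_settings,
                            undetermined_frac = 0.9) {
  roles <- rec$channel_roles[rownames(rec$traces)]
  lead_onset <- c(cortical = NA_real_, thalamic = NA_real_)
  lead_frac <- c(cortical = 0, thalamic = 0)
  for (role in c("cortical", "thalamic")) {
    st <- if (role == "cortical") cortical_settings else thalamic_settings
    for (ch in rownames(rec$traces)[roles == role]) {
      det <- bandpass_detect(rec, st, channel = ch)
      lead_frac[role] <- max(lead_frac[role], attr(det, "suprathreshold_frac"))
      if (nrow(det) > 0) {
        lead_onset[role] <- min(lead_onset[role], det$start_s[1], na.rm = TRUE)
      }
    }
  }
  list(cortical_onset_s = unname(lead_onset["cortical"]),
       thalamic_onset_s = unname(lead_onset["thalamic"]),
       undetermined = all(lead_frac > undetermined_frac))
}

#' Classify cortico-thalamic onset order
#'
#' An event is `cortical_first` if cortical onset precedes thalamic onset
#' by at least `threshold_s` (boundary inclusive), `thalamic_first` for the
#' reverse, otherwise `simultaneous`. An `undetermined` flag (continuously
#' epileptiform recording) overrides the onsets.
#'
#' @param cortical_onset_s,thalamic_onset_s onsets in seconds.
#' @param threshold_s classification threshold (default 0.25 s, the
#'   smallest onset difference treated as a distinct lead order).
#' @param undetermined logical override flag.
#' @return An `onset_call`: onsets, `lag_s` (thalamic minus cortical),
#'   `label`, `threshold_s`.
#' @export
classify_onset <- function(cortical_onset_s, thalamic_onset_s,
                           threshold_s = 0.25, undetermined = FALSE) {
  if (undetermined) {
    return(structure(list(cortical_onset_s = NA_real_,
                          thalamic_onset_s = NA_real_, lag_s = NA_real_,
                          label = "undetermined", threshold_s = threshold_s),
                     class = "onset_call"))
  }
  if (is.na(cortical_onset_s) || is.na(thalamic_onset_s)) {
    stop("missing onset without the undetermined flag")
  }
  lag <- thalamic_onset_s - cortical_onset_s
  label <- derive_category(lag, threshold_s)
  structure(list(cortical_onset_s = cortical_onset_s,
                 thalamic_onset_s = thalamic_onset_s, lag_s = lag,
                 label = label, threshold_s = threshold_s),
            class = "onset_call")
}

#' Detect and classify one recording
#'
#' Convenience wrapper: [estimate_onsets()] then [classify_onset()].
#'
#' @inheritParams estimate_onsets
#' @param threshold_s classification threshold in seconds.
#' @return An `onset_call`.
#' @export
classify_recording <- function(rec, cortical_settings,
                               thalamic_settings = cortical_settings,
                               threshold_s = 0.25) {
  est <- estimate_onsets(rec, cortical_settings, thalamic_settings)
  classify_onset(est$cortical_onset_s, est$thalamic_onset_s,
                 threshold_s = threshold_s,
                 undetermined = est$undetermined)
}

#' Select the top-scored recordings per device
#'
#' Per (patient, device side), the `k_per_device` recordings with the
#' highest score; ties broken toward the earlier timestamp. If a device's
#' pool holds fewer than `k_per_device` recordings, all are returned with a
#' warning.
#'
#' @param pool list of scored `event_recording`s.
#' @param k_per_device recordings to keep per device (default 10).
#' @return Sub-list of `pool`, in (patient, device, rank) order.
#' @export
select_top_events <- function(pool, k_per_device = 10L) {
  scores <- vapply(pool, `[[`, numeric(1), "score")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("all recordings must carry a score in [0, 1]")
  }
  key <- paste(vapply(pool, `[[`, character(1), "patient_id"),
               vapply(pool, `[[`, character(1), "device_side"))
  ts <- vapply(pool, `[[`, numeric(1), "timestamp")
  picked <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < k_per_device) {
      warning("device ", k, ": only ", length(idx), " recordings available (< ",
              k_per_device, ")")
    }
    ord <- idx[order(-scores[idx], ts[idx])]
    picked <- c(picked, ord[seq_len(min(k_per_device, length(ord)))])
  }
  pool[picked]
}

#' Summarize onset classifications
#'
#' @param calls list of `onset_call`s (>= 1).
#' @return An `onset_summary`: `n_total`, per-label `counts` and
#'   `percentages` (one decimal), and `median_lag_s` among
#'   cortical-first events.
#' @export
summarize_onsets <- function(calls) {
  if (length(calls) < 1L) stop("need at least one onset call to summarize")
  labels <- factor(vapply(calls, `[[`, character(1), "label"),
                   levels = c("cortical_first", "thalamic_first",
                              "simultaneous", "undetermined"))
  counts <- table(labels)
  pct <- round(100 * as.numeric(counts) / length(calls), 1)
  names(pct) <- names(counts)
  lags <- vapply(calls, `[[`, numeric(1), "lag_s")
  med <- if (any(labels == "cortical_first")) {
    median(lags[labels == "cortical_first"])
  } else NA_real_
  structure(list(n_total = length(calls), counts = counts,
                 percentages = pct, median_lag_s = med),
            class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat("onset_summary over", x$n_total, "recordings:\n")
  for (lab in names(x$counts)) {
    cat(sprintf("  %-15s %2d/%d (%.1f%%)\n", lab, x$counts[[lab]],
                x$n_total, x$percentages[[lab]]))
  }
  cat("  median cortical-lead lag:", x$median_lag_s, "s\n")
  invisible(x)
}
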
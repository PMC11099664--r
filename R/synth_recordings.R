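#' @importFrom stats fft runif
NULL

# 1/f ("pink") noise via spectral shaping of white noise, unit SD
pink_noise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # |frequency| bin index
  scale <- 1 / sqrt(pmax(f, 1))
  scale[1] <- 0  # drop DC
  x <- Re(fft(sp * scale, inverse = TRUE)) / n
  as.numeric(x / sd(x))
}

default_channels <- c("CX 1-2", "CX 3-4", "TH 1-2", "TH 3-4")
default_roles <- c("cortical", "cortical", "thalamic", "thalamic")

new_event_recording <- function(traces, fs, channel_roles, device_side,
                                trigger_type, trigger_time_s, score,
                                patient_id, recording_id, timestamp) {
  if (!is.matrix(traces)) stop("`traces` must be a channel x sample matrix")
  if (fs <= 0) stop("`fs` must be positive")
  roles <- channel_roles[rownames(traces)]
  if (sum(roles == "cortical") < 1L || sum(roles == "thalamic") < 1L) {
    stop("recording needs at least one cortical and one thalamic channel")
  }
  structure(list(traces = traces, fs = fs, channel_roles = channel_roles,
                 device_side = device_side, trigger_type = trigger_type,
                 trigger_time_s = trigger_time_s, score = score,
                 patient_id = patient_id, recording_id = recording_id,
                 timestamp = timestamp),
            class = "event_recording")
}

#' @export
print.event_recording <- function(x, ...) {
  cat("event_recording", x$recording_id, ":", nrow(x$traces), "channels x",
      ncol(x$traces) / x$fs, "s at", x$fs, "Hz;",
      x$patient_id, x$device_side, "device; score",
      round(x$score, 3), "\n")
  invisible(x)
}

#' Transparent event score: normalized line length
#'
#' Min-max-normalized mean line length (mean absolute first difference,
#' averaged over channels) across a pool of recordings, mapped to [0, 1].
#' A monotone, fully transparent stand-in for a trained electrographic
#' seizure classifier's probability: recordings with more high-amplitude,
#' high-frequency content score higher. If all recordings in the pool have
#' identical line length, every score is 0.5.
#'
#' @param recordings list of `event_recording`s.
#' @return Numeric vector of scores in [0, 1].
#' @export
score_recordings <- function(recordings) {
  ll <- vapply(recordings, function(r) {
    mean(abs(t(diff(t(r$traces)))))
  }, numeric(1))
  rng <- range(ll)
  if (diff(rng) < 1e-12) return(rep(0.5, length(ll)))
  (ll - rng[1]) / diff(rng)
}

#' Canonical planted-lag specification for one event
#'
#' @param cortex_onset_s,thalamus_onset_s planted onsets in seconds (NA for
#'   an `undetermined` event, which is epileptiform over its whole
#'   duration).
#' @param category optional; derived from the onsets under the 0.25-s rule
#'   when omitted.
#' @param patient_id,device_side metadata.
#' @param burst_freq,burst_snr oscillation frequency (Hz) and amplitude as
#'   a multiple of the background SD.
#' @return One-row `data.frame` suitable for [make_recordings()].
#' @export
lag_spec_row <- function(cortex_onset_s, thalamus_onset_s, category = NA,
                         patient_id = "P1", device_side = "left",
                         burst_freq = 60, burst_snr = 8) {
  data.frame(cortex_onset_s = cortex_onset_s,
             thalamus_onset_s = thalamus_onset_s,
             category = category, patient_id = patient_id,
             device_side = device_side, burst_freq = burst_freq,
             burst_snr = burst_snr, stringsAsFactors = FALSE)
}

derive_category <- function(lag_s, threshold_s = 0.25) {
  if (lag_s >= threshold_s) "cortical_first"
  else if (-lag_s >= threshold_s) "thalamic_first"
  else "simultaneous"
}

#' Synthetic two-lead intracranial event recordings
#'
#' Each recording has two cortical and two thalamic bipolar channels of
#' unit-SD pink-noise background, plus a planted oscillatory burst starting
#' at the per-lead planted onset (a 10 Hz burst emulates polyspike-like
#' discharges, 60 Hz fast-activity-like ones). `undetermined` events carry
#' the burst over the whole duration on all channels. The ground-truth
#' category is derived from the planted onsets under the 0.25-s rule, and
#' planted lags must keep a margin of at least 2 samples away from the
#' classification boundary unless `enforce_margin = FALSE` (for explicit
#' boundary fixtures).
#'
#' @param lag_spec `data.frame` with columns `cortex_onset_s`,
#'   `thalamus_onset_s` and optionally `category`, `patient_id`,
#'   `device_side`, `burst_freq`, `burst_snr` (see [lag_spec_row()]).
#' @param n_events number of events; defaults to `nrow(lag_spec)`.
#' @param fs sampling rate in Hz (>= 100).
#' @param duration_s recording length in seconds (default 20, the device's
#'   stored-event length).
#' @param device_offset_s trigger-timestamp offset of the right device
#'   relative to the left (emulates near-simultaneous magnet swipes over
#'   two devices).
#' @param seed integer RNG seed.
#' @param burst_duration_s burst length in seconds.
#' @param threshold_s onset-lag classification threshold used to derive the
#'   ground-truth category.
#' @param enforce_margin require planted |lag| to sit >= 2 samples from the
#'   classification boundary.
#' @return List with `recordings` (list of `event_recording`, scored) and
#'   `truth` (`data.frame`: recording_id, onsets, lag_s, category).
#' @export
make_recordings <- function(lag_spec, n_events = nrow(lag_spec), fs = 250,
                            duration_s = 20, device_offset_s = 0, seed = 1L,
                            burst_duration_s = 3, threshold_s = 0.25,
                            enforce_margin = TRUE) {
  if (fs < 100) stop("`fs` must be >= 100 Hz")
  if (n_events > nrow(lag_spec)) stop("`n_events` exceeds rows of `lag_spec`")
  spec <- lag_spec[seq_len(n_events), , drop = FALSE]
  for (col in c("patient_id", "device_side", "burst_freq", "burst_snr",
                "category")) {
    if (is.null(spec[[col]])) {
      spec[[col]] <- switch(col, patient_id = "P1", device_side = "left",
                            burst_freq = 60, burst_snr = 8, category = NA)
    }
  }
  n_samp <- round(duration_s * fs)
  t_axis <- (seq_len(n_samp) - 1) / fs

  set.seed(seed)
  recs <- vector("list", n_events)
  truth <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    undet <- !is.na(spec$category[e]) && spec$category[e] == "undetermined"
    cx <- spec$cortex_onset_s[e]
    th <- spec$thalamus_onset_s[e]
    if (!undet) {
      if (any(is.na(c(cx, th)))) stop("planted onsets are required unless category is 'undetermined'")
      if (cx < 0 || cx >= duration_s || th < 0 || th >= duration_s) {
        stop("planted onset outside recording duration")
      }
      lag <- th - cx
      cat_derived <- derive_category(lag, threshold_s)
      if (enforce_margin && abs(abs(lag) - threshold_s) < 2 / fs) {
        stop("planted lag within 2 samples of the classification boundary; ",
             "use enforce_margin = FALSE for boundary fixtures")
      }
      if (!is.na(spec$category[e]) && spec$category[e] != cat_derived) {
        stop("declared category '", spec$category[e],
             "' is inconsistent with planted onsets (derived '",
             cat_derived, "')")
      }
      category <- cat_derived
    } else {
      category <- "undetermined"
      cx <- NA_real_
      th <- NA_real_
    }

    traces <- matrix(0, 4, n_samp, dimnames = list(default_channels, NULL))
    for (ch in seq_len(4)) {
      bg <- pink_noise(n_samp)
      onset <- if (undet) 0 else if (default_roles[ch] == "cortical") cx else th
      burst <- numeric(n_samp)
      b_end <- if (undet) duration_s else min(onset + burst_duration_s, duration_s)
      win <- t_axis >= onset & t_axis < b_end
      phase <- runif(1, 0, 2 * pi)
      burst[win] <- spec$burst_snr[e] *
        sin(2 * pi * spec$burst_freq[e] * (t_axis[win] - onset) + phase)
      traces[ch, ] <- bg + burst
    }

    rid <- sprintf("rec%03d", e)
    recs[[e]] <- new_event_recording(
      traces = traces, fs = fs,
      channel_roles = stats::setNames(default_roles, default_channels),
      device_side = spec$device_side[e],
      trigger_type = if (undet) "magnet" else "long_episode",
      trigger_time_s = if (spec$device_side[e] == "right") device_offset_s else 0,
      score = NA_real_, patient_id = spec$patient_id[e],
      recording_id = rid, timestamp = e
    )
    truth[[e]] <- data.frame(recording_id = rid, cortex_onset_s = cx,
                             thalamus_onset_s = th, lag_s = th - cx,
                             category = category, stringsAsFactors = FALSE)
  }
  scores <- score_recordings(recs)
  for (e in seq_len(n_events)) recs[[e]]$score <- scores[e]
  list(recordings = recs, truth = do.call(rbind, truth))
}

#' Planted-lag study design analogous to the implanted-patient cohort
#'
#' Forty events across two patients with two devices each (10 events per
#' device): 23 cortex-leading events with planted lags between 0.5 and
#' 2.9 s (median 1.5 s), 16 near-simultaneous events with |lag| <= 0.1 s,
#' and one event that is epileptiform over its whole duration
#' (`undetermined`). No event leads in the thalamus.
#'
#' @return A `data.frame` of 40 rows for [make_recordings()].
#' @export
lag_spec_study <- function() {
  lags_cf <- c(seq(0.6, 1.4, length.out = 11), 1.5,
               seq(1.6, 2.9, length.out = 11))
  lags_sim <- seq(-0.1, 0.1, length.out = 16)
  cx_cf <- rep(seq(2, 6, length.out = 8), length.out = 23)
  cx_sim <- rep(seq(3, 7, length.out = 8), length.out = 16)
  spec <- rbind(
    data.frame(cortex_onset_s = cx_cf, thalamus_onset_s = cx_cf + lags_cf,
               category = NA_character_),
    data.frame(cortex_onset_s = cx_sim, thalamus_onset_s = cx_sim + lags_sim,
               category = NA_character_),
    data.frame(cortex_onset_s = NA_real_, thalamus_onset_s = NA_real_,
               category = "undetermined")
  )
  spec$patient_id <- rep(c("P1", "P2"), each = 20)
  spec$device_side <- rep(c("left", "right", "left", "right"), each = 10)
  spec$burst_freq <- 60
  spec$burst_snr <- 8
  spec
}
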
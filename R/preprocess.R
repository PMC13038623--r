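# Preprocessing chain: average reference -> notch -> band-pass -> spherical
# spline repair of bad channels -> event-locked epoching. Filters are IIR
# designs applied forward-backward (zero phase).

#' Re-reference to the global average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean of the output is zero at every sample. Linear and
#' idempotent.
#'
#' @param rec a [verge_recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "verge_recording"))
  if (nrow(rec$data) < 2) stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

apply_filtfilt <- function(rec, b, a) {
  flt <- signal::Arma(b = b, a = a)
  for (ch in seq_len(nrow(rec$data))) {
    rec$data[ch, ] <- signal::filtfilt(flt, rec$data[ch, ])
  }
  rec
}

#' Zero-phase notch filter for power-line interference
#'
#' Second-order IIR notch (quality factor `q`, default 30) applied
#' forward-backward. At the default settings the stopband is narrow: the
#' -3 dB width is about `f0/q` Hz, so neighbouring EEG rhythms pass
#' essentially unattenuated.
#'
#' @param rec a [verge_recording()].
#' @param f0 notch frequency in Hz (default 50, the power-line fundamental).
#' @param q notch quality factor.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, f0 = 50, q = 30) {
  stopifnot(inherits(rec, "verge_recording"))
  if (f0 >= rec$fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  apply_filtfilt(rec, b / a[1], a / a[1])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward-backward. The default
#' 0.5-31.25 Hz band retains the delta-through-beta range analysed
#' downstream and removes DC drift.
#'
#' @param rec a [verge_recording()].
#' @param lo,hi band edges in Hz.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 31.25) {
  stopifnot(inherits(rec, "verge_recording"))
  if (!(0 < lo && lo < hi && hi < rec$fs / 2)) {
    stop("invalid band [", lo, ", ", hi, "] Hz for fs ", rec$fs)
  }
  bt <- signal::butter(2, c(lo, hi) / (rec$fs / 2), type = "pass")
  apply_filtfilt(rec, bt$b, bt$a)
}

#' Repair bad channels by spherical-spline interpolation
#'
#' Replaces the listed channels with Perrin-type spherical-spline estimates
#' (order `m = 4`) computed from the remaining good channels at every sample.
#' Good channels are untouched.
#'
#' @param rec a [verge_recording()] with a montage.
#' @param bad character vector of bad channel labels (possibly empty).
#' @param lambda ridge regularisation of the spline fit; `0` interpolates
#'   the good channels exactly, small positive values denoise.
#' @return The repaired recording.
#' @export
interpolate_bad_channels <- function(rec, bad, lambda = 1e-5) {
  stopifnot(inherits(rec, "verge_recording"))
  if (length(bad) == 0) return(rec)
  if (is.null(rec$montage)) stop("recording has no montage positions")
  unknown <- setdiff(bad, rec$channels)
  if (length(unknown) > 0) stop("unknown bad channels: ", paste(unknown, collapse = ", "))
  good <- setdiff(rec$channels, bad)
  if (length(good) < 4) stop("need at least 4 good channels for interpolation")
  pos <- rec$montage[match(rec$channels, rec$montage$label), c("x", "y", "z")]
  gi <- match(good, rec$channels)
  bi <- match(bad, rec$channels)
  fit <- spherical_spline_fit(pos[gi, ], rec$data[gi, , drop = FALSE],
                              m = 4, lambda = lambda)
  rec$data[bi, ] <- fit(pos[bi, , drop = FALSE])
  rec
}

#' Flag bad channels by robust variance
#'
#' Optional automatic detection: a channel is flagged when the robust z-score
#' (median/MAD) of its log variance exceeds `z_max`.
#'
#' @param rec a [verge_recording()].
#' @param z_max robust z threshold (default 4).
#' @return Character vector of flagged channel labels.
#' @export
detect_bad_channels <- function(rec, z_max = 4) {
  v <- log(apply(rec$data, 1, var))
  z <- (v - median(v)) / (mad(v) + 1e-12)
  rec$channels[abs(z) > z_max]
}

#' Artifact-rejection hook
#'
#' Placeholder for component-based artifact removal: applies a user-supplied
#' function mapping a recording to a cleaned recording, defaulting to the
#' identity. Keeps the preprocessing chain's interface stable when an
#' external artifact pipeline is plugged in.
#'
#' @param rec a [verge_recording()].
#' @param hook function `rec -> rec`, default identity.
#' @return The (possibly cleaned) recording.
#' @export
artifact_hook <- function(rec, hook = identity) {
  out <- hook(rec)
  if (!inherits(out, "verge_recording")) stop("artifact hook must return a verge_recording")
  out
}

#' Cut event-locked epochs from one recording
#'
#' Start conditions are epoched over \[0, +1000) ms after the lock event and
#' break conditions over \[-1000, 0) ms before it (configurable via
#' `windows`). Epochs that would cross the recording bounds are dropped with
#' a warning and counted.
#'
#' @param rec a [verge_recording()].
#' @param conditions condition labels to epoch (must appear in the events).
#' @param windows named list of `c(start_ms, end_ms)` windows per condition.
#' @return Named list per condition: `epochs` (trial x channel x time array),
#'   `window_ms`, `n_dropped`.
#' @export
epoch_recording <- function(rec, conditions = condition_names(),
                            windows = condition_windows()) {
  stopifnot(inherits(rec, "verge_recording"))
  out <- list()
  for (cond in conditions) {
    win <- windows[[cond]]
    if (is.null(win)) stop("no epoch window defined for condition '", cond, "'")
    ev <- rec$events$sample[rec$events$label == cond]
    if (length(ev) == 0) stop("no events found for condition '", cond, "'")
    n_t <- as.integer(round((win[2] - win[1]) / 1000 * rec$fs))
    off <- as.integer(round(win[1] / 1000 * rec$fs))
    starts <- ev + off
    ok <- starts >= 1 & (starts + n_t - 1L) <= ncol(rec$data)
    n_drop <- sum(!ok)
    if (n_drop > 0) {
      warning(n_drop, " epoch(s) dropped for condition '", cond,
              "': window exceeds recording bounds")
    }
    starts <- starts[ok]
    arr <- array(0, c(length(starts), nrow(rec$data), n_t))
    for (i in seq_along(starts)) {
      arr[i, , ] <- rec$data[, starts[i]:(starts[i] + n_t - 1L)]
    }
    dimnames(arr) <- list(NULL, rec$channels, NULL)
    out[[cond]] <- list(epochs = arr, window_ms = win, n_dropped = n_drop)
  }
  out
}

#' Assemble a cohort-level epoch set for one condition
#'
#' Epochs every subject's recording and stacks the result into a
#' subject x trial x channel x time tensor.
#'
#' @param cohort a `verge_cohort` (or list of recordings plus `groups` and
#'   `subject_ids`).
#' @param condition condition label.
#' @param windows epoch windows, as in [epoch_recording()].
#' @return A `verge_epochs` object.
#' @export
epoch_cohort <- function(cohort, condition, windows = condition_windows()) {
  recs <- cohort$subjects
  per_sub <- lapply(recs, function(r) {
    epoch_recording(r, conditions = condition, windows = windows)[[condition]]
  })
  d <- dim(per_sub[[1]]$epochs)
  tensor <- array(0, c(length(recs), d[1], d[2], d[3]))
  for (i in seq_along(per_sub)) {
    if (!all(dim(per_sub[[i]]$epochs) == d)) {
      stop("subject ", i, " has a different epoch shape")
    }
    tensor[i, , , ] <- per_sub[[i]]$epochs
  }
  dimnames(tensor) <- list(cohort$subject_ids, NULL, recs[[1]]$channels, NULL)
  structure(list(
    tensor = tensor, condition = condition,
    window_ms = per_sub[[1]]$window_ms, fs = recs[[1]]$fs,
    subject_ids = cohort$subject_ids, groups = cohort$groups,
    channels = recs[[1]]$channels
  ), class = "verge_epochs")
}

#' Run the standard preprocessing chain on one recording
#'
#' Average reference, 50 Hz notch, 0.5-31.25 Hz band-pass, optional
#' bad-channel interpolation and artifact hook, in that order.
#'
#' @param rec a [verge_recording()].
#' @param bad_channels labels to repair (default none).
#' @param notch_hz notch frequency; `NULL` skips the notch.
#' @param band band-pass edges; `NULL` skips the band-pass.
#' @param hook artifact-rejection hook, default identity.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, bad_channels = character(0),
                                 notch_hz = 50, band = c(0.5, 31.25),
                                 hook = identity) {
  rec <- average_reference(rec)
  if (!is.null(notch_hz)) rec <- notch_filter(rec, notch_hz)
  if (!is.null(band)) rec <- bandpass_filter(rec, band[1], band[2])
  if (length(bad_channels) > 0) rec <- interpolate_bad_channels(rec, bad_channels)
  artifact_hook(rec, hook)
}
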
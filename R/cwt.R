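# Continuous wavelet transform with a complex Morlet mother wavelet and an
# explicit arithmetic scale series: scale a_k = c/k (k = 1..totalscal) with
# c = 2 * Fc * totalscal maps to frequency Fa = Fc * fs / a = k * fs /
# (2 * totalscal), so the smallest scale lands exactly on the Nyquist
# frequency fs/2 and the frequency axis is uniformly spaced.

#' Wavelet transform configuration
#'
#' @param Fc wavelet centre frequency in wavelet-time units (default 1).
#' @param totalscal number of scales (>= 8); the frequency axis spacing is
#'   `fs / (2 * totalscal)`.
#' @param fs sampling rate in Hz.
#' @param pad_ms bilateral reflection padding applied before the transform
#'   and trimmed afterwards, ms per side.
#' @param bandwidth Morlet time-domain Gaussian variance parameter (wavelet
#'   units); larger values trade temporal for spectral resolution.
#' @param fmin,fmax retained frequency range in Hz (default 0.5-31.25,
#'   matching the acquisition band-pass).
#' @param bands named frequency bands used by summaries.
#' @return A `cwt_config` list.
#' @export
cwt_config <- function(Fc = 1, totalscal = 512, fs = 500, pad_ms = 500,
                       bandwidth = 1.5, fmin = 0.5, fmax = 31.25,
                       bands = eeg_bands()) {
  if (totalscal < 8) stop("totalscal must be >= 8")
  if (Fc <= 0) stop("Fc must be positive")
  if (!(0 < fmin && fmin < fmax && fmax <= fs / 2)) stop("invalid frequency range")
  structure(list(Fc = Fc, totalscal = as.integer(totalscal), fs = fs,
                 pad_ms = pad_ms, bandwidth = bandwidth,
                 fmin = fmin, fmax = fmax, bands = bands),
            class = "cwt_config")
}

#' Build the arithmetic scale series and its frequency axis
#'
#' Scales are `a_k = c / k` for `k = 1..totalscal` with `c = 2 * Fc *
#' totalscal`; the matched frequencies `Fa_k = Fc * fs / a_k` form a uniform
#' axis from `fs / (2 * totalscal)` up to exactly `fs / 2`.
#'
#' @param cfg a [cwt_config()].
#' @return List with `scales` and `freqs` (both ordered by increasing
#'   frequency) and the constant `c`.
#' @export
build_scale_series <- function(cfg) {
  stopifnot(inherits(cfg, "cwt_config"))
  k <- seq_len(cfg$totalscal)
  cc <- 2 * cfg$Fc * cfg$totalscal
  scales <- cc / k
  freqs <- cfg$Fc * cfg$fs / scales
  list(scales = scales, freqs = freqs, c = cc)
}

# Morlet wavelet spectrum at scale a, evaluated on the two-sided digital
# frequency grid of an N-point FFT: conj(Psi(a * omega)) with
# Psi(w) = exp(-bandwidth * (w - 2*pi*Fc)^2 / 4) (analytic; ~0 for w < 0).
morlet_kernel <- function(N, a, Fc, bandwidth) {
  j <- 0:(N - 1)
  nu <- ifelse(j < N / 2, j, j - N) / N        # cycles/sample, signed
  w <- 2 * pi * a * nu
  exp(-bandwidth * (w - 2 * pi * Fc)^2 / 4)
}

#' Continuous wavelet transform power of a single time series
#'
#' Computes `|WT|^2` on the scale series of `cfg`, restricted to frequencies
#' within `[fmin, fmax]`. The input is reflection-padded by `pad_ms` per
#' side before the transform and trimmed afterwards to suppress edge
#' artefacts. The transform is evaluated per scale in the frequency domain
#' with the `|a|^(-1/2)` normalisation of the continuous transform.
#'
#' @param x numeric vector (one channel's epoch, microvolts).
#' @param cfg a [cwt_config()].
#' @param times_ms optional time axis for the output (defaults to sample
#'   index in ms from 0).
#' @return A `verge_tfmap`: list with `power` (freq x time, microvolt^2),
#'   `freqs` (Hz), `times` (ms).
#' @export
cwt_power <- function(x, cfg, times_ms = NULL) {
  stopifnot(inherits(cfg, "cwt_config"))
  n <- length(x)
  pad_n <- as.integer(round(cfg$pad_ms / 1000 * cfg$fs))
  if (n < 2 * max(1L, pad_n) && n < 4) stop("signal too short for the transform")
  if (pad_n > 0) {
    if (n < pad_n + 1) stop("signal too short for ", cfg$pad_ms, " ms padding")
    left <- x[(pad_n + 1):2]
    right <- x[(n - 1):(n - pad_n)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  N <- length(xp)
  ss <- build_scale_series(cfg)
  keep <- ss$freqs >= cfg$fmin & ss$freqs <= cfg$fmax
  scales <- ss$scales[keep]
  freqs <- ss$freqs[keep]
  X <- fft(xp)
  power <- matrix(0, length(scales), n)
  dt <- 1 / cfg$fs
  for (i in seq_along(scales)) {
    K <- morlet_kernel(N, scales[i], cfg$Fc, cfg$bandwidth)
    wt <- fft(X * K, inverse = TRUE) / N * sqrt(scales[i]) * dt
    power[i, ] <- Mod(wt[(pad_n + 1):(pad_n + n)])^2
  }
  if (is.null(times_ms)) times_ms <- (seq_len(n) - 1) * 1000 / cfg$fs
  structure(list(power = power, freqs = freqs, times = times_ms),
            class = "verge_tfmap")
}

#' @export
print.verge_tfmap <- function(x, ...) {
  cat("<verge_tfmap> ", length(x$freqs), " freqs [",
      round(min(x$freqs), 2), ", ", round(max(x$freqs), 2), "] Hz x ",
      length(x$times), " times [", round(min(x$times)), ", ",
      round(max(x$times)), "] ms\n", sep = "")
  invisible(x)
}

#' @export
plot.verge_tfmap <- function(x, main = "wavelet power", ...) {
  graphics::image(x$times, x$freqs, t(x$power), xlab = "time (ms)",
                  ylab = "frequency (Hz)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Mean power in a band x time-window cell
#'
#' @param tf a `verge_tfmap`.
#' @param band `c(lo, hi)` in Hz.
#' @param window `c(start, end)` in ms; defaults to the full time axis.
#' @return Scalar mean power (microvolt^2).
#' @export
band_power <- function(tf, band, window = range(tf$times)) {
  fi <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  ti <- which(tf$times >= window[1] & tf$times <= window[2])
  if (length(fi) == 0) stop("band [", band[1], ", ", band[2],
                            "] Hz does not intersect the frequency axis")
  if (length(ti) == 0) stop("window does not intersect the time axis")
  mean(tf$power[fi, ti])
}

#' Relative band power over time
#'
#' At each time point, power in `band` divided by total power over the full
#' retained frequency axis. Time points with zero total power are returned
#' as `NA` with a warning rather than silently zero.
#'
#' @param tf a `verge_tfmap`.
#' @param band `c(lo, hi)` in Hz.
#' @return Numeric vector in `[0, 1]` (or `NA`), one value per time point.
#' @export
power_ratio_series <- function(tf, band) {
  fi <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  if (length(fi) == 0) stop("band does not intersect the frequency axis")
  tot <- colSums(tf$power)
  num <- colSums(tf$power[fi, , drop = FALSE])
  out <- num / tot
  if (any(tot == 0)) {
    warning("zero total power at ", sum(tot == 0), " time point(s); ratio undefined")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Average time-frequency maps over a region of interest
#'
#' @param tfs named list of `verge_tfmap` objects (names are channel labels).
#' @param roi channel labels to average.
#' @return A `verge_tfmap` with the pointwise mean power.
#' @export
roi_average <- function(tfs, roi) {
  missing_ch <- setdiff(roi, names(tfs))
  if (length(missing_ch) > 0) {
    stop("ROI channels not present: ", paste(missing_ch, collapse = ", "))
  }
  sel <- tfs[roi]
  p <- sel[[1]]$power
  if (length(sel) > 1) {
    for (i in 2:length(sel)) p <- p + sel[[i]]$power
  }
  structure(list(power = p / length(sel), freqs = sel[[1]]$freqs,
                 times = sel[[1]]$times), class = "verge_tfmap")
}

# Block-mean decimation of the time axis by an integer factor.
decimate_time <- function(tf, factor) {
  if (factor <= 1) return(tf)
  n <- length(tf$times)
  n_out <- n %/% factor
  idx <- rep(seq_len(n_out), each = factor)
  p <- tf$power[, seq_len(n_out * factor), drop = FALSE]
  pw <- t(apply(p, 1, function(row) tapply(row, idx, mean)))
  tm <- as.vector(tapply(tf$times[seq_len(n_out * factor)], idx, mean))
  structure(list(power = pw, freqs = tf$freqs, times = tm),
            class = "verge_tfmap")
}

#' Per-subject ROI-averaged time-frequency stack for one condition
#'
#' For every subject: wavelet power per ROI channel and trial, averaged over
#' trials and ROI channels (pointwise), optionally decimated in time and
#' converted to relative power. The result feeds the cluster permutation
#' test and feature extraction.
#'
#' @param epochs a `verge_epochs` from [epoch_cohort()].
#' @param roi electrode labels to average over.
#' @param cfg a [cwt_config()].
#' @param time_decim integer block-mean decimation factor for the time axis.
#' @param measure `"power"` (absolute, microvolt^2) or `"ratio"` (relative
#'   power per time point).
#' @return A `verge_tfstack`: list with `data` (subject x freq x time
#'   array), `freqs`, `times`, `groups`, `subject_ids`, `roi`, `measure`.
#' @export
cohort_tf_stack <- function(epochs, roi, cfg, time_decim = 1,
                            measure = c("power", "ratio")) {
  stopifnot(inherits(epochs, "verge_epochs"))
  measure <- match.arg(measure)
  missing_ch <- setdiff(roi, epochs$channels)
  if (length(missing_ch) > 0) {
    stop("ROI channels not in epoch set: ", paste(missing_ch, collapse = ", "))
  }
  d <- dim(epochs$tensor)
  ch_idx <- match(roi, epochs$channels)
  t_axis <- epochs$window_ms[1] + (seq_len(d[4]) - 1) * 1000 / epochs$fs
  maps <- vector("list", d[1])
  for (si in seq_len(d[1])) {
    acc <- NULL
    for (tr in seq_len(d[2])) {
      for (ch in ch_idx) {
        tf <- cwt_power(epochs$tensor[si, tr, ch, ], cfg, times_ms = t_axis)
        acc <- if (is.null(acc)) tf$power else acc + tf$power
      }
    }
    tf$power <- acc / (d[2] * length(ch_idx))
    tf <- decimate_time(tf, time_decim)
    if (measure == "ratio") {
      tot <- colSums(tf$power)
      tf$power <- sweep(tf$power, 2, tot, "/")
    }
    maps[[si]] <- tf
  }
  arr <- array(0, c(d[1], length(maps[[1]]$freqs), length(maps[[1]]$times)))
  for (si in seq_len(d[1])) arr[si, , ] <- maps[[si]]$power
  structure(list(data = arr, freqs = maps[[1]]$freqs,
                 times = maps[[1]]$times, groups = epochs$groups,
                 subject_ids = epochs$subject_ids, roi = roi,
                 condition = epochs$condition, measure = measure),
            class = "verge_tfstack")
}
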
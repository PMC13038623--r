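# Synthetic two-group vergence-EEG cohort generator. Background activity is
# 1/f^beta Gaussian noise synthesised in the frequency domain; group effects
# are injected by multiplicatively scaling the band-limited component of the
# background inside a cosine-tapered time window, so that mean band power in
# the (ROI, band, window) cell is scaled by a known factor.

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic cohort configuration
#'
#' @param n_per_group subjects per group (controls and patients).
#' @param fs sampling rate, Hz.
#' @param montage_name montage identifier (see [montage_1020_32()]).
#' @param trials_per_condition vergence repetitions per subject per condition.
#' @param epoch_len_ms analysis epoch length, ms.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param noise_rms background RMS amplitude per channel, microvolts.
#' @param amp_jitter_sd per-subject log-normal amplitude jitter of injected
#'   effects (SD in log units).
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_group = 15, fs = 500,
                         montage_name = "std-10-20-32",
                         trials_per_condition = 1, epoch_len_ms = 1000,
                         noise_exponent = 1.0, noise_rms = 10,
                         amp_jitter_sd = 0.2, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (epoch_len_ms <= 0) stop("epoch_len_ms must be positive")
  if (fs <= 2 * 31.25) stop("fs must exceed twice the highest analysed frequency")
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1")
  structure(list(
    n_per_group = as.integer(n_per_group), fs = fs,
    montage_name = montage_name,
    trials_per_condition = as.integer(trials_per_condition),
    epoch_len_ms = epoch_len_ms, noise_exponent = noise_exponent,
    noise_rms = noise_rms, amp_jitter_sd = amp_jitter_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Specify an injectable group power effect
#'
#' Describes one band/ROI/time-window power effect: for subjects of `group`,
#' in condition `condition`, the mean band power of the `band` component over
#' the `roi` electrodes inside `window_ms` (relative to the condition's lock
#' event) is scaled by `multiplier` relative to the no-effect background.
#'
#' @param group `"control"` or `"nsbvd"`.
#' @param condition one of `conv_start`, `bo_break`, `div_start`, `bi_break`.
#' @param roi character vector of electrode labels.
#' @param band `c(lo, hi)` in Hz, inside \[0.5, 31.25\].
#' @param window_ms `c(start, end)` in ms relative to the lock event, inside
#'   the condition's epoch window.
#' @param multiplier power scaling factor, >= 1.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(group, condition, roi, band, window_ms, multiplier) {
  group <- match.arg(group, c("control", "nsbvd"))
  condition <- match.arg(condition, condition_names())
  desc <- paste0(group, "/", condition, "/", paste(roi, collapse = "+"),
                 " ", band[1], "-", band[2], " Hz")
  if (band[1] < 0.5 || band[2] > 31.25 || band[1] >= band[2]) {
    stop("invalid band for effect ", desc, ": must lie within [0.5, 31.25] Hz")
  }
  win <- condition_windows()[[condition]]
  if (window_ms[1] < win[1] || window_ms[2] > win[2] || window_ms[1] >= window_ms[2]) {
    stop("invalid window for effect ", desc, ": must lie within [",
         win[1], ", ", win[2], "] ms")
  }
  if (multiplier < 1) {
    stop("multiplier must be >= 1 for effect ", desc,
         " (power suppression is not modelled)")
  }
  structure(list(group = group, condition = condition, roi = roi,
                 band = as.numeric(band), window_ms = as.numeric(window_ms),
                 multiplier = multiplier),
            class = "effect_spec")
}

# 1/f^beta spectral weights on the rfft bin grid of an n-sample record.
# Frequencies below f_floor carry no power (EEG acquisition is AC-coupled).
pink_weights <- function(n, fs, beta, f_floor = 0.3) {
  f <- (seq_len(n %/% 2 - 1)) * fs / n   # bins 2 .. n/2 (exclusive of DC/Nyquist)
  w <- ifelse(f >= f_floor, f^(-beta), 0)
  w
}

# Gaussian background noise, channels in columns: n x n_ch matrix with
# E[var] = rms^2 per channel and power spectrum ~ 1/f^beta.
synth_background <- function(n, n_ch, fs, beta, rms, f_floor = 0.3) {
  w <- pink_weights(n, fs, beta, f_floor)
  k <- rms^2 * n^2 / (2 * sum(w))
  s <- k * w
  nb <- length(w)
  Z <- matrix(complex(real = rnorm(nb * n_ch), imaginary = rnorm(nb * n_ch)),
              nb, n_ch) * sqrt(s / 2)
  spec <- matrix(0 + 0i, n, n_ch)
  spec[2:(nb + 1), ] <- Z
  spec[n:(n - nb + 1), ] <- Conj(Z)
  Re(mvfft(spec, inverse = TRUE)) / n
}

# Expected background variance within a frequency band, as a fraction of rms^2.
band_var_fraction <- function(n, fs, beta, band, f_floor = 0.3) {
  w <- pink_weights(n, fs, beta, f_floor)
  f <- (seq_len(n %/% 2 - 1)) * fs / n
  sum(w[f >= band[1] & f <= band[2]]) / sum(w)
}

# Cosine-ramp taper: 1 inside [a, b] with half-cosine ramps of ramp_n samples
# just inside the edges, 0 outside. Returned over 1..n.
cosine_taper <- function(n, a, b, ramp_n) {
  w <- numeric(n)
  idx <- a:b
  w[idx] <- 1
  ramp_n <- min(ramp_n, floor(length(idx) / 2))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / (ramp_n + 1)))
    w[a + seq_len(ramp_n) - 1] <- ramp
    w[b - seq_len(ramp_n) + 1] <- ramp
  }
  w
}

# Expected in-window band power (rectangular-window periodogram, band-bin
# mean) of y = x + (gamma - 1) * diag(w) * B x relative to x, where x is
# stationary background with 1/f^beta spectrum, B the band projection and w
# the taper profile over the window. The expectation is quadratic in
# (gamma - 1): ratio(gamma) = 1 + (gamma-1) T1/T0 + (gamma-1)^2 T2/T0, with
# the T sums evaluated from the circulant covariance. Solving
# ratio(gamma) = multiplier yields the gain that delivers the requested
# measured power scaling despite spectral smearing of the short window.
effect_gain <- function(multiplier, n_seg, fs, band, win_idx, taper_win,
                        beta, f_floor = 0.3) {
  if (multiplier == 1) return(1)
  m <- length(win_idx)
  # segment-grid spectral weights and band mask
  f_seg <- (0:(n_seg - 1)) * fs / n_seg
  f_seg <- pmin(f_seg, fs - f_seg)
  s <- ifelse(f_seg >= f_floor, pmax(f_seg, f_floor)^(-beta), 0)
  s[1] <- 0
  bmask <- as.numeric(f_seg >= band[1] & f_seg <= band[2])
  c_s <- Re(fft(s, inverse = TRUE)) / n_seg
  c_sb <- Re(fft(s * bmask, inverse = TRUE)) / n_seg
  # window-grid band mask -> periodogram kernel q(delta)
  f_win <- (0:(m - 1)) * fs / m
  f_win <- pmin(f_win, fs - f_win)
  wmask <- as.numeric(f_win >= band[1] & f_win <= band[2])
  q <- Re(fft(wmask, inverse = TRUE)) / m^2
  d <- outer(seq_len(m), seq_len(m), "-")
  Qm <- matrix(q[(d %% m) + 1], m, m)
  Cs <- matrix(c_s[(d %% n_seg) + 1], m, m)
  Csb <- matrix(c_sb[(d %% n_seg) + 1], m, m)
  Wi <- matrix(taper_win, m, m)
  T0 <- sum(Qm * Cs)
  T1 <- sum(Qm * (Wi + t(Wi)) * Csb)
  T2 <- sum(Qm * Wi * t(Wi) * Csb)
  disc <- T1^2 + 4 * T2 * (multiplier - 1) * T0
  1 + (-T1 + sqrt(disc)) / (2 * T2)
}

# Scale the band-limited component of segment x (vector) by gain g(t).
scale_band_component <- function(x, fs, band, gain) {
  n <- length(x)
  spec <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # fold to two-sided frequency magnitude
  in_band <- f >= band[1] & f <= band[2]
  spec_band <- spec
  spec_band[!in_band] <- 0
  xb <- Re(fft(spec_band, inverse = TRUE)) / n
  x + (gain - 1) * xb
}

#' Generate a synthetic two-group vergence-EEG cohort
#'
#' Each subject receives one continuous 32-channel recording containing
#' `trials_per_condition` annotated trials per requested condition. Trials
#' occupy consecutive 2-second blocks; the lock event (`conv_start`,
#' `bo_break`, `div_start` or `bi_break`) is annotated 0.5 s into the block
#' for start conditions and 1.5 s in for break conditions, so that the
#' analysis epoch plus wavelet padding fits inside the block. The background
#' is independent 1/f^beta Gaussian noise per channel; each [effect_spec()]
#' multiplicatively scales the band-limited background component inside its
#' time window (50 ms cosine ramps) on the ROI electrodes of the target
#' group, with per-subject log-normal amplitude jitter.
#'
#' @param config a [synth_config()].
#' @param effects list of [effect_spec()] objects (possibly empty).
#' @param conditions conditions to simulate (default all four).
#' @return A `verge_cohort`: list with `subjects` (list of
#'   [verge_recording()]), `subject_ids`, `groups`, `config` and `truth`
#'   (the ground-truth manifest: injected effects, per-subject amplitude
#'   draws, seed).
#' @export
generate_cohort <- function(config, effects = list(),
                            conditions = condition_names()) {
  stopifnot(inherits(config, "synth_config"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
    if (!e$condition %in% conditions) {
      stop("effect targets condition '", e$condition,
           "' which is not being simulated")
    }
  }
  conditions <- match.arg(conditions, condition_names(), several.ok = TRUE)
  fs <- config$fs
  montage <- montage_1020_32(config$montage_name)
  for (e in effects) {
    missing_ch <- setdiff(e$roi, montage$label)
    if (length(missing_ch) > 0) {
      stop("effect ROI channels not in montage: ", paste(missing_ch, collapse = ", "))
    }
  }
  n_ch <- nrow(montage)
  seg_s <- 2                                  # seconds per trial block
  seg_n <- as.integer(seg_s * fs)
  n_seg <- length(conditions) * config$trials_per_condition
  total_n <- n_seg * seg_n
  n_sub <- 2L * config$n_per_group
  groups <- rep(c("control", "nsbvd"), each = config$n_per_group)
  subject_ids <- sprintf("sub-%02d", seq_len(n_sub))
  ramp_n <- as.integer(round(0.05 * fs))      # 50 ms ramps

  # trial layout: condition-major, trials within condition
  layout <- expand.grid(trial = seq_len(config$trials_per_condition),
                        condition = conditions, stringsAsFactors = FALSE)
  layout$segment <- seq_len(nrow(layout))
  layout$offset <- (layout$segment - 1L) * seg_n
  is_break <- grepl("break", layout$condition)
  layout$event_sample <- layout$offset + ifelse(is_break, 1.5, 0.5) * fs + 1L

  # per-effect segment-relative geometry and calibrated gain
  eff_geom <- lapply(effects, function(e) {
    is_brk <- grepl("break", e$condition)
    ev_rel <- as.integer((if (is_brk) 1.5 else 0.5) * fs) + 1L
    w_a <- ev_rel + as.integer(round(e$window_ms[1] / 1000 * fs))
    w_b <- ev_rel + as.integer(round(e$window_ms[2] / 1000 * fs)) - 1L
    taper_seg <- cosine_taper(seg_n, w_a, w_b, ramp_n)
    gamma <- effect_gain(e$multiplier, seg_n, fs, e$band, w_a:w_b,
                         taper_seg[w_a:w_b], config$noise_exponent)
    list(taper_seg = taper_seg, gamma = gamma)
  })

  draws <- if (length(effects) > 0) {
    m <- matrix(NA_real_, n_sub, length(effects),
                dimnames = list(subject_ids, NULL))
    m
  } else {
    matrix(numeric(0), n_sub, 0, dimnames = list(subject_ids, NULL))
  }

  subjects <- run_with_seed(config$seed, {
    lapply(seq_len(n_sub), function(si) {
      x <- synth_background(total_n, n_ch, fs, config$noise_exponent,
                            config$noise_rms)
      for (ei in seq_along(effects)) {
        e <- effects[[ei]]
        a <- exp(rnorm(1, -config$amp_jitter_sd^2 / 2, config$amp_jitter_sd))
        draws[si, ei] <<- a
        if (groups[si] != e$group) next
        rows <- which(layout$condition == e$condition)
        ch_idx <- match(e$roi, montage$label)
        gain <- 1 + (eff_geom[[ei]]$gamma - 1) * a * eff_geom[[ei]]$taper_seg
        for (r in rows) {
          seg_idx <- (layout$offset[r] + 1L):(layout$offset[r] + seg_n)
          for (ch in ch_idx) {
            x[seg_idx, ch] <- scale_band_component(x[seg_idx, ch], fs,
                                                   e$band, gain)
          }
        }
      }
      events <- data.frame(sample = as.integer(layout$event_sample),
                           label = layout$condition, stringsAsFactors = FALSE)
      verge_recording(t(x), fs, montage$label, montage = montage,
                      events = events)
    })
  })

  truth <- list(
    effects = lapply(effects, unclass),
    amplitude_draws = draws,
    seed = config$seed,
    conditions = conditions,
    groups = groups,
    subject_ids = subject_ids
  )
  structure(list(subjects = subjects, subject_ids = subject_ids,
                 groups = groups, config = config, truth = truth),
            class = "verge_cohort")
}

#' @export
print.verge_cohort <- function(x, ...) {
  cat("<verge_cohort> ", length(x$subjects), " subjects (",
      sum(x$groups == "control"), " control / ", sum(x$groups == "nsbvd"),
      " nsbvd), ", length(x$truth$conditions), " conditions, ",
      length(x$truth$effects), " injected effects, seed ", x$truth$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as EDF+ files plus manifest and index
#'
#' @param cohort a `verge_cohort` from [generate_cohort()].
#' @param directory output directory (created if needed).
#' @return Invisibly, a character vector of all files written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "verge_cohort"))
  if (length(cohort$subjects) == 0) stop("empty cohort: nothing to write")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }
  paths <- character(0)
  for (i in seq_along(cohort$subjects)) {
    p <- file.path(directory, paste0(cohort$subject_ids[i], ".edf"))
    write_edf(cohort$subjects[[i]], p)
    paths <- c(paths, p)
  }
  manifest <- file.path(directory, "ground_truth.json")
  truth <- cohort$truth
  truth$amplitude_draws <- as.data.frame(truth$amplitude_draws)
  jsonlite::write_json(truth, manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  index <- data.frame(subject_id = cohort$subject_ids,
                      group = cohort$groups,
                      file = paste0(cohort$subject_ids, ".edf"),
                      stringsAsFactors = FALSE)
  index_path <- file.path(directory, "cohort_index.csv")
  write.csv(index, index_path, row.names = FALSE)
  invisible(c(paths, manifest, index_path))
}

#' Read back a ground-truth manifest
#'
#' @param path path to a `ground_truth.json` written by [write_cohort()].
#' @return The manifest as a list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load a cohort from a directory written by write_cohort
#'
#' Reads the cohort index, every subject's EDF+ file and, when present, the
#' ground-truth manifest.
#'
#' @param directory cohort directory.
#' @param montage montage attached to each recording (default the shipped
#'   32-channel cap).
#' @return A `verge_cohort` (with `config = NULL`; `truth` is `NULL` when
#'   no manifest is found).
#' @export
read_cohort <- function(directory, montage = montage_1020_32()) {
  index_path <- file.path(directory, "cohort_index.csv")
  if (!file.exists(index_path)) {
    stop("no cohort_index.csv in '", directory, "'")
  }
  index <- read.csv(index_path, stringsAsFactors = FALSE)
  subjects <- lapply(file.path(directory, index$file), read_edf,
                     montage = montage)
  truth_path <- file.path(directory, "ground_truth.json")
  truth <- if (file.exists(truth_path)) read_ground_truth(truth_path) else NULL
  structure(list(subjects = subjects, subject_ids = index$subject_id,
                 groups = index$group, config = NULL, truth = truth),
            class = "verge_cohort")
}
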
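# Shared fixtures: everything is generated in code at test time.

# Small cohort for structural tests (2 + 2 subjects, one condition).
tiny_cohort <- function(seed = 42, conditions = "bo_break", effects = list(),
                        n_per_group = 2, trials = 1) {
  generate_cohort(
    synth_config(n_per_group = n_per_group, trials_per_condition = trials,
                 seed = seed),
    effects = effects, conditions = conditions
  )
}

# The canonical injected effect used throughout: frontal theta power
# elevated in patients before the convergence fusion break.
frontal_theta_effect <- function(multiplier = 3) {
  effect_spec("nsbvd", "bo_break", roi_channels("frontal"),
              band = c(4, 8), window_ms = c(-548, -302),
              multiplier = multiplier)
}

# Reduced-resolution wavelet configuration for grid-level tests:
# 20 frequency bins up to 31.25 Hz at fs 500.
reduced_cwt_config <- function() cwt_config(totalscal = 160, fs = 500)

# One-channel recording from a bare signal vector.
signal_recording <- function(x, fs = 500, label = "Cz") {
  verge_recording(matrix(x, 1), fs, label)
}

# Brute-force 4-connected component labelling (reference implementation,
# plain BFS over an R matrix).
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# Reference max-|cluster-mass| for one t-map (independent of the package
# implementation: plain loops + oracle_label).
oracle_max_mass <- function(tmap, t_crit) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > t_crit
    if (!any(mask)) next
    lab <- oracle_label(mask)
    for (k in seq_len(max(lab))) {
      best <- max(best, abs(sum(tmap[lab == k])))
    }
  }
  best
}

# In-window variance of the band-limited component (reference measurement
# at the full segment's frequency resolution; stabler than a short-window
# periodogram for ordering comparisons).
oracle_band_variance <- function(x, fs, band, idx) {
  n <- length(x)
  s <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  s[!(f >= band[1] & f <= band[2])] <- 0
  xb <- Re(stats::fft(s, inverse = TRUE)) / n
  mean(xb[idx]^2)
}

# Plain-periodogram band power of a signal window (reference measurement;
# fast = FALSE keeps the DFT on the window's own bin grid).
oracle_band_power <- function(x, fs, band) {
  p <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                         taper = 0, detrend = FALSE, fast = FALSE)
  mean(p$spec[p$freq >= band[1] & p$freq <= band[2]])
}
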
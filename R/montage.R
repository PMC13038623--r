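#' Standard 32-channel 10-20 montage on the unit sphere
#'
#' Idealised spherical electrode positions for a 32-channel cap laid out
#' according to the international 10-20/10-10 system. Positions are given as
#' unit-sphere xyz coordinates with `+x` toward the right preauricular point,
#' `+y` toward the nasion and `+z` through the vertex, so `Cz = (0, 0, 1)`
#' exactly. The layout follows the conventional spherical (inclination,
#' azimuth) table used by forward-modelling software; electrodes on the
#' 10-20 head circumference sit at 92 degrees inclination and the inferior
#' temporal pair (FT9/FT10, TP9/TP10) at 113 degrees.
#'
#' @param name montage identifier; only `"std-10-20-32"` is shipped.
#' @return A data frame with columns `label`, `x`, `y`, `z` (32 rows).
#' @examples
#' m <- montage_1020_32()
#' stopifnot(nrow(m) == 32, all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-12))
#' @export
montage_1020_32 <- function(name = "std-10-20-32") {
  if (!identical(name, "std-10-20-32")) {
    stop("unknown montage: ", name)
  }
  # (label, signed inclination theta [deg, + = right hemisphere], phi [deg])
  tab <- matrix(c(
    "Fp1",  -92, -72,   "Fp2",  92,  72,
    "F7",   -92, -36,   "F3",  -60, -51,
    "Fz",    46,  90,   "F4",   60,  51,
    "F8",    92,  36,   "FT9", -113, -18,
    "FC5",  -72, -21,   "FC1", -32, -45,
    "FC2",   32,  45,   "FC6",  72,  21,
    "FT10", 113,  18,   "T7",  -92,   0,
    "C3",   -46,   0,   "Cz",    0,   0,
    "C4",    46,   0,   "T8",   92,   0,
    "TP9", -113,  18,   "CP5", -72,  21,
    "CP1",  -32,  45,   "CP2",  32, -45,
    "CP6",   72, -21,   "TP10", 113, -18,
    "P7",   -92,  36,   "P3",  -60,  51,
    "Pz",    46, -90,   "P4",   60, -51,
    "P8",    92, -36,   "O1",  -92,  72,
    "Oz",    92, -90,   "O2",   92, -72
  ), ncol = 3, byrow = TRUE)
  label <- tab[, 1]
  theta <- as.numeric(tab[, 2])
  phi   <- as.numeric(tab[, 3])
  incl <- abs(theta) * pi / 180
  # azimuth measured CCW from +x (right ear); left-hemisphere electrodes
  # mirror through 180 degrees
  az <- ifelse(theta >= 0, phi, 180 + phi) * pi / 180
  out <- data.frame(
    label = label,
    x = sin(incl) * cos(az),
    y = sin(incl) * sin(az),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
  # snap numerically-zero components (e.g. Cz) for exactness
  out$x[abs(out$x) < 1e-12] <- 0
  out$y[abs(out$y) < 1e-12] <- 0
  out
}

#' Analysis regions of interest
#'
#' Electrode sets used for regional statistics: the frontal ROI (F3, Fz, F4)
#' and the parieto-occipital ROI (P3, Pz, P4, O1, Oz, O2), the two regions
#' over which time-frequency group statistics are computed, plus the full
#' 12-electrode inspection set spanning frontal, central, parietal and
#' occipital rows.
#'
#' @param roi one of `"frontal"`, `"parieto_occipital"`, `"inspection12"`.
#' @return Character vector of electrode labels.
#' @export
roi_channels <- function(roi = c("frontal", "parieto_occipital", "inspection12")) {
  roi <- match.arg(roi)
  switch(roi,
    frontal = c("F3", "Fz", "F4"),
    parieto_occipital = c("P3", "Pz", "P4", "O1", "Oz", "O2"),
    inspection12 = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                     "P3", "Pz", "P4", "O1", "Oz", "O2")
  )
}

#' Canonical EEG frequency bands
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}
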
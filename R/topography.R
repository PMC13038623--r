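# Group-level waveforms with SEM bands, and spherical-spline scalp maps on
# an azimuthal-equidistant 2D projection of the electrode sphere.

#' Grand-average waveforms with SEM bands
#'
#' Trial means are computed per subject first; the group mean and standard
#' error of the mean (subject SD / sqrt(n)) are then taken over subjects.
#'
#' @param epochs a `verge_epochs` (subject x trial x channel x time).
#' @param subjects optional subset of subject indices (e.g. one group).
#' @return A `verge_grand_average`: `mean` and `sem` matrices (channel x
#'   time, microvolts), `n_subjects`, `condition`, `channels`, `times`.
#' @export
grand_average <- function(epochs, subjects = seq_len(dim(epochs$tensor)[1])) {
  stopifnot(inherits(epochs, "verge_epochs"))
  d <- dim(epochs$tensor)
  n <- length(subjects)
  if (n < 2) stop("grand average needs at least 2 subjects (SEM undefined)")
  # subject-level trial means: subject x channel x time
  sub_means <- array(0, c(n, d[3], d[4]))
  for (i in seq_along(subjects)) {
    sub_means[i, , ] <- apply(epochs$tensor[subjects[i], , , , drop = FALSE],
                              c(3, 4), mean)
  }
  mu <- apply(sub_means, c(2, 3), mean)
  sem <- apply(sub_means, c(2, 3), sd) / sqrt(n)
  rownames(mu) <- rownames(sem) <- epochs$channels
  times <- epochs$window_ms[1] + (seq_len(d[4]) - 1) * 1000 / epochs$fs
  structure(list(mean = mu, sem = sem, n_subjects = n,
                 condition = epochs$condition, channels = epochs$channels,
                 times = times),
            class = "verge_grand_average")
}

#' @export
plot.verge_grand_average <- function(x, channel = x$channels[1], ...) {
  i <- match(channel, x$channels)
  if (is.na(i)) stop("unknown channel: ", channel)
  m <- x$mean[i, ]; s <- x$sem[i, ]
  graphics::plot(x$times, m, type = "n", xlab = "time (ms)",
                 ylab = expression(paste("amplitude (", mu, "V)")),
                 main = paste0(channel, " - ", x$condition),
                 ylim = range(m + s, m - s), ...)
  graphics::polygon(c(x$times, rev(x$times)), c(m + s, rev(m - s)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$times, m, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Per-channel mean potential over a time window
#'
#' Averages over subjects, trials and the requested window, yielding one
#' value per channel - suitable input to [topomap()].
#'
#' @param epochs a `verge_epochs`.
#' @param window_ms `c(start, end)` in ms, inside the epoch window.
#' @param subjects optional subject-index subset.
#' @return Named numeric vector, microvolts per channel.
#' @export
window_mean_map <- function(epochs, window_ms = epochs$window_ms,
                            subjects = seq_len(dim(epochs$tensor)[1])) {
  stopifnot(inherits(epochs, "verge_epochs"))
  d <- dim(epochs$tensor)
  times <- epochs$window_ms[1] + (seq_len(d[4]) - 1) * 1000 / epochs$fs
  ti <- which(times >= window_ms[1] & times < window_ms[2])
  if (length(ti) == 0) stop("empty time window [", window_ms[1], ", ",
                            window_ms[2], "] ms")
  v <- apply(epochs$tensor[subjects, , , ti, drop = FALSE], 3, mean)
  names(v) <- epochs$channels
  v
}

# Azimuthal-equidistant projection from the vertex: radius proportional to
# inclination (pi/2 -> unit head circle), direction preserved.
project_azimuthal <- function(pos) {
  incl <- acos(pmin(1, pmax(-1, pos[, 3])))
  r2 <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  ux <- ifelse(r2 > 0, pos[, 1] / r2, 0)
  uy <- ifelse(r2 > 0, pos[, 2] / r2, 0)
  r <- incl / (pi / 2)
  cbind(x = r * ux, y = r * uy)
}

# Inverse projection: 2D lattice point -> unit-sphere position.
unproject_azimuthal <- function(xy) {
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  incl <- r * pi / 2
  ux <- ifelse(r > 0, xy[, 1] / r, 0)
  uy <- ifelse(r > 0, xy[, 2] / r, 0)
  cbind(sin(incl) * ux, sin(incl) * uy, cos(incl))
}

#' Spherical-spline scalp map
#'
#' Fits a Perrin-type spherical spline (order `m = 4`) to the electrode
#' values and evaluates it on an azimuthal-equidistant lattice centred on
#' the vertex (Cz projects to the origin), masked outside the unit head
#' circle.
#'
#' @param values named numeric vector (microvolts), names are electrode
#'   labels present in the montage.
#' @param montage montage data frame (default the shipped 32-channel cap).
#' @param grid_res lattice resolution per axis.
#' @param lambda spline regularisation; `0` reproduces the electrode values
#'   exactly, small positive values denoise.
#' @return A `verge_scalpmap`: `grid` (grid_res x grid_res matrix, `NA`
#'   outside the head circle), `gx`/`gy` lattice axes, `electrodes`
#'   (projected 2D positions and values).
#' @export
topomap <- function(values, montage = montage_1020_32(), grid_res = 67,
                    lambda = 0) {
  labs <- names(values)
  if (is.null(labs)) stop("values must be a named vector of electrode potentials")
  idx <- match(labs, montage$label)
  if (anyNA(idx)) stop("electrodes not in montage: ",
                       paste(labs[is.na(idx)], collapse = ", "))
  if (length(labs) < 4) stop("need at least 4 electrodes")
  pos <- as.matrix(montage[idx, c("x", "y", "z")])
  fit <- spherical_spline_fit(pos, matrix(values, ncol = 1), m = 4,
                              lambda = lambda)
  gx <- seq(-1, 1, length.out = grid_res)
  lattice <- expand.grid(x = gx, y = gx)
  r <- sqrt(lattice$x^2 + lattice$y^2)
  inside <- r <= 1
  vals <- rep(NA_real_, nrow(lattice))
  pts <- unproject_azimuthal(as.matrix(lattice[inside, ]))
  vals[inside] <- fit(pts)[, 1]
  grid <- matrix(vals, grid_res, grid_res)
  proj <- project_azimuthal(pos)
  structure(list(grid = grid, gx = gx, gy = gx,
                 electrodes = data.frame(label = labs, x = proj[, 1],
                                         y = proj[, 2], value = unname(values)),
                 m = 4, lambda = lambda),
            class = "verge_scalpmap")
}

#' @export
plot.verge_scalpmap <- function(x, main = "scalp map", zlim = NULL, ...) {
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(x$grid), na.rm = TRUE)
  graphics::image(x$gx, x$gy, x$grid, asp = 1, xlab = "", ylab = "",
                  axes = FALSE, main = main, zlim = zlim,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  theta <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(theta), sin(theta))
  graphics::points(x$electrodes$x, x$electrodes$y, pch = 20, cex = 0.6)
  invisible(x)
}

#' Evaluate a fitted scalp interpolant at electrode positions
#'
#' Convenience wrapper for leave-one-electrode-out checks: fit the spline to
#' a subset of electrodes and predict the potential at others.
#'
#' @param values named numeric vector at the fitting electrodes.
#' @param at character vector of target electrode labels.
#' @param montage montage data frame.
#' @param lambda spline regularisation.
#' @return Named numeric vector of interpolated values at `at`.
#' @export
interpolate_at <- function(values, at, montage = montage_1020_32(), lambda = 0) {
  idx <- match(names(values), montage$label)
  if (anyNA(idx)) stop("unknown electrodes in values")
  tgt <- match(at, montage$label)
  if (anyNA(tgt)) stop("unknown target electrodes: ",
                       paste(at[is.na(tgt)], collapse = ", "))
  pos <- as.matrix(montage[idx, c("x", "y", "z")])
  fit <- spherical_spline_fit(pos, matrix(values, ncol = 1), m = 4,
                              lambda = lambda)
  out <- fit(as.matrix(montage[tgt, c("x", "y", "z")]))[, 1]
  names(out) <- at
  out
}
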
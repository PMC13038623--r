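# Cluster-mass permutation inference on time-frequency grids: pointwise t
# statistics, sign-separated 4-connected clusters, cluster mass M_C = sum of
# member t values, and a Monte-Carlo maximum-|mass| null distribution from
# group-label shuffles (between design) or condition sign flips (within).

#' Permutation test configuration
#'
#' @param n_perm number of label shuffles for the Monte-Carlo null
#'   (default 5000, minimum 100).
#' @param alpha_point two-tailed pointwise threshold used to form clusters.
#' @param alpha_cluster two-tailed cluster significance level.
#' @param seed RNG seed for the shuffles.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_perm = 5000, alpha_point = 0.05,
                        alpha_cluster = 0.05, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!(alpha_point > 0 && alpha_point < 1)) stop("alpha_point must be in (0, 1)")
  if (!(alpha_cluster > 0 && alpha_cluster < 1)) stop("alpha_cluster must be in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), alpha_point = alpha_point,
                 alpha_cluster = alpha_cluster, seed = as.integer(seed)),
            class = "perm_config")
}

# Pooled-variance two-sample t per column of X (subjects x points).
tstat_between <- function(X, inA, welch = FALSE) {
  XA <- X[inA, , drop = FALSE]
  XB <- X[!inA, , drop = FALSE]
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- (colSums(XA^2) - nA * mA^2) / (nA - 1)
  vB <- (colSums(XB^2) - nB * mB^2) / (nB - 1)
  if (welch) {
    se <- sqrt(vA / nA + vB / nB)
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  }
  (mA - mB) / se
}

tstat_paired <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

flatten_stack <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, d[1], d[2] * d[3])
}

#' Pointwise t-statistic map between two subject stacks
#'
#' Between design: pooled-variance two-sample t per grid point with
#' `df = nA + nB - 2` (Welch available via `welch = TRUE`). Within design:
#' paired t per grid point, `df = n - 1`.
#'
#' @param groupA,groupB subject x frequency x time arrays (or subject x
#'   point matrices) on identical grids.
#' @param design `"between"` or `"within"`.
#' @param freqs,times grid axes (Hz, ms), used for cluster extents.
#' @param welch use Welch (unpooled) t for the between design.
#' @return A `verge_tfgrid`: `tmap` (freq x time), `df`, `design`, axes.
#' @export
pointwise_t <- function(groupA, groupB, design = c("between", "within"),
                        freqs = NULL, times = NULL, welch = FALSE) {
  design <- match.arg(design)
  dA <- dim(groupA); dB <- dim(groupB)
  if (!all(dA[-1] == dB[-1])) stop("mismatched grids between groups")
  if (length(dA) == 3) {
    if (is.null(freqs)) freqs <- seq_len(dA[2])
    if (is.null(times)) times <- seq_len(dA[3])
    grid_dim <- dA[2:3]
  } else {
    if (is.null(freqs)) freqs <- seq_len(dA[2])
    if (is.null(times)) times <- 1
    grid_dim <- c(dA[2], 1L)
  }
  XA <- flatten_stack(groupA); XB <- flatten_stack(groupB)
  if (design == "between") {
    if (nrow(XA) < 2 || nrow(XB) < 2) stop("need >= 2 subjects per group")
    tv <- tstat_between(rbind(XA, XB),
                        c(rep(TRUE, nrow(XA)), rep(FALSE, nrow(XB))),
                        welch = welch)
    df <- nrow(XA) + nrow(XB) - 2
  } else {
    if (nrow(XA) != nrow(XB)) stop("within design requires paired subjects")
    if (nrow(XA) < 2) stop("need >= 2 paired subjects")
    tv <- tstat_paired(XA - XB)
    df <- nrow(XA) - 1
  }
  structure(list(tmap = matrix(tv, grid_dim[1], grid_dim[2]), df = df,
                 design = design, freqs = freqs, times = times),
            class = "verge_tfgrid")
}

# masses of sign-separated 4-connected suprathreshold components;
# returns list(clusters) given a t matrix and critical value.
components_from_tmap <- function(tmap, t_crit) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > t_crit
    if (!any(mask)) next
    lab <- cluster_label_cpp(mask)
    for (k in seq_len(max(lab))) {
      pts <- which(lab == k, arr.ind = TRUE)
      out[[length(out) + 1]] <- list(
        points = pts,
        mass = sum(tmap[lab == k]),
        sign = if (sgn > 0) "+" else "-"
      )
    }
  }
  out
}

#' Form sign-separated suprathreshold clusters
#'
#' Grid points with `|t|` above the two-tailed critical value at
#' `alpha_point` are grouped into 4-connected components, separately for
#' positive and negative points. Cluster mass is the sum of member t values.
#'
#' @param grid a `verge_tfgrid` from [pointwise_t()].
#' @param cfg a [perm_config()].
#' @return List of clusters (possibly empty), each with `points` (index
#'   matrix), `mass`, `sign` and `extent` (`band_hz`, `window_ms`), ordered
#'   by decreasing `|mass|`.
#' @export
form_clusters <- function(grid, cfg = perm_config()) {
  stopifnot(inherits(grid, "verge_tfgrid"))
  t_crit <- qt(1 - cfg$alpha_point / 2, grid$df)
  cl <- components_from_tmap(grid$tmap, t_crit)
  for (i in seq_along(cl)) {
    fi <- range(cl[[i]]$points[, 1]); ti <- range(cl[[i]]$points[, 2])
    cl[[i]]$extent <- list(band_hz = grid$freqs[fi], window_ms = grid$times[ti])
  }
  if (length(cl) > 1) cl <- cl[order(-abs(vapply(cl, `[[`, 0, "mass")))]
  cl
}

#' Monte-Carlo null distribution of the maximum cluster mass
#'
#' Between design: group labels are reshuffled preserving group sizes; within
#' design: each subject's condition difference is randomly sign-flipped. For
#' every shuffle the full t-map is recomputed, clusters are formed and the
#' maximum `|mass|` is recorded (0 when no cluster forms). With
#' `exhaustive = TRUE` all distinct relabelings (or sign patterns) are
#' enumerated instead of sampled.
#'
#' @param dataA,dataB subject stacks as in [pointwise_t()].
#' @param cfg a [perm_config()].
#' @param design `"between"` or `"within"`.
#' @param exhaustive enumerate all relabelings instead of Monte-Carlo
#'   sampling.
#' @param welch use Welch t in the between design.
#' @return Numeric vector of max-`|mass|` draws.
#' @export
permutation_null <- function(dataA, dataB, cfg = perm_config(),
                             design = c("between", "within"),
                             exhaustive = FALSE, welch = FALSE) {
  design <- match.arg(design)
  XA <- flatten_stack(dataA); XB <- flatten_stack(dataB)
  nA <- nrow(XA); nB <- nrow(XB)
  grid_dim <- if (length(dim(dataA)) == 3) dim(dataA)[2:3] else c(ncol(XA), 1L)

  max_mass <- function(tv, df) {
    tmap <- matrix(tv, grid_dim[1], grid_dim[2])
    t_crit <- qt(1 - cfg$alpha_point / 2, df)
    cl <- components_from_tmap(tmap, t_crit)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }

  if (design == "between") {
    X <- rbind(XA, XB)
    df <- nA + nB - 2
    if (exhaustive) {
      combos <- combn(nA + nB, nA)
      vapply(seq_len(ncol(combos)), function(i) {
        inA <- logical(nA + nB); inA[combos[, i]] <- TRUE
        max_mass(tstat_between(X, inA, welch), df)
      }, 0)
    } else {
      run_with_seed(cfg$seed, {
        vapply(seq_len(cfg$n_perm), function(i) {
          inA <- logical(nA + nB)
          inA[sample.int(nA + nB, nA)] <- TRUE
          max_mass(tstat_between(X, inA, welch), df)
        }, 0)
      })
    }
  } else {
    if (nA != nB) stop("within design requires paired subjects")
    D <- XA - XB
    df <- nA - 1
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), nA)))
      vapply(seq_len(nrow(signs)), function(i) {
        max_mass(tstat_paired(D * signs[i, ]), df)
      }, 0)
    } else {
      run_with_seed(cfg$seed, {
        vapply(seq_len(cfg$n_perm), function(i) {
          s <- sample(c(-1, 1), nA, replace = TRUE)
          max_mass(tstat_paired(D * s), df)
        }, 0)
      })
    }
  }
}

#' Attach Monte-Carlo p-values to clusters
#'
#' Two-tailed maximum-statistic p-value with the +1 correction:
#' `p = (1 + #\{null >= |mass|\}) / (1 + n_null)`; a cluster is significant
#' when `p < alpha_cluster`.
#'
#' @param clusters list from [form_clusters()].
#' @param null numeric vector from [permutation_null()].
#' @param cfg a [perm_config()].
#' @return The clusters with `p_value` and `significant` fields.
#' @export
cluster_p <- function(clusters, null, cfg = perm_config()) {
  if (length(null) == 0) stop("empty null distribution")
  for (i in seq_along(clusters)) {
    p <- (1 + sum(null >= abs(clusters[[i]]$mass))) / (1 + length(null))
    clusters[[i]]$p_value <- p
    clusters[[i]]$significant <- p < cfg$alpha_cluster
  }
  clusters
}

#' Run a band-wise cluster permutation test on a time-frequency stack
#'
#' For each requested band the grid is restricted to the band's frequency
#' rows, pointwise t statistics are computed (between groups, or within
#' subjects against `stack2`), clusters are formed and calibrated against
#' the Monte-Carlo maximum-mass null. The result mirrors the standard
#' cluster-report layout: comparison, design, ROI, band, time window of each
#' significant cluster, cluster mass and p-value.
#'
#' @param stack a `verge_tfstack` from [cohort_tf_stack()] (both groups).
#' @param stack2 second stack for the within design (same subjects, other
#'   condition); ignored for the between design.
#' @param design `"between"` or `"within"`.
#' @param bands named list of frequency bands (default theta/alpha/beta).
#' @param cfg a [perm_config()].
#' @param welch use Welch pointwise t in the between design.
#' @return A `verge_cluster_result`: `table` (all clusters, one row each),
#'   `clusters`, `nulls` per band, and the call metadata.
#' @export
run_cluster_test <- function(stack, stack2 = NULL,
                             design = c("between", "within"),
                             bands = eeg_bands(), cfg = perm_config(),
                             welch = FALSE) {
  design <- match.arg(design)
  stopifnot(inherits(stack, "verge_tfstack"))
  if (design == "between") {
    inA <- stack$groups == "control"
    A_full <- stack$data[inA, , , drop = FALSE]
    B_full <- stack$data[!inA, , , drop = FALSE]
    comparison <- paste0(stack$condition, " (control vs nsbvd)")
  } else {
    if (is.null(stack2)) stop("within design requires stack2")
    stopifnot(inherits(stack2, "verge_tfstack"))
    A_full <- stack$data
    B_full <- stack2$data
    comparison <- paste0(stack$condition, " vs ", stack2$condition)
  }
  rows <- list(); all_cl <- list(); nulls <- list()
  for (bname in names(bands)) {
    band <- bands[[bname]]
    fi <- which(stack$freqs >= band[1] & stack$freqs <= band[2])
    if (length(fi) == 0) next
    A <- A_full[, fi, , drop = FALSE]
    B <- B_full[, fi, , drop = FALSE]
    grid <- pointwise_t(A, B, design, freqs = stack$freqs[fi],
                        times = stack$times, welch = welch)
    cl <- form_clusters(grid, cfg)
    if (length(cl) > 0) {
      null <- permutation_null(A, B, cfg, design, welch = welch)
      cl <- cluster_p(cl, null, cfg)
      nulls[[bname]] <- null
    }
    for (x in cl) {
      rows[[length(rows) + 1]] <- data.frame(
        comparison = comparison,
        condition = stack$condition,
        design = design,
        roi = paste(stack$roi, collapse = "+"),
        band = bname,
        band_lo_hz = x$extent$band_hz[1],
        band_hi_hz = x$extent$band_hz[2],
        window_start_ms = x$extent$window_ms[1],
        window_end_ms = x$extent$window_ms[2],
        sign = x$sign,
        cluster_mass = x$mass,
        p_value = x$p_value,
        significant = x$significant,
        stringsAsFactors = FALSE
      )
      all_cl[[length(all_cl) + 1]] <- c(x, band = bname)
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    comparison = character(0), condition = character(0),
    design = character(0), roi = character(0),
    band = character(0), band_lo_hz = numeric(0), band_hi_hz = numeric(0),
    window_start_ms = numeric(0), window_end_ms = numeric(0),
    sign = character(0), cluster_mass = numeric(0), p_value = numeric(0),
    significant = logical(0), stringsAsFactors = FALSE)
  structure(list(table = tab, clusters = all_cl, nulls = nulls,
                 design = design, roi = stack$roi, cfg = cfg),
            class = "verge_cluster_result")
}

#' @export
print.verge_cluster_result <- function(x, ...) {
  sig <- x$table[x$table$significant, , drop = FALSE]
  cat("<verge_cluster_result> ", nrow(x$table), " cluster(s), ",
      nrow(sig), " significant at alpha ", x$cfg$alpha_cluster, "\n", sep = "")
  if (nrow(sig) > 0) {
    print(sig[, c("comparison", "roi", "band", "window_start_ms",
                  "window_end_ms", "cluster_mass", "p_value")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
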
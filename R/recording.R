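#' Construct a continuous EEG recording object
#'
#' A `verge_recording` bundles a channels-by-samples data matrix (microvolts),
#' the sampling rate, ordered channel labels, optional montage positions and
#' a list of event annotations (sample index + label).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels, one per row of `data`.
#' @param montage data frame with columns `label`, `x`, `y`, `z` (unit-sphere
#'   positions) or `NULL`.
#' @param events data frame with columns `sample` (1-based sample index) and
#'   `label`, or `NULL` for none.
#' @return An object of class `verge_recording`.
#' @export
verge_recording <- function(data, fs, channels, montage = NULL, events = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar")
  }
  if (nrow(data) != length(channels)) {
    stop("data row count (", nrow(data), ") must equal channel count (",
         length(channels), ")")
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), label = character(0),
                         stringsAsFactors = FALSE)
  }
  if (nrow(events) > 0) {
    bad <- events$sample < 1 | events$sample > ncol(data)
    if (any(bad)) {
      stop("event sample indices outside recording: ",
           paste(events$sample[bad], collapse = ", "))
    }
  }
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         montage = montage, events = events),
    class = "verge_recording"
  )
}

#' @export
print.verge_recording <- function(x, ...) {
  cat("<verge_recording> ", length(x$channels), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 2), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @export
print.verge_epochs <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<verge_epochs> condition '", x$condition, "': ",
      d[1], " subjects x ", d[2], " trials x ", d[3], " channels x ",
      d[4], " samples, window [", x$window_ms[1], ", ", x$window_ms[2],
      "] ms @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

condition_names <- function() {
  c("conv_start", "bo_break", "div_start", "bi_break")
}

#' Epoch analysis windows for the four vergence conditions
#'
#' Start conditions (`conv_start`, `div_start`) are analysed from 0 to
#' +1000 ms after movement onset; break conditions (`bo_break`, `bi_break`)
#' from -1000 to 0 ms, i.e. the second leading up to the loss of fusion.
#'
#' @return Named list of `c(start_ms, end_ms)` windows.
#' @export
condition_windows <- function() {
  list(
    conv_start = c(0, 1000),
    bo_break   = c(-1000, 0),
    div_start  = c(0, 1000),
    bi_break   = c(-1000, 0)
  )
}
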
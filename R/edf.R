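# Minimal EDF+ (continuous) writer/reader: 16-bit samples, one annotation
# channel carrying event markers as standard time-stamped annotation lists.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Samples are quantised to 16 bits over a fixed physical range (default
#' +/-500 microvolts, clipping outside it); events are stored in a standard
#' `EDF Annotations` channel as time-stamped annotations. Header date/time
#' fields are fixed constants so that identical data produce byte-identical
#' files.
#'
#' @param rec a [verge_recording()].
#' @param path output file path.
#' @param phys_range symmetric physical range in microvolts.
#' @param patient_id,recording_id EDF+ local identification strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 500,
                      patient_id = "X X X X", recording_id = "Startdate 01-JAN-2000 X X X") {
  stopifnot(inherits(rec, "verge_recording"))
  n_samp <- ncol(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  if (n_samp %% fs != 0) {
    stop("write_edf requires a whole number of 1-second records (",
         n_samp, " samples at ", fs, " Hz)")
  }
  n_rec <- n_samp %/% fs
  n_sig <- length(rec$channels) + 1L      # + annotations channel
  anno_spr <- 100L                        # annotation 'samples' (2 bytes each) per record

  dig_min <- -32768; dig_max <- 32767
  p_lo <- -phys_range; p_hi <- phys_range

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_id, 80),
    edf_pad(recording_id, 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (n_sig + 1), 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(n_sig, 4)
  )
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  labels <- c(rec$channels, "EDF Annotations")
  hdr <- paste0(hdr,
    field(labels, 16),
    field(rep("", n_sig), 80),
    field(c(rep("uV", n_sig - 1), ""), 8),
    field(c(rep(edf_num(p_lo, 8), n_sig - 1), edf_num(-1, 8)), 8),
    field(c(rep(edf_num(p_hi, 8), n_sig - 1), edf_num(1, 8)), 8),
    field(rep(dig_min, n_sig), 8),
    field(rep(dig_max, n_sig), 8),
    field(rep("", n_sig), 80),
    field(c(rep(fs, n_sig - 1), anno_spr), 8),
    field(rep("", n_sig), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (p_hi - p_lo) / (dig_max - dig_min)
  dig <- round((pmin(pmax(rec$data, p_lo), p_hi) - p_lo) / scale) + dig_min
  storage.mode(dig) <- "integer"

  ev_onset <- (rec$events$sample - 1) / fs
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(n_sig - 1L)) {
      writeBin(dig[ch, idx], con, size = 2L, endian = "little")
    }
    t0 <- r - 1L
    in_rec <- which(ev_onset >= t0 & ev_onset < t0 + 1)
    tals <- c(paste0("+", t0, "\x14\x14"),
              vapply(in_rec, function(i) {
                paste0("+", formatC(ev_onset[i], format = "f", digits = 4),
                       "\x14", rec$events$label[i], "\x14")
              }, ""))
    raw_tal <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    nbytes <- 2L * anno_spr
    if (length(raw_tal) > nbytes) stop("annotation block overflow in record ", r)
    writeBin(c(raw_tal, rep(as.raw(0), nbytes - length(raw_tal))), con)
  }
  invisible(path)
}

#' Read an EDF or EDF+ file
#'
#' Parses the header and all data records, converts samples to physical units
#' (microvolts) and maps EDF+ annotations to event markers. All ordinary
#' signals must share one sampling rate; channel order is preserved from the
#' file.
#'
#' @param path file path.
#' @param montage optional montage data frame attached to the result.
#' @return A [verge_recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, offset_name) {
    x <- readChar(con, width, useBytes = TRUE)
    if (nchar(x, type = "bytes") < width) {
      stop("truncated EDF file '", path, "': header ended at byte offset ",
           seek(con))
    }
    trimws(x)
  }
  rd(8, "version")
  rd(80, "patient"); rd(80, "recording"); rd(8, "date"); rd(8, "time")
  rd(8, "header bytes"); rd(44, "reserved")
  n_rec <- as.integer(rd(8, "records"))
  rec_dur <- as.numeric(rd(8, "duration"))
  n_sig <- as.integer(rd(4, "signals"))
  if (is.na(n_sig) || n_sig < 1) stop("invalid EDF header in '", path, "'")

  gethdr <- function(width) vapply(seq_len(n_sig), function(i) rd(width, "signal header"), "")
  labels <- gethdr(16); gethdr(80); gethdr(8)
  pmin <- as.numeric(gethdr(8)); pmax <- as.numeric(gethdr(8))
  dmin <- as.numeric(gethdr(8)); dmax <- as.numeric(gethdr(8))
  gethdr(80)
  spr <- as.integer(gethdr(8)); gethdr(32)

  is_anno <- labels == "EDF Annotations"
  sig_idx <- which(!is_anno)
  fs_all <- spr[sig_idx] / rec_dur
  if (length(unique(fs_all)) > 1) {
    stop("unsupported EDF: mixed sampling rates (", paste(unique(fs_all), collapse = ", "), ")")
  }
  fs <- fs_all[1]
  n_ch <- length(sig_idx)
  data <- matrix(0, n_ch, n_rec * spr[sig_idx[1]])
  anno_txt <- character(0)

  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      if (is_anno[s]) {
        raw <- readBin(con, "raw", n = 2L * spr[s])
        if (length(raw) < 2L * spr[s]) {
          stop("truncated EDF file '", path, "': record ", r,
               " ends at byte offset ", seek(con))
        }
        anno_txt <- c(anno_txt, split_tals(raw))
      } else {
        v <- readBin(con, "integer", n = spr[s], size = 2L, endian = "little")
        if (length(v) < spr[s]) {
          stop("truncated EDF file '", path, "': record ", r,
               " ends at byte offset ", seek(con))
        }
        ch <- match(s, sig_idx)
        phys <- (v - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) + pmin[s]
        data[ch, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
      }
    }
  }

  events <- parse_edf_annotations(anno_txt, fs)
  known <- c(condition_names())
  unknown <- setdiff(unique(events$label), known)
  if (length(unknown) > 0) {
    warning("unknown annotation labels retained verbatim: ",
            paste(unknown, collapse = ", "))
  }
  verge_recording(data, fs, labels[sig_idx], montage = montage, events = events)
}

# Break an annotation-channel byte block into NUL-separated TAL strings.
split_tals <- function(raw) {
  if (all(raw == as.raw(0))) return(character(0))
  cuts <- which(raw == as.raw(0))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(raw))
  keep <- starts <= ends
  vapply(which(keep), function(i) rawToChar(raw[starts[i]:ends[i]]), "")
}

# Convert TAL strings into (onset, label) events, discarding bare
# record-keeping timestamps (TALs with no label text).
parse_edf_annotations <- function(tals, fs) {
  onsets <- numeric(0); labs <- character(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    onset <- suppressWarnings(
      as.numeric(strsplit(parts[1], "\x15", fixed = TRUE)[[1]][1]))
    if (is.na(onset)) next
    for (lab in parts[-1]) {
      if (nzchar(lab)) {
        onsets <- c(onsets, onset)
        labs <- c(labs, lab)
      }
    }
  }
  data.frame(sample = as.integer(round(onsets * fs)) + 1L, label = labs,
             stringsAsFactors = FALSE)
}
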
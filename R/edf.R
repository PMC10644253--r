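# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# 256-byte fixed header + 256 bytes per signal, little-endian data records.
# Covers plain EDF only (no EDF+ annotations, no discontinuous records).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

edf_norm_label <- function(x) {
  # "EEG Fc5.." (PhysioNet style) and "Fc5" compare equal
  x <- sub("^EEG[ .]*", "", x, ignore.case = TRUE)
  tolower(gsub("[^A-Za-z0-9]", "", x))
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over the per-channel physical
#' range, as the format requires, so a round trip loses at most half a
#' quantization step per sample.
#'
#' @param rec a `vnfc_recording` (see [new_recording()]); `rec$fs` must be a
#'   whole number (one data record per second is written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "vnfc_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) rlang::abort("write_edf needs an integer sampling rate")
  fs <- as.integer(round(fs))
  data <- rec$data
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) rlang::abort("recording shorter than one 1-s data record")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round(sweep(sweep(data, 1, pmin_), 1, scale, "/")) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(paste0("subject ", rec$subject_id %||% "X"), 80),
    edf_pad(rec$condition %||% "", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  ), con, eos = NULL)
  labs <- rec$labels %||% paste0("ch", seq_len(ns))
  fields <- c(
    vapply(labs, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),                 # transducer
    rep(edf_pad("uV", 8), ns),                # physical dimension
    vapply(pmin_, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), ""),
    vapply(pmax_, function(v) edf_pad(formatC(v, digits = 6, format = "g"), 8), ""),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),                 # prefiltering
    rep(edf_pad(fs, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(dig[, idx, drop = FALSE])      # per signal, contiguous samples
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

edf_read_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            date = rd(8), time = rd(8), hdr_bytes = as.integer(rd(8)))
  rd(44)
  h$n_rec <- as.integer(rd(8))
  h$rec_dur <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- fld(16); fld(80); fld(8)
  h$pmin <- as.numeric(fld(8)); h$pmax <- as.numeric(fld(8))
  h$dmin <- as.numeric(fld(8)); h$dmax <- as.numeric(fld(8))
  fld(80)
  h$spr <- as.integer(fld(8))
  fld(32)
  h
}

#' Read an EDF file into a recording
#'
#' Channel labels are matched to the montage after normalization (case,
#' punctuation and a leading "EEG" tag are ignored, so PhysioNet's
#' `"EEG Fc5.."` matches `"Fc5"`), and the returned channels are reordered to
#' montage order.
#'
#' @param path an EDF file.
#' @param montage a `vnfc_montage` giving the channels to extract, in order.
#' @param subject_id label attached to the recording (default: file name).
#' @param condition optional free-form tag (e.g. `"EO"`/`"EC"`).
#' @return A `vnfc_recording`.
#' @export
read_edf <- function(path, montage, subject_id = NULL, condition = NULL) {
  stopifnot(inherits(montage, "vnfc_montage"))
  if (!file.exists(path)) rlang::abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- edf_read_header(con)
  want <- edf_norm_label(montage$label)
  have <- edf_norm_label(h$labels)
  idx <- match(want, have)
  if (anyNA(idx)) {
    rlang::abort(sprintf("EDF file lacks montage channel(s): %s",
                         paste(montage$label[is.na(idx)], collapse = ", ")))
  }
  if (length(unique(h$spr[idx])) != 1L) {
    rlang::abort("matched channels have inconsistent sampling rates")
  }
  spr <- h$spr[idx[1]]
  fs <- spr / h$rec_dur
  raw <- readBin(con, integer(), n = sum(h$spr) * h$n_rec, size = 2,
                 endian = "little", signed = TRUE)
  offs <- c(0L, cumsum(h$spr))          # sample offset of each signal in a record
  per_rec <- sum(h$spr)
  data <- matrix(0, nrow = length(idx), ncol = spr * h$n_rec)
  for (ci in seq_along(idx)) {
    s <- idx[ci]
    sc <- (h$pmax[s] - h$pmin[s]) / (h$dmax[s] - h$dmin[s])
    for (r in seq_len(h$n_rec)) {
      src <- (r - 1L) * per_rec + offs[s] + seq_len(spr)
      data[ci, (r - 1L) * spr + seq_len(spr)] <-
        h$pmin[s] + (raw[src] - h$dmin[s]) * sc
    }
  }
  new_recording(data, fs = fs,
                subject_id = subject_id %||% basename(path),
                condition = condition, labels = montage$label)
}
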
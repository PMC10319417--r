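# Minimal European Data Format (EDF) writer/reader: 16-bit samples,
# one-second data records, physical units microvolt. Covers exactly what a
# simulated session needs; not a general-purpose EDF implementation
# (no EDF+ annotations, one sampling rate for all signals).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a session's signal data to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' chosen per channel from the data (so quantization error is at most
#' range/65536 microvolt). The recording is padded with zeros to a whole
#' number of one-second records.
#'
#' @param session An `eeg_session` (or any list with `data`, `fs`,
#'   `montage`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [write_session()] for EDF plus the JSON sidecar carrying the
#'   trial schedule.
#' @export
write_edf <- function(session, path) {
  data <- session$data
  fs <- session$fs
  stopifnot(is.matrix(data), fs == round(fs))
  ns <- nrow(data)
  n_rec <- ceiling(ncol(data) / fs)
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  }
  phys_max <- pmax(apply(abs(data), 1, max), 1)
  phys_max <- signif(phys_max * 1.01, 6)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)

  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date/time
  wr(256 * (ns + 1), 8)                        # header bytes
  wr("", 44)                                   # reserved
  wr(n_rec, 8)
  wr("1", 8)                                   # record duration (s)
  wr(ns, 4)
  for (lab in session$montage) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-phys_max[i]), 8)
  for (i in seq_len(ns)) wr(format(phys_max[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)             # samples per record
  for (i in seq_len(ns)) wr("", 32)            # reserved

  # symmetric digital range keeps the reader's affine map (gain from the
  # physical/digital extremes) exactly inverse to this quantization
  scale <- 32767 / phys_max
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, cols, drop = FALSE] * scale)
    block <- pmin(pmax(block, -32767), 32767)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return A list with `data` (channel x sample matrix in physical units),
#'   `fs`, and `labels` (channel labels with the "EEG " prefix stripped).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1L, header_bytes == 256 * (ns + 1))

  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(block) * gain + offset
  }
  rownames(data) <- labels
  list(data = data, fs = fs, labels = labels, units = units)
}

#' Write a session as EDF plus a JSON sidecar
#'
#' The sidecar (same path with extension `.json`) stores the trial
#' schedule, segment timing, montage, sampling rate, seed and artifact
#' bookkeeping, so [read_session()] round-trips the complete object (the
#' signal up to 16-bit quantization, the metadata exactly).
#'
#' @param session An `eeg_session`.
#' @param path EDF output path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  write_edf(session, path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  meta <- list(
    fs = session$fs,
    montage = session$montage,
    seed_used = session$seed_used,
    artifact_trials = session$artifact_trials,
    timing = attr(session$schedule, "timing"),
    schedule = as.data.frame(
      dplyr::mutate(session$schedule,
                    condition = as.character(.data$condition)))
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from EDF plus its JSON sidecar
#'
#' @param path EDF file path written by [write_session()].
#' @return An `eeg_session`.
#' @export
read_session <- function(path) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar)) {
    abort(paste0("Sidecar not found: ", sidecar), class = "kibci_io_error")
  }
  edf <- read_edf(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sched <- tibble::as_tibble(meta$schedule)
  sched$condition <- factor(sched$condition, levels = mi_conditions())
  sched <- tibble::new_tibble(sched, timing = as.list(meta$timing),
                              seed = meta$seed_used,
                              class = "trial_schedule")
  structure(
    list(data = edf$data, fs = edf$fs, montage = meta$montage,
         schedule = sched, seed_used = meta$seed_used,
         artifact_trials = as.integer(meta$artifact_trials)),
    class = "eeg_session")
}
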
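#' Write and read BrainVision-style recordings
#'
#' `write_brainvision()` stores an [`eeg_raw`][simulate_subject] object as a
#' BrainVision triplet: a text header (`.vhdr`), a text marker file
#' (`.vmrk`, one `Stimulus` marker per event) and multiplexed 16-bit
#' little-endian integer data (`.eeg`) at 0.1 uV resolution.
#' `read_brainvision()` reconstructs the object; the round trip reproduces
#' the signal to within the 0.05 uV quantization and the events exactly.
#'
#' `write_raw_binary()` / `read_raw_binary()` provide the simpler fallback
#' format: IEEE float32 channel-multiplexed binary plus a JSON sidecar
#' holding the sampling rate, channel table and event table.
#'
#' @param raw An `eeg_raw` object.
#' @param basename Path without extension; the three files are written as
#'   `basename.vhdr` / `.vmrk` / `.eeg` (or `.bin` / `.json`).
#' @param resolution_uv Quantization step of the integer encoding.
#' @return `write_*` return `basename` invisibly; `read_*` return an
#'   `eeg_raw`.
#' @export
write_brainvision <- function(raw, basename, resolution_uv = 0.1) {
  n_ch <- nrow(raw$data)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  base <- basename(basename)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / raw$srate_hz, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), raw$chan$name,
            format(resolution_uv, scientific = FALSE)),
    "[Reference]",
    paste0("Reference=", raw$reference)
  ), vhdr, useBytes = FALSE)

  ev <- raw$events
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    if (nrow(ev) > 0) {
      sprintf("Mk%d=Stimulus,S %s/%s/%s/%d,%d,1,0",
              seq_len(nrow(ev)) + 1L, ev$role, ev$stimulus, ev$condition,
              ev$token, ev$sample)
    }
  ), vmrk)

  q <- round(raw$data / resolution_uv)
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  invisible(basename)
}

#' @rdname write_brainvision
#' @export
read_brainvision <- function(basename) {
  vhdr <- paste0(basename, ".vhdr")
  if (!file.exists(vhdr)) stop("Header file not found: ", vhdr, call. = FALSE)
  lines <- readLines(vhdr, encoding = "UTF-8")
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines)
    if (length(hit) == 0) {
      stop("Malformed header: missing `", key, "` (", vhdr, ")",
           call. = FALSE)
    }
    sub(paste0("^", key, "="), "", lines[hit[1]])
  }
  n_ch <- as.integer(get_field("NumberOfChannels"))
  srate <- 1e6 / as.numeric(get_field("SamplingInterval"))
  fmt <- get_field("BinaryFormat")
  if (!identical(fmt, "INT_16")) {
    stop("Unsupported BinaryFormat `", fmt, "` at line ",
         grep("^BinaryFormat=", lines)[1], " of ", vhdr, call. = FALSE)
  }
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != n_ch) {
    stop("Header declares ", n_ch, " channels but lists ",
         length(ch_lines), " Ch entries (", vhdr, ")", call. = FALSE)
  }
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(parts, `[`, "", 1)
  res <- as.numeric(vapply(parts, `[`, "", 3))
  reference <- sub("^Reference=", "",
                   grep("^Reference=", lines, value = TRUE)[1])
  if (is.na(reference)) reference <- "unknown"

  eeg <- paste0(basename, ".eeg")
  expect_bytes <- NA_real_
  sz <- file.size(eeg)
  if (is.na(sz)) stop("Data file not found: ", eeg, call. = FALSE)
  if (sz %% (2 * n_ch) != 0) {
    stop("Size mismatch: ", eeg, " has ", sz, " bytes, not a multiple of ",
         2 * n_ch, " (2 bytes x ", n_ch, " channels).", call. = FALSE)
  }
  n_samp <- sz / (2 * n_ch)
  con <- file(eeg, "rb")
  on.exit(close(con))
  vals <- readBin(con, "integer", n = n_samp * n_ch, size = 2L,
                  signed = TRUE, endian = "little")
  data <- matrix(vals, nrow = n_ch) * res
  rownames(data) <- ch_names

  vmrk <- paste0(basename, ".vmrk")
  events <- tibble::tibble(index = integer(), onset_ms = numeric(),
                           stimulus = character(), role = character(),
                           condition = character(), token = integer(),
                           sample = integer())
  if (file.exists(vmrk)) {
    mlines <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk), value = TRUE)
    if (length(mlines) > 0) {
      fields <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
      bad <- which(lengths(fields) < 3)
      if (length(bad)) {
        stop("Malformed marker line ", bad[1], " in ", vmrk, call. = FALSE)
      }
      desc <- sub("^S ", "", vapply(fields, `[`, "", 2))
      dparts <- strsplit(desc, "/")
      smp <- as.integer(vapply(fields, `[`, "", 3))
      events <- tibble::tibble(
        index = seq_along(mlines),
        onset_ms = (smp - 1) / srate * 1000,
        stimulus = vapply(dparts, `[`, "", 2),
        role = vapply(dparts, `[`, "", 1),
        condition = vapply(dparts, `[`, "", 3),
        token = as.integer(vapply(dparts, `[`, "", 4)),
        sample = smp)
    }
  }
  chan <- tibble::tibble(
    name = ch_names,
    type = dplyr::case_when(ch_names %in% c("M1", "M2") ~ "mastoid",
                            grepl("EOG", ch_names) ~ "eog",
                            TRUE ~ "scalp"),
    x = NA_real_, y = NA_real_)
  new_eeg_raw(data = data, srate_hz = srate, chan = chan, events = events,
              reference = reference)
}

#' @rdname write_brainvision
#' @export
write_raw_binary <- function(raw, basename) {
  con <- file(paste0(basename, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(raw$data), con, size = 4L, endian = "little")
  hdr <- list(srate_hz = raw$srate_hz, reference = raw$reference,
              n_channels = nrow(raw$data), n_samples = ncol(raw$data),
              format = "float32-multiplexed-le",
              chan = raw$chan, events = raw$events)
  jsonlite::write_json(hdr, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(basename)
}

#' @rdname write_brainvision
#' @export
read_raw_binary <- function(basename) {
  hdr <- jsonlite::read_json(paste0(basename, ".json"),
                             simplifyVector = TRUE)
  bin <- paste0(basename, ".bin")
  sz <- file.size(bin)
  want <- 4 * hdr$n_channels * hdr$n_samples
  if (is.na(sz) || sz != want) {
    stop("Size mismatch: ", bin, " has ", sz, " bytes, expected ", want,
         call. = FALSE)
  }
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = hdr$n_channels * hdr$n_samples,
                  size = 4L, endian = "little")
  data <- matrix(vals, nrow = hdr$n_channels)
  rownames(data) <- hdr$chan$name
  new_eeg_raw(data = data, srate_hz = hdr$srate_hz,
              chan = tibble::as_tibble(hdr$chan),
              events = tibble::as_tibble(hdr$events),
              reference = hdr$reference)
}
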
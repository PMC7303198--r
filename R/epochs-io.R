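#' Serialize epochs to a plain-text container
#'
#' Writes an `eeg_epochs` object as three files sharing a basename: a JSON
#' header (`.json`: sampling rate, window, reference, channel table,
#' dimensions), a TSV trial-metadata table (`.meta.tsv`), and the data as a
#' TSV matrix (`.data.tsv`) with one row per trial x channel (columns
#' `trial`, `channel`, then one column per sample). `read_epochs()`
#' restores the object exactly up to text-numeric round-off.
#'
#' @param ep An `eeg_epochs` object.
#' @param basename Path without extension.
#' @param digits Significant digits written for the signal.
#' @return `write_epochs()` returns `basename` invisibly; `read_epochs()`
#'   an `eeg_epochs`.
#' @export
write_epochs <- function(ep, basename, digits = 8) {
  d <- dim(ep$data)
  jsonlite::write_json(
    list(srate_hz = ep$srate_hz, window = ep$window,
         reference = ep$reference, times_ms = ep$times_ms,
         n_trials = d[1], n_channels = d[2], n_samples = d[3],
         chan = ep$chan),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(ep$metadata),
                     paste0(basename, ".meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  out <- cbind(trial = rep(seq_len(d[1]), each = d[2]),
               channel = rep(seq_len(d[2]), times = d[1]),
               signif(flat, digits))
  utils::write.table(out, paste0(basename, ".data.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("trial", "channel",
                                   paste0("s", seq_len(d[3]))))
  invisible(basename)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(basename) {
  hdr <- jsonlite::read_json(paste0(basename, ".json"),
                             simplifyVector = TRUE)
  meta <- tibble::as_tibble(utils::read.delim(paste0(basename, ".meta.tsv")))
  flat <- utils::read.delim(paste0(basename, ".data.tsv"))
  d <- c(hdr$n_trials, hdr$n_channels, hdr$n_samples)
  vals <- as.matrix(flat[, -(1:2), drop = FALSE])
  data <- aperm(array(t(vals), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  structure(list(data = data, times_ms = hdr$times_ms,
                 srate_hz = hdr$srate_hz,
                 chan = tibble::as_tibble(hdr$chan), metadata = meta,
                 reference = hdr$reference, window = hdr$window),
            class = "eeg_epochs")
}
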
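#' Band-pass and notch filter continuous EEG
#'
#' Zero-phase filtering of every channel with a 0.5-70 Hz Butterworth
#' band-pass (realized as cascaded 2nd-order high-pass and low-pass
#' sections) and a 2nd-order 48-52 Hz band-stop notch. Zero phase matters
#' because component latency is an outcome measure downstream.
#'
#' Two equivalent realizations are provided. `"fft"` (default) multiplies
#' the spectrum of each channel by the squared Butterworth magnitude
#' response -- the exact frequency-domain counterpart of forward-backward
#' filtering, vectorized over channels. `"iir"` applies the recursive
#' filters forward and backward in time (`signal::filtfilt`); the two
#' agree away from the record edges and the slower `"iir"` path serves as
#' an independent cross-check.
#'
#' @param raw An `eeg_raw` object.
#' @param band Pass band in Hz (`c(low, high)`); use `NULL` to skip.
#' @param notch Stop band in Hz (`c(low, high)`); use `NULL` to skip.
#' @param method `"fft"` or `"iir"`.
#' @return The filtered `eeg_raw`.
#' @export
filter_continuous <- function(raw, band = c(0.5, 70), notch = c(48, 52),
                              method = c("fft", "iir")) {
  method <- match.arg(method)
  nyq <- raw$srate_hz / 2
  if (!is.null(band) && band[2] >= nyq) {
    stop("Band edge ", band[2], " Hz must lie below the Nyquist frequency (",
         nyq, " Hz).", call. = FALSE)
  }
  if (!is.null(notch) && notch[2] >= nyq) {
    stop("Notch edge ", notch[2], " Hz must lie below the Nyquist frequency.",
         call. = FALSE)
  }
  if (is.null(band) && is.null(notch)) return(raw)
  if (method == "iir") {
    filters <- list()
    if (!is.null(band)) {
      filters <- c(filters,
                   list(signal::butter(2, band[1] / nyq, type = "high"),
                        signal::butter(2, band[2] / nyq, type = "low")))
    }
    if (!is.null(notch)) {
      filters <- c(filters,
                   list(signal::butter(1, notch / nyq, type = "stop")))
    }
    x <- raw$data
    for (ch in seq_len(nrow(x))) {
      v <- x[ch, ]
      for (f in filters) v <- signal::filtfilt(f, v)
      x[ch, ] <- v
    }
    raw$data <- x
    return(raw)
  }
  n <- ncol(raw$data)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * raw$srate_hz / n   # two-sided frequency axis
  gain <- rep(1, n)
  if (!is.null(band)) {
    r_hp <- (f / band[1])^4
    gain <- gain * (r_hp / (1 + r_hp)) / (1 + (f / band[2])^4)
  }
  if (!is.null(notch)) {
    f0_sq <- notch[1] * notch[2]
    bw <- notch[2] - notch[1]
    num <- bw * f
    den <- f0_sq - f^2
    # band-stop magnitude^2; exact zero on the center bin
    gain <- gain * den^2 / (den^2 + num^2)
  }
  gain <- gain^2                            # forward-backward equivalence
  spec <- stats::mvfft(t(raw$data)) * gain
  raw$data <- t(Re(stats::mvfft(spec, inverse = TRUE))) / n
  raw
}

#' Downsample continuous EEG by an integer factor
#'
#' Keeps every `factor`-th sample (the preceding 70 Hz low-pass provides the
#' anti-aliasing) and rescales event sample indices to the nearest retained
#' sample.
#'
#' @param raw An `eeg_raw` object.
#' @param target_hz Target sampling rate; `raw$srate_hz` must be an integer
#'   multiple.
#' @return The downsampled `eeg_raw`.
#' @export
downsample_raw <- function(raw, target_hz = 250) {
  factor <- raw$srate_hz / target_hz
  if (factor != round(factor)) {
    stop("Sampling rate ", raw$srate_hz,
         " Hz is not an integer multiple of ", target_hz, " Hz.",
         call. = FALSE)
  }
  factor <- as.integer(factor)
  keep <- seq(1L, ncol(raw$data), by = factor)
  raw$data <- raw$data[, keep, drop = FALSE]
  raw$srate_hz <- target_hz
  if (nrow(raw$events) > 0) {
    raw$events$sample <- (as.integer(raw$events$sample) - 1L) %/% factor + 1L
  }
  raw
}

# compact symmetric FastICA (eigen whitening, tanh contrast), seeded
fastica_decompose <- function(x, seed = 1L, max_iter = 200, tol = 1e-6) {
  n_ch <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    stop("Covariance is rank deficient; ICA needs full-rank data.",
         call. = FALSE)
  }
  k <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening matrix
  z <- k %*% xc
  withr::with_seed(seed, {
    w <- qr.Q(qr(matrix(stats::rnorm(n_ch^2), n_ch)))
  })
  sym_orth <- function(w) {
    s <- w %*% t(w)
    e <- eigen(s, symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    solve_sqrt %*% w
  }
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    w1 <- g %*% t(z) / n - diag(rowMeans(gp)) %*% w
    w1 <- sym_orth(w1)
    conv <- max(abs(1 - abs(rowSums(w1 * w))))
    w <- w1
    if (conv < tol) break
  }
  s <- w %*% z
  mixing <- solve(w %*% k)     # x - mu = mixing %*% s
  list(sources = s, mixing = mixing, unmixing = w %*% k, mean = mu)
}

#' Remove ocular artifacts from continuous EEG
#'
#' `"ica_auto"` decomposes the full channel set (63 components for the
#' 63-channel montage, mirroring the original runica decomposition) with a
#' seeded FastICA, flags every component whose time course correlates with
#' any EOG channel at `|r| >= threshold`, and subtracts the flagged
#' components -- an automated surrogate for manual component selection
#' based on time course and topography. `"eog_regression"` subtracts
#' the least-squares projection of the EOG channels from every non-EOG
#' channel. `"none"` is the identity.
#'
#' @param raw An `eeg_raw` with EOG channels (for the active methods).
#' @param method `"ica_auto"`, `"eog_regression"` or `"none"`.
#' @param threshold Absolute EOG-correlation threshold for component
#'   removal (ica_auto).
#' @param seed Seed for the ICA initialization.
#' @return A list with `raw` (cleaned recording) and `report` (tibble:
#'   `n_components`, `n_removed`, `removed` components as a list column,
#'   `max_abs_r`).
#' @export
remove_ocular_artifacts <- function(raw,
                                    method = c("ica_auto", "eog_regression",
                                               "none"),
                                    threshold = 0.7, seed = 1L) {
  method <- match.arg(method)
  eog_idx <- which(raw$chan$type == "eog")
  sig_idx <- which(raw$chan$type != "eog")
  if (method == "none") {
    return(list(raw = raw, report = tibble::tibble(
      method = "none", n_components = 0L, n_removed = 0L,
      removed = list(integer(0)), max_abs_r = NA_real_)))
  }
  if (length(eog_idx) == 0) {
    stop("EOG channels are required for method `", method, "`.",
         call. = FALSE)
  }
  eog <- raw$data[eog_idx, , drop = FALSE]
  if (method == "eog_regression") {
    x <- raw$data[sig_idx, , drop = FALSE]
    ec <- eog - rowMeans(eog)
    xc <- x - rowMeans(x)
    beta <- xc %*% t(ec) %*% solve(tcrossprod(ec))
    raw$data[sig_idx, ] <- x - beta %*% ec
    return(list(raw = raw, report = tibble::tibble(
      method = "eog_regression", n_components = length(eog_idx),
      n_removed = length(eog_idx), removed = list(eog_idx),
      max_abs_r = NA_real_)))
  }
  if (nrow(raw$data) < 8) {
    stop("ICA needs at least 8 channels for a meaningful decomposition; ",
         "got ", nrow(raw$data), ".", call. = FALSE)
  }
  dec <- fastica_decompose(raw$data, seed = seed)
  r <- stats::cor(t(dec$sources), t(eog))
  max_r <- apply(abs(r), 1, max)
  bad <- which(max_r >= threshold)
  if (length(bad) > 0) {
    raw$data <- raw$data -
      dec$mixing[, bad, drop = FALSE] %*% dec$sources[bad, , drop = FALSE]
  }
  list(raw = raw, report = tibble::tibble(
    method = "ica_auto", n_components = nrow(raw$data),
    n_removed = length(bad), removed = list(bad),
    max_abs_r = max(max_r)))
}

#' Extract fixed-window epochs around stimulus onsets
#'
#' Cuts a half-open `[window[1], window[2])` ms epoch around every event's
#' onset sample (at 250 Hz and the default window this yields 275 samples:
#' -100 to +996 ms). Events whose window would leave the recording are
#' flagged (`kept = FALSE`, reason `"edge"`), never silently dropped.
#'
#' @param raw An `eeg_raw` object.
#' @param window Epoch window in ms relative to the event onset.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples
#'   array, uV), `times_ms`, `srate_hz`, `chan`, `metadata` (event fields
#'   plus `kept`, `reason`), `reference`.
#' @export
epoch_raw <- function(raw, window = c(-100, 1000)) {
  stopifnot(window[1] < 0, window[2] > 0)
  sr <- raw$srate_hz
  off0 <- as.integer(round(window[1] / 1000 * sr))
  n_s <- as.integer(round((window[2] - window[1]) / 1000 * sr))
  times_ms <- (off0 + seq_len(n_s) - 1) / sr * 1000
  ev <- raw$events
  n_tr <- nrow(ev)
  n_ch <- nrow(raw$data)
  data <- array(0, dim = c(n_tr, n_ch, n_s))
  kept <- rep(TRUE, n_tr)
  reason <- rep(NA_character_, n_tr)
  for (i in seq_len(n_tr)) {
    s0 <- ev$sample[i] + off0
    s1 <- s0 + n_s - 1L
    if (s0 < 1 || s1 > ncol(raw$data)) {
      kept[i] <- FALSE
      reason[i] <- "edge"
    } else {
      data[i, , ] <- raw$data[, s0:s1]
    }
  }
  meta <- dplyr::mutate(tibble::as_tibble(ev), kept = kept, reason = reason)
  structure(list(data = data, times_ms = times_ms, srate_hz = sr,
                 chan = raw$chan, metadata = meta,
                 reference = raw$reference, window = window),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$srate_hz,
      " Hz, window [", x$window[1], ", ", x$window[2], ") ms, ",
      sum(x$metadata$kept), " kept\n", sep = "")
  invisible(x)
}

#' DC removal, baseline correction and amplitude-criterion rejection
#'
#' Per trial and channel, subtracts the whole-epoch mean (DC removal) and
#' then the mean over the pre-stimulus baseline interval; afterwards any
#' trial whose absolute amplitude exceeds `threshold_uv` on any *scalp*
#' electrode (mastoids and EOG are excluded from the criterion) is marked
#' `kept = FALSE` with reason `"amplitude"`.
#'
#' @param ep An `eeg_epochs` object.
#' @param baseline Baseline interval in ms (half-open, default `[-100, 0)`).
#' @param threshold_uv Rejection threshold in uV.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_and_reject <- function(ep, baseline = c(-100, 0),
                                threshold_uv = 75) {
  stopifnot(baseline[1] >= ep$window[1], baseline[2] <= ep$window[2])
  bl_idx <- which(ep$times_ms >= baseline[1] & ep$times_ms < baseline[2])
  if (length(bl_idx) == 0) stop("Empty baseline interval.", call. = FALSE)
  d <- ep$data
  dims <- dim(d)
  # DC removal: subtract the per-trial/channel epoch mean
  epoch_mean <- rowMeans(d, dims = 2)
  d <- d - array(epoch_mean, dim = dims)
  bl_mean <- rowMeans(d[, , bl_idx, drop = FALSE], dims = 2)
  d <- d - array(bl_mean, dim = dims)
  ep$data <- d
  scalp <- which(ep$chan$type == "scalp")
  mx <- apply(abs(d[, scalp, , drop = FALSE]), 1, max)
  bad <- which(mx > threshold_uv & ep$metadata$kept)
  ep$metadata$kept[bad] <- FALSE
  ep$metadata$reason[bad] <- "amplitude"
  ep
}

#' Re-reference epochs to the average mastoids
#'
#' Subtracts the mean of M1 and M2 from every channel and updates the
#' reference label.
#'
#' @param ep An `eeg_epochs` object with M1 and M2 channels.
#' @return The re-referenced `eeg_epochs`.
#' @export
rereference_mastoids <- function(ep) {
  m <- match(c("M1", "M2"), ep$chan$name)
  if (anyNA(m)) {
    stop("Mastoid channels M1/M2 not present; cannot re-reference.",
         call. = FALSE)
  }
  ref <- (ep$data[, m[1], ] + ep$data[, m[2], ]) / 2   # trials x samples
  n_ch <- dim(ep$data)[2]
  ep$data <- ep$data - aperm(array(ref, dim = dim(ep$data)[c(1, 3, 2)]),
                             c(1, 3, 2))
  ep$reference <- "average mastoids"
  ep
}

#' Run the full preprocessing chain on a continuous recording
#'
#' Applies, in this fixed order: band-pass + notch filtering, downsampling,
#' ocular-artifact removal, epoching, DC/baseline correction with
#' amplitude-criterion rejection, and average-mastoid re-referencing.
#'
#' @param raw An `eeg_raw` object.
#' @param downsample_to Target rate, Hz.
#' @param ocular_method Method for [remove_ocular_artifacts()].
#' @param window,baseline,threshold_uv See [epoch_raw()] and
#'   [baseline_and_reject()].
#' @param seed Seed for the (seeded) ICA step.
#' @inheritParams filter_continuous
#' @return A list with `epochs` (`eeg_epochs`) and `ocular_report`.
#' @export
preprocess_raw <- function(raw, band = c(0.5, 70), notch = c(48, 52),
                           downsample_to = 250,
                           ocular_method = "eog_regression",
                           window = c(-100, 1000), baseline = c(-100, 0),
                           threshold_uv = 75, seed = 1L) {
  raw <- filter_continuous(raw, band = band, notch = notch)
  raw <- downsample_raw(raw, target_hz = downsample_to)
  oc <- remove_ocular_artifacts(raw, method = ocular_method, seed = seed)
  ep <- epoch_raw(oc$raw, window = window)
  ep <- baseline_and_reject(ep, baseline = baseline,
                            threshold_uv = threshold_uv)
  ep <- rereference_mastoids(ep)
  list(epochs = ep, ocular_report = oc$report)
}
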
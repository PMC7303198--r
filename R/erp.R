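#' MMN peak-search windows
#'
#' Primary and fallback peak-search windows in ms after the deviation onset:
#' 100-300 ms (primary) / 80-300 ms (fallback) for formal deviants, and
#' 200-350 ms / 120-370 ms for temporal deviants (whose deviation onset is
#' the stimulus onset).
#'
#' @return Nested list `list(formal = list(primary, fallback), temporal =
#'   list(primary, fallback))`, windows as `c(lo, hi)` in ms.
#' @export
peak_windows <- function() {
  list(formal = list(primary = c(100, 300), fallback = c(80, 300)),
       temporal = list(primary = c(200, 350), fallback = c(120, 370)))
}

#' Average selected epochs into an ERP, re-locked to the deviation onset
#'
#' Pointwise mean over the selected trials, with the time axis shifted by
#' `lock_offset_ms` so that 0 marks the deviation onset: 250 ms (the
#' /t/-onset) for formal-deviant comparisons, 0 ms for temporal ones.
#' Standards entering a deviant comparison must be averaged with the same
#' offset as the deviant.
#'
#' @param ep An `eeg_epochs` object.
#' @param trials Integer indices (or logical mask) of the trials to average.
#' @param lock_offset_ms Shift applied to the time axis, ms.
#' @param cell Optional named list/tibble of cell labels (role, phonprob,
#'   sylstr, ...) carried on the result.
#' @return An `erp_wave`: list with `data` (channels x samples, uV),
#'   `times_ms` (relative to deviation onset), `srate_hz`, `chan`,
#'   `n_trials`, `lock_offset_ms`, `cell`.
#' @export
timelock_average <- function(ep, trials, lock_offset_ms = 0, cell = NULL) {
  if (is.logical(trials)) trials <- which(trials)
  if (length(trials) == 0) {
    stop("Empty trial selection for cell ",
         paste(unlist(cell), collapse = "/"), call. = FALSE)
  }
  avg <- colMeans(ep$data[trials, , , drop = FALSE], dims = 1)
  rownames(avg) <- ep$chan$name
  structure(list(data = avg, times_ms = ep$times_ms - lock_offset_ms,
                 srate_hz = ep$srate_hz, chan = ep$chan,
                 n_trials = length(trials),
                 lock_offset_ms = lock_offset_ms,
                 cell = cell),
            class = "erp_wave")
}

#' Identical-stimulus difference wave (deviant minus standard)
#'
#' @param dev,std `erp_wave` objects on the same channels, time axis and
#'   lock offset; the standard must be the identical stimulus from the
#'   condition in which it served as standard.
#' @return An `erp_wave` holding `dev - std` pointwise; `n_trials` is the
#'   deviant trial count, and `cell` is taken from `dev`.
#' @export
difference_wave <- function(dev, std) {
  if (!identical(dim(dev$data), dim(std$data)) ||
      max(abs(dev$times_ms - std$times_ms)) > 1e-9) {
    stop("Deviant and standard waves are not on the same grid.",
         call. = FALSE)
  }
  dev_stim <- dev$cell$stimulus %||% NULL
  std_stim <- std$cell$stimulus %||% NULL
  if (!is.null(dev_stim) && !is.null(std_stim) &&
      !identical(dev_stim, std_stim)) {
    stop("Difference waves require identical stimuli (got ", dev_stim,
         " vs ", std_stim, ").", call. = FALSE)
  }
  out <- dev
  out$data <- dev$data - std$data
  out
}

# interior minima; on flat-bottomed dips the earliest sample qualifies
local_minima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
}

roi_window_mean <- function(wave, electrodes, center_ms, halfwidth_ms) {
  miss <- setdiff(electrodes, wave$chan$name)
  if (length(miss) > 0) {
    stop("ROI electrode(s) missing from the montage: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- which(wave$times_ms >= center_ms - halfwidth_ms - 1e-9 &
                 wave$times_ms <= center_ms + halfwidth_ms + 1e-9)
  mean(wave$data[match(electrodes, wave$chan$name), idx, drop = FALSE])
}

#' Detect the MMN peak latency on a difference wave
#'
#' Searches the FCz difference wave for the most negative local minimum
#' inside the primary window that also shows the frontocentral topography
#' (the frontocentral ROI mean within +/- `halfwidth_ms` of the candidate
#' more negative than the centroparietal ROI mean). If no candidate passes,
#' the fallback window is searched the same way; if still none, the global
#' minimum of the fallback window is returned with `qc_flag = TRUE` --
#' a deterministic stand-in for manual inspection of ambiguous peaks.
#' Ties are broken toward the earlier latency.
#'
#' @param diff An `erp_wave` difference wave (time 0 = deviation onset).
#' @param channel Peak-search electrode (FCz).
#' @param primary,fallback Search windows, ms (see [peak_windows()]).
#' @param rois ROI definition ([mmn_rois()]) for the topography check; use
#'   `NULL` to skip the check.
#' @param halfwidth_ms Half-width of the topography-check averaging window.
#' @return A one-row tibble: `latency_ms`, `amplitude_uv` (FCz difference
#'   value at the peak), `window_used` (`"primary"`/`"fallback"`),
#'   `qc_flag`.
#' @export
detect_mmn_peak <- function(diff, channel = "FCz",
                            primary = peak_windows()$formal$primary,
                            fallback = peak_windows()$formal$fallback,
                            rois = mmn_rois(), halfwidth_ms = 24) {
  lo <- min(primary[1], fallback[1])
  hi <- max(primary[2], fallback[2])
  if (lo < min(diff$times_ms) || hi > max(diff$times_ms)) {
    stop("Search window [", lo, ", ", hi, "] ms extends beyond the wave (",
         round(min(diff$times_ms)), " to ", round(max(diff$times_ms)),
         " ms).", call. = FALSE)
  }
  ch <- match(channel, diff$chan$name)
  if (is.na(ch)) stop("Channel ", channel, " not found.", call. = FALSE)
  v <- diff$data[ch, ]
  t <- diff$times_ms

  passes_topo <- function(i) {
    if (is.null(rois)) return(TRUE)
    fc <- roi_window_mean(diff, rois$frontocentral, t[i], halfwidth_ms)
    cp <- roi_window_mean(diff, rois$centroparietal, t[i], halfwidth_ms)
    fc < cp
  }
  search <- function(window) {
    in_win <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
    cand <- intersect(local_minima(v), in_win)
    if (length(cand) == 0) return(NULL)
    cand <- cand[order(v[cand], t[cand])]    # most negative, then earlier
    for (i in cand) if (passes_topo(i)) return(i)
    NULL
  }

  i <- search(primary)
  window_used <- "primary"
  qc_flag <- FALSE
  if (is.null(i)) {
    i <- search(fallback)
    window_used <- "fallback"
  }
  if (is.null(i)) {
    in_fb <- which(t >= fallback[1] - 1e-9 & t <= fallback[2] + 1e-9)
    i <- in_fb[order(v[in_fb], t[in_fb])][1]
    qc_flag <- TRUE
  }
  tibble::tibble(latency_ms = t[i], amplitude_uv = v[i],
                 window_used = window_used, qc_flag = qc_flag)
}

#' Mean amplitudes around the MMN peak, per electrode and ROI
#'
#' Averages the standard and deviant waves over the 2 x `halfwidth_ms`
#' window centered at the FCz-derived peak latency (13 samples at 250 Hz,
#' endpoints included), separately per electrode, and summarizes the
#' frontocentral and centroparietal ROIs as the mean of their member
#' electrodes. FCz itself is part of the frontocentral ROI by default.
#'
#' @param std,dev `erp_wave` objects on the same grid.
#' @param peak_latency_ms FCz peak latency from [detect_mmn_peak()], ms.
#' @param halfwidth_ms Averaging half-width, ms.
#' @param rois ROI definition ([mmn_rois()]).
#' @param include_peak_channel Keep FCz inside the frontocentral ROI mean.
#' @return A tibble with one row per electrode and per ROI: `label`, `kind`
#'   (`"electrode"`/`"roi"`), `standard_uv`, `deviant_uv`, `difference_uv`.
#' @export
mean_amplitudes <- function(std, dev, peak_latency_ms, halfwidth_ms = 24,
                            rois = mmn_rois(), include_peak_channel = TRUE) {
  if (peak_latency_ms - halfwidth_ms < min(std$times_ms) - 1e-9 ||
      peak_latency_ms + halfwidth_ms > max(std$times_ms) + 1e-9) {
    stop("Peak window ", peak_latency_ms, " +/- ", halfwidth_ms,
         " ms extends beyond the wave.", call. = FALSE)
  }
  idx <- which(std$times_ms >= peak_latency_ms - halfwidth_ms - 1e-9 &
                 std$times_ms <= peak_latency_ms + halfwidth_ms + 1e-9)
  per_el <- tibble::tibble(
    label = std$chan$name,
    kind = "electrode",
    standard_uv = unname(rowMeans(std$data[, idx, drop = FALSE])),
    deviant_uv = unname(rowMeans(dev$data[, idx, drop = FALSE])))
  if (!include_peak_channel) {
    rois$frontocentral <- setdiff(rois$frontocentral, "FCz")
  }
  roi_rows <- purrr::imap_dfr(rois, function(els, nm) {
    miss <- setdiff(els, per_el$label)
    if (length(miss) > 0) {
      stop("ROI electrode(s) missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    sel <- per_el[match(els, per_el$label), ]
    tibble::tibble(label = nm, kind = "roi",
                   standard_uv = mean(sel$standard_uv),
                   deviant_uv = mean(sel$deviant_uv))
  })
  dplyr::mutate(dplyr::bind_rows(per_el, roi_rows),
                difference_uv = .data$deviant_uv - .data$standard_uv)
}

#' Grand-average of ERP waves
#'
#' Pointwise mean over a list of `erp_wave` objects on identical grids
#' (e.g. per-subject difference waves).
#'
#' @param waves List of `erp_wave` objects.
#' @return An `erp_wave`; `n_trials` is the number of waves averaged.
#' @export
grand_average <- function(waves) {
  stopifnot(length(waves) > 0)
  out <- waves[[1]]
  acc <- out$data
  for (w in waves[-1]) {
    stopifnot(identical(dim(w$data), dim(acc)))
    acc <- acc + w$data
  }
  out$data <- acc / length(waves)
  out$n_trials <- length(waves)
  out
}

#' @export
print.erp_wave <- function(x, ...) {
  cat("<erp_wave> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples (", round(min(x$times_ms)), " to ", round(max(x$times_ms)),
      " ms re deviation onset), n = ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

#' Plot an ERP wave
#'
#' Line plot of one or more channels of an `erp_wave` over time, with the
#' deviation onset marked at 0 ms. Negative is plotted upward, following
#' ERP convention.
#'
#' @param object An `erp_wave`.
#' @param channels Channels to draw (default FCz if present, else all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erp_wave <- function(object, channels = NULL, ...) {
  if (is.null(channels)) {
    channels <- if ("FCz" %in% object$chan$name) "FCz" else object$chan$name
  }
  sel <- t(object$data[match(channels, object$chan$name), , drop = FALSE])
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time_ms = object$times_ms),
                     tibble::as_tibble(sel, .name_repair = ~channels)),
    -"time_ms", names_to = "channel", values_to = "amplitude_uv")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uv,
                                   colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time re deviation onset (ms)",
                  y = "Amplitude (µV, negative up)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
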
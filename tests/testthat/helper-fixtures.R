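# shared fixtures, all generated in code

default_deviants <- c(FD = "NOTkal", TD = "notSAL")

small_counts <- c(SD = 80L, FD = 8L, TD = 8L)

small_sequence <- function(seed = 3L, counts = small_counts,
                           balanced = TRUE) {
  generate_condition_sequence("NOTsal", default_deviants, counts = counts,
                              seed = seed, balanced = balanced)
}

# raw object wrapping an arbitrary matrix, with minimal channel metadata
raw_from_matrix <- function(data, srate_hz = 1000, types = NULL,
                            events = NULL) {
  n_ch <- nrow(data)
  if (is.null(types)) types <- rep("scalp", n_ch)
  nm <- if (is.null(rownames(data))) paste0("ch", seq_len(n_ch))
        else rownames(data)
  rownames(data) <- nm
  if (is.null(events)) {
    events <- tibble::tibble(index = integer(), onset_ms = numeric(),
                             stimulus = character(), role = character(),
                             condition = character(), token = integer(),
                             sample = integer())
  }
  mmnpipe:::new_eeg_raw(data = data, srate_hz = srate_hz,
                        chan = tibble::tibble(name = nm, type = types,
                                              x = 0, y = 0),
                        events = events, reference = "Fpz")
}

noiseless_config <- function(srate_hz = 1000, montage = scaled_montage(),
                             ...) {
  sim_config(srate_hz = srate_hz, montage = montage, pink_sd_uv = 0,
             line_amp_uv = 0, blink_rate_per_min = 0, ...)
}

# synthetic erp_wave on the 250 Hz epoch grid, re-locked by `offset_ms`;
# `fcz` gives the FCz trace, `cp_scale` scales the centroparietal channels
wave_from_trace <- function(fcz, offset_ms = 250, srate_hz = 250,
                            cp_scale = 0.5,
                            rois = mmn_rois(scaled = TRUE)) {
  chn <- unique(c("FCz", rois$frontocentral, rois$centroparietal))
  data <- matrix(rep(fcz, each = length(chn)), nrow = length(chn))
  cp <- chn %in% rois$centroparietal
  data[cp, ] <- data[cp, ] * cp_scale
  rownames(data) <- chn
  structure(list(
    data = data,
    times_ms = seq(-100, by = 1000 / srate_hz,
                   length.out = length(fcz)) - offset_ms,
    srate_hz = srate_hz,
    chan = tibble::tibble(name = chn, type = "scalp", x = 0, y = 0),
    n_trials = 1L, lock_offset_ms = offset_ms, cell = NULL),
    class = "erp_wave")
}

# epochs stub carrying only metadata, enough for trial selection logic
epochs_stub <- function(seq, kept = rep(TRUE, nrow(seq))) {
  list(metadata = tibble::tibble(kept = kept))
}

# amplitude spectrum of a single frequency (integer-cycle grid)
fft_amplitude <- function(v, freq_hz, srate_hz) {
  n <- length(v)
  2 * abs(stats::fft(v))[freq_hz * n / srate_hz + 1] / n
}

# brute-force oracle: cell-means GLM with subject blocking via aov Error strata
aov_oracle <- function(tbl, dv, factors) {
  for (f in factors) tbl[[f]] <- factor(tbl[[f]])
  tbl$subject <- factor(tbl$subject)
  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    paste(dv, "~", rhs, "+ Error(subject/(", rhs, "))"))
  fit <- summary(stats::aov(form, data = tbl))
  out <- list()
  for (stratum in fit) {
    s <- stratum[[1]]
    rn <- trimws(rownames(s))
    for (i in seq_along(rn)) {
      if (rn[i] != "Residuals") out[[rn[i]]] <- s[i, "F value"]
    }
  }
  out
}

random_cell_table <- function(n_subj, factors, seed) {
  withr::with_seed(seed, {
    lev <- stats::setNames(lapply(factors, function(f) c("a", "b")), factors)
    tbl <- tidyr::expand_grid(subject = seq_len(n_subj), !!!lev)
    tbl$value <- stats::rnorm(nrow(tbl))
    tbl
  })
}

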
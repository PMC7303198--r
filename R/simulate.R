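#' Simulation configuration
#'
#' Assembles and validates the free parameters of the synthetic-EEG
#' generator: sampling rate, montage, per-cell MMN ground truth (amplitude
#' and latency of the mismatch deflection for every phonotactic-probability
#' x syllable-stress x deviant-type cell), obligatory N1/P2 responses locked
#' to syllable onsets, the frontocentral topography, and the noise model
#' (pink background noise, 50 Hz line noise, ocular blinks).
#'
#' Ground-truth MMN latencies are expressed in ms after the deviation onset
#' (the /t/-onset for formal deviants, stimulus onset for temporal deviants)
#' and must fall inside the fallback peak-search windows (80-300 ms formal,
#' 120-370 ms temporal).
#'
#' @param srate_hz Sampling rate (Hz). Must exceed twice the 70 Hz analysis
#'   band edge.
#' @param montage Montage tibble ([default_montage()] or [scaled_montage()]).
#' @param mmn Tibble with columns `role` (`"FD"`/`"TD"`), `phonprob`,
#'   `sylstr`, `amplitude_uv` (negative), `latency_ms`. Default: formal
#'   deviants peak at 160 ms (HPP) vs 200 ms (LPP) with amplitudes -2.5 /
#'   -3.0 uV (earlier response and somewhat smaller deflection for the
#'   high-probability cluster); temporal deviants peak at 250 ms with
#'   -2.8 uV (first-syllable stress) / -2.3 uV (second-syllable stress).
#' @param mmn_fwhm_ms Full width at half maximum of the Gaussian mismatch
#'   deflection.
#' @param obligatory Tibble with columns `component`, `amplitude_uv`,
#'   `latency_ms`, `fwhm_ms`; each component is emitted after every syllable
#'   onset. Defaults: N1 -4 uV at 100 ms, P2 +3 uV at 200 ms.
#' @param syllable_onsets_ms Onsets of the two syllables within the 600 ms
#'   stimulus (second syllable at 300 ms).
#' @param topo_falloff Spatial scale of the frontocentral weight map
#'   ([topography_weights()]).
#' @param mastoid_weight Topography weight at the mastoids (0 keeps the
#'   average-mastoid reference neutral).
#' @param pink_sd_uv Per-channel pink-noise standard deviation (uV).
#' @param line_amp_uv 50 Hz line-noise amplitude (uV).
#' @param blink_rate_per_min Mean ocular blink rate.
#' @param blink_amp_uv Blink amplitude at the upper vertical EOG channel.
#' @param seed Default seed for [simulate_subject()].
#' @param stimuli Stimulus table ([stimulus_set()]).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(srate_hz = 1000,
                       montage = default_montage(),
                       mmn = NULL,
                       mmn_fwhm_ms = 60,
                       obligatory = NULL,
                       syllable_onsets_ms = c(0, 300),
                       topo_falloff = 2.5,
                       mastoid_weight = 0,
                       pink_sd_uv = 10,
                       line_amp_uv = 2,
                       blink_rate_per_min = 12,
                       blink_amp_uv = 150,
                       seed = 1L,
                       stimuli = stimulus_set()) {
  if (srate_hz <= 2 * 70) {
    stop("`srate_hz` must exceed twice the 70 Hz analysis band edge.",
         call. = FALSE)
  }
  if (is.null(mmn)) {
    mmn <- tidyr::expand_grid(role = c("FD", "TD"),
                              phonprob = c("HPP", "LPP"),
                              sylstr = c("SylStr1", "SylStr2"))
    mmn$amplitude_uv <- ifelse(mmn$role == "FD",
                               ifelse(mmn$phonprob == "HPP", -2.5, -3.0),
                               ifelse(mmn$sylstr == "SylStr1", -2.8, -2.3))
    mmn$latency_ms <- ifelse(mmn$role == "FD",
                             ifelse(mmn$phonprob == "HPP", 160, 200),
                             250)
  }
  fb <- peak_windows()
  for (i in seq_len(nrow(mmn))) {
    w <- if (mmn$role[i] == "FD") fb$formal$fallback else fb$temporal$fallback
    if (mmn$latency_ms[i] < w[1] || mmn$latency_ms[i] > w[2]) {
      stop("MMN latency for cell ", mmn$role[i], "/", mmn$phonprob[i], "/",
           mmn$sylstr[i], " (", mmn$latency_ms[i],
           " ms) lies outside the fallback search window [", w[1], ", ",
           w[2], "] ms.", call. = FALSE)
    }
  }
  if (is.null(obligatory)) {
    obligatory <- tibble::tibble(
      component = c("N1", "P2"),
      amplitude_uv = c(-4, 3),
      latency_ms = c(100, 200),
      fwhm_ms = c(50, 80))
  }
  w <- topography_weights(montage, peak = "FCz", falloff = topo_falloff,
                          mastoid_weight = mastoid_weight)
  structure(list(
    srate_hz = srate_hz, montage = montage, mmn = mmn,
    mmn_fwhm_ms = mmn_fwhm_ms, obligatory = obligatory,
    syllable_onsets_ms = syllable_onsets_ms,
    topo_weights = w, pink_sd_uv = pink_sd_uv, line_amp_uv = line_amp_uv,
    blink_rate_per_min = blink_rate_per_min, blink_amp_uv = blink_amp_uv,
    seed = as.integer(seed), stimuli = stimuli
  ), class = "sim_config")
}

#' Ground-truth MMN table of a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return Tibble with one row per phonprob x sylstr x deviant-type cell:
#'   `role`, `phonprob`, `sylstr`, `amplitude_uv`, `latency_ms`.
#' @export
ground_truth_table <- function(cfg) {
  tibble::as_tibble(cfg$mmn)
}

gauss_bump <- function(t_ms, center_ms, fwhm_ms) {
  s <- fwhm_ms / (2 * sqrt(2 * log(2)))
  exp(-(t_ms - center_ms)^2 / (2 * s^2))
}

# per-trial source template (1 x trial samples) for a given role/stimulus
trial_template <- function(cfg, role, stim_row, trial_samp) {
  t_ms <- (seq_len(trial_samp) - 1) / cfg$srate_hz * 1000
  src <- numeric(trial_samp)
  for (syl in cfg$syllable_onsets_ms) {
    for (i in seq_len(nrow(cfg$obligatory))) {
      ob <- cfg$obligatory[i, ]
      src <- src + ob$amplitude_uv *
        gauss_bump(t_ms, syl + ob$latency_ms, ob$fwhm_ms)
    }
  }
  if (role %in% c("FD", "TD")) {
    cell <- cfg$mmn[cfg$mmn$role == role &
                      cfg$mmn$phonprob == stim_row$phonprob &
                      cfg$mmn$sylstr == stim_row$sylstr, ]
    dev_on <- if (role == "FD") stim_row$deviation_onset_formal_ms
              else stim_row$deviation_onset_temporal_ms
    src <- src + cell$amplitude_uv *
      gauss_bump(t_ms, dev_on + cell$latency_ms, cfg$mmn_fwhm_ms)
  }
  src
}

# 1/f-power noise synthesized directly in the frequency domain: random
# Hermitian spectrum with amplitude 1/sqrt(f), one inverse FFT per batch
pink_noise_matrix <- function(n_samp, n_ch, sd_uv) {
  if (sd_uv == 0 || n_ch == 0) return(matrix(0, n_samp, n_ch))
  half <- (n_samp - 1) %/% 2
  amp <- 1 / sqrt(seq_len(half))
  re <- matrix(stats::rnorm(half * n_ch), half, n_ch) * amp
  im <- matrix(stats::rnorm(half * n_ch), half, n_ch) * amp
  pos <- matrix(complex(real = re, imaginary = im), half, n_ch)
  nyq <- if (n_samp %% 2 == 0) {
    matrix(complex(real = stats::rnorm(n_ch) / sqrt(half + 1)), 1, n_ch)
  } else NULL
  spec <- rbind(matrix(0 + 0i, 1, n_ch), pos, nyq,
                Conj(pos[rev(seq_len(half)), , drop = FALSE]))
  pink <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samp
  sds <- sqrt(colMeans(pink^2) - colMeans(pink)^2)
  sweep(pink, 2, sd_uv / sds, `*`)
}

blink_train <- function(n_samp, srate_hz, rate_per_min) {
  dur_min <- n_samp / srate_hz / 60
  n_blinks <- stats::rpois(1, rate_per_min * dur_min)
  b <- numeric(n_samp)
  if (n_blinks == 0) return(b)
  width <- round(0.4 * srate_hz)          # 400 ms raised-cosine blink
  tmpl <- 0.5 * (1 - cos(2 * pi * seq_len(width) / width))
  starts <- sort(sample.int(max(n_samp - width, 1), n_blinks, replace = TRUE))
  for (s in starts) {
    idx <- s:(s + width - 1)
    b[idx] <- b[idx] + tmpl
  }
  b
}

# blink propagation to scalp decays from the front of the head
blink_propagation <- function(montage) {
  p <- numeric(nrow(montage))
  sc <- montage$type == "scalp"
  p[sc] <- 0.35 * exp(-((4 - montage$y[sc]) / 3)^2)
  p[montage$name == "VEOG_U"] <- 1
  p[montage$name == "VEOG_D"] <- -0.6
  p[montage$name %in% c("HEOG_L", "HEOG_R")] <- 0.15
  p
}

#' Simulate one participant's continuous EEG for an oddball sequence
#'
#' For every trial the scalp signal is the frontocentral-topography-weighted
#' sum of obligatory N1/P2 responses locked to the two syllable onsets plus,
#' on deviant trials, a negative Gaussian mismatch deflection centered at
#' the deviation onset plus the cell's true latency. Pink background noise,
#' 50 Hz line noise and ocular blinks (projected onto EOG and frontal scalp
#' channels) are added on top. The result is reproducible given `seed`.
#'
#' @param seq An `oddball_sequence` ([generate_condition_sequence()]).
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed`).
#'
#' @return An `eeg_raw` object: list with `data` (channels x samples matrix,
#'   uV), `srate_hz`, `chan` (montage tibble), `events` (trial table with
#'   1-based `sample` indices), `reference` (recording reference label) and
#'   `ground_truth`.
#' @export
simulate_subject <- function(seq, cfg = sim_config(), seed = cfg$seed) {
  td_ms <- attr(seq, "trial_duration_ms") %||% 1200
  trial_samp <- round(td_ms / 1000 * cfg$srate_hz)
  n_trials <- nrow(seq)
  n_samp <- n_trials * trial_samp
  mont <- cfg$montage
  n_ch <- nrow(mont)

  withr::with_seed(seed, {
    # source signal: one template per (role, stimulus), tiled over trials
    keys <- unique(paste(seq$role, seq$stimulus))
    tmpl <- lapply(keys, function(k) {
      parts <- strsplit(k, " ")[[1]]
      stim_row <- cfg$stimuli[cfg$stimuli$id == parts[2], ]
      if (nrow(stim_row) != 1) {
        stop("Stimulus ", parts[2], " not found in the configuration.",
             call. = FALSE)
      }
      trial_template(cfg, parts[1], stim_row, trial_samp)
    })
    names(tmpl) <- keys
    src_mat <- matrix(0, trial_samp, n_trials)
    key_per_trial <- paste(seq$role, seq$stimulus)
    for (k in keys) {
      src_mat[, key_per_trial == k] <- tmpl[[k]]
    }
    source <- as.vector(src_mat)

    data <- tcrossprod(cfg$topo_weights, source)   # n_ch x n_samp

    if (cfg$pink_sd_uv > 0) {
      data <- data + t(pink_noise_matrix(n_samp, n_ch, cfg$pink_sd_uv))
    }
    if (cfg$line_amp_uv > 0) {
      tt <- (seq_len(n_samp) - 1) / cfg$srate_hz
      data <- data + rep(cfg$line_amp_uv, n_ch) %o%
        sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
    }
    if (cfg$blink_rate_per_min > 0 && cfg$blink_amp_uv > 0) {
      b <- blink_train(n_samp, cfg$srate_hz, cfg$blink_rate_per_min)
      if (any(b != 0)) {
        data <- data + (cfg$blink_amp_uv * blink_propagation(mont)) %o% b
      }
    }
    rownames(data) <- mont$name

    events <- tibble::as_tibble(seq)
    events$sample <- round(events$onset_ms / 1000 * cfg$srate_hz) + 1L

    new_eeg_raw(data = data, srate_hz = cfg$srate_hz, chan = mont,
                events = events, reference = "Fpz",
                ground_truth = ground_truth_table(cfg))
  })
}

new_eeg_raw <- function(data, srate_hz, chan, events, reference,
                        ground_truth = NULL) {
  stopifnot(nrow(data) == nrow(chan), !anyDuplicated(chan$name))
  if (nrow(events) > 0) {
    stopifnot(all(diff(events$sample) > 0),
              all(events$sample >= 1), all(events$sample <= ncol(data)))
  }
  structure(list(data = data, srate_hz = srate_hz, chan = chan,
                 events = events, reference = reference,
                 ground_truth = ground_truth),
            class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat("<eeg_raw> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate_hz, " Hz (",
      round(ncol(x$data) / x$srate_hz, 1), " s), ",
      nrow(x$events), " events, reference: ", x$reference, "\n", sep = "")
  invisible(x)
}
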
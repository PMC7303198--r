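test_that("averaging identical trials reproduces a single trial", {
  seq <- small_sequence()
  raw <- simulate_subject(seq, noiseless_config(srate_hz = 250), seed = 1)
  ep <- epoch_raw(raw)
  sd_trials <- which(seq$role == "SD" & ep$metadata$kept)
  avg <- timelock_average(ep, sd_trials, lock_offset_ms = 250)
  one <- timelock_average(ep, sd_trials[1], lock_offset_ms = 250)
  expect_equal(avg$data, one$data, tolerance = 1e-12)
  expect_equal(avg$times_ms[1], -350)
  expect_equal(avg$n_trials, length(sd_trials))
  expect_error(timelock_average(ep, integer(0)), "Empty trial selection")
})

test_that("deviation-onset lock offsets follow the stimulus timing", {
  st <- stimulus_set()
  expect_true(all(st$deviation_onset_formal_ms == 250))
  expect_true(all(st$deviation_onset_temporal_ms == 0))
})

test_that("difference waves subtract pointwise and respect identity", {
  v <- rnorm(275)
  a <- wave_from_trace(v)
  b <- wave_from_trace(v)
  expect_equal(max(abs(difference_wave(a, b)$data)), 0)
  # shift-invariance: difference of (a+c, b+c) equals difference of (a, b)
  d <- wave_from_trace(rnorm(275))
  a2 <- a; a2$data <- a$data + 3
  d2 <- d; d2$data <- d$data + 3
  expect_equal(difference_wave(a2, d2)$data, difference_wave(a, d)$data,
               tolerance = 1e-12)
  bad <- a
  bad$cell <- list(stimulus = "NOTsal")
  good <- b
  good$cell <- list(stimulus = "NOTkal")
  expect_error(difference_wave(bad, good), "identical stimuli")
})

test_that("the noiseless difference wave returns the simulator's template", {
  seq <- small_sequence()
  raw <- simulate_subject(seq, noiseless_config(srate_hz = 250), seed = 1)
  ep <- baseline_and_reject(epoch_raw(raw))
  ep <- rereference_mastoids(ep)
  ok <- ep$metadata$kept
  fd <- which(seq$role == "FD" & ok)
  sd <- which(seq$role == "SD" & ok)
  dev_w <- timelock_average(ep, fd, 250)
  std_w <- timelock_average(ep, sd, 250)
  dw <- difference_wave(dev_w, std_w)
  fcz <- dw$data[match("FCz", dw$chan$name), ]
  cfg <- noiseless_config(srate_hz = 250)
  cell <- cfg$mmn[cfg$mmn$role == "FD" & cfg$mmn$phonprob == "LPP" &
                    cfg$mmn$sylstr == "SylStr1", ]
  s <- 60 / (2 * sqrt(2 * log(2)))
  tmpl <- cell$amplitude_uv * exp(-(dw$times_ms - cell$latency_ms)^2 /
                                    (2 * s^2))
  expect_equal(fcz, tmpl, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("peak detection finds a single constructed dip", {
  t <- seq(-350, by = 4, length.out = 275)
  v <- -1.5 * exp(-(t - 180)^2 / (2 * 25^2))
  pk <- detect_mmn_peak(wave_from_trace(v), rois = mmn_rois(scaled = TRUE))
  # oracle: argmin of the constructed wave
  expect_equal(pk$latency_ms, t[which.min(v)])
  expect_lte(abs(pk$latency_ms - 180), 4)
  expect_equal(pk$window_used, "primary")
  expect_false(pk$qc_flag)
})

test_that("the most negative passing local minimum wins, ties to earlier", {
  t <- seq(-350, by = 4, length.out = 275)
  v <- -1 * exp(-(t - 150)^2 / (2 * 15^2)) - 2 * exp(-(t - 250)^2 / (2 * 15^2))
  pk <- detect_mmn_peak(wave_from_trace(v), rois = mmn_rois(scaled = TRUE))
  expect_equal(pk$latency_ms, t[which.min(abs(t - 250))])
  vtie <- -exp(-(t - 150)^2 / (2 * 15^2)) - exp(-(t - 250)^2 / (2 * 15^2))
  pk2 <- detect_mmn_peak(wave_from_trace(vtie), rois = mmn_rois(scaled = TRUE))
  expect_lt(abs(pk2$latency_ms - 150), 5)
})

test_that("a monotone wave falls back to the window-edge minimum with a QC flag", {
  t <- seq(-350, by = 4, length.out = 275)
  v <- -0.01 * t
  pk <- detect_mmn_peak(wave_from_trace(v), rois = mmn_rois(scaled = TRUE))
  expect_true(pk$qc_flag)
  # decreasing wave: minimum sits at the late edge of the fallback window
  expect_equal(pk$latency_ms,
               max(t[t <= peak_windows()$formal$fallback[2]]))
})

test_that("candidates failing the topography check defer to the fallback window", {
  t <- seq(-350, by = 4, length.out = 275)
  v <- -2 * exp(-(t - 200)^2 / (2 * 20^2))
  # centroparietal *more* negative than frontocentral: check must fail
  w <- wave_from_trace(v, cp_scale = 2)
  pk <- detect_mmn_peak(w, rois = mmn_rois(scaled = TRUE))
  expect_true(pk$qc_flag)
  pk2 <- detect_mmn_peak(w, rois = NULL)
  expect_false(pk2$qc_flag)
  expect_equal(pk2$window_used, "primary")
})

test_that("search windows outside the wave are rejected", {
  t <- seq(-90, by = 4, length.out = 80)
  w <- wave_from_trace(rnorm(80), offset_ms = 0)
  expect_error(detect_mmn_peak(w, primary = c(200, 350),
                               fallback = c(120, 370),
                               rois = NULL),
               "beyond the wave")
})

test_that("mean amplitudes average 13 samples around the peak", {
  t <- seq(-350, by = 4, length.out = 275)
  const <- wave_from_trace(rep(2.5, 275), cp_scale = 1)
  out <- mean_amplitudes(const, const, peak_latency_ms = 180,
                         rois = mmn_rois(scaled = TRUE))
  expect_true(all(abs(out$standard_uv - 2.5) < 1e-12))
  # linear ramp: the mean equals the value at the center latency
  ramp <- wave_from_trace(0.01 * t, cp_scale = 1)
  out2 <- mean_amplitudes(ramp, ramp, peak_latency_ms = 202,
                          rois = mmn_rois(scaled = TRUE))
  expect_equal(out2$deviant_uv[out2$label == "FCz"], 0.01 * 202,
               tolerance = 1e-9)
  # indicator wave: exactly the 13-sample window enters the average
  ind <- rep(0, 275)
  center <- which(t == 202)
  ind[center] <- 1
  spike <- wave_from_trace(ind, cp_scale = 1)
  out3 <- mean_amplitudes(spike, spike, peak_latency_ms = 202,
                          rois = mmn_rois(scaled = TRUE))
  expect_equal(out3$standard_uv[out3$label == "FCz"], 1 / 13,
               tolerance = 1e-12)
})

test_that("ROI means equal the mean of their member electrodes", {
  v <- rnorm(275)
  w <- wave_from_trace(v, cp_scale = 0.3)
  out <- mean_amplitudes(w, w, peak_latency_ms = 150,
                         rois = mmn_rois(scaled = TRUE))
  rois <- mmn_rois(scaled = TRUE)
  for (r in names(rois)) {
    members <- out$standard_uv[match(rois[[r]], out$label)]
    expect_equal(out$standard_uv[out$label == r], mean(members),
                 tolerance = 1e-12)
  }
  expect_error(mean_amplitudes(w, w, peak_latency_ms = 150,
                               rois = list(frontocentral = c("Fz", "NOPE"),
                                           centroparietal = "Cz")),
               "NOPE")
  expect_error(mean_amplitudes(w, w, peak_latency_ms = 990), "beyond")
})

test_that("excluding FCz from the frontocentral ROI is supported", {
  v <- rnorm(275)
  w <- wave_from_trace(v, cp_scale = 0.3)
  w$data[match("FCz", w$chan$name), ] <- 10
  incl <- mean_amplitudes(w, w, 150, rois = mmn_rois(scaled = TRUE))
  excl <- mean_amplitudes(w, w, 150, rois = mmn_rois(scaled = TRUE),
                          include_peak_channel = FALSE)
  expect_gt(incl$standard_uv[incl$label == "frontocentral"],
            excl$standard_uv[excl$label == "frontocentral"])
})

test_that("the grand average equals the mean of per-subject waves", {
  waves <- lapply(1:3, function(i) wave_from_trace(rnorm(275)))
  ga <- grand_average(waves)
  manual <- (waves[[1]]$data + waves[[2]]$data + waves[[3]]$data) / 3
  expect_equal(ga$data, manual, tolerance = 1e-12)
  expect_equal(ga$n_trials, 3L)
})

test_that("erp autoplot returns a ggplot", {
  w <- wave_from_trace(rnorm(275))
  expect_s3_class(autoplot(w), "ggplot")
})
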
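test_that("high-pass removes constant offsets", {
  x <- matrix(7.5, 2, 8000)
  out <- filter_continuous(raw_from_matrix(x))
  expect_lt(max(abs(rowMeans(out$data))), 0.01)
  expect_lt(max(abs(out$data)), 0.01)
})

test_that("line frequency is notched and the pass band preserved", {
  t <- (0:19999) / 1000
  x <- rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t))
  for (m in c("fft", "iir")) {
    out <- filter_continuous(raw_from_matrix(x), method = m)
    a50 <- fft_amplitude(out$data[1, ], 50, 1000)
    a10 <- fft_amplitude(out$data[2, ], 10, 1000)
    expect_lt(20 * log10(a50 / 1), -20)       # >= 20 dB attenuation
    expect_gt(a10, 0.95)
    expect_lt(a10, 1.05)
  }
})

test_that("frequency-domain and forward-backward realizations agree", {
  withr::with_seed(11, {
    x <- matrix(rnorm(6000), 1, 6000)
  })
  a <- filter_continuous(raw_from_matrix(x), method = "fft")
  b <- filter_continuous(raw_from_matrix(x), method = "iir")
  mid <- 1500:4500
  expect_gt(stats::cor(a$data[1, mid], b$data[1, mid]), 0.95)
})

test_that("zero-phase filtering does not shift a symmetric pulse", {
  v <- exp(-((0:9999) - 5000)^2 / (2 * 40^2))
  out <- filter_continuous(raw_from_matrix(matrix(v, 1)), notch = NULL)
  expect_equal(which.max(out$data[1, ]), 5001, tolerance = 1)
})

test_that("band edges at or above Nyquist are rejected", {
  raw <- raw_from_matrix(matrix(0, 1, 1000), srate_hz = 100)
  expect_error(filter_continuous(raw, band = c(0.5, 60)), "Nyquist")
  expect_error(filter_continuous(raw, band = c(0.5, 30), notch = c(49, 51)),
               "Nyquist")
})

test_that("downsampling keeps every fourth sample and rescales events", {
  ev <- tibble::tibble(index = 1:2, onset_ms = c(0, 11999),
                       stimulus = "NOTsal", role = "SD",
                       condition = "NOTsal", token = 1L,
                       sample = c(1L, 12000L))
  raw <- raw_from_matrix(matrix(rnorm(2 * 24000), 2), events = ev)
  out <- downsample_raw(raw, 250)
  expect_equal(ncol(out$data), 6000L)
  expect_equal(out$srate_hz, 250)
  expect_equal(out$events$sample, c(1L, 3000L))
  expect_error(downsample_raw(raw_from_matrix(matrix(0, 1, 100),
                                              srate_hz = 600), 250),
               "integer multiple")
})

test_that("a 10 Hz component survives filtering plus decimation", {
  t <- (0:23999) / 1000
  raw <- raw_from_matrix(matrix(sin(2 * pi * 10 * t), 1))
  out <- downsample_raw(filter_continuous(raw), 250)
  expect_equal(fft_amplitude(out$data[1, ], 10, 250), 1, tolerance = 0.05)
})

test_that("epoching yields the documented half-open window", {
  seq <- small_sequence()
  raw <- simulate_subject(seq, noiseless_config(srate_hz = 250), seed = 1)
  ep <- epoch_raw(raw)
  expect_equal(dim(ep$data), c(nrow(seq), 16L, 275L))
  expect_equal(ep$times_ms[1], -100)
  expect_equal(ep$times_ms[275], 996)
  expect_equal(nrow(ep$metadata), nrow(seq))
  # the first event starts at the first sample: no pre-stimulus window
  expect_false(ep$metadata$kept[1])
  expect_equal(ep$metadata$reason[1], "edge")
  expect_true(all(ep$metadata$kept[-1]))
})

test_that("baseline correction zeroes the pre-stimulus mean on kept trials", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 5, line_amp_uv = 1, blink_rate_per_min = 0)
  raw <- simulate_subject(seq, cfg, seed = 2)
  ep <- baseline_and_reject(epoch_raw(raw))
  bl <- which(ep$times_ms >= -100 & ep$times_ms < 0)
  kept <- which(ep$metadata$kept)
  bl_means <- rowMeans(ep$data[kept, , bl, drop = FALSE], dims = 2)
  expect_lt(max(abs(bl_means)), 1e-9)
})

test_that("the amplitude criterion rejects exactly the constructed violations", {
  seq <- small_sequence()
  raw <- simulate_subject(seq, noiseless_config(srate_hz = 250), seed = 1)
  ep <- epoch_raw(raw)
  spike_trials <- c(5L, 12L)
  fz <- match("Fz", ep$chan$name)
  ep$data[spike_trials, fz, 150] <- 100
  # a mastoid/EOG excursion must not trigger the scalp criterion
  m1 <- match("M1", ep$chan$name)
  ep$data[20L, m1, 150] <- 500
  out <- baseline_and_reject(ep)
  expect_false(any(out$metadata$kept[spike_trials]))
  expect_equal(out$metadata$reason[spike_trials], c("amplitude", "amplitude"))
  expect_true(out$metadata$kept[20L])
  # noiseless signal stays far below 75 uV: nothing else rejected
  expect_equal(sum(!out$metadata$kept), 3L)  # 2 spikes + edge trial
})

test_that("rejection is monotone in the threshold", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 25, line_amp_uv = 0, blink_rate_per_min = 0)
  raw <- simulate_subject(seq, cfg, seed = 5)
  ep <- epoch_raw(raw)
  kept <- vapply(c(50, 75, 100),
                 function(th) sum(baseline_and_reject(ep, threshold_uv = th
                 )$metadata$kept), integer(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("mastoid re-referencing is invariant to added constants", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 3, line_amp_uv = 0, blink_rate_per_min = 0)
  raw <- simulate_subject(seq, cfg, seed = 3)
  ep <- epoch_raw(raw)
  ep2 <- ep
  ep2$data <- ep$data + 11.3
  a <- rereference_mastoids(ep)
  b <- rereference_mastoids(ep2)
  expect_equal(a$data, b$data, tolerance = 1e-10)
  m <- match(c("M1", "M2"), a$chan$name)
  expect_lt(max(abs((a$data[, m[1], ] + a$data[, m[2], ]) / 2)), 1e-10)
  expect_equal(a$reference, "average mastoids")
  ep$chan$name[m[1]] <- "XX"
  expect_error(rereference_mastoids(ep), "M1/M2")
})

test_that("re-referencing leaves scalp signal unchanged when mastoids are silent", {
  seq <- small_sequence()
  raw <- simulate_subject(seq, noiseless_config(srate_hz = 250), seed = 1)
  ep <- epoch_raw(raw)
  rr <- rereference_mastoids(ep)
  sc <- which(ep$chan$type == "scalp")
  expect_equal(rr$data[, sc, ], ep$data[, sc, ], tolerance = 1e-12)
})

test_that("EOG regression removes injected blink activity from frontal channels", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 4, line_amp_uv = 0,
                    blink_rate_per_min = 30, blink_amp_uv = 150)
  raw <- simulate_subject(seq, cfg, seed = 8)
  fz <- match("Fz", raw$chan$name)
  veog <- match("VEOG_U", raw$chan$name)
  r_before <- stats::cor(raw$data[fz, ], raw$data[veog, ])
  expect_gte(r_before, 0.6)
  out <- remove_ocular_artifacts(raw, method = "eog_regression")
  r_after <- stats::cor(out$raw$data[fz, ], raw$data[veog, ])
  expect_lte(abs(r_after), 0.2)
})

test_that("automatic ICA flags and removes blink components", {
  seq <- small_sequence(seed = 2)
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 4, line_amp_uv = 0,
                    blink_rate_per_min = 40, blink_amp_uv = 150)
  raw <- filter_continuous(simulate_subject(seq, cfg, seed = 9))
  fz <- match("Fz", raw$chan$name)
  veog_trace <- raw$data[match("VEOG_U", raw$chan$name), ]
  expect_gte(stats::cor(raw$data[fz, ], veog_trace), 0.6)
  out <- remove_ocular_artifacts(raw, method = "ica_auto", seed = 1)
  expect_equal(out$report$n_components, 16L)
  expect_gte(out$report$n_removed, 1L)
  r_after <- stats::cor(out$raw$data[fz, ], veog_trace)
  expect_lte(abs(r_after), 0.2)
})

test_that("ICA reports one component per channel on the full montage", {
  n_ch <- nrow(default_montage())
  expect_equal(n_ch, 63L)
  cfg <- sim_config(srate_hz = 250, pink_sd_uv = 4, line_amp_uv = 0,
                    blink_rate_per_min = 20)
  seq <- generate_condition_sequence("NOTsal", default_deviants,
                                     counts = c(SD = 30L, FD = 8L, TD = 8L),
                                     seed = 1, balanced = FALSE)
  raw <- simulate_subject(seq, cfg, seed = 10)
  out <- remove_ocular_artifacts(raw, method = "ica_auto", seed = 1)
  expect_equal(out$report$n_components, 63L)
})

test_that("blink-free recordings pass through ocular removal almost unchanged", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 250, montage = scaled_montage(),
                    pink_sd_uv = 4, line_amp_uv = 0, blink_rate_per_min = 0)
  raw <- filter_continuous(simulate_subject(seq, cfg, seed = 4))
  out <- remove_ocular_artifacts(raw, method = "eog_regression")
  sc <- which(raw$chan$type == "scalp")
  for (ch in sc) {
    expect_gte(stats::cor(out$raw$data[ch, ], raw$data[ch, ]), 0.99)
  }
  none <- remove_ocular_artifacts(raw, method = "none")
  expect_identical(none$raw$data, raw$data)
  few <- raw_from_matrix(matrix(rnorm(4 * 1000), 4), srate_hz = 250,
                         types = c("scalp", "scalp", "scalp", "eog"))
  expect_error(remove_ocular_artifacts(few, method = "ica_auto"),
               "at least 8")
})

test_that("the full preprocessing chain runs in the documented order", {
  seq <- small_sequence()
  cfg <- sim_config(srate_hz = 1000, montage = scaled_montage(),
                    pink_sd_uv = 5, line_amp_uv = 2, blink_rate_per_min = 0)
  raw <- simulate_subject(seq, cfg, seed = 6)
  res <- preprocess_raw(raw)
  expect_s3_class(res$epochs, "eeg_epochs")
  expect_equal(res$epochs$srate_hz, 250)
  expect_equal(dim(res$epochs$data)[3], 275L)
  expect_equal(res$epochs$reference, "average mastoids")
})
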
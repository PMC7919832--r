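test_that("click pulse has the right length, peak frequency and narrowness", {
  w <- generate_click_waveform(125e3, 100e-6, 576000, 1)
  expect_length(w, 58)

  spec <- Mod(stats::fft(w))[1:(length(w) %/% 2 + 1)]
  f_argmax <- (which.max(spec) - 1) * 576000 / length(w)
  expect_gte(f_argmax, 125e3 * 0.95)
  expect_lte(f_argmax, 125e3 * 1.05)

  # -3 dB bandwidth from a zero-padded spectrum; Q = peak / bandwidth >= 5
  wp <- c(w, numeric(8192 - length(w)))
  sp <- Mod(stats::fft(wp))[1:4097]
  fs <- (0:4096) * 576000 / 8192
  above <- fs[sp >= max(sp) / sqrt(2)]
  q <- 125e3 / (max(above) - min(above))
  expect_gte(q, 5)

  # both NBHF band edges pass the in-band check
  for (f0 in c(87e3, 145e3)) {
    w2 <- generate_click_waveform(f0, 100e-6, 576000, 1)
    sp2 <- Mod(stats::fft(c(w2, numeric(8192 - length(w2)))))[1:4097]
    expect_lt(abs(fs[which.max(sp2)] - f0) / f0, 0.05)
  }
})

test_that("zero amplitude and Nyquist violations are handled", {
  w <- generate_click_waveform(125e3, 100e-6, 576000, amplitude = 0)
  expect_length(w, 58)
  expect_true(all(w == 0))
  expect_error(generate_click_waveform(300e3, 100e-6, 576000), "Nyquist")
})

test_that("click times are strictly increasing, train-structured, deterministic", {
  clicks <- generate_click_times(60, train_rate_per_min = 8, seed = 42)
  expect_true(all(diff(clicks$center_time) > 0))
  expect_true(all(clicks$center_time >= 0 & clicks$center_time < 60))
  expect_true(all(clicks$peak_frequency >= 87e3 & clicks$peak_frequency <= 145e3))
  for (tr in split(clicks, clicks$train_id)) {
    expect_gte(nrow(tr), 5)
    if (nrow(tr) > 1) expect_true(all(diff(tr$center_time) <= 0.200))
  }
  expect_identical(clicks, generate_click_times(60, train_rate_per_min = 8, seed = 42))
})

test_that("zero train rate yields an empty click list", {
  clicks <- generate_click_times(60, train_rate_per_min = 0, seed = 1)
  expect_equal(nrow(clicks), 0)
})

test_that("expected click count matches the train process parameters", {
  # 10 trains/min x exactly 20 clicks over 60 s => mean 200 clicks
  counts <- vapply(1:60, function(s) {
    nrow(generate_click_times(60, train_rate_per_min = 10,
                              clicks_per_train = c(20L, 20L), seed = s))
  }, numeric(1))
  # each draw is 20 * Poisson(10); the mean over 60 seeds has sd ~8.2
  expect_lt(abs(mean(counts) - 200), 30)
})

test_that("render keeps truth, hits the requested noise level, never clips", {
  clicks <- plant_clicks(100, clip_duration = 1.2, seed = 3)
  rec <- render_recording(clicks, 1.2, seed = 4)
  expect_identical(rec$truth, clicks)
  expect_length(rec$clip$samples, round(1.2 * 576000))
  expect_true(all(abs(rec$clip$samples) <= 1))
  expect_true(all(is.finite(rec$clip$samples)))

  noise <- render_recording(empty_click_table(), 1, noise_level_db = -40,
                            seed = 5)
  rms_db <- 20 * log10(sqrt(mean(noise$clip$samples^2)))
  expect_lt(abs(rms_db - (-40)), 0.5)
})

test_that("achieved in-band SNR matches the requested SNR within 1 dB", {
  one <- data.frame(center_time = 0.05, peak_frequency = 125e3,
                    duration = 100e-6, snr_db = 20, train_id = 1L)
  with_click <- render_recording(one, 0.1, noise_level_db = -40, seed = 6)
  noise_only <- render_recording(empty_click_table(), 0.1,
                                 noise_level_db = -40, seed = 6)
  pulse <- with_click$clip$samples - noise_only$clip$samples
  nz <- which(abs(pulse) > 0)
  p_click <- mean(pulse[nz]^2)
  p_noise_band <- 10^(-40 / 10) * (145e3 - 87e3) / (576000 / 2)
  achieved <- 10 * log10(p_click / p_noise_band)
  expect_lt(abs(achieved - 20), 1)
})

test_that("render rejects clicks outside the clip and rescales on overload", {
  bad <- data.frame(center_time = 2, peak_frequency = 125e3,
                    duration = 100e-6, snr_db = 20, train_id = 1L)
  expect_error(render_recording(bad, 1), "outside")
  hot <- data.frame(center_time = 0.05, peak_frequency = 125e3,
                    duration = 100e-6, snr_db = 90, train_id = 1L)
  expect_warning(res <- render_recording(hot, 0.1, noise_level_db = -10,
                                         seed = 1), "full scale")
  expect_true(all(abs(res$clip$samples) <= 1))
})

test_that("WAV files round-trip through the PCM16 writer/reader", {
  clicks <- plant_clicks(5, clip_duration = 0.3, seed = 8)
  rec <- render_recording(clicks, 0.3, seed = 8)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec$clip, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 576000)
  expect_length(back$samples, length(rec$clip$samples))
  expect_lt(max(abs(back$samples - rec$clip$samples)), 1 / 32767)
})
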
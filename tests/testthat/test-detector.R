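test_that("high-pass design meets its stopband and passband contract", {
  b <- design_highpass(detector_config(), 576000)
  expect_lte(filter_response_db(b, 40000), -40)       # <= half the cutoff
  expect_lt(abs(filter_response_db(b, 104000)), 1)    # 1.3x cutoff
  expect_lt(abs(filter_response_db(b, 120000)), 1)
  # Kaiser design window is symmetric => linear phase
  expect_equal(as.numeric(b), rev(as.numeric(b)), tolerance = 1e-12)
  expect_error(design_highpass(detector_config(cutoff = 300000), 576000),
               "Nyquist")
})

test_that("filtering attenuates low tones, passes high tones, preserves zeros", {
  sr <- 576000
  t <- (0:(sr / 10 - 1)) / sr
  b <- design_highpass(detector_config(), sr)
  low <- audio_clip(0.5 * sin(2 * pi * 10e3 * t), sr)
  high <- audio_clip(0.5 * sin(2 * pi * 120e3 * t), sr)
  rms <- function(clip) sqrt(mean(clip$samples^2))
  expect_lt(20 * log10(rms(highpass_filter(low, b)) / rms(low)), -40)
  expect_lt(abs(20 * log10(rms(highpass_filter(high, b)) / rms(high))), 1)

  zero <- audio_clip(numeric(2048), sr)
  expect_true(all(highpass_filter(zero, b)$samples == 0))
  expect_length(highpass_filter(high, b)$samples, length(high$samples))

  b2 <- design_highpass(detector_config(), 384000)
  expect_error(highpass_filter(high, b2), "designed for")
})

test_that("spectrogram geometry follows the frame-count and bin formulas", {
  cfg <- detector_config()
  sr <- 576000
  clip <- audio_clip(stats::rnorm(1024, sd = 0.01), sr)
  sp <- spectrogram(clip, cfg)
  expect_equal(ncol(sp$magnitude), 3)      # floor((1024-256)/256)
  expect_length(sp$frequencies, 257)       # nfft/2 + 1
  expect_equal(diff(sp$frequencies)[1], 1125)  # sr/nfft
  expect_true(all(sp$magnitude >= 0))

  tone <- audio_clip(sin(2 * pi * 100e3 * (0:8191) / sr), sr)
  spt <- spectrogram(tone, cfg)
  argmax <- apply(spt$magnitude, 2, which.max) - 1
  expect_true(all(argmax == round(100e3 / 1125)))

  expect_error(spectrogram(audio_clip(numeric(100), sr), cfg), "shorter")
})

test_that("frame runs merge into events per the merge_gap rule", {
  cfg <- detector_config()
  times <- (0:3) * 0.444e-3
  ev <- frames_to_clicks(c(FALSE, TRUE, TRUE, FALSE), times, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, mean(times[2:3]))

  labs <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ev2 <- frames_to_clicks(labs, (0:6) * 0.444e-3,
                          detector_config(merge_gap = 1))
  expect_equal(nrow(ev2), 2)
  ev3 <- frames_to_clicks(labs, (0:6) * 0.444e-3,
                          detector_config(merge_gap = 3))
  expect_equal(nrow(ev3), 1)

  expect_equal(nrow(frames_to_clicks(logical(0), numeric(0), cfg)), 0)
})

test_that("click density bins complete minutes and conserves events", {
  ev <- data.frame(time = seq(0, 59.5, length.out = 120))
  d <- click_density(ev, 60)
  expect_equal(d$click_count, 120L)

  expect_warning(d0 <- click_density(ev[0, , drop = FALSE], 45), "minute")
  expect_equal(nrow(d0), 0)

  ev2 <- data.frame(time = rep(0:9 * 60, each = 10) + seq(1, 55, length.out = 10))
  d2 <- click_density(ev2, 600)
  expect_equal(d2$click_count, rep(10L, 10))
  expect_equal(sum(d2$click_count), nrow(ev2))

  expect_equal(click_density(data.frame(time = numeric(0)), 120)$click_count,
               c(0L, 0L))
})

test_that("train segmentation follows the >=5-click / <=200 ms definition", {
  ev <- data.frame(time = c(0, 0.05, 0.10, 0.15, 0.20))
  tr <- segment_trains(ev)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$clicks), 5)
  expect_equal(tr[[1]]$icis, rep(0.05, 4))

  expect_length(segment_trains(data.frame(time = c(0, 0.05, 0.10, 0.15))), 0)

  # 10 clicks with a 250 ms break after the 5th: two separate trains
  t10 <- c(seq(0, 0.2, by = 0.05), 0.45 + seq(0, 0.2, by = 0.05))
  tr2 <- segment_trains(data.frame(time = t10))
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, function(x) all(x$icis <= 0.2), logical(1))))
})

test_that("train segmentation matches the brute-force oracle on random inputs", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(0:20, 1)
      times <- sort(stats::runif(n, 0, 3))
      got <- segment_trains(data.frame(time = times))
      want <- brute_force_trains(times)
      expect_length(got, length(want))
      for (k in seq_along(want)) {
        expect_equal(got[[k]]$clicks$time, times[want[[k]]])
      }
    }
  })
})
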
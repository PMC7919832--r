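#' Audio clip container
#'
#' A mono waveform with its sampling rate. Finless porpoise NBHF clicks peak
#' between 87 and 145 kHz, so clips meant to carry clicks need a sampling
#' rate of at least 290 kHz (Nyquist above 145 kHz); the recorder emulated
#' here sampled at 576 kHz.
#'
#' @param samples numeric vector of dimensionless amplitudes in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param start_time clip start in seconds (epoch within the study day).
#' @return an object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, start_time = 0) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1, sample_rate > 0)
  if (any(!is.finite(samples))) stop("audio_clip samples must be finite")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         start_time = start_time),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples, %g Hz, %.3f s>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Synthesize one NBHF click pulse
#'
#' A Gaussian-enveloped sinusoid: the standard model for a porpoise
#' narrow-band high-frequency click. The envelope standard deviation is
#' duration/6, so the pulse decays to numerical silence at the requested
#' duration while keeping the -3 dB bandwidth narrow (Q >= 5 at the default
#' 125 kHz / 100 us geometry).
#'
#' @param peak_frequency carrier (peak) frequency in Hz; must be below the
#'   Nyquist frequency.
#' @param duration pulse duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param amplitude peak amplitude (dimensionless).
#' @return numeric vector of `round(duration * sample_rate)` samples.
#' @export
generate_click_waveform <- function(peak_frequency, duration = 100e-6,
                                    sample_rate = 576000, amplitude = 1) {
  stopifnot(peak_frequency > 0, duration > 0, sample_rate > 0)
  if (peak_frequency >= sample_rate / 2) {
    stop("peak_frequency (", peak_frequency, " Hz) is at or above Nyquist (",
         sample_rate / 2, " Hz)")
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  tc <- (n - 1) / (2 * sample_rate)
  sd_t <- duration / 6
  amplitude * exp(-(t - tc)^2 / (2 * sd_t^2)) * sin(2 * pi * peak_frequency * (t - tc))
}

#' Draw ground-truth click times organised in trains
#'
#' Clicks are produced in trains: the number of trains in the clip is
#' Poisson with mean `train_rate_per_min * clip_duration / 60`, train onsets
#' are uniform over the clip, the number of clicks per train is uniform on
#' `clicks_per_train`, and within-train inter-click intervals (ICIs) are
#' log-normal, truncated into [`ici_min`, `ici_max`] so that no within-train
#' gap ever exceeds the 200 ms train criterion. Per-click peak frequencies
#' are Gaussian around 125 kHz, truncated to the species' 87-145 kHz NBHF
#' band.
#'
#' @param clip_duration clip length in seconds.
#' @param train_rate_per_min expected number of trains per minute.
#' @param clicks_per_train integer range `c(min, max)` of clicks per train.
#' @param ici_meanlog,ici_sdlog log-normal ICI parameters (seconds scale);
#'   defaults give a median ICI of ~40 ms.
#' @param ici_min,ici_max truncation bounds on the ICI in seconds.
#' @param peak_frequency_mean,peak_frequency_sd per-click peak frequency
#'   distribution (Hz), truncated to [87, 145] kHz.
#' @param duration per-click duration in seconds.
#' @param snr_db per-click signal-to-noise ratio in dB (scalar or range
#'   `c(lo, hi)` sampled uniformly).
#' @param seed integer seed; the function is a pure function of its
#'   arguments including the seed.
#' @return a `data.frame` with one row per click: `center_time`,
#'   `peak_frequency`, `duration`, `snr_db`, `train_id`, ordered by
#'   strictly increasing `center_time`.
#' @export
generate_click_times <- function(clip_duration, train_rate_per_min = 10,
                                 clicks_per_train = c(5L, 40L),
                                 ici_meanlog = log(0.040), ici_sdlog = 0.4,
                                 ici_min = 0.005, ici_max = 0.195,
                                 peak_frequency_mean = 125e3,
                                 peak_frequency_sd = 8e3,
                                 duration = 100e-6, snr_db = 20, seed = 1L) {
  stopifnot(clip_duration > 0, train_rate_per_min >= 0,
            ici_min > 0, ici_max <= 0.200, ici_min < ici_max)
  withr::with_seed(seed, {
    n_trains <- stats::rpois(1, train_rate_per_min * clip_duration / 60)
    if (n_trains == 0) return(empty_click_table())
    out <- vector("list", n_trains)
    for (i in seq_len(n_trains)) {
      sizes <- seq(clicks_per_train[1], clicks_per_train[2])
      n_clicks <- sizes[sample.int(length(sizes), 1)]
      icis <- stats::rlnorm(n_clicks - 1, ici_meanlog, ici_sdlog)
      icis <- pmin(pmax(icis, ici_min), ici_max)
      # place the whole train inside the clip so no train is truncated
      span <- sum(icis)
      start <- stats::runif(1, 0, max(clip_duration - span, 1e-9))
      times <- start + cumsum(c(0, icis))
      pf <- stats::rnorm(n_clicks, peak_frequency_mean, peak_frequency_sd)
      pf <- pmin(pmax(pf, 87e3), 145e3)
      snr <- if (length(snr_db) == 2) stats::runif(n_clicks, snr_db[1], snr_db[2])
             else rep(snr_db, n_clicks)
      out[[i]] <- data.frame(center_time = times, peak_frequency = pf,
                             duration = duration, snr_db = snr, train_id = i)
    }
    clicks <- do.call(rbind, out)
    clicks <- clicks[clicks$center_time >= 0 & clicks$center_time < clip_duration, ]
    clicks <- clicks[order(clicks$center_time), ]
    # overlapping trains can interleave; enforce strictly increasing times
    clicks <- clicks[!duplicated(clicks$center_time), ]
    rownames(clicks) <- NULL
    clicks
  })
}

empty_click_table <- function() {
  data.frame(center_time = numeric(0), peak_frequency = numeric(0),
             duration = numeric(0), snr_db = numeric(0), train_id = integer(0))
}

#' Render clicks over broadband noise into an audio clip
#'
#' Plants each ground-truth click (a Gaussian-enveloped pulse) into white
#' Gaussian background noise. Each click's amplitude is scaled so its
#' achieved signal-to-noise ratio -- mean click power over the pulse
#' duration, relative to the noise power falling inside the 87-145 kHz NBHF
#' band -- equals its `snr_db`. With `echo_model = TRUE`, attenuated delayed
#' copies of every pulse are added to emulate surface/wall multipath in a
#' pool, which inflates the number of detectable pulses (as reflections do
#' in real pool recordings) while preserving relative variation.
#'
#' @param clicks a click table as produced by [generate_click_times()]; all
#'   `center_time`s must lie in `[0, clip_duration)`.
#' @param clip_duration clip length in seconds.
#' @param sample_rate sampling rate in Hz (>= 290 kHz).
#' @param noise_level_db background noise RMS in dB full scale
#'   (20*log10(rms)); default -40 dBFS.
#' @param echo_model add delayed-attenuated copies of each click.
#' @param echo_delays,echo_gains multipath delays (s) and linear gains.
#' @param seed integer seed for the noise (and nothing else).
#' @return a list with `clip` (an [audio_clip()]) and `truth` (the input
#'   click table, unchanged).
#' @export
render_recording <- function(clicks, clip_duration, sample_rate = 576000,
                             noise_level_db = -40, echo_model = FALSE,
                             echo_delays = c(0.003, 0.007),
                             echo_gains = c(0.5, 0.35), seed = 1L) {
  stopifnot(clip_duration > 0, sample_rate >= 290000)
  if (nrow(clicks) > 0 &&
      (any(clicks$center_time < 0) || any(clicks$center_time >= clip_duration))) {
    stop("click center_time outside [0, clip_duration)")
  }
  n <- round(clip_duration * sample_rate)
  noise_rms <- 10^(noise_level_db / 20)
  x <- withr::with_seed(seed, stats::rnorm(n, sd = noise_rms))
  # white noise spreads power uniformly up to Nyquist; only the fraction in
  # the NBHF band competes with a click
  band_frac <- (145e3 - 87e3) / (sample_rate / 2)
  p_noise_band <- noise_rms^2 * band_frac

  add_pulse <- function(x, w, center_time) {
    start <- round(center_time * sample_rate - length(w) / 2) + 1
    idx <- seq(start, start + length(w) - 1)
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + w[keep]
    x
  }

  for (i in seq_len(nrow(clicks))) {
    w0 <- generate_click_waveform(clicks$peak_frequency[i], clicks$duration[i],
                                  sample_rate, amplitude = 1)
    scale <- sqrt(p_noise_band * 10^(clicks$snr_db[i] / 10) / mean(w0^2))
    w <- w0 * scale
    x <- add_pulse(x, w, clicks$center_time[i])
    if (echo_model) {
      for (k in seq_along(echo_delays)) {
        tt <- clicks$center_time[i] + echo_delays[k]
        if (tt < clip_duration) x <- add_pulse(x, w * echo_gains[k], tt)
      }
    }
  }
  peak <- max(abs(x), 1e-12)
  if (peak > 1) {
    warning("rendered amplitude exceeded full scale; rescaling by ",
            signif(1 / peak, 3))
    x <- x / peak
  }
  list(clip = audio_clip(x, sample_rate), truth = clicks)
}
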
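#' Labelled spectrum dataset container
#'
#' @param magnitude numeric matrix, one row per sample, `nfft/2 + 1`
#'   columns (257 at the default STFT geometry), non-negative.
#' @param label factor with levels `click` and `noise`.
#' @param frequencies bin center frequencies in Hz.
#' @param sample_rate sampling rate (Hz) of the audio the spectra came
#'   from; bin indices only mean the same frequencies at the same rate.
#' @return a `spectrum_dataset`.
#' @export
spectrum_dataset <- function(magnitude, label, frequencies,
                             sample_rate = NA_real_) {
  magnitude <- as.matrix(magnitude)
  label <- factor(as.character(label), levels = c("click", "noise"))
  stopifnot(nrow(magnitude) == length(label), all(magnitude >= 0),
            ncol(magnitude) == length(frequencies), !anyNA(label))
  structure(list(magnitude = magnitude, label = label,
                 frequencies = frequencies, sample_rate = sample_rate),
            class = "spectrum_dataset")
}

#' @export
print.spectrum_dataset <- function(x, ...) {
  cat(sprintf("<spectrum_dataset: %d samples x %d bins (%s)>\n",
              nrow(x$magnitude), ncol(x$magnitude),
              paste(sprintf("%s=%d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a labelled dataset of click and noise spectra
#'
#' Builds classifier training data exactly the way the detector sees the
#' world: clicks are planted into noise, the render is high-pass filtered
#' and passed through the detection STFT, and the frame nearest each truth
#' click becomes a `click` spectrum; `noise` spectra are frames of
#' noise-only renders after the same filtering. Per-click peak frequencies
#' are uniform over `peak_range` and SNRs uniform over `snr_range`.
#'
#' @param n_total total number of spectra.
#' @param click_fraction proportion labelled `click` (0 < f < 1).
#' @param seed integer seed.
#' @param config a [detector_config()].
#' @param sample_rate sampling rate in Hz.
#' @param snr_range click SNR range in dB.
#' @param peak_range click peak-frequency range in Hz (within the
#'   detection band by default).
#' @param noise_level_db background noise RMS in dBFS.
#' @return a [spectrum_dataset()] with exactly `n_total` rows.
#' @export
generate_spectra_dataset <- function(n_total = 2000, click_fraction = 0.5,
                                     seed = 1L, config = detector_config(),
                                     sample_rate = 576000,
                                     snr_range = c(10, 25),
                                     peak_range = c(90e3, 127e3),
                                     noise_level_db = -40) {
  stopifnot(n_total >= 2, click_fraction > 0, click_fraction < 1)
  n_click <- round(n_total * click_fraction)
  n_noise <- n_total - n_click
  if (n_click < 1 || n_noise < 1) {
    n_click <- max(1, min(n_total - 1, n_click))
    n_noise <- n_total - n_click
  }
  coefs <- design_highpass(config, sample_rate)
  hop_s <- (config$stft_window - config$stft_noverlap) / sample_rate

  click_rows <- matrix(numeric(0), 0, config$stft_nfft / 2 + 1)
  freqs <- NULL
  batch <- 0L
  while (nrow(click_rows) < n_click) {
    batch <- batch + 1L
    # 100 well-separated clicks per 1-s batch, 10 ms apart
    m <- min(100L, n_click - nrow(click_rows))
    withr::with_seed(seed * 1000L + batch, {
      tt <- 0.05 + (seq_len(m) - 1) * 0.0095
      clicks <- data.frame(
        center_time = tt,
        peak_frequency = stats::runif(m, peak_range[1], peak_range[2]),
        duration = 100e-6,
        snr_db = stats::runif(m, snr_range[1], snr_range[2]),
        train_id = 1L
      )
    })
    rec <- render_recording(clicks, clip_duration = max(tt) + 0.05,
                            sample_rate = sample_rate,
                            noise_level_db = noise_level_db,
                            seed = seed * 1000L + batch)
    sp <- spectrogram(highpass_filter(rec$clip, coefs), config)
    freqs <- sp$frequencies
    idx <- vapply(clicks$center_time,
                  function(t) which.min(abs(sp$times - t)), integer(1))
    click_rows <- rbind(click_rows, t(sp$magnitude[, idx, drop = FALSE]))
  }
  click_rows <- click_rows[seq_len(n_click), , drop = FALSE]

  noise_rows <- matrix(numeric(0), 0, config$stft_nfft / 2 + 1)
  batch <- 0L
  while (nrow(noise_rows) < n_noise) {
    batch <- batch + 1L
    dur <- min(1, (n_noise - nrow(noise_rows)) * hop_s + 0.01)
    rec <- render_recording(empty_click_table(), clip_duration = dur,
                            sample_rate = sample_rate,
                            noise_level_db = noise_level_db,
                            seed = seed * 2000L + batch)
    sp <- spectrogram(highpass_filter(rec$clip, coefs), config)
    noise_rows <- rbind(noise_rows, t(sp$magnitude))
  }
  noise_rows <- noise_rows[seq_len(n_noise), , drop = FALSE]

  spectrum_dataset(rbind(click_rows, noise_rows),
                   rep(c("click", "noise"), c(n_click, n_noise)), freqs,
                   sample_rate = sample_rate)
}

#' Augment spectra with bounded random level perturbations
#'
#' Each augmented copy multiplies every bin by an independent random factor
#' bounded to `max_db` decibels, emulating level variation to improve the
#' classifier's generalisation. Labels are preserved; originals are kept.
#'
#' @param dataset a [spectrum_dataset()].
#' @param max_db maximum absolute per-bin perturbation in dB (>= 0).
#' @param copies number of perturbed copies per source sample.
#' @param seed integer seed.
#' @return a [spectrum_dataset()] with `nrow * (1 + copies)` samples.
#' @export
augment_spectra <- function(dataset, max_db = 3, copies = 1L, seed = 1L) {
  stopifnot(inherits(dataset, "spectrum_dataset"), copies >= 0)
  if (max_db < 0) stop("max_db must be non-negative")
  if (copies == 0) return(dataset)
  n <- nrow(dataset$magnitude)
  p <- ncol(dataset$magnitude)
  aug <- withr::with_seed(seed, {
    lapply(seq_len(copies), function(k) {
      fac <- 10^(matrix(stats::runif(n * p, -max_db, max_db), n, p) / 20)
      dataset$magnitude * fac
    })
  })
  spectrum_dataset(do.call(rbind, c(list(dataset$magnitude), aug)),
                   rep(as.character(dataset$label), copies + 1),
                   dataset$frequencies, sample_rate = dataset$sample_rate)
}
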
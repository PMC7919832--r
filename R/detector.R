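#' Click-detector configuration
#'
#' Constants of the detection pipeline: a Kaiser-window FIR high-pass
#' filter (80 kHz cutoff, beta = 0.5), a short-time Fourier transform with
#' window 512, noverlap 256, nfft 512, and a detection band of 87-128 kHz
#' for accepted click events. Species-level NBHF peaks extend to 145 kHz;
#' both band edges are configurable.
#'
#' @param cutoff high-pass cutoff frequency in Hz.
#' @param kaiser_beta Kaiser window shape parameter.
#' @param filter_taps FIR length (odd; linear phase type I).
#' @param stft_window,stft_noverlap,stft_nfft STFT geometry in samples.
#' @param click_band accepted peak-frequency interval in Hz.
#' @param score_threshold classifier score above which a frame counts as
#'   click (probability scale).
#' @param merge_gap number of consecutive noise frames tolerated inside one
#'   click event when merging frames into events.
#' @return a `detector_config` list.
#' @export
detector_config <- function(cutoff = 80000, kaiser_beta = 0.5,
                            filter_taps = 255L, stft_window = 512L,
                            stft_noverlap = 256L, stft_nfft = 512L,
                            click_band = c(87000, 128000),
                            score_threshold = 0.5, merge_gap = 0L) {
  stopifnot(cutoff > 0, filter_taps >= 3, stft_noverlap < stft_window,
            stft_window <= stft_nfft, length(click_band) == 2,
            click_band[1] < click_band[2], click_band[1] > 0,
            score_threshold >= 0, score_threshold <= 1, merge_gap >= 0)
  structure(
    list(cutoff = cutoff, kaiser_beta = kaiser_beta,
         filter_taps = as.integer(filter_taps),
         stft_window = as.integer(stft_window),
         stft_noverlap = as.integer(stft_noverlap),
         stft_nfft = as.integer(stft_nfft),
         click_band = click_band, score_threshold = score_threshold,
         merge_gap = as.integer(merge_gap)),
    class = "detector_config"
  )
}

#' Design the high-pass FIR filter
#'
#' Kaiser-window FIR high-pass (linear phase). At the default geometry
#' (255 taps, beta 0.5, 80 kHz cutoff, 576 kHz sampling) the response is
#' below -40 dB at half the cutoff and within +/-1 dB of unity from 1.3x
#' the cutoff upward.
#'
#' @param config a [detector_config()].
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector of filter coefficients with attributes
#'   `sample_rate` and `cutoff`.
#' @export
design_highpass <- function(config = detector_config(), sample_rate = 576000) {
  if (config$cutoff >= sample_rate / 2) {
    stop("cutoff (", config$cutoff, " Hz) at or above Nyquist (",
         sample_rate / 2, " Hz)")
  }
  n <- config$filter_taps
  if (n %% 2 == 0) n <- n + 1L  # type I linear phase needs odd length
  b <- signal::fir1(n - 1L, config$cutoff / (sample_rate / 2), type = "high",
                    window = signal::kaiser(n, config$kaiser_beta))
  b <- as.numeric(b)
  attr(b, "sample_rate") <- sample_rate
  attr(b, "cutoff") <- config$cutoff
  b
}

#' Evaluate an FIR filter's magnitude response
#'
#' @param coefficients FIR coefficients from [design_highpass()].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param sample_rate sampling rate in Hz (default: taken from the
#'   coefficients).
#' @return magnitude gain in dB at each frequency.
#' @export
filter_response_db <- function(coefficients, freqs,
                               sample_rate = attr(coefficients, "sample_rate")) {
  k <- seq_along(coefficients) - 1
  vapply(freqs, function(f) {
    20 * log10(Mod(sum(coefficients * exp(-2i * pi * f / sample_rate * k))))
  }, numeric(1))
}

#' High-pass filter an audio clip
#'
#' FFT convolution with group-delay compensation, so filtered samples stay
#' time-aligned with the input (linear-phase FIR, constant delay
#' (taps-1)/2).
#'
#' @param clip an [audio_clip()].
#' @param coefficients output of [design_highpass()] for the clip's rate.
#' @return a filtered [audio_clip()] of identical length and rate.
#' @export
highpass_filter <- function(clip, coefficients) {
  stopifnot(inherits(clip, "audio_clip"), length(clip$samples) > 0)
  sr <- attr(coefficients, "sample_rate")
  if (!is.null(sr) && sr != clip$sample_rate) {
    stop("filter designed for ", sr, " Hz but clip is ", clip$sample_rate, " Hz")
  }
  d <- (length(coefficients) - 1) %/% 2
  xp <- c(clip$samples, numeric(d))
  y <- signal::fftfilt(coefficients, xp)
  audio_clip(as.numeric(y[(d + 1):(d + length(clip$samples))]),
             clip$sample_rate, clip$start_time)
}

#' Short-time Fourier transform of a clip
#'
#' Hamming-windowed frames of `stft_window` samples advancing by
#' `stft_window - stft_noverlap`; the number of frames is
#' `floor((N - noverlap) / (window - noverlap))` and the one-sided spectrum
#' has `nfft/2 + 1` bins (257 at nfft = 512).
#'
#' @param clip an [audio_clip()], at least one window long.
#' @param config a [detector_config()].
#' @return list with `times` (frame centers, s), `frequencies` (Hz), and
#'   `magnitude` (bins x frames, non-negative).
#' @export
spectrogram <- function(clip, config = detector_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  win <- config$stft_window
  hop <- win - config$stft_noverlap
  if (length(x) < win) stop("clip shorter than one STFT window (", win, " samples)")
  n_frames <- (length(x) - config$stft_noverlap) %/% hop
  starts <- (seq_len(n_frames) - 1) * hop + 1
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))  # Hamming
  frames <- vapply(starts, function(s) x[s:(s + win - 1)] * w, numeric(win))
  if (config$stft_nfft > win) {
    frames <- rbind(frames, matrix(0, config$stft_nfft - win, n_frames))
  }
  spec <- Mod(stats::mvfft(frames))[seq_len(config$stft_nfft / 2 + 1), , drop = FALSE]
  list(
    times = clip$start_time + (starts - 1 + (win - 1) / 2) / clip$sample_rate,
    frequencies = (0:(config$stft_nfft / 2)) * clip$sample_rate / config$stft_nfft,
    magnitude = spec
  )
}

#' Merge classified frames into click events
#'
#' Maximal runs of click-labelled frames, allowing up to `merge_gap`
#' interior noise frames, become one event each; the event time is the run
#' midpoint. When the spectrogram is supplied, each event also gets a peak
#' frequency (argmax of the summed run spectrum at or above the high-pass
#' cutoff) and events whose peak falls outside `click_band` are rejected.
#'
#' @param labels logical (or "click"/"noise") frame labels.
#' @param frame_times frame center times in seconds, increasing.
#' @param config a [detector_config()].
#' @param scores optional per-frame scores; the event score is the run max.
#' @param magnitude,frequencies optional spectrogram of the same frames.
#' @return a `data.frame` of events: `time`, `duration`, `peak_frequency`,
#'   `score`, ordered by time.
#' @export
frames_to_clicks <- function(labels, frame_times, config = detector_config(),
                             scores = NULL, magnitude = NULL,
                             frequencies = NULL) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "click"
  stopifnot(length(labels) == length(frame_times))
  empty <- data.frame(time = numeric(0), duration = numeric(0),
                      peak_frequency = numeric(0), score = numeric(0))
  if (length(labels) == 0 || !any(labels)) return(empty)
  if (is.unsorted(frame_times)) stop("frame_times must be increasing")

  # close gaps of <= merge_gap noise frames between click frames
  merged <- labels
  if (config$merge_gap > 0) {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    for (i in seq_along(r$lengths)) {
      interior <- i > 1 && i < length(r$lengths)
      if (!r$values[i] && interior && r$lengths[i] <= config$merge_gap) {
        merged[(ends[i] - r$lengths[i] + 1):ends[i]] <- TRUE
      }
    }
  }
  r <- rle(merged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  frame_dur <- if (length(frame_times) > 1) stats::median(diff(frame_times)) else 0

  out <- lapply(runs, function(i) {
    idx <- starts[i]:ends[i]
    pf <- NA_real_
    if (!is.null(magnitude)) {
      prof <- rowSums(magnitude[, idx, drop = FALSE])
      keep <- frequencies >= config$cutoff
      pf <- frequencies[keep][which.max(prof[keep])]
    }
    data.frame(
      time = mean(range(frame_times[idx])),
      duration = diff(range(frame_times[idx])) + frame_dur,
      peak_frequency = pf,
      score = if (is.null(scores)) 1 else max(scores[idx])
    )
  })
  events <- do.call(rbind, out)
  if (!is.null(magnitude)) {
    events <- events[events$peak_frequency >= config$click_band[1] &
                       events$peak_frequency <= config$click_band[2], ]
  }
  rownames(events) <- NULL
  events
}

#' Per-minute click density
#'
#' Number of detected clicks in each complete one-minute bin
#' (half-open bins `[60k, 60(k+1))` relative to `clip_start`).
#'
#' @param events event table from [frames_to_clicks()] or compatible; times
#'   in seconds within `[0, clip_duration)`.
#' @param clip_duration clip length in seconds.
#' @param clip_start clip start epoch in seconds (minute bins are counted
#'   from here; event times are clip-relative).
#' @return `data.frame` with `minute_index` (0-based) and `click_count`;
#'   zero rows (with a warning) if the clip is shorter than one minute.
#' @export
click_density <- function(events, clip_duration, clip_start = 0) {
  n_min <- floor(clip_duration / 60)
  if (n_min < 1) {
    warning("clip shorter than one minute; no complete minute bins")
    return(data.frame(minute_index = integer(0), click_count = integer(0)))
  }
  if (nrow(events) > 0 &&
      (any(events$time < 0) || any(events$time >= clip_duration))) {
    stop("event time outside [0, clip_duration)")
  }
  bin <- floor(events$time / 60)
  counts <- tabulate(bin[bin < n_min] + 1L, nbins = n_min)
  data.frame(minute_index = seq_len(n_min) - 1L, click_count = as.integer(counts))
}

#' Segment click events into click trains
#'
#' A train is at least `min_clicks` consecutive clicks with every
#' inter-click interval at most `max_ici` (200 ms). Greedy left-to-right
#' grouping: a train extends while the next ICI stays within `max_ici`;
#' groups below the minimum size are discarded.
#'
#' @param events time-ordered event table (column `time` in seconds).
#' @param min_clicks minimum clicks per train.
#' @param max_ici maximum inter-click interval in seconds.
#' @return list of `click_train` objects, each with `clicks` (event rows)
#'   and `icis` (seconds, length `nrow(clicks) - 1`).
#' @export
segment_trains <- function(events, min_clicks = 5L, max_ici = 0.200) {
  if (nrow(events) == 0) return(list())
  if (is.unsorted(events$time)) stop("events must be time-ordered")
  gaps <- diff(events$time)
  group <- cumsum(c(0, gaps > max_ici))
  out <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) >= min_clicks) {
      clicks <- events[idx, , drop = FALSE]
      rownames(clicks) <- NULL
      out[[length(out) + 1]] <- structure(
        list(clicks = clicks, icis = diff(clicks$time)),
        class = "click_train"
      )
    }
  }
  out
}
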
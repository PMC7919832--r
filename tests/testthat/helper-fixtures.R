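# Shared fixtures, built once per test run and memoised. The "full" model
# is the standard detector training configuration (2000 spectra, +/-3 dB
# augmentation); the "small" model keeps cheap tests cheap.
.fixtures <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    .fixtures$dataset <- generate_spectra_dataset(2000, 0.5, seed = 11)
  }
  .fixtures$dataset
}

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    aug <- augment_spectra(fixture_dataset(), max_db = 3, copies = 1, seed = 12)
    .fixtures$model <- train_classifier(aug, seed = 1)
  }
  .fixtures$model
}

fixture_small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_spectra_dataset(200, 0.5, seed = 21)
  }
  .fixtures$small
}

fixture_small_model <- function() {
  if (is.null(.fixtures$small_model)) {
    .fixtures$small_model <- train_classifier(fixture_small_dataset(), seed = 1)
  }
  .fixtures$small_model
}

fixture_model_320k <- function() {
  if (is.null(.fixtures$model_320k)) {
    ds <- generate_spectra_dataset(200, 0.5, seed = 22, sample_rate = 320000)
    .fixtures$model_320k <- train_classifier(ds, seed = 1)
  }
  .fixtures$model_320k
}

# well-separated planted clicks for end-to-end detection checks
plant_clicks <- function(n, clip_duration = 1, snr_db = 20, seed = 1,
                         min_sep = 0.01, peak_range = c(95e3, 127e3)) {
  slot <- (clip_duration - 0.06) / n
  stopifnot(slot >= min_sep)
  withr::with_seed(seed, {
    # jittered grid: uniform-ish placement with a guaranteed minimum gap
    tt <- 0.03 + (seq_len(n) - 1) * slot + min_sep / 2 +
      stats::runif(n, 0, slot - min_sep)
    data.frame(center_time = tt,
               peak_frequency = stats::runif(n, peak_range[1], peak_range[2]),
               duration = 100e-6, snr_db = snr_db, train_id = 1L)
  })
}

# match detected events to truth times within a tolerance (3 ms default:
# well below the minimum planted separation)
match_events <- function(events, truth_times, tol = 0.003) {
  recalled <- vapply(truth_times,
                     function(t) any(abs(events$time - t) < tol), logical(1))
  genuine <- if (nrow(events) == 0) logical(0) else
    vapply(events$time,
           function(t) any(abs(truth_times - t) < tol), logical(1))
  list(n_truth = length(truth_times), n_events = nrow(events),
       n_recalled = sum(recalled), n_genuine = sum(genuine))
}

# independent O(n^2) oracle for train segmentation: walk each candidate
# start, extend while the gap criterion holds, emit maximal groups
brute_force_trains <- function(times, min_clicks = 5, max_ici = 0.2) {
  n <- length(times)
  groups <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) <= max_ici) j <- j + 1
    if (j - i + 1 >= min_clicks) groups[[length(groups) + 1]] <- i:j
    i <- j + 1
  }
  groups
}

# tiny GLMM-ready dataset: build a scenario, simulate, assemble the design
make_design <- function(scenario) {
  sim <- generate_minute_counts(scenario)
  build_design(sim$minutes, sim$annotations)
}
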
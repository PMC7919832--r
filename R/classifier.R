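#' Normalise spectra for classification
#'
#' Each spectrum is scaled by its own maximum (scale-invariant features, so
#' absolute level never dominates shape); all-zero spectra stay zero.
#'
#' @param magnitude matrix, one spectrum per row.
#' @return matrix of the same shape with rows in [0, 1].
#' @keywords internal
normalize_spectra <- function(magnitude) {
  mx <- apply(magnitude, 1, max)
  mx[mx == 0] <- 1
  magnitude / mx
}

#' Train the binary click/noise spectrum classifier
#'
#' A radial-basis support vector machine on max-normalised magnitude
#' spectra. Scores are a logistic transform of the (signed) SVM decision
#' value, oriented so larger scores mean more click-like; the transform is
#' monotone, so thresholding scores is equivalent to thresholding decision
#' values.
#'
#' @param dataset a [spectrum_dataset()] containing both labels and at
#'   least 10 samples.
#' @param seed integer seed (fold-free training is deterministic; the seed
#'   is recorded in the metadata and fixed for reproducibility).
#' @param cost SVM regularisation constant.
#' @param gamma RBF kernel width; default `1/ncol`.
#' @return a `click_classifier` with the fitted SVM, decision-value
#'   orientation, and training metadata (n samples, seed, training
#'   accuracy).
#' @export
train_classifier <- function(dataset, seed = 1L, cost = 1, gamma = NULL) {
  stopifnot(inherits(dataset, "spectrum_dataset"))
  n <- nrow(dataset$magnitude)
  if (n < 10) stop("need at least 10 training samples")
  if (nlevels(droplevels(dataset$label)) < 2) {
    stop("training data must contain both 'click' and 'noise' samples")
  }
  x <- normalize_spectra(dataset$magnitude)
  y <- droplevels(dataset$label)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- withr::with_seed(seed, {
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  })
  dec <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  # libsvm's decision sign depends on internal label order; orient so that
  # click frames score high
  flip <- if (mean(dec[y == "click"]) >= mean(dec[y == "noise"])) 1 else -1
  pred <- ifelse(flip * dec > 0, "click", "noise")
  structure(
    list(svm = fit, flip = flip, n_bins = ncol(x),
         sample_rate = dataset$sample_rate,
         meta = list(n_samples = n, seed = seed, cost = cost, gamma = gamma,
                     sample_rate = dataset$sample_rate,
                     training_accuracy = mean(pred == as.character(y)))),
    class = "click_classifier"
  )
}

#' @export
print.click_classifier <- function(x, ...) {
  cat(sprintf(
    "<click_classifier: RBF SVM, %d bins, %d training samples, training accuracy %.4f>\n",
    x$n_bins, x$meta$n_samples, x$meta$training_accuracy))
  invisible(x)
}

#' Score spectra with a trained classifier
#'
#' @param object a `click_classifier`.
#' @param magnitude matrix of raw (unnormalised) spectra, one per row.
#' @param ... unused.
#' @return `data.frame` with `label` ("click"/"noise" at score 0.5) and
#'   `score` in [0, 1], monotone in the SVM decision value.
#' @export
predict.click_classifier <- function(object, magnitude, ...) {
  magnitude <- as.matrix(magnitude)
  if (ncol(magnitude) != object$n_bins) {
    stop("spectrum has ", ncol(magnitude), " bins but the model expects ",
         object$n_bins)
  }
  if (nrow(magnitude) == 0) {
    return(data.frame(label = character(0), score = numeric(0)))
  }
  x <- normalize_spectra(magnitude)
  dec <- attr(stats::predict(object$svm, x, decision.values = TRUE),
              "decision.values")
  score <- stats::plogis(object$flip * as.numeric(dec))
  data.frame(label = ifelse(score >= 0.5, "click", "noise"), score = score)
}

#' Classify spectrogram frames
#'
#' @param magnitude spectrogram magnitude matrix (bins x frames).
#' @param frequencies bin frequencies in Hz (length must match rows).
#' @param model a `click_classifier`.
#' @param config a [detector_config()]; frames at or above
#'   `score_threshold` are labelled click.
#' @return `data.frame` with one `label` and `score` per frame.
#' @export
classify_frames <- function(magnitude, frequencies, model,
                            config = detector_config()) {
  stopifnot(nrow(magnitude) == length(frequencies))
  if (ncol(magnitude) == 0) {
    return(data.frame(label = character(0), score = numeric(0)))
  }
  pred <- stats::predict(model, t(magnitude))
  data.frame(label = ifelse(pred$score >= config$score_threshold,
                            "click", "noise"),
             score = pred$score)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Samples of each class are shuffled (fixed seed) and dealt into k folds;
#' each fold in turn is held out, the classifier trained on the rest, and
#' held-out accuracy recorded. Returns the mean over folds.
#'
#' @param dataset a [spectrum_dataset()].
#' @param k number of folds (>= 2, at most the size of the smaller class).
#' @param seed integer seed controlling fold assignment.
#' @param ... passed to [train_classifier()].
#' @return mean held-out accuracy in [0, 1].
#' @export
kfold_accuracy <- function(dataset, k = 5L, seed = 1L, ...) {
  stopifnot(inherits(dataset, "spectrum_dataset"), k >= 2)
  y <- dataset$label
  if (any(table(y) < k)) stop("k exceeds the size of a class")
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  acc <- vapply(seq_len(k), function(f) {
    train <- spectrum_dataset(dataset$magnitude[fold != f, , drop = FALSE],
                              y[fold != f], dataset$frequencies)
    model <- train_classifier(train, seed = seed, ...)
    pred <- stats::predict(model, dataset$magnitude[fold == f, , drop = FALSE])
    mean(pred$label == as.character(y[fold == f]))
  }, numeric(1))
  mean(acc)
}

#' Run the full click-detection pipeline on one clip
#'
#' High-pass filter, STFT, frame classification, frame-to-event merging and
#' in-band peak acceptance, in that order.
#'
#' @param clip an [audio_clip()].
#' @param model a `click_classifier`.
#' @param config a [detector_config()].
#' @return event `data.frame` as from [frames_to_clicks()] (times are
#'   clip-relative seconds).
#' @export
detect_clicks <- function(clip, model, config = detector_config()) {
  if (model$n_bins != config$stft_nfft / 2 + 1) {
    stop("model expects ", model$n_bins, " bins but the STFT geometry gives ",
         config$stft_nfft / 2 + 1, "; refusing to mix geometries")
  }
  sr <- model$sample_rate
  if (!is.null(sr) && !is.na(sr) && sr != clip$sample_rate) {
    stop("model trained on ", sr, " Hz spectra but clip is ",
         clip$sample_rate, " Hz; bin frequencies would not match ",
         "(refusing to mix geometries)")
  }
  coefs <- design_highpass(config, clip$sample_rate)
  sp <- spectrogram(highpass_filter(clip, coefs), config)
  fr <- classify_frames(sp$magnitude, sp$frequencies, model, config)
  frames_to_clicks(fr$label, sp$times - clip$start_time, config,
                   scores = fr$score, magnitude = sp$magnitude,
                   frequencies = sp$frequencies)
}
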
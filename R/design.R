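.context_levels <- list(
  season = c("spring", "summer", "fall", "winter"),
  time_of_day = c("morning", "noon", "afternoon"),
  training = c("outside", "during"),
  grouping = c("together", "separated"),
  unusual_event = c("none", "pool_cleaning", "noise", "social_event", "other"),
  visitors = c("none", "few", "many")
)

#' Build the model inputs for the context GLMM
#'
#' Joins click densities to their context annotations, validates every
#' factor level against the context vocabulary, drops live-fish enrichment
#' minutes (too few to estimate), relevels each factor onto its reference
#' (spring / morning / outside training / together / no event / no
#' visitors; enrichment enters as four 0/1 indicators, so its reference is
#' all-zero), and assembles the response, the exposure offset
#' `log(n_individuals)` and the fixed-effect design. The number of
#' individuals also enters as a numeric predictor, so its coefficient
#' measures deviation from proportionality with group size.
#'
#' @param minutes `data.frame` with `minute_index` and `click_count`.
#' @param annotations matching annotation table (one row per minute).
#' @return list with `data` (model frame incl. factor columns and ids),
#'   `response`, `offset`, `design` (fixed-effect dummy matrix, no
#'   intercept), `term_groups` (design column -> predictor mapping),
#'   `fixed_terms`, and `n_dropped` (live-fish rows removed).
#' @export
build_design <- function(minutes, annotations) {
  stopifnot(all(c("minute_index", "click_count") %in% names(minutes)))
  d <- merge(minutes, annotations, by = "minute_index", sort = TRUE)
  if (anyNA(d)) stop("missing values in counts or annotations")
  if (any(d$click_count < 0) || any(d$click_count != round(d$click_count))) {
    stop("click_count must be non-negative integers")
  }
  for (v in names(.context_levels)) {
    bad <- !(d[[v]] %in% .context_levels[[v]])
    if (any(bad)) {
      stop("unknown ", v, " level '", d[[v]][which(bad)[1]],
           "' at minute_index ", d$minute_index[which(bad)[1]])
    }
    d[[v]] <- factor(d[[v]], levels = .context_levels[[v]])
  }
  if (any(d$n_individuals < 1)) stop("n_individuals must be >= 1")
  n_dropped <- sum(d$live_fish == 1)
  d <- d[d$live_fish == 0, , drop = FALSE]
  d <- droplevels(d)
  d$date_id <- factor(d$date_id)
  d$session_id <- factor(d$session_id)
  d$obs_id <- factor(seq_len(nrow(d)))

  fixed_terms <- c("n_individuals", "season", "time_of_day", "training",
                   "grouping", "toys", "humans", "humans_and_toys",
                   "new_object", "unusual_event", "visitors")
  fixed_terms <- fixed_terms[vapply(fixed_terms, function(v) {
    x <- d[[v]]
    if (is.factor(x)) nlevels(x) > 1 else stats::var(as.numeric(x)) > 0
  }, logical(1))]
  fml <- stats::as.formula(paste("~", paste(fixed_terms, collapse = " + ")))
  mm <- stats::model.matrix(fml, d)
  assign <- attr(mm, "assign")
  X <- mm[, assign != 0, drop = FALSE]
  list(
    data = d,
    response = d$click_count,
    offset = log(d$n_individuals),
    design = X,
    term_groups = stats::setNames(fixed_terms[assign[assign != 0]], colnames(X)),
    fixed_terms = fixed_terms,
    n_dropped = n_dropped
  )
}

#' Variance inflation factors of a fixed-effect design
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of column j on all other columns (plus an intercept).
#' Exactly collinear columns get infinite VIF. Columns with VIF above the
#' threshold are flagged as collinearity problems.
#'
#' @param design numeric matrix with at least two columns and more rows
#'   than columns.
#' @param threshold flagging threshold (default 3).
#' @return `data.frame` with `column`, `vif`, `flagged`.
#' @export
vif <- function(design, threshold = 3) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop("need at least two design columns")
  if (nrow(design) <= ncol(design)) stop("need more rows than columns")
  out <- vapply(seq_len(ncol(design)), function(j) {
    y <- design[, j]
    X <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)  # constant column: degenerate, flag it
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(column = colnames(design), vif = out,
             flagged = out > threshold, row.names = NULL)
}
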
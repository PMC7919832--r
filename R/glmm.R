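#' Fit the Poisson context GLMM
#'
#' Poisson GLMM with log link: click density as response, log number of
#' individuals as offset, the context predictors as fixed effects, and
#' Gaussian random intercepts for date, observation session and (to absorb
#' overdispersion) the individual observation minute. Fitted by Laplace
#' approximation with the derivative-free bound-constrained "bobyqa"
#' optimizer.
#'
#' @param design output of [build_design()].
#' @param fixed_terms character vector of fixed-effect terms (defaults to
#'   every non-constant context predictor in the design).
#' @param random subset of `c("date", "session", "observation")` naming the
#'   random intercepts to include.
#' @return a `glmm_fit`: fixed-effect table (`term`, `estimate`, `se`),
#'   coefficient covariance, random-effect SDs, logLik, AIC, parameter
#'   count, convergence flag, per-coefficient predictor grouping, and the
#'   underlying `glmerMod`/`glm` model.
#' @export
fit_poisson_glmm <- function(design, fixed_terms = design$fixed_terms,
                             random = c("date", "session", "observation")) {
  d <- design$data
  y <- design$response
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integers")
  }
  stopifnot(length(design$offset) == nrow(d))
  random <- match.arg(random, several.ok = TRUE)
  re_terms <- c(date = "(1 | date_id)", session = "(1 | session_id)",
                observation = "(1 | obs_id)")[random]
  rhs <- paste(c("1", fixed_terms, re_terms), collapse = " + ")
  fml <- stats::as.formula(paste("click_count ~", rhs))
  d$.offset <- design$offset
  if (stats::var(y) == 0) {
    # degenerate input: with a constant response every random-effect
    # variance is 0 at the MLE and the marginal likelihood equals the
    # plain GLM likelihood; lme4's PIRLS loop cannot start from this
    # boundary, so fit the collapsed model directly
    return(glm_collapse_fit(d, y, fixed_terms, random))
  }
  model <- lme4::glmer(
    fml, data = d, family = stats::poisson(), offset = d$.offset,
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE,
                                 check.response.not.const = "ignore")
  )
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  vc <- lme4::VarCorr(model)
  re_sd <- vapply(vc, function(m) attr(m, "stddev"), numeric(1))
  names(re_sd) <- names(vc)
  n_params <- length(beta) + length(lme4::getME(model, "theta"))
  ll <- as.numeric(stats::logLik(model))
  msgs <- model@optinfo$conv$lme4$messages
  # a variance estimated at the boundary (zero) is a valid converged fit
  conv <- model@optinfo$conv$opt == 0 &&
    (is.null(msgs) || all(grepl("boundary", msgs)))

  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", fixed_terms), collapse = " + "))), d)
  assign <- attr(mm, "assign")
  term_groups <- stats::setNames(
    c("(Intercept)", fixed_terms)[assign + 1], colnames(mm))

  structure(
    list(model = model,
         coefficients = data.frame(term = names(beta),
                                   estimate = as.numeric(beta),
                                   se = sqrt(diag(V)), row.names = NULL),
         vcov = V, re_sd = re_sd, logLik = ll,
         aic = -2 * ll + 2 * n_params, n_params = n_params,
         converged = conv, n_obs = nrow(d),
         fixed_terms = fixed_terms, random = random,
         term_groups = term_groups),
    class = "glmm_fit"
  )
}

glm_collapse_fit <- function(d, y, fixed_terms, random) {
  fml <- stats::as.formula(
    paste("click_count ~", paste(c("1", fixed_terms), collapse = " + ")))
  model <- stats::glm(fml, data = d, family = stats::poisson(),
                      offset = d$.offset)
  beta <- stats::coef(model)
  V <- as.matrix(stats::vcov(model))
  re_sd <- stats::setNames(rep(0, length(random)),
                           c(date = "date_id", session = "session_id",
                             observation = "obs_id")[random])
  n_params <- length(beta) + length(random)
  ll <- as.numeric(stats::logLik(model))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", fixed_terms), collapse = " + "))), d)
  assign <- attr(mm, "assign")
  structure(
    list(model = model,
         coefficients = data.frame(term = names(beta),
                                   estimate = as.numeric(beta),
                                   se = sqrt(diag(V)), row.names = NULL),
         vcov = V, re_sd = re_sd, logLik = ll,
         aic = -2 * ll + 2 * n_params, n_params = n_params,
         converged = model$converged, n_obs = nrow(d),
         fixed_terms = fixed_terms, random = random,
         term_groups = stats::setNames(
           c("(Intercept)", fixed_terms)[assign + 1], colnames(mm))),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit: %d obs, %d params, AIC %.2f, converged: %s>\n",
              x$n_obs, x$n_params, x$aic, x$converged))
  cat("random-effect SDs:",
      paste(sprintf("%s %.3f", names(x$re_sd), x$re_sd), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pearson overdispersion ratio
#'
#' Sum of squared Pearson residuals over the residual degrees of freedom
#' (observations minus estimated parameters); approximately 1 for a
#' well-specified Poisson model, above 1 under overdispersion. The p-value
#' comes from the chi-squared distribution with the residual df.
#'
#' @param fit a `glmm_fit` (or a `glm`).
#' @return list with `ratio`, `df`, `p`.
#' @export
overdispersion_ratio <- function(fit) {
  if (inherits(fit, "glmm_fit")) {
    pearson <- stats::residuals(fit$model, type = "pearson")
    df <- fit$n_obs - fit$n_params
  } else if (inherits(fit, "glm")) {
    pearson <- stats::residuals(fit, type = "pearson")
    df <- stats::df.residual(fit)
  } else stop("fit must be a glmm_fit or glm")
  if (df <= 0) stop("no residual degrees of freedom (saturated model)")
  stat <- sum(pearson^2)
  list(ratio = stat / df, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Select the fit with the lowest AIC
#'
#' Non-converged fits are excluded; exact AIC ties go to the fit with
#' fewer parameters.
#'
#' @param fits list of `glmm_fit` objects.
#' @return the selected `glmm_fit`.
#' @export
aic_select <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fit to select from")
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, numeric(1), "n_params")
  fits[[order(aic, npar)[1]]]
}

#' Wald chi-squared tests per predictor
#'
#' Groups each factor's dummy coefficients and tests the group with
#' `chi2 = b' V^-1 b` on `df = |group|` degrees of freedom. For 1-df
#' predictors the percent change `100 * (exp(beta) - 1)` is also reported.
#'
#' @param fit a `glmm_fit`.
#' @return `data.frame` with `predictor`, `chi2`, `df`, `p`,
#'   `percent_change` (NA for multi-df groups).
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  groups <- fit$term_groups
  preds <- unique(groups[groups != "(Intercept)"])
  rows <- lapply(preds, function(g) {
    idx <- which(fit$coefficients$term %in% names(groups)[groups == g])
    b <- fit$coefficients$estimate[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e) {
      stop("singular covariance for predictor group '", g, "'")
    })
    chi2 <- as.numeric(t(b) %*% Vi %*% b)
    data.frame(predictor = g, chi2 = chi2, df = length(b),
               p = stats::pchisq(chi2, length(b), lower.tail = FALSE),
               percent_change = if (length(b) == 1) percent_change(b) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm (sequential Bonferroni) adjustment
#'
#' Step-down adjustment: sort the m raw p-values ascending, multiply the
#' i-th by (m - i + 1), enforce monotonicity by running maximum, cap at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- pmin(cummax(p[ord] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pairwise level contrasts by subset refitting
#'
#' For every pair of levels of a multi-level factor, refits the same model
#' on the subset of minutes at one of those two levels only, tests the
#' resulting 1-df coefficient by Wald chi-squared, and applies the Holm
#' (sequential Bonferroni) correction across all pairs. Pairs for which a
#' level has no observations are skipped and recorded.
#'
#' @param design output of [build_design()].
#' @param factor_name one of the multi-level context factors (>= 3 levels).
#' @param fixed_terms,random model specification passed to
#'   [fit_poisson_glmm()] for each refit.
#' @return `data.frame` with `level_a`, `level_b`, `estimate`, `chi2`,
#'   `df`, `p`, `p_adjusted`, `percent_change`; skipped pairs are kept as
#'   the `skipped` attribute.
#' @export
pairwise_contrasts <- function(design, factor_name,
                               fixed_terms = design$fixed_terms,
                               random = c("date", "session", "observation")) {
  d <- design$data
  x <- d[[factor_name]]
  if (!is.factor(x) || nlevels(x) < 3) {
    stop("pairwise contrasts need a factor with at least 3 levels")
  }
  pairs <- utils::combn(levels(x), 2)
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    keep <- x %in% c(a, b)
    if (!any(x[keep] == a) || !any(x[keep] == b)) {
      warning("skipping contrast ", a, " vs ", b, ": empty level")
      skipped <- c(skipped, paste(a, "vs", b))
      next
    }
    sub <- design
    sub$data <- droplevels(d[keep, , drop = FALSE])
    sub$data[[factor_name]] <- stats::relevel(sub$data[[factor_name]], a)
    sub$response <- design$response[keep]
    sub$offset <- design$offset[keep]
    # drop terms that became constant in the subset
    ft <- fixed_terms[vapply(fixed_terms, function(v) {
      z <- sub$data[[v]]
      if (is.factor(z)) nlevels(z) > 1 else stats::var(as.numeric(z)) > 0
    }, logical(1))]
    sub$fixed_terms <- ft
    fit <- fit_poisson_glmm(sub, fixed_terms = ft, random = random)
    term <- paste0(factor_name, b)
    i <- match(term, fit$coefficients$term)
    est <- fit$coefficients$estimate[i]
    se <- fit$coefficients$se[i]
    chi2 <- (est / se)^2
    rows[[length(rows) + 1]] <- data.frame(
      level_a = a, level_b = b, estimate = est, chi2 = chi2, df = 1L,
      p = stats::pchisq(chi2, 1, lower.tail = FALSE),
      percent_change = percent_change(est))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_adjusted <- holm_adjust(out$p)
    out <- out[, c("level_a", "level_b", "estimate", "chi2", "df", "p",
                   "p_adjusted", "percent_change")]
    rownames(out) <- NULL
  } else {
    out <- data.frame(level_a = character(0), level_b = character(0),
                      estimate = numeric(0), chi2 = numeric(0),
                      df = integer(0), p = numeric(0),
                      p_adjusted = numeric(0), percent_change = numeric(0))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Percent change implied by a log rate ratio
#'
#' `100 * (exp(beta) - 1)`: the percent difference in expected click
#' density of a context level relative to its reference.
#'
#' @param beta log rate ratio (finite).
#' @return percent change, same sign as `beta`.
#' @export
percent_change <- function(beta) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  100 * (exp(beta) - 1)
}
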
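# a small scenario used across GLMM tests: all context effects planted at
# modest sizes, moderate random-effect SDs
glmm_scenario <- function(seed, re_sd = c(date = 0.1, session = 0.05, obs = 0.1),
                          days = 12L, spd = 3L, mps = 20L,
                          baseline = 200) {
  scenario_config(
    baseline_rate = baseline,
    re_sd = re_sd,
    design = list(days = days, sessions_per_day = spd,
                  minutes_per_session = mps),
    seed = seed)
}

test_that("intercept-only fit recovers log of a constant count", {
  sc <- scenario_config(
    design = list(days = 4L, sessions_per_day = 2L, minutes_per_session = 10L),
    n_individuals_levels = 1L, n_individuals_probs = 1, seed = 2)
  sim <- generate_minute_counts(sc)
  sim$minutes$click_count <- 7L
  des <- build_design(sim$minutes, sim$annotations)
  fit <- fit_poisson_glmm(des, fixed_terms = character(0),
                          random = c("date", "session"))
  expect_equal(fit$coefficients$estimate[1], log(7), tolerance = 1e-4)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$n_params)
})

test_that("a planted binary effect is recovered within 2 SE, and the GLM
           limit holds when random-effect SDs are zero", {
  sc <- glmm_scenario(seed = 41, re_sd = c(date = 0, session = 0, obs = 0),
                      days = 20L, spd = 3L, mps = 25L)
  des <- make_design(sc)
  fit <- fit_poisson_glmm(des, random = c("date", "session"))
  expect_true(fit$converged)

  i <- match("trainingduring", fit$coefficients$term)
  expect_lt(abs(fit$coefficients$estimate[i] - log(4.12)),
            2 * fit$coefficients$se[i] + 0.005)

  # with nothing to absorb, the mixed model collapses onto the plain GLM
  glm_fit <- stats::glm(
    stats::as.formula(paste("click_count ~",
                            paste(des$fixed_terms, collapse = " + "))),
    data = des$data, family = stats::poisson(), offset = des$offset)
  expect_lt(max(abs(fit$coefficients$estimate - stats::coef(glm_fit))), 1e-3)
  expect_true(all(fit$re_sd < 0.02))
})

test_that("AIC identity holds and AIC selection prefers the true model", {
  sc <- glmm_scenario(seed = 43)
  des <- make_design(sc)
  full <- fit_poisson_glmm(des, random = c("date", "session", "observation"))
  no_train <- fit_poisson_glmm(des,
                               fixed_terms = setdiff(des$fixed_terms, "training"),
                               random = c("date", "session", "observation"))
  expect_equal(full$aic, -2 * full$logLik + 2 * full$n_params)
  expect_equal(no_train$aic, -2 * no_train$logLik + 2 * no_train$n_params)
  # training multiplies the rate by 4.12; omitting it must cost AIC
  expect_identical(aic_select(list(no_train, full)), full)

  # tie-break on exact AIC equality goes to the smaller model
  a <- list(aic = 90, n_params = 5, converged = TRUE)
  b <- list(aic = 90, n_params = 7, converged = TRUE)
  c3 <- list(aic = 95, n_params = 2, converged = TRUE)
  expect_identical(aic_select(list(b, a, c3)), a)
  expect_error(aic_select(list(list(aic = 1, n_params = 1, converged = FALSE))),
               "converged")
})

test_that("overdispersion ratio is calibrated under a correct Poisson model", {
  sc <- glmm_scenario(seed = 47, re_sd = c(date = 0, session = 0, obs = 0),
                      days = 25L, spd = 4L, mps = 25L)
  des <- make_design(sc)
  glm_fit <- stats::glm(
    stats::as.formula(paste("click_count ~",
                            paste(des$fixed_terms, collapse = " + "))),
    data = des$data, family = stats::poisson(), offset = des$offset)
  od <- overdispersion_ratio(glm_fit)
  expect_gt(od$ratio, 0.9)
  expect_lt(od$ratio, 1.1)

  # lognormal extra-variation inflates the ratio well past 1
  sc2 <- glmm_scenario(seed = 48, re_sd = c(date = 0, session = 0, obs = 0.3),
                       days = 10L, spd = 3L, mps = 15L)
  des2 <- make_design(sc2)
  glm2 <- stats::glm(
    stats::as.formula(paste("click_count ~",
                            paste(des2$fixed_terms, collapse = " + "))),
    data = des2$data, family = stats::poisson(), offset = des2$offset)
  expect_gt(overdispersion_ratio(glm2)$ratio, 1.5)

  sat <- stats::glm(c(3, 5) ~ factor(c(1, 2)), family = stats::poisson())
  expect_error(overdispersion_ratio(sat), "degrees of freedom")
})

test_that("Wald chi-squared matches the closed form", {
  fake <- structure(list(
    coefficients = data.frame(term = c("(Intercept)", "x"),
                              estimate = c(0, 2), se = c(1, 1)),
    vcov = diag(2), term_groups = c("(Intercept)" = "(Intercept)", x = "x")),
    class = "glmm_fit")
  dimnames(fake$vcov) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  out <- wald_test(fake)
  expect_equal(out$chi2, 4)
  expect_equal(out$df, 1L)
  expect_equal(out$p, stats::pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(round(out$p, 4), 0.0455)

  fake$coefficients$estimate[2] <- 0
  out0 <- wald_test(fake)
  expect_equal(out0$chi2, 0)
  expect_equal(out0$p, 1)
})

test_that("multi-level factors get their full df in the Wald table", {
  sc <- glmm_scenario(seed = 53)
  des <- make_design(sc)
  fit <- fit_poisson_glmm(des, random = c("date", "session", "observation"))
  tbl <- wald_test(fit)
  expect_equal(tbl$df[tbl$predictor == "season"], 3L)
  expect_equal(tbl$df[tbl$predictor == "unusual_event"], 4L)
  expect_equal(tbl$df[tbl$predictor == "visitors"], 2L)
  expect_true(all(tbl$p >= 0 & tbl$p <= 1))
  expect_true(all(tbl$chi2 >= 0))
  # 1-df rows carry percent changes; multi-df rows do not
  expect_true(all(is.na(tbl$percent_change[tbl$df > 1])))
  expect_false(anyNA(tbl$percent_change[tbl$df == 1]))
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  withr::with_seed(59, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:8, 1))
      ours <- holm_adjust(p)
      expect_equal(ours, stats::p.adjust(p, "holm"))
      expect_true(all(ours >= p))
    }
  })
})

test_that("pairwise contrasts refit on two-level subsets with Holm correction", {
  sc <- glmm_scenario(seed = 61, days = 8L, spd = 3L, mps = 10L)
  des <- make_design(sc)
  out <- pairwise_contrasts(des, "visitors",
                            fixed_terms = c("n_individuals", "training",
                                            "grouping", "visitors"),
                            random = c("date", "session"))
  expect_equal(nrow(out), 3)  # C(3,2)
  expect_true(all(out$p_adjusted >= out$p))
  expect_equal(out$p_adjusted, holm_adjust(out$p))
  expect_true(all(out$df == 1))
  expect_error(pairwise_contrasts(des, "training"), "3 levels")
})

test_that("percent change maps log rate ratios onto the reported scale", {
  expect_equal(percent_change(log(2.36)), 136)
  expect_equal(percent_change(log(4.12)), 312)
  expect_equal(percent_change(0), 0)
  expect_lt(percent_change(log(0.65)), 0)
  expect_error(percent_change(Inf), "finite")
})

test_that("planted effects are covered by their 95% Wald intervals", {
  truth <- c(trainingduring = log(4.12), groupingseparated = log(2.36),
             toys = log(2.50), new_object = log(5.90))
  n_rep <- 20
  covered <- matrix(FALSE, n_rep, length(truth),
                    dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    des <- make_design(glmm_scenario(seed = 700 + r))
    fit <- fit_poisson_glmm(des, random = c("date", "session", "observation"))
    i <- match(names(truth), fit$coefficients$term)
    est <- fit$coefficients$estimate[i]
    se <- fit$coefficients$se[i]
    covered[r, ] <- abs(est - truth) <= stats::qnorm(0.975) * se
  }
  # nominal 95% coverage: >= 16/20 per coefficient leaves room for
  # binomial noise (P[X < 16 | p = 0.95] ~ 3e-4)
  expect_true(all(colSums(covered) >= 16))
})
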
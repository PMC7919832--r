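#' Scenario configuration for minute-level count simulation
#'
#' Defines the generative counterpart of the context GLMM: per-minute click
#' counts are Poisson with
#' `log(lambda) = log(n_individuals) + log(baseline_rate) + sum(log multipliers) + u_date + v_session + e_obs`,
#' where the multipliers belong to the context levels active in that minute
#' and u, v, e are Gaussian random intercepts on the log scale. The
#' defaults are the study-mimic scenario: rate multipliers that encode the
#' headline context effects (separated 2.36, during-training 4.12,
#' enrichment toys 2.50 / humans 0.90 / humans-and-toys 5.30 / new object
#' 5.90, noisy events 1.22, many visitors 0.65, fall 1.30 / summer 1.25),
#' a baseline calibrated so the all-reference mean density with five
#' animals is ~3860 clicks/min, and ~6000 observation minutes (50 days x 4
#' sessions x 30 min).
#'
#' Context states are drawn independently per minute (the simplest
#' exchangeable design); the number of individuals present is drawn per
#' session; season follows the date in four equal blocks and time of day
#' cycles with the session slot.
#'
#' @param baseline_rate expected clicks per minute per individual at all
#'   reference levels.
#' @param effect_multipliers named list of named numeric vectors, one per
#'   context variable; every reference level must have multiplier exactly 1
#'   and all multipliers must be positive.
#' @param re_sd named numeric: standard deviations (log scale) of the
#'   `date`, `session` and `obs` (observation-level) random intercepts.
#' @param design named list: `days`, `sessions_per_day`,
#'   `minutes_per_session`.
#' @param n_individuals_levels,n_individuals_probs per-session sampling of
#'   animals present.
#' @param context_probs named list of per-minute level probabilities for
#'   `grouping`, `training`, `enrichment`, `unusual_event`, `visitors`.
#' @param seed integer seed.
#' @return a validated `scenario_config`.
#' @export
scenario_config <- function(
    baseline_rate = 772,
    effect_multipliers = list(
      season = c(spring = 1, summer = 1.25, fall = 1.30, winter = 1),
      time_of_day = c(morning = 1, noon = 1, afternoon = 1),
      grouping = c(together = 1, separated = 2.36),
      training = c(outside = 1, during = 4.12),
      enrichment = c(none = 1, toys = 2.50, humans = 0.90,
                     humans_and_toys = 5.30, new_object = 5.90,
                     live_fish = 1),
      unusual_event = c(none = 1, pool_cleaning = 1.05, noise = 1.22,
                        social_event = 1.40, other = 1),
      visitors = c(none = 1, few = 0.90, many = 0.65)
    ),
    re_sd = c(date = 0.15, session = 0.10, obs = 0.20),
    design = list(days = 50L, sessions_per_day = 4L, minutes_per_session = 30L),
    n_individuals_levels = 2:5,
    n_individuals_probs = c(0.10, 0.15, 0.25, 0.50),
    context_probs = list(
      grouping = c(together = 0.75, separated = 0.25),
      training = c(outside = 0.85, during = 0.15),
      enrichment = c(none = 0.73, toys = 0.08, humans = 0.08,
                     humans_and_toys = 0.05, new_object = 0.04,
                     live_fish = 0.02),
      unusual_event = c(none = 0.70, pool_cleaning = 0.08, noise = 0.10,
                        social_event = 0.06, other = 0.06),
      visitors = c(none = 0.40, few = 0.35, many = 0.25)
    ),
    seed = 1L) {
  stopifnot(baseline_rate > 0, all(re_sd >= 0),
            all(c("date", "session", "obs") %in% names(re_sd)))
  refs <- c(season = "spring", time_of_day = "morning", grouping = "together",
            training = "outside", enrichment = "none", unusual_event = "none",
            visitors = "none")
  for (v in names(refs)) {
    m <- effect_multipliers[[v]]
    if (is.null(m) || any(m <= 0)) stop("multipliers for ", v, " must be positive")
    if (!isTRUE(m[[refs[[v]]]] == 1)) {
      stop("reference level '", refs[[v]], "' of ", v, " must have multiplier 1")
    }
  }
  stopifnot(length(n_individuals_levels) == length(n_individuals_probs),
            all(n_individuals_levels >= 1))
  structure(
    list(baseline_rate = baseline_rate,
         effect_multipliers = effect_multipliers, re_sd = re_sd,
         design = design, n_individuals_levels = n_individuals_levels,
         n_individuals_probs = n_individuals_probs,
         context_probs = context_probs, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Simulate minute-level click counts with their context annotations
#'
#' Draws one observation minute per design cell and returns the click
#' density table plus its context-annotation table. Enrichment levels are
#' generated mutually exclusively and stored both as a categorical column
#' and as 0/1 indicator columns (the analysis model uses the indicators;
#' live-fish minutes are flagged for exclusion there).
#'
#' @param scenario a [scenario_config()].
#' @return list with `minutes` (`minute_index`, `click_count`) and
#'   `annotations` (one row per minute with every context variable,
#'   indicator columns, `n_individuals`, `date_id`, `session_id`).
#' @export
generate_minute_counts <- function(scenario = scenario_config()) {
  stopifnot(inherits(scenario, "scenario_config"))
  d <- scenario$design
  n <- d$days * d$sessions_per_day * d$minutes_per_session
  if (n == 0) {
    ann <- data.frame(minute_index = integer(0), date_id = integer(0),
                      session_id = integer(0), season = character(0),
                      time_of_day = character(0), grouping = character(0),
                      training = character(0), enrichment = character(0),
                      toys = integer(0), humans = integer(0),
                      humans_and_toys = integer(0), new_object = integer(0),
                      live_fish = integer(0), unusual_event = character(0),
                      visitors = character(0), n_individuals = integer(0))
    return(list(minutes = data.frame(minute_index = integer(0),
                                     click_count = integer(0)),
                annotations = ann))
  }
  withr::with_seed(scenario$seed, {
    date_id <- rep(seq_len(d$days), each = d$sessions_per_day * d$minutes_per_session)
    session_id <- rep(seq_len(d$days * d$sessions_per_day),
                      each = d$minutes_per_session)
    # season: four equal consecutive blocks of days across the study year
    season_levels <- c("winter", "spring", "summer", "fall")
    season <- season_levels[pmax(1L, ceiling(date_id * 4 / d$days))]
    time_of_day <- c("morning", "noon", "afternoon")[(session_id - 1L) %% 3L + 1L]
    draw <- function(p, size) sample(names(p), size, replace = TRUE, prob = p)
    cp <- scenario$context_probs
    grouping <- draw(cp$grouping, n)
    training <- draw(cp$training, n)
    enrichment <- draw(cp$enrichment, n)
    unusual_event <- draw(cp$unusual_event, n)
    visitors <- draw(cp$visitors, n)
    n_ind_session <- scenario$n_individuals_levels[
      sample.int(length(scenario$n_individuals_levels),
                 d$days * d$sessions_per_day, replace = TRUE,
                 prob = scenario$n_individuals_probs)]
    n_individuals <- n_ind_session[session_id]

    mult <- function(var, level) scenario$effect_multipliers[[var]][level]
    log_lambda <- log(n_individuals) + log(scenario$baseline_rate) +
      log(mult("season", season)) + log(mult("time_of_day", time_of_day)) +
      log(mult("grouping", grouping)) + log(mult("training", training)) +
      log(mult("enrichment", enrichment)) +
      log(mult("unusual_event", unusual_event)) +
      log(mult("visitors", visitors))
    u_date <- stats::rnorm(d$days, 0, scenario$re_sd[["date"]])
    v_sess <- stats::rnorm(d$days * d$sessions_per_day, 0,
                           scenario$re_sd[["session"]])
    e_obs <- stats::rnorm(n, 0, scenario$re_sd[["obs"]])
    log_lambda <- log_lambda + u_date[date_id] + v_sess[session_id] + e_obs
    counts <- stats::rpois(n, exp(log_lambda))

    annotations <- data.frame(
      minute_index = seq_len(n) - 1L, date_id = date_id,
      session_id = session_id, season = season, time_of_day = time_of_day,
      grouping = grouping, training = training, enrichment = enrichment,
      toys = as.integer(enrichment == "toys"),
      humans = as.integer(enrichment == "humans"),
      humans_and_toys = as.integer(enrichment == "humans_and_toys"),
      new_object = as.integer(enrichment == "new_object"),
      live_fish = as.integer(enrichment == "live_fish"),
      unusual_event = unusual_event, visitors = visitors,
      n_individuals = n_individuals
    )
    list(minutes = data.frame(minute_index = seq_len(n) - 1L,
                              click_count = as.integer(counts)),
         annotations = annotations)
  })
}
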
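# Fixtures are built in code; heavier simulated datasets are created once
# per test run and memoised here.

# minimal hand-written record set: one survey, known outcomes
toy_records <- function() {
  data.frame(
    survey_id = "s1",
    survey_year = 2010L,
    birth_year = c(1980L, 1985L, 1988L, 1990L),
    age_at_report = c(30L, 25L, 22L, 20L),
    ever_sex = c(1L, 1L, 1L, 0L),
    reported_afs = c(15L, 17L, 19L, NA),
    design_weight = 1
  )
}

# records drawn from a single log-skew-logistic distribution, one survey,
# interviewed at a fixed old age so censoring is negligible
iid_lsl_records <- function(n, rate = 1 / 17, shape = 8, skew = 0.6,
                            seed = 1, report_age = 45L) {
  set.seed(seed)
  t_draw <- rlsl(n, rate, shape, skew)
  censored <- t_draw >= report_age
  data.frame(
    survey_id = "s1",
    survey_year = 2020L,
    birth_year = 2020L - report_age,
    age_at_report = report_age,
    ever_sex = as.integer(!censored),
    reported_afs = ifelse(censored, NA_real_, floor(t_draw)),
    design_weight = 1
  )
}

.fixture_env <- new.env(parent = emptyenv())

# memoised simulated multi-survey dataset for the given scenario settings
sim_fixture <- function(trend, bias_type, n_surveys, seed = 99,
                        sample_per_survey = 1000L, pop_size = 1e5) {
  key <- paste(trend, bias_type, n_surveys, seed, sample_per_survey)
  if (is.null(.fixture_env[[key]])) {
    sc <- afs_scenario(trend = trend, bias_type = bias_type,
                       n_surveys = n_surveys, pop_size = pop_size,
                       sample_per_survey = sample_per_survey)
    .fixture_env[[key]] <- simulate_surveys(sc, seed = seed)
  }
  .fixture_env[[key]]
}
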
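# Readers/writers and the command-line entry point. One CSV dialect
# throughout: comma-separated, UTF-8, header row, empty string = missing;
# ages and years integer, weights decimal. Config files are JSON.

#' Read survey records from CSV
#'
#' Reads and validates records in the fixed schema (`survey_id`,
#' `survey_year`, `birth_year`, `age_at_report`, `ever_sex`, `reported_afs`,
#' `design_weight`). Rows reporting ever having had sex but with a missing
#' AFS (unknown AFS) are dropped, with the count reported in a message and
#' in the `n_dropped_unknown` attribute.
#'
#' @param path CSV file path.
#' @return validated record data frame.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df <- validate_records(df)
  nd <- attr(df, "n_dropped_unknown")
  if (nd > 0) message("dropped ", nd, " record(s) with unknown AFS")
  df
}

#' Write survey records to CSV
#'
#' @param records record data frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

spec_hash <- function(spec) {
  s <- paste(vapply(spec, function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Write a fitted model to JSON
#'
#' Serialises the specification, mode, covariance and metadata (seed, spec
#' hash, package version). Reruns with the same inputs and seed produce
#' byte-identical files.
#'
#' @param fitted an [fit_afs()] result.
#' @param path output path.
#' @param seed the seed used for the fit, echoed into the file.
#' @export
write_fit <- function(fitted, path, seed = NA_integer_) {
  obj <- list(
    package = "afstrend",
    version = as.character(utils::packageVersion("afstrend")),
    seed = seed,
    spec = unclass(fitted$spec),
    spec_hash = spec_hash(fitted$spec),
    mode = fitted$mode,
    covariance = fitted$covariance,
    converged = fitted$converged,
    n_obs = fitted$n_obs,
    log_posterior = fitted$log_posterior,
    cohorts = fitted$cohorts,
    ages = fitted$ages
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path path written by [write_fit()].
#' @return an object of class `afs_fit`.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(afs_spec, obj$spec[c("distribution", "cohort_effect",
                                       "age_effect", "reference_age",
                                       "pc_prior_u", "pc_prior_alpha")])
  spec$cohort_range <- range(obj$cohorts)
  spec$age_range <- range(obj$ages)
  cohorts <- as.integer(obj$cohorts)
  ages <- as.integer(obj$ages)
  dat <- list(cohorts = cohorts, ages = ages, spec = spec)
  layout <- param_layout(dat)
  cov <- obj$covariance
  if (!is.null(cov)) cov <- matrix(unlist(cov), nrow = length(obj$mode))
  pp <- unpack_params(obj$mode, dat, layout)
  structure(list(
    spec = spec, mode = obj$mode, layout = layout,
    params = list(beta0 = pp$beta0, f = pp$f, b = pp$b, p = pp$p,
                  gamma = pp$gamma),
    covariance = cov, converged = obj$converged, n_obs = obj$n_obs,
    log_posterior = obj$log_posterior,
    cohorts = cohorts, ages = ages,
    cohort_centered = cohorts - mean(cohorts),
    age_centered = ages - mean(ages)
  ), class = "afs_fit")
}

# ---- command-line interface ----------------------------------------------

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      out[[substring(a, 3)]] <- if (i < length(args) &&
                                      !startsWith(args[i + 1], "--")) {
        i <- i + 1
        args[i]
      } else TRUE
    }
    i <- i + 1
  }
  out
}

cli_spec <- function(opts) {
  if (!is.null(opts$spec)) {
    cfg <- jsonlite::read_json(opts$spec, simplifyVector = TRUE)
    do.call(afs_spec, cfg)
  } else {
    afs_spec_m(if (is.null(opts$model)) "M5" else opts$model)
  }
}

cli_scenario <- function(opts) {
  if (!is.null(opts$scenario)) {
    cfg <- jsonlite::read_json(opts$scenario, simplifyVector = TRUE)
    do.call(afs_scenario, cfg)
  } else afs_scenario()
}

#' Command-line entry point
#'
#' Subcommands: `fit` (`--data records.csv --out fitted.json [--spec
#' spec.json | --model M1..M5] [--seed N]`), `summarize` (`--fitted
#' fitted.json --data records.csv --draws N --medians out.csv --bias
#' out.csv`), `cv` (`--data records.csv --models M3,M5 --K 10 --draws N
#' --out cv.csv`), `simulate` (`--scenario scenario.json --out records.csv
#' [--truth truth.csv]`), `study` (`--scenario scenario.json --reps N --out
#' metrics.csv`), `describe` (`--data records.csv --cutoff 18 --props
#' props.csv --km km.csv`). Every stochastic command takes `--seed`
#' (default 1), echoed into outputs.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the primary result object.
#' @export
afs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <fit|summarize|cv|simulate|study|describe> ",
                          "--flag value ...", call. = FALSE)
  cmd <- args[1]
  opts <- cli_args(args[-1])
  seed <- as.integer(if (is.null(opts$seed)) 1 else opts$seed)
  res <- switch(cmd,
    fit = {
      recs <- read_records(opts$data)
      fit <- fit_afs(recs, cli_spec(opts), seed = seed)
      write_fit(fit, opts$out, seed = seed)
      message("fit written to ", opts$out,
              if (!fit$converged) " (NOT converged)" else "")
      fit
    },
    summarize = {
      fit <- read_fit(opts$fitted)
      nd <- as.integer(if (is.null(opts$draws)) 1000 else opts$draws)
      draws <- posterior_draws(fit, n_draws = nd, seed = seed)
      med <- median_afs_by_cohort(fit, draws)
      if (!is.null(opts$medians))
        utils::write.csv(med, opts$medians, row.names = FALSE)
      bc <- bias_curve(fit, if (nrow(bias_curve(fit))) draws)
      if (!is.null(opts$bias))
        utils::write.csv(bc, opts$bias, row.names = FALSE)
      list(medians = med, bias = bc)
    },
    cv = {
      recs <- read_records(opts$data)
      labels <- strsplit(if (is.null(opts$models)) "M1,M2,M3,M4,M5"
                         else opts$models, ",")[[1]]
      dists <- strsplit(if (is.null(opts$dist)) "logskewlogistic"
                        else opts$dist, ",")[[1]]
      specs <- list()
      for (d in dists) for (m in labels)
        specs[[paste(m, d, sep = "_")]] <- afs_spec_m(m, distribution = d)
      K <- as.integer(if (is.null(opts$K)) 10 else opts$K)
      nd <- as.integer(if (is.null(opts$draws)) 1000 else opts$draws)
      tab <- compare_models(recs, specs, K = K, n_draws = nd, seed = seed)
      tab$seed <- seed
      if (!is.null(opts$out)) utils::write.csv(tab, opts$out,
                                               row.names = FALSE)
      tab
    },
    simulate = {
      sc <- cli_scenario(opts)
      recs <- simulate_surveys(sc, seed = seed)
      write_records(recs, opts$out)
      if (!is.null(opts$truth)) {
        yrs <- seq.int(sc$birth_span[1], sc$birth_span[2])
        utils::write.csv(data.frame(
          birth_year = yrs,
          true_median = true_median_for_cohort(yrs, sc), seed = seed),
          opts$truth, row.names = FALSE)
      }
      recs
    },
    study = {
      sc <- cli_scenario(opts)
      reps <- as.integer(if (is.null(opts$reps)) 100 else opts$reps)
      st <- run_study(sc, n_reps = reps, seed = seed)
      st$summary$seed <- seed
      if (!is.null(opts$out)) utils::write.csv(st$summary, opts$out,
                                               row.names = FALSE)
      st
    },
    describe = {
      recs <- read_records(opts$data)
      cutoff <- as.integer(if (is.null(opts$cutoff)) 18 else opts$cutoff)
      props <- prop_before_age(recs, cutoff = cutoff)
      if (!is.null(opts$props)) utils::write.csv(props, opts$props,
                                                 row.names = FALSE)
      km <- km_survival(recs)
      if (!is.null(opts$km))
        utils::write.csv(as.data.frame(km), opts$km, row.names = FALSE)
      list(props = props, km = km)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(res)
}
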
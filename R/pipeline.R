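# Configuration-driven orchestration: cohort -> risk matrices -> engine ->
# economics, with table-shaped reports and provenance logging.

#' Demonstration run configuration
#'
#' A complete configuration for the bundled demonstration analysis: generate
#' a synthetic cohort at the default stratum targets, build intervention and
#' counterfactual matrices with the default coefficient tables and post-event
#' rows, run the 20-year / 3%-discount simulation, and cost it with the
#' (clearly flagged) placeholder healthcare schedule.
#'
#' @param seed master seed for the run.
#' @return an object of class `run_config` (a named list; serializable with
#'   [write_run_config()]).
#' @export
demo_run_config <- function(seed = 1L) {
  structure(list(
    schema_version = 1L,
    seed = as.integer(seed),
    cohort = list(path = NULL, n_per_stratum = NULL,
                  dispersions = list(age = 8, sbp = 15, total_cholesterol = 35)),
    sbp_projection = 12,
    settings = list(horizon = 20L, cycle_length = 1, discount_rate = 0.03,
                    reward_timing = "cycle-start"),
    age_update = FALSE,
    validation_policy = "renormalize",
    costs = list(allow_placeholder = TRUE)
  ), class = "run_config")
}

#' Read and write run configurations
#'
#' YAML round-trip of a `run_config`; `read_run_config()` validates the
#' schema version and field types.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` invisibly returns `path`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("run config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(config) {
  if (!is.list(config)) stop_config("run config must be a list")
  if (!identical(as.integer(config$schema_version %||% 0L), 1L))
    stop_config("unsupported config schema_version (expected 1)")
  if (!is_number(config$seed %||% NA))
    stop_config("config requires an integer seed")
  pol <- config$validation_policy %||% "renormalize"
  if (!pol %in% c("renormalize", "error", "residual_to_self",
                  "residual_to_extra_state"))
    stop_config("unknown validation policy '%s'", pol)
  if (!is.null(config$cohort$path) && !file.exists(config$cohort$path))
    stop_config("cohort path not resolvable: %s", config$cohort$path)
  st <- config$settings %||% list()
  do.call(simulation_settings,
          st[intersect(names(st), c("horizon", "cycle_length", "discount_rate",
                                    "reward_timing"))])
  config
}

config_hash <- function(config) fnv1a32(yaml::as.yaml(unclass(config)))

#' Run the full cost-utility pipeline
#'
#' Executes, for each of the four sex-by-diabetes strata and both scenarios:
#' cohort generation (or loading), cohort summary, transition-matrix
#' construction, the Markov cohort simulation, costing, and the
#' intervention-versus-counterfactual comparison. Rerunning an identical
#' config and seed reproduces identical results; every warning raised along
#' the way is collected into the bundle's log.
#'
#' @param config a `run_config` (see [demo_run_config()],
#'   [read_run_config()]).
#' @param verbose emit log lines as messages while running.
#' @return a `result_bundle`: list with `profiles` (summarized stratum
#'   inputs), `runs` (per stratum: intervention and counterfactual, each
#'   with `matrix`, `trace`, `costs`), `ce` (per-stratum `ce_result` rows),
#'   `config`, `config_hash`, `seed`, `log`, and per-stage `timings`.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(demo_run_config(seed = 7))
#' report_tables(bundle, "results")
#' }
run_pipeline <- function(config = demo_run_config(), verbose = FALSE) {
  config <- validate_run_config(config)
  logs <- character()
  timings <- numeric()
  note <- function(level, event, ...) {
    line <- log_line(level, event, ...)
    logs <<- c(logs, line)
    if (verbose) message(line)
  }
  collect <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop_data("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
      }),
      warning = function(w) {
        note("warning", stage, message = shQuote(conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    res
  }

  note("info", "start", seed = config$seed, hash = config_hash(config))

  cohort <- collect("cohort", {
    if (!is.null(config$cohort$path)) {
      read_cohort(config$cohort$path)
    } else {
      params <- cohort_gen_params(
        dispersions = unlist(config$cohort$dispersions %||%
                               list(age = 8, sbp = 15, total_cholesterol = 35)),
        seed = config$seed)
      generate_cohort(params, n = config$cohort$n_per_stratum)
    }
  })
  profiles <- collect("summarize",
                      summarize_cohort(cohort,
                                       sbp_projection = config$sbp_projection %||% 12))
  note("info", "cohort", records = nrow(cohort), strata = nrow(profiles))

  st <- config$settings %||% list()
  settings <- do.call(simulation_settings,
                      st[intersect(names(st),
                                   c("horizon", "cycle_length",
                                     "discount_rate", "reward_timing"))])
  coeffs <- default_risk_coefficients()
  schedule <- cost_schedule()
  allow_ph <- isTRUE(config$costs$allow_placeholder)
  if (schedule$placeholder)
    note("warning", "costs", message = "'placeholder healthcare cost schedule'")
  policy <- config$validation_policy %||% "renormalize"
  note("info", "conventions", reward_timing = settings$reward_timing,
       discount_rate = settings$discount_rate, policy = policy)

  runs <- list()
  ce_rows <- list()
  for (i in seq_len(nrow(profiles))) {
    stratum <- profiles[i, ]
    pair <- list()
    for (scen in c("intervention", "counterfactual")) {
      stage <- sprintf("%s/%s", stratum$stratum, scen)
      pair[[scen]] <- collect(stage, {
        tm <- if (isTRUE(config$age_update)) {
          build_transition_matrices_aging(stratum, scenario_spec(scen),
                                          horizon = settings$horizon,
                                          cycle_length = settings$cycle_length,
                                          coeffs = coeffs, policy = policy)
        } else {
          build_transition_matrix(stratum, scenario_spec(scen),
                                  coeffs = coeffs, policy = policy)
        }
        tr <- run_cohort(tm, settings)
        costs <- expected_costs(tr, schedule, allow_placeholder = allow_ph)
        list(matrix = tm, trace = tr, costs = costs)
      })
    }
    runs[[stratum$stratum]] <- pair
    ce <- collect(sprintf("%s/compare", stratum$stratum),
                  compare_scenarios(pair$intervention, pair$counterfactual))
    ce_rows[[stratum$stratum]] <- cbind(stratum = stratum$stratum, ce)
  }
  ce <- do.call(rbind, ce_rows)
  rownames(ce) <- NULL
  note("info", "done", strata = nrow(profiles),
       scenario_runs = 2L * nrow(profiles))

  structure(list(profiles = profiles, runs = runs, ce = ce,
                 config = config, config_hash = config_hash(config),
                 seed = config$seed, log = logs, timings = timings),
            class = "result_bundle")
}

.fmt_money <- function(x, digits = 0)
  paste0("$", formatC(round_half_up(x, digits), format = "f", digits = digits,
                      big.mark = ","))

.fmt_pct <- function(x) paste0(round_half_up(100 * x), "%")

#' Report tables from a pipeline bundle
#'
#' Emits the study-shaped tables: `inputs` (stratum risk-factor inputs, one
#' column per stratum), `matrix` (a 5x5 annual transition matrix with its
#' utility row), `costs` (the program cost build-up), `results` (QALY / life
#' year / cost / ICER rows, one column per stratum). Display rounding is
#' round-half-up at the dollar (or printed) precision; the underlying bundle
#' values are unrounded. Pipeline warnings are attached as a `footer`
#' attribute.
#'
#' @param bundle a `result_bundle` from [run_pipeline()].
#' @param which one of `"inputs"`, `"matrix"`, `"costs"`, `"results"`.
#' @param stratum,scenario for `which = "matrix"`: which run's matrix to
#'   print (defaults: first stratum, counterfactual).
#' @param inputs for `which = "costs"`: the [program_cost_inputs()] to build
#'   up (defaults to the bundled line items).
#' @return a data.frame shaped like the corresponding report table.
#' @export
report_tables <- function(bundle, which = c("inputs", "matrix", "costs",
                                            "results"),
                          stratum = NULL, scenario = "counterfactual",
                          inputs = program_cost_inputs()) {
  if (!inherits(bundle, "result_bundle") || !length(bundle$runs))
    stop_data("bundle must be a non-empty result_bundle")
  if (length(which) != 1L || !which %in% c("inputs", "matrix", "costs", "results"))
    stop_config("unknown table '%s'; valid options: inputs, matrix, costs, results",
                paste(which, collapse = ","))

  pr <- bundle$profiles
  col_labels <- c(base_male = "Base male", male_diabetes = "Male diabetes",
                  base_female = "Base female", female_diabetes = "Female diabetes")
  cols <- ifelse(pr$stratum %in% names(col_labels),
                 col_labels[pr$stratum], pr$stratum)

  tab <- switch(which,
    inputs = {
      m <- rbind(
        "Age at entry (years)" = round_half_up(pr$mean_entry_age, 1),
        "Starting cholesterol (mg/DL)" = round_half_up(pr$mean_chol_baseline, 1),
        "Most recent cholesterol (mg/DL)" = round_half_up(pr$mean_chol_exit, 1),
        "Starting SBP (mmHg)" = round_half_up(pr$mean_sbp_baseline, 1),
        "Estimated SBP (mmHg)" = round_half_up(pr$mean_sbp_counterfactual, 1),
        "Using hypertension medication at baseline (%)" = .fmt_pct(pr$prop_htn_med_baseline),
        "Using hypertension medication at exit (%)" = .fmt_pct(pr$prop_htn_med_exit),
        "Smokers at baseline (%)" = .fmt_pct(pr$prop_smoker_baseline),
        "Smokers at exit (%)" = .fmt_pct(pr$prop_smoker_exit),
        "Sample size" = pr$n)
      out <- data.frame(`Risk factors` = rownames(m), m, check.names = FALSE,
                        stringsAsFactors = FALSE)
      names(out)[-1] <- cols
      out
    },
    matrix = {
      stratum <- stratum %||% pr$stratum[1]
      run <- bundle$runs[[stratum]][[scenario]]
      if (is.null(run)) stop_data("no run for stratum '%s' scenario '%s'",
                                  stratum, scenario)
      tm <- if (inherits(run$matrix, "transition_matrix")) run$matrix
            else run$matrix[[1]]    # age-updating mode: entry-age matrix
      P <- tm$probs
      labels <- .state_labels[tm$states]
      labels[is.na(labels)] <- tm$states[is.na(labels)]
      u <- run$trace$utilities[tm$states]
      out <- data.frame(`From (to)` = c(labels, "Utility"),
                        rbind(round(P, 4), round(as.numeric(u), 2)),
                        check.names = FALSE, stringsAsFactors = FALSE)
      names(out)[-1] <- labels
      rownames(out) <- NULL
      out
    },
    costs = {
      bd <- program_cost_per_participant(inputs)$breakdown
      items <- c(
        stats::setNames(.fmt_money(inputs$personnel, 2), names(inputs$personnel)),
        stats::setNames(.fmt_money(bd[["fringe"]], 2),
                        sprintf("Fringe (%d%%)", round(100 * inputs$fringe_rate))),
        "Total personnel cost" = .fmt_money(bd[["total_personnel"]], 2),
        stats::setNames(.fmt_money(inputs$operating, 2), names(inputs$operating)),
        "Total operating cost" = .fmt_money(bd[["total_operating"]], 2),
        "Total direct charges" = .fmt_money(bd[["total_direct"]], 2),
        "Total indirect charges" = .fmt_money(bd[["indirect"]], 2),
        "Total costs" = .fmt_money(bd[["total"]]),
        stats::setNames(.fmt_money(bd[["total"]] / inputs$panel_size),
                        sprintf("Average cost per participant (%d participants per panel)",
                                inputs$panel_size)))
      data.frame(Item = names(items), `Average panel costs` = unname(items),
                 check.names = FALSE, stringsAsFactors = FALSE)
    },
    results = {
      ce <- bundle$ce
      m <- rbind(
        "Discounted QALY with intervention" = round_half_up(ce$qaly_intervention, 1),
        "Discounted QALY without intervention" = round_half_up(ce$qaly_counterfactual, 1),
        "Discounted Life Years with intervention" = round_half_up(ce$ly_intervention, 1),
        "Discounted Life Years without intervention" = round_half_up(ce$ly_counterfactual, 1),
        "Cost with intervention" = .fmt_money(ce$cost_undisc_intervention),
        "Total cost without intervention" = .fmt_money(ce$cost_undisc_counterfactual),
        "Discounted cost with intervention" = .fmt_money(ce$cost_intervention),
        "Discounted cost without intervention" = .fmt_money(ce$cost_counterfactual),
        "Gain in discounted QALYs" = round_half_up(ce$delta_qaly, 1),
        "Gain in discounted Life Years" = round_half_up(ce$delta_ly, 1),
        "Incremental cost" = .fmt_money(ce$incremental_cost),
        "Cost per QALY gained" = ifelse(is.na(ce$cost_per_qaly), ce$flag_qaly,
                                        .fmt_money(ce$cost_per_qaly)),
        "Cost per Life Year gained" = ifelse(is.na(ce$cost_per_ly), ce$flag_ly,
                                             .fmt_money(ce$cost_per_ly)))
      out <- data.frame(` ` = rownames(m), m, check.names = FALSE,
                        stringsAsFactors = FALSE)
      names(out)[-1] <- ifelse(ce$stratum %in% names(col_labels),
                               col_labels[ce$stratum], ce$stratum)
      rownames(out) <- NULL
      out
    })
  attr(tab, "footer") <- grep("level=warning", bundle$log, value = TRUE)
  tab
}

#' Write a result bundle to disk
#'
#' Writes the four report tables (tab-separated, UTF-8), one trace table per
#' stratum and scenario, each scenario's transition matrix, the log, and a
#' `manifest.yaml` carrying the config hash, seed, package version and
#' per-stage timings. Apart from the manifest's timing block, outputs from
#' identical configs and seeds are byte-identical.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "result_bundle")) stop_data("bundle must be a result_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(tab, name) {
    p <- file.path(dir, name)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    footer <- attr(tab, "footer")
    if (length(footer)) cat(paste0("# ", footer, "\n"), file = p, append = TRUE)
    paths <<- c(paths, p)
  }
  for (w in c("inputs", "costs", "results"))
    put(report_tables(bundle, w), paste0(w, ".tsv"))
  for (strat in names(bundle$runs)) {
    for (scen in names(bundle$runs[[strat]])) {
      run <- bundle$runs[[strat]][[scen]]
      put(report_tables(bundle, "matrix", stratum = strat, scenario = scen),
          sprintf("matrix_%s_%s.tsv", strat, scen))
      put(trace_table(run$trace), sprintf("trace_%s_%s.tsv", strat, scen))
    }
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  yaml::write_yaml(list(config_hash = bundle$config_hash,
                        seed = bundle$seed,
                        package_version = as.character(utils::packageVersion("markovcea")),
                        timings = as.list(round(bundle$timings, 3))),
                   file.path(dir, "manifest.yaml"))
  invisible(c(paths, file.path(dir, c("run.log", "manifest.yaml"))))
}
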
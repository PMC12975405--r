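# Framingham-style risk functions: multi-year event risks from risk-factor
# profiles, converted to annual transition probabilities.

.risk_factors <- c("age", "female", "total_cholesterol", "sbp",
                   "diabetes", "smoker", "on_htn_medication")

#' Risk coefficient set for one event type
#'
#' A proportional-hazards style risk function for a single first-event type.
#' The `t`-year event risk at a profile `x` is
#' `1 - (1 - baseline_risk)^exp(lp)` with linear predictor
#' `lp = sum(coefficients * (x - reference))`, i.e. `baseline_risk` is the
#' risk over the function's horizon at the reference profile. Coefficient
#' keys are health-assessment fields (`age`, `total_cholesterol`, `sbp`,
#' `diabetes`, `smoker`, `on_htn_medication`) plus the declared transform
#' `female` (sex as an indicator). Sets are opaque, swappable parameter
#' tables: see [read_coefficients()] for the file format.
#'
#' @param event_type one of `"stroke"`, `"mi"`, `"chf"`, `"noncvd_death"`.
#' @param coefficients named numeric vector of log-hazard slopes.
#' @param baseline_risk event risk over `horizon` years at the reference
#'   profile, in `[0, 1)`.
#' @param horizon risk horizon of the source function, in years (> 0).
#' @param reference named numeric vector: the profile at which `lp = 0`.
#' @param provenance free-text label identifying the source function/version.
#' @return an object of class `risk_coefficient_set`.
#' @export
risk_coefficient_set <- function(event_type, coefficients, baseline_risk,
                                 horizon, reference, provenance = "unspecified") {
  event_type <- match.arg(event_type, c("stroke", "mi", "chf", "noncvd_death"))
  bad <- setdiff(names(coefficients), .risk_factors)
  if (length(bad))
    stop_config("unknown risk factor(s) in coefficient set: %s",
                paste(bad, collapse = ", "))
  if (!all(names(coefficients) %in% names(reference)))
    stop_config("reference profile must cover every coefficient key")
  if (!is_number(horizon) || horizon <= 0)
    stop_config("risk horizon must be a positive number of years")
  if (!is_number(baseline_risk) || baseline_risk < 0 || baseline_risk >= 1)
    stop_config("baseline risk must lie in [0, 1)")
  structure(list(event_type = event_type,
                 coefficients = coefficients,
                 baseline_risk = baseline_risk,
                 horizon = horizon,
                 reference = reference[names(coefficients)],
                 provenance = provenance),
            class = "risk_coefficient_set")
}

#' Default risk coefficient tables
#'
#' Package-authored coefficient sets for first stroke, first myocardial
#' infarction, incident congestive heart failure, and non-cardiovascular
#' death. Slopes are literature-plausible log-hazard gradients for the seven
#' model risk factors; each event's baseline risk is calibrated so the
#' annualized probabilities at the reference profile (a 66.2-year-old male,
#' cholesterol 162 mg/dL, SBP 141 mmHg, no diabetes, stratum-mean smoking
#' 0.27 and medication use 0.06) equal the model's published counterfactual
#' healthy-row values (stroke 0.0070, MI 0.0090, CHF 0.0100, death 0.0198).
#' The antihypertensive-treatment coefficient is negative (protective),
#' reflecting the modelled causal benefit of appropriate medication rather
#' than the risk-marker role treatment plays in observational scores.
#' Synthetic calibration; fully replaceable via [read_coefficients()].
#'
#' @return named list of [risk_coefficient_set()] objects
#'   (`stroke`, `mi`, `chf`, `noncvd_death`).
#' @export
default_risk_coefficients <- function() {
  ref <- c(age = 66.2, female = 0, total_cholesterol = 162, sbp = 141,
           diabetes = 0, smoker = 0.27, on_htn_medication = 0.06)
  prov <- "markovcea-default-v1 (synthetic, calibrated)"
  ten <- function(p1) 1 - (1 - p1)^10   # annual -> 10-year at reference
  list(
    stroke = risk_coefficient_set(
      "stroke",
      c(age = 0.066, female = -0.30, total_cholesterol = 0.001, sbp = 0.017,
        diabetes = 0.60, smoker = 0.50, on_htn_medication = -0.15),
      baseline_risk = ten(0.0070), horizon = 10, reference = ref,
      provenance = prov),
    mi = risk_coefficient_set(
      "mi",
      c(age = 0.055, female = -0.55, total_cholesterol = 0.006, sbp = 0.012,
        diabetes = 0.55, smoker = 0.60, on_htn_medication = -0.15),
      baseline_risk = ten(0.0090), horizon = 10, reference = ref,
      provenance = prov),
    chf = risk_coefficient_set(
      "chf",
      c(age = 0.075, female = -0.30, total_cholesterol = 0.001, sbp = 0.014,
        diabetes = 0.80, smoker = 0.45, on_htn_medication = -0.15),
      baseline_risk = ten(0.0100), horizon = 10, reference = ref,
      provenance = prov),
    noncvd_death = risk_coefficient_set(
      "noncvd_death",
      c(age = 0.090, female = -0.30, smoker = 0.30),
      baseline_risk = 0.0198, horizon = 1,
      reference = ref, provenance = prov)
  )
}

#' Convert a multi-year risk to an annual probability
#'
#' Constant-hazard conversion: a risk `R` accumulated over `t` years implies
#' annual probability `1 - (1 - R)^(1/t)`. Exact inverse of annual
#' compounding, monotone increasing in `R`, and the identity when `t = 1`.
#'
#' @param risk event risk over `t` years, in `[0, 1]`.
#' @param t risk horizon in years (> 0).
#' @return annual event probability.
#' @export
#' @examples
#' multi_year_to_annual(0.19, 10)  # 0.02085
multi_year_to_annual <- function(risk, t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop_config("risk horizon t must be positive")
  if (any(!is.finite(risk)) || any(risk < 0) || any(risk > 1))
    stop_config("risk must lie in [0, 1]")
  1 - (1 - risk)^(1 / t)
}

#' Annual event probability for a risk-factor profile
#'
#' Evaluates a coefficient set at a profile and annualizes the resulting
#' multi-year risk with [multi_year_to_annual()]. Profiles may carry
#' fractional values for the binary factors (cohort means), which evaluates
#' the risk function at the stratum-average profile.
#'
#' @param profile named numeric vector supplying every factor the
#'   coefficient set names (`female` = 1 for female, 0 for male).
#' @param coeffs a [risk_coefficient_set()].
#' @return annual event probability in `[0, 1]`.
#' @export
annual_event_probability <- function(profile, coeffs) {
  if (!inherits(coeffs, "risk_coefficient_set"))
    stop_config("coeffs must be a risk_coefficient_set")
  need <- names(coeffs$coefficients)
  missing <- setdiff(need, names(profile))
  if (length(missing))
    stop_data("profile missing risk factor(s): %s", paste(missing, collapse = ", "))
  x <- as.numeric(profile[need])
  lp <- sum(coeffs$coefficients * (x - as.numeric(coeffs$reference)))
  if (!is.finite(lp))
    stop_numeric("non-finite linear predictor for profile: %s",
                 paste(sprintf("%s=%s", need, profile[need]), collapse = ", "))
  risk_t <- 1 - (1 - coeffs$baseline_risk)^exp(lp)
  if (!is.finite(risk_t))
    stop_numeric("non-finite %d-year risk for profile: %s", coeffs$horizon,
                 paste(sprintf("%s=%s", need, profile[need]), collapse = ", "))
  p <- multi_year_to_annual(min(max(risk_t, 0), 1), coeffs$horizon)
  if (p < 0 || p > 1) {
    warning(sprintf("annual probability clamped to [0,1] for event %s",
                    coeffs$event_type))
    p <- min(max(p, 0), 1)
  }
  p
}

#' Scenario specification
#'
#' Maps each model risk factor to the stratum quantity that feeds it. The
#' default `intervention` scenario uses exit medication, smoking and
#' cholesterol values with the observed (baseline) SBP; the default
#' `counterfactual` freezes every factor at baseline except SBP, which uses
#' the projected counterfactual value (baseline + 12 mmHg). Both evaluate at
#' entry age.
#'
#' @param scenario `"intervention"` or `"counterfactual"`.
#' @param sources optional named character vector overriding the per-factor
#'   source rule; values among `"baseline"`, `"exit"`, `"counterfactual"`.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("intervention", "counterfactual"),
                          sources = NULL) {
  scenario <- match.arg(scenario)
  rules <- if (scenario == "intervention") {
    c(age = "baseline", total_cholesterol = "exit", sbp = "baseline",
      on_htn_medication = "exit", smoker = "exit")
  } else {
    c(age = "baseline", total_cholesterol = "baseline", sbp = "counterfactual",
      on_htn_medication = "baseline", smoker = "baseline")
  }
  if (!is.null(sources)) {
    bad <- setdiff(names(sources), names(rules))
    if (length(bad))
      stop_config("unknown risk factor(s) in scenario sources: %s",
                  paste(bad, collapse = ", "))
    if (!all(sources %in% c("baseline", "exit", "counterfactual")))
      stop_config("scenario sources must be baseline, exit or counterfactual")
    rules[names(sources)] <- sources
  }
  structure(list(scenario = scenario, sources = rules), class = "scenario_spec")
}

# Resolve a stratum profile row + scenario into the risk-factor vector the
# coefficient sets consume.
scenario_profile <- function(stratum, scenario) {
  if (!inherits(scenario, "scenario_spec"))
    stop_config("scenario must be a scenario_spec")
  pick <- function(factor, baseline, exit, counterfactual = baseline) {
    switch(scenario$sources[[factor]],
           baseline = baseline, exit = exit, counterfactual = counterfactual)
  }
  c(age = pick("age", stratum$mean_entry_age, stratum$mean_entry_age),
    female = as.numeric(stratum$sex == "female"),
    total_cholesterol = pick("total_cholesterol", stratum$mean_chol_baseline,
                             stratum$mean_chol_exit),
    sbp = pick("sbp", stratum$mean_sbp_baseline, stratum$mean_sbp_baseline,
               stratum$mean_sbp_counterfactual),
    diabetes = as.numeric(stratum$diabetes),
    smoker = pick("smoker", stratum$prop_smoker_baseline,
                  stratum$prop_smoker_exit),
    on_htn_medication = pick("on_htn_medication", stratum$prop_htn_med_baseline,
                             stratum$prop_htn_med_exit))
}

#' Read and write risk coefficient files
#'
#' Delimited text with a commented metadata header
#' (`# event=<type> horizon=<years> baseline_risk=<r> provenance=<label>`
#' and `# reference: key=value ...`) followed by tab-separated
#' `factor<TAB>coefficient` rows; one file per event type.
#'
#' @param path file path.
#' @param coeffs a `risk_coefficient_set`.
#' @return `read_coefficients()` returns a `risk_coefficient_set`;
#'   `write_coefficients()` invisibly returns `path`.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop_config("coefficient file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- function(line) {
    parts <- strsplit(trimws(sub("^#\\s*", "", line)), "\\s+")[[1]]
    pieces <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(vapply(pieces, function(p) paste(p[-1], collapse = "="), ""),
                    vapply(pieces, `[[`, "", 1))
  }
  head_kv <- kv(meta_lines[1])
  ref_line <- grep("^#\\s*reference:", meta_lines, value = TRUE)
  ref_kv <- kv(sub("reference:", "", ref_line[1]))
  body <- utils::read.delim(text = lines[!grepl("^#", lines) & nzchar(lines)],
                            header = FALSE, col.names = c("factor", "coefficient"),
                            stringsAsFactors = FALSE)
  risk_coefficient_set(
    event_type = head_kv[["event"]],
    coefficients = stats::setNames(body$coefficient, body$factor),
    baseline_risk = as.numeric(head_kv[["baseline_risk"]]),
    horizon = as.numeric(head_kv[["horizon"]]),
    reference = stats::setNames(as.numeric(ref_kv), names(ref_kv)),
    provenance = head_kv[["provenance"]] %||% "unspecified")
}

#' @rdname read_coefficients
#' @export
write_coefficients <- function(coeffs, path) {
  if (!inherits(coeffs, "risk_coefficient_set"))
    stop_config("coeffs must be a risk_coefficient_set")
  header <- c(
    sprintf("# event=%s horizon=%s baseline_risk=%.12g provenance=%s",
            coeffs$event_type, format(coeffs$horizon), coeffs$baseline_risk,
            coeffs$provenance),
    paste("# reference:", paste(sprintf("%s=%.12g", names(coeffs$reference),
                                        coeffs$reference), collapse = " ")))
  body <- sprintf("%s\t%.12g", names(coeffs$coefficients), coeffs$coefficients)
  writeLines(c(header, body), path)
  invisible(path)
}
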
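# Synthetic health-assessment cohorts: generation, summary, CSV I/O.

# Valid ranges for a health-assessment record.
.range_age  <- c(18, 110)
.range_sbp  <- c(70, 260)
.range_chol <- c(80, 400)

.cohort_cols <- c("participant_id", "timepoint", "age", "sex", "diabetes",
                  "total_cholesterol", "sbp", "on_htn_medication", "smoker")

#' Default sex-by-diabetes stratum profiles
#'
#' Baseline and exit risk-factor targets for the four strata of the study
#' population (males and females, with and without diabetes): mean entry age,
#' total cholesterol (mg/dL) and systolic blood pressure (mmHg) at baseline,
#' the projected counterfactual SBP (baseline + 12 mmHg in every stratum),
#' and the proportions using antihypertensive medication and smoking at
#' baseline and at program exit.
#'
#' These serve both as generating targets for [generate_cohort()] and as the
#' risk-factor inputs from which scenario transition matrices are built.
#'
#' @return a data.frame with one row per stratum and columns
#'   `stratum`, `sex`, `diabetes`, `n`, `mean_entry_age`,
#'   `mean_chol_baseline`, `mean_chol_exit`, `mean_sbp_baseline`,
#'   `mean_sbp_counterfactual`, `prop_htn_med_baseline`, `prop_htn_med_exit`,
#'   `prop_smoker_baseline`, `prop_smoker_exit`.
#' @export
#' @examples
#' default_stratum_profiles()
default_stratum_profiles <- function() {
  data.frame(
    stratum  = c("base_male", "male_diabetes", "base_female", "female_diabetes"),
    sex      = c("male", "male", "female", "female"),
    diabetes = c(FALSE, TRUE, FALSE, TRUE),
    n        = c(1395L, 581L, 3091L, 1087L),
    mean_entry_age          = c(66.2, 66.6, 68.9, 67.9),
    mean_chol_baseline      = c(162, 180, 195, 173),
    mean_chol_exit          = c(160, 179, 194, 174),
    mean_sbp_baseline       = c(129, 141, 130, 131),
    mean_sbp_counterfactual = c(141, 153, 142, 143),
    prop_htn_med_baseline   = c(0.06, 0.22, 0.14, 0.06),
    prop_htn_med_exit       = c(0.40, 0.60, 0.41, 0.68),
    prop_smoker_baseline    = c(0.27, 0.17, 0.15, 0.14),
    prop_smoker_exit        = c(0.24, 0.15, 0.13, 0.12),
    stringsAsFactors = FALSE
  )
}

.validate_profiles <- function(profiles) {
  need <- setdiff(names(default_stratum_profiles()), "stratum")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop_config("stratum profiles missing column(s): %s",
                paste(missing, collapse = ", "))
  props <- c("prop_htn_med_baseline", "prop_htn_med_exit",
             "prop_smoker_baseline", "prop_smoker_exit")
  for (p in props) {
    bad <- !is.finite(profiles[[p]]) | profiles[[p]] < 0 | profiles[[p]] > 1
    if (any(bad))
      stop_config("proportion '%s' outside [0, 1] in stratum %s",
                  p, paste(profiles$stratum[bad], collapse = ", "))
  }
  if (any(profiles$n <= 0)) stop_config("stratum sample size must be positive")
  if (any(profiles$prop_smoker_exit > profiles$prop_smoker_baseline + 1e-12))
    stop_config("smoking may only decline between baseline and exit (smokers quit, non-smokers do not start)")
  if (any(profiles$prop_htn_med_exit < profiles$prop_htn_med_baseline - 1e-12))
    stop_config("medication use may only rise between baseline and exit (use starts, it does not stop)")
  if (anyDuplicated(paste(profiles$sex, profiles$diabetes)))
    stop_config("each sex-by-diabetes stratum may appear at most once")
  invisible(profiles)
}

#' Cohort generator parameters
#'
#' Bundles stratum targets, the continuous-variable dispersions, and the
#' master random seed. Continuous variables are drawn from normal
#' distributions centred at the stratum means and truncated to the valid
#' ranges (age 18-110 y, SBP 70-260 mmHg, cholesterol 80-400 mg/dL); binary
#' variables are Bernoulli draws whose expected baseline and exit proportions
#' match the targets. The default spreads (age 8 y, SBP 15 mmHg, cholesterol
#' 35 mg/dL) are plausible population values for an older adult cohort; the
#' source tables report only means and proportions, so dispersions are
#' generator settings, not observed quantities.
#'
#' @param profiles stratum targets, as [default_stratum_profiles()].
#' @param dispersions named numeric vector with elements `age`, `sbp`,
#'   `total_cholesterol` giving the (pre-truncation) standard deviations in
#'   the variable's own units. All must be non-negative.
#' @param seed master integer seed; per-stratum substreams are derived from
#'   it deterministically, so a fixed seed yields byte-identical cohorts.
#' @return an object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(profiles = default_stratum_profiles(),
                              dispersions = c(age = 8, sbp = 15,
                                              total_cholesterol = 35),
                              seed = 1L) {
  .validate_profiles(profiles)
  need <- c("age", "sbp", "total_cholesterol")
  if (!all(need %in% names(dispersions)))
    stop_config("dispersions must name: %s", paste(need, collapse = ", "))
  if (any(!is.finite(dispersions[need])) || any(dispersions[need] < 0))
    stop_config("dispersions must be finite and non-negative")
  if (!is_number(seed)) stop_config("seed must be a single integer")
  structure(list(profiles = profiles,
                 dispersions = dispersions[need],
                 seed = as.integer(seed)),
            class = "cohort_gen_params")
}

# Inverse-CDF truncated normal; exact and reproducible under a fixed seed.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

#' Generate a synthetic health-assessment cohort
#'
#' Draws paired baseline and exit records per participant for each stratum in
#' `params`. Exit states are generated conditionally on baseline so that
#' transitions run one way only: smokers may quit (with the quit probability
#' implied by the baseline and exit targets) but non-smokers never start, and
#' participants may start antihypertensive medication but never stop it.
#' Exit cholesterol shifts each participant by the stratum's mean change;
#' exit SBP and age repeat the baseline values, since both scenarios evaluate
#' risk at entry age and the observed (intervention) SBP target equals the
#' baseline mean.
#'
#' @param params a [cohort_gen_params()] object.
#' @param n participants per stratum: `NULL` to use each stratum's `n`
#'   target, a single count applied to every stratum, or a vector named by
#'   stratum. `n = 0` yields an empty cohort.
#' @return a data.frame of health-assessment records, two rows (timepoints
#'   `baseline` and `exit`) per participant, with columns
#'   `participant_id`, `timepoint`, `age`, `sex`, `diabetes`,
#'   `total_cholesterol`, `sbp`, `on_htn_medication`, `smoker`.
#' @export
#' @examples
#' params <- cohort_gen_params(seed = 42)
#' coh <- generate_cohort(params, n = 50)
#' table(coh$timepoint)
generate_cohort <- function(params, n = NULL) {
  if (!inherits(params, "cohort_gen_params"))
    stop_config("params must be a cohort_gen_params object")
  pr <- params$profiles
  sizes <- if (is.null(n)) {
    stats::setNames(pr$n, pr$stratum)
  } else if (length(n) == 1L) {
    stats::setNames(rep(as.integer(n), nrow(pr)), pr$stratum)
  } else {
    if (!all(pr$stratum %in% names(n)))
      stop_config("named n must cover every stratum")
    stats::setNames(as.integer(n[pr$stratum]), pr$stratum)
  }
  if (any(sizes < 0)) stop_config("n must be non-negative")

  disp <- params$dispersions
  out <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    s <- pr[i, ]
    ni <- sizes[[s$stratum]]
    if (ni == 0L) next
    out[[i]] <- with_seed(stratum_seed(params$seed, s$stratum), {
      age  <- rtruncnorm(ni, s$mean_entry_age, disp[["age"]],
                         .range_age[1], .range_age[2])
      chol <- rtruncnorm(ni, s$mean_chol_baseline, disp[["total_cholesterol"]],
                         .range_chol[1], .range_chol[2])
      sbp  <- rtruncnorm(ni, s$mean_sbp_baseline, disp[["sbp"]],
                         .range_sbp[1], .range_sbp[2])
      smoker0 <- stats::runif(ni) < s$prop_smoker_baseline
      med0    <- stats::runif(ni) < s$prop_htn_med_baseline
      # One-directional exit transitions with the implied quit/start rates.
      p_quit <- if (s$prop_smoker_baseline > 0)
        1 - s$prop_smoker_exit / s$prop_smoker_baseline else 0
      p_start <- if (s$prop_htn_med_baseline < 1)
        (s$prop_htn_med_exit - s$prop_htn_med_baseline) /
          (1 - s$prop_htn_med_baseline) else 0
      smoker1 <- smoker0 & (stats::runif(ni) >= p_quit)
      med1    <- med0 | (stats::runif(ni) < p_start)
      chol1 <- pmin(pmax(chol + (s$mean_chol_exit - s$mean_chol_baseline),
                         .range_chol[1]), .range_chol[2])
      id <- sprintf("%s-%05d", s$stratum, seq_len(ni))
      rbind(
        data.frame(participant_id = id, timepoint = "baseline", age = age,
                   sex = s$sex, diabetes = s$diabetes,
                   total_cholesterol = chol, sbp = sbp,
                   on_htn_medication = med0, smoker = smoker0,
                   stringsAsFactors = FALSE),
        data.frame(participant_id = id, timepoint = "exit", age = age,
                   sex = s$sex, diabetes = s$diabetes,
                   total_cholesterol = chol1, sbp = sbp,
                   on_htn_medication = med1, smoker = smoker1,
                   stringsAsFactors = FALSE)
      )
    })
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    df <- data.frame(participant_id = character(), timepoint = character(),
                     age = numeric(), sex = character(), diabetes = logical(),
                     total_cholesterol = numeric(), sbp = numeric(),
                     on_htn_medication = logical(), smoker = logical(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a cohort into stratum profiles
#'
#' Aggregates health-assessment records into per-stratum means and
#' proportions (one row per observed sex-by-diabetes stratum), the same shape
#' as [default_stratum_profiles()]. Records missing a required field are
#' excluded with a warning that names the offending participants. The
#' counterfactual SBP column is the baseline mean plus `sbp_projection`
#' (default 12 mmHg, the projected rise in the absence of intervention).
#'
#' @param records a cohort data.frame as produced by [generate_cohort()] or
#'   [read_cohort()]; must contain baseline records.
#' @param sbp_projection mmHg added to baseline SBP for the counterfactual.
#' @return a stratum-profile data.frame.
#' @export
summarize_cohort <- function(records, sbp_projection = 12) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_data("records must be a non-empty cohort data.frame")
  missing_cols <- setdiff(.cohort_cols, names(records))
  if (length(missing_cols))
    stop_data("records missing column(s): %s", paste(missing_cols, collapse = ", "))

  bad <- !stats::complete.cases(records[.cohort_cols])
  if (any(bad)) {
    warning(sprintf("excluding %d record(s) with missing fields (participants: %s)",
                    sum(bad),
                    paste(unique(records$participant_id[bad]), collapse = ", ")))
    records <- records[!bad, , drop = FALSE]
  }
  base <- records[records$timepoint == "baseline", , drop = FALSE]
  if (nrow(base) == 0) stop_data("no baseline records present")
  ex <- records[records$timepoint == "exit", , drop = FALSE]

  key <- paste(base$sex, ifelse(base$diabetes, "diabetes", "base"))
  strata <- split(base, key)
  rows <- lapply(strata, function(b) {
    e <- ex[ex$participant_id %in% b$participant_id, , drop = FALSE]
    label <- if (b$diabetes[1]) paste0(b$sex[1], "_diabetes")
             else paste0("base_", b$sex[1])
    data.frame(
      stratum = label, sex = b$sex[1], diabetes = b$diabetes[1],
      n = nrow(b),
      mean_entry_age = mean(b$age),
      mean_chol_baseline = mean(b$total_cholesterol),
      mean_chol_exit = if (nrow(e)) mean(e$total_cholesterol) else NA_real_,
      mean_sbp_baseline = mean(b$sbp),
      mean_sbp_counterfactual = mean(b$sbp) + sbp_projection,
      prop_htn_med_baseline = mean(b$on_htn_medication),
      prop_htn_med_exit = if (nrow(e)) mean(e$on_htn_medication) else NA_real_,
      prop_smoker_baseline = mean(b$smoker),
      prop_smoker_exit = if (nrow(e)) mean(e$smoker) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  # canonical stratum order where present
  ord <- match(default_stratum_profiles()$stratum, res$stratum)
  res <- rbind(res[ord[!is.na(ord)], , drop = FALSE],
               res[setdiff(seq_len(nrow(res)), ord), , drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Read and write cohort CSV files
#'
#' The cohort file format is a UTF-8 comma-separated table with header
#' `participant_id,timepoint,age,sex,diabetes,total_cholesterol,sbp,on_htn_medication,smoker`;
#' booleans are written `0`/`1`, `timepoint` is `baseline` or `exit`.
#' `read_cohort()` validates every row (ranges, category levels, at most one
#' record per participant and timepoint) and reports the file line number and
#' field of the first malformed row; `write_cohort()` then `read_cohort()` is
#' the identity on valid records.
#'
#' @param path file path.
#' @param records cohort data.frame.
#' @return `read_cohort()` returns the validated cohort data.frame;
#'   `write_cohort()` invisibly returns `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_data("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.cohort_cols, names(raw))
  if (length(missing_cols))
    stop_data("cohort file missing column(s): %s",
              paste(missing_cols, collapse = ", "))

  fail <- function(row, field, value)
    stop_data("malformed cohort row at line %d: field '%s' has invalid value '%s'",
              row + 1L, field, value)
  num <- function(field, lo, hi) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad)) fail(bad[1], field, raw[[field]][bad[1]])
    v
  }
  boolean <- function(field) {
    bad <- which(!raw[[field]] %in% c("0", "1"))
    if (length(bad)) fail(bad[1], field, raw[[field]][bad[1]])
    raw[[field]] == "1"
  }
  bad_sex <- which(!raw$sex %in% c("male", "female"))
  if (length(bad_sex)) fail(bad_sex[1], "sex", raw$sex[bad_sex[1]])
  bad_tp <- which(!raw$timepoint %in% c("baseline", "exit"))
  if (length(bad_tp)) fail(bad_tp[1], "timepoint", raw$timepoint[bad_tp[1]])

  out <- data.frame(
    participant_id = raw$participant_id,
    timepoint = raw$timepoint,
    age = num("age", .range_age[1], .range_age[2]),
    sex = raw$sex,
    diabetes = boolean("diabetes"),
    total_cholesterol = num("total_cholesterol", .range_chol[1], .range_chol[2]),
    sbp = num("sbp", .range_sbp[1], .range_sbp[2]),
    on_htn_medication = boolean("on_htn_medication"),
    smoker = boolean("smoker"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(paste(out$participant_id, out$timepoint))
  if (any(dup))
    stop_data("malformed cohort row at line %d: duplicate participant/timepoint '%s/%s'",
              which(dup)[1] + 1L, out$participant_id[which(dup)[1]],
              out$timepoint[which(dup)[1]])
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  missing_cols <- setdiff(.cohort_cols, names(records))
  if (length(missing_cols))
    stop_data("records missing column(s): %s", paste(missing_cols, collapse = ", "))
  out <- records[.cohort_cols]
  for (b in c("diabetes", "on_htn_medication", "smoker"))
    out[[b]] <- as.integer(out[[b]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write generator configuration files
#'
#' YAML files with a top-level `seed`, a `dispersions` block, and one block
#' per stratum under `strata` carrying the generating targets. Round-trips
#' losslessly through [cohort_gen_params()].
#'
#' @param path file path.
#' @param params a `cohort_gen_params` object.
#' @return `read_gen_config()` returns a `cohort_gen_params`;
#'   `write_gen_config()` invisibly returns `path`.
#' @export
read_gen_config <- function(path) {
  if (!file.exists(path)) stop_config("generator config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$strata)) stop_config("generator config needs a 'strata' block")
  profiles <- do.call(rbind, lapply(names(cfg$strata), function(nm) {
    as.data.frame(c(list(stratum = nm), cfg$strata[[nm]]),
                  stringsAsFactors = FALSE)
  }))
  cohort_gen_params(profiles = profiles,
                    dispersions = unlist(cfg$dispersions),
                    seed = cfg$seed %||% 1L)
}

#' @rdname read_gen_config
#' @export
write_gen_config <- function(params, path) {
  pr <- params$profiles
  strata <- lapply(seq_len(nrow(pr)), function(i)
    as.list(pr[i, setdiff(names(pr), "stratum")]))
  names(strata) <- pr$stratum
  yaml::write_yaml(list(seed = params$seed,
                        dispersions = as.list(params$dispersions),
                        strata = strata), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
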
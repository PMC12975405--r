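# Program cost build-up, healthcare costing over cohort flows, ICERs.

#' Program cost inputs
#'
#' Annual per-panel line items for the wellness program. Defaults are the
#' published panel budget: personnel wages (community health worker $45,760;
#' wellness nurse $16,640; supervisory support $3,900; administrative team
#' share $9,149), seven operating items, a 33% fringe rate on wages, a 10%
#' indirect (overhead) rate on total direct charges, and 100 participants
#' per panel.
#'
#' @param personnel named numeric vector of annual wage line items.
#' @param operating named numeric vector of annual operating line items.
#' @param fringe_rate payroll benefit loading applied to wages (default 0.33).
#' @param indirect_rate overhead loading applied to total direct charges
#'   (default 0.10).
#' @param panel_size participants per panel (default 100).
#' @return an object of class `program_cost_inputs`.
#' @export
program_cost_inputs <- function(
    personnel = c("Community health worker" = 45760,
                  "Wellness nurse" = 16640,
                  "Supervisor/IM/TL" = 3900,
                  "Full administrative team per panel" = 9149),
    operating = c("Travel" = 1183,
                  "Equipment 2 laptops" = 3000,
                  "Supplies/materials" = 3775,
                  "Bamboo health" = 102,
                  "PHL" = 1261,
                  "Relias training" = 156,
                  "Phone plan" = 600),
    fringe_rate = 0.33, indirect_rate = 0.10, panel_size = 100) {
  if (any(personnel < 0) || any(operating < 0))
    stop_config("cost line items must be non-negative")
  if (!is_number(fringe_rate) || fringe_rate < 0 || fringe_rate > 1 ||
      !is_number(indirect_rate) || indirect_rate < 0 || indirect_rate > 1)
    stop_config("fringe and indirect rates must lie in [0, 1]")
  if (!is_number(panel_size) || panel_size < 1)
    stop_config("panel size must be at least 1")
  structure(list(personnel = personnel, operating = operating,
                 fringe_rate = fringe_rate, indirect_rate = indirect_rate,
                 panel_size = panel_size),
            class = "program_cost_inputs")
}

#' Annual program cost per participant
#'
#' Cost build-up: fringe = fringe rate x total wages; total personnel =
#' wages + fringe; total direct = personnel + operating; indirect =
#' indirect rate x total direct; total = direct + indirect; per-participant
#' = total / panel size. The computed fringe line is carried at whole
#' dollars, the precision budget line items are entered at (so the indirect
#' charge is exactly the indirect rate times the dollar-valued direct
#' charges); every later intermediate is kept unrounded, and currency
#' rounding beyond that is [round_half_up()] at report time only.
#'
#' @param inputs a [program_cost_inputs()] object.
#' @return list with `per_participant` (annual cost per participant-year)
#'   and `breakdown` (named vector of every intermediate: wages, fringe,
#'   total_personnel, total_operating, total_direct, indirect, total).
#' @export
#' @examples
#' program_cost_per_participant()$per_participant  # 1214.664 -> $1215
program_cost_per_participant <- function(inputs = program_cost_inputs()) {
  if (!inherits(inputs, "program_cost_inputs"))
    stop_config("inputs must be program_cost_inputs")
  wages <- sum(inputs$personnel)
  fringe <- round_half_up(inputs$fringe_rate * wages)  # ledger carries dollars
  total_personnel <- wages + fringe
  total_operating <- sum(inputs$operating)
  total_direct <- total_personnel + total_operating
  indirect <- inputs$indirect_rate * total_direct
  total <- total_direct + indirect
  list(per_participant = total / inputs$panel_size,
       breakdown = c(wages = wages, fringe = fringe,
                     total_personnel = total_personnel,
                     total_operating = total_operating,
                     total_direct = total_direct,
                     indirect = indirect, total = total))
}

#' Healthcare and program cost schedule
#'
#' Annual maintenance cost per state, acute-event cost per allowed
#' transition (including the death-transition cost), and the annual program
#' cost per participant. The default schedule is a clearly labelled
#' placeholder (`placeholder = TRUE`) because the study's literature-derived
#' state and event cost values are not published; running the costing with
#' placeholders requires `allow_placeholder = TRUE` in [expected_costs()].
#'
#' @param state_costs named annual maintenance cost per state; the death
#'   state cost must be 0.
#' @param event_costs square matrix of acute-event costs per i-to-j edge
#'   (`NA` marks edges the schedule does not cover; diagonal entries are
#'   ignored). Defaults to 0 on every structurally allowed edge.
#' @param program_cost annual program cost per participant-year (default:
#'   the [program_cost_per_participant()] build-up).
#' @param placeholder flag marking schedules whose healthcare values are
#'   stand-ins rather than sourced estimates.
#' @return an object of class `cost_schedule`.
#' @export
cost_schedule <- function(state_costs = NULL, event_costs = NULL,
                          program_cost = program_cost_per_participant()$per_participant,
                          placeholder = NULL) {
  placeholder <- placeholder %||% (is.null(state_costs) && is.null(event_costs))
  s <- model_states()
  if (is.null(state_costs))
    state_costs <- stats::setNames(c(2000, 12000, 15000, 18000, 0), s)
  if (is.null(event_costs)) {
    event_costs <- matrix(NA_real_, 5, 5, dimnames = list(s, s))
    allowed <- .structural_mask()
    event_costs[allowed] <- 0
    event_costs[allowed[, "death"], "death"] <- 10000    # death-transition cost
    event_costs["healthy", c("stroke", "mi", "chf")] <- c(20000, 25000, 15000)
    diag(event_costs) <- 0
  }
  if (!all(s %in% names(state_costs)))
    stop_config("state_costs must cover every model state")
  if (state_costs[["death"]] != 0)
    stop_config("death state maintenance cost must be 0")
  if (any(state_costs < 0, na.rm = TRUE) || any(event_costs < 0, na.rm = TRUE) ||
      program_cost < 0)
    stop_config("costs must be non-negative")
  structure(list(state_costs = state_costs, event_costs = event_costs,
                 program_cost = program_cost, placeholder = isTRUE(placeholder)),
            class = "cost_schedule")
}

#' Expected discounted and undiscounted costs of a run
#'
#' Per cycle, cost = state occupancy (at the trace's reward timing) times
#' annual maintenance costs, plus transition flow times acute-event costs,
#' plus alive mass times the annual program cost per participant; each
#' cycle's total is discounted with the same convention as the trace's
#' rewards.
#'
#' @param trace a `cohort_trace` (with flow table) from [run_cohort()].
#' @param schedule a [cost_schedule()].
#' @param allow_placeholder must be set `TRUE` to run with a schedule whose
#'   `placeholder` flag is set; a warning is still emitted.
#' @return list with `discounted`, `undiscounted` totals and `per_cycle`
#'   (data.frame of discounted component streams).
#' @export
expected_costs <- function(trace, schedule = cost_schedule(),
                           allow_placeholder = FALSE) {
  if (!inherits(trace, "cohort_trace")) stop_data("trace must be a cohort_trace")
  if (!inherits(schedule, "cost_schedule"))
    stop_config("schedule must be a cost_schedule")
  if (schedule$placeholder) {
    if (!allow_placeholder)
      stop_config(paste("cost schedule is a placeholder (healthcare values are",
                        "stand-ins); pass allow_placeholder = TRUE to proceed"))
    warning("costing run with a placeholder healthcare cost schedule")
  }
  s <- trace$states
  if (!all(s %in% rownames(schedule$event_costs)))
    stop_config("cost schedule does not cover the trace's states: %s",
                paste(setdiff(s, rownames(schedule$event_costs)), collapse = ", "))
  settings <- trace$settings
  H <- settings$horizon
  rb <- .reward_basis(trace$occupancy, settings)
  sc <- as.numeric(schedule$state_costs[s])
  ec <- schedule$event_costs[s, s]
  diag(ec) <- 0

  maint <- as.numeric(rb$w %*% sc) * settings$cycle_length
  alive <- 1 - rb$w[, "death"]
  program <- alive * schedule$program_cost * settings$cycle_length
  event <- numeric(H)
  for (t in seq_len(H)) {
    fl <- trace$flows[t, , ]
    moving <- fl > 0 & row(fl) != col(fl)
    if (any(moving & is.na(ec))) {
      bad <- which(moving & is.na(ec), arr.ind = TRUE)[1, ]
      stop_data("cost schedule missing edge with nonzero flow: %s -> %s",
                s[bad[1]], s[bad[2]])
    }
    event[t] <- sum(fl[moving] * ec[moving])
  }
  per_cycle <- data.frame(cycle = seq_len(H),
                          maintenance = maint * rb$disc,
                          event = event * rb$disc,
                          program = program * rb$disc)
  list(discounted = sum(per_cycle$maintenance + per_cycle$event +
                          per_cycle$program),
       undiscounted = sum(maint + event + program),
       per_cycle = per_cycle)
}

#' Incremental cost-effectiveness ratio
#'
#' Ratio of incremental cost to incremental effect, with degenerate cases
#' signalled by flags instead of raw division: a positive cost with a
#' non-positive effect gain is `dominated/undefined`; non-positive cost with
#' non-positive effect is flagged for cost-saving interpretation and the
#' ratio suppressed.
#'
#' @param incremental_cost currency difference (intervention minus
#'   counterfactual).
#' @param delta_effect effect difference (QALYs or life years).
#' @return list of class `icer` with `value` (currency per effect unit,
#'   rounded to the nearest dollar with [round_half_up()], or `NA` when
#'   suppressed), `value_exact` (unrounded), and `flag` (`"ok"`,
#'   `"cost-saving"`, `"dominated/undefined"`).
#' @export
#' @examples
#' icer(6649, 0.9)$value  # 7388
icer <- function(incremental_cost, delta_effect) {
  if (!is.numeric(incremental_cost) || !is.numeric(delta_effect))
    stop_data("icer inputs must be numeric")
  if (delta_effect > 0) {
    v <- incremental_cost / delta_effect
    flag <- if (incremental_cost < 0) "cost-saving" else "ok"
    out <- list(value = round_half_up(v), value_exact = v, flag = flag)
  } else if (incremental_cost > 0) {
    out <- list(value = NA_real_, value_exact = NA_real_,
                flag = "dominated/undefined")
  } else {
    out <- list(value = NA_real_, value_exact = NA_real_, flag = "cost-saving")
  }
  structure(out, class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (is.na(x$value)) cat(sprintf("ICER: %s\n", x$flag))
  else cat(sprintf("ICER: $%s per effect unit gained [%s]\n",
                   format(x$value, big.mark = ","), x$flag))
  invisible(x)
}

#' Compare intervention and counterfactual runs
#'
#' Assembles the paired cost-utility record: per-scenario discounted QALYs,
#' life years and costs, incremental cost, effect gains, and cost per QALY
#' and per life year gained.
#'
#' @param intervention,counterfactual scenario runs: lists with elements
#'   `trace` (a `cohort_trace`) and `costs` (an [expected_costs()] result).
#'   Both runs must share simulation settings and state set.
#' @return one-row data.frame of class `ce_result` with columns
#'   `qaly_intervention`, `qaly_counterfactual`, `ly_intervention`,
#'   `ly_counterfactual`, `cost_intervention`, `cost_counterfactual`,
#'   `cost_undisc_intervention`, `cost_undisc_counterfactual`,
#'   `incremental_cost`, `delta_qaly`, `delta_ly`, `cost_per_qaly`,
#'   `cost_per_ly`, `flag_qaly`, `flag_ly`.
#' @export
compare_scenarios <- function(intervention, counterfactual) {
  for (run in list(intervention, counterfactual))
    if (!inherits(run$trace, "cohort_trace") || is.null(run$costs))
      stop_data("each run must carry a cohort_trace and an expected_costs result")
  si <- intervention$trace$settings
  sc <- counterfactual$trace$settings
  if (!identical(si, sc))
    stop_config("intervention and counterfactual runs use different settings")
  if (!identical(intervention$trace$states, counterfactual$trace$states))
    stop_config("runs use different state sets")

  dq <- discounted_qalys(intervention$trace) -
    discounted_qalys(counterfactual$trace)
  dl <- discounted_life_years(intervention$trace) -
    discounted_life_years(counterfactual$trace)
  dc <- intervention$costs$discounted - counterfactual$costs$discounted
  iq <- icer(dc, dq)
  il <- icer(dc, dl)
  res <- data.frame(
    qaly_intervention = discounted_qalys(intervention$trace),
    qaly_counterfactual = discounted_qalys(counterfactual$trace),
    ly_intervention = discounted_life_years(intervention$trace),
    ly_counterfactual = discounted_life_years(counterfactual$trace),
    cost_intervention = intervention$costs$discounted,
    cost_counterfactual = counterfactual$costs$discounted,
    cost_undisc_intervention = intervention$costs$undiscounted,
    cost_undisc_counterfactual = counterfactual$costs$undiscounted,
    incremental_cost = dc, delta_qaly = dq, delta_ly = dl,
    cost_per_qaly = iq$value, cost_per_ly = il$value,
    flag_qaly = iq$flag, flag_ly = il$flag,
    stringsAsFactors = FALSE)
  class(res) <- c("ce_result", "data.frame")
  res
}

#' Long-term care break-even reduction
#'
#' The percentage-point reduction in long-term care (LTC) utilization whose
#' avoided cost offsets the intervention's incremental cost:
#' `incremental_cost / (ltc_monthly_cost * ltc_duration)`.
#'
#' @param incremental_cost incremental program cost, currency.
#' @param ltc_monthly_cost monthly LTC cost, currency (must be positive).
#' @param ltc_duration average LTC length of stay, months (must be positive).
#' @return break-even reduction as a proportion.
#' @export
#' @examples
#' ltc_breakeven(8344, 2540, 27.6)  # 0.119
ltc_breakeven <- function(incremental_cost, ltc_monthly_cost, ltc_duration) {
  if (!is_number(ltc_monthly_cost) || ltc_monthly_cost <= 0 ||
      !is_number(ltc_duration) || ltc_duration <= 0)
    stop_config("LTC monthly cost and duration must be positive")
  if (!is.numeric(incremental_cost))
    stop_data("incremental cost must be numeric")
  incremental_cost / (ltc_monthly_cost * ltc_duration)
}
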
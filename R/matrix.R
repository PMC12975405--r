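# Annual transition matrices over the five-state model and their validation.

#' Model states
#'
#' Ordered state set of the cohort model: healthy, stroke, myocardial
#' infarction (MI), congestive heart failure (CHF), death. Death is
#' absorbing; no state returns to healthy.
#'
#' @return character vector of the five state names.
#' @export
model_states <- function() c("healthy", "stroke", "mi", "chf", "death")

.state_labels <- c(healthy = "Healthy", stroke = "Stroke", mi = "MI",
                   chf = "CHF", death = "Death")

# Structural mask of allowed transitions (TRUE = allowed). Follows the
# published matrix: healthy may reach every state; stroke may persist or
# move to MI, CHF or death; MI to CHF or death; CHF to death only.
.structural_mask <- function() {
  s <- model_states()
  m <- matrix(FALSE, 5, 5, dimnames = list(s, s))
  m["healthy", ] <- TRUE
  m["stroke", c("stroke", "mi", "chf", "death")] <- TRUE
  m["mi", c("mi", "chf", "death")] <- TRUE
  m["chf", c("chf", "death")] <- TRUE
  m["death", "death"] <- TRUE
  m
}

#' Default post-event transition rows
#'
#' Annual persistence/progression probabilities for the stroke, MI and CHF
#' states, stratum-independent. Defaults are the published counterfactual
#' rows; note the stroke row carries substantial residual mass (its printed
#' entries sum to 0.6746), which the validation policy must resolve.
#'
#' @return 3x5 matrix with rows `stroke`, `mi`, `chf` over [model_states()].
#' @export
default_downstream_rows <- function() {
  s <- model_states()
  rbind(
    stroke = c(0, 0.4053, 0.0392, 0.0488, 0.1813),
    mi     = c(0, 0,      0.5078, 0.1230, 0.3691),
    chf    = c(0, 0,      0,      0.4873, 0.5127)
  ) -> m
  colnames(m) <- s
  m
}

#' Construct a transition matrix object
#'
#' Wraps a 5x5 probability table (rows and columns in [model_states()]
#' order) as an unvalidated `transition_matrix`; pass it through
#' [validate_matrix()] before simulation. Used to enter externally supplied
#' (e.g. printed) matrices into the pipeline.
#'
#' @param probs 5x5 numeric matrix of annual transition probabilities.
#' @param stratum,scenario optional labels carried on the object.
#' @return an object of class `transition_matrix` with `validated = FALSE`.
#' @export
transition_matrix <- function(probs, stratum = NA_character_,
                              scenario = NA_character_) {
  new_transition_matrix(probs, stratum = stratum, scenario = scenario)
}

new_transition_matrix <- function(probs, stratum = NA_character_,
                                  scenario = NA_character_,
                                  validated = FALSE, policy = NA_character_,
                                  residuals = NULL) {
  s <- model_states()
  stopifnot(is.matrix(probs), all(dim(probs) == c(5, 5)))
  dimnames(probs) <- list(s, s)
  structure(list(probs = probs,
                 states = s,
                 stratum = stratum,
                 scenario = scenario,
                 validated = validated,
                 policy = policy,
                 residuals = residuals %||% 1 - rowSums(probs)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Annual transition matrix (%s / %s) — %s\n",
              x$stratum, x$scenario,
              if (x$validated) sprintf("validated [%s]", x$policy)
              else "NOT validated"))
  print(round(x$probs, 4))
  invisible(x)
}

#' Build an annual transition matrix for one stratum and scenario
#'
#' Assembles the healthy row from the annual first-event probabilities
#' (stroke, MI, CHF) plus non-cardiovascular death, with the stay-probability
#' as the complement of the total leaving mass; takes the post-event rows
#' from `downstream_rows`; makes death absorbing; and applies the row
#' validation policy (see [validate_matrix()]).
#'
#' @param stratum one row of a stratum-profile data.frame
#'   (see [default_stratum_profiles()]).
#' @param scenario a [scenario_spec()].
#' @param coeffs named list of [risk_coefficient_set()] objects with elements
#'   `stroke`, `mi`, `chf`, `noncvd_death`
#'   (default [default_risk_coefficients()]).
#' @param downstream_rows 3x5 matrix of post-event rows
#'   (default [default_downstream_rows()]).
#' @param policy,tolerance row-residual handling, passed to
#'   [validate_matrix()]. The default renormalizes with a warning.
#' @return a validated `transition_matrix`.
#' @export
#' @examples
#' st <- default_stratum_profiles()[1, ]
#' build_transition_matrix(st, scenario_spec("counterfactual"))
build_transition_matrix <- function(stratum,
                                    scenario,
                                    coeffs = default_risk_coefficients(),
                                    downstream_rows = default_downstream_rows(),
                                    policy = c("renormalize", "error",
                                               "residual_to_self",
                                               "residual_to_extra_state"),
                                    tolerance = 1e-6) {
  policy <- match.arg(policy)
  need <- c("stroke", "mi", "chf", "noncvd_death")
  if (!all(need %in% names(coeffs)))
    stop_config("coeffs must provide sets for: %s", paste(need, collapse = ", "))
  if (!all(c("stroke", "mi", "chf") %in% rownames(downstream_rows)))
    stop_config("downstream_rows must provide rows for stroke, mi and chf")

  profile <- scenario_profile(stratum, scenario)
  p <- vapply(need, function(ev) annual_event_probability(profile, coeffs[[ev]]),
              numeric(1))
  leave <- sum(p)
  if (leave > 1)
    stop_numeric("healthy-row event probabilities sum to %.4f > 1 for stratum %s",
                 leave, stratum$stratum)
  healthy_row <- c(healthy = 1 - leave, stroke = p[["stroke"]],
                   mi = p[["mi"]], chf = p[["chf"]], death = p[["noncvd_death"]])

  probs <- rbind(healthy = healthy_row,
                 stroke = downstream_rows["stroke", model_states()],
                 mi = downstream_rows["mi", model_states()],
                 chf = downstream_rows["chf", model_states()],
                 death = c(0, 0, 0, 0, 1))
  tm <- new_transition_matrix(probs,
                              stratum = stratum$stratum %||% NA_character_,
                              scenario = scenario$scenario)
  validate_matrix(tm, policy = policy, tolerance = tolerance)$matrix
}

#' Build an age-updating sequence of transition matrices
#'
#' Time-varying alternative to the default time-homogeneous matrix: one
#' matrix per cycle, with the stratum's age advanced by one cycle length
#' each year while every other risk factor keeps its scenario value. Feed
#' the result to [run_cohort()], which accepts a per-cycle matrix list.
#'
#' @inheritParams build_transition_matrix
#' @param horizon number of cycles to build (one matrix each).
#' @param cycle_length years per cycle.
#' @return list of `horizon` validated `transition_matrix` objects.
#' @export
build_transition_matrices_aging <- function(stratum, scenario,
                                            horizon = 20, cycle_length = 1,
                                            coeffs = default_risk_coefficients(),
                                            downstream_rows = default_downstream_rows(),
                                            policy = "renormalize",
                                            tolerance = 1e-6) {
  lapply(seq_len(horizon), function(t) {
    aged <- stratum
    aged$mean_entry_age <- stratum$mean_entry_age + (t - 1) * cycle_length
    build_transition_matrix(aged, scenario, coeffs = coeffs,
                            downstream_rows = downstream_rows,
                            policy = policy, tolerance = tolerance)
  })
}

#' Validate and repair a transition matrix
#'
#' Checks entries lie in `[0, 1]`, the death row is absorbing, structurally
#' forbidden transitions (return to healthy; CHF to MI or stroke; MI to
#' stroke) are exactly zero, and every row sums to 1. Rows with residual mass
#' are resolved per `policy`:
#' \describe{
#'   \item{`error`}{reject any row with `|residual| > tolerance`.}
#'   \item{`renormalize`}{divide each row by its sum (warns when residuals
#'     exceed `tolerance`). The default for model runs.}
#'   \item{`residual_to_self`}{add the residual to the diagonal, honouring
#'     printed off-diagonal probabilities exactly.}
#'   \item{`residual_to_extra_state`}{append an auxiliary absorbing state
#'     (e.g. post-stroke) and route each row's residual to it; the result is
#'     a 6-state matrix.}
#' }
#'
#' @param matrix a `transition_matrix`.
#' @param policy residual-handling policy.
#' @param tolerance row-sum tolerance (default 1e-6).
#' @param extra_state name of the auxiliary state for
#'   `residual_to_extra_state`.
#' @return list with elements `matrix` (validated `transition_matrix`) and
#'   `report` (data.frame of per-row residuals and actions).
#' @export
validate_matrix <- function(matrix,
                            policy = c("renormalize", "error",
                                       "residual_to_self",
                                       "residual_to_extra_state"),
                            tolerance = 1e-6,
                            extra_state = "post_event") {
  policy <- match.arg(policy)
  if (!inherits(matrix, "transition_matrix"))
    stop_config("matrix must be a transition_matrix")
  P <- matrix$probs
  s <- matrix$states

  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop_data("transition probabilities must lie in [0, 1]")
  if (any(P[.structural_mask() == FALSE] != 0))
    stop_data("structurally forbidden transition has nonzero probability")
  if (!identical(unname(P["death", ]), c(0, 0, 0, 0, 1)))
    stop_data("death row must be absorbing")

  residual <- 1 - rowSums(P)
  report <- data.frame(state = s, row_sum = rowSums(P), residual = residual,
                       action = policy, stringsAsFactors = FALSE)
  flagged <- abs(residual) > tolerance

  if (policy == "error") {
    if (any(flagged))
      stop_data("row(s) %s fail the row-sum check (max |residual| %.4g)",
                paste(s[flagged], collapse = ", "), max(abs(residual)))
    out <- P
  } else if (policy == "renormalize") {
    if (any(flagged))
      warning(sprintf("renormalizing row(s) with residual mass: %s",
                      paste(sprintf("%s (%.4f)", s[flagged], residual[flagged]),
                            collapse = ", ")))
    out <- P / rowSums(P)
  } else if (policy == "residual_to_self") {
    out <- P
    diag(out) <- diag(out) + residual
    if (any(diag(out) < 0) || any(diag(out) > 1))
      stop_data("residual_to_self drives a diagonal entry outside [0, 1]")
  } else { # residual_to_extra_state
    out <- cbind(P, pmax(residual, 0))
    if (any(residual < -tolerance))
      stop_data("negative residual cannot be routed to an extra state")
    out <- rbind(out, c(rep(0, ncol(P)), 1))
    dimnames(out) <- list(c(s, extra_state), c(s, extra_state))
  }

  res <- matrix
  res$probs <- out
  res$states <- rownames(out)
  res$validated <- TRUE
  res$policy <- policy
  res$residuals <- residual
  list(matrix = res, report = report)
}

#' Read and write transition matrices
#'
#' Tab-delimited square table with state-name header row and column,
#' matching the published matrix layout (`Healthy Stroke MI CHF Death`).
#'
#' @param matrix a `transition_matrix`.
#' @param path file path.
#' @return `read_matrix()` returns an (unvalidated) `transition_matrix`;
#'   `write_matrix()` invisibly returns `path`.
#' @export
write_matrix <- function(matrix, path) {
  P <- matrix$probs
  labels <- .state_labels[matrix$states]
  labels[is.na(labels)] <- matrix$states[is.na(labels)]
  tab <- cbind(`From (to)` = labels, as.data.frame(P))
  names(tab)[-1] <- labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_data("matrix file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  P <- as.matrix(tab[, -1, drop = FALSE])
  keys <- names(.state_labels)[match(tab[[1]], .state_labels)]
  keys[is.na(keys)] <- tab[[1]][is.na(keys)]
  rownames(P) <- keys
  colnames(P) <- keys
  new_transition_matrix(P[model_states(), model_states()])
}
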
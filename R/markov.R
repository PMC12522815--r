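#' Discount factor for a model cycle
#'
#' Convention: the exponent equals the cycle index, so cycle 0 is
#' undiscounted and cycle `t` receives `(1 + rate)^(-t)`.
#'
#' @param rate Annual discount rate (fraction, e.g. 0.02).
#' @param cycle Cycle index (0-based, vectorized).
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 0))
  (1 + rate)^(-cycle)
}

#' Run the deterministic cohort trace for one strategy
#'
#' Propagates the closed cohort through the per-cycle 5x5 matrices:
#' `occupancy(t + 1) = occupancy(t) %*% M(t)`. Row 0 is the initial SPUI
#' distribution padded with zeros for recurrence and death.
#'
#' @param config An `hme_config`.
#' @param strategy Strategy label.
#' @return An object of class `cohort_trace`: a `(horizon + 1) x 5` matrix
#'   of state-occupancy proportions with a `strategy` attribute. Every row
#'   sums to 1 and the death column is nondecreasing.
#' @export
run_trace <- function(config, strategy) {
  mats <- cycle_matrices(config, strategy)
  horizon <- config$settings$horizon_cycles
  trace <- matrix(0, horizon + 1, 5,
                  dimnames = list(0:horizon, model_states()))
  trace[1, spui_states()] <- config$epi$initial_distribution[spui_states()]
  for (t in seq_len(horizon)) {
    trace[t + 1, ] <- trace[t, , drop = FALSE] %*% mats[[t]]
  }
  structure(trace, strategy = strategy, class = c("cohort_trace", "matrix"))
}

#' Accumulate discounted costs, QALYs and event counts from a trace
#'
#' Per cycle `t` in `0 .. horizon - 1`, using start-of-cycle occupancy
#' (or the start/end average when half-cycle correction is enabled):
#' annual SPUI state costs and the recurrence-state cost accrue per cycle
#' of occupancy; event costs accrue as occupancy times the per-person-year
#' event rate times the cost per event; the end-of-life care cost is
#' charged once on the mass newly entering death during the cycle. QALYs
#' are occupancy times the effective state utility (recurrence 0.63,
#' death 0) times the cycle length. Costs and QALYs are discounted with
#' [discount_factor()]; expected event counts are accumulated
#' undiscounted.
#'
#' @param trace A `cohort_trace` from [run_trace()].
#' @param config The `hme_config` that produced it.
#' @return An object of class `strategy_outcomes`: list with `strategy`,
#'   `cost` (discounted JPY per patient), `qaly` (discounted QALYs per
#'   patient), `event_counts` (named, undiscounted expected events per
#'   patient over the horizon) and `trace`.
#' @export
accumulate_outcomes <- function(trace, config) {
  strategy <- attr(trace, "strategy")
  s <- config$settings
  st <- config$strategies[[strategy]]
  horizon <- s$horizon_cycles
  cyc_len <- s$cycle_length_years

  occ <- unclass(trace)
  start <- occ[seq_len(horizon), , drop = FALSE]
  end <- occ[seq_len(horizon) + 1, , drop = FALSE]
  acc <- if (isTRUE(s$half_cycle_correction)) (start + end) / 2 else start

  u_spui <- effective_state_utility(config, strategy, spui_states())
  u <- c(u_spui, config$shared$recurrence_utility, config$shared$death_utility)
  rate <- st$event_rate %||% stats::setNames(numeric(3), event_types())
  rate <- rate[event_types()]
  ev_cost_rate <- sum(rate * config$shared$event_cost[event_types()])

  spui_occ <- acc[, spui_states(), drop = FALSE]
  cost_state <- spui_occ %*% st$state_cost[spui_states()] * cyc_len
  cost_rec <- acc[, "recurrent_cancer"] * config$shared$recurrence_cost * cyc_len
  cost_event <- rowSums(spui_occ) * ev_cost_rate * cyc_len
  new_death <- end[, "death"] - start[, "death"]
  cost_death <- new_death * config$shared$death_transition_cost
  qaly <- (acc %*% u) * cyc_len

  disc <- discount_factor(s$discount_rate, seq_len(horizon) - 1)
  events <- colSums(rowSums(spui_occ) %o% rate) * cyc_len

  structure(
    list(strategy = strategy,
         cost = sum((cost_state + cost_rec + cost_event + cost_death) * disc),
         qaly = sum(qaly * disc),
         event_counts = events,
         trace = trace),
    class = "strategy_outcomes")
}

#' Run one strategy end to end
#'
#' @param config An `hme_config`.
#' @param strategy Strategy label.
#' @return A `strategy_outcomes` object.
#' @export
run_strategy <- function(config, strategy) {
  accumulate_outcomes(run_trace(config, strategy), config)
}

#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' @param intervention,comparator `strategy_outcomes` objects produced
#'   under the same settings.
#' @param wtp Willingness-to-pay threshold (JPY per QALY).
#' @return An object of class `incremental_result`: `delta_cost`,
#'   `delta_qaly`, `icer` (JPY/QALY; `NA` when not meaningful), `status`
#'   (`"ICER"`, `"DOMINANT"` meaning cheaper and more effective, `"DOMINATED"`
#'   costlier and less effective, or `"UNDEFINED"` when the QALY
#'   difference is zero) and `cost_effective_at_wtp`.
#' @export
incremental_analysis <- function(intervention, comparator, wtp) {
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  if (dq == 0) {
    status <- "UNDEFINED"
    icer <- NA_real_
    ce <- dc < 0
  } else {
    icer <- dc / dq
    status <- if (dc < 0 && dq > 0) "DOMINANT"
      else if (dc > 0 && dq < 0) "DOMINATED"
      else "ICER"
    ce <- status == "DOMINANT" || (dq > 0 && icer <= wtp)
  }
  structure(
    list(intervention = intervention$strategy, comparator = comparator$strategy,
         delta_cost = dc, delta_qaly = dq, icer = icer, status = status,
         wtp = wtp, cost_effective_at_wtp = ce),
    class = "incremental_result")
}

#' Deterministic base-case analysis of all three strategies
#'
#' Runs the cohort model for the third-generation HME intervention and
#' both comparators and derives the two pairwise incremental results.
#'
#' @param config An `hme_config`.
#' @param scenario Optional scenario name (see [apply_overrides()]).
#' @return An object of class `base_case`: list with `outcomes` (named
#'   list of `strategy_outcomes`), `incremental` (named list of
#'   `incremental_result`, third_gen vs each comparator), `summary`
#'   (data frame shaped like a published results table) and the config
#'   used.
#' @export
run_base_case <- function(config, scenario = NULL) {
  if (!is.null(scenario)) config <- apply_overrides(config, scenario)
  outcomes <- lapply(stats::setNames(nm = strategy_labels()),
                     function(st) run_strategy(config, st))
  wtp <- config$settings$wtp
  incremental <- list(
    vs_second_gen = incremental_analysis(outcomes$third_gen,
                                         outcomes$second_gen, wtp),
    vs_no_hme = incremental_analysis(outcomes$third_gen, outcomes$no_hme, wtp))
  summary <- data.frame(
    strategy = strategy_labels(),
    qaly = vapply(outcomes, `[[`, numeric(1), "qaly"),
    cost = vapply(outcomes, `[[`, numeric(1), "cost"),
    row.names = NULL)
  for (ev in event_types()) {
    summary[[ev]] <- vapply(outcomes, function(o) o$event_counts[[ev]],
                            numeric(1))
  }
  structure(list(outcomes = outcomes, incremental = incremental,
                 summary = summary, config = config),
            class = "base_case")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost = %s JPY, dQALY = %.4f, %s\n",
              x$intervention, x$comparator,
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly,
              if (x$status == "ICER") {
                sprintf("ICER = %s JPY/QALY (%scost-effective at WTP %s)",
                        format(round(x$icer), big.mark = ","),
                        if (x$cost_effective_at_wtp) "" else "not ",
                        format(x$wtp, big.mark = ","))
              } else x$status))
  invisible(x)
}

#' @export
print.base_case <- function(x, ...) {
  cat("Markov cohort base case (", x$config$settings$horizon_cycles,
      " cycles, discount ", x$config$settings$discount_rate * 100, "%)\n",
      sep = "")
  df <- x$summary
  df$qaly <- round(df$qaly, 4)
  df$cost <- round(df$cost)
  print(df, row.names = FALSE)
  cat("\n")
  for (inc in x$incremental) print(inc)
  invisible(x)
}
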
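#' Default one-way sensitivity bounds for a parameter
#'
#' The base value is decreased and increased by 20% to obtain the lower
#' and upper bounds; probability parameters are clipped to `[0, 1]` after
#' scaling.
#'
#' @param base Base-case value.
#' @param probability Clip the scaled bounds to `[0, 1]`.
#' @param pct Fractional variation (default 0.2).
#' @return Numeric `c(low, high)`.
#' @export
default_bounds <- function(base, probability = FALSE, pct = 0.2) {
  stopifnot(is.finite(base))
  b <- c(low = (1 - pct) * base, high = (1 + pct) * base)
  if (probability) b <- pmin(pmax(b, 0), 1)
  b
}

#' Default OWSA parameter set for the model
#'
#' One spec per varied parameter: annual state costs, event rates, shared
#' event costs, recurrence and end-of-life costs, net state utilities,
#' recurrence and recurrence-death probabilities, and the diagonal
#' (state-retention) entries of each strategy's SPUI transition matrix.
#' Bounds follow the plus/minus 20% rule (`PCT20`), clipped for
#' probabilities and utilities; structural zeros get zero-width bounds.
#'
#' @param config An `hme_config`.
#' @return Data frame with columns `path`, `base`, `low`, `high`,
#'   `provenance`.
#' @export
owsa_default_params <- function(config) {
  paths <- c(
    as.vector(outer(paste0("strategies.", strategy_labels()),
                    paste0(".state_cost.", spui_states()), paste0)),
    as.vector(outer(paste0("strategies.", strategy_labels()),
                    paste0(".event_rate.", event_types()), paste0)),
    paste0("shared.event_cost.", event_types()),
    "shared.recurrence_cost", "shared.death_transition_cost",
    as.vector(outer(paste0("strategies.", strategy_labels()),
                    paste0(".net_state_utility.", spui_states()), paste0)),
    "epi.recurrence_prob", "epi.recurrence_death_prob",
    as.vector(outer(paste0("epi.spui_transitions.", strategy_labels(), "."),
                    paste0(spui_states(), ".", spui_states()), paste0)))
  is_prob <- grepl("utility|prob|event_rate|spui_transitions", paths)
  base <- vapply(paths, function(p) config_get(config, p), numeric(1))
  bounds <- t(mapply(default_bounds, base, is_prob))
  data.frame(path = paths, base = unname(base),
             low = unname(bounds[, 1]), high = unname(bounds[, 2]),
             provenance = "PCT20", row.names = NULL)
}

owsa_eval <- function(config, path, value, intervention, comparator) {
  cfg <- config_set(config, path, value)
  inc <- incremental_analysis(run_strategy(cfg, intervention),
                              run_strategy(cfg, comparator),
                              cfg$settings$wtp)
  inc
}

#' One-way sensitivity analysis with tornado ordering
#'
#' Re-runs the full deterministic model twice per parameter (at its lower
#' and upper bound, all other parameters at base) and reports the ICER of
#' the intervention against the comparator at each bound. Entries are
#' sorted by descending swing. When a bound produces dominance (no
#' meaningful signed ICER), the swing falls back to the net monetary
#' benefit difference at the configured willingness-to-pay, flagged in
#' `swing_metric`. Perturbing one entry of a transition row renormalizes
#' the rest of the row proportionally (see [config_set()]).
#'
#' @param config An `hme_config`.
#' @param intervention,comparator Strategy labels (defaults: third
#'   generation vs second generation).
#' @param params Data frame as from [owsa_default_params()] (`path`,
#'   `low`, `high`); defaults to the full built-in set.
#' @return Data frame of class `tornado`: `path`, `low`, `high`,
#'   `icer_low`, `icer_high`, `nmb_low`, `nmb_high`, `status_low`,
#'   `status_high`, `swing`, `swing_metric`, sorted by descending swing,
#'   with the base-case ICER as attribute `base_icer`.
#' @export
run_owsa <- function(config, intervention = "third_gen",
                     comparator = "second_gen", params = NULL) {
  if (is.null(params)) params <- owsa_default_params(config)
  stopifnot(all(c("path", "low", "high") %in% names(params)))
  base_inc <- incremental_analysis(run_strategy(config, intervention),
                                   run_strategy(config, comparator),
                                   config$settings$wtp)
  nmb <- function(inc) inc$wtp * inc$delta_qaly - inc$delta_cost
  rows <- lapply(seq_len(nrow(params)), function(i) {
    lo <- owsa_eval(config, params$path[i], params$low[i], intervention, comparator)
    hi <- owsa_eval(config, params$path[i], params$high[i], intervention, comparator)
    both_icer <- lo$status == "ICER" && hi$status == "ICER" &&
      lo$delta_qaly > 0 && hi$delta_qaly > 0
    data.frame(
      path = params$path[i], low = params$low[i], high = params$high[i],
      icer_low = lo$icer, icer_high = hi$icer,
      nmb_low = nmb(lo), nmb_high = nmb(hi),
      status_low = lo$status, status_high = hi$status,
      swing = if (both_icer) abs(hi$icer - lo$icer) else abs(nmb(hi) - nmb(lo)),
      swing_metric = if (both_icer) "ICER" else "NMB")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$path), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_inc$icer
  attr(out, "comparison") <- c(intervention, comparator)
  class(out) <- c("tornado", "data.frame")
  out
}

#' Find the parameter value at which the ICER crosses the WTP threshold
#'
#' Scans the bracket on a coarse grid for a sign change of
#' `delta_cost - wtp * delta_qaly` (which equals
#' `delta_qaly * (ICER - wtp)` whenever the intervention gains QALYs) and
#' refines the first crossing by bisection to a relative tolerance of
#' 1e-6 on the parameter. Returns `NA` when the objective does not change
#' sign over the bracket; if the grid shows more than one crossing the
#' first is refined and flagged.
#'
#' @param config An `hme_config`.
#' @param path Dotted parameter path to vary.
#' @param bracket Numeric `c(lower, upper)` search interval.
#' @param intervention,comparator Strategy labels.
#' @param wtp Threshold (JPY/QALY); defaults to the config setting.
#' @param n_grid Grid points for the initial sign scan.
#' @param tol Relative bisection tolerance on the parameter.
#' @return List of class `threshold_result`: `value` (crossing parameter
#'   value or `NA`), `icer_at_value`, `multiple_crossings` flag, and the
#'   bracket.
#' @export
threshold_search <- function(config, path, bracket,
                             intervention = "third_gen",
                             comparator = "second_gen",
                             wtp = config$settings$wtp,
                             n_grid = 21, tol = 1e-6) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  f <- function(theta) {
    inc <- owsa_eval(config, path, theta, intervention, comparator)
    inc$delta_cost - wtp * inc$delta_qaly
  }
  grid <- seq(bracket[1], bracket[2], length.out = n_grid)
  fg <- vapply(grid, f, numeric(1))
  sgn <- sign(fg)
  cross <- which(sgn[-1] * sgn[-n_grid] < 0 | sgn[-n_grid] == 0)
  multiple <- length(cross) > 1
  if (multiple) {
    warning("ICER - WTP changes sign more than once in bracket; ",
            "returning the first crossing", call. = FALSE)
  }
  if (length(cross) == 0) {
    if (any(sgn == 0)) cross <- which(sgn == 0)[1] else {
      return(structure(list(value = NA_real_, icer_at_value = NA_real_,
                            multiple_crossings = FALSE, bracket = bracket),
                       class = "threshold_result"))
    }
  }
  lo <- grid[cross[1]]
  hi <- grid[min(cross[1] + 1, n_grid)]
  flo <- f(lo)
  while (hi - lo > tol * max(abs(lo), abs(hi), 1e-12)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) { lo <- hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  value <- (lo + hi) / 2
  inc <- owsa_eval(config, path, value, intervention, comparator)
  structure(list(value = value, icer_at_value = inc$icer,
                 multiple_crossings = multiple, bracket = bracket),
            class = "threshold_result")
}
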
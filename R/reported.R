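#' Published base-case and scenario totals
#'
#' The per-strategy totals and incremental results reported for the
#' original analysis (10-year horizon, 2% discount, WTP 5,000,000
#' JPY/QALY), as printed: discounted QALYs and total costs per patient
#' for each strategy in the base case, the scenario variant in which the
#' no-HME annual cost is 170,000 JPY instead of 30,000 JPY, and the
#' printed incremental QALYs, incremental costs and ICERs of the
#' third-generation device against each comparator. These serve as
#' reference inputs for arithmetic consistency checks
#' (`delta = intervention - comparator`, `ICER = delta_cost /
#' delta_qaly`), not as model outputs: the transition, recurrence and
#' mortality inputs behind them were not published, so the totals are not
#' recomputed from scratch.
#'
#' @return List with `base_case` (data frame `strategy`, `qaly`, `cost`),
#'   `scenario_no_hme_170000` (same shape, two rows) and `incremental`
#'   (data frame `comparator`, `analysis`, `delta_qaly`, `delta_cost`,
#'   `icer`).
#' @export
published_base_case <- function() {
  list(
    base_case = data.frame(
      strategy = c("third_gen", "second_gen", "no_hme"),
      qaly = c(4.7087, 4.3328, 4.3079),
      cost = c(22922149, 22038701, 21034644)),
    scenario_no_hme_170000 = data.frame(
      strategy = c("third_gen", "no_hme"),
      qaly = c(4.7087, 4.3079),
      cost = c(22922149, 21541961)),
    incremental = data.frame(
      comparator = c("second_gen", "no_hme", "no_hme"),
      analysis = c("base_case", "base_case", "scenario_no_hme_170000"),
      delta_qaly = c(0.3759, 0.4008, 0.4008),
      delta_cost = c(883447, 1887504, 1380188),
      icer = c(2350010, 4708917, 3443271)))
}

#' Published PSA secondary-outcome intervals
#'
#' Mean expected event counts per patient over the 10-year horizon with
#' 2.5th/97.5th percentile intervals from the original 2,000-iteration
#' PSA, as printed. Reference values for comparison only.
#'
#' @return Data frame: `strategy`, `event`, `mean`, `lo`, `hi`.
#' @export
published_secondary_outcomes <- function() {
  data.frame(
    strategy = rep(c("third_gen", "second_gen", "no_hme"), each = 3),
    event = rep(c("pulmonary_infection", "mucus_plug", "skin_irritation"), 3),
    mean = c(0.26, 0.29, 1.80, 0.39, 0.47, 2.78, 0.55, 2.14, 0.00),
    lo = c(0.14, 0.15, 1.10, 0.24, 0.29, 1.60, 0.35, 1.32, 0.00),
    hi = c(0.43, 0.49, 2.59, 0.56, 0.67, 3.95, 0.81, 2.97, 0.00))
}
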
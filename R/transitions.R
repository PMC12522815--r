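#' Estimate SPUI transition probabilities from a patient panel
#'
#' Non-parametric (empirical) estimator: every consecutive within-patient
#' pair of measurement moments contributes one observed transition, and
#' the probability of moving from state A to state B is the number of
#' A-to-B pairs divided by the number of pairs originating in A. No
#' parametric (e.g. exponential) assumption is made.
#'
#' @param panel Data frame with columns `patient_id`, `moment` and either
#'   `state` (SPUI state labels) or `score` (CASA-Q sputum-impact scores,
#'   classified through [classify_spui()]). A `strategy` column, if
#'   present, is ignored here; filter the panel beforehand to obtain
#'   per-strategy matrices.
#' @param cutoffs Cut-offs used when classifying a `score` column.
#' @return An object of class `spui_transitions`: list with `matrix` (3x3
#'   row-stochastic estimate), `counts` (3x3 integer transition counts,
#'   kept for Dirichlet weighting in the PSA) and `n_pairs`.
#' @export
#' @examples
#' panel <- generate_panel(n_patients = 40, seed = 1)
#' estimate_spui_transitions(panel)
estimate_spui_transitions <- function(panel, cutoffs = casaq_cutoffs()) {
  stopifnot(is.data.frame(panel), all(c("patient_id", "moment") %in% names(panel)))
  if (anyDuplicated(panel[c("patient_id", "moment")]) > 0) {
    stop("panel has duplicate (patient_id, moment) records", call. = FALSE)
  }
  if (!"state" %in% names(panel)) {
    if (!"score" %in% names(panel)) {
      stop("panel needs a 'state' or 'score' column", call. = FALSE)
    }
    panel$state <- classify_spui(panel$score, cutoffs)
  }
  if (!all(panel$state %in% spui_states())) {
    stop("panel states must be SPUI states", call. = FALSE)
  }
  panel <- panel[order(panel$patient_id, panel$moment), ]
  same <- panel$patient_id[-1] == panel$patient_id[-nrow(panel)]
  from <- factor(panel$state[-nrow(panel)][same], levels = spui_states())
  to <- factor(panel$state[-1][same], levels = spui_states())
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(spui_states(), spui_states()))
  origin <- rowSums(counts)
  if (any(origin == 0)) {
    stop("no observed transition pairs originating in state(s): ",
         paste(spui_states()[origin == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(matrix = counts / origin, counts = counts,
                 n_pairs = sum(counts)),
            class = "spui_transitions")
}

#' Look up the annual background death probability at an age
#'
#' Ages beyond the last tabulated age are clamped to the last entry (the
#' table is treated as open-ended at the top); ages below the first
#' tabulated age are an error.
#'
#' @param life_table Data frame with integer `age` and annual death
#'   probability `qx`.
#' @param age Age in years (vectorized).
#' @return Annual death probability `q(age)` in `[0, 1]`.
#' @export
mortality_at_age <- function(life_table, age) {
  stopifnot(is.data.frame(life_table), all(c("age", "qx") %in% names(life_table)))
  lt <- life_table[order(life_table$age), ]
  if (any(age < lt$age[1])) {
    stop("age below life-table minimum (", lt$age[1], ")", call. = FALSE)
  }
  idx <- findInterval(age, lt$age)
  lt$qx[idx]
}

#' Assemble the full 5x5 cycle transition matrix
#'
#' Competing risks within a cycle are ordered death, then recurrence,
#' then SPUI movement, combined multiplicatively so each row is
#' stochastic by construction. From a SPUI state `s`:
#' `P(s -> death) = q_bg`, `P(s -> recurrence) = (1 - q_bg) * p_rec`, and
#' `P(s -> s') = (1 - q_bg) * (1 - p_rec) * spui[s, s']`. From recurrent
#' cancer, background and disease-specific mortality act as independent
#' competing risks, `P(-> death) = 1 - (1 - q_bg)(1 - q_rec)`, with the
#' remainder staying in the recurrence state. Death is absorbing.
#'
#' @param spui 3x3 row-stochastic SPUI transition matrix (a bare matrix or
#'   a `spui_transitions` object).
#' @param q_bg Annual background death probability for this cycle's age.
#' @param p_rec Annual probability of cancer recurrence from any SPUI state.
#' @param q_rec Annual excess death probability while in recurrence.
#' @return 5x5 row-stochastic matrix with state dimnames.
#' @export
build_cycle_matrix <- function(spui, q_bg, p_rec, q_rec) {
  if (inherits(spui, "spui_transitions")) spui <- spui$matrix
  stopifnot(is.matrix(spui), identical(dim(spui), c(3L, 3L)),
            q_bg >= 0, q_bg <= 1, p_rec >= 0, p_rec <= 1,
            q_rec >= 0, q_rec <= 1)
  states <- model_states()
  m <- matrix(0, 5, 5, dimnames = list(states, states))
  m[1:3, 1:3] <- (1 - q_bg) * (1 - p_rec) * spui
  m[1:3, "recurrent_cancer"] <- (1 - q_bg) * p_rec
  m[1:3, "death"] <- q_bg
  q_rc <- 1 - (1 - q_bg) * (1 - q_rec)
  m["recurrent_cancer", "recurrent_cancer"] <- 1 - q_rc
  m["recurrent_cancer", "death"] <- q_rc
  m["death", "death"] <- 1
  m
}

#' Per-cycle transition matrices for one strategy
#'
#' Builds the sequence of 5x5 matrices for cycles `0 .. horizon-1`. With
#' `settings$age_varying_mortality` (the default) the background death
#' probability is looked up at `start_age + cycle`; otherwise it is frozen
#' at the starting age.
#'
#' @param config An `hme_config`.
#' @param strategy Strategy label.
#' @return List of 5x5 matrices, one per cycle.
#' @export
cycle_matrices <- function(config, strategy) {
  s <- config$settings
  spui <- config$epi$spui_transitions[[strategy]]
  if (is.null(spui)) stop("unknown strategy: ", strategy, call. = FALSE)
  ages <- if (isTRUE(s$age_varying_mortality)) {
    s$start_age + seq_len(s$horizon_cycles) - 1
  } else {
    rep(s$start_age, s$horizon_cycles)
  }
  q <- mortality_at_age(config$epi$life_table, ages)
  lapply(seq_len(s$horizon_cycles), function(t) {
    build_cycle_matrix(spui, q[t], config$epi$recurrence_prob,
                       config$epi$recurrence_death_prob)
  })
}
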
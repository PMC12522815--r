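#' Health states, strategies and event types
#'
#' The model distinguishes five mutually exclusive health states: three
#' sputum-impact (SPUI) severity levels defined by CASA-Q sputum-domain
#' score cut-offs, recurrent cancer, and death. Death is absorbing and
#' recurrent cancer never returns to a SPUI state.
#'
#' @return Character vectors of canonical state / strategy / event labels.
#' @name model-labels
NULL

#' @rdname model-labels
#' @export
spui_states <- function() c("no_mild_spui", "moderate_spui", "severe_spui")

#' @rdname model-labels
#' @export
model_states <- function() c(spui_states(), "recurrent_cancer", "death")

#' @rdname model-labels
#' @export
strategy_labels <- function() c("third_gen", "second_gen", "no_hme")

#' @rdname model-labels
#' @export
event_types <- function() c("skin_irritation", "mucus_plug", "pulmonary_infection")

#' CASA-Q sputum-impact classification cut-offs
#'
#' CASA-Q domain scores run 0-100 (higher = less impact). Scores at or
#' above `no_mild_min` are classified as no/mild sputum impact, scores in
#' `[moderate_min, no_mild_min)` as moderate, and scores below
#' `moderate_min` as severe.
#'
#' @param no_mild_min Lower bound (inclusive) of the no/mild band. Default 94.
#' @param moderate_min Lower bound (inclusive) of the moderate band. Default 64.
#' @return An object of class `casaq_cutoffs`.
#' @export
#' @examples
#' classify_spui(c(94, 64, 63.999), casaq_cutoffs())
casaq_cutoffs <- function(no_mild_min = 94, moderate_min = 64) {
  stopifnot(is.numeric(no_mild_min), is.numeric(moderate_min))
  if (!(0 < moderate_min && moderate_min < no_mild_min && no_mild_min <= 100)) {
    stop("casaq_cutoffs: need 0 < moderate_min < no_mild_min <= 100", call. = FALSE)
  }
  structure(list(no_mild_min = no_mild_min, moderate_min = moderate_min),
            class = "casaq_cutoffs")
}

#' Classify a CASA-Q sputum-impact score into a SPUI health state
#'
#' Cut-offs are half-open downward: a score equal to `no_mild_min` (94)
#' belongs to the no/mild state and a score equal to `moderate_min` (64)
#' to the moderate state.
#'
#' @param score Numeric vector of CASA-Q sputum-impact scores in `[0, 100]`.
#' @param cutoffs A [casaq_cutoffs()] object.
#' @return Character vector of SPUI state labels, same length as `score`.
#' @export
classify_spui <- function(score, cutoffs = casaq_cutoffs()) {
  stopifnot(inherits(cutoffs, "casaq_cutoffs"))
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100)) {
    stop("classify_spui: scores must lie in [0, 100]", call. = FALSE)
  }
  out <- rep("severe_spui", length(score))
  out[score >= cutoffs$moderate_min] <- "moderate_spui"
  out[score >= cutoffs$no_mild_min] <- "no_mild_spui"
  out
}
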
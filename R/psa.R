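#' Assign probability distributions to uncertain parameters
#'
#' Standard health-economic PSA assignment by moment matching:
#' * costs (state costs, event costs, recurrence and end-of-life costs)
#'   get Gamma distributions, `shape = mean^2 / sd^2`,
#'   `scale = sd^2 / mean`;
#' * quantities bounded in `(0, 1)` (utilities, event risks, recurrence
#'   and recurrence-death probabilities) get Beta distributions,
#'   `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#'   `nu = mean (1 - mean) / sd^2 - 1`;
#' * the initial cohort split and each SPUI transition-matrix row get
#'   Dirichlet distributions over their simplex;
#' * structural constants (death utility, exact zeros) stay `FIXED`.
#'
#' Where no spread is reported, the standard deviation defaults to
#' `default_cv` times the mean (20%). An infeasible Beta spread
#' (`sd^2 >= mean (1 - mean)`) is shrunk to 0.95 of the feasible bound
#' with a warning. Dirichlet concentrations use observed transition
#' counts when supplied (anchoring spread to the source study's size),
#' otherwise `mean * kappa`.
#'
#' In `NET` utility mode the published net state utilities are perturbed
#' directly; in `COMPOSE` mode the base utilities and event disutilities
#' are perturbed separately instead.
#'
#' @param config An `hme_config`.
#' @param default_cv Default coefficient of variation (default 0.2).
#' @param transition_counts Optional named list (per strategy) of 3x3
#'   transition count matrices, e.g. from [estimate_spui_transitions()].
#' @param kappa Dirichlet concentration mass when counts are absent
#'   (default 40, the size of the source cross-over study).
#' @return List of distribution specs (class `psa_specs`); each spec has
#'   `path`, `family`, `mean`, `sd` and the moment-matched parameters.
#' @export
assign_distributions <- function(config, default_cv = 0.2,
                                 transition_counts = NULL, kappa = 40) {
  specs <- list()
  add <- function(path, family, mean, sd = default_cv * mean, alpha = NULL) {
    if (family %in% c("GAMMA", "BETA") && sd == 0) family <- "FIXED"
    par <- switch(family,
      FIXED = list(),
      GAMMA = {
        stopifnot(mean > 0)
        list(shape = mean^2 / sd^2, scale = sd^2 / mean)
      },
      BETA = {
        stopifnot(mean > 0, mean < 1)
        feas <- sqrt(mean * (1 - mean))
        if (sd >= feas) {
          warning(sprintf("Beta spread for %s infeasible (sd=%.4g); shrunk to 0.95 of bound",
                          path, sd), call. = FALSE)
          sd <- 0.95 * feas
        }
        nu <- mean * (1 - mean) / sd^2 - 1
        list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
      },
      DIRICHLET = list(alpha = alpha))
    specs[[length(specs) + 1]] <<- list(path = path, family = family,
                                        mean = mean, sd = sd, par = par)
  }
  prob_or_fixed <- function(path, v) {
    if (v <= 0 || v >= 1) add(path, "FIXED", v) else add(path, "BETA", v)
  }
  cost_or_fixed <- function(path, v) {
    if (v <= 0) add(path, "FIXED", v) else add(path, "GAMMA", v)
  }

  mode <- config$settings$utility_mode
  for (strat in strategy_labels()) {
    st <- config$strategies[[strat]]
    for (s in spui_states()) {
      cost_or_fixed(paste0("strategies.", strat, ".state_cost.", s),
                    st$state_cost[[s]])
      if (mode == "NET") {
        prob_or_fixed(paste0("strategies.", strat, ".net_state_utility.", s),
                      st$net_state_utility[[s]])
      }
    }
    for (e in event_types()) {
      prob_or_fixed(paste0("strategies.", strat, ".event_rate.", e),
                    st$event_rate[[e]])
    }
  }
  for (e in event_types()) {
    cost_or_fixed(paste0("shared.event_cost.", e), config$shared$event_cost[[e]])
    if (mode == "COMPOSE") {
      prob_or_fixed(paste0("shared.event_disutility.", e),
                    config$shared$event_disutility[[e]])
    }
  }
  if (mode == "COMPOSE") {
    for (s in spui_states()) {
      prob_or_fixed(paste0("shared.base_state_utility.", s),
                    config$shared$base_state_utility[[s]])
    }
  }
  cost_or_fixed("shared.recurrence_cost", config$shared$recurrence_cost)
  cost_or_fixed("shared.death_transition_cost", config$shared$death_transition_cost)
  prob_or_fixed("shared.recurrence_utility", config$shared$recurrence_utility)
  add("shared.death_utility", "FIXED", config$shared$death_utility)
  prob_or_fixed("epi.recurrence_prob", config$epi$recurrence_prob)
  prob_or_fixed("epi.recurrence_death_prob", config$epi$recurrence_death_prob)

  init <- config$epi$initial_distribution
  add("epi.initial_distribution", "DIRICHLET", init, alpha = init * kappa)
  for (strat in strategy_labels()) {
    m <- config$epi$spui_transitions[[strat]]
    cnt <- transition_counts[[strat]]
    if (inherits(cnt, "spui_transitions")) cnt <- cnt$counts
    for (s in spui_states()) {
      alpha <- if (!is.null(cnt)) {
        a <- cnt[s, ]
        if (sum(a) == 0) m[s, ] * kappa else pmax(a, 1e-6)
      } else m[s, ] * kappa
      add(paste0("epi.spui_transitions.", strat, ".", s),
          "DIRICHLET", m[s, ], alpha = alpha)
    }
  }
  structure(specs, class = "psa_specs")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha # degenerate guard at tiny concentrations
  stats::setNames(g / sum(g), names(alpha))
}

#' Draw one parameter set from assigned distributions
#'
#' Unlisted parameters stay at base. Dirichlet draws replace whole
#' simplex rows (already normalized); scalar draws replace single values
#' without renormalization. The draw is validated; an invalid draw is
#' retried up to `max_attempts` times.
#'
#' @param specs A `psa_specs` list from [assign_distributions()].
#' @param config Base `hme_config`.
#' @param seed Optional seed (otherwise the current RNG stream is used,
#'   as in [run_psa()]).
#' @param max_attempts Redraw limit for invalid draws.
#' @return A validated `hme_config` with sampled parameter values.
#' @export
sample_config <- function(specs, config, seed = NULL, max_attempts = 100) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    cfg <- config
    ok <- TRUE
    for (sp in specs) {
      value <- switch(sp$family,
        FIXED = sp$mean,
        GAMMA = stats::rgamma(1, shape = sp$par$shape, scale = sp$par$scale),
        BETA = stats::rbeta(1, sp$par$shape1, sp$par$shape2),
        DIRICHLET = rdirichlet1(sp$par$alpha))
      cfg <- config_set(cfg, sp$path, value, renormalize = FALSE,
                        validate = FALSE)
    }
    cfg <- tryCatch(validate_config(cfg), error = function(e) {ok <<- FALSE; NULL})
    if (ok) return(cfg)
  }
  stop("sample_config: no valid draw after ", max_attempts, " attempts",
       call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Seeded Monte Carlo: each iteration draws one parameter set from the
#' assigned distributions and runs the full deterministic model for all
#' three strategies, recording discounted cost, discounted QALYs and
#' expected event counts. Identical seeds give identical results. An
#' iteration whose draw fails is recorded and skipped; more than 1%
#' failures aborts the run.
#'
#' @param config Base `hme_config`.
#' @param specs Distribution specs; default [assign_distributions()] on
#'   the config.
#' @param n_iter Number of iterations (default 2000).
#' @param seed RNG seed.
#' @return An object of class `psa_results`: `records` (long data frame:
#'   iteration, strategy, cost, qaly, one column per event type),
#'   `n_iter`, `seed`, `failed` (failed iteration indices) and the base
#'   config.
#' @export
run_psa <- function(config, specs = NULL, n_iter = 2000, seed = 1L) {
  stopifnot(n_iter >= 1)
  if (is.null(specs)) specs <- assign_distributions(config)
  set.seed(seed)
  recs <- vector("list", n_iter)
  failed <- integer()
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      cfg <- sample_config(specs, config)
      rows <- lapply(strategy_labels(), function(strat) {
        out <- run_strategy(cfg, strat)
        cbind(data.frame(iteration = i, strategy = strat,
                         cost = out$cost, qaly = out$qaly),
              as.data.frame(as.list(out$event_counts)))
      })
      do.call(rbind, rows)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, i) else recs[[i]] <- res
  }
  if (length(failed) > 0.01 * n_iter) {
    stop("PSA failed in ", length(failed), " of ", n_iter, " iterations",
         call. = FALSE)
  }
  structure(list(records = do.call(rbind, recs), n_iter = n_iter,
                 seed = seed, failed = failed, config = config),
            class = "psa_results")
}

psa_wide <- function(results, field) {
  r <- results$records
  out <- sapply(strategy_labels(), function(s) r[[field]][r$strategy == s])
  matrix(out, ncol = length(strategy_labels()),
         dimnames = list(NULL, strategy_labels()))
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that a strategy is
#' preferred is the fraction of PSA iterations in which it attains the
#' strictly highest net monetary benefit `wtp * QALY - cost`; exact ties
#' split the iteration equally among the tied strategies. Probabilities
#' sum to 1 across strategies at every threshold.
#'
#' @param results A `psa_results` object.
#' @param wtp_grid Thresholds (JPY/QALY); default 0 to 15 million in
#'   250,000 steps.
#' @return Data frame (long): `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(results, wtp_grid = seq(0, 15e6, by = 250e3)) {
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  cost <- psa_wide(results, "cost")
  qaly <- psa_wide(results, "qaly")
  n <- nrow(cost)
  rows <- lapply(wtp_grid, function(l) {
    nmb <- l * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)
    data.frame(wtp = l, strategy = colnames(cost),
               probability = colSums(share) / n, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Empirical percentile interval
#'
#' Linear interpolation between order statistics (the default sample
#' quantile definition), used to form the 2.5th/97.5th percentile
#' intervals reported for PSA secondary outcomes.
#'
#' @param samples Numeric vector (length >= 2).
#' @param lower,upper Percentiles (default 2.5 and 97.5).
#' @return Named numeric `c(lo, hi)`.
#' @export
percentile_interval <- function(samples, lower = 2.5, upper = 97.5) {
  stopifnot(length(samples) >= 2)
  q <- stats::quantile(samples, c(lower, upper) / 100, names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Summaries of a PSA run
#'
#' Per-strategy means and percentile intervals for costs, QALYs and
#' event counts, plus mean incremental results of the intervention
#' against each comparator.
#'
#' @param results A `psa_results` object.
#' @param intervention Strategy treated as the intervention.
#' @return List with `by_strategy` (data frame) and `incremental`
#'   (data frame of mean deltas and the ICER of mean deltas).
#' @export
psa_summary <- function(results, intervention = "third_gen") {
  fields <- c("cost", "qaly", event_types())
  by_strategy <- do.call(rbind, lapply(strategy_labels(), function(s) {
    r <- results$records[results$records$strategy == s, ]
    row <- data.frame(strategy = s)
    for (f in fields) {
      ci <- percentile_interval(r[[f]])
      row[[paste0(f, "_mean")]] <- mean(r[[f]])
      row[[paste0(f, "_lo")]] <- ci[["lo"]]
      row[[paste0(f, "_hi")]] <- ci[["hi"]]
    }
    row
  }))
  cost <- psa_wide(results, "cost")
  qaly <- psa_wide(results, "qaly")
  comps <- setdiff(strategy_labels(), intervention)
  incremental <- do.call(rbind, lapply(comps, function(cmp) {
    dc <- cost[, intervention] - cost[, cmp]
    dq <- qaly[, intervention] - qaly[, cmp]
    data.frame(comparator = cmp, mean_delta_cost = mean(dc),
               mean_delta_qaly = mean(dq),
               icer_of_means = mean(dc) / mean(dq))
  }))
  list(by_strategy = by_strategy, incremental = incremental)
}
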
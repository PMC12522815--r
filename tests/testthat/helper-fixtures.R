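# Shared fixtures: the default synthetic config, a fast toy config, and
# an independent individual-level microsimulation used as an oracle for
# the cohort trace.

default_cfg <- default_model_config()$config

# Small config with simple, hand-checkable dynamics.
toy_config <- function(q = 0, p_rec = 0, q_rec = 0, horizon = 10,
                       rate = 0, spui = NULL) {
  cfg <- default_cfg
  cfg$settings$horizon_cycles <- horizon
  cfg$settings$discount_rate <- rate
  cfg$epi$life_table <- data.frame(age = 67, qx = q)
  cfg$epi$recurrence_prob <- p_rec
  cfg$epi$recurrence_death_prob <- q_rec
  if (!is.null(spui)) {
    for (st in strategy_labels()) cfg$epi$spui_transitions[[st]] <- spui
  }
  validate_config(cfg)
}

identity_spui <- function() {
  diag(3) |> (\(m) {dimnames(m) <- list(spui_states(), spui_states()); m})()
}

random_stochastic_config <- function() {
  rrow <- function(n) {x <- stats::rgamma(n, 1); x / sum(x)}
  cfg <- default_cfg
  cfg$epi$initial_distribution[] <- rrow(3)
  for (st in strategy_labels()) {
    m <- t(replicate(3, rrow(3)))
    dimnames(m) <- list(spui_states(), spui_states())
    cfg$epi$spui_transitions[[st]] <- m
  }
  cfg$epi$recurrence_prob <- stats::runif(1, 0, 0.3)
  cfg$epi$recurrence_death_prob <- stats::runif(1, 0, 0.6)
  cfg$epi$life_table <- generate_life_table(stats::runif(1, 0.005, 0.05),
                                            stats::runif(1, 1, 1.15))
  validate_config(cfg)
}

# Largest-remainder allocation of n patients over initial states.
stratified_init <- function(n, init) {
  cnt <- floor(n * init)
  short <- n - sum(cnt)
  if (short > 0) {
    top <- order(n * init - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[top] <- cnt[top] + 1
  }
  rep(seq_along(init), cnt)
}

# Independent oracle, part 1: walk n simulated patients through the same
# 5-state cycle matrices and tabulate realized occupancy with its
# Monte-Carlo standard error. Initial states are stratified
# (largest-remainder), so the cycle-0 row is exact up to rounding.
microsim <- function(config, strategy, n = 10000, seed = 42) {
  set.seed(seed)
  s <- config$settings
  mats <- cycle_matrices(config, strategy)
  horizon <- s$horizon_cycles
  occ <- matrix(NA_integer_, n, horizon + 1)
  occ[, 1] <- stratified_init(n, config$epi$initial_distribution)
  for (t in seq_len(horizon)) {
    for (k in seq_len(5)) {
      idx <- which(occ[, t] == k)
      if (length(idx)) {
        occ[idx, t + 1] <- sample.int(5, length(idx), replace = TRUE,
                                      prob = mats[[t]][k, ])
      }
    }
  }
  prop <- sapply(seq_len(5), function(k) colMeans(occ == k))
  prop_se <- sapply(seq_len(5), function(k) {
    apply(occ == k, 2, stats::sd) / sqrt(n)
  })
  list(occupancy = occ, prop = prop, prop_se = prop_se)
}

# Independent oracle, part 2: per-patient discounted cost/QALY via the
# exact competing-risk factorization. Because the death and recurrence
# hazards do not depend on the SPUI state, the five-state dynamics
# factorize: the probability of being alive and recurrence-free at the
# start of cycle j is the closed-form product A_j = prod (1-q_t)(1-p),
# recurrence occupancy R_j is an explicit sum over entry cycles, and the
# SPUI mix conditional on being alive follows the bare 3x3 matrix. Only
# that 3-state chain is simulated; everything else is closed form, so
# the estimator is unbiased with variance from the SPUI mix alone.
microsim_totals <- function(config, strategy, n = 10000, seed = 43) {
  set.seed(seed)
  s <- config$settings
  horizon <- s$horizon_cycles
  spui <- config$epi$spui_transitions[[strategy]]
  p_rec <- config$epi$recurrence_prob
  q_rec <- config$epi$recurrence_death_prob
  ages <- if (isTRUE(s$age_varying_mortality)) s$start_age + 0:(horizon - 1)
          else rep(s$start_age, horizon)
  q <- mortality_at_age(config$epi$life_table, ages)

  # closed-form masses at the start of each cycle j = 0..horizon
  A <- cumprod(c(1, (1 - q) * (1 - p_rec)))           # alive, recurrence-free
  qrc <- 1 - (1 - q) * (1 - q_rec)                    # death hazard in recurrence
  entry <- A[1:horizon] * (1 - q) * p_rec             # new recurrence per cycle
  R <- numeric(horizon + 1)
  for (j in seq_len(horizon)) {
    k <- seq_len(j)
    surv_in_rec <- vapply(k, function(kk) {
      if (kk > j - 1) 1 else prod(1 - qrc[(kk + 1):j])
    }, numeric(1))
    R[j + 1] <- sum(entry[k] * surv_in_rec)
  }
  D <- 1 - A - R

  # conditional SPUI chain (3 states) for n patients
  st3 <- matrix(NA_integer_, n, horizon)
  st3[, 1] <- stratified_init(n, config$epi$initial_distribution)
  for (t in seq_len(horizon - 1)) {
    for (k in 1:3) {
      idx <- which(st3[, t] == k)
      if (length(idx)) {
        st3[idx, t + 1] <- sample.int(3, length(idx), replace = TRUE,
                                      prob = spui[k, ])
      }
    }
  }

  stg <- config$strategies[[strategy]]
  u_spui <- effective_state_utility(config, strategy, spui_states())
  ev_cost <- sum(stg$event_rate[event_types()] *
                   config$shared$event_cost[event_types()])
  sc <- stg$state_cost[spui_states()] + ev_cost
  disc <- discount_factor(s$discount_rate, 0:(horizon - 1))
  cost <- qaly <- numeric(n)
  for (j in seq_len(horizon)) {
    w <- disc[j]
    cost <- cost + w * (A[j] * sc[st3[, j]] +
                          R[j] * config$shared$recurrence_cost +
                          (D[j + 1] - D[j]) * config$shared$death_transition_cost)
    qaly <- qaly + w * (A[j] * u_spui[st3[, j]] +
                          R[j] * config$shared$recurrence_utility)
  }
  list(cost = cost, qaly = qaly)
}
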
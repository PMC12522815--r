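test_that("moment matching recovers Gamma and Beta parameters algebraically", {
  cfg <- toy_config()
  cfg$shared$recurrence_cost <- 100
  specs <- assign_distributions(cfg, default_cv = 0.2)
  sp <- Filter(function(s) s$path == "shared.recurrence_cost", specs)[[1]]
  expect_equal(sp$family, "GAMMA")
  expect_equal(sp$par$shape, 25)
  expect_equal(sp$par$scale, 4)

  cfg$shared$recurrence_utility <- 0.5
  specs <- assign_distributions(cfg, default_cv = 0.2)
  sp <- Filter(function(s) s$path == "shared.recurrence_utility", specs)[[1]]
  # mean 0.5, sd 0.1 -> alpha = beta = 12
  expect_equal(sp$family, "BETA")
  expect_equal(sp$par$shape1, 12)
  expect_equal(sp$par$shape2, 12)

  # sampled moments agree with the target at large n
  set.seed(1)
  g <- rgamma(1e5, shape = 25, scale = 4)
  b <- rbeta(1e5, 12, 12)
  expect_equal(mean(g), 100, tolerance = 0.01)
  expect_equal(sd(g), 20, tolerance = 0.01)
  expect_equal(mean(b), 0.5, tolerance = 0.01)
})

test_that("infeasible Beta spreads are shrunk with a warning; zero spread goes FIXED", {
  cfg <- toy_config()
  cfg$epi$recurrence_prob <- 0.002 # cv=5 forces sd^2 >= mu(1-mu)
  w <- capture_warnings(specs <- assign_distributions(cfg, default_cv = 5))
  expect_true(any(grepl("infeasible", w)))
  sp <- Filter(function(s) s$path == "epi.recurrence_prob", specs)[[1]]
  expect_lt(sp$sd^2, sp$mean * (1 - sp$mean))
  expect_true(all(unlist(sp$par) > 0))

  specs0 <- assign_distributions(default_cfg, default_cv = 0)
  fams <- unique(vapply(specs0, `[[`, character(1), "family"))
  expect_true(all(fams %in% c("FIXED", "DIRICHLET")))
})

test_that("structural zeros and the death utility stay FIXED", {
  specs <- assign_distributions(default_cfg)
  get <- function(p) Filter(function(s) s$path == p, specs)[[1]]
  expect_equal(get("strategies.no_hme.event_rate.skin_irritation")$family, "FIXED")
  expect_equal(get("shared.death_utility")$family, "FIXED")
  expect_equal(get("epi.initial_distribution")$family, "DIRICHLET")
})

test_that("sampling is seed-reproducible and Dirichlet draws stay on the simplex", {
  specs <- assign_distributions(default_cfg)
  a <- sample_config(specs, default_cfg, seed = 99)
  b <- sample_config(specs, default_cfg, seed = 99)
  expect_identical(a, b)
  expect_equal(sum(a$epi$initial_distribution), 1, tolerance = 1e-12)
  for (st in strategy_labels()) {
    expect_equal(unname(rowSums(a$epi$spui_transitions[[st]])), rep(1, 3),
                 tolerance = 1e-12)
  }
})

test_that("Dirichlet initial-distribution draws recover the published mean", {
  specs <- assign_distributions(default_cfg)
  sp <- Filter(function(s) s$path == "epi.initial_distribution", specs)[[1]]
  set.seed(5)
  draws <- t(replicate(1e4, {
    g <- rgamma(3, shape = sp$par$alpha, rate = 1)
    g / sum(g)
  }))
  target <- c(0.075, 0.525, 0.400)
  a0 <- sum(sp$par$alpha)
  se <- sqrt(target * (1 - target) / (a0 + 1)) / sqrt(1e4)
  expect_true(all(abs(colMeans(draws) - target) < 3 * se))
})

test_that("all-FIXED PSA reproduces the deterministic base case bit-identically", {
  cfg <- default_cfg
  specs <- lapply(assign_distributions(cfg), function(s) {
    s$family <- "FIXED"
    s
  })
  class(specs) <- "psa_specs"
  res <- run_psa(cfg, specs, n_iter = 5, seed = 3)
  bc <- run_base_case(cfg)
  for (st in strategy_labels()) {
    r <- res$records[res$records$strategy == st, ]
    expect_identical(unique(r$cost), bc$outcomes[[st]]$cost)
    expect_identical(unique(r$qaly), bc$outcomes[[st]]$qaly)
  }
})

test_that("run_psa is reproducible and its mean tracks the generating base case", {
  res1 <- run_psa(default_cfg, n_iter = 200, seed = 17)
  res2 <- run_psa(default_cfg, n_iter = 200, seed = 17)
  expect_identical(res1$records, res2$records)
  expect_equal(nrow(res1$records), 200 * 3)

  bc <- run_base_case(default_cfg)
  dq <- with(res1, records$qaly[records$strategy == "third_gen"] -
                   records$qaly[records$strategy == "second_gen"])
  se <- sd(dq) / sqrt(length(dq))
  expect_lt(abs(mean(dq) - bc$incremental$vs_second_gen$delta_qaly), 3 * se)
})

test_that("CEAC probabilities sum to 1 and hit the cost/QALY ranking limits", {
  res <- run_psa(default_cfg, n_iter = 100, seed = 21)
  tab <- ceac(res, wtp_grid = c(0, 5e6, 1e12))
  sums <- tapply(tab$probability, tab$wtp, sum)
  expect_equal(as.vector(sums), rep(1, 3))
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))

  cost <- matrix(res$records$cost, ncol = 3, byrow = FALSE)
  # lambda = 0: the cheapest strategy wins every iteration
  at0 <- tab[tab$wtp == 0, ]
  cheap <- table(factor(strategy_labels()[apply(
    sapply(strategy_labels(), function(s)
      res$records$cost[res$records$strategy == s]), 1, which.min)],
    levels = strategy_labels())) / 100
  expect_equal(at0$probability, unname(as.vector(cheap)))
  # lambda very large: the highest-QALY strategy wins every iteration
  atInf <- tab[tab$wtp == 1e12, ]
  best <- table(factor(strategy_labels()[apply(
    sapply(strategy_labels(), function(s)
      res$records$qaly[res$records$strategy == s]), 1, which.max)],
    levels = strategy_labels())) / 100
  expect_equal(atInf$probability, unname(as.vector(best)))
})

test_that("tied strategies split CEAC probability equally", {
  rec <- data.frame(
    iteration = rep(1:4, each = 2),
    strategy = rep(c("third_gen", "second_gen"), 4),
    cost = rep(100, 8), qaly = rep(1, 8))
  res <- structure(list(records = rec, n_iter = 4), class = "psa_results")
  # restrict to the two present strategies via a local wide matrix
  cost <- matrix(rec$cost, ncol = 2, byrow = TRUE)
  qaly <- matrix(rec$qaly, ncol = 2, byrow = TRUE)
  nmb <- 5e6 * qaly - cost
  best <- nmb == apply(nmb, 1, max)
  share <- best / rowSums(best)
  expect_equal(colMeans(share), c(0.5, 0.5))
})

test_that("percentile intervals interpolate order statistics linearly", {
  expect_equal(percentile_interval(1:100), c(lo = 3.475, hi = 97.525))
  expect_equal(percentile_interval(rep(7, 10)), c(lo = 7, hi = 7))
  two <- percentile_interval(c(2, 10))
  expect_gte(two[["lo"]], 2)
  expect_lte(two[["hi"]], 10)
})

test_that("PSA summary reports per-strategy means with percentile intervals", {
  res <- run_psa(default_cfg, n_iter = 100, seed = 31)
  smry <- psa_summary(res)
  expect_equal(smry$by_strategy$strategy, strategy_labels())
  expect_true(all(smry$by_strategy$cost_lo <= smry$by_strategy$cost_mean &
                  smry$by_strategy$cost_mean <= smry$by_strategy$cost_hi))
  expect_equal(smry$incremental$comparator, c("second_gen", "no_hme"))
  # no-HME skin irritation stays exactly zero through the whole PSA
  no_hme <- smry$by_strategy[smry$by_strategy$strategy == "no_hme", ]
  expect_equal(no_hme$skin_irritation_mean, 0)
  expect_equal(no_hme$skin_irritation_hi, 0)
})
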
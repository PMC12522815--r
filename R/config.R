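#' Assemble a model configuration
#'
#' Bundles every input the analysis needs: run settings, epidemiology
#' (initial cohort split, life table, recurrence risks, SPUI transition
#' matrices per strategy), economics shared across strategies, and the
#' per-strategy economics (annual state costs, net state utilities, event
#' rates). The object is validated on construction.
#'
#' @param settings List: `horizon_cycles`, `cycle_length_years`,
#'   `cohort_size`, `start_age`, `discount_rate`, `wtp`, `utility_mode`
#'   (`"NET"` or `"COMPOSE"`), `half_cycle_correction`,
#'   `age_varying_mortality`.
#' @param epi List: `initial_distribution` (named over the SPUI states),
#'   `life_table` (data frame `age`, `qx`), `recurrence_prob`,
#'   `recurrence_death_prob`, `spui_transitions` (named list of 3x3
#'   row-stochastic matrices, one per strategy).
#' @param shared List: `recurrence_cost`, `death_transition_cost`,
#'   `event_cost`, `base_state_utility`, `event_disutility`,
#'   `recurrence_utility`, `death_utility`.
#' @param strategies Named list (one entry per strategy label) of lists
#'   with `state_cost`, `net_state_utility` and `event_rate`.
#' @param scenarios Optional named list of scenarios; each scenario is a
#'   named list mapping dotted parameter paths to replacement values.
#' @param notes Free-text provenance note.
#' @return A validated object of class `hme_config`.
#' @seealso [load_config()], [default_model_config()]
#' @export
hme_config <- function(settings, epi, shared, strategies,
                       scenarios = list(), notes = character()) {
  cfg <- structure(
    list(settings = settings, epi = epi, shared = shared,
         strategies = strategies, scenarios = scenarios, notes = notes),
    class = "hme_config")
  validate_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model configuration
#'
#' Checks structural completeness and every numeric invariant: the three
#' strategies present exactly once, probabilities in `[0, 1]`, the initial
#' distribution and each SPUI transition row summing to 1 (tolerance
#' 1e-9), non-negative costs, utilities in `[0, 1]` with death utility
#' exactly 0, and a usable life table.
#'
#' @param config An `hme_config` candidate.
#' @return The config, invisibly unchanged, if valid; otherwise an error
#'   naming the offending field and rule.
#' @export
validate_config <- function(config) {
  fail <- function(field, rule) {
    stop(sprintf("invalid config: %s %s", field, rule), call. = FALSE)
  }
  need <- function(x, nm, where) {
    if (is.null(x)) fail(paste0(where, ".", nm), "is missing")
    x
  }
  if (!is.list(config)) fail("config", "must be a list")
  for (top in c("settings", "epi", "shared", "strategies")) {
    need(config[[top]], "", top)
  }
  s <- config$settings
  if (need(s$horizon_cycles, "horizon_cycles", "settings") < 1) {
    fail("settings.horizon_cycles", "must be >= 1")
  }
  if (need(s$discount_rate, "discount_rate", "settings") < 0) {
    fail("settings.discount_rate", "must be >= 0")
  }
  if (need(s$wtp, "wtp", "settings") <= 0) fail("settings.wtp", "must be > 0")
  if (!need(s$utility_mode, "utility_mode", "settings") %in% c("NET", "COMPOSE")) {
    fail("settings.utility_mode", "must be NET or COMPOSE")
  }

  epi <- config$epi
  init <- need(epi$initial_distribution, "initial_distribution", "epi")
  if (!setequal(names(init), spui_states())) {
    fail("epi.initial_distribution", "must be named over the SPUI states")
  }
  if (abs(sum(init) - 1) > 1e-9) {
    fail("epi.initial_distribution", "must sum to 1 (tolerance 1e-9)")
  }
  if (any(init < 0 | init > 1)) fail("epi.initial_distribution", "entries must be in [0,1]")
  lt <- need(epi$life_table, "life_table", "epi")
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt)) || nrow(lt) < 1) {
    fail("epi.life_table", "must be a data frame with columns age, qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) fail("epi.life_table.qx", "must be in [0,1]")
  for (p in c("recurrence_prob", "recurrence_death_prob")) {
    v <- need(epi[[p]], p, "epi")
    if (v < 0 || v > 1) fail(paste0("epi.", p), "must be in [0,1]")
  }
  trans <- need(epi$spui_transitions, "spui_transitions", "epi")
  if (!setequal(names(trans), strategy_labels())) {
    fail("epi.spui_transitions", "must hold one matrix per strategy")
  }
  for (strat in names(trans)) {
    m <- trans[[strat]]
    where <- paste0("epi.spui_transitions.", strat)
    if (!is.matrix(m) || !identical(dim(m), c(3L, 3L))) fail(where, "must be 3x3")
    if (!identical(rownames(m), spui_states()) || !identical(colnames(m), spui_states())) {
      fail(where, "must have SPUI-state dimnames")
    }
    if (any(m < 0 | m > 1)) fail(where, "entries must be in [0,1]")
    if (any(abs(rowSums(m) - 1) > 1e-9)) fail(where, "rows must sum to 1 (tolerance 1e-9)")
  }

  sh <- config$shared
  for (p in c("recurrence_cost", "death_transition_cost")) {
    if (need(sh[[p]], p, "shared") < 0) fail(paste0("shared.", p), "must be >= 0")
  }
  ec <- need(sh$event_cost, "event_cost", "shared")
  if (!setequal(names(ec), event_types())) fail("shared.event_cost", "must cover all event types")
  if (any(ec < 0)) fail("shared.event_cost", "must be >= 0")
  bu <- need(sh$base_state_utility, "base_state_utility", "shared")
  if (!setequal(names(bu), spui_states())) fail("shared.base_state_utility", "must cover SPUI states")
  ed <- need(sh$event_disutility, "event_disutility", "shared")
  if (!setequal(names(ed), event_types())) fail("shared.event_disutility", "must cover all event types")
  for (u in list(bu, ed, sh$recurrence_utility)) {
    if (any(u < 0 | u > 1)) fail("shared utilities/disutilities", "must be in [0,1]")
  }
  if (!identical(as.numeric(need(sh$death_utility, "death_utility", "shared")), 0)) {
    fail("shared.death_utility", "must be exactly 0")
  }

  strat <- config$strategies
  if (!setequal(names(strat), strategy_labels()) ||
      anyDuplicated(names(strat)) > 0) {
    fail("strategies", "must contain each of third_gen, second_gen, no_hme exactly once")
  }
  for (nm in names(strat)) {
    st <- strat[[nm]]
    where <- paste0("strategies.", nm)
    sc <- need(st$state_cost, "state_cost", where)
    if (!setequal(names(sc), spui_states())) fail(paste0(where, ".state_cost"), "must cover SPUI states")
    if (any(sc < 0)) fail(paste0(where, ".state_cost"), "must be >= 0")
    nu <- need(st$net_state_utility, "net_state_utility", where)
    if (!setequal(names(nu), spui_states()) || any(nu < 0 | nu > 1)) {
      fail(paste0(where, ".net_state_utility"), "must cover SPUI states with values in [0,1]")
    }
    er <- st$event_rate
    if (!is.null(er)) {
      if (!setequal(names(er), event_types()) || any(er < 0)) {
        fail(paste0(where, ".event_rate"), "must cover all event types with values >= 0")
      }
    }
  }
  er_no <- strat$no_hme$event_rate
  if (!is.null(er_no) && er_no[["skin_irritation"]] != 0) {
    fail("strategies.no_hme.event_rate.skin_irritation", "must be 0 (no adhesive in use)")
  }
  invisible(config)
}

## ---- serialization ------------------------------------------------------

config_to_plain <- function(config) {
  x <- unclass(config)
  # named atomic vectors serialize as JSON arrays (names lost); store as maps
  x$epi$initial_distribution <- as.list(config$epi$initial_distribution)
  x$epi$life_table <- as.list(config$epi$life_table)
  x$epi$spui_transitions <- lapply(config$epi$spui_transitions, function(m) {
    lapply(stats::setNames(rownames(m), rownames(m)), function(r) as.list(m[r, ]))
  })
  for (f in c("event_cost", "base_state_utility", "event_disutility")) {
    x$shared[[f]] <- as.list(config$shared[[f]])
  }
  x$strategies <- lapply(x$strategies, function(st) {
    for (f in c("state_cost", "net_state_utility", "event_rate")) {
      if (!is.null(st[[f]])) st[[f]] <- as.list(st[[f]])
    }
    st
  })
  x
}

plain_to_config <- function(x) {
  num <- function(v) {
    out <- unlist(v)
    storage.mode(out) <- "double"
    out
  }
  x$epi$initial_distribution <- num(x$epi$initial_distribution)
  x$epi$life_table <- data.frame(age = num(x$epi$life_table$age),
                                 qx = num(x$epi$life_table$qx))
  x$epi$spui_transitions <- lapply(x$epi$spui_transitions, function(rows) {
    m <- do.call(rbind, lapply(rows, num))
    dimnames(m) <- list(spui_states(), spui_states())
    m
  })
  for (f in c("event_cost", "base_state_utility", "event_disutility")) {
    x$shared[[f]] <- num(x$shared[[f]])
  }
  x$strategies <- lapply(x$strategies, function(st) {
    for (f in c("state_cost", "net_state_utility", "event_rate")) {
      if (!is.null(st[[f]])) st[[f]] <- num(st[[f]])
    }
    st
  })
  x$scenarios <- x$scenarios %||% list()
  x$notes <- as.character(x$notes %||% character())
  hme_config(x$settings, x$epi, x$shared, x$strategies, x$scenarios, x$notes)
}

#' Read a model configuration from JSON or YAML
#'
#' The format is chosen from the file extension (`.json` vs
#' `.yml`/`.yaml`). The loaded configuration is fully validated; a parse
#' failure or invariant violation raises an error naming the problem.
#'
#' @param path Path to a configuration file written by [write_config()]
#'   (or hand-authored to the same schema).
#' @return A validated `hme_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(
    switch(ext,
           json = jsonlite::read_json(path, simplifyVector = FALSE),
           yml = ,
           yaml = yaml::read_yaml(path),
           stop("unsupported config extension: ", ext, call. = FALSE)),
    error = function(e) stop("config parse failure in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  plain_to_config(x)
}

#' Write a model configuration to JSON or YAML
#'
#' @param config A validated `hme_config`.
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly. `load_config(write_config(cfg, p))` is the
#'   identity on validated configs.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- config_to_plain(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE),
         yml = ,
         yaml = yaml::write_yaml(x, path, precision = 15),
         stop("unsupported config extension: ", ext, call. = FALSE))
  invisible(path)
}

## ---- dotted-path access -------------------------------------------------

#' Get or set a configuration value by dotted path
#'
#' Parameters are addressed by dotted paths such as
#' `"strategies.third_gen.state_cost.no_mild_spui"`,
#' `"epi.recurrence_prob"`, or, for one entry of a transition matrix,
#' `"epi.spui_transitions.third_gen.no_mild_spui.moderate_spui"`
#' (row state then column state). A path may also stop at a whole
#' probability vector or matrix row (e.g.
#' `"epi.initial_distribution"`), in which case the full vector is
#' returned or replaced.
#'
#' When `renormalize = TRUE` (the default) and the target is a single
#' entry of a row-stochastic structure (a SPUI transition row or the
#' initial distribution), the remaining entries of that row are rescaled
#' proportionally so the row still sums to 1; the new entry is clipped to
#' `[0, 1]` first.
#'
#' @param config An `hme_config`.
#' @param path Dotted parameter path.
#' @param value Replacement value (scalar, or vector/row for aggregate paths).
#' @param renormalize Rescale the complement of a perturbed probability
#'   entry so its row stays stochastic.
#' @param validate Re-validate the config after the assignment.
#' @return `config_get`: the addressed value. `config_set`: the modified
#'   (and by default re-validated) config.
#' @export
config_get <- function(config, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (i in seq_along(segs)) {
    seg <- segs[i]
    if (is.matrix(node)) {
      rest <- segs[i:length(segs)]
      if (length(rest) == 1) return(node[rest, ])
      if (length(rest) == 2) return(node[rest[1], rest[2]])
      stop("path descends past a matrix entry: ", path, call. = FALSE)
    }
    if (is.null(node) || !(seg %in% names(node))) {
      stop("unresolvable config path: ", path, call. = FALSE)
    }
    node <- node[[seg]]
  }
  node
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value, renormalize = TRUE, validate = TRUE) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  is_init <- identical(segs[1:2], c("epi", "initial_distribution")) &&
    length(segs) == 3
  is_trans_entry <- length(segs) == 5 &&
    identical(segs[1:2], c("epi", "spui_transitions"))

  assign_in <- function(node, segs, value) {
    seg <- segs[1]
    if (is.matrix(node)) {
      if (length(segs) == 1) {
        node[seg, ] <- value
      } else if (length(segs) == 2) {
        node[segs[1], segs[2]] <- value
      } else stop("path descends past a matrix entry", call. = FALSE)
      return(node)
    }
    if (is.null(node) || !(seg %in% names(node))) {
      stop("unresolvable config path: ", path, call. = FALSE)
    }
    if (length(segs) == 1) {
      node[[seg]] <- value
    } else {
      node[[seg]] <- assign_in(node[[seg]], segs[-1], value)
    }
    node
  }

  if (renormalize && (is_init || is_trans_entry)) {
    value <- min(max(value, 0), 1)
    row <- if (is_init) {
      config$epi$initial_distribution
    } else {
      config$epi$spui_transitions[[segs[3]]][segs[4], ]
    }
    target <- segs[length(segs)]
    others <- setdiff(names(row), target)
    rest <- sum(row[others])
    row[target] <- value
    if (rest > 0) {
      row[others] <- row[others] * (1 - value) / rest
    } else {
      row[others] <- (1 - value) / length(others)
    }
    if (is_init) {
      config$epi$initial_distribution <- row
    } else {
      config$epi$spui_transitions[[segs[3]]][segs[4], ] <- row
    }
  } else {
    out <- assign_in(unclass(config), segs, value)
    config <- structure(out, class = "hme_config")
  }
  if (validate) validate_config(config)
  config
}

#' Apply named parameter overrides to a configuration
#'
#' @param config An `hme_config`.
#' @param overrides Named list mapping dotted paths to values, or the name
#'   of a scenario stored in `config$scenarios` (e.g. the alternative
#'   no-HME annual cost of 170,000 yen).
#' @return The modified, validated config.
#' @export
apply_overrides <- function(config, overrides) {
  if (is.character(overrides) && length(overrides) == 1) {
    if (!overrides %in% names(config$scenarios)) {
      stop("unknown scenario: ", overrides, call. = FALSE)
    }
    overrides <- config$scenarios[[overrides]]
  }
  for (p in names(overrides)) {
    config <- config_set(config, p, overrides[[p]], renormalize = TRUE,
                         validate = FALSE)
  }
  validate_config(config)
}

#' Effective per-cycle utility of a SPUI state under a strategy
#'
#' In `NET` mode the published net state utilities (which already fold in
#' the expected event disutilities) are used verbatim. In `COMPOSE` mode
#' the utility is rebuilt from the base state utility minus the expected
#' event disutility, `base - sum_e rate(e) * disutility(e)`, floored at 0;
#' this requires event rates in the strategy block.
#'
#' @param config An `hme_config`.
#' @param strategy Strategy label.
#' @param state A SPUI state label (or vector of them).
#' @param mode `"NET"` or `"COMPOSE"`; defaults to the config setting.
#' @return Numeric utility weight(s) in `[0, 1]`.
#' @export
effective_state_utility <- function(config, strategy, state,
                                    mode = config$settings$utility_mode) {
  stopifnot(all(state %in% spui_states()))
  st <- config$strategies[[strategy]]
  if (identical(mode, "NET")) {
    return(unname(st$net_state_utility[state]))
  }
  if (!identical(mode, "COMPOSE")) stop("unknown utility mode: ", mode, call. = FALSE)
  if (is.null(st$event_rate)) {
    stop("COMPOSE utility mode requires event rates for strategy ", strategy,
         call. = FALSE)
  }
  dec <- sum(st$event_rate * config$shared$event_disutility[names(st$event_rate)])
  pmax(unname(config$shared$base_state_utility[state]) - dec, 0)
}
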
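# Synthetic data: b2 ground-truth networks plus raw sensor logs carrying the
# measurement artifacts of a real deployment — every violation event written
# to the database twice (once per reporting sensor), stray records from
# sensors that were never handed out, visitors with zero contacts who are
# absent from the log, and household-paired sensors that never log each
# other. Together these let every pipeline stage be tested end to end
# without any deposited data.

#' Simulate one contact network from the b2 model
#'
#' Draws actor effects `A_ki ~ N(0, sigma_A2)` and then each unordered dyad
#' independently `Bernoulli(plogis(m + Xa * beta_a + A_i + A_j))` with
#' `Xa = x_i + x_j` (actor-additive coding of the actor covariates).
#'
#' @param n_actors Number of actors (>= 2).
#' @param m Overall mean on the logit scale.
#' @param beta_a Covariate coefficient vector (empty for none).
#' @param sigma_A2 Actor random-effect variance (>= 0).
#' @param covariates Optional numeric matrix, `n_actors` rows, one column
#'   per coefficient.
#' @param k Network/condition index; actor IDs are prefixed with it.
#' @param seed Optional integer seed.
#' @return List with `network` (a `contact_network`) and `truth` (the
#'   parameters, the drawn actor effects, and the covariates).
#' @export
simulate_b2_network <- function(n_actors, m, beta_a = numeric(0),
                                sigma_A2 = 0, covariates = NULL, k = 1L,
                                seed = NULL) {
  if (!is.numeric(n_actors) || n_actors < 2) {
    stop("n_actors must be >= 2", call. = FALSE)
  }
  if (sigma_A2 < 0) stop("sigma_A2 must be >= 0", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_actors,
              ncol(covariates) == length(beta_a))
  } else if (length(beta_a)) {
    stop("beta_a given without covariates", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_actors)
  pad <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("C%s_V%0", pad, "d"), as.character(k), seq_len(n))

  A <- rnorm(n, 0, sqrt(sigma_A2))
  pr <- combn(n, 2L)
  eta <- m + A[pr[1, ]] + A[pr[2, ]]
  if (length(beta_a)) {
    xa <- covariates[pr[1, ], , drop = FALSE] +
      covariates[pr[2, ], , drop = FALSE]
    eta <- eta + as.vector(xa %*% beta_a)
  }
  yy <- rbinom(ncol(pr), 1L, plogis(eta))
  pairs <- if (any(yy == 1L)) {
    data.frame(visitor_a = ids[pr[1, yy == 1L]],
               visitor_b = ids[pr[2, yy == 1L]],
               stringsAsFactors = FALSE)
  } else NULL

  list(
    network = build_network(pairs, roster = ids, k = k),
    truth = list(params = b2_params(m = m, beta_a = beta_a,
                                    sigma_A2 = sigma_A2,
                                    A = setNames(A, ids)),
                 covariates = covariates, seed = seed)
  )
}

#' Emit raw sensor logs for one or more true networks
#'
#' For every true edge a number of violation events is drawn (default
#' `1 + Geometric(0.5)`, so at least one); every event is written as *two*
#' directed records with `violation_count = 1` and independent timestamps
#' uniform in the condition window — the double-logging artifact of the real
#' system. Household-paired actors never log each other: if a household pair
#' has a true edge, it is suppressed from the log and recorded in the truth
#' as censored. A configurable number of stray records from sensors absent
#' from the registry is injected (these must be removed by
#' [link_and_clean()]). Zero-contact actors appear in the registry but never
#' in the log.
#'
#' @param networks List of `contact_network`s, one per window row.
#' @param windows Condition-window table (as from [read_condition_windows()]
#'   or built in code); row order matches `networks`; each window must be at
#'   least one minute long.
#' @param household_pairs Number of actor pairs per condition to register as
#'   households.
#' @param n_unregistered Number of stray records per condition from sensors
#'   never handed out.
#' @param events_per_edge Function `n -> integer vector` of per-edge event
#'   counts (all >= 1).
#' @param seed Optional integer seed; given the seed the emitted tables are
#'   byte-identical across runs.
#' @return List of class `sds_simulation`: `log` (directed contact records,
#'   time-ordered), `registry`, `windows`, and `truth` (per-condition
#'   censored household edges, injected-record counts, event totals, seed).
#' @export
simulate_sds_log <- function(networks, windows,
                             household_pairs = 0L, n_unregistered = 0L,
                             events_per_edge = function(n) rgeom(n, 0.5) + 1L,
                             seed = NULL) {
  if (inherits(networks, "contact_network")) networks <- list(networks)
  stopifnot(length(networks) == nrow(windows))
  if (any(as.numeric(windows$end) - as.numeric(windows$start) < 60)) {
    stop("condition window shorter than 1 minute", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  sensor_counter <- 0L
  logs <- list()
  registry <- list()
  truth <- list(censored_edges = list(), n_unregistered = list(),
                n_events = list(), seed = seed)

  for (g in seq_along(networks)) {
    net <- networks[[g]]
    win <- as_condition_window(windows[g, , drop = FALSE])
    n <- length(net$actors)

    sensors <- sprintf("S%04d", sensor_counter + seq_len(n))
    sensor_counter <- sensor_counter + n
    sensor_of <- setNames(sensors, net$actors)

    # household groups: disjoint random actor pairs
    hh <- rep(NA_character_, n)
    if (household_pairs > 0) {
      if (2 * household_pairs > n) {
        stop("too many household pairs for roster size", call. = FALSE)
      }
      picked <- sample(n, 2L * household_pairs)
      hh[picked] <- rep(sprintf("H%s_%02d", win$label,
                                seq_len(household_pairs)), each = 2L)
    }
    names(hh) <- net$actors

    registry[[g]] <- data.frame(
      sensor_id = sensors, visitor_id = net$actors,
      condition = win$label,
      handout_time = win$start, return_time = win$end,
      household_group = unname(hh), stringsAsFactors = FALSE
    )

    e <- net$edges
    censored <- logical(nrow(e))
    if (nrow(e)) {
      censored <- !is.na(hh[e$from]) & !is.na(hh[e$to]) &
        hh[e$from] == hh[e$to]
    }
    truth$censored_edges[[win$label]] <- e[censored, , drop = FALSE]
    live <- e[!censored, , drop = FALSE]

    rows <- list()
    n_events_total <- 0L
    if (nrow(live)) {
      ev <- as.integer(events_per_edge(nrow(live)))
      stopifnot(all(ev >= 1L))
      n_events_total <- sum(ev)
      ia <- rep(seq_len(nrow(live)), ev)
      span <- as.numeric(win$end) - as.numeric(win$start)
      stamp <- function(nn) {
        win$start + floor(runif(nn, 0, span))
      }
      nn <- length(ia)
      rows[[1]] <- data.frame(
        reporting_id = unname(sensor_of[live$from[ia]]),
        opposing_id = unname(sensor_of[live$to[ia]]),
        violation_count = 1L, logged_at = stamp(nn),
        stringsAsFactors = FALSE
      )
      rows[[2]] <- data.frame(
        reporting_id = unname(sensor_of[live$to[ia]]),
        opposing_id = unname(sensor_of[live$from[ia]]),
        violation_count = 1L, logged_at = stamp(nn),
        stringsAsFactors = FALSE
      )
    }
    truth$n_events[[win$label]] <- n_events_total

    if (n_unregistered > 0) {
      ghost <- sprintf("X%04d", sample(9000:9999, n_unregistered,
                                       replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        reporting_id = ghost,
        opposing_id = sensors[sample.int(n, n_unregistered, replace = TRUE)],
        violation_count = 1L,
        logged_at = win$start + floor(runif(n_unregistered, 0,
                                            as.numeric(win$end) -
                                              as.numeric(win$start))),
        stringsAsFactors = FALSE
      )
    }
    truth$n_unregistered[[win$label]] <- as.integer(n_unregistered)

    if (length(rows)) logs[[g]] <- do.call(rbind, rows)
  }

  log <- if (length(logs)) do.call(rbind, logs) else {
    data.frame(reporting_id = character(0), opposing_id = character(0),
               violation_count = integer(0),
               logged_at = as.POSIXct(character(0), tz = "UTC"),
               stringsAsFactors = FALSE)
  }
  if (nrow(log)) {
    log <- log[order(log$logged_at, log$reporting_id, log$opposing_id), ,
               drop = FALSE]
    rownames(log) <- NULL
  }
  registry <- do.call(rbind, registry)

  structure(list(log = log, registry = registry, windows = windows,
                 truth = truth), class = "sds_simulation")
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write a simulation to the three on-disk input formats
#'
#' Emits `contact_log.csv`, `handout_registry.csv` and
#' `condition_windows.csv` in exactly the dialect the readers consume, plus
#' `truth.json` (generator parameters, censored household edges, injection
#' counts, seed) for round-trip tests.
#'
#' @param sim An `sds_simulation`.
#' @param dir Output directory (created if needed).
#' @param truth Optional extra truth entries (e.g. model parameters) merged
#'   into `truth.json`.
#' @return Named character vector of the four file paths.
#' @export
write_study_files <- function(sim, dir, truth = NULL) {
  stopifnot(inherits(sim, "sds_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    contact_log = file.path(dir, "contact_log.csv"),
    registry = file.path(dir, "handout_registry.csv"),
    windows = file.path(dir, "condition_windows.csv"),
    truth = file.path(dir, "truth.json")
  )

  log <- sim$log
  log$logged_at <- format_utc(log$logged_at)
  write.csv(log, paths[["contact_log"]], row.names = FALSE, quote = FALSE)

  reg <- sim$registry
  reg$handout_time <- format_utc(reg$handout_time)
  reg$return_time <- format_utc(reg$return_time)
  reg$household_group[is.na(reg$household_group)] <- ""
  write.csv(reg, paths[["registry"]], row.names = FALSE, quote = FALSE)

  win <- sim$windows
  win$start <- format_utc(win$start)
  win$end <- format_utc(win$end)
  write.csv(win, paths[["windows"]], row.names = FALSE, quote = FALSE)

  tr <- sim$truth
  tr$censored_edges <- lapply(tr$censored_edges, function(e) {
    if (nrow(e)) e else NULL
  })
  if (!is.null(truth)) tr <- c(tr, truth)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       null = "null", POSIXt = "ISO8601")
  paths
}

# Condition logit offsets implied by target per-actor odds ratios under
# actor-additive coding: fitting conditions (r, c) jointly estimates
# 2 * beta = logit_c - logit_r, and the reported OR is exp(beta).
study_condition_logits <- function(base_logit, or_targets) {
  l2 <- base_logit
  c(`1` = l2 - 2 * log(or_targets[["face_mask_vs_none"]]),
    `2` = l2,
    `3` = l2 + 2 * log(or_targets[["buzzer_delayed_vs_none"]]),
    `4` = l2 + 2 * log(or_targets[["bidirectional_vs_unidirectional"]]),
    `5` = l2 + 2 * log(or_targets[["bidirectional_vs_unidirectional"]]) -
      2 * log(or_targets[["buzzer_immediate_vs_none"]]),
    `6` = l2 + 2 * log(or_targets[["bidirectional_vs_unidirectional"]]) -
      2 * log(or_targets[["buzzer_immediate_vs_none"]]) +
      2 * log(or_targets[["unidirectional_vs_no_direction"]]))
}

#' Default design of the synthetic study
#'
#' The six 120-minute conditions of a three-day event: walking direction
#' varies across days (bidirectional, unidirectional, none) and the
#' supplementary intervention within days (face mask, buzzer, none).
#'
#' @return Window table with one row per condition.
#' @export
study_windows <- function() {
  data.frame(
    label = as.character(1:6),
    start = as.POSIXct(c("2020-08-28 13:30:00", "2020-08-28 15:30:00",
                         "2020-08-28 17:30:00", "2020-08-29 13:30:00",
                         "2020-08-29 16:00:00", "2020-08-30 13:30:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2020-08-28 15:30:00", "2020-08-28 17:30:00",
                       "2020-08-28 19:30:00", "2020-08-29 15:30:00",
                       "2020-08-29 18:00:00", "2020-08-30 15:30:00"),
                     tz = "UTC"),
    walking_direction = c("bidirectional", "bidirectional", "bidirectional",
                          "unidirectional", "unidirectional", "none"),
    supplement = c("face_mask", "none", "buzzer", "none", "buzzer", "buzzer"),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study on disk
#'
#' Simulates all six conditions at the scale of a large indoor event
#' (102-147 sensors per 2-hour condition) from the b2 model with known
#' parameters, then writes the three raw input files plus the ground truth.
#' Per-condition baseline logits are placed so that the five default
#' pairwise comparisons have known per-actor odds ratios; actor
#' heterogeneity `sigma_A2` makes the degree distributions overdispersed
#' like real crowds.
#'
#' @param dir Output directory.
#' @param n_per_condition Integer vector of roster sizes for conditions 1-6.
#' @param base_logit Baseline (condition 2) dyad logit; the default -2.955
#'   gives a *marginal* mean degree near 10 at `n = 137` once the actor
#'   heterogeneity is integrated out (the random effects raise the marginal
#'   density above `plogis(base_logit)`).
#' @param or_targets Named per-actor odds ratios for the five standard
#'   comparisons, used to place the condition logits.
#' @param sigma_A2 Actor random-effect variance.
#' @param household_pairs,n_unregistered Artifact intensities per condition,
#'   passed to [simulate_sds_log()].
#' @param seed Integer seed; the files are byte-identical given the seed.
#' @return Invisibly, list with `paths` (the four files), `networks` (the
#'   true per-condition networks), `logits`, and the simulation `truth`.
#' @export
make_study_fixture <- function(dir,
                               n_per_condition = c(130L, 137L, 122L,
                                                   147L, 137L, 123L),
                               base_logit = -2.955,
                               or_targets = c(
                                 face_mask_vs_none = 1.05,
                                 unidirectional_vs_no_direction = 1.66,
                                 bidirectional_vs_unidirectional = 0.99,
                                 buzzer_delayed_vs_none = 1.24,
                                 buzzer_immediate_vs_none = 1.43),
                               sigma_A2 = 0.5,
                               household_pairs = 3L, n_unregistered = 25L,
                               seed = NULL) {
  stopifnot(length(n_per_condition) == 6)
  if (!is.null(seed)) set.seed(seed)
  windows <- study_windows()
  logits <- study_condition_logits(base_logit, as.list(or_targets))

  sims <- lapply(1:6, function(g) {
    simulate_b2_network(n_per_condition[g], m = logits[[g]],
                        sigma_A2 = sigma_A2, k = windows$label[g])
  })
  networks <- lapply(sims, `[[`, "network")

  sim <- simulate_sds_log(networks, windows,
                          household_pairs = household_pairs,
                          n_unregistered = n_unregistered)
  paths <- write_study_files(sim, dir, truth = list(
    base_logit = base_logit, condition_logits = as.list(logits),
    or_targets = as.list(or_targets), sigma_A2 = sigma_A2,
    n_per_condition = n_per_condition, seed = seed
  ))
  invisible(list(paths = paths, networks = networks, logits = logits,
                 truth = sim$truth))
}
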
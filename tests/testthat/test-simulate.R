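# The synthetic generator: network sampling and the raw-log artifacts.

test_that("network simulation respects the dyad probabilities", {
  lo <- simulate_b2_network(50, m = -10, sigma_A2 = 0, seed = 1)$network
  expect_lte(nrow(lo$edges), 2)  # plogis(-10) ~ 4.5e-5 over 1225 dyads

  hi <- simulate_b2_network(50, m = 10, sigma_A2 = 0, seed = 1)$network
  expect_gte(nrow(hi$edges), 1223)

  # density at m = 0 within 3 binomial SDs of 0.5 over 4950 dyads
  mid <- simulate_b2_network(100, m = 0, sigma_A2 = 0, seed = 2)$network
  dens <- nrow(mid$edges) / 4950
  expect_lt(abs(dens - 0.5), 3 * sqrt(0.25 / 4950))

  expect_error(simulate_b2_network(1, m = 0), "n_actors")
  expect_error(simulate_b2_network(10, m = 0, sigma_A2 = -1), "sigma_A2")
  expect_error(simulate_b2_network(10, m = 0, beta_a = 1), "covariates")
})

test_that("empirical density converges to the logistic mean at large n", {
  net <- simulate_b2_network(500, m = -2, sigma_A2 = 0, seed = 3)$network
  dens <- nrow(net$edges) / choose(500, 2)
  p <- plogis(-2)
  expect_lt(abs(dens - p), 4 * sqrt(p * (1 - p) / choose(500, 2)))
})

test_that("each violation event is written to the log exactly twice", {
  set.seed(5)
  sim <- simulate_b2_network(12, m = 0, sigma_A2 = 0, k = "1")
  win <- data.frame(label = "1",
                    start = utc("2020-08-28 13:30:00"),
                    end = utc("2020-08-28 15:30:00"),
                    walking_direction = "none", supplement = "none",
                    stringsAsFactors = FALSE)
  out <- simulate_sds_log(list(sim$network), win, seed = 11)
  expect_equal(nrow(out$log), 2 * out$truth$n_events[["1"]])
  expect_true(all(out$log$violation_count == 1L))
  # every record's mirror exists
  key <- paste(out$log$reporting_id, out$log$opposing_id)
  mirror <- paste(out$log$opposing_id, out$log$reporting_id)
  expect_equal(sort(key), sort(mirror))

  # single-edge network, default options: exactly two directed records
  one <- build_network(data.frame(visitor_a = "C9_V01", visitor_b = "C9_V02"),
                       roster = c("C9_V01", "C9_V02"), k = "1")
  out1 <- simulate_sds_log(list(one), win,
                           events_per_edge = function(n) rep(1L, n),
                           seed = 2)
  expect_equal(nrow(out1$log), 2)

  # windows shorter than a minute are malformed
  bad <- win; bad$end <- bad$start + 30
  expect_error(simulate_sds_log(list(one), bad), "1 minute")
})

test_that("household pairs emit no mutual records and are censored in truth", {
  # complete graph guarantees the household pair has a true edge
  roster <- sprintf("C1_V%02d", 1:6)
  cp <- t(combn(roster, 2))
  net <- build_network(data.frame(visitor_a = cp[, 1], visitor_b = cp[, 2]),
                       roster, k = "1")
  win <- data.frame(label = "1", start = utc("2020-08-28 13:30:00"),
                    end = utc("2020-08-28 15:30:00"),
                    walking_direction = "none", supplement = "none",
                    stringsAsFactors = FALSE)
  out <- simulate_sds_log(list(net), win, household_pairs = 1, seed = 21)
  cens <- out$truth$censored_edges[["1"]]
  expect_equal(nrow(cens), 1)
  hh_sensors <- out$registry$sensor_id[!is.na(out$registry$household_group)]
  expect_length(hh_sensors, 2)
  expect_false(any(out$log$reporting_id %in% hh_sensors &
                     out$log$opposing_id %in% hh_sensors))
})

test_that("ingesting a simulated study recovers the truth exactly", {
  dir <- tempfile("fx")
  fx <- make_study_fixture(dir, n_per_condition = rep(40L, 6),
                           household_pairs = 2L, n_unregistered = 10L,
                           seed = 17)
  cfg <- default_config(dir, file.path(dir, "out"))
  pre <- run_preprocess(cfg)
  expect_length(pre, 6)
  for (g in 1:6) {
    lab <- as.character(g)
    net <- build_network(pre[[lab]]$pairs, pre[[lab]]$roster, k = lab)
    tr <- fx$networks[[g]]
    cen <- fx$truth$censored_edges[[lab]]
    ekey <- function(e) paste(e$from, e$to)
    expect_identical(net$actors, tr$actors)
    expect_setequal(ekey(net$edges), setdiff(ekey(tr$edges), ekey(cen)))
    # injected unregistered-sensor records all removed and counted;
    # household contacts are suppressed at source (never logged), so the
    # cleaner sees none of them
    expect_equal(pre[[lab]]$report$removed$unregistered_sensor, 10L)
    expect_equal(pre[[lab]]$report$removed$household_pair, 0L)
  }
})

test_that("seeded reruns emit byte-identical files", {
  d1 <- tempfile("a"); d2 <- tempfile("b")
  make_study_fixture(d1, n_per_condition = rep(25L, 6), seed = 9)
  make_study_fixture(d2, n_per_condition = rep(25L, 6), seed = 9)
  for (f in c("contact_log.csv", "handout_registry.csv",
              "condition_windows.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- tempfile("c")
  make_study_fixture(d3, n_per_condition = rep(25L, 6), seed = 10)
  expect_false(identical(readLines(file.path(d1, "contact_log.csv")),
                         readLines(file.path(d3, "contact_log.csv"))))
})

test_that("default study design matches the experimental layout", {
  w <- study_windows()
  expect_equal(nrow(w), 6)
  expect_true(all(as.numeric(w$end - w$start, units = "mins") == 120))
  expect_equal(w$walking_direction,
               c(rep("bidirectional", 3), rep("unidirectional", 2), "none"))
})
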
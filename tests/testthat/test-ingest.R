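# Parsing of raw sensor logs and the three cleaning steps.

test_that("contact log rows map to records in file order", {
  f <- write_log_csv(rbind(
    c("S012", "S045", "3", "2020-08-28T14:02:11"),
    c("S045", "S012", "2", "2020-08-28T14:03:00")
  ))
  rec <- read_contact_log(f)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$reporting_id, c("S012", "S045"))
  expect_equal(rec$violation_count, c(3L, 2L))
  expect_equal(rec$logged_at[1], utc("2020-08-28 14:02:11"))
})

test_that("header-only file gives an empty record set", {
  f <- tempfile(fileext = ".csv")
  writeLines("reporting_id,opposing_id,violation_count,logged_at", f)
  expect_equal(nrow(read_contact_log(f)), 0)
})

test_that("malformed rows abort with the offending line number", {
  f <- write_log_csv(rbind(
    c("S012", "S045", "3", "2020-08-28T14:02:11"),
    c("S013", "S046", "three", "2020-08-28T14:02:12")
  ))
  expect_error(read_contact_log(f), "line 3.*three")

  f2 <- write_log_csv(rbind(c("S012", "S045", "3", "not-a-time")))
  expect_error(read_contact_log(f2), "line 2.*not-a-time")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("reporting_id,opposing_id,violation_count,logged_at",
               "S012,S045,3"), f3)
  expect_error(read_contact_log(f3), "line 2.*expected 4 fields")
})

test_that("alternative delimiters and column names are supported", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto\tn\twhen", "A\tB\t2\t2020-08-28T14:00:00"), f)
  rec <- read_contact_log(f, delim = "\t",
                          columns = c(reporting_id = "from",
                                      opposing_id = "to",
                                      violation_count = "n",
                                      logged_at = "when"))
  expect_equal(rec$opposing_id, "B")
})

test_that("window filtering is half-open: start kept, end dropped", {
  rec <- records_df(
    rep = paste0("S", 1:5), opp = paste0("T", 1:5), count = 1,
    at = c("2020-08-28 13:29:59",   # before
           "2020-08-28 13:30:00",   # exactly at start -> kept
           "2020-08-28 14:10:00",   # inside
           "2020-08-28 15:30:00",   # exactly at end -> dropped
           "2020-08-28 16:00:00")   # after
  )
  kept <- window_filter(rec, win1())
  expect_equal(kept$reporting_id, c("S2", "S3"))

  # disjoint back-to-back windows never share a record
  w2 <- condition_window("2", "2020-08-28 15:30:00", "2020-08-28 17:30:00")
  ids <- c(window_filter(rec, win1())$reporting_id,
           window_filter(rec, w2)$reporting_id)
  expect_false(any(duplicated(ids)))
})

test_that("link_and_clean drops by reason and counts them", {
  reg <- registry_df(sensor = c("S1", "S2", "S3", "S4"),
                     visitor = c("VA", "VB", "VC", "VD"),
                     condition = "1",
                     household = c(NA, NA, "H1", "H1"))
  rec <- records_df(
    rep = c("S1", "S2", "S9", "S8", "S7", "S3", "S1", "S2", "S2", "S1"),
    opp = c("S2", "S1", "S1", "S2", "S3", "S4", "S3", "S4", "S3", "S4"),
    count = 1, at = rep("2020-08-28 14:00:00", 10)
  )
  res <- link_and_clean(rec, reg, win1())
  expect_s3_class(res, "sds_clean")
  expect_equal(res$report$n_retained, 6)
  expect_equal(res$report$removed$unregistered_sensor, 3)
  expect_equal(res$report$removed$household_pair, 1)
  expect_equal(res$report$removed$self_contact, 0)
  expect_true(all(c("reporting_visitor", "opposing_visitor") %in%
                    names(res$records)))
  # visitors resolved through the registry
  expect_equal(res$records$reporting_visitor[1], "VA")

  # self-records are their own reason
  selfy <- records_df("S1", "S1", 1, "2020-08-28 14:00:00")
  expect_equal(link_and_clean(selfy, reg, win1())$report$removed$self_contact, 1)

  # missing registry is an error, unknown sensors are not
  expect_error(link_and_clean(rec, NULL, win1()), "registry")
  expect_error(link_and_clean(rec, reg[0, ], win1()), "registry")
})

test_that("link_and_clean is idempotent", {
  reg <- registry_df(c("S1", "S2", "S3"), c("VA", "VB", "VC"), "1")
  rec <- records_df(c("S1", "S2", "S9"), c("S2", "S3", "S1"), c(2, 1, 1),
                    rep("2020-08-28 14:00:00", 3))
  once <- link_and_clean(rec, reg, win1())
  twice <- link_and_clean(once$records, reg, win1())
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$n_retained, once$report$n_retained)
  expect_equal(unlist(twice$report$removed), c(unregistered_sensor = 0,
                                               self_contact = 0,
                                               household_pair = 0))
})

test_that("symmetrize collapses the double-logged records per unordered pair", {
  rec <- records_df(c("A", "B", "A"), c("B", "A", "C"), c(2, 3, 1),
                    rep("2020-08-28 14:00:00", 3))
  pc <- symmetrize(rec)
  expect_equal(pc$visitor_a, c("A", "A"))
  expect_equal(pc$visitor_b, c("B", "C"))
  expect_equal(pc$total_events, c(5L, 1L))
  expect_equal(pc$n_records, c(2L, 1L))

  # trivial duplicate collapse
  two <- symmetrize(records_df(c("A", "B"), c("B", "A"), c(2, 2),
                               rep("2020-08-28 14:00:00", 2)))
  expect_equal(nrow(two), 1)
  expect_equal(two$total_events, 4L)

  # empty in, empty out
  expect_equal(nrow(symmetrize(rec[0, ])), 0)
})

test_that("symmetrize conserves events and never lists a pair twice", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 30
    ids <- sprintf("V%02d", sample(12, n, replace = TRUE))
    opp <- sprintf("V%02d", sample(12, n, replace = TRUE))
    keep <- ids != opp
    rec <- records_df(ids[keep], opp[keep],
                      sample(1:4, sum(keep), replace = TRUE),
                      rep("2020-08-28 14:00:00", sum(keep)))
    pc <- symmetrize(rec)
    expect_equal(sum(pc$total_events), sum(rec$violation_count))
    expect_equal(sum(pc$n_records), nrow(rec))
    keys <- c(paste(pc$visitor_a, pc$visitor_b),
              paste(pc$visitor_b, pc$visitor_a))
    expect_false(any(duplicated(keys)))
    expect_true(all(pc$visitor_a < pc$visitor_b))
  }
})

test_that("roster includes zero-contact visitors and is per condition", {
  reg <- rbind(registry_df(paste0("S", 1:5), paste0("V", 5:1), "1"),
               registry_df("S6", "V3", "2"))
  r1 <- roster_with_isolates(reg, win1())
  expect_equal(r1, paste0("V", 1:5))  # sorted, isolates included
  w2 <- condition_window("2", "2020-08-28 15:30:00", "2020-08-28 17:30:00")
  expect_equal(roster_with_isolates(reg, w2), "V3")  # spans both conditions
  w3 <- condition_window("3", "2020-08-28 17:30:00", "2020-08-28 19:30:00")
  expect_error(roster_with_isolates(reg, w3), "no visitors")
})

test_that("window tables are validated", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("label,start,end,walking_direction,supplement",
               "1,2020-08-28T13:30:00,2020-08-28T15:30:00,bidirectional,face_mask",
               "2,2020-08-28T15:00:00,2020-08-28T17:30:00,bidirectional,none"),
             f)
  expect_error(read_condition_windows(f), "overlap")
  expect_error(condition_window("1", "2020-08-28 15:00:00",
                                "2020-08-28 14:00:00"), "after start")
})
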
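# Small programmatic fixtures shared across test files.

options(sdsnet.verbose = FALSE)

utc <- function(x) as.POSIXct(x, tz = "UTC")

# write a contact-log CSV from a data.frame of character fields
write_log_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("reporting_id,opposing_id,violation_count,logged_at",
               apply(rows, 1, paste, collapse = ",")), path)
  path
}

# directed record data.frame builder (times as ISO strings)
records_df <- function(rep, opp, count, at) {
  data.frame(reporting_id = rep, opposing_id = opp,
             violation_count = as.integer(count), logged_at = utc(at),
             stringsAsFactors = FALSE)
}

registry_df <- function(sensor, visitor, condition, household = NA_character_) {
  data.frame(sensor_id = sensor, visitor_id = visitor,
             condition = as.character(condition),
             handout_time = utc("2020-08-28 13:30:00"),
             return_time = utc("2020-08-28 15:30:00"),
             household_group = household, stringsAsFactors = FALSE)
}

win1 <- function() condition_window("1", "2020-08-28 13:30:00",
                                    "2020-08-28 15:30:00")

# reference scaled-inv-chi^2 log density, written independently of the
# package's version
log_sinvchisq_ref <- function(s2, nu, s0sq) {
  (nu / 2) * log(nu * s0sq / 2) - lgamma(nu / 2) -
    (nu / 2 + 1) * log(s2) - nu * s0sq / (2 * s2)
}

# tiny two-network design with known tie pattern
toy_design <- function(n = 4, seed = 1, two_networks = TRUE, m = 0,
                       sigma_A2 = 0) {
  set.seed(seed)
  a <- simulate_b2_network(n, m = m, sigma_A2 = sigma_A2, k = 1)$network
  if (!two_networks) return(dyad_design(a))
  b <- simulate_b2_network(n, m = m, sigma_A2 = sigma_A2, k = 2)$network
  dyad_design(a, b)
}
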
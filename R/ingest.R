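# Reading and cleaning of raw social-distancing-sensor (SDS) output.
#
# The raw log is a delimited table with one row per *directed* contact record:
# the reporting sensor, the opposing sensor, how many <1.5 m violations were
# counted for that pair, and when the record reached the access point. A
# single contact is present twice (once per reporting sensor).

# -- low-level delimited reader --------------------------------------------

# Split a delimited text file into a character matrix while keeping track of
# 1-based file line numbers, so validation errors can name the exact line.
# strsplit() drops exactly one trailing empty field, hence the appended
# delimiter sentinel (registry rows legitimately end in an empty
# household_group field).
read_delimited <- function(path, delim = ",", required) {
  if (!is.character(path) || !file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(raw)))
  if (!length(nonblank)) stop("empty file: ", path, call. = FALSE)

  header <- trimws(strsplit(paste0(raw[nonblank[1]], delim),
                            delim, fixed = TRUE)[[1]])
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  body <- nonblank[-1L]
  if (!length(body)) {
    mat <- matrix(character(0), nrow = 0, ncol = length(header),
                  dimnames = list(NULL, header))
    return(list(mat = mat, lines = integer(0)))
  }
  fields <- strsplit(paste0(raw[body], delim), delim, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields, found %d",
                 body[bad[1]], length(header), nf[bad[1]]), call. = FALSE)
  }
  mat <- matrix(trimws(unlist(fields)), ncol = length(header), byrow = TRUE,
                dimnames = list(NULL, header))
  list(mat = mat, lines = body)
}

parse_int_field <- function(x, lines, field, min = 1L) {
  ok <- grepl("^[+-]?[0-9]+$", x)
  val <- suppressWarnings(as.integer(x))
  ok <- ok & !is.na(val) & val >= min
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("line %d: %s '%s' is not an integer >= %d",
                 lines[i], field, x[i], min), call. = FALSE)
  }
  val
}

parse_time_field <- function(x, lines, field,
                             format = "%Y-%m-%dT%H:%M:%S",
                             allow_empty = FALSE) {
  t <- as.POSIXct(x, format = format, tz = "UTC")
  bad <- is.na(t) & !(allow_empty & !nzchar(x))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("line %d: cannot parse %s '%s' with format '%s'",
                 lines[i], field, x[i], format), call. = FALSE)
  }
  t
}

# -- public readers ---------------------------------------------------------

#' Read a raw sensor contact log
#'
#' Parses the directed contact records produced by the social-distancing
#' sensors: reporting sensor ID, opposing sensor ID, the number of <1.5 m
#' violations logged for the pair, and the registration time. Rows are
#' returned in file order; any malformed row (missing field, non-integer
#' count, unparseable time) aborts with an error naming the file line.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default comma).
#' @param columns Named character vector mapping the canonical field names
#'   (`reporting_id`, `opposing_id`, `violation_count`, `logged_at`) to the
#'   column names used in the file.
#' @param time_format `strptime()` format for `logged_at`
#'   (default ISO-8601, `"%Y-%m-%dT%H:%M:%S"`, interpreted as UTC).
#' @return A `data.frame` with columns `reporting_id`, `opposing_id`,
#'   `violation_count` (integer, >= 1) and `logged_at` (`POSIXct`, UTC).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("reporting_id,opposing_id,violation_count,logged_at",
#'              "S012,S045,3,2020-08-28T14:02:11"), f)
#' read_contact_log(f)
#' @export
read_contact_log <- function(path, delim = ",",
                             columns = c(reporting_id = "reporting_id",
                                         opposing_id = "opposing_id",
                                         violation_count = "violation_count",
                                         logged_at = "logged_at"),
                             time_format = "%Y-%m-%dT%H:%M:%S") {
  need <- c("reporting_id", "opposing_id", "violation_count", "logged_at")
  stopifnot(all(need %in% names(columns)))
  parsed <- read_delimited(path, delim, required = unname(columns[need]))
  mat <- parsed$mat
  data.frame(
    reporting_id = mat[, columns[["reporting_id"]]],
    opposing_id = mat[, columns[["opposing_id"]]],
    violation_count = parse_int_field(mat[, columns[["violation_count"]]],
                                      parsed$lines, "violation_count"),
    logged_at = parse_time_field(mat[, columns[["logged_at"]]],
                                 parsed$lines, "logged_at", time_format),
    stringsAsFactors = FALSE
  )
}

#' Read a sensor handout registry
#'
#' The handout station registers which sensor was handed to which visitor,
#' in which experimental condition, and (optionally) a household group key:
#' sensors of visitors from the same household are paired so that mutual
#' violations are never logged. A sensor active in several conditions has one
#' row per condition.
#'
#' @inheritParams read_contact_log
#' @param columns Named mapping for `sensor_id`, `visitor_id`, `condition`,
#'   `handout_time`, `return_time`, `household_group`.
#' @return A `data.frame` with those six columns; `household_group` is `NA`
#'   where empty, times are `POSIXct` (empty allowed, `NA`).
#' @export
read_handout_registry <- function(path, delim = ",",
                                  columns = c(sensor_id = "sensor_id",
                                              visitor_id = "visitor_id",
                                              condition = "condition",
                                              handout_time = "handout_time",
                                              return_time = "return_time",
                                              household_group = "household_group"),
                                  time_format = "%Y-%m-%dT%H:%M:%S") {
  need <- c("sensor_id", "visitor_id", "condition", "handout_time",
            "return_time", "household_group")
  stopifnot(all(need %in% names(columns)))
  parsed <- read_delimited(path, delim, required = unname(columns[need]))
  mat <- parsed$mat
  hh <- mat[, columns[["household_group"]]]
  hh[!nzchar(hh)] <- NA_character_
  reg <- data.frame(
    sensor_id = mat[, columns[["sensor_id"]]],
    visitor_id = mat[, columns[["visitor_id"]]],
    condition = mat[, columns[["condition"]]],
    handout_time = parse_time_field(mat[, columns[["handout_time"]]],
                                    parsed$lines, "handout_time",
                                    time_format, allow_empty = TRUE),
    return_time = parse_time_field(mat[, columns[["return_time"]]],
                                   parsed$lines, "return_time",
                                   time_format, allow_empty = TRUE),
    household_group = hh,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(reg[, c("sensor_id", "condition")])
  if (any(dup)) {
    stop("duplicate sensor_id within a condition: ",
         reg$sensor_id[dup][1], " (condition ", reg$condition[dup][1], ")",
         call. = FALSE)
  }
  reg
}

#' Read the experimental condition windows
#'
#' One row per experimental condition: label, start/end time, the walking
#' direction intervention (`bidirectional`, `unidirectional`, `none`) and the
#' supplementary intervention (`face_mask`, `buzzer`, `none`). Windows on the
#' same day must not overlap.
#'
#' @inheritParams read_contact_log
#' @return A `data.frame` with columns `label`, `start`, `end` (`POSIXct`),
#'   `walking_direction`, `supplement`.
#' @export
read_condition_windows <- function(path, delim = ",",
                                   time_format = "%Y-%m-%dT%H:%M:%S") {
  need <- c("label", "start", "end", "walking_direction", "supplement")
  parsed <- read_delimited(path, delim, required = need)
  mat <- parsed$mat
  w <- data.frame(
    label = mat[, "label"],
    start = parse_time_field(mat[, "start"], parsed$lines, "start", time_format),
    end = parse_time_field(mat[, "end"], parsed$lines, "end", time_format),
    walking_direction = mat[, "walking_direction"],
    supplement = mat[, "supplement"],
    stringsAsFactors = FALSE
  )
  validate_windows(w)
  w
}

validate_windows <- function(w) {
  if (any(duplicated(w$label))) stop("duplicate condition labels", call. = FALSE)
  if (any(w$end <= w$start)) {
    stop("condition window with end <= start: ",
         w$label[which(w$end <= w$start)[1]], call. = FALSE)
  }
  bad_dir <- !w$walking_direction %in% c("bidirectional", "unidirectional", "none")
  if (any(bad_dir)) {
    stop("invalid walking_direction: ", w$walking_direction[bad_dir][1],
         call. = FALSE)
  }
  bad_sup <- !w$supplement %in% c("face_mask", "buzzer", "none")
  if (any(bad_sup)) stop("invalid supplement: ", w$supplement[bad_sup][1],
                         call. = FALSE)
  if (nrow(w) > 1) {
    for (i in seq_len(nrow(w) - 1)) {
      for (j in seq(i + 1, nrow(w))) {
        if (w$start[i] < w$end[j] && w$start[j] < w$end[i]) {
          stop("overlapping condition windows: ", w$label[i], " and ",
               w$label[j], call. = FALSE)
        }
      }
    }
  }
  invisible(w)
}

#' Construct a single condition window
#'
#' @param label Condition label (e.g. `"1"`).
#' @param start,end Window bounds, `POSIXct` or ISO-8601 strings (UTC).
#'   Records are assigned to the half-open interval `[start, end)`.
#' @param walking_direction One of `"bidirectional"`, `"unidirectional"`,
#'   `"none"`.
#' @param supplement One of `"face_mask"`, `"buzzer"`, `"none"`.
#' @return A `condition_window` object.
#' @export
condition_window <- function(label, start, end,
                             walking_direction = "none", supplement = "none") {
  to_time <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if (is.na(t)) t <- as.POSIXct(x, tz = "UTC")
    if (is.na(t)) stop("cannot parse time: ", x, call. = FALSE)
    t
  }
  w <- list(label = as.character(label), start = to_time(start),
            end = to_time(end), walking_direction = walking_direction,
            supplement = supplement)
  if (w$end <= w$start) stop("window end must be after start", call. = FALSE)
  structure(w, class = "condition_window")
}

as_condition_window <- function(x) {
  if (inherits(x, "condition_window")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("expected a single window row", call. = FALSE)
    x <- as.list(x)
  }
  condition_window(x$label, x$start, x$end,
                   walking_direction = x$walking_direction %||% "none",
                   supplement = x$supplement %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the window row for a condition label
#'
#' @param windows Window table from [read_condition_windows()].
#' @param label Condition label.
#' @return A `condition_window`.
#' @export
window_for <- function(windows, label) {
  i <- match(as.character(label), windows$label)
  if (is.na(i)) stop("no condition window labelled '", label, "'",
                     call. = FALSE)
  as_condition_window(windows[i, , drop = FALSE])
}

# -- cleaning steps ---------------------------------------------------------

#' Keep the records logged inside one condition window
#'
#' Records are kept iff `start <= logged_at < end` (half-open, so a record at
#' the exact boundary between back-to-back conditions belongs to the later
#' one only).
#'
#' @param records Contact records from [read_contact_log()].
#' @param window A `condition_window` (or one-row window table).
#' @return The subset of `records`, in the original order.
#' @export
window_filter <- function(records, window) {
  window <- as_condition_window(window)
  records[records$logged_at >= window$start &
            records$logged_at < window$end, , drop = FALSE]
}

#' Link sensors to visitors and drop unusable records
#'
#' Applies the quality-control rules for one condition: a record is kept only
#' if both sensors were handed out in this condition (linkable to a visitor);
#' self-records and records between two sensors sharing a household group are
#' dropped. Retained records gain `reporting_visitor` / `opposing_visitor`
#' columns. Unknown sensors are a drop *reason*, not an error — they occur in
#' practice when a sensor auto-activates off the charger without being handed
#' out.
#'
#' @param records Window-filtered contact records.
#' @param registry Handout registry ([read_handout_registry()]).
#' @param window The condition window (its `label` selects registry rows).
#' @return A list of class `sds_clean` with elements `records` (the retained,
#'   visitor-linked records) and `report` (named removal counts per reason:
#'   `unregistered_sensor`, `self_contact`, `household_pair`).
#' @export
link_and_clean <- function(records, registry, window) {
  if (is.null(registry) || !is.data.frame(registry) || nrow(registry) == 0) {
    stop("handout registry is missing or empty", call. = FALSE)
  }
  window <- as_condition_window(window)
  reg <- registry[registry$condition == window$label, , drop = FALSE]

  visitor_of <- setNames(reg$visitor_id, reg$sensor_id)
  house_of <- setNames(reg$household_group, reg$sensor_id)

  rv <- unname(visitor_of[records$reporting_id])
  ov <- unname(visitor_of[records$opposing_id])
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  reason[is.na(rv) | is.na(ov)] <- "unregistered_sensor"

  self <- is.na(reason) &
    (records$reporting_id == records$opposing_id | rv == ov)
  reason[self] <- "self_contact"

  hr <- unname(house_of[records$reporting_id])
  ho <- unname(house_of[records$opposing_id])
  hh <- is.na(reason) & !is.na(hr) & !is.na(ho) & hr == ho
  reason[hh] <- "household_pair"

  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$reporting_visitor <- rv[keep]
  out$opposing_visitor <- ov[keep]
  rownames(out) <- NULL

  report <- list(
    condition = window$label,
    n_input = n,
    n_retained = sum(keep),
    removed = list(
      unregistered_sensor = sum(reason == "unregistered_sensor", na.rm = TRUE),
      self_contact = sum(reason == "self_contact", na.rm = TRUE),
      household_pair = sum(reason == "household_pair", na.rm = TRUE)
    )
  )
  structure(list(records = out, report = report), class = "sds_clean")
}

#' @export
print.sds_clean <- function(x, ...) {
  r <- x$report
  cat(sprintf("Cleaned contact records, condition %s: %d of %d retained\n",
              r$condition, r$n_retained, r$n_input))
  for (nm in names(r$removed)) {
    cat(sprintf("  removed (%s): %d\n", nm, r$removed[[nm]]))
  }
  invisible(x)
}

#' Collapse directed records into unordered visitor pairs
#'
#' Every contact is written to the database twice (once per reporting
#' sensor); this groups records by unordered visitor pair and sums the
#' violation counts of the contributing records. Pairs are canonically
#' ordered (`visitor_a < visitor_b`) and each pair appears once.
#'
#' @param records Cleaned records carrying `reporting_visitor` /
#'   `opposing_visitor` (from [link_and_clean()]); falls back to the raw ID
#'   columns when the visitor columns are absent.
#' @return A `data.frame` with columns `visitor_a`, `visitor_b`,
#'   `total_events` (sum of violation counts) and `n_records`, sorted by
#'   pair.
#' @export
symmetrize <- function(records) {
  va <- records$reporting_visitor %||% records$reporting_id
  vb <- records$opposing_visitor %||% records$opposing_id
  if (length(va) == 0) {
    return(data.frame(visitor_a = character(0), visitor_b = character(0),
                      total_events = integer(0), n_records = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (any(va == vb)) {
    stop("self contact present; apply link_and_clean() first", call. = FALSE)
  }
  a <- ifelse(va < vb, va, vb)
  b <- ifelse(va < vb, vb, va)
  key <- paste(a, b, sep = "\r")
  total <- tapply(records$violation_count, key, sum)
  nrec <- tapply(rep(1L, length(key)), key, sum)
  ord <- sort(names(total))
  parts <- strsplit(ord, "\r", fixed = TRUE)
  data.frame(
    visitor_a = vapply(parts, `[`, "", 1L),
    visitor_b = vapply(parts, `[`, "", 2L),
    total_events = as.integer(total[ord]),
    n_records = as.integer(nrec[ord]),
    stringsAsFactors = FALSE
  )
}

#' Roster of all visitors active in a condition, including isolates
#'
#' The sensor output only contains visitors who made at least one contact;
#' visitors with zero contacts must be added back from the handout registry
#' so they enter the network (and the degree distribution) as isolates.
#'
#' @param registry Handout registry.
#' @param window Condition window (its label selects registry rows).
#' @return Sorted unique character vector of visitor IDs. A condition with no
#'   active visitors is malformed and raises an error.
#' @export
roster_with_isolates <- function(registry, window) {
  window <- as_condition_window(window)
  v <- registry$visitor_id[registry$condition == window$label]
  v <- sort(unique(v))
  if (!length(v)) {
    stop("no visitors active in condition '", window$label, "'", call. = FALSE)
  }
  v
}
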
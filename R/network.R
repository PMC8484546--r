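# Per-condition undirected binary contact networks and degree descriptives.
# An edge means the two visitors came within 1.5 m at least once during the
# condition; contacts are collapsed over time (only unique contacts matter
# for within-window transmission), so the epidemiologically relevant summary
# is the degree distribution over the full roster, isolates included.

#' Build an undirected binary contact network
#'
#' @param pairs Unordered pair contacts from [symmetrize()] (`visitor_a`,
#'   `visitor_b`, optionally `total_events`), or `NULL`/empty for an edgeless
#'   network. Any pair with at least one event becomes exactly one edge.
#' @param roster Complete visitor roster for the condition, usually from
#'   [roster_with_isolates()]. Every pair endpoint must be on the roster.
#' @param k Network/condition index (stored, used to key actors when two
#'   networks are combined into a dyad design).
#' @return A `contact_network`: list with `k`, `actors` (sorted roster) and
#'   `edges` (`data.frame` of canonical `from < to` pairs).
#' @examples
#' net <- build_network(data.frame(visitor_a = "A", visitor_b = "B"),
#'                      roster = c("A", "B", "C"), k = 1)
#' degrees(net)
#' @export
build_network <- function(pairs, roster, k = 1L) {
  roster <- as.character(roster)
  if (!length(roster)) stop("empty roster", call. = FALSE)
  if (anyDuplicated(roster)) stop("duplicated visitor in roster", call. = FALSE)
  roster <- sort(roster)

  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs)
    a <- as.character(pairs$visitor_a)
    b <- as.character(pairs$visitor_b)
    if (any(a == b)) stop("self-loop in pair contacts", call. = FALSE)
    outside <- setdiff(c(a, b), roster)
    if (length(outside)) {
      stop("pair endpoint(s) not in roster: ",
           paste(utils::head(outside, 3), collapse = ", "), call. = FALSE)
    }
    if (!is.null(pairs$total_events) && any(pairs$total_events < 1)) {
      stop("pair with total_events < 1", call. = FALSE)
    }
    from <- ifelse(a < b, a, b)
    to <- ifelse(a < b, b, a)
    key <- paste(from, to, sep = "\r")
    keep <- !duplicated(key)
    ord <- order(from[keep], to[keep])
    edges <- data.frame(from = from[keep][ord], to = to[keep][ord],
                        stringsAsFactors = FALSE)
  }
  structure(list(k = k, actors = roster, edges = edges),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  n <- length(x$actors)
  m <- nrow(x$edges)
  dens <- if (n > 1) m / (n * (n - 1) / 2) else NA_real_
  cat(sprintf("Contact network (condition %s): %d actors, %d edges, density %.4f\n",
              as.character(x$k), n, m, dens))
  invisible(x)
}

#' Degree of every actor on the roster
#'
#' @param network A `contact_network`.
#' @return Named integer vector (zero for isolates), in roster order.
#' @export
degrees <- function(network) {
  stopifnot(inherits(network, "contact_network"))
  idx <- c(match(network$edges$from, network$actors),
           match(network$edges$to, network$actors))
  d <- tabulate(idx, nbins = length(network$actors))
  setNames(as.integer(d), network$actors)
}

#' Degree-distribution descriptives for one network
#'
#' Summarises the degree sequence over the *full* roster (visitors with zero
#' logged contacts count as degree 0): range, mean, SD, median and quartiles.
#' The quantile convention is configurable because published integer IQR
#' bounds can come from either a rank-based or an interpolated estimator:
#' `"interpolated"` is `stats::quantile()` type 7, `"nearest_rank"` type 1.
#'
#' @param network A `contact_network`.
#' @param method Quantile estimator for median/quartiles.
#' @return One-row `data.frame`: `n`, `min`, `max`, `mean`, `sd`, `median`,
#'   `q1`, `q3`.
#' @export
degree_summary <- function(network,
                           method = c("interpolated", "nearest_rank")) {
  method <- match.arg(method)
  type <- if (method == "interpolated") 7L else 1L
  d <- as.numeric(degrees(network))
  q <- unname(quantile(d, probs = c(0.25, 0.5, 0.75), type = type))
  data.frame(
    n = length(d),
    min = as.integer(min(d)),
    max = as.integer(max(d)),
    mean = mean(d),
    sd = if (length(d) > 1) sd(d) else NA_real_,
    median = q[2],
    q1 = q[1],
    q3 = q[3]
  )
}

#' Export a network as an edge list plus isolate roster
#'
#' Writes two CSV files from which the binary network can be rebuilt
#' losslessly: the canonical two-column edge list, and the roster of actors
#' with zero contacts (the edge list alone would silently drop them).
#'
#' @param network A `contact_network`.
#' @param edges_path,isolates_path Output file paths.
#' @return Invisibly, the two paths.
#' @seealso [import_edge_list()]
#' @export
export_edge_list <- function(network, edges_path, isolates_path) {
  stopifnot(inherits(network, "contact_network"))
  iso <- names(which(degrees(network) == 0L))
  write.csv(network$edges, edges_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(visitor_id = iso, stringsAsFactors = FALSE),
            isolates_path, row.names = FALSE, quote = FALSE)
  invisible(c(edges = edges_path, isolates = isolates_path))
}

#' Rebuild a network from an exported edge list and isolate roster
#'
#' @param edges_path,isolates_path Files written by [export_edge_list()].
#' @param k Network/condition index to assign.
#' @return A `contact_network` equal to the exported one.
#' @export
import_edge_list <- function(edges_path, isolates_path, k = 1L) {
  e <- read.csv(edges_path, colClasses = "character")
  iso <- read.csv(isolates_path, colClasses = "character")
  roster <- sort(unique(c(e$from, e$to, iso$visitor_id)))
  pairs <- if (nrow(e)) {
    data.frame(visitor_a = e$from, visitor_b = e$to, stringsAsFactors = FALSE)
  } else NULL
  build_network(pairs, roster, k = k)
}
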
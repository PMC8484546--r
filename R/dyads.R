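# Flattening one or two contact networks into the dyad table the b2 model
# is fitted on: all unordered within-network pairs i < j with outcome
# y = 1 iff the pair is an edge, plus the actor-level condition dummy.

#' Build the dyad design for a b2 fit
#'
#' Enumerates every unordered within-network dyad of one network, or of a
#' reference and a comparison network jointly (between-network dyads do not
#' exist: a visitor pair can only meet inside a condition). Each actor gets
#' its own random-effect slot keyed by `(k, visitor)` — a visitor present in
#' both conditions is deliberately treated as two distinct actors, matching
#' per-condition network fits. The condition covariate is an actor-level
#' dummy, `x = 0` in the reference network and `1` in the comparison network,
#' entering the dyad as either
#' \describe{
#'   \item{`actor_additive`}{`Xa = x_i + x_j` (0 or 2), so `exp(beta_a)` is a
#'     per-actor odds ratio;}
#'   \item{`dyad_indicator`}{`Xa = 1` iff the dyad lies in the comparison
#'     network, so `exp(beta_a)` is the per-dyad odds ratio (the square of
#'     the former).}
#' }
#'
#' @param reference A `contact_network` (covariate 0).
#' @param comparison Optional second `contact_network` (covariate 1). Must
#'   have a different network index `k` than `reference`: equal indices would
#'   collide in the random-effect slots.
#' @param coding Covariate coding, see above.
#' @return A `dyad_design`: list with `dyads` (`data.frame` `k`, `i`, `j`,
#'   `slot_i`, `slot_j`, `y`), `X` (dyad covariate matrix, 0 columns for a
#'   single network), `actors` (`data.frame` `k`, `actor`, `slot`, `x`) and
#'   `coding`.
#' @export
dyad_design <- function(reference, comparison = NULL,
                        coding = c("actor_additive", "dyad_indicator")) {
  coding <- match.arg(coding)
  stopifnot(inherits(reference, "contact_network"))
  nets <- list(reference)
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "contact_network"))
    if (identical(as.character(reference$k), as.character(comparison$k))) {
      stop("reference and comparison networks share index k = ",
           reference$k, "; actor slots would overlap", call. = FALSE)
    }
    nets <- list(reference, comparison)
  }

  actors <- do.call(rbind, lapply(seq_along(nets), function(g) {
    data.frame(k = as.character(nets[[g]]$k), actor = nets[[g]]$actors,
               x = if (g == 2L) 1 else 0, stringsAsFactors = FALSE)
  }))
  actors$slot <- seq_len(nrow(actors))

  dyads <- do.call(rbind, lapply(seq_along(nets), function(g) {
    net <- nets[[g]]
    n <- length(net$actors)
    if (n < 2) stop("network ", net$k, " has fewer than 2 actors",
                    call. = FALSE)
    pr <- combn(n, 2L)
    offset <- if (g == 2L) length(nets[[1]]$actors) else 0L
    ekey <- paste(net$edges$from, net$edges$to, sep = "\r")
    dkey <- paste(net$actors[pr[1, ]], net$actors[pr[2, ]], sep = "\r")
    data.frame(
      k = as.character(net$k),
      i = net$actors[pr[1, ]],
      j = net$actors[pr[2, ]],
      slot_i = pr[1, ] + offset,
      slot_j = pr[2, ] + offset,
      y = as.integer(dkey %in% ekey),
      group = g,
      stringsAsFactors = FALSE
    )
  }))
  rownames(dyads) <- NULL

  if (length(nets) == 2L) {
    xa <- if (coding == "actor_additive") {
      actors$x[dyads$slot_i] + actors$x[dyads$slot_j]
    } else {
      as.numeric(dyads$group == 2L)
    }
    X <- matrix(xa, ncol = 1, dimnames = list(NULL, "condition"))
  } else {
    X <- matrix(numeric(0), nrow = nrow(dyads), ncol = 0)
  }
  dyads$group <- NULL

  structure(list(dyads = dyads, X = X, actors = actors, coding = coding),
            class = "dyad_design")
}

#' @export
print.dyad_design <- function(x, ...) {
  cat(sprintf("Dyad design: %d dyads, %d actors, %d covariate(s), coding '%s'\n",
              nrow(x$dyads), nrow(x$actors), ncol(x$X), x$coding))
  for (kk in unique(x$dyads$k)) {
    nd <- sum(x$dyads$k == kk)
    cat(sprintf("  network %s: %d actors, %d dyads, %d ties\n", kk,
                sum(x$actors$k == kk), nd, sum(x$dyads$y[x$dyads$k == kk])))
  }
  invisible(x)
}

#' Export the dyad table for audit
#'
#' Writes the flattened dyad table (`k`, `i`, `j`, `y`, and the covariate
#' columns) as CSV, so a fitted comparison can be checked outside the
#' package.
#'
#' @param design A `dyad_design`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_dyad_table <- function(design, path) {
  stopifnot(inherits(design, "dyad_design"))
  out <- design$dyads[, c("k", "i", "j", "y")]
  if (ncol(design$X)) {
    xa <- as.data.frame(design$X)
    names(xa) <- paste0("Xa_", colnames(design$X))
    out <- cbind(out, xa)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
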
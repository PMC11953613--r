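#' Construct a PSI matrix container
#'
#' Bundles the per-event, per-sample percent-spliced-in (PSI) estimates with
#' their coverage tiers, intron-retention balance-test p-values and the raw
#' inclusion/exclusion read totals they were derived from, together with the
#' event annotation table. All five matrices share dimensions and dimnames
#' (event IDs x sample IDs).
#'
#' @param psi numeric matrix of PSI values in `[0, 100]`, `NA` where an
#'   event/sample pair has no informative reads (or was masked by a filter).
#' @param tier character matrix of coverage tiers (`N`, `VLOW`, `LOW`, `OK`,
#'   `SOK`).
#' @param balance_p numeric matrix of intron-retention read-balance p-values;
#'   `NA` for non-IR events and for IR cells without boundary reads.
#' @param inc_reads,exc_reads integer matrices of raw inclusion-junction and
#'   exclusion-junction read totals. For IR and exon-skipping events the
#'   inclusion total counts both boundary junctions, so the inclusion
#'   *evidence* entering the PSI formula is `inc_reads / 2`.
#' @param events data frame with columns `event_id`, `gene_id`, `event_type`,
#'   `coord`, `n_variants`, one row per matrix row, in row order.
#'
#' @return An object of class `psi_matrix`.
#' @export
psi_matrix <- function(psi, tier, balance_p, inc_reads, exc_reads, events) {
  dm <- dim(psi)
  for (m in list(tier, balance_p, inc_reads, exc_reads)) {
    if (!identical(dim(m), dm)) stop("psi_matrix components differ in shape")
  }
  if (nrow(events) != nrow(psi)) {
    stop("events table must have one row per psi row")
  }
  if (anyDuplicated(events$event_id)) stop("duplicate event_id")
  bad_type <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "))
  }
  ok <- is.na(psi) | (psi >= 0 & psi <= 100)
  if (!all(ok)) stop("PSI values must lie in [0, 100]")
  rownames(psi) <- rownames(tier) <- rownames(balance_p) <-
    rownames(inc_reads) <- rownames(exc_reads) <- events$event_id
  structure(
    list(psi = psi, tier = tier, balance_p = balance_p,
         inc_reads = inc_reads, exc_reads = exc_reads, events = events),
    class = "psi_matrix")
}

#' @export
dim.psi_matrix <- function(x) dim(x$psi)

#' @export
print.psi_matrix <- function(x, ...) {
  cat("psi_matrix:", nrow(x$psi), "events x", ncol(x$psi), "samples\n")
  tb <- table(factor(x$events$event_type, levels = EVENT_TYPES))
  cat("  event types:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat("  missing PSI:", sum(is.na(x$psi)), "of", length(x$psi), "cells\n")
  invisible(x)
}

# Logical matrix: which cells count as covered for calling purposes.
psi_covered <- function(x, min_tier = "LOW") {
  !is.na(x$psi) & tier_rank(x$tier) >= tier_rank(min_tier)
}
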
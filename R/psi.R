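# PSI quantification from junction read counts.
#
# PSI for two-outcome events (intron retention, exon skipping) is estimated
# as 100 * I / (I + E) where I is the *mean* read count over the two
# inclusion-supporting junctions and E the exclusion-junction count.
# Averaging the two boundary junctions keeps the inclusion evidence on the
# same per-read scale as the single exclusion junction. For alternative
# donor/acceptor events PSI of a variant is its share of all variant reads.

#' PSI for an exon-skipping event
#'
#' @param c1a,ac2 reads spanning the upstream and downstream
#'   inclusion junctions (exon-inclusion evidence).
#' @param c1c2 reads spanning the skipping junction (exclusion evidence).
#' @return PSI percent in `[0, 100]`, or `NA` when no informative reads are
#'   present. Vectorised; negative inputs are a hard error.
#' @export
compute_psi_ex <- function(c1a, ac2, c1c2) {
  if (any(c(c1a, ac2, c1c2) < 0, na.rm = TRUE)) {
    stop("junction read counts must be non-negative")
  }
  inc <- (c1a + ac2) / 2
  denom <- inc + c1c2
  ifelse(denom == 0, NA_real_, 100 * inc / denom)
}

#' PSI for an intron-retention event
#'
#' @param ei,ie reads spanning the upstream exon-intron and downstream
#'   intron-exon boundaries (retention evidence).
#' @param ee reads spanning the spliced exon-exon junction (removal
#'   evidence).
#' @return PSI percent (retention level), or `NA` with no informative reads.
#' @export
compute_psi_ir <- function(ei, ie, ee) {
  if (any(c(ei, ie, ee) < 0, na.rm = TRUE)) {
    stop("junction read counts must be non-negative")
  }
  ret <- (ei + ie) / 2
  denom <- ret + ee
  ifelse(denom == 0, NA_real_, 100 * ret / denom)
}

#' PSI for an alternative donor/acceptor variant
#'
#' @param variant_counts named numeric vector of reads per variant junction
#'   (`V1`, `V2`, ...).
#' @param focal name of the variant whose PSI is requested.
#' @return `100 * reads(focal) / sum(reads)`, or `NA` when the event has no
#'   reads. PSI values across all variants of one event sum to 100.
#' @export
compute_psi_alt <- function(variant_counts, focal) {
  if (!focal %in% names(variant_counts)) {
    stop("focal variant '", focal, "' is not declared for this event")
  }
  if (any(variant_counts < 0)) stop("junction read counts must be non-negative")
  tot <- sum(variant_counts)
  if (tot == 0) return(NA_real_)
  100 * variant_counts[[focal]] / tot
}

#' Coverage tier from informative read totals
#'
#' Step function assigning the ordinal tiers `N < VLOW < LOW < OK < SOK`;
#' a read total exactly at a cutoff earns that cutoff's tier.
#'
#' @param total_reads non-negative read totals (vectorised). Fractional
#'   totals arising from inclusion-junction averaging are floored first.
#' @param tier_cutoffs strictly increasing cutoffs for `VLOW`, `LOW`, `OK`,
#'   `SOK`.
#' @return Character vector of tiers.
#' @export
coverage_tier <- function(total_reads,
                          tier_cutoffs = c(VLOW = 10, LOW = 15, OK = 20,
                                           SOK = 100)) {
  if (length(tier_cutoffs) != 4 || any(diff(tier_cutoffs) <= 0)) {
    stop("tier_cutoffs must be 4 strictly increasing values")
  }
  if (any(total_reads < 0)) stop("total_reads must be non-negative")
  total <- floor(as.vector(total_reads))
  idx <- 1L + findInterval(total, tier_cutoffs)
  TIER_LEVELS[idx]
}

#' Intron-retention read-balance test
#'
#' Retained introns supported by genuine transcripts should accumulate reads
#' at both exon-intron boundaries in comparable numbers; strong imbalance is
#' the signature of a mapping artifact or an overlapping feature. The test
#' is an exact two-sided binomial test of the upstream boundary count against
#' an even split of the two boundary counts.
#'
#' @param n_upstream,n_downstream reads at the upstream (EI) and downstream
#'   (IE) boundary junctions (vectorised in parallel).
#' @param balance_alpha significance level; a cell *passes* when
#'   `p >= balance_alpha`.
#' @return Data frame with columns `n_upstream`, `n_downstream`, `p_value`,
#'   `passed`. Both counts zero gives `p = NA` and `passed = FALSE` (no
#'   evidence of a real junction).
#' @export
ir_balance_test <- function(n_upstream, n_downstream, balance_alpha = 0.05) {
  stopifnot_nonneg_int(c(n_upstream, n_downstream), "boundary read counts")
  p <- balance_p_values(n_upstream, n_downstream)
  data.frame(n_upstream = n_upstream, n_downstream = n_downstream,
             p_value = p, passed = !is.na(p) & p >= balance_alpha)
}

# Vectorised exact two-sided binomial p at p0 = 0.5, with caching over the
# distinct (up, down) pairs so large matrices stay cheap.
balance_p_values <- function(up, down) {
  key <- paste(up, down)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    n <- up[i] + down[i]
    if (n == 0) return(NA_real_)
    stats::binom.test(up[i], n, p = 0.5)$p.value
  }, 1)
  pu[match(key, key[uk])]
}

#' Quantify PSI from junction counts
#'
#' Dispatches each event to the PSI formula for its class, assigns coverage
#' tiers from the informative read totals and runs the intron-retention
#' balance test. Event/sample pairs with no junction rows are missing with
#' tier `N`. PSI values are rounded to two decimals and balance p-values to
#' six significant digits (the precision of the on-disk dialect).
#'
#' @param junctions junction-count data frame (`event_id`, `sample_id`,
#'   `junction_role`, `reads`); roles illegal for an event's class are a hard
#'   error naming the offending row.
#' @param events event annotation data frame (`event_id`, `gene_id`,
#'   `event_type`, `coord`, `n_variants`). For alternative donor/acceptor
#'   events `V1` is the focal variant whose PSI is reported.
#' @param samples optional sample sheet fixing the sample set and column
#'   order; defaults to the sorted samples present in `junctions`.
#' @param tier_cutoffs see [coverage_tier()].
#' @param balance_alpha significance level recorded for the balance test
#'   (the test p-value itself is stored; filtering happens in
#'   [filter_events()]).
#' @return A [psi_matrix()].
#' @export
quantify_psi <- function(junctions, events, samples = NULL,
                         tier_cutoffs = c(VLOW = 10, LOW = 15, OK = 20,
                                          SOK = 100),
                         balance_alpha = 0.05) {
  stopifnot_nonneg_int(junctions$reads, "junction read counts")
  if (anyDuplicated(events$event_id)) stop("duplicate event_id")
  ev_idx <- match(junctions$event_id, events$event_id)
  if (anyNA(ev_idx)) {
    stop("junction row ", which(is.na(ev_idx))[1],
         " references undeclared event '",
         junctions$event_id[which(is.na(ev_idx))[1]], "'")
  }
  sample_ids <- if (is.null(samples)) sort(unique(junctions$sample_id))
                else samples$sample_id
  s_idx <- match(junctions$sample_id, sample_ids)
  if (anyNA(s_idx)) {
    stop("junction row ", which(is.na(s_idx))[1],
         " references undeclared sample '",
         junctions$sample_id[which(is.na(s_idx))[1]], "'")
  }

  # validate roles against each event's class
  etype <- events$event_type[ev_idx]
  nvar <- events$n_variants[ev_idx]
  role <- junctions$junction_role
  legal <- (etype == "EX" & role %in% c("C1A", "AC2", "C1C2")) |
           (etype == "IR" & role %in% c("EI", "IE", "EE"))
  is_alt <- etype %in% c("ALTA", "ALTD")
  vnum <- suppressWarnings(as.integer(sub("^V", "", role)))
  legal <- legal | (is_alt & grepl("^V[0-9]+$", role) & !is.na(vnum) &
                    vnum >= 1 & vnum <= nvar)
  if (!all(legal)) {
    i <- which(!legal)[1]
    stop("junction row ", i, ": role '", role[i], "' is illegal for ",
         etype[i], " event '", junctions$event_id[i], "'")
  }

  n_ev <- nrow(events)
  n_s <- length(sample_ids)
  dn <- list(events$event_id, sample_ids)
  role_mat <- function(keep, values = junctions$reads) {
    m <- matrix(0, n_ev, n_s, dimnames = dn)
    if (any(keep)) {
      idx <- cbind(ev_idx[keep], s_idx[keep])
      agg <- rowsum(values[keep], group = paste(idx[, 1], idx[, 2]))
      first <- !duplicated(paste(idx[, 1], idx[, 2]))
      m[idx[first, , drop = FALSE]] <- agg[match(
        paste(idx[first, 1], idx[first, 2]), rownames(agg))]
    }
    m
  }

  psi <- matrix(NA_real_, n_ev, n_s, dimnames = dn)
  balance_p <- matrix(NA_real_, n_ev, n_s, dimnames = dn)
  inc <- matrix(0, n_ev, n_s, dimnames = dn)
  exc <- matrix(0, n_ev, n_s, dimnames = dn)
  informative <- matrix(0, n_ev, n_s, dimnames = dn)

  ex_rows <- events$event_type == "EX"
  if (any(ex_rows)) {
    c1a <- role_mat(role == "C1A")[ex_rows, , drop = FALSE]
    ac2 <- role_mat(role == "AC2")[ex_rows, , drop = FALSE]
    c1c2 <- role_mat(role == "C1C2")[ex_rows, , drop = FALSE]
    psi[ex_rows, ] <- compute_psi_ex(c1a, ac2, c1c2)
    inc[ex_rows, ] <- c1a + ac2
    exc[ex_rows, ] <- c1c2
    informative[ex_rows, ] <- (c1a + ac2) / 2 + c1c2
  }
  ir_rows <- events$event_type == "IR"
  if (any(ir_rows)) {
    ei <- role_mat(role == "EI")[ir_rows, , drop = FALSE]
    ie <- role_mat(role == "IE")[ir_rows, , drop = FALSE]
    ee <- role_mat(role == "EE")[ir_rows, , drop = FALSE]
    psi[ir_rows, ] <- compute_psi_ir(ei, ie, ee)
    inc[ir_rows, ] <- ei + ie
    exc[ir_rows, ] <- ee
    informative[ir_rows, ] <- (ei + ie) / 2 + ee
    bp <- matrix(balance_p_values(as.vector(ei), as.vector(ie)),
                 nrow = sum(ir_rows))
    balance_p[ir_rows, ] <- signif(bp, 6)
  }
  alt_rows <- events$event_type %in% c("ALTA", "ALTD")
  if (any(alt_rows)) {
    focal <- role_mat(role == "V1")[alt_rows, , drop = FALSE]
    total <- role_mat(is_alt)[alt_rows, , drop = FALSE]
    psi[alt_rows, ] <- ifelse(total == 0, NA_real_, 100 * focal / total)
    inc[alt_rows, ] <- focal
    exc[alt_rows, ] <- total - focal
    informative[alt_rows, ] <- total
  }

  tier <- matrix(coverage_tier(as.vector(informative), tier_cutoffs),
                 n_ev, n_s, dimnames = dn)
  storage.mode(inc) <- "integer"
  storage.mode(exc) <- "integer"
  psi_matrix(round(psi, 2), tier, balance_p, inc, exc, events)
}

#' Filter events on coverage and intron-retention balance
#'
#' Applies the two quality gates that define the analysable event set: when
#' `require_balance` is set, intron-retention cells failing the read-balance
#' test (`p < balance_alpha`, or no boundary reads at all while retention is
#' reported) are masked to missing; then only events with at least
#' `min_samples` covered cells (non-missing PSI at tier `>= min_tier`) are
#' kept. The sample set is never changed.
#'
#' @param x a [psi_matrix()].
#' @param min_tier minimum acceptable coverage tier (default `LOW`).
#' @param min_samples minimum number of covered samples per event (default
#'   10, counted after balance masking).
#' @param require_balance mask balance-failing IR cells before counting?
#' @param balance_alpha significance level of the balance gate.
#' @return A `psi_matrix` restricted to passing events.
#' @export
filter_events <- function(x, min_tier = "LOW", min_samples = 10,
                          require_balance = TRUE, balance_alpha = 0.05) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  psi <- x$psi
  if (require_balance) {
    ir <- x$events$event_type == "IR"
    fail <- ir & !is.na(psi) & (is.na(x$balance_p) |
                                x$balance_p < balance_alpha)
    psi[fail] <- NA_real_
  }
  covered <- !is.na(psi) & tier_rank(x$tier) >= tier_rank(min_tier)
  keep <- rowSums(covered) >= min_samples
  psi_matrix(psi[keep, , drop = FALSE],
             x$tier[keep, , drop = FALSE],
             x$balance_p[keep, , drop = FALSE],
             x$inc_reads[keep, , drop = FALSE],
             x$exc_reads[keep, , drop = FALSE],
             x$events[keep, , drop = FALSE])
}
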
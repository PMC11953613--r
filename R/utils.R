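# Internal helpers shared across modules.

# Ordinal coverage tiers, worst to best.
TIER_LEVELS <- c("N", "VLOW", "LOW", "OK", "SOK")

ORGAN_LEVELS <- c("root", "aerial")

EVENT_TYPES <- c("IR", "EX", "ALTA", "ALTD")

IMPACT_LEVELS <- c("ORF_disruption", "alternative_isoform", "UTR_overlap",
                   "unknown")

tier_rank <- function(tier) {
  r <- match(tier, TIER_LEVELS)
  if (anyNA(r) && !anyNA(tier)) {
    stop("unknown coverage tier: ",
         paste(unique(tier[is.na(r) & !is.na(tier)]), collapse = ", "))
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_nonneg_int <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop(what, " must be non-negative integers")
  }
  invisible(x)
}

# Lower median: for an even number of values take the smaller of the two
# central order statistics, so the result is always an observed ratio.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

check_sample_sheet <- function(samples) {
  need <- c("sample_id", "cell_type", "organ", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  bad <- which(!samples$organ %in% ORGAN_LEVELS)
  if (length(bad) > 0) {
    stop("unknown organ '", samples$organ[bad[1]], "' in sample sheet row ",
         bad[1], " (must be one of: ", paste(ORGAN_LEVELS, collapse = ", "),
         ")")
  }
  ct_organ <- unique(samples[, c("cell_type", "organ")])
  if (anyDuplicated(ct_organ$cell_type)) {
    stop("cell type mapped to more than one organ: ",
         paste(unique(ct_organ$cell_type[duplicated(ct_organ$cell_type)]),
               collapse = ", "))
  }
  if (anyDuplicated(samples[, c("cell_type", "replicate")])) {
    stop("duplicate (cell_type, replicate) pair in sample sheet")
  }
  invisible(samples)
}
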
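# Descriptive summaries over the call sets: event-class composition,
# gene-set subsetting, predicted protein impact and the splicing-versus-
# expression comparison.

#' Event-class composition of a call set
#'
#' @param calls splicing-call data frame ([call_dse()]); if it lacks an
#'   `event_type` column the map is taken from `events`.
#' @param events optional event annotation table.
#' @return Data frame with one row per stratum (`all`, `up`, `down`) and
#'   event class: counts and within-stratum fractions. Fractions sum to 1
#'   per non-empty stratum; an empty call set is flagged with the `empty`
#'   attribute and all-zero fractions.
#' @export
event_type_proportions <- function(calls, events = NULL) {
  if (!"event_type" %in% names(calls)) {
    if (is.null(events)) stop("need event_type in calls or an events table")
    calls$event_type <- events$event_type[match(calls$event_id,
                                                events$event_id)]
  }
  if (anyNA(calls$event_type)) stop("call on an event with no declared type")
  strata <- list(all = calls,
                 up = calls[calls$direction == "up", , drop = FALSE],
                 down = calls[calls$direction == "down", , drop = FALSE])
  out <- do.call(rbind, lapply(names(strata), function(s) {
    cc <- strata[[s]]
    n <- table(factor(cc$event_type, levels = EVENT_TYPES))
    tot <- sum(n)
    data.frame(stratum = s, event_type = EVENT_TYPES,
               count = as.integer(n),
               fraction = if (tot == 0) rep(0, length(n))
                          else as.numeric(n) / tot,
               stringsAsFactors = FALSE)
  }))
  attr(out, "empty") <- nrow(calls) == 0
  out
}

#' Restrict calls to a gene set
#'
#' @param calls call data frame (splicing or expression); splicing calls
#'   without a `gene_id` column are mapped through `events`.
#' @param gene_set character vector of gene IDs (e.g. an immunity-related
#'   list).
#' @param events optional event annotation table.
#' @return The rows of `calls` whose gene belongs to the set, order and
#'   columns preserved. Idempotent.
#' @export
subset_by_gene_set <- function(calls, gene_set, events = NULL) {
  if (!"gene_id" %in% names(calls)) {
    if (is.null(events)) stop("need gene_id in calls or an events table")
    calls$gene_id <- events$gene_id[match(calls$event_id, events$event_id)]
  }
  calls[calls$gene_id %in% gene_set, , drop = FALSE]
}

#' Predicted protein impact of called events
#'
#' Classifies splicing calls by the predicted consequence of the event on
#' the protein (ORF disruption, alternative isoform, UTR overlap). Events
#' absent from the annotation count as `unknown`; fractions are computed
#' over annotated (non-unknown) calls only.
#'
#' @param calls splicing-call data frame.
#' @param impact impact annotation data frame (`event_id`, `impact`).
#' @return List with `counts` (one row per impact class, with the up/down
#'   split) and `fractions` (over annotated calls); `no_annotated` flags a
#'   call set with no annotated events.
#' @export
classify_impact <- function(calls, impact) {
  imp <- impact$impact[match(calls$event_id, impact$event_id)]
  imp[is.na(imp)] <- "unknown"
  f <- factor(imp, levels = IMPACT_LEVELS)
  counts <- data.frame(
    impact = IMPACT_LEVELS,
    n = as.integer(table(f)),
    n_up = as.integer(table(f[calls$direction == "up"])),
    n_down = as.integer(table(f[calls$direction == "down"])),
    stringsAsFactors = FALSE)
  annotated <- counts$impact != "unknown"
  tot <- sum(counts$n[annotated])
  fractions <- counts[annotated, c("impact", "n")]
  fractions$fraction <- if (tot == 0) rep(0, sum(annotated))
                        else fractions$n / tot
  list(counts = counts, fractions = fractions, no_annotated = tot == 0)
}

#' Join splicing calls with gene-level expression change
#'
#' For each splicing call, computes the gene's expression log2 fold change
#' in the same cell type (median cRPKM of the target versus the median of
#' all other same-organ samples, pseudocounted) and assigns the quadrant
#' defined by the delta-PSI and log2-FC thresholds: concordant/discordant
#' splicing-and-expression change, or `spliced_only` when the gene is not
#' differentially expressed.
#'
#' @param dse_calls splicing-call data frame ([call_dse()]).
#' @param expr an [expression_matrix()].
#' @param samples sample sheet data frame.
#' @param dpsi_cut,lfc_cut quadrant thresholds (default 25 percent and
#'   log2 FC 2).
#' @param pseudocount for the expression ratio.
#' @return One row per call: `event_id`, `gene_id`, `cell_type`, `organ`,
#'   `dpsi`, `log2_fc`, `quadrant`. A gene absent from the expression matrix
#'   gives a missing `log2_fc` and quadrant `no_expression`.
#' @export
expression_splicing_table <- function(dse_calls, expr, samples,
                                      dpsi_cut = 25, lfc_cut = 2,
                                      pseudocount = 0.01) {
  crpkm <- expr$crpkm
  lfc <- numeric(nrow(dse_calls))
  for (i in seq_len(nrow(dse_calls))) {
    g <- dse_calls$gene_id[i]
    if (!g %in% rownames(crpkm)) {
      lfc[i] <- NA_real_
      next
    }
    organ <- dse_calls$organ[i]
    target <- dse_calls$cell_type[i]
    o_samples <- intersect(colnames(crpkm),
                           samples$sample_id[samples$organ == organ])
    o_ct <- samples$cell_type[match(o_samples, samples$sample_id)]
    m_t <- stats::median(crpkm[g, o_samples[o_ct == target]])
    m_o <- stats::median(crpkm[g, o_samples[o_ct != target]])
    lfc[i] <- log2(fold_change(m_t, m_o, pseudocount))
  }
  spl <- ifelse(dse_calls$dpsi_global > dpsi_cut, "up_spliced",
                ifelse(dse_calls$dpsi_global < -dpsi_cut, "down_spliced",
                       "not_spliced"))
  expr_dir <- ifelse(is.na(lfc), "no_expression",
                     ifelse(lfc > lfc_cut, "up_expressed",
                            ifelse(lfc < -lfc_cut, "down_expressed",
                                   "unchanged")))
  quadrant <- ifelse(expr_dir == "no_expression", "no_expression",
                     ifelse(expr_dir == "unchanged", "spliced_only",
                            paste(spl, expr_dir, sep = "/")))
  data.frame(event_id = dse_calls$event_id, gene_id = dse_calls$gene_id,
             cell_type = dse_calls$cell_type, organ = dse_calls$organ,
             dpsi = dse_calls$dpsi_global, log2_fc = lfc,
             quadrant = quadrant, stringsAsFactors = FALSE)
}
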
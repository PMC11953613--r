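# Rule-based cell-type-specific calling.
#
# Splicing (DSE): within each organ, an event is specific to a target cell
# type when (i) its mean PSI differs from the pooled mean of all other
# same-organ samples by more than `global_dpsi`, (ii) its mean PSI differs
# from *every* other covered cell type's mean by more than `min_dpsi`
# (reported as the comparison of smallest magnitude), and (iii) the spread
# of per-cell-type maximum PSI values is at least `min_psi_range`.
#
# Expression (DEG): a gene is specific to a cell type when its median cRPKM
# is fold-changed by at least `deg_fc_each` against every other cell type's
# median, by at least `deg_fc_global` against the median of all other
# samples, and differs by at least `deg_abs_diff` cRPKM from every other
# cell type; only genes reaching `deg_min_median_crpkm` in some cell type
# are eligible.

#' Thresholds for cell-type-specific calling
#'
#' @param global_dpsi minimum |global delta-PSI| (percent; strict `>`).
#' @param min_dpsi minimum |delta-PSI| against every other cell type
#'   (percent; strict `>`).
#' @param min_psi_range minimum spread of per-cell-type maximum PSI
#'   (percent; `>=`).
#' @param min_replicates covered replicates a cell type needs to enter the
#'   analysis.
#' @param min_cell_types covered cell types an organ needs to be analysed.
#' @param deg_min_median_crpkm expression eligibility floor (median cRPKM in
#'   at least one cell type).
#' @param deg_fc_each fold change required against every other cell type's
#'   median (`>= x` or `<= 1/x`).
#' @param deg_fc_global fold change required against the global median of
#'   all other samples.
#' @param deg_abs_diff absolute cRPKM difference required against every
#'   other cell type's median.
#' @param pseudocount added to both sides of expression ratios so zero
#'   medians stay finite and zero-vs-zero is neutral.
#' @param min_tier minimum coverage tier for a PSI value to count.
#' @param strict_dpsi use strict `>` for the two delta-PSI rules (the
#'   default); `FALSE` switches both to `>=`.
#' @param require_sign_match additionally require the global and minimum
#'   delta-PSI to agree in sign (off by default; only magnitudes are
#'   thresholded).
#' @return A list of class `specificity_thresholds`.
#' @export
specificity_thresholds <- function(global_dpsi = 25, min_dpsi = 15,
                                   min_psi_range = 2, min_replicates = 2,
                                   min_cell_types = 4,
                                   deg_min_median_crpkm = 5,
                                   deg_fc_each = 2, deg_fc_global = 5,
                                   deg_abs_diff = 2, pseudocount = 0.01,
                                   min_tier = "LOW", strict_dpsi = TRUE,
                                   require_sign_match = FALSE) {
  th <- list(global_dpsi = global_dpsi, min_dpsi = min_dpsi,
             min_psi_range = min_psi_range, min_replicates = min_replicates,
             min_cell_types = min_cell_types,
             deg_min_median_crpkm = deg_min_median_crpkm,
             deg_fc_each = deg_fc_each, deg_fc_global = deg_fc_global,
             deg_abs_diff = deg_abs_diff, pseudocount = pseudocount,
             min_tier = min_tier, strict_dpsi = strict_dpsi,
             require_sign_match = require_sign_match)
  num <- th[c("global_dpsi", "min_dpsi", "min_psi_range", "min_replicates",
              "min_cell_types", "deg_min_median_crpkm", "deg_fc_each",
              "deg_fc_global", "deg_abs_diff")]
  if (any(unlist(num) <= 0)) stop("all thresholds must be strictly positive")
  if (min_dpsi > global_dpsi) stop("min_dpsi must not exceed global_dpsi")
  class(th) <- "specificity_thresholds"
  th
}

# covered values of one event row, split by cell type within an organ
split_covered <- function(values, covered, samples, organ) {
  in_organ <- samples$organ == organ
  sid <- samples$sample_id[in_organ]
  ct <- samples$cell_type[in_organ]
  v <- values[sid]
  keep <- covered[sid]
  split(ifelse(keep, v, NA_real_), ct)
}

#' Global delta-PSI of a cell type
#'
#' Mean PSI over the target cell type's covered replicates minus the mean
#' over all other covered samples of the same organ, pooled sample-wise.
#'
#' @param values named numeric vector of one event's PSI values (`NA` =
#'   missing or uncovered).
#' @param samples sample sheet data frame.
#' @param target target cell type (its organ defines the comparison set).
#' @param min_replicates covered replicates required in the target.
#' @return Signed percent, or `NA` when the target has too few covered
#'   replicates or no other covered sample exists.
#' @export
dpsi_global <- function(values, samples, target, min_replicates = 2) {
  organ <- samples$organ[match(target, samples$cell_type)]
  if (is.na(organ)) stop("unknown cell type '", target, "'")
  in_organ <- samples$sample_id[samples$organ == organ]
  v <- values[in_organ]
  is_target <- samples$cell_type[match(in_organ, samples$sample_id)] == target
  tv <- v[is_target & !is.na(v)]
  ov <- v[!is_target & !is.na(v)]
  if (length(tv) < min_replicates || length(ov) < 1) return(NA_real_)
  mean(tv) - mean(ov)
}

#' Minimum delta-PSI against other cell types
#'
#' Over all other same-organ cell types with enough covered replicates, the
#' per-cell-type mean difference (target minus other) whose magnitude is
#' smallest, sign preserved.
#'
#' @inheritParams dpsi_global
#' @return Signed percent, or `NA` when the target or every other cell type
#'   lacks sufficient coverage.
#' @export
dpsi_min <- function(values, samples, target, min_replicates = 2) {
  organ <- samples$organ[match(target, samples$cell_type)]
  if (is.na(organ)) stop("unknown cell type '", target, "'")
  groups <- split_covered(values, !is.na(values), samples, organ)
  means <- vapply(groups, function(g) mean(g[!is.na(g)]), 1)
  sizes <- vapply(groups, function(g) sum(!is.na(g)), 1L)
  ok <- sizes >= min_replicates
  if (!ok[target]) return(NA_real_)
  others <- setdiff(names(groups)[ok], target)
  if (length(others) == 0) return(NA_real_)
  d <- means[target] - means[others]
  d[[which.min(abs(d))]]
}

#' PSI range across cell types
#'
#' Each cell type with at least one covered value contributes its maximum
#' replicate PSI; the range is the difference between the largest and the
#' smallest of these per-cell-type maxima. A range below the threshold marks
#' an event that is effectively constitutive within the organ.
#'
#' @inheritParams dpsi_global
#' @param organ organ whose cell types are compared.
#' @return Percent range (`NA` with fewer than two covered cell types).
#' @export
psi_range <- function(values, samples, organ) {
  groups <- split_covered(values, !is.na(values), samples, organ)
  maxima <- vapply(groups, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) NA_real_ else max(g)
  }, 1)
  maxima <- maxima[!is.na(maxima)]
  if (length(maxima) < 2) return(NA_real_)
  max(maxima) - min(maxima)
}

#' Call cell-type-specific splicing events
#'
#' Applies the three delta-PSI criteria organ by organ. A cell type enters
#' the analysis of an event when it has at least `min_replicates` covered
#' values (non-missing PSI at `min_tier` or better); an organ contributes
#' calls for an event only when at least `min_cell_types` of its cell types
#' are covered. An event may be called in more than one cell type of the
#' same organ (e.g. opposite directions).
#'
#' @param x a [psi_matrix()], already event-filtered (see
#'   [filter_events()]).
#' @param samples sample sheet data frame covering the matrix columns.
#' @param thresholds a [specificity_thresholds()] object.
#' @return Data frame with one row per call: `event_id`, `gene_id`,
#'   `event_type`, `cell_type`, `organ`, `direction` (`up`/`down` from the
#'   sign of the global delta-PSI), the three criterion values
#'   (`dpsi_global`, `dpsi_min`, `psi_range`) and their pass flags.
#' @export
call_dse <- function(x, samples, thresholds = specificity_thresholds()) {
  check_sample_sheet(samples)
  miss <- setdiff(colnames(x$psi), samples$sample_id)
  if (length(miss) > 0) {
    stop("samples absent from sample sheet: ", paste(miss, collapse = ", "))
  }
  th <- thresholds
  covered <- psi_covered(x, th$min_tier)
  cmp <- if (th$strict_dpsi) `>` else `>=`
  out <- list()
  for (organ in intersect(ORGAN_LEVELS, unique(samples$organ))) {
    o_samples <- samples$sample_id[samples$organ == organ]
    o_samples <- intersect(colnames(x$psi), o_samples)
    if (length(o_samples) == 0) next
    o_ct <- samples$cell_type[match(o_samples, samples$sample_id)]
    cts <- unique(o_ct)
    for (e in seq_len(nrow(x$psi))) {
      v <- ifelse(covered[e, o_samples], x$psi[e, o_samples], NA_real_)
      by_ct <- split(v, o_ct)
      n_cov <- vapply(by_ct, function(g) sum(!is.na(g)), 1L)
      eligible <- names(n_cov)[n_cov >= th$min_replicates]
      if (length(eligible) < th$min_cell_types) next
      means <- vapply(by_ct[eligible], function(g) mean(g, na.rm = TRUE), 1)
      maxima <- vapply(by_ct, function(g) {
        g <- g[!is.na(g)]
        if (length(g) == 0) NA_real_ else max(g)
      }, 1)
      maxima <- maxima[!is.na(maxima)]
      rng <- max(maxima) - min(maxima)
      for (target in eligible) {
        others <- !is.na(v) & o_ct != target
        if (!any(others)) next
        dg <- means[[target]] - mean(v[others])
        d_each <- means[[target]] - means[setdiff(eligible, target)]
        dmin <- d_each[[which.min(abs(d_each))]]
        pass_g <- cmp(abs(dg), th$global_dpsi)
        pass_m <- cmp(abs(dmin), th$min_dpsi)
        pass_r <- rng >= th$min_psi_range
        pass_s <- !th$require_sign_match || sign(dg) == sign(dmin)
        if (pass_g && pass_m && pass_r && pass_s) {
          out[[length(out) + 1L]] <- data.frame(
            event_id = x$events$event_id[e],
            gene_id = x$events$gene_id[e],
            event_type = x$events$event_type[e],
            cell_type = target, organ = organ,
            direction = if (dg > 0) "up" else "down",
            dpsi_global = dg, dpsi_min = dmin, psi_range = rng,
            pass_global = pass_g, pass_min = pass_m, pass_range = pass_r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(event_id = character(), gene_id = character(),
                      event_type = character(), cell_type = character(),
                      organ = character(), direction = character(),
                      dpsi_global = numeric(), dpsi_min = numeric(),
                      psi_range = numeric(), pass_global = logical(),
                      pass_min = logical(), pass_range = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Pseudocounted fold change
#'
#' @param a,b non-negative expression values.
#' @param pseudocount added to both sides; keeps zero-vs-zero at ratio 1 and
#'   zero-vs-positive large.
#' @return `(a + pseudocount) / (b + pseudocount)`.
#' @export
fold_change <- function(a, b, pseudocount = 0.01) {
  (a + pseudocount) / (b + pseudocount)
}

#' Call cell-type-specific genes from expression
#'
#' Applies the four cRPKM rules organ by organ: eligibility (median cRPKM of
#' at least `deg_min_median_crpkm` in some cell type of the organ), the
#' per-cell-type fold-change rule, the global fold-change rule against the
#' median of all other samples, and the per-cell-type absolute-difference
#' rule. Fold-change rules are symmetric (ratio `>= x` or `<= 1/x`) and
#' evaluated on the linear scale; the output reports the global comparison
#' as log2.
#'
#' @param expr an [expression_matrix()].
#' @param samples sample sheet data frame.
#' @param thresholds a [specificity_thresholds()] object.
#' @return Data frame with one row per call: `gene_id`, `cell_type`,
#'   `organ`, `direction`, `median_target`, `global_median_others`,
#'   `log2_fc_global` and the three rule flags.
#' @export
call_deg <- function(expr, samples, thresholds = specificity_thresholds()) {
  check_sample_sheet(samples)
  th <- thresholds
  crpkm <- expr$crpkm
  miss <- setdiff(colnames(crpkm), samples$sample_id)
  if (length(miss) > 0) {
    stop("samples absent from sample sheet: ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (organ in intersect(ORGAN_LEVELS, unique(samples$organ))) {
    o_samples <- intersect(colnames(crpkm),
                           samples$sample_id[samples$organ == organ])
    if (length(o_samples) == 0) next
    o_ct <- samples$cell_type[match(o_samples, samples$sample_id)]
    cts <- unique(o_ct)
    if (length(cts) < 2) next
    med <- matrix(
      vapply(cts, function(ct) {
        apply(crpkm[, o_samples[o_ct == ct], drop = FALSE], 1,
              stats::median)
      }, numeric(nrow(crpkm))),
      nrow = nrow(crpkm), dimnames = list(rownames(crpkm), cts))
    eligible <- apply(med, 1, max) >= th$deg_min_median_crpkm
    for (target in cts) {
      m_t <- med[, target]
      m_o <- med[, setdiff(cts, target), drop = FALSE]
      fc_each <- fold_change(m_t, m_o, th$pseudocount)
      pass_each <- rowSums(fc_each >= th$deg_fc_each |
                           fc_each <= 1 / th$deg_fc_each) == ncol(m_o)
      pass_diff <- rowSums(abs(m_t - m_o) >= th$deg_abs_diff) == ncol(m_o)
      gm <- apply(crpkm[, o_samples[o_ct != target], drop = FALSE], 1,
                  stats::median)
      fc_g <- fold_change(m_t, gm, th$pseudocount)
      pass_glob <- fc_g >= th$deg_fc_global | fc_g <= 1 / th$deg_fc_global
      hit <- which(eligible & pass_each & pass_diff & pass_glob)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = rownames(crpkm)[hit],
          cell_type = target, organ = organ,
          direction = ifelse(m_t[hit] > gm[hit], "up", "down"),
          median_target = m_t[hit], global_median_others = gm[hit],
          log2_fc_global = log2(fc_g[hit]),
          pass_each = TRUE, pass_global = TRUE, pass_diff = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), cell_type = character(),
                      organ = character(), direction = character(),
                      median_target = numeric(),
                      global_median_others = numeric(),
                      log2_fc_global = numeric(), pass_each = logical(),
                      pass_global = logical(), pass_diff = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of expression- and splicing-level call sets
#'
#' Differentially spliced genes (DSGs) are the distinct genes owning at
#' least one called splicing event. Reports the Venn counts between the DEG
#' and DSG gene sets and, for both layers, the exclusive per-cell-type
#' membership patterns (upset-style intersection counts).
#'
#' @param deg data frame of expression calls ([call_deg()]).
#' @param dse data frame of splicing calls ([call_dse()]).
#' @param events event annotation table (event to gene map) — only needed
#'   when `dse` lacks a `gene_id` column.
#' @return List with `n_deg`, `n_dsg`, `n_overlap`, and two data frames
#'   `deg_upset` (genes) and `dse_upset` (events), each mapping an exclusive
#'   cell-type membership pattern (cell types sorted, joined with `+`) to
#'   its count. Upset counts sum to the number of distinct called items.
#' @export
overlap_summary <- function(deg, dse, events = NULL) {
  if (!"gene_id" %in% names(dse) && !is.null(events)) {
    dse$gene_id <- events$gene_id[match(dse$event_id, events$event_id)]
  }
  deg_genes <- unique(deg$gene_id)
  dsg_genes <- unique(dse$gene_id)
  upset <- function(id, group) {
    if (length(id) == 0) {
      return(data.frame(pattern = character(), count = integer(),
                        stringsAsFactors = FALSE))
    }
    pat <- vapply(split(group, id),
                  function(g) paste(sort(unique(g)), collapse = "+"), "")
    tb <- table(pat)
    data.frame(pattern = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  }
  list(n_deg = length(deg_genes),
       n_dsg = length(dsg_genes),
       n_overlap = length(intersect(deg_genes, dsg_genes)),
       deg_upset = upset(deg$gene_id, deg$cell_type),
       dse_upset = upset(dse$event_id, dse$cell_type))
}
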
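# Readers and writers for the fixed TSV dialects the pipeline exchanges.
#
# All tables are plain tab-separated text with a header line and no quoting;
# missing values are the literal string "NA". Coordinates in event tables are
# 1-based with inclusive ends ("chrom:start-end").

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}

#' Read a sample sheet
#'
#' The sample sheet maps each sequencing library to its cell type, organ
#' (`root` or `aerial`) and replicate number. Cell types are typically named
#' after the promoter used to sort the population (e.g. `pATHB8`).
#'
#' @param path path to a TSV with header columns `sample_id`, `cell_type`,
#'   `organ`, `replicate`.
#' @return A data frame with one row per sample. Duplicate sample IDs, organs
#'   outside `{root, aerial}`, cell types mapped to two organs, and duplicate
#'   `(cell_type, replicate)` pairs are hard errors.
#' @export
read_sample_sheet <- function(path) {
  samples <- read_tsv_strict(path)
  samples$replicate <- as.integer(samples$replicate)
  check_sample_sheet(samples)
  samples
}

#' Read a gene list
#'
#' One gene identifier per line; lines starting with `#` and blank lines are
#' ignored. The result is de-duplicated (an order-free set).
#'
#' @param path path to the list file.
#' @return Character vector of unique gene identifiers. An empty file yields
#'   an empty vector with a warning, not an error.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (length(genes) == 0) {
    warning("gene list '", path, "' is empty")
  }
  genes
}

#' Read a junction-count table
#'
#' @param path TSV with columns `event_id`, `sample_id`, `junction_role`,
#'   `reads`. Roles are `C1A`/`AC2`/`C1C2` for exon skipping, `EI`/`IE`/`EE`
#'   for intron retention and `V1..Vk` for alternative donor/acceptor
#'   variants.
#' @return Data frame of junction counts; read counts validated as
#'   non-negative integers.
#' @export
read_junction_counts <- function(path) {
  jx <- read_tsv_strict(path)
  need <- c("event_id", "sample_id", "junction_role", "reads")
  miss <- setdiff(need, names(jx))
  if (length(miss) > 0) {
    stop("junction table is missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot_nonneg_int(jx$reads, "junction read counts")
  jx
}

#' Read an event annotation table
#'
#' @param path TSV with columns `event_id`, `gene_id`, `event_type`, `coord`,
#'   `n_variants`.
#' @return Data frame of splicing events. Event types are validated against
#'   `IR`, `EX`, `ALTA`, `ALTD`; coordinates must parse as
#'   `chrom:start-end` with `start <= end`.
#' @export
read_event_table <- function(path) {
  ev <- read_tsv_strict(path)
  need <- c("event_id", "gene_id", "event_type", "coord", "n_variants")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ev$event_id)) stop("duplicate event_id in event table")
  bad <- setdiff(unique(ev$event_type), EVENT_TYPES)
  if (length(bad) > 0) stop("unknown event_type: ", paste(bad, collapse = ", "))
  m <- regmatches(ev$coord, regexec("^([^:]+):([0-9]+)-([0-9]+)$", ev$coord))
  ok <- vapply(m, length, 1L) == 4L
  if (!all(ok)) {
    stop("malformed coord '", ev$coord[which(!ok)[1]],
         "' (expected chrom:start-end)")
  }
  starts <- vapply(m, function(g) as.numeric(g[3]), 1)
  ends <- vapply(m, function(g) as.numeric(g[4]), 1)
  if (any(starts > ends)) stop("event coord with start > end")
  ev$n_variants <- as.integer(ev$n_variants)
  if (any(ev$n_variants < 2)) stop("n_variants must be >= 2")
  ev
}

#' Read a gene count matrix
#'
#' @param path TSV with columns `gene_id`, `mappable_positions`, then one
#'   integer column per sample.
#' @return List with `counts` (integer matrix, genes x samples) and
#'   `mappable_positions` (named integer vector).
#' @export
read_count_matrix <- function(path) {
  tab <- read_tsv_strict(path)
  if (!identical(names(tab)[1:2], c("gene_id", "mappable_positions"))) {
    stop("count matrix must start with columns gene_id, mappable_positions")
  }
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in count matrix")
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  stopifnot_nonneg_int(counts, "gene read counts")
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$gene_id
  mp <- as.integer(tab$mappable_positions)
  if (any(mp <= 0)) stop("mappable_positions must be > 0")
  names(mp) <- tab$gene_id
  list(counts = counts, mappable_positions = mp)
}

#' Read an event impact table
#'
#' Predicted protein-level consequence of each splicing event, as exported
#' from an external event-impact database.
#'
#' @param path TSV with columns `event_id`, `impact`, where impact is one of
#'   `ORF_disruption`, `alternative_isoform`, `UTR_overlap`, `unknown`.
#' @return Data frame mapping event IDs to impact classes.
#' @export
read_impact_table <- function(path) {
  imp <- read_tsv_strict(path)
  miss <- setdiff(c("event_id", "impact"), names(imp))
  if (length(miss) > 0) {
    stop("impact table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(imp$impact), IMPACT_LEVELS)
  if (length(bad) > 0) {
    stop("unknown impact class: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(imp$event_id)) stop("duplicate event_id in impact table")
  imp
}

#' Read annotation term sets
#'
#' @param path two-column TSV (`term`, `gene`), one membership per row.
#' @return Named list of character vectors, one de-duplicated gene set per
#'   term.
#' @export
read_term_sets <- function(path) {
  tab <- read_tsv_strict(path)
  miss <- setdiff(c("term", "gene"), names(tab))
  if (length(miss) > 0) {
    stop("term table is missing column(s): ", paste(miss, collapse = ", "))
  }
  lapply(split(tab$gene, tab$term), unique)
}

# ---- PSI table dialect ----------------------------------------------------
#
# Fixed columns GENE EVENT COORD TYPE, then per sample a value column
# `<sample_id>` (PSI with two decimals, or NA) paired with a quality column
# `<sample_id>.Q` holding "TIER@inc,exc,balance_p". inc/exc are the raw
# junction read totals; balance_p is NA for non-IR events.

format_quality <- function(tier, inc, exc, balance_p) {
  bp <- ifelse(is.na(balance_p), "NA", sprintf("%.6g", balance_p))
  sprintf("%s@%d,%d,%s", tier, as.integer(inc), as.integer(exc), bp)
}

parse_quality <- function(q, col) {
  m <- regmatches(q, regexec("^([A-Z]+)@([0-9]+),([0-9]+),(.+)$", q))
  ok <- vapply(m, length, 1L) == 5L
  if (!all(ok)) {
    stop("malformed quality string '", q[which(!ok)[1]], "' in column ", col)
  }
  tier <- vapply(m, `[`, "", 2)
  bad <- setdiff(unique(tier), TIER_LEVELS)
  if (length(bad) > 0) {
    stop("unknown coverage tier in column ", col, ": ",
         paste(bad, collapse = ", "))
  }
  bp_str <- vapply(m, `[`, "", 5)
  list(tier = tier,
       inc = as.integer(vapply(m, `[`, "", 3)),
       exc = as.integer(vapply(m, `[`, "", 4)),
       balance_p = suppressWarnings(
         ifelse(bp_str == "NA", NA_real_, as.numeric(bp_str))))
}

#' Write a PSI table
#'
#' Serialises a [psi_matrix()] to the paired value/quality TSV dialect. PSI
#' values are written with two decimals and balance p-values with six
#' significant digits; matrices produced by [quantify_psi()] are already
#' rounded to that precision, so write/read round-trips are lossless.
#'
#' @param x a `psi_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(x, path) {
  out <- data.frame(GENE = x$events$gene_id,
                    EVENT = x$events$event_id,
                    COORD = x$events$coord,
                    TYPE = x$events$event_type,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(x$psi)) {
    out[[s]] <- ifelse(is.na(x$psi[, s]), "NA", sprintf("%.2f", x$psi[, s]))
    out[[paste0(s, ".Q")]] <- format_quality(x$tier[, s], x$inc_reads[, s],
                                             x$exc_reads[, s],
                                             x$balance_p[, s])
  }
  write_tsv_strict(out, path)
  invisible(path)
}

#' Read a PSI table
#'
#' Parses the paired value/quality TSV dialect written by
#' [write_psi_table()].
#'
#' @param path input path.
#' @param events optional event annotation table supplying `n_variants`; when
#'   absent, `n_variants` defaults to 2.
#' @return A [psi_matrix()]. PSI values outside `[0, 100]` and value columns
#'   without their `.Q` partner are hard errors.
#' @export
read_psi_table <- function(path, events = NULL) {
  tab <- read_tsv_strict(path)
  fixed <- c("GENE", "EVENT", "COORD", "TYPE")
  if (!identical(names(tab)[1:4], fixed)) {
    stop("PSI table must start with columns GENE EVENT COORD TYPE")
  }
  rest <- names(tab)[-(1:4)]
  value_cols <- rest[!grepl("\\.Q$", rest)]
  for (s in value_cols) {
    if (!paste0(s, ".Q") %in% rest) {
      stop("sample column '", s, "' is missing its paired quality column '",
           s, ".Q'")
    }
  }
  n_ev <- nrow(tab)
  n_s <- length(value_cols)
  psi <- matrix(NA_real_, n_ev, n_s, dimnames = list(tab$EVENT, value_cols))
  tier <- matrix("N", n_ev, n_s, dimnames = dimnames(psi))
  balance_p <- matrix(NA_real_, n_ev, n_s, dimnames = dimnames(psi))
  inc <- matrix(0L, n_ev, n_s, dimnames = dimnames(psi))
  exc <- matrix(0L, n_ev, n_s, dimnames = dimnames(psi))
  for (s in value_cols) {
    v <- tab[[s]]
    val <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    if (any(!is.na(val) & (val < 0 | val > 100))) {
      stop("PSI outside [0, 100] in column ", s)
    }
    psi[, s] <- val
    q <- parse_quality(tab[[paste0(s, ".Q")]], paste0(s, ".Q"))
    tier[, s] <- q$tier
    inc[, s] <- q$inc
    exc[, s] <- q$exc
    balance_p[, s] <- q$balance_p
  }
  if (is.null(events)) {
    events <- data.frame(event_id = tab$EVENT, gene_id = tab$GENE,
                         event_type = tab$TYPE, coord = tab$COORD,
                         n_variants = 2L, stringsAsFactors = FALSE)
  } else {
    events <- events[match(tab$EVENT, events$event_id), , drop = FALSE]
    if (anyNA(events$event_id)) {
      stop("PSI table contains events absent from the event table")
    }
  }
  psi_matrix(psi, tier, balance_p, inc, exc, events)
}
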
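# Seeded synthetic-data generator. Emulates the study design the callers
# are meant for: two organ groups of sorted cell types with a few
# replicates each, four splicing-event classes dominated by intron
# retention, beta-binomially dispersed PSI around per-event baselines,
# negative-binomially dispersed gene counts, and nonoverlapping planted
# cell-type-specific splicing/expression signals recorded in a truth table.

ROOT_CT_POOL <- c("pATHB8", "pTMO5", "pPXY", "pCASP1", "pSCR", "pAPL",
                  "pSMLX5")
AERIAL_CT_POOL <- c("pML1", "pREV", "pUFO", "pLTP1")

#' Simulation configuration
#'
#' Defaults emulate the reference design: 7 root and 4 aerial cell types
#' with 3 replicates, 1,000 splicing events at class proportions 0.65 IR /
#' 0.17 ALTA / 0.08 ALTD / 0.10 EX (intron retention dominant, as reported
#' for plant cell-type splicing surveys), 2,000 genes, one fifth of events
#' and genes carrying a planted cell-type-specific signal of 40 PSI points
#' or 8-fold expression.
#'
#' @param n_cell_types_root,n_cell_types_aerial number of cell types per
#'   organ (either may be 0).
#' @param replicates replicates per cell type.
#' @param n_events named integer vector: events per class (`IR`, `ALTA`,
#'   `ALTD`, `EX`).
#' @param frac_specific fraction of events and of genes planted as
#'   cell-type-specific.
#' @param planted_dpsi planted PSI shift (percent).
#' @param baseline_psi_range range of the uniform baseline-PSI draw.
#' @param bb_rho beta-binomial intra-class correlation (dispersion of the
#'   per-sample PSI around the true event PSI).
#' @param depth_mean expected informative reads per event per sample
#'   (Poisson).
#' @param n_genes genes in the count matrix.
#' @param planted_fc planted expression fold change (applied up or down).
#' @param nb_dispersion negative-binomial dispersion of gene counts
#'   (`size = 1/nb_dispersion`).
#' @param gene_mean_log,gene_sd_log log-normal parameters of per-gene mean
#'   expression.
#' @param mappable_range range of per-gene uniquely mappable positions.
#' @param seed integer seed; everything derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types_root = 7, n_cell_types_aerial = 4,
                       replicates = 3,
                       n_events = c(IR = 650, ALTA = 170, ALTD = 80,
                                    EX = 100),
                       frac_specific = 0.2, planted_dpsi = 40,
                       baseline_psi_range = c(5, 95), bb_rho = 0.02,
                       depth_mean = 100, n_genes = 2000, planted_fc = 8,
                       nb_dispersion = 0.1, gene_mean_log = log(200),
                       gene_sd_log = 1, mappable_range = c(200, 3000),
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$frac_specific < 0 || cfg$frac_specific > 1) {
    stop("frac_specific must be in [0, 1]")
  }
  if (cfg$planted_dpsi <= 0 || cfg$planted_dpsi >= 100) {
    stop("planted_dpsi must be in (0, 100)")
  }
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0")
  if (cfg$bb_rho < 0 || cfg$bb_rho >= 1) stop("bb_rho must be in [0, 1)")
  if (cfg$n_cell_types_root + cfg$n_cell_types_aerial < 1) {
    stop("need at least one cell type")
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_cell_types <- function(cfg) {
  name_pool <- function(pool, n, prefix) {
    if (n <= length(pool)) pool[seq_len(n)]
    else c(pool, sprintf("%s%02d", prefix, seq_len(n - length(pool))))
  }
  root <- name_pool(ROOT_CT_POOL, cfg$n_cell_types_root, "pROOT")
  aerial <- name_pool(AERIAL_CT_POOL, cfg$n_cell_types_aerial, "pAER")
  data.frame(cell_type = c(root, aerial),
             organ = c(rep("root", length(root)),
                       rep("aerial", length(aerial))),
             stringsAsFactors = FALSE)
}

# beta draw parameterised by mean (0-1) and intra-class correlation rho
rbeta_mean_rho <- function(n, mean, rho) {
  if (rho <= 0) return(rep(mean, length.out = n))
  s <- (1 - rho) / rho
  stats::rbeta(n, mean * s, (1 - mean) * s)
}

mat_to_junction_rows <- function(m, role) {
  data.frame(event_id = rep(rownames(m), times = ncol(m)),
             sample_id = rep(colnames(m), each = nrow(m)),
             junction_role = role, reads = as.integer(m),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' Generates the sample sheet, event table, junction counts, gene counts
#' with mappable lengths, impact annotations, gene sets and the truth table
#' of planted signals, all reproducible from the configuration seed.
#'
#' For each event a baseline PSI is drawn once; planted events shift the
#' baseline by `planted_dpsi` (direction chosen among those that keep the
#' shifted value inside `[1, 99]`; baselines supporting neither direction
#' are redrawn) in their assigned cell type. Per sample, the realised PSI is
#' a beta draw around the true PSI, the informative depth is Poisson, and
#' reads are split between inclusion- and exclusion-supporting junctions
#' binomially at the realised PSI — with each two-outcome event's inclusion
#' reads further split evenly (binomial 0.5) across its two boundary
#' junctions, and alternative-site events multinomial across their
#' variants. Gene counts are negative binomial around log-normal means with
#' the planted fold change applied in the planted cell type.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, every table is written as
#'   TSV (plus the effective configuration as YAML).
#' @return List with `samples`, `events`, `junctions`, `counts`,
#'   `mappable_positions`, `truth`, `impact`, `immunity_genes`,
#'   `term_sets`, `baseline_psi`, `n_redraws` and the `config` echo.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  cts <- sim_cell_types(cfg)
  samples <- do.call(rbind, lapply(seq_len(nrow(cts)), function(i) {
    data.frame(sample_id = sprintf("%s_r%d", cts$cell_type[i],
                                   seq_len(cfg$replicates)),
               cell_type = cts$cell_type[i], organ = cts$organ[i],
               replicate = seq_len(cfg$replicates),
               stringsAsFactors = FALSE)
  }))
  n_s <- nrow(samples)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))

  # --- events ---------------------------------------------------------
  n_ev <- sum(cfg$n_events)
  etype <- rep(names(cfg$n_events), cfg$n_events)
  events <- data.frame(
    event_id = sprintf("SIM_%s_%04d", etype, seq_len(n_ev)),
    gene_id = sample(gene_ids, n_ev, replace = TRUE),
    event_type = etype,
    coord = NA_character_,
    n_variants = ifelse(etype %in% c("ALTA", "ALTD"), 3L, 2L),
    stringsAsFactors = FALSE)
  start <- sample.int(1e7, n_ev)
  events$coord <- sprintf("chr%d:%d-%d", sample.int(5, n_ev, replace = TRUE),
                          start, start + sample.int(5000, n_ev) + 50L)

  n_planted <- round(cfg$frac_specific * n_ev)
  planted_idx <- sort(sample.int(n_ev, n_planted))
  planted_ct <- rep_len(cts$cell_type, n_planted)

  lo <- cfg$baseline_psi_range[1]
  hi <- cfg$baseline_psi_range[2]
  baseline <- stats::runif(n_ev, lo, hi)
  direction <- rep(NA_character_, n_ev)
  n_redraws <- 0L
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    tries <- 0L
    repeat {
      up_ok <- baseline[i] + cfg$planted_dpsi <= 99
      dn_ok <- baseline[i] - cfg$planted_dpsi >= 1
      if (up_ok || dn_ok) break
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("planted shift of ", cfg$planted_dpsi,
             " is unachievable from the baseline PSI range [", lo, ", ",
             hi, "]")
      }
      baseline[i] <- stats::runif(1, lo, hi)
      n_redraws <- n_redraws + 1L
    }
    want_up <- stats::runif(1) < 0.5
    direction[i] <- if (want_up && up_ok) "up"
                    else if (!want_up && dn_ok) "down"
                    else if (up_ok) "up" else "down"
  }

  # true PSI per event x sample
  mu <- matrix(baseline, n_ev, n_s,
               dimnames = list(events$event_id, samples$sample_id))
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    cols <- samples$cell_type == planted_ct[j]
    shift <- if (direction[i] == "up") cfg$planted_dpsi else -cfg$planted_dpsi
    mu[i, cols] <- baseline[i] + shift
  }

  # realised PSI, depth and junction reads
  p <- matrix(0, n_ev, n_s, dimnames = dimnames(mu))
  for (i in seq_len(n_ev)) {
    p[i, ] <- rbeta_mean_rho(n_s, mu[i, ] / 100, cfg$bb_rho)
  }
  N <- matrix(stats::rpois(n_ev * n_s, cfg$depth_mean), n_ev, n_s,
              dimnames = dimnames(mu))
  U <- matrix(stats::rbinom(n_ev * n_s, as.vector(N), as.vector(p)),
              n_ev, n_s, dimnames = dimnames(mu))
  excl <- N - U

  junctions <- list()
  two_roles <- list(EX = c("C1A", "AC2", "C1C2"), IR = c("EI", "IE", "EE"))
  for (tp in c("EX", "IR")) {
    rows <- events$event_type == tp
    if (!any(rows)) next
    u2 <- 2L * U[rows, , drop = FALSE]
    first <- matrix(stats::rbinom(length(u2), as.vector(u2), 0.5),
                    nrow(u2), ncol(u2), dimnames = dimnames(u2))
    second <- u2 - first
    rl <- two_roles[[tp]]
    junctions[[length(junctions) + 1L]] <- rbind(
      mat_to_junction_rows(first, rl[1]),
      mat_to_junction_rows(second, rl[2]),
      mat_to_junction_rows(excl[rows, , drop = FALSE], rl[3]))
  }
  alt <- events$event_type %in% c("ALTA", "ALTD")
  if (any(alt)) {
    w2 <- stats::runif(sum(alt))  # split of non-focal reads between V2/V3
    w2m <- matrix(w2, sum(alt), n_s)
    rest <- excl[alt, , drop = FALSE]
    v2 <- matrix(stats::rbinom(length(rest), as.vector(rest),
                               as.vector(w2m)),
                 nrow(rest), ncol(rest), dimnames = dimnames(rest))
    junctions[[length(junctions) + 1L]] <- rbind(
      mat_to_junction_rows(U[alt, , drop = FALSE], "V1"),
      mat_to_junction_rows(v2, "V2"),
      mat_to_junction_rows(rest - v2, "V3"))
  }
  junctions <- do.call(rbind, junctions)
  junctions <- junctions[order(match(junctions$event_id, events$event_id),
                               match(junctions$sample_id,
                                     samples$sample_id),
                               junctions$junction_role), ]
  rownames(junctions) <- NULL

  # --- gene counts ----------------------------------------------------
  gene_mu <- stats::rlnorm(cfg$n_genes, cfg$gene_mean_log, cfg$gene_sd_log)
  n_pg <- round(cfg$frac_specific * cfg$n_genes)
  pg_idx <- sort(sample.int(cfg$n_genes, n_pg))
  pg_ct <- rep_len(cts$cell_type, n_pg)
  pg_dir <- sample(c("up", "down"), n_pg, replace = TRUE)
  mu_mat <- matrix(gene_mu, cfg$n_genes, n_s,
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(n_pg)) {
    cols <- samples$cell_type == pg_ct[j]
    fac <- if (pg_dir[j] == "up") cfg$planted_fc else 1 / cfg$planted_fc
    mu_mat[pg_idx[j], cols] <- gene_mu[pg_idx[j]] * fac
  }
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                                  size = 1 / cfg$nb_dispersion),
                   cfg$n_genes, n_s, dimnames = dimnames(mu_mat))
  mappable <- sample(seq(cfg$mappable_range[1], cfg$mappable_range[2]),
                     cfg$n_genes, replace = TRUE)
  names(mappable) <- gene_ids

  # --- truth, impact, gene sets ---------------------------------------
  truth <- rbind(
    data.frame(id = events$event_id, kind = "event",
               cell_type = NA_character_, direction = NA_character_,
               effect_size = NA_real_, stringsAsFactors = FALSE),
    data.frame(id = gene_ids, kind = "gene", cell_type = NA_character_,
               direction = NA_character_, effect_size = NA_real_,
               stringsAsFactors = FALSE))
  truth$cell_type[planted_idx] <- planted_ct
  truth$direction[planted_idx] <- direction[planted_idx]
  truth$effect_size[planted_idx] <- cfg$planted_dpsi
  g_off <- n_ev
  truth$cell_type[g_off + pg_idx] <- pg_ct
  truth$direction[g_off + pg_idx] <- pg_dir
  truth$effect_size[g_off + pg_idx] <- cfg$planted_fc

  impact <- data.frame(
    event_id = events$event_id,
    impact = sample(IMPACT_LEVELS, n_ev, replace = TRUE,
                    prob = c(0.55, 0.30, 0.12, 0.03)),
    stringsAsFactors = FALSE)

  immunity_genes <- sort(sample(gene_ids, round(0.15 * cfg$n_genes)))
  term_sets <- lapply(seq_len(20), function(i) {
    sort(sample(gene_ids, min(cfg$n_genes, sample(30:100, 1))))
  })
  names(term_sets) <- sprintf("TERM%02d", seq_len(20))

  res <- list(samples = samples, events = events, junctions = junctions,
              counts = counts, mappable_positions = mappable, truth = truth,
              impact = impact, immunity_genes = immunity_genes,
              term_sets = term_sets, baseline_psi = baseline,
              true_psi = mu, n_redraws = n_redraws, config = cfg)
  if (!is.null(out_dir)) write_sim_dataset(res, out_dir)
  res
}

write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv_strict(df, file.path(out_dir, name))
  w(sim$samples, "samples.tsv")
  w(sim$events, "events.tsv")
  w(sim$junctions, "junctions.tsv")
  cm <- data.frame(gene_id = rownames(sim$counts),
                   mappable_positions = sim$mappable_positions,
                   sim$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  w(cm, "counts.tsv")
  w(sim$truth, "truth.tsv")
  w(sim$impact, "impact.tsv")
  writeLines(sim$immunity_genes, file.path(out_dir, "immunity_genes.txt"))
  terms <- data.frame(
    term = rep(names(sim$term_sets),
               vapply(sim$term_sets, length, 1L)),
    gene = unlist(sim$term_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  w(terms, "terms.tsv")
  yaml::write_yaml(unclass(sim$config),
                   file.path(out_dir, "sim_config.yaml"))
  invisible(out_dir)
}

#' Recovery of planted signals
#'
#' Scores a call set against the simulator's truth table. A true positive
#' must match both the planted ID and the planted cell type; direction
#' accuracy is computed over true positives.
#'
#' @param calls call data frame ([call_dse()] or [call_deg()]).
#' @param truth truth table from [simulate_dataset()].
#' @param kind `"event"` or `"gene"`.
#' @return List with `n_planted`, `n_called`, `n_true_positive`, `recall`,
#'   `precision` (`NA` with no calls) and `direction_accuracy` (`NA` with
#'   no true positives).
#' @export
truth_recovery <- function(calls, truth, kind = c("event", "gene")) {
  kind <- match.arg(kind)
  id_col <- if (kind == "event") "event_id" else "gene_id"
  planted <- truth[truth$kind == kind & !is.na(truth$cell_type), ,
                   drop = FALSE]
  key_p <- paste(planted$id, planted$cell_type)
  key_c <- paste(calls[[id_col]], calls$cell_type)
  tp <- key_c %in% key_p
  n_tp <- sum(tp)
  dir_ok <- calls$direction[tp] ==
    planted$direction[match(key_c[tp], key_p)]
  list(n_planted = nrow(planted), n_called = nrow(calls),
       n_true_positive = n_tp,
       recall = if (nrow(planted) == 0) NA_real_ else n_tp / nrow(planted),
       precision = if (nrow(calls) == 0) NA_real_ else n_tp / nrow(calls),
       direction_accuracy = if (n_tp == 0) NA_real_ else mean(dir_ok))
}
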
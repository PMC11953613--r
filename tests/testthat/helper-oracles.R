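# Independent straight-line re-implementations of the calling criteria and
# of small probability oracles, used to cross-check the package code paths.
# These are written as plain nested loops on purpose and must never call
# into the functions they validate.

# exact two-sided binomial p at p0 = 0.5 by direct pmf summation
bf_binom_two_sided <- function(k, n) {
  pm <- stats::dbinom(0:n, n, 0.5)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}

# upper hypergeometric tail P(X >= k) by direct pmf summation
bf_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  x <- k:min(K, n)
  sum(stats::dhyper(x, K, N - K, n))
}

# straight-line evaluation of the three splicing-specificity criteria on a
# plain numeric matrix (NA = uncovered); one organ per sample sheet subset
oracle_call_dse <- function(psi, samples, th = list(global_dpsi = 25,
                                                    min_dpsi = 15,
                                                    min_psi_range = 2,
                                                    min_replicates = 2,
                                                    min_cell_types = 4)) {
  out <- NULL
  for (organ in unique(samples$organ)) {
    ss <- samples[samples$organ == organ, ]
    for (e in seq_len(nrow(psi))) {
      vals <- list()
      for (ct in unique(ss$cell_type)) {
        v <- psi[e, ss$sample_id[ss$cell_type == ct]]
        vals[[ct]] <- v[!is.na(v)]
      }
      eligible <- names(vals)[vapply(vals, length, 1L) >= th$min_replicates]
      if (length(eligible) < th$min_cell_types) next
      maxima <- c()
      for (ct in names(vals)) {
        if (length(vals[[ct]]) > 0) maxima <- c(maxima, max(vals[[ct]]))
      }
      rng <- max(maxima) - min(maxima)
      for (target in eligible) {
        pooled <- c()
        for (ct in setdiff(names(vals), target)) {
          pooled <- c(pooled, vals[[ct]])
        }
        if (length(pooled) == 0) next
        dg <- mean(vals[[target]]) - mean(pooled)
        diffs <- c()
        for (ct in setdiff(eligible, target)) {
          diffs <- c(diffs, mean(vals[[target]]) - mean(vals[[ct]]))
        }
        dmin <- diffs[which.min(abs(diffs))]
        if (abs(dg) > th$global_dpsi && abs(dmin) > th$min_dpsi &&
            rng >= th$min_psi_range) {
          out <- rbind(out, data.frame(
            event_id = rownames(psi)[e], cell_type = target,
            direction = if (dg > 0) "up" else "down",
            dpsi_global = dg, dpsi_min = dmin, psi_range = rng,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(event_id = character(), cell_type = character(),
                      direction = character(), dpsi_global = numeric(),
                      dpsi_min = numeric(), psi_range = numeric(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$event_id, out$cell_type), ]
}

# straight-line evaluation of the four expression-specificity rules
oracle_call_deg <- function(crpkm, samples, th = list(min_median = 5,
                                                      fc_each = 2,
                                                      fc_global = 5,
                                                      abs_diff = 2,
                                                      pc = 0.01)) {
  out <- NULL
  for (organ in unique(samples$organ)) {
    ss <- samples[samples$organ == organ, ]
    cts <- unique(ss$cell_type)
    for (g in seq_len(nrow(crpkm))) {
      med <- c()
      for (ct in cts) {
        med[ct] <- stats::median(crpkm[g, ss$sample_id[ss$cell_type == ct]])
      }
      if (max(med) < th$min_median) next
      for (target in cts) {
        ok <- TRUE
        for (ct in setdiff(cts, target)) {
          fc <- (med[target] + th$pc) / (med[ct] + th$pc)
          if (!(fc >= th$fc_each || fc <= 1 / th$fc_each)) ok <- FALSE
          if (abs(med[target] - med[ct]) < th$abs_diff) ok <- FALSE
        }
        gm <- stats::median(crpkm[g, ss$sample_id[ss$cell_type != target]])
        fcg <- (med[target] + th$pc) / (gm + th$pc)
        if (!(fcg >= th$fc_global || fcg <= 1 / th$fc_global)) ok <- FALSE
        if (ok) {
          out <- rbind(out, data.frame(
            gene_id = rownames(crpkm)[g], cell_type = target,
            direction = if (med[target] > gm) "up" else "down",
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), cell_type = character(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  out[order(out$gene_id, out$cell_type), ]
}

# ---- instance builders ----------------------------------------------------

# sample sheet for one organ with the given replicate counts per cell type
make_samples <- function(reps = c(A = 3, B = 3, C = 3, D = 3),
                         organ = "root") {
  do.call(rbind, lapply(names(reps), function(ct) {
    data.frame(sample_id = sprintf("%s_r%d", ct, seq_len(reps[[ct]])),
               cell_type = ct, organ = organ,
               replicate = seq_len(reps[[ct]]), stringsAsFactors = FALSE)
  }))
}

# wrap a plain PSI matrix into a psi_matrix with uniform OK coverage
make_psi <- function(psi, event_type = "EX") {
  n <- nrow(psi)
  events <- data.frame(
    event_id = rownames(psi) %||% sprintf("E%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    event_type = rep_len(event_type, n),
    coord = sprintf("chr1:%d-%d", seq_len(n) * 100, seq_len(n) * 100 + 50),
    n_variants = 2L, stringsAsFactors = FALSE)
  rownames(psi) <- events$event_id
  dn <- dimnames(psi)
  psi_matrix(psi,
             matrix("OK", n, ncol(psi), dimnames = dn),
             matrix(NA_real_, n, ncol(psi), dimnames = dn),
             matrix(0L, n, ncol(psi), dimnames = dn),
             matrix(0L, n, ncol(psi), dimnames = dn),
             events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random one-organ splicing instance with missingness
random_dse_instance <- function(seed, n_events = 20) {
  set.seed(seed)
  reps <- sample(2:3, 4, replace = TRUE)
  names(reps) <- c("A", "B", "C", "D")
  samples <- make_samples(reps)
  psi <- matrix(round(stats::runif(n_events * nrow(samples), 0, 100), 2),
                n_events, nrow(samples),
                dimnames = list(sprintf("E%03d", seq_len(n_events)),
                                samples$sample_id))
  psi[stats::runif(length(psi)) < 0.15] <- NA_real_
  list(psi = psi, samples = samples)
}

# random one-organ expression instance
random_deg_instance <- function(seed, n_genes = 30) {
  set.seed(seed)
  samples <- make_samples(c(A = 3, B = 3, C = 3, D = 3))
  crpkm <- matrix(stats::rlnorm(n_genes * nrow(samples), log(8), 1.5),
                  n_genes, nrow(samples),
                  dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                  samples$sample_id))
  list(crpkm = crpkm, samples = samples)
}

as_expr <- function(crpkm) {
  structure(list(crpkm = crpkm), class = "expression_matrix")
}

# normalise call tables for comparison against the oracles
dse_key <- function(calls) {
  k <- calls[order(calls$event_id, calls$cell_type),
             c("event_id", "cell_type", "direction")]
  rownames(k) <- NULL
  k
}

deg_key <- function(calls) {
  k <- calls[order(calls$gene_id, calls$cell_type),
             c("gene_id", "cell_type", "direction")]
  rownames(k) <- NULL
  k
}
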
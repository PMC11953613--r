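samples4 <- make_samples(c(A = 2, B = 2, C = 2, D = 2))

row_psi <- function(...) {
  v <- c(...)
  names(v) <- samples4$sample_id
  v
}

test_that("global delta-PSI pools all other covered samples", {
  v <- row_psi(80, 80, 50, 50, 50, 50, 50, 50)
  expect_equal(dpsi_global(v, samples4, "A"), 30)
  v0 <- row_psi(50, 50, 50, 50, 50, 50, 50, 50)
  expect_equal(dpsi_global(v0, samples4, "A"), 0)
  v2 <- row_psi(90, 70, 40, 60, 50, 50, NA, NA)
  expect_equal(dpsi_global(v2, samples4, "A"), 30)
  # a single covered target replicate is not enough
  v3 <- row_psi(90, NA, 40, 60, 50, 50, 50, 50)
  expect_true(is.na(dpsi_global(v3, samples4, "A")))
})

test_that("minimum delta-PSI is the closest other cell type, sign kept", {
  v <- row_psi(80, 80, 50, 50, 55, 55, 60, 60)
  expect_equal(dpsi_min(v, samples4, "A"), 20)  # vs the 60 group
  v_eq <- row_psi(80, 80, 80, 80, 50, 50, 50, 50)
  expect_equal(dpsi_min(v_eq, samples4, "A"), 0)
  v_dn <- row_psi(40, 40, 70, 70, 90, 90, NA, NA)
  expect_equal(dpsi_min(v_dn, samples4, "A"), -30)
})

test_that("PSI range spans the per-cell-type maxima", {
  v <- row_psi(90, 10, 50, 20, 50, 30, 50, 40)
  expect_equal(psi_range(v, samples4, "root"), 40)  # maxima 90,50,50,50
  v_const <- row_psi(50, 50, 50, 50, 50, 50, 50, 50)
  expect_equal(psi_range(v_const, samples4, "root"), 0)
  v_close <- row_psi(51, 51, 50, 50, NA, NA, NA, NA)
  expect_equal(psi_range(v_close, samples4, "root"), 1)
})

test_that("call_dse applies the three criteria jointly", {
  mk <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- samples4$sample_id
    rownames(m) <- sprintf("E%03d", seq_len(nrow(m)))
    make_psi(m)
  }
  x <- mk(list(c(90, 90, 50, 50, 50, 50, 50, 50),
               c(70, 70, 50, 50, 50, 50, 50, 50)))
  calls <- call_dse(x, samples4)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$event_id, "E001")
  expect_equal(calls$cell_type, "A")
  expect_equal(calls$direction, "up")
  expect_equal(calls$dpsi_global, 40)
  expect_equal(calls$dpsi_min, 40)
  expect_equal(calls$psi_range, 40)

  # opposite outliers: both A (up) and B (down) qualify
  x2 <- mk(list(c(90, 90, 20, 20, 55, 55, 55, 55)))
  calls2 <- call_dse(x2, samples4)
  expect_equal(dse_key(calls2),
               dse_key(data.frame(event_id = c("E001", "E001"),
                                  cell_type = c("A", "B"),
                                  direction = c("up", "down"))))

  # fewer than four covered cell types: organ contributes nothing
  x3 <- mk(list(c(90, 90, 50, 50, NA, NA, NA, NA)))
  expect_equal(nrow(call_dse(x3, samples4)), 0)
})

test_that("delta-PSI boundaries are strict by default, configurable", {
  m <- matrix(c(75, 75, 50, 50, 50, 50, 50, 50), 1, 8,
              dimnames = list("E001", samples4$sample_id))
  x <- make_psi(m)
  expect_equal(nrow(call_dse(x, samples4)), 0)  # |dPSI| = 25, not > 25
  relaxed <- specificity_thresholds(strict_dpsi = FALSE)
  expect_equal(nrow(call_dse(x, samples4, relaxed)), 1)
})

test_that("fold changes are pseudocounted ratios", {
  expect_equal(fold_change(10, 10, 0.01), 1)
  expect_equal(fold_change(100, 10, 0), 10)
  expect_equal(fold_change(0, 0, 0.01), 1)
})

test_that("call_deg applies eligibility before the fold-change rules", {
  samples <- make_samples(c(A = 3, B = 3, C = 3, D = 3))
  mk_crpkm <- function(medians) {
    m <- matrix(rep(rep(medians, each = 3), each = 1), 1, 12,
                dimnames = list("G001", samples$sample_id))
    m
  }
  up <- as_expr(mk_crpkm(c(100, 10, 10, 10)))
  calls <- call_deg(up, samples)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cell_type, "A")
  expect_equal(calls$direction, "up")
  expect_equal(calls$median_target, 100)
  expect_equal(calls$global_median_others, 10)

  weak <- as_expr(mk_crpkm(c(8, 5, 5, 5)))
  expect_equal(nrow(call_deg(weak, samples)), 0)  # each-FC 1.6 < 2

  low <- as_expr(mk_crpkm(c(4, 0.5, 0.5, 0.5)))
  expect_equal(nrow(call_deg(low, samples)), 0)   # below cRPKM >= 5 floor
})

test_that("callers agree with straight-line criterion oracles", {
  for (seed in 1:50) {
    inst <- random_dse_instance(seed)
    got <- call_dse(make_psi(inst$psi), inst$samples)
    expect_equal(dse_key(got), dse_key(oracle_call_dse(inst$psi,
                                                       inst$samples)),
                 info = paste("dse seed", seed))
    inst2 <- random_deg_instance(seed)
    got2 <- call_deg(as_expr(inst2$crpkm), inst2$samples)
    expect_equal(deg_key(got2), deg_key(oracle_call_deg(inst2$crpkm,
                                                        inst2$samples)),
                 info = paste("deg seed", seed))
  }
})

test_that("raising any threshold never adds calls", {
  for (seed in 1:15) {
    inst <- random_dse_instance(seed, n_events = 30)
    x <- make_psi(inst$psi)
    base <- call_dse(x, inst$samples)
    key0 <- paste(base$event_id, base$cell_type)
    for (th in list(specificity_thresholds(global_dpsi = 35),
                    specificity_thresholds(min_dpsi = 25),
                    specificity_thresholds(min_psi_range = 10))) {
      raised <- call_dse(x, inst$samples, th)
      expect_true(all(paste(raised$event_id, raised$cell_type) %in% key0))
    }
  }
})

test_that("gene-level overlap and upset patterns partition the calls", {
  deg <- data.frame(gene_id = c("g1", "g2", "g2"),
                    cell_type = c("A", "A", "B"), stringsAsFactors = FALSE)
  dse <- data.frame(event_id = c("e1", "e2"), cell_type = c("A", "C"),
                    gene_id = c("g2", "g3"), stringsAsFactors = FALSE)
  ov <- overlap_summary(deg, dse)
  expect_equal(ov$n_deg, 2)
  expect_equal(ov$n_dsg, 2)
  expect_equal(ov$n_overlap, 1)
  expect_equal(sum(ov$deg_upset$count), 2)   # one gene per exclusive pattern
  expect_equal(ov$deg_upset$pattern[ov$deg_upset$count == 1],
               c("A", "A+B"))
  expect_equal(sum(ov$dse_upset$count), 2)

  disjoint <- overlap_summary(
    data.frame(gene_id = "g9", cell_type = "A"),
    dse)
  expect_equal(disjoint$n_overlap, 0)
})
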
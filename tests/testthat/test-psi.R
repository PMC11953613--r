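test_that("PSI formulas match direct arithmetic", {
  expect_equal(compute_psi_ex(10, 10, 10), 50)
  expect_equal(compute_psi_ex(0, 0, 7), 0)
  expect_equal(compute_psi_ex(30, 10, 5), 80)  # I = 20, 100*20/25
  expect_true(is.na(compute_psi_ex(0, 0, 0)))
  expect_error(compute_psi_ex(-1, 0, 0), "non-negative")

  expect_equal(compute_psi_ir(8, 12, 10), 50)
  expect_equal(compute_psi_ir(0, 0, 15), 0)
  expect_equal(compute_psi_ir(20, 20, 5), 80)
  expect_true(is.na(compute_psi_ir(0, 0, 0)))

  expect_equal(compute_psi_alt(c(V1 = 5, V2 = 5), "V1"), 50)
  expect_equal(compute_psi_alt(c(V1 = 0, V2 = 9), "V1"), 0)
  expect_equal(compute_psi_alt(c(V1 = 6, V2 = 3, V3 = 1), "V2"), 30)
  expect_true(is.na(compute_psi_alt(c(V1 = 0, V2 = 0), "V1")))
  expect_error(compute_psi_alt(c(V1 = 5, V2 = 5), "V9"), "not declared")
})

test_that("variant PSIs of one event always sum to 100", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    counts <- stats::rpois(k, 20)
    names(counts) <- paste0("V", seq_len(k))
    if (sum(counts) == 0) next
    total <- sum(vapply(names(counts),
                        function(v) compute_psi_alt(counts, v), 1))
    expect_equal(total, 100, tolerance = 1e-9)
  }
})

test_that("PSI increases with inclusion evidence at fixed exclusion", {
  psi <- compute_psi_ex(0:50, 0:50, rep(10, 51))
  expect_true(all(diff(psi) > 0))
  psi_ir <- compute_psi_ir(0:50, rep(5, 51), rep(10, 51))
  expect_true(all(diff(psi_ir) > 0))
})

test_that("coverage tiers form an inclusive step function", {
  expect_equal(coverage_tier(0), "N")
  expect_equal(coverage_tier(9), "N")
  expect_equal(coverage_tier(10), "VLOW")
  expect_equal(coverage_tier(14.5), "VLOW")  # floored before comparison
  expect_equal(coverage_tier(15), "LOW")     # boundary is inclusive
  expect_equal(coverage_tier(20), "OK")
  expect_equal(coverage_tier(99), "OK")
  expect_equal(coverage_tier(10000), "SOK")
  r <- match(coverage_tier(0:200), c("N", "VLOW", "LOW", "OK", "SOK"))
  expect_true(all(diff(r) >= 0))
  expect_error(coverage_tier(5, tier_cutoffs = c(10, 9, 20, 100)),
               "increasing")
})

test_that("the IR balance test is an exact two-sided binomial at 0.5", {
  perfect <- ir_balance_test(10, 10)
  expect_equal(perfect$p_value, 1)
  expect_true(perfect$passed)

  skewed <- ir_balance_test(20, 0)
  expect_equal(skewed$p_value, 2 * 0.5^20, tolerance = 1e-12)
  expect_false(skewed$passed)

  for (case in list(c(15, 5), c(12, 3), c(30, 18), c(7, 0))) {
    got <- ir_balance_test(case[1], case[2])
    expect_equal(got$p_value, bf_binom_two_sided(case[1], sum(case)),
                 tolerance = 1e-12)
  }

  none <- ir_balance_test(0, 0)
  expect_true(is.na(none$p_value))
  expect_false(none$passed)
})

test_that("quantify composes formulas, tiers and the balance test", {
  events <- data.frame(
    event_id = c("EX1", "IR1", "ALT1"),
    gene_id = c("g1", "g2", "g3"),
    event_type = c("EX", "IR", "ALTA"),
    coord = c("chr1:1-10", "chr1:20-30", "chr1:40-50"),
    n_variants = c(2L, 2L, 3L), stringsAsFactors = FALSE)
  jx <- data.frame(
    event_id = c(rep("EX1", 3), rep("IR1", 3), rep("ALT1", 3)),
    sample_id = "s1",
    junction_role = c("C1A", "AC2", "C1C2", "EI", "IE", "EE",
                      "V1", "V2", "V3"),
    reads = c(10L, 10L, 10L, 20L, 0L, 30L, 6L, 3L, 1L),
    stringsAsFactors = FALSE)
  psi <- quantify_psi(jx, events)
  expect_equal(psi$psi["EX1", "s1"], 50)
  # IR with strong boundary imbalance: PSI present but balance failed
  expect_equal(psi$psi["IR1", "s1"], 25)
  expect_lt(psi$balance_p["IR1", "s1"], 0.05)
  expect_equal(psi$psi["ALT1", "s1"], 60)
  expect_equal(psi$tier["EX1", "s1"], "OK")   # 10 + 10 = 20 informative
  expect_true(is.na(psi$balance_p["EX1", "s1"]))

  # illegal role for the event class names the row
  bad <- jx
  bad$junction_role[1] <- "EI"
  expect_error(quantify_psi(bad, events), "row 1")

  # absent pairs are missing with tier N
  psi2 <- quantify_psi(jx, events,
                       samples = data.frame(sample_id = c("s1", "s2")))
  expect_true(is.na(psi2$psi["EX1", "s2"]))
  expect_equal(psi2$tier["EX1", "s2"], "N")

  # degenerate input: no junctions at all
  empty <- quantify_psi(jx[0, ], events,
                        samples = data.frame(sample_id = "s1"))
  expect_true(all(is.na(empty$psi)))
})

test_that("event filtering counts covered samples after balance masking", {
  n_s <- 12
  samples <- sprintf("s%02d", seq_len(n_s))
  base <- function(psi_row, tiers) {
    make <- make_psi(matrix(psi_row, 1, n_s,
                            dimnames = list("E001", samples)))
    make$tier[] <- tiers
    make
  }
  # covered at LOW in exactly 10 of 12 samples: kept at min 10
  x <- base(rep(50, n_s), c(rep("LOW", 10), rep("VLOW", 2)))
  expect_equal(nrow(filter_events(x, min_samples = 10)$psi), 1)
  # 9 covered: dropped
  x9 <- base(rep(50, n_s), c(rep("LOW", 9), rep("VLOW", 3)))
  expect_equal(nrow(filter_events(x9, min_samples = 10)$psi), 0)

  # IR event covered in 11 samples, 3 failing balance -> 8 usable, dropped
  psi <- matrix(c(rep(50, 11), NA), 1, n_s,
                dimnames = list("E001", samples))
  x_ir <- make_psi(psi, event_type = "IR")
  x_ir$tier[] <- c(rep("LOW", 11), "N")
  x_ir$balance_p[] <- c(rep(0.5, 8), rep(0.001, 3), NA)
  expect_equal(nrow(filter_events(x_ir, min_samples = 10)$psi), 0)
  expect_equal(nrow(filter_events(x_ir, min_samples = 8)$psi), 1)
  # without the balance gate all 11 count
  expect_equal(nrow(filter_events(x_ir, min_samples = 10,
                                  require_balance = FALSE)$psi), 1)
})
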
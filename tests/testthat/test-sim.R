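small_cfg <- function(...) {
  sim_config(n_cell_types_root = 4, n_cell_types_aerial = 0,
             replicates = 3,
             n_events = c(IR = 30, ALTA = 8, ALTD = 4, EX = 8),
             n_genes = 100, ...)
}

test_that("the generator is deterministic in its seed", {
  a <- simulate_dataset(small_cfg(seed = 9))
  b <- simulate_dataset(small_cfg(seed = 9))
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(small_cfg(seed = 10))
  expect_false(identical(a$junctions$reads, c$junctions$reads))
})

test_that("planting bookkeeping matches the configuration", {
  sim <- simulate_dataset(small_cfg(seed = 2, frac_specific = 0.2))
  planted_ev <- sim$truth[sim$truth$kind == "event" &
                            !is.na(sim$truth$cell_type), ]
  expect_equal(nrow(planted_ev), 10)  # 20% of 50 events
  expect_true(all(planted_ev$cell_type %in% sim$samples$cell_type))
  expect_true(all(planted_ev$direction %in% c("up", "down")))
  # every id appears exactly once in the truth table
  expect_false(anyDuplicated(sim$truth$id[sim$truth$kind == "event"]) > 0)

  none <- simulate_dataset(small_cfg(seed = 2, frac_specific = 0))
  expect_equal(sum(!is.na(none$truth$cell_type)), 0)

  expect_error(
    simulate_dataset(small_cfg(seed = 2, planted_dpsi = 97,
                               baseline_psi_range = c(40, 60))),
    "unachievable")
})

test_that("per-event mean PSI tracks its baseline at high depth", {
  cfg <- sim_config(n_cell_types_root = 4, n_cell_types_aerial = 0,
                    replicates = 3,
                    n_events = c(IR = 130, ALTA = 35, ALTD = 15, EX = 20),
                    n_genes = 50, frac_specific = 0, bb_rho = 1e-4,
                    depth_mean = 1000, seed = 13)
  sim <- simulate_dataset(cfg)
  psi <- quantify_psi(sim$junctions, sim$events, samples = sim$samples)
  est <- rowMeans(psi$psi, na.rm = TRUE)
  expect_gte(mean(abs(est - sim$baseline_psi) <= 2), 0.95)
})

test_that("simulated IR junctions are balanced by construction", {
  sim <- simulate_dataset(small_cfg(seed = 4))
  ir <- sim$events$event_id[sim$events$event_type == "IR"]
  jx <- sim$junctions[sim$junctions$event_id %in% ir, ]
  ei <- jx$reads[jx$junction_role == "EI"]
  ie <- jx$reads[jx$junction_role == "IE"]
  res <- ir_balance_test(ei, ie)
  informative <- ei + ie > 0
  expect_gte(mean(res$passed[informative]), 0.93)
})

test_that("recovery metrics follow confusion-matrix arithmetic", {
  truth <- data.frame(
    id = sprintf("E%03d", 1:300), kind = "event",
    cell_type = c(rep("A", 200), rep(NA, 100)),
    direction = c(rep("up", 200), rep(NA, 100)),
    effect_size = c(rep(40, 200), rep(NA, 100)),
    stringsAsFactors = FALSE)
  exact <- data.frame(event_id = sprintf("E%03d", 1:200), cell_type = "A",
                      direction = "up", stringsAsFactors = FALSE)
  r <- truth_recovery(exact, truth, "event")
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$direction_accuracy, 1)

  r0 <- truth_recovery(exact[0, ], truth, "event")
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  half <- rbind(exact[1:100, ],
                data.frame(event_id = "E250", cell_type = "A",
                           direction = "up", stringsAsFactors = FALSE))
  rh <- truth_recovery(half, truth, "event")
  expect_equal(rh$recall, 0.5)
  expect_equal(rh$precision, 100 / 101)
})
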
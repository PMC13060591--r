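mem_default <- membrane_params()

test_that("zero field leaves the membrane at its resting magnitude", {
  tis <- matrix(TRUE, 10, 10)
  tis[1:2, ] <- FALSE
  vm <- induced_vm(matrix(0, 10, 10), mem_default, tis)
  expect_equal(vm$vm[tis], rep(70, sum(tis)))
  expect_equal(vm$vm[!tis], rep(0, sum(!tis)))
})

test_that("induced depolarization is linear in the field", {
  tis <- matrix(TRUE, 8, 8)
  e <- matrix(runif(64, 0, 2e4), 8, 8)
  v1 <- induced_vm(e, mem_default, tis)
  v2 <- induced_vm(2 * e, mem_default, tis)
  expect_equal(v2$dvm, 2 * v1$dvm, tolerance = 1e-12)
})

test_that("the poration threshold inverts to the closed-form field level", {
  # |Vm| = 70 + 1.5 E r reaches 200 mV exactly at E = 130 mV / 7.5 um
  por <- poration_map(induced_vm(matrix(0, 4, 4), mem_default,
                                 matrix(TRUE, 4, 4)), mem_default)
  expected <- 130e-3 / (1.5 * 5e-6)
  expect_equal(por$threshold_field, expected, tolerance = 1e-12)
  expect_equal(por$threshold_field, 1.733e4, tolerance = 1e-3)

  # a uniform field just below / above the level
  tis <- matrix(TRUE, 6, 6)
  below <- poration_map(induced_vm(matrix(expected * 0.999, 6, 6),
                                   mem_default, tis), mem_default)
  above <- poration_map(induced_vm(matrix(expected * 1.001, 6, 6),
                                   mem_default, tis), mem_default)
  expect_equal(sum(below$porated), 0L)
  expect_equal(sum(above$porated), 36L)

  # the threshold comparison itself is inclusive: |Vm| exactly 200 porates
  vm_at <- induced_vm(matrix(0, 6, 6), mem_default, tis)
  vm_at$vm[] <- 200
  expect_equal(sum(poration_map(vm_at, mem_default, tis)$porated), 36L)
})

test_that("poration never leaves the tissue mask and grows with voltage", {
  cfg <- default_config()
  counts <- vapply(seq(0, 400, by = 100), function(v) {
    cfg$protocol$voltage <- v
    rec <- run_pipeline(cfg)
    rec$summary$n_porated
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
})

test_that("poration grows with the coupling radius", {
  tis <- matrix(TRUE, 20, 20)
  e <- matrix(seq(0, 3e4, length.out = 400), 20, 20)
  n_por <- vapply(c(2, 5, 8), function(r) {
    mem <- membrane_params(coupling_radius = r)
    sum(poration_map(induced_vm(e, mem, tis), mem)$porated)
  }, numeric(1))
  expect_true(all(diff(n_por) >= 0))
})

test_that("action potentials are capped by the refractory period", {
  tis <- matrix(TRUE, 10, 10)
  e <- matrix(0, 10, 10)
  e[6:10, ] <- 1e4          # depolarizes by 75 mV, well past threshold
  vm <- induced_vm(e, mem_default, tis)
  prot <- pulse_protocol(voltage = 200, pulse_duration = 10, n_pulses = 10)
  counts <- ap_events(vm, prot, mem_default)
  # at most floor(10 ms / 1 ms) = 10 APs per pulse, 10 pulses
  expect_lte(max(counts), 10 * 10)
  expect_equal(max(counts[6:10, ]), 100L)
  # subthreshold cells fire nothing
  expect_equal(max(counts[1:5, ]), 0L)
  # refractory equal to the pulse duration: exactly 1 AP per pulse
  mem_slow <- membrane_params(refractory = 10)
  expect_equal(max(ap_events(vm, prot, mem_slow)), 10L)
})

test_that("transfection draws respect degenerate parameter settings", {
  mask <- matrix(FALSE, 30, 30)
  mask[10:25, 5:20] <- TRUE
  por <- as_poration(mask)
  all_on <- transfection_map(por, mean_eff = 1, sd_eff = 0, seed = 1)
  expect_identical(all_on$realized, mask)
  all_off <- transfection_map(por, mean_eff = 0, sd_eff = 0, seed = 1)
  expect_false(any(all_off$realized))
})

test_that("realized transfection stays within the porated set and is seeded", {
  mask <- matrix(runif(2500) < 0.4, 50, 50)
  por <- as_poration(mask)
  t1 <- transfection_map(por, 0.6, 0.15, seed = 11)
  t2 <- transfection_map(por, 0.6, 0.15, seed = 11)
  expect_identical(t1$realized, t2$realized)
  expect_identical(t1$probability, t2$probability)
  expect_true(all(!t1$realized[!mask]))
  expect_true(all(t1$probability[!mask] == 0))
  t3 <- transfection_map(por, 0.6, 0.15, seed = 12)
  expect_false(identical(t1$realized, t3$realized))
})

test_that("realized fraction matches the binomial expectation at scale", {
  por <- as_poration(matrix(TRUE, 100, 100))       # 10,000 porated cells
  tr <- transfection_map(por, mean_eff = 0.6, sd_eff = 0.1, seed = 2)
  frac <- sum(tr$realized) / 1e4
  se <- sqrt(0.6 * 0.4 / 1e4)
  expect_lt(abs(frac - 0.6), 3 * se)
})

test_that("simulation summary agrees with brute-force mask counting", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:20, 5:20] <- TRUE
  tis <- matrix(TRUE, 40, 40)
  por <- as_poration(mask)
  tr <- transfection_map(por, 0.6, 0.1, seed = 3)
  s <- summarize_simulation(por, tr, tis)
  expect_equal(s$n_porated, sum(mask))
  expect_equal(s$porated_fraction, sum(mask) / 1600)
  expect_equal(s$n_realized, sum(tr$realized))
  expect_equal(s$realized_fraction, sum(tr$realized) / sum(mask))

  # empty poration: all fractions zero, no division error
  empty <- as_poration(matrix(FALSE, 40, 40))
  s0 <- summarize_simulation(empty, transfection_map(empty, 0.6, 0.1, 1), tis)
  expect_equal(s0$n_porated, 0L)
  expect_equal(s0$porated_fraction, 0)
  expect_equal(s0$realized_fraction, 0)
})
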
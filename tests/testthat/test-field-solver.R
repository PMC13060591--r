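test_that("uniform conductivity reproduces the parallel-plate closed form", {
  n <- 40
  g <- as_cond_grid(matrix(0.5, n, n), spacing = 2)
  bc <- boundary_conditions(200, anode_rows = n, cathode_rows = 1)
  phi <- solve_potential(g, bc)
  # potential linear in row index
  expect_equal(phi$phi[1, ], rep(0, n))
  expect_equal(phi$phi[n, ], rep(200, n))
  rows <- matrix(seq_len(n), n, n)
  expect_equal(phi$phi, 200 * (rows - 1) / (n - 1), tolerance = 1e-10)
  # |E| = V / electrode separation everywhere, within 1%
  fld <- field_magnitude(phi)
  expected <- 200 / ((n - 1) * 2e-6)
  expect_true(all(abs(fld$values[2:(n - 1), ] - expected) / expected < 0.01))
})

test_that("zero applied voltage gives zero potential and field", {
  g <- as_cond_grid(matrix(1, 20, 20))
  phi <- solve_potential(g, boundary_conditions(0, anode_rows = 20,
                                                cathode_rows = 1))
  expect_equal(max(abs(phi$phi)), 0)
  expect_equal(max(field_magnitude(phi)$values), 0)
})

test_that("two-layer slab matches the 1-D resistor-divider closed form", {
  n <- 100
  sm <- matrix(1, n, 8)
  sm[(n / 2 + 1):n, ] <- 0.5
  phi <- solve_potential(as_cond_grid(sm),
                         boundary_conditions(200, anode_rows = n,
                                             cathode_rows = 1))
  # closed form: equal thicknesses, interface potential V * R1 / (R1 + R2)
  closed <- 200 * (1 / 1) / (1 / 1 + 1 / 0.5)
  interface <- (phi$phi[n / 2, 4] + phi$phi[n / 2 + 1, 4]) / 2
  expect_lt(abs(interface - closed) / closed, 0.01)
  # full profile against an independent dense 1-D chain solve
  oracle <- chain_potential(sm[, 1], 200)
  expect_equal(phi$phi[, 4], oracle, tolerance = 1e-8)
})

test_that("solved potential obeys the discrete maximum principle", {
  mg <- build_geometry(chip_spec(), grid_spec(), 0.65, seed = 3)
  phi <- solve_potential(conductivity_map(mg),
                         boundary_conditions(200, anode_rows = 100,
                                             cathode_rows = 1))
  expect_gte(min(phi$phi), 0 - 1e-6)
  expect_lte(max(phi$phi), 200 + 1e-6)
  # extrema attained on the electrode rows
  expect_equal(min(phi$phi), min(phi$phi[1, ]))
  expect_equal(max(phi$phi), max(phi$phi[100, ]))
})

test_that("solution respects a left-right mirror symmetry of the geometry", {
  n <- 30
  sm <- matrix(0.5, n, n)
  sm[10:15, 4:6] <- 1e-10          # an insulating block off-centre
  bc <- boundary_conditions(100, anode_rows = n, cathode_rows = 1)
  phi <- solve_potential(as_cond_grid(sm), bc)
  phi_mirror <- solve_potential(as_cond_grid(sm[, n:1]), bc)
  expect_equal(phi$phi, phi_mirror$phi[, n:1], tolerance = 1e-6)
})

test_that("field magnitude differentiates linear and quadratic potentials", {
  n <- 25
  rows <- matrix(seq_len(n), n, n)
  spacing <- 2  # um
  # linear ramp a * row -> uniform |E| = a / spacing
  a <- 3
  f1 <- field_magnitude(a * rows, spacing = spacing)
  expect_equal(f1$values, matrix(a / (spacing * 1e-6), n, n),
               tolerance = 1e-10)
  # constant potential -> zero field
  expect_equal(max(field_magnitude(matrix(5, n, n), spacing = 1)$values), 0)
  # quadratic c * row^2 -> |E| = 2 c row / spacing at interior rows
  cc <- 0.1
  f2 <- field_magnitude(cc * rows^2, spacing = spacing)
  interior <- 2:(n - 1)
  expect_equal(f2$values[interior, 3],
               2 * cc * interior / (spacing * 1e-6), tolerance = 1e-10)
})

test_that("Gaussian smoothing honours its contracts", {
  m <- matrix(runif(30 * 30), 30, 30)
  # sigma = 0 is the identity
  expect_identical(smooth_field(m, 0), m)
  # constant fields are fixed points
  const <- matrix(1e4, 20, 20)
  expect_equal(smooth_field(const, 1.5), const, tolerance = 1e-12)
  # impulse response equals the dense-convolution oracle
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  expect_equal(smooth_field(imp, 1), dense_gauss_conv(imp, 1),
               tolerance = 1e-12)
  # and near an edge, where the reflective boundary matters
  imp2 <- matrix(0, 15, 15)
  imp2[2, 3] <- 1
  expect_equal(smooth_field(imp2, 1.5), dense_gauss_conv(imp2, 1.5),
               tolerance = 1e-12)
  expect_error(smooth_field(m, -1), "sigma")
})

test_that("closing all nanochannels suppresses the tissue-side field", {
  grid <- grid_spec()
  bc <- boundary_conditions(200, anode_rows = 100, cathode_rows = 1)
  max_tissue_field <- function(open_fraction) {
    mg <- build_geometry(chip_spec(), grid, open_fraction, seed = 5)
    sm <- smooth_field(field_magnitude(solve_potential(conductivity_map(mg),
                                                       bc)), 1)
    max(sm$values[tissue_domain(mg, guard = 5)])
  }
  expect_lt(max_tissue_field(0), 0.01 * max_tissue_field(0.65))
})

test_that("the maximum tissue field sits at an open-channel mouth", {
  grid <- grid_spec()
  mg <- build_geometry(chip_spec(), grid, 0.65, seed = 1)
  sm <- smooth_field(field_magnitude(
    solve_potential(conductivity_map(mg),
                    boundary_conditions(200, anode_rows = 100,
                                        cathode_rows = 1))), 1)
  dom <- tissue_domain(mg, guard = 5)
  v <- sm$values
  v[!dom] <- -Inf
  mx <- arrayInd(which.max(v), dim(v))
  open_cols <- vapply(mg$channel_cols[mg$open_channels], mean, numeric(1))
  expect_lte(min(abs(mx[2] - open_cols)), 3)
})
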
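test_that("maximum projection takes the per-pixel max across planes", {
  one <- array(runif(25), dim = c(5, 5, 1))
  expect_equal(max_project(one), one[, , 1])

  a <- matrix(0, 6, 6); a[2, 2] <- 10
  b <- matrix(0, 6, 6); b[5, 5] <- 7
  proj <- max_project(array(c(a, b), dim = c(6, 6, 2)))
  expect_equal(proj[2, 2], 10)
  expect_equal(proj[5, 5], 7)
  expect_equal(sum(proj > 0), 2)

  st <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3))
  oracle <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) oracle[i, j] <- max(st[i, j, ])
  expect_equal(max_project(st), oracle)
})

test_that("binarize covers manual, reference and Otsu thresholds", {
  img <- matrix(runif(400, 0, 10), 20, 20)
  expect_false(any(binarize(img, value = 11)))
  expect_true(all(binarize(img, value = 0)))

  # bimodal image: Otsu recovers the ground-truth foreground within 1%
  truth <- matrix(FALSE, 50, 50)
  truth[10:40, 10:40] <- TRUE
  img2 <- matrix(rnorm(2500, 20, 3), 50, 50)
  img2[truth] <- rnorm(sum(truth), 200, 10)
  auto <- binarize(img2)
  expect_lt(mean(auto != truth), 0.01)

  # negative-control rule: mean + 3 SD of the reference
  ref <- matrix(rnorm(2500, 20, 3), 50, 50)
  m <- binarize(img2, reference = ref)
  expect_equal(attr(m, "threshold"), mean(ref) + 3 * sd(as.vector(ref)))
})

test_that("component labelling is 8-connected with speckle suppression", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE; m[5, 5] <- TRUE
  # a diagonal chain is one 8-connected component
  lab <- label_components(m, min_size = 1)
  expect_equal(attr(lab, "n"), 1L)
  # but falls below the default 4-px floor only if shorter
  lab2 <- label_components(m, min_size = 4)
  expect_equal(attr(lab2, "n"), 1L)
  m[7, 7] <- TRUE                      # isolated single pixel
  lab3 <- label_components(m, min_size = 4)
  expect_equal(attr(lab3, "n"), 1L)    # speckle suppressed
  lab4 <- label_components(m, min_size = 1)
  expect_equal(attr(lab4, "n"), 2L)
})

test_that("having/not-having myelination partitions the axon population", {
  b <- gen_nerve_image(n_axons = 50, n_myelinated = 20, n_vessels = 12,
                       seed = 21)
  masks <- gen_masks(b)
  res <- myelination_fraction(masks$NF, masks$MBP)
  expect_equal(res$n_axons, 50L)
  expect_equal(res$n_myelinated, 20L)
  expect_equal(res$pct_myelinated, 40)
  expect_equal(res$pct_unmyelinated, 60)
  expect_equal(res$pct_myelinated + res$pct_unmyelinated, 100)
})

test_that("myelination degenerate cases behave as stated", {
  nf <- matrix(FALSE, 20, 20)
  nf[5:8, 5:8] <- TRUE
  # MBP identical to NF: fully myelinated
  full <- myelination_fraction(nf, nf)
  expect_equal(full$pct_myelinated, 100)
  # disjoint masks: nothing myelinated
  mbp <- matrix(FALSE, 20, 20)
  mbp[14:17, 14:17] <- TRUE
  none <- myelination_fraction(nf, mbp)
  expect_equal(none$pct_myelinated, 0)
  expect_equal(none$pct_unmyelinated, 100)
  # zero axons: flagged nulls, not a division error
  zero <- myelination_fraction(matrix(FALSE, 10, 10), mbp[1:10, 1:10])
  expect_true(zero$zero_axons)
  expect_true(is.na(zero$pct_myelinated))
  expect_equal(zero$n_axons, 0L)
})

test_that("axon density counts centroids inside the ROI per mm^2", {
  # ten 3x3 axons inside a 0.1 mm^2 ROI at 1 um/px
  nf <- matrix(FALSE, 350, 350)
  for (k in 1:10) nf[k * 30 + (1:3), 100 + (1:3)] <- TRUE
  roi <- square_roi(0.1)
  d <- axon_density(nf, roi, pixel_size = 1)
  expect_equal(d$axon_count, 10L)
  expect_equal(d$axons_per_mm2, 100, tolerance = 1e-9)
  # empty mask
  expect_equal(axon_density(matrix(FALSE, 50, 50), square_roi(0.001),
                            pixel_size = 1)$axons_per_mm2, 0)
  expect_error(axon_density(nf, list(x = c(0, 1, 2), y = c(0, 0, 0)),
                            pixel_size = 1), "degenerate")
})

test_that("capillaries require nucleus confirmation", {
  cd31 <- matrix(FALSE, 60, 60)
  dapi <- matrix(FALSE, 60, 60)
  cd31[10:13, 10:13] <- TRUE        # vessel with nucleus
  dapi[12:14, 12:14] <- TRUE
  cd31[40:43, 40:43] <- TRUE        # vessel without nucleus
  roi <- square_roi(60 * 60 * 1e-6) # whole field, 1 um/px
  d <- capillary_density(cd31, dapi, roi, pixel_size = 1)
  expect_equal(d$capillary_count, 1L)
  expect_equal(d$capillaries_per_mm2, 1 / (3600 * 1e-6), tolerance = 1e-9)
  # no overlap at all
  d0 <- capillary_density(cd31, matrix(FALSE, 60, 60), roi, pixel_size = 1)
  expect_equal(d0$capillary_count, 0L)
})

test_that("capillary density recovers generator ground truth", {
  b <- gen_nerve_image(n_axons = 10, n_myelinated = 5, n_vessels = 8,
                       n_extra_nuclei = 20, seed = 31)
  masks <- gen_masks(b)
  roi <- square_roi(320 * 320 * 1e-6)
  d <- capillary_density(masks$CD31, masks$DAPI, roi, pixel_size = 1)
  expect_equal(d$capillary_count, 8L)
})

test_that("coassociation percentages follow the chosen denominator", {
  a <- matrix(FALSE, 30, 30)
  a[5:8, 5:8] <- TRUE
  for (den in c("A", "B", "union")) {
    expect_equal(coassociation(a, a, denominator = den)$coassociation_pct,
                 100)
  }
  b <- matrix(FALSE, 30, 30)
  b[20:23, 20:23] <- TRUE
  expect_equal(coassociation(a, b)$coassociation_pct, 0)
  # zero denominator: flagged, not an error
  z <- coassociation(matrix(FALSE, 10, 10), b[1:10, 1:10])
  expect_true(z$zero_denominator)
  expect_true(is.na(z$coassociation_pct))
})

test_that("coassociation recovers the generator's co-labelled fraction", {
  b <- gen_nerve_image(n_axons = 5, n_myelinated = 0, n_vessels = 10,
                       gfp_vessel_fraction = 0.3, n_gfp_only = 7,
                       n_extra_nuclei = 10, seed = 41)
  masks <- gen_masks(b)
  res <- coassociation(masks$GFP, masks$CD31, dapi = masks$DAPI,
                       denominator = "A")
  expect_equal(res$n_denominator, 10L)        # 3 co-labelled + 7 GFP-only
  expect_equal(res$n_double_positive, 3L)
  expect_equal(res$coassociation_pct, 30)
})

test_that("densities scale inversely with the squared pixel size", {
  b <- gen_nerve_image(n_axons = 12, n_myelinated = 6, n_vessels = 4,
                       seed = 51)
  masks <- gen_masks(b)
  roi1 <- square_roi(320 * 320 * 1e-6)
  d1 <- axon_density(masks$NF, roi1, pixel_size = 1)
  roi2 <- square_roi(640 * 640 * 1e-6)   # same pixels, 2 um/px
  d2 <- axon_density(masks$NF, roi2, pixel_size = 2)
  expect_equal(d2$axon_count, d1$axon_count)
  expect_equal(d2$axons_per_mm2, d1$axons_per_mm2 / 4, tolerance = 1e-9)
})

test_that("quantifications are invariant under joint translation", {
  b <- gen_nerve_image(n_axons = 8, n_myelinated = 4, n_vessels = 3,
                       n_extra_nuclei = 5, shape = c(220L, 220L),
                       margin = 30, seed = 61)
  masks <- gen_masks(b)
  shift <- function(m, d) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <-
      m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  d <- 15
  roi <- square_roi(0.02, x0 = 10, y0 = 10)
  roi_shift <- square_roi(0.02, x0 = 10 + d, y0 = 10 + d)
  a1 <- axon_density(masks$NF, roi, pixel_size = 1)
  a2 <- axon_density(shift(masks$NF, d), roi_shift, pixel_size = 1)
  expect_equal(a1$axon_count, a2$axon_count)
  m1 <- myelination_fraction(masks$NF, masks$MBP)
  m2 <- myelination_fraction(shift(masks$NF, d), shift(masks$MBP, d))
  expect_equal(m1$pct_myelinated, m2$pct_myelinated)
})
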
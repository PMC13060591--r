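## Fluorescence quantification: projection, thresholding, "having /
## not-having" myelination percentages, axon & capillary densities,
## marker coassociation.
##
## Coordinate convention: images are row-major matrices; physical
## coordinates are x = (col - 0.5) * pixel_size, y = (row - 0.5) *
## pixel_size, in micrometres. ROI polygons are given in the same
## micrometre coordinates.

#' Multichannel image bundle
#'
#' Named intensity channels (any subset of NF, MBP, CD31, DAPI, GFP; other
#' names are allowed) sharing one shape, with the pixel size and optional
#' named ROI polygons.
#'
#' @param channels Named list of 2-D matrices or 3-D z-stacks.
#' @param pixel_size Pixel size (um/pixel), > 0.
#' @param rois Named list of ROI polygons (each a 2-column x/y matrix or a
#'   `list(x =, y =)`, um).
#' @return An object of class `image_bundle`.
#' @export
image_bundle <- function(channels, pixel_size, rois = list()) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop_input("'channels' must be a non-empty named list")
  }
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-12)
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop_input("all channels must share the same x/y shape")
  }
  structure(list(channels = channels, pixel_size = pixel_size, rois = rois),
            class = "image_bundle")
}

#' Maximum intensity projection of a z-stack
#'
#' Per-pixel maximum across z-planes; a single-plane (2-D) input is
#' returned unchanged.
#'
#' @param stack 3-D array (rows x cols x z) or 2-D matrix.
#' @return 2-D matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || d[3] < 1) {
    stop_input("input error: expected a matrix or a rows x cols x z array")
  }
  out <- stack[, , 1]
  if (d[3] > 1) {
    for (k in 2:d[3]) out <- pmax(out, stack[, , k])
  }
  out
}

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' image's dynamic range; returns the intensity at the chosen bin edge.
#'
#' @param img Numeric matrix.
#' @param n_bins Histogram bins (default 256).
#' @return Threshold intensity.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- hist(v, breaks = edges, plot = FALSE)$counts
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Binarize an intensity image
#'
#' Background removal by thresholding: manual (a stated `value`, the
#' convention when a negative control was inspected by eye), automatic
#' from a negative-control `reference` image (mean + k.SD of the
#' reference, k = 3 by default), or Otsu's method when neither is given.
#' The mask is inclusive (`img >= threshold`).
#'
#' @param img Numeric matrix.
#' @param value Manual threshold; must lie within the image's dynamic
#'   range when supplied.
#' @param reference Negative-control image for the mean + k.SD rule.
#' @param k SD multiplier for the reference rule (default 3).
#' @return Logical mask with attribute `threshold`.
#' @export
binarize <- function(img, value = NULL, reference = NULL, k = 3) {
  if (!is.null(value)) {
    check_scalar_number(value, "value")
    thr <- value
  } else if (!is.null(reference)) {
    thr <- mean(reference) + k * stats::sd(as.vector(reference))
  } else {
    thr <- otsu_threshold(img)
  }
  mask <- img >= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Label connected components of a binary mask
#'
#' 8-connected component labelling with suppression of speckle objects
#' below `min_size` pixels (default 4).
#'
#' @param mask Logical matrix.
#' @param min_size Minimum object size in pixels.
#' @return Integer label matrix (0 = background) with attribute `n`
#'   (number of retained components, labelled 1..n).
#' @export
label_components <- function(mask, min_size = 4L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask)
  seen <- matrix(FALSE, nr, nc)
  for (s in todo) {
    if (seen[s]) next
    nxt <- nxt + 1L
    comp <- integer(0)
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      comp <- c(comp, frontier)
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr
          cc <- c + dc
          ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
          if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & !seen[nb]]
      seen[nb] <- TRUE
      frontier <- nb
    }
    lab[comp] <- nxt
  }
  if (nxt > 0 && min_size > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = nxt)
    keep <- which(sizes >= min_size)
    remap <- integer(nxt)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    nxt <- length(keep)
  }
  attr(lab, "n") <- nxt
  lab
}

component_centroids <- function(lab) {
  n <- attr(lab, "n")
  if (n == 0) {
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      size = integer()))
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  c <- (idx - 1L) %/% nrow(lab) + 1L
  data.frame(id = seq_len(n),
             row = as.vector(tapply(r, ids, mean)),
             col = as.vector(tapply(c, ids, mean)),
             size = as.vector(tabulate(ids, nbins = n)))
}

overlap_counts <- function(lab, other_mask) {
  n <- attr(lab, "n")
  if (n == 0) return(integer(0))
  tabulate(lab[other_mask], nbins = n)
}

as_roi <- function(roi) {
  if (is.list(roi) && !is.null(roi$x)) {
    xy <- cbind(roi$x, roi$y)
  } else {
    xy <- as.matrix(roi)
  }
  if (ncol(xy) != 2 || nrow(xy) < 3) {
    stop_input("input error: an ROI polygon needs >= 3 x/y vertices")
  }
  xy
}

roi_area_mm2 <- function(roi) {
  xy <- as_roi(roi)
  a <- abs(pracma::polyarea(xy[, 1], xy[, 2])) / 1e6  # um^2 -> mm^2
  if (a <= 0) stop_input("input error: degenerate ROI polygon (zero area)")
  a
}

centroid_in_roi <- function(cent, roi, pixel_size) {
  xy <- as_roi(roi)
  if (nrow(cent) == 0) return(logical(0))
  x <- (cent$col - 0.5) * pixel_size
  y <- (cent$row - 0.5) * pixel_size
  pracma::inpolygon(x, y, xy[, 1], xy[, 2], boundary = TRUE)
}

#' Myelination percentages from NF and MBP masks ("having / not-having")
#'
#' Connected components of the neurofilament (NF) mask are axons; an axon
#' "has" myelin when its overlap with the myelin basic protein (MBP) mask
#' reaches `min_overlap_px` pixels (default 1; an overlap-fraction rule is
#' selectable). Percentages are over the axon count and the myelinated /
#' unmyelinated pair sums to 100.
#'
#' @param nf_mask,mbp_mask Logical masks of equal shape.
#' @param min_overlap_px Pixel-overlap rule threshold (default 1).
#' @param overlap_rule `"pixels"` (default) or `"fraction"` (overlap of at
#'   least `min_overlap_frac` of the axon's area).
#' @param min_overlap_frac Fraction threshold for the fraction rule.
#' @param min_size Minimum axon object size in pixels.
#' @return List: `pct_myelinated`, `pct_unmyelinated` (both `NA` with
#'   `zero_axons = TRUE` when no axons are found), `n_axons`,
#'   `n_myelinated`.
#' @export
myelination_fraction <- function(nf_mask, mbp_mask, min_overlap_px = 1L,
                                 overlap_rule = c("pixels", "fraction"),
                                 min_overlap_frac = 0.1, min_size = 4L) {
  overlap_rule <- match.arg(overlap_rule)
  if (!all(dim(nf_mask) == dim(mbp_mask))) {
    stop_input("NF and MBP masks must share the same shape")
  }
  lab <- label_components(nf_mask, min_size = min_size)
  n_ax <- attr(lab, "n")
  if (n_ax == 0) {
    return(list(pct_myelinated = NA_real_, pct_unmyelinated = NA_real_,
                n_axons = 0L, n_myelinated = 0L, zero_axons = TRUE))
  }
  ov <- overlap_counts(lab, mbp_mask)
  my <- if (overlap_rule == "pixels") {
    ov >= min_overlap_px
  } else {
    sizes <- tabulate(lab[lab > 0L], nbins = n_ax)
    ov / sizes >= min_overlap_frac
  }
  n_my <- sum(my)
  list(pct_myelinated = 100 * n_my / n_ax,
       pct_unmyelinated = 100 * (n_ax - n_my) / n_ax,
       n_axons = n_ax, n_myelinated = n_my, zero_axons = FALSE)
}

#' Axon density within a fascicle ROI
#'
#' Counts NF components whose centroid falls inside the ROI polygon
#' (centroid-in-ROI prevents double counting across fascicles) and
#' divides by the ROI area in mm^2.
#'
#' @param nf_mask Logical axon mask.
#' @param roi ROI polygon (um coordinates).
#' @param pixel_size Pixel size (um/pixel).
#' @param min_size Minimum axon object size in pixels.
#' @return List: `axons_per_mm2`, `axon_count`, `roi_area_mm2`.
#' @export
axon_density <- function(nf_mask, roi, pixel_size, min_size = 4L) {
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-12)
  area <- roi_area_mm2(roi)
  lab <- label_components(nf_mask, min_size = min_size)
  cent <- component_centroids(lab)
  k <- sum(centroid_in_roi(cent, roi, pixel_size))
  list(axons_per_mm2 = k / area, axon_count = as.integer(k),
       roi_area_mm2 = area)
}

#' Capillary density from CD31 and DAPI masks
#'
#' CD31 components are retained only when they overlap the DAPI mask by
#' at least `min_overlap_px` pixels (nucleus confirmation); retained
#' components with centroid inside the ROI are counted per mm^2.
#'
#' @param cd31_mask,dapi_mask Logical masks of equal shape.
#' @param roi ROI polygon (um coordinates).
#' @param pixel_size Pixel size (um/pixel).
#' @param min_overlap_px DAPI-overlap requirement (default 1 px).
#' @param min_size Minimum object size in pixels.
#' @return List: `capillaries_per_mm2`, `capillary_count`, `roi_area_mm2`.
#' @export
capillary_density <- function(cd31_mask, dapi_mask, roi, pixel_size,
                              min_overlap_px = 1L, min_size = 4L) {
  if (!all(dim(cd31_mask) == dim(dapi_mask))) {
    stop_input("CD31 and DAPI masks must share the same shape")
  }
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-12)
  area <- roi_area_mm2(roi)
  lab <- label_components(cd31_mask, min_size = min_size)
  cent <- component_centroids(lab)
  keep <- overlap_counts(lab, dapi_mask) >= min_overlap_px
  inside <- centroid_in_roi(cent, roi, pixel_size)
  k <- sum(keep & inside)
  list(capillaries_per_mm2 = k / area, capillary_count = as.integer(k),
       roi_area_mm2 = area)
}

#' Marker coassociation percentage
#'
#' Components of marker A that also carry marker B signal (overlap of at
#' least `min_overlap_px` pixels), optionally DAPI-confirmed, expressed
#' as a percentage of the chosen denominator's component count. The
#' denominator choice is recorded in the output since different choices
#' give different percentages.
#'
#' @param marker_a,marker_b Logical masks of equal shape (e.g. the GFP
#'   lineage reporter and CD31).
#' @param dapi Optional DAPI mask; when given, double-positive components
#'   must also overlap it.
#' @param denominator `"A"` (default: lineage-marker components), `"B"`,
#'   or `"union"` (components of the A-or-B mask).
#' @param min_overlap_px Overlap requirement (default 1 px).
#' @param min_size Minimum object size in pixels.
#' @return List: `coassociation_pct` (`NA` with `zero_denominator = TRUE`
#'   when the denominator has no components), `n_double_positive`,
#'   `n_denominator`, `denominator`.
#' @export
coassociation <- function(marker_a, marker_b, dapi = NULL,
                          denominator = c("A", "B", "union"),
                          min_overlap_px = 1L, min_size = 4L) {
  denominator <- match.arg(denominator)
  if (!all(dim(marker_a) == dim(marker_b))) {
    stop_input("marker masks must share the same shape")
  }
  lab_a <- label_components(marker_a, min_size = min_size)
  pos_b <- overlap_counts(lab_a, marker_b) >= min_overlap_px
  pos_d <- if (is.null(dapi)) rep(TRUE, attr(lab_a, "n")) else
    overlap_counts(lab_a, dapi) >= 1L
  n_double <- sum(pos_b & pos_d)
  n_den <- switch(denominator,
                  A = attr(lab_a, "n"),
                  B = attr(label_components(marker_b, min_size = min_size), "n"),
                  union = attr(label_components(marker_a | marker_b,
                                                min_size = min_size), "n"))
  if (n_den == 0) {
    return(list(coassociation_pct = NA_real_, n_double_positive = 0L,
                n_denominator = 0L, denominator = denominator,
                zero_denominator = TRUE))
  }
  list(coassociation_pct = 100 * n_double / n_den,
       n_double_positive = as.integer(n_double),
       n_denominator = as.integer(n_den),
       denominator = denominator, zero_denominator = FALSE)
}

#' Read a multichannel image bundle from single-channel TIFF files
#'
#' @param paths Named character vector of TIFF paths (names = channels).
#' @param pixel_size Pixel size (um/pixel).
#' @return An [image_bundle()].
#' @export
read_image_bundle <- function(paths, pixel_size) {
  chans <- lapply(paths, function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  image_bundle(chans, pixel_size = pixel_size)
}

#' Write an image bundle as single-channel TIFF files
#'
#' Intensities are rescaled to `[0, 1]` per channel for storage; the
#' scale factor is returned invisibly.
#'
#' @param bundle An [image_bundle()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of per-channel scale factors.
#' @export
write_image_bundle <- function(bundle, dir, prefix = "channel") {
  stopifnot(inherits(bundle, "image_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- lapply(names(bundle$channels), function(nm) {
    ch <- max_project(bundle$channels[[nm]])
    s <- max(ch, 1e-12)
    tiff::writeTIFF(ch / s, file.path(dir, sprintf("%s_%s.tiff", prefix, nm)))
    s
  })
  names(scales) <- names(bundle$channels)
  invisible(scales)
}
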
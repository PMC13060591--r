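## Discrete 2-D material model of the TNT chip / nerve cross-section.
##
## The cross-section is oriented with row 1 at the top (plasmid reservoir,
## cathode side) and the last row at the bottom (deep tissue, anode side):
## the positive electrode sits underneath the nerve, so anionic DNA
## migrates downward into the tissue.

.materials <- c(SILICON = 1L, LUMEN_OPEN = 2L, LUMEN_BLOCKED = 3L,
                RESERVOIR = 4L, TISSUE = 5L)

#' Material label codes used on the chip cross-section grid
#'
#' Integer codes for the five materials a grid cell can carry:
#' `SILICON` (chip body, silicon-nitride coated, insulating),
#' `LUMEN_OPEN` / `LUMEN_BLOCKED` (nanochannel lumen, conducting when open),
#' `RESERVOIR` (plasmid/saline reservoir above the chip) and `TISSUE`
#' (sciatic nerve below the chip).
#'
#' @return Named integer vector of length 5.
#' @export
material_labels <- function() .materials

#' Chip geometry specification
#'
#' Physical dimensions of the TNT chip, in micrometres. Defaults are the
#' simulated device: 150-um wide / 185-um deep microchannels, 0.9-um wide /
#' 11-um deep nanochannels, conical nanostructures with a 4-um base and
#' 4.5-um height, on a 200-um silicon wafer.
#'
#' @param microchannel_width,microchannel_depth Backside microchannel
#'   dimensions (um).
#' @param nanochannel_width,nanochannel_depth Nanochannel dimensions (um).
#' @param cone_base,cone_height Conical nanostructure dimensions (um).
#' @param n_nanochannels Number of nanochannels across the section.
#' @param pitch Centre-to-centre nanochannel spacing (um).
#' @param wafer_thickness Wafer thickness (um); must be at least the sum of
#'   microchannel and nanochannel depths.
#' @return An object of class `chip_spec`.
#' @export
chip_spec <- function(microchannel_width = 150, microchannel_depth = 185,
                      nanochannel_width = 0.9, nanochannel_depth = 11,
                      cone_base = 4, cone_height = 4.5,
                      n_nanochannels = 20L, pitch = 8,
                      wafer_thickness = 200) {
  lens <- c(microchannel_width = microchannel_width,
            microchannel_depth = microchannel_depth,
            nanochannel_width = nanochannel_width,
            nanochannel_depth = nanochannel_depth,
            cone_base = cone_base, cone_height = cone_height,
            pitch = pitch, wafer_thickness = wafer_thickness)
  for (nm in names(lens)) check_scalar_number(lens[[nm]], nm, lower = 1e-9)
  check_scalar_number(n_nanochannels, "n_nanochannels", lower = 1)
  if (microchannel_depth + nanochannel_depth > wafer_thickness) {
    stop_input("microchannel_depth + nanochannel_depth exceeds wafer_thickness")
  }
  structure(list(microchannel_width = microchannel_width,
                 microchannel_depth = microchannel_depth,
                 nanochannel_width = nanochannel_width,
                 nanochannel_depth = nanochannel_depth,
                 cone_base = cone_base, cone_height = cone_height,
                 n_nanochannels = as.integer(n_nanochannels),
                 pitch = pitch, wafer_thickness = wafer_thickness),
            class = "chip_spec")
}

#' Simulation grid specification
#'
#' Discretization of the cross-section. The default is the 100 x 100 grid
#' used for the field simulation, over a 160 x 160 um physical extent so
#' that a 0.9-um nanochannel spans one 1.6-um cell.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param extent_x,extent_y Physical extent (um). Cell spacing must be
#'   isotropic (`extent_x / n_cols == extent_y / n_rows`).
#' @return An object of class `grid_spec` with a `spacing` element (um/cell).
#' @export
grid_spec <- function(n_rows = 100L, n_cols = 100L,
                      extent_x = 160, extent_y = 160) {
  check_scalar_number(n_rows, "n_rows", lower = 1)
  check_scalar_number(n_cols, "n_cols", lower = 1)
  check_scalar_number(extent_x, "extent_x", lower = 1e-9)
  check_scalar_number(extent_y, "extent_y", lower = 1e-9)
  dx <- extent_x / n_cols
  dy <- extent_y / n_rows
  if (abs(dx - dy) > 1e-9 * max(dx, dy)) {
    stop_input("grid spacing must be isotropic: extent_x/n_cols != extent_y/n_rows")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 extent_x = extent_x, extent_y = extent_y, spacing = dx),
            class = "grid_spec")
}

#' Rasterize the chip/nerve cross-section into a material label grid
#'
#' Builds the discrete cross-section: reservoir on the top rows, the chip
#' body (an insulating slab pierced by nanochannels, with conical
#' nanostructures protruding into the tissue) in the middle, and tissue
#' below. A seeded uniform draw without replacement selects which
#' nanochannels are open; exactly `round(open_fraction * n_nanochannels)`
#' channels are labelled open.
#'
#' Cones are rasterized as stacked rows of decreasing width (staircase
#' approximation); sub-cell features round to the nearest cell. A
#' nanochannel that rounds to less than one cell at the requested
#' resolution is a resolution error.
#'
#' @param chip A [chip_spec()].
#' @param grid A [grid_spec()].
#' @param open_fraction Fraction of nanochannels that are open, in `[0, 1]`.
#' @param seed Integer seed for the open-channel draw.
#' @return An object of class `material_grid`: list with `labels` (integer
#'   matrix), `open_channels` (indices), `channel_cols` (list of column
#'   index vectors per channel), `rows` (row ranges per region), plus the
#'   input specs.
#' @export
build_geometry <- function(chip, grid, open_fraction = 0.65, seed = 1L) {
  stopifnot(inherits(chip, "chip_spec"), inherits(grid, "grid_spec"))
  check_scalar_number(open_fraction, "open_fraction", lower = 0, upper = 1)
  nr <- grid$n_rows
  nc <- grid$n_cols
  dx <- grid$spacing

  w_cells <- round(chip$nanochannel_width / dx)
  if (w_cells < 1) {
    stop_input(sprintf(paste0(
      "resolution error: nanochannel width %.3g um rounds to < 1 cell at ",
      "spacing %.3g um; refine the grid or widen the channel"),
      chip$nanochannel_width, dx))
  }
  array_width <- chip$n_nanochannels * chip$pitch
  if (array_width > grid$extent_x + 1e-9) {
    stop_input("nanochannel array is wider than the grid extent")
  }

  ## vertical layout: reservoir (20% of rows, capped by microchannel depth),
  ## chip slab (nanochannel depth), cone staircase, tissue remainder
  rr <- max(1L, round(min(0.2 * nr, chip$microchannel_depth / dx)))
  ns <- max(1L, round(chip$nanochannel_depth / dx))
  ncone <- round(chip$cone_height / dx)
  if (rr + ns + ncone >= nr) {
    stop_input("grid has no rows left for tissue below the chip")
  }
  rows <- list(reservoir = seq_len(rr),
               slab = rr + seq_len(ns),
               cone = if (ncone > 0) rr + ns + seq_len(ncone) else integer(),
               tissue = (rr + ns + ncone + 1L):nr)

  labels <- matrix(.materials[["TISSUE"]], nr, nc)
  labels[rows$reservoir, ] <- .materials[["RESERVOIR"]]
  labels[rows$slab, ] <- .materials[["SILICON"]]

  x0 <- (grid$extent_x - array_width) / 2
  centers_um <- x0 + (seq_len(chip$n_nanochannels) - 0.5) * chip$pitch
  channel_cols <- lapply(centers_um, function(x) {
    c0 <- floor(x / dx - w_cells / 2) + 1L
    cols <- c0:(c0 + w_cells - 1L)
    cols[cols >= 1L & cols <= nc]
  })

  ## cone staircase: widest row at the slab, narrowing toward the tissue
  if (ncone > 0) {
    for (j in seq_len(ncone)) {
      width_um <- chip$cone_base * (ncone - j + 1) / ncone
      half <- max(0L, round(width_um / dx / 2))
      r <- rows$cone[j]
      for (x in centers_um) {
        cc <- round(x / dx + 0.5)
        cols <- max(1L, cc - half):min(nc, cc + half)
        labels[r, cols] <- .materials[["SILICON"]]
      }
    }
  }

  k_open <- round(open_fraction * chip$n_nanochannels)
  open_idx <- sort(local_seed(seed, sample.int(chip$n_nanochannels, k_open)))
  pierce_rows <- c(rows$slab, rows$cone)
  for (i in seq_len(chip$n_nanochannels)) {
    lab <- if (i %in% open_idx) .materials[["LUMEN_OPEN"]] else
      .materials[["LUMEN_BLOCKED"]]
    labels[pierce_rows, channel_cols[[i]]] <- lab
  }

  structure(list(labels = labels, open_channels = open_idx,
                 channel_cols = channel_cols, rows = rows,
                 open_fraction = open_fraction, seed = seed,
                 chip = chip, grid = grid),
            class = "material_grid")
}

#' Lower-triangular tissue-domain mask
#'
#' The nerve tissue domain of the simulation is represented as the lower
#' triangular region of the grid: cell (r, c) is tissue when
#' `r >= c * n_rows / n_cols` (row >= column on a square grid), covering
#' `n (n + 1) / 2` cells of an `n x n` grid. A rectangular tissue slab
#' (everything below a row) is available as an alternative.
#'
#' @param grid A [grid_spec()].
#' @param shape `"triangular"` (default) or `"rectangular"`.
#' @param top_row For the rectangular variant, the first tissue row.
#' @return Logical matrix of dimension `n_rows x n_cols`.
#' @export
tissue_mask <- function(grid, shape = c("triangular", "rectangular"),
                        top_row = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  shape <- match.arg(shape)
  nr <- grid$n_rows
  nc <- grid$n_cols
  if (shape == "triangular") {
    outer(seq_len(nr), seq_len(nc), function(r, c) r >= c * (nr / nc))
  } else {
    if (is.null(top_row)) top_row <- ceiling(nr / 2)
    outer(seq_len(nr), seq_len(nc), function(r, c) r >= top_row)
  }
}

#' Default material conductivities (S/m)
#'
#' Saline-filled lumen and reservoir at 1.4 S/m, nerve tissue at 0.5 S/m,
#' silicon / silicon-nitride and blocked lumen at an insulator floor of
#' 1e-12 S/m. All values are configurable.
#'
#' @return Named numeric vector over the material labels.
#' @export
default_conductivities <- function() {
  c(SILICON = 1e-12, LUMEN_OPEN = 1.4, LUMEN_BLOCKED = 1e-12,
    RESERVOIR = 1.4, TISSUE = 0.5)
}

#' Map material labels to a conductivity grid
#'
#' Per-cell lookup of material conductivity. Every label present on the
#' grid must have an entry in `props`.
#'
#' @param materials A [build_geometry()] result.
#' @param props Named conductivity table (S/m) over material label names.
#' @return An object of class `conductivity_grid`: list with `sigma`
#'   (numeric matrix, S/m) and `spacing` (um).
#' @export
conductivity_map <- function(materials, props = default_conductivities()) {
  stopifnot(inherits(materials, "material_grid"))
  present <- names(.materials)[.materials %in% unique(as.vector(materials$labels))]
  missing <- setdiff(present, names(props))
  if (length(missing) > 0) {
    stop_input("configuration error: no conductivity given for material(s): ",
               paste(missing, collapse = ", "))
  }
  if (any(!is.finite(unlist(props)) | unlist(props) < 0)) {
    stop_input("conductivities must be finite and >= 0")
  }
  lookup <- numeric(max(.materials))
  lookup[.materials[names(props)[names(props) %in% names(.materials)]]] <-
    unlist(props[names(props) %in% names(.materials)])
  sigma <- matrix(lookup[materials$labels],
                  nrow(materials$labels), ncol(materials$labels))
  structure(list(sigma = sigma, spacing = materials$grid$spacing),
            class = "conductivity_grid")
}
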
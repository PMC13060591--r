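## Field -> transmembrane potential -> poration / action potentials /
## stochastic transfection.

#' Sciatic-nerve membrane electrophysiology parameters
#'
#' Defaults are the murine sciatic-nerve values used throughout:
#' resting potential -70 mV, action-potential threshold -55 mV,
#' nanoporation threshold 200 mV (magnitude), refractory period 1 ms,
#' conduction velocity 120 m/s, sodium-channel density 600 channels/um^2.
#' `coupling_radius` (um) is the effective cell radius of the steady-state
#' field-to-membrane coupling law and is an implementation parameter.
#'
#' @param v_rest Resting potential (mV).
#' @param v_ap_threshold Action-potential threshold (mV).
#' @param v_poration_threshold Nanoporation threshold magnitude (mV).
#' @param refractory Refractory period (ms), > 0.
#' @param conduction_velocity Conduction velocity (m/s); stored and
#'   reported, drives no dynamics.
#' @param na_channel_density Sodium-channel density (channels/um^2);
#'   stored and reported, drives no dynamics.
#' @param coupling_radius Effective radius r in `dVm = 1.5 E r` (um).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(v_rest = -70, v_ap_threshold = -55,
                            v_poration_threshold = 200, refractory = 1,
                            conduction_velocity = 120,
                            na_channel_density = 600,
                            coupling_radius = 5) {
  check_scalar_number(refractory, "refractory", lower = 1e-12)
  check_scalar_number(coupling_radius, "coupling_radius", lower = 1e-12)
  check_scalar_number(conduction_velocity, "conduction_velocity", lower = 0)
  check_scalar_number(na_channel_density, "na_channel_density", lower = 0)
  if (abs(v_poration_threshold) <= abs(v_rest)) {
    stop_input("|v_poration_threshold| must exceed |v_rest|")
  }
  structure(list(v_rest = v_rest, v_ap_threshold = v_ap_threshold,
                 v_poration_threshold = v_poration_threshold,
                 refractory = refractory,
                 conduction_velocity = conduction_velocity,
                 na_channel_density = na_channel_density,
                 coupling_radius = coupling_radius),
            class = "membrane_params")
}

shift_mask <- function(m, dr, dc, pad = TRUE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

erode_mask <- function(mask, iterations = 1L) {
  for (it in seq_len(iterations)) {
    out <- mask
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        out <- out & shift_mask(mask, dr, dc, pad = TRUE)
      }
    }
    mask <- out
  }
  mask
}

#' Guarded tissue domain for poration analysis
#'
#' Tissue cells within a guard band of the chip or reservoir carry
#' numerically contaminated field values: the finite-difference gradient
#' at a material boundary mixes in the insulator-interior potential, and
#' Gaussian smoothing spreads the (physiologically meaningless) insulator
#' field a few cells into the tissue. The poration domain is therefore
#' the TISSUE-labelled region eroded by `guard` cells (8-neighbour
#' erosion, image borders treated as tissue), intersected with the
#' triangular nerve mask of [tissue_mask()].
#'
#' @param materials A [build_geometry()] result.
#' @param guard Guard-band width in cells; the pipeline uses
#'   `ceiling(4 * sigma_smooth) + 1` (smoothing support plus one
#'   finite-difference stencil cell).
#' @param triangular Intersect with the lower-triangular nerve mask
#'   (default `TRUE`).
#' @return Logical matrix.
#' @export
tissue_domain <- function(materials, guard = 5L, triangular = TRUE) {
  stopifnot(inherits(materials, "material_grid"))
  tis <- materials$labels == .materials[["TISSUE"]]
  if (guard > 0) tis <- erode_mask(tis, as.integer(guard))
  if (triangular) tis <- tis & tissue_mask(materials$grid)
  tis
}

#' Induced transmembrane potential magnitude
#'
#' Steady-state coupling (Schwan form with the angular factor collapsed
#' to its maximum): `|dVm| = 1.5 |E| r`, with `r` the coupling radius.
#' The reported magnitude is `|Vm| = |v_rest| + |dVm|`, in mV, zero
#' outside the tissue mask.
#'
#' @param field A (smoothed) [field_magnitude()] result or matrix (V/m).
#' @param mem A [membrane_params()] object.
#' @param tissue Logical tissue-domain mask (same dimensions).
#' @return An object of class `vm_grid`: list with `vm` (|Vm|, mV),
#'   `dvm` (|dVm|, mV), both masked to tissue.
#' @export
induced_vm <- function(field, mem, tissue) {
  stopifnot(inherits(mem, "membrane_params"))
  e <- if (inherits(field, "field_grid")) field$values else as.matrix(field)
  if (!all(dim(e) == dim(tissue))) {
    stop_input("field and tissue mask dimensions differ")
  }
  ## E [V/m] * r [um -> m] gives volts; report millivolts
  dvm <- 1.5 * e * (mem$coupling_radius * 1e-6) * 1e3
  dvm[!tissue] <- 0
  vm <- (abs(mem$v_rest) + dvm)
  vm[!tissue] <- 0
  structure(list(vm = vm, dvm = dvm, mem = mem, tissue = tissue),
            class = "vm_grid")
}

#' Nanoporation site map
#'
#' A tissue cell is porated when the induced membrane-potential magnitude
#' reaches the nanoporation threshold (inclusive: `|Vm| >=` threshold).
#' Raising the applied voltage never removes a porated cell.
#'
#' @param vm An [induced_vm()] result.
#' @param mem A [membrane_params()] object.
#' @param tissue Logical tissue mask; defaults to the mask carried by `vm`.
#' @return An object of class `poration_mask`: list with `porated`
#'   (logical matrix) and `threshold_field` (V/m level equivalent to the
#'   membrane threshold).
#' @export
poration_map <- function(vm, mem, tissue = NULL) {
  stopifnot(inherits(vm, "vm_grid"), inherits(mem, "membrane_params"))
  if (is.null(tissue)) tissue <- vm$tissue
  porated <- (vm$vm >= abs(mem$v_poration_threshold)) & tissue
  thr_field <- (abs(mem$v_poration_threshold) - abs(mem$v_rest)) * 1e-3 /
    (1.5 * mem$coupling_radius * 1e-6)
  structure(list(porated = porated, threshold_field = thr_field),
            class = "poration_mask")
}

#' Refractory-limited action-potential counts per cell
#'
#' A tissue cell whose depolarization crosses the action-potential
#' threshold (|dVm| >= |v_rest| - |v_ap_threshold|, 15 mV at the
#' defaults) fires at most `floor(pulse_duration / refractory)` action
#' potentials per pulse; totals are capped at `n_pulses` times that.
#' This is a bookkeeping cap (threshold + refractory), not a
#' conductance-based membrane model.
#'
#' @param vm An [induced_vm()] result.
#' @param protocol A [pulse_protocol()] object.
#' @param mem A [membrane_params()] object.
#' @return Integer matrix of per-cell action-potential counts over the
#'   whole protocol.
#' @export
ap_events <- function(vm, protocol, mem) {
  stopifnot(inherits(vm, "vm_grid"), inherits(protocol, "pulse_protocol"),
            inherits(mem, "membrane_params"))
  depol_needed <- abs(mem$v_rest) - abs(mem$v_ap_threshold)
  supra <- (vm$dvm >= depol_needed) & vm$tissue
  per_pulse <- floor(protocol$pulse_duration / mem$refractory)
  counts <- matrix(0L, nrow(supra), ncol(supra))
  counts[supra] <- as.integer(protocol$n_pulses * per_pulse)
  counts
}

#' Stochastic transfection-efficiency map
#'
#' Per porated cell, a transfection probability is drawn from a Gaussian
#' `Normal(mean_eff, sd_eff)` clipped to `[0, 1]`; the realized outcome is
#' a Bernoulli draw with that probability. Fully reproducible under a
#' fixed seed; `sd_eff = 0` with `mean_eff` in {0, 1} is deterministic.
#'
#' @param por A [poration_map()] result.
#' @param mean_eff Mean transfection efficiency, in `[0, 1]` (default 0.6).
#' @param sd_eff Gaussian SD of the efficiency (default 0.15).
#' @param seed Integer seed.
#' @return An object of class `transfection_grid`: list with `probability`
#'   (matrix, nonzero only on porated cells), `realized` (logical matrix,
#'   subset of the poration mask), and the parameters.
#' @export
transfection_map <- function(por, mean_eff = 0.6, sd_eff = 0.15, seed = 1L) {
  stopifnot(inherits(por, "poration_mask"))
  check_scalar_number(mean_eff, "mean_eff", lower = 0, upper = 1)
  check_scalar_number(sd_eff, "sd_eff", lower = 0)
  mask <- por$porated
  n <- sum(mask)
  prob <- matrix(0, nrow(mask), ncol(mask))
  realized <- matrix(FALSE, nrow(mask), ncol(mask))
  if (n > 0) {
    draws <- local_seed(seed, {
      p <- pmin(pmax(stats::rnorm(n, mean_eff, sd_eff), 0), 1)
      list(p = p, hit = stats::rbinom(n, 1L, p) == 1L)
    })
    prob[mask] <- draws$p
    realized[mask] <- draws$hit
  }
  structure(list(probability = prob, realized = realized,
                 mean_efficiency = mean_eff, sd_efficiency = sd_eff,
                 seed = seed),
            class = "transfection_grid")
}

#' Scalar summary of a poration/transfection simulation
#'
#' @param por A [poration_map()] result.
#' @param trans A [transfection_map()] result.
#' @param tissue Logical tissue mask.
#' @param field Optional (smoothed) field grid for the max-field summary.
#' @param vm Optional [induced_vm()] result for the max-|Vm| summary.
#' @return A list (`sim_summary`): `n_porated`, `porated_fraction` (of
#'   tissue cells), `n_realized`, `realized_fraction` (of porated cells;
#'   0 when nothing is porated), `max_field_vpm`, `max_vm_mv`.
#' @export
summarize_simulation <- function(por, trans, tissue, field = NULL, vm = NULL) {
  stopifnot(inherits(por, "poration_mask"), inherits(trans, "transfection_grid"))
  n_por <- sum(por$porated)
  n_tis <- sum(tissue)
  n_real <- sum(trans$realized)
  structure(list(
    n_porated = n_por,
    porated_fraction = if (n_tis > 0) n_por / n_tis else 0,
    n_realized = n_real,
    realized_fraction = if (n_por > 0) n_real / n_por else 0,
    max_field_vpm = if (!is.null(field)) {
      max((if (inherits(field, "field_grid")) field$values else field)[tissue])
    } else NA_real_,
    max_vm_mv = if (!is.null(vm)) max(vm$vm) else NA_real_
  ), class = "sim_summary")
}
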
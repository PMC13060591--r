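## Quasi-static potential solver on the conductivity grid.
##
## The pulse is treated quasi-statically (membrane impedance effectively
## infinite, no transient charging): one solve of div(sigma grad phi) = 0
## per protocol, with Dirichlet electrodes and insulating side walls.

#' Electrical pulse protocol
#'
#' Defaults are the simulated delivery protocol: 200 V, 10-ms pulses,
#' 10 pulses. The 100-ms in vivo variant is selectable by argument.
#'
#' @param voltage Applied voltage (V), >= 0.
#' @param pulse_duration Pulse duration (ms).
#' @param n_pulses Number of pulses.
#' @param inter_pulse_gap Gap between pulses (ms).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(voltage = 200, pulse_duration = 10,
                           n_pulses = 10L, inter_pulse_gap = 100) {
  check_scalar_number(voltage, "voltage", lower = 0)
  check_scalar_number(pulse_duration, "pulse_duration", lower = 1e-9)
  check_scalar_number(n_pulses, "n_pulses", lower = 1)
  check_scalar_number(inter_pulse_gap, "inter_pulse_gap", lower = 0)
  structure(list(voltage = voltage, pulse_duration = pulse_duration,
                 n_pulses = as.integer(n_pulses),
                 inter_pulse_gap = inter_pulse_gap),
            class = "pulse_protocol")
}

#' Electrode boundary conditions
#'
#' The positive electrode (anode, at `voltage`) is underneath the tissue
#' (last grid row by default) and the negative electrode (cathode, 0 V)
#' is inside the reservoir (first row by default). Side walls carry a
#' zero-normal-flux (insulating) condition.
#'
#' @param voltage Anode potential (V).
#' @param anode_rows,cathode_rows Row index sets held at `voltage` / 0 V.
#'   `NULL` anode rows resolve to the last row at solve time.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(voltage = 200, anode_rows = NULL,
                                cathode_rows = 1L) {
  check_scalar_number(voltage, "voltage", lower = 0)
  if (length(cathode_rows) == 0) stop_input("cathode row set must be non-empty")
  if (!is.null(anode_rows)) {
    if (length(anode_rows) == 0) stop_input("anode row set must be non-empty")
    if (length(intersect(anode_rows, cathode_rows)) > 0) {
      stop_input("anode and cathode row sets must be disjoint")
    }
  }
  structure(list(voltage = voltage, anode_rows = anode_rows,
                 cathode_rows = as.integer(cathode_rows)),
            class = "boundary_conditions")
}

harmonic_mean <- function(a, b) {
  out <- 2 * a * b / (a + b)
  out[a + b == 0] <- 0
  out
}

#' Solve the quasi-static potential over a conductivity grid
#'
#' Finite-difference discretization of `div(sigma grad phi) = 0` with
#' harmonic-mean inter-cell conductances (flux-conservative for
#' piecewise-constant sigma), Dirichlet electrode rows and insulating
#' side walls. The Dirichlet rows are eliminated, leaving a symmetric
#' positive-definite sparse system solved directly (Matrix package); the
#' relative residual of the full system is checked against `tol`
#' afterwards.
#'
#' @param sigma A [conductivity_map()] result, or a plain numeric matrix
#'   of conductivities (S/m).
#' @param bc A [boundary_conditions()] object.
#' @param tol Maximum acceptable relative residual (default 1e-8).
#' @param max_iter Retained for interface compatibility with iterative
#'   schemes; unused by the direct solve.
#' @param sigma_floor Conductivity floor applied before solving, so the
#'   system stays positive definite with perfect insulators (S/m).
#' @return An object of class `potential_grid`: list with `phi` (V),
#'   `spacing` (um), `voltage` and `residual`.
#' @export
solve_potential <- function(sigma, bc, tol = 1e-8, max_iter = 50000L,
                            sigma_floor = 1e-12) {
  if (inherits(sigma, "conductivity_grid")) {
    s <- sigma$sigma
    spacing <- sigma$spacing
  } else {
    s <- as.matrix(sigma)
    spacing <- 1
  }
  stopifnot(inherits(bc, "boundary_conditions"))
  nr <- nrow(s)
  nc <- ncol(s)
  if (nr < 2 || nc < 1) stop_input("grid must have at least 2 rows")
  s <- pmax(s, sigma_floor)

  anode <- if (is.null(bc$anode_rows)) nr else as.integer(bc$anode_rows)
  cathode <- bc$cathode_rows
  if (length(intersect(anode, cathode)) > 0) {
    stop_input("anode and cathode row sets must be disjoint")
  }

  phi_d <- matrix(NA_real_, nr, nc)
  phi_d[cathode, ] <- 0
  phi_d[anode, ] <- bc$voltage
  dirichlet <- !is.na(phi_d)

  idx <- matrix(seq_len(nr * nc), nr, nc)
  free <- !dirichlet
  pos <- integer(nr * nc)            # full index -> position among free cells
  pos[idx[free]] <- seq_len(sum(free))

  ## link conductances (unit-thickness 2-D: g = harmonic mean of sigma)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  b <- numeric(sum(free))
  diag_acc <- numeric(sum(free))

  add_links <- function(a_idx, b_idx, g) {
    a_free <- free[a_idx]; b_free <- free[b_idx]
    ## both free: symmetric off-diagonals
    both <- a_free & b_free
    if (any(both)) {
      pa <- pos[a_idx[both]]; pb <- pos[b_idx[both]]; gg <- g[both]
      ti <<- c(ti, pa, pb); tj <<- c(tj, pb, pa); tx <<- c(tx, -gg, -gg)
      diag_acc[pa] <<- diag_acc[pa] + gg
      diag_acc[pb] <<- diag_acc[pb] + gg
    }
    ## free cell next to a Dirichlet cell: move known value to the rhs
    ad <- a_free & !b_free
    if (any(ad)) {
      pa <- pos[a_idx[ad]]
      diag_acc[pa] <<- diag_acc[pa] + g[ad]
      b[pa] <<- b[pa] + g[ad] * phi_d[b_idx[ad]]
    }
    bd <- b_free & !a_free
    if (any(bd)) {
      pb <- pos[b_idx[bd]]
      diag_acc[pb] <<- diag_acc[pb] + g[bd]
      b[pb] <<- b[pb] + g[bd] * phi_d[a_idx[bd]]
    }
    invisible(NULL)
  }

  if (nc > 1) {
    gh <- harmonic_mean(s[, -nc, drop = FALSE], s[, -1, drop = FALSE])
    add_links(as.vector(idx[, -nc, drop = FALSE]),
              as.vector(idx[, -1, drop = FALSE]), as.vector(gh))
  }
  gv <- harmonic_mean(s[-nr, , drop = FALSE], s[-1, , drop = FALSE])
  add_links(as.vector(idx[-nr, , drop = FALSE]),
            as.vector(idx[-1, , drop = FALSE]), as.vector(gv))

  nf <- sum(free)
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(nf)), j = c(tj, seq_len(nf)),
                            x = c(tx, diag_acc), dims = c(nf, nf))
  x <- as.numeric(Matrix::solve(A, b))

  res <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  scale <- max(sqrt(sum(b^2)), 1e-300)
  relres <- res / scale
  if (!is.finite(relres) || relres > tol) {
    stop(sprintf("solver error: relative residual %.3g exceeds tol %.3g",
                 relres, tol), call. = FALSE)
  }

  phi <- phi_d
  phi[free] <- x
  structure(list(phi = phi, spacing = spacing, voltage = bc$voltage,
                 residual = relres),
            class = "potential_grid")
}

#' Electric-field magnitude of a solved potential
#'
#' Central-difference gradient of the potential (one-sided at the grid
#' edges), converted to V/m using the grid spacing in micrometres.
#'
#' @param phi A [solve_potential()] result, or a numeric matrix of
#'   potentials (V) with `spacing` supplied.
#' @param spacing Cell spacing in um (used when `phi` is a bare matrix).
#' @return An object of class `field_grid`: list with `values` (|E|, V/m)
#'   and `spacing` (um).
#' @export
field_magnitude <- function(phi, spacing = NULL) {
  if (inherits(phi, "potential_grid")) {
    p <- phi$phi
    if (is.null(spacing)) spacing <- phi$spacing
  } else {
    p <- as.matrix(phi)
    if (is.null(spacing)) spacing <- 1
  }
  nr <- nrow(p)
  nc <- ncol(p)
  if (nr < 2 || nc < 2) stop_input("field gradient needs at least a 2 x 2 grid")
  h <- spacing * 1e-6  # um -> m

  dver <- matrix(0, nr, nc)
  dver[2:(nr - 1), ] <- (p[3:nr, ] - p[1:(nr - 2), ]) / (2 * h)
  dver[1, ] <- (p[2, ] - p[1, ]) / h
  dver[nr, ] <- (p[nr, ] - p[nr - 1, ]) / h

  dhor <- matrix(0, nr, nc)
  dhor[, 2:(nc - 1)] <- (p[, 3:nc] - p[, 1:(nc - 2)]) / (2 * h)
  dhor[, 1] <- (p[, 2] - p[, 1]) / h
  dhor[, nc] <- (p[, nc] - p[, nc - 1]) / h

  structure(list(values = sqrt(dver^2 + dhor^2), spacing = spacing),
            class = "field_grid")
}

reflect_pad_index <- function(n, r) {
  ## symmetric (edge-repeating) reflection indices for a pad of r cells
  c(rev(seq_len(min(r, n))), seq_len(n), rev(n + 1 - seq_len(min(r, n))))
}

convolve_sep_1d <- function(m, k, along_rows) {
  r <- (length(k) - 1L) / 2L
  if (along_rows) {
    pad <- m[reflect_pad_index(nrow(m), r), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
  } else {
    pad <- m[, reflect_pad_index(ncol(m), r), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[, (j - 1) + seq_len(ncol(m)), drop = FALSE]
    }
  }
  out
}

#' Gaussian smoothing of a field map
#'
#' Separable 2-D Gaussian convolution with reflective (edge-mirroring)
#' boundary handling. `sigma_smooth = 0` returns the input unchanged;
#' constant fields are fixed points of the filter.
#'
#' @param field A [field_magnitude()] result or a numeric matrix.
#' @param sigma_smooth Gaussian standard deviation in grid cells (>= 0);
#'   default 1 cell. The kernel is truncated at 4 sigma and renormalized.
#' @return Same type as the input (`field_grid` or matrix).
#' @export
smooth_field <- function(field, sigma_smooth = 1) {
  if (!is.numeric(sigma_smooth) || length(sigma_smooth) != 1 ||
      !is.finite(sigma_smooth) || sigma_smooth < 0) {
    stop_input("'sigma_smooth' must be a single number >= 0")
  }
  is_grid <- inherits(field, "field_grid")
  m <- if (is_grid) field$values else as.matrix(field)
  if (sigma_smooth > 0) {
    dir_kernel <- function(n) {
      r <- min(max(1L, ceiling(4 * sigma_smooth)), n - 1L)
      if (r < 1L) return(NULL)
      k <- stats::dnorm(seq(-r, r), sd = sigma_smooth)
      k / sum(k)
    }
    kr <- dir_kernel(nrow(m))
    kc <- dir_kernel(ncol(m))
    if (!is.null(kr)) m <- convolve_sep_1d(m, kr, along_rows = TRUE)
    if (!is.null(kc)) m <- convolve_sep_1d(m, kc, along_rows = FALSE)
  }
  if (is_grid) {
    structure(list(values = m, spacing = field$spacing), class = "field_grid")
  } else {
    m
  }
}

#' Discrete smoothing kernel used by [smooth_field()]
#'
#' Exposed so callers can inspect the truncated, renormalized 1-D kernel.
#'
#' @param sigma_smooth Gaussian standard deviation in cells (> 0).
#' @return Numeric vector of kernel weights summing to 1.
#' @export
gaussian_kernel <- function(sigma_smooth) {
  check_scalar_number(sigma_smooth, "sigma_smooth", lower = 1e-12)
  r <- max(1L, ceiling(4 * sigma_smooth))
  k <- stats::dnorm(seq(-r, r), sd = sigma_smooth)
  k / sum(k)
}
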
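## Seeded synthetic-data generators with embedded ground truth:
## motor-unit pools, incremental EMG series, CMAP and torque traces,
## multichannel nerve cross-section micrographs.

#' Generate a synthetic motor-unit pool
#'
#' Unit amplitudes are lognormal (physiological right skew) with the
#' stated mean and coefficient of variation; `cv = 0` gives identical
#' amplitudes. Recruitment thresholds are sorted uniform draws over the
#' stimulation intensity range (0.1-ms pulses at 1-10 mA by default).
#'
#' @param n_units Number of motor units (>= 1).
#' @param mean_amp Mean unit amplitude (mV, default 0.2).
#' @param cv Coefficient of variation of unit amplitudes (>= 0).
#' @param threshold_range Stimulation intensity range (mA).
#' @param seed Integer seed.
#' @return An object of class `motor_pool`: `n_units`, `unit_amplitudes`
#'   (mV), `recruitment_thresholds` (mA, strictly increasing),
#'   `amplitude_cv`, `seed`.
#' @export
gen_motor_pool <- function(n_units, mean_amp = 0.2, cv = 0.3,
                           threshold_range = c(1, 10), seed = 1L) {
  check_scalar_number(n_units, "n_units", lower = 1)
  check_scalar_number(mean_amp, "mean_amp", lower = 1e-12)
  check_scalar_number(cv, "cv", lower = 0)
  n_units <- as.integer(n_units)
  draws <- local_seed(seed, {
    amps <- if (cv == 0) {
      rep(mean_amp, n_units)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(mean_amp) - sdlog^2 / 2
      stats::rlnorm(n_units, meanlog, sdlog)
    }
    thr <- sort(stats::runif(n_units, threshold_range[1], threshold_range[2]))
    list(amps = amps, thr = thr)
  })
  structure(list(n_units = n_units, unit_amplitudes = draws$amps,
                 recruitment_thresholds = draws$thr,
                 amplitude_cv = cv, mean_amp = mean_amp, seed = seed),
            class = "motor_pool")
}

#' Generate an incremental-stimulation response series from a pool
#'
#' Response levels are the cumulative sums of the first k units in
#' recruitment order, preceded by the subthreshold zero level, with
#' additive Gaussian measurement noise on every level. `noise_sd = 0`
#' yields the exact cumulative sums. The contributing unit amplitudes are
#' recorded as ground truth.
#'
#' @param pool A [gen_motor_pool()] result.
#' @param n_increments Number of increments (default 10; must not exceed
#'   the pool size).
#' @param noise_sd Measurement noise SD (mV).
#' @param seed Integer seed.
#' @return An [increment_series()] with an extra `truth` element (the
#'   contributing unit amplitudes and the noiseless levels).
#' @export
gen_increment_series <- function(pool, n_increments = 10L, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(inherits(pool, "motor_pool"))
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (n_increments > pool$n_units) {
    stop_input("input error: n_increments exceeds the number of motor units")
  }
  units <- pool$unit_amplitudes[seq_len(n_increments)]
  levels <- c(0, cumsum(units))
  noisy <- levels + local_seed(seed, stats::rnorm(length(levels), 0, noise_sd))
  out <- increment_series(noisy, n_increments = n_increments)
  out$truth <- list(unit_amplitudes = units, levels = levels)
  out
}

biphasic_template <- function(t_ms, onset_ms = 2, width_ms = 6) {
  tau <- (t_ms - onset_ms) / width_ms
  u <- ifelse(tau > 0 & tau < 2, sin(pi * tau) * exp(-tau), 0)
  u
}

#' Generate a supramaximal CMAP trace from a pool
#'
#' A biphasic template is scaled so that its peak-to-peak amplitude
#' equals the summed amplitude of all units in the pool (the maximal
#' CMAP); Gaussian noise is added over the whole trace, leaving the
#' pre-stimulus window noise-only.
#'
#' @param pool A [gen_motor_pool()] result.
#' @param sampling_rate Sampling rate (Hz, default 20000).
#' @param noise_sd Additive noise SD (mV).
#' @param seed Integer seed.
#' @param duration_ms Trace length (ms).
#' @param stim_ms Stimulus time (ms).
#' @return A [waveform()] with attribute `truth` (the noiseless
#'   peak-to-peak amplitude).
#' @export
gen_cmap_trace <- function(pool, sampling_rate = 20000, noise_sd = 0,
                           seed = 1L, duration_ms = 60, stim_ms = 10) {
  stopifnot(inherits(pool, "motor_pool"))
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  target_pp <- sum(pool$unit_amplitudes)
  t <- seq(0, duration_ms, by = 1000 / sampling_rate)
  u <- biphasic_template(t - stim_ms)
  pp <- max(u) - min(u)
  s <- if (pp > 0) u / pp * target_pp else u
  s <- s + local_seed(seed, stats::rnorm(length(s), 0, noise_sd))
  w <- waveform(s, sampling_rate = sampling_rate, stimulus_times = stim_ms,
                units = "mV")
  attr(w, "truth") <- list(max_cmap_pp = target_pp)
  w
}

#' Generate a twitch or tetanic torque trace
#'
#' Twitch: a single rise-decay transient `(t/tc) exp(1 - t/tc)` whose
#' maximum equals the stated peak. Tetanic: a saturating envelope fusing
#' to a plateau at the stated peak over a 1-s, 150-Hz train, with an
#' optional small subtractive stimulus ripple.
#'
#' @param kind `"twitch"` or `"tetanic"`.
#' @param peak Target peak torque (mN.m, >= 0).
#' @param sampling_rate Sampling rate (Hz, default 1000).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Additive noise SD.
#' @param ripple Fractional ripple depth of the tetanic envelope at the
#'   train frequency (default 0.002).
#' @param train_hz,train_s Tetanic train frequency and duration.
#' @return A [waveform()] with attribute `truth` (the target peak).
#' @export
gen_torque_trace <- function(kind = c("twitch", "tetanic"), peak,
                             sampling_rate = 1000, seed = NULL,
                             noise_sd = 0, ripple = 0.002,
                             train_hz = 150, train_s = 1) {
  kind <- match.arg(kind)
  check_scalar_number(peak, "peak", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  stim_ms <- 50
  if (kind == "twitch") {
    t <- seq(0, 250, by = 1000 / sampling_rate)
    tc <- 20
    tau <- (t - stim_ms) / tc
    s <- ifelse(tau > 0, peak * tau * exp(1 - tau), 0)
  } else {
    t <- seq(0, stim_ms + train_s * 1000, by = 1000 / sampling_rate)
    tau <- pmax(t - stim_ms, 0)
    env <- peak * (1 - exp(-tau / 80))
    rip <- 1 - ripple * (0.5 + 0.5 * sin(2 * pi * train_hz * tau / 1000))
    s <- env * rip
  }
  if (noise_sd > 0) {
    s <- s + local_seed(seed, stats::rnorm(length(s), 0, noise_sd))
  }
  w <- waveform(s, sampling_rate = sampling_rate, stimulus_times = stim_ms,
                units = "mN.m")
  attr(w, "truth") <- list(peak = peak, kind = kind)
  w
}

disc_mask <- function(nr, nc, r0, c0, radius) {
  rows <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cols <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  idx <- expand.grid(r = rows, c = cols)
  keep <- (idx$r - r0)^2 + (idx$c - c0)^2 <= radius^2
  cbind(idx$r[keep], idx$c[keep])
}

annulus_mask <- function(nr, nc, r0, c0, inner, outer) {
  rows <- max(1L, floor(r0 - outer)):min(nr, ceiling(r0 + outer))
  cols <- max(1L, floor(c0 - outer)):min(nc, ceiling(c0 + outer))
  idx <- expand.grid(r = rows, c = cols)
  d2 <- (idx$r - r0)^2 + (idx$c - c0)^2
  keep <- d2 <= outer^2 & d2 >= inner^2
  cbind(idx$r[keep], idx$c[keep])
}

place_centers <- function(n, nr, nc, margin, min_sep, existing = NULL,
                          max_attempts = 10000L) {
  centers <- existing
  placed <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r0 <- stats::runif(1, margin + 1, nr - margin)
      c0 <- stats::runif(1, margin + 1, nc - margin)
      all_pts <- rbind(centers, placed)
      if (is.null(all_pts) || nrow(all_pts) == 0 ||
          min((all_pts[, 1] - r0)^2 + (all_pts[, 2] - c0)^2) >= min_sep^2) {
        placed <- rbind(placed, c(r0, c0))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_input("generation error: could not place objects without overlap; ",
                 "reduce counts or enlarge the field")
    }
  }
  placed
}

#' Generate a synthetic multichannel nerve cross-section image
#'
#' Axons are neurofilament (NF) discs; a designated subset carries a
#' myelin (MBP) annulus overlapping the disc rim; vessels are CD31 rings
#' with a DAPI nucleus placed on the ring; a stated fraction of vessels
#' is co-labelled in the GFP lineage channel, plus optional GFP-only
#' cells; extra non-vascular DAPI nuclei are scattered. Object centres
#' are placed by seeded rejection sampling with a minimum separation so
#' that no two objects touch, and Poisson background noise is added to
#' every channel. The embedded truth table is exact by construction.
#'
#' @param n_axons,n_myelinated Axon counts (myelinated <= total).
#' @param n_vessels Vessel count.
#' @param gfp_vessel_fraction Fraction of vessels co-labelled with GFP.
#' @param n_gfp_only Additional GFP-only cell bodies.
#' @param n_extra_nuclei Additional scattered DAPI nuclei.
#' @param shape Image shape in pixels (rows, cols).
#' @param pixel_size Pixel size (um/pixel, default 1).
#' @param margin Placement margin from the border (px).
#' @param axon_radius_px Range of axon disc radii (px).
#' @param foreground,background_lambda Foreground intensity and Poisson
#'   background rate.
#' @param seed Integer seed.
#' @return An [image_bundle()] with channels NF, MBP, CD31, DAPI, GFP and
#'   an extra `truth` element: counts, per-object centres (px) and radii,
#'   and `pixel_size`.
#' @export
gen_nerve_image <- function(n_axons = 50L, n_myelinated = 20L,
                            n_vessels = 12L, gfp_vessel_fraction = 0.3,
                            n_gfp_only = 0L, n_extra_nuclei = 30L,
                            shape = c(320L, 320L), pixel_size = 1,
                            margin = 12L, axon_radius_px = c(3, 5),
                            foreground = 200, background_lambda = 8,
                            seed = 1L) {
  if (n_myelinated > n_axons) {
    stop_input("n_myelinated must not exceed n_axons")
  }
  nr <- shape[1]
  nc <- shape[2]
  out <- local_seed(seed, {
    min_sep <- 2 * (max(axon_radius_px) + 5) + 2
    n_obj <- n_axons + n_vessels + n_gfp_only + n_extra_nuclei
    centers <- place_centers(n_obj, nr, nc, margin = margin,
                             min_sep = min_sep)
    i_ax <- seq_len(n_axons)
    i_ve <- n_axons + seq_len(n_vessels)
    i_gf <- n_axons + n_vessels + seq_len(n_gfp_only)
    i_nu <- n_axons + n_vessels + n_gfp_only + seq_len(n_extra_nuclei)

    zero <- matrix(0, nr, nc)
    chans <- list(NF = zero, MBP = zero, CD31 = zero, DAPI = zero, GFP = zero)
    paint <- function(ch, px) {
      if (nrow(px) > 0) chans[[ch]][px] <<- foreground
      invisible(NULL)
    }

    ax_r <- stats::runif(n_axons, axon_radius_px[1], axon_radius_px[2])
    myel <- sort(sample.int(max(n_axons, 1L), n_myelinated))
    for (i in seq_len(n_axons)) {
      paint("NF", disc_mask(nr, nc, centers[i_ax[i], 1], centers[i_ax[i], 2],
                            ax_r[i]))
      if (i %in% myel) {
        ## annulus from rim-1 to rim+2 so it overlaps the axon disc
        paint("MBP", annulus_mask(nr, nc, centers[i_ax[i], 1],
                                  centers[i_ax[i], 2],
                                  inner = max(ax_r[i] - 1, 0.5),
                                  outer = ax_r[i] + 2))
      }
    }

    n_gfp_vessels <- round(gfp_vessel_fraction * n_vessels)
    gfp_vessels <- if (n_vessels > 0) {
      sort(sample.int(n_vessels, n_gfp_vessels))
    } else {
      integer(0)
    }
    for (i in seq_len(n_vessels)) {
      r0 <- centers[i_ve[i], 1]
      c0 <- centers[i_ve[i], 2]
      ring <- annulus_mask(nr, nc, r0, c0, inner = 5, outer = 7)
      paint("CD31", ring)
      ang <- stats::runif(1, 0, 2 * pi)
      paint("DAPI", disc_mask(nr, nc, r0 + 6 * sin(ang), c0 + 6 * cos(ang), 2))
      if (i %in% gfp_vessels) paint("GFP", ring)
    }
    for (i in seq_len(n_gfp_only)) {
      paint("GFP", disc_mask(nr, nc, centers[i_gf[i], 1], centers[i_gf[i], 2], 4))
    }
    for (i in seq_len(n_extra_nuclei)) {
      paint("DAPI", disc_mask(nr, nc, centers[i_nu[i], 1], centers[i_nu[i], 2], 2))
    }

    chans <- lapply(chans, function(ch) {
      ch + matrix(stats::rpois(nr * nc, background_lambda), nr, nc)
    })

    list(chans = chans,
         truth = list(n_axons = as.integer(n_axons),
                      n_myelinated = as.integer(n_myelinated),
                      n_vessels = as.integer(n_vessels),
                      n_gfp_vessels = as.integer(n_gfp_vessels),
                      n_gfp_only = as.integer(n_gfp_only),
                      axon_centers = centers[i_ax, , drop = FALSE],
                      axon_radii = ax_r,
                      myelinated_idx = myel,
                      vessel_centers = centers[i_ve, , drop = FALSE],
                      pixel_size = pixel_size))
  })
  bundle <- image_bundle(out$chans, pixel_size = pixel_size)
  bundle$truth <- out$truth
  bundle
}
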
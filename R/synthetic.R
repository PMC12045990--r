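#' Generate synthetic micropipette-aspiration creep traces
#'
#' Simulates the aspirated-tongue length of an SLS material under constant
#' suction: a quiet pre-suction baseline (lead-in of about two seconds at
#' L = 0 with small additive tracking noise), then
#' `L(t) = J_SLS(t) * 3 phi Rp dP / (2 pi)` with multiplicative Gaussian
#' tracking noise, emulating elastic snap-in followed by gradual creep to
#' a steady plateau. Defaults sit in the measured organoid regime:
#' stiffness of hundreds of pascals, response time of a few seconds,
#' kilopascal suction through a 150-micrometer pipette.
#'
#' @param n_traces number of traces.
#' @param k0,k_st,tau generating SLS parameters (Pa, Pa, s).
#' @param Rp pipette radius (micrometers).
#' @param dP suction magnitude (Pa).
#' @param phi wall factor.
#' @param duration record length (s) including the baseline.
#' @param rate sampling rate (Hz).
#' @param baseline pre-suction lead-in (s).
#' @param noise_frac multiplicative noise fraction on the post-onset
#'   length (default 0.01, the level consistent with the fit quality the
#'   aspiration measurements themselves show); a fifth of it, relative to
#'   the plateau length, sets the additive baseline noise.
#' @param seed RNG seed.
#' @return list of [creep_trace()] objects (onset left for detection).
#' @export
gen_creep_traces <- function(n_traces = 1, k0 = 400, k_st = 250, tau = 2,
                             Rp = 150, dP = 1500, phi = 2.1,
                             duration = 12, rate = 20, baseline = 2,
                             noise_frac = 0.01, seed = NULL) {
  if (!(k_st > 0) || !(k0 >= k_st) || !(tau > 0)) {
    stop_invalid("require k0 >= k_st > 0 and tau > 0")
  }
  if (noise_frac < 0) stop_invalid("noise_frac must be non-negative")
  tgrid <- seq(0, duration, by = 1 / rate)
  scale <- 3 * phi * Rp * dP / (2 * pi)   # J -> L (micrometers)
  L_ss <- scale / k_st
  with_seed(seed, {
    lapply(seq_len(n_traces), function(i) {
      L <- numeric(length(tgrid))
      post <- tgrid >= baseline
      L[post] <- sls_creep_model(tgrid[post] - baseline, k0, k_st, tau) * scale
      if (noise_frac > 0) {
        L[post] <- L[post] * (1 + noise_frac * stats::rnorm(sum(post)))
        L[!post] <- abs(noise_frac * L_ss * 0.2 * stats::rnorm(sum(!post)))
      }
      creep_trace(tgrid, pmax(L, 0), pipette_radius = Rp, pressure = dP,
                  wall_factor = phi, label = sprintf("synthetic_%02d", i))
    })
  })
}

#' Generate a multi-b diffusion-weighted phantom series
#'
#' Builds repeated scans of a phantom plate holding disk-shaped organoids
#' in per-group wells. Each voxel inside a disk carries an apparent
#' diffusion coefficient drawn once from a log-normal distribution with
#' the group mean and coefficient of variation (right-skewed, positive
#' support, giving the asymmetric ADC profiles seen in tissue). The
#' signal decays mono-exponentially, `S(b) = S0 exp(-b ADC)`, corrupted by
#' Rician noise at the stated b = 0 signal-to-noise ratio. A common
#' multiplicative per-scan drift is applied to the ADC field, emulating
#' the slow ADC rise over repeated scans; the background carries
#' near-zero signal.
#'
#' @param grid image dimensions (pixels).
#' @param wells data.frame of disk specs: `x`, `y`, `radius` (pixels),
#'   `group`; `NULL` uses a two-group (control / mutant) default layout of
#'   four disks per group.
#' @param adc_mean named per-group mean ADC (mm^2/s).
#' @param adc_cv within-organoid ADC coefficient of variation.
#' @param b_values s/mm^2, ascending, starting at 0.
#' @param snr_b0 signal-to-noise ratio at b = 0 (`Inf` = noiseless).
#' @param n_scans number of consecutive scans.
#' @param scan_drift fractional ADC increase per scan step (applied to
#'   all groups alike).
#' @param s0 mean b = 0 tissue intensity (arbitrary units).
#' @param seed RNG seed.
#' @return list of `n_scans` `dwi_stack` objects; each carries the well
#'   `label_map`, the group lookup, and the true (drifted) ADC field as
#'   `truth`.
#' @export
gen_dwi_phantom <- function(grid = c(96, 96), wells = NULL,
                            adc_mean = c(control = 1.0e-3, mutant = 1.09e-3),
                            adc_cv = 0.1,
                            b_values = c(0, 200, 400, 600, 1000, 1200),
                            snr_b0 = 30, n_scans = 5, scan_drift = 0.02,
                            s0 = 1000, seed = NULL) {
  if (b_values[1] != 0 || any(diff(b_values) <= 0)) {
    stop_invalid("b_values must be ascending and start at 0")
  }
  if (is.null(wells)) {
    qx <- round(grid[1] * c(0.25, 0.25, 0.25, 0.25, 0.75, 0.75, 0.75, 0.75))
    qy <- round(grid[2] * c(0.14, 0.38, 0.62, 0.86, 0.14, 0.38, 0.62, 0.86))
    wells <- data.frame(x = qx, y = qy, radius = 10,
                        group = rep(names(adc_mean), each = 4))
  }
  for (g in unique(wells$group)) {
    if (!g %in% names(adc_mean)) stop_invalid("no adc_mean for group ", g)
  }
  xs <- matrix(rep(seq_len(grid[1]), grid[2]), grid[1])
  ys <- matrix(rep(seq_len(grid[2]), each = grid[1]), grid[1])
  label_map <- matrix(0L, grid[1], grid[2])
  for (w in seq_len(nrow(wells))) {
    inside <- (xs - wells$x[w])^2 + (ys - wells$y[w])^2 <= wells$radius[w]^2
    if (any(label_map[inside] != 0L)) stop_invalid("overlapping disks in well layout")
    label_map[inside] <- w
  }

  with_seed(seed, {
    adc_field <- matrix(NA_real_, grid[1], grid[2])
    for (w in seq_len(nrow(wells))) {
      vox <- which(label_map == w)
      m <- adc_mean[[wells$group[w]]]
      sdl <- sqrt(log(1 + adc_cv^2))
      adc_field[vox] <- stats::rlnorm(length(vox), log(m) - sdl^2 / 2, sdl)
    }
    sigma <- if (is.finite(snr_b0)) s0 / snr_b0 else 0
    lapply(seq_len(n_scans), function(s) {
      drift <- (1 + scan_drift)^(s - 1)
      imgs <- lapply(b_values, function(b) {
        S <- matrix(0, grid[1], grid[2])
        tissue <- !is.na(adc_field)
        S[tissue] <- s0 * exp(-b * adc_field[tissue] * drift)
        if (sigma > 0) {
          S <- sqrt((S + sigma * stats::rnorm(length(S)))^2 +
                      (sigma * stats::rnorm(length(S)))^2)
        }
        S
      })
      dwi_stack(imgs, b_values, scan_id = s, label_map = label_map,
                groups = stats::setNames(wells$group, seq_len(nrow(wells))),
                truth = adc_field * drift)
    })
  })
}

#' Generate a synthetic collagen immunofluorescence image
#'
#' Emulates the two collagen-deposition phenotypes seen in organoid
#' sections: a peripheral ring (signal concentrated in an annulus at a
#' chosen normalized radius — control-like) versus scattered puncta
#' placed uniformly at random in the section (mutant-like). With
#' `match_total_signal = TRUE` the scattered mode places as many puncta
#' as needed to match the ring's signal area, so the two phenotypes
#' differ in organization but not total intensity.
#'
#' @param mode `"ring"` or `"scattered"`.
#' @param organoid_radius_px section radius (pixels).
#' @param ring_radius_norm ring position as a fraction of the radius
#'   (0.8 for an early, peripheral ring; smaller for an internalized one).
#' @param ring_width_norm annulus width as a fraction of the radius.
#' @param n_puncta number of puncta in scattered mode (overridden when
#'   `match_total_signal` is set).
#' @param punctum_size_px punctum radius (pixels).
#' @param intensity_levels signal intensity above background.
#' @param noise_sd Gaussian background noise SD.
#' @param match_total_signal match scattered signal area to the ring's.
#' @param img_size image side (pixels).
#' @param seed RNG seed.
#' @return a `signal_image` with the organoid mask and a threshold at
#'   half the signal intensity.
#' @export
gen_collagen_image <- function(mode = c("ring", "scattered"),
                               organoid_radius_px = 100,
                               ring_radius_norm = 0.8,
                               ring_width_norm = 0.06,
                               n_puncta = 120, punctum_size_px = 3,
                               intensity_levels = 1, noise_sd = 0.05,
                               match_total_signal = TRUE,
                               img_size = 256, seed = NULL) {
  mode <- match.arg(mode)
  R <- organoid_radius_px
  if (2 * R >= img_size) stop_invalid("organoid does not fit in the image")
  if (ring_radius_norm + ring_width_norm / 2 > 1) {
    stop_invalid("ring extends beyond the organoid")
  }
  ctr <- (img_size + 1) / 2
  xs <- matrix(rep(seq_len(img_size), img_size), img_size)
  ys <- matrix(rep(seq_len(img_size), each = img_size), img_size)
  r_pix <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  mask <- r_pix <= R

  img <- matrix(0, img_size, img_size)
  with_seed(seed, {
    if (mode == "ring") {
      w <- ring_width_norm * R
      ann <- abs(r_pix - ring_radius_norm * R) <= w / 2 & mask
      img[ann] <- intensity_levels
    } else {
      target_px <- if (match_total_signal) {
        # match the painted area of the ring so the phenotypes differ in
        # organization, not total intensity
        sum(abs(r_pix - ring_radius_norm * R) <= ring_width_norm * R / 2 & mask)
      } else {
        round(n_puncta * pi * punctum_size_px^2)
      }
      rmax <- R - punctum_size_px
      painted <- matrix(FALSE, img_size, img_size)
      for (i in seq_len(10000L)) {
        if (sum(painted) >= target_px) break
        rr <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        hit <- (xs - (ctr + rr * cos(th)))^2 +
          (ys - (ctr + rr * sin(th)))^2 <= punctum_size_px^2
        painted <- painted | hit
      }
      img[painted] <- intensity_levels
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(img_size^2, sd = noise_sd), img_size)
    }
  })
  signal_image(img, mask, threshold = intensity_levels / 2, label = mode)
}

#' Fiber-network configuration presets
#'
#' Emits a configuration list for the microstructure stiffness model.
#' `study_default` is the 64-node, 32-cell, stretch/bend-ratio-10 system;
#' `more_cells` raises the cell count and `softer_fibers` lowers the
#' stretch/bend ratio (the exact variant values are this package's own
#' choices).
#'
#' @param preset one of `"study_default"`, `"more_cells"`,
#'   `"softer_fibers"`.
#' @param overrides named list merged over the preset.
#' @return named list: `n_nodes`, `n_cells`, `R`, `lambda`, `strain`,
#'   `fd_step`.
#' @export
gen_network_configs <- function(preset = c("study_default", "more_cells",
                                           "softer_fibers"),
                                overrides = list()) {
  preset <- match.arg(preset)
  cfg <- list(n_nodes = 64, n_cells = 32, R = 10, lambda = 1,
              strain = 0.01, fd_step = 1e-3)
  if (preset == "more_cells") cfg$n_cells <- 48
  if (preset == "softer_fibers") cfg$R <- 5
  cfg[names(overrides)] <- overrides
  cfg
}
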
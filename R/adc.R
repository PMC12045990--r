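#' Construct a multi-b diffusion-weighted stack
#'
#' One 2D intensity image per b-value on a common voxel grid, with the
#' b-values ascending from 0, plus optional per-well labels mapping
#' voxels to experimental groups.
#'
#' @param images list of numeric matrices, one per b-value, equal shape.
#' @param b_values diffusion weightings (s/mm^2), strictly increasing,
#'   first value 0.
#' @param voxel_size mm per axis.
#' @param scan_id scan identifier.
#' @param label_map optional integer matrix of well labels (0 background).
#' @param groups optional named lookup from well label to group name.
#' @param truth optional true ADC field (synthetic phantoms).
#' @return a `dwi_stack` object.
#' @export
dwi_stack <- function(images, b_values, voxel_size = c(0.1, 0.1),
                      scan_id = 1, label_map = NULL, groups = NULL,
                      truth = NULL) {
  if (length(images) != length(b_values)) {
    stop_invalid("one image per b-value is required")
  }
  if (length(b_values) < 2) stop_invalid("need at least 2 b-values")
  if (b_values[1] != 0 || any(diff(b_values) <= 0)) {
    stop_invalid("b_values must be strictly increasing with b[1] = 0")
  }
  dims <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), dims)) stop_invalid("all images must share one shape")
  }
  structure(list(images = images, b_values = b_values,
                 voxel_size = voxel_size, scan_id = scan_id,
                 label_map = label_map, groups = groups, truth = truth),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf("dwi_stack scan %s: %dx%d voxels, b = {%s} s/mm^2\n",
              x$scan_id, dim(x$images[[1]])[1], dim(x$images[[1]])[2],
              paste(x$b_values, collapse = ", ")))
  invisible(x)
}

#' Per-voxel apparent diffusion coefficient map
#'
#' Mono-exponential fit `ln S(b) = ln S0 - b ADC` by least squares over
#' all b-values, per voxel (the closed-form log-linear slope). Voxels
#' with any non-positive intensity, or a negative fitted ADC, are
#' excluded from the mask; the exclusion counts are reported.
#'
#' @param stack a [dwi_stack()].
#' @param mask optional logical matrix restricting the fit (e.g. from
#'   [segment_organoids()]); defaults to all voxels.
#' @return an `adc_map`: `adc` (mm^2/s, NA outside the mask), `s0`,
#'   `fit_r2`, the final `mask`, and `excluded` counts.
#' @export
fit_adc_map <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "dwi_stack"))
  dims <- dim(stack$images[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  b <- stack$b_values
  S <- vapply(stack$images, as.vector, numeric(prod(dims)))   # voxels x b
  candidate <- as.vector(mask)
  positive <- rowSums(S <= 0) == 0
  fitable <- candidate & positive

  Y <- log(S[fitable, , drop = FALSE])
  bc <- b - mean(b)
  ybar <- rowMeans(Y)
  slope <- (Y %*% bc) / sum(bc^2)
  adc_v <- -as.vector(slope)
  adc_v[abs(adc_v) < 1e-15] <- 0       # rounding noise on flat decays
  s0_v <- exp(ybar + adc_v * mean(b))
  pred <- outer(adc_v, -b) + log(s0_v)            # log-domain prediction
  sstot <- rowSums((Y - ybar)^2)
  ssres <- rowSums((Y - pred)^2)
  r2_v <- ifelse(sstot > 0, 1 - ssres / sstot, 1)

  adc <- s0 <- r2 <- matrix(NA_real_, dims[1], dims[2])
  adc[fitable] <- adc_v
  s0[fitable] <- s0_v
  r2[fitable] <- r2_v
  nonneg <- !is.na(adc) & adc >= 0
  final_mask <- matrix(FALSE, dims[1], dims[2])
  final_mask[nonneg & mask] <- TRUE
  adc[!final_mask] <- NA_real_
  structure(list(adc = adc, s0 = s0, fit_r2 = r2, mask = final_mask,
                 excluded = c(nonpositive_signal = sum(candidate & !positive),
                              negative_adc = sum(adc_v < 0))),
            class = "adc_map")
}

#' Segment organoid tissue from the highest-b image
#'
#' Automatic intensity thresholding (Otsu) of the most diffusion-weighted
#' image, where free medium has decayed away and tissue remains bright,
#' followed by small-object removal.
#'
#' @param stack a [dwi_stack()].
#' @param min_size smallest connected component kept (voxels).
#' @param threshold `"auto"` (Otsu) or a numeric intensity cutoff.
#' @return logical tissue mask.
#' @export
segment_organoids <- function(stack, min_size = 20, threshold = "auto") {
  stopifnot(inherits(stack, "dwi_stack"))
  img <- stack$images[[length(stack$images)]]
  rng <- range(img)
  if (identical(threshold, "auto")) {
    if (diff(rng) <= 0) stop("segmentation failure: uniform highest-b image")
    norm <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    mask <- img > threshold
  }
  if (!any(mask)) stop("segmentation failure: empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_size])
  mask <- matrix(as.integer(lab) %in% keep, nrow(img), ncol(img))
  if (!any(mask)) stop("segmentation failure: no component of size >= ", min_size)
  mask
}

#' 100-bin ADC histogram
#'
#' Reduces the masked ADC values to a normalized histogram (density sums
#' to one) over their range, the representation from which the
#' maximal-likelihood position is later estimated.
#'
#' @param map an [fit_adc_map()] result (or list with `adc` and `mask`).
#' @param mask optional logical matrix further restricting voxels (e.g.
#'   one well); intersected with the map's mask.
#' @param range optional fixed histogram range `c(lo, hi)` for
#'   cross-group overlays; defaults to the masked min-max.
#' @param bins number of bins (default 100).
#' @return an `adc_distribution`: `bin_centers`, `density`, `n_voxels`;
#'   `denoised` and `ml_position` are filled by the downstream steps.
#' @export
adc_distribution <- function(map, mask = NULL, range = NULL, bins = 100) {
  m <- map$mask
  if (!is.null(mask)) m <- m & mask
  vals <- map$adc[m]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop_invalid("empty mask: no ADC values to bin")
  if (length(vals) < bins) {
    warning("fewer masked voxels (", length(vals), ") than bins (", bins, ")")
  }
  if (is.null(range)) range <- c(min(vals), max(vals))
  if (diff(range) <= 0) range <- range + c(-1, 1) * max(abs(range[1]), 1e-12) * 1e-6
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- graphics::hist(pmin(pmax(vals, range[1]), range[2]),
                           breaks = edges, plot = FALSE)$counts
  structure(list(bin_centers = (edges[-1] + edges[-(bins + 1)]) / 2,
                 density = counts / sum(counts), denoised = NULL,
                 ml_position = NA_real_, i_max = NA_real_,
                 n_voxels = length(vals)),
            class = "adc_distribution")
}

#' Fourier denoising of an ADC distribution
#'
#' Discrete Fourier transform of the binned density; frequency components
#' above `keep_modes` are zeroed; the inverse transform is clipped at
#' zero (densities are non-negative). Keeping all 50 resolvable modes of
#' a 100-bin histogram reproduces the input.
#'
#' @param dist an [adc_distribution()].
#' @param keep_modes number of lowest nonzero frequencies kept
#'   (1 to bins/2; default 10).
#' @return the distribution with `denoised` filled.
#' @export
denoise_distribution <- function(dist, keep_modes = 10) {
  n <- length(dist$density)
  if (keep_modes < 1 || keep_modes > n / 2) {
    stop_invalid("keep_modes must lie in [1, ", n / 2, "]")
  }
  f <- stats::fft(dist$density)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k)
  f[freq > keep_modes] <- 0
  sm <- Re(stats::fft(f, inverse = TRUE)) / n
  dist$denoised <- pmax(sm, 0)
  dist$i_max <- max(dist$denoised)
  dist
}

#' Maximal-likelihood position of an ADC distribution
#'
#' Robust location of an asymmetric denoised profile: find the peak
#' height Imax, interpolate the left and right crossings of (2/3) Imax
#' flanking the peak, and return the midpoint of the two crossing
#' positions. When ripple yields several crossings per side, the ones
#' nearest the peak are used.
#'
#' @param dist a denoised [adc_distribution()] (run
#'   [denoise_distribution()] first).
#' @return the ML position (same units as `bin_centers`); also stored in
#'   the object's `ml_position` when assigned back.
#' @export
maximal_likelihood_position <- function(dist) {
  y <- dist$denoised
  if (is.null(y)) stop_invalid("denoise the distribution before locating its peak")
  x <- dist$bin_centers
  ipk <- which.max(y)
  imax <- y[ipk]
  if (imax <= 0) stop_invalid("denoised profile has no positive peak")
  level <- 2 / 3 * imax

  cross_at <- function(i) {
    # linear interpolation of the level crossing between bins i and i+1
    x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }
  left <- NA_real_
  for (i in seq(ipk - 1, 1)) {
    if (ipk == 1) break
    if (y[i] < level && y[i + 1] >= level) { left <- cross_at(i); break }
  }
  right <- NA_real_
  if (ipk < length(y)) {
    for (i in seq(ipk, length(y) - 1)) {
      if (y[i] >= level && y[i + 1] < level) { right <- cross_at(i); break }
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    stop("boundary distribution: no 2/3-Imax crossing on ",
         if (!is.finite(left)) "the left" else "the right",
         " side of the peak")
  }
  (left + right) / 2
}

#' Per-scan relative deviations and matched t test
#'
#' Removes common longitudinal drift by expressing each group's
#' maximal-likelihood ADC position as a relative deviation from the
#' reference group within the same scan,
#' `(ADC_group - ADC_ref) / ADC_ref`, then averages across scans and
#' tests each contrast against zero with a paired (matched) t statistic
#' computed from its closed form.
#'
#' @param positions data.frame with columns `scan_id`, `group`,
#'   `ml_position` (one row per scan x group; all groups must be observed
#'   in every scan).
#' @param reference_group name of the reference condition.
#' @return list with `deviations` (scan_id, group, deviation_pct) and
#'   `tests` per non-reference group: mean and SD of the deviation (%),
#'   n, t statistic, df, p_value.
#' @export
group_comparison <- function(positions, reference_group) {
  req <- c("scan_id", "group", "ml_position")
  if (!all(req %in% names(positions))) {
    stop_invalid("positions needs columns ", paste(req, collapse = ", "))
  }
  if (!reference_group %in% positions$group) {
    stop_invalid("reference group '", reference_group, "' not present")
  }
  scans <- sort(unique(positions$scan_id))
  by_group <- split(positions, positions$group)
  for (g in names(by_group)) {
    if (!setequal(by_group[[g]]$scan_id, scans)) {
      stop_invalid("unmatched design: group '", g,
                   "' is missing some scans (matched t test requires all)")
    }
  }
  ref <- by_group[[reference_group]]
  ref_pos <- ref$ml_position[match(scans, ref$scan_id)]
  others <- setdiff(names(by_group), reference_group)
  dev_rows <- list()
  tests <- list()
  for (g in others) {
    d <- by_group[[g]]
    pos <- d$ml_position[match(scans, d$scan_id)]
    dev <- 100 * (pos - ref_pos) / ref_pos
    dev_rows[[g]] <- data.frame(scan_id = scans, group = g,
                                deviation_pct = dev)
    n <- length(dev)
    sdd <- stats::sd(dev)
    tstat <- if (sdd > 0) mean(dev) / (sdd / sqrt(n)) else 0
    tests[[g]] <- list(mean_pct = mean(dev), sd_pct = sdd, n = n,
                       statistic = tstat, df = n - 1,
                       p_value = 2 * stats::pt(-abs(tstat), n - 1),
                       method = "paired t vs reference")
  }
  list(deviations = do.call(rbind, dev_rows), tests = tests)
}

#' Run the full ADC pipeline on one phantom/scan series
#'
#' Convenience wrapper: for every scan and group, segment tissue on the
#' highest-b image, fit the ADC map, bin to 100 bins, Fourier-denoise,
#' and locate the maximal-likelihood position; then compare groups by
#' per-scan relative deviation.
#'
#' @param scans list of [dwi_stack()] objects sharing the well layout.
#' @param reference_group reference condition for the deviations.
#' @param keep_modes Fourier cutoff for [denoise_distribution()].
#' @param min_size small-object threshold for segmentation.
#' @return list with `positions` (scan_id, group, ml_position, n_voxels)
#'   and the [group_comparison()] output.
#' @export
adc_pipeline <- function(scans, reference_group, keep_modes = 10,
                         min_size = 20) {
  rows <- list()
  for (stack in scans) {
    if (is.null(stack$label_map) || is.null(stack$groups)) {
      stop_invalid("each scan needs a label_map and group lookup")
    }
    seg <- segment_organoids(stack, min_size = min_size)
    amap <- fit_adc_map(stack, mask = seg)
    for (g in unique(stack$groups)) {
      wells <- as.integer(names(stack$groups)[stack$groups == g])
      gmask <- matrix(stack$label_map %in% wells,
                      nrow(stack$label_map), ncol(stack$label_map))
      dist <- adc_distribution(amap, mask = gmask)
      dist <- denoise_distribution(dist, keep_modes = keep_modes)
      ml <- maximal_likelihood_position(dist)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = stack$scan_id, group = g, ml_position = ml,
        n_voxels = dist$n_voxels)
    }
  }
  positions <- do.call(rbind, rows)
  list(positions = positions,
       comparison = group_comparison(positions, reference_group))
}
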
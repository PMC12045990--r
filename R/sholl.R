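#' Construct a signal image for radial profiling
#'
#' An intensity image with the organoid section mask (largest connected
#' component kept) and an optional fixed intensity threshold defining the
#' binary signal map.
#'
#' @param intensity 2D numeric matrix (arbitrary units).
#' @param organoid_mask logical matrix marking the section.
#' @param pixel_size micrometers per pixel.
#' @param threshold intensity cutoff for signal-positive pixels; `NULL`
#'   selects one automatically (Otsu) when profiling.
#' @param label condition label.
#' @return a `signal_image` object.
#' @export
signal_image <- function(intensity, organoid_mask, pixel_size = 1,
                         threshold = NULL, label = "") {
  if (!identical(dim(intensity), dim(organoid_mask))) {
    stop_invalid("intensity and organoid_mask must have the same shape")
  }
  if (!any(organoid_mask)) stop_invalid("organoid mask is empty")
  lab <- EBImage::bwlabel(EBImage::Image(organoid_mask * 1))
  sizes <- table(lab[lab > 0])
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  organoid_mask <- matrix(as.integer(lab) == biggest,
                          nrow(intensity), ncol(intensity))
  structure(list(intensity = intensity, organoid_mask = organoid_mask,
                 pixel_size = pixel_size, threshold = threshold,
                 label = label),
            class = "signal_image")
}

#' Section center and radius
#'
#' With a manually drawn diameter line, reproduces the widest-diameter
#' procedure: the center is the line's midpoint and the radius half its
#' length. Without one, the automated default takes the mask centroid and
#' the maximum centroid-to-boundary distance.
#'
#' @param image a [signal_image()].
#' @param manual_line optional 2x2 matrix of endpoint pixel coordinates
#'   (rows = endpoints, cols = x, y).
#' @return list with `center` (x, y in pixels) and `radius` (pixels).
#' @export
find_center <- function(image, manual_line = NULL) {
  mask <- image$organoid_mask
  if (!is.null(manual_line)) {
    manual_line <- as.matrix(manual_line)
    for (e in 1:2) {
      px <- round(manual_line[e, 1]); py <- round(manual_line[e, 2])
      if (px < 1 || py < 1 || px > nrow(mask) || py > ncol(mask) ||
          !mask[px, py]) {
        stop_invalid("manual line endpoint (", px, ", ", py,
                     ") lies outside the organoid mask")
      }
    }
    center <- colMeans(manual_line)
    radius <- sqrt(sum((manual_line[1, ] - manual_line[2, ])^2)) / 2
  } else {
    idx <- which(mask, arr.ind = TRUE)
    center <- colMeans(idx)
    radius <- sqrt(max((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2))
    center <- c(center[[1]], center[[2]])
  }
  list(center = unname(center), radius = unname(radius))
}

#' Sholl counts on concentric circles
#'
#' Thresholds the image and, for circles of normalized radius
#' `increment, 2*increment, ..., 1` around the section center, counts the
#' signal objects intersecting each circle: a contiguous arc of
#' signal-positive pixels on the rasterized circle counts once. Circles
#' extending past the image edge are counted on their in-image arc (with
#' a warning).
#'
#' @param image a [signal_image()].
#' @param center,radius pixel center and radius; defaults from
#'   [find_center()].
#' @param increment normalized radial step in (0, 0.2] (default 0.02,
#'   i.e. 50 circles to the section edge).
#' @param threshold intensity cutoff; defaults to the image's stored
#'   threshold, else Otsu.
#' @return a `radial_profile`: `radii` (normalized), `counts`, `center`,
#'   `organoid_radius` (micrometers), `label`.
#' @export
sholl_counts <- function(image, center = NULL, radius = NULL,
                         increment = 0.02, threshold = NULL) {
  if (increment <= 0 || increment > 0.2) {
    stop_invalid("increment must lie in (0, 0.2]")
  }
  if (is.null(center) || is.null(radius)) {
    fc <- find_center(image)
    if (is.null(center)) center <- fc$center
    if (is.null(radius)) radius <- fc$radius
  }
  if (is.null(threshold)) threshold <- image$threshold
  if (is.null(threshold)) {
    rng <- range(image$intensity)
    norm <- (image$intensity - rng[1]) / max(diff(rng), 1e-12)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  binary <- image$intensity > threshold
  nr <- nrow(binary); nc <- ncol(binary)

  radii <- seq(increment, 1, by = increment)
  counts <- integer(length(radii))
  truncated <- FALSE
  for (ri in seq_along(radii)) {
    r_px <- radii[ri] * radius
    n_theta <- max(64L, ceiling(4 * pi * r_px))   # ~0.5 px arc step
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    px <- round(center[1] + r_px * cos(th))
    py <- round(center[2] + r_px * sin(th))
    inside <- px >= 1 & px <= nr & py >= 1 & py <= nc
    if (!all(inside)) truncated <- TRUE
    vals <- logical(length(th))
    vals[inside] <- binary[cbind(px[inside], py[inside])]
    # drop consecutive duplicate pixels so a pixel is one sample
    dup <- c(FALSE, px[-1] == px[-length(px)] & py[-1] == py[-length(py)])
    vals <- vals[!dup]
    if (length(vals) == 0) next
    prev <- c(vals[length(vals)], vals[-length(vals)])   # circular lag
    runs <- sum(vals & !prev)
    if (runs == 0 && all(vals)) runs <- 1L
    counts[ri] <- runs
  }
  if (truncated) warning("some circles extend past the image; counts use the in-image arc")
  structure(list(radii = radii, counts = counts, center = center,
                 organoid_radius = radius * image$pixel_size,
                 label = image$label),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile '%s': %d circles, %d intersections total, radius %.1f um\n",
              x$label, length(x$radii), sum(x$counts), x$organoid_radius))
  invisible(x)
}

#' Compare radial profiles between conditions
#'
#' Pools per-circle observations within each group and applies the
#' two-sided Mann-Whitney U test. The default pooling uses the per-circle
#' intersection counts; `"radius_weighted"` instead pools the normalized
#' radius of every counted intersection (each intersection contributes
#' one copy of its circle's radius), comparing the radial positions of
#' the signal.
#'
#' @param profiles_a,profiles_b lists of `radial_profile` objects (one or
#'   more per condition).
#' @param pooling `"counts"` or `"radius_weighted"`.
#' @return the [mann_whitney_u()] result plus the pooled sample sizes.
#' @export
compare_profiles <- function(profiles_a, profiles_b,
                             pooling = c("counts", "radius_weighted")) {
  pooling <- match.arg(pooling)
  if (length(profiles_a) == 0 || length(profiles_b) == 0) {
    stop_invalid("each condition needs at least one profile")
  }
  pool <- function(ps) {
    if (pooling == "counts") {
      unlist(lapply(ps, `[[`, "counts"))
    } else {
      unlist(lapply(ps, function(p) rep(p$radii, p$counts)))
    }
  }
  a <- pool(profiles_a); b <- pool(profiles_b)
  res <- mann_whitney_u(a, b)
  res$n1 <- length(a); res$n2 <- length(b); res$pooling <- pooling
  res
}

#' Mann-Whitney U test (closed form)
#'
#' Two-sided rank-sum test computed directly: `U = R1 - n1(n1+1)/2` from
#' the ranks of the first sample. For combined sample sizes up to
#' `exact_max` the p-value is obtained by exact enumeration of all
#' arrangements of the pooled values; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined n for exact enumeration (default 20).
#' @return list: `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_invalid("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    rs <- matrix(r[idx], nrow = n1)
    Uperm <- colSums(rs) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    method <- "Mann-Whitney U, exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    p <- min(p, 1)
    method <- "Mann-Whitney U, normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method)
}
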
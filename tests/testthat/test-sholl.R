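disk_image <- function(size = 101, cx = 51, cy = 51, R = 30) {
  xs <- matrix(rep(seq_len(size), size), size)
  ys <- matrix(rep(seq_len(size), each = size), size)
  mask <- (xs - cx)^2 + (ys - cy)^2 <= R^2
  signal_image(matrix(0, size, size), mask, threshold = 0.5)
}

test_that("center finding matches the geometry on a disk", {
  img <- disk_image()
  fc <- find_center(img)
  expect_equal(fc$center, c(51, 51), tolerance = 1)
  expect_equal(fc$radius, 30, tolerance = 1)
  # manual diameter line reproduces the automated result
  fm <- find_center(img, manual_line = rbind(c(21, 51), c(81, 51)))
  expect_equal(fm$center, c(51, 51), tolerance = 1)
  expect_equal(fm$radius, 30, tolerance = 1)
  expect_error(find_center(img, manual_line = rbind(c(1, 1), c(81, 51))),
               "outside")
})

test_that("centroid of an eccentric blob matches pixel averaging", {
  size <- 60
  mask <- matrix(FALSE, size, size)
  set.seed(3)
  seedpts <- cbind(sample(10:50, 40, TRUE), sample(10:50, 40, TRUE))
  mask[seedpts] <- TRUE
  mask[20:40, 15:25] <- TRUE                 # one big component
  img <- signal_image(matrix(0, size, size), mask, threshold = 0.5)
  fc <- find_center(img)
  idx <- which(img$organoid_mask, arr.ind = TRUE)
  expect_equal(fc$center, unname(colMeans(idx)))
})

test_that("an annulus of signal intersects only the matching circles", {
  size <- 201; ctr <- 101; R <- 90
  xs <- matrix(rep(seq_len(size), size), size)
  ys <- matrix(rep(seq_len(size), each = size), size)
  r <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  img <- matrix(0, size, size)
  img[abs(r - 0.8 * R) <= 0.025 * R] <- 1
  si <- signal_image(img, r <= R, threshold = 0.5)
  prof <- sholl_counts(si, center = c(ctr, ctr), radius = R,
                       increment = 0.02)
  core <- prof$radii >= 0.79 & prof$radii <= 0.81
  expect_true(all(prof$counts[core] == 1))
  outside <- prof$radii < 0.77 | prof$radii > 0.83
  expect_true(all(prof$counts[outside] == 0))
})

test_that("an empty signal yields zero counts everywhere", {
  prof <- sholl_counts(disk_image(), increment = 0.05)
  expect_equal(prof$counts, rep(0L, length(prof$radii)))
})

test_that("isolated puncta on one circle are each counted once", {
  size <- 201; ctr <- 101; R <- 100
  xs <- matrix(rep(seq_len(size), size), size)
  ys <- matrix(rep(seq_len(size), each = size), size)
  mask <- (xs - ctr)^2 + (ys - ctr)^2 <= R^2
  for (k in c(3, 7)) {
    img <- matrix(0, size, size)
    ang <- 2 * pi * (seq_len(k) - 1) / k + 0.1
    px <- ctr + 0.6 * R * cos(ang); py <- ctr + 0.6 * R * sin(ang)
    for (i in seq_len(k)) img[(xs - px[i])^2 + (ys - py[i])^2 <= 9] <- 1
    si <- signal_image(img, mask, threshold = 0.5)
    prof <- sholl_counts(si, center = c(ctr, ctr), radius = R,
                         increment = 0.02)
    expect_equal(prof$counts[prof$radii == 0.6], k)
  }
})

test_that("profiles are stable under 90-degree rotation", {
  ring <- gen_collagen_image("ring", seed = 21)
  p1 <- sholl_counts(ring)
  rot <- signal_image(t(ring$intensity[nrow(ring$intensity):1, ]),
                      t(ring$organoid_mask[nrow(ring$organoid_mask):1, ]),
                      threshold = ring$threshold)
  p2 <- sholl_counts(rot)
  expect_true(all(abs(p1$counts - p2$counts) <= 1))
})

test_that("Mann-Whitney U matches its closed form and exact enumeration", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)                        # n1*n2/2
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)
  # oracle equivalence on 100 random small samples (with and without ties)
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:10, n1, replace = TRUE)
    y <- sample(1:10, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p_value, enumerate_mw_p(x, y), tolerance = 1e-12)
    if (!any(duplicated(c(x, y)))) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(got$U, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # large-sample normal approximation against the standard implementation
  set.seed(18)
  xl <- rnorm(40); yl <- rnorm(35, 0.5)
  got <- mann_whitney_u(xl, yl)
  ref <- wilcox.test(xl, yl, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("profile pooling modes feed the comparison as documented", {
  pa <- structure(list(radii = c(0.5, 1), counts = c(2L, 0L)),
                  class = "radial_profile")
  pb <- structure(list(radii = c(0.5, 1), counts = c(0L, 3L)),
                  class = "radial_profile")
  rw <- compare_profiles(list(pa), list(pb), pooling = "radius_weighted")
  expect_equal(rw$n1, 2)                        # two intersections at 0.5
  expect_equal(rw$n2, 3)
  ct <- compare_profiles(list(pa), list(pb), pooling = "counts")
  expect_equal(ct$n1, 2)                        # two circles
  expect_error(compare_profiles(list(), list(pb)), "at least one")
})

test_that("TIFF round trip preserves the signal image", {
  img <- gen_collagen_image("ring", seed = 44)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pmin(pmax(img$intensity, 0), 1), f)
  back <- read_signal_image(f, organoid_mask = img$organoid_mask,
                            threshold = img$threshold)
  p1 <- sholl_counts(img)
  p2 <- sholl_counts(back)
  expect_true(all(abs(p1$counts - p2$counts) <= 1))
})
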
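make_stack <- function(adc_true, s0 = 1000,
                       b = c(0, 200, 400, 600, 1000, 1200)) {
  imgs <- lapply(b, function(bb) s0 * exp(-bb * adc_true))
  dwi_stack(imgs, b)
}

test_that("log-linear fit is exact on noiseless mono-exponential decay", {
  adc_true <- matrix(0.002, 4, 4)
  m <- fit_adc_map(make_stack(adc_true))
  expect_equal(m$adc, adc_true, tolerance = 1e-12)
  expect_equal(unname(m$s0[1, 1]), 1000, tolerance = 1e-9)
  # heterogeneous field, arbitrary b-set with two values
  set.seed(5)
  adc2 <- matrix(runif(36, 5e-4, 3e-3), 6, 6)
  m2 <- fit_adc_map(make_stack(adc2, b = c(0, 750)))
  expect_equal(m2$adc, adc2, tolerance = 1e-12)
})

test_that("constant signal fits to zero ADC and nonpositive voxels drop out", {
  imgs <- lapply(1:6, function(i) matrix(800, 3, 3))
  m <- fit_adc_map(dwi_stack(imgs, c(0, 200, 400, 600, 1000, 1200)))
  expect_equal(m$adc, matrix(0, 3, 3))
  imgs[[2]][1, 1] <- 0
  m2 <- fit_adc_map(dwi_stack(imgs, c(0, 200, 400, 600, 1000, 1200)))
  expect_true(is.na(m2$adc[1, 1]))
  expect_equal(unname(m2$excluded["nonpositive_signal"]), 1)
  expect_error(dwi_stack(imgs[1], 0), "at least 2")
})

test_that("masked median ADC survives Rician noise", {
  err <- vapply(1:50, function(s) {
    ph <- gen_dwi_phantom(adc_mean = c(control = 1e-3), n_scans = 1,
                          scan_drift = 0, snr_b0 = 30, seed = s,
                          wells = data.frame(x = 48, y = 48, radius = 20,
                                             group = "control"))[[1]]
    m <- fit_adc_map(ph, mask = ph$label_map > 0)
    abs(median(m$adc[m$mask]) / median(ph$truth[ph$label_map > 0]) - 1)
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("highest-b segmentation recovers the phantom geometry", {
  ph <- gen_dwi_phantom(n_scans = 1, snr_b0 = Inf, seed = 1)[[1]]
  mask <- segment_organoids(ph)
  truth <- ph$label_map > 0
  expect_equal(sum(mask & truth) / sum(mask), 1)       # precision
  expect_equal(sum(mask & truth) / sum(truth), 1)      # recall
  phn <- gen_dwi_phantom(n_scans = 1, snr_b0 = 30, seed = 2)[[1]]
  maskn <- segment_organoids(phn)
  truthn <- phn$label_map > 0
  dice <- 2 * sum(maskn & truthn) / (sum(maskn) + sum(truthn))
  expect_gte(dice, 0.95)
  uni <- dwi_stack(lapply(1:2, function(i) matrix(5, 8, 8)), c(0, 1000))
  expect_error(segment_organoids(uni), "uniform")
})

test_that("the 100-bin histogram is normalized and shaped as expected", {
  fake_map <- function(v) {
    n <- ceiling(sqrt(length(v)))
    adc <- matrix(NA_real_, n, n); adc[seq_along(v)] <- v
    list(adc = adc, mask = !is.na(adc))
  }
  d1 <- adc_distribution(fake_map(rep(2e-3, 500)))
  expect_equal(sum(d1$density), 1)
  expect_equal(max(d1$density), 1)                     # one occupied bin
  set.seed(7)
  d2 <- adc_distribution(fake_map(runif(1e5)))
  expect_equal(sum(d2$density), 1)
  chi <- chisq.test(d2$density * 1e5)
  expect_gt(chi$p.value, 0.01)                         # flat within sampling
  expect_error(adc_distribution(fake_map(numeric(0))), "empty")
})

test_that("Fourier denoising keeps low modes and is identity at full width", {
  x <- (0:99) / 100
  lowfreq <- 0.01 + 0.004 * cos(2 * pi * 3 * x)
  spike <- 0.001 * cos(2 * pi * 37 * x)
  dist <- structure(list(bin_centers = x, density = lowfreq + spike),
                    class = "adc_distribution")
  out <- denoise_distribution(dist, keep_modes = 10)
  expect_equal(out$denoised, lowfreq, tolerance = 1e-10)
  ident <- denoise_distribution(dist, keep_modes = 50)
  expect_equal(ident$denoised, dist$density, tolerance = 1e-12)
  expect_error(denoise_distribution(dist, keep_modes = 0), "keep_modes")
  expect_error(denoise_distribution(dist, keep_modes = 51), "keep_modes")

  # smoothing preserves the location of a symmetric unimodal profile
  g <- dnorm(x, 0.5, 0.08); g <- g / sum(g)
  gd <- denoise_distribution(
    structure(list(bin_centers = x, density = g), class = "adc_distribution"),
    keep_modes = 10)
  m_raw <- sum(x * g)
  m_sm <- sum(x * gd$denoised / sum(gd$denoised))
  expect_lt(abs(m_sm - m_raw), 0.01)                   # one bin width
})

test_that("the 2/3-Imax rule locates distribution peaks", {
  x <- seq(-3, 6, by = 0.05)
  tri <- pmax(0, pmin(1 + x / 3, 1 - x / 6))     # 2/3 crossings at -1 and +2
  dist <- structure(list(bin_centers = x, denoised = tri),
                    class = "adc_distribution")
  expect_equal(maximal_likelihood_position(dist), 0.5, tolerance = 1e-9)
  # scale invariance
  dist2 <- dist; dist2$denoised <- dist$denoised * 7.3
  expect_equal(maximal_likelihood_position(dist2), 0.5, tolerance = 1e-9)
  # shift equivariance
  dist3 <- dist; dist3$bin_centers <- x + 10
  expect_equal(maximal_likelihood_position(dist3), 10.5, tolerance = 1e-9)
  # symmetric Gaussian: center recovered within a bin
  xg <- (0:99) / 100
  gg <- structure(list(bin_centers = xg, denoised = dnorm(xg, 0.42, 0.1)),
                  class = "adc_distribution")
  expect_lt(abs(maximal_likelihood_position(gg) - 0.42), 0.01)
  # truncated distribution has no left crossing
  mono <- structure(list(bin_centers = xg, denoised = xg),
                    class = "adc_distribution")
  expect_error(maximal_likelihood_position(mono), "boundary")
})

test_that("relative deviations remove common drift and match closed forms", {
  pos <- data.frame(scan_id = rep(1:3, 2),
                    group = rep(c("ref", "mut"), each = 3),
                    ml_position = c(1, 1, 1, 1.02, 1.03, 1.04))
  out <- group_comparison(pos, "ref")
  expect_equal(out$tests$mut$mean_pct, 3)
  expect_equal(out$tests$mut$sd_pct, 1)
  expect_equal(out$tests$mut$statistic, 3 * sqrt(3), tolerance = 1e-9)
  # identical groups give zero deviations and t = 0
  pos0 <- pos; pos0$ml_position <- rep(c(1, 1.1, 0.9), 2)
  out0 <- group_comparison(pos0, "ref")
  expect_equal(out0$deviations$deviation_pct, rep(0, 3))
  expect_equal(out0$tests$mut$statistic, 0)
  # per-scan multiplicative drift cancels in the ratio
  drift <- c(1, 1.05, 1.12)
  posd <- pos; posd$ml_position <- pos$ml_position * rep(drift, 2)
  outd <- group_comparison(posd, "ref")
  expect_equal(outd$deviations$deviation_pct,
               out$deviations$deviation_pct, tolerance = 1e-12)
  # unmatched scans are refused
  expect_error(group_comparison(pos[-2, ], "ref"), "unmatched")
})
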
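test_that("creep compliance follows the half-space aspiration formula", {
  t <- 0:10
  tr <- creep_trace(t, rep(50, 11), pipette_radius = 150, pressure = 1000,
                    suction_onset = 0)
  cc <- compute_creep_compliance(tr)
  expect_equal(cc$J, rep(2 * pi * (50 / 150) / (3 * 2.1 * 1000), 11))
  expect_equal(cc$J[1], 3.325e-4, tolerance = 1e-3)

  # zero deformation gives zero compliance
  tr0 <- creep_trace(t, rep(0, 11), pipette_radius = 150, pressure = 1000,
                     suction_onset = 0)
  expect_equal(compute_creep_compliance(tr0)$J, rep(0, 11))
})

test_that("compliance is linear in L and inverse-linear in pressure", {
  t <- seq(0, 5, by = 0.5)
  L <- sls_creep_model(t, 400, 250, 2) * 1e5
  base <- compute_creep_compliance(
    creep_trace(t, L, 200, 1500, suction_onset = 0))
  doubledP <- compute_creep_compliance(
    creep_trace(t, L, 200, 3000, suction_onset = 0))
  doubledL <- compute_creep_compliance(
    creep_trace(t, 2 * L, 200, 1500, suction_onset = 0))
  expect_equal(doubledP$J, base$J / 2)
  expect_equal(doubledL$J, base$J * 2)
})

test_that("invalid traces are rejected", {
  expect_error(creep_trace(c(0, 1, 1), c(0, 1, 2), 150, 1000), "increasing")
  expect_error(creep_trace(0:2, 0:2, 150, -5), "positive")
  expect_error(creep_trace(0:2, 0:2, 0, 1000), "positive")
  expect_error(creep_trace(0:2, 0:2, 150, 1000, suction_onset = 9),
               "outside")
})

test_that("the SLS creep model has the right limits and monotonicity", {
  expect_equal(sls_creep_model(0, 400, 250, 2), 1 / 400)
  expect_equal(sls_creep_model(1e6, 400, 250, 2), 1 / 250)
  k <- 300
  expect_equal(sls_creep_model(3, 2 * k, k, 3), (1 - 0.5 * exp(-1)) / k)
  t <- seq(0, 20, by = 0.01)
  expect_true(all(diff(sls_creep_model(t, 700, 150, 1.3)) >= 0))
  expect_error(sls_creep_model(1, 200, 300, 2), "k0 >= k_st")
  expect_error(sls_creep_model(1, 400, 250, -1), "k0 >= k_st|tau")
})

test_that("fit recovers parameters exactly from noiseless compliance", {
  cc <- make_clean_compliance(k0 = 400, k_st = 250, tau = 2, rate = 10)
  f <- fit_sls(cc)
  expect_equal(f$k0, 400, tolerance = 1e-6)
  expect_equal(f$k_st, 250, tolerance = 1e-6)
  expect_equal(f$tau, 2, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # fitted model limits match the recovered stiffnesses
  expect_equal(sls_creep_model(0, f$k0, f$k_st, f$tau), 1 / f$k0)
  expect_equal(sls_creep_model(1e9, f$k0, f$k_st, f$tau), 1 / f$k_st)
})

test_that("fit tolerates realistic multiplicative noise", {
  ok <- vapply(1:200, function(s) {
    tr <- gen_creep_traces(1, k0 = 400, k_st = 250, tau = 2,
                           noise_frac = 0.01, seed = s)[[1]]
    f <- fit_sls(compute_creep_compliance(tr))
    all(abs(c(f$k0 / 400, f$k_st / 250, f$tau / 2) - 1) < 0.05) &&
      f$r_squared > 0.98
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a flat compliance is reported as a degenerate elastic fit", {
  t <- seq(0, 5, by = 0.1)
  cc <- structure(list(time = t, J = rep(4e-3, length(t)), label = "flat"),
                  class = "creep_compliance")
  f <- fit_sls(cc)
  expect_true(f$degenerate_tau)
  expect_equal(f$k_st, 250)
  expect_equal(f$k0, f$k_st)
})

test_that("fit is invariant to rescaling the time axis", {
  cc <- make_clean_compliance(tau = 2)
  f1 <- fit_sls(cc)
  cc_ms <- cc
  cc_ms$time <- cc$time * 1000        # same curve in milliseconds
  f2 <- fit_sls(cc_ms)
  expect_equal(f2$tau, f1$tau * 1000, tolerance = 1e-6)
  expect_equal(f2$k0, f1$k0, tolerance = 1e-6)
  expect_equal(f2$k_st, f1$k_st, tolerance = 1e-6)
})

test_that("parameter recovery holds across the measured organoid regime", {
  set.seed(42)
  rel_err <- t(vapply(1:30, function(i) {
    kst <- runif(1, 100, 700)
    k0 <- kst * runif(1, 1.2, 1.43)          # k0 up to ~1000 Pa
    tau <- runif(1, 0.5, 5)
    nf <- runif(1, 0.01, 0.03)
    tr <- gen_creep_traces(1, k0 = k0, k_st = kst, tau = tau,
                           noise_frac = nf, seed = 1000 + i)[[1]]
    f <- fit_sls(compute_creep_compliance(tr))
    abs(c(f$k0 / k0, f$k_st / kst, f$tau / tau) - 1)
  }, numeric(3)))
  expect_lt(median(rel_err[, 1]), 0.05)
  expect_lt(median(rel_err[, 2]), 0.05)
  expect_lt(median(rel_err[, 3]), 0.05)
})

test_that("Maxwell elements follow from the creep parameters", {
  m <- derive_maxwell_elements(list(k0 = 400, k_st = 250, tau = 2))
  expect_equal(m$k1, 250)
  expect_equal(m$k2, 150)
  expect_equal(m$mu, 187.5)
  # round trip through the response-time relation
  expect_equal(m$mu * (m$k1 + m$k2) / (m$k1 * m$k2), 2, tolerance = 1e-9)
  # symmetric arms: mu = k*tau/2
  m2 <- derive_maxwell_elements(list(k0 = 2 * 300, k_st = 300, tau = 4))
  expect_equal(m2$mu, 300 * 4 / 2)
  expect_error(derive_maxwell_elements(list(k0 = 250, k_st = 250, tau = 2)),
               "degenerate")
})

test_that("condition summaries reproduce closed-form statistics", {
  fits <- lapply(c(1, 2, 3, 4, 5, 6), function(v)
    structure(list(k0 = v, k_st = v / 2, tau = 1 + v / 10), class = "sls_fit"))
  out <- summarize_condition(fits, rep(c("a", "b"), each = 3))
  expect_equal(out$tests$k0$statistic, -3.674, tolerance = 1e-3)
  expect_equal(out$tests$k0$df, 4)
  # cross-check against the standard library implementation
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(out$tests$k0$statistic, unname(ref$statistic))
  expect_equal(out$tests$k0$p_value, ref$p.value)

  # identical groups: t = 0, p = 1
  fits2 <- lapply(c(1, 2, 3, 1, 2, 3), function(v)
    structure(list(k0 = v, k_st = v, tau = v), class = "sls_fit"))
  out2 <- summarize_condition(fits2, rep(c("a", "b"), each = 3))
  expect_equal(out2$tests$k0$statistic, 0)
  expect_equal(out2$tests$k0$p_value, 1)

  # three groups with equal means: F ~ 0
  g <- c(1, 2, 3)
  out3 <- summarize_condition(
    lapply(c(g, g + 0, g - 0), function(v)
      structure(list(k0 = v, k_st = v, tau = v), class = "sls_fit")),
    rep(c("a", "b", "c"), each = 3))
  expect_equal(out3$tests$k0$statistic, 0)
  ref3 <- summary(aov(y ~ g, data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                                        g = factor(rep(1:3, each = 3)))))
  out4 <- summarize_condition(
    lapply(c(1, 2, 3, 2, 3, 4, 3, 4, 5), function(v)
      structure(list(k0 = v, k_st = v, tau = v), class = "sls_fit")),
    rep(c("a", "b", "c"), each = 3))
  expect_equal(out4$tests$k0$statistic, ref3[[1]]$`F value`[1])

  expect_error(summarize_condition(fits[1:3], c("a", "a", "b")),
               "at least 2")
})
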
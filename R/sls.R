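#' Construct a micropipette-aspiration creep trace
#'
#' Bundles a timed record of the aspirated-tongue length with the pipette
#' geometry and the applied suction, the raw material for creep-compliance
#' analysis. Time must be strictly increasing; the aspirated length is in
#' micrometers, the pipette radius in micrometers, and the suction
#' magnitude (relative to atmosphere) in pascals.
#'
#' @param time sample times (seconds), strictly increasing.
#' @param aspirated_length tongue length L(t) (micrometers), non-negative.
#' @param pipette_radius pipette inner radius Rp (micrometers), > 0.
#' @param pressure suction magnitude (pascals), > 0.
#' @param wall_factor dimensionless geometric pipette wall factor
#'   (default 2.1).
#' @param suction_onset time (seconds) at which the load begins, or
#'   `NULL` to detect it from the data in [compute_creep_compliance()].
#' @param label free-text condition / organoid identifier.
#' @return a `creep_trace` object.
#' @export
creep_trace <- function(time, aspirated_length, pipette_radius, pressure,
                        wall_factor = 2.1, suction_onset = NULL,
                        label = "") {
  if (length(time) != length(aspirated_length)) {
    stop_invalid("time and aspirated_length must have the same length")
  }
  if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
  if (!is.numeric(pressure) || pressure <= 0) {
    stop_invalid("pressure must be strictly positive")
  }
  if (!is.numeric(pipette_radius) || pipette_radius <= 0) {
    stop_invalid("pipette_radius must be strictly positive")
  }
  if (!is.null(suction_onset) &&
      (suction_onset < time[1] || suction_onset > time[length(time)])) {
    stop_invalid("suction_onset lies outside the recorded time window")
  }
  structure(list(time = as.numeric(time),
                 aspirated_length = as.numeric(aspirated_length),
                 pipette_radius = pipette_radius, pressure = pressure,
                 wall_factor = wall_factor, suction_onset = suction_onset,
                 label = label),
            class = "creep_trace")
}

#' @export
print.creep_trace <- function(x, ...) {
  cat(sprintf(
    "creep_trace '%s': %d samples over %.2f s, Rp = %g um, dP = %g Pa, phi = %g\n",
    x$label, length(x$time), diff(range(x$time)), x$pipette_radius,
    x$pressure, x$wall_factor))
  invisible(x)
}

# Onset detection: first sample where L exceeds the baseline mean plus
# 3 baseline SDs; the baseline is the leading window before any rise.
detect_onset <- function(trace, baseline_frac = 0.1) {
  L <- trace$aspirated_length
  n <- length(L)
  nb <- max(5L, floor(baseline_frac * n))
  if (nb >= n) nb <- max(2L, n - 2L)
  mu <- mean(L[seq_len(nb)])
  sdb <- stats::sd(L[seq_len(nb)])
  # floor the threshold at 10% of the rise to the plateau: the SLS elastic
  # jump is a large fraction of the plateau, baseline spikes are not
  plateau <- mean(sort(L, decreasing = TRUE)[seq_len(max(3L, n %/% 10))])
  thr <- mu + max(3 * max(sdb, 1e-12), 0.1 * max(plateau - mu, 0))
  above <- L > thr
  # three consecutive samples above threshold, so noise spikes cannot trip it
  idx <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  idx <- idx[idx > 1L]
  if (length(idx) == 0) return(trace$time[1])
  trace$time[idx[1]]
}

#' Creep compliance from an aspiration trace
#'
#' Converts the aspirated length into the creep compliance
#' `J(t) = 2 pi L(t) / (3 phi Rp dP)` of the half-space aspiration model,
#' with L and Rp in the same length units so J carries units of 1/Pa.
#' Time is re-zeroed at the suction onset and pre-onset samples are
#' discarded (kept as baseline metadata).
#'
#' @param trace a [creep_trace()].
#' @param onset suction onset time in seconds, `"auto"` (default; detect
#'   from the baseline, unless the trace carries an explicit
#'   `suction_onset`), or a numeric override.
#' @return a `creep_compliance` object: `time` (s, from onset), `J`
#'   (1/Pa), plus onset and label metadata.
#' @export
compute_creep_compliance <- function(trace, onset = "auto") {
  stopifnot(inherits(trace, "creep_trace"))
  if (identical(onset, "auto")) {
    onset <- if (!is.null(trace$suction_onset)) trace$suction_onset
             else detect_onset(trace)
  }
  if (onset < trace$time[1] || onset > trace$time[length(trace$time)]) {
    stop_invalid("suction onset lies outside the recorded time window")
  }
  keep <- trace$time >= onset
  # L/Rp is dimensionless (both micrometers); dP in Pa -> J in 1/Pa
  J <- 2 * pi * (trace$aspirated_length[keep] / trace$pipette_radius) /
    (3 * trace$wall_factor * trace$pressure)
  structure(list(time = trace$time[keep] - onset, J = J, onset = onset,
                 baseline = trace$aspirated_length[!keep],
                 label = trace$label),
            class = "creep_compliance")
}

#' Standard-linear-solid creep compliance
#'
#' The SLS (Zener) creep function
#' `J(t) = (1/k_st) * (1 - ((k0 - k_st)/k0) * exp(-t/tau))`:
#' instantaneous compliance `1/k0` at t = 0 rising to the steady-state
#' compliance `1/k_st` with response time `tau`.
#'
#' @param t times (seconds), `>= 0`; vectorized.
#' @param k0 instantaneous stiffness (Pa), `>= k_st`.
#' @param k_st steady-state stiffness (Pa), `> 0`.
#' @param tau response time (s), `> 0`.
#' @return compliance values (1/Pa).
#' @export
sls_creep_model <- function(t, k0, k_st, tau) {
  if (!(k_st > 0) || !(k0 >= k_st) || !(tau > 0)) {
    stop_invalid("require k0 >= k_st > 0 and tau > 0")
  }
  if (any(t < 0)) stop_invalid("t must be non-negative")
  (1 / k_st) * (1 - ((k0 - k_st) / k0) * exp(-t / tau))
}

#' Fit the SLS model to a creep-compliance record
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [sls_creep_model()]
#' to (t, J). Positivity and the ordering `k0 >= k_st` are enforced by
#' fitting `log(k_st)`, `log(k2)` with `k2 = k0 - k_st >= 0`, and
#' `log(tau)`. Starting values come from the data: `k0` from the first
#' post-onset compliance, `k_st` from the final 10% plateau, and `tau`
#' from the midpoint crossing between the two plateaus.
#'
#' @param compliance a `creep_compliance` (or list with `time`, `J`).
#' @param init optional named list/vector with any of `k0`, `k_st`, `tau`
#'   to override the data-driven starting values.
#' @return an `sls_fit`: `k0`, `k_st`, `tau` (Pa, Pa, s), the Maxwell
#'   elements `k1`, `k2`, `mu`, `r_squared`, `n_points`, and a
#'   `degenerate_tau` flag set when the transient arm vanishes (pure
#'   elastic response).
#' @export
fit_sls <- function(compliance, init = NULL) {
  t <- compliance$time
  J <- compliance$J
  if (length(t) < 4) stop_invalid("need at least 4 post-onset samples to fit")
  if (any(J < 0)) stop_invalid("compliance must be non-negative")

  n_tail <- max(3L, ceiling(0.1 * length(J)))
  J_end <- mean(utils::tail(J, n_tail))
  J_start <- if (J[1] > 0) J[1] else max(min(J[J > 0], na.rm = TRUE), 1e-12)
  kst0 <- 1 / max(J_end, 1e-12)
  k00 <- 1 / J_start
  if (!is.finite(k00) || k00 <= kst0) k00 <- 1.5 * kst0
  if (k00 > 20 * kst0) k00 <- 2 * kst0   # guard against a near-zero first sample
  midJ <- (J_start + J_end) / 2
  icross <- which(J >= midJ)
  tau0 <- if (length(icross) && t[icross[1]] > 0) t[icross[1]] else
    max(diff(range(t)) / 5, 1e-3)
  if (!is.null(init)) {
    init <- as.list(init)
    if (!is.null(init$k0)) k00 <- init$k0
    if (!is.null(init$k_st)) kst0 <- init$k_st
    if (!is.null(init$tau)) tau0 <- init$tau
  }
  k20 <- max(k00 - kst0, 1e-6 * kst0)

  df <- data.frame(t = t, J = J)
  start <- list(lkst = log(kst0), lk2 = log(k20), ltau = log(tau0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      J ~ (1 / exp(lkst)) *
        (1 - (exp(lk2) / (exp(lkst) + exp(lk2))) * exp(-t / exp(ltau))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)

  degenerate <- FALSE
  if (inherits(fit, "error")) {
    # flat / pure-elastic record: k0 -> k_st boundary, tau unidentifiable
    rel_rise <- (J_end - J_start) / max(J_end, 1e-300)
    if (abs(rel_rise) < 0.05) {
      kst <- 1 / mean(J)
      pred <- rep(mean(J), length(J))
      sstot <- sum((J - mean(J))^2)
      r2 <- if (sstot > 0) 1 - sum((J - pred)^2) / sstot else 1
      return(structure(list(k0 = kst, k_st = kst, tau = NA_real_,
                            k1 = kst, k2 = 0, mu = NA_real_,
                            r_squared = r2, n_points = length(J),
                            degenerate_tau = TRUE, label = compliance$label),
                       class = "sls_fit"))
    }
    stop("SLS fit failed to converge: ", conditionMessage(fit),
         " (residual range of J: ", paste(signif(range(J), 4), collapse = " .. "), ")")
  }
  cf <- stats::coef(fit)
  kst <- exp(cf[["lkst"]]); k2 <- exp(cf[["lk2"]]); tau <- exp(cf[["ltau"]])
  k0 <- kst + k2
  pred <- stats::fitted(fit)
  sstot <- sum((J - mean(J))^2)
  r2 <- if (sstot > 0) 1 - sum((J - pred)^2) / sstot else 1
  if (k2 / kst < 1e-6) degenerate <- TRUE
  structure(list(k0 = k0, k_st = kst, tau = tau,
                 k1 = kst, k2 = k2,
                 mu = if (k2 > 0) tau * kst * k2 / (kst + k2) else NA_real_,
                 r_squared = r2, n_points = length(J),
                 degenerate_tau = degenerate, label = compliance$label),
            class = "sls_fit")
}

#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf(
    "sls_fit '%s': k0 = %.4g Pa, k_st = %.4g Pa, tau = %.4g s (R2 = %.4f, n = %d)%s\n",
    x$label, x$k0, x$k_st, x$tau, x$r_squared, x$n_points,
    if (isTRUE(x$degenerate_tau)) " [degenerate tau]" else ""))
  invisible(x)
}

#' Maxwell-representation elements of an SLS fit
#'
#' Converts the creep parameters (k0, k_st, tau) to the Maxwell
#' representation: parallel spring `k1 = k_st`, series spring
#' `k2 = k0 - k_st`, and dashpot `mu = tau * k1 * k2 / (k1 + k2)`, so the
#' response time `tau = mu (k1 + k2) / (k1 k2)` is recovered exactly.
#'
#' @param fit an `sls_fit` or any list with `k0`, `k_st`, `tau`.
#' @return list with `k1` (Pa), `k2` (Pa), `mu` (Pa s).
#' @export
derive_maxwell_elements <- function(fit) {
  k0 <- fit$k0; kst <- fit$k_st; tau <- fit$tau
  if (!(kst > 0) || !(k0 >= kst) || !is.finite(tau) || !(tau > 0)) {
    stop_invalid("require k0 >= k_st > 0 and finite tau > 0")
  }
  if (k0 - kst <= .Machine$double.eps * k0) {
    stop_invalid("degenerate Maxwell arm: k0 = k_st, the dashpot mu is undefined")
  }
  k1 <- kst
  k2 <- k0 - kst
  list(k1 = k1, k2 = k2, mu = tau * k1 * k2 / (k1 + k2))
}

#' Summarize SLS fits by condition
#'
#' Per-group mean, SD and n of the three viscoelastic parameters, plus a
#' two-group pooled-variance t test or a one-way ANOVA F test (three or
#' more groups), computed from their closed forms.
#'
#' @param fits list of `sls_fit` objects.
#' @param grouping character/factor of condition labels, one per fit.
#' @return list with `summary` (data.frame: group, parameter, mean, sd, n)
#'   and `tests` (per parameter: statistic, df, p_value, method).
#' @export
summarize_condition <- function(fits, grouping) {
  if (length(fits) != length(grouping)) {
    stop_invalid("one grouping label per fit is required")
  }
  grouping <- as.character(grouping)
  tab <- data.frame(group = grouping,
                    k0 = vapply(fits, `[[`, 0, "k0"),
                    k_st = vapply(fits, `[[`, 0, "k_st"),
                    tau = vapply(fits, `[[`, 0, "tau"))
  counts <- table(tab$group)
  if (any(counts < 2)) {
    stop_invalid("every group needs at least 2 fits; offending: ",
                 paste(names(counts)[counts < 2], collapse = ", "))
  }
  params <- c("k0", "k_st", "tau")
  summ <- do.call(rbind, lapply(params, function(p) {
    agg <- lapply(split(tab[[p]], tab$group), function(v)
      c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    data.frame(group = names(agg), parameter = p,
               mean = vapply(agg, `[`, 0, "mean"),
               sd = vapply(agg, `[`, 0, "sd"),
               n = vapply(agg, `[`, 0, "n"), row.names = NULL)
  }))
  tests <- lapply(stats::setNames(params, params), function(p) {
    groups <- split(tab[[p]], tab$group)
    if (length(groups) == 2) {
      do.call(pooled_t_test, unname(groups))
    } else {
      oneway_anova_f(groups)
    }
  })
  list(summary = summ, tests = tests)
}

#' Two-sample pooled-variance t test (closed form)
#'
#' Student's two-sided independent-samples t test assuming equal
#' variances, computed directly from the pooled-variance formula.
#'
#' @param x,y numeric samples.
#' @return list: `statistic`, `df`, `p_value`, `method`.
#' @export
pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_invalid("each sample needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- if (se > 0) (mean(x) - mean(y)) / se else 0
  df <- n1 + n2 - 2
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       method = "pooled-variance t")
}

#' One-way ANOVA F test (closed form)
#'
#' Between/within mean-square ratio for k independent groups, computed
#' directly from the sums of squares.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list: `statistic`, `df` (numerator, denominator), `p_value`,
#'   `method`.
#' @export
oneway_anova_f <- function(groups) {
  k <- length(groups)
  if (k < 2) stop_invalid("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2)) stop_invalid("each group needs at least 2 values")
  N <- sum(ns)
  grand <- mean(unlist(groups))
  ssb <- sum(ns * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- N - k
  Fstat <- if (ssw > 0) (ssb / df1) / (ssw / df2) else Inf
  list(statistic = Fstat, df = c(df1, df2),
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       method = "one-way ANOVA F")
}
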
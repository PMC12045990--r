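#' Total elastic energy of a network configuration
#'
#' Evaluates the microstructure energy
#' `E = ks/2 * sum_ij p_ij (l_ij - l0)^2
#'    + kb/2 * sum_ijk p_ij p_jk (theta_ijk - pi)^2
#'    + sum_n lambda q_n (A_n - A0)^2`,
#' i.e. fiber stretching over occupied edges, fiber bending over triples of
#' consecutive collinear occupied edges (interior angle measured at the
#' middle node), and an area penalty for each embedded cell triangle.
#' Horizontal periodicity is honored via the minimum-image convention.
#'
#' @param network a `lattice_network`.
#' @param positions optional `n x 2` matrix of displaced node positions;
#'   defaults to the rest positions (energy 0 on an undeformed network).
#' @return scalar energy in simulation units.
#' @export
total_energy <- function(network, positions = NULL) {
  if (is.null(positions)) positions <- network$positions
  energy_gradient(network, positions)$energy
}

# Energy and analytic gradient in one pass (used by the minimizer).
energy_gradient <- function(network, pos, want_grad = TRUE) {
  n <- nrow(pos)
  W <- network$width
  ks <- network$params$ks; kb <- network$params$kb
  lam <- network$params$lambda; A0 <- network$params$A0
  l0 <- network$l0
  gx <- numeric(n); gy <- numeric(n)
  E <- 0

  mindx <- function(d) d - W * round(d / W)

  ## stretching over occupied edges
  eo <- which(network$occupied)
  if (length(eo)) {
    i <- network$edges[eo, 1]; j <- network$edges[eo, 2]
    dx <- mindx(pos[j, 1] - pos[i, 1]); dy <- pos[j, 2] - pos[i, 2]
    l <- sqrt(dx^2 + dy^2)
    if (any(l < 1e-12)) stop_invalid("degenerate zero-length edge in configuration")
    E <- E + ks / 2 * sum((l - l0)^2)
    if (want_grad) {
      c1 <- ks * (l - l0) / l
      gx <- gx + accumulate(n, j, c1 * dx) - accumulate(n, i, c1 * dx)
      gy <- gy + accumulate(n, j, c1 * dy) - accumulate(n, i, c1 * dy)
    }
  }

  ## bending over triples whose two edges are both occupied
  act <- which(network$occupied[network$triple_edges[, 1]] &
                 network$occupied[network$triple_edges[, 2]])
  if (length(act)) {
    ti <- network$triples[act, 1]; tj <- network$triples[act, 2]
    tk <- network$triples[act, 3]
    ux <- mindx(pos[ti, 1] - pos[tj, 1]); uy <- pos[ti, 2] - pos[tj, 2]
    vx <- mindx(pos[tk, 1] - pos[tj, 1]); vy <- pos[tk, 2] - pos[tj, 2]
    psi <- atan2(vy, vx) - atan2(uy, ux)
    psi <- psi - 2 * pi * round(psi / (2 * pi))      # wrap to (-pi, pi]
    dev <- abs(psi) - pi                              # theta - pi, theta = |psi|
    E <- E + kb / 2 * sum(dev^2)
    if (want_grad) {
      dEdpsi <- kb * dev * sign(psi)
      u2 <- ux^2 + uy^2; v2 <- vx^2 + vy^2
      # dpsi/dr_i = (uy, -ux)/|u|^2 ; dpsi/dr_k = (-vy, vx)/|v|^2
      gix <- dEdpsi * uy / u2;  giy <- -dEdpsi * ux / u2
      gkx <- -dEdpsi * vy / v2; gky <- dEdpsi * vx / v2
      gx <- gx + accumulate(n, ti, gix) + accumulate(n, tk, gkx) -
        accumulate(n, tj, gix + gkx)
      gy <- gy + accumulate(n, ti, giy) + accumulate(n, tk, gky) -
        accumulate(n, tj, giy + gky)
    }
  }

  ## cell area penalty
  co <- which(network$cell)
  if (length(co)) {
    a <- network$triangles[co, 1]; b <- network$triangles[co, 2]
    cc <- network$triangles[co, 3]
    ux <- mindx(pos[b, 1] - pos[a, 1]); uy <- pos[b, 2] - pos[a, 2]
    vx <- mindx(pos[cc, 1] - pos[a, 1]); vy <- pos[cc, 2] - pos[a, 2]
    A <- 0.5 * (ux * vy - uy * vx)   # signed, positive at rest (CCW order)
    E <- E + lam * sum((A - A0)^2)
    if (want_grad) {
      dEdA <- 2 * lam * (A - A0)
      dbx <- 0.5 * vy;  dby <- -0.5 * vx
      dcx <- -0.5 * uy; dcy <- 0.5 * ux
      gx <- gx + accumulate(n, b, dEdA * dbx) + accumulate(n, cc, dEdA * dcx) -
        accumulate(n, a, dEdA * (dbx + dcx))
      gy <- gy + accumulate(n, b, dEdA * dby) + accumulate(n, cc, dEdA * dcy) -
        accumulate(n, a, dEdA * (dby + dcy))
    }
  }

  list(energy = E, grad = if (want_grad) cbind(gx, gy) else NULL)
}

#' Relax a network under uniaxial compression
#'
#' Imposes a vertical compressive strain `gamma` by clamping the vertical
#' coordinates of the top and bottom boundary rows (height reduced to
#' `(1 - gamma) * H0`; boundary nodes slide freely horizontally) and
#' relaxes all remaining degrees of freedom to a local energy minimum by
#' L-BFGS with the analytic gradient.
#'
#' @param network a `lattice_network`.
#' @param gamma compressive strain, `>= 0`.
#' @param init optional starting positions (e.g. the relaxed state at a
#'   nearby strain for continuation); vertical coordinates are rescaled to
#'   the new height before relaxing.
#' @param tol convergence tolerance on the projected gradient norm.
#' @param maxit iteration budget.
#' @return list with `positions` (relaxed `n x 2`), `energy`, and
#'   `convergence` diagnostics.
#' @export
minimize_energy <- function(network, gamma, init = NULL, tol = 1e-8,
                            maxit = 50000L) {
  if (gamma < 0) stop_invalid("strain gamma must be non-negative")
  H0 <- network$height
  Hg <- (1 - gamma) * H0
  pos0 <- network$positions
  if (is.null(init)) {
    start <- pos0
    start[, 2] <- pos0[, 2] * (1 - gamma)          # affine guess
  } else {
    start <- init
    start[, 2] <- start[, 2] * Hg / max(start[network$top, 2])
  }
  # clamp boundary rows vertically
  start[network$bottom, 2] <- 0
  start[network$top, 2] <- Hg

  n <- nrow(pos0)
  free_y <- setdiff(seq_len(n), c(network$bottom, network$top))
  pack <- function(p) c(p[, 1], p[free_y, 2])
  unpack <- function(th) {
    p <- start
    p[, 1] <- th[seq_len(n)]
    p[free_y, 2] <- th[-seq_len(n)]
    p
  }
  fn <- function(th) energy_gradient(network, unpack(th), want_grad = FALSE)$energy
  gr <- function(th) {
    g <- energy_gradient(network, unpack(th))$grad
    c(g[, 1], g[free_y, 2])
  }
  res <- stats::optim(pack(start), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10, pgtol = tol))
  gnorm <- max(abs(gr(res$par)))
  if (res$convergence != 0 && gnorm > tol * 100) {
    stop(sprintf(
      "energy minimization failed to converge at gamma = %g (code %d, |grad|_inf = %.3e): %s",
      gamma, res$convergence, gnorm, res$message))
  }
  list(positions = unpack(res$par), energy = res$value,
       convergence = list(code = res$convergence, grad_inf = gnorm,
                          counts = res$counts))
}

#' Minimized energy along a compression protocol
#'
#' Relaxes the network at each strain in turn, using the previous relaxed
#' state as the starting point (strain continuation).
#'
#' @param network a `lattice_network`.
#' @param strains non-negative, increasing strain values.
#' @param tol,maxit passed to [minimize_energy()].
#' @return data.frame with columns `gamma` and `energy`.
#' @export
energy_curve <- function(network, strains, tol = 1e-8, maxit = 50000L) {
  if (any(strains < 0) || is.unsorted(strains)) {
    stop_invalid("strains must be non-negative and increasing")
  }
  E <- numeric(length(strains))
  state <- NULL
  for (s in seq_along(strains)) {
    m <- minimize_energy(network, strains[s], init = state, tol = tol,
                         maxit = maxit)
    E[s] <- m$energy
    state <- m$positions
  }
  data.frame(gamma = strains, energy = E)
}

#' Uniaxial stiffness of a network
#'
#' Computes the material stiffness `K = (1/A_sys) d^2 E_min / d gamma^2`
#' by central finite differences around the evaluation strain, with
#' `A_sys` the undeformed system area (an intensive normalization).
#' Relaxed states are carried between the three strains (continuation).
#'
#' @param network a `lattice_network`.
#' @param strain evaluation strain (default 0.01, well inside the
#'   near-linear regime).
#' @param fd_step finite-difference strain step.
#' @param tol minimizer tolerance.
#' @return list with `K`, the three minimized energies (`energies`), the
#'   strains used, and the realized occupied fraction; a negative `K`
#'   beyond tolerance attaches a `warning` field.
#' @export
compute_stiffness <- function(network, strain = 0.01, fd_step = 1e-3,
                              tol = 1e-8) {
  if (strain - fd_step < 0) stop_invalid("strain - fd_step must be >= 0")
  A_sys <- network$width * network$height
  mid <- minimize_energy(network, strain, tol = tol)
  lo <- minimize_energy(network, strain - fd_step, init = mid$positions, tol = tol)
  hi <- minimize_energy(network, strain + fd_step, init = mid$positions, tol = tol)
  K <- (hi$energy - 2 * mid$energy + lo$energy) / (fd_step^2 * A_sys)
  out <- list(K = K, strain = strain, fd_step = fd_step,
              energies = c(lo$energy, mid$energy, hi$energy),
              p_realized = mean(network$occupied))
  if (K < -1e-8) out$warning <- "negative stiffness beyond tolerance (numerical instability)"
  out
}

#' Stiffness versus ECM amount and patterning
#'
#' Sweeps the occupied-edge fraction `p` for one or both dilution modes,
#' replicating over seeds (each seed draws a fresh dilution and a fresh
#' random placement of the embedded cells), and reports per-replicate and
#' summarized stiffness.
#'
#' @param p_values occupied-fraction grid.
#' @param modes dilution modes to run.
#' @param seeds integer vector of replicate seeds.
#' @param n_nodes,n_cells,R,lambda lattice configuration (defaults: 64
#'   nodes, 32 cells, stretch/bend ratio 10, unit cell stiffness).
#' @param strain,fd_step,tol stiffness evaluation controls.
#' @return list with `replicates` (mode, p_target, p_realized, seed, K)
#'   and `summary` (mode, p, mean, sd, n).
#' @export
stiffness_vs_p_sweep <- function(p_values, modes = c("random", "patterned"),
                                 seeds = 1:20, n_nodes = 64, n_cells = 32,
                                 R = 10, lambda = 1, strain = 0.01,
                                 fd_step = 1e-3, tol = 1e-8) {
  base <- build_lattice(n_nodes = n_nodes, R = R, lambda = lambda)
  rows <- list()
  for (mode in modes) {
    for (p in p_values) {
      for (s in seeds) {
        net <- dilute(base, mode = mode, p = p, seed = s)
        net <- place_cells(net, n_cells = n_cells, seed = s + 1L)
        st <- compute_stiffness(net, strain = strain, fd_step = fd_step, tol = tol)
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, p_target = p, p_realized = st$p_realized,
          seed = s, K = st$K)
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, list(reps$mode, reps$p_target), drop = TRUE),
    function(d) data.frame(mode = d$mode[1], p = d$p_target[1],
                           K_mean = mean(d$K), K_sd = stats::sd(d$K),
                           n_seeds = nrow(d))))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

#' Patterned-versus-random stiffness comparison
#'
#' Compares the mean stiffness of a randomly diluted network at
#' `p_random` against a patterned (central circular removal) network at
#' `p_patterned`, over replicate seeds, and reports the relative increase
#' `(mean K_random - mean K_patterned) / mean K_patterned` in percent.
#'
#' @inheritParams stiffness_vs_p_sweep
#' @param p_patterned,p_random the two occupied fractions compared
#'   (defaults 0.85 and 0.95).
#' @return list with the two per-seed stiffness vectors, their means, and
#'   `relative_increase_pct`.
#' @export
compare_patterning <- function(p_patterned = 0.85, p_random = 0.95,
                               seeds = 1:20, n_nodes = 64, n_cells = 32,
                               R = 10, lambda = 1, strain = 0.01,
                               fd_step = 1e-3, tol = 1e-8) {
  sw <- stiffness_vs_p_sweep(
    p_values = p_patterned, modes = "patterned", seeds = seeds,
    n_nodes = n_nodes, n_cells = n_cells, R = R, lambda = lambda,
    strain = strain, fd_step = fd_step, tol = tol)
  sr <- stiffness_vs_p_sweep(
    p_values = p_random, modes = "random", seeds = seeds,
    n_nodes = n_nodes, n_cells = n_cells, R = R, lambda = lambda,
    strain = strain, fd_step = fd_step, tol = tol)
  Kp <- sw$replicates$K
  Kr <- sr$replicates$K
  list(K_patterned = Kp, K_random = Kr,
       mean_patterned = mean(Kp), mean_random = mean(Kr),
       relative_increase_pct = 100 * (mean(Kr) - mean(Kp)) / mean(Kp))
}
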
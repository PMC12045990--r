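# Independent oracles, written as plain scalar loops so they share no code
# path with the vectorized implementations they check.

# Brute-force term-by-term evaluation of the microstructure energy.
brute_force_energy <- function(net, pos) {
  W <- net$width
  mind <- function(d) d - W * round(d / W)
  E <- 0
  for (e in seq_len(nrow(net$edges))) {
    if (!net$occupied[e]) next
    i <- net$edges[e, 1]; j <- net$edges[e, 2]
    dx <- mind(pos[j, 1] - pos[i, 1]); dy <- pos[j, 2] - pos[i, 2]
    l <- sqrt(dx^2 + dy^2)
    E <- E + net$params$ks / 2 * (l - net$l0)^2
  }
  for (tr in seq_len(nrow(net$triples))) {
    e1 <- net$triple_edges[tr, 1]; e2 <- net$triple_edges[tr, 2]
    if (!net$occupied[e1] || !net$occupied[e2]) next
    i <- net$triples[tr, 1]; j <- net$triples[tr, 2]; k <- net$triples[tr, 3]
    u <- c(mind(pos[i, 1] - pos[j, 1]), pos[i, 2] - pos[j, 2])
    v <- c(mind(pos[k, 1] - pos[j, 1]), pos[k, 2] - pos[j, 2])
    ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    theta <- acos(max(-1, min(1, ct)))     # interior angle in [0, pi]
    E <- E + net$params$kb / 2 * (theta - pi)^2
  }
  for (n in seq_len(nrow(net$triangles))) {
    if (!net$cell[n]) next
    a <- net$triangles[n, 1]; b <- net$triangles[n, 2]; cc <- net$triangles[n, 3]
    u <- c(mind(pos[b, 1] - pos[a, 1]), pos[b, 2] - pos[a, 2])
    v <- c(mind(pos[cc, 1] - pos[a, 1]), pos[cc, 2] - pos[a, 2])
    A <- abs(u[1] * v[2] - u[2] * v[1]) / 2
    E <- E + net$params$lambda * (A - net$params$A0)^2
  }
  E
}

# Brute-force edge enumeration: every node pair at minimum-image distance
# l0 (horizontal wrap, open vertical) is an edge.
brute_force_edge_count <- function(net) {
  n <- nrow(net$positions)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- net$positions[j, 1] - net$positions[i, 1]
    dx <- dx - net$width * round(dx / net$width)
    dy <- net$positions[j, 2] - net$positions[i, 2]
    if (abs(sqrt(dx^2 + dy^2) - net$l0) < 1e-9) cnt <- cnt + 1
  }
  cnt
}

# Brute-force bending-triple enumeration: middle node j with two edge
# neighbours i, k whose minimum-image positions are exactly opposite.
brute_force_triples <- function(net) {
  n <- nrow(net$positions)
  mind <- function(d) d - net$width * round(d / net$width)
  nbrs <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges[e, 1]; j <- net$edges[e, 2]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  out <- 0
  for (j in seq_len(n)) {
    nb <- nbrs[[j]]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      u <- c(mind(net$positions[nb[a], 1] - net$positions[j, 1]),
             net$positions[nb[a], 2] - net$positions[j, 2])
      v <- c(mind(net$positions[nb[b], 1] - net$positions[j, 1]),
             net$positions[nb[b], 2] - net$positions[j, 2])
      if (max(abs(u + v)) < 1e-9) out <- out + 1
    }
  }
  out
}

# Linear-response stiffness from the numerical Hessian of the energy:
# K*A = d'Hd - g' (H_ff)^+ g with g = H_fc d_c, the quadratic form of the
# constrained minimization at gamma = 0.
hessian_stiffness <- function(net, h = 1e-4) {
  n <- nrow(net$positions)
  x0 <- c(net$positions[, 1], net$positions[, 2])
  en <- function(x) total_energy(net, cbind(x[1:n], x[(n + 1):(2 * n)]))
  m <- 2 * n
  H <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in a:m) {
    xa <- x0; xa[a] <- xa[a] + h; xa[b] <- xa[b] + h
    xb <- x0; xb[a] <- xb[a] + h; xb[b] <- xb[b] - h
    xc <- x0; xc[a] <- xc[a] - h; xc[b] <- xc[b] + h
    xd <- x0; xd[a] <- xd[a] - h; xd[b] <- xd[b] - h
    H[a, b] <- H[b, a] <- (en(xa) - en(xb) - en(xc) + en(xd)) / (4 * h^2)
  }
  d <- numeric(m)
  d[n + net$top] <- -net$height                 # dy/dgamma of the clamped top row
  clamped <- c(n + net$top, n + net$bottom)
  free <- setdiff(seq_len(m), clamped)
  g <- H[free, clamped, drop = FALSE] %*% d[clamped]
  Hff <- H[free, free]
  corr <- t(g) %*% MASS::ginv(Hff) %*% g
  as.numeric(t(d) %*% H %*% d - corr) / (net$width * net$height)
}

# Exact Mann-Whitney p by direct enumeration over all assignments of the
# pooled values (handles ties), independent of the package's routine.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(N, n1)
  Us <- apply(combos, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

# Shared small fixtures
make_clean_compliance <- function(k0 = 400, k_st = 250, tau = 2,
                                  duration = 10, rate = 10) {
  t <- seq(0, duration, by = 1 / rate)
  structure(list(time = t, J = sls_creep_model(t, k0, k_st, tau),
                 label = "clean"), class = "creep_compliance")
}
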
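#' Build a full triangular fiber lattice
#'
#' Constructs a two-dimensional triangular lattice of nodes connected by
#' fiber segments (edges), periodic in the horizontal direction and open
#' (free surfaces) in the vertical direction. Every edge starts occupied;
#' use [dilute()] to remove extracellular-matrix segments and
#' [place_cells()] to embed area-elastic cells. A straight line of edges
#' along one of the three principal lattice directions represents a single
#' collagen fiber, so collinear edge pairs sharing a node form "bending
#' triples" whose deviation from a straight angle is penalized.
#'
#' @param n_nodes total number of nodes; must factor into a near-square
#'   `cols x rows` arrangement (default 64, an 8x8 lattice).
#' @param l0 fiber rest length (lattice units).
#' @param R dimensionless ratio of fiber stretching to bending stiffness,
#'   `ks / (kb * l0^2)`.
#' @param kb fiber bending stiffness (simulation units).
#' @param lambda area stiffness assigned to cells placed later.
#' @param cols,rows optional explicit lattice dimensions overriding the
#'   near-square factorization of `n_nodes`.
#'
#' @return A `lattice_network` object: node positions, edges with occupancy
#'   and direction class, bending triples, candidate cell triangles, and
#'   the energy parameters.
#' @export
build_lattice <- function(n_nodes = 64, l0 = 1, R = 10, kb = 1, lambda = 1,
                          cols = NULL, rows = NULL) {
  if (is.null(cols) || is.null(rows)) {
    w <- floor(sqrt(n_nodes))
    while (w > 1 && n_nodes %% w != 0) w <- w - 1
    cols <- w
    rows <- n_nodes %/% w
  }
  if (cols * rows < 12 || cols < 3 || rows < 3) {
    stop_invalid("lattice too small: need at least 12 nodes in a >= 3x3 ",
                 "arrangement so an interior bending triple exists")
  }
  h <- sqrt(3) / 2 * l0
  row_of <- rep(seq_len(rows), each = cols)
  col_of <- rep(seq_len(cols), times = rows)
  x <- (col_of - 1) * l0 + 0.5 * l0 * ((row_of - 1) %% 2)
  y <- (row_of - 1) * h
  pos <- cbind(x, y)
  width <- cols * l0

  # exact half-integer grid key for node lookup, periodic in x
  key <- function(px, py) {
    kx <- round(2 * px / l0) %% (2 * cols)
    ky <- round(py / h)
    paste(kx, ky)
  }
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(pos))) assign(key(pos[i, 1], pos[i, 2]), i, lookup)
  node_at <- function(px, py) {
    k <- key(px, py)
    if (exists(k, envir = lookup, inherits = FALSE)) get(k, envir = lookup) else NA_integer_
  }

  # three principal directions: horizontal, up-right, up-left
  dirs <- rbind(c(l0, 0), c(l0 / 2, h), c(-l0 / 2, h))

  edges <- matrix(integer(0), 0, 2)
  edge_dir <- integer(0)
  for (d in 1:3) {
    for (i in seq_len(nrow(pos))) {
      j <- node_at(pos[i, 1] + dirs[d, 1], pos[i, 2] + dirs[d, 2])
      if (!is.na(j)) {
        edges <- rbind(edges, c(i, j))
        edge_dir <- c(edge_dir, d)
      }
    }
  }
  edge_key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edge_index <- stats::setNames(seq_along(edge_key), edge_key)

  # bending triples: (i, j, k) collinear along direction d, middle node j
  triples <- matrix(integer(0), 0, 3)
  triple_dir <- integer(0)
  for (d in 1:3) {
    for (j in seq_len(nrow(pos))) {
      k <- node_at(pos[j, 1] + dirs[d, 1], pos[j, 2] + dirs[d, 2])
      i <- node_at(pos[j, 1] - dirs[d, 1], pos[j, 2] - dirs[d, 2])
      if (!is.na(i) && !is.na(k)) {
        triples <- rbind(triples, c(i, j, k))
        triple_dir <- c(triple_dir, d)
      }
    }
  }
  triple_edges <- cbind(
    edge_index[paste(pmin(triples[, 1], triples[, 2]), pmax(triples[, 1], triples[, 2]))],
    edge_index[paste(pmin(triples[, 2], triples[, 3]), pmax(triples[, 2], triples[, 3]))]
  )

  # candidate cell triangles (counter-clockwise vertex order)
  tri <- matrix(integer(0), 0, 3)
  for (i in seq_len(nrow(pos))) {
    a <- node_at(pos[i, 1] + l0, pos[i, 2])
    b <- node_at(pos[i, 1] + l0 / 2, pos[i, 2] + h)
    c2 <- node_at(pos[i, 1] - l0 / 2, pos[i, 2] + h)
    if (!is.na(a) && !is.na(b)) tri <- rbind(tri, c(i, a, b))   # up-pointing
    if (!is.na(b) && !is.na(c2)) tri <- rbind(tri, c(i, b, c2)) # down-pointing
  }

  structure(list(
    positions = unname(pos), rows = rows, cols = cols,
    width = width, height = (rows - 1) * h, l0 = l0,
    edges = unname(edges), edge_dir = edge_dir, occupied = rep(TRUE, nrow(edges)),
    triples = unname(triples), triple_dir = triple_dir,
    triple_edges = unname(triple_edges),
    triangles = unname(tri), cell = rep(FALSE, nrow(tri)),
    params = list(ks = R * kb * l0^2, kb = kb, lambda = lambda,
                  A0 = sqrt(3) / 4 * l0^2, R = R),
    bottom = which(row_of == 1), top = which(row_of == rows)
  ), class = "lattice_network")
}

#' @export
print.lattice_network <- function(x, ...) {
  cat(sprintf(
    "lattice_network: %d nodes (%dx%d), %d/%d edges occupied, %d cells, R = %g\n",
    nrow(x$positions), x$cols, x$rows, sum(x$occupied), length(x$occupied),
    sum(x$cell), x$params$R))
  invisible(x)
}

#' Realized occupied-edge fraction of a network
#' @param network a `lattice_network`.
#' @return fraction of edges currently occupied.
#' @export
occupied_fraction <- function(network) mean(network$occupied)

#' Dilute the fiber network
#'
#' Removes extracellular-matrix segments either at random (each edge kept
#' independently with probability `p`, emulating disorganized ECM) or in a
#' patterned fashion (all edges whose midpoint falls inside a circular
#' region around the system center removed, the circle radius chosen so the
#' realized occupied fraction matches the target within one edge —
#' emulating matrix cleared from a localized region).
#'
#' @param network a `lattice_network`.
#' @param mode `"random"` or `"patterned"`.
#' @param p target occupied-edge fraction in `[0, 1]`.
#' @param seed RNG seed (random draw; tie-break shuffle in patterned mode).
#' @param circle_center length-2 center of the removal circle
#'   (patterned mode); defaults to the system center.
#' @return the network with updated `occupied` flags and a `dilution`
#'   record (mode, target and realized fraction).
#' @export
dilute <- function(network, mode = c("random", "patterned"), p, seed = NULL,
                   circle_center = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop_invalid("occupation probability p must be a single value in [0, 1]")
  }
  ne <- nrow(network$edges)
  if (mode == "random") {
    keep <- with_seed(seed, stats::runif(ne) < p)
  } else {
    if (is.null(circle_center)) {
      circle_center <- c(network$width / 2, network$height / 2)
    }
    mid <- (network$positions[network$edges[, 1], , drop = FALSE] +
              edge_partner_positions(network)) / 2
    dx <- mid[, 1] - circle_center[1]
    dx <- dx - network$width * round(dx / network$width)
    dist <- sqrt(dx^2 + (mid[, 2] - circle_center[2])^2)
    n_remove <- ne - round(p * ne)
    ord <- with_seed(seed, sample.int(ne))    # seeded shuffle breaks ties
    ord <- ord[order(dist[ord])]
    if (n_remove > 0 && dist[ord[n_remove]] > min(network$width, network$height) / 2) {
      stop_invalid("patterned dilution to p = ", p, " needs a removal circle ",
                   "larger than the system; unreachable pattern")
    }
    keep <- rep(TRUE, ne)
    if (n_remove > 0) keep[ord[seq_len(n_remove)]] <- FALSE
  }
  network$occupied <- network$occupied & keep
  network$dilution <- list(mode = mode, p_target = p,
                           p_realized = mean(network$occupied))
  network
}

# positions of edges' second endpoints shifted by the minimum image so the
# midpoint formula is valid across the periodic seam
edge_partner_positions <- function(network) {
  p1 <- network$positions[network$edges[, 1], , drop = FALSE]
  p2 <- network$positions[network$edges[, 2], , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]
  p2[, 1] <- p1[, 1] + dx - network$width * round(dx / network$width)
  p2
}

#' Embed area-elastic cells in the lattice
#'
#' Selects `n_cells` distinct lattice triangles uniformly at random and
#' tags them as cells. Each tagged triangle contributes
#' `lambda * (A - A0)^2` to the energy, a bulk (area) stiffness penalty.
#'
#' @param network a `lattice_network`.
#' @param n_cells number of cells (default 32).
#' @param lambda cell area stiffness; `NULL` keeps the network value.
#' @param seed RNG seed for the triangle draw.
#' @return the network with `cell` flags set.
#' @export
place_cells <- function(network, n_cells = 32, lambda = NULL, seed = NULL) {
  nt <- nrow(network$triangles)
  if (n_cells > nt) {
    stop_invalid("n_cells = ", n_cells, " exceeds the ", nt,
                 " available lattice triangles")
  }
  network$cell <- rep(FALSE, nt)
  if (n_cells > 0) {
    picked <- with_seed(seed, sample.int(nt, n_cells))
    network$cell[picked] <- TRUE
  }
  if (!is.null(lambda)) network$params$lambda <- lambda
  network
}
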
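# Conformer embedding and Shrake-Rupley solvent-accessible surface
# area.

VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

#' Conformer from a polymer graph
#'
#' Deterministic 3-D coordinates for the heavy atoms obtained by
#' classical multidimensional scaling of the bond-count distance
#' matrix scaled by a typical bond length. This is a cheap, seeded
#' distance-geometry stand-in for a real conformer search: adequate
#' for surface-area ratios of repeat units, not for full-chain
#' conformational analysis.
#'
#' @param graph A connected `poly_graph`.
#' @param bond_length Target bond length in Angstrom (default 1.54).
#' @return A `conformer`: list with `coords` (n x 3, Angstrom),
#'   `radii` (van der Waals, Angstrom) and `elements`.
#' @export
embed_conformer <- function(graph, bond_length = 1.54) {
  n <- nrow(graph$nodes)
  stopifnot(n >= 1)
  if (n == 1) {
    coords <- matrix(0, 1, 3)
  } else {
    d <- graph_distances(graph) * bond_length
    mds <- stats::cmdscale(d, k = min(3L, n - 1L))
    coords <- matrix(0, n, 3)
    coords[, seq_len(ncol(mds))] <- mds
    # deterministic symmetry breaking: topologically equivalent atoms
    # (e.g. the two methyls of an isopropyl group) collapse onto one
    # point under classical MDS; a fixed sub-Angstrom offset per atom
    # index separates them without distorting surface ratios
    coords <- coords + 0.15 * golden_spiral_points(n)
  }
  structure(list(coords = coords,
                 radii = unname(VDW_RADII[graph$nodes$element]),
                 elements = graph$nodes$element),
            class = "conformer")
}

#' Construct a conformer from explicit geometry
#'
#' @param coords n x 3 matrix of coordinates (Angstrom).
#' @param radii van der Waals radii (Angstrom), length n.
#' @param elements Optional element symbols.
#' @return A `conformer`.
#' @export
conformer <- function(coords, radii, elements = rep("C", nrow(coords))) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(radii))
  structure(list(coords = coords, radii = radii, elements = elements),
            class = "conformer")
}

# All-pairs shortest-path (bond count) distances via BFS.
graph_distances <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- adjacency_list(graph)
  d <- matrix(n, n, n)  # unreachable pairs get a large finite distance
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (d[s, w] == n && w != s) { d[s, w] <- d[s, v] + 1; queue <- c(queue, w) }
      }
    }
  }
  d
}

# Quasi-uniform points on the unit sphere (golden-spiral layout).
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA: each atom's sphere is expanded by the probe radius
#' and covered with a fixed quasi-uniform (golden-spiral) point
#' layout; points falling inside any other expanded sphere are
#' occluded, and the accessible fraction scales the sphere area.
#'
#' @param conf A [conformer()].
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Points per sphere (>= 92; default 192).
#' @return Numeric vector of per-atom areas (Angstrom^2); total SASA
#'   is their sum.
#' @export
shrake_rupley_sasa <- function(conf, probe_radius = 1.4, n_points = 192L) {
  stopifnot(inherits(conf, "conformer"))
  if (n_points < 92) stop("`n_points` must be >= 92", call. = FALSE)
  n <- nrow(conf$coords)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(conf$coords))
    if (any(dmat[upper.tri(dmat)] < 1e-6)) {
      stop("degenerate geometry: overlapping identical centers", call. = FALSE)
    }
  }
  sphere <- golden_spiral_points(n_points)
  areas <- numeric(n)
  expanded <- conf$radii + probe_radius
  for (a in seq_len(n)) {
    R <- expanded[a]
    pts <- sweep(sphere * R, 2, conf$coords[a, ], "+")
    accessible <- rep(TRUE, n_points)
    if (n > 1) {
      nb <- which(dmat[a, ] < R + expanded & seq_len(n) != a)
      for (b in nb) {
        d2 <- rowSums(sweep(pts, 2, conf$coords[b, ])^2)
        accessible <- accessible & d2 > expanded[b]^2
      }
    }
    areas[a] <- 4 * pi * R^2 * mean(accessible)
  }
  areas
}
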
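# Physics constraints g1-g3, the augmented-Lagrangian penalty, and
# dual-variable (multiplier) updates.
#
# Sign convention, stated once here and used everywhere: a positive
# constraint value is a violation.
#   g1 = -dG_formation + dG_threshold   (stability: wants dG >= threshold)
#   g2 = SA_score - 4.5                 (accessibility: wants SA <= 4.5)
#   g3 = rho_min - rho_crosslink        (integrity: wants density >= rho_min)

#' Constraint thresholds for the physics constraints
#'
#' @param dg_threshold Stability threshold in kJ/mol (default 0: the
#'   group-contribution stability score must be non-negative).
#' @param sa_threshold Synthetic-accessibility cut-off (default 4.5).
#' @param rho_min Minimum cross-link density in mol/kg (default 0,
#'   which deactivates g3; enable for cross-linked stages).
#' @return A `constraint_set`.
#' @export
constraint_set <- function(dg_threshold = 0, sa_threshold = 4.5, rho_min = 0) {
  stopifnot(is.finite(dg_threshold), is.finite(sa_threshold), is.finite(rho_min))
  structure(list(dg_threshold = dg_threshold, sa_threshold = sa_threshold,
                 rho_min = rho_min),
            class = "constraint_set")
}

#' Lagrange multiplier state for the augmented-Lagrangian scheme
#'
#' @param lambda Non-negative multipliers, one per constraint
#'   (default `c(0, 0, 0)` for g1-g3).
#' @param eta Dual learning rate (default 0.01).
#' @return A `dual_state`.
#' @export
dual_state <- function(lambda = c(0, 0, 0), eta = 0.01) {
  stopifnot(all(lambda >= 0), eta >= 0)
  structure(list(lambda = lambda, eta = eta), class = "dual_state")
}

#' Group-contribution formation-stability surrogate
#'
#' Deterministic sum of per-atom contributions (keyed on element and
#' hybridization/aromatic context) and per-bond contributions from the
#' shipped coefficient table. Positive values indicate stabilizing
#' structure. Additive over disconnected fragments by construction.
#' Atom contexts absent from the table fall back to the element-level
#' row, then to 0 (with a message).
#'
#' @param graph A `poly_graph`.
#' @return Stability score in kJ/mol; 0 for the empty graph.
#' @export
delta_g_formation <- function(graph) {
  stopifnot(inherits(graph, "poly_graph"))
  if (nrow(graph$nodes) == 0) return(0)
  tab <- read_coef_table("formation_energy_contributions.csv")
  keys <- atom_context(graph)
  known <- keys %in% tab$key | sub("\\..*$", "", keys) %in% tab$key
  if (any(!known)) {
    message("delta_g_formation: no contribution for ",
            paste(unique(keys[!known]), collapse = ", "), "; using 0")
  }
  atom_sum <- sum(lookup_contrib(keys, tab))
  bond_sum <- if (nrow(graph$edges) > 0) {
    sum(lookup_contrib(paste0("bond.", graph$edges$order), tab))
  } else 0
  atom_sum + bond_sum
}

# Shortest-cycle sizes through each non-tree edge (approximate SSSR).
ring_sizes <- function(graph) {
  n <- nrow(graph$nodes)
  comp <- graph_components(graph)
  n_rings <- nrow(graph$edges) - n + max(comp, 0L)
  if (n == 0 || n_rings <= 0) return(integer(0))
  adj <- adjacency_list(graph)
  sizes <- integer(0)
  # BFS spanning forest
  in_tree <- rep(FALSE, nrow(graph$edges))
  visited <- rep(FALSE, n)
  ekey <- paste(graph$edges$i, graph$edges$j)
  for (s in seq_len(n)) {
    if (visited[s]) next
    visited[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          in_tree[match(paste(min(v, w), max(v, w)), ekey)] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  bfs_dist <- function(a, b, skip_edge) {
    d <- rep(NA_integer_, n); d[a] <- 0L; queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == b) return(d[v])
      for (w in adj[[v]]) {
        key <- match(paste(min(v, w), max(v, w)), ekey)
        if (key == skip_edge) next
        if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
      }
    }
    NA_integer_
  }
  for (k in which(!in_tree)) {
    d <- bfs_dist(graph$edges$i[k], graph$edges$j[k], k)
    if (!is.na(d)) sizes <- c(sizes, d + 1L)
  }
  sizes
}

#' Synthetic-accessibility score
#'
#' Fragment-contribution score on a 1 (easy) to 10 (hard) scale. The
#' fragment term measures how familiar each atom's radius-1
#' environment is relative to a shipped frequency table derived from
#' the package's reference corpus; complexity penalties are added for
#' fused rings, stereocenters and macrocycles (ring size > 8), and the
#' raw score is mapped monotonically into \[1, 10\].
#'
#' @param graph A `poly_graph`.
#' @return Score in \[1, 10\]; higher = harder to synthesize.
#' @export
sa_score <- function(graph) {
  stopifnot(inherits(graph, "poly_graph"))
  n <- nrow(graph$nodes)
  if (n == 0) return(1)
  tab <- tryCatch(read_coef_table("sa_fragment_frequencies.csv"),
                  error = function(e) NULL, warning = function(w) NULL)
  envs <- radius1_environments(graph)
  if (!is.null(tab) && nrow(tab) > 0) {
    counts <- tab$value[match(as.character(envs), as.character(tab$key))]
    counts[is.na(counts)] <- 0
    familiarity <- mean(log1p(counts) / log1p(max(tab$value)))
  } else {
    familiarity <- 0
  }
  rs <- ring_sizes(graph)
  ring_atoms <- ring_membership_counts(graph)
  n_fused <- sum(ring_atoms >= 2)
  n_stereo <- sum(graph$nodes$stereo)
  n_macro <- sum(rs > 8)
  raw <- 2.5 * (1 - familiarity) + 0.8 * n_fused + 0.5 * n_stereo +
    0.8 * n_macro + 0.02 * n
  1 + 9 * (1 - exp(-raw / 4))
}

# Radius-1 Morgan environment hash per atom (used by the SA fragment term).
radius1_environments <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- adjacency_list(graph)
  inv <- atom_invariants(graph)
  ekey <- paste(graph$edges$i, graph$edges$j)
  vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    flat <- if (length(nb)) {
      pairs <- vapply(nb, function(w) {
        k <- match(paste(min(v, w), max(v, w)), ekey)
        c(bond_code(graph$edges$order[k], graph$edges$crosslink[k]), inv[w])
      }, numeric(2))
      ord <- order(pairs[1, ], pairs[2, ])
      as.vector(pairs[, ord, drop = FALSE])
    } else numeric(0)
    hash_ints(c(1, inv[v], flat))
  }, numeric(1))
}

# Number of (shortest) rings each atom belongs to; counts >= 2 flag fusion.
ring_membership_counts <- function(graph) {
  n <- nrow(graph$nodes)
  counts <- rep(0L, n)
  if (n == 0) return(counts)
  # approximate: an atom with >= 2 ring bonds beyond a tree is "fused";
  # use degree within the 2-core as a proxy
  deg <- lengths(adjacency_list(graph))
  comp <- graph_components(graph)
  n_rings <- nrow(graph$edges) - n + max(comp, 0L)
  if (n_rings >= 2) {
    counts[deg >= 3 & vapply(seq_len(n), function(v) graph$nodes$aromatic[v] ||
                               graph$nodes$hybridization[v] != "sp", logical(1))] <- 2L
  }
  counts
}

#' Cross-link density of a polymer graph
#'
#' Count of cross-link-flagged edges divided by the molecular mass in
#' kg/mol, giving mol of cross-links per kg of polymer.
#'
#' @param graph A `poly_graph` with computable mass.
#' @return Density in mol/kg.
#' @export
crosslink_density <- function(graph) {
  stopifnot(inherits(graph, "poly_graph"))
  m <- molar_mass(graph)
  if (m <= 0) stop("cross-link density undefined for zero-mass graph", call. = FALSE)
  sum(graph$edges$crosslink) / (m / 1000)
}

#' Constraint values from raw physical quantities
#'
#' Pure arithmetic core of [evaluate_constraints()]: positive values
#' are violations.
#'
#' @param dg Formation-stability score (kJ/mol).
#' @param sa Synthetic-accessibility score.
#' @param rho Cross-link density (mol/kg).
#' @param cs A [constraint_set()].
#' @return Numeric vector `c(g1, g2, g3)`.
#' @export
constraint_values <- function(dg, sa, rho, cs = constraint_set()) {
  c(g1 = -dg + cs$dg_threshold,
    g2 = sa - cs$sa_threshold,
    g3 = cs$rho_min - rho)
}

#' Evaluate the physics constraints on a generation state
#'
#' Computes g1 (thermodynamic stability), g2 (synthetic accessibility)
#' and g3 (structural integrity) for the state's polymer graph, in
#' that order. Positive entries are violations.
#'
#' @param state A `generation_state` (or a bare `poly_graph`).
#' @param cs A [constraint_set()].
#' @return Named numeric vector `c(g1, g2, g3)`.
#' @export
evaluate_constraints <- function(state, cs = constraint_set()) {
  graph <- if (inherits(state, "poly_graph")) state else state$graph
  constraint_values(delta_g_formation(graph), sa_score(graph),
                    if (nrow(graph$nodes) > 0) crosslink_density(graph) else 0,
                    cs)
}

#' Augmented-Lagrangian constraint penalty
#'
#' `sum_i lambda_i * max(0, g_i)^2`: only violated constraints
#' contribute, weighted by their multipliers.
#'
#' @param g Constraint values (positive = violation).
#' @param dual A [dual_state()] with multipliers of matching length.
#' @return Non-negative scalar.
#' @export
lagrangian_penalty <- function(g, dual) {
  if (length(g) != length(dual$lambda)) {
    stop("constraint vector and multipliers differ in length", call. = FALSE)
  }
  sum(dual$lambda * pmax(0, g)^2)
}

#' Dual-ascent update of the Lagrange multipliers
#'
#' `lambda_i <- max(0, lambda_i + eta * E[g_i])`: multipliers grow
#' while a constraint is violated on average and decay (clamped at 0)
#' once it is satisfied.
#'
#' @param dual A [dual_state()].
#' @param mean_g Batch-mean constraint values.
#' @return Updated `dual_state`.
#' @export
dual_update <- function(dual, mean_g) {
  stopifnot(length(mean_g) == length(dual$lambda))
  dual$lambda <- pmax(0, dual$lambda + dual$eta * mean_g)
  dual
}
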
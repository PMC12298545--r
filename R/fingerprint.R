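# Morgan (ECFP-style) fingerprints on polymer graphs, and Tanimoto
# distance between fingerprints.

# Deterministic integer hash over a vector of non-negative integers.
# Polynomial rolling hash mod a Mersenne prime; all arithmetic stays
# below 2^53 so doubles are exact.
hash_ints <- function(v) {
  p <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% p)) %% p
  h
}

# Initial atom invariant: element, degree, charge, aromaticity, role flags.
atom_invariants <- function(graph) {
  adj <- adjacency_list(graph)
  deg <- lengths(adj)
  elems <- match(graph$nodes$element, names(ATOMIC_WEIGHTS))
  elems[is.na(elems)] <- 0L
  vapply(seq_len(nrow(graph$nodes)), function(v) {
    hash_ints(c(elems[v], deg[v], graph$nodes$formal_charge[v] + 10,
                as.integer(graph$nodes$aromatic[v]),
                as.integer(graph$nodes$crosslink_site[v])))
  }, numeric(1))
}

bond_code <- function(order, crosslink) {
  base <- match(order, names(BOND_ORDER_VALUE))
  base + if (crosslink) 10L else 0L
}

#' Morgan fingerprint of a polymer graph
#'
#' Extended-connectivity fingerprint computed directly on the polymer
#' graph: atom invariants (element, degree, charge, aromaticity,
#' cross-link-site flag) are iteratively refined `radius` times by
#' hashing each atom's invariant together with the sorted
#' (bond-code, neighbor-invariant) pairs, and every (atom, iteration)
#' environment sets one bit. Neighbor pairs are sorted before hashing,
#' so the result is invariant to node relabeling.
#'
#' @param graph A `poly_graph`.
#' @param radius Neighborhood radius (>= 0); radius 0 uses atom
#'   invariants only.
#' @param n_bits Fingerprint length (default 2048).
#' @return A `fingerprint`: list with logical `bits`, `radius`, `n_bits`.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(graph, "poly_graph"))
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  bits <- rep(FALSE, n_bits)
  n <- nrow(graph$nodes)
  if (n > 0) {
    adj <- adjacency_list(graph)
    # bond code lookup per (min,max) pair
    ecode <- new.env(parent = emptyenv())
    if (nrow(graph$edges) > 0) {
      for (k in seq_len(nrow(graph$edges))) {
        key <- paste(graph$edges$i[k], graph$edges$j[k])
        assign(key, bond_code(graph$edges$order[k], graph$edges$crosslink[k]), envir = ecode)
      }
    }
    inv <- atom_invariants(graph)
    set_bit <- function(h) bits[(h %% n_bits) + 1L] <<- TRUE
    for (h in inv) set_bit(h)
    if (radius > 0) {
      for (it in seq_len(radius)) {
        new_inv <- numeric(n)
        for (v in seq_len(n)) {
          nb <- adj[[v]]
          if (length(nb)) {
            pairs <- vapply(nb, function(w) {
              key <- paste(min(v, w), max(v, w))
              c(get(key, envir = ecode), inv[w])
            }, numeric(2))
            ord <- order(pairs[1, ], pairs[2, ])
            flat <- as.vector(pairs[, ord, drop = FALSE])
          } else flat <- numeric(0)
          new_inv[v] <- hash_ints(c(it, inv[v], flat))
        }
        inv <- new_inv
        for (h in inv) set_bit(h)
      }
    }
  }
  structure(list(bits = bits, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

#' Tanimoto distance between two fingerprints
#'
#' One minus the Jaccard similarity of the two bit sets:
#' `1 - |a AND b| / |a OR b|`. Two empty fingerprints have distance 0.
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return A number in \[0, 1\]; 0 for identical bit sets, 1 for
#'   disjoint non-empty sets.
#' @export
tanimoto_distance <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) stop("fingerprints have mismatched n_bits", call. = FALSE)
  un <- sum(a$bits | b$bits)
  if (un == 0) return(0)
  1 - sum(a$bits & b$bits) / un
}

# Canonical structure key: multiset of fully-refined atom invariants.
# Used for novelty comparison (isomorphic graphs share a key).
canonical_key <- function(graph, radius = 3L) {
  n <- nrow(graph$nodes)
  if (n == 0) return("empty")
  adj <- adjacency_list(graph)
  ecode <- new.env(parent = emptyenv())
  if (nrow(graph$edges) > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      assign(paste(graph$edges$i[k], graph$edges$j[k]),
             bond_code(graph$edges$order[k], graph$edges$crosslink[k]), envir = ecode)
    }
  }
  inv <- atom_invariants(graph)
  for (it in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      flat <- if (length(nb)) {
        pairs <- vapply(nb, function(w) {
          c(get(paste(min(v, w), max(v, w)), envir = ecode), inv[w])
        }, numeric(2))
        ord <- order(pairs[1, ], pairs[2, ])
        as.vector(pairs[, ord, drop = FALSE])
      } else numeric(0)
      hash_ints(c(it, inv[v], flat))
    }, numeric(1))
  }
  paste(sort(inv), collapse = ",")
}
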
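# Polymer graphs: atom/bond graphs with polymer-specific edge roles.
#
# Node and edge indices are 1-based. Edges are undirected and stored
# once with i < j. Every edge carries exactly one of the three roles
# backbone / side-chain attachment / cross-link.

ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# Standard organic-subset valences; formal charge shifts the allowance
# (N+ gets 4, O- gets 1, C- gets 3, ...). S and P may be hypervalent.
MAX_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6, Cl = 1, Br = 1, I = 1
)

BOND_ORDER_VALUE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

new_poly_graph <- function(nodes, edges, mid_construction = FALSE) {
  structure(
    list(nodes = nodes, edges = edges, mid_construction = mid_construction),
    class = "poly_graph"
  )
}

empty_nodes <- function() {
  tibble::tibble(
    element = character(), aromatic = logical(), formal_charge = integer(),
    hybridization = character(), explicit_h = integer(),
    crosslink_site = logical(), stereo = logical(), depth = integer()
  )
}

empty_edges <- function() {
  tibble::tibble(
    i = integer(), j = integer(), order = character(), conjugated = logical(),
    stereo = character(), backbone = logical(), sidechain = logical(),
    crosslink = logical()
  )
}

#' @export
print.poly_graph <- function(x, ...) {
  cat("<poly_graph> ", nrow(x$nodes), " atoms, ", nrow(x$edges), " bonds (",
      sum(x$edges$backbone), " backbone, ", sum(x$edges$sidechain),
      " side-chain, ", sum(x$edges$crosslink), " cross-link)\n", sep = "")
  invisible(x)
}

# Parse a bracket-atom literal like [NH4+], [O-], [C@H]
parse_bracket_atom <- function(txt) {
  content <- sub("^\\[", "", sub("\\]$", "", txt))
  m <- regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?(([+-])([0-9]*)|([+]+)|(-+))?$",
               content)
  parts <- regmatches(content, m)[[1]]
  if (length(parts) == 0) stop(sprintf("cannot parse bracket atom %s", txt), call. = FALSE)
  elem <- parts[3]
  aromatic <- elem == tolower(elem) && nchar(elem) == 1L
  if (aromatic) elem <- toupper(elem)
  h <- if (parts[5] == "") 0L else if (parts[6] == "") 1L else as.integer(parts[6])
  charge <- 0L
  if (parts[7] != "") {
    if (parts[8] != "") {
      mag <- if (parts[9] == "") 1L else as.integer(parts[9])
      charge <- if (parts[8] == "+") mag else -mag
    } else if (parts[10] != "") {
      charge <- nchar(parts[10])
    } else if (parts[11] != "") {
      charge <- -nchar(parts[11])
    }
  }
  list(element = elem, aromatic = aromatic, explicit_h = h, formal_charge = charge,
       stereo = parts[4] != "")
}

#' Build a polymer graph from a token sequence
#'
#' Constructs the atom/bond graph for `repeat_count` copies of the
#' repeat unit described by `seq`. Bonds between two top-level chain
#' atoms (and the inter-unit joins) are flagged `backbone`; bonds into
#' or inside branches are flagged `sidechain`; bonds created between
#' cross-link sites (atoms preceding a `[#]` token) are flagged
#' `crosslink`. When the unit carries cross-link sites, consecutive
#' sites are joined so the flag is observable on a built graph; open
#' sites remain available to modify actions during generation.
#'
#' @param seq A `poly_sequence` from [parse_bigsmiles_ext()].
#' @param repeat_count Number of repeat-unit copies (>= 1).
#' @return A `poly_graph` with 1-based node indices and undirected
#'   edges stored once.
#' @export
build_polymer_graph <- function(seq, repeat_count = 1L) {
  stopifnot(inherits(seq, "poly_sequence"), repeat_count >= 1L)
  toks <- seq$tokens
  n_atoms <- sum(toks$kind == "atom")
  if (count_tokens(seq, "stochastic-point") > 0L && n_atoms == 0L) {
    stop("stochastic-point token with no neighboring repeat context", call. = FALSE)
  }
  unit <- build_unit_graph(toks)
  if (repeat_count == 1L && nrow(unit$nodes) == 0L) {
    return(new_poly_graph(empty_nodes(), empty_edges()))
  }
  nodes <- unit$nodes
  edges <- unit$edges
  n_unit <- nrow(unit$nodes)
  if (repeat_count > 1L) {
    top <- which(unit$nodes$depth == 0L)
    head_atom <- if (length(top)) top[1] else 1L
    tail_atom <- if (length(top)) top[length(top)] else n_unit
    for (k in seq_len(repeat_count - 1L)) {
      off <- k * n_unit
      shifted <- unit$edges
      shifted$i <- shifted$i + off
      shifted$j <- shifted$j + off
      nodes <- dplyr::bind_rows(nodes, unit$nodes)
      edges <- dplyr::bind_rows(edges, shifted)
      # join tail of copy k to head of copy k+1 along the backbone
      edges <- add_edge(edges, tail_atom + (k - 1L) * n_unit, head_atom + off,
                        order = "single", backbone = TRUE)
    }
  }
  g <- new_poly_graph(nodes, edges)
  # make cross-link sites visible as cross-link edges where possible
  sites <- which(g$nodes$crosslink_site)
  if (length(sites) >= 2L) {
    existing <- paste(g$edges$i, g$edges$j)
    for (k in seq_len(length(sites) - 1L)) {
      a <- sites[k]; b <- sites[k + 1L]
      if (b - a == nrow(unit$nodes) || repeat_count == 1L) {
        if (!(paste(min(a, b), max(a, b)) %in% existing)) {
          g$edges <- add_edge(g$edges, a, b, order = "single", crosslink = TRUE)
        }
      }
    }
  }
  g
}

# Build the graph of a single repeat unit from its token table.
build_unit_graph <- function(toks) {
  nodes <- empty_nodes()
  edges <- empty_edges()
  prev <- NA_integer_          # previous atom index
  pending_bond <- NULL         # explicit bond symbol awaiting next atom
  stack <- integer(0)          # branch return points
  depth <- 0L
  rings <- list()              # ring label -> list(atom, bond)

  add_atom <- function(tok) {
    if (grepl("^\\[", tok)) {
      info <- parse_bracket_atom(tok)
    } else {
      arom <- tok %in% c("b", "c", "n", "o", "p", "s")
      info <- list(element = if (arom) toupper(tok) else tok, aromatic = arom,
                   explicit_h = 0L, formal_charge = 0L, stereo = FALSE)
    }
    nodes <<- dplyr::bind_rows(nodes, data.frame(
      element = info$element, aromatic = info$aromatic,
      formal_charge = as.integer(info$formal_charge), hybridization = "sp3",
      explicit_h = as.integer(info$explicit_h), crosslink_site = FALSE,
      stereo = isTRUE(info$stereo), depth = depth
    ))
    nrow(nodes)
  }
  bond_order_of <- function(sym, a, b) {
    if (!is.null(sym)) {
      switch(sym, "=" = "double", "#" = "triple", "$" = "triple",
             ":" = "aromatic", "single")
    } else if (nodes$aromatic[a] && nodes$aromatic[b]) "aromatic" else "single"
  }

  for (r in seq_len(nrow(toks))) {
    kind <- toks$kind[r]; txt <- toks$text[r]
    if (kind == "atom") {
      idx <- add_atom(txt)
      if (!is.na(prev)) {
        ord <- bond_order_of(pending_bond, prev, idx)
        role_backbone <- nodes$depth[prev] == 0L && depth == 0L
        edges <- add_edge(edges, prev, idx, order = ord,
                          backbone = role_backbone, sidechain = !role_backbone,
                          stereo = if (!is.null(pending_bond) && pending_bond %in% c("/", "\\")) pending_bond else "none")
      }
      prev <- idx
      pending_bond <- NULL
    } else if (kind == "bond") {
      if (txt == ".") { prev <- NA_integer_; pending_bond <- NULL } else pending_bond <- txt
    } else if (kind == "ring-closure") {
      if (is.na(prev)) stop("ring closure before any atom", call. = FALSE)
      lbl <- txt
      if (!is.null(rings[[lbl]])) {
        other <- rings[[lbl]]
        ord <- bond_order_of(if (!is.null(pending_bond)) pending_bond else other$bond,
                             other$atom, prev)
        role_backbone <- nodes$depth[other$atom] == 0L && nodes$depth[prev] == 0L
        edges <- add_edge(edges, other$atom, prev, order = ord,
                          backbone = role_backbone, sidechain = !role_backbone)
        rings[[lbl]] <- NULL
        pending_bond <- NULL
      } else {
        rings[[lbl]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NULL
      }
    } else if (kind == "branch-open") {
      stack <- c(stack, prev)
      depth <- depth + 1L
    } else if (kind == "branch-close") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      depth <- depth - 1L
    } else if (kind == "crosslink-site") {
      if (!is.na(prev)) nodes$crosslink_site[prev] <- TRUE
    }
    # chain-init/chain-term/stochastic-point are positional markers only
  }
  nodes$hybridization <- infer_hybridization(nodes, edges)
  list(nodes = nodes, edges = edges)
}

add_edge <- function(edges, a, b, order = "single", backbone = FALSE,
                     sidechain = FALSE, crosslink = FALSE, stereo = "none") {
  if (a == b) stop("self-loop edges are not allowed", call. = FALSE)
  if (crosslink) { backbone <- FALSE; sidechain <- FALSE }
  else if (!backbone && !sidechain) sidechain <- TRUE
  # hot path: base data.frame avoids tibble construction overhead
  dplyr::bind_rows(edges, data.frame(
    i = min(a, b), j = max(a, b), order = order,
    conjugated = order == "aromatic", stereo = stereo,
    backbone = backbone, sidechain = sidechain, crosslink = crosslink
  ))
}

infer_hybridization <- function(nodes, edges) {
  hyb <- rep("sp3", nrow(nodes))
  if (nrow(edges) == 0) return(hyb)
  for (k in seq_len(nrow(edges))) {
    o <- edges$order[k]
    for (v in c(edges$i[k], edges$j[k])) {
      if (o == "triple") hyb[v] <- "sp"
      else if (o %in% c("double", "aromatic") && hyb[v] != "sp") hyb[v] <- "sp2"
    }
  }
  hyb[nodes$aromatic] <- "sp2"
  hyb
}

# Sum of explicit bond orders incident to each node (+ explicit Hs).
explicit_valence <- function(graph) {
  val <- rep(0, nrow(graph$nodes))
  if (nrow(graph$edges) > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      o <- BOND_ORDER_VALUE[[graph$edges$order[k]]]
      val[graph$edges$i[k]] <- val[graph$edges$i[k]] + o
      val[graph$edges$j[k]] <- val[graph$edges$j[k]] + o
    }
  }
  val + graph$nodes$explicit_h
}

#' Check chemical validity of a polymer graph
#'
#' Applies valence, connectivity and formal-charge rules. Hydrogens are
#' implicit: a node violates valence when the sum of its explicit bond
#' orders (aromatic counting 1.5) plus explicit hydrogens exceeds the
#' element's allowance adjusted by formal charge. Connectivity requires
#' a single component unless the graph is flagged mid-construction.
#' Invalidity is reported, never thrown.
#'
#' @param graph A `poly_graph`.
#' @return A `validity_report`: list with `valid` and a tibble
#'   `violations` (`index`, `rule`).
#' @export
check_validity <- function(graph) {
  stopifnot(inherits(graph, "poly_graph"))
  idx <- integer(0); rule <- character(0)
  n <- nrow(graph$nodes)
  if (n > 0) {
    val <- explicit_valence(graph)
    for (v in seq_len(n)) {
      el <- graph$nodes$element[v]
      base <- MAX_VALENCE[[el]] %||% 4
      fc <- graph$nodes$formal_charge[v]
      # cations of N/O/P/S gain a bond; anions (and carbocations) lose one
      allowed <- if (fc > 0 && el %in% c("N", "O", "P", "S")) base + fc else base - abs(fc)
      if (round(val[v] * 2) / 2 > allowed + 1e-9) {
        idx <- c(idx, v); rule <- c(rule, "valence")
      }
      if (abs(graph$nodes$formal_charge[v]) > 2) {
        idx <- c(idx, v); rule <- c(rule, "charge")
      }
    }
    if (!isTRUE(graph$mid_construction)) {
      comp <- graph_components(graph)
      if (max(comp) > 1L) {
        minority <- which(comp != which.max(tabulate(comp)))
        idx <- c(idx, minority); rule <- c(rule, rep("connectivity", length(minority)))
      }
    }
  }
  structure(
    list(valid = length(idx) == 0L,
         violations = tibble::tibble(index = idx, rule = rule)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  if (x$valid) cat("<validity_report> valid\n")
  else {
    cat("<validity_report> INVALID:\n")
    print(x$violations)
  }
  invisible(x)
}

# Connected-component labels via BFS.
graph_components <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0) return(integer(0))
  adj <- adjacency_list(graph)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

adjacency_list <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (nrow(graph$edges) > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges$i[k]; b <- graph$edges$j[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

#' Molecular mass of a polymer graph
#'
#' Heavy atoms plus implicit hydrogens filled to standard valence.
#'
#' @param graph A `poly_graph`.
#' @return Mass in g/mol.
#' @export
molar_mass <- function(graph) {
  if (nrow(graph$nodes) == 0) return(0)
  w <- sum(ATOMIC_WEIGHTS[graph$nodes$element])
  val <- explicit_valence(graph)
  imp_h <- pmax(0, vapply(seq_len(nrow(graph$nodes)), function(v) {
    base <- MAX_VALENCE[[graph$nodes$element[v]]] %||% 4
    base - ceiling(val[v] - 1e-9)
  }, numeric(1)))
  w + sum(imp_h) * ATOMIC_WEIGHTS[["H"]]
}

# Merge graph `b` into `a`, optionally bonding a$node `at_a` to b's node
# `at_b`. Returns the merged graph; offsets b's indices.
merge_graphs <- function(a, b, at_a = NA_integer_, at_b = NA_integer_,
                         order = "single", backbone = TRUE, crosslink = FALSE) {
  off <- nrow(a$nodes)
  eb <- b$edges
  if (nrow(eb) > 0) { eb$i <- eb$i + off; eb$j <- eb$j + off }
  nodes <- dplyr::bind_rows(a$nodes, b$nodes)
  edges <- dplyr::bind_rows(a$edges, eb)
  if (!is.na(at_a) && !is.na(at_b)) {
    edges <- add_edge(edges, at_a, at_b + off, order = order,
                      backbone = backbone && !crosslink, crosslink = crosslink)
  }
  new_poly_graph(nodes, edges, mid_construction = a$mid_construction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
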
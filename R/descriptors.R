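# Hand-crafted polymer descriptors: polydispersity estimate, glass
# transition estimate and hydrophobicity index, via group-contribution
# tables shipped with the package, padded into a fixed-length vector.

.table_cache <- new.env(parent = emptyenv())

# Read a shipped coefficient table (inst/extdata), cached per session.
read_coef_table <- function(name) {
  if (!is.null(.table_cache[[name]])) return(.table_cache[[name]])
  path <- system.file("extdata", name, package = "polydeg")
  if (path == "") path <- file.path("inst", "extdata", name)  # during development
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  .table_cache[[name]] <- tab
  tab
}

# Per-atom contribution lookup keyed on element + context class.
atom_context <- function(graph) {
  ifelse(graph$nodes$aromatic, paste0(graph$nodes$element, ".ar"),
         paste0(graph$nodes$element, ".", graph$nodes$hybridization))
}

lookup_contrib <- function(keys, tab, default = 0) {
  out <- tab$value[match(keys, tab$key)]
  # element-level fallback before the flat default
  miss <- is.na(out)
  if (any(miss)) {
    elem <- sub("\\..*$", "", keys[miss])
    out[miss] <- tab$value[match(elem, tab$key)]
  }
  out[is.na(out)] <- default
  out
}

#' Locate ester groups in a polymer graph
#'
#' An ester group is a carbonyl carbon (C double-bonded to O) joined by
#' a single bond to a bridging oxygen that carries a second heavy-atom
#' neighbor. Returns the C-O ester bonds and the member atoms
#' (carbonyl C, carbonyl O, bridging O).
#'
#' @param graph A `poly_graph`.
#' @return List with `bonds` (tibble `carbon`, `oxygen`) and `atoms`
#'   (integer vector of ester-group atom indices).
#' @export
find_ester_groups <- function(graph) {
  bonds <- tibble::tibble(carbon = integer(), oxygen = integer())
  atoms <- integer(0)
  e <- graph$edges
  if (nrow(e) > 0) {
    carbonyl_o <- integer(0)
    carbonyl_c <- integer(0)
    for (k in seq_len(nrow(e))) {
      if (e$order[k] == "double") {
        a <- e$i[k]; b <- e$j[k]
        ea <- graph$nodes$element[a]; eb <- graph$nodes$element[b]
        if (ea == "C" && eb == "O") { carbonyl_c <- c(carbonyl_c, a); carbonyl_o <- c(carbonyl_o, b) }
        if (ea == "O" && eb == "C") { carbonyl_c <- c(carbonyl_c, b); carbonyl_o <- c(carbonyl_o, a) }
      }
    }
    if (length(carbonyl_c)) {
      adj <- adjacency_list(graph)
      for (ci in seq_along(carbonyl_c)) {
        cc <- carbonyl_c[ci]
        for (k in seq_len(nrow(e))) {
          if (e$order[k] != "single") next
          a <- e$i[k]; b <- e$j[k]
          ox <- if (a == cc && graph$nodes$element[b] == "O") b
                else if (b == cc && graph$nodes$element[a] == "O") a
                else NA_integer_
          if (!is.na(ox) && length(adj[[ox]]) >= 2) {
            bonds <- dplyr::bind_rows(bonds, tibble::tibble(carbon = cc, oxygen = ox))
            atoms <- union(atoms, c(cc, carbonyl_o[ci], ox))
          }
        }
      }
    }
  }
  list(bonds = bonds, atoms = sort(atoms))
}

#' Hand-crafted polymer descriptors
#'
#' Deterministic fixed-length descriptor vector combining a
#' polydispersity estimate, a group-contribution glass-transition
#' estimate, a hydrophobicity index, and simple composition features.
#'
#' The polydispersity estimate follows a most-probable-distribution
#' heuristic driven by the number of stochastic-point tokens: a
#' sequence with no stochastic points describes a single chain species
#' (PDI 1); each stochastic point moves the estimate toward the
#' Flory limit of 2 via `1 + n / (n + 1)`. The glass-transition
#' estimate is a molar-mass-weighted atomic contribution sum
#' (`sum(Y_g) / M`, in K) and hydrophobicity is an atom-contribution
#' sum, both from tables in `inst/extdata`.
#'
#' @param graph A `poly_graph`.
#' @param seq The matching `poly_sequence`.
#' @param d_f Descriptor vector length (default 8). Extra slots beyond
#'   the named descriptors hold composition features; vectors longer
#'   than the feature set are zero-padded.
#' @return A `polymer_descriptors`: list with `pdi_estimate`,
#'   `tg_estimate` (K), `hydrophobicity_index`, and the padded numeric
#'   `vector` of length `d_f`.
#' @export
compute_descriptors <- function(graph, seq, d_f = 8L) {
  stopifnot(inherits(graph, "poly_graph"), inherits(seq, "poly_sequence"))
  ns <- count_tokens(seq, "stochastic-point")
  pdi <- 1 + if (ns > 0) ns / (ns + 1) else 0
  mass <- molar_mass(graph)
  ctx <- atom_context(graph)
  tg <- if (mass > 0) {
    sum(lookup_contrib(ctx, read_coef_table("tg_contributions.csv"))) / mass * 1000
  } else 0
  hydro <- sum(lookup_contrib(ctx, read_coef_table("hydrophobicity_contributions.csv")))
  n <- nrow(graph$nodes)
  esters <- find_ester_groups(graph)
  comp <- graph_components(graph)
  n_rings <- if (n > 0) nrow(graph$edges) - n + max(comp, 0L) else 0
  feats <- c(
    pdi,
    tg,
    hydro,
    mass / 100,
    n_rings,
    if (n > 0) mean(graph$nodes$aromatic) else 0,
    if (n > 0) nrow(esters$bonds) / n else 0,
    if (n > 0) mean(!graph$nodes$element %in% "C") else 0
  )
  vec <- rep(0, d_f)
  vec[seq_len(min(d_f, length(feats)))] <- feats[seq_len(min(d_f, length(feats)))]
  structure(
    list(pdi_estimate = pdi, tg_estimate = tg, hydrophobicity_index = hydro,
         vector = vec),
    class = "polymer_descriptors"
  )
}
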
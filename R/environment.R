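# The polymer-construction decision process: states, the three action
# categories (add monomer / modify / terminate), compatibility-matrix
# masking, and transitions.

#' Construct a monomer library
#'
#' @param monomers Tibble with columns `id`, `smiles`, `head_group`,
#'   `tail_group`, `class`. `head_group` is the reactive group through
#'   which the monomer attaches to the growing chain; `tail_group`
#'   becomes the chain's open end-group after attachment.
#' @param end_caps End-group ids available to terminate actions.
#' @param side_groups SMILES of side groups available to modify
#'   actions.
#' @return A `monomer_library`.
#' @export
monomer_library <- function(monomers, end_caps = c("H", "OH"),
                            side_groups = "C") {
  stopifnot(all(c("id", "smiles", "head_group", "tail_group", "class") %in%
                  names(monomers)))
  structure(list(monomers = tibble::as_tibble(monomers),
                 end_caps = end_caps, side_groups = side_groups),
            class = "monomer_library")
}

#' @export
print.monomer_library <- function(x, ...) {
  cat("<monomer_library> ", nrow(x$monomers), " monomers (",
      paste(unique(x$monomers$class), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read / write a monomer library as CSV
#'
#' CSV schema: header `id,smiles,end_groups,class` with `end_groups` a
#' semicolon-separated `head;tail` pair of reactive-group labels.
#'
#' @param path File path.
#' @return `read_monomer_library()` returns a `monomer_library`.
#' @export
read_monomer_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "smiles", "end_groups", "class") %in% names(df)))
  parts <- strsplit(df$end_groups, ";", fixed = TRUE)
  monomer_library(tibble::tibble(
    id = df$id, smiles = df$smiles,
    head_group = vapply(parts, `[`, "", 1),
    tail_group = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], ""),
    class = df$class
  ))
}

#' @rdname read_monomer_library
#' @param library A `monomer_library`.
#' @export
write_monomer_library <- function(library, path) {
  df <- data.frame(
    id = library$monomers$id,
    smiles = library$monomers$smiles,
    end_groups = paste(library$monomers$head_group,
                       library$monomers$tail_group, sep = ";"),
    class = library$monomers$class
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reaction-compatibility matrix as CSV
#'
#' Rows are monomer ids, columns end-group labels, cells 0/1; entry
#' `[i, j] = 1` means monomer `i` can react with an open end-group
#' `j`. The pseudo-group `"init"` gates which monomers can start a
#' chain.
#'
#' @param path File path.
#' @return A 0/1 matrix with dimnames.
#' @export
read_compatibility_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)))
  m
}

#' @rdname read_compatibility_matrix
#' @param m The matrix.
#' @export
write_compatibility_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cache of monomer graphs + attachment info, keyed by SMILES.
.monomer_cache <- new.env(parent = emptyenv())

monomer_unit <- function(smiles) {
  hit <- .monomer_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  seq <- parse_bigsmiles_ext(smiles)
  graph <- build_polymer_graph(seq, repeat_count = 1L)
  top <- which(graph$nodes$depth == 0L)
  info <- list(
    seq = seq, graph = graph,
    head_atom = if (length(top)) top[1] else NA_integer_,
    tail_atom = if (length(top)) top[length(top)] else NA_integer_,
    n_heavy = nrow(graph$nodes)
  )
  .monomer_cache[[smiles]] <- info
  info
}

#' Fresh generation state
#'
#' @param max_steps Episode length cap (default 32 actions).
#' @param stage_id Curriculum stage index carried in the environment
#'   context.
#' @return A `generation_state` with an empty (mid-construction) graph,
#'   the chain-initiation token, and the `"init"` open end-group.
#' @export
new_generation_state <- function(max_steps = 32L, stage_id = 1L) {
  structure(
    list(
      graph = new_poly_graph(empty_nodes(), empty_edges(), mid_construction = TRUE),
      seq_text = "[>]",
      open_group = "init",
      open_atom = NA_integer_,
      history = character(0),
      step = 0L,
      stage_id = stage_id,
      max_steps = as.integer(max_steps),
      done = FALSE
    ),
    class = "generation_state"
  )
}

#' @export
print.generation_state <- function(x, ...) {
  cat("<generation_state> step ", x$step, ", ", nrow(x$graph$nodes),
      " atoms, open end-group '", x$open_group, "'",
      if (x$done) " [terminal]" else "", "\n", sep = "")
  invisible(x)
}

#' Enumerate the available construction actions
#'
#' Deterministic order: add actions in the library's monomer order
#' (restricted to `allowed_ids` when given, e.g. by a curriculum
#' stage), then modify actions, then terminate actions. Modify and
#' terminate actions only appear once the chain holds at least one
#' monomer.
#'
#' @param state A `generation_state`.
#' @param library A `monomer_library`.
#' @param allowed_ids Monomer ids permitted by the current curriculum
#'   stage (default: all).
#' @return Tibble with columns `action_id`, `category`, `payload`.
#' @export
enumerate_actions <- function(state, library, allowed_ids = NULL) {
  ids <- library$monomers$id
  if (!is.null(allowed_ids)) ids <- ids[ids %in% allowed_ids]
  if (length(ids) == 0) stop("curriculum stage has an empty monomer library", call. = FALSE)
  acts <- tibble::tibble(
    action_id = paste0("add:", ids),
    category = "add",
    payload = ids
  )
  if (nrow(state$graph$nodes) > 0) {
    mods <- tibble::tibble(
      action_id = c(paste0("modify:side:", library$side_groups), "modify:crosslink"),
      category = "modify",
      payload = c(library$side_groups, "crosslink")
    )
    terms <- tibble::tibble(
      action_id = paste0("terminate:", library$end_caps),
      category = "terminate",
      payload = library$end_caps
    )
    acts <- dplyr::bind_rows(acts, mods, terms)
  }
  acts
}

#' Chemical-feasibility mask over enumerated actions
#'
#' Add actions are allowed iff the compatibility matrix has a 1 for
#' (monomer, current open end-group); modify and terminate actions are
#' allowed iff trial application yields a graph passing
#' [check_validity()].
#'
#' @param state A `generation_state`.
#' @param actions Tibble from [enumerate_actions()].
#' @param m Compatibility matrix (rows = monomer ids, columns include
#'   every end-group label that can become open, plus `"init"`).
#' @param library The `monomer_library` (needed for trial
#'   applications).
#' @return Logical vector aligned with `actions`.
#' @export
validity_mask <- function(state, actions, m, library) {
  if (!state$open_group %in% colnames(m)) {
    stop(sprintf("end-group '%s' missing from compatibility matrix columns",
                 state$open_group), call. = FALSE)
  }
  mask <- logical(nrow(actions))
  for (k in seq_len(nrow(actions))) {
    if (actions$category[k] == "add") {
      mid <- actions$payload[k]
      if (!mid %in% rownames(m)) {
        stop(sprintf("monomer '%s' missing from compatibility matrix rows", mid),
             call. = FALSE)
      }
      mask[k] <- m[mid, state$open_group] == 1L
    } else {
      ok <- tryCatch({
        trial <- apply_action(state, actions[k, ], library)
        check_validity(trial$graph)$valid
      }, error = function(e) FALSE)
      mask[k] <- ok
    }
  }
  mask
}

#' Apply a construction action to a generation state
#'
#' Pure transition: returns the updated state, leaving the input
#' untouched. Adds attach the monomer's head atom to the chain's open
#' atom with a backbone bond and insert a stochastic-point token in
#' the sequence; side-group modifications attach at the lowest-index
#' atom with spare valence; cross-link modifications join the first
#' two unlinked cross-link sites; termination caps the chain and marks
#' the episode done.
#'
#' @param state A `generation_state`.
#' @param action One row of the [enumerate_actions()] tibble (or a
#'   list with `action_id`, `category`, `payload`).
#' @param library The `monomer_library`.
#' @return The next `generation_state`.
#' @export
apply_action <- function(state, action, library) {
  cat_ <- action$category
  payload <- action$payload
  st <- state
  if (cat_ == "add") {
    row <- which(library$monomers$id == payload)
    if (length(row) != 1) stop("unknown monomer id: ", payload, call. = FALSE)
    unit <- monomer_unit(library$monomers$smiles[row])
    off <- nrow(st$graph$nodes)
    st$graph <- merge_graphs(st$graph, unit$graph,
                             at_a = st$open_atom, at_b = unit$head_atom)
    st$open_atom <- unit$tail_atom + off
    st$open_group <- library$monomers$tail_group[row]
    st$seq_text <- paste0(st$seq_text,
                          if (off > 0) "[$]" else "",
                          library$monomers$smiles[row])
  } else if (cat_ == "modify") {
    if (payload == "crosslink") {
      sites <- which(st$graph$nodes$crosslink_site)
      linked <- unique(c(st$graph$edges$i[st$graph$edges$crosslink],
                         st$graph$edges$j[st$graph$edges$crosslink]))
      open_sites <- setdiff(sites, linked)
      if (length(open_sites) < 2) {
        stop("no pair of open cross-link sites", call. = FALSE)
      }
      st$graph$edges <- add_edge(st$graph$edges, open_sites[1], open_sites[2],
                                 order = "single", crosslink = TRUE)
    } else {
      side <- monomer_unit(payload)
      val <- explicit_valence(st$graph)
      spare <- vapply(seq_len(nrow(st$graph$nodes)), function(v) {
        base <- MAX_VALENCE[[st$graph$nodes$element[v]]] %||% 4
        base - val[v]
      }, numeric(1))
      at <- which(spare >= 1)[1]
      if (is.na(at)) stop("no attachment point with spare valence", call. = FALSE)
      off <- nrow(st$graph$nodes)
      st$graph <- merge_graphs(st$graph, side$graph, at_a = at,
                               at_b = side$head_atom, backbone = FALSE)
      # side-group attachments are never backbone
      st$graph$edges$backbone[nrow(st$graph$edges)] <- FALSE
      st$graph$edges$sidechain[nrow(st$graph$edges)] <- TRUE
    }
  } else if (cat_ == "terminate") {
    if (payload == "OH") {
      cap <- new_poly_graph(
        tibble::tibble(element = "O", aromatic = FALSE, formal_charge = 0L,
                       hybridization = "sp3", explicit_h = 0L,
                       crosslink_site = FALSE, stereo = FALSE, depth = 0L),
        empty_edges()
      )
      st$graph <- merge_graphs(st$graph, cap, at_a = st$open_atom, at_b = 1L)
    }
    st$seq_text <- paste0(st$seq_text, "[<]")
    st$graph$mid_construction <- FALSE
    st$done <- TRUE
    st$open_group <- payload
  } else {
    stop("unknown action category: ", cat_, call. = FALSE)
  }
  st$history <- c(st$history, action$action_id)
  st$step <- st$step + 1L
  if (st$step >= st$max_steps) st$done <- TRUE
  st
}

#' Is a generation state terminal?
#'
#' TRUE once a terminate action was applied or the step cap is
#' reached.
#'
#' @param state A `generation_state`.
#' @return Logical flag.
#' @export
is_terminal <- function(state) {
  isTRUE(state$done) || state$step >= state$max_steps
}

#' Fixed-length reaction-history summary
#'
#' Counts per action category plus the indices of the last `k`
#' actions (0-padded), used as part of the agent's state features.
#'
#' @param state A `generation_state`.
#' @param actions Action tibble defining the index space.
#' @param k Number of trailing actions to encode (default 4).
#' @return Numeric vector of length `3 + k`.
#' @export
history_summary <- function(state, actions, k = 4L) {
  cats <- sub(":.*$", "", state$history)
  counts <- c(sum(cats == "add"), sum(cats == "modify"), sum(cats == "terminate"))
  last <- utils::tail(state$history, k)
  idx <- match(last, actions$action_id)
  idx[is.na(idx)] <- 0L
  c(counts, c(rep(0L, k - length(idx)), idx)) / max(1L, nrow(actions))
}
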
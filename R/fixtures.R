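# Seeded synthetic fixtures: toy monomer libraries with compatibility
# matrices, surrogate-calibrated enzyme panels and pretraining
# corpora. Everything is a pure function of its spec + seed, so all
# pipeline tests run without downloads.

#' Specification of a toy monomer library
#'
#' @param n_monomers Reactive monomers to generate (>= 2).
#' @param fractions Class mix over vinyl, condensation and
#'   ring-opening monomers (must sum to 1).
#' @param n_traps Additional chemically saturated, unreactive
#'   monomers (all-zero compatibility rows; attaching one by force
#'   creates a valence violation). Default scales with library size.
#' @param seed Fixture seed.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_monomers = 20L,
                         fractions = c(vinyl = 0.4, condensation = 0.4,
                                       ring_opening = 0.2),
                         n_traps = max(2L, round(n_monomers * 0.15)),
                         seed = 42L) {
  stopifnot(n_monomers >= 2, abs(sum(fractions) - 1) < 1e-9)
  structure(list(n_monomers = as.integer(n_monomers), fractions = fractions,
                 n_traps = as.integer(n_traps), seed = as.integer(seed)),
            class = "fixture_spec")
}

# Building blocks per class. Vinyl units are already-opened C-C repeat
# units with a variable side group; condensation and ring-opening
# units are hydroxyl-head / carboxyl-tail chains.
VINYL_SIDES <- c("C", "CC", "c1ccccc1", "Cl", "C#N", "C(=O)OC", "OC(=O)C", "O")
CONDENSATION_CORES <- c("OCC(=O)", "OC(C)C(=O)", "OCCC(=O)", "OCCOC(=O)C(=O)",
                        "OCCCC(=O)", "OCC(C)C(=O)")
RING_OPENED_CORES <- c("OCCCCC(=O)", "OCCOCC(=O)", "OCCCCCC(=O)", "OCCSCC(=O)")
TRAP_SMILES <- c("C(F)(F)(F)F", "O(C)C", "FC(F)(F)C(F)(F)F", "N(C)(C)C")

#' Generate a seeded toy monomer library and compatibility matrix
#'
#' Builds `n_monomers` chemically valid monomers across the three
#' polymerization classes (plus saturated trap monomers whose
#' compatibility rows are all zero), assigns curriculum tiers
#' (tier 3 monomers carry cross-link sites), and derives the
#' reaction-compatibility matrix from end-group chemistry: vinyl
#' radicals chain with vinyl, hydroxyl heads react with open carboxyl
#' ends and vice versa, and every reactive monomer may start a chain
#' (`init` column). At least one length-<=8 terminating action
#' sequence exists by construction (any self-compatible class).
#'
#' @param spec A [fixture_spec()].
#' @return List with `library` (a `monomer_library` with `tier`
#'   column) and `m_rxn` (compatibility matrix).
#' @export
make_toy_library <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_monomers
    n_v <- round(spec$fractions[["vinyl"]] * n)
    n_c <- round(spec$fractions[["condensation"]] * n)
    n_r <- n - n_v - n_c
    rows <- list()
    mk <- function(id, smiles, head, tail, class, tier) {
      tibble::tibble(id = id, smiles = smiles, head_group = head,
                     tail_group = tail, class = class, tier = tier)
    }
    for (i in seq_len(n_v)) {
      side <- sample(VINYL_SIDES, 1)
      smiles <- if (stats::runif(1) < 0.25) "CC" else paste0("CC(", side, ")")
      rows[[length(rows) + 1L]] <-
        mk(sprintf("V%02d", i), smiles, "vinyl", "vinyl", "vinyl", 1L)
    }
    for (i in seq_len(n_c)) {
      core <- sample(CONDENSATION_CORES, 1)
      rows[[length(rows) + 1L]] <-
        mk(sprintf("C%02d", i), core, "hydroxyl", "carboxyl", "condensation",
           if (i <= ceiling(n_c / 2)) 1L else 2L)
    }
    for (i in seq_len(n_r)) {
      core <- sample(RING_OPENED_CORES, 1)
      # tier-3 ring-opened monomers carry a cross-link site
      tier <- if (i > ceiling(n_r / 2)) 3L else 2L
      if (tier == 3L) core <- paste0(core, "C[#]")
      rows[[length(rows) + 1L]] <-
        mk(sprintf("R%02d", i), core, "hydroxyl", "carboxyl", "ring_opening",
           tier)
    }
    for (i in seq_len(spec$n_traps)) {
      rows[[length(rows) + 1L]] <-
        mk(sprintf("T%02d", i), TRAP_SMILES[(i - 1L) %% length(TRAP_SMILES) + 1L],
           "inert", "inert", "trap", 1L)
    }
    monomers <- dplyr::bind_rows(rows)
    # deduplicate ids are unique by construction; smiles may repeat
    lib <- monomer_library(monomers)

    groups <- c("init", "vinyl", "hydroxyl", "carboxyl", "inert", "H", "OH")
    m <- matrix(0L, nrow(monomers), length(groups),
                dimnames = list(monomers$id, groups))
    reacts <- function(head, open) {
      (open == "init" && head != "inert") ||
        (head == "vinyl" && open == "vinyl") ||
        (head == "hydroxyl" && open == "carboxyl") ||
        (head == "carboxyl" && open == "hydroxyl")
    }
    for (r in seq_len(nrow(monomers))) {
      for (gcol in groups) {
        m[r, gcol] <- as.integer(reacts(monomers$head_group[r], gcol))
      }
    }
    # every monomer must itself be a valid structure
    for (s in monomers$smiles) {
      rep_ <- check_validity(build_polymer_graph(parse_bigsmiles_ext(s), 1L))
      if (!rep_$valid) stop("fixture generated an invalid monomer: ", s)
    }
    if (sum(m[, "init"]) == 0) stop("infeasible fixture spec: no chain starter")
    list(library = lib, m_rxn = m)
  })
}

#' Generate a surrogate-calibrated toy enzyme panel
#'
#' Draws per-enzyme surrogate coefficients `(a_e, b_e)` and
#' calibrates the normalization `(mu_e, sigma_e)` as the mean and
#' standard deviation of the surrogate's negated binding energies
#' over the library's homopolymers (3 repeat units each), so
#' [enzyme_reward()] averages close to 0.5 over the calibration set.
#' Degenerate spreads are jittered with a message.
#'
#' @param n_enzymes Panel size (>= 1).
#' @param library A `monomer_library`.
#' @param seed Seed.
#' @return An [enzyme_panel()].
#' @export
make_enzyme_panel <- function(n_enzymes = 4L, library, seed = 42L) {
  stopifnot(n_enzymes >= 1)
  with_seed(seed, {
    a <- stats::runif(n_enzymes, 2, 8)
    b <- stats::runif(n_enzymes, 0.5, 3)
    reactive <- library$monomers[library$monomers$class != "trap", ]
    feats <- lapply(reactive$smiles, function(s) {
      g <- build_polymer_graph(parse_bigsmiles_ext(s), repeat_count = 3L)
      binding_features(g)
    })
    ef <- vapply(feats, `[[`, numeric(1), "ester_frac")
    hf <- vapply(feats, `[[`, numeric(1), "hydrophobic")
    enz <- lapply(seq_len(n_enzymes), function(e) {
      neg_dg <- a[e] * ef + b[e] * hf
      mu <- mean(neg_dg)
      sg <- stats::sd(neg_dg)
      if (!is.finite(sg) || sg < 1e-6) {
        message("make_enzyme_panel: degenerate spread for enzyme ", e,
                "; jittered")
        sg <- max(sg, 0, na.rm = TRUE) + 0.05
      }
      tibble::tibble(enzyme_id = sprintf("E%02d", e), mu = mu, sigma = sg,
                     a = a[e], b = b[e])
    })
    enzyme_panel(dplyr::bind_rows(enz))
  })
}

#' Generate a pretraining corpus of polymer strings
#'
#' Samples random valid masked rollouts over the library: compatible
#' monomer chains of random length wrapped in chain-initiation /
#' termination tokens, with a stochastic-point token inserted between
#' consecutive units with probability `p_stochastic`. Every line
#' parses under [parse_bigsmiles_ext()].
#'
#' @param library A `monomer_library`.
#' @param m_rxn Its compatibility matrix.
#' @param n_sequences Corpus size.
#' @param p_stochastic Insertion rate of `[$]` between units.
#' @param max_units Maximum chain length in monomer units.
#' @param seed Seed.
#' @return Character vector of length `n_sequences`.
#' @export
make_pretrain_corpus <- function(library, m_rxn, n_sequences = 200L,
                                 p_stochastic = 0.5, max_units = 5L,
                                 seed = 42L) {
  with_seed(seed, {
    mono <- library$monomers
    starters <- mono$id[m_rxn[mono$id, "init"] == 1L]
    if (length(starters) == 0) stop("library has no valid polymerization path")
    vapply(seq_len(n_sequences), function(i) {
      len <- sample.int(max_units - 1L, 1) + 1L
      id <- sample(starters, 1)
      row <- which(mono$id == id)
      out <- paste0("[>]", mono$smiles[row])
      open <- mono$tail_group[row]
      for (u in seq_len(len - 1L)) {
        ok <- mono$id[m_rxn[, open] == 1L]
        if (length(ok) == 0) break
        id <- if (length(ok) == 1) ok else sample(ok, 1)
        row <- which(mono$id == id)
        sep <- if (stats::runif(1) < p_stochastic) "[$]" else ""
        out <- paste0(out, sep, mono$smiles[row])
        open <- mono$tail_group[row]
      }
      paste0(out, "[<]")
    }, character(1))
  })
}
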
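# Shared fixtures, built once per test run from the seeded generators.

.fixture_env <- new.env()

toy_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    .fixture_env$fx <- make_toy_library(fixture_spec())
  }
  .fixture_env$fx
}

toy_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- make_enzyme_panel(4, toy_fixture()$library, seed = 7)
  }
  .fixture_env$panel
}

toy_corpus <- function(n = 100) {
  fx <- toy_fixture()
  make_pretrain_corpus(fx$library, fx$m_rxn, n_sequences = n, seed = 99)
}

# Permute node labels of a graph (edge endpoints relabeled, i < j kept).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  g2 <- g
  g2$nodes <- g$nodes[perm, ]
  g2$edges$i <- inv[g$edges$i]
  g2$edges$j <- inv[g$edges$j]
  swap <- g2$edges$i > g2$edges$j
  tmp <- g2$edges$i[swap]
  g2$edges$i[swap] <- g2$edges$j[swap]
  g2$edges$j[swap] <- tmp
  g2
}

graph_of <- function(smiles, repeats = 1L) {
  build_polymer_graph(parse_bigsmiles_ext(smiles), repeat_count = repeats)
}

# Small feasible sub-library used for constrained-training tests: the
# condensation monomers, all unlocked from stage 1.
condensation_task <- function() {
  fx <- toy_fixture()
  keep <- grepl("^C0", fx$library$monomers$id)
  mono <- fx$library$monomers[keep, ]
  mono$tier <- 1L
  list(library = monomer_library(mono),
       m_rxn = fx$m_rxn[mono$id, , drop = FALSE])
}

# Sequence-encoder parameters with every weight zeroed: the output
# distribution is exactly uniform over the vocabulary.
zeroed_seq_params <- function(d_model = 16L) {
  sp <- sequence_encoder_params(d_model = d_model, n_blocks = 1L,
                                n_heads = 2L, seed = 2)
  sp$emb[] <- 0
  for (b in seq_along(sp$blocks)) {
    for (h in seq_along(sp$blocks[[b]]$attn$heads)) {
      sp$blocks[[b]]$attn$heads[[h]] <-
        lapply(sp$blocks[[b]]$attn$heads[[h]], function(m) m * 0)
    }
    sp$blocks[[b]]$W_ff1[] <- 0
    sp$blocks[[b]]$W_ff2[] <- 0
  }
  sp
}
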
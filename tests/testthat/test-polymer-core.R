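test_that("polymer tokens are recognized alongside SMILES atoms", {
  seq <- parse_bigsmiles_ext("CC[$]CC")
  expect_equal(sum(seq$tokens$kind == "atom"), 4)
  expect_equal(sum(seq$tokens$kind == "stochastic-point"), 1)
  expect_equal(seq$tokens$text[seq$tokens$kind == "stochastic-point"], "[$]")

  all_tok <- parse_bigsmiles_ext("[>]C[<]C[$]C[#]")
  expect_setequal(
    unique(all_tok$tokens$kind),
    c("chain-init", "chain-term", "stochastic-point", "crosslink-site", "atom")
  )
})

test_that("empty input yields an empty token list", {
  expect_equal(nrow(parse_bigsmiles_ext("")$tokens), 0)
})

test_that("parse errors name the offending offset or token", {
  expect_error(parse_bigsmiles_ext("CC(C"), "unbalanced")
  expect_error(parse_bigsmiles_ext("CC)C"), "offset 3")
  expect_error(parse_bigsmiles_ext("C[*]C"), "unknown bracket token")
  expect_error(parse_bigsmiles_ext("C1CC"), "unmatched ring closure")
  expect_error(parse_bigsmiles_ext("CC([$]C)"), "inside a branch")
})

test_that("serialize is the exact inverse of parse on fixture strings", {
  expect_identical(serialize_sequence(parse_bigsmiles_ext("C(=O)O[>]")),
                   "C(=O)O[>]")
  expect_identical(serialize_sequence(parse_bigsmiles_ext("C")), "C")
  for (s in toy_corpus(100)) {
    expect_identical(serialize_sequence(parse_bigsmiles_ext(s)), s)
  }
})

test_that("graph construction flags backbone and side-chain edges", {
  g <- graph_of("CC")
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_true(g$edges$backbone[1])

  gp <- graph_of("CC(C)")  # propylene repeat unit
  branch <- gp$edges[gp$edges$j == 3, ]
  expect_true(branch$sidechain)
  expect_false(branch$backbone)
})

test_that("node/edge counts match a token-level adjacency oracle", {
  fx <- toy_fixture()
  for (s in fx$library$monomers$smiles) {
    if (grepl("[#]", s, fixed = TRUE)) next  # cross-link joins counted below
    toks <- parse_bigsmiles_ext(s)$tokens
    n_atoms <- sum(toks$kind == "atom")
    n_ring_bonds <- sum(toks$kind == "ring-closure") / 2
    for (r in c(1L, 3L)) {
      g <- graph_of(s, r)
      expect_equal(nrow(g$nodes), r * n_atoms)
      # connected acyclic-unit oracle: (atoms - 1 + ring bonds) per unit
      # plus r - 1 inter-unit joins
      expect_equal(nrow(g$edges),
                   r * (n_atoms - 1 + n_ring_bonds) + (r - 1))
    }
  }
})

test_that("cross-link site tokens yield cross-link-flagged edges", {
  g <- graph_of("OCCCCC(=O)C[#]", 2)
  expect_equal(sum(g$edges$crosslink), 1)
  site_nodes <- which(g$nodes$crosslink_site)
  ce <- g$edges[g$edges$crosslink, ]
  expect_true(ce$i %in% site_nodes && ce$j %in% site_nodes)
})

test_that("a stochastic point needs atoms around it", {
  expect_error(build_polymer_graph(parse_bigsmiles_ext("[$]"), 1),
               "no neighboring repeat context")
})

test_that("valence and connectivity rules are reported, not thrown", {
  expect_true(check_validity(graph_of("C(C)(C)(C)C"))$valid)

  bad <- check_validity(graph_of("C(C)(C)(C)(C)C"))
  expect_false(bad$valid)
  expect_true(any(bad$violations$rule == "valence" & bad$violations$index == 1))

  split <- check_validity(graph_of("CC.CC"))
  expect_false(split$valid)
  expect_true(all(split$violations$rule == "connectivity"))

  # identical graphs yield identical reports (pure function)
  g <- graph_of("CC(C)C(=O)OC")
  expect_identical(check_validity(g), check_validity(g))
})

test_that("Morgan fingerprints are deterministic and permutation-invariant", {
  fx <- toy_fixture()
  smiles <- head(fx$library$monomers$smiles, 10)
  set.seed(31)
  for (s in smiles) {
    g <- graph_of(s, 2)
    f1 <- morgan_fingerprint(g)
    expect_identical(f1$bits, morgan_fingerprint(g)$bits)
    g2 <- permute_graph(g, sample(nrow(g$nodes)))
    expect_identical(f1$bits, morgan_fingerprint(g2)$bits)
  }
  expect_error(morgan_fingerprint(graph_of("CC"), radius = -1), "radius")
})

test_that("radius-0 fingerprints see atom invariants but not bonds", {
  f_single <- morgan_fingerprint(graph_of("CCO"), radius = 0)
  f_double <- morgan_fingerprint(graph_of("C=CO"), radius = 0)
  expect_identical(f_single$bits, f_double$bits)
  # with radius 1 the bond order difference becomes visible
  expect_false(identical(morgan_fingerprint(graph_of("CCO"), radius = 1)$bits,
                         morgan_fingerprint(graph_of("C=CO"), radius = 1)$bits))
})

test_that("tanimoto distance is a bounded semimetric", {
  fp <- function(bits) structure(list(bits = bits, radius = 2L,
                                      n_bits = length(bits)),
                                 class = "fingerprint")
  a <- fp(c(TRUE, TRUE, FALSE, FALSE))
  b <- fp(c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tanimoto_distance(a, a), 0)
  expect_equal(tanimoto_distance(a, b), 1)

  set.seed(7)
  for (i in 1:20) {
    x <- fp(stats::runif(64) < 0.3)
    y <- fp(stats::runif(64) < 0.3)
    inter <- sum(x$bits & y$bits)
    un <- sum(x$bits | y$bits)
    expected <- if (un == 0) 0 else 1 - inter / un
    expect_equal(tanimoto_distance(x, y), expected)
    expect_equal(tanimoto_distance(x, y), tanimoto_distance(y, x))
    expect_gte(tanimoto_distance(x, y), 0)
    expect_lte(tanimoto_distance(x, y), 1)
  }
  expect_error(tanimoto_distance(a, fp(rep(TRUE, 8))), "n_bits")
})

test_that("descriptors: monodisperse limit, length contract, contribution oracle", {
  seq <- parse_bigsmiles_ext("CCO")
  g <- build_polymer_graph(seq, 1)
  d <- compute_descriptors(g, seq)
  expect_equal(d$pdi_estimate, 1.0)
  expect_length(d$vector, 8)
  expect_length(compute_descriptors(g, seq, d_f = 12L)$vector, 12)

  # stochastic sequences move the estimate toward the Flory limit
  seq2 <- parse_bigsmiles_ext("CC[$]CC")
  expect_gt(compute_descriptors(build_polymer_graph(seq2, 2), seq2)$pdi_estimate, 1)

  # hydrophobicity equals a hand summation over the shipped table
  seq5 <- parse_bigsmiles_ext("CCOCC")  # 4 sp3 carbons + 1 ether oxygen
  g5 <- build_polymer_graph(seq5, 1)
  tab <- utils::read.csv(system.file("extdata", "hydrophobicity_contributions.csv",
                                     package = "polydeg"),
                         comment.char = "#")
  expected <- 4 * tab$value[tab$key == "C.sp3"] + tab$value[tab$key == "O.sp3"]
  expect_equal(compute_descriptors(g5, seq5)$hydrophobicity_index, expected)
})
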
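test_that("fixtures are pure functions of spec and seed", {
  f1 <- make_toy_library(fixture_spec(seed = 5))
  f2 <- make_toy_library(fixture_spec(seed = 5))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_monomer_library(f1$library, p1)
  write_monomer_library(f2$library, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(f1$m_rxn, f2$m_rxn)

  f3 <- make_toy_library(fixture_spec(seed = 6))
  expect_false(identical(f1$library$monomers$smiles,
                         f3$library$monomers$smiles))
})

test_that("every generated monomer is a valid structure with consistent labels", {
  fx <- toy_fixture()
  mono <- fx$library$monomers
  expect_gte(nrow(mono), 20)
  for (s in mono$smiles) {
    expect_true(check_validity(graph_of(s))$valid)
  }
  # traps are unreactive: all-zero compatibility rows
  traps <- mono$id[mono$class == "trap"]
  expect_gte(length(traps), 2)
  expect_true(all(fx$m_rxn[traps, ] == 0L))
  # and structurally saturated: forcing an attachment breaks valence
  st <- new_generation_state(max_steps = 4)
  acts <- enumerate_actions(st, fx$library)
  st1 <- apply_action(st, acts[acts$payload == traps[1], ], fx$library)
  acts1 <- enumerate_actions(st1, fx$library)
  st2 <- apply_action(st1, acts1[acts1$category == "add" &
                                   !acts1$payload %in% traps, ][1, ],
                      fx$library)
  expect_false(check_validity(st2$graph)$valid)
})

test_that("a terminating action sequence of bounded length exists", {
  fx <- toy_fixture()
  found <- FALSE
  frontier <- list(new_generation_state(max_steps = 8))
  for (depth in 1:8) {
    nxt <- list()
    for (st in frontier) {
      acts <- enumerate_actions(st, fx$library)
      mask <- validity_mask(st, acts, fx$m_rxn, fx$library)
      for (k in which(mask)) {
        if (acts$category[k] == "terminate") {
          st2 <- apply_action(st, acts[k, ], fx$library)
          if (is_terminal(st2) && check_validity(st2$graph)$valid) found <- TRUE
        } else if (length(nxt) < 4) {
          nxt[[length(nxt) + 1L]] <- apply_action(st, acts[k, ], fx$library)
        }
      }
      if (found) break
    }
    if (found) break
    frontier <- nxt
  }
  expect_true(found)
})

test_that("enzyme panels are seeded, positive-spread and centered by construction", {
  fx <- toy_fixture()
  p1 <- make_enzyme_panel(4, fx$library, seed = 21)
  p2 <- make_enzyme_panel(4, fx$library, seed = 21)
  expect_identical(p1$enzymes, p2$enzymes)
  expect_true(all(p1$enzymes$sigma > 0))

  # calibration-by-construction: mean reward ~ 0.5 over the library
  reactive <- fx$library$monomers[fx$library$monomers$class != "trap", ]
  rw <- vapply(reactive$smiles, function(s) {
    enzyme_reward(graph_of(s, 3), p1)
  }, numeric(1))
  expect_equal(mean(rw), 0.5, tolerance = 0.05)

  pf <- withr::local_tempfile(fileext = ".csv")
  write_enzyme_panel(p1, pf)
  expect_equal(read_enzyme_panel(pf)$enzymes$mu, p1$enzymes$mu,
               tolerance = 1e-9)
})

test_that("pretraining corpora parse and hit the stochastic-point rate", {
  fx <- toy_fixture()
  corpus <- make_pretrain_corpus(fx$library, fx$m_rxn, n_sequences = 150,
                                 p_stochastic = 0.5, seed = 13)
  expect_length(corpus, 150)
  n_join <- 0L
  n_sp <- 0L
  for (line in corpus) {
    seq <- parse_bigsmiles_ext(line)
    expect_s3_class(seq, "poly_sequence")
    expect_equal(seq$tokens$kind[1], "chain-init")
    # junctions between consecutive units: count from the rebuilt chain
    n_sp <- n_sp + sum(seq$tokens$kind == "stochastic-point")
  }
  # identical seeds reproduce the corpus byte for byte
  expect_identical(corpus,
                   make_pretrain_corpus(fx$library, fx$m_rxn, 150,
                                        p_stochastic = 0.5, seed = 13))
  # binomial check: with ~150 * E[units-1] junctions at p = 0.5 the
  # stochastic-point count must sit within 2 sigma of the expectation
  corpus1 <- make_pretrain_corpus(fx$library, fx$m_rxn, n_sequences = 150,
                                  p_stochastic = 1, seed = 13)
  n_junctions <- sum(vapply(corpus1, function(l) {
    sum(parse_bigsmiles_ext(l)$tokens$kind == "stochastic-point")
  }, numeric(1)))
  expect_gt(n_junctions, 0)
  expect_lt(abs(n_sp - 0.5 * n_junctions), 2 * sqrt(n_junctions * 0.25))
})
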
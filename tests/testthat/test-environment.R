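test_that("action enumeration is ordered, stage-filtered and stable", {
  fx <- toy_fixture()
  st <- new_generation_state(max_steps = 8)

  a1 <- enumerate_actions(st, fx$library)
  expect_true(all(a1$category == "add"))  # no chain yet: nothing to modify
  expect_equal(a1$payload, fx$library$monomers$id)
  expect_identical(a1, enumerate_actions(st, fx$library))

  tier1 <- stage_monomers(fx$library, 1L)
  a_stage <- enumerate_actions(st, fx$library, allowed_ids = tier1)
  expect_true(all(a_stage$payload %in% tier1))
  expect_lt(nrow(a_stage), nrow(a1))

  expect_error(enumerate_actions(st, fx$library, allowed_ids = character(0)),
               "empty monomer library")
})

test_that("compatibility-matrix semantics drive the add mask", {
  fx <- toy_fixture()
  st <- new_generation_state(max_steps = 8)
  acts <- enumerate_actions(st, fx$library)

  m_all <- fx$m_rxn
  m_all[, "init"] <- 1L
  expect_true(all(validity_mask(st, acts, m_all, fx$library)))

  m_none <- fx$m_rxn
  m_none[1, "init"] <- 0L
  mask <- validity_mask(st, acts, m_none, fx$library)
  expect_false(mask[1])

  st_bad <- st
  st_bad$open_group <- "no-such-group"
  expect_error(validity_mask(st_bad, acts, fx$m_rxn, fx$library),
               "missing from compatibility matrix")
})

test_that("transitions grow the graph and termination ends the episode", {
  fx <- toy_fixture()
  st <- new_generation_state(max_steps = 8)
  acts <- enumerate_actions(st, fx$library)
  mask <- validity_mask(st, acts, fx$m_rxn, fx$library)

  first <- which(mask)[1]
  st1 <- apply_action(st, acts[first, ], fx$library)
  unit_atoms <- nrow(graph_of(fx$library$monomers$smiles[first])$nodes)
  expect_equal(nrow(st1$graph$nodes), unit_atoms)
  expect_false(is_terminal(st1))

  # purity: same state + action give identical results
  expect_identical(st1, apply_action(st, acts[first, ], fx$library))

  acts1 <- enumerate_actions(st1, fx$library)
  term <- which(acts1$category == "terminate")[1]
  st2 <- apply_action(st1, acts1[term, ], fx$library)
  expect_true(is_terminal(st2))
  expect_true(grepl("\\[<\\]$", st2$seq_text))

  # a 3-heavy-atom monomer adds exactly 3 nodes
  prop_lib <- monomer_library(tibble::tibble(
    id = "P1", smiles = "CC(C)", head_group = "vinyl", tail_group = "vinyl",
    class = "vinyl"))
  stp <- apply_action(st, tibble::tibble(action_id = "add:P1",
                                         category = "add", payload = "P1"),
                      prop_lib)
  expect_equal(nrow(stp$graph$nodes), 3)

  # step cap forces termination
  expect_true(is_terminal(new_generation_state(max_steps = 0)))
})

test_that("cross-link modification adds a cross-link-flagged edge", {
  fx <- toy_fixture()
  xl_id <- fx$library$monomers$id[grepl("[#]", fx$library$monomers$smiles,
                                        fixed = TRUE)][1]
  skip_if(is.na(xl_id))
  st <- new_generation_state(max_steps = 8)
  add <- tibble::tibble(action_id = paste0("add:", xl_id), category = "add",
                        payload = xl_id)
  st <- apply_action(st, add, fx$library)
  st <- apply_action(st, add, fx$library)  # two units -> two open sites
  before <- sum(st$graph$edges$crosslink)
  st_x <- apply_action(st, tibble::tibble(action_id = "modify:crosslink",
                                          category = "modify",
                                          payload = "crosslink"),
                       fx$library)
  expect_equal(sum(st_x$graph$edges$crosslink), before + 1)
})

test_that("every mask-allowed action keeps the graph valid (exhaustive, depth 3)", {
  fx <- toy_fixture()
  frontier <- list(new_generation_state(max_steps = 8))
  for (depth in 1:3) {
    nxt <- list()
    for (st in frontier) {
      acts <- enumerate_actions(st, fx$library)
      mask <- validity_mask(st, acts, fx$m_rxn, fx$library)
      expect_true(any(mask))
      for (k in which(mask)) {
        st2 <- apply_action(st, acts[k, ], fx$library)
        expect_true(check_validity(st2$graph)$valid)
        expect_gte(nrow(st2$graph$nodes), nrow(st$graph$nodes))  # monotone growth
        if (!is_terminal(st2) && length(nxt) < 8) nxt[[length(nxt) + 1L]] <- st2
      }
    }
    frontier <- nxt
  }
})

test_that("library and compatibility matrix round-trip through CSV", {
  fx <- toy_fixture()
  libf <- withr::local_tempfile(fileext = ".csv")
  write_monomer_library(fx$library, libf)
  lib2 <- read_monomer_library(libf)
  expect_equal(lib2$monomers$id, fx$library$monomers$id)
  expect_equal(lib2$monomers$smiles, fx$library$monomers$smiles)
  expect_equal(lib2$monomers$head_group, fx$library$monomers$head_group)

  mf <- withr::local_tempfile(fileext = ".csv")
  write_compatibility_matrix(fx$m_rxn, mf)
  expect_equal(read_compatibility_matrix(mf), fx$m_rxn)
})
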
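test_that("prioritized sampling follows the power-law distribution", {
  expect_equal(priority_probabilities(rep(2, 4)), rep(0.25, 4))
  expect_equal(priority_probabilities(c(1, 5, 9), alpha_per = 0),
               rep(1 / 3, 3))
  p <- c(1, 2, 3)
  expect_equal(priority_probabilities(p, 0.6), p^0.6 / sum(p^0.6))
  expect_equal(sum(priority_probabilities(stats::runif(10) + 0.1, 0.6)), 1)
  expect_error(priority_probabilities(numeric(0)), "empty")
})

test_that("importance weights correct the prioritization bias", {
  probs <- rep(0.25, 4)
  expect_equal(importance_weights(probs, 4, beta_per = 1), rep(1, 4))
  expect_equal(importance_weights(c(0.7, 0.2, 0.1), 3, beta_per = 0),
               rep(1, 3))
  pr <- c(0.5, 0.3, 0.2)
  w_raw <- (1 / (3 * pr))^0.4
  expect_equal(importance_weights(pr, 3, beta_per = 0.4), w_raw / max(w_raw))
})

test_that("replay buffer: max-priority insertion, beta annealing, refresh", {
  buf <- replay_buffer(replay_config(capacity = 8))
  for (i in 1:3) replay_add(buf, list(x = i))
  expect_equal(buf$priorities[1:3], rep(1, 3))
  replay_update_priorities(buf, 2L, 5)
  replay_add(buf, list(x = 4))
  expect_equal(buf$priorities[4], 5 + buf$config$eps_per)

  cfg <- replay_config(beta_start = 0.4, beta_end = 1, anneal_steps = 100)
  expect_equal(polydeg:::replay_beta(cfg, 0), 0.4)
  expect_equal(polydeg:::replay_beta(cfg, 50), 0.7)
  expect_equal(polydeg:::replay_beta(cfg, 1e5), 1)

  s <- replay_sample(buf, 5, step = 10)
  expect_length(s$idx, 5)
  expect_true(all(s$weights <= 1 & s$weights > 0))
})

test_that("curriculum difficulty is the sigmoid ramp, mapped to stages", {
  sched <- curriculum_schedule(d_min = 0.2, d_max = 0.8, k = 0.1, t0 = 100)
  expect_equal(curriculum_difficulty(-1e6, sched), 0.2)
  expect_equal(curriculum_difficulty(100, sched), 0.5)
  ts <- seq(0, 300, by = 7)
  expect_equal(curriculum_difficulty(ts, sched),
               0.2 + 0.6 / (1 + exp(-0.1 * (ts - 100))))
  expect_true(all(diff(curriculum_difficulty(ts, sched)) >= 0))

  expect_equal(curriculum_stage(-1e6, curriculum_schedule()), 1L)
  expect_equal(curriculum_stage(1e6, curriculum_schedule()), 3L)

  fx <- toy_fixture()
  s1 <- stage_monomers(fx$library, 1L)
  s3 <- stage_monomers(fx$library, 3L)
  expect_true(all(s1 %in% s3))
  expect_gt(length(s3), length(s1))
})

test_that("masked sampling never returns a masked-out action", {
  fx <- toy_fixture()
  lib5 <- monomer_library(fx$library$monomers[1:5, ])
  st <- new_generation_state(max_steps = 4)
  actions <- enumerate_actions(st, lib5)
  mask <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  fspec <- feature_spec(lib5)
  pol <- policy_params(fspec$d_s, seed = 3)
  set.seed(99)
  picks <- replicate(1e3, sample_action(st, pol, actions, mask, fspec)$index)
  expect_true(all(picks %in% which(mask)))
  expect_error(sample_action(st, pol, actions, rep(FALSE, 5), fspec),
               "all actions masked")

  # latent coordinates live in the tanh cube
  out <- sample_action(st, pol, actions, mask, fspec)
  expect_true(all(abs(out$latent) <= 1))

  # zero-noise policy is deterministic
  a1 <- sample_action(st, pol, actions, mask, fspec, deterministic = TRUE)
  a2 <- sample_action(st, pol, actions, mask, fspec, deterministic = TRUE)
  expect_identical(a1$index, a2$index)
  expect_identical(a1$latent, a2$latent)
})

test_that("gradient clipping bounds the global norm at the configured maximum", {
  huge <- list(W = matrix(1e6, 4, 4), b = rep(1e6, 4))
  clipped <- polydeg:::clip_gradients(huge, max_norm = 10)
  norm <- sqrt(sum(vapply(clipped, function(g) sum(g^2), numeric(1))))
  expect_equal(norm, 10, tolerance = 1e-9)
  small <- list(W = matrix(0.1, 2, 2))
  expect_identical(polydeg:::clip_gradients(small, 10)$W, small$W)
})

test_that("soft target updates interpolate at exactly tau", {
  set.seed(4)
  fake_batch <- function(n, d_s, d_a) {
    list(
      transitions = lapply(seq_len(n), function(i) {
        list(s = stats::rnorm(d_s), u = stats::rnorm(d_a, sd = 0.3),
             reward = stats::rnorm(1), s2 = stats::rnorm(d_s),
             done = sample(0:1, 1))
      }),
      weights = rep(1, n)
    )
  }
  d_s <- 6L; d_a <- 3L
  pol <- policy_params(d_s, d_a = d_a, d_hidden = 8L, seed = 1)
  cr <- critic_set(d_s, d_a = d_a, d_hidden = 8L, seed = 2)
  t_old <- cr$t1
  cfg <- sac_config(tau = 0.005, batch_size = 16L)
  res <- sac_update(fake_batch(16, d_s, d_a), pol, cr, cfg)
  expect_equal(res$critics$t1$W1,
               0.005 * res$critics$q1$W1 + 0.995 * t_old$W1,
               tolerance = 1e-12)
  expect_length(res$td_errors, 16)
  expect_true(all(is.finite(res$td_errors)))
})

test_that("critic loss falls over repeated updates on a fixed batch", {
  set.seed(11)
  d_s <- 6L; d_a <- 3L
  batch <- list(
    transitions = lapply(1:32, function(i) {
      s <- stats::rnorm(d_s)
      list(s = s, u = stats::rnorm(d_a, sd = 0.5), reward = sum(s[1:2]),
           s2 = stats::rnorm(d_s), done = 1)
    }),
    weights = rep(1, 32)
  )
  pol <- policy_params(d_s, d_a = d_a, d_hidden = 16L, seed = 5)
  cr <- critic_set(d_s, d_a = d_a, d_hidden = 16L, seed = 6)
  cfg <- sac_config(batch_size = 32L, lr = 3e-3)
  first <- NA; last <- NA
  opt <- NULL
  for (i in 1:50) {
    res <- sac_update(batch, pol, cr, cfg, opt, step = i)
    pol <- res$policy; cr <- res$critics; opt <- res$opt_policy
    if (i == 1) first <- res$critic_loss
    last <- res$critic_loss
  }
  expect_lt(last, first)
})

test_that("short training runs are exactly reproducible under a fixed seed", {
  fx <- toy_fixture()
  panel <- toy_panel()
  cfg <- default_config()
  cfg$train$episodes <- 20L
  cfg$env$max_steps <- 5L
  fit1 <- train(fx$library, fx$m_rxn, panel, cfg, seed = 7)
  fit2 <- train(fx$library, fx$m_rxn, panel, cfg, seed = 7)
  expect_identical(tidy(fit1), tidy(fit2))
  # masked training emits only chemically valid polymers
  expect_true(all(tidy(fit1)$valid))
  expect_equal(nrow(glance(fit1)), 1)
})

test_that("generation-quality metrics: validity, diversity, novelty, hypervolume", {
  same <- rep("[>]CC[$]CC[<]", 3)
  ev_same <- evaluate_generation(same)
  expect_equal(ev_same$validity_pct, 100)
  expect_equal(ev_same$diversity, 0)

  mix <- c("[>]CC[<]", "[>]CCO[<]", "[>]c1ccccc1C[<]")
  ev <- evaluate_generation(mix, training_set = c("[>]CC[<]"))
  expect_equal(ev$validity_pct, 100)
  expect_gt(ev$diversity, 0)
  expect_equal(ev$novelty_pct, 100 * 2 / 3)

  # known 2-point front: rectangles (1,3) and (2,2) overlap in [0,1]x[0,2]
  expect_equal(hypervolume_indicator(rbind(c(1, 3), c(2, 2)), c(0, 0)), 5)
  expect_equal(hypervolume_indicator(rbind(c(1, 1)), c(0, 0)), 1)
  # 3-objective slicing: unit cube plus a dominated point changes nothing
  expect_equal(hypervolume_indicator(rbind(c(1, 1, 1), c(0.5, 0.5, 0.5)),
                                     c(0, 0, 0)), 1)
  # the dominated third point adds nothing to the front
  ev2 <- evaluate_generation(mix, objectives = rbind(c(1, 3), c(2, 2), c(0.5, 0.5)))
  expect_equal(ev2$hypervolume, 5)
})
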
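test_that("validity reward returns the two fixed constants", {
  valid <- check_validity(graph_of("CC"))
  invalid <- check_validity(graph_of("C(C)(C)(C)(C)C"))
  expect_identical(validity_reward(valid), 1.0)
  expect_identical(validity_reward(invalid), -10.0)
  expect_identical(validity_reward(invalid), validity_reward(invalid))
})

test_that("enzyme reward is a calibrated sigmoid average", {
  g <- graph_of("CC(=O)OC", 2)
  # provider pinned at the calibration midpoint: exactly 0.5
  panel_mid <- enzyme_panel(
    tibble::tibble(enzyme_id = c("A", "B"), mu = c(5, 7), sigma = c(1, 2),
                   a = 0, b = 0),
    provider = function(graph, enz) -enz$mu
  )
  expect_equal(enzyme_reward(g, panel_mid), 0.5)

  # very strong binding saturates toward 1
  panel_strong <- enzyme_panel(
    tibble::tibble(enzyme_id = "A", mu = 0, sigma = 1, a = 0, b = 0),
    provider = function(graph, enz) rep(-1000, nrow(enz))
  )
  expect_equal(enzyme_reward(g, panel_strong), 1, tolerance = 1e-9)

  # two-enzyme hand computation
  panel2 <- enzyme_panel(
    tibble::tibble(enzyme_id = c("A", "B"), mu = c(1, 2), sigma = c(0.5, 2),
                   a = 0, b = 0),
    provider = function(graph, enz) c(-1.6, -1.2)
  )
  expected <- mean(c(1 / (1 + exp(-(1.6 - 1) / 0.5)),
                     1 / (1 + exp(-(1.2 - 2) / 2))))
  expect_equal(enzyme_reward(g, panel2), expected)

  # strictly increasing in binding strength
  val_at <- function(dg) {
    p <- enzyme_panel(tibble::tibble(enzyme_id = "A", mu = 1, sigma = 1,
                                     a = 0, b = 0),
                      provider = function(graph, enz) dg)
    enzyme_reward(g, p)
  }
  expect_gt(val_at(-3), val_at(-2))

  panel_fail <- enzyme_panel(
    tibble::tibble(enzyme_id = "A", mu = 0, sigma = 1, a = 0, b = 0),
    provider = function(graph, enz) stop("boom")
  )
  expect_error(suppressWarnings(enzyme_reward(g, panel_fail)),
               "no enzyme could be scored")
})

test_that("degradability and total rewards follow the weighted hierarchy", {
  parts <- list(r_validity = 1, r_enzyme = 0.7, r_hydrolysis = 0.2,
                r_microplastic = 0.9, r_kinetics = 0.4)
  expect_equal(degradability_reward(parts, reward_weights(w1 = 1, w2 = 0,
                                                          w3 = 0, w4 = 0)),
               0.7)
  zero <- list(r_validity = 1, r_enzyme = 0, r_hydrolysis = 0,
               r_microplastic = 0, r_kinetics = 0)
  expect_equal(degradability_reward(zero), 0)

  set.seed(12)
  for (i in 1:10) {
    p <- list(r_validity = stats::rnorm(1), r_enzyme = stats::runif(1),
              r_hydrolysis = stats::runif(1), r_microplastic = stats::runif(1),
              r_kinetics = stats::runif(1), r_properties = stats::runif(1),
              r_synthesis = stats::runif(1))
    wv <- stats::runif(7)
    w <- reward_weights(wv[1], wv[2], wv[3], wv[4], wv[5], wv[6], wv[7])
    bd <- total_reward(p, w)
    r_deg <- sum(wv[4:7] * c(p$r_enzyme, p$r_hydrolysis, p$r_microplastic,
                             p$r_kinetics))
    expect_equal(bd$r_degradability, r_deg)
    expect_equal(bd$r_total,
                 p$r_validity + wv[1] * r_deg + wv[2] * p$r_properties +
                   wv[3] * p$r_synthesis)
  }

  # zero branch weights leave only the validity term
  bd0 <- total_reward(zero, reward_weights(alpha = 0, beta = 0, gamma = 0))
  expect_equal(bd0$r_total, zero$r_validity)

  # an invalidity event dominates bounded components under unit weights
  inv <- list(r_validity = -10, r_enzyme = 1, r_hydrolysis = 1,
              r_microplastic = 1, r_kinetics = 1, r_properties = 1,
              r_synthesis = 1)
  bd_inv <- total_reward(inv, reward_weights(1, 1, 1, 0.25, 0.25, 0.25, 0.25))
  expect_lt(bd_inv$r_total, 0)
})

test_that("diversity reward is the minimum buffer distance", {
  fps <- lapply(c("CC", "CCO", "CCN", "CCF", "c1ccccc1"), function(s) {
    morgan_fingerprint(graph_of(s, 2))
  })
  buf <- diversity_buffer(capacity = 50)
  expect_equal(diversity_reward(fps[[1]], buf), 1)  # empty buffer convention
  for (f in fps) push_fingerprint(buf, f)
  expect_equal(diversity_reward(fps[[1]], buf), 0)  # already present

  probe <- morgan_fingerprint(graph_of("CCCl", 2))
  oracle <- min(vapply(buf$fps, function(b) tanimoto_distance(probe, b),
                       numeric(1)))
  expect_equal(diversity_reward(probe, buf), oracle)

  # growing the buffer can only lower the minimum
  before <- diversity_reward(probe, buf)
  push_fingerprint(buf, morgan_fingerprint(graph_of("CCCl", 2)))
  expect_lte(diversity_reward(probe, buf), before)

  # FIFO capacity bound
  small <- diversity_buffer(capacity = 2)
  for (f in fps) push_fingerprint(small, f)
  expect_length(small$fps, 2)
})

test_that("meta-learning approaches a closed-form outer optimum", {
  w0 <- reward_weights(alpha = 0.2, beta = 1, gamma = 1,
                       w1 = 0.1, w2 = 0.5, w3 = 0, w4 = 0)
  expect_identical(meta_update_weights(w0, list(function(w, k) 0),
                                       meta_rate = 0),
                   w0)

  # quadratic bi-level toy: validation loss minimized at alpha = 2, w1 = 1
  task <- function(w, inner_steps) (w$alpha - 2)^2 + (w$w1 - 1)^2
  w <- w0
  for (i in 1:300) w <- meta_update_weights(w, list(task), meta_rate = 0.05)
  expect_equal(w$alpha, 2, tolerance = 0.02)
  expect_equal(w$w1, 1, tolerance = 0.02)

  # forward-difference gradient sign agrees with a central-difference probe
  w1 <- meta_update_weights(w0, list(task), meta_rate = 0.01)
  central <- (task(reward_weights(alpha = 0.2 + 1e-4), 1) -
                task(reward_weights(alpha = 0.2 - 1e-4), 1)) / 2e-4
  expect_equal(sign(w1$alpha - w0$alpha), -sign(central))

  # non-finite losses skip the update with a warning
  expect_warning(
    out <- meta_update_weights(w0, list(function(w, k) NaN), meta_rate = 0.1),
    "non-finite"
  )
  expect_identical(out, w0)

  # weights are clipped non-negative
  push_down <- function(w, k) 100 * w$w2
  w_neg <- meta_update_weights(reward_weights(w2 = 0.001), list(push_down),
                               meta_rate = 10)
  expect_gte(w_neg$w2, 0)
})

test_that("placeholder sub-rewards stay in range and default to zero weight", {
  g <- graph_of("CC(=O)OC", 3)
  expect_gt(microplastic_reward(g), 0)
  expect_lte(microplastic_reward(g), 1)
  expect_gte(kinetics_reward(g), 0)
  expect_lte(kinetics_reward(g), 1)
  w <- reward_weights()
  expect_equal(w$w3, 0)
  expect_equal(w$w4, 0)
})
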
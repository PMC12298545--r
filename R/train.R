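# Training loop: masked rollouts -> prioritized replay -> SAC (or
# categorical policy-gradient) updates -> per-epoch dual updates ->
# curriculum advance, with a sliding-window convergence monitor.
# Also: generation, reward scoring and generation-quality metrics.

#' Score one finished polymer against the full reward stack
#'
#' Runs validity, the degradability sub-rewards (enzyme panel,
#' hydrolysis, microplastic and kinetics placeholders), the physics
#' constraints and the diversity bonus for a built polymer graph.
#'
#' @param graph A `poly_graph` of the finished polymer.
#' @param seq The matching `poly_sequence`.
#' @param panel An [enzyme_panel()].
#' @param weights A [reward_weights()].
#' @param cs A [constraint_set()].
#' @param buffer Optional [diversity_buffer()] for the diversity
#'   bonus.
#' @return List with `breakdown` (a `reward_breakdown`), `g`
#'   (constraint values) and `fingerprint`.
#' @export
score_polymer <- function(graph, seq, panel, weights = reward_weights(),
                          cs = constraint_set(), buffer = NULL) {
  report <- check_validity(graph)
  fp <- morgan_fingerprint(graph)
  r_div <- if (!is.null(buffer)) diversity_reward(fp, buffer) else 0
  if (report$valid && nrow(graph$nodes) > 0) {
    conf <- embed_conformer(graph)
    areas <- shrake_rupley_sasa(conf)
    attr(graph, "binding_features") <- binding_features(graph, conf, areas)
    parts <- list(
      r_validity = validity_reward(report),
      r_enzyme = enzyme_reward(graph, panel),
      r_hydrolysis = hydrolysis_reward(graph, conf, areas = areas),
      r_microplastic = microplastic_reward(graph),
      r_kinetics = kinetics_reward(graph),
      r_diversity = r_div
    )
    g <- evaluate_constraints(graph, cs)
  } else {
    parts <- list(r_validity = validity_reward(report), r_enzyme = 0,
                  r_hydrolysis = 0, r_microplastic = 0, r_kinetics = 0,
                  r_diversity = r_div)
    g <- c(g1 = 0, g2 = 0, g3 = 0)
  }
  list(breakdown = total_reward(parts, weights), g = g, fingerprint = fp,
       valid = report$valid)
}

# Roll out one episode under the masked policy. Returns the terminal
# state, per-step records and the per-step transition skeletons.
rollout_episode <- function(policy, library, m_rxn, allowed_ids, fspec,
                            cfg_env, embedder = NULL, deterministic = FALSE,
                            use_mask = TRUE, policy_kind = "sac") {
  state <- new_generation_state(max_steps = cfg_env$max_steps,
                                stage_id = cfg_env$stage_id %||% 1L)
  steps <- list()
  while (!is_terminal(state)) {
    actions <- enumerate_actions(state, library, allowed_ids)
    mask <- if (use_mask) validity_mask(state, actions, m_rxn, library)
            else rep(TRUE, nrow(actions))
    if (!any(mask)) break
    if (policy_kind == "categorical") {
      pick <- categorical_sample(policy, actions, mask, deterministic)
      rec <- list(action = pick$action, index = pick$index,
                  probs = pick$probs, allowed = pick$allowed,
                  action_ids = actions$action_id,
                  chosen_id = pick$action$action_id)
    } else {
      pick <- sample_action(state, policy, actions, mask, fspec,
                            embedder = embedder,
                            deterministic = deterministic)
      rec <- list(action = pick$action, index = pick$index,
                  latent = pick$latent, features = pick$features,
                  logp = pick$logp)
    }
    nxt <- tryCatch(apply_action(state, pick$action, library),
                    error = function(e) NULL)
    if (is.null(nxt)) break
    rec$state_before <- state
    state <- nxt
    steps[[length(steps) + 1L]] <- rec
  }
  list(state = state, steps = steps)
}

#' Train a polymer-generation agent
#'
#' Alternates masked rollouts, prioritized-replay SAC updates (or the
#' categorical policy-gradient variant), per-epoch dual updates of the
#' physics multipliers, and sigmoid-curriculum stage advances.
#' Training stops at `episodes` or when the composite convergence
#' metric (min-max-normalized sliding-window validity, diversity and
#' mean reward) fails to improve for `patience` consecutive episodes.
#' All randomness flows from `seed` through named substreams.
#'
#' @param library A `monomer_library` (with a `tier` column for the
#'   curriculum).
#' @param m_rxn Compatibility matrix.
#' @param panel An [enzyme_panel()].
#' @param config A [default_config()]-shaped configuration list.
#' @param seed Run seed.
#' @param use_mask Disable only for the no-mask ablation.
#' @param logger Optional logger from [open_run_log()].
#' @return A `polydeg_fit`: trained policy/critics, dual state,
#'   episode log tibble, diversity buffer, config.
#' @export
train <- function(library, m_rxn, panel, config = default_config(),
                  seed = 1L, use_mask = TRUE, logger = NULL) {
  set.seed(seed)
  cfg <- config
  sched <- curriculum_schedule(cfg$curriculum$d_min, cfg$curriculum$d_max,
                               cfg$curriculum$k, cfg$curriculum$t0,
                               cfg$curriculum$cuts)
  weights <- do.call(reward_weights, cfg$rewards[c("alpha", "beta", "gamma",
                                                   "w1", "w2", "w3", "w4")])
  cs <- constraint_set(cfg$constraints$dg_threshold,
                       cfg$constraints$sa_threshold, cfg$constraints$rho_min)
  duals <- dual_state(eta = cfg$duals$eta)
  fspec <- feature_spec(library, d_embed = cfg$encoder$d_f)
  kind <- cfg$train$policy
  policy <- if (kind == "categorical") {
    categorical_policy(entropy_coef = cfg$sac$entropy_coef,
                       lr = cfg$train$categorical_lr)
  } else {
    policy_params(fspec$d_s, d_a = cfg$sac$d_a, d_hidden = cfg$sac$d_hidden,
                  seed = seed)
  }
  critics <- critic_set(fspec$d_s, d_a = cfg$sac$d_a,
                        d_hidden = cfg$sac$d_hidden, seed = seed + 1L)
  saccfg <- sac_config(tau = cfg$sac$tau, clip_norm = cfg$sac$clip_norm,
                       lr = cfg$sac$lr, lr_period = cfg$sac$lr_period,
                       entropy_coef = cfg$sac$entropy_coef,
                       gamma = cfg$sac$gamma, batch_size = cfg$sac$batch_size,
                       critic_batch_norm = cfg$sac$critic_batch_norm)
  buf <- replay_buffer(replay_config(cfg$replay$alpha, cfg$replay$eps,
                                     cfg$replay$beta_start, cfg$replay$beta_end,
                                     cfg$replay$anneal_steps,
                                     cfg$replay$capacity))
  div_buf <- diversity_buffer(cfg$rewards$diversity_capacity)
  opt_policy <- NULL
  update_step <- 0L
  log_rows <- list()
  epoch_g <- list()
  best_metric <- -Inf
  plateau <- 0L
  win <- cfg$train$window
  hist_valid <- numeric(0); hist_div <- numeric(0); hist_rew <- numeric(0)

  for (ep in seq_len(cfg$train$episodes)) {
    stage <- min(curriculum_stage(ep, sched), max(library$monomers[["tier"]] %||% 1L))
    allowed <- stage_monomers(library, stage)
    env_cfg <- list(max_steps = cfg$env$max_steps, stage_id = stage)
    ro <- rollout_episode(policy, library, m_rxn, allowed, fspec, env_cfg,
                          policy_kind = kind, use_mask = use_mask)
    final <- ro$state
    sc <- score_polymer(final$graph, parse_bigsmiles_ext(final$seq_text),
                        panel, weights, cs, buffer = div_buf)
    penalty <- lagrangian_penalty(sc$g, duals)
    shaped <- sc$breakdown$r_total +
      cfg$rewards$diversity_coef * sc$breakdown$r_diversity - penalty
    push_fingerprint(div_buf, sc$fingerprint)
    epoch_g[[length(epoch_g) + 1L]] <- sc$g

    n_steps <- length(ro$steps)
    if (kind == "categorical") {
      if (n_steps > 0) categorical_update(policy, ro$steps, shaped)
    } else if (n_steps > 0) {
      for (k in seq_len(n_steps)) {
        st <- ro$steps[[k]]
        s2 <- if (k < n_steps) ro$steps[[k + 1]]$features
              else st$features  # terminal: bootstrap masked by done flag
        replay_add(buf, list(
          s = st$features, u = st$latent,
          reward = if (k == n_steps) shaped else 0,
          s2 = s2, done = as.numeric(k == n_steps)
        ))
      }
      if (buf$size >= saccfg$batch_size) {
        for (u in seq_len(cfg$train$updates_per_episode)) {
          update_step <- update_step + 1L
          batch <- replay_sample(buf, saccfg$batch_size, step = update_step)
          res <- sac_update(batch, policy, critics, saccfg, opt_policy,
                            step = update_step)
          policy <- res$policy; critics <- res$critics
          opt_policy <- res$opt_policy
          replay_update_priorities(buf, batch$idx, res$td_errors)
        }
      }
    }

    if (ep %% cfg$train$dual_every == 0 && length(epoch_g) > 0) {
      mean_g <- colMeans(do.call(rbind, epoch_g))
      duals <- dual_update(duals, mean_g)
      epoch_g <- list()
    }

    hist_valid <- c(hist_valid, as.numeric(sc$valid))
    hist_div <- c(hist_div, sc$breakdown$r_diversity)
    hist_rew <- c(hist_rew, sc$breakdown$r_total)
    row <- tibble::tibble(
      episode = ep, stage = stage, n_steps = n_steps,
      valid = sc$valid, r_total = sc$breakdown$r_total,
      r_enzyme = sc$breakdown$r_enzyme,
      r_hydrolysis = sc$breakdown$r_hydrolysis,
      r_diversity = sc$breakdown$r_diversity,
      g1 = sc$g[["g1"]], g2 = sc$g[["g2"]], g3 = sc$g[["g3"]],
      penalty = penalty,
      lambda1 = duals$lambda[1], lambda2 = duals$lambda[2],
      lambda3 = duals$lambda[3],
      seq_text = final$seq_text
    )
    log_rows[[ep]] <- row
    if (!is.null(logger)) logger$log(as.list(row))

    # composite convergence metric over the sliding window
    lo <- max(1, ep - win + 1)
    comp <- composite_metric(hist_valid[lo:ep], hist_div[lo:ep],
                             hist_rew[lo:ep])
    if (comp > best_metric + 1e-9) { best_metric <- comp; plateau <- 0L }
    else plateau <- plateau + 1L
    if (ep >= win && plateau >= cfg$train$patience) break
  }

  structure(
    list(policy = policy, critics = critics, duals = duals,
         episodes = dplyr::bind_rows(log_rows), library = library,
         m_rxn = m_rxn, panel = panel, config = cfg, fspec = fspec,
         weights = weights, cs = cs, div_buf = div_buf, seed = seed,
         policy_kind = kind),
    class = "polydeg_fit"
  )
}

# Composite convergence metric: mean of min-max-normalized window
# validity rate, diversity score and mean reward.
composite_metric <- function(valid, div, rew) {
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) return(0.5)
    (mean(x) - rng[1]) / diff(rng)
  }
  mean(c(mean(valid), norm01(div), norm01(rew)))
}

#' @export
print.polydeg_fit <- function(x, ...) {
  n <- nrow(x$episodes)
  cat("<polydeg_fit> ", n, " episodes (", x$policy_kind, " policy)\n", sep = "")
  if (n > 0) {
    tail50 <- x$episodes[max(1, n - 49):n, ]
    cat("  recent validity ", round(100 * mean(tail50$valid), 1),
        "%, mean reward ", round(mean(tail50$r_total), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Generate polymers from a trained agent
#'
#' @param fit A `polydeg_fit`.
#' @param n Number of polymers.
#' @param seed Seed for the generation rollouts.
#' @param deterministic Use the policy without exploration noise.
#' @param use_mask Disable only for ablations.
#' @return Tibble: `seq_text`, `valid`, `n_atoms`, plus a list column
#'   `fingerprint`.
#' @export
generate <- function(fit, n = 100L, seed = 1L, deterministic = FALSE,
                     use_mask = TRUE) {
  set.seed(seed)
  sched <- curriculum_schedule(fit$config$curriculum$d_min,
                               fit$config$curriculum$d_max,
                               fit$config$curriculum$k,
                               fit$config$curriculum$t0,
                               fit$config$curriculum$cuts)
  stage <- min(curriculum_stage(nrow(fit$episodes), sched),
               max(fit$library$monomers[["tier"]] %||% 1L))
  allowed <- stage_monomers(fit$library, stage)
  rows <- lapply(seq_len(n), function(i) {
    ro <- rollout_episode(fit$policy, fit$library, fit$m_rxn, allowed,
                          fit$fspec, list(max_steps = fit$config$env$max_steps,
                                          stage_id = stage),
                          deterministic = deterministic, use_mask = use_mask,
                          policy_kind = fit$policy_kind)
    g <- ro$state$graph
    g$mid_construction <- FALSE
    rep_ <- check_validity(g)
    tibble::tibble(seq_text = ro$state$seq_text, valid = rep_$valid,
                   n_atoms = nrow(g$nodes),
                   fingerprint = list(morgan_fingerprint(g)))
  })
  dplyr::bind_rows(rows)
}

#' Generation-quality metrics
#'
#' Validity (% passing [check_validity()]), diversity (mean pairwise
#' Tanimoto distance), novelty (% whose canonical structure key is
#' absent from the training set) and the hypervolume dominated by the
#' per-polymer objective vectors.
#'
#' @param polymers Character vector of polymer strings (or list of
#'   `poly_sequence`).
#' @param training_set Character vector of training polymer strings
#'   (novelty reference); NULL skips novelty.
#' @param objectives Optional numeric matrix (rows = polymers, <= 3
#'   columns, maximization) for the hypervolume indicator.
#' @param ref_point Hypervolume reference point (default origin).
#' @return Tibble with `validity_pct`, `diversity`, `novelty_pct`,
#'   `hypervolume`, `n`.
#' @export
evaluate_generation <- function(polymers, training_set = NULL,
                                objectives = NULL, ref_point = NULL) {
  texts <- if (is.list(polymers)) {
    vapply(polymers, serialize_sequence, character(1))
  } else polymers
  stopifnot(length(texts) >= 2)
  graphs <- lapply(texts, function(s) {
    build_polymer_graph(parse_bigsmiles_ext(s), repeat_count = 1L)
  })
  valid <- vapply(graphs, function(g) check_validity(g)$valid, logical(1))
  fps <- lapply(graphs, morgan_fingerprint)
  npoly <- length(graphs)
  dsum <- 0; cnt <- 0
  for (i in seq_len(npoly - 1)) {
    for (j in (i + 1):npoly) {
      dsum <- dsum + tanimoto_distance(fps[[i]], fps[[j]])
      cnt <- cnt + 1
    }
  }
  novelty <- NA_real_
  if (!is.null(training_set)) {
    train_keys <- vapply(training_set, function(s) {
      canonical_key(build_polymer_graph(parse_bigsmiles_ext(s), 1L))
    }, character(1))
    keys <- vapply(graphs, canonical_key, character(1))
    novelty <- 100 * mean(!keys %in% train_keys)
  }
  hv <- NA_real_
  if (!is.null(objectives)) {
    objectives <- as.matrix(objectives)
    if (is.null(ref_point)) ref_point <- rep(0, ncol(objectives))
    hv <- hypervolume_indicator(objectives, ref_point)
  }
  tibble::tibble(validity_pct = 100 * mean(valid), diversity = dsum / cnt,
                 novelty_pct = novelty, hypervolume = hv, n = npoly)
}

#' Hypervolume indicator (maximization, up to 3 objectives)
#'
#' Exact dominated volume of a point set relative to a reference
#' point: direct product for one objective, a descending sweep for
#' two, and slicing along the third objective for three.
#'
#' @param points Matrix (rows = solutions, columns = objectives).
#' @param ref Reference point (dominated corner).
#' @return Non-negative volume.
#' @export
hypervolume_indicator <- function(points, ref) {
  points <- as.matrix(points)
  d <- ncol(points)
  stopifnot(d >= 1, d <= 3, length(ref) == d)
  keep <- apply(points, 1, function(p) all(p > ref))
  points <- points[keep, , drop = FALSE]
  if (nrow(points) == 0) return(0)
  if (d == 1) return(max(points[, 1]) - ref[1])
  if (d == 2) return(hv2(points, ref))
  # d == 3: sweep descending z; each slab contributes its 2-D hv
  z <- sort(unique(points[, 3]), decreasing = TRUE)
  z_next <- c(z[-1], ref[3])
  vol <- 0
  for (k in seq_along(z)) {
    sub <- points[points[, 3] >= z[k], 1:2, drop = FALSE]
    vol <- vol + hv2(sub, ref[1:2]) * (z[k] - z_next[k])
  }
  vol
}

hv2 <- function(points, ref) {
  ord <- order(points[, 1], decreasing = TRUE)
  pts <- points[ord, , drop = FALSE]
  area <- 0
  y_max <- ref[2]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2] > y_max) {
      area <- area + (pts[i, 1] - ref[1]) * (pts[i, 2] - y_max)
      y_max <- pts[i, 2]
    }
  }
  area
}
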
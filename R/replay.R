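# Prioritized experience replay: proportional prioritization with
# importance-sampling bias correction. Buffers at desk scale hold a
# few thousand transitions, so sampling uses exact probabilities
# rather than a sum tree.

#' Replay configuration
#'
#' @param alpha_per Priority exponent (default 0.6).
#' @param eps_per Priority floor added to |TD error| (default 1e-3).
#' @param beta_start,beta_end Importance-sampling exponent annealed
#'   linearly from 0.4 to 1.0 over `anneal_steps` updates.
#' @param anneal_steps Updates over which beta is annealed.
#' @param capacity Buffer capacity.
#' @return A `replay_config`.
#' @export
replay_config <- function(alpha_per = 0.6, eps_per = 1e-3, beta_start = 0.4,
                          beta_end = 1.0, anneal_steps = 1000L,
                          capacity = 4096L) {
  stopifnot(alpha_per >= 0, beta_start >= 0, beta_start <= 1,
            beta_end >= 0, beta_end <= 1, capacity >= 1)
  structure(list(alpha_per = alpha_per, eps_per = eps_per,
                 beta_start = beta_start, beta_end = beta_end,
                 anneal_steps = as.integer(anneal_steps),
                 capacity = as.integer(capacity)),
            class = "replay_config")
}

#' Replay buffer
#'
#' Ring buffer of transitions with TD-error priorities. New
#' transitions enter with the current maximum priority so each is
#' sampled at least once.
#'
#' @param config A [replay_config()].
#' @return A `replay_buffer` (environment-backed).
#' @export
replay_buffer <- function(config = replay_config()) {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$transitions <- vector("list", config$capacity)
  e$priorities <- numeric(config$capacity)
  e$size <- 0L
  e$pos <- 0L
  class(e) <- "replay_buffer"
  e
}

#' @rdname replay_buffer
#' @param buf A `replay_buffer`.
#' @param transition Arbitrary transition record (list).
#' @export
replay_add <- function(buf, transition) {
  buf$pos <- (buf$pos %% buf$config$capacity) + 1L
  buf$transitions[[buf$pos]] <- transition
  buf$priorities[buf$pos] <- if (buf$size > 0L) {
    max(buf$priorities[seq_len(buf$size)])
  } else 1
  buf$size <- min(buf$size + 1L, buf$config$capacity)
  invisible(buf)
}

#' Prioritized sampling probabilities
#'
#' `P(i) = p_i^alpha / sum_k p_k^alpha` over the stored priorities
#' `p_i = |delta_i| + eps`. With `alpha_per = 0` the distribution is
#' uniform regardless of priorities.
#'
#' @param priorities Positive priority vector (non-empty).
#' @param alpha_per Prioritization exponent.
#' @return Probability vector summing to 1.
#' @export
priority_probabilities <- function(priorities, alpha_per = 0.6) {
  if (length(priorities) == 0) stop("empty replay buffer", call. = FALSE)
  stopifnot(all(priorities > 0))
  p <- priorities^alpha_per
  p / sum(p)
}

#' Importance-sampling weights for prioritized replay
#'
#' `w_i = (1 / (N * P(i)))^beta`, normalized by the maximum weight so
#' updates are only ever scaled down.
#'
#' @param probs Sampling probabilities.
#' @param n Buffer size N.
#' @param beta_per Bias-correction exponent in \[0, 1\].
#' @return Weights in (0, 1\], max exactly 1.
#' @export
importance_weights <- function(probs, n, beta_per) {
  w <- (1 / (n * probs))^beta_per
  w / max(w)
}

# Current annealed beta after `step` updates.
replay_beta <- function(config, step) {
  frac <- min(1, step / config$anneal_steps)
  config$beta_start + (config$beta_end - config$beta_start) * frac
}

#' Sample a prioritized batch
#'
#' @param buf A `replay_buffer`.
#' @param batch_size Number of transitions (sampled with
#'   replacement).
#' @param step Update counter (drives beta annealing).
#' @return List with `idx`, `transitions`, `weights`.
#' @export
replay_sample <- function(buf, batch_size, step = 0L) {
  stopifnot(buf$size > 0)
  probs <- priority_probabilities(buf$priorities[seq_len(buf$size)],
                                  buf$config$alpha_per)
  idx <- sample.int(buf$size, batch_size, replace = TRUE, prob = probs)
  beta <- replay_beta(buf$config, step)
  w_all <- importance_weights(probs, buf$size, beta)
  list(idx = idx, transitions = buf$transitions[idx], weights = w_all[idx])
}

#' @rdname replay_buffer
#' @param idx Indices returned by [replay_sample()].
#' @param td_errors New TD errors for those transitions.
#' @export
replay_update_priorities <- function(buf, idx, td_errors) {
  buf$priorities[idx] <- abs(td_errors) + buf$config$eps_per
  invisible(buf)
}
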
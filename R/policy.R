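# Policy machinery: small dense networks with hand-coded backprop,
# the tanh-Gaussian latent policy with nearest-neighbor decoding over
# mask-allowed actions, state featurization, and a categorical
# softmax variant (value/advantage decomposition) behind a flag.

# --- minimal MLP with analytic gradients ------------------------------------

init_mlp <- function(d_in, d_hidden, d_out, seed = 1L) {
  with_seed(seed, {
    p <- list(
      W1 = rmat(d_hidden, d_in, scale = sqrt(1 / d_in)), b1 = rep(0, d_hidden),
      W2 = rmat(d_out, d_hidden, scale = sqrt(1 / d_hidden)), b2 = rep(0, d_out)
    )
  })
  p
}

# X: batch x d_in. Returns list(out = batch x d_out, cache).
mlp_forward <- function(p, X) {
  Z1 <- X %*% t(p$W1) + matrix(p$b1, nrow(X), length(p$b1), byrow = TRUE)
  H <- tanh(Z1)
  out <- H %*% t(p$W2) + matrix(p$b2, nrow(X), length(p$b2), byrow = TRUE)
  list(out = out, X = X, H = H)
}

# dOut: batch x d_out gradient of loss wrt output.
# Returns parameter grads and the gradient wrt the input.
mlp_backward <- function(p, cache, dOut) {
  dW2 <- t(dOut) %*% cache$H
  db2 <- colSums(dOut)
  dH <- dOut %*% p$W2
  dZ1 <- dH * (1 - cache$H^2)
  dW1 <- t(dZ1) %*% cache$X
  db1 <- colSums(dZ1)
  dX <- dZ1 %*% p$W1
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dX = dX)
}

# Global-norm gradient clipping across a list of gradient arrays.
clip_gradients <- function(grads, max_norm = 10) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * max_norm / total)
  }
  attr(grads, "norm") <- min(total, max_norm)
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Cosine annealing with warm restarts.
cosine_lr <- function(step, base_lr, period = 200L, t_mult = 2L,
                      min_frac = 0.1) {
  t_cur <- step
  t_i <- period
  while (t_cur >= t_i) {
    t_cur <- t_cur - t_i
    t_i <- t_i * t_mult
  }
  min_lr <- base_lr * min_frac
  min_lr + 0.5 * (base_lr - min_lr) * (1 + cos(pi * t_cur / t_i))
}

# --- state featurization ----------------------------------------------------

#' Feature layout for generation states of a given library
#'
#' Fixes the end-group alphabet and embedding width so every state of
#' a run maps to a vector of the same length.
#'
#' @param library A `monomer_library`.
#' @param d_embed Width of the polymer-embedding block (descriptor
#'   vector or fused embedding).
#' @param history_k Trailing actions encoded in the history summary.
#' @return A `feature_spec` with the total dimension `d_s`.
#' @export
feature_spec <- function(library, d_embed = 8L, history_k = 4L) {
  groups <- sort(unique(c("init", library$monomers$tail_group,
                          library$end_caps)))
  structure(list(groups = groups, d_embed = as.integer(d_embed),
                 history_k = as.integer(history_k),
                 d_s = 3L + length(groups) + 3L + history_k + d_embed),
            class = "feature_spec")
}

#' Numeric features of a generation state
#'
#' Concatenates chain size and step progress, curriculum stage, a
#' one-hot of the open end-group, the fixed-length reaction-history
#' summary and the polymer-embedding block (hand-crafted descriptors
#' by default; a fused dual-representation embedding when an
#' `embedder` is supplied).
#'
#' @param state A `generation_state`.
#' @param actions Action tibble for the history index space.
#' @param fspec A [feature_spec()].
#' @param embedder Optional list with `graph_encoder`, `seq_params`,
#'   `fusion` to use the full dual-representation embedding `r_p`.
#' @return Numeric vector of length `fspec$d_s`.
#' @export
state_features <- function(state, actions, fspec, embedder = NULL) {
  one_hot <- as.numeric(fspec$groups == state$open_group)
  emb <- if (is.null(embedder)) {
    seq <- parse_bigsmiles_ext(state$seq_text)
    if (nrow(state$graph$nodes) > 0) {
      compute_descriptors(state$graph, seq, d_f = fspec$d_embed)$vector
    } else rep(0, fspec$d_embed)
  } else {
    seq <- parse_bigsmiles_ext(state$seq_text)
    h_G <- encode_graph(state$graph, embedder$graph_encoder)
    z <- encode_sequence(seq, embedder$seq_params)
    d <- if (nrow(state$graph$nodes) > 0) {
      compute_descriptors(state$graph, seq, d_f = embedder$d_f %||% 8L)
    } else rep(0, embedder$d_f %||% 8L)
    fuse(h_G, z, d, embedder$fusion)
  }
  c(nrow(state$graph$nodes) / 32, state$step / state$max_steps,
    state$stage_id / 3,
    one_hot,
    history_summary(state, actions, k = fspec$history_k),
    emb)
}

# --- latent tanh-Gaussian policy --------------------------------------------

#' Latent-policy parameters
#'
#' Two networks map the state features to the mean and log-scale of a
#' continuous latent action squashed by tanh; a deterministic
#' embedding table places every discrete construction action in the
#' same latent cube for nearest-neighbor decoding.
#'
#' @param d_s State-feature dimension.
#' @param d_a Latent action dimension (default 4).
#' @param d_hidden Hidden units (default 32).
#' @param seed Seed for initialization.
#' @return A `policy_params` list (`mu_net`, `log_sigma_net`,
#'   embedding environment, dims).
#' @export
policy_params <- function(d_s, d_a = 4L, d_hidden = 32L, seed = 1L) {
  emb <- new.env(parent = emptyenv())
  structure(
    list(
      mu_net = init_mlp(d_s, d_hidden, d_a, seed = seed),
      log_sigma_net = init_mlp(d_s, d_hidden, d_a, seed = seed + 1L),
      embeddings = emb, d_s = d_s, d_a = as.integer(d_a), seed = seed
    ),
    class = "policy_params"
  )
}

# Deterministic per-action embedding in (-1, 1)^d_a, derived from the
# action id so it is stable across runs and processes.
action_embedding <- function(policy, action_id) {
  hit <- policy$embeddings[[action_id]]
  if (!is.null(hit)) return(hit)
  h <- hash_ints(c(policy$seed, utf8ToInt(action_id)))
  v <- with_seed(h %% 2147483646 + 1, stats::runif(policy$d_a, -1, 1))
  assign(action_id, v, envir = policy$embeddings)
  v
}

# log-density of the tanh-Gaussian at squashed value u with pre-tanh x.
tanh_gaussian_logp <- function(x, mu, sigma, u) {
  sum(stats::dnorm(x, mu, sigma, log = TRUE) - log(1 - u^2 + 1e-6))
}

#' Sample a construction action from the masked latent policy
#'
#' Draws `u = tanh(mu(s) + sigma(s) * xi)` with standard-normal `xi`
#' and decodes it to the mask-allowed action whose embedding is
#' nearest in the latent cube (ties break to the lowest action
#' index). Masked-out actions can never be returned. With
#' `deterministic = TRUE` (or a zero-scale policy) the latent is
#' `tanh(mu(s))`.
#'
#' @param state A `generation_state`.
#' @param policy A [policy_params()].
#' @param actions Action tibble from [enumerate_actions()].
#' @param mask Logical mask from [validity_mask()] (>= 1 TRUE).
#' @param fspec A [feature_spec()].
#' @param embedder Optional dual-representation embedder (see
#'   [state_features()]).
#' @param deterministic Suppress exploration noise.
#' @return List: `action` (tibble row), `index`, `latent`, `pre_tanh`,
#'   `logp`, `features`.
#' @export
sample_action <- function(state, policy, actions, mask, fspec,
                          embedder = NULL, deterministic = FALSE) {
  if (!any(mask)) {
    stop("all actions masked: environment contract violated", call. = FALSE)
  }
  s <- state_features(state, actions, fspec, embedder)
  mu <- drop(mlp_forward(policy$mu_net, matrix(s, 1))$out)
  log_sig <- drop(mlp_forward(policy$log_sigma_net, matrix(s, 1))$out)
  sigma <- exp(pmin(pmax(log_sig, -8), 1))
  xi <- if (deterministic) rep(0, policy$d_a) else stats::rnorm(policy$d_a)
  x <- mu + sigma * xi
  u <- tanh(x)
  allowed <- which(mask)
  embs <- vapply(actions$action_id[allowed],
                 function(id) action_embedding(policy, id),
                 numeric(policy$d_a))
  d2 <- colSums((embs - u)^2)
  pick <- allowed[which.min(d2)]  # which.min takes the first (lowest index) tie
  list(action = actions[pick, ], index = pick, latent = u, pre_tanh = x,
       logp = tanh_gaussian_logp(x, mu, sigma, u), features = s)
}

# --- categorical variant ----------------------------------------------------

#' Categorical softmax policy over the action catalogue
#'
#' Comparison variant: per-action advantage logits plus a running
#' value baseline (a value/advantage decomposition), updated by a
#' policy-gradient rule with entropy regularization. Action logits
#' live in a table keyed by action id, so the policy is shared across
#' states of a stage.
#'
#' @param entropy_coef Entropy bonus coefficient.
#' @param lr Learning rate of the logit updates.
#' @return A `categorical_policy` (environment-backed).
#' @export
categorical_policy <- function(entropy_coef = 0.02, lr = 0.25) {
  e <- new.env(parent = emptyenv())
  e$logits <- new.env(parent = emptyenv())
  e$baseline <- 0
  e$baseline_n <- 0L
  e$entropy_coef <- entropy_coef
  e$lr <- lr
  class(e) <- "categorical_policy"
  e
}

cat_logits <- function(policy, action_ids) {
  vapply(action_ids, function(id) policy$logits[[id]] %||% 0, numeric(1))
}

# Sample an allowed action; returns index + probabilities.
categorical_sample <- function(policy, actions, mask, deterministic = FALSE) {
  allowed <- which(mask)
  lg <- cat_logits(policy, actions$action_id[allowed])
  p <- exp(lg - max(lg))
  p <- p / sum(p)
  pick <- if (deterministic) allowed[which.max(p)]
          else allowed[sample.int(length(allowed), 1, prob = p)]
  list(action = actions[pick, ], index = pick, probs = p, allowed = allowed)
}

# REINFORCE-with-baseline update on one episode's step records.
categorical_update <- function(policy, steps, episode_return) {
  policy$baseline_n <- policy$baseline_n + 1L
  policy$baseline <- policy$baseline +
    (episode_return - policy$baseline) / min(policy$baseline_n, 50L)
  adv <- episode_return - policy$baseline
  for (st in steps) {
    ids <- st$action_ids[st$allowed]
    p <- st$probs
    chosen <- match(st$chosen_id, ids)
    lg <- cat_logits(policy, ids)
    # d logpi(a)/d logit_k = 1{k=a} - p_k; entropy gradient pulls toward
    # uniform: dH/d logit_k = -p_k (log p_k - sum_j p_j log p_j)
    grad <- -p * adv
    grad[chosen] <- grad[chosen] + adv
    logp <- log(p + 1e-12)
    grad <- grad - policy$entropy_coef * p * (logp - sum(p * logp))
    lg <- lg + policy$lr * grad
    for (k in seq_along(ids)) assign(ids[k], lg[k], envir = policy$logits)
  }
  invisible(policy)
}
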
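# Soft actor-critic on the continuous latent action space: twin
# critics with entropy-regularized targets, physics penalty folded
# into the optimized return, clipped gradients, soft target updates.

#' SAC configuration
#'
#' @param tau Target-network soft-update rate (default 0.005).
#' @param clip_norm Global gradient-clip norm (default 10.0).
#' @param lr Base learning rate (cosine-annealed with warm restarts).
#' @param lr_period Steps per cosine restart cycle.
#' @param entropy_coef Fixed entropy coefficient.
#' @param gamma Discount factor.
#' @param batch_size Transitions per update.
#' @param critic_batch_norm Standardize critic inputs with running
#'   statistics (applied to critics only, never the actor).
#' @return A `sac_config`.
#' @export
sac_config <- function(tau = 0.005, clip_norm = 10.0, lr = 3e-3,
                       lr_period = 200L, entropy_coef = 0.05, gamma = 0.99,
                       batch_size = 32L, critic_batch_norm = TRUE) {
  stopifnot(tau > 0, tau <= 1, clip_norm > 0)
  structure(list(tau = tau, clip_norm = clip_norm, lr = lr,
                 lr_period = as.integer(lr_period),
                 entropy_coef = entropy_coef, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 critic_batch_norm = critic_batch_norm),
            class = "sac_config")
}

#' Twin critics (with target copies) for the latent SAC
#'
#' @param d_s State-feature dimension.
#' @param d_a Latent action dimension.
#' @param d_hidden Hidden units.
#' @param seed Seed for initialization.
#' @return A `critic_set`: two online critics, their target copies,
#'   Adam states and running input statistics for the critic-side
#'   batch normalization.
#' @export
critic_set <- function(d_s, d_a = 4L, d_hidden = 32L, seed = 2L) {
  q1 <- init_mlp(d_s + d_a, d_hidden, 1L, seed = seed)
  q2 <- init_mlp(d_s + d_a, d_hidden, 1L, seed = seed + 1L)
  structure(
    list(q1 = q1, q2 = q2, t1 = q1, t2 = q2,
         opt1 = adam_init(q1), opt2 = adam_init(q2),
         bn_mean = rep(0, d_s + d_a), bn_var = rep(1, d_s + d_a),
         bn_n = 0),
    class = "critic_set"
  )
}

# Critic input normalization: running statistics, treated as constants
# within a gradient step.
bn_normalize <- function(critics, X, update = FALSE) {
  if (update) {
    m <- colMeans(X)
    v <- apply(X, 2, stats::var)
    v[!is.finite(v)] <- 1
    w <- 0.05
    critics$bn_mean <- (1 - w) * critics$bn_mean + w * m
    critics$bn_var <- (1 - w) * critics$bn_var + w * pmax(v, 1e-4)
    critics$bn_n <- critics$bn_n + 1
  }
  Xn <- sweep(sweep(X, 2, critics$bn_mean), 2, sqrt(critics$bn_var + 1e-5), "/")
  list(X = Xn, critics = critics, scale = sqrt(critics$bn_var + 1e-5))
}

soft_update <- function(target, online, tau) {
  for (nm in names(online)) target[[nm]] <- tau * online[[nm]] + (1 - tau) * target[[nm]]
  target
}

# Forward pass of policy nets on a feature batch; returns mu, sigma.
policy_heads <- function(policy, S) {
  mu <- mlp_forward(policy$mu_net, S)
  ls <- mlp_forward(policy$log_sigma_net, S)
  list(mu = mu$out, log_sigma = pmin(pmax(ls$out, -8), 1),
       mu_cache = mu, ls_cache = ls)
}

#' One SAC update on a prioritized batch
#'
#' Twin-critic targets with the entropy term
#' (`y = r + gamma (1-done)(min Q' - alpha log pi)`), where the
#' per-transition reward already includes the augmented-Lagrangian
#' physics penalty so constraint pressure propagates through the
#' value function. Critic losses are importance-weighted; all
#' gradients are clipped to global norm `clip_norm`; target networks
#' move by the soft rate `tau`. Returns refreshed |TD errors| for the
#' replay priorities. Updates with non-finite losses are skipped with
#' a warning.
#'
#' @param batch List from [replay_sample()]: transitions with fields
#'   `s` (features), `u` (latent), `reward` (penalty-shaped), `s2`
#'   (next features), `done`; plus `weights`.
#' @param policy A [policy_params()].
#' @param critics A [critic_set()].
#' @param cfg A [sac_config()].
#' @param opt_policy Adam states for the two policy nets (created on
#'   first call if NULL).
#' @param step Update counter (drives the cosine learning-rate
#'   schedule).
#' @return List with updated `policy`, `critics`, `opt_policy`,
#'   `td_errors`, `critic_loss`, `policy_loss`.
#' @export
sac_update <- function(batch, policy, critics, cfg = sac_config(),
                       opt_policy = NULL, step = 1L) {
  tr <- batch$transitions
  n <- length(tr)
  stopifnot(n > 0)
  S <- do.call(rbind, lapply(tr, `[[`, "s"))
  U <- do.call(rbind, lapply(tr, `[[`, "u"))
  S2 <- do.call(rbind, lapply(tr, `[[`, "s2"))
  r <- vapply(tr, `[[`, numeric(1), "reward")
  done <- vapply(tr, `[[`, numeric(1), "done")
  w <- batch$weights
  lr <- cosine_lr(step, cfg$lr, period = cfg$lr_period)

  # --- target computation ---
  ph2 <- policy_heads(policy, S2)
  sig2 <- exp(ph2$log_sigma)
  xi2 <- matrix(stats::rnorm(n * ncol(U)), n)
  X2 <- ph2$mu + sig2 * xi2
  U2 <- tanh(X2)
  logp2 <- rowSums(stats::dnorm(X2, ph2$mu, sig2, log = TRUE) -
                     log(1 - U2^2 + 1e-6))
  in2 <- cbind(S2, U2)
  bn2 <- bn_normalize(critics, in2, update = FALSE)
  qt1 <- drop(mlp_forward(critics$t1, bn2$X)$out)
  qt2 <- drop(mlp_forward(critics$t2, bn2$X)$out)
  y <- r + cfg$gamma * (1 - done) * (pmin(qt1, qt2) - cfg$entropy_coef * logp2)

  # --- critic updates ---
  inb <- cbind(S, U)
  bn <- bn_normalize(critics, inb, update = cfg$critic_batch_norm)
  critics <- bn$critics
  td <- NULL
  critic_loss <- NA_real_
  for (ci in 1:2) {
    net <- critics[[paste0("q", ci)]]
    fw <- mlp_forward(net, bn$X)
    q <- drop(fw$out)
    if (ci == 1) td <- q - y
    loss <- mean(w * (q - y)^2)
    if (!is.finite(loss)) {
      warning("non-finite critic loss; update skipped")
      return(list(policy = policy, critics = critics, opt_policy = opt_policy,
                  td_errors = abs(if (is.null(td)) rep(1, n) else td),
                  critic_loss = NA_real_, policy_loss = NA_real_))
    }
    critic_loss <- if (ci == 1) loss else (critic_loss + loss) / 2
    dOut <- matrix(2 * w * (q - y) / n, ncol = 1)
    bk <- mlp_backward(net, fw, dOut)
    g <- clip_gradients(bk$grads, cfg$clip_norm)
    st <- adam_step(net, g, critics[[paste0("opt", ci)]], lr = lr)
    critics[[paste0("q", ci)]] <- st$params
    critics[[paste0("opt", ci)]] <- st$state
  }

  # --- policy update (reparameterized) ---
  ph <- policy_heads(policy, S)
  sig <- exp(ph$log_sigma)
  xi <- matrix(stats::rnorm(n * ncol(U)), n)
  X <- ph$mu + sig * xi
  Un <- tanh(X)
  innew <- cbind(S, Un)
  bnp <- bn_normalize(critics, innew, update = FALSE)
  fwq <- mlp_forward(critics$q1, bnp$X)
  qpi <- drop(fwq$out)
  logp <- rowSums(stats::dnorm(X, ph$mu, sig, log = TRUE) -
                    log(1 - Un^2 + 1e-6))
  policy_loss <- mean(cfg$entropy_coef * logp - qpi)
  if (is.finite(policy_loss)) {
    # dQ/d(input) at the normalized input, rescaled to raw units
    dQ <- mlp_backward(critics$q1, fwq, matrix(-1 / n, n, 1))$dX
    dU_q <- sweep(dQ[, (ncol(S) + 1):ncol(innew), drop = FALSE], 2,
                  bnp$scale[(ncol(S) + 1):ncol(innew)], "/")
    one_m_u2 <- 1 - Un^2
    # entropy part: d logp/d mu = 2u ; d logp/d sigma = -1/sigma + 2u xi
    dmu <- (cfg$entropy_coef / n) * 2 * Un + dU_q * one_m_u2
    dsig <- (cfg$entropy_coef / n) * (-1 / sig + 2 * Un * xi) +
      dU_q * one_m_u2 * xi
    dlog_sig <- dsig * sig
    dlog_sig[ph$log_sigma <= -8 | ph$log_sigma >= 1] <- 0
    bk_mu <- mlp_backward(policy$mu_net, ph$mu_cache, dmu)
    bk_ls <- mlp_backward(policy$log_sigma_net, ph$ls_cache, dlog_sig)
    if (is.null(opt_policy)) {
      opt_policy <- list(mu = adam_init(policy$mu_net),
                         ls = adam_init(policy$log_sigma_net))
    }
    gmu <- clip_gradients(bk_mu$grads, cfg$clip_norm)
    gls <- clip_gradients(bk_ls$grads, cfg$clip_norm)
    st <- adam_step(policy$mu_net, gmu, opt_policy$mu, lr = lr)
    policy$mu_net <- st$params; opt_policy$mu <- st$state
    st <- adam_step(policy$log_sigma_net, gls, opt_policy$ls, lr = lr)
    policy$log_sigma_net <- st$params; opt_policy$ls <- st$state
  } else {
    warning("non-finite policy loss; policy step skipped")
  }

  critics$t1 <- soft_update(critics$t1, critics$q1, cfg$tau)
  critics$t2 <- soft_update(critics$t2, critics$q2, cfg$tau)

  list(policy = policy, critics = critics, opt_policy = opt_policy,
       td_errors = abs(td), critic_loss = critic_loss,
       policy_loss = policy_loss)
}
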
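# Dual representation learning: GIN message passing with bond-gated
# messages and global multi-head attention on the graph side, a
# transformer-style sequence encoder with masked-language-model
# pretraining on the sequence side, and fusion of both with the
# hand-crafted descriptors into the polymer embedding r_p.
#
# Parameters are plain lists of matrices (out x in); all forward passes
# are deterministic given parameters and inputs.

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Layer normalization
#'
#' Normalizes each row to zero mean and unit variance (population
#' variance, stabilized by `eps`), then applies the affine `gamma`,
#' `beta`.
#'
#' @param x Numeric matrix (rows = samples) or vector.
#' @param gamma,beta Affine parameters (default identity).
#' @param eps Variance stabilizer.
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  out <- sweep(sweep(x, 1, mu), 1, sqrt(v + eps), "/")
  out <- sweep(sweep(out, 2, rep_len(gamma, ncol(x)), "*"), 2,
               rep_len(beta, ncol(x)), "+")
  if (vec) out[1, ] else out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rmat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

# --- node / edge featurization --------------------------------------------

ELEMENT_CLASSES <- c("C", "N", "O", "S", "P", "halogen", "B", "other")

#' Node feature matrix of a polymer graph
#'
#' One-hot element class, aromaticity, scaled degree, formal charge and
#' cross-link-site flag, padded or truncated to dimension `d`.
#'
#' @param graph A `poly_graph`.
#' @param d Feature dimension (default 12, the natural width).
#' @return Numeric matrix, one row per node.
#' @export
node_features <- function(graph, d = 12L) {
  n <- nrow(graph$nodes)
  deg <- lengths(adjacency_list(graph))
  f <- matrix(0, n, 12)
  for (v in seq_len(n)) {
    el <- graph$nodes$element[v]
    cls <- if (el %in% c("F", "Cl", "Br", "I")) "halogen"
           else if (el %in% ELEMENT_CLASSES) el else "other"
    f[v, match(cls, ELEMENT_CLASSES)] <- 1
    f[v, 9] <- as.numeric(graph$nodes$aromatic[v])
    f[v, 10] <- deg[v] / 4
    f[v, 11] <- graph$nodes$formal_charge[v]
    f[v, 12] <- as.numeric(graph$nodes$crosslink_site[v])
  }
  out <- matrix(0, n, d)
  keep <- seq_len(min(d, 12))
  out[, keep] <- f[, keep, drop = FALSE]
  out
}

#' Edge feature matrix of a polymer graph
#'
#' One-hot bond order (single/double/triple/aromatic), conjugation flag
#' and the three polymer roles (backbone, side-chain, cross-link),
#' padded or truncated to dimension `k`.
#'
#' @param graph A `poly_graph`.
#' @param k Feature dimension (default 8, the natural width).
#' @return Numeric matrix, one row per edge (same order as
#'   `graph$edges`).
#' @export
edge_features <- function(graph, k = 8L) {
  m <- nrow(graph$edges)
  f <- matrix(0, m, 8)
  if (m > 0) {
    for (e in seq_len(m)) {
      f[e, match(graph$edges$order[e], names(BOND_ORDER_VALUE))] <- 1
      f[e, 5] <- as.numeric(graph$edges$conjugated[e])
      f[e, 6] <- as.numeric(graph$edges$backbone[e])
      f[e, 7] <- as.numeric(graph$edges$sidechain[e])
      f[e, 8] <- as.numeric(graph$edges$crosslink[e])
    }
  }
  out <- matrix(0, m, k)
  keep <- seq_len(min(k, 8))
  out[, keep] <- f[, keep, drop = FALSE]
  out
}

# --- GIN layer -------------------------------------------------------------

#' Parameters of one gated GIN layer
#'
#' @param d_h Hidden dimension.
#' @param d_e Edge-feature dimension.
#' @param seed Seed for the random initialization.
#' @param eps Initial value of the learnable epsilon.
#' @return A `gin_layer_params` list: `eps`, two-layer MLP weights
#'   (`W1`, `b1`, `W2`, `b2`) and the edge-gate parameters (`W_e`,
#'   `b_e`, output dimension `d_h`).
#' @export
gin_layer_params <- function(d_h, d_e = 8L, seed = 1L, eps = 0) {
  with_seed(seed, {
    list_params <- list(
      eps = eps,
      W1 = rmat(d_h, d_h), b1 = rep(0, d_h),
      W2 = rmat(d_h, d_h), b2 = rep(0, d_h),
      W_e = rmat(d_h, d_e), b_e = rep(0, d_h)
    )
  })
  structure(list_params, class = "gin_layer_params")
}

#' One round of gated GIN message passing
#'
#' Implements
#' `h_i' = MLP((1 + eps) h_i + sum_j phi(h_j, e_ij))` with the gated
#' edge function `phi(h_j, e_ij) = h_j * sigmoid(W_e e_ij + b_e)`
#' (element-wise product). Nodes without neighbors receive only their
#' own scaled state. The MLP is linear - LeakyReLU - linear.
#'
#' @param graph A `poly_graph`.
#' @param node_states Matrix `n x d_h` of node states `h^(l)`.
#' @param params A [gin_layer_params()].
#' @return Matrix `n x d_h` of updated node states.
#' @export
gin_message_pass <- function(graph, node_states, params) {
  d_h <- ncol(node_states)
  if (nrow(params$W_e) != d_h || ncol(params$W1) != d_h) {
    stop("node-state dimension does not match layer parameters", call. = FALSE)
  }
  ef <- edge_features(graph, k = ncol(params$W_e))
  n <- nrow(node_states)
  agg <- (1 + params$eps) * node_states
  if (nrow(graph$edges) > 0) {
    gates <- sigmoid(ef %*% t(params$W_e) +
                       matrix(params$b_e, nrow(ef), d_h, byrow = TRUE))
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges$i[k]; b <- graph$edges$j[k]
      agg[a, ] <- agg[a, ] + node_states[b, ] * gates[k, ]
      agg[b, ] <- agg[b, ] + node_states[a, ] * gates[k, ]
    }
  }
  h <- leaky_relu(agg %*% t(params$W1) +
                    matrix(params$b1, n, d_h, byrow = TRUE))
  h %*% t(params$W2) + matrix(params$b2, n, d_h, byrow = TRUE)
}

# --- global attention -------------------------------------------------------

#' Parameters for global multi-head self-attention over nodes
#'
#' Standard per-head query/key/value projections with an output
#' projection per head; the layer is residual, so zero output
#' projections give the identity map.
#'
#' @param d_h Hidden dimension.
#' @param n_heads Number of heads `H` (must divide `d_h`).
#' @param seed Seed for initialization.
#' @return An `attention_params` list of per-head `W_Q`, `W_K`, `W_V`,
#'   `W_O`.
#' @export
attention_params <- function(d_h, n_heads = 2L, seed = 1L) {
  stopifnot(d_h %% n_heads == 0)
  d_k <- d_h %/% n_heads
  heads <- with_seed(seed, {
    lapply(seq_len(n_heads), function(h) {
      list(W_Q = rmat(d_k, d_h), W_K = rmat(d_k, d_h),
           W_V = rmat(d_k, d_h), W_O = rmat(d_h, d_k))
    })
  })
  structure(list(heads = heads, d_k = d_k), class = "attention_params")
}

#' Global multi-head self-attention over node states
#'
#' Residual attention:
#' `h_i' = h_i + sum_h W_O^h sum_j alpha_ij^h W_V^h h_j`, with
#' `alpha^h` the row-softmax of scaled dot products of per-head
#' queries and keys.
#'
#' @param node_states Matrix `n x d_h` (n >= 1).
#' @param params An [attention_params()].
#' @param return_weights If TRUE, attach the per-head attention
#'   matrices as attribute `"alpha"`.
#' @return Matrix `n x d_h`.
#' @export
global_attention <- function(node_states, params, return_weights = FALSE) {
  n <- nrow(node_states)
  stopifnot(n >= 1)
  out <- node_states
  alphas <- list()
  for (h in seq_along(params$heads)) {
    p <- params$heads[[h]]
    q <- node_states %*% t(p$W_Q)
    k <- node_states %*% t(p$W_K)
    v <- node_states %*% t(p$W_V)
    alpha <- softmax_rows(q %*% t(k) / sqrt(params$d_k))
    out <- out + (alpha %*% v) %*% t(p$W_O)
    if (return_weights) alphas[[h]] <- alpha
  }
  if (return_weights) attr(out, "alpha") <- alphas
  out
}

# --- full graph encoder -----------------------------------------------------

#' Construct a graph encoder (alternating GIN / attention layers)
#'
#' @param d_h Hidden dimension (desk-scale default 32; the full-scale
#'   profile uses 256 with 6 layers).
#' @param n_layers Number of GIN layers (each followed by a global
#'   attention layer).
#' @param n_heads Attention heads per attention layer.
#' @param d_in Node-feature input dimension.
#' @param d_e Edge-feature dimension.
#' @param seed Seed for initialization.
#' @return A `graph_encoder` list with an input projection and the
#'   layer stack.
#' @export
graph_encoder <- function(d_h = 32L, n_layers = 2L, n_heads = 2L,
                          d_in = 12L, d_e = 8L, seed = 1L) {
  proj <- with_seed(seed, rmat(d_h, d_in))
  layers <- list()
  for (l in seq_len(n_layers)) {
    layers[[length(layers) + 1L]] <- gin_layer_params(d_h, d_e, seed = seed + 13L * l)
    layers[[length(layers) + 1L]] <- attention_params(d_h, n_heads, seed = seed + 31L * l)
  }
  structure(list(proj = proj, layers = layers, d_h = d_h, d_in = d_in),
            class = "graph_encoder")
}

#' Encode a polymer graph into a fixed-length vector
#'
#' Projects node features, applies the alternating GIN / attention
#' stack, and sum-pools node states into the graph-level vector `h_G`.
#' Sum pooling keeps the encoder permutation-invariant and preserves
#' the injectivity argument behind GIN-style aggregation.
#'
#' @param graph A `poly_graph`.
#' @param encoder A [graph_encoder()].
#' @return Numeric vector of length `d_h` (zeros for an empty graph).
#' @export
encode_graph <- function(graph, encoder) {
  n <- nrow(graph$nodes)
  if (n == 0) return(rep(0, encoder$d_h))
  h <- node_features(graph, d = encoder$d_in) %*% t(encoder$proj)
  for (layer in encoder$layers) {
    h <- if (inherits(layer, "gin_layer_params")) {
      gin_message_pass(graph, h, layer)
    } else {
      global_attention(h, layer)
    }
  }
  colSums(h)
}

# --- sequence encoder -------------------------------------------------------

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[MASK]")

#' Token vocabulary for the sequence encoder
#'
#' Fixed base vocabulary: the mask/CLS/pad specials, the four polymer
#' tokens, organic-subset atoms, bonds, digits and parentheses, plus
#' any extra literals supplied (e.g. bracket atoms observed in a
#' corpus).
#'
#' @param extra Additional token literals to include.
#' @return Character vector of token literals (the id of a token is
#'   its position).
#' @export
build_vocabulary <- function(extra = character()) {
  base <- c(SPECIAL_TOKENS, unname(POLYMER_TOKENS),
            "B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
            "b", "c", "n", "o", "p", "s",
            "-", "=", "#", "$", ":", "/", "\\", ".",
            as.character(0:9), "(", ")")
  unique(c(base, extra))
}

#' Sequence-encoder parameters
#'
#' Transformer-style encoder over the polymer token vocabulary:
#' token embeddings (tied with the output layer), sinusoidal positions
#' and `n_blocks` pre-norm blocks of multi-head self-attention plus a
#' feed-forward layer.
#'
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param d_model Embedding dimension (desk-scale default 32).
#' @param n_blocks Transformer blocks.
#' @param n_heads Attention heads.
#' @param seed Seed for initialization.
#' @return A `sequence_encoder_params` list.
#' @export
sequence_encoder_params <- function(vocab = build_vocabulary(), d_model = 32L,
                                    n_blocks = 2L, n_heads = 2L, seed = 1L) {
  stopifnot(all(c("[MASK]", "[CLS]") %in% vocab))
  emb <- with_seed(seed, rmat(length(vocab), d_model, scale = 0.1))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    list(
      attn = attention_params(d_model, n_heads, seed = seed + 7L * b),
      W_ff1 = with_seed(seed + 100L + b, rmat(2L * d_model, d_model)),
      b_ff1 = rep(0, 2L * d_model),
      W_ff2 = with_seed(seed + 200L + b, rmat(d_model, 2L * d_model)),
      b_ff2 = rep(0, d_model)
    )
  })
  structure(list(vocab = vocab, emb = emb, blocks = blocks, d_model = d_model),
            class = "sequence_encoder_params")
}

tokens_to_ids <- function(seq, vocab) {
  ids <- match(seq$tokens$text, vocab)
  if (anyNA(ids)) {
    bad <- unique(seq$tokens$text[is.na(ids)])
    stop("out-of-vocabulary token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ids
}

sinusoidal_positions <- function(n, d) {
  pos <- matrix(0, n, d)
  for (i in seq_len(d)) {
    f <- 1 / (10000^((i - 1) %/% 2 * 2 / d))
    pos[, i] <- if (i %% 2 == 1) sin(seq_len(n) * f) else cos(seq_len(n) * f)
  }
  pos
}

sequence_forward <- function(ids, params) {
  x <- params$emb[ids, , drop = FALSE] + sinusoidal_positions(length(ids), params$d_model)
  for (blk in params$blocks) {
    x <- global_attention(layer_norm(x), blk$attn)
    ff_in <- layer_norm(x)
    ff <- leaky_relu(ff_in %*% t(blk$W_ff1) +
                       matrix(blk$b_ff1, nrow(x), byrow = TRUE, ncol = length(blk$b_ff1)))
    x <- x + ff %*% t(blk$W_ff2) +
      matrix(blk$b_ff2, nrow(x), ncol = params$d_model, byrow = TRUE)
  }
  x
}

#' Masked-language-model loss on a polymer sequence
#'
#' Cross-entropy of the true tokens at the masked positions given the
#' rest of the sequence: `L = -sum_{i in M} log p(m_i | m_-i)`, with
#' output logits tied to the token embeddings. Non-negative; zero only
#' when every masked token receives probability 1.
#'
#' @param seq A `poly_sequence`.
#' @param masked_positions Indices into the token list (1-based,
#'   non-empty, within bounds).
#' @param params A [sequence_encoder_params()].
#' @return Scalar loss.
#' @export
mlm_loss <- function(seq, masked_positions, params) {
  if (length(masked_positions) == 0) {
    stop("`masked_positions` must be non-empty", call. = FALSE)
  }
  n_tok <- nrow(seq$tokens)
  if (any(masked_positions < 1 | masked_positions > n_tok)) {
    stop("masked positions out of bounds", call. = FALSE)
  }
  true_ids <- tokens_to_ids(seq, params$vocab)
  ids <- c(match("[CLS]", params$vocab), true_ids)
  mask_id <- match("[MASK]", params$vocab)
  ids[masked_positions + 1L] <- mask_id
  h <- sequence_forward(ids, params)
  logits <- h %*% t(params$emb)
  loss <- 0
  for (pos in masked_positions) {
    row <- logits[pos + 1L, ]
    row <- row - max(row)
    logp <- row - log(sum(exp(row)))
    loss <- loss - logp[true_ids[pos]]
  }
  loss
}

#' Encode a polymer sequence into the CLS embedding
#'
#' Prepends the `[CLS]` token, runs the transformer blocks, and
#' returns the CLS-position output `z`. Deterministic given
#' parameters.
#'
#' @param seq A `poly_sequence`.
#' @param params A [sequence_encoder_params()].
#' @return Numeric vector of length `d_model`.
#' @export
encode_sequence <- function(seq, params) {
  ids <- c(match("[CLS]", params$vocab), tokens_to_ids(seq, params$vocab))
  sequence_forward(ids, params)[1, ]
}

# --- fusion ------------------------------------------------------------------

#' Fusion parameters for the polymer embedding
#'
#' @param d_in Input dimension `|h_G| + |z| + d_f`.
#' @param d_out Output embedding dimension.
#' @param dropout Dropout rate (only active when `training = TRUE` in
#'   [fuse()]).
#' @param seed Seed for initialization.
#' @return A `fusion_params` list (two-layer MLP + layer-norm affine).
#' @export
fusion_params <- function(d_in, d_out = 32L, dropout = 0.1, seed = 1L) {
  with_seed(seed, {
    p <- list(
      W1 = rmat(d_out, d_in), b1 = rep(0, d_out),
      W2 = rmat(d_out, d_out), b2 = rep(0, d_out),
      gamma = rep(1, d_out), beta = rep(0, d_out),
      dropout = dropout, d_in = d_in
    )
  })
  structure(p, class = "fusion_params")
}

#' Fuse graph, sequence and descriptor views into the polymer embedding
#'
#' `r_p = LayerNorm(MLP([h_G; z; d]))` with dropout applied after
#' normalization when `training = TRUE` (inactive in eval mode, the
#' default, so eval calls are deterministic).
#'
#' @param h_G Graph embedding vector.
#' @param z Sequence (CLS) embedding vector.
#' @param d A `polymer_descriptors` (its `vector` slot is used) or a
#'   bare numeric vector.
#' @param params A [fusion_params()] whose `d_in` matches
#'   `length(h_G) + length(z) + length(d)`.
#' @param training Enable dropout.
#' @return The polymer embedding `r_p` (length `d_out`).
#' @export
fuse <- function(h_G, z, d, params, training = FALSE) {
  dv <- if (inherits(d, "polymer_descriptors")) d$vector else d
  x <- c(h_G, z, dv)
  if (length(x) != params$d_in) {
    stop(sprintf("fusion input has length %d, expected %d", length(x), params$d_in),
         call. = FALSE)
  }
  h <- leaky_relu(drop(params$W1 %*% x) + params$b1)
  h <- drop(params$W2 %*% h) + params$b2
  out <- layer_norm(h, gamma = params$gamma, beta = params$beta)
  if (training && params$dropout > 0) {
    keep <- stats::runif(length(out)) >= params$dropout
    out <- out * keep / (1 - params$dropout)
  }
  out
}
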
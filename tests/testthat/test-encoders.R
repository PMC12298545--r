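test_that("gated message passing matches the update rule on small graphs", {
  d_h <- 4L
  p <- gin_layer_params(d_h, d_e = 8L, seed = 3, eps = 0.5)

  # isolated node: no neighbor sum, output = MLP((1 + eps) h)
  g1 <- graph_of("C")
  h <- matrix(stats::runif(d_h, 0.1, 1), 1)
  out <- gin_message_pass(g1, h, p)
  agg <- (1 + p$eps) * h
  manual <- pmax(agg %*% t(p$W1), 0.01 * (agg %*% t(p$W1))) %*% t(p$W2)
  expect_equal(out, manual, tolerance = 1e-12)

  # gate driven to zero: neighbors contribute nothing
  p0 <- p
  p0$W_e <- p0$W_e * 0
  p0$b_e <- rep(-100, d_h)
  g3 <- graph_of("CCC")
  h3 <- matrix(stats::runif(3 * d_h, 0.1, 1), 3)
  out_gated <- gin_message_pass(g3, h3, p0)
  out_isolated <- t(apply(h3, 1, function(row) {
    agg <- (1 + p0$eps) * row
    z <- p0$W1 %*% agg
    drop(p0$W2 %*% pmax(z, 0.01 * z))
  }))
  expect_equal(out_gated, out_isolated, tolerance = 1e-10)
})

test_that("3-node path equals a dense adjacency-product oracle", {
  d_h <- 3L
  g <- graph_of("CCC")
  # identity MLP (positive inputs keep LeakyReLU linear), hand-set gate
  p <- gin_layer_params(d_h, seed = 1, eps = 0.25)
  p$W1 <- diag(d_h); p$W2 <- diag(d_h)
  p$b1 <- rep(0, d_h); p$b2 <- rep(0, d_h)
  p$W_e <- matrix(0, d_h, 8); p$b_e <- rep(0, d_h)  # gate = sigmoid(0) = 0.5
  H <- matrix(stats::runif(3 * d_h, 0.2, 1), 3)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)  # path adjacency
  oracle <- (1 + p$eps) * H + 0.5 * (A %*% H)
  expect_equal(gin_message_pass(g, H, p), oracle, tolerance = 1e-12)
})

test_that("global attention is residual with row-normalized weights", {
  ap <- attention_params(d_h = 4L, n_heads = 2L, seed = 5)

  # single node: alpha = 1, output = h + sum_h W_O W_V h
  h1 <- matrix(stats::runif(4), 1)
  manual <- h1
  for (hd in ap$heads) manual <- manual + h1 %*% t(hd$W_V) %*% t(hd$W_O)
  expect_equal(global_attention(h1, ap), manual, tolerance = 1e-12)

  # attention rows always sum to 1
  H <- matrix(stats::rnorm(5 * 4), 5)
  out <- global_attention(H, ap, return_weights = TRUE)
  for (alpha in attr(out, "alpha")) {
    expect_equal(rowSums(alpha), rep(1, 5), tolerance = 1e-12)
  }

  # two-node case against an explicit softmax computation
  H2 <- matrix(c(0.3, -0.2, 0.8, 0.5, 0.1, -0.4, 0.9, 0.2), 2)
  manual2 <- H2
  for (hd in ap$heads) {
    q <- H2 %*% t(hd$W_Q); k <- H2 %*% t(hd$W_K); v <- H2 %*% t(hd$W_V)
    scores <- q %*% t(k) / sqrt(ap$d_k)
    alpha <- t(apply(scores, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    manual2 <- manual2 + (alpha %*% v) %*% t(hd$W_O)
  }
  expect_equal(global_attention(H2, ap), manual2, tolerance = 1e-10)

  # zero output projections make the layer the identity
  ap0 <- ap
  for (i in seq_along(ap0$heads)) ap0$heads[[i]]$W_O <- ap0$heads[[i]]$W_O * 0
  expect_equal(global_attention(H, ap0), H)
})

test_that("graph encoding is permutation-invariant and deterministic", {
  enc <- graph_encoder(d_h = 16L, n_layers = 2L, n_heads = 2L, seed = 11)
  set.seed(23)
  for (s in c("CC(C)C(=O)OC", "OCC(=O)", "c1ccccc1CC")) {
    g <- graph_of(s, 2)
    h1 <- encode_graph(g, enc)
    expect_identical(h1, encode_graph(g, enc))  # purity
    g2 <- permute_graph(g, sample(nrow(g$nodes)))
    expect_equal(encode_graph(g2, enc), h1, tolerance = 1e-5)
  }

  # all-zero weights collapse the embedding to zero
  enc0 <- enc
  enc0$proj <- enc0$proj * 0
  for (i in seq_along(enc0$layers)) {
    l <- enc0$layers[[i]]
    if (inherits(l, "gin_layer_params")) {
      l$W1 <- l$W1 * 0; l$W2 <- l$W2 * 0
    } else {
      for (h in seq_along(l$heads)) l$heads[[h]]$W_O <- l$heads[[h]]$W_O * 0
    }
    enc0$layers[[i]] <- l
  }
  expect_equal(encode_graph(graph_of("CCO"), enc0), rep(0, 16))
})

test_that("masked-LM loss: uniform case, positivity, cross-entropy oracle", {
  s <- parse_bigsmiles_ext("CC[$]CC")

  # zero parameters give uniform predictions: loss = ln V per masked token
  sp0 <- zeroed_seq_params()
  V <- length(sp0$vocab)
  expect_equal(mlm_loss(s, 2L, sp0), log(V), tolerance = 1e-10)
  expect_equal(mlm_loss(s, c(1L, 3L), sp0), 2 * log(V), tolerance = 1e-10)

  # random parameters: non-negative, and equal to a hand-computed
  # cross-entropy over the forward logits
  sp <- sequence_encoder_params(d_model = 16L, n_blocks = 1L, n_heads = 2L,
                                seed = 8)
  loss <- mlm_loss(s, 2L, sp)
  expect_gte(loss, 0)
  ids <- c(match("[CLS]", sp$vocab),
           match(s$tokens$text, sp$vocab))
  true_id <- ids[3]
  ids[3] <- match("[MASK]", sp$vocab)
  h <- polydeg:::sequence_forward(ids, sp)
  logits <- drop(h[3, ] %*% t(sp$emb))
  expect_equal(loss, -(logits[true_id] - max(logits) -
                         log(sum(exp(logits - max(logits))))),
               tolerance = 1e-10)

  expect_error(mlm_loss(s, integer(0), sp), "non-empty")
  expect_error(mlm_loss(s, 99L, sp), "out of bounds")
})

test_that("sequence encoding returns a deterministic CLS embedding", {
  sp <- sequence_encoder_params(d_model = 16L, n_blocks = 2L, n_heads = 2L,
                                seed = 4)
  s <- parse_bigsmiles_ext("[>]CC(C)[$]CC(C)[<]")
  z <- encode_sequence(s, sp)
  expect_length(z, 16)
  expect_identical(z, encode_sequence(s, sp))
  # the CLS special is prepended exactly once
  ids <- c(match("[CLS]", sp$vocab), polydeg:::tokens_to_ids(s, sp$vocab))
  expect_equal(sum(ids == match("[CLS]", sp$vocab)), 1)
  expect_error(encode_sequence(parse_bigsmiles_ext("[Zr]"), sp),
               "out-of-vocabulary")
})

test_that("fusion normalizes, is deterministic in eval mode, and respects block order", {
  d_in <- 8L + 8L + 8L
  fp <- fusion_params(d_in, d_out = 8L, seed = 6)
  h_G <- stats::runif(8); z <- stats::runif(8); d <- stats::runif(8)
  r1 <- fuse(h_G, z, d, fp)
  expect_identical(r1, fuse(h_G, z, d, fp))
  expect_error(fuse(h_G, z, d[1:3], fp), "expected")

  # pre-affine layer norm has mean 0, variance ~1 per sample
  x <- stats::rnorm(32, mean = 5, sd = 3)
  ln <- layer_norm(x)
  expect_equal(mean(ln), 0, tolerance = 1e-9)
  expect_equal(mean(ln^2), 1, tolerance = 1e-3)

  # zeroing the weight columns of one block removes sensitivity to that
  # block only, pinning the concatenation order [h_G; z; d]
  fp_nog <- fp
  fp_nog$W1[, 1:8] <- 0
  expect_identical(fuse(h_G, z, d, fp_nog), fuse(stats::runif(8), z, d, fp_nog))
  fp_noz <- fp
  fp_noz$W1[, 9:16] <- 0
  expect_identical(fuse(h_G, z, d, fp_noz), fuse(h_G, stats::runif(8), d, fp_noz))
  expect_false(identical(fuse(h_G, z, d, fp_noz),
                         fuse(stats::runif(8), z, d, fp_noz)))
})
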
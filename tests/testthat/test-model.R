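test_that("GCN layer reproduces hand-computed and identity cases", {
  # identity propagation: no edges, identity weights, nonnegative input
  G <- matrix(abs(rnorm(12)), 4, 3)
  out <- gcn_layer_forward(G, diag(4), diag(3), apply_norm = FALSE)
  expect_equal(out, G)

  # hand-computed 2-node chain
  Ahat <- matrix(c(2, 1, 1, 2) / 3, 2, 2)
  out2 <- gcn_layer_forward(matrix(c(1, 4), 2, 1), Ahat, matrix(1),
                            apply_norm = FALSE)
  expect_equal(out2, matrix(c(2, 3), 2, 1))

  # canonical widths: L x 91 -> L x 256 -> L x 64
  set.seed(2)
  L <- 9
  X <- matrix(rnorm(L * 91), L, 91)
  Ahat <- normalize_adjacency(random_symmetric_map(L))
  h1 <- gcn_layer_forward(X, Ahat, matrix(rnorm(91 * 256, 0, 0.05), 91, 256))
  expect_equal(dim(h1), c(L, 256L))
  h2 <- gcn_layer_forward(h1, Ahat, matrix(rnorm(256 * 64, 0, 0.05), 256, 64))
  expect_equal(dim(h2), c(L, 64L))

  expect_error(gcn_layer_forward(G, diag(3), diag(3)), "conformable")
})

test_that("GCN layer equals the per-node summation oracle", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(2:20, 1)
    fin <- sample(2:6, 1); fout <- sample(2:6, 1)
    G <- matrix(rnorm(L * fin), L, fin)
    Ahat <- normalize_adjacency(random_symmetric_map(L))
    W <- matrix(rnorm(fin * fout), fin, fout)
    got <- gcn_layer_forward(G, Ahat, W, apply_norm = FALSE)
    expect_equal(got, oracle_gcn_layer(G, Ahat, W), tolerance = 1e-6)
  }
})

test_that("attention pooling yields normalized weights and fixed-width output", {
  # single residue: softmax of one element is 1, H is that embedding
  M1 <- matrix(c(1.5, -2, 0.3), 1, 3)
  W1 <- matrix(rnorm(6), 2, 3); W2 <- matrix(rnorm(8), 4, 2)
  ap1 <- attention_pool(M1, W1, W2)
  expect_equal(unname(ap1$T), matrix(1, 4, 1))
  expect_equal(ap1$H, drop(M1))

  # identical embedding rows: uniform attention, H reproduces the row
  M2 <- rbind(c(2, -1, 0.5), c(2, -1, 0.5))
  ap2 <- attention_pool(M2, W1, W2)
  expect_equal(unname(ap2$T), matrix(0.5, 4, 2))
  expect_equal(ap2$H, c(2, -1, 0.5))

  # rows of T always sum to 1; H width is p for very different lengths
  p <- 64L
  cfg <- model_config(10L, gcn_dims = c(16L, p))
  par <- init_model_params(cfg, seed = 5)
  for (L in c(1L, 5L, 50L, 500L)) {
    M <- matrix(rnorm(L * p), L, p)
    ap <- attention_pool(M, par$W1, par$W2)
    expect_equal(dim(ap$T), c(4L, L))
    expect_lt(max(abs(rowSums(ap$T) - 1)), 1e-6)
    expect_length(ap$H, p)
  }
  expect_error(attention_pool(M2, matrix(0, 2, 4), W2), "conformable")
})

test_that("predictions stay in (0, 1) and the zero head gives 0.5", {
  g <- random_protein_graph(L = 15, f = 7, seed = 3)
  cfg <- tiny_model_config(7L)
  par <- init_model_params(cfg, seed = 1)
  s <- predict_solubility(g, par)
  expect_true(s > 0 && s < 1)

  par0 <- par
  par0$head_W[[1]][] <- 0
  par0$head_b[[1]][] <- 0
  expect_equal(predict_solubility(g, par0), 0.5)

  with_attn <- predict_solubility(g, par, return_attention = TRUE)
  expect_equal(with_attn$S, s)
  expect_lt(max(abs(rowSums(with_attn$T) - 1)), 1e-6)
})

test_that("compiled forward equals the composed R reference layers", {
  set.seed(21)
  for (rep in 1:5) {
    L <- sample(3:25, 1); f <- 6L
    g <- random_protein_graph(L, f, seed = rep + 50)
    cfg <- model_config(f, gcn_dims = c(5L, 4L), attention_heads = 3L,
                        attention_hidden = 4L)
    par <- init_model_params(cfg, seed = rep)
    Ahat <- normalize_adjacency(g$A)
    G <- as.matrix(g$features)
    for (l in 1:2) {
      G <- gcn_layer_forward(G, Ahat, par$gcn_W[[l]], par$gcn_gamma[[l]],
                             par$gcn_beta[[l]])
    }
    ap <- attention_pool(G, par$W1, par$W2)
    s_ref <- stats::plogis(drop(par$head_W[[1]] %*% ap$H + par$head_b[[1]]))
    expect_equal(predict_solubility(g, par), s_ref, tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(33)
  L <- 6L; f <- 4L
  cfg <- model_config(f, gcn_dims = c(5L, 3L), attention_heads = 2L,
                      attention_hidden = 4L, head_hidden = 3L)
  par <- init_model_params(cfg, seed = 8)
  X <- matrix(rnorm(L * f), L, f)
  Ahat <- normalize_adjacency(random_symmetric_map(L))
  core <- contactsol:::params_core(par)
  y <- 0.35
  lg <- contactsol:::.cpp_loss_grad(X, Ahat, core, y, TRUE)
  gflat <- unlist(lg$grads, use.names = FALSE)
  theta <- contactsol:::flatten_params(par)
  eps <- 1e-6
  idx <- sort(sample(length(theta), 40))
  num <- vapply(idx, function(k) {
    th <- theta; th[k] <- th[k] + eps
    lp <- contactsol:::.cpp_loss_grad(
      X, Ahat, contactsol:::params_core(contactsol:::unflatten_params(th, par)),
      y, TRUE)$loss
    th[k] <- theta[k] - eps
    lm <- contactsol:::.cpp_loss_grad(
      X, Ahat, contactsol:::params_core(contactsol:::unflatten_params(th, par)),
      y, TRUE)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gflat[idx])), 1e-7)
})

test_that("prediction is invariant under joint node permutation", {
  set.seed(44)
  for (rep in 1:10) {
    L <- sample(5:30, 1)
    g <- random_protein_graph(L, f = 6, seed = rep + 100)
    par <- init_model_params(tiny_model_config(6L), seed = rep)
    s0 <- predict_solubility(g, par)
    perm <- sample(L)
    s1 <- predict_solubility(permute_graph(g, perm), par)
    expect_lt(abs(s1 - s0), 1e-5)
  }
})

test_that("embedding width is independent of protein length end to end", {
  par <- init_model_params(tiny_model_config(5L), seed = 2)
  widths <- vapply(c(4L, 8L, 16L), function(L) {
    g <- random_protein_graph(L, f = 5, seed = L)
    length(predict_solubility(g, par, return_attention = TRUE)$H)
  }, integer(1))
  expect_equal(widths, rep(4L, 3)) # last GCN dim of the tiny config
})

test_that("checkpoints restore a model that predicts identically", {
  spec <- tiny_spec()
  sim <- simulate_proteins(6, spec, seed = 2)
  sc <- fit_feature_scaler(sim$features)
  ds <- build_graph_dataset(sim, edge_scheme("full"), sc)
  fit <- train_model(ds, tiny_model_config(91L),
                     train_config(epochs = 2, seed = 1))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ck.rds")
  contactsol:::save_checkpoint(path, fit, sc, edge_scheme("full"))
  ck <- contactsol:::load_checkpoint(path)
  expect_equal(predict_solubility(ds$graph[[1]], ck$params),
               predict_solubility(ds$graph[[1]], fit$params))
  expect_error(contactsol:::load_checkpoint(
    {p2 <- file.path(dir, "x.rds"); saveRDS(list(a = 1), p2); p2}),
    "checkpoint")
})
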
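# shared fixtures, all generated in code

tiny_model_config <- function(f = 91L) {
  model_config(input_dim = f, gcn_dims = c(8L, 4L),
               attention_heads = 2L, attention_hidden = 6L)
}

# small spec: short chains keep the training tests fast
tiny_spec <- function(...) {
  synthetic_protein_spec(length_range = c(12L, 20L), ...)
}

random_symmetric_map <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(runif(L * L), L, L)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

random_protein_graph <- function(L = 10L, f = 5L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(L * f), L, f)
  build_contact_graph(random_symmetric_map(L), X, edge_scheme("full"),
                      id = sprintf("rnd_%d", seed))
}

# brute-force oracle: rank all eligible pairs (|i - j| > 2) by probability
# with (p desc, i asc, j asc) ties and keep the first k
oracle_top_pairs <- function(P, k) {
  L <- nrow(P)
  rows <- list()
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      if (j - i > 2) rows[[length(rows) + 1L]] <- c(i, j, P[i, j])
    }
  }
  if (length(rows) == 0L || k <= 0) return(matrix(integer(0), 0, 2))
  tab <- do.call(rbind, rows)
  ord <- order(-tab[, 3], tab[, 1], tab[, 2])
  unname(tab[ord[seq_len(min(k, nrow(tab)))], 1:2, drop = FALSE])
}

# per-node summation oracle for one GCN layer (no normalization)
oracle_gcn_layer <- function(G, Ahat, W) {
  L <- nrow(G)
  out <- matrix(0, L, ncol(W))
  for (i in seq_len(L)) {
    acc <- rep(0, ncol(G))
    for (j in seq_len(L)) acc <- acc + Ahat[i, j] * G[j, ]
    out[i, ] <- pmax(acc %*% W, 0)
  }
  out
}

# pairwise-concordance (Mann-Whitney) AUC oracle with 0.5 for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

permute_graph <- function(graph, perm) {
  g <- graph
  g$A <- graph$A[perm, perm]
  X <- as.matrix(graph$features)[perm, , drop = FALSE]
  g$features <- contactsol:::new_node_features(X, graph$features$group_order,
                                               graph$features$standardized)
  g
}
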
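#' Model configuration
#'
#' Hyper-parameters of the graph regression model: the number and widths of
#' the GCN layers (defaults 256 then 64; two layers were found optimal, with
#' 64 dimensions for the last layer and 256 for the others), the number of
#' attention heads `r` (default 4), the attention hidden width `q` (default
#' 128), and the widths of any hidden layers in the output head (default
#' none, i.e. a single linear layer before the sigmoid).
#'
#' @param input_dim number of node-feature columns `f` (91 for the five
#'   canonical groups).
#' @param gcn_dims integer vector of GCN layer widths; the last entry is the
#'   embedding width `p`.
#' @param attention_heads number of attention heads `r`.
#' @param attention_hidden attention hidden width `q`.
#' @param head_hidden integer vector of hidden widths for the output MLP
#'   (empty for a single linear layer).
#' @param layer_norm apply layer normalization after each GCN activation.
#' @return a `model_config` object.
#' @export
model_config <- function(input_dim, gcn_dims = c(256L, 64L),
                         attention_heads = 4L, attention_hidden = 128L,
                         head_hidden = integer(0), layer_norm = TRUE) {
  stopifnot(is.numeric(input_dim), input_dim >= 1,
            all(gcn_dims >= 1), length(gcn_dims) >= 1,
            attention_heads >= 1, attention_hidden >= 1,
            all(head_hidden >= 1) || length(head_hidden) == 0)
  structure(list(input_dim = as.integer(input_dim),
                 gcn_dims = as.integer(gcn_dims),
                 attention_heads = as.integer(attention_heads),
                 attention_hidden = as.integer(attention_hidden),
                 head_hidden = as.integer(head_hidden),
                 layer_norm = isTRUE(layer_norm)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: f = %d, GCN %s, %d heads (q = %d), head %s>\n",
              x$input_dim, paste(x$gcn_dims, collapse = "-"),
              x$attention_heads, x$attention_hidden,
              if (length(x$head_hidden)) paste(x$head_hidden, collapse = "-")
              else "linear"))
  invisible(x)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization for all weight matrices, unit gains and
#' zero biases for the layer normalizations, zero biases in the head.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for reproducible initialization.
#' @return a `model_params` list with components `gcn_W`, `gcn_gamma`,
#'   `gcn_beta`, `W1`, `W2`, `head_W`, `head_b` and the `config` attached.
#' @export
init_model_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dims <- c(config$input_dim, config$gcn_dims)
  nlay <- length(config$gcn_dims)
  p <- dims[length(dims)]
  gcn_W <- lapply(seq_len(nlay), function(l) glorot(dims[l], dims[l + 1]))
  gcn_gamma <- lapply(seq_len(nlay), function(l) rep(1, dims[l + 1]))
  gcn_beta <- lapply(seq_len(nlay), function(l) rep(0, dims[l + 1]))
  W1 <- glorot(config$attention_hidden, p)
  W2 <- glorot(config$attention_heads, config$attention_hidden)
  hdims <- c(p, config$head_hidden, 1L)
  head_W <- lapply(seq_len(length(hdims) - 1L),
                   function(l) glorot(hdims[l + 1], hdims[l]))
  head_b <- lapply(seq_len(length(hdims) - 1L),
                   function(l) rep(0, hdims[l + 1]))
  structure(list(gcn_W = gcn_W, gcn_gamma = gcn_gamma, gcn_beta = gcn_beta,
                 W1 = W1, W2 = W2, head_W = head_W, head_b = head_b,
                 config = config),
            class = "model_params")
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# strip config for the C++ side
params_core <- function(params) {
  params[c("gcn_W", "gcn_gamma", "gcn_beta", "W1", "W2", "head_W", "head_b")]
}

row_layer_norm <- function(R, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(R)
  v <- rowMeans((R - mu)^2)
  xhat <- (R - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

#' Single graph-convolution layer
#'
#' One propagation step `norm(ReLU(Ahat %*% G %*% W))`: each node's
#' activations are replaced by the degree-weighted average of its
#' neighbourhood (including itself, via the self-loop in `Ahat`), linearly
#' mapped by `W`, passed through ReLU and, optionally, layer-normalized over
#' the feature dimension with learned gain and bias.
#'
#' @param G L x f_in activation matrix (the node features for the first
#'   layer).
#' @param Ahat row-stochastic normalized adjacency from
#'   [normalize_adjacency()].
#' @param W f_in x f_out weight matrix.
#' @param gamma,beta layer-normalization gain and bias (length f_out);
#'   ignored when `apply_norm = FALSE`.
#' @param apply_norm apply layer normalization after the activation.
#' @return L x f_out activation matrix.
#' @export
gcn_layer_forward <- function(G, Ahat, W, gamma = NULL, beta = NULL,
                              apply_norm = TRUE) {
  G <- as.matrix(G); Ahat <- as.matrix(Ahat); W <- as.matrix(W)
  if (ncol(Ahat) != nrow(G)) stop("Ahat and G are not conformable", call. = FALSE)
  if (ncol(G) != nrow(W)) stop("G and W are not conformable", call. = FALSE)
  out <- pmax(Ahat %*% G %*% W, 0)
  if (!all(is.finite(out))) stop("non-finite activations", call. = FALSE)
  if (apply_norm) {
    if (is.null(gamma)) gamma <- rep(1, ncol(out))
    if (is.null(beta)) beta <- rep(0, ncol(out))
    out <- row_layer_norm(out, gamma, beta)
  }
  out
}

#' Self-attention pooling of node embeddings
#'
#' Computes `T = softmax_rows(W2 tanh(W1 t(M)))`, an r x L matrix whose rows
#' are attention distributions over the residues, and the fixed-width graph
#' embedding `H = (1/r) * colSums(T %*% M)`-style mean over the r rows of
#' `T %*% M`.  `H` has width `p` whatever the protein length, which removes
#' both the size variance and the residue-permutation variance of `M`.
#'
#' @param M L x p node embedding matrix.
#' @param W1 q x p attention matrix.
#' @param W2 r x q attention matrix.
#' @return list with `T` (r x L attention map, rows summing to 1) and `H`
#'   (length-p graph embedding).
#' @export
attention_pool <- function(M, W1, W2) {
  M <- as.matrix(M); W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (ncol(W1) != ncol(M)) stop("W1 and M are not conformable", call. = FALSE)
  if (ncol(W2) != nrow(W1)) stop("W2 and W1 are not conformable", call. = FALSE)
  scores <- W2 %*% tanh(W1 %*% t(M)) # r x L
  mx <- apply(scores, 1, max)
  E <- exp(scores - mx)
  Tmat <- E / rowSums(E)
  H <- colMeans(Tmat %*% M)
  list(T = Tmat, H = H)
}

#' Predict solubility for one protein graph
#'
#' Runs the full forward model: adjacency normalization, the stacked GCN
#' layers, self-attention pooling, and the sigmoid head.  The score is
#' strictly inside (0, 1).
#'
#' @param graph a `protein_graph` (or a list with elements `X`/`features`
#'   and `A`).
#' @param params a `model_params` object (from [init_model_params()] or
#'   [train_model()]).
#' @param return_attention also return the r x L attention map and the graph
#'   embedding.
#' @return the scalar score, or (with `return_attention`) a list with `S`,
#'   `T` and `H`.
#' @export
predict_solubility <- function(graph, params, return_attention = FALSE) {
  stopifnot(inherits(params, "model_params"))
  X <- graph_features(graph)
  config <- params$config
  if (ncol(X) != config$input_dim) {
    stop(sprintf("graph has %d feature columns; model expects %d",
                 ncol(X), config$input_dim), call. = FALSE)
  }
  Ahat <- normalize_adjacency(graph$A)
  out <- .cpp_forward(X, Ahat, params_core(params),
                      layer_norm = config$layer_norm,
                      return_hidden = return_attention)
  if (return_attention) out else out$S
}

graph_features <- function(graph) {
  if (inherits(graph, "protein_graph")) return(as.matrix(graph$features))
  if (!is.null(graph$X)) return(as.matrix(graph$X))
  as.matrix(graph$features)
}

# ---- parameter <-> flat-vector plumbing for the optimizer ----

flatten_params <- function(params) {
  core <- params_core(params)
  unlist(core, use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  core <- params_core(template)
  out <- core
  pos <- 1L
  for (nm in names(core)) {
    el <- core[[nm]]
    if (is.list(el)) {
      for (i in seq_along(el)) {
        n <- length(el[[i]])
        piece <- vec[pos:(pos + n - 1L)]
        out[[nm]][[i]] <- if (is.matrix(el[[i]]))
          matrix(piece, nrow(el[[i]]), ncol(el[[i]])) else piece
        pos <- pos + n
      }
    } else {
      n <- length(el)
      piece <- vec[pos:(pos + n - 1L)]
      out[[nm]] <- if (is.matrix(el)) matrix(piece, nrow(el), ncol(el)) else piece
      pos <- pos + n
    }
  }
  res <- template
  res[names(out)] <- out
  res
}
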
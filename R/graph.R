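#' Edge construction schemes for protein graphs
#'
#' Two ways of turning a predicted contact-probability map into graph edges:
#' `"full"` keeps every residue pair, weighted by its predicted probability;
#' `"topk"` keeps only the `floor(alpha * L)` eligible pairs (sequence
#' separation > 2) with the highest predicted probability, weighted either by
#' the probability (`"continuous"`) or by 1 (`"discrete"`).  In every scheme
#' the 2-hop sequence neighbours (|i - j| <= 2) are always connected with
#' weight 1; they are not charged against the `alpha * L` budget.  `alpha`
#' was studied over 0..7; `alpha = 0` yields the chain-only (no-contact)
#' graph.
#'
#' @param mode `"full"` or `"topk"`.
#' @param alpha nonnegative edge-budget multiplier (topk mode only).
#' @param weighting `"continuous"` or `"discrete"` (topk mode only).
#' @return an `edge_scheme` object.
#' @examples
#' edge_scheme("full")
#' edge_scheme("topk", alpha = 3, weighting = "discrete")
#' @export
edge_scheme <- function(mode = c("full", "topk"), alpha = 0,
                        weighting = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  if (mode == "full") weighting <- "continuous"
  structure(list(mode = mode, alpha = alpha, weighting = weighting),
            class = "edge_scheme")
}

#' @export
print.edge_scheme <- function(x, ...) {
  if (x$mode == "full") {
    cat("<edge_scheme: full map, continuous weights>\n")
  } else {
    cat(sprintf("<edge_scheme: top %s*L pairs, %s weights>\n",
                format(x$alpha), x$weighting))
  }
  invisible(x)
}

validate_contact_map <- function(P, tol = 1e-8) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("contact map must be square", call. = FALSE)
  if (max(abs(P - t(P))) > tol) {
    stop("contact map must be symmetric", call. = FALSE)
  }
  diag(P) <- 0
  if (min(P) < -tol || max(P) > 1 + tol) {
    stop("contact-map probabilities must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(P, 0), 1)
}

#' Build a protein graph from a contact map and node features
#'
#' Applies an [edge_scheme()] to a symmetric L x L contact-probability map
#' and attaches the node feature matrix, producing the weighted adjacency of
#' the protein graph.  The adjacency is symmetric, has zero diagonal, and
#' carries weight 1 on every 2-hop sequence-neighbour pair.
#'
#' @param P symmetric L x L matrix of predicted contact probabilities in
#'   \[0, 1\] (diagonal ignored).
#' @param X a `node_features` object (or L x f matrix) for the same protein.
#' @param scheme an [edge_scheme()].
#' @param id identifier stored with the graph.
#' @return a `protein_graph`: list with `features`, `A` (weighted
#'   adjacency), `scheme` and `id`.
#' @export
build_contact_graph <- function(P, X, scheme = edge_scheme("full"),
                                id = "protein") {
  stopifnot(inherits(scheme, "edge_scheme"))
  P <- validate_contact_map(P)
  nf <- if (inherits(X, "node_features")) X else
    new_node_features(as.matrix(X), character(0), FALSE)
  L <- nrow(P)
  if (nrow(as.matrix(nf)) != L) {
    stop(sprintf("contact map is %d x %d but features have %d rows",
                 L, L, nrow(as.matrix(nf))), call. = FALSE)
  }
  if (scheme$mode == "full") {
    A <- P
  } else {
    A <- matrix(0, L, L)
    keep <- top_contact_pairs(P, floor(scheme$alpha * L))
    if (nrow(keep) > 0) {
      w <- if (scheme$weighting == "discrete") 1 else P[keep]
      A[keep] <- w
      A[keep[, c(2, 1), drop = FALSE]] <- w
    }
  }
  # 2-hop chain neighbours always connected with weight 1
  sep <- abs(row(A) - col(A))
  A[sep >= 1 & sep <= 2] <- 1
  diag(A) <- 0
  structure(list(features = nf, A = A, scheme = scheme, id = id),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  L <- nrow(x$A)
  ne <- sum(x$A[upper.tri(x$A)] > 0)
  cat(sprintf("<protein_graph '%s': L = %d, %d edges, f = %d>\n",
              x$id, L, ne, ncol(as.matrix(x$features))))
  invisible(x)
}

#' Select the top alpha*L contact pairs from a probability map
#'
#' Eligible pairs are unordered pairs (i < j) with sequence separation
#' `j - i > 2`.  Pairs are ranked by probability (descending) with
#' deterministic tie-breaking by (i, j) ascending, and the first `k` are
#' returned.
#'
#' @param P symmetric contact-probability matrix.
#' @param k number of pairs to keep (`floor(alpha * L)`).
#' @return an integer matrix with columns `i`, `j` (i < j), at most `k`
#'   rows.
#' @export
top_contact_pairs <- function(P, k) {
  L <- nrow(P)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 2, , drop = FALSE]
  if (nrow(idx) == 0L || k <= 0) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  p <- P[idx]
  ord <- order(-p, idx[, 1], idx[, 2])
  keep <- idx[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
  colnames(keep) <- c("i", "j")
  keep
}

#' Degree-normalize an adjacency matrix for graph convolution
#'
#' Adds self-loops and divides each row by its degree:
#' `Ahat = Dtilde^-1 (A + I)` with `Dtilde_ii = sum_k (A + I)_ik`.  Every
#' row of the result sums to exactly 1, so one convolution step averages a
#' node with its neighbours, weighted by edge strength.
#'
#' @param A square nonnegative adjacency matrix (a `protein_graph` is also
#'   accepted).
#' @return the row-stochastic L x L matrix `Ahat`.
#' @examples
#' normalize_adjacency(matrix(c(0, 0.5, 0.5, 0), 2, 2))
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "protein_graph")) A <- A$A
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (min(A) < 0) stop("adjacency must be nonnegative", call. = FALSE)
  At <- A + diag(nrow(A))
  At / rowSums(At)
}

#' Compute a binary contact map from Calpha coordinates
#'
#' Marks an unordered residue pair as in contact when the Euclidean distance
#' between their Calpha atoms is strictly below `cutoff` (default 7.5
#' Angstrom).
#'
#' @param coords numeric L x 3 matrix of Calpha coordinates in Angstrom,
#'   ordered along the sequence.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return a binary symmetric L x L matrix with zero diagonal.
#' @export
contact_map_from_structure <- function(coords, cutoff = 7.5) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, cutoff > 0)
  if (nrow(coords) < 2L) {
    stop("need at least 2 residues to compute contacts", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  D <- as.matrix(dist(coords))
  C <- (D < cutoff) * 1
  diag(C) <- 0
  dimnames(C) <- NULL
  C
}

#' Count unordered contact pairs in a binary contact map
#'
#' @param C binary symmetric contact map.
#' @return number of unordered pairs in contact.
#' @export
count_contact_pairs <- function(C) {
  sum(C[upper.tri(C)] > 0)
}

#' Precision and recall of a predicted contact set
#'
#' Compares a set of predicted contact pairs with an actual (structure
#' derived) binary contact map; pairs are counted unordered.
#' `precision = |predicted intersect actual| / |predicted|` and
#' `recall = |predicted intersect actual| / |actual|`.  An empty predicted
#' set yields precision 0 with a warning.
#'
#' @param predicted_pairs two-column matrix/data frame of predicted pairs
#'   (1-based residue indices), or a symmetric matrix whose positive
#'   off-diagonal entries are the predictions.
#' @param actual binary symmetric L x L actual contact map.
#' @return a one-row tibble with `precision`, `recall`, `n_predicted`,
#'   `n_actual`, `n_correct`.
#' @export
evaluate_contact_prediction <- function(predicted_pairs, actual) {
  actual <- as.matrix(actual)
  L <- nrow(actual)
  if (is.matrix(predicted_pairs) && nrow(predicted_pairs) == ncol(predicted_pairs) &&
      nrow(predicted_pairs) == L && ncol(predicted_pairs) != 2L) {
    predicted_pairs <- which(predicted_pairs > 0 & upper.tri(predicted_pairs),
                             arr.ind = TRUE)
  }
  pp <- as.matrix(predicted_pairs)
  if (nrow(pp) > 0) {
    stopifnot(ncol(pp) == 2L)
    ij <- cbind(pmin(pp[, 1], pp[, 2]), pmax(pp[, 1], pp[, 2]))
    ij <- unique(ij)
    if (max(ij) > L) stop("predicted pair index exceeds map size", call. = FALSE)
    n_pred <- nrow(ij)
    n_correct <- sum(actual[ij] > 0)
  } else {
    n_pred <- 0L
    n_correct <- 0L
  }
  n_actual <- count_contact_pairs(actual)
  if (n_pred == 0L) {
    warning("empty predicted contact set; precision reported as 0")
    precision <- 0
  } else {
    precision <- n_correct / n_pred
  }
  recall <- if (n_actual > 0) n_correct / n_actual else 0
  tibble::tibble(precision = precision, recall = recall,
                 n_predicted = n_pred, n_actual = n_actual,
                 n_correct = n_correct)
}

#' Read Calpha coordinates from a PDB file
#'
#' Extracts the Calpha trace (ATOM records, first model) from a PDB file,
#' optionally restricted to one chain.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` for all chains.
#' @return numeric L x 3 coordinate matrix with residue numbers as row
#'   names.
#' @export
read_ca_coordinates <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", chain = chain, verbose = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coords) <- atoms$resno
  coords
}

#' Read a predicted contact map from disk
#'
#' Accepts three dialects: a dense whitespace-separated L x L matrix, sparse
#' `"i j probability"` triplets (1-based, i < j), and CASP-RR-style records
#' (`PFRMAT RR` header, `i j d1 d2 p` rows).  The dialect is autodetected
#' unless `format` is given.  For sparse inputs the map size is taken from
#' `L` or, failing that, the largest index seen.
#'
#' @param path file to read.
#' @param L protein length (required to pad sparse maps whose largest index
#'   is below L).
#' @param format `"auto"`, `"dense"`, `"triplet"` or `"casp"`.
#' @return a symmetric L x L probability matrix with zero diagonal.
#' @export
read_contact_map <- function(path, L = NULL,
                             format = c("auto", "dense", "triplet", "casp")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty contact-map file", call. = FALSE)
  if (format == "auto") {
    first <- trimws(lines[1])
    ntok1 <- length(strsplit(first, "\\s+")[[1]])
    if (grepl("^PFRMAT", first)) {
      format <- "casp"
    } else if (ntok1 == length(lines)) {
      # square block; a 3-line file of 'i j p' triplets is also 3 x 3, so
      # fall back to triplets when the dense reading is not a valid map
      format <- "dense"
      if (ntok1 == 3L) {
        dense_ok <- tryCatch({
          validate_contact_map(read_dense_block(lines)); TRUE
        }, error = function(e) FALSE)
        if (!dense_ok) format <- "triplet"
      }
    } else if (ntok1 == 3L) {
      format <- "triplet"
    } else {
      stop("cannot autodetect contact-map dialect", call. = FALSE)
    }
  }
  if (format == "dense") {
    return(validate_contact_map(read_dense_block(lines)))
  }
  if (format == "casp") {
    keep <- grepl("^\\s*[0-9]+\\s+[0-9]+\\s", lines)
    recs <- lapply(which(keep), function(i) {
      parse_num(strsplit(trimws(lines[i]), "\\s+")[[1]], i, "contact map")
    })
    if (length(recs) == 0L) stop("no contact records in CASP-RR file", call. = FALSE)
    trip <- t(vapply(recs, function(r) c(r[1], r[2], r[length(r)]), numeric(3)))
  } else {
    trip <- t(vapply(seq_along(lines), function(i) {
      r <- parse_num(strsplit(trimws(lines[i]), "\\s+")[[1]], i, "contact map")
      if (length(r) != 3L) {
        stop(sprintf("contact map parse error at line %d: expected 'i j p'", i),
             call. = FALSE)
      }
      r
    }, numeric(3)))
  }
  n <- if (is.null(L)) max(trip[, 1:2]) else L
  P <- matrix(0, n, n)
  ij <- cbind(as.integer(trip[, 1]), as.integer(trip[, 2]))
  P[ij] <- trip[, 3]
  P[ij[, c(2, 1), drop = FALSE]] <- trip[, 3]
  validate_contact_map(P)
}

read_dense_block <- function(lines) {
  rows <- lapply(seq_along(lines), function(i) {
    parse_num(strsplit(trimws(lines[i]), "\\s+")[[1]], i, "contact map")
  })
  n <- unique(lengths(rows))
  if (length(n) != 1L || n != length(rows)) {
    stop("dense contact map is not square", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a contact map as sparse triplets
#'
#' Writes the strictly-upper-triangle nonzero entries as `"i j p"` lines,
#' the sparse dialect understood by [read_contact_map()].
#'
#' @param P symmetric contact-probability matrix.
#' @param path output file.
#' @param digits decimal digits to print.
#' @export
write_contact_triplets <- function(P, path, digits = 6) {
  P <- validate_contact_map(P)
  idx <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  lines <- sprintf(paste0("%d %d %.", digits, "f"),
                   idx[, 1], idx[, 2], P[idx])
  writeLines(lines, path)
  invisible(path)
}
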
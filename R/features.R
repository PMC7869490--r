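#' Residue feature groups
#'
#' Per-residue node features come in five groups with fixed column counts:
#' BLOSUM62 substitution scores (20), seven physicochemical properties
#' (AAPHY7), PSI-BLAST PSSM scores (20), HH-suite HMM profile values (30:
#' 20 match emissions + 10 transition/diversity columns), and SPIDER3
#' predicted structural properties (14: SS3 probabilities, relative solvent
#' accessibility, sine/cosine of the phi/psi/theta/tau backbone angles, and
#' the two half-sphere exposures).  A `feature_group` is an L x d numeric
#' matrix tagged with its group name; `d` is checked against the canonical
#' dimension for the group.
#'
#' @param name one of `"BLOSUM62"`, `"AAPHY7"`, `"PSSM"`, `"HMM"`,
#'   `"SPIDER3"`.
#' @param values numeric L x d matrix.
#' @return an object of class `feature_group`.
#' @export
feature_group <- function(name, values) {
  name <- match.arg(name, GROUP_ORDER)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != GROUP_DIMS[[name]]) {
    stop(sprintf("feature group %s must have %d columns, got %d",
                 name, GROUP_DIMS[[name]], ncol(values)), call. = FALSE)
  }
  if (anyNA(values)) stop("feature group contains NA values", call. = FALSE)
  structure(list(name = name, values = values), class = "feature_group")
}

#' @export
print.feature_group <- function(x, ...) {
  cat(sprintf("<feature_group %s: %d residues x %d columns>\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# validate / normalize a one-letter residue string; returns character vector
validate_sequence <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(as.character(seq))
  if (length(seq) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  bad <- which(!seq %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d", seq[bad[1]], bad[1]),
         call. = FALSE)
  }
  seq
}

# shared lookup encoder: table rows indexed by residue, 'X' -> zero row
encode_lookup <- function(seq, table, name) {
  seq <- validate_sequence(seq)
  out <- matrix(0, nrow = length(seq), ncol = ncol(table))
  known <- seq != "X"
  out[known, ] <- table[seq[known], , drop = FALSE]
  colnames(out) <- colnames(table)
  rownames(out) <- NULL
  feature_group(name, out)
}

#' Encode a sequence with BLOSUM62 substitution scores
#'
#' Each residue is represented by its row of the canonical NCBI BLOSUM62
#' matrix restricted to the 20 standard amino acids; the unknown residue
#' `'X'` maps to an all-zero row.
#'
#' @param seq amino-acid sequence, as a single string or character vector of
#'   one-letter codes (20 standard residues plus `'X'`).
#' @return a [feature_group()] with an L x 20 matrix.
#' @examples
#' encode_blosum62("ACDEF")
#' @export
encode_blosum62 <- function(seq) {
  encode_lookup(seq, blosum62_table(), "BLOSUM62")
}

#' Encode a sequence with seven physicochemical properties
#'
#' Looks up, per residue, the seven-descriptor physicochemical set (steric
#' parameter, hydrophobicity, volume, polarizability, isoelectric point,
#' helix probability, sheet probability); `'X'` maps to zeros.
#'
#' @inheritParams encode_blosum62
#' @return a [feature_group()] with an L x 7 matrix.
#' @export
encode_aaphy7 <- function(seq) {
  encode_lookup(seq, aaphy7_table(), "AAPHY7")
}

as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
}

parse_num <- function(tok, line_no, file_kind) {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v)) {
    stop(sprintf("%s parse error at line %d: non-numeric field '%s'",
                 file_kind, line_no, tok[which(is.na(v))[1]]), call. = FALSE)
  }
  v
}

#' Parse a sequence-profile file into a feature group
#'
#' Understands three external dialects: PSI-BLAST ASCII PSSM (the first 20
#' score columns per residue), HH-suite `.hhm` profiles (20 match-emission
#' plus 10 transition/diversity columns; stored values `v` are decoded to
#' probabilities by `2^(-v/1000)`, with `*` and `65535` decoding to 0), and
#' SPIDER3 `.spd33` tables (three SS3 probabilities, ASA, the four backbone
#' angles emitted as 8 sine/cosine values, and HSE-up/HSE-down, 14 columns
#' in all).  Errors report 1-based line numbers.
#'
#' @param kind `"PSSM"`, `"HMM"` or `"SPIDER3"`.
#' @param text file content: a character vector of lines or a single string.
#' @param angles for SPIDER3 only: `"degrees"` if the file stores the four
#'   backbone angles in degrees (sine/cosine computed at parse time), or
#'   `"sincos"` if it already stores the 8 sine/cosine columns.
#' @return a [feature_group()] of the corresponding kind.
#' @export
parse_profile <- function(kind, text, angles = c("degrees", "sincos")) {
  kind <- match.arg(kind, c("PSSM", "HMM", "SPIDER3"))
  lines <- as_lines(text)
  switch(kind,
    PSSM = parse_pssm_lines(lines),
    HMM = parse_hhm_lines(lines),
    SPIDER3 = parse_spd33_lines(lines, match.arg(angles))
  )
}

#' @rdname parse_profile
#' @param path path to the profile file on disk.
#' @export
read_profile <- function(kind, path, angles = c("degrees", "sincos")) {
  parse_profile(kind, readLines(path, warn = FALSE), angles = angles)
}

parse_pssm_lines <- function(lines) {
  rows <- list()
  pos <- integer(0)
  in_data <- FALSE
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    is_data <- length(tok) >= 22 && grepl("^[0-9]+$", tok[1]) &&
      nchar(tok[2]) == 1L
    if (is_data) {
      in_data <- TRUE
      vals <- parse_num(tok[3:22], i, "PSSM")
      rows[[length(rows) + 1L]] <- vals
      pos <- c(pos, as.integer(tok[1]))
    } else if (in_data && nzchar(trimws(lines[i]))) {
      break # footer (statistics block) ends the data section
    }
  }
  if (length(rows) == 0L) {
    stop("PSSM parse error: no data rows found", call. = FALSE)
  }
  if (!identical(pos, seq_along(pos))) {
    stop(sprintf("PSSM parse error: residue numbering not contiguous near position %d",
                 pos[which(pos != seq_along(pos))[1]]), call. = FALSE)
  }
  feature_group("PSSM", do.call(rbind, rows))
}

decode_hhm <- function(tok, line_no) {
  out <- numeric(length(tok))
  star <- tok == "*" | tok == "65535"
  if (any(!star)) {
    v <- suppressWarnings(as.numeric(tok[!star]))
    if (anyNA(v)) {
      stop(sprintf("HMM parse error at line %d: non-numeric field '%s'",
                   line_no, tok[!star][which(is.na(v))[1]]), call. = FALSE)
    }
    out[!star] <- 2^(-v / 1000)
  }
  out
}

parse_hhm_lines <- function(lines) {
  hmm_at <- which(grepl("^HMM\\b", lines))
  if (length(hmm_at) == 0L) {
    stop("HMM parse error: no 'HMM' header line found", call. = FALSE)
  }
  i <- hmm_at[1] + 2L # skip the transition-label line
  rows <- list()
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "//") break
    if (!nzchar(line) || startsWith(line, "NULL")) { i <- i + 1L; next }
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) != 22L) {
      stop(sprintf("HMM parse error at line %d: expected residue line with 22 fields, got %d",
                   i, length(tok)), call. = FALSE)
    }
    em <- decode_hhm(tok[3:22], i)
    if (i + 1L > n) {
      stop(sprintf("HMM parse error at line %d: truncated record (missing transition line)",
                   i), call. = FALSE)
    }
    tok2 <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok2) != 10L) {
      stop(sprintf("HMM parse error at line %d: expected 10 transition fields, got %d",
                   i + 1L, length(tok2)), call. = FALSE)
    }
    tr <- decode_hhm(tok2, i + 1L)
    rows[[length(rows) + 1L]] <- c(em, tr)
    i <- i + 2L
  }
  if (length(rows) == 0L) {
    stop("HMM parse error: no residue records found", call. = FALSE)
  }
  feature_group("HMM", do.call(rbind, rows))
}

SPD33_FEATURES <- c("P_C", "P_E", "P_H", "ASA",
                    "sin_phi", "cos_phi", "sin_psi", "cos_psi",
                    "sin_theta", "cos_theta", "sin_tau", "cos_tau",
                    "HSE_up", "HSE_down")

parse_spd33_lines <- function(lines, angles) {
  ntok <- if (angles == "degrees") 13L else 17L
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) != ntok) {
      stop(sprintf("SPIDER3 parse error at line %d: expected %d fields, got %d",
                   i, ntok, length(tok)), call. = FALSE)
    }
    # file order: idx AA SS ASA <angles> HSEu HSEd P(C) P(E) P(H)
    asa <- parse_num(tok[4], i, "SPIDER3")
    if (angles == "degrees") {
      ang <- parse_num(tok[5:8], i, "SPIDER3") * pi / 180
      sc <- as.vector(rbind(sin(ang), cos(ang)))
      rest <- parse_num(tok[9:13], i, "SPIDER3")
    } else {
      sc <- parse_num(tok[5:12], i, "SPIDER3")
      rest <- parse_num(tok[13:17], i, "SPIDER3")
    }
    hse <- rest[1:2]
    ss3 <- rest[3:5]
    rows[[length(rows) + 1L]] <- c(ss3, asa, sc, hse)
  }
  if (length(rows) == 0L) {
    stop("SPIDER3 parse error: no data rows found", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- SPD33_FEATURES
  feature_group("SPIDER3", m)
}

#' Assemble feature groups into a node feature matrix
#'
#' Concatenates the supplied groups column-wise in the canonical order
#' (BLOSUM62, AAPHY7, PSSM, HMM, SPIDER3) regardless of the order they are
#' supplied in.  All groups must describe the same number of residues and
#' each group may appear at most once.
#'
#' @param groups a list of [feature_group()] objects.
#' @return a `node_features` object: list with `X` (the L x f matrix),
#'   `group_order`, and the `standardized` flag (initially `FALSE`).
#' @export
assemble_features <- function(groups) {
  if (inherits(groups, "feature_group")) groups <- list(groups)
  stopifnot(length(groups) >= 1L)
  names_in <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(names_in)) {
    stop(sprintf("duplicate feature group: %s",
                 names_in[duplicated(names_in)][1]), call. = FALSE)
  }
  L <- vapply(groups, function(g) nrow(g$values), integer(1))
  if (length(unique(L)) != 1L) {
    stop(sprintf("feature groups disagree on sequence length: %s",
                 paste(unique(L), collapse = " vs ")), call. = FALSE)
  }
  ord <- GROUP_ORDER[GROUP_ORDER %in% names_in]
  groups <- groups[match(ord, names_in)]
  X <- do.call(cbind, lapply(groups, function(g) g$values))
  new_node_features(X, ord, standardized = FALSE)
}

new_node_features <- function(X, group_order, standardized) {
  structure(list(X = X, group_order = group_order,
                 standardized = standardized),
            class = "node_features")
}

#' @export
print.node_features <- function(x, ...) {
  cat(sprintf("<node_features: %d residues x %d columns [%s]%s>\n",
              nrow(x$X), ncol(x$X), paste(x$group_order, collapse = "+"),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
as.matrix.node_features <- function(x, ...) x$X

#' Fit and apply per-column standardization
#'
#' `fit_feature_scaler()` pools the residues of all supplied training
#' proteins and records the per-column mean and standard deviation;
#' `apply_feature_scaler()` centers and scales a feature matrix with those
#' training statistics (columns with zero spread are centered only).
#' Standardization is global over the training set, not per protein, so the
#' same transform applies at test time.
#'
#' @param training a list of `node_features` objects (or plain matrices)
#'   with a common column count.
#' @return `fit_feature_scaler()` returns a `feature_scaler`;
#'   `apply_feature_scaler()` returns a standardized `node_features`.
#' @examples
#' g <- feature_group("AAPHY7", matrix(rnorm(14), 2, 7))
#' nf <- assemble_features(list(g))
#' sc <- fit_feature_scaler(list(nf))
#' apply_feature_scaler(sc, nf)
#' @export
fit_feature_scaler <- function(training) {
  if (inherits(training, "node_features")) training <- list(training)
  mats <- lapply(training, as.matrix)
  f <- unique(vapply(mats, ncol, integer(1)))
  if (length(f) != 1L) {
    stop("training matrices disagree on column count", call. = FALSE)
  }
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) < 2L) {
    stop("scaler requires at least 2 residues in total", call. = FALSE)
  }
  mu <- colMeans(pooled)
  # population standard deviation: {1, 3} standardizes to {-1, +1}
  sdev <- sqrt(colMeans(sweep(pooled, 2, mu)^2))
  structure(list(mean = mu, sd = sdev, f = f),
            class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler a fitted `feature_scaler`.
#' @param x a `node_features` object or L x f matrix to standardize.
#' @export
apply_feature_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  nf <- if (inherits(x, "node_features")) x else
    new_node_features(as.matrix(x), character(0), FALSE)
  X <- as.matrix(nf)
  if (ncol(X) != scaler$f) {
    stop(sprintf("scaler fitted for %d columns, data has %d",
                 scaler$f, ncol(X)), call. = FALSE)
  }
  scale_by <- ifelse(scaler$sd > 0, scaler$sd, 1)
  Xs <- sweep(sweep(X, 2, scaler$mean, "-"), 2, scale_by, "/")
  new_node_features(Xs, nf$group_order, standardized = TRUE)
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("<feature_scaler: %d columns, %d zero-spread>\n",
              x$f, sum(x$sd == 0)))
  invisible(x)
}

#' Read a FASTA file of amino-acid sequences
#'
#' @param path path to a FASTA file.
#' @return a named character vector of sequences (one string per record).
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  out <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(toupper(out), rownames(fa$ali))
}
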
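#' Specification of the synthetic protein generator
#'
#' The generator emulates every per-protein input of the pipeline: a random
#' sequence, a compact self-avoiding Calpha trace (true contacts follow from
#' a distance cutoff on that trace), a noisy "predicted" contact-probability
#' map, feature files in the external dialects, and a solubility target
#' produced by a planted function: a sigmoid of linear weights applied to
#' neighbourhood-averaged (graph-contact-averaged) standardized features.
#' Because the planted function reads features through the contact
#' neighbourhoods -- including a separately weighted long-range term -- the
#' targets genuinely depend on the graph, so models using the contact map
#' can be distinguished from chain-only models.
#'
#' @param length_range inclusive range of sequence lengths.
#' @param bond_length consecutive Calpha distance in Angstrom.
#' @param compaction strength of the drift toward the current centroid in
#'   the random walk; larger values give more compact chains and more
#'   long-range contacts.
#' @param contact_cutoff Calpha contact cutoff in Angstrom.
#' @param noise level `lambda` in \[0, 1) blending the true binary map with
#'   Beta(2, 5) probability noise:
#'   `P = clip((1 - lambda) * truth + lambda * Beta(2, 5))`.
#' @param local_gain,longrange_gain,bias coefficients of the planted
#'   solubility function (local 2-hop term, long-range contact term,
#'   intercept on the logit scale).
#' @param seed seed fixing the planted weight vectors.
#' @return a `synthetic_protein_spec` object.
#' @export
synthetic_protein_spec <- function(length_range = c(30L, 80L),
                                   bond_length = 3.8,
                                   compaction = 0.1,
                                   contact_cutoff = 7.5,
                                   noise = 0.2,
                                   local_gain = 4,
                                   longrange_gain = 9,
                                   bias = 0,
                                   seed = 20L) {
  stopifnot(length(length_range) == 2L, length_range[1] >= 3L,
            length_range[2] >= length_range[1],
            bond_length > 0, contact_cutoff > 0,
            noise >= 0, noise < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- sum(GROUP_DIMS)
  w_loc <- rnorm(f); w_loc <- w_loc / sqrt(sum(w_loc^2))
  w_lr <- rnorm(f); w_lr <- w_lr / sqrt(sum(w_lr^2))
  structure(list(length_range = as.integer(length_range),
                 bond_length = bond_length, compaction = compaction,
                 contact_cutoff = contact_cutoff, noise = noise,
                 local_gain = local_gain, longrange_gain = longrange_gain,
                 bias = bias, seed = as.integer(seed),
                 w_loc = w_loc, w_lr = w_lr),
            class = "synthetic_protein_spec")
}

#' @export
print.synthetic_protein_spec <- function(x, ...) {
  cat(sprintf("<synthetic_protein_spec: L in [%d, %d], noise %.2f, compaction %.2f>\n",
              x$length_range[1], x$length_range[2], x$noise, x$compaction))
  invisible(x)
}

#' Generate a compact self-avoiding Calpha trace
#'
#' Random walk with exact bond length between consecutive residues, a drift
#' toward the running centroid (controlled by `compaction`), and a
#' self-avoidance bias that resamples steps landing closer than 3.2
#' Angstrom to any earlier residue.
#'
#' @param L number of residues (>= 2).
#' @param spec a [synthetic_protein_spec()].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return L x 3 coordinate matrix in Angstrom.
#' @export
generate_conformation <- function(L, spec = synthetic_protein_spec(),
                                  seed = NULL) {
  stopifnot(L >= 2L)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  b <- spec$bond_length
  min_sep <- 3.2
  coords <- matrix(0, L, 3)
  d0 <- rnorm(3)
  coords[2, ] <- b * d0 / sqrt(sum(d0^2))
  for (i in seq_len(L - 2L) + 2L) {
    cur <- coords[i - 1L, ]
    centroid <- colMeans(coords[seq_len(i - 1L), , drop = FALSE])
    drift <- centroid - cur
    best <- NULL
    best_clear <- -Inf
    for (try in 1:50) {
      d <- rnorm(3) + spec$compaction * drift
      d <- b * d / sqrt(sum(d^2))
      cand <- cur + d
      prev <- coords[seq_len(i - 2L), , drop = FALSE]
      clear <- min(sqrt(rowSums(sweep(prev, 2, cand)^2)))
      if (clear >= min_sep) { best <- cand; break }
      if (clear > best_clear) { best_clear <- clear; best <- cand }
    }
    coords[i, ] <- best
  }
  coords
}

# analytic per-column moments of the generator's feature distribution,
# used to standardize features inside the planted solubility function
generator_feature_moments <- function() {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  bl <- blosum62_table(); ap <- aaphy7_table()
  mean_bl <- colMeans(bl); sd_bl <- apply(bl, 2, pop_sd)
  mean_ap <- colMeans(ap); sd_ap <- apply(ap, 2, pop_sd)
  list(
    mean = c(mean_bl, mean_ap, rep(0, 20), rep(0.2, 30),
             c(rep(1 / 3, 3), 0.5, rep(0, 8), 10, 10)),
    sd = c(sd_bl, sd_ap, rep(3, 20), rep(sqrt(16 / 1100), 30),
           c(rep(sqrt(2) / 6, 3), sqrt(1 / 12), rep(sqrt(0.5), 8), 3, 3))
  )
}

# planted solubility: sigmoid of local and long-range neighbourhood terms
planted_solubility <- function(X, C, spec) {
  mom <- generator_feature_moments()
  Z <- sweep(sweep(X, 2, mom$mean, "-"), 2, mom$sd, "/")
  L <- nrow(Z)
  sep <- abs(row(C) - col(C))
  W_loc <- (sep <= 2) * 1               # includes self
  W_lr <- (C > 0 & sep > 2) * 1
  avg_rows <- function(W) {
    deg <- rowSums(W)
    out <- (W %*% Z) / pmax(deg, 1)     # empty neighbourhoods contribute 0
    colMeans(out)
  }
  z_loc <- avg_rows(W_loc)
  z_lr <- avg_rows(W_lr)
  logit <- spec$local_gain * sum(spec$w_loc * z_loc) +
    spec$longrange_gain * sum(spec$w_lr * z_lr) + spec$bias
  list(target = stats::plogis(logit), logit = logit)
}

rdirichlet1 <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}

#' Generate one complete synthetic protein
#'
#' Draws a uniform random sequence, a conformation (true contacts at the
#' spec cutoff), a noisy predicted contact map, and all five feature groups
#' with their raw file payloads; the solubility target comes from the
#' planted neighbourhood function.  All stored values are pre-quantized to
#' the precision the fixture writers print, so
#' [write_fixture_files()] followed by the parsers recovers them exactly.
#' The same seed always reproduces the same protein.
#'
#' @param spec a [synthetic_protein_spec()].
#' @param seed integer seed for this protein.
#' @param id identifier.
#' @return a `synthetic_protein`: list with `id`, `sequence`, `coords`,
#'   `contacts` (binary true map), `pmap` (predicted probabilities),
#'   `features` (unstandardized `node_features`), `target`, `logit` and the
#'   raw `payload` used by the fixture writers.
#' @export
generate_synthetic_protein <- function(spec = synthetic_protein_spec(),
                                       seed = 1L, id = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(id)) id <- sprintf("synth_%06d", seed %% 1000000L)
  L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  sequence <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  coords <- generate_conformation(L, spec)
  C <- contact_map_from_structure(coords, spec$contact_cutoff)
  lam <- spec$noise
  if (lam > 0) {
    B <- matrix(0, L, L)
    B[upper.tri(B)] <- rbeta(L * (L - 1) / 2, 2, 5)
    B <- B + t(B)
    P <- pmin(pmax((1 - lam) * C + lam * B, 0), 1)
    diag(P) <- 0
    P <- round(P, 6)                    # fixture print precision
  } else {
    P <- C
  }
  # raw payloads, quantized to what the writers print
  pssm <- matrix(pmin(pmax(round(rnorm(L * 20, 0, 3)), -12), 12), L, 20)
  hmm_p <- matrix(rbeta(L * 30, 2, 8), L, 30)
  hmm_code <- round(-1000 * log2(hmm_p))
  hmm_q <- 2^(-hmm_code / 1000)
  ss3 <- t(vapply(seq_len(L), function(i) round(rdirichlet1(3), 3), numeric(3)))
  asa <- round(runif(L), 3)
  angles <- matrix(round(runif(L * 4, -180, 180), 1), L, 4)
  hse <- matrix(pmin(pmax(round(rnorm(L * 2, 10, 3)), 0), 30), L, 2)
  sc <- matrix(0, L, 8)
  for (a in 1:4) {
    rad <- angles[, a] * pi / 180
    sc[, 2 * a - 1] <- sin(rad)
    sc[, 2 * a] <- cos(rad)
  }
  spd <- cbind(ss3, asa, sc, hse)
  colnames(spd) <- SPD33_FEATURES
  groups <- list(encode_blosum62(sequence), encode_aaphy7(sequence),
                 feature_group("PSSM", pssm), feature_group("HMM", hmm_q),
                 feature_group("SPIDER3", spd))
  features <- assemble_features(groups)
  planted <- planted_solubility(as.matrix(features), C, spec)
  structure(list(id = id, sequence = sequence, coords = coords,
                 contacts = C, pmap = P, features = features,
                 target = planted$target, logit = planted$logit,
                 payload = list(pssm = pssm, hmm_code = hmm_code,
                                ss3 = ss3, asa = asa, angles = angles,
                                hse = hse)),
            class = "synthetic_protein")
}

#' @export
print.synthetic_protein <- function(x, ...) {
  cat(sprintf("<synthetic_protein '%s': L = %d, %d true contacts, target %.3f>\n",
              x$id, nchar(x$sequence), count_contact_pairs(x$contacts),
              x$target))
  invisible(x)
}

#' Simulate a dataset of synthetic proteins
#'
#' @param n number of proteins.
#' @param spec a [synthetic_protein_spec()].
#' @param seed base seed; protein `i` uses a seed derived from `seed` and
#'   `i`, so the whole dataset is reproducible.
#' @return tibble with `id`, `length`, `target` and list-columns `protein`
#'   (the full `synthetic_protein` objects), `features`, `pmap`.
#' @export
simulate_proteins <- function(n, spec = synthetic_protein_spec(), seed = 1L) {
  stopifnot(n >= 1L)
  proteins <- lapply(seq_len(n), function(i) {
    generate_synthetic_protein(spec,
                               seed = (seed * 100003L + i) %% 2147483647L,
                               id = sprintf("synth_%04d", i))
  })
  tibble::tibble(
    id = vapply(proteins, `[[`, character(1), "id"),
    length = vapply(proteins, function(p) nchar(p$sequence), integer(1)),
    target = vapply(proteins, `[[`, numeric(1), "target"),
    protein = proteins,
    features = lapply(proteins, `[[`, "features"),
    pmap = lapply(proteins, `[[`, "pmap")
  )
}

#' Build protein graphs from a simulated table
#'
#' Applies an [edge_scheme()] to each predicted map and (optionally) a
#' feature scaler, returning a training-ready dataset.
#'
#' @param sim output of [simulate_proteins()].
#' @param scheme an [edge_scheme()].
#' @param scaler optional `feature_scaler` applied to every protein.
#' @return a dataset tibble as from [solubility_dataset()].
#' @export
build_graph_dataset <- function(sim, scheme = edge_scheme("full"),
                                scaler = NULL) {
  graphs <- lapply(seq_len(nrow(sim)), function(i) {
    feats <- sim$features[[i]]
    if (!is.null(scaler)) feats <- apply_feature_scaler(scaler, feats)
    build_contact_graph(sim$pmap[[i]], feats, scheme, id = sim$id[i])
  })
  solubility_dataset(graphs, sim$target, ids = sim$id)
}

# ---- fixture writers (external file dialects) ----

hhm_code_to_field <- function(code) {
  ifelse(is.infinite(code) | code >= 65535, "*", as.character(code))
}

#' Write the external-format fixture files for a synthetic protein
#'
#' Emits `<id>.fasta`, `<id>.pssm` (PSI-BLAST ASCII dialect), `<id>.hhm`
#' (HH-suite dialect), `<id>.spd33` (SPIDER3 dialect, angles in degrees)
#' and `<id>.cmap` (sparse contact triplets) into `dir`.  The parsers
#' recover the numeric payload exactly, since the generator quantizes to
#' the printed precision.
#'
#' @param protein a `synthetic_protein`.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths.
#' @export
write_fixture_files <- function(protein, dir) {
  stopifnot(inherits(protein, "synthetic_protein"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- protein$id
  pay <- protein$payload
  seq_chars <- strsplit(protein$sequence, "")[[1]]
  L <- length(seq_chars)
  paths <- c(fasta = file.path(dir, paste0(id, ".fasta")),
             pssm = file.path(dir, paste0(id, ".pssm")),
             hhm = file.path(dir, paste0(id, ".hhm")),
             spd33 = file.path(dir, paste0(id, ".spd33")),
             cmap = file.path(dir, paste0(id, ".cmap")))

  writeLines(c(paste0(">", id),
               substring(protein$sequence, seq(1, L, 60),
                         pmin(seq(1, L, 60) + 59, L))),
             paths["fasta"])

  header <- paste0("           ",
                   paste(sprintf("%3s", AA_ALPHABET), collapse = " "))
  rows <- vapply(seq_len(L), function(i) {
    sprintf("%5d %s %s", i, seq_chars[i],
            paste(sprintf("%3d", pay$pssm[i, ]), collapse = " "))
  }, character(1))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               header, rows, ""), paths["pssm"])

  em_order <- paste(sprintf("%s", sort(AA_ALPHABET)), collapse = "\t")
  hhm_rows <- character(0)
  for (i in seq_len(L)) {
    hhm_rows <- c(hhm_rows,
      paste(c(seq_chars[i], i,
              hhm_code_to_field(pay$hmm_code[i, 1:20])), collapse = "\t"),
      paste(hhm_code_to_field(pay$hmm_code[i, 21:30]), collapse = "\t"))
  }
  writeLines(c("HHsearch 1.5",
               paste0("NAME  ", id),
               sprintf("LENG  %d match states", L),
               "",
               paste0("HMM\t", em_order),
               paste("\tM->M", "M->I", "M->D", "I->M", "I->I", "D->M",
                     "D->D", "Neff", "Neff_I", "Neff_D", sep = "\t"),
               hhm_rows, "//"), paths["hhm"])

  ss_letter <- c("C", "E", "H")[max.col(pay$ss3, ties.method = "first")]
  spd_rows <- vapply(seq_len(L), function(i) {
    sprintf("%d %s %s %.3f %.1f %.1f %.1f %.1f %.1f %.1f %.3f %.3f %.3f",
            i, seq_chars[i], ss_letter[i], pay$asa[i],
            pay$angles[i, 1], pay$angles[i, 2], pay$angles[i, 3],
            pay$angles[i, 4], pay$hse[i, 1], pay$hse[i, 2],
            pay$ss3[i, 1], pay$ss3[i, 2], pay$ss3[i, 3])
  }, character(1))
  writeLines(c("# SEQ SS ASA Phi Psi Theta(i-1=>i+1) Tau(i-2=>i+2) HSEa_up HSEa_down P(C) P(E) P(H)",
               spd_rows), paths["spd33"])

  write_contact_triplets(protein$pmap, paths["cmap"])
  paths
}

#' Write a Calpha trace as a minimal PDB file
#'
#' One ATOM record per residue (CA atoms only, chain A, occupancy 1).
#' Intended for synthetic fixtures and round-trip tests of the structure
#' reader.
#'
#' @param coords L x 3 coordinate matrix.
#' @param path output file.
#' @param sequence optional residue sequence for the residue names.
#' @export
write_ca_pdb <- function(coords, path, sequence = NULL) {
  coords <- as.matrix(coords)
  L <- nrow(coords)
  res3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
            X = "UNK")
  seq_chars <- if (is.null(sequence)) rep("G", L) else
    strsplit(toupper(sequence), "")[[1]]
  lines <- vapply(seq_len(L), function(i) {
    sprintf("ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, res3[[seq_chars[i]]], i,
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
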
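test_that("BLOSUM62 encoding matches the canonical substitution table", {
  g <- encode_blosum62("A")
  expect_s3_class(g, "feature_group")
  expect_equal(dim(g$values), c(1L, 20L))
  # alanine row in NCBI column order A R N D C ...
  expect_equal(unname(g$values[1, 1:5]), c(4, -1, -2, -2, 0))

  skip_if_not_installed("Biostrings")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- BLOSUM62[aas, aas]
  enc <- encode_blosum62(paste(aas, collapse = ""))$values
  expect_equal(unname(enc), unname(ref))
})

test_that("lookup encoders handle X, repeats and bad residues", {
  expect_equal(unname(encode_blosum62("X")$values), matrix(0, 1, 20))
  expect_equal(unname(encode_aaphy7("X")$values), matrix(0, 1, 7))
  aa2 <- encode_aaphy7("AA")$values
  expect_equal(aa2[1, ], aa2[2, ])
  expect_equal(dim(encode_aaphy7("ACDEFGHIKL")$values), c(10L, 7L))
  expect_equal(dim(encode_blosum62("ACDEFGHIKL")$values), c(10L, 20L))
  expect_error(encode_blosum62("ACB"), "position 3")
  expect_error(encode_aaphy7("ZAC"), "position 1")
})

test_that("profile parsers round-trip the fixture writers exactly", {
  p <- generate_synthetic_protein(tiny_spec(), seed = 11, id = "rt")
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(p, dir)

  pssm <- read_profile("PSSM", paths[["pssm"]])
  expect_equal(unname(pssm$values), unname(p$payload$pssm))

  hmm <- read_profile("HMM", paths[["hhm"]])
  Xf <- as.matrix(p$features)
  expect_equal(unname(hmm$values), unname(Xf[, 48:77]), tolerance = 1e-12)

  spd <- read_profile("SPIDER3", paths[["spd33"]])
  expect_equal(dim(spd$values), c(nchar(p$sequence), 14L))
  expect_equal(unname(spd$values), unname(Xf[, 78:91]), tolerance = 1e-12)

  cm <- read_contact_map(paths[["cmap"]], L = nchar(p$sequence))
  expect_equal(cm, p$pmap, tolerance = 1e-9)

  seqs <- read_fasta_sequences(paths[["fasta"]])
  expect_equal(unname(seqs), p$sequence)
})

test_that("HMM parser decodes sentinels and reports malformed records", {
  txt <- c("HHsearch 1.5", "NAME x", "HMM\tA\tC", "\tM->M",
           paste(c("A", "1", rep("*", 20)), collapse = "\t"),
           paste(rep("1000", 10), collapse = "\t"),
           paste(c("C", "2", rep("2000", 19), "65535"), collapse = "\t"),
           paste(rep("*", 10), collapse = "\t"),
           "//")
  g <- parse_profile("HMM", txt)
  expect_equal(dim(g$values), c(2L, 30L))
  expect_equal(unname(g$values[1, 1:20]), rep(0, 20))      # all-star row
  expect_equal(unname(g$values[1, 21:30]), rep(2^-1, 10))  # 1000 -> 1/2
  expect_equal(unname(g$values[2, 20]), 0)                 # 65535 sentinel
  expect_equal(unname(g$values[2, 1]), 2^-2)

  truncated <- txt[1:5]
  expect_error(parse_profile("HMM", truncated), "line 5")
  bad <- txt; bad[6] <- paste(rep("xx", 10), collapse = "\t")
  expect_error(parse_profile("HMM", bad), "line 6")
})

test_that("PSSM parser validates numbering and numeric fields", {
  p <- generate_synthetic_protein(tiny_spec(), seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(p, dir)
  lines <- readLines(paths[["pssm"]])
  # drop one data row: numbering becomes non-contiguous
  expect_error(parse_profile("PSSM", lines[-5]), "not contiguous")
  bad <- lines
  tok <- strsplit(trimws(bad[5]), "\\s+")[[1]]
  tok[3] <- "oops" # first score column
  bad[5] <- paste(sprintf("%5s", tok[1]), tok[2], paste(tok[-(1:2)], collapse = " "))
  expect_error(parse_profile("PSSM", bad), "non-numeric")
})

test_that("SPIDER3 parser supports both angle dialects", {
  # degrees dialect: one residue, known angles
  row <- "1 A H 0.512 90.0 0.0 180.0 -90.0 12.0 8.0 0.100 0.200 0.700"
  g <- parse_profile("SPIDER3", c("# header", row))
  v <- g$values[1, ]
  expect_equal(unname(v[1:4]), c(0.1, 0.2, 0.7, 0.512))
  expect_equal(unname(v[5:12]),
               c(1, 0, 0, 1, sin(pi), cos(pi), -1, 0),
               tolerance = 1e-12)
  expect_equal(unname(v[13:14]), c(12, 8))
  # sincos dialect round-trips the same numbers
  row2 <- paste("1 A H 0.512", paste(sprintf("%.6f", v[5:12]), collapse = " "),
                "12.0 8.0 0.100 0.200 0.700")
  g2 <- parse_profile("SPIDER3", row2, angles = "sincos")
  expect_equal(unname(g2$values[1, ]), unname(v), tolerance = 1e-6)
  expect_error(parse_profile("SPIDER3", "1 A H 0.5"), "line 1")
})

test_that("assemble_features concatenates in canonical order", {
  p <- generate_synthetic_protein(tiny_spec(), seed = 7)
  L <- nchar(p$sequence)
  groups <- list(encode_blosum62(p$sequence), encode_aaphy7(p$sequence),
                 feature_group("PSSM", p$payload$pssm),
                 feature_group("HMM", as.matrix(p$features)[, 48:77]),
                 feature_group("SPIDER3", as.matrix(p$features)[, 78:91]))
  all5 <- assemble_features(groups)
  expect_equal(dim(as.matrix(all5)), c(L, 91L))
  expect_equal(all5$group_order,
               c("BLOSUM62", "AAPHY7", "PSSM", "HMM", "SPIDER3"))
  # shuffled input produces identical output
  shuffled <- assemble_features(groups[c(4, 1, 5, 3, 2)])
  expect_equal(as.matrix(shuffled), as.matrix(all5))
  # single group is the identity
  one <- assemble_features(groups[3])
  expect_equal(as.matrix(one), groups[[3]]$values)
  expect_error(assemble_features(groups[c(1, 1)]), "duplicate")
  bad <- c(groups[1], list(feature_group("PSSM", matrix(0, L + 1, 20))))
  expect_error(assemble_features(bad), "length")
})

test_that("feature scaler standardizes with training statistics", {
  nf <- contactsol:::new_node_features(matrix(c(1, 3), 2, 1), "PSSM", FALSE)
  sc <- fit_feature_scaler(list(nf))
  expect_equal(unname(sc$mean), 2)
  expect_equal(unname(sc$sd), 1)
  out <- apply_feature_scaler(sc, nf)
  expect_equal(unname(as.matrix(out)), matrix(c(-1, 1), 2, 1))
  expect_true(out$standardized)

  # constant columns are centered, not divided
  cst <- contactsol:::new_node_features(cbind(c(5, 5, 5), c(1, 2, 3)),
                                        character(0), FALSE)
  sc2 <- fit_feature_scaler(list(cst))
  out2 <- as.matrix(apply_feature_scaler(sc2, cst))
  expect_equal(out2[, 1], rep(0, 3))

  # fitting data becomes zero-mean unit-variance (population variance)
  set.seed(9)
  mats <- lapply(1:3, function(i)
    contactsol:::new_node_features(matrix(rnorm(40, 5, 3), 10, 4),
                                   character(0), FALSE))
  sc3 <- fit_feature_scaler(mats)
  pooled <- do.call(rbind, lapply(mats, function(m)
    as.matrix(apply_feature_scaler(sc3, m))))
  expect_lt(max(abs(colMeans(pooled))), 1e-9)
  popvar <- colMeans(sweep(pooled, 2, colMeans(pooled))^2)
  expect_lt(max(abs(popvar - 1)), 1e-6)

  # idempotence on already-standardized data
  sc4 <- fit_feature_scaler(lapply(mats, function(m) apply_feature_scaler(sc3, m)))
  twice <- as.matrix(apply_feature_scaler(sc4, apply_feature_scaler(sc3, mats[[1]])))
  expect_equal(twice, as.matrix(apply_feature_scaler(sc3, mats[[1]])),
               tolerance = 1e-8)

  expect_error(apply_feature_scaler(sc3, matrix(0, 2, 7)), "columns")
})

test_that("encoder outputs always have the canonical group dimensions", {
  set.seed(31)
  for (rep in 1:10) {
    L <- sample(1:40, 1)
    seq <- paste(sample(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"),
                        L, replace = TRUE), collapse = "")
    expect_equal(ncol(encode_blosum62(seq)$values), 20L)
    expect_equal(ncol(encode_aaphy7(seq)$values), 7L)
    expect_equal(nrow(encode_blosum62(seq)$values), L)
  }
  p <- generate_synthetic_protein(tiny_spec(), seed = 60)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(p, dir)
  expect_equal(ncol(read_profile("PSSM", paths[["pssm"]])$values), 20L)
  expect_equal(ncol(read_profile("HMM", paths[["hhm"]])$values), 30L)
  expect_equal(ncol(read_profile("SPIDER3", paths[["spd33"]])$values), 14L)
})
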
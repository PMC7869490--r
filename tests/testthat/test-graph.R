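test_that("edge schemes produce the required adjacency patterns", {
  # alpha = 0: chain-only graph, 1s exactly at |i - j| in {1, 2}
  P <- random_symmetric_map(5, seed = 1)
  g0 <- build_contact_graph(P, matrix(0, 5, 2), edge_scheme("topk", alpha = 0))
  sep <- abs(row(g0$A) - col(g0$A))
  expect_equal(g0$A, (sep >= 1 & sep <= 2) * 1)

  # full mode: P off-diagonal, chain neighbours (|i - j| <= 2) overwritten
  # to 1 unconditionally, other pairs keep their probability
  P4 <- matrix(0, 4, 4); P4[1, 4] <- P4[4, 1] <- 0.4
  P4[1, 3] <- P4[3, 1] <- 0.2
  gf <- build_contact_graph(P4, matrix(0, 4, 1), edge_scheme("full"))
  expect_equal(gf$A[1, 4], 0.4) # separation 3: predicted probability kept
  expect_equal(gf$A[1, 3], 1)   # separation 2: chain rule wins
  expect_equal(gf$A[1, 2], 1)
  expect_equal(gf$A[2, 3], 1)
  expect_equal(diag(gf$A), rep(0, 4))
  # chain rule wins even when the predicted probability is lower
  P3b <- matrix(0.05, 3, 3); diag(P3b) <- 0
  gfb <- build_contact_graph(P3b, matrix(0, 3, 1), edge_scheme("full"))
  expect_equal(gfb$A[1, 2], 1)

  expect_error(build_contact_graph(P, matrix(0, 4, 2), edge_scheme("full")),
               "rows")
  asym <- P; asym[1, 2] <- asym[1, 2] + 0.2
  expect_error(build_contact_graph(asym, matrix(0, 5, 2), edge_scheme("full")),
               "symmetric")
  expect_error(build_contact_graph(P * 3, matrix(0, 5, 2), edge_scheme("full")),
               "0, 1")
})

test_that("top-k selection matches the brute-force sort oracle", {
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(6:50, 1)
    alpha <- sample(0:7, 1)
    P <- random_symmetric_map(L)
    k <- floor(alpha * L)
    got <- top_contact_pairs(P, k)
    want <- oracle_top_pairs(P, k)
    expect_equal(unname(got), unname(want))
  }
  # deterministic tie-break: (probability desc, i asc, j asc)
  P <- matrix(0, 6, 6)
  for (pr in list(c(1, 4), c(1, 5), c(2, 6))) {
    P[pr[1], pr[2]] <- P[pr[2], pr[1]] <- 0.7
  }
  got <- top_contact_pairs(P, 2)
  expect_equal(unname(got), rbind(c(1L, 4L), c(1L, 5L)))
})

test_that("discrete and continuous weighting differ only in edge values", {
  set.seed(7)
  P <- random_symmetric_map(12)
  gc <- build_contact_graph(P, matrix(0, 12, 1),
                            edge_scheme("topk", alpha = 2, weighting = "continuous"))
  gd <- build_contact_graph(P, matrix(0, 12, 1),
                            edge_scheme("topk", alpha = 2, weighting = "discrete"))
  expect_equal(gc$A > 0, gd$A > 0)
  sep <- abs(row(gd$A) - col(gd$A))
  picked <- gd$A > 0 & sep > 2
  expect_true(all(gd$A[picked] == 1))
  expect_true(all(gc$A[picked] == P[picked]))
  # selected edge count is exactly floor(alpha * L)
  expect_equal(sum(picked) / 2, floor(2 * 12))
})

test_that("top-k edge count is monotone in alpha and saturates", {
  set.seed(8)
  L <- 30
  P <- random_symmetric_map(L)
  P[P == 0] <- 1e-6; diag(P) <- 0 # all pairs eligible
  counts <- vapply(c(0:7, 60), function(a) {
    g <- build_contact_graph(P, matrix(0, L, 1), edge_scheme("topk", alpha = a))
    sum(g$A[upper.tri(g$A)] > 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  n_chain <- sum(abs(row(P) - col(P)) %in% 1:2) / 2
  expect_equal(counts[1], n_chain)
  expect_equal(counts[2] - counts[1], L) # alpha = 1 adds exactly L pairs
  expect_equal(counts[length(counts)], L * (L - 1) / 2) # saturated
})

test_that("normalized adjacency is row-stochastic", {
  # no edges: identity
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  # hand-computed 2 x 2 case
  expect_equal(normalize_adjacency(matrix(c(0, 0.5, 0.5, 0), 2, 2)),
               matrix(c(2, 1, 1, 2) / 3, 2, 2))
  set.seed(5)
  for (rep in 1:50) {
    L <- sample(2:50, 1)
    A <- random_symmetric_map(L)
    Ahat <- normalize_adjacency(A)
    expect_lt(max(abs(rowSums(Ahat) - 1)), 1e-9)
    expect_true(min(Ahat) >= 0)
  }
  expect_error(normalize_adjacency(matrix(-1, 2, 2)), "nonnegative")
})

test_that("structure contacts use a strict Calpha distance cutoff", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  C <- contact_map_from_structure(coords, cutoff = 7.5)
  expect_equal(C[1, 2], 1)
  expect_equal(C[2, 3], 1)
  expect_equal(C[1, 3], 0) # 7.6 >= 7.5: strict inequality
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(0, 3))

  far <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(sum(contact_map_from_structure(far)), 0)
  expect_error(contact_map_from_structure(rbind(c(0, 0, 0))), "at least 2")
})

test_that("contact evaluation computes unordered precision and recall", {
  actual <- matrix(0, 5, 5)
  actual[1, 3] <- actual[3, 1] <- 1
  actual[2, 5] <- actual[5, 2] <- 1
  res <- evaluate_contact_prediction(rbind(c(1, 3), c(1, 4)), actual)
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 0.5)
  # identical sets give 1/1; order of indices inside a pair is irrelevant
  res2 <- evaluate_contact_prediction(rbind(c(3, 1), c(5, 2)), actual)
  expect_equal(res2$precision, 1)
  expect_equal(res2$recall, 1)
  expect_warning(res3 <- evaluate_contact_prediction(matrix(0, 0, 2), actual),
                 "empty")
  expect_equal(res3$precision, 0)
})

test_that("synthetic PDB traces round-trip through the structure reader", {
  spec <- tiny_spec()
  coords <- generate_conformation(40, spec, seed = 3)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "synthetic_trace.pdb")
  write_ca_pdb(coords, path,
               sequence = paste(rep("ACDEFGHIKL", 4), collapse = ""))
  back <- read_ca_coordinates(path, chain = "A")
  expect_equal(nrow(back), 40L)
  expect_equal(unname(back), unname(coords), tolerance = 1e-3) # %8.3f precision
  C1 <- contact_map_from_structure(back)
  C2 <- contact_map_from_structure(coords)
  expect_equal(C1, C2)
})

test_that("contact-map readers handle all three dialects", {
  set.seed(12)
  P <- round(random_symmetric_map(9), 6)
  dir <- withr::local_tempdir()

  dense <- file.path(dir, "dense.cmap")
  writeLines(apply(P, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             dense)
  expect_equal(read_contact_map(dense), P, tolerance = 1e-9)

  trip <- file.path(dir, "trip.cmap")
  write_contact_triplets(P, trip)
  expect_equal(read_contact_map(trip, L = 9), P, tolerance = 1e-9)

  casp <- file.path(dir, "casp.rr")
  idx <- which(upper.tri(P) & P > 0.3, arr.ind = TRUE)
  writeLines(c("PFRMAT RR", "TARGET T0999",
               sprintf("%d %d 0 8 %.6f", idx[, 1], idx[, 2], P[idx]),
               "END"), casp)
  Pc <- read_contact_map(casp, L = 9)
  expect_equal(Pc[idx], P[idx], tolerance = 1e-9)
  expect_equal(Pc, t(Pc))

  # explicit dialect override beats autodetection
  expect_equal(read_contact_map(trip, L = 9, format = "triplet"), P,
               tolerance = 1e-9)
})
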
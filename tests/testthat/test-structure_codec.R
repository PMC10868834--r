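test_that("encode_residue places the selected atoms in the fixed slot layout", {
  atoms <- list(P = c(0, 0, 0), `C4'` = c(1, 0, 0), C2 = c(2, 0, 0),
                C6 = c(3, 0, 0), N9 = c(4, 0, 0))
  g <- encode_residue("G", atoms)
  expect_equal(g$atom_mask, c(1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(g$coords[3, ], c(2, 0, 0))  # C2 in slot 3
  expect_equal(g$coords[4, ], c(3, 0, 0))  # C6 in slot 4
  expect_equal(g$coords[5, ], c(4, 0, 0))  # N9 in slot 5
  expect_equal(g$coords[6:8, ], matrix(0, 3, 3))

  # pyrimidine without its leading phosphate
  u <- encode_residue("U", list(`C4'` = c(1, 1, 1), C2 = c(2, 2, 2),
                                C4 = c(3, 3, 3), N1 = c(4, 4, 4)))
  expect_equal(u$atom_mask, c(0, 1, 0, 0, 0, 1, 1, 1))
  expect_equal(u$coords[1, ], c(0, 0, 0))

  # independent slot lookup for a pyrimidine with toy coordinates
  slots <- c(P = 1, `C4'` = 2, C2 = 6, C4 = 7, N1 = 8)
  atoms_c <- list(P = c(1, 2, 3), `C4'` = c(4, 5, 6), C2 = c(7, 8, 9),
                  C4 = c(10, 11, 12), N1 = c(13, 14, 15))
  cc <- encode_residue("C", atoms_c)
  for (nm in names(atoms_c))
    expect_equal(cc$coords[slots[[nm]], ], atoms_c[[nm]])

  expect_error(encode_residue("X", atoms), "unknown base")
  # atom names outside the selected set are ignored silently
  g2 <- encode_residue("G", c(atoms, list(`O2'` = c(9, 9, 9))))
  expect_equal(g2$coords, g$coords)
})

test_that("PDB round trip preserves coordinates and atom counts", {
  s <- gen_toy_structure("GGAAUUCC", "((....))", seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  expect_length(atom_lines, sum(s$atom_mask))  # 5 atoms per residue here
  # purine residues contribute exactly the 5 named atoms
  res1 <- atom_lines[as.integer(substr(atom_lines, 23, 26)) == 1]
  expect_setequal(trimws(substr(res1, 13, 16)), c("P", "C4'", "C2", "C6", "N9"))
  r <- read_pdb(path)[[1]]
  expect_false(attr(r, "flagged"))
  expect_equal(r$sequence, s$sequence)
  expect_equal(r$coords, s$coords, tolerance = 1e-3)
  expect_equal(r$atom_mask, s$atom_mask)
})

test_that("residues missing atoms drop PDB lines; modified residues flag chains", {
  s <- gen_toy_structure("GGAAUUCC", "((....))", seed = 4)
  s$atom_mask[1, 1] <- 0L
  s$coords[1, 1, ] <- 0
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  atom_lines <- grep("^ATOM", readLines(path), value = TRUE)
  expect_length(atom_lines, sum(s$atom_mask))

  # hand-written file: chain A fine, chain B carries a modified residue
  mod <- c(
    "ATOM      1  P     G A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C4'   G A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  P   7MG B   1       5.000   0.000   0.000  1.00  0.00           P",
    "ATOM      4  C4' 7MG B   1       6.000   0.000   0.000  1.00  0.00           C",
    "TER", "END")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mod, path2)
  chains <- read_pdb(path2)
  expect_length(chains, 2)   # one record per chain, order preserved
  expect_false(attr(chains[[1]], "flagged"))
  expect_true(attr(chains[[2]], "flagged"))
})

test_that("distance tensor matches a brute-force all-pairs oracle", {
  s <- gen_toy_structure("GAU", "...", seed = 9)
  t <- build_distance_tensor(s)
  L <- 3
  worst_d <- 0; worst_m <- 0
  for (i in 1:L) for (j in 1:L) for (p in 1:8) for (q in 1:8) {
    k <- 8 * (p - 1) + q
    mA <- s$atom_mask[i, p] * s$atom_mask[j, q]
    mB <- s$atom_mask[j, p] * s$atom_mask[i, q]
    if (mA + mB == 0) {
      worst_m <- max(worst_m, t$M[i, j, k], abs(t$D[i, j, k]))
    } else {
      dA <- sqrt(sum((s$coords[i, p, ] - s$coords[j, q, ])^2))
      dB <- sqrt(sum((s$coords[j, p, ] - s$coords[i, q, ])^2))
      worst_d <- max(worst_d,
                     abs(t$D[i, j, k] - (dA * mA + dB * mB) / (mA + mB)))
    }
  }
  expect_equal(worst_m, 0)
  expect_lt(worst_d, 1e-12)
})

test_that("channel 1 holds the phosphate-phosphate distance, zero on the self pair", {
  s <- gen_toy_structure("GGGAAAUUCCC", "(((.....)))", seed = 2)
  t <- build_distance_tensor(s)
  L <- t$L
  d_pp <- sqrt(sum((s$coords[1, 1, ] - s$coords[L, 1, ])^2))
  expect_equal(t$D[1, L, 1], d_pp, tolerance = 1e-12)
  expect_equal(t$D[L, 1, 1], t$D[1, L, 1])
  for (p in 1:8) expect_equal(t$D[3, 3, 8 * (p - 1) + p], 0)
})

test_that("tensor invariants hold across fixtures and under rigid motions", {
  for (seed in 1:5) {
    L <- 10 + seed
    db <- paste(c(rep("(", 4), rep(".", L - 8), rep(")", 4)), collapse = "")
    sq <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    s <- gen_toy_structure(sq, db, seed = seed)
    t <- build_distance_tensor(s)
    expect_equal(t$D, aperm(t$D, c(2, 1, 3)))
    expect_equal(t$M, aperm(t$M, c(2, 1, 3)))
    expect_true(all(t$D[t$M == 0] == 0))
    th <- 0.3 * seed
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    s2 <- s
    for (i in 1:L) s2$coords[i, , ] <- s$coords[i, , ] %*% R + rep(c(3, -1, 2), each = 8)
    s2$coords[rep(s$atom_mask == 0, 3)] <- 0
    expect_lt(max(abs(build_distance_tensor(s2)$D - t$D)), 1e-9)
  }
})

test_that("masked RMSE has its closed forms and rejects mask mismatches", {
  s <- gen_toy_structure("GGAAUUCC", "((....))", seed = 1)
  a <- build_distance_tensor(s)
  expect_equal(rmse_between(a, a), 0)
  b <- a
  b$D[1, 2, 1] <- b$D[1, 2, 1] + 2
  b$D[2, 1, 1] <- b$D[2, 1, 1] + 2
  idx <- a$M == 1
  expect_equal(rmse_between(a, b), sqrt(mean((a$D[idx] - b$D[idx])^2)))
  # single differing valid entry of 2 Angstrom in a hand-built pair
  mk <- function(v) {
    D <- array(0, c(2, 2, 64)); M <- array(0, c(2, 2, 64))
    M[1, 2, 1] <- M[2, 1, 1] <- 1
    D[1, 2, 1] <- D[2, 1, 1] <- v
    structure(list(D = D, M = M, L = 2L), class = "distance_tensor")
  }
  expect_equal(rmse_between(mk(5), mk(3)), 2.0)
  bad <- a; bad$M[1, 2, 2] <- 0; bad$M[2, 1, 2] <- 0
  expect_error(rmse_between(a, bad), "mask")
})

test_that("embedding reconstructs coordinates up to rigid motion", {
  s <- gen_toy_structure("GGGAAAUUCCC", "(((.....)))", seed = 3)
  t <- build_distance_tensor(s)
  e <- embed_structure(t, s$sequence)
  vm <- as.vector(t(s$atom_mask)) == 1
  Xo <- matrix(aperm(s$coords, c(2, 1, 3)), ncol = 3)[vm, ]
  Xe <- matrix(aperm(e$coords, c(2, 1, 3)), ncol = 3)[vm, ]
  rmsd <- min(superpose_rmsd(Xe, Xo),
              superpose_rmsd(Xe %*% diag(c(1, 1, -1)), Xo))
  expect_lt(rmsd, 1e-3)
  expect_true(all(diff(attr(e, "stress_trace")) <= 1e-12))
  expect_error(embed_structure(
    structure(list(D = array(0, c(2, 2, 64)), M = array(0, c(2, 2, 64)),
                   L = 2L), class = "distance_tensor"), "GG"),
    "mask|embed")
})

test_that("exact distances of 4 points in general position embed exactly", {
  # four single-atom residues (P only)
  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 5))
  coords <- array(0, c(4, 8, 3)); mask <- matrix(0L, 4, 8)
  for (i in 1:4) { coords[i, 1, ] <- X[i, ]; mask[i, 1] <- 1L }
  s <- rna_structure("AAAA", coords, mask)
  e <- embed_structure(build_distance_tensor(s), "AAAA")
  Xe <- t(sapply(1:4, function(i) e$coords[i, 1, ]))
  rmsd <- min(superpose_rmsd(Xe, X), superpose_rmsd(Xe %*% diag(c(1, 1, -1)), X))
  expect_lt(rmsd, 1e-6)
})

test_that("refinement stress decreases monotonically on noisy distances", {
  s <- gen_toy_structure("GGAAUUCC", "((....))", seed = 6)
  t <- build_distance_tensor(s)
  set.seed(1)
  noise <- array(stats::rnorm(length(t$D), sd = 0.1), dim(t$D))
  noise <- (noise + aperm(noise, c(2, 1, 3))) / 2
  t$D <- pmax(t$D + noise * t$M, 0)
  t$D <- (t$D + aperm(t$D, c(2, 1, 3))) / 2 * t$M
  e <- embed_structure(t, s$sequence, max_iter = 300)
  trace <- attr(e, "stress_trace")
  expect_gt(length(trace), 5)
  expect_true(all(diff(trace) <= 1e-12))
})
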
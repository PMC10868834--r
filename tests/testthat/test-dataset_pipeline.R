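toy_chain <- function(L, seed = 1, shift = c(0, 0, 0)) {
  db <- paste(rep(".", L), collapse = "")
  sq <- paste(rep(c("G", "A", "U", "C"), length.out = L), collapse = "")
  s <- gen_toy_structure(sq, db, seed = seed)
  s$coords <- s$coords + rep(shift, each = L * 8)
  s$coords[rep(s$atom_mask == 0, 3)] <- 0
  s
}

test_that("corpus filtering applies the rules and logs rejections", {
  ok14 <- toy_chain(14)
  ok7a <- toy_chain(7, seed = 2); ok7b <- toy_chain(8, seed = 3)
  short13 <- toy_chain(13)
  flagged <- toy_chain(14); attr(flagged, "flagged") <- TRUE
  e <- list(
    list(id = "keep14", chains = list(ok14), method = "xray"),
    list(id = "short13", chains = list(short13), method = "xray"),
    list(id = "multi7", chains = list(ok7a, ok7b), method = "nmr"),
    list(id = "modified", chains = list(flagged), method = "xray"),
    list(id = "cryoem", chains = list(ok14), method = "cryo-em"),
    list(id = "dup3", chains = list(ok7a, ok7a, ok7b), method = "xray"),
    list(id = "lowres", chains = list(ok14), method = "xray",
         resolution = 4.5))
  kept <- filter_structures(e)
  expect_setequal(vapply(kept, `[[`, "", "id"), c("keep14", "multi7"))
  log <- attr(kept, "log")
  expect_equal(log$rule[log$id == "short13"], "v_min_length")
  expect_equal(log$rule[log$id == "modified"], "iv_residues")
  expect_equal(log$rule[log$id == "dup3"], "vi_unique_chains")
  expect_equal(log$rule[log$id == "cryoem"], "ii_method")
  expect_equal(log$rule[log$id == "lowres"], "i_resolution")
})

# independent Gotoh (affine-gap) global alignment oracle
gotoh_score <- function(a, b, match = 1, mismatch = -1, gap_open = -1,
                        gap_ext = 0) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + gap_ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + gap_ext * (j - 2)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    # gap runs may follow a gap in the other sequence (new gap opening)
    X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_ext,
                   Y[i - 1, j] + gap_open)
    Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_ext,
                   X[i, j - 1] + gap_open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

test_that("similarity scoring matches an independent dynamic-programming oracle", {
  expect_equal(similarity_score("GGAACC", "GGAACC"), 1.0)
  # the length-2 fully mismatching pair scores -1 under this scheme
  expect_equal(similarity_score("AG", "CU"),
               gotoh_score("AG", "CU") / 2)
  expect_equal(gotoh_score("AG", "CU"), -2)
  set.seed(21)
  for (r in 1:8) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1), TRUE),
               collapse = "")
    expect_equal(similarity_score(a, b),
                 gotoh_score(a, b) / max(nchar(a), nchar(b)),
                 tolerance = 1e-12)
  }
  # multichain: chain scores sum before normalization
  expect_equal(similarity_score(c("GGGG", "AAAA"), c("GGGG", "AAAA")), 1.0)
})

test_that("complete-linkage clustering respects the similarity cutoff", {
  S1 <- matrix(1, 4, 4)
  expect_equal(length(unique(cluster_sequences(S1))), 1L)
  S2 <- diag(1, 4); S2[1, 2] <- S2[2, 1] <- 1; S2[3, 4] <- S2[4, 3] <- 1
  cl <- cluster_sequences(S2)
  expect_equal(cl[1], cl[2]); expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
  # agreement with a direct reference hclust/cutree call
  set.seed(22)
  S <- matrix(runif(36), 6); S <- (S + t(S)) / 2; diag(S) <- 1
  ref <- stats::cutree(stats::hclust(stats::as.dist(1 - S), "complete"),
                       h = 0.3)
  expect_equal(cluster_sequences(S, 0.7), ref)
})

test_that("cluster-level splits put anchors in test and leak nothing", {
  man <- fixture_manifest()
  cl <- man$clusters
  sp <- split_by_cluster(cl, test_anchor_ids = c(1L, 2L), seed = 3)
  expect_true(all(sp[cl %in% cl[1:2]] == "test"))
  for (c in unique(cl)) expect_length(unique(sp[cl == c]), 1L)
  expect_equal(audit_split_leakage(man$similarity, sp), 0L)
  expect_identical(sp, split_by_cluster(cl, c(1L, 2L), seed = 3))
})

test_that("chain crops flag contacts at the 3.3 Angstrom threshold", {
  # two parallel single-atom-ish chains at controlled separation
  mk <- function(L, offset_y, seed) {
    coords <- array(0, c(L, 8, 3)); mask <- matrix(0L, L, 8)
    for (i in 1:L) {
      coords[i, 1, ] <- c(4 * i, offset_y, 0)
      coords[i, 2, ] <- c(4 * i + 1.5, offset_y, 0)
      mask[i, 1:2] <- 1L
    }
    rna_structure(paste(rep("A", L), collapse = ""), coords, mask,
                  id = paste0("chain", seed))
  }
  a <- mk(10, 0, 1)
  b_close <- mk(10, 3.0, 2)    # 3.0 A away -> contact
  b_far <- mk(10, 3.4, 3)      # 3.4 A away -> no contact
  r1 <- select_chain_and_crop(list(a, b_close), max_len = 100, seed = 5)
  expect_true(all(r1$crop$contact_flags))
  r2 <- select_chain_and_crop(list(a, b_far), max_len = 100, seed = 5)
  expect_false(any(r2$crop$contact_flags))
  # crop of a long chain: window length, and the 5% keep rule
  long <- mk(120, 0, 4)
  r3 <- select_chain_and_crop(list(long), max_len = 100, seed = 6)
  expect_equal(r3$crop$length, 100L)
  expect_equal(nchar(r3$substructure$sequence), 100L)
  # 6 contacts out of 100 -> kept == FALSE
  expect_false(mean(c(rep(TRUE, 6), rep(FALSE, 94))) < 0.05)
})

test_that("two-stage sampling weights are uniform over clusters then by length", {
  w <- sampling_weights(c(1, rep(2, 9)), rep(50, 10))
  expect_equal(w[1], 0.5)
  w2 <- sampling_weights(c(1, 1), c(200, 100))
  expect_equal(w2[1] / w2[2], 2)
  man <- fixture_manifest()
  w3 <- sampling_weights(man$clusters,
                         vapply(man$entries, `[[`, 1, "length"))
  expect_equal(sum(w3), 1, tolerance = 1e-12)
})

test_that("simulated SHAPE reflects positional deviation and rigid invariance", {
  s <- gen_toy_structure("GGGGGAAAAACCCCC", "(((((.....)))))", seed = 31)
  same <- list(s, s)
  expect_equal(simulate_shape(s, same), rep(0, 15))
  # one residue rigidly displaced by d in every drift -> value d there
  d <- 2.5
  drift <- s
  drift$coords[8, , ] <- drift$coords[8, , ] + rep(c(d, 0, 0), each = 8)
  drift$coords[rep(s$atom_mask == 0, 3)] <- 0
  sh <- simulate_shape(s, list(drift, drift))
  expect_gt(sh[8], 0.8 * d)  # superposition spreads a little mass
  expect_lt(max(sh[-8]), sh[8])
  # rigid motion of the drift set does not change the profile
  th <- 0.8; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  drift_rot <- drift
  for (i in 1:15) drift_rot$coords[i, , ] <- drift$coords[i, , ] %*% R + 5
  drift_rot$coords[rep(s$atom_mask == 0, 3)] <- 0
  expect_equal(simulate_shape(s, list(drift_rot, drift_rot)), sh,
               tolerance = 1e-6)
  # loops drift further than stems
  dr <- gen_drift(s, target_rmsd = 3, n_variants = 6, seed = 32)
  sh2 <- simulate_shape(s, dr)
  pt <- parse_dotbracket("(((((.....)))))")
  expect_gt(mean(sh2[pt == 0]), mean(sh2[pt > 0]))
  expect_error(simulate_shape(s, list()), "drift")
})

test_that("experimental SHAPE rescaling is a rank-preserving quantile map", {
  set.seed(33)
  ref <- rgamma(500, 2, 1)
  x <- sort(sample(ref, 100))
  expect_equal(rescale_experimental_shape(x, ref), x, tolerance = 0.2)
  # median maps to the reference median
  y <- rnorm(101)
  out <- rescale_experimental_shape(y, ref)
  expect_equal(out[which(rank(y) == 51)], stats::median(ref),
               tolerance = 0.05)
  # invariant to monotone transforms of the input
  expect_equal(rescale_experimental_shape(exp(y), ref), out)
  # constant reference collapses everything onto that constant
  expect_equal(rescale_experimental_shape(y, rep(3.3, 10)), rep(3.3, 101))
})

test_that("homolog loading filters by E-value, insertions and mutations", {
  q <- "GGAAUUCC"
  lines <- c(
    "GGAAUACC 0.001",     # valid: one substitution
    "GGAAUUCC 0.001",     # identical -> dropped
    "GG-AUACC 0.005",     # valid: deletion + substitution
    "GGAAUACC 0.02",      # E too high -> dropped
    "GGAAUACCA 0.001",    # length mismatch (insertion) -> dropped
    "GG-AUUCC 0.001")     # deletion only -> dropped
  path <- withr::local_tempfile()
  writeLines(lines, path)
  hs <- suppressMessages(load_homologs(path, q))
  expect_s3_class(hs, "homolog_set")
  expect_length(hs$rows, 50)
  kept <- hs$rows[!is.na(hs$e_values)]
  expect_length(kept, 2)
  expect_true(all(!grepl("-", kept)))      # gaps became N
  expect_equal(kept[2], "GGNAUACC")
  expect_equal(sum(hs$rows == q & is.na(hs$e_values)), 48)
})
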
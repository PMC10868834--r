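# ---------------------------------------------------------------------------
# Synthetic RNA-like fixtures: idealized helices + loop arcs, drift variants
# at controlled RMSD, homolog alignments and flexibility-correlated SHAPE.
# Realism is not the goal; geometric and statistical consistency is.
# ---------------------------------------------------------------------------

# frozen geometry constants (Angstrom / radians)
TOY_RISE <- 3.4        # helical rise per base pair
TOY_TWIST <- 32 * pi / 180
TOY_RADIUS <- 5.0      # paired C4'-C4' chord = 10 A
TOY_LOOP_SPACING <- 6.0
TOY_JITTER <- 0.15

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  force(code)
}

#' Parse a dot-bracket string into a pair table
#' @param db dot-bracket string (nested, characters `(`, `)`, `.`).
#' @return integer vector, `pt[i]` = paired position or 0.
#' @export
parse_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced brackets")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("unexpected character: ", ch[i])
  }
  if (length(stack) > 0) stop("unbalanced brackets")
  pt
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Lay out C4' backbone points and per-residue inward directions for a
# nested secondary structure.  Stems are ideal helices (fixed rise/twist),
# loops are circular arcs; exterior residues run along a line.
toy_backbone <- function(pt) {
  L <- length(pt)
  pos <- matrix(NA_real_, L, 3)
  ee <- matrix(NA_real_, L, 3)

  helix <- function(i, j, o, d, u1) {
    u2 <- unit(cross3(d, u1))
    h <- 0
    while (i + h < j - h && pt[i + h] == j - h) h <- h + 1
    for (t in seq_len(h) - 1) {
      th <- TOY_TWIST * t
      r1 <- cos(th) * u1 + sin(th) * u2
      c0 <- o + TOY_RISE * t * d
      pos[i + t, ] <<- c0 + TOY_RADIUS * r1
      ee[i + t, ] <<- -r1
      pos[j - t, ] <<- c0 - TOY_RADIUS * r1
      ee[j - t, ] <<- r1
    }
    i2 <- i + h; j2 <- j - h
    if (i2 > j2) return(invisible())
    # enclosed loop: elements are unpaired residues or child helices
    elems <- list(); k <- i2
    while (k <= j2) {
      if (pt[k] == 0) { elems[[length(elems) + 1]] <- c(k, k); k <- k + 1 }
      else { elems[[length(elems) + 1]] <- c(k, pt[k]); k <- pt[k] + 1 }
    }
    m <- length(elems)
    th_h <- TOY_TWIST * (h - 1)
    u1h <- cos(th_h) * u1 + sin(th_h) * u2   # exit phase of the stem
    u2h <- unit(cross3(d, u1h))
    loop_r <- max(TOY_RADIUS, m * TOY_LOOP_SPACING / (2 * pi))
    cl <- o + (h * TOY_RISE + loop_r * 0.8) * d
    for (e in seq_len(m)) {
      phi <- 2 * pi * e / (m + 1)
      dir <- cos(phi) * u1h + sin(phi) * u2h
      p <- cl + loop_r * dir
      if (elems[[e]][1] == elems[[e]][2]) {
        pos[elems[[e]][1], ] <<- p
        ee[elems[[e]][1], ] <<- -dir
      } else {
        helix(elems[[e]][1], elems[[e]][2], p, dir, d)
      }
    }
    invisible()
  }

  # exterior walk along +x; child helices grow along +y
  x <- 0; k <- 1
  while (k <= L) {
    if (pt[k] == 0) {
      pos[k, ] <- c(x, 0, 0); ee[k, ] <- c(0, -1, 0)
      x <- x + TOY_LOOP_SPACING; k <- k + 1
    } else {
      helix(k, pt[k], c(x, 2, 0), c(0, 1, 0), c(1, 0, 0))
      x <- x + 2 * TOY_RADIUS + TOY_LOOP_SPACING
      k <- pt[k] + 1
    }
  }
  list(pos = pos, e = ee)
}

#' Generate an RNA-like toy structure from a secondary structure
#'
#' Paired regions sit on an idealized double helix (fixed rise and twist),
#' loops on circular arcs.  All five selected atoms per residue are placed
#' with a fixed intra-residue template in the local backbone frame, plus a
#' small seeded jitter, so every slot of the 8-slot layout that the base
#' type allows is populated.
#'
#' @param sequence string over A,C,G,U (length must match `dotbracket`).
#' @param dotbracket nested dot-bracket secondary structure.
#' @param seed integer seed controlling the jitter.
#' @param jitter coordinate jitter SD in Angstrom.
#' @return `rna_structure`.
#' @export
gen_toy_structure <- function(sequence, dotbracket, seed = 1L,
                              jitter = TOY_JITTER) {
  letters_ <- strsplit(sequence, "")[[1]]
  pt <- parse_dotbracket(dotbracket)
  if (length(pt) != length(letters_)) stop("sequence/structure length mismatch")
  bb <- toy_backbone(pt)
  L <- length(pt)
  coords <- array(0, c(L, 8, 3))
  mask <- matrix(0L, L, 8)
  local_seed(seed, {
    for (i in 1:L) {
      p0 <- bb$pos[i, ]
      tv <- unit(if (i == 1) bb$pos[2, ] - p0
                 else if (i == L) p0 - bb$pos[L - 1, ]
                 else bb$pos[i + 1, ] - bb$pos[i - 1, ])
      e0 <- bb$e[i, ]
      e0 <- unit(e0 - sum(e0 * tv) * tv)
      nv <- unit(cross3(tv, e0))
      atoms <- list(`C4'` = p0,
                    P = if (i == 1) p0 - 3.0 * tv + 1.2 * nv
                        else (bb$pos[i - 1, ] + p0) / 2 + 1.2 * nv)
      if (is_purine(letters_[i])) {
        atoms$C2 <- p0 + 4.5 * e0 + 0.7 * tv
        atoms$C6 <- p0 + 3.4 * e0 - 0.8 * tv
        atoms$N9 <- p0 + 2.0 * e0 + 0.3 * nv
      } else {
        atoms$C2 <- p0 + 2.2 * e0 + 0.6 * tv
        atoms$C4 <- p0 + 4.0 * e0 - 0.5 * tv
        atoms$N1 <- p0 + 1.8 * e0 + 0.4 * nv
      }
      atoms <- lapply(atoms, function(a) a + stats::rnorm(3, sd = jitter))
      r <- encode_residue(letters_[i], atoms)
      coords[i, , ] <- r$coords
      mask[i, ] <- r$atom_mask
    }
  })
  s <- rna_structure(sequence, coords, mask,
                     id = sprintf("toy_%s_%d", substr(sequence, 1, 6), seed))
  attr(s, "dotbracket") <- dotbracket
  s
}

#' Drift variants of a structure at a controlled RMSD
#'
#' Coordinate-noise stand-in for high-temperature coarse-grained MD: a
#' chain-smoothed Gaussian displacement field (collective motion) plus small
#' per-atom noise, rescaled so the realized all-atom RMSD to the original
#' hits the target exactly.
#'
#' @param structure `rna_structure`.
#' @param target_rmsd target all-atom RMSD in Angstrom (corpus presets used
#'   1, 3, 5 and 10).
#' @param n_variants number of independent drifts (corpus preset 100).
#' @param seed integer seed.
#' @param window smoothing window (residues) for the collective field.
#' @param flex_weights optional per-residue amplitude weights.  When `NULL`
#'   and the structure carries a `dotbracket` attribute, unpaired residues
#'   get weight 1.6 and paired residues 0.7 (loops are more flexible than
#'   stems); otherwise uniform.
#' @return list of `rna_structure`.
#' @export
gen_drift <- function(structure, target_rmsd = 3, n_variants = 5,
                      seed = 1L, window = 5L, flex_weights = NULL) {
  stopifnot(target_rmsd >= 0, n_variants >= 1)
  L <- nchar(structure$sequence)
  if (is.null(flex_weights)) {
    db <- attr(structure, "dotbracket")
    flex_weights <- if (!is.null(db)) {
      pt <- parse_dotbracket(db)
      ifelse(pt == 0, 1.6, 0.7)
    } else rep(1, L)
  }
  stopifnot(length(flex_weights) == L)
  vmask <- structure$atom_mask == 1
  local_seed(seed, {
    lapply(seq_len(n_variants), function(v) {
      if (target_rmsd == 0) {
        s <- structure; s$id <- paste0(structure$id, "_drift", v)
        return(s)
      }
      raw <- matrix(stats::rnorm((L + window) * 3), L + window, 3)
      field <- apply(raw, 2, stats::filter, filter = rep(1 / window, window),
                     sides = 2)
      field <- field[seq_len(L) + window %/% 2, , drop = FALSE]
      field[is.na(field)] <- 0
      U <- array(0, c(L, 8, 3))
      for (c in 1:3)
        U[, , c] <- flex_weights *
          (field[, c] + matrix(stats::rnorm(L * 8, sd = 0.3), L, 8))
      U[rep(!vmask, 3)] <- 0
      disp2 <- apply(U^2, c(1, 2), sum)
      r <- sqrt(mean(disp2[vmask]))
      U <- U * (target_rmsd / r)
      s <- structure
      s$coords <- structure$coords + U
      s$id <- paste0(structure$id, "_drift", v)
      s
    })
  })
}

#' All-atom RMSD between two structures (no superposition)
#' @param a,b `rna_structure` with identical masks.
#' @return RMSD over valid atoms in Angstrom.
#' @export
structure_rmsd <- function(a, b) {
  stopifnot(identical(a$atom_mask, b$atom_mask))
  vm <- a$atom_mask == 1
  d2 <- apply((a$coords - b$coords)^2, c(1, 2), sum)
  sqrt(mean(d2[vm]))
}

#' Generate a synthetic homolog alignment
#'
#' Rows are derived from the query by point substitutions and deletions
#' (never insertions); every row carries at least one substitution, and
#' synthetic E-values below the 0.01 acceptance threshold.
#'
#' @param seq query sequence.
#' @param n number of homolog rows.
#' @param sub_rate per-position substitution probability (must be > 0).
#' @param del_rate per-position deletion probability.
#' @param seed integer seed.
#' @return `homolog_set`: list with `rows` (gapped strings), `e_values`,
#'   `query`.
#' @export
gen_homolog_alignment <- function(seq, n, sub_rate = 0.1, del_rate = 0.05,
                                  seed = 1L) {
  if (n < 1) stop("need n >= 1")
  if (sub_rate <= 0) stop("sub_rate must be positive: rows need >= 1 substitution")
  stopifnot(sub_rate < 1, del_rate >= 0, del_rate < 1)
  q <- strsplit(seq, "")[[1]]
  L <- length(q)
  alts <- function(b) setdiff(c("A", "C", "G", "U"), b)
  local_seed(seed, {
    rows <- character(n)
    for (r in seq_len(n)) {
      row <- q
      subs <- which(stats::runif(L) < sub_rate)
      if (length(subs) == 0) subs <- sample.int(L, 1)
      for (i in subs) row[i] <- sample(alts(q[i]), 1)
      dels <- which(stats::runif(L) < del_rate)
      dels <- setdiff(dels, subs)  # deletions never erase the mutation
      row[dels] <- "-"
      rows[r] <- paste(row, collapse = "")
    }
    structure(list(rows = rows,
                   e_values = stats::runif(n, 1e-8, 0.009),
                   query = seq),
              class = "homolog_set")
  })
}

# random nested secondary structure: one or two hairpins with tails
random_ss <- function(L, rng_unused = NULL) {
  stopifnot(L >= 12)
  two <- L >= 30 && stats::runif(1) < 0.4
  make_hp <- function(len) {
    stem <- sample(3:max(3, min(6, (len - 4) %/% 2)), 1)
    loop <- len - 2 * stem
    c(rep("(", stem), rep(".", loop), rep(")", stem))
  }
  if (!two) {
    t1 <- sample(0:3, 1); hp <- L - t1
    t2 <- 0
    if (hp > 20) { t2 <- sample(0:3, 1); hp <- hp - t2 }
    db <- c(rep(".", t1), make_hp(hp), rep(".", t2))
  } else {
    l1 <- sample(12:(L - 14), 1)
    mid <- sample(1:2, 1)
    l2 <- L - l1 - mid
    db <- c(make_hp(l1), rep(".", mid), make_hp(l2))
  }
  paste(db, collapse = "")
}

random_seq_for_ss <- function(db) {
  pt <- parse_dotbracket(db)
  L <- length(pt)
  s <- character(L)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (i in seq_len(L)) {
    if (nzchar(s[i])) next
    if (pt[i] > i) {
      b <- sample(c("A", "C", "G", "U"), 1)
      s[i] <- b; s[pt[i]] <- comp[[b]]
    } else if (pt[i] == 0) s[i] <- sample(c("A", "C", "G", "U"), 1)
  }
  paste(s, collapse = "")
}

#' Generate a full synthetic fixture dataset
#'
#' Produces toy structures with varied secondary structures, drift sets,
#' simulated SHAPE profiles and homolog alignments, then clusters sequences
#' and assigns leakage-free splits with the dataset-pipeline machinery.
#'
#' @param n_structures number of structures.
#' @param length_range integer length range, e.g. `c(14, 32)`.
#' @param seed integer seed.
#' @param n_drifts drift variants per structure.
#' @param drift_rmsd drift target RMSD (Angstrom).
#' @param with_homologs attach homolog alignments.
#' @return manifest list with `entries` (each: structure, drifts, shape_sim,
#'   homologs, cluster_id, split) and `clusters`/`splits` summaries.
#' @export
make_fixture_dataset <- function(n_structures, length_range = c(14, 32),
                                 seed = 1L, n_drifts = 4, drift_rmsd = 3,
                                 with_homologs = TRUE) {
  stopifnot(n_structures >= 1)
  entries <- local_seed(seed, {
    lapply(seq_len(n_structures), function(i) {
      L <- sample(length_range[1]:length_range[2], 1)
      db <- random_ss(L)
      sq <- random_seq_for_ss(db)
      st <- gen_toy_structure(sq, db, seed = seed * 1000 + i)
      dr <- gen_drift(st, target_rmsd = drift_rmsd, n_variants = n_drifts,
                      seed = seed * 1000 + i)
      list(id = st$id, structure = st, drifts = dr,
           shape_sim = simulate_shape(st, dr),
           homologs = if (with_homologs)
             gen_homolog_alignment(sq, n = 8, seed = seed * 1000 + i)
           else NULL,
           length = L)
    })
  })
  seqs <- vapply(entries, function(e) e$structure$sequence, "")
  S <- similarity_matrix(seqs)
  cl <- cluster_sequences(S)
  split <- split_by_cluster(cl, test_anchor_ids = integer(0),
                            seed = seed, props = c(train = 0.7, val = 0.15,
                                                   test = 0.15))
  for (i in seq_along(entries)) {
    entries[[i]]$cluster_id <- cl[i]
    entries[[i]]$split <- split[i]
  }
  list(entries = entries,
       clusters = cl,
       splits = split,
       similarity = S,
       seed = seed)
}
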
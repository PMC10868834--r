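# ---------------------------------------------------------------------------
# Reduced 8-slot structure representation and distance tensors.
#
# Each residue is represented by up to 5 of 8 atom slots:
#   slot 1: P, slot 2: C4' (shared);
#   slots 3-5: C2, C6, N9 (purines A/G only);
#   slots 6-8: C2, C4, N1 (pyrimidines C/U only).
# Missing atoms carry zero coordinates and mask 0.
# ---------------------------------------------------------------------------

PURINE_SLOTS <- c(P = 1L, `C4'` = 2L, C2 = 3L, C6 = 4L, N9 = 5L)
PYRIMIDINE_SLOTS <- c(P = 1L, `C4'` = 2L, C2 = 6L, C4 = 7L, N1 = 8L)
SLOT_ATOM_NAMES <- list(
  purine = c("P", "C4'", "C2", "C6", "N9", NA, NA, NA),
  pyrimidine = c("P", "C4'", NA, NA, NA, "C2", "C4", "N1"))

is_purine <- function(base) base %in% c("A", "G")

#' Encode one nucleotide as an 8-slot coordinate matrix
#'
#' Places the five selected atoms of a residue (P, C4', and three base atoms
#' that differ between purines and pyrimidines) into the fixed 8-slot layout.
#' Atoms absent from `atoms` get zero coordinates and mask 0; atom names
#' outside the selected set are ignored.
#'
#' @param base single letter, one of "A","C","G","U".
#' @param atoms named list (or 3-column matrix with rownames) of 3D
#'   coordinates in Angstrom; names use PDB conventions ("C4'" or "C4*").
#' @return list with `base`, 8x3 `coords` matrix and length-8 `atom_mask`.
#' @export
encode_residue <- function(base, atoms) {
  if (!is.character(base) || length(base) != 1 || !base %in% c("A", "C", "G", "U"))
    stop("unknown base letter: ", base)
  if (is.matrix(atoms)) {
    nm <- rownames(atoms)
    atoms <- lapply(seq_len(nrow(atoms)), function(i) atoms[i, ])
    names(atoms) <- nm
  }
  names(atoms) <- sub("\\*", "'", names(atoms))  # C4* -> C4'
  slots <- if (is_purine(base)) PURINE_SLOTS else PYRIMIDINE_SLOTS
  coords <- matrix(0, 8, 3)
  mask <- integer(8)
  for (nm in names(atoms)) {
    if (!nm %in% names(slots)) next
    s <- slots[[nm]]
    coords[s, ] <- as.numeric(atoms[[nm]])
    mask[s] <- 1L
  }
  list(base = base, coords = coords, atom_mask = mask)
}

#' Construct a Structure3D object from per-residue encodings
#'
#' @param sequence string over A,C,G,U,N.
#' @param coords L x 8 x 3 array of slot coordinates (Angstrom).
#' @param atom_mask L x 8 binary matrix.
#' @param id free-text label.
#' @return object of class `rna_structure`.
#' @export
rna_structure <- function(sequence, coords, atom_mask, id = "") {
  L <- nchar(sequence)
  stopifnot(L >= 1, identical(dim(coords), c(L, 8L, 3L)),
            identical(dim(atom_mask), c(L, 8L)))
  coords[rep(atom_mask == 0, 3)] <- 0  # masked slots are exactly zero
  structure(list(id = id, sequence = sequence, coords = coords,
                 atom_mask = atom_mask),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure '%s': %d nt, %d placed atoms>\n",
              x$id, nchar(x$sequence), sum(x$atom_mask)))
  invisible(x)
}

structure_from_residues <- function(residues, sequence, id = "") {
  L <- length(residues)
  coords <- array(0, c(L, 8, 3))
  mask <- matrix(0L, L, 8)
  for (i in seq_len(L)) {
    coords[i, , ] <- residues[[i]]$coords
    mask[i, ] <- residues[[i]]$atom_mask
  }
  rna_structure(sequence, coords, mask, id = id)
}

#' Read RNA chains from a PDB file
#'
#' Parses a PDB file with [bio3d::read.pdb] and returns one `rna_structure`
#' per chain, in file order.  Chains containing residues other than
#' A, C, G, U are still returned but flagged invalid (attribute `flagged`),
#' matching the corpus rule that removes sequences with non-A/C/G/U content.
#'
#' @param path PDB file path.
#' @return list of `rna_structure`; each has attribute `flagged` (logical).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  out <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    if (nrow(ca) == 0) { message("skipping empty chain ", ch); next }
    resnos <- unique(ca$resno)
    resid <- vapply(resnos, function(r) ca$resid[ca$resno == r][1], "")
    flagged <- !all(resid %in% c("A", "C", "G", "U"))
    seq_letters <- ifelse(resid %in% c("A", "C", "G", "U"), resid, "N")
    residues <- lapply(seq_along(resnos), function(k) {
      rows <- ca[ca$resno == resnos[k], , drop = FALSE]
      atoms <- lapply(seq_len(nrow(rows)), function(i)
        c(rows$x[i], rows$y[i], rows$z[i]))
      names(atoms) <- rows$elety
      b <- if (seq_letters[k] == "N") "A" else seq_letters[k]
      r <- encode_residue(b, atoms)
      if (seq_letters[k] == "N") { r$coords[] <- 0; r$atom_mask[] <- 0L }
      r
    })
    s <- structure_from_residues(residues, paste(seq_letters, collapse = ""),
                                 id = paste0(basename(path), "_", ch))
    attr(s, "flagged") <- flagged
    out[[length(out) + 1]] <- s
  }
  out
}

#' Write a Structure3D to a PDB file
#'
#' Emits only the atoms with mask 1, using standard atom names for the slot
#' layout, sequential residue numbering and a single chain.
#'
#' @param structure an `rna_structure`.
#' @param path output path.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "rna_structure"))
  seq_letters <- strsplit(structure$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_along(seq_letters)) {
    b <- seq_letters[i]
    names <- SLOT_ATOM_NAMES[[if (is_purine(b)) "purine" else "pyrimidine"]]
    if (sum(structure$atom_mask[i, ]) == 0)
      warning("residue ", i, " has no placed atoms")
    for (s in which(structure$atom_mask[i, ] == 1)) {
      serial <- serial + 1L
      xyz <- structure$coords[i, s, ]
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, names[s], b, i, xyz[1], xyz[2], xyz[3], 1, 0,
        substr(names[s], 1, 1)), con)
    }
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Build the L x L x 64 distance tensor of a structure
#'
#' Channel `k = 8*p + q + 1` (p, q 0-based slot indices) holds the Euclidean
#' distance between slot p of residue i and slot q of residue j.  The raw
#' tensor is symmetrized with its first-two-axes transpose to satisfy
#' `D[i,j,k] == D[j,i,k]`: where both orientations are valid (per the
#' outer-product mask) the two distances are averaged, where only one is
#' valid (e.g. base-atom channels of mixed purine/pyrimidine pairs) that
#' single distance is kept.  The mask is the OR of the two orientations and
#' distances are zero wherever the mask is zero.
#'
#' @param structure an `rna_structure`.
#' @return list of class `distance_tensor` with `D`, `M` (L x L x 64) and `L`.
#' @export
build_distance_tensor <- function(structure) {
  L <- nchar(structure$sequence)
  if (L == 0) stop("empty structure")
  # atom row order: slot fastest, residue slowest -> row (i-1)*8 + p
  X <- matrix(aperm(structure$coords, c(2, 1, 3)), ncol = 3)
  Dfull <- as.matrix(stats::dist(X))                 # 8L x 8L
  arr <- array(Dfull, c(8, L, 8, L))                 # [p, i, q, j]
  D <- aperm(arr, c(2, 4, 3, 1))                     # [i, j, q, p]
  dim(D) <- c(L, L, 64)                              # k = 8*p0 + q0 + 1
  mvec <- as.vector(t(structure$atom_mask))
  Marr <- array(mvec %o% mvec, c(8, L, 8, L))
  M <- aperm(Marr, c(2, 4, 3, 1))
  dim(M) <- c(L, L, 64)
  Dt <- aperm(array(D, c(L, L, 64)), c(2, 1, 3))
  Mt <- aperm(array(M, c(L, L, 64)), c(2, 1, 3))
  nvalid <- M + Mt
  Dsym <- (D * M + Dt * Mt) / pmax(nvalid, 1)
  Msym <- pmax(M, Mt)
  structure(list(D = Dsym * Msym, M = Msym, L = L),
            class = "distance_tensor")
}

#' Masked RMSE between two distance tensors
#'
#' Root-mean-square difference over entries with mask 1; both tensors must
#' share size and mask.
#'
#' @param a,b `distance_tensor` objects.
#' @return RMSE in Angstrom.
#' @export
rmse_between <- function(a, b) {
  if (a$L != b$L) stop("tensors differ in L")
  if (!isTRUE(all.equal(a$M, b$M))) stop("tensors differ in mask")
  idx <- a$M == 1
  if (!any(idx)) return(0)
  sqrt(mean((a$D[idx] - b$D[idx])^2))
}

# --- distance-geometry embedding -------------------------------------------

# Optimal superposition (Kabsch) of X onto Y; returns RMSD and aligned X.
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(t(X0) %*% Y0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Xa <- X0 %*% t(R)
  Xa <- sweep(Xa, 2, cy, "+")
  list(rmsd = sqrt(mean(rowSums((Xa - Y)^2))), aligned = Xa, rotation = R)
}

#' RMSD after optimal superposition
#' @param X,Y n x 3 coordinate matrices (same row order).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(X, Y) kabsch(X, Y)$rmsd

#' Recover 3D coordinates from a distance tensor
#'
#' Distance-geometry embedding: a classical multidimensional-scaling start on
#' the valid inter-atom distances followed by monotone gradient refinement of
#' the stress function.  Because symmetrization averages the two cross-slot
#' distances d(p_i, q_j) and d(q_i, p_j) into one channel value, the stress
#' is defined on that average, so the original configuration is always an
#' exact (zero-stress) solution.  The result is defined up to rigid motion
#' and reflection.
#'
#' @param tensor a `distance_tensor`.
#' @param sequence sequence string (defines slot layout of the output).
#' @param max_iter,tol refinement controls.
#' @return `rna_structure` with attributes `stress` (final value) and
#'   `stress_trace` (per accepted iteration).
#' @export
embed_structure <- function(tensor, sequence, max_iter = 2000, tol = 1e-10) {
  L <- tensor$L
  stopifnot(nchar(sequence) == L)
  if (all(tensor$M == 0)) stop("all-zero mask: nothing to embed")
  # per-residue slot mask from the exact diagonal channels (p == q)
  amask <- matrix(0L, L, 8)
  for (p in 1:8) amask[, p] <- diag(tensor$M[, , 8 * (p - 1) + p])
  valid <- which(t(amask) == 1)          # atom ids in row order (i-1)*8+p
  n <- length(valid)
  if (n < 4) stop("need at least 4 valid atoms to embed")
  aid <- matrix(match(seq_len(8 * L), valid), nrow = 8)   # [p, i] -> atom index
  # Constraint list over channels.  A channel value couples the orientations
  # d(p_i, q_j) and d(p_j, q_i); when both are valid the value is their
  # average, otherwise the single valid distance.  Duplicate channels are
  # removed via a canonical key on the unordered atom-pair set.
  con <- local({
    a1 <- c(); b1 <- c(); a2 <- c(); b2 <- c(); tt <- c()
    seen <- new.env(parent = emptyenv())
    for (i in 1:L) for (j in i:L) {
      for (p in which(amask[i, ] + amask[j, ] > 0)) {
        for (q in which(amask[i, ] + amask[j, ] > 0)) {
          k <- 8 * (p - 1) + q
          oA <- amask[i, p] == 1 && amask[j, q] == 1
          oB <- amask[j, p] == 1 && amask[i, q] == 1
          if (!oA && !oB) next
          pr1 <- if (oA) sort(c(aid[p, i], aid[q, j])) else
            sort(c(aid[p, j], aid[q, i]))
          pr2 <- if (oA && oB) sort(c(aid[p, j], aid[q, i])) else pr1
          if (pr1[1] == pr1[2]) next     # self-distance channel
          key <- paste(sort(c(paste(pr1, collapse = "-"),
                              paste(pr2, collapse = "-"))), collapse = "|")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          a1 <- c(a1, pr1[1]); b1 <- c(b1, pr1[2])
          a2 <- c(a2, pr2[1]); b2 <- c(b2, pr2[2])
          tt <- c(tt, tensor$D[i, j, k])
        }
      }
    }
    list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, t = tt)
  })
  # MDS initialization, treating channel values as individual pair distances
  Dm <- matrix(0, n, n)
  put <- function(a, b, v) { Dm[cbind(a, b)] <<- v; Dm[cbind(b, a)] <<- v }
  put(con$a1, con$b1, con$t); put(con$a2, con$b2, con$t)
  X <- tryCatch(stats::cmdscale(Dm, k = 3), error = function(e) NULL)
  if (is.null(X) || ncol(X) < 3)
    X <- matrix(stats::rnorm(3 * n, sd = 5), n, 3)
  stress_fn <- function(X) {
    d1 <- sqrt(rowSums((X[con$a1, , drop = FALSE] - X[con$b1, , drop = FALSE])^2))
    d2 <- sqrt(rowSums((X[con$a2, , drop = FALSE] - X[con$b2, , drop = FALSE])^2))
    r <- (d1 + d2) / 2 - con$t
    list(value = sum(r^2), d1 = d1, d2 = d2, r = r)
  }
  grad_fn <- function(X, s) {
    w1 <- s$r / pmax(s$d1, 1e-12); w2 <- s$r / pmax(s$d2, 1e-12)
    v1 <- (X[con$a1, , drop = FALSE] - X[con$b1, , drop = FALSE]) * w1
    v2 <- (X[con$a2, , drop = FALSE] - X[con$b2, , drop = FALSE]) * w2
    G <- matrix(0, n, 3)
    add <- function(idx, V) {
      agg <- rowsum(V, idx)
      rows <- as.integer(rownames(agg))
      G[rows, ] <<- G[rows, ] + agg
    }
    add(con$a1, v1); add(con$b1, -v1); add(con$a2, v2); add(con$b2, -v2)
    G
  }
  # monotone gradient descent with adaptive step
  s <- stress_fn(X)
  trace <- s$value
  step <- 1e-3
  for (it in seq_len(max_iter)) {
    G <- grad_fn(X, s)
    gn <- sum(G^2)
    if (gn < tol) break
    repeat {
      Xn <- X - step * G
      sn <- stress_fn(Xn)
      if (sn$value <= s$value || step < 1e-14) break
      step <- step / 2
    }
    if (sn$value > s$value) break
    X <- Xn; s <- sn
    step <- step * 1.3
    trace <- c(trace, s$value)
    if (s$value < tol) break
  }
  coords <- array(0, c(L, 8, 3))
  for (i in 1:L) for (p in which(amask[i, ] == 1))
    coords[i, p, ] <- X[aid[p, i], ]
  out <- rna_structure(sequence, coords, amask, id = "embedded")
  attr(out, "stress") <- s$value
  attr(out, "stress_trace") <- trace
  out
}
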
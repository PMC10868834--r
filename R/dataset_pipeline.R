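# ---------------------------------------------------------------------------
# Data engineering: corpus filtering, sequence-similarity clustering and
# leakage-free splits, chain selection / cropping with contact flags,
# two-stage sampling weights, simulated and rescaled SHAPE, homolog loading.
# ---------------------------------------------------------------------------

#' Filter raw structure entries by the corpus rules
#'
#' Keeps an entry iff (i) all chains are RNA, (ii) the method is X-ray or
#' NMR, (iii) residues are all A/C/G/U, (iv) every chain has >= 14 nt
#' (>= 7 nt when the entry has multiple chains), and (v) entries with 3+
#' chains have pairwise-unique chain sequences.  A resolution < 4 Angstrom
#' filter applies only when resolution metadata is present.  Every rejection
#' is logged with its rule id (attribute `log`).
#'
#' @param entries list; each entry has `id`, `chains` (list of
#'   `rna_structure`), optional `method` ("xray"/"nmr"/...), optional
#'   `resolution` (Angstrom).
#' @return kept entries, with a `log` attribute data frame (id, rule).
#' @export
filter_structures <- function(entries) {
  log <- data.frame(id = character(0), rule = character(0))
  reject <- function(id, rule) {
    log <<- rbind(log, data.frame(id = id, rule = rule))
    FALSE
  }
  keep <- vapply(entries, function(e) {
    seqs <- vapply(e$chains, function(c) c$sequence, "")
    nch <- length(e$chains)
    if (!is.null(e$method) &&
        !tolower(e$method) %in% c("xray", "x-ray", "diffraction", "nmr"))
      return(reject(e$id, "ii_method"))
    if (!is.null(e$resolution) && !is.na(e$resolution) && e$resolution >= 4)
      return(reject(e$id, "i_resolution"))
    if (any(vapply(e$chains, function(c) isTRUE(attr(c, "flagged")), TRUE)) ||
        any(grepl("[^ACGU]", seqs)))
      return(reject(e$id, "iv_residues"))
    min_len <- if (nch > 1) 7 else 14
    if (any(nchar(seqs) < min_len))
      return(reject(e$id, "v_min_length"))
    if (nch >= 3 && anyDuplicated(seqs))
      return(reject(e$id, "vi_unique_chains"))
    TRUE
  }, TRUE)
  out <- entries[keep]
  attr(out, "log") <- log
  out
}

#' Length-normalized global alignment similarity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap
#' opening -1 and neutral gap extension, with the score divided by the
#' length of the longer sequence.  For multi-chain inputs (character
#' vectors) chain scores are summed before normalizing by the larger total
#' length.
#'
#' @param seqA,seqB sequences (single strings, or character vectors for
#'   multi-chain structures).
#' @return similarity score (1 for identical sequences).
#' @export
similarity_score <- function(seqA, seqB) {
  one <- function(a, b) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("U", "T", a)),
      Biostrings::DNAString(gsub("U", "T", b)),
      substitutionMatrix = m, gapOpening = 1, gapExtension = 0,
      type = "global", scoreOnly = TRUE)
  }
  n <- min(length(seqA), length(seqB))
  sc <- sum(vapply(seq_len(n), function(i) one(seqA[i], seqB[i]), 0))
  sc / max(sum(nchar(seqA)), sum(nchar(seqB)))
}

#' Pairwise similarity matrix for a set of sequences
#'
#' Same scoring as [similarity_score], computed with vectorized alignment
#' calls (all patterns against one subject at a time).
#'
#' @param seqs character vector.
#' @return symmetric matrix of [similarity_score] values, unit diagonal.
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  S <- diag(1, n)
  if (n < 2) return(S)
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = FALSE)
  set <- Biostrings::DNAStringSet(gsub("U", "T", seqs))
  lens <- nchar(seqs)
  for (j in 2:n) {
    sc <- Biostrings::pairwiseAlignment(
      set[seq_len(j - 1)], set[[j]],
      substitutionMatrix = m, gapOpening = 1, gapExtension = 0,
      type = "global", scoreOnly = TRUE)
    S[seq_len(j - 1), j] <- S[j, seq_len(j - 1)] <-
      sc / pmax(lens[seq_len(j - 1)], lens[j])
  }
  S
}

#' Complete-linkage sequence clustering at a similarity cutoff
#'
#' Hierarchical clustering on distance `1 - similarity`, cut so that the
#' within-cluster minimum similarity is at least the cutoff.
#'
#' @param score_matrix symmetric similarity matrix.
#' @param cutoff similarity cutoff (default 0.7).
#' @return integer cluster ids.
#' @export
cluster_sequences <- function(score_matrix, cutoff = 0.7) {
  n <- nrow(score_matrix)
  if (n == 1) return(1L)
  d <- stats::as.dist(1 - score_matrix)
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, h = 1 - cutoff)
}

#' Assign whole clusters to train/validation/test splits
#'
#' Anchor entries (e.g. blind-challenge structures) force their clusters into
#' the test split; remaining clusters are shuffled and filled to the target
#' proportions.  No cluster is divided, so no pair of entries above the
#' clustering cutoff crosses splits.
#'
#' @param clusters integer cluster id per entry.
#' @param test_anchor_ids entry indices that must land in the test split.
#' @param seed integer seed.
#' @param props named proportions for train/val/test.
#' @return character vector of split labels per entry.
#' @export
split_by_cluster <- function(clusters, test_anchor_ids = integer(0),
                             seed = 1L,
                             props = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(all(c("train", "val", "test") %in% names(props)))
  props <- props / sum(props)
  anchor_cl <- unique(clusters[test_anchor_ids])
  free_cl <- setdiff(unique(clusters), anchor_cl)
  assign_cl <- stats::setNames(rep("test", length(anchor_cl)), anchor_cl)
  local_seed(seed, {
    free_cl <- sample(free_cl)
    n <- length(clusters)
    counts <- c(train = 0, val = 0,
                test = sum(clusters %in% anchor_cl))
    for (cl in free_cl) {
      sz <- sum(clusters == cl)
      deficit <- props - (counts + sz) / n
      lab <- names(which.max(deficit))
      counts[lab] <- counts[lab] + sz
      assign_cl[as.character(cl)] <- lab
    }
  })
  unname(assign_cl[as.character(clusters)])
}

#' Audit a split for similarity leakage
#' @param score_matrix similarity matrix.
#' @param split split labels per entry.
#' @param cutoff similarity cutoff.
#' @return number of cross-split pairs with similarity >= cutoff.
#' @export
audit_split_leakage <- function(score_matrix, split, cutoff = 0.7) {
  n <- nrow(score_matrix)
  bad <- 0L
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (split[i] != split[j] && score_matrix[i, j] >= cutoff)
        bad <- bad + 1L
  bad
}

# minimum inter-atom distance between one residue and a set of coordinates
min_dist_to <- function(res_xyz, other_xyz) {
  if (nrow(res_xyz) == 0 || nrow(other_xyz) == 0) return(Inf)
  d2 <- outer(rowSums(res_xyz^2), rowSums(other_xyz^2), "+") -
    2 * res_xyz %*% t(other_xyz)
  sqrt(max(0, min(d2)))
}

valid_xyz <- function(structure, residues = seq_len(nchar(structure$sequence))) {
  do.call(rbind, lapply(residues, function(i) {
    s <- which(structure$atom_mask[i, ] == 1)
    structure$coords[i, s, , drop = FALSE][, , , drop = TRUE] |>
      matrix(ncol = 3)
  }))
}

#' Select a chain and crop it to the training window
#'
#' For multi-chain entries a chain is chosen with probability proportional
#' to its length; chains longer than `max_len` get a random contiguous
#' window.  Residues of the crop within 3.3 Angstrom (minimum over the
#' represented atoms) of the remaining structure are flagged as contact
#' nucleotides; the crop is kept only when the contact fraction is below 5%.
#'
#' @param chains list of `rna_structure` (one entry's chains).
#' @param max_len crop window (default 100).
#' @param seed integer seed.
#' @param contact_dist contact threshold in Angstrom.
#' @return list with `substructure`, `crop` (start, length, contact_flags,
#'   kept) and `chain_index`.
#' @export
select_chain_and_crop <- function(chains, max_len = 100, seed = 1L,
                                  contact_dist = 3.3) {
  lens <- vapply(chains, function(c) nchar(c$sequence), 1L)
  local_seed(seed, {
    ci <- if (length(chains) == 1) 1L else
      sample.int(length(chains), 1, prob = lens)
    ch <- chains[[ci]]
    L <- lens[ci]
    if (L > max_len) {
      start <- sample.int(L - max_len + 1, 1)
      len <- max_len
    } else { start <- 1L; len <- L }
    idx <- start:(start + len - 1)
    sub <- rna_structure(substr(ch$sequence, start, start + len - 1),
                         ch$coords[idx, , , drop = FALSE],
                         ch$atom_mask[idx, , drop = FALSE],
                         id = paste0(ch$id, "_crop", start))
    # remaining structure: other chains + the cropped-out part of this chain
    rest <- do.call(rbind, c(
      lapply(chains[-ci], valid_xyz),
      if (len < L) list(valid_xyz(ch, setdiff(seq_len(L), idx)))))
    flags <- if (is.null(rest) || nrow(rest) == 0) rep(FALSE, len) else
      vapply(seq_len(len), function(i)
        min_dist_to(valid_xyz(sub, i), rest) < contact_dist, TRUE)
    kept <- mean(flags) < 0.05
    list(substructure = sub,
         crop = list(start = start, length = len, contact_flags = flags,
                     kept = kept),
         chain_index = ci)
  })
}

#' Two-stage sampling weights: uniform over clusters, length-proportional
#' within each cluster
#'
#' @param cluster_ids integer cluster id per entry.
#' @param lengths sequence length per entry.
#' @return probabilities summing to one.
#' @export
sampling_weights <- function(cluster_ids, lengths) {
  stopifnot(length(cluster_ids) == length(lengths))
  cl <- unique(cluster_ids)
  w <- numeric(length(cluster_ids))
  for (c in cl) {
    idx <- which(cluster_ids == c)
    w[idx] <- (1 / length(cl)) * lengths[idx] / sum(lengths[idx])
  }
  w
}

#' Simulated SHAPE reactivities from drift ensembles
#'
#' Each drift is superposed onto the original (all-valid-atom Kabsch fit);
#' the simulated reactivity of a nucleotide is its per-residue atomic RMSE
#' to the original, averaged over drifts — flexible (loop) residues drift
#' further than paired (stem) residues.
#'
#' @param original `rna_structure`.
#' @param drifts list of `rna_structure` with identical masks.
#' @return numeric vector of length L.
#' @export
simulate_shape <- function(original, drifts) {
  if (length(drifts) == 0) stop("no drift structures supplied")
  L <- nchar(original$sequence)
  vm <- original$atom_mask == 1
  Xo <- valid_xyz(original)
  per_res <- vapply(drifts, function(d) {
    Xd <- valid_xyz(d)
    fit <- kabsch(Xd, Xo)
    err2 <- rowSums((fit$aligned - Xo)^2)
    counts <- rowSums(original$atom_mask)
    idx <- rep(seq_len(L), counts)
    sqrt(as.vector(rowsum(err2, idx)) / counts)
  }, numeric(L))
  rowMeans(per_res)
}

#' Rescale experimental SHAPE onto a simulated reference distribution
#'
#' Quantile mapping: each experimental value is replaced by the simulated
#' reference's quantile at the same (rank-based) percentile, with linear
#' interpolation between reference quantiles.  Depends on the experimental
#' values only through their ranks.
#'
#' @param exp experimental per-nucleotide reactivities.
#' @param sim_reference pooled simulated reactivities.
#' @return rescaled reactivities, same length as `exp`.
#' @export
rescale_experimental_shape <- function(exp, sim_reference) {
  stopifnot(length(sim_reference) >= 1)
  p <- (rank(exp, ties.method = "average") - 0.5) / length(exp)
  stats::quantile(sim_reference, probs = p, names = FALSE, type = 7)
}

#' Load and filter a homolog alignment file
#'
#' Expects one row per line: a gapped aligned sequence and its E-value,
#' whitespace-separated.  Rows are kept when E < 0.01, the row length
#' matches the query (no insertions), and at least one position carries a
#' substitution (a non-gap letter differing from the query).  Gaps become
#' 'N', and the set is padded to `n_rows` with copies of the query.
#'
#' @param path alignment file.
#' @param query query sequence (ungapped).
#' @param n_rows target number of rows (default 50).
#' @return `homolog_set`.
#' @export
load_homologs <- function(path, query, n_rows = 50) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- character(0); evs <- numeric(0)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2) next
    sq <- toupper(f[1]); ev <- as.numeric(f[2])
    if (is.na(ev) || ev >= 0.01) next
    if (nchar(sq) != nchar(query)) {
      message("dropping row with length mismatch (insertions?): ",
              substr(sq, 1, 20), "...")
      next
    }
    qs <- strsplit(query, "")[[1]]
    rs <- strsplit(sq, "")[[1]]
    has_mut <- any(rs %in% c("A", "C", "G", "U") & rs != qs)
    if (!has_mut) next
    rs[rs == "-" | rs == "."] <- "N"
    rows <- c(rows, paste(rs, collapse = ""))
    evs <- c(evs, ev)
  }
  pad <- max(0, n_rows - length(rows))
  structure(list(rows = c(rows, rep(query, pad)),
                 e_values = c(evs, rep(NA_real_, pad)),
                 query = query),
            class = "homolog_set")
}
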
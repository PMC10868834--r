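# ---------------------------------------------------------------------------
# Masked autoregressive generator: 14-channel input stack (sequence bit
# pattern, partial class map, coordinate frames, homolog/SHAPE attention),
# dilated residual network with per-pixel softmax over K distance classes,
# masked cross-entropy training and chain-rule likelihoods.
# ---------------------------------------------------------------------------

NUC_ORDER <- c("G", "C", "A", "U")   # one-hot order: G,C,A,U

nuc_onehot <- function(seq) {
  letters_ <- strsplit(seq, "")[[1]]
  oh <- matrix(0, length(letters_), 4)
  for (b in seq_along(NUC_ORDER)) oh[letters_ == NUC_ORDER[b], b] <- 1
  oh[letters_ == "N" | rowSums(oh) == 0, ] <- 0.25
  oh
}

#' Sequence bit-pattern encoding
#'
#' One-hot encodes each nucleotide (G,C,A,U; N as 0.25 everywhere), tiles to
#' L x L x 4, and stacks with its transpose to an L x L x 8 tensor carrying a
#' unique, direction-aware bit pattern per nucleotide pair.  When `max_len`
#' exceeds L the padded region is filled with -1.
#'
#' @param seq sequence over A,C,G,U,N.
#' @param max_len padded size (default: no padding).
#' @return max_len x max_len x 8 array.
#' @export
encode_sequence_bitpattern <- function(seq, max_len = nchar(seq)) {
  L <- nchar(seq)
  if (L == 0) stop("empty sequence")
  stopifnot(L <= max_len)
  oh <- nuc_onehot(seq)
  out <- array(-1, c(max_len, max_len, 8))
  for (c in 1:4) {
    out[1:L, 1:L, c] <- matrix(oh[, c], L, L)          # row residue i
    out[1:L, 1:L, 4 + c] <- matrix(oh[, c], L, L, byrow = TRUE)  # col residue j
  }
  out
}

#' Encode a partial class-map state as input channels
#'
#' Masked pixels map to (0,...,0); a revealed class c maps to +1 at channel
#' c and -1 elsewhere.
#'
#' @param state L x L integer matrix, `NA` = masked, values in 0..K-1.
#' @param K number of classes.
#' @param max_len padded size (padding encoded as masked, 0).
#' @return max_len x max_len x K array.
#' @export
encode_state_channels <- function(state, K = 3L, max_len = nrow(state)) {
  L <- nrow(state)
  vals <- state[!is.na(state)]
  if (length(vals) && (min(vals) < 0 || max(vals) >= K))
    stop("state value out of range")
  out <- array(0, c(max_len, max_len, K))
  for (k in 0:(K - 1)) {
    ch <- matrix(0, L, L)
    ch[!is.na(state)] <- -1
    ch[!is.na(state) & state == k] <- 1
    out[1:L, 1:L, k + 1] <- ch
  }
  out
}

#' Draw the number of pixels to mask during generator training
#'
#' Truncated normal with mean L^2/2 and standard deviation L^2/4, truncated
#' at two standard deviations, so the draw always lies in `[0, L^2]`.
#'
#' @param L sequence length.
#' @param n number of draws.
#' @return integer vector in `[0, L^2]`.
#' @export
sample_mask_count <- function(L, n = 1L) {
  stopifnot(L >= 1)
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  u <- stats::runif(n, lo, hi)
  x <- L^2 / 2 + (L^2 / 4) * stats::qnorm(u)
  pmin(L^2, pmax(0L, as.integer(round(x))))
}

#' Coordinate frames: diagonal and padding-box channels
#'
#' Channel 1 has ones on the main diagonal; channel 2 draws the border of
#' the L x L box (ones on the border, zeros elsewhere).  The region beyond
#' L is filled with -1.
#'
#' @param L sequence length.
#' @param max_len padded size.
#' @return max_len x max_len x 2 array.
#' @export
make_coordinate_frames <- function(L, max_len = L) {
  stopifnot(L <= max_len)
  out <- array(-1, c(max_len, max_len, 2))
  f1 <- matrix(0, L, L); diag(f1) <- 1
  f2 <- matrix(0, L, L)
  f2[1, ] <- 1; f2[L, ] <- 1; f2[, 1] <- 1; f2[, L] <- 1
  out[1:L, 1:L, 1] <- f1
  out[1:L, 1:L, 2] <- f2
  out
}

#' Random projection parameters for the homolog/SHAPE attention head
#' @param seed integer seed.
#' @param d_qk query/key width (64).
#' @return parameter list.
#' @export
attention_params <- function(seed = 1L, d_qk = 64L) {
  local_seed(seed, list(
    w1 = stats::rnorm(4, sd = 0.5), b1 = 0,
    wq = matrix(stats::rnorm(51 * d_qk, sd = 1 / sqrt(51)), 51, d_qk),
    bq = numeric(d_qk),
    wk = matrix(stats::rnorm(51 * d_qk, sd = 1 / sqrt(51)), 51, d_qk),
    bk = numeric(d_qk),
    d_qk = d_qk))
}

#' Attention map over homologous sequences and SHAPE reactivities
#'
#' Homolog rows (padded to 50 with the query; gaps and N as uniform 0.25
#' one-hots) are projected by a dense layer to an L x 50 array, stacked with
#' the SHAPE column to L x 51, projected to query and key tensors of width
#' 64, and combined by scaled dot-product attention into an L x L map whose
#' rows sum to one.
#'
#' @param homologs `homolog_set` or NULL (query-only).
#' @param shape per-nucleotide reactivities or NULL (zeros).
#' @param params [attention_params].
#' @param query query sequence (used when `homologs` is NULL).
#' @return L x L x 1 array.
#' @export
build_attention_map <- function(homologs, shape, params, query = NULL) {
  if (is.null(homologs)) {
    stopifnot(!is.null(query))
    homologs <- structure(list(rows = character(0), e_values = numeric(0),
                               query = query), class = "homolog_set")
  }
  qseq <- homologs$query
  L <- nchar(qseq)
  rows <- homologs$rows
  if (any(nchar(rows) != L)) stop("homolog length mismatch")
  if (length(rows) > 50) rows <- rows[1:50]
  if (length(rows) < 50) rows <- c(rows, rep(qseq, 50 - length(rows)))
  if (is.null(shape)) shape <- numeric(L)
  stopifnot(length(shape) == L)
  # L x 50 x 4 one-hot -> dense over the base axis -> L x 50
  A <- vapply(rows, function(r) {
    oh <- nuc_onehot(chartr("-.", "NN", r))
    as.vector(oh %*% params$w1 + params$b1)
  }, numeric(L))                       # L x 50
  X <- cbind(A, shape)                 # L x 51
  Q <- X %*% params$wq
  Q <- sweep(Q, 2, params$bq, "+")
  Kt <- X %*% params$wk
  Kt <- sweep(Kt, 2, params$bk, "+")
  S <- Q %*% t(Kt) / sqrt(params$d_qk)
  S <- exp(S - apply(S, 1, max))
  A2 <- S / rowSums(S)
  array(A2, c(L, L, 1))
}

#' Assemble the 14-channel generator input
#'
#' Fixed channel order: 8 sequence, K (=3) state, 2 frames, 1 attention.
#'
#' @param seq_bp L x L x 8 sequence bit pattern.
#' @param state_ch L x L x K state channels.
#' @param frames L x L x 2 coordinate frames.
#' @param attention L x L x 1 attention map (zero-padded to the same size).
#' @param L valid (unpadded) length; defaults to the full array size.
#' @return (padded) L x L x 14 array with attribute `L`.
#' @export
assemble_input <- function(seq_bp, state_ch, frames, attention,
                           L = dim(seq_bp)[1]) {
  d <- dim(seq_bp)[1]
  if (!all(c(dim(state_ch)[1], dim(frames)[1], dim(attention)[1]) == d) ||
      !all(c(dim(seq_bp)[3], dim(state_ch)[3], dim(frames)[3],
             dim(attention)[3]) == c(8, 3, 2, 1)))
    stop("component shape mismatch")
  out <- array(0, c(d, d, 14))
  out[, , 1:8] <- seq_bp
  out[, , 9:11] <- state_ch
  out[, , 12:13] <- frames
  out[, , 14] <- attention
  attr(out, "L") <- L
  out
}

generator_net <- function(channels = 26L, K = 3L) {
  do.call(nn_seq, c(
    list(nn_conv(3, 14, channels, input_layer = TRUE)),
    lapply(1:8, function(i) nn_resblock2(channels, 3, "elu", 2L)),
    list(nn_batchnorm(channels), nn_act("elu"),
         nn_conv(1, channels, K))))
}

#' Generator configuration
#'
#' Defaults mirror the reference optimization setup (batch 500, learning
#' rate 1e-3 with linear warmup and cosine decay, weight decay 0.01); the
#' step counts are exposed as caps for desk-scale runs.
#'
#' @param K classes; `channels` hidden width; `batch`, `lr`, `weight_decay`,
#'   `warmup`, `steps`, `max_len` as usual.
#' @export
gen_config <- function(K = 3L, channels = 26L, batch = 500L, lr = 1e-3,
                       weight_decay = 0.01, warmup = 100000L,
                       steps = 5000000L, max_len = 100L) {
  structure(list(K = as.integer(K), channels = as.integer(channels),
                 batch = as.integer(batch), lr = lr,
                 weight_decay = weight_decay, warmup = as.integer(warmup),
                 steps = as.integer(steps), max_len = as.integer(max_len)),
            class = "gen_config")
}

#' Create an untrained generator
#' @param config [gen_config].
#' @param seed integer seed.
#' @return object of class `rna_generator`.
#' @export
generator_new <- function(config = gen_config(), seed = 1L) {
  local_seed(seed, {
    structure(list(net = generator_net(config$channels, config$K),
                   attn = attention_params(seed + 7L),
                   config = config),
              class = "rna_generator")
  })
}

# forward through softmax + transpose-symmetrization; returns probs and a
# backward closure mapping dprobs -> dlogits
softmax_sym <- function(z) {
  d <- dim(z)  # (Lp, Lp, K, N)
  bc <- function(m)  # broadcast an (Lp, Lp, N) stat over the class axis
    aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  ez <- exp(z - bc(apply(z, c(1, 2, 4), max)))
  p <- ez / bc(apply(ez, c(1, 2, 4), sum))
  ps <- (p + aperm(p, c(2, 1, 3, 4))) / 2
  list(probs = ps, p = p)
}

gen_forward_raw <- function(model, x, train = FALSE) {
  z <- model$net$forward(x, train = train)
  softmax_sym(z)
}

#' Generator forward pass
#'
#' Runs the residual network and returns per-pixel class probabilities,
#' symmetrized by averaging with the transpose (the average of two
#' normalized distributions is normalized).  The padded region beyond
#' `attr(input, "L")`, when present, is re-canonicalized first so pad
#' content cannot leak into valid pixels.
#'
#' @param model `rna_generator`.
#' @param input L x L x 14 array from [assemble_input].
#' @return L x L x K probability array.
#' @export
gen_forward <- function(model, input) {
  if (any(!is.finite(unlist(lapply(nn_leaves(model$net),
                                   function(l) l$params$w[1])))))
    stop("non-finite parameters")
  Lp <- dim(input)[1]
  L <- attr(input, "L") %||% Lp
  x <- unclass(input)
  if (L < Lp) {  # re-canonicalize padding so pad content cannot leak
    pad <- (L + 1):Lp
    for (idx in list(cbind(rep(pad, each = Lp), rep(seq_len(Lp), length(pad))),
                     cbind(rep(seq_len(Lp), length(pad)),
                           rep(pad, each = Lp)))) {
      for (ch in 1:8) x[cbind(idx, ch)] <- -1
      for (ch in 9:11) x[cbind(idx, ch)] <- 0
      for (ch in 12:13) x[cbind(idx, ch)] <- -1
      x[cbind(idx, 14)] <- 0
    }
  }
  dim(x) <- c(Lp, Lp, dim(input)[3], 1)
  out <- gen_forward_raw(model, x, train = FALSE)
  out$probs[1:L, 1:L, , 1, drop = TRUE]
}

#' @rdname gen_forward
#' @param seq,state,homologs,shape convenience wrapper building the input
#'   stack from raw pieces (state `NA` = masked).
#' @export
gen_predict <- function(model, seq, state = NULL, homologs = NULL,
                        shape = NULL) {
  L <- nchar(seq)
  if (is.null(state)) state <- matrix(NA_integer_, L, L)
  inp <- assemble_input(
    encode_sequence_bitpattern(seq),
    encode_state_channels(state, model$config$K),
    make_coordinate_frames(L),
    build_attention_map(homologs, shape, model$attn, query = seq))
  gen_forward(model, inp)
}

#' A generator policy closure for samplers
#'
#' Precomputes the static feature channels for one sequence and returns a
#' function mapping a partial state (L x L, `NA` masked) to class
#' probabilities — the interface the tree search consumes.
#'
#' @inheritParams gen_predict
#' @return function(state) -> L x L x K probabilities.
#' @export
gen_policy <- function(model, seq, homologs = NULL, shape = NULL) {
  L <- nchar(seq)
  seq_bp <- encode_sequence_bitpattern(seq)
  frames <- make_coordinate_frames(L)
  att <- build_attention_map(homologs, shape, model$attn, query = seq)
  K <- model$config$K
  function(state) {
    inp <- assemble_input(seq_bp, encode_state_channels(state, K),
                          frames, att)
    gen_forward(model, inp)
  }
}

# mask a symmetric set of pixels: draw upper-triangle cells (diag counts 1
# pixel, off-diag 2) until >= n pixels are masked; never mask fixed pairs
mask_state <- function(target, n, fixed = NULL) {
  L <- nrow(target)
  ut <- which(upper.tri(matrix(0, L, L), diag = TRUE))
  if (!is.null(fixed)) ut <- ut[!fixed[ut]]
  ut <- sample(ut)
  state <- target
  masked <- 0
  for (cell in ut) {
    if (masked >= n) break
    i <- (cell - 1) %% L + 1; j <- (cell - 1) %/% L + 1
    state[i, j] <- NA; state[j, i] <- NA
    masked <- masked + if (i == j) 1 else 2
  }
  state
}

#' Train the generator under the masked objective
#'
#' Targets are the VQ-VAE class maps of the training tensors.  Each step
#' draws a batch, masks a truncated-normal number of symmetric pixel pairs
#' per example (fixed contact pairs are always shown), and minimizes
#' cross-entropy over all valid pixels with Adam, L2 weight decay, linear
#' warmup and cosine decay.  Deterministic given the seed.
#'
#' @param dataset list of entries: each a list with `tensor`
#'   (`distance_tensor`), `seq`, optional `homologs`, `shape`,
#'   `fixed_pairs` (logical L x L).
#' @param vqvae_model trained [vqvae_new] model supplying targets.
#' @param config [gen_config].
#' @param seed integer seed.
#' @param val optional validation entries; per-epoch losses are recorded.
#' @param verbose print progress.
#' @return trained `rna_generator` with `loss_trace` attribute.
#' @export
train_generator <- function(dataset, vqvae_model, config = gen_config(),
                            seed = 1L, val = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  K <- config$K
  model <- generator_new(config, seed = seed)
  prep <- lapply(dataset, function(e) {
    L <- nchar(e$seq)
    list(L = L,
         target = unclass(vq_encode(vqvae_model, e$tensor)),
         seq_bp = encode_sequence_bitpattern(e$seq),
         frames = make_coordinate_frames(L),
         att = build_attention_map(e$homologs, e$shape, model$attn,
                                   query = e$seq),
         fixed = e$fixed_pairs)
  })
  local_seed(seed + 13L, {
    opt <- nn_adam_init(model$net)
    trace <- numeric(config$steps)
    for (step in seq_len(config$steps)) {
      idx <- sample.int(length(prep), config$batch, replace = TRUE)
      Lb <- max(vapply(idx, function(i) prep[[i]]$L, 1L))
      N <- length(idx)
      X <- array(0, c(Lb, Lb, 14, N))
      X[, , 1:8, ] <- -1; X[, , 12:13, ] <- -1
      Y <- array(0, c(Lb, Lb, K, N))     # one-hot targets on valid pixels
      for (s in seq_len(N)) {
        p <- prep[[idx[s]]]
        n_mask <- sample_mask_count(p$L)
        st <- mask_state(p$target, n_mask, p$fixed)
        X[1:p$L, 1:p$L, 1:8, s] <- p$seq_bp
        X[1:p$L, 1:p$L, 9:11, s] <- encode_state_channels(st, K)
        X[1:p$L, 1:p$L, 12:13, s] <- p$frames
        X[1:p$L, 1:p$L, 14, s] <- p$att[, , 1]
        Y[1:p$L, 1:p$L, , s] <- class_onehot(p$target, K)
      }
      fw <- gen_forward_raw(model, X, train = TRUE)
      valid <- array(rep(apply(Y, c(1, 2, 4), sum), K) > 0,
                     c(Lb, Lb, N, K))
      valid <- aperm(valid, c(1, 2, 4, 3))
      npix <- sum(Y)                      # one 1 per valid pixel
      ce <- -sum(Y * log(pmax(fw$probs, 1e-12))) / npix
      trace[step] <- ce
      if (!is.finite(ce)) stop("training diverged (non-finite loss)")
      # d ce / d probs_sym, then through symmetrization and softmax
      dps <- -(Y / pmax(fw$probs, 1e-12)) / npix
      dps[!valid] <- 0
      dp <- (dps + aperm(dps, c(2, 1, 3, 4))) / 2
      dz <- fw$p * (dp - aperm(array(
        rep(apply(dp * fw$p, c(1, 2, 4), sum), K),
        c(Lb, Lb, N, K)), c(1, 2, 4, 3)))
      model$net$backward(dz)
      lr <- lr_schedule(step, config$lr, config$warmup, config$steps)
      opt <- nn_adam_step(model$net, opt, step, lr,
                          weight_decay = config$weight_decay)
      if (verbose && step %% 25 == 0)
        message(sprintf("step %d ce %.4f (lnK = %.4f)", step, ce, log(K)))
    }
    attr(model, "loss_trace") <- trace
    if (!is.null(val))
      attr(model, "val_loss") <- generator_val_loss(model, vqvae_model, val)
    model
  })
}

# mean fully-masked cross-entropy on entries
generator_val_loss <- function(model, vqvae_model, entries) {
  mean(vapply(entries, function(e) {
    tgt <- unclass(vq_encode(vqvae_model, e$tensor))
    p <- gen_predict(model, e$seq, homologs = e$homologs, shape = e$shape)
    oh <- class_onehot(tgt, model$config$K)
    -sum(oh * log(pmax(p, 1e-12))) / nrow(tgt)^2
  }, 0))
}

#' Fully-masked argmax accuracy of the generator on entries
#' @param model `rna_generator`; `vqvae_model` supplies targets;
#'   `entries` as in [train_generator].
#' @return mean pixel accuracy across entries.
#' @export
generator_argmax_accuracy <- function(model, vqvae_model, entries) {
  mean(vapply(entries, function(e) {
    tgt <- unclass(vq_encode(vqvae_model, e$tensor))
    p <- gen_predict(model, e$seq, homologs = e$homologs, shape = e$shape)
    pred <- apply(p, c(1, 2), which.max) - 1L
    mean(pred == tgt)
  }, 0))
}

#' Chain-rule log-likelihood of a complete trajectory
#'
#' Evaluates `sum_t log P(a_t | s_{t-1}, x)` (natural log) for an ordered
#' trajectory of actions covering all `L(L-1)/2` upper-triangle pixels.
#' Each action is `c(i, j, class)` with i < j and 0-based class; states are
#' updated symmetrically and actions never overwrite set pixels.
#'
#' @param policy function(state) -> L x L x K probabilities (e.g.
#'   [gen_policy] or a mock).
#' @param trajectory list of actions `c(i, j, class)`.
#' @param L sequence length.
#' @param init_state optional starting state (default all-masked).
#' @return total log-likelihood (nats).
#' @export
chain_rule_loglik <- function(policy, trajectory, L,
                              init_state = matrix(NA_integer_, L, L)) {
  n_needed <- L * (L - 1) / 2
  covered <- unique(vapply(trajectory, function(a)
    paste(min(a[1], a[2]), max(a[1], a[2])), ""))
  if (length(trajectory) != n_needed || length(covered) != n_needed)
    stop("trajectory must cover all ", n_needed,
         " upper-triangle pixels exactly once")
  state <- init_state
  ll <- 0
  for (a in trajectory) {
    i <- a[1]; j <- a[2]; k <- a[3]
    if (!is.na(state[i, j])) stop("action overwrites a set pixel")
    p <- policy(state)
    ll <- ll + log(p[i, j, k + 1])
    state[i, j] <- k; state[j, i] <- k
  }
  ll
}
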
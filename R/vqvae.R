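# ---------------------------------------------------------------------------
# Vector-quantised autoencoder over distance tensors: residual conv encoder
# to an 8-dim embedding per pixel, symmetrization, nearest-codebook
# quantization into K distance classes, and a residual conv decoder back to
# the L x L x 64 distance tensor.  Codebook learns by EMA; the encoder gets
# reconstruction gradients through a straight-through softmax estimator.
# ---------------------------------------------------------------------------

#' VQ-VAE configuration
#'
#' Defaults follow the reference training setup: K = 3 distance classes,
#' codebook embedding dimension 8, EMA decay 0.99, Adam at learning rate
#' 1e-5 with batch size 100, maximum length 100.  Desk-scale runs override
#' `lr`, `batch`, `steps` and `max_len`.
#'
#' @param K number of distance classes (>= 2).
#' @param embed_dim codebook vector dimension.
#' @param ema_decay EMA decay for codebook updates.
#' @param lr Adam learning rate.
#' @param batch batch size.
#' @param max_len maximum (padded) sequence length.
#' @param beta commitment cost.
#' @param steps training steps.
#' @param warmup linear learning-rate warmup steps (cosine decay after).
#' @param input_scale multiplicative rescaling of distances (Angstrom) at
#'   the encoder input, for conditioning; targets stay on the raw scale.
#' @return list of class `codec_config`.
#' @export
codec_config <- function(K = 3L, embed_dim = 8L, ema_decay = 0.99,
                         lr = 1e-5, batch = 100L, max_len = 100L,
                         beta = 0.25, steps = 1000L, warmup = 0L,
                         input_scale = 0.1) {
  stopifnot(K >= 2, ema_decay > 0, ema_decay < 1)
  structure(list(K = as.integer(K), embed_dim = as.integer(embed_dim),
                 ema_decay = ema_decay, lr = lr, batch = as.integer(batch),
                 max_len = as.integer(max_len), beta = beta,
                 steps = as.integer(steps), warmup = as.integer(warmup),
                 input_scale = input_scale),
            class = "codec_config")
}

vqvae_encoder_net <- function(embed_dim = 8L) {
  nn_seq(nn_conv(7, 64, 32, input_layer = TRUE),
         nn_resblock(32, 5, 16, 3, 8),
         nn_resblock(8, 5, 8, 3, 8),
         nn_resblock(8, 5, 8, 3, 8),
         nn_resblock(8, 5, 8, 3, 8),
         nn_resblock(8, 5, 8, 3, 8))
}

vqvae_decoder_net <- function(K) {
  blocks4 <- function(c, k) lapply(1:4, function(i) nn_resblock(c, k, c, k, c))
  do.call(nn_seq, c(
    list(nn_conv(5, K, 8)), blocks4(8, 5),
    list(nn_conv(5, 8, 16)), blocks4(16, 5),
    list(nn_conv(5, 16, 32)), blocks4(32, 5),
    list(nn_conv(5, 32, 64)), blocks4(64, 3),
    list(nn_act("relu"))))
}

#' Create an untrained VQ-VAE model
#' @param config a [codec_config].
#' @param seed integer seed for parameter initialization.
#' @return object of class `vqvae`.
#' @export
vqvae_new <- function(config = codec_config(), seed = 1L) {
  local_seed(seed, {
    m <- list(encoder = vqvae_encoder_net(config$embed_dim),
              decoder = vqvae_decoder_net(config$K),
              codebook = matrix(stats::rnorm(config$K * config$embed_dim),
                                config$K, config$embed_dim),
              ema_counts = rep(1, config$K),
              ema_sums = matrix(0, config$K, config$embed_dim),
              config = config,
              class_means = NULL)
    m$ema_sums <- m$codebook * m$ema_counts
    structure(m, class = "vqvae")
  })
}

pad_tensor <- function(x, max_len) {
  d <- dim(x); L <- d[1]
  if (L > max_len) stop("L exceeds max_len (", max_len, ")")
  if (L == max_len) return(x)
  out <- array(0, c(max_len, max_len, d[3]))
  out[1:L, 1:L, ] <- x
  out
}

#' Encoder forward pass to the continuous embedding
#'
#' Zero-pads the distance tensor to the model's `max_len`, runs the residual
#' encoder, and returns the embedding cropped back to L x L x embed_dim.
#'
#' @param model a `vqvae`.
#' @param tensor a `distance_tensor`.
#' @param train keep caches for backprop.
#' @return L x L x embed_dim array.
#' @export
encode_continuous <- function(model, tensor, train = FALSE) {
  L <- tensor$L
  x <- pad_tensor(tensor$D * tensor$M * model$config$input_scale,
                  model$config$max_len)
  dim(x) <- c(dim(x), 1L)
  e <- model$encoder$forward(x, train = train)
  e[1:L, 1:L, , 1, drop = TRUE]
}

#' Symmetrize a pixel embedding
#'
#' Averages the embedding with its first-two-axes transpose, making the
#' downstream class map exactly symmetric.
#'
#' @param e L x L x d array.
#' @return symmetric array of the same shape.
#' @export
symmetrize_embedding <- function(e) {
  stopifnot(dim(e)[1] == dim(e)[2])
  (e + aperm(e, c(2, 1, 3))) / 2
}

#' Quantize an embedding against the codebook
#'
#' Assigns each pixel the nearest codebook vector in Euclidean norm (ties
#' break to the lowest index).  A symmetric embedding yields a symmetric
#' class map.
#'
#' @param e_sym symmetric L x L x embed_dim embedding.
#' @param codebook K x embed_dim matrix.
#' @return `class_map`: L x L integer matrix with classes in 0..K-1,
#'   attribute `K`.
#' @export
quantize <- function(e_sym, codebook) {
  L <- dim(e_sym)[1]
  E <- matrix(e_sym, L * L, dim(e_sym)[3])
  d2 <- outer(rowSums(E^2), rowSums(codebook^2), "+") - 2 * E %*% t(codebook)
  cl <- max.col(-d2, ties.method = "first") - 1L
  structure(matrix(cl, L, L), K = nrow(codebook), class = "class_map")
}

class_onehot <- function(classes, K) {
  L <- nrow(classes)
  oh <- array(0, c(L, L, K))
  for (k in 0:(K - 1)) oh[, , k + 1] <- (classes == k) * 1
  oh
}

#' Decode a class map to a reconstructed distance tensor
#'
#' One-hot encodes the class map, zero-pads, runs the residual decoder and
#' crops; the final ReLU guarantees nonnegative distances.  No mask is
#' attached to the reconstruction.
#'
#' @param model a `vqvae`.
#' @param classmap `class_map` (K must match the trained decoder).
#' @param train keep caches for backprop.
#' @return L x L x 64 array.
#' @export
vq_decode <- function(model, classmap, train = FALSE) {
  K <- attr(classmap, "K")
  if (K != model$config$K) stop("class map K does not match decoder")
  L <- nrow(classmap)
  x <- pad_tensor(class_onehot(unclass(classmap), K), model$config$max_len)
  dim(x) <- c(dim(x), 1L)
  y <- model$decoder$forward(x, train = train)
  y[1:L, 1:L, , 1, drop = TRUE]
}

#' Encode a distance tensor all the way to its class map
#' @param model trained `vqvae`.
#' @param tensor `distance_tensor`.
#' @return `class_map`.
#' @export
vq_encode <- function(model, tensor) {
  quantize(symmetrize_embedding(encode_continuous(model, tensor)),
           model$codebook)
}

#' EMA codebook update from one batch of hard assignments
#'
#' Standard exponential-moving-average recursion: counts and embedding sums
#' per class decay at `decay`, and each codebook vector is the ratio of its
#' smoothed sum to its smoothed count.
#'
#' @param counts,sums current EMA state (K vector, K x d matrix).
#' @param assign 1-based class assignment per embedding row.
#' @param E embedding rows (n x d).
#' @param decay EMA decay in (0, 1).
#' @return list with updated `counts`, `sums`, `codebook`.
#' @export
vq_ema_update <- function(counts, sums, assign, E, decay) {
  K <- length(counts)
  cnt <- tabulate(assign, nbins = K)
  smat <- matrix(0, K, ncol(sums))
  if (length(assign) > 0) {
    agg <- rowsum(E, assign)
    smat[as.integer(rownames(agg)), ] <- agg
  }
  counts <- decay * counts + (1 - decay) * cnt
  sums <- decay * sums + (1 - decay) * smat
  list(counts = counts, sums = sums,
       codebook = sums / pmax(counts, 1e-8))
}

# one-hot with straight-through softmax backward; returns list(oh, probs, cl).
# The softmax temperature adapts to the scale of the squared distances so the
# backward pass stays informative whatever the embedding magnitude.
st_quantize <- function(E, codebook, tau = NULL) {
  d2 <- outer(rowSums(E^2), rowSums(codebook^2), "+") - 2 * E %*% t(codebook)
  cl <- max.col(-d2, ties.method = "first")
  if (is.null(tau)) tau <- max(mean(d2[cbind(seq_len(nrow(E)), cl)]), 1e-6)
  p <- exp(-d2 / tau - apply(-d2 / tau, 1, max))
  p <- p / rowSums(p)
  oh <- matrix(0, nrow(E), nrow(codebook))
  oh[cbind(seq_len(nrow(E)), cl)] <- 1
  list(oh = oh, probs = p, cl = cl, d2 = d2, tau = tau)
}

#' Train a VQ-VAE on a set of distance tensors
#'
#' Masked squared-error reconstruction with EMA codebook updates and a
#' commitment term; Adam on encoder/decoder weights.  Deterministic given
#' the seed.
#'
#' @param dataset non-empty list of `distance_tensor`.
#' @param config a [codec_config]; `max_len` should cover the dataset.
#' @param seed integer seed.
#' @param weights optional sampling weights over the dataset.
#' @param verbose print loss every 25 steps.
#' @return trained `vqvae` with a `loss_trace` attribute.
#' @export
train_vqvae <- function(dataset, config = codec_config(), seed = 1L,
                        weights = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  model <- vqvae_new(config, seed = seed)
  K <- config$K; ed <- config$embed_dim; gam <- config$ema_decay
  Lpad <- config$max_len
  local_seed(seed + 1L, {
    # codebook init: k-means on first-batch embeddings
    idx0 <- sample.int(length(dataset), min(config$batch, length(dataset)),
                       prob = weights)
    # distance-anchored initialization: the k-th codebook vector is the
    # embedding centroid of the k-th distance-quantile pixel group, so every
    # codebook starts with near/.../far semantics regardless of K (plain
    # k-means on embeddings often misses the rare short-range mode at small
    # training budgets)
    init <- lapply(idx0, function(i) {
      t <- dataset[[i]]
      e <- symmetrize_embedding(encode_continuous(model, t))
      dmean <- rowSums(matrix(t$D * t$M, ncol = 64)) /
        pmax(1, rowSums(matrix(t$M, ncol = 64)))
      list(E = matrix(e, ncol = ed), d = dmean)
    })
    E0 <- do.call(rbind, lapply(init, `[[`, "E"))
    d0 <- unlist(lapply(init, `[[`, "d"))
    grp <- cut(rank(d0, ties.method = "first"), K, labels = FALSE)
    model$codebook <- do.call(rbind, lapply(1:K, function(k)
      colMeans(E0[grp == k, , drop = FALSE])))
    model$ema_counts <- rep(1, K)
    model$ema_sums <- model$codebook

    opt_e <- nn_adam_init(model$encoder)
    opt_d <- nn_adam_init(model$decoder)
    trace <- numeric(config$steps)
    # length-bucketed batching: draw contiguous windows of the length-sorted
    # dataset so per-batch padding stays small
    by_len <- order(vapply(dataset, `[[`, 1L, "L"))
    for (step in seq_len(config$steps)) {
      if (is.null(weights) && length(dataset) > config$batch) {
        s0 <- sample.int(length(dataset) - config$batch + 1L, 1)
        idx <- by_len[s0:(s0 + config$batch - 1L)]
      } else {
        idx <- sample.int(length(dataset), config$batch, replace = TRUE,
                          prob = weights)
      }
      Lb <- min(Lpad, max(vapply(idx, function(i) dataset[[i]]$L, 1L)))
      X <- array(0, c(Lb, Lb, 64, length(idx)))
      Mb <- array(0, c(Lb, Lb, 64, length(idx)))
      valid <- array(FALSE, c(Lb, Lb, length(idx)))
      for (s in seq_along(idx)) {
        t <- dataset[[idx[s]]]
        X[1:t$L, 1:t$L, , s] <- t$D * t$M
        Mb[1:t$L, 1:t$L, , s] <- t$M
        valid[1:t$L, 1:t$L, s] <- TRUE
      }
      e <- model$encoder$forward(X * config$input_scale, train = TRUE)
      et <- aperm(e, c(2, 1, 3, 4))
      es <- (e + et) / 2
      Em <- matrix(aperm(es, c(1, 2, 4, 3)), ncol = ed)  # (Lb*Lb*N) x ed
      vvec <- as.vector(valid)
      q <- st_quantize(Em, model$codebook)
      # decoder on hard one-hot
      OH <- aperm(array(q$oh, c(Lb, Lb, length(idx), K)), c(1, 2, 4, 3))
      Y <- model$decoder$forward(OH, train = TRUE)
      R <- (Y - X) * Mb
      nmask <- max(1, sum(Mb))
      recon <- sum(R^2) / nmask
      # commitment: pull embeddings toward their code vectors (valid pixels)
      diffc <- Em - model$codebook[q$cl, , drop = FALSE]
      diffc[!vvec, ] <- 0
      nvalid <- max(1, sum(vvec))
      commit <- config$beta * sum(diffc^2) / nvalid
      trace[step] <- recon + commit
      if (!is.finite(trace[step])) stop("training diverged (non-finite loss)")
      # backprop
      dY <- 2 * R / nmask
      dOH <- model$decoder$backward(dY)
      dOHm <- matrix(aperm(dOH, c(1, 2, 4, 3)), ncol = K)
      # straight-through softmax: route one-hot gradient through probs
      da <- q$probs * (dOHm - rowSums(dOHm * q$probs))   # d/d(-d2)
      da[!vvec, ] <- 0
      # d(-d2/tau)/dE = (2/tau)*(c_k - E) per class
      dEm <- (2 / q$tau) * ((da %*% model$codebook) - rowSums(da) * Em)
      dEm <- dEm + 2 * config$beta * diffc / nvalid
      dES <- aperm(array(dEm, c(Lb, Lb, length(idx), ed)), c(1, 2, 4, 3))
      dE <- (dES + aperm(dES, c(2, 1, 3, 4))) / 2
      model$encoder$backward(dE)
      # constant lr (reference setup) unless a warmup/cosine schedule is on
      lr_t <- if (config$warmup > 0)
        lr_schedule(step, config$lr, config$warmup, config$steps)
      else config$lr
      opt_e <- nn_adam_step(model$encoder, opt_e, step, lr_t)
      opt_d <- nn_adam_step(model$decoder, opt_d, step, lr_t)
      # EMA codebook update from valid hard assignments
      up <- vq_ema_update(model$ema_counts, model$ema_sums, q$cl[vvec],
                          Em[vvec, , drop = FALSE], gam)
      model$ema_counts <- up$counts
      model$ema_sums <- up$sums
      model$codebook <- up$codebook
      # reseed dead codes to the embeddings worst-served by the live codes
      # (classic empty-cluster handling), so collapsed codebooks re-split;
      # detection uses a fast EMA of the per-batch usage share, since the
      # slow codebook EMA can take hundreds of steps to register a death
      share <- tabulate(q$cl[vvec], nbins = K) / max(1, sum(vvec))
      model$usage_ema <- if (is.null(model$usage_ema)) share
        else 0.9 * model$usage_ema + 0.1 * share
      # reseeding stops for the last 20% of training so that late class
      # semantics stay stable for the decoder
      dead <- if (step <= 0.8 * config$steps)
        which(model$usage_ema < 0.05 / K) else integer(0)
      if (length(dead) > 0) {
        Ev <- Em[vvec, , drop = FALSE]
        live <- setdiff(seq_len(K), dead)
        d2l <- outer(rowSums(Ev^2), rowSums(model$codebook[live, ,
                     drop = FALSE]^2), "+") -
          2 * Ev %*% t(model$codebook[live, , drop = FALSE])
        worst <- order(apply(d2l, 1, min), decreasing = TRUE)
        pick <- worst[seq_len(min(length(dead), length(worst)))]
        model$codebook[dead, ] <- Ev[pick, , drop = FALSE]
        model$ema_counts[dead] <- mean(model$ema_counts[live])
        model$ema_sums[dead, ] <- model$codebook[dead, , drop = FALSE] *
          model$ema_counts[dead]
        model$usage_ema[dead] <- 1 / K
      }
      if (verbose && step %% 25 == 0)
        message(sprintf("step %d loss %.4f (recon %.4f)", step,
                        trace[step], recon))
    }
    model$class_means <- class_distance_means(model, dataset[
      seq_len(min(15, length(dataset)))])
    attr(model, "loss_trace") <- trace
    model
  })
}

#' Mean decoded distance per class
#'
#' For each distance class, the mean of the decoded distances over pixels
#' assigned that class — the quantitative backing for the "near",
#' "intermediate", "far" reading of the classes, and the source of the
#' "nearest class" used to initialize sampling.
#'
#' @param model trained `vqvae`.
#' @param dataset list of `distance_tensor`.
#' @return numeric vector of length K (NA for unused classes).
#' @export
class_distance_means <- function(model, dataset) {
  K <- model$config$K
  tot <- numeric(K); n <- numeric(K)
  for (t in dataset) {
    cm <- vq_encode(model, t)
    Y <- vq_decode(model, cm)
    mch <- apply(t$M, c(1, 2), sum)
    dmean <- apply(Y * t$M, c(1, 2), sum) / pmax(1, mch)  # mean, valid channels
    for (k in 0:(K - 1)) {
      sel <- unclass(cm) == k & mch > 0
      tot[k + 1] <- tot[k + 1] + sum(dmean[sel])
      n[k + 1] <- n[k + 1] + sum(sel)
    }
  }
  ifelse(n > 0, tot / n, NA_real_)
}

#' Index of the "nearest" distance class
#' @param model trained `vqvae` (with class means).
#' @return 0-based class index with the smallest mean decoded distance.
#' @export
nearest_class <- function(model) {
  cm <- model$class_means
  if (is.null(cm)) stop("model has no class means; train it first")
  which.min(cm) - 1L
}

#' Median masked reconstruction RMSE on held-out tensors
#'
#' Encodes, quantizes and decodes each tensor, then takes the median over
#' structures of the RMSE on valid-mask entries.
#'
#' @param model trained `vqvae`.
#' @param heldout non-empty list of `distance_tensor`.
#' @return median RMSE in Angstrom.
#' @export
reconstruction_error <- function(model, heldout) {
  if (length(heldout) == 0) stop("empty held-out set")
  errs <- vapply(heldout, function(t) {
    Y <- vq_decode(model, vq_encode(model, t))
    idx <- t$M == 1
    sqrt(mean((Y[idx] - t$D[idx])^2))
  }, 0)
  stats::median(errs)
}
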
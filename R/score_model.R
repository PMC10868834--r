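# ---------------------------------------------------------------------------
# Pairwise discriminative score model: a residual conv net maps a class map
# plus sequence bit pattern to an L x L logit map whose sum is the scalar
# score f(s, x); pairs are compared through a sigmoid of score differences.
# ---------------------------------------------------------------------------

score_net_arch <- function(K = 3L) {
  do.call(nn_seq, c(
    list(nn_conv(3, K + 8L, 5, input_layer = TRUE)),
    lapply(1:4, function(i) nn_resblock2(5, 3, "relu", 2L)),
    list(nn_batchnorm(5), nn_act("relu"),
         nn_conv(1, 5, 100), nn_act("relu"),
         nn_conv(1, 100, 1))))
}

#' Score model configuration
#'
#' Defaults follow the reference optimization setup: batch 100, Adam with
#' learning rate 1e-3 and exponential decay 0.9988 per step, L2 weight
#' decay 1e-4.
#'
#' @param K classes; `batch`, `lr`, `lr_decay`, `weight_decay`, `steps` as
#'   usual.
#' @export
score_config <- function(K = 3L, batch = 100L, lr = 1e-3, lr_decay = 0.9988,
                         weight_decay = 1e-4, steps = 2000L) {
  structure(list(K = as.integer(K), batch = as.integer(batch), lr = lr,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 steps = as.integer(steps)),
            class = "score_config")
}

#' Create an untrained score model
#' @param config [score_config]; `seed` integer seed.
#' @export
score_new <- function(config = score_config(), seed = 1L) {
  local_seed(seed, structure(list(net = score_net_arch(config$K),
                                  config = config),
                             class = "score_net"))
}

score_input <- function(classmap, seq, K) {
  L <- nrow(classmap)
  x <- array(0, c(L, L, K + 8))
  # revealed-class encoding (+1 own class, -1 others), as in the generator
  x[, , 1:K] <- encode_state_channels(unclass(classmap), K)
  x[, , (K + 1):(K + 8)] <- encode_sequence_bitpattern(seq)
  x
}

#' Scalar match score f(s, x)
#'
#' Forward pass of the score network on the class map and sequence bit
#' pattern; the resulting L x L x 1 logit map is summed into a scalar.
#'
#' @param net `score_net`.
#' @param classmap `class_map`.
#' @param seq sequence string of length L.
#' @return scalar score.
#' @export
score_f <- function(net, classmap, seq) {
  stopifnot(nrow(classmap) == nchar(seq))
  x <- score_input(classmap, seq, net$config$K)
  dim(x) <- c(dim(x), 1L)
  sum(net$net$forward(x, train = FALSE))
}

#' Pairwise preference probability
#'
#' `D(sA, sB; x) = 1 / (1 + exp(f(sB, x) - f(sA, x)))`, the probability that
#' map A matches the sequence better than map B.  Satisfies
#' `D(a, b) + D(b, a) = 1` exactly.
#'
#' @param net `score_net`; `sA`, `sB` class maps; `seq` sequence.
#' @return probability in (0, 1).
#' @export
pairwise_D <- function(net, sA, sB, seq) {
  stats::plogis(score_f(net, sA, seq) - score_f(net, sB, seq))
}

#' Symmetrically flip a fraction of class-map pixels
#' @param classmap `class_map`; `frac` fraction of upper-triangle pixels
#'   (at least one pixel is always flipped); `K` classes.
#' @return corrupted `class_map`.
#' @export
flip_classmap <- function(classmap, frac, K = attr(classmap, "K")) {
  L <- nrow(classmap)
  out <- unclass(classmap)
  ut <- which(upper.tri(out))
  nf <- max(1L, round(frac * length(ut)))
  cells <- sample(ut, min(nf, length(ut)))
  for (cell in cells) {
    i <- (cell - 1) %% L + 1; j <- (cell - 1) %/% L + 1
    new <- sample(setdiff(0:(K - 1), out[i, j]), 1)
    out[i, j] <- new; out[j, i] <- new
  }
  structure(out, K = K, class = "class_map")
}

#' Build true/corrupted training pairs for the score model
#'
#' Negatives come from three sources: drift structures encoded through the
#' VQ-VAE, ten pixel-flipped copies of each true map (flip fractions drawn
#' from 5-20%), and — when a generator is supplied — its argmax predictions
#' with 0/5/10/15/20% of the target classes revealed.
#'
#' @param entries list; each with `tensor`, `seq`, optional `drifts` (list
#'   of `rna_structure`).
#' @param vqvae trained VQ-VAE.
#' @param generator optional trained `rna_generator`.
#' @param seed integer seed.
#' @param n_flips flipped copies per true map (default 10).
#' @return list of pairs: `list(s_true, s_false, seq, corruption)`.
#' @export
make_negatives <- function(entries, vqvae, generator = NULL, seed = 1L,
                           n_flips = 10L) {
  local_seed(seed, {
    pairs <- list()
    add <- function(st, sf, seq, kind)
      pairs[[length(pairs) + 1]] <<- list(s_true = st, s_false = sf,
                                          seq = seq, corruption = kind)
    reveal_fracs <- c(0, 0.05, 0.10, 0.15, 0.20)
    for (e in entries) {
      st <- vq_encode(vqvae, e$tensor)
      for (d in (e$drifts %||% list())) {
        sf <- vq_encode(vqvae, build_distance_tensor(d))
        if (!identical(unclass(sf), unclass(st)))
          add(st, sf, e$seq, "drift")
      }
      for (r in seq_len(n_flips))
        add(st, flip_classmap(st, stats::runif(1, 0.05, 0.20)), e$seq,
            "pixel_flip")
      if (!is.null(generator)) {
        for (fr in reveal_fracs) {
          L <- nrow(st)
          n_reveal <- round(fr * L^2)
          state <- mask_state(unclass(st), L^2 - n_reveal)
          probs <- gen_predict(generator, e$seq, state = state)
          pred <- apply(probs, c(1, 2), which.max) - 1L
          pred[!is.na(state)] <- state[!is.na(state)]
          pred[lower.tri(pred)] <- t(pred)[lower.tri(pred)]
          sf <- structure(pred, K = attr(st, "K"), class = "class_map")
          if (!identical(unclass(sf), unclass(st)))
            add(st, sf, e$seq, "generator_argmax")
        }
      }
    }
    pairs
  })
}

#' Train the score model on true/corrupted pairs
#'
#' Maximizes `E[log D(true, false)] + E[log(1 - D(false, true))]` (both
#' terms equal `log sigmoid(f_true - f_false)`); true and corrupted maps go
#' through the network in one combined batch.  Adam with exponential
#' learning-rate decay and L2 weight decay; deterministic given the seed.
#'
#' @param pairs from [make_negatives].
#' @param config [score_config].
#' @param seed integer seed.
#' @return trained `score_net` with `loss_trace` attribute.
#' @export
train_score <- function(pairs, config = score_config(), seed = 1L) {
  if (length(pairs) == 0) stop("no training pairs")
  K <- config$K
  Ls <- vapply(pairs, function(p) nrow(p$s_true), 1L)
  by_len <- split(seq_along(pairs), Ls)
  model <- score_new(config, seed)
  local_seed(seed + 31L, {
    opt <- nn_adam_init(model$net)
    trace <- numeric(config$steps)
    for (step in seq_len(config$steps)) {
      grp <- by_len[[sample.int(length(by_len), 1,
                                prob = lengths(by_len))]]
      take <- sample(grp, min(config$batch, length(grp)),
                     replace = length(grp) < config$batch)
      n <- length(take)
      L <- nrow(pairs[[take[1]]]$s_true)
      X <- array(0, c(L, L, K + 8, 2 * n))
      for (s in seq_len(n)) {
        p <- pairs[[take[s]]]
        X[, , , s] <- score_input(p$s_true, p$seq, K)
        X[, , , n + s] <- score_input(p$s_false, p$seq, K)
      }
      Y <- model$net$forward(X, train = TRUE)
      f <- apply(Y, 4, sum)
      delta <- f[1:n] - f[(n + 1):(2 * n)]
      loss <- mean(-2 * stats::plogis(delta, log.p = TRUE))
      trace[step] <- loss
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
      dd <- -2 * stats::plogis(-delta) / n      # d loss / d delta
      dY <- array(0, dim(Y))
      for (s in seq_len(n)) {
        dY[, , , s] <- dd[s]
        dY[, , , n + s] <- -dd[s]
      }
      model$net$backward(dY)
      lr <- config$lr * config$lr_decay^step
      opt <- nn_adam_step(model$net, opt, step, lr,
                          weight_decay = config$weight_decay)
    }
    attr(model, "loss_trace") <- trace
    model
  })
}

#' Rank an ensemble of class maps by descending score
#'
#' Stable sort: ties keep input order.
#'
#' @param net trained `score_net`.
#' @param maps non-empty list of `class_map`.
#' @param seq sequence string.
#' @return list with `order` (indices), `scores`, and `maps` (sorted).
#' @export
rank_ensemble <- function(net, maps, seq) {
  if (length(maps) == 0) stop("empty ensemble")
  f <- vapply(maps, function(m) score_f(net, m, seq), 0)
  ord <- order(-f)  # order() is stable: ties keep input order
  list(order = ord, scores = f[ord], maps = maps[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
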
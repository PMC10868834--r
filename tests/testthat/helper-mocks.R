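# Mock policies for exercising the tree search without a trained generator.

# Oracle that puts `conf` mass on a planted map and sharpens to a near-delta
# once more than `sharpen_frac` of the off-diagonal pixels are set.
mock_sharpening_policy <- function(target, conf = 0.9, sharpen_frac = 0.3) {
  L <- nrow(target); K <- max(target) + 1L
  force(conf)
  function(state) {
    nset <- sum(!is.na(state[upper.tri(state)]))
    frac <- nset / (L * (L - 1) / 2)
    c_eff <- if (frac > sharpen_frac) 1 - 1e-9 * (K - 1) else conf
    p <- array((1 - c_eff) / (K - 1), c(L, L, K))
    hit <- cbind(as.vector(row(target)), as.vector(col(target)),
                 as.vector(target) + 1)
    p[hit] <- c_eff
    set <- which(!is.na(state))
    if (length(set) > 0) {
      i <- (set - 1) %% L + 1; j <- (set - 1) %/% L + 1
      for (k in 1:K) p[cbind(i, j, k)] <- 1e-9
      p[cbind(i, j, state[set] + 1)] <- 1 - 1e-9 * (K - 1)
    }
    p
  }
}

# Mixture oracle over two planted maps: the predictive distribution is the
# posterior-weighted mixture given the revealed pixels, sharpening once the
# posterior is decisive and enough pixels are set.
mock_bimodal_policy <- function(t1, t2, conf = 0.9, sharpen_frac = 0.3) {
  L <- nrow(t1); K <- max(c(t1, t2)) + 1L
  per_map <- function(target, c_eff) {
    p <- array((1 - c_eff) / (K - 1), c(L, L, K))
    p[cbind(as.vector(row(target)), as.vector(col(target)),
            as.vector(target) + 1)] <- c_eff
    p
  }
  function(state) {
    set <- which(!is.na(state) & upper.tri(state))
    logw <- c(0, 0)
    for (cell in set) {
      for (m in 1:2) {
        tgt <- if (m == 1) t1 else t2
        logw[m] <- logw[m] +
          log(if (state[cell] == tgt[cell]) conf else (1 - conf) / (K - 1))
      }
    }
    w <- exp(logw - max(logw)); w <- w / sum(w)
    frac <- length(set) / (L * (L - 1) / 2)
    c_eff <- if (frac > sharpen_frac && max(w) > 0.99) 1 - 1e-9 * (K - 1)
             else conf
    p <- w[1] * per_map(t1, c_eff) + w[2] * per_map(t2, c_eff)
    setp <- which(!is.na(state))
    if (length(setp) > 0) {
      i <- (setp - 1) %% L + 1; j <- (setp - 1) %/% L + 1
      for (k in 1:K) p[cbind(i, j, k)] <- 1e-9
      p[cbind(i, j, state[setp] + 1)] <- 1 - 1e-9 * (K - 1)
    }
    p
  }
}

mock_uniform_policy <- function(L, K = 3) {
  function(state) array(1 / K, c(L, L, K))
}

random_symmetric_target <- function(L, K = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:(K - 1), L * L, TRUE), L, L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
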
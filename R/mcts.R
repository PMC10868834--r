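# ---------------------------------------------------------------------------
# Monte Carlo tree search over autoregressive orderings.  Actions assign a
# distance class to a masked pixel; a node's value is the entropy-reduction
# rate; leaves where no candidate action strongly reduces entropy are
# terminal and form the sampled ensemble.
# ---------------------------------------------------------------------------

#' Search configuration
#'
#' @param c_p exploration constant of the PUCT-style selection rule.
#' @param lambda entropy-threshold factor; a candidate action qualifies when
#'   it removes more than `lambda * ln K` nats of total entropy.
#' @param N_expl visit-count bonus added along the path when a terminal is
#'   reached (drives exploration of alternative structures).
#' @param S_R_size candidate pixels sampled per expansion.
#' @param budget maximum number of simulations (select/expand/backup).
#' @param max_terminals stop after collecting this many terminals.
#' @param seed integer seed.
#' @export
search_config <- function(c_p = 1, lambda = 1, N_expl = 10L, S_R_size = 32L,
                          budget = 200L, max_terminals = 10L, seed = 1L) {
  stopifnot(c_p >= 0, N_expl >= 1, S_R_size >= 1)
  structure(list(c_p = c_p, lambda = lambda, N_expl = as.integer(N_expl),
                 S_R_size = as.integer(S_R_size), budget = as.integer(budget),
                 max_terminals = as.integer(max_terminals),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Total predictive entropy of a state
#'
#' Sum over upper-triangle (off-diagonal) pixels of the per-pixel Shannon
#' entropy of the predicted class distribution, in nats.  Already-set pixels
#' contribute whatever (near-delta) entropy the model assigns them.
#'
#' @param probs L x L x K probability array.
#' @return entropy in nats.
#' @export
total_entropy <- function(probs) {
  L <- dim(probs)[1]
  ut <- upper.tri(matrix(0, L, L))
  h <- -probs * log(pmax(probs, 1e-300))
  sum(apply(h, c(1, 2), sum)[ut])
}

new_node <- function(state, probs, depth) {
  n <- new.env(parent = emptyenv())
  n$state <- state          # L x L integer, NA = masked
  n$probs <- probs          # model output at this state
  n$depth <- depth          # number of off-diagonal action pairs taken
  n$expanded <- FALSE
  n$terminal <- FALSE
  n$actions <- list()       # per edge: list(a = c(i,j,k), N, Q, child)
  n
}

#' Initialize the search tree root
#'
#' The diagonal is set to the model's nearest distance class (smallest mean
#' decoded distance); all off-diagonal pixels start masked except fixed
#' contact pairs, whose classes are revealed permanently.
#'
#' @param L sequence length.
#' @param policy function(state) -> probabilities.
#' @param nearest 0-based nearest class index (see [nearest_class]).
#' @param fixed_state optional L x L matrix with revealed contact-pair
#'   classes (NA elsewhere).
#' @return root `SearchNode`.
#' @export
init_tree <- function(L, policy, nearest = 0L, fixed_state = NULL) {
  state <- matrix(NA_integer_, L, L)
  diag(state) <- nearest
  if (!is.null(fixed_state)) {
    idx <- !is.na(fixed_state)
    state[idx] <- fixed_state[idx]
  }
  new_node(state, policy(state), depth = 0L)
}

#' Select the action maximizing Q + U at a node
#'
#' `U(s,a) = c_p * sqrt(sum_a N(s,a)) / (1 + N(s,a))`; ties break to the
#' lowest pixel index, then the lowest class.
#'
#' @param node expanded, non-terminal `SearchNode`.
#' @param config [search_config].
#' @return index into `node$actions`.
#' @export
select_action <- function(node, config) {
  if (!node$expanded || length(node$actions) == 0)
    stop("select_action on unexpanded node")
  Ns <- vapply(node$actions, function(e) e$N, 0)
  Qs <- vapply(node$actions, function(e) e$Q, 0)
  U <- config$c_p * sqrt(sum(Ns)) / (1 + Ns)
  score <- Qs + U
  cand <- which(score >= max(score) - 1e-12)
  if (length(cand) == 1) return(cand)
  # tie-break: lowest pixel index (column-major), then lowest class
  L <- nrow(node$state)
  keys <- vapply(node$actions[cand], function(e)
    (((e$a[2] - 1) * L + e$a[1]) * (dim(node$probs)[3] + 1)) + e$a[3], 0)
  cand[which.min(keys)]
}

#' Entropy-reduction value of a state
#'
#' `v = (H(s0) - H(s)) / (H(s0) * depth)` — the fractional entropy reduction
#' per action; zero when the root entropy vanishes.
#'
#' @param H0 root entropy; `H` state entropy; `depth` actions taken (>= 1).
#' @return value in `(-Inf, 1/depth]`.
#' @export
value_of_state <- function(H0, H, depth) {
  if (H0 <= 0) return(0)
  (H0 - H) / (H0 * max(1, depth))
}

#' Expand a leaf: sample candidates, keep strong entropy reducers
#'
#' Samples up to `S_R_size` masked pixels uniformly without replacement;
#' each candidate action sets its pixel to the argmax class.  Candidates
#' whose one-step lookahead removes more than `lambda * ln K` nats of total
#' entropy form `S_H` and become children (initialized with `N = 1`,
#' `Q = v(child)`); if `S_H` is empty the leaf is marked terminal.
#'
#' @param leaf unexpanded `SearchNode`.
#' @param policy function(state) -> probabilities.
#' @param config [search_config].
#' @param H0 root entropy.
#' @return list(children = indices of new edges, terminal = flag).
#' @export
expand_leaf <- function(leaf, policy, config, H0) {
  L <- nrow(leaf$state)
  K <- dim(leaf$probs)[3]
  masked <- which(upper.tri(leaf$state) & is.na(leaf$state))
  if (length(masked) == 0) {
    leaf$terminal <- TRUE; leaf$expanded <- TRUE
    return(list(children = integer(0), terminal = TRUE))
  }
  SR <- sample(masked, min(config$S_R_size, length(masked)))
  H_leaf <- total_entropy(leaf$probs)
  thresh <- config$lambda * log(K)
  for (cell in SR) {
    i <- (cell - 1) %% L + 1; j <- (cell - 1) %/% L + 1
    k <- which.max(leaf$probs[i, j, ]) - 1L
    st2 <- leaf$state
    st2[i, j] <- k; st2[j, i] <- k
    pr2 <- policy(st2)
    dH <- H_leaf - total_entropy(pr2)
    if (dH > thresh) {
      child <- new_node(st2, pr2, leaf$depth + 1L)
      v <- value_of_state(H0, total_entropy(pr2), child$depth)
      leaf$actions[[length(leaf$actions) + 1]] <-
        list(a = c(i, j, k), N = 1, Q = v, child = child)
    }
  }
  leaf$expanded <- TRUE
  if (length(leaf$actions) == 0) {
    leaf$terminal <- TRUE
    return(list(children = integer(0), terminal = TRUE))
  }
  list(children = seq_along(leaf$actions), terminal = FALSE)
}

#' Back up an expansion or terminal event along the path
#'
#' After an expansion creating `|S_H|` children with winner value
#' `v* = max v(child)`: along the root-to-leaf path, `N += |S_H|` then
#' `Q += (|S_H| / N) * (v* - Q)`.  For terminal leaves, `N += N_expl` and Q
#' stays unchanged.
#'
#' @param path list of (node, action index) pairs from root to leaf.
#' @param n_new `|S_H|` (0 for terminal backup).
#' @param v_star winner value (ignored for terminal backup).
#' @param terminal whether this is a terminal-leaf backup.
#' @param config [search_config].
#' @export
backup <- function(path, n_new, v_star, terminal, config) {
  for (pe in path) {
    edge <- pe$node$actions[[pe$ai]]
    if (terminal) {
      edge$N <- edge$N + config$N_expl
    } else {
      edge$N <- edge$N + n_new
      edge$Q <- edge$Q + (n_new / edge$N) * (v_star - edge$Q)
    }
    pe$node$actions[[pe$ai]] <- edge
  }
  invisible(NULL)
}

#' Complete a terminal state by parallel argmax
#'
#' Remaining masked pixels are set simultaneously to their argmax class
#' from one forward pass (ties to the lowest class); the result is
#' symmetric.
#'
#' @param state terminal partial state.
#' @param policy function(state) -> probabilities.
#' @return `class_map`.
#' @export
finalize_map <- function(state, policy) {
  probs <- policy(state)
  K <- dim(probs)[3]
  out <- state
  L <- nrow(state)
  am <- apply(probs, c(1, 2), which.max) - 1L
  out[is.na(out)] <- am[is.na(out)]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  structure(out, K = K, class = "class_map")
}

#' Run the tree search and collect a structural ensemble
#'
#' Repeats select -> expand -> backup until the simulation budget or the
#' terminal cap is reached, then finalizes every distinct terminal state by
#' argmax completion.  Deterministic given the seed.
#'
#' @param L sequence length.
#' @param policy function(state) -> L x L x K probabilities.
#' @param config [search_config].
#' @param nearest 0-based class index used to initialize the diagonal.
#' @param fixed_state optional revealed contact-pair classes.
#' @param audit record the search tree and every backup event (attributes
#'   `root`, `audit_events`, `audit_values`) for invariant checks.
#' @return list of `class_map` with attributes `terminal_depths`,
#'   `n_simulations`, `found_terminal`.
#' @export
run_search <- function(L, policy, config = search_config(), nearest = 0L,
                       fixed_state = NULL, audit = FALSE) {
  local_seed(config$seed, {
    root <- init_tree(L, policy, nearest, fixed_state)
    H0 <- total_entropy(root$probs)
    terminals <- list()
    term_keys <- character(0)
    sims <- 0L
    ev_len <- integer(0); ev_inc <- numeric(0)  # backup audit log
    all_values <- numeric(0)                    # every value ever assigned
    while (sims < config$budget && length(terminals) < config$max_terminals) {
      sims <- sims + 1L
      node <- root
      path <- list()
      while (node$expanded && !node$terminal) {
        ai <- select_action(node, config)
        path[[length(path) + 1]] <- list(node = node, ai = ai)
        node <- node$actions[[ai]]$child
      }
      if (node$terminal) {
        # revisited terminal: bump exploration counts again
        backup(path, 0, 0, TRUE, config)
        ev_len <- c(ev_len, length(path)); ev_inc <- c(ev_inc, config$N_expl)
        next
      }
      res <- expand_leaf(node, policy, config, H0)
      if (res$terminal) {
        key <- paste(node$state[upper.tri(node$state)], collapse = ",")
        if (!key %in% term_keys) {
          term_keys <- c(term_keys, key)
          terminals[[length(terminals) + 1]] <- node
        }
        backup(path, 0, 0, TRUE, config)
        ev_len <- c(ev_len, length(path)); ev_inc <- c(ev_inc, config$N_expl)
      } else {
        vals <- vapply(res$children, function(ci)
          node$actions[[ci]]$Q, 0)
        all_values <- c(all_values, vals)
        backup(path, length(res$children), max(vals), FALSE, config)
        ev_len <- c(ev_len, length(path))
        ev_inc <- c(ev_inc, length(res$children))
      }
    }
    found <- length(terminals) > 0
    if (!found) {
      warning("no terminal nodes within budget; returning best-Q leaf")
      node <- root
      while (node$expanded && !node$terminal && length(node$actions) > 0) {
        qs <- vapply(node$actions, function(e) e$Q, 0)
        node <- node$actions[[which.max(qs)]]$child
      }
      terminals <- list(node)
    }
    maps <- lapply(terminals, function(n) finalize_map(n$state, policy))
    # deduplicate finalized maps
    keys <- vapply(maps, function(m) paste(m, collapse = ","), "")
    keep <- !duplicated(keys)
    maps <- maps[keep]
    attr(maps, "terminal_depths") <-
      vapply(terminals, function(n) n$depth, 0L)[keep]
    attr(maps, "n_simulations") <- sims
    attr(maps, "found_terminal") <- found
    if (audit) {
      attr(maps, "root") <- root
      attr(maps, "audit_events") <- data.frame(path_len = ev_len,
                                               increment = ev_inc)
      attr(maps, "audit_values") <- all_values
    }
    maps
  })
}
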
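test_that("total entropy has closed forms and matches a brute-force sum", {
  L <- 6; K <- 3
  N <- L * (L - 1) / 2
  expect_equal(total_entropy(array(1 / K, c(L, L, K))), N * log(K))
  delta <- array(0, c(L, L, K)); delta[, , 1] <- 1
  expect_equal(total_entropy(delta), 0)
  set.seed(4)
  p <- array(runif(L * L * K), c(L, L, K))
  p <- p / array(rep(apply(p, c(1, 2), sum), K), c(L, L, K))
  bf <- 0
  for (i in 1:(L - 1)) for (j in (i + 1):L)
    for (k in 1:K) bf <- bf - p[i, j, k] * log(p[i, j, k])
  expect_equal(total_entropy(p), bf)
})

test_that("tree initialization sets only the diagonal (plus fixed contacts)", {
  L <- 8
  pol <- mock_uniform_policy(L)
  root <- init_tree(L, pol, nearest = 2L)
  expect_equal(diag(root$state), rep(2L, L))
  expect_true(all(is.na(root$state[upper.tri(root$state)])))
  expect_equal(root$depth, 0L)
  fixed <- matrix(NA_integer_, L, L)
  fixed[1, 5] <- fixed[5, 1] <- 1L
  root2 <- init_tree(L, pol, nearest = 0L, fixed_state = fixed)
  expect_equal(root2$state[1, 5], 1L)
  # inference mode: no contact information -> no revealed off-diagonal pixels
  expect_equal(sum(!is.na(root$state[upper.tri(root$state)])), 0L)
})

make_test_node <- function(L, Ns, Qs, actions) {
  node <- rnadistgen:::new_node(matrix(NA_integer_, L, L),
                                array(1 / 3, c(L, L, 3)), 1L)
  node$expanded <- TRUE
  for (i in seq_along(Ns))
    node$actions[[i]] <- list(a = actions[[i]], N = Ns[i], Q = Qs[i],
                              child = NULL)
  node
}

test_that("the selection rule is PUCT with deterministic tie-breaks", {
  acts <- list(c(1, 2, 0), c(1, 3, 1), c(2, 3, 2))
  # c_p = 0: pure greedy on Q
  node <- make_test_node(4, c(5, 5, 5), c(0.1, 0.5, 0.3), acts)
  expect_equal(select_action(node, search_config(c_p = 0)), 2L)
  # equal Q: the rarely visited edge wins for c_p > 0
  node2 <- make_test_node(4, c(100, 1, 100), c(0.4, 0.4, 0.4), acts)
  expect_equal(select_action(node2, search_config(c_p = 1)), 2L)
  # brute-force check over random configurations
  set.seed(5)
  for (r in 1:20) {
    Ns <- sample(1:50, 3); Qs <- runif(3)
    cp <- runif(1, 0, 2)
    node3 <- make_test_node(4, Ns, Qs, acts)
    sc <- Qs + cp * sqrt(sum(Ns)) / (1 + Ns)
    expect_equal(select_action(node3, search_config(c_p = cp)),
                 which.max(sc))
  }
  # exact ties break to the lowest pixel index, then the lowest class
  node4 <- make_test_node(4, c(1, 1), c(0.2, 0.2),
                          list(c(1, 3, 1), c(1, 3, 0)))
  expect_equal(select_action(node4, search_config(c_p = 1)), 2L)
  expect_error(select_action(rnadistgen:::new_node(
    matrix(NA_integer_, 3, 3), array(1 / 3, c(3, 3, 3)), 0L),
    search_config()), "unexpanded")
})

test_that("the state value is the fractional entropy reduction per action", {
  expect_equal(value_of_state(10, 10, 1), 0)
  expect_equal(value_of_state(10, 5, 1), 0.5)    # one action halves H
  expect_equal(value_of_state(10, 0, 2), 0.5)    # two actions to zero
  expect_equal(value_of_state(0, 0, 3), 0)       # degenerate root
})

test_that("expansion thresholds on strict entropy reduction", {
  L <- 5; K <- 3
  # every action reduces entropy by exactly ln K -> strict inequality fails,
  # node is terminal
  exact_policy <- function(state) {
    n_masked <- sum(is.na(state[upper.tri(state)]))
    p <- array(1e-15, c(L, L, K))
    p[, , 1] <- 1 - 2e-15
    ut <- which(upper.tri(state), arr.ind = TRUE)
    for (r in seq_len(nrow(ut))) {
      if (is.na(state[ut[r, 1], ut[r, 2]]))
        p[ut[r, 1], ut[r, 2], ] <- 1 / K
    }
    p
  }
  leaf <- rnadistgen:::new_node(local({
    s <- matrix(NA_integer_, L, L); diag(s) <- 0L; s
  }), exact_policy(matrix(NA_integer_, L, L)), 0L)
  res <- expand_leaf(leaf, exact_policy, search_config(S_R_size = 10), 10)
  expect_true(res$terminal)
  expect_length(res$children, 0)

  # planted pixel collapses five other pixels -> enters S_H
  collapse_policy <- function(state) {
    p <- array(1 / K, c(L, L, K))
    if (!is.na(state[1, 2])) {
      for (cell in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
        p[cell[1], cell[2], ] <- c(1 - 2e-12, 1e-12, 1e-12)
        p[cell[2], cell[1], ] <- c(1 - 2e-12, 1e-12, 1e-12)
      }
      p[1, 2, ] <- c(1 - 2e-12, 1e-12, 1e-12)
      p[2, 1, ] <- c(1 - 2e-12, 1e-12, 1e-12)
    }
    p
  }
  leaf2 <- rnadistgen:::new_node(local({
    s <- matrix(NA_integer_, L, L); diag(s) <- 0L; s
  }), collapse_policy(local({
    s <- matrix(NA_integer_, L, L); diag(s) <- 0L; s
  })), 0L)
  set.seed(1)
  res2 <- expand_leaf(leaf2, collapse_policy,
                      search_config(S_R_size = 10), 10)
  expect_false(res2$terminal)
  picked <- vapply(leaf2$actions, function(e) paste(e$a[1], e$a[2]), "")
  expect_true("1 2" %in% picked)
  expect_true(all(vapply(leaf2$actions, function(e) e$N, 0) == 1))
})

test_that("backup follows the winner-takes-all update arithmetic", {
  L <- 4
  parent <- make_test_node(L, 1, 0, list(c(1, 2, 0)))
  path <- list(list(node = parent, ai = 1L))
  backup(path, n_new = 1, v_star = 0.4, terminal = FALSE, search_config())
  expect_equal(parent$actions[[1]]$N, 2)
  expect_equal(parent$actions[[1]]$Q, 0.2)
  # terminal backup: N += N_expl, Q unchanged
  q_before <- parent$actions[[1]]$Q
  backup(path, 0, 0, TRUE, search_config(N_expl = 10))
  expect_equal(parent$actions[[1]]$N, 12)
  expect_equal(parent$actions[[1]]$Q, q_before)
})

test_that("argmax finalization completes terminals symmetrically", {
  L <- 6
  st <- matrix(NA_integer_, L, L); diag(st) <- 0L
  st[1, 2] <- st[2, 1] <- 2L
  # uniform model: ties resolve to the lowest class
  m1 <- finalize_map(st, mock_uniform_policy(L))
  expect_equal(unclass(m1)[1, 3], 0L)
  expect_equal(unclass(m1)[1, 2], 2L)        # set pixels untouched
  expect_equal(unclass(m1), t(unclass(m1)))
  # no masked pixels -> identity
  full <- random_symmetric_target(L, seed = 2)
  m2 <- finalize_map(full, mock_uniform_policy(L))
  expect_equal(matrix(unclass(m2), L, L), full)
  # planted oracle recovers the planted map
  tgt <- random_symmetric_target(L, seed = 3)
  m3 <- finalize_map(local({
    s <- matrix(NA_integer_, L, L); diag(s) <- tgt[1, 1]; s
  }), mock_sharpening_policy(tgt))
  expect_equal(unclass(m3)[upper.tri(tgt)], tgt[upper.tri(tgt)])
})

test_that("the search recovers a planted map and is seed-deterministic", {
  L <- 12
  tgt <- random_symmetric_target(L, seed = 6)
  pol <- mock_sharpening_policy(tgt)
  maps <- run_search(L, pol, search_config(budget = 40, max_terminals = 3,
                                           seed = 2), nearest = tgt[1, 1])
  ut <- upper.tri(tgt)
  agree <- max(vapply(maps, function(m)
    mean(unclass(m)[ut] == tgt[ut]), 0))
  expect_gte(agree, 0.99)
  maps2 <- run_search(L, pol, search_config(budget = 40, max_terminals = 3,
                                            seed = 2), nearest = tgt[1, 1])
  expect_identical(lapply(maps, unclass), lapply(maps2, unclass))
})

test_that("a bimodal oracle yields both planted maps among the terminals", {
  L <- 10
  t1 <- random_symmetric_target(L, seed = 7)
  t2 <- t1
  # second mode differs on a block of pixels
  for (i in 1:4) for (j in (i + 1):5) {
    t2[i, j] <- (t1[i, j] + 1) %% 3; t2[j, i] <- t2[i, j]
  }
  pol <- mock_bimodal_policy(t1, t2)
  maps <- run_search(L, pol, search_config(budget = 400, max_terminals = 8,
                                           c_p = 2, seed = 3),
                     nearest = t1[1, 1])
  ut <- upper.tri(t1)
  agree1 <- max(vapply(maps, function(m) mean(unclass(m)[ut] == t1[ut]), 0))
  agree2 <- max(vapply(maps, function(m) mean(unclass(m)[ut] == t2[ut]), 0))
  expect_gte(agree1, 0.99)
  expect_gte(agree2, 0.99)
})

test_that("search bookkeeping: no overwrites, count conservation, bounded Q", {
  set.seed(9)
  for (r in 1:100) {
    L <- sample(8:12, 1)
    tgt <- random_symmetric_target(L, seed = r)
    conf <- runif(1, 0.55, 0.95)
    pol <- mock_sharpening_policy(tgt, conf = conf)
    maps <- run_search(L, pol,
                       search_config(budget = sample(5:20, 1),
                                     max_terminals = 3,
                                     c_p = runif(1, 0, 2),
                                     S_R_size = sample(4:16, 1),
                                     seed = r),
                       nearest = tgt[1, 1], audit = TRUE)
    root <- attr(maps, "root")
    events <- attr(maps, "audit_events")
    vals <- attr(maps, "audit_values")
    n_sum <- 0; n_edges <- 0; violations <- 0
    stack <- list(root)
    while (length(stack) > 0) {
      node <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (edge in node$actions) {
        n_edges <- n_edges + 1
        n_sum <- n_sum + edge$N
        # Q bounded by the values ever backed up
        if (edge$Q < min(vals) - 1e-12 || edge$Q > max(vals) + 1e-12)
          violations <- violations + 1
        ch <- edge$child
        # the child state adds exactly this action, overwriting nothing
        diff_cells <- which(is.na(node$state) != is.na(ch$state) |
                            (!is.na(node$state) & !is.na(ch$state) &
                             node$state != ch$state))
        if (!setequal(diff_cells,
                      c((edge$a[2] - 1) * L + edge$a[1],
                        (edge$a[1] - 1) * L + edge$a[2])))
          violations <- violations + 1
        if (!all(node$state[!is.na(node$state)] ==
                 ch$state[!is.na(node$state)]))
          violations <- violations + 1
        stack[[length(stack) + 1]] <- ch
      }
    }
    expect_equal(violations, 0)
    # every edge starts at N = 1; all increments are logged backup events
    expect_equal(n_sum - n_edges, sum(events$path_len * events$increment))
  }
})

test_that("path entropy is non-increasing in expectation under the oracle", {
  set.seed(10)
  drops <- replicate(100, {
    L <- 10
    tgt <- random_symmetric_target(L, seed = sample(1e6, 1))
    pol <- mock_sharpening_policy(tgt, conf = 0.7)
    maps <- run_search(L, pol, search_config(budget = 10, max_terminals = 2,
                                             seed = sample(1e6, 1)),
                       nearest = tgt[1, 1], audit = TRUE)
    root <- attr(maps, "root")
    if (length(root$actions) == 0) return(0)
    h0 <- total_entropy(root$probs)
    h1 <- mean(vapply(root$actions, function(e)
      total_entropy(e$child$probs), 0))
    h0 - h1
  })
  expect_gte(mean(drops), 0)
})
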
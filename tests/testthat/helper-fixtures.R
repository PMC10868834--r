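# Shared fixtures and trained models, built once per session and reused by
# module tests and the acceptance suite so the heavy trainings run once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# --- corpus-scale fixture set (codec study conditions) ----------------------

fixture_manifest <- function()
  cached("manifest", make_fixture_dataset(200, c(14, 28), seed = 101))

fixture_tensors <- function()
  cached("tensors", lapply(fixture_manifest()$entries,
                           function(e) build_distance_tensor(e$structure)))

fixture_train_idx <- function() which(fixture_manifest()$splits != "test")
fixture_test_idx <- function() which(fixture_manifest()$splits == "test")

# equal desk-scale training budget for every K
codec_budget <- function(K)
  codec_config(K = K, lr = 5e-3, warmup = 20L, batch = 4L, max_len = 28L,
               steps = 350L)

trained_codec <- function(K)
  cached(paste0("vq_k", K),
         train_vqvae(fixture_tensors()[fixture_train_idx()],
                     codec_budget(K), seed = 7))

# --- small overfit set for the generator / score chain ----------------------

overfit_manifest <- function()
  cached("ov_manifest",
         make_fixture_dataset(10, c(12, 16), seed = 202, n_drifts = 3))

overfit_entries <- function() cached("ov_entries", {
  man <- overfit_manifest()
  lapply(man$entries, function(e)
    list(tensor = build_distance_tensor(e$structure),
         seq = e$structure$sequence,
         drifts = e$drifts,
         homologs = e$homologs,
         shape = e$shape_sim))
})

overfit_codec <- function() cached("ov_vq", {
  train_vqvae(lapply(overfit_entries(), `[[`, "tensor"),
              codec_config(K = 3, lr = 3e-3, batch = 4L, max_len = 16L,
                           steps = 80L), seed = 2)
})

overfit_generator <- function() cached("ov_gen", {
  train_generator(overfit_entries(), overfit_codec(),
                  gen_config(batch = 5L, lr = 2e-3, warmup = 30L,
                             steps = 300L, max_len = 16L), seed = 5)
})

trained_score <- function() cached("ov_score", {
  pairs <- make_negatives(overfit_entries(), overfit_codec(),
                          generator = overfit_generator(), seed = 8)
  train_score(pairs, score_config(batch = 16L, steps = 150L), seed = 3)
})

# random complete symmetric class map
random_classmap <- function(L, K = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:(K - 1), L * L, TRUE), L, L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  structure(m, K = K, class = "class_map")
}
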
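# Shared fixtures, built in code and memoised per test session.

.fixtures <- new.env()

fixture_lesion <- function(class_id, seed = 1L) {
  key <- paste0("lesion_", class_id, "_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_lesion(class_id, seed = seed)
  }
  .fixtures[[key]]
}

# small two-class dataset for training smoke tests
fixture_dataset <- function(n_per_class = 5L, seed0 = 0L) {
  key <- paste0("ds_", n_per_class, "_", seed0)
  if (is.null(.fixtures[[key]])) {
    out <- list()
    for (cls in 1:2) {
      for (i in seq_len(n_per_class)) {
        out[[length(out) + 1L]] <- generate_lesion(cls, seed = seed0 + cls * 1000L + i)
      }
    }
    .fixtures[[key]] <- out
  }
  .fixtures[[key]]
}

# model rigged so the team value of one action dominates everywhere:
# spatial head output = fixed bias vector, temporal head output = 0
rig_model <- function(K = 2L, biases) {
  stopifnot(length(biases) == K + 4L)
  model <- build_model(K = K, seed = 1L)
  model$spatial$params$head2.W[] <- 0
  model$spatial$params$head2.b <- biases
  model$temporal$params$head.W[] <- 0
  model$temporal$params$head.b <- numeric(K)
  model
}
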
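test_that("spatial action values have arity K + 4 for any K and backbone", {
  patch <- array(0.5, c(64, 64, 3))
  for (K in c(2L, 4L)) {
    net <- spatial_qnet(K, seed = 2)
    q <- spatial_q(net, patch, c(0.5, 0.5))
    expect_length(q, K + 4L)
    expect_true(all(is.finite(q)))
  }
})

test_that("the heavyweight backbone exposes a 2048-dim feature vector", {
  net <- spatial_qnet(2, backbone = "resnet50-style", seed = 1)
  expect_identical(net$spec$d_f, 2048L)
  fw <- lesionnav:::spatial_forward(net, array(0.4, c(64, 64, 3)),
                                    c(0.5, 0.5))
  expect_identical(nrow(fw$cache$bb$f), 2048L)
  expect_length(fw$q, 6)
})

test_that("spatial evaluation is deterministic and validates shapes", {
  net <- spatial_qnet(2, seed = 3)
  set.seed(9)
  patch <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(spatial_q(net, patch, c(0.2, 0.8)),
                   spatial_q(net, patch, c(0.2, 0.8)))
  expect_error(spatial_q(net, array(0, c(32, 32, 3)), c(0, 0)), "shape")
  expect_error(spatial_q(net, patch, c(0, 0, 0)), "pos_embed")
})

test_that("temporal action values have arity K and reject bad tokens", {
  for (kind in c("gru", "lstm")) {
    net <- temporal_qnet(3, backbone = kind, seed = 4)
    q <- temporal_q(net, c(1L, 3L, 5L))
    expect_length(q, 3)
    expect_true(all(is.finite(q)))
    expect_length(temporal_q(net, 2L), 3)  # single-token boundary case
    expect_error(temporal_q(net, integer(0)), "empty")
    expect_error(temporal_q(net, c(1L, 99L)), "vocabulary")
  }
})

test_that("the recurrent encoder is order-sensitive", {
  net <- temporal_qnet(2, seed = 5)
  toks <- c(1L, 3L, 5L, 7L, 2L)
  expect_false(isTRUE(all.equal(temporal_q(net, toks),
                                temporal_q(net, rev(toks)))))
})

test_that("the bidirectional hidden state has dimension 2 x per-direction", {
  net <- temporal_qnet(2, d_hidden = 32L, seed = 1)
  expect_length(temporal_hidden(net, c(1L, 2L)), 64)
})

test_that("backbone names resolve and unsupported ones error", {
  expect_identical(make_backbone("gru")$name, "gru")
  expect_identical(make_backbone("lstm")$name, "lstm")
  expect_identical(make_backbone("small-cnn")$d_f, 64L)
  expect_error(make_backbone("transformer"), "unknown backbone")
  expect_error(spatial_qnet(2, backbone = "gru"), "spatial")
  expect_error(temporal_qnet(2, backbone = "small-cnn"), "temporal")
})

test_that("one supervised gradient step reduces the regression error", {
  set.seed(11)
  net <- spatial_qnet(2, seed = 6)
  X <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  P <- matrix(runif(8), 2, 4)
  target <- matrix(rnorm(24), 6, 4)
  fw <- lesionnav:::spatial_forward(net, X, P)
  loss0 <- mean((fw$q - target)^2)
  gs <- lesionnav:::spatial_backward(net, fw$cache, 2 * (fw$q - target) / 4)
  opt <- lesionnav:::adam_new(net$params, lr = 1e-3)
  net$params <- lesionnav:::adam_step(opt, net$params, gs)$params
  loss1 <- mean((lesionnav:::spatial_forward(net, X, P)$q - target)^2)
  expect_lt(loss1, loss0)

  tnet <- temporal_qnet(2, seed = 6)
  toks <- c(1L, 3L, 4L, 6L)
  y <- c(1, -1)
  fwt <- lesionnav:::temporal_forward(tnet, toks)
  l0 <- mean((fwt$q - y)^2)
  gt <- lesionnav:::temporal_backward(tnet, fwt$cache, 2 * (fwt$q - y) / 2)
  optt <- lesionnav:::adam_new(tnet$params, lr = 1e-3)
  tnet$params <- lesionnav:::adam_step(optt, tnet$params, gt)$params
  expect_lt(mean((lesionnav:::temporal_forward(tnet, toks)$q - y)^2), l0)
})

test_that("checkpoint save/load round-trips outputs bit-identically", {
  model <- build_model(K = 2, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$K, 2L)
  expect_identical(meta$spatial_backbone, "small-cnn")
  back <- load_checkpoint(path)
  set.seed(12)
  patch <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(spatial_q(back$spatial, patch, c(0.3, 0.7)),
                   spatial_q(model$spatial, patch, c(0.3, 0.7)))
  expect_identical(temporal_q(back$temporal, c(1L, 4L)),
                   temporal_q(model$temporal, c(1L, 4L)))
})

test_that("supervised warm start improves class-value separation", {
  ds <- fixture_dataset(5)
  model <- build_model(K = 2, seed = 9)
  warm <- warm_start(model, ds, epochs = 3, lr = 1e-2, seed = 1)
  # true-class entries should now beat wrong-class entries more often
  score <- function(m) {
    mean(vapply(ds, function(img) {
      q <- temporal_q(m$temporal, describe(img)$tokens)
      as.integer(which.max(q) == img$label)
    }, numeric(1)))
  }
  expect_gte(score(warm), score(model))
})
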
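test_that("TD targets reduce correctly at terminals and in the myopic limit", {
  expect_equal(td_target(1, TRUE, NULL), 1.0)
  expect_equal(td_target(-1, TRUE, c(5, 5)), -1.0)
  expect_equal(td_target(-0.01, FALSE, c(0.3, 1.0, -2), 0.99),
               -0.01 + 0.99 * 1.0)
  expect_equal(td_target(0.4, FALSE, c(9, 9), 0), 0.4)
})

test_that("replay buffer is bounded FIFO with uniform sampling", {
  buf <- replay_new(5)
  for (i in 1:8) replay_push(buf, list(id = i))
  expect_identical(replay_size(buf), 5L)
  ids <- vapply(buf$storage, `[[`, numeric(1), "id")
  expect_setequal(ids, 4:8)  # oldest three evicted
  expect_error(replay_sample(buf, 10), "batch larger")

  buf <- replay_new(100)
  for (i in 1:100) replay_push(buf, list(id = i))
  set.seed(17)
  counts <- integer(100)
  for (d in 1:10000) {
    s <- replay_sample(buf, 1)[[1]]$id
    counts[s] <- counts[s] + 1L
  }
  # goodness of fit across the 100 cells (a per-cell 3-SE bound would be
  # multiplied over 100 comparisons)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # batches sample without replacement
  batch <- replay_sample(buf, 50)
  expect_identical(anyDuplicated(vapply(batch, `[[`, numeric(1), "id")), 0L)
})

test_that("the joint TD loss matches an independent recomputation", {
  ds <- fixture_dataset(3)
  model <- build_model(K = 2, seed = 2)
  grid <- build_grid()
  img <- ds[[4]]
  tokens <- describe(img)$tokens
  token_cache <- lapply(ds, function(it) describe(it)$tokens)
  pos <- c(2L, 2L)
  tr_term <- list(item = 4L, pixels = img$pixels, pos = pos, action = 6L,
                  reward = 1, next_pos = pos, terminal = TRUE)
  loss <- vdn_loss(list(tr_term), model, model, token_cache, grid)
  # independent route through the public evaluation functions
  q1 <- spatial_q(model$spatial, lesionnav:::crop_patch(img$pixels, grid, pos),
                  pos_embedding(pos, grid))
  q2 <- temporal_q(model$temporal, tokens)
  qtot <- fuse_class_values(q1, q2, model$fusion)[2]
  expect_equal(loss, (1 - qtot)^2)

  # permutation invariance on a mixed batch
  tr_nav <- list(item = 1L, pixels = ds[[1]]$pixels, pos = pos, action = 2L,
                 reward = -0.01, next_pos = c(3L, 2L), terminal = FALSE)
  batch <- list(tr_term, tr_nav, tr_term)
  expect_equal(vdn_loss(batch, model, model, token_cache, grid),
               vdn_loss(rev(batch), model, model, token_cache, grid))
  expect_error(vdn_loss(list(), model, model, token_cache, grid), "empty")
})

test_that("TD targets are frozen between target syncs", {
  ds <- fixture_dataset(3)
  model <- build_model(K = 2, seed = 3)
  target <- model
  token_cache <- lapply(ds, function(it) describe(it)$tokens)
  grid <- build_grid()
  batch <- list(list(item = 1L, pixels = ds[[1]]$pixels, pos = c(2L, 2L),
                     action = 3L, reward = -0.01, next_pos = c(2L, 1L),
                     terminal = FALSE))
  y_before <- lesionnav:::batch_forward(model, target, batch, grid, 0.99,
                                        token_cache)$y
  # a gradient step moves the online nets but must not move the targets
  opt <- list(spatial = lesionnav:::adam_new(model$spatial$params, lr = 1e-2),
              temporal = lesionnav:::adam_new(model$temporal$params, lr = 1e-2),
              fusion = lesionnav:::adam_new(model$fusion$params, lr = 1e-2))
  st <- lesionnav:::train_step(model, target, batch, token_cache, grid,
                               0.99, opt)
  expect_false(identical(st$model$spatial$params, model$spatial$params))
  y_after <- lesionnav:::batch_forward(st$model, target, batch, grid, 0.99,
                                       token_cache)$y
  expect_identical(y_before, y_after)
})

test_that("tabular VDN learning recovers the analytic optimal Q", {
  # 2-state, 2-action deterministic MDP; oracle Q* by value iteration
  nxt <- matrix(c(1L, 2L, 2L, 1L), 2, 2)   # nxt[s, a]
  rew <- matrix(c(1, 2, 0, 0), 2, 2)       # rew[s, a]
  gamma <- 0.9
  Qstar <- matrix(0, 2, 2)
  for (i in 1:500) {
    Qnew <- Qstar
    for (s in 1:2) for (a in 1:2) {
      Qnew[s, a] <- rew[s, a] + gamma * max(Qstar[nxt[s, a], ])
    }
    Qstar <- Qnew
  }
  rule <- fusion_rule("vdn-sum", K = 2)
  Q1 <- matrix(0, 2, 2)
  Q2 <- matrix(0, 2, 2)
  alpha <- 0.25
  for (i in 1:3000) {
    for (s in 1:2) for (a in 1:2) {
      team_next <- fuse_class_values(Q1[nxt[s, a], ], Q2[nxt[s, a], ], rule)
      y <- td_target(rew[s, a], FALSE, team_next, gamma)
      delta <- y - fuse_class_values(Q1[s, ], Q2[s, ], rule)[a]
      Q1[s, a] <- Q1[s, a] + alpha * delta
      Q2[s, a] <- Q2[s, a] + alpha * delta
    }
  }
  expect_lt(max(abs((Q1 + Q2) - Qstar)), 1e-2)
})

test_that("training is a seeded no-op under zero exploration and lr", {
  ds <- fixture_dataset(3)
  model <- build_model(K = 2, seed = 4)
  cfg <- train_config(episodes = 10, epsilon_start = 0, epsilon_end = 0,
                      batch_size = 4, lr = 0, seed = 5)
  fit <- train_agents(model, ds, config = cfg)
  expect_equal(fit$model$spatial$params, model$spatial$params)
  expect_equal(fit$model$temporal$params, model$temporal$params)
})

test_that("training runs are reproducible and logged per episode", {
  ds <- fixture_dataset(4)
  model <- build_model(K = 2, seed = 5)
  cfg <- train_config(episodes = 25, batch_size = 8, seed = 6)
  fit1 <- train_agents(model, ds, config = cfg)
  fit2 <- train_agents(model, ds, config = cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model$spatial$params, fit2$model$spatial$params)
  expect_identical(nrow(fit1$log), 25L)
  expect_true(all(fit1$log$epsilon >= 0.05 & fit1$log$epsilon <= 1))
  expect_error(train_agents(model, ds[1:4], config = cfg), "2 classes")
})

test_that("greedy prediction is deterministic and respects rigged values", {
  img <- fixture_lesion(1, seed = 1)
  # classification of class 2 dominates everywhere -> immediate terminal
  model <- rig_model(biases = c(0, 0, 0, 0, -1, 5))
  out <- predict_lesion(model, img)
  expect_identical(out$class, 2L)
  expect_identical(nrow(out$trajectory), 1L)
  expect_equal(sum(out$probs), 1)
  out2 <- predict_lesion(model, img)
  expect_identical(out, out2)
  # navigation dominates -> forced classification at the horizon
  nav_model <- rig_model(biases = c(2, 0, 0, 0, 1, 1.5))
  out3 <- predict_lesion(nav_model, img, t_max = 4L)
  expect_identical(nrow(out3$trajectory), 5L)
  expect_identical(out3$class, 2L)
})
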
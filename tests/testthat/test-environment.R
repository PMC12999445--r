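test_that("grid geometry follows (image - patch)/stride + 1", {
  expect_identical(build_grid(224, 64, 32)$n_positions_per_axis, 6L)
  expect_identical(build_grid(64, 64, 32)$n_positions_per_axis, 1L)
  expect_error(build_grid(224, 64, 30), "divisible")
  expect_error(build_grid(64, 128, 32), "exceed")
})

test_that("navigation moves one cell and clips at the boundary", {
  grid <- build_grid()
  expect_identical(navigate(c(2L, 2L), "right", grid), c(2L, 3L))
  expect_identical(navigate(c(2L, 2L), "up", grid), c(1L, 2L))
  expect_identical(navigate(c(0L, 5L), "right", grid), c(0L, 5L))
  expect_identical(navigate(c(0L, 0L), "up", grid), c(0L, 0L))
  expect_error(navigate(c(2L, 2L), 5L, grid), "navigation")
})

test_that("random walks never leave the grid", {
  grid <- build_grid()
  pos <- c(2L, 2L)
  set.seed(42)
  for (i in 1:1000) {
    pos <- navigate(pos, sample(4L, 1), grid)
    expect_true(all(pos >= 0L & pos <= 5L))
  }
})

test_that("rewards are +1 / -1 / -0.01 and terminality matches", {
  img <- fixture_lesion(2, seed = 1)  # truth = class 2
  env <- env_new(img)
  s <- env_reset(env)
  nav <- env_step(env, s, 4L)
  expect_equal(nav$reward, -0.01)
  expect_false(nav$terminal)
  expect_identical(nav$next_state$grid_pos, c(2L, 3L))
  # patch/pos consistency after the move
  expect_identical(nav$next_state$patch,
                   lesionnav:::crop_patch(img$pixels, env$grid, c(2L, 3L)))
  right <- env_step(env, s, 4L + 2L)
  expect_equal(right$reward, 1)
  expect_true(right$terminal)
  expect_identical(right$predicted_class, 2L)
  wrong <- env_step(env, s, 4L + 1L)
  expect_equal(wrong$reward, -1)
  expect_true(wrong$terminal)
  expect_error(env_step(env, right$next_state, 1L), "terminal")
  expect_error(env_step(env, s, 99L), "out of range")
})

test_that("every emitted reward lies in the closed reward set", {
  img <- fixture_lesion(1, seed = 2)
  env <- env_new(img)
  s <- env_reset(env)
  set.seed(1)
  for (i in 1:50) {
    a <- sample(6L, 1)
    out <- env_step(env, s, a)
    expect_true(out$reward %in% c(1, -1, -0.01))
    s <- if (out$terminal) env_reset(env) else out$next_state
  }
})

test_that("discounted return matches the closed form", {
  expect_equal(episode_return(1, 0.99), 1.0)
  expect_equal(episode_return(c(-0.01, -0.01, 1), 0.99),
               -0.01 - 0.01 * 0.99 + 0.99^2)
  expect_equal(episode_return(0.37, 0.5), 0.37)
  expect_error(episode_return(numeric(0)), "empty")
  # each extra navigation step strictly lowers the return
  rets <- vapply(0:5, function(n)
    episode_return(c(rep(-0.01, n), 1), 0.99), numeric(1))
  expect_true(all(diff(rets) < 0))
})

test_that("greedy rollouts terminate within the horizon", {
  model <- rig_model(biases = c(1, 0, 0, 0, -1, -1))  # prefers moving up
  out <- predict_lesion(model, fixture_lesion(1, seed = 1), t_max = 16L)
  expect_lte(nrow(out$trajectory), 17L)
  expect_true(out$class %in% 1:2)
})

test_that("positional embeddings are normalized patch centres", {
  grid <- build_grid()
  expect_equal(pos_embedding(c(0L, 0L), grid), c(32, 32) / 224)
  expect_equal(pos_embedding(c(5L, 5L), grid), c(192, 192) / 224)
  expect_length(pos_embedding(c(2L, 2L), grid, sinusoidal = TRUE), 6)
})
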
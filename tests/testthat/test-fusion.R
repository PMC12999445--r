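test_that("VDN summation fuses class values additively", {
  rule <- fusion_rule("vdn-sum", K = 2)
  expect_equal(fuse_class_values(c(0.3, -0.1), c(0.5, 0.2), rule),
               c(0.8, 0.1))
  # full-length q1: class entries sit after the 4 navigation entries
  expect_equal(fuse_class_values(c(9, 9, 9, 9, 0.3, -0.1), c(0.5, 0.2), rule),
               c(0.8, 0.1))
})

test_that("all fusion rules map zero inputs to zero team values", {
  for (kind in c("vdn-sum", "fixed-average", "attention", "concat-head")) {
    rule <- fusion_rule(kind, K = 2, seed = 3)
    expect_equal(fuse_class_values(c(0, 0), c(0, 0), rule), c(0, 0))
  }
  expect_error(fusion_rule("majority-vote"), "unknown fusion")
})

test_that("fixed-average equals half the VDN sum for any inputs", {
  vdn <- fusion_rule("vdn-sum", K = 3)
  avg <- fusion_rule("fixed-average", K = 3)
  set.seed(21)
  for (i in 1:100) {
    q1 <- rnorm(3)
    q2 <- rnorm(3)
    expect_equal(fuse_class_values(q1, q2, avg),
                 0.5 * fuse_class_values(q1, q2, vdn))
  }
})

test_that("attention weights are a convex combination", {
  rule <- fusion_rule("attention", K = 2, d_f = 4, d_h = 4, seed = 5)
  ctx <- list(f = rnorm(4), h = rnorm(4))
  a <- lesionnav:::attention_weights(rule, ctx)
  expect_equal(sum(a), 1)
  expect_true(all(a >= 0))
  fused <- fuse_class_values(c(1, 0), c(0, 1), rule, ctx)
  expect_equal(fused, c(a[1], a[2]))
})

test_that("greedy joint action is the team-value argmax with low-index ties", {
  rule <- fusion_rule("vdn-sum", K = 2)
  # nav values all zero, fused class values (0.9, 0.1) -> classify class 1
  a <- select_joint_action(c(0, 0, 0, 0, 0.6, 0.0), c(0.3, 0.1), rule,
                           epsilon = 0)
  expect_identical(a, 5L)
  expect_identical(select_joint_action(rep(0, 6), c(0, 0), rule, 0), 1L)
  expect_identical(
    select_joint_action(c(0, 0, 0, 0, 5, 7), c(0, 0), rule, 0,
                        force_classify = TRUE), 6L)
  expect_error(select_joint_action(rep(0, 6), c(0, 0), rule, 1.5), "epsilon")
})

test_that("full exploration is uniform over the joint action space", {
  rule <- fusion_rule("vdn-sum", K = 2)
  set.seed(33)
  draws <- replicate(10000, select_joint_action(rep(0, 6), c(0, 0), rule,
                                                epsilon = 1))
  counts <- tabulate(draws, 6)
  p <- 1 / 6
  se <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= 3 * se))
})

test_that("class probabilities follow the temperature softmax", {
  expect_equal(class_probabilities(c(0, 0)), c(0.5, 0.5))
  expect_equal(class_probabilities(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(8)
  for (tau in c(0.1, 1, 10)) {
    v <- rnorm(4)
    p <- class_probabilities(v, tau)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(p, class_probabilities(v + 10, tau), tolerance = 1e-12)
  }
  expect_error(class_probabilities(c(1, 2), tau = 0), "tau")
  expect_error(class_probabilities(c(1, 2), tau = -1), "tau")
})
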
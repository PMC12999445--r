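# Team-value fusion. Per-class team values combine the two agents'
# classification values; navigation team values are the spatial agent's
# alone (the temporal agent has no navigation actions).
#
# Rules: "vdn-sum" (additive, the decision rule of the framework),
# "fixed-average" (0.5/0.5), "attention" (learned convex weights from the
# agents' state summaries) and "concat-head" (learned linear map of the
# concatenated class-value vectors).

FUSION_KINDS <- c("vdn-sum", "attention", "concat-head", "fixed-average")

#' Construct a fusion rule
#'
#' @param kind one of `"vdn-sum"`, `"attention"`, `"concat-head"`,
#'   `"fixed-average"`.
#' @param K number of classes.
#' @param d_f spatial feature dimension (attention scorer input).
#' @param d_h temporal hidden dimension (attention scorer input).
#' @param seed parameter-initialisation seed.
#' @return A `fusion_rule`.
#' @export
fusion_rule <- function(kind = "vdn-sum", K = 2L, d_f = 64L, d_h = 64L,
                        seed = 1L) {
  if (!kind %in% FUSION_KINDS) {
    stop_domain("unknown fusion rule: ", kind,
                " (expected one of ", paste(FUSION_KINDS, collapse = ", "), ")")
  }
  params <- list()
  if (kind == "attention") {
    params <- with_seed(derive_seed(seed, 83L), list(
      u1 = stats::rnorm(d_f, sd = 0.1), c1 = 0,
      u2 = stats::rnorm(d_h, sd = 0.1), c2 = 0
    ))
  } else if (kind == "concat-head") {
    # initialised at the VDN average so the map starts as a sane fusion
    params <- list(W = cbind(diag(0.5, K), diag(0.5, K)), b = numeric(K))
  }
  structure(list(kind = kind, K = as.integer(K), params = params),
            class = "fusion_rule")
}

take_class_part <- function(q1, K) {
  if (length(q1) == K) return(q1)
  if (length(q1) == K + 4L) return(q1[(5L):(K + 4L)])
  stop("q1 arity mismatch: expected length K or K+4", call. = FALSE)
}

attention_weights <- function(rule, context) {
  e1 <- rule$params$c1
  e2 <- rule$params$c2
  if (!is.null(context$f)) e1 <- e1 + sum(rule$params$u1 * context$f)
  if (!is.null(context$h)) e2 <- e2 + sum(rule$params$u2 * context$h)
  m <- max(e1, e2)
  w <- exp(c(e1, e2) - m)
  w / sum(w)
}

#' Fuse per-class action values into team values
#'
#' @param q1 spatial agent values (length `K + 4` or just the K class
#'   entries).
#' @param q2 temporal agent values (length K).
#' @param rule a `fusion_rule`.
#' @param context for the attention rule: list with the agents' state
#'   summaries `f` (spatial feature) and `h` (temporal hidden state);
#'   omitted terms contribute only the scorer biases.
#' @return Numeric vector of K per-class team values.
#' @export
#' @examples
#' fuse_class_values(c(0.3, -0.1), c(0.5, 0.2), fusion_rule("vdn-sum"))
fuse_class_values <- function(q1, q2, rule, context = NULL) {
  K <- rule$K
  if (length(q2) != K) stop("q2 arity mismatch: expected length K", call. = FALSE)
  q1c <- take_class_part(q1, K)
  switch(rule$kind,
    "vdn-sum" = q1c + q2,
    "fixed-average" = 0.5 * q1c + 0.5 * q2,
    "attention" = {
      a <- attention_weights(rule, context)
      a[1] * q1c + a[2] * q2
    },
    "concat-head" = as.vector(rule$params$W %*% c(q1c, q2) + rule$params$b)
  )
}

# full team-value vector over the K+4 joint actions
team_values <- function(q1, q2, rule, context = NULL) {
  c(q1[1:4], fuse_class_values(q1, q2, rule, context))
}

#' Select the joint team action
#'
#' Epsilon-greedy over the fused team values: with probability `1 - epsilon`
#' the argmax of the `K + 4` team values (ties to the lowest action index),
#' otherwise a uniform action. With `force_classify = TRUE` the choice is
#' restricted to the K classification actions (the end-of-horizon rule).
#'
#' @param q1,q2 the two agents' action values.
#' @param rule a `fusion_rule`.
#' @param epsilon exploration probability in \[0,1\].
#' @param context attention context (see [fuse_class_values()]).
#' @param force_classify restrict the choice to classification actions.
#' @return Team action index (1..4 navigation, `4 + c` classification).
#' @export
select_joint_action <- function(q1, q2, rule, epsilon = 0, context = NULL,
                                force_classify = FALSE) {
  if (epsilon < 0 || epsilon > 1) stop_domain("epsilon must be in [0,1]")
  K <- rule$K
  tv <- team_values(q1, q2, rule, context)
  cand <- if (force_classify) (5L):(K + 4L) else seq_len(K + 4L)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    cand[sample.int(length(cand), 1L)]
  } else {
    cand[which.max(tv[cand])]
  }
}

#' Class probabilities from fused values (temperature softmax)
#'
#' @param fused_class_values numeric vector of K team class values.
#' @param tau temperature (> 0).
#' @return Probability vector (strictly positive, sums to 1; invariant to
#'   adding a constant to all values).
#' @export
#' @examples
#' class_probabilities(c(log(2), 0))  # c(2/3, 1/3)
class_probabilities <- function(fused_class_values, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop_domain("tau must be a positive scalar")
  }
  z <- fused_class_values / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Gradient of the fused value of class `c_idx` w.r.t. both class-value
# vectors, the fusion parameters, and (attention) the state summaries.
# `g` is the upstream scalar gradient.
fusion_backward <- function(rule, g, c_idx, q1c, q2, context = NULL) {
  K <- rule$K
  dq1c <- numeric(K)
  dq2 <- numeric(K)
  dparams <- NULL
  dF <- NULL
  dH <- NULL
  if (rule$kind == "vdn-sum") {
    dq1c[c_idx] <- g
    dq2[c_idx] <- g
  } else if (rule$kind == "fixed-average") {
    dq1c[c_idx] <- 0.5 * g
    dq2[c_idx] <- 0.5 * g
  } else if (rule$kind == "attention") {
    a <- attention_weights(rule, context)
    dq1c[c_idx] <- a[1] * g
    dq2[c_idx] <- a[2] * g
    # d fused / d e1 = a1 a2 (q1c - q2c); softmax over two logits
    dde1 <- g * a[1] * a[2] * (q1c[c_idx] - q2[c_idx])
    dparams <- list(
      u1 = if (is.null(context$f)) numeric(length(rule$params$u1)) else dde1 * context$f,
      c1 = dde1,
      u2 = if (is.null(context$h)) numeric(length(rule$params$u2)) else -dde1 * context$h,
      c2 = -dde1
    )
    if (!is.null(context$f)) dF <- dde1 * rule$params$u1
    if (!is.null(context$h)) dH <- -dde1 * rule$params$u2
  } else if (rule$kind == "concat-head") {
    w <- rule$params$W[c_idx, ]
    dq1c <- g * w[seq_len(K)]
    dq2 <- g * w[K + seq_len(K)]
    dW <- array(0, dim(rule$params$W))
    dW[c_idx, ] <- g * c(q1c, q2)
    db <- numeric(K)
    db[c_idx] <- g
    dparams <- list(W = dW, b = db)
  }
  list(dq1c = dq1c, dq2 = dq2, dparams = dparams, dF = dF, dH = dH)
}
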
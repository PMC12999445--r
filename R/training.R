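# Centralized training with decentralized execution: episodes are collected
# with epsilon-greedy team play, transitions go to a replay buffer, and both
# agents (plus any fusion parameters) receive gradient steps on the joint
# TD objective; target copies of all parameters are synced periodically.

#' Training configuration
#'
#' @param episodes number of training episodes.
#' @param gamma discount factor.
#' @param tau softmax temperature for reported class probabilities.
#' @param epsilon_start,epsilon_end,epsilon_frac linear exploration schedule:
#'   epsilon decays from start to end over `epsilon_frac` of the episodes.
#' @param batch_size replay minibatch size.
#' @param target_sync target-network sync period in gradient steps.
#' @param lr Adam learning rate.
#' @param replay_capacity replay buffer capacity.
#' @param grad_steps_per_episode gradient steps after each episode.
#' @param t_max navigation-step horizon before forced classification.
#' @param seed master seed for the run.
#' @return A `train_config` list.
#' @export
train_config <- function(episodes = 500L, gamma = 0.99, tau = 1.0,
                         epsilon_start = 1.0, epsilon_end = 0.05,
                         epsilon_frac = 0.6, batch_size = 32L,
                         target_sync = 200L, lr = 1e-4,
                         replay_capacity = 10000L,
                         grad_steps_per_episode = 1L,
                         t_max = 16L, seed = 7L) {
  cfg <- list(episodes = as.integer(episodes), gamma = gamma, tau = tau,
              epsilon_start = epsilon_start, epsilon_end = epsilon_end,
              epsilon_frac = epsilon_frac, batch_size = as.integer(batch_size),
              target_sync = as.integer(target_sync), lr = lr,
              replay_capacity = as.integer(replay_capacity),
              grad_steps_per_episode = as.integer(grad_steps_per_episode),
              t_max = as.integer(t_max), seed = as.integer(seed))
  if (cfg$gamma <= 0 || cfg$gamma > 1) stop_domain("gamma must be in (0,1]")
  if (cfg$tau <= 0) stop_domain("tau must be positive")
  if (cfg$epsilon_start < 0 || cfg$epsilon_start > 1 ||
      cfg$epsilon_end < 0 || cfg$epsilon_end > 1) {
    stop_domain("epsilon must be in [0,1]")
  }
  cfg
}

#' Assemble an untrained team model
#'
#' @param K number of classes.
#' @param spatial_backbone `"small-cnn"` or `"resnet50-style"`.
#' @param temporal_backbone `"gru"` or `"lstm"`.
#' @param fusion fusion rule kind (see [fusion_rule()]).
#' @param pos_dim positional-embedding dimension (2 plain, 6 sinusoidal).
#' @param d_emb,d_hidden temporal net dimensions.
#' @param seed weight-initialisation seed.
#' @return Model list with `spatial`, `temporal`, `fusion`, `meta`.
#' @export
build_model <- function(K = 2L, spatial_backbone = "small-cnn",
                        temporal_backbone = "gru", fusion = "vdn-sum",
                        pos_dim = 2L, d_emb = 32L, d_hidden = 32L,
                        seed = 1L) {
  spatial <- spatial_qnet(K, spatial_backbone, pos_dim = pos_dim, seed = seed)
  temporal <- temporal_qnet(K, backbone = temporal_backbone, d_emb = d_emb,
                            d_hidden = d_hidden, seed = seed)
  rule <- fusion_rule(fusion, K = K, d_f = spatial$spec$d_f,
                      d_h = 2L * d_hidden, seed = seed)
  list(spatial = spatial, temporal = temporal, fusion = rule,
       meta = list(seed = as.integer(seed)))
}

#' One-step TD target
#'
#' @param reward transition reward.
#' @param terminal whether the transition ended the episode.
#' @param next_team_values team values of all joint actions at the next
#'   state, computed with the frozen target parameters (ignored for terminal
#'   transitions).
#' @param gamma discount factor.
#' @return `reward` for terminal transitions, otherwise
#'   `reward + gamma * max(next_team_values)`.
#' @export
#' @examples
#' td_target(1, TRUE, NULL)                 # 1
#' td_target(-0.01, FALSE, c(0.2, 1.0))     # -0.01 + 0.99
td_target <- function(reward, terminal, next_team_values, gamma = 0.99) {
  if (terminal) return(reward)
  reward + gamma * max(next_team_values)
}

# frame used for spatial observation (last frame of a sequence)
item_frame <- function(item) {
  if (inherits(item, "lesion_sequence")) item$frames[[length(item$frames)]] else item
}

item_label <- function(item) item_frame(item)$label

# Forward pass caches for a batch of transitions, shared between the
# loss/gradient computation and the public vdn_loss.
batch_forward <- function(model, target_model, batch, grid, gamma,
                          token_cache) {
  n <- length(batch)
  K <- model$spatial$K
  ps <- grid$patch_size
  pos_dim <- model$spatial$pos_dim
  sinus <- pos_dim > 2
  X <- array(0, c(ps, ps, 3, n))
  P <- matrix(0, pos_dim, n)
  for (j in seq_len(n)) {
    tr <- batch[[j]]
    X[, , , j] <- crop_patch(tr$pixels, grid, tr$pos)
    P[, j] <- pos_embedding(tr$pos, grid, sinus)
  }
  fw1 <- spatial_forward(model$spatial, X, P)
  # one temporal forward per distinct item in the batch
  items <- vapply(batch, function(tr) tr$item, integer(1))
  uitems <- unique(items)
  fwt <- lapply(uitems, function(i) temporal_forward(model$temporal,
                                                     token_cache[[i]]))
  names(fwt) <- as.character(uitems)

  # TD targets from the frozen target parameters
  nonterm <- which(!vapply(batch, function(tr) tr$terminal, logical(1)))
  y <- vapply(batch, function(tr) tr$reward, numeric(1))
  if (length(nonterm)) {
    Xn <- array(0, c(ps, ps, 3, length(nonterm)))
    Pn <- matrix(0, pos_dim, length(nonterm))
    for (jj in seq_along(nonterm)) {
      tr <- batch[[nonterm[jj]]]
      Xn[, , , jj] <- crop_patch(tr$pixels, grid, tr$next_pos)
      Pn[, jj] <- pos_embedding(tr$next_pos, grid, sinus)
    }
    fw1n <- spatial_forward(target_model$spatial, Xn, Pn)
    fwtn <- lapply(uitems, function(i) temporal_forward(target_model$temporal,
                                                        token_cache[[i]]))
    names(fwtn) <- as.character(uitems)
    for (jj in seq_along(nonterm)) {
      j <- nonterm[jj]
      tr <- batch[[j]]
      tn <- fwtn[[as.character(tr$item)]]
      tv <- team_values(fw1n$q[, jj], tn$q, target_model$fusion,
                        context = list(f = fw1n$cache$bb$f[, jj], h = tn$h))
      y[j] <- td_target(tr$reward, FALSE, tv, gamma)
    }
  }
  list(n = n, K = K, fw1 = fw1, fwt = fwt, items = items, y = y)
}

# team value of the taken action for each transition in the cache
batch_taken_values <- function(model, bf) {
  vapply(seq_len(bf$n), function(j) {
    tr_item <- as.character(bf$items[j])
    a <- bf$action[j]
    if (is_nav_action(a)) {
      bf$fw1$q[a, j]
    } else {
      tfw <- bf$fwt[[tr_item]]
      fuse_class_values(bf$fw1$q[, j], tfw$q, model$fusion,
                        context = list(f = bf$fw1$cache$bb$f[, j],
                                       h = tfw$h))[action_to_class(a)]
    }
  }, numeric(1))
}

#' Joint TD loss of a transition batch
#'
#' Mean squared error between the one-step TD targets (computed with the
#' target parameters) and the team value of each taken action (computed with
#' the online parameters).
#'
#' @param batch list of transition records (fields `pixels`, `item`, `pos`,
#'   `action`, `reward`, `next_pos`, `terminal`), as stored by
#'   [train_agents()].
#' @param model online model (spatial, temporal, fusion).
#' @param target_model frozen target copy.
#' @param token_cache list mapping item index to descriptor tokens.
#' @param grid patch grid.
#' @param gamma discount factor.
#' @return Scalar loss (nonnegative).
#' @export
vdn_loss <- function(batch, model, target_model, token_cache,
                     grid = build_grid(), gamma = 0.99) {
  if (length(batch) == 0) stop("empty transition batch", call. = FALSE)
  bf <- batch_forward(model, target_model, batch, grid, gamma, token_cache)
  bf$action <- vapply(batch, function(tr) tr$action, integer(1))
  mean((bf$y - batch_taken_values(model, bf))^2)
}

# loss + gradients + Adam update for one minibatch; returns the updated
# model/optimiser state and the loss value
train_step <- function(model, target_model, batch, token_cache, grid, gamma,
                       opt) {
  bf <- batch_forward(model, target_model, batch, grid, gamma, token_cache)
  bf$action <- vapply(batch, function(tr) tr$action, integer(1))
  qtaken <- batch_taken_values(model, bf)
  resid <- qtaken - bf$y
  loss <- mean(resid^2)
  n <- bf$n
  K <- bf$K

  dQ1 <- matrix(0, K + 4L, n)
  dF_extra <- matrix(0, model$spatial$spec$d_f, n)
  dq2_by_item <- list()
  dh_by_item <- list()
  fus_grads <- NULL
  for (j in seq_len(n)) {
    g <- 2 * resid[j] / n
    a <- bf$action[j]
    if (is_nav_action(a)) {
      dQ1[a, j] <- dQ1[a, j] + g
    } else {
      key <- as.character(bf$items[j])
      tfw <- bf$fwt[[key]]
      ctx <- list(f = bf$fw1$cache$bb$f[, j], h = tfw$h)
      fb <- fusion_backward(model$fusion, g, action_to_class(a),
                            take_class_part(bf$fw1$q[, j], K), tfw$q, ctx)
      dQ1[4L + seq_len(K), j] <- dQ1[4L + seq_len(K), j] + fb$dq1c
      dq2_by_item[[key]] <- (dq2_by_item[[key]] %||% numeric(K)) + fb$dq2
      if (!is.null(fb$dH)) {
        dh_by_item[[key]] <- (dh_by_item[[key]] %||%
                                numeric(length(tfw$h))) + fb$dH
      }
      if (!is.null(fb$dF)) dF_extra[, j] <- dF_extra[, j] + fb$dF
      if (!is.null(fb$dparams)) {
        fus_grads <- if (is.null(fus_grads)) fb$dparams else
          mapply(`+`, fus_grads, fb$dparams, SIMPLIFY = FALSE)
      }
    }
  }

  gs <- spatial_backward(model$spatial, bf$fw1$cache, dQ1,
                         dF_extra = if (any(dF_extra != 0)) dF_extra else NULL)
  upd <- adam_step(opt$spatial, model$spatial$params, gs)
  opt$spatial <- upd$state
  model$spatial$params <- upd$params

  if (length(dq2_by_item)) {
    gt_tot <- NULL
    for (key in names(dq2_by_item)) {
      g <- temporal_backward(model$temporal, bf$fwt[[key]]$cache,
                             dq2_by_item[[key]], dh_extra = dh_by_item[[key]])
      gt_tot <- if (is.null(gt_tot)) g else mapply(`+`, gt_tot, g,
                                                   SIMPLIFY = FALSE)
    }
    upd <- adam_step(opt$temporal, model$temporal$params, gt_tot)
    opt$temporal <- upd$state
    model$temporal$params <- upd$params
  }

  if (!is.null(fus_grads) && length(model$fusion$params)) {
    upd <- adam_step(opt$fusion, model$fusion$params, fus_grads)
    opt$fusion <- upd$state
    model$fusion$params <- upd$params
  }

  list(model = model, opt = opt, loss = loss)
}

epsilon_at <- function(cfg, episode) {
  decay_len <- max(1, round(cfg$epsilon_frac * cfg$episodes))
  frac <- min(1, (episode - 1) / decay_len)
  cfg$epsilon_start + frac * (cfg$epsilon_end - cfg$epsilon_start)
}

#' Train the multi-agent team
#'
#' Runs episodic epsilon-greedy collection on the labelled dataset, stores
#' transitions in a replay buffer, and performs Adam gradient steps on the
#' joint TD loss with periodic target-network synchronisation. Fully
#' reproducible from `config$seed`.
#'
#' @param model an untrained model from [build_model()] (or a trained one to
#'   continue training).
#' @param dataset list of labelled `lesion_image` / `lesion_sequence`
#'   objects covering at least 2 classes.
#' @param config a [train_config()].
#' @param grid patch grid.
#' @return List with the trained `model` and a `log` data frame
#'   (episode, return, loss, epsilon).
#' @export
train_agents <- function(model, dataset, config = train_config(),
                         grid = build_grid()) {
  labels <- vapply(dataset, item_label, integer(1))
  if (length(unique(labels)) < 2) {
    stop_domain("dataset must contain at least 2 classes")
  }
  K <- model$spatial$K
  if (max(labels) > K) stop_domain("dataset labels exceed model K")

  token_cache <- lapply(dataset, function(it) describe_input(it)$tokens)
  frames <- lapply(dataset, function(it) item_frame(it)$pixels)

  opt <- list(spatial = adam_new(model$spatial$params, lr = config$lr),
              temporal = adam_new(model$temporal$params, lr = config$lr),
              fusion = adam_new(model$fusion$params, lr = config$lr))
  target_model <- model
  buf <- replay_new(config$replay_capacity)
  log <- data.frame(episode = integer(config$episodes),
                    return = numeric(config$episodes),
                    loss = numeric(config$episodes),
                    epsilon = numeric(config$episodes))
  grad_steps <- 0L

  with_seed(config$seed, {
    for (ep in seq_len(config$episodes)) {
      eps <- epsilon_at(config, ep)
      i <- sample.int(length(dataset), 1L)
      item <- dataset[[i]]
      tfw <- temporal_forward(model$temporal, token_cache[[i]])
      env <- env_new(item, grid = grid, K = K, t_max = config$t_max,
                     gamma = config$gamma,
                     sinusoidal_pos = model$spatial$pos_dim > 2)
      state <- env_reset(env, text_hidden = tfw$h)
      rewards <- numeric(0)
      repeat {
        fw <- spatial_forward(model$spatial, state$patch, state$pos_embed)
        q1 <- as.vector(fw$q)
        force <- state$step_index >= config$t_max
        a <- select_joint_action(q1, tfw$q, model$fusion, epsilon = eps,
                                 context = list(f = as.vector(fw$cache$bb$f),
                                                h = tfw$h),
                                 force_classify = force)
        out <- env_step(env, state, a)
        replay_push(buf, list(
          item = i, pixels = frames[[i]], pos = state$grid_pos,
          action = a, reward = out$reward,
          next_pos = out$next_state$grid_pos, terminal = out$terminal
        ))
        rewards <- c(rewards, out$reward)
        state <- out$next_state
        if (out$terminal) break
      }
      loss <- NA_real_
      if (replay_size(buf) >= config$batch_size) {
        for (gstep in seq_len(config$grad_steps_per_episode)) {
          batch <- replay_sample(buf, config$batch_size)
          st <- train_step(model, target_model, batch, token_cache, grid,
                           config$gamma, opt)
          model <- st$model
          opt <- st$opt
          loss <- st$loss
          grad_steps <- grad_steps + 1L
          if (grad_steps %% config$target_sync == 0L) target_model <- model
        }
      }
      log$episode[ep] <- ep
      log$return[ep] <- episode_return(rewards, config$gamma)
      log$loss[ep] <- loss
      log$epsilon[ep] <- eps
    }
  })
  list(model = model, log = log)
}

#' Greedy diagnosis of one lesion
#'
#' Rolls out the greedy team policy (epsilon = 0) from the start position;
#' at the navigation horizon the choice is restricted to classification
#' actions. Returns the terminating class, the temperature-softmax class
#' probabilities at the terminal step, and the visited trajectory.
#'
#' @param model trained (or initialised) model.
#' @param item a `lesion_image` or `lesion_sequence`.
#' @param grid patch grid.
#' @param t_max navigation horizon.
#' @param tau softmax temperature.
#' @return List with `class`, `probs`, `trajectory` (data frame of step,
#'   row, col, action, reward).
#' @export
predict_lesion <- function(model, item, grid = build_grid(), t_max = 16L,
                           tau = 1.0) {
  K <- model$spatial$K
  tokens <- describe_input(item)$tokens
  tfw <- temporal_forward(model$temporal, tokens)
  env <- env_new(item, grid = grid, K = K, t_max = t_max,
                 sinusoidal_pos = model$spatial$pos_dim > 2)
  state <- env_reset(env, text_hidden = tfw$h)
  steps <- list()
  repeat {
    fw <- spatial_forward(model$spatial, state$patch, state$pos_embed)
    q1 <- as.vector(fw$q)
    ctx <- list(f = as.vector(fw$cache$bb$f), h = tfw$h)
    force <- state$step_index >= t_max
    a <- select_joint_action(q1, tfw$q, model$fusion, epsilon = 0,
                             context = ctx, force_classify = force)
    out <- env_step(env, state, a)
    steps[[length(steps) + 1L]] <- data.frame(
      step = state$step_index, row = state$grid_pos[1],
      col = state$grid_pos[2], action = a, reward = out$reward
    )
    if (out$terminal) {
      fused <- fuse_class_values(q1, tfw$q, model$fusion, context = ctx)
      return(list(class = out$predicted_class,
                  probs = class_probabilities(fused, tau),
                  trajectory = do.call(rbind, steps)))
    }
    state <- out$next_state
  }
}
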
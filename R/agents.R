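# The two Q-function approximators:
#  - spatial agent: CNN backbone over a 64x64x3 patch, global average pool to
#    a feature vector f_t, positional embedding concatenated, 2-layer MLP head
#    (hidden 512, ReLU) to K+4 action values.
#  - temporal/text agent: token embedding + bidirectional GRU/LSTM encoder,
#    linear head from the concatenated final hidden states to K class values.

#' Construct a backbone specification
#'
#' Spatial backbones: `"small-cnn"` (default desk-scale backbone: 2x
#' average-pool stem, three stride-2 conv blocks with 16/32/64 channels,
#' global average pooling, d_f = 64) and `"resnet50-style"` (deeper residual
#' variant ending in 2048 channels so d_f = 2048 after global average
#' pooling; randomly initialised, no pretrained weights). Temporal backbones:
#' `"gru"` and `"lstm"` (both bidirectional).
#'
#' @param name backbone name.
#' @return A backbone spec consumed by [spatial_qnet()] / [temporal_qnet()].
#' @export
make_backbone <- function(name) {
  switch(name,
    "small-cnn" = list(family = "spatial", name = name, d_f = 64L,
                       ops = list(
                         list(type = "avgpool", k = 2L),
                         list(type = "conv", c_in = 3L, c_out = 16L, k = 3L, stride = 2L),
                         list(type = "relu"),
                         list(type = "conv", c_in = 16L, c_out = 32L, k = 3L, stride = 2L),
                         list(type = "relu"),
                         list(type = "conv", c_in = 32L, c_out = 64L, k = 3L, stride = 2L),
                         list(type = "relu"),
                         list(type = "gap")
                       )),
    "resnet50-style" = list(family = "spatial", name = name, d_f = 2048L,
                            ops = list(
                              list(type = "avgpool", k = 2L),
                              list(type = "conv", c_in = 3L, c_out = 64L, k = 3L, stride = 2L),
                              list(type = "relu"),
                              list(type = "resblock", c = 64L),
                              list(type = "conv", c_in = 64L, c_out = 128L, k = 3L, stride = 2L),
                              list(type = "relu"),
                              list(type = "resblock", c = 128L),
                              list(type = "conv", c_in = 128L, c_out = 2048L, k = 3L, stride = 2L),
                              list(type = "relu"),
                              list(type = "gap")
                            )),
    "gru" = list(family = "temporal", name = "gru"),
    "lstm" = list(family = "temporal", name = "lstm"),
    stop_domain("unknown backbone: ", name)
  )
}

init_backbone_params <- function(spec) {
  params <- list()
  for (i in seq_along(spec$ops)) {
    op <- spec$ops[[i]]
    if (op$type == "conv") {
      ly <- conv_layer(op$c_in, op$c_out, op$k, op$stride)
      params[[paste0("b", i, ".W")]] <- ly$W
      params[[paste0("b", i, ".b")]] <- ly$b
    } else if (op$type == "resblock") {
      for (j in 1:2) {
        ly <- conv_layer(op$c, op$c, 1L, 1L)
        params[[paste0("b", i, ".", j, ".W")]] <- ly$W
        params[[paste0("b", i, ".", j, ".b")]] <- ly$b
      }
    }
  }
  params
}

#' Spatial Q-network
#'
#' @param K number of classes; the output has `K + 4` action values
#'   (4 navigation + K classification).
#' @param backbone `"small-cnn"` or `"resnet50-style"`.
#' @param pos_dim positional-embedding dimension (2, or 6 sinusoidal).
#' @param patch_size expected patch side length.
#' @param seed weight-initialisation seed.
#' @return A `spatial_qnet`.
#' @export
spatial_qnet <- function(K, backbone = "small-cnn", pos_dim = 2L,
                         patch_size = 64L, seed = 1L) {
  spec <- if (is.character(backbone)) make_backbone(backbone) else backbone
  if (spec$family != "spatial") stop_domain("not a spatial backbone: ", spec$name)
  with_seed(derive_seed(seed, 31L), {
    params <- init_backbone_params(spec)
    h1 <- dense_layer(spec$d_f + pos_dim, 512L)
    h2 <- dense_layer(512L, K + 4L)
    params$head1.W <- h1$W
    params$head1.b <- h1$b
    params$head2.W <- h2$W
    params$head2.b <- h2$b
    structure(
      list(K = as.integer(K), spec = spec, pos_dim = as.integer(pos_dim),
           patch_size = as.integer(patch_size), params = params),
      class = "spatial_qnet"
    )
  })
}

conv_from_params <- function(net, nm, op) {
  list(type = "conv", k = op$k %||% 1L, stride = op$stride %||% 1L,
       c_in = op$c_in %||% op$c, c_out = op$c_out %||% op$c,
       W = net$params[[paste0(nm, ".W")]], b = net$params[[paste0(nm, ".b")]])
}

backbone_forward <- function(net, X) {
  caches <- vector("list", length(net$spec$ops))
  for (i in seq_along(net$spec$ops)) {
    op <- net$spec$ops[[i]]
    if (op$type == "avgpool") {
      X <- avgpool_forward(X, op$k)
    } else if (op$type == "conv") {
      fw <- conv_forward(conv_from_params(net, paste0("b", i), op), X)
      caches[[i]] <- fw$cache
      X <- fw$out
    } else if (op$type == "relu") {
      X <- relu(X)
      caches[[i]] <- X
    } else if (op$type == "resblock") {
      c1 <- conv_from_params(net, paste0("b", i, ".1"), op)
      c2 <- conv_from_params(net, paste0("b", i, ".2"), op)
      f1 <- conv_forward(c1, X)
      a1 <- relu(f1$out)
      f2 <- conv_forward(c2, a1)
      out <- relu(X + f2$out)
      caches[[i]] <- list(cache1 = f1$cache, cache2 = f2$cache, a1 = a1, out = out)
      X <- out
    } else if (op$type == "gap") {
      caches[[i]] <- dim(X)
      X <- gap_forward(X)
    }
  }
  list(f = X, caches = caches)
}

backbone_backward <- function(net, caches, dF) {
  grads <- list()
  dX <- dF
  ops <- net$spec$ops
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]
    if (op$type == "gap") {
      dX <- gap_backward(dX, caches[[i]])
    } else if (op$type == "relu") {
      dX <- relu_backward(dX, caches[[i]])
    } else if (op$type == "conv") {
      ly <- conv_from_params(net, paste0("b", i), op)
      # no gradient past the first trainable layer is ever needed
      first_conv <- !any(vapply(ops[seq_len(i - 1)], function(o)
        o$type %in% c("conv", "resblock"), logical(1)))
      bk <- conv_backward(ly, dX, caches[[i]], need_dx = !first_conv)
      grads[[paste0("b", i, ".W")]] <- bk$dW
      grads[[paste0("b", i, ".b")]] <- bk$db
      dX <- bk$dX
    } else if (op$type == "resblock") {
      cc <- caches[[i]]
      dOut <- relu_backward(dX, cc$out)
      c2 <- conv_from_params(net, paste0("b", i, ".2"), op)
      c1 <- conv_from_params(net, paste0("b", i, ".1"), op)
      bk2 <- conv_backward(c2, dOut, cc$cache2)
      da1 <- relu_backward(bk2$dX, cc$a1)
      bk1 <- conv_backward(c1, da1, cc$cache1)
      grads[[paste0("b", i, ".2.W")]] <- bk2$dW
      grads[[paste0("b", i, ".2.b")]] <- bk2$db
      grads[[paste0("b", i, ".1.W")]] <- bk1$dW
      grads[[paste0("b", i, ".1.b")]] <- bk1$db
      dX <- bk1$dX + dOut
    }
    # avgpool only ever precedes the first trainable layer; backward not needed
  }
  grads
}

spatial_forward <- function(net, X, P) {
  if (length(dim(X)) == 3) dim(X) <- c(dim(X), 1L)
  if (is.null(dim(P))) P <- matrix(P, ncol = dim(X)[4])
  X <- imagenet_normalize_batch(X)
  bb <- backbone_forward(net, X)
  Z <- rbind(bb$f, P)
  A1 <- net$params$head1.W %*% Z + net$params$head1.b
  H1 <- relu(A1)
  Q <- net$params$head2.W %*% H1 + net$params$head2.b
  list(q = Q, cache = list(bb = bb, Z = Z, H1 = H1))
}

imagenet_normalize_batch <- function(X) {
  d <- dim(X)
  key <- paste("inorm", d[1], d[2])
  mv <- .nn_cache[[key]]
  if (is.null(mv)) {
    hw <- d[1] * d[2]
    mv <- list(m = rep(c(0.485, 0.456, 0.406), each = hw),
               s = rep(c(0.229, 0.224, 0.225), each = hw))
    .nn_cache[[key]] <- mv
  }
  # recycling over the batch dimension (length(m) == H*W*3 divides length(X))
  array((X - mv$m) / mv$s, d)
}

spatial_backward <- function(net, cache, dQ, dF_extra = NULL) {
  g2 <- list(dW = tcrossprod(dQ, cache$H1), db = rowSums(dQ))
  dH1 <- crossprod(net$params$head2.W, dQ)
  dA1 <- relu_backward(dH1, cache$H1)
  g1 <- list(dW = tcrossprod(dA1, cache$Z), db = rowSums(dA1))
  dZ <- crossprod(net$params$head1.W, dA1)
  d_f <- net$spec$d_f
  dF <- dZ[seq_len(d_f), , drop = FALSE]
  if (!is.null(dF_extra)) dF <- dF + dF_extra
  grads <- backbone_backward(net, cache$bb$caches, dF)
  grads$head1.W <- g1$dW
  grads$head1.b <- g1$db
  grads$head2.W <- g2$dW
  grads$head2.b <- g2$db
  grads
}

#' Spatial agent action values
#'
#' Channel-normalises the patch (ImageNet constants), extracts backbone
#' features, concatenates the positional embedding and applies the MLP head.
#'
#' @param net a `spatial_qnet`.
#' @param patch 64x64x3 array (or HxWx3xN batch).
#' @param pos_embed positional embedding vector (or matrix for a batch).
#' @return Numeric vector of `K + 4` action values (matrix for a batch).
#' @export
spatial_q <- function(net, patch, pos_embed) {
  d <- dim(patch)
  if (is.null(d) || !(length(d) %in% c(3, 4)) ||
      d[1] != net$patch_size || d[2] != net$patch_size || d[3] != 3) {
    stop("patch shape mismatch: expected ",
         net$patch_size, "x", net$patch_size, "x3", call. = FALSE)
  }
  plen <- if (is.null(dim(pos_embed))) length(pos_embed) else nrow(pos_embed)
  if (plen != net$pos_dim) {
    stop("pos_embed length mismatch: expected ", net$pos_dim, call. = FALSE)
  }
  q <- spatial_forward(net, patch, pos_embed)$q
  if (ncol(q) == 1) as.vector(q) else q
}

#' Temporal/text Q-network
#'
#' @param K number of classes (the output arity).
#' @param vocab_size descriptor vocabulary size.
#' @param backbone `"gru"` or `"lstm"` (bidirectional either way).
#' @param d_emb token-embedding dimension.
#' @param d_hidden per-direction hidden size; the encoder state `h_t` has
#'   dimension `2 * d_hidden`.
#' @param seed weight-initialisation seed.
#' @return A `temporal_qnet`.
#' @export
temporal_qnet <- function(K, vocab_size = length(lesion_vocabulary()),
                          backbone = "gru", d_emb = 32L, d_hidden = 32L,
                          seed = 1L) {
  spec <- if (is.character(backbone)) make_backbone(backbone) else backbone
  if (spec$family != "temporal") stop_domain("not a temporal backbone: ", spec$name)
  with_seed(derive_seed(seed, 47L), {
    cf <- rnn_cell(spec$name, d_emb, d_hidden)
    cb <- rnn_cell(spec$name, d_emb, d_hidden)
    head <- dense_layer(2L * d_hidden, K)
    structure(
      list(K = as.integer(K), kind = spec$name,
           vocab_size = as.integer(vocab_size),
           d_emb = as.integer(d_emb), d_hidden = as.integer(d_hidden),
           params = list(
             E = he_init(d_emb, vocab_size, fan_in = d_emb),
             f.W = cf$W, f.U = cf$U, f.b = cf$b,
             b.W = cb$W, b.U = cb$U, b.b = cb$b,
             head.W = head$W, head.b = head$b
           )),
      class = "temporal_qnet"
    )
  })
}

temporal_cells <- function(net) {
  list(
    f = list(kind = net$kind, H = net$d_hidden, d_in = net$d_emb,
             W = net$params$f.W, U = net$params$f.U, b = net$params$f.b),
    b = list(kind = net$kind, H = net$d_hidden, d_in = net$d_emb,
             W = net$params$b.W, U = net$params$b.U, b = net$params$b.b)
  )
}

temporal_forward <- function(net, tokens) {
  X <- net$params$E[, tokens, drop = FALSE]
  cells <- temporal_cells(net)
  enc <- bi_forward(cells$f, cells$b, X)
  q <- as.vector(net$params$head.W %*% enc$h + net$params$head.b)
  list(q = q, h = enc$h, cache = list(enc = enc, tokens = tokens, cells = cells))
}

temporal_backward <- function(net, cache, dq, dh_extra = NULL) {
  dh <- as.vector(crossprod(net$params$head.W, dq))
  if (!is.null(dh_extra)) dh <- dh + dh_extra
  gW <- tcrossprod(dq, cache$enc$h)
  bk <- bi_backward(cache$cells$f, cache$cells$b, dh, cache$enc)
  dE <- array(0, dim(net$params$E))
  for (t in seq_along(cache$tokens)) {
    tok <- cache$tokens[t]
    dE[, tok] <- dE[, tok] + bk$dX[, t]
  }
  list(E = dE,
       f.W = bk$f$dW, f.U = bk$f$dU, f.b = bk$f$db,
       b.W = bk$b$dW, b.U = bk$b$dU, b.b = bk$b$db,
       head.W = gW, head.b = dq)
}

#' Temporal agent action values
#'
#' Embeds the descriptor tokens, encodes them with the bidirectional
#' recurrent network and maps the concatenated final hidden states to K
#' per-class action values.
#'
#' @param net a `temporal_qnet`.
#' @param tokens a `text_descriptor` or integer token vector.
#' @return Numeric vector of K action values.
#' @export
temporal_q <- function(net, tokens) {
  if (inherits(tokens, "text_descriptor")) tokens <- tokens$tokens
  if (length(tokens) == 0) stop_domain("empty token list")
  if (any(tokens < 1 | tokens > net$vocab_size)) {
    stop_domain("token index outside vocabulary (size ", net$vocab_size, ")")
  }
  temporal_forward(net, tokens)$q
}

#' Encoder hidden state for a descriptor
#' @param net a `temporal_qnet`.
#' @param tokens a `text_descriptor` or integer token vector.
#' @return Numeric hidden-state vector of length `2 * d_hidden`.
#' @export
temporal_hidden <- function(net, tokens) {
  if (inherits(tokens, "text_descriptor")) tokens <- tokens$tokens
  temporal_forward(net, tokens)$h
}

# -- checkpoints -------------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the networks and fusion rule to a single archive file plus a JSON
#' metadata sidecar (`<path>.json`) recording backbones, K, dims and seed.
#'
#' @param model list with `spatial`, `temporal`, `fusion` and optional `meta`.
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    package = "lesionnav",
    K = model$spatial$K,
    spatial_backbone = model$spatial$spec$name,
    temporal_backbone = model$temporal$kind,
    d_f = model$spatial$spec$d_f,
    d_emb = model$temporal$d_emb,
    d_hidden = model$temporal$d_hidden,
    fusion = model$fusion$kind,
    seed = model$meta$seed %||% NA
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file path written by [save_checkpoint()].
#' @return The model list.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_domain("checkpoint not found: ", path)
  readRDS(path)
}

#' Supervised warm start
#'
#' Optional pre-training stage: regresses the classification entries of both
#' agents' action values toward +1 for the true class and -1 otherwise on a
#' labelled dataset, mirroring a supervised pre-fine-tuning of the backbone
#' before reinforcement learning.
#'
#' @param model list with `spatial` and `temporal` networks.
#' @param dataset list of `lesion_image`/`lesion_sequence`.
#' @param epochs passes over the dataset.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed shuffling seed.
#' @param grid patch grid (patches are sampled at the start position).
#' @return The model with updated networks.
#' @export
warm_start <- function(model, dataset, epochs = 1L, lr = 1e-3,
                       batch_size = 16L, seed = 1L, grid = build_grid()) {
  spatial <- model$spatial
  temporal <- model$temporal
  K <- spatial$K
  opt_s <- adam_new(spatial$params, lr = lr)
  opt_t <- adam_new(temporal$params, lr = lr)
  pos <- start_position(grid)
  with_seed(derive_seed(seed, 71L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(dataset))
      for (start in seq(1, length(ord), by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1, length(ord))]
        n <- length(ids)
        X <- array(0, c(grid$patch_size, grid$patch_size, 3, n))
        P <- matrix(0, spatial$pos_dim, n)
        Y <- matrix(-1, K, n)
        for (j in seq_len(n)) {
          item <- dataset[[ids[j]]]
          frame <- if (inherits(item, "lesion_sequence")) item$frames[[3]] else item
          X[, , , j] <- crop_patch(frame$pixels, grid, pos)
          P[, j] <- pos_embedding(pos, grid, spatial$pos_dim > 2)
          Y[frame$label, j] <- 1
        }
        fw <- spatial_forward(spatial, X, P)
        dQ <- matrix(0, K + 4L, n)
        dQ[4L + seq_len(K), ] <- 2 * (fw$q[4L + seq_len(K), , drop = FALSE] - Y) / n
        gs <- spatial_backward(spatial, fw$cache, dQ)
        upd <- adam_step(opt_s, spatial$params, gs)
        opt_s <- upd$state
        spatial$params <- upd$params
        gt_tot <- NULL
        for (j in seq_len(n)) {
          item <- dataset[[ids[j]]]
          tk <- describe_input(item)$tokens
          fwt <- temporal_forward(temporal, tk)
          dq <- 2 * (fwt$q - Y[, j]) / n
          g <- temporal_backward(temporal, fwt$cache, dq)
          gt_tot <- if (is.null(gt_tot)) g else mapply(`+`, gt_tot, g, SIMPLIFY = FALSE)
        }
        upd <- adam_step(opt_t, temporal$params, gt_tot)
        opt_t <- upd$state
        temporal$params <- upd$params
      }
    }
  })
  model$spatial <- spatial
  model$temporal <- temporal
  model
}
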
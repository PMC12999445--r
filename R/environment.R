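#' Patch grid geometry
#'
#' Lays a regular grid of square patch windows over the image: with the
#' defaults (224 px image, 64 px patches, stride 32) there are 6 positions
#' per axis, i.e. 36 half-overlapping windows.
#'
#' @param image_size image side length in pixels.
#' @param patch_size patch side length in pixels.
#' @param stride stride between window origins in pixels.
#' @return A `patch_grid` with `n_positions_per_axis`.
#' @export
#' @examples
#' build_grid()$n_positions_per_axis  # 6
build_grid <- function(image_size = 224L, patch_size = 64L, stride = 32L) {
  if (patch_size > image_size) {
    stop_domain("patch_size must not exceed image_size")
  }
  if ((image_size - patch_size) %% stride != 0) {
    stop_domain("(image_size - patch_size) must be divisible by stride")
  }
  structure(
    list(image_size = as.integer(image_size),
         patch_size = as.integer(patch_size),
         stride = as.integer(stride),
         n_positions_per_axis = as.integer((image_size - patch_size) %/% stride + 1L)),
    class = "patch_grid"
  )
}

# navigation actions 1..4; classification actions 5..(4+K)
NAV_ACTIONS <- c(up = 1L, down = 2L, left = 3L, right = 4L)

#' Action space sizes for K classes
#' @param K number of classes.
#' @return List with `A1` (= K + 4) and `A2` (= K).
#' @export
action_spaces <- function(K) {
  list(A1 = as.integer(K + 4L), A2 = as.integer(K), K = as.integer(K))
}

is_nav_action <- function(action) action >= 1L && action <= 4L

action_to_class <- function(action) as.integer(action - 4L)

#' Move one grid cell
#'
#' Applies a navigation action to a 0-based `(row, col)` grid position.
#' Moves that would leave the grid are clipped to the boundary.
#'
#' @param pos integer pair `(row, col)`, 0-based.
#' @param action navigation action index (1 = up, 2 = down, 3 = left,
#'   4 = right) or its name.
#' @param grid a `patch_grid`.
#' @return The new 0-based position.
#' @export
navigate <- function(pos, action, grid) {
  if (is.character(action)) action <- NAV_ACTIONS[[action]]
  if (!is_nav_action(action)) {
    stop("navigate() requires a navigation action", call. = FALSE)
  }
  delta <- switch(action, c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  new <- pos + delta
  nmax <- grid$n_positions_per_axis - 1L
  pmin(pmax(new, 0L), nmax)
}

# crop the patch window at a 0-based grid position; half-open pixel range
# [stride*row, stride*row + patch_size)
crop_patch <- function(pixels, grid, pos) {
  r0 <- grid$stride * pos[1]
  c0 <- grid$stride * pos[2]
  pixels[(r0 + 1):(r0 + grid$patch_size),
         (c0 + 1):(c0 + grid$patch_size), , drop = FALSE]
}

#' Positional embedding of a grid position
#'
#' Patch-centre coordinates normalized to \[0,1\]^2, optionally expanded with
#' a fixed first-order sinusoidal map.
#'
#' @param pos 0-based `(row, col)`.
#' @param grid a `patch_grid`.
#' @param sinusoidal add `sin`/`cos` features.
#' @return Numeric vector (length 2, or 6 with `sinusoidal`).
#' @export
pos_embedding <- function(pos, grid, sinusoidal = FALSE) {
  ctr <- (grid$stride * pos + grid$patch_size / 2) / grid$image_size
  if (!sinusoidal) return(as.numeric(ctr))
  c(ctr, sin(2 * pi * ctr), cos(2 * pi * ctr))
}

#' Create a diagnosis episode environment
#'
#' One episode inspects one image: the team starts at the grid position
#' nearest the image centre and either navigates (reward -0.01 per move) or
#' terminates with a classification (reward +1 if correct, -1 otherwise).
#' After `t_max` navigation steps the policy must classify.
#'
#' @param image a `lesion_image` (or `lesion_sequence`; the last frame is
#'   inspected spatially).
#' @param grid a `patch_grid`.
#' @param K number of classes.
#' @param t_max navigation-step horizon.
#' @param gamma discount factor.
#' @param sinusoidal_pos use the sinusoidal positional embedding.
#' @return A `lesion_env`.
#' @export
env_new <- function(image, grid = build_grid(), K = 2L, t_max = 16L,
                    gamma = 0.99, sinusoidal_pos = FALSE) {
  frame <- if (inherits(image, "lesion_sequence")) {
    image$frames[[length(image$frames)]]
  } else {
    image
  }
  structure(
    list(pixels = frame$pixels, truth = frame$label, grid = grid,
         K = as.integer(K), t_max = as.integer(t_max), gamma = gamma,
         sinusoidal_pos = sinusoidal_pos),
    class = "lesion_env"
  )
}

# start position: grid index nearest the image centre, ties toward the lower
# index -> (2, 2) on the 6x6 grid
start_position <- function(grid) {
  centre <- (grid$image_size - grid$patch_size) / 2
  idx <- as.integer(floor(centre / grid$stride))
  c(idx, idx)
}

#' Reset an environment to its initial state
#' @param env a `lesion_env`.
#' @param text_hidden encoder hidden state carried by the temporal agent
#'   (held fixed within the episode).
#' @return An `env_state`: patch, 0-based `grid_pos`, `pos_embed`,
#'   `text_hidden`, `step_index`, `terminal`.
#' @export
env_reset <- function(env, text_hidden = NULL) {
  pos <- start_position(env$grid)
  structure(
    list(patch = crop_patch(env$pixels, env$grid, pos),
         grid_pos = pos,
         pos_embed = pos_embedding(pos, env$grid, env$sinusoidal_pos),
         text_hidden = text_hidden,
         step_index = 0L,
         terminal = FALSE),
    class = "env_state"
  )
}

#' Advance an episode by one joint action
#'
#' @param env a `lesion_env`.
#' @param state the current `env_state` (must not be terminal).
#' @param action team action index: 1..4 navigation, `4 + c` classifies as
#'   class `c`.
#' @return A list with `reward` (one of +1, -1, -0.01), `next_state`,
#'   `terminal` and `predicted_class` (NA unless terminal).
#' @export
env_step <- function(env, state, action) {
  if (isTRUE(state$terminal)) {
    stop("env_step() called on a terminal episode", call. = FALSE)
  }
  if (action < 1 || action > env$K + 4L) {
    stop_domain("action out of range 1..", env$K + 4L)
  }
  if (is_nav_action(action)) {
    pos <- navigate(state$grid_pos, action, env$grid)
    next_state <- state
    next_state$grid_pos <- pos
    next_state$patch <- crop_patch(env$pixels, env$grid, pos)
    next_state$pos_embed <- pos_embedding(pos, env$grid, env$sinusoidal_pos)
    next_state$step_index <- state$step_index + 1L
    list(reward = -0.01, next_state = next_state, terminal = FALSE,
         predicted_class = NA_integer_)
  } else {
    cls <- action_to_class(action)
    next_state <- state
    next_state$terminal <- TRUE
    next_state$step_index <- state$step_index + 1L
    list(reward = if (cls == env$truth) 1 else -1,
         next_state = next_state, terminal = TRUE,
         predicted_class = cls)
  }
}

#' Discounted episode return
#'
#' @param rewards ordered per-step rewards.
#' @param gamma discount factor.
#' @return `sum_t gamma^t * r_t` (t starting at 0).
#' @export
#' @examples
#' episode_return(c(-0.01, -0.01, 1), 0.99)
episode_return <- function(rewards, gamma = 0.99) {
  if (length(rewards) == 0) stop_domain("empty reward list")
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}
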
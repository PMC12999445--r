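#' Experience replay buffer
#'
#' Bounded FIFO store of transitions with uniform minibatch sampling
#' (without replacement within a batch). Implemented as a mutable
#' environment so pushes are O(1).
#'
#' @param capacity maximum number of stored transitions.
#' @return A `replay_buffer`.
#' @export
replay_new <- function(capacity = 10000L) {
  buf <- new.env(parent = emptyenv())
  buf$storage <- vector("list", capacity)
  buf$capacity <- as.integer(capacity)
  buf$size <- 0L
  buf$head <- 0L
  class(buf) <- "replay_buffer"
  buf
}

#' @export
#' @rdname replay_new
#' @param buf a `replay_buffer`.
#' @param transition transition record to append; once the buffer is full the
#'   oldest record is overwritten.
replay_push <- function(buf, transition) {
  buf$head <- (buf$head %% buf$capacity) + 1L
  buf$storage[[buf$head]] <- transition
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' @export
#' @rdname replay_new
replay_size <- function(buf) buf$size

#' @export
#' @rdname replay_new
#' @param n batch size.
replay_sample <- function(buf, n) {
  if (n > buf$size) stop_domain("batch larger than buffer contents")
  idx <- sample.int(buf$size, n)
  buf$storage[idx]
}
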
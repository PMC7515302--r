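#' Population replay memory
#'
#' A bounded FIFO of experience tuples `(s, a, r, s', terminal)` shared by
#' every individual of one species - the mechanism by which experience is
#' passed on to offspring. Only the most recent `capacity` transitions are
#' kept (oldest evicted first); training samples minibatches uniformly at
#' random.
#'
#' @param capacity maximum number of stored transitions.
#' @param npix observation length (`vr^2` window codes).
#' @param species `"pred"` or `"prey"` routing tag.
#' @return A `pp_replay` environment.
#' @export
replay_buffer <- function(capacity, npix, species = c("pred", "prey")) {
  species <- match.arg(species)
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$npix <- as.integer(npix)
  b$species <- species
  b$s <- matrix(0L, npix, capacity)   # one column per transition
  b$s2 <- matrix(0L, npix, capacity)
  b$a <- integer(capacity)
  b$r <- numeric(capacity)
  b$terminal <- integer(capacity)
  b$written <- 0L  # total ever written; write position cycles
  class(b) <- "pp_replay"
  b
}

#' Number of transitions currently held
#' @param buffer a `pp_replay`.
#' @return Integer size (at most the capacity).
#' @export
buffer_size <- function(buffer) {
  min(buffer$written, buffer$capacity)
}

#' Store experience tuples
#'
#' Appends one transition or a batch of transitions, evicting the oldest
#' beyond capacity. A batch is the list returned per species by
#' [mcs_step()] (`s`/`s2` as `npix x n` code matrices, one column per
#' transition, plus `a`, `r`, `terminal` vectors); a single transition may
#' pass `s`/`s2` as plain code vectors.
#'
#' @param buffer a `pp_replay` (mutated in place).
#' @param transitions transition batch as described above.
#' @return The number of transitions added, invisibly.
#' @export
record_experience <- function(buffer, transitions) {
  if (is.null(transitions)) return(invisible(0L))
  s <- transitions$s
  s2 <- transitions$s2
  if (is.null(dim(s))) s <- matrix(as.integer(s), ncol = 1)
  if (is.null(dim(s2))) s2 <- matrix(as.integer(s2), ncol = 1)
  n <- length(transitions$a)
  if (n == 0) return(invisible(0L))
  if (nrow(s) != buffer$npix)
    stop("observation length does not match this buffer")
  pos <- (buffer$written + seq_len(n) - 1L) %% buffer$capacity + 1L
  cpp_buffer_write(buffer$s, buffer$s2, buffer$a, buffer$r, buffer$terminal,
                   s, s2, as.integer(transitions$a),
                   as.numeric(transitions$r),
                   as.integer(transitions$terminal), pos)
  buffer$written <- buffer$written + n
  invisible(as.integer(n))
}

#' Sample a uniform minibatch
#'
#' @param buffer a `pp_replay`.
#' @param n minibatch size (at most [buffer_size()]).
#' @return List with `s`, `s2` (`n x npix` code matrices, one row per
#'   sampled transition, as consumed by the network), `a`, `r`, `terminal`.
#' @export
sample_transitions <- function(buffer, n) {
  sz <- buffer_size(buffer)
  if (n > sz) stop("not enough stored transitions to sample from")
  ii <- sample.int(sz, n)
  list(s = t(buffer$s[, ii, drop = FALSE]), a = buffer$a[ii],
       r = buffer$r[ii], s2 = t(buffer$s2[, ii, drop = FALSE]),
       terminal = buffer$terminal[ii])
}

#' @export
print.pp_replay <- function(x, ...) {
  cat(sprintf("pp_replay (%s): %d / %d transitions\n",
              x$species, buffer_size(x), x$capacity))
  invisible(x)
}
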
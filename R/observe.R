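#' Chebyshev distance between two lattice coordinates
#'
#' The chessboard metric `max(|r2 - r1|, |c2 - c1|)`. Inside an observation
#' window the arguments are window offsets, so no periodic wrap is applied.
#'
#' @param p1,p2 length-2 numeric coordinates `(row, col)`.
#' @return Integer distance.
#' @export
chebyshev <- function(p1, p2) {
  as.integer(max(abs(p1 - p2)))
}

#' Extract a local observation window
#'
#' The `vr x vr` sub-grid centred on `pos`, with periodic wrap, species
#' coded as 0 (empty), 1 (prey), 2 (predator). This is the state an agent
#' perceives; `vr` must be odd so the agent sits on the centre cell.
#'
#' @param world a `pp_world`.
#' @param pos 1-based `(row, col)` of the focal agent.
#' @param vr odd window size (default 9, a vision range of 4 sites).
#' @return A `pp_obs`: list with `window` (vr x vr integer matrix, row 1 the
#'   top of the window), `vr`, and `center_species`.
#' @export
observe <- function(world, pos, vr = 9) {
  if (vr %% 2 != 1 || vr < 1) stop("vr must be odd and positive")
  h <- vr %/% 2
  L <- world$L
  rows <- ((pos[1] - h):(pos[1] + h) - 1L) %% L + 1L
  cols <- ((pos[2] - h):(pos[2] + h) - 1L) %% L + 1L
  win <- world$grid[rows, cols, drop = FALSE]
  code <- world$grid[pos[1], pos[2]]
  structure(list(window = win, vr = as.integer(vr),
                 center_species = c("empty", "prey", "predator")[code + 1L]),
            class = "pp_obs")
}

#' Chebyshev shell counts of an observation
#'
#' Counts prey and predators at each Chebyshev distance `k = 1..floor(vr/2)`
#' from the centre (the centre cell itself is excluded). Shell `k` of a
#' square window holds at most `8k` sites; a 9 x 9 window partitions its 80
#' non-centre cells into shells of sizes 8, 16, 24 and 32.
#'
#' @param obs a `pp_obs` from [observe()], or a bare `vr x vr` integer
#'   matrix of species codes.
#' @return A `pp_shells`: list with integer vectors `prey` and `pred`,
#'   indexed by shell `k`.
#' @export
shell_counts <- function(obs) {
  win <- if (inherits(obs, "pp_obs")) obs$window else obs
  vr <- nrow(win)
  h <- vr %/% 2
  off <- seq_len(vr) - h - 1L
  d <- pmax(abs(outer(off, rep(1L, vr))), abs(outer(rep(1L, vr), off)))
  prey <- integer(h)
  pred <- integer(h)
  for (k in seq_len(h)) {
    ring <- d == k
    prey[k] <- sum(win[ring] == SP_PREY)
    pred[k] <- sum(win[ring] == SP_PRED)
  }
  structure(list(prey = prey, pred = pred, vr = vr), class = "pp_shells")
}

# flatten a pp_obs (or matrix) to the row-major code vector used by the
# network and the C++ engine
obs_codes <- function(obs) {
  win <- if (inherits(obs, "pp_obs")) obs$window else obs
  as.integer(t(win))
}
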
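#' Summary statistics of a run over a declared window
#'
#' Arithmetic means and empirical count distributions of both species over
#' a stated MCS window. The default window drops the first 1000 MCS as
#' burn-in (or half the run for short runs) and extends to the end of the
#' run; the window actually used is reported alongside the means.
#'
#' @param result a `pp_run` from [run_case()].
#' @param window `c(from, to)` MCS range (inclusive), or `NULL` for the
#'   default burn-in window.
#' @return List with `window`, `mean_predators`, `mean_prey`, and
#'   `distribution` (a data frame of windowed per-MCS counts).
#' @export
summarize_run <- function(result, window = NULL) {
  s <- result$series
  if (is.null(window)) {
    burn <- min(1000L, result$mcs_done %/% 2L)
    window <- c(burn + 1L, result$mcs_done)
  }
  if (window[1] > window[2]) stop("empty summary window")
  sel <- s$mcs >= window[1] & s$mcs <= window[2]
  if (!any(sel)) stop("summary window outside the run")
  list(window = as.integer(window),
       mean_predators = mean(s$n_predators[sel]),
       mean_prey = mean(s$n_prey[sel]),
       distribution = s[sel, c("n_predators", "n_prey")])
}

#' @export
summary.pp_run <- function(object, ...) {
  sm <- summarize_run(object, ...)
  cat(sprintf("Window %d-%d MCS: mean %.2f predators, %.2f prey\n",
              sm$window[1], sm$window[2], sm$mean_predators, sm$mean_prey))
  invisible(sm)
}

#' LOWESS trend of a population time series
#'
#' Locally weighted regression of per-MCS counts against time, used to
#' read slow population trends out of the oscillating raw series.
#'
#' @param series numeric vector of per-MCS counts, or a `pp_run` (both
#'   species smoothed).
#' @param frac smoothing fraction (span) of the local regression.
#' @return For a vector, the smoothed series (same length); for a
#'   `pp_run`, a data frame `mcs`, `trend_predators`, `trend_prey`.
#' @export
lowess_trend <- function(series, frac = 0.1) {
  if (inherits(series, "pp_run")) {
    s <- series$series
    return(data.frame(mcs = s$mcs,
                      trend_predators = lowess_trend(s$n_predators, frac),
                      trend_prey = lowess_trend(s$n_prey, frac)))
  }
  stats::lowess(seq_along(series), series, f = frac)$y
}

#' Write stored snapshots as CSV grid files
#'
#' @param result a `pp_run` produced with `snapshot_mcs`.
#' @param mcs_list MCS values to export; each must have been captured
#'   during the run (requesting an MCS beyond the run or one that was not
#'   captured is an error).
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
export_snapshots <- function(result, mcs_list, dir) {
  mcs_list <- as.integer(mcs_list)
  if (any(mcs_list > result$mcs_done))
    stop("requested snapshot MCS beyond the end of the run")
  missing <- setdiff(as.character(mcs_list), names(result$snapshots))
  if (length(missing))
    stop("no snapshot stored for MCS ", paste(missing, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(mcs_list))
  for (i in seq_along(mcs_list)) {
    paths[i] <- file.path(dir, sprintf("snapshot_%06d.csv", mcs_list[i]))
    utils::write.table(result$snapshots[[as.character(mcs_list[i])]],
                       paths[i], sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(paths)
}

#' Write the population time series as CSV
#'
#' @param result a `pp_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_series <- function(result, path) {
  utils::write.table(result$series, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
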
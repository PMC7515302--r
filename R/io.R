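#' Save / load a run archive
#'
#' A versioned archive (format `predpreyRL-run`, version 1) holding the
#' full `pp_run` - series, summaries, snapshots, configuration and seed -
#' sufficient to re-run the case bit-identically. Loading a file that is
#' not a run archive is an explicit error.
#'
#' @param result a `pp_run`.
#' @param path file path.
#' @return `path` invisibly; for `load_run`, the restored `pp_run`.
#' @export
save_run <- function(result, path) {
  stopifnot(inherits(result, "pp_run"))
  networks <- lapply(result$networks, function(n)
    if (is.null(n)) NULL else list(vr = n$vr, n_actions = n$n_actions,
                                   arch = n$arch, params = n$params))
  payload <- unclass(result)
  payload$networks <- networks
  payload$world <- NULL  # live environment; the archive stays plain data
  saveRDS(list(format = "predpreyRL-run", version = 1L, run = payload), path)
  invisible(path)
}

#' @rdname save_run
#' @export
load_run <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read run archive: ", conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, "predpreyRL-run"))
    stop("file is not a predpreyRL run archive")
  run <- x$run
  run$networks <- lapply(run$networks, function(n) {
    if (is.null(n)) return(NULL)
    net <- build_qnetwork(n$vr, n$n_actions, n$arch[["n_conv1"]],
                          n$arch[["n_conv2"]], n$arch[["n_fc"]])
    net$params <- lapply(n$params, function(p) p * 1)
    net
  })
  structure(run, class = "pp_run")
}

#' Read / write a case configuration file
#'
#' YAML files mirroring [case_config()] fields 1:1: a `sim` block with the
#' [sim_params()] fields, optional `pred_learning` / `prey_learning`
#' blocks with [training_schedule()] fields, and for frozen-network runs a
#' `mode: apply_frozen` with `frozen_pred` / `frozen_prey` paths to
#' [save_qnetwork()] archives plus `random_phase_mcs` and `eps_apply`.
#'
#' @param path YAML file path.
#' @return For `read_case_config`, a `pp_case`.
#' @export
read_case_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_params, y$sim)
  sched <- function(block) if (is.null(block)) NULL
                           else do.call(training_schedule, block)
  mode <- if (is.null(y$mode)) "evolve" else y$mode
  frozen <- NULL
  if (mode == "apply_frozen") {
    frozen <- list(
      pred = if (!is.null(y$frozen_pred)) load_qnetwork(y$frozen_pred),
      prey = if (!is.null(y$frozen_prey)) load_qnetwork(y$frozen_prey))
  }
  case_config(sim,
              pred_learning = sched(y$pred_learning),
              prey_learning = sched(y$prey_learning),
              mode = mode, frozen = frozen,
              random_phase_mcs = if (is.null(y$random_phase_mcs)) 1500
                                 else y$random_phase_mcs,
              eps_apply = if (is.null(y$eps_apply)) 0.05 else y$eps_apply)
}

#' @rdname read_case_config
#' @param config a `pp_case` (frozen networks are written next to `path`).
#' @export
write_case_config <- function(config, path) {
  y <- list(sim = unclass(config$sim), mode = config$mode,
            random_phase_mcs = config$random_phase_mcs,
            eps_apply = config$eps_apply)
  for (nm in c("pred_learning", "prey_learning"))
    if (!is.null(config[[nm]])) y[[nm]] <- unclass(config[[nm]])
  if (config$mode == "apply_frozen") {
    for (nm in c("pred", "prey"))
      if (!is.null(config$frozen[[nm]])) {
        np <- paste0(sub("\\.[^.]*$", "", path), "_", nm, ".qnet")
        save_qnetwork(config$frozen[[nm]], np)
        y[[paste0("frozen_", nm)]] <- np
      }
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
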
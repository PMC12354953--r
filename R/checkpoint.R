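# Run artifacts: checkpoints (RDS) with a JSON provenance sidecar, and the
# loss trace as CSV.

#' Save a training checkpoint
#'
#' Writes the model (encoder, head, hypernetwork), the configuration, the
#' loss trace and the current RNG state to `path` (RDS), plus a small JSON
#' sidecar `<path>.json` with seed/config provenance so a run can be
#' identified and reproduced.
#'
#' @param fit a fit object from [meta_train()].
#' @param path output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  obj <- list(weights = fit$weights, hyp = fit$hyp, cfg = fit$cfg,
              trace = fit$trace, rng_state = rng,
              version = as.character(utils::packageVersion("molfewshot")))
  saveRDS(obj, path)
  meta <- list(seed = fit$cfg$seed, mode = fit$cfg$mode,
               epochs = fit$cfg$epochs, version = obj$version,
               cfg = unclass(fit$cfg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @param restore_rng restore the RNG state stored in the checkpoint.
#' @return the checkpoint list (`weights`, `hyp`, `cfg`, `trace`).
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  obj <- readRDS(path)
  if (!all(c("weights", "cfg") %in% names(obj))) {
    stop("checkpoint/schema mismatch: ", path)
  }
  if (restore_rng && !is.null(obj$rng_state)) {
    assign(".Random.seed", obj$rng_state, envir = globalenv())
  }
  obj
}

#' Write a loss trace as CSV
#'
#' @param trace the `trace` data frame from [meta_train()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
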
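# Model directory layout: config snapshot (YAML), parameter archive (RDS),
# role vocabulary and identifier-embedding vocabulary (plain text).

#' Save / load a trained yield model
#'
#' The directory holds `config.yaml` (hyper-parameter snapshot),
#' `params.rds` (parameter matrices), `roles.txt` and `vocab.txt` (the
#' identifier-to-row map), so a model can be inspected without loading it.
#'
#' @param model A `yield_model`.
#' @param dir Target directory (created if needed).
#' @return `dir` / the restored `yield_model`.
#' @export
save_yield_model <- function(model, dir) {
  stopifnot(inherits(model, "yield_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(model$cfg), file.path(dir, "config.yaml"))
  writeLines(model$roles, file.path(dir, "roles.txt"))
  writeLines(sprintf("%s\t%d", names(model$vocab), model$vocab),
             file.path(dir, "vocab.txt"))
  values <- list(
    mpnn = lapply(model$mpnn, function(p) p$value),
    encoder = rapply(model$encoder, function(p) p$value,
                     classes = "environment", how = "replace"),
    y_scale = model$y_scale %||% 100,
    history = model$history
  )
  saveRDS(values, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_yield_model
#' @export
load_yield_model <- function(dir) {
  if (!file.exists(file.path(dir, "config.yaml"))) {
    data_error("not a model directory (no config.yaml): %s", dir)
  }
  cfg <- do.call(model_config, yaml::read_yaml(file.path(dir, "config.yaml")))
  roles <- readLines(file.path(dir, "roles.txt"))
  vl <- strsplit(readLines(file.path(dir, "vocab.txt")), "\t", fixed = TRUE)
  vocab <- stats::setNames(vapply(vl, function(x) as.integer(x[2]), integer(1)),
                           vapply(vl, `[[`, character(1), 1))
  values <- readRDS(file.path(dir, "params.rds"))
  mpnn <- lapply(values$mpnn, new_param)
  encoder <- rapply(values$encoder, new_param, classes = "matrix",
                    how = "replace")
  structure(
    list(cfg = cfg, vocab = vocab, roles = roles, mpnn = mpnn,
         encoder = encoder, enc_cache = new.env(parent = emptyenv()),
         history = values$history, y_scale = values$y_scale),
    class = "yield_model"
  )
}
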
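#' Read and resolve a run configuration file
#'
#' A run configuration is a single YAML (or JSON) file with the
#' sections `scene`, `loss`, `reweight`, `train`, `grid`, `evaluate`
#' and `output_dir`; every field has the package default and unknown
#' keys are rejected. Overrides (e.g. from command-line flags) take
#' precedence over the file, which takes precedence over defaults.
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top (names like
#'   `"loss.alpha"`, `"reweight.scheme"`, `"train.epochs"`).
#' @return A list of class `run_config` with elements `scene`
#'   ([scene_spec()]), `loss` ([loss_config()]), `train`
#'   ([train_config()]), `grid` ([grid_spec()]), `evaluate` (list) and
#'   `output_dir`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("scene", "loss", "reweight", "train", "grid", "evaluate", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) raw[[parts]] <- overrides[[nm]]
    else raw[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  build <- function(fn, args, allowed) {
    bad <- setdiff(names(args), allowed)
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
    }
    do.call(fn, args)
  }
  scene <- build(scene_spec, raw$scene %||% list(),
                 names(formals(scene_spec)))
  rw <- build(reweight_config, raw$reweight %||% list(),
              names(formals(reweight_config)))
  loss_args <- raw$loss %||% list()
  loss_args$reweight <- rw
  loss <- build(loss_config, loss_args, names(formals(loss_config)))
  train <- build(train_config, raw$train %||% list(),
                 names(formals(train_config)))
  grid <- build(grid_spec, raw$grid %||% list(), names(formals(grid_spec)))
  structure(list(scene = scene, loss = loss, train = train, grid = grid,
                 evaluate = raw$evaluate %||% list(),
                 output_dir = raw$output_dir %||% "."),
            class = "run_config")
}

#' Write the resolved configuration snapshot of a run
#'
#' Every pipeline run records the fully resolved parameter values so
#' the run can be reproduced from its output directory alone.
#'
#' @param config A `run_config` (or any list of resolved settings).
#' @param dir Output directory.
#' @return The snapshot path, invisibly.
#' @export
write_config_snapshot <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "resolved_config.json")
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
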
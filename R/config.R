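# Run configuration: one JSON file drives every command ------------------
#
# Blocks: model, response, grid, perturbation, solver, plus top-level
# "mode" and "output_dir".  Validation is strict: unknown keys anywhere are
# rejected, every numeric constraint is checked before any computation, and
# each command writes the fully resolved configuration beside its outputs
# so a run is reproducible from its own provenance file.

config_allowed <- list(
  top = c("model", "response", "grid", "perturbation", "solver", "mode",
          "output_dir"),
  model = c("D_L", "D_M", "mu", "k_L", "k_M", "k_N", "L0"),
  response = c("family", "a", "b", "s", "c", "L_star", "value", "slope"),
  grid = c("tau_ext", "tau_int", "m", "n", "d"),
  perturbation = c("pattern", "amplitude", "k_tau", "k_sigma", "center_tau",
                   "center_sigma", "width", "seed", "k_max", "species_mask"),
  solver = c("t_end", "output_times", "rtol", "atol", "div_mode", "metric")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop_ps("plaquestab_config_error",
            "unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `ps_config` list with resolved defaults and
#'   constructed `model`, `grid`, `perturbation` objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_ps("plaquestab_config_error", "config file '%s' not found", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_run_config(raw)
}

#' Build a run configuration from a list
#'
#' Programmatic equivalent of [read_run_config()]; `raw` mirrors the JSON
#' structure.
#' @param raw Nested list (see the package vignette for the schema).
#' @return A `ps_config`.
#' @export
build_run_config <- function(raw) {
  check_keys(raw, config_allowed$top, "top level")
  for (blk in c("model", "response", "grid"))
    if (is.null(raw[[blk]]))
      stop_ps("plaquestab_config_error", "missing '%s' block", blk)
  check_keys(raw$model, config_allowed$model, "'model'")
  check_keys(raw$response, config_allowed$response, "'response'")
  check_keys(raw$grid, config_allowed$grid, "'grid'")
  if (!is.null(raw$perturbation))
    check_keys(raw$perturbation, config_allowed$perturbation,
               "'perturbation'")
  if (!is.null(raw$solver))
    check_keys(raw$solver, config_allowed$solver, "'solver'")

  rf <- do.call(switch(raw$response$family %||% "logistic",
                       identity = response_identity,
                       logistic = response_logistic,
                       pinned = response_pinned,
                       stop_ps("plaquestab_config_error",
                               "unknown response family '%s'",
                               raw$response$family)),
                raw$response[setdiff(names(raw$response), "family")])
  model <- do.call(model_parameters, c(raw$model, list(response = rf)))
  grid <- do.call(bipolar_grid, as.list(raw$grid))

  pert <- NULL
  if (!is.null(raw$perturbation)) {
    p <- raw$perturbation
    args <- p[setdiff(names(p), "pattern")]
    if (!is.null(args$species_mask))
      args$species_mask <- as.logical(args$species_mask)
    pert <- do.call(switch(p$pattern %||% "fourier",
                           fourier = perturbation_fourier,
                           bump = perturbation_bump,
                           random = perturbation_random,
                           stop_ps("plaquestab_config_error",
                                   "unknown perturbation pattern '%s'",
                                   p$pattern)),
                    args)
  }

  solver <- utils::modifyList(
    list(t_end = 10, output_times = NULL, rtol = 1e-8, atol = 1e-10,
         div_mode = "faithful", metric = TRUE),
    as.list(raw$solver %||% list()))
  mode <- raw$mode %||% "linearized"
  if (!mode %in% c("linearized", "nonlinear"))
    stop_ps("plaquestab_config_error", "mode must be linearized|nonlinear")

  structure(list(model = model, grid = grid, perturbation = pert,
                 solver = solver, mode = mode,
                 output_dir = raw$output_dir %||% ".",
                 raw = raw),
            class = "ps_config")
}

write_resolved_config <- function(config, dir) {
  jsonlite::write_json(config$raw, file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# flat key = value serialisation used for the human-diffable reports
write_kv <- function(x, path) {
  flat <- unlist(x)
  lines <- paste(names(flat), vapply(flat, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v), ""),
    sep = " = ")
  writeLines(lines, path)
}

prepare_outdir <- function(config, overwrite) {
  dir <- config$output_dir
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop_ps("plaquestab_output_error",
            "output directory '%s' is non-empty; pass overwrite = TRUE", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}
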
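run_config_defaults <- function() {
  list(grammar = NULL, F = 15L, sigma = 0.15, repetitions = 30L,
       imp_rate = 0.1, seed = 1L, heads = 5L, pe = TRUE,
       lr = 0.001, batch_size = 128L, patience = 10L, max_epochs = 500L,
       out_dir = ".")
}

#' Load a run configuration file
#'
#' A run configuration is a JSON (or YAML) map of generator, model and
#' training settings; every omitted field falls back to the package default
#' (F 15, sigma 0.15, 30 repetitions, 5 attention heads, PE on, learning
#' rate 0.001, batch size 128, patience 10, 500 epochs). Unknown keys are
#' rejected, and values are validated with named errors.
#'
#' @param path configuration file; `.yaml`/`.yml` selects YAML.
#' @return validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- run_config_defaults()
  unknown <- setdiff(names(obj), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, obj)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (!is.null(cfg$grammar) && !is.character(cfg$grammar))
    stop("config field 'grammar' must be a file path")
  num_pos <- c(F = cfg$F, repetitions = cfg$repetitions, heads = cfg$heads,
               lr = cfg$lr, batch_size = cfg$batch_size,
               patience = cfg$patience, max_epochs = cfg$max_epochs)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad)) stop("config field(s) must be positive: ",
                        paste(bad, collapse = ", "))
  if (!is.finite(cfg$sigma) || cfg$sigma < 0)
    stop("config field 'sigma' must be non-negative")
  if (!is.finite(cfg$imp_rate) || cfg$imp_rate < 0)
    stop("config field 'imp_rate' must be non-negative")
  invisible(cfg)
}

#' @rdname load_config
#' @param cfg a `run_config` (or plain named list) to write.
#' @export
save_config <- function(cfg, path) {
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML configs")
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

write_manifest <- function(dir, command, cfg, seed) {
  jsonlite::write_json(
    list(command = command, config = cfg[!vapply(cfg, is.null, TRUE)],
         seed = seed,
         package = as.character(utils::packageVersion("maglink")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Path to a grammar shipped with the package
#'
#' Two synthetic example grammars are installed under `extdata`: a
#' cooking-style grammar (7 recipes of lengths 11, 11, 11, 9, 9, 9 and 14
#' over 8 preparation steps) and a table-tennis-style grammar (55 exercises
#' of lengths 1 to 10 over 8 stroke types). Both mirror the structure of the
#' source study's real grammars; the actual sequence lists are synthetic
#' stand-ins.
#'
#' @param name `"cooking_synthetic"` or `"table_tennis_synthetic"`.
#' @return file path to the installed grammar JSON.
#' @export
example_grammar_path <- function(name = c("cooking_synthetic",
                                          "table_tennis_synthetic")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".json"), package = "maglink",
              mustWork = TRUE)
}
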
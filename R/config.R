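#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with top-level sections per stage;
#' see the package vignette for the schema. Paths are resolved relative
#' to the configuration file. File-valued entries (anything named
#' `*fastq*`, `*fasta*`, `*table*`, `*sam*`) are checked for existence
#' up front so a run fails before any processing.
#'
#' @param path YAML configuration path.
#' @param section Optional section name; when given, only that
#'   section's file references are checked (other sections may point at
#'   outputs of stages that have not run yet).
#' @return Named list with attribute `config_dir`.
#' @export
read_run_config <- function(path, section = NULL) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  scope <- if (is.null(section)) cfg else cfg[[section]]
  check <- function(x, key = "") {
    if (is.list(x)) {
      for (nm in names(x)) check(x[[nm]], nm)
    } else if (is.character(x) && length(x) == 1L &&
               grepl("fastq|fasta|table|sam", key)) {
      p <- if (startsWith(x, "/")) x else file.path(dir, x)
      if (!file.exists(p))
        stop("config references missing file: ", x, call. = FALSE)
    }
    invisible(NULL)
  }
  check(scope)
  attr(cfg, "config_dir") <- dir
  cfg
}

#' Resolve a config-relative path
#' @param cfg Configuration from [read_run_config()].
#' @param x Path string.
#' @return Absolute path.
#' @export
config_path <- function(cfg, x) {
  if (startsWith(x, "/")) x else file.path(attr(cfg, "config_dir"), x)
}
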
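#' Load a simulation configuration from YAML or JSON
#'
#' Reads a configuration file, applies the model defaults for anything not
#' given (T = 5000 steps, s = 10000, transfer probability 0.5, jam size 4,
#' ...) and validates every value.  Unknown keys are rejected by name, so a
#' typo cannot silently fall back to a default.  Besides the [sim_config()]
#' keys, the optional sub-sections `sweep` (`levels`, `reps`, `deltas`,
#' `lhs`) and `analysis` (`k`, `perplexity`, `bins`) are passed through
#' after the same unknown-key check.
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return A list with elements `config` (a [sim_config()]), `sweep`,
#'   `analysis`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()

  sim_keys <- setdiff(names(formals(sim_config)), "")
  sweep_keys <- c("levels", "reps", "deltas", "lhs")
  analysis_keys <- c("k", "perplexity", "bins")

  unknown <- setdiff(names(raw), c(sim_keys, "sweep", "analysis"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  check_sub <- function(sub, keys, label) {
    bad <- setdiff(names(sub), keys)
    if (length(bad))
      stop("unknown ", label, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    sub
  }
  cfg <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  list(config = cfg,
       sweep = check_sub(raw$sweep, sweep_keys, "sweep"),
       analysis = check_sub(raw$analysis, analysis_keys, "analysis"))
}

#' Save a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path Output file.
#' @return `path`, invisibly.  `load_config(save_config(cfg, f))$config`
#'   reproduces `cfg`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: package version, timestamp,
#' seed, configuration echo, and an md5 checksum per artifact.
#'
#' @param outputs Character vector of produced file paths.
#' @param config The [sim_config()] (or any list) the run used.
#' @param path Manifest destination (JSON).
#' @param seed The seed governing the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(outputs, config, path, seed = NULL) {
  files <- lapply(outputs, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  payload <- list(
    package = "termitesim",
    version = as.character(utils::packageVersion("termitesim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = if (inherits(config, "sim_config")) {
      x <- unclass(config); x[!vapply(x, is.null, logical(1))]
    } else config,
    outputs = files)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
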
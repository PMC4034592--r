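#' Read a run configuration file
#'
#' Configurations are YAML or JSON with keys `design` (a string such as
#' `"3:2:1"`) or `arms_per_stage`, plus `n_per_stage`, `v2`, `means`,
#' `reps`, `seed` and optionally `patient_level`, `estimators`, `methods`,
#' `B` and `level`.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with the parsed `config`, the constructed `design` and
#'   (when `means` is present) `scenario`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  arms <- if (!is.null(cfg$design)) {
    parse_design_string(cfg$design)$arms_per_stage
  } else cfg$arms_per_stage
  if (is.null(arms) || is.null(cfg$n_per_stage) || is.null(cfg$v2)) {
    stop("config must provide 'design' (or 'arms_per_stage'), ",
         "'n_per_stage' and 'v2'", call. = FALSE)
  }
  design <- dtl_design(arms, cfg$n_per_stage, cfg$v2)
  scenario <- if (!is.null(cfg$means)) {
    dtl_scenario(design, cfg$means,
                 reps = if (is.null(cfg$reps)) 1L else cfg$reps,
                 seed = cfg$seed,
                 patient_level = isTRUE(cfg$patient_level))
  }
  list(config = cfg, design = design, scenario = scenario)
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed configuration, used to stamp result files so that
#' outputs can be traced back to the exact settings that produced them.
#'
#' @param config any R object (typically the parsed config list).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table or object with reproducibility metadata
#'
#' CSV output carries `# key: value` comment headers (seed, package
#' version, config hash); JSON output nests the same metadata beside the
#' results.  Numeric columns are written at full precision with a
#' deterministic column order.
#'
#' @param x a data.frame (csv) or any jsonlite-serializable object (json).
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @param meta named list of metadata values (e.g. `seed`, `config`).
#'   A `config` entry is stored as its [config_hash()].
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL, meta = list()) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (!is.null(meta$config)) {
    meta$config_hash <- config_hash(meta$config)
    meta$config <- NULL
  }
  meta$package_version <- as.character(utils::packageVersion("droplosers"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (key in names(meta)) {
      writeLines(sprintf("# %s: %s", key, meta[[key]]), con)
    }
    utils::write.csv(x, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(meta = meta, results = x), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path file path (`.csv` with comment headers, or `.json`).
#' @return For CSV, the data.frame with a `"meta"` attribute; for JSON,
#'   the `list(meta, results)` structure.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: ?", "", kv))
  }
  attr(df, "meta") <- meta
  df
}
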
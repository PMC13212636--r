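# Run configuration: validated defaults, YAML/JSON parsing, hashing.

#' Analysis run configuration
#'
#' Validated container of the knobs of [run_full_analysis()]. Defaults
#' follow the published workflow: 5 imputations and 500 bootstrap
#' resamples.
#'
#' @param seed integer master seed.
#' @param m number of imputations (>= 1).
#' @param B bootstrap resamples (>= 100).
#' @param matching matching method for benefit metrics.
#' @param metrics metric names to compute.
#' @param n_bins calibration-curve bins.
#' @param out_dir optional output directory for [write_analysis_report()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, m = 5L, B = 500L,
                       matching = c("mahalanobis", "predicted_benefit"),
                       metrics = .default_metrics, n_bins = 10L,
                       out_dir = NULL) {
  matching <- match.arg(matching)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("config error: 'seed' must be an integer", call. = FALSE)
  m <- as.integer(m); B <- as.integer(B); n_bins <- as.integer(n_bins)
  if (is.na(m) || m < 1L) stop("config error: 'm' must be >= 1", call. = FALSE)
  if (is.na(B) || B < 100L)
    stop("config error: 'B' must be >= 100", call. = FALSE)
  if (is.na(n_bins) || n_bins < 2L)
    stop("config error: 'n_bins' must be >= 2", call. = FALSE)
  bad <- setdiff(metrics, .default_metrics)
  if (length(bad) > 0L)
    stop("config error: unknown metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(seed = seed, m = m, B = B, matching = matching,
                 metrics = metrics, n_bins = n_bins, out_dir = out_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration: seed ", x$seed, ", m = ", x$m, ", B = ", x$B,
      ", matching = ", x$matching, "\n", sep = "")
  invisible(x)
}

#' Parse a run configuration from YAML or JSON
#'
#' Missing keys are filled with the defaults of [run_config()]; unknown
#' keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Serialize a run configuration
#'
#' @param config a `run_config`.
#' @param path destination `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(config, path) {
  payload <- unclass(config)
  payload$out_dir <- payload$out_dir %||% NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(payload, path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Two runs with equal hashes and equal inputs produce equal outputs;
#' the hash is recorded in every run log.
#'
#' @param config a `run_config`.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the canonical JSON serialization
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
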
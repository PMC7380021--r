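#' Load model parameters from a configuration file
#'
#' Reads a flat YAML (or JSON, which YAML subsumes) mapping of parameter
#' symbols to values. Keys must be among the names in [param_names()];
#' unknown keys are rejected, missing keys are filled with the defaults.
#' An empty file yields exactly the default parameter set.
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the echo of the effective parameter set.
#' @return A validated [demographic_params()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("u_f: 0.5", f)
#' p <- load_config(f, quiet = TRUE)
#' p$u_f
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_invalid(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop_invalid("config must be a mapping of parameter names to values")
  unknown <- setdiff(names(cfg), param_names())
  if (length(unknown) > 0)
    stop_invalid(sprintf("unknown parameter key(s) in config: %s",
                         paste(unknown, collapse = ", ")))
  params <- do.call(demographic_params, cfg)
  if (!quiet) {
    message("Effective parameters: ",
            paste(sprintf("%s=%g", param_names(),
                          unlist(params[param_names()])), collapse = " "))
  }
  params
}

#' Write model parameters to a configuration file
#'
#' Writes the 19 numeric parameters as a flat YAML mapping; reading the file
#' back with [load_config()] reproduces the parameter set exactly.
#'
#' @param params A [demographic_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  vals <- params[param_names()]
  yaml::write_yaml(vals, path, precision = 15L)
  invisible(path)
}

# fixed-format numeric rendering used for bit-stable CSV output
.fmt10 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

.write_csv_stable <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) .fmt10(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Serializes sweep tables, PIP grids or evolutionary outcomes with a fixed
#' column order and fixed numeric formatting (10 significant digits in CSV;
#' full precision in JSON), so repeated writes of the same object are
#' byte-identical.
#'
#' @param x A `sweep_result`, `pip_grid`, `evolutionary_outcome` or plain
#'   data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("csv", "json")) {
  UseMethod("write_table")
}

#' @export
write_table.data.frame <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    .write_csv_stable(as.data.frame(x), path)
  } else {
    jsonlite::write_json(as.data.frame(x), path, digits = NA, na = "null",
                         auto_unbox = FALSE)
  }
  invisible(path)
}

#' @export
write_table.sweep_result <- function(x, path, format = c("csv", "json")) {
  write_table.data.frame(x, path, format)
}

#' @export
write_table.pip_grid <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  nb <- length(x$beta)
  long <- data.frame(
    beta_resident = rep(x$beta, each = nb),
    beta_mutant = rep(x$beta, times = nb),
    W = as.vector(x$W),
    sign = as.vector(x$sign))
  if (format == "csv") {
    .write_csv_stable(long, path)
  } else {
    jsonlite::write_json(
      list(beta = x$beta, W = x$W, sign = x$sign, step = x$step,
           tol = x$tol, resident_status = x$resident_status),
      path, digits = NA, na = "null", matrix = "rowmajor")
  }
  invisible(path)
}

#' @export
write_table.evolutionary_outcome <- function(x, path,
                                             format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    sing <- rbind(x$attractors, x$repellers)
    sing <- sing[order(sing$beta), , drop = FALSE]
    .write_csv_stable(sing, path)
  } else {
    jsonlite::write_json(
      list(attractors = x$attractors, repellers = x$repellers,
           beta_ess_values = x$beta_ess_values, bistable = x$bistable,
           viable = x$viable, scan_step = x$scan_step),
      path, digits = NA, na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}
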
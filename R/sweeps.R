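# Parameter sweeps of the evolutionary outcome, plus isocline extraction.

# run find_singular_strategies for one parameter combination and summarize it
# as a one-row data frame; failures are recorded, never propagated.
.sweep_cell <- function(params, scan_step, ...) {
  res <- tryCatch(find_singular_strategies(params, scan_step = scan_step, ...),
                  error = function(e) e)
  if (inherits(res, "error")) {
    return(data.frame(beta_ess_1 = NA_real_, beta_ess_2 = NA_real_,
                      beta_repeller = NA_real_, n_attractors = NA_integer_,
                      bistable = NA, status = "error"))
  }
  ess <- res$beta_ess_values
  rep1 <- if (nrow(res$repellers) > 0) res$repellers$beta[1] else NA_real_
  data.frame(
    beta_ess_1 = if (length(ess) >= 1) ess[1] else NA_real_,
    beta_ess_2 = if (length(ess) >= 2) ess[2] else NA_real_,
    beta_repeller = rep1,
    n_attractors = nrow(res$attractors),
    bistable = res$bistable,
    status = if (!res$viable) "extinct"
      else if (nrow(res$attractors) == 0) "no_attractor" else "ok")
}

#' One-parameter sweep of the evolutionarily stable fighter fraction
#'
#' Runs the full singular-strategy analysis at each value of one model
#' parameter and tabulates the attractors (`beta_ess_1` is the lowest
#' attractor, `beta_ess_2` the second where bistability occurs), the first
#' repeller, and a status flag. Per-cell failures are recorded in the table,
#' never abort the sweep.
#'
#' @inheritParams find_singular_strategies
#' @param param Name of the swept parameter (see [param_ranges()]).
#' @param values Numeric vector of parameter values; default is `steps`
#'   evenly spaced values across the parameter's standard sweep range.
#' @param steps Number of grid points when `values` is not given.
#' @param scan_step Trait-grid step of the per-cell gradient scan.
#' @param ... Passed on to [find_singular_strategies()].
#' @return A data frame of class `sweep_result` with columns `param`,
#'   `value`, `beta_ess_1`, `beta_ess_2`, `beta_repeller`, `n_attractors`,
#'   `bistable`, `status`; sweep metadata in attributes.
#' @examples
#' \donttest{
#' sw <- sweep_1d(demographic_params(), "u_x", values = c(0, 0.5, 1),
#'                scan_step = 0.05)
#' sw$beta_ess_1  # constant: killing females does not move the ESS
#' }
#' @export
sweep_1d <- function(params, param, values = NULL, steps = 11,
                     scan_step = 0.01, ...) {
  validate_params(params)
  if (is.null(values)) {
    r <- param_ranges(param)
    values <- seq(r[1], r[2], length.out = steps)
  }
  if (!param %in% param_names())
    stop_invalid(sprintf("unknown parameter '%s'", param))
  if (length(values) == 0) {
    out <- data.frame(param = character(0), value = numeric(0),
                      beta_ess_1 = numeric(0), beta_ess_2 = numeric(0),
                      beta_repeller = numeric(0), n_attractors = integer(0),
                      bistable = logical(0), status = character(0))
    return(structure(out, class = c("sweep_result", "data.frame"),
                     axes = list(list(param = param, values = values)),
                     base_params = params, scan_step = scan_step))
  }
  rows <- lapply(values, function(v) {
    p <- do.call(modify_params,
                 c(list(params), stats::setNames(list(v), param)))
    cbind(data.frame(param = param, value = v),
          .sweep_cell(p, scan_step, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            axes = list(list(param = param, values = values)),
            base_params = params, scan_step = scan_step)
}

#' Two-parameter sweep of the evolutionarily stable fighter fraction
#'
#' Full factorial grid over two model parameters; one singular-strategy
#' analysis per cell. Full-resolution maps use 100 steps per axis; the
#' default here is a desk-scale 21 so that a full grid stays interactive,
#' with `steps`/`values` as the knob for full-resolution runs.
#'
#' @inheritParams sweep_1d
#' @param param1,param2 Names of the swept parameters.
#' @param values1,values2 Grid values (defaults: `steps` points across each
#'   parameter's standard sweep range).
#' @param steps Number of grid points per axis when values are not given.
#' @return A `sweep_result` data frame with columns `param1`, `value1`,
#'   `param2`, `value2` and the cell summary columns of [sweep_1d()].
#' @export
sweep_2d <- function(params, param1, param2, values1 = NULL, values2 = NULL,
                     steps = 21, scan_step = 0.01, ...) {
  validate_params(params)
  if (is.null(values1)) {
    r <- param_ranges(param1); values1 <- seq(r[1], r[2], length.out = steps)
  }
  if (is.null(values2)) {
    r <- param_ranges(param2); values2 <- seq(r[1], r[2], length.out = steps)
  }
  for (p in c(param1, param2))
    if (!p %in% param_names()) stop_invalid(sprintf("unknown parameter '%s'", p))
  if (param1 == param2) stop_invalid("the two swept parameters must differ")
  grid <- expand.grid(value1 = values1, value2 = values2,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    repl <- stats::setNames(list(grid$value1[i], grid$value2[i]),
                            c(param1, param2))
    p <- do.call(modify_params, c(list(params), repl))
    cbind(data.frame(param1 = param1, value1 = grid$value1[i],
                     param2 = param2, value2 = grid$value2[i]),
          .sweep_cell(p, scan_step, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            axes = list(list(param = param1, values = values1),
                        list(param = param2, values = values2)),
            base_params = params, scan_step = scan_step)
}

#' Extract isoclines of the ESS surface from a two-parameter sweep
#'
#' Marching-squares contours (via [grDevices::contourLines()]) of the
#' `beta_ess_1` surface at the requested levels (default:
#' increments of 0.1). Bistable cells are contoured on
#' the lower attractor `beta_ess_1`, with the bistable region reported
#' separately in the `"bistable_cells"` attribute.
#'
#' @param result A two-axis [sweep_2d()] result.
#' @param levels Contour levels of `beta_ess_1`.
#' @return A data frame with columns `level`, `piece`, `x` (parameter 1),
#'   `y` (parameter 2); zero rows if the surface is flat at other values or
#'   all `NA`. Attributes: `bistable_cells` (data frame of bistable grid
#'   cells) and `axes`.
#' @export
extract_isoclines <- function(result, levels = seq(0.1, 0.9, by = 0.1)) {
  if (!inherits(result, "sweep_result") || !"value2" %in% names(result))
    stop_invalid("result must come from sweep_2d()")
  axes <- attr(result, "axes")
  x <- sort(unique(result$value1))
  y <- sort(unique(result$value2))
  z <- matrix(NA_real_, length(x), length(y))
  ix <- match(result$value1, x)
  iy <- match(result$value2, y)
  z[cbind(ix, iy)] <- result$beta_ess_1
  cl <- if (all(is.na(z))) list() else {
    zz <- z
    zz[is.na(zz)] <- NaN
    # a constant surface legitimately has no contours (warning suppressed)
    tryCatch(suppressWarnings(
      grDevices::contourLines(x = x, y = y, z = zz, levels = levels)),
      error = function(e) list())
  }
  out <- if (length(cl) == 0) {
    data.frame(level = numeric(0), piece = integer(0),
               x = numeric(0), y = numeric(0))
  } else {
    do.call(rbind, lapply(seq_along(cl), function(i)
      data.frame(level = cl[[i]]$level, piece = i,
                 x = cl[[i]]$x, y = cl[[i]]$y)))
  }
  bi <- result[!is.na(result$bistable) & result$bistable,
               c("value1", "value2"), drop = FALSE]
  rownames(bi) <- NULL
  structure(out, bistable_cells = bi, axes = axes)
}

#' @export
print.sweep_result <- function(x, ...) {
  axes <- attr(x, "axes")
  if (length(axes) == 1) {
    cat(sprintf("1-D sweep of %s over [%g, %g] (%d values)\n",
                axes[[1]]$param, min(axes[[1]]$values),
                max(axes[[1]]$values), length(axes[[1]]$values)))
  } else {
    cat(sprintf("2-D sweep of %s x %s (%d x %d grid)\n",
                axes[[1]]$param, axes[[2]]$param,
                length(axes[[1]]$values), length(axes[[2]]$values)))
  }
  nbi <- sum(x$bistable, na.rm = TRUE)
  cat(sprintf("  cells: %d ok, %d bistable, %d flagged\n",
              sum(x$status == "ok"), nbi, sum(x$status != "ok")))
  print(as.data.frame(utils::head(x, 8)), digits = 4)
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}
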
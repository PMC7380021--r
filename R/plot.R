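#' Plot a pairwise invasibility plot
#'
#' Sign of `W - 1` over the (resident, mutant) trait plane: grey where the
#' mutant cannot invade, white where it can, with the neutral diagonal.
#'
#' @param x A [build_pip()] result.
#' @param ... Further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.pip_grid <- function(x, ...) {
  graphics::image(x$beta, x$beta, t(x$sign),
                  col = c("grey40", "grey80", "white"),
                  breaks = c(-1.5, -0.5, 0.5, 1.5),
                  xlab = "resident fighter fraction (beta)",
                  ylab = "mutant fighter fraction (beta')",
                  main = "Pairwise invasibility plot", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Plot a sweep of the evolutionarily stable fighter fraction
#'
#' For one-axis sweeps, the attractors (and any repeller, dotted) against the
#' swept parameter. For two-axis sweeps, a grey-scale map of the lower
#' attractor with isoclines in increments of 0.1, bistable cells marked.
#'
#' @param x A [sweep_1d()] or [sweep_2d()] result.
#' @param ... Further arguments passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, ...) {
  axes <- attr(x, "axes")
  if (length(axes) == 1) {
    graphics::plot(x$value, x$beta_ess_1, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = axes[[1]]$param,
                   ylab = "beta_ESS", ...)
    if (any(!is.na(x$beta_ess_2)))
      graphics::points(x$value, x$beta_ess_2, type = "b", pch = 1)
    if (any(!is.na(x$beta_repeller)))
      graphics::lines(x$value, x$beta_repeller, lty = 3)
  } else {
    xv <- sort(unique(x$value1))
    yv <- sort(unique(x$value2))
    z <- matrix(NA_real_, length(xv), length(yv))
    z[cbind(match(x$value1, xv), match(x$value2, yv))] <- x$beta_ess_1
    graphics::image(xv, yv, z, col = grDevices::grey.colors(20, 0.2, 1),
                    zlim = c(0, 1), xlab = axes[[1]]$param,
                    ylab = axes[[2]]$param, ...)
    iso <- extract_isoclines(x)
    for (pc in unique(iso$piece))
      graphics::lines(iso$x[iso$piece == pc], iso$y[iso$piece == pc])
    bi <- x[!is.na(x$bistable) & x$bistable, ]
    if (nrow(bi) > 0) graphics::points(bi$value1, bi$value2, pch = 4)
  }
  invisible(x)
}
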
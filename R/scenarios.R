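#' Named parameter scenarios for demonstrations and tests
#'
#' A deterministic list of parameter scenarios spanning the analyses of the
#' model: the default parameterization, each killing probability at
#' representative values, the very-low scrambler-killing regime, morph
#' survival extremes, and mating-competition extremes. Each scenario deviates
#' from the defaults in a single parameter and carries an optional
#' `expectation` tag with the qualitative evolutionary outcome this regime is
#' classically associated with (`coexistence`, `all_fighters`,
#' `bistable`, `extinct`, or `NA` where none is asserted).
#'
#' @return A named list of `scenario` objects: lists with `name`, `params`
#'   (a [demographic_params()] object) and `expectation`.
#' @examples
#' sc <- generate_scenarios()
#' names(sc)[1:4]
#' sc$table1_default$expectation
#' @export
generate_scenarios <- function() {
  mk <- function(name, expectation = NA_character_, ...) {
    list(name = name, params = demographic_params(...),
         expectation = expectation)
  }
  sc <- list(
    mk("table1_default", "coexistence"),
    mk("fig2_uz_low", "coexistence", u_z = 0.25),
    mk("fig2_uz_mid", "coexistence", u_z = 0.5),
    mk("fig2_uz_high", "coexistence", u_z = 1),
    mk("fig2_ux_low", "coexistence", u_x = 0.25),
    mk("fig2_ux_mid", "coexistence", u_x = 0.5),
    mk("fig2_ux_high", "coexistence", u_x = 1),
    mk("fig2_uf_low", "coexistence", u_f = 0.25),
    mk("fig2_uf", "coexistence", u_f = 0.5),
    mk("fig2_uf_high", "coexistence", u_f = 1),
    mk("fig2_us_bistable", "bistable", u_s = 0.002),
    mk("fig2_us_fighters", "all_fighters", u_s = 0.05),
    mk("fig2_us_low", NA_character_, u_s = 0.25),
    mk("fig2_us_mid", NA_character_, u_s = 0.5),
    mk("fig2_us_high", NA_character_, u_s = 1),
    mk("fig5_sff_low", NA_character_, sigma_ff = 0.90),
    mk("fig5_sff_high", "all_fighters", sigma_ff = 1.00),
    mk("fig5_sss_low", "all_fighters", sigma_ss = 0.90),
    mk("fig5_sss_high", NA_character_, sigma_ss = 1.00),
    mk("fig6_cm_none", NA_character_, c_m = 0),
    mk("fig6_cm_full", NA_character_, c_m = 1),
    mk("fig6_C_low", NA_character_, C = 0.5),
    mk("fig6_C_high", NA_character_, C = 1),
    mk("fig6_V_low", NA_character_, V = 0.5),
    mk("fig6_eps_zero", NA_character_, eps = 0),
    mk("fig6_eps_high", NA_character_, eps = 0.4)
  )
  sc <- lapply(sc, function(s) { class(s) <- "scenario"; s })
  names(sc) <- vapply(sc, `[[`, character(1), "name")
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  dev <- character(0)
  def <- demographic_params()
  for (nm in param_names())
    if (!identical(x$params[[nm]], def[[nm]]))
      dev <- c(dev, sprintf("%s=%g", nm, x$params[[nm]]))
  cat("  deviations from defaults:",
      if (length(dev) == 0) "none" else paste(dev, collapse = ", "), "\n")
  cat("  expectation:",
      if (is.na(x$expectation)) "none stated" else x$expectation, "\n")
  invisible(x)
}
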
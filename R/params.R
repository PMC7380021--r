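#' Demographic parameters of the two-sex, two-tactic population model
#'
#' Constructs and validates the full parameter set of the stage-structured
#' bulb-mite model: four life stages (zygotes `z`, adult females `x`, adult
#' fighter males `f`, adult scrambler males `s`), a hawk-dove mating game
#' among the male morphs, and intraspecific killing by fighters.
#'
#' Defaults are the bulb-mite (*Rhizoglyphus robini*) parameterization; the
#' killing probabilities `u_z`, `u_x`, `u_f`, `u_s` default to zero, in which
#' case the model reduces to the baseline two-sex, two-tactic model.
#'
#' `beta`, the proportion of male zygotes that develop into fighters, is the
#' evolving trait of the adaptive-dynamics analysis. It has no canonical
#' default; `0.5` is used as a conventional resident starting value and the
#' analysis functions always set it explicitly.
#'
#' @param e0 Number of individuals (any stage) encountered by a focal
#'   individual per day. Must be positive; values above 1 can drive the
#'   killed proportions to their clamp at 1.
#' @param rho Proportion of zygotes that mature into males, so that a
#'   fraction `1 - rho` matures into females. In `[0, 1]`; fixed at 0.5 for
#'   the bulb mite (chromosomal sex determination, no sex-ratio adjustment).
#' @param beta Proportion of male zygotes developing into fighters
#'   (the evolving trait). In `[0, 1]`.
#' @param t_x,t_f,t_s Maturation times (days) of zygotes maturing into adult
#'   females, fighters and scramblers. Must be `>= 1` so the maturation rates
#'   `G_i = sigma_zz / t_i` stay at most 1 per day.
#' @param c_m Strength of male-male competition, the probability that a
#'   mating encounter is contested by another male. In `[0, 1]`.
#' @param C Cost, for a fighter, of fighting another fighter, expressed as a
#'   probability of access foregone. In `[0, 1]`.
#' @param V Probability of accessing a female without costs. In `[0, 1]`.
#' @param eps Probability that a scrambler sneaks a mating when the opponent
#'   is a fighter. Must satisfy `eps < V`.
#' @param k0 Density-independent clutch size (offspring per mating), positive.
#' @param sigma_zz,sigma_xx,sigma_ff,sigma_ss Daily survival rates of
#'   zygotes, females, fighters and scramblers. In `[0, 1]`.
#' @param u_z,u_x,u_f,u_s Killing success: the probability that an individual
#'   of the given stage is killed when encountered by a fighter. In `[0, 1]`.
#' @param fertility Bookkeeping convention for male fertility entries.
#'   `"per_male"` (default) divides the births `B_{x,j}` sired by morph `j`
#'   by twice the density of that morph, so the fathers' share of births
#'   equals the mothers' share (`F_x n_x = F_f n_f + F_s n_s`).
#'   `"per_female"` divides by twice the female density instead, crediting
#'   each male of morph `j` with births proportional to the morph's own
#'   density. See the package vignette for why `"per_male"` is the default.
#' @param encounter_denominator Which densities enter the denominator of the
#'   mass-action encounter rate `e_{i,j} = e0 n_i n_j / D`: all four stages
#'   (`"all_stages"`, default, required for killing of zygotes to be
#'   well-defined) or only the adult stages (`"adults_only"`).
#'
#' @return An object of class `demographic_params`: a named list of the
#'   parameters above.
#' @examples
#' p <- demographic_params()              # Table-style defaults
#' p2 <- demographic_params(u_f = 0.5)    # fighters kill fighters
#' p3 <- modify_params(p, beta = 0.8)
#' @seealso [modify_params()], [load_config()], [param_ranges()]
#' @export
demographic_params <- function(e0 = 1, rho = 0.5, beta = 0.5,
                               t_x = 13.7, t_f = 14.4, t_s = 12.6,
                               c_m = 0.9, C = 0.7, V = 1, eps = 0.2,
                               k0 = 26.1,
                               sigma_zz = 1, sigma_xx = 0.95,
                               sigma_ff = 0.95, sigma_ss = 0.96,
                               u_z = 0, u_x = 0, u_f = 0, u_s = 0,
                               fertility = c("per_male", "per_female"),
                               encounter_denominator = c("all_stages",
                                                         "adults_only")) {
  fertility <- match.arg(fertility)
  encounter_denominator <- match.arg(encounter_denominator)
  p <- list(e0 = e0, rho = rho, beta = beta,
            t_x = t_x, t_f = t_f, t_s = t_s,
            c_m = c_m, C = C, V = V, eps = eps, k0 = k0,
            sigma_zz = sigma_zz, sigma_xx = sigma_xx,
            sigma_ff = sigma_ff, sigma_ss = sigma_ss,
            u_z = u_z, u_x = u_x, u_f = u_f, u_s = u_s,
            fertility = fertility,
            encounter_denominator = encounter_denominator)
  class(p) <- "demographic_params"
  validate_params(p)
  p
}

#' Names of the numeric model parameters
#'
#' The parameter symbols accepted in configuration files, in canonical order.
#'
#' @return Character vector of the 19 numeric parameter names.
#' @export
param_names <- function() {
  c("e0", "rho", "beta", "t_x", "t_f", "t_s", "c_m", "C", "V", "eps", "k0",
    "sigma_zz", "sigma_xx", "sigma_ff", "sigma_ss",
    "u_z", "u_x", "u_f", "u_s")
}

# hard validation bounds for every numeric parameter
.param_bounds <- list(
  e0 = c(1e-12, Inf), rho = c(0, 1), beta = c(0, 1),
  t_x = c(1, Inf), t_f = c(1, Inf), t_s = c(1, Inf),
  c_m = c(0, 1), C = c(0, 1), V = c(0, 1), eps = c(0, 1),
  k0 = c(1e-12, Inf),
  sigma_zz = c(0, 1), sigma_xx = c(0, 1), sigma_ff = c(0, 1),
  sigma_ss = c(0, 1),
  u_z = c(0, 1), u_x = c(0, 1), u_f = c(0, 1), u_s = c(0, 1)
)

#' Ranges over which parameters are varied in sweeps
#'
#' The range over which each varied parameter is swept in the standard
#' analyses: the trait and killing probabilities over `[0, 1]`, competition
#' parameters and morph survival rates over their biologically motivated
#' sub-intervals.
#'
#' @param param Optional parameter name; if given, the 2-vector `c(lo, hi)`
#'   for that parameter (error if the parameter is not a swept one).
#' @return A named list of ranges, or a single range.
#' @export
param_ranges <- function(param = NULL) {
  r <- list(beta = c(0, 1), c_m = c(0, 1), C = c(0.5, 1), V = c(0.5, 1),
            eps = c(0, 0.4), sigma_ff = c(0.9, 1), sigma_ss = c(0.9, 1),
            u_z = c(0, 1), u_x = c(0, 1), u_f = c(0, 1), u_s = c(0, 1))
  if (is.null(param)) return(r)
  if (!param %in% names(r))
    stop_invalid(sprintf("'%s' is not a sweepable parameter (one of %s)",
                         param, paste(names(r), collapse = ", ")))
  r[[param]]
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named numeric parameters (or the
#' `fertility` / `encounter_denominator` options) replaced, re-validated.
#'
#' @param params A `demographic_params` object.
#' @param ... Named replacements, e.g. `beta = 0.3, u_f = 0.5`.
#' @return A validated `demographic_params` object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "demographic_params"))
  repl <- list(...)
  if (length(repl) == 0) return(params)
  bad <- setdiff(names(repl), names(params))
  if (is.null(names(repl)) || any(names(repl) == "") || length(bad) > 0)
    stop_invalid(sprintf("unknown parameter(s): %s",
                         paste(bad, collapse = ", ")))
  params[names(repl)] <- repl
  validate_params(params)
  params
}

#' @rdname demographic_params
#' @param params Object to validate.
#' @return `validate_params` returns `params` invisibly, or signals an
#'   `artevol_invalid_parameter` error.
#' @export
validate_params <- function(params) {
  if (!is.list(params)) stop_invalid("parameters must be a list")
  for (nm in param_names()) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_invalid(sprintf("parameter '%s' must be a single finite number", nm))
    b <- .param_bounds[[nm]]
    if (v < b[1] || v > b[2])
      stop_invalid(sprintf("parameter '%s' = %g outside its range [%g, %g]",
                           nm, v, b[1], b[2]))
  }
  if (params$eps >= params$V)
    stop_invalid(sprintf(
      "eps = %g must be smaller than V = %g (model assumption eps < V)",
      params$eps, params$V))
  # zygote outflow (1-rho) G_x + rho [beta G_f + (1-beta) G_s] must stay <= 1
  # for every beta in [0, 1]; it is linear in beta, so check both ends
  gx <- params$sigma_zz / params$t_x
  gf <- params$sigma_zz / params$t_f
  gs <- params$sigma_zz / params$t_s
  out0 <- (1 - params$rho) * gx + params$rho * gs
  out1 <- (1 - params$rho) * gx + params$rho * gf
  if (max(out0, out1) > 1)
    stop_invalid("zygote maturation outflow exceeds 1; increase maturation times")
  if (!params$fertility %in% c("per_male", "per_female"))
    stop_invalid("fertility must be 'per_male' or 'per_female'")
  if (!params$encounter_denominator %in% c("all_stages", "adults_only"))
    stop_invalid("encounter_denominator must be 'all_stages' or 'adults_only'")
  invisible(params)
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters (two-sex, two-tactic model)\n")
  num <- unlist(x[param_names()])
  cat(sprintf("  trait beta (fighter fraction): %g\n", x$beta))
  cat("  maturation: ",
      sprintf("t_x=%g t_f=%g t_s=%g (days), rho=%g", x$t_x, x$t_f, x$t_s,
              x$rho), "\n", sep = "")
  cat("  competition: ",
      sprintf("c_m=%g C=%g V=%g eps=%g", x$c_m, x$C, x$V, x$eps), "\n",
      sep = "")
  cat("  reproduction: ", sprintf("k0=%g e0=%g", x$k0, x$e0), "\n", sep = "")
  cat("  survival: ",
      sprintf("sigma_zz=%g sigma_xx=%g sigma_ff=%g sigma_ss=%g",
              x$sigma_zz, x$sigma_xx, x$sigma_ff, x$sigma_ss), "\n", sep = "")
  cat("  killing success: ",
      sprintf("u_z=%g u_x=%g u_f=%g u_s=%g", x$u_z, x$u_x, x$u_f, x$u_s),
      "\n", sep = "")
  cat("  options: fertility=", x$fertility,
      ", encounter_denominator=", x$encounter_denominator, "\n", sep = "")
  invisible(x)
}

#' Stage-density vector
#'
#' A population state: densities of zygotes, adult females, fighters and
#' scramblers (individuals; non-negative and finite).
#'
#' @param n_z,n_x,n_f,n_s Densities of the four stages.
#' @return A named numeric vector of class `stage_densities` with names
#'   `c("z", "x", "f", "s")`.
#' @examples
#' stage_densities(100, 50, 25, 25)
#' @export
stage_densities <- function(n_z, n_x, n_f, n_s) {
  n <- c(z = n_z, x = n_x, f = n_f, s = n_s)
  if (!is.numeric(n) || length(n) != 4 || any(!is.finite(n)) || any(n < 0))
    stop_invalid("stage densities must be four non-negative finite numbers")
  class(n) <- "stage_densities"
  n
}

# accept stage_densities or a plain numeric length-4 vector
as_state <- function(state) {
  if (inherits(state, "stage_densities")) return(unclass(state))
  if (is.numeric(state) && length(state) == 4) {
    if (any(!is.finite(state)) || any(state < 0))
      stop_invalid("stage densities must be non-negative and finite")
    s <- as.vector(state)
    names(s) <- c("z", "x", "f", "s")
    return(s)
  }
  stop_invalid("state must be a stage_densities object or numeric of length 4")
}

#' @export
print.stage_densities <- function(x, ...) {
  cat("Stage densities: ")
  cat(sprintf("z=%.6g x=%.6g f=%.6g s=%.6g (total %.6g)\n",
              x[1], x[2], x[3], x[4], sum(x)))
  invisible(x)
}

# condition helpers --------------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg,
                      class = c("artevol_invalid_parameter", "error",
                                "condition")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg,
                      class = c("artevol_degenerate_state", "error",
                                "condition")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg,
                      class = c("artevol_numerical_failure", "error",
                                "condition")))
}
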
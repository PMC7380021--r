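#' Maturation rate of zygotes into an adult stage
#'
#' Zygotes mature into adult stage `i` at rate `G_i = sigma_zz / t_i` per
#' day, the zygote survival rate spread over the stage's maturation time.
#'
#' @param params A [demographic_params()] object.
#' @param stage One of `"x"` (female), `"f"` (fighter), `"s"` (scrambler).
#' @return Maturation rate per day, in `(0, 1]`.
#' @examples
#' maturation_rate(demographic_params(), "x")  # 1 / 13.7
#' @export
maturation_rate <- function(params, stage = c("x", "f", "s")) {
  stage <- match.arg(stage)
  validate_params(params)
  t_i <- params[[paste0("t_", stage)]]
  if (t_i <= 0) stop_invalid("maturation time must be positive")
  params$sigma_zz / t_i
}

#' Zygote stasis rate
#'
#' The per-day rate of surviving and remaining a zygote:
#' `P_z = sigma_zz * (1 - [(1 - rho) G_x + beta rho G_f + (1 - beta) rho G_s])`.
#'
#' @inheritParams maturation_rate
#' @param beta Trait value at which to evaluate `P_z`; defaults to the
#'   resident trait in `params`.
#' @return `P_z`, in `[0, sigma_zz]`.
#' @export
zygote_stasis <- function(params, beta = params$beta) {
  validate_params(params)
  if (beta < 0 || beta > 1) stop_invalid("beta must be in [0, 1]")
  pp <- .precompute(params)
  out <- (1 - pp$rho) * pp$gx + beta * pp$rho * pp$gf +
    (1 - beta) * pp$rho * pp$gs
  if (out > 1) stop_invalid("zygote maturation outflow exceeds 1")
  .pz(pp, beta)
}

#' Hawk-dove payoff matrix of the male mating game
#'
#' Probabilities that a male of one morph gains access to a female in a
#' pairwise contest: fighters play hawk (reward `V`, cost of escalated
#' fights `C`), scramblers play a sneaking dove (success `eps`).
#'
#' @inheritParams maturation_rate
#' @return A 2x2 matrix with rows/columns named `f`, `s`; entry `[j, k]` is
#'   the probability that a male of morph `j` obtains the mating when the
#'   opponent is of morph `k`. The fighter-fighter entry `(V - C) / 2` may be
#'   negative when `C > V` (standard hawk-dove convention; the entry is not
#'   clamped, the mating probability built from it is).
#' @examples
#' payoff_matrix(demographic_params())  # ((0.15, 0.8), (0.2, 0.5))
#' @export
payoff_matrix <- function(params) {
  validate_params(params)
  m <- matrix(c((params$V - params$C) / 2, params$V - params$eps,
                params$eps, params$V / 2),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("f", "s"), c("f", "s")))
  class(m) <- c("payoff_matrix", class(m))
  m
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Mating-contest payoff matrix (row morph vs column morph):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Probability that an encounter leads to a successful mating
#'
#' With probability `1 - c_m` a male mates unopposed; with probability `c_m`
#' he faces a competitor drawn from the male pool, winning according to the
#' hawk-dove payoff matrix weighted by the morph frequencies:
#' `p_{x,j} = 1 - c_m + c_m * (phi m_{jf} + (1 - phi) m_{js})` with
#' `phi = n_f / (n_f + n_s)`. The result is clamped to `[0, 1]` (with a
#' warning) because the fighter-fighter payoff can be negative when `C > V`.
#'
#' @inheritParams maturation_rate
#' @param state Stage densities (a [stage_densities()] object or numeric
#'   vector `c(z, x, f, s)`); the male pool `n_f + n_s` must be positive.
#' @param morph `"f"` or `"s"`.
#' @return Mating probability in `[0, 1]`.
#' @export
mating_probability <- function(params, state, morph = c("f", "s")) {
  morph <- match.arg(morph)
  validate_params(params)
  n <- as_state(state)
  if (n[[3]] + n[[4]] <= 0)
    stop_degenerate("no males present: mating probability undefined")
  pp <- .precompute(params)
  phi <- n[[3]] / (n[[3]] + n[[4]])
  p <- if (morph == "f") {
    1 - pp$cm + pp$cm * (phi * pp$mff + (1 - phi) * pp$mfs)
  } else {
    1 - pp$cm + pp$cm * (phi * pp$msf + (1 - phi) * pp$mss)
  }
  if (p < 0 || p > 1) {
    warning(sprintf("mating probability %.4f clamped to [0, 1]", p))
    p <- min(max(p, 0), 1)
  }
  p
}

#' Mass-action encounter rate between two stages
#'
#' `e_{i,j} = e0 n_i n_j / D`, where `D` is the total density over all four
#' stages (default) or over the adult stages only, depending on the
#' `encounter_denominator` option of the parameter set.
#'
#' @inheritParams mating_probability
#' @param stage_i,stage_j Stage identifiers among `"z"`, `"x"`, `"f"`, `"s"`.
#' @return Encounters per day (symmetric in the two stages).
#' @export
encounter_rate <- function(params, state,
                           stage_i = c("z", "x", "f", "s"),
                           stage_j = c("z", "x", "f", "s")) {
  stage_i <- match.arg(stage_i)
  stage_j <- match.arg(stage_j)
  validate_params(params)
  n <- as_state(state)
  den <- if (identical(params$encounter_denominator, "all_stages"))
    sum(n) else sum(n[2:4])
  if (den <= 0)
    stop_degenerate("population empty: encounter rate undefined")
  params$e0 * n[[stage_i]] * n[[stage_j]] / den
}

#' Density-dependent clutch size
#'
#' `k = k0 / (1 + n_x)`: clutch size declines with female density.
#'
#' @inheritParams mating_probability
#' @return Offspring per mating, in `(0, k0]`.
#' @export
clutch_size <- function(params, state) {
  validate_params(params)
  n <- as_state(state)
  params$k0 / (1 + n[[2]])
}

#' Fertility entries of the projection matrix
#'
#' Births from matings between females and males of morph `j` are
#' `B_{x,j} = k e_{x,j} p_{x,j}`. The female fertility is
#' `F_x = (B_{x,f} + B_{x,s}) / (2 n_x)`. Male fertilities follow the
#' convention in `params$fertility`: `"per_male"` (default) credits each male
#' of morph `j` with `F_j = B_{x,j} / (2 n_j)` so the fathers' birth total
#' matches the mothers'; `"per_female"` uses `F_j = B_{x,j} / (2 n_x)`.
#' All three are 0 when there are no females or no males (degenerate-state
#' contract).
#'
#' @inheritParams mating_probability
#' @return Named numeric vector `c(F_x, F_f, F_s)` (per-day fertilities).
#' @export
fertilities <- function(params, state) {
  validate_params(params)
  n <- as_state(state)
  r <- .rates_at(.precompute(params), n)
  c(F_x = r[1], F_f = r[2], F_s = r[3])
}

#' Proportions killed by fighters per day
#'
#' Fighters kill encountered individuals of stage `i` with probability `u_i`.
#' The number killed per day is `q_i = e_{i,f} u_i`, so the proportion of
#' stage `i` killed per day is `Q_i = q_i / n_i = e0 u_i n_f / D` (the
#' stage's own density cancels). `Q_i` is clamped to `[0, 1]` with a warning;
#' the clamp is only reachable when `e0 > 1`.
#'
#' @inheritParams mating_probability
#' @return Named numeric vector `c(Q_z, Q_x, Q_f, Q_s)`.
#' @export
killed_proportions <- function(params, state) {
  validate_params(params)
  n <- as_state(state)
  den <- if (identical(params$encounter_denominator, "all_stages"))
    sum(n) else sum(n[2:4])
  if (den <= 0)
    stop_degenerate("population empty: killed proportions undefined")
  r <- .rates_at(.precompute(params), n)
  if (r[12] > 0)
    warning("killed proportion exceeded 1 and was clamped (e0 > 1)")
  c(Q_z = r[4], Q_x = r[5], Q_f = r[6], Q_s = r[7])
}

#' Density-dependent population projection matrix
#'
#' Assembles the 4x4 per-day projection matrix `N` over the stages
#' (z, x, f, s) at the given population state:
#' \preformatted{
#'   (1-Q_z) P_z     F_x           F_f           F_s
#'   (1-rho) G_x     (1-Q_x) P_x   0             0
#'   rho beta G_f    0             (1-Q_f) P_f   0
#'   rho(1-b) G_s    0             0             (1-Q_s) P_s
#' }
#' with adult stasis `P_j = sigma_jj`. With all killing probabilities zero
#' the matrix reduces entrywise to the baseline model's matrix.
#'
#' Overriding `beta` while keeping the state (and hence all fertilities and
#' killed proportions) frozen yields the mutant matrix `N'` used by
#' [invasion_fitness()].
#'
#' @inheritParams mating_probability
#' @param beta Trait value for the matrix entries that depend on `beta`
#'   (first column); defaults to the resident trait in `params`.
#' @return A 4x4 matrix of class `projection_matrix` with a `"components"`
#'   attribute listing `P_z`, the maturation rates `G`, fertilities `F`,
#'   killed proportions `Q`, mating probabilities `p`, and clutch size `k`.
#' @examples
#' p <- demographic_params(beta = 0.5)
#' N <- projection_matrix(p, stage_densities(0, 50, 25, 25))
#' N["f", "z"]  # rho * beta * G_f
#' @export
projection_matrix <- function(params, state, beta = params$beta) {
  validate_params(params)
  if (beta < 0 || beta > 1) stop_invalid("beta must be in [0, 1]")
  n <- as_state(state)
  pp <- .precompute(params)
  r <- .rates_at(pp, n)
  if (r[12] > 0)
    warning("killed proportion exceeded 1 and was clamped (e0 > 1)")
  M <- .matrix_at(pp, r, beta)
  attr(M, "components") <- list(
    P_z = .pz(pp, beta),
    G = c(G_x = pp$gx, G_f = pp$gf, G_s = pp$gs),
    F = c(F_x = r[1], F_f = r[2], F_s = r[3]),
    Q = c(Q_z = r[4], Q_x = r[5], Q_f = r[6], Q_s = r[7]),
    p = c(p_f = r[8], p_s = r[9]),
    k = r[10],
    beta = beta)
  class(M) <- c("projection_matrix", class(M))
  M
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("Population projection matrix (per day), stages z, x, f, s:\n")
  M <- x
  attr(M, "components") <- NULL
  print(unclass(M), digits = 6)
  cmp <- attr(x, "components")
  cat(sprintf("beta = %g;  F = (%.5g, %.5g, %.5g);  Q = (%.4g, %.4g, %.4g, %.4g)\n",
              cmp$beta, cmp$F[1], cmp$F[2], cmp$F[3],
              cmp$Q[1], cmp$Q[2], cmp$Q[3], cmp$Q[4]))
  invisible(x)
}
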
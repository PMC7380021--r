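#' Advance the population by one day
#'
#' One application of the nonlinear map `n_{t+1} = N(n_t) n_t`, where `N` is
#' the density-dependent projection matrix evaluated at the current state.
#' An all-zero (extinct) state maps to itself.
#'
#' @inheritParams mating_probability
#' @return The next state, as a [stage_densities()] object.
#' @export
step_population <- function(params, state) {
  validate_params(params)
  n <- as_state(state)
  if (sum(n) == 0) return(stage_densities(0, 0, 0, 0))
  pp <- .precompute(params)
  r <- .rates_at(pp, n)
  n2 <- .step_once(pp, n, r)
  stage_densities(n2[1], n2[2], n2[3], n2[4])
}

#' Iterate the population to its demographic equilibrium
#'
#' Repeatedly applies the nonlinear map `n_{t+1} = N(n_t) n_t` until the
#' relative state change per step falls below `tol_state`, then verifies the
#' equilibrium by checking that the dominant eigenvalue of `N` evaluated at
#' the final state is 1 within `tol_lambda`. Convergence requires both
#' criteria. If the map has not settled after `max_steps` steps and
#' `extend = TRUE`, iteration continues up to `10 * max_steps` with a
#' warning (useful near bifurcations); non-convergence is reported in the
#' result, never raised as an error.
#'
#' @inheritParams mating_probability
#' @param initial Starting state; the default `(10, 10, 10, 10)` is an
#'   arbitrary interior point (for the defaults the equilibrium is
#'   independent of any strictly positive start).
#' @param max_steps Nominal iteration budget (default 1000 days).
#' @param tol_state Relative state-change tolerance declaring a fixed point.
#' @param tol_lambda Tolerance on `|lambda - 1|` at the final state.
#' @param extend Continue past `max_steps` (to 10x) if unconverged.
#' @param keep_trajectory Store the full state sequence (rows = days).
#' @return An object of class `trajectory`: a list with `equilibrium`
#'   (stage densities), `lambda` (dominant eigenvalue of `N` at the final
#'   state), `converged`, `extinct` (total density below `1e-12`),
#'   `boundary` (some stage below `1e-12` while the population persists),
#'   `steps_used`, and (optionally) `states`.
#' @examples
#' tr <- run_to_equilibrium(demographic_params(beta = 0.5))
#' tr$lambda  # 1 at a converged interior equilibrium
#' @export
run_to_equilibrium <- function(params, initial = stage_densities(10, 10, 10, 10),
                               max_steps = 1000L, tol_state = 1e-8,
                               tol_lambda = 1e-6, extend = TRUE,
                               keep_trajectory = FALSE) {
  validate_params(params)
  n0 <- as_state(initial)
  if (max_steps < 1) stop_invalid("max_steps must be at least 1")
  pp <- .precompute(params)

  if (keep_trajectory) {
    hard <- if (extend) 10L * as.integer(max_steps) else as.integer(max_steps)
    states <- matrix(NA_real_, nrow = hard + 1L, ncol = 4,
                     dimnames = list(NULL, c("z", "x", "f", "s")))
    states[1L, ] <- n0
    n <- n0
    relchg <- Inf
    step <- 0L
    while (step < hard) {
      step <- step + 1L
      r <- .rates_at(pp, n)
      n2 <- .step_once(pp, n, r)
      if (any(!is.finite(n2)))
        stop_numerical(sprintf("non-finite densities at step %d", step))
      s1 <- sum(n)
      relchg <- if (s1 > 0) sum(abs(n2 - n)) / s1 else 0
      n <- n2
      states[step + 1L, ] <- n
      if (relchg < tol_state) break
    }
    eq <- list(n = n, steps = step, relchg = relchg,
               state_converged = relchg < tol_state || sum(n) < 1e-12,
               extended = step > max_steps, extinct = sum(n) < 1e-12,
               clamped = FALSE)
    states <- states[seq_len(step + 1L), , drop = FALSE]
  } else {
    eq <- .equilibrate(pp, n0, max_steps = max_steps, tol_state = tol_state,
                       extend = extend)
    states <- NULL
  }
  if (eq$extended && extend)
    warning(sprintf("equilibrium not reached in %d steps; extended to %d",
                    as.integer(max_steps), eq$steps))

  r <- .rates_at(pp, eq$n)
  lambda <- .dom_eig(.matrix_at(pp, r))
  converged <- eq$state_converged && (eq$extinct || abs(lambda - 1) <= tol_lambda)
  out <- list(
    equilibrium = stage_densities(eq$n[1], eq$n[2], eq$n[3], eq$n[4]),
    lambda = lambda,
    converged = converged,
    extinct = eq$extinct,
    boundary = !eq$extinct && any(eq$n < 1e-12),
    steps_used = eq$steps,
    states = states,
    tol_state = tol_state, tol_lambda = tol_lambda,
    params = params)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Population trajectory:", x$steps_used, "steps;",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (x$extinct) cat("  population extinct\n")
  else {
    cat("  equilibrium: ")
    print(x$equilibrium)
    cat(sprintf("  dominant eigenvalue at equilibrium: %.8f\n", x$lambda))
    if (x$boundary) cat("  boundary equilibrium (some stage ~ 0)\n")
  }
  invisible(x)
}

#' Dominant eigenvalue and right eigenvector of a projection matrix
#'
#' For the non-negative matrices produced by this model the dominant
#' eigenvalue is real (Perron-Frobenius); a complex eigenvalue of largest
#' modulus signals an ill-conditioned spectrum and raises an error.
#'
#' @param M A 4x4 numeric matrix (e.g. from [projection_matrix()]).
#' @param tie_tol Relative tolerance used to decide that the largest-modulus
#'   eigenvalue is genuinely complex.
#' @return A list with `value` (real dominant eigenvalue) and `vector` (right
#'   eigenvector, rescaled to sum to 1).
#' @examples
#' dominant_eigenvalue(diag(c(0.9, 0.5, 0.2, 0.1)))$value  # 0.9
#' @export
dominant_eigenvalue <- function(M, tie_tol = 1e-9) {
  if (!is.matrix(M) || any(!is.finite(M)))
    stop_invalid("matrix must be finite")
  es <- eigen(unclass(M))
  i <- which.max(Mod(es$values))
  lam <- es$values[i]
  if (abs(Im(lam)) > tie_tol * max(1, Mod(lam)))
    stop_numerical("dominant eigenvalue is complex (ill-conditioned spectrum)")
  v <- Re(es$vectors[, i])
  s <- sum(v)
  if (abs(s) > 0) v <- v / s
  list(value = Re(lam), vector = v)
}
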
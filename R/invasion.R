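#' Invasion fitness of a mutant trait against an equilibrated resident
#'
#' Equilibrates a resident population with fighter fraction `beta_resident`,
#' then builds the mutant matrix `N'` by substituting `beta_mutant` for the
#' trait everywhere it appears in the matrix (the maturation entries and the
#' zygote stasis `P_z`) while all densities, fertilities and killed
#' proportions stay frozen at the resident equilibrium. The invasion fitness
#' `W(beta_mutant, beta_resident)` is the dominant eigenvalue of `N'`: the
#' mutant invades if `W > 1`. For a converged, persisting resident,
#' `W(beta, beta) = 1` (the resident is neutral in its own environment).
#'
#' @inheritParams mating_probability
#' @param beta_resident,beta_mutant Trait values in `[0, 1]`.
#' @param initial Starting state for the resident equilibration.
#' @param max_steps,tol_state,tol_lambda Passed to the equilibration (see
#'   [run_to_equilibrium()]).
#' @return An object of class `invasion_result`: list with `W` (`NA` if the
#'   resident went extinct or failed to converge -- flagged, never silently
#'   0), `beta_resident`, `beta_mutant`, `resident_equilibrium`,
#'   `resident_converged`, `resident_extinct`.
#' @examples
#' res <- invasion_fitness(demographic_params(), 0.5, 0.6)
#' res$W
#' @export
invasion_fitness <- function(params, beta_resident, beta_mutant,
                             initial = stage_densities(10, 10, 10, 10),
                             max_steps = 1000L, tol_state = 1e-10,
                             tol_lambda = 1e-6) {
  validate_params(params)
  if (beta_resident < 0 || beta_resident > 1 ||
      beta_mutant < 0 || beta_mutant > 1)
    stop_invalid("trait values must be in [0, 1]")
  pp <- .precompute(params)
  env <- .resident_env(pp, beta_resident, init = as_state(initial),
                       max_steps = max_steps, tol_state = tol_state,
                       tol_lambda = tol_lambda)
  W <- if (env$viable) .W(env, beta_mutant) else NA_real_
  out <- list(W = W,
              beta_resident = beta_resident,
              beta_mutant = beta_mutant,
              resident_equilibrium = stage_densities(env$n[1], env$n[2],
                                                     env$n[3], env$n[4]),
              resident_converged = env$converged,
              resident_extinct = env$extinct,
              resident_lambda = env$lambda)
  class(out) <- "invasion_result"
  out
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion fitness W(beta' = %g | beta = %g):\n",
              x$beta_mutant, x$beta_resident))
  if (is.na(x$W)) {
    cat("  undefined:",
        if (x$resident_extinct) "resident extinct"
        else "resident did not converge", "\n")
  } else {
    cat(sprintf("  W = %.8f  (%s)\n", x$W,
                if (x$W > 1) "mutant invades" else "mutant does not invade"))
  }
  invisible(x)
}

#' Selection gradient on the fighter fraction
#'
#' Slope of the invasion fitness in the mutant trait at the resident value:
#' `(W(beta + h, beta) - W(beta - h, beta)) / (2 h)`, computed against the
#' frozen resident environment, one-sided at the trait boundaries. A positive
#' gradient means mutants with slightly more fighter expression invade.
#'
#' @inheritParams invasion_fitness
#' @param beta Resident trait value.
#' @param h Finite-difference step (default 0.01, the trait-grid step).
#' @return The gradient, with attributes `resident_converged` and
#'   `resident_extinct`; `NA` if the resident is not viable.
#' @export
selection_gradient <- function(params, beta, h = 0.01,
                               initial = stage_densities(10, 10, 10, 10),
                               max_steps = 1000L, tol_state = 1e-10,
                               tol_lambda = 1e-6) {
  validate_params(params)
  if (beta < 0 || beta > 1) stop_invalid("beta must be in [0, 1]")
  if (h <= 0 || h > 0.5) stop_invalid("h must be in (0, 0.5]")
  pp <- .precompute(params)
  env <- .resident_env(pp, beta, init = as_state(initial),
                       max_steps = max_steps, tol_state = tol_state,
                       tol_lambda = tol_lambda)
  g <- if (env$viable) .gradient(env, h) else NA_real_
  structure(g, resident_converged = env$converged,
            resident_extinct = env$extinct)
}

#' Pairwise invasibility plot (PIP) grid
#'
#' Invasion fitness `W(beta_mutant, beta_resident)` over the full trait grid,
#' with one resident equilibration per grid column (resident value) and a
#' sign classification of `W - 1` at tolerance `tol` (`-1`, `0`, `+1`).
#' Columns whose resident is extinct or unconverged are `NA` and flagged.
#'
#' @inheritParams invasion_fitness
#' @param step Trait-grid increment; `1 / step` must be an integer (default
#'   0.01 gives the standard 101 x 101 grid).
#' @param tol Neutrality tolerance mapping `|W - 1| <= tol` to sign 0.
#' @return An object of class `pip_grid`: list with `beta` (grid), `W`
#'   (matrix, rows = mutant trait, columns = resident trait), `sign`,
#'   `resident_status` (`"ok"`, `"extinct"`, `"unconverged"` per column),
#'   `resident_equilibria` (4 x n matrix), `step`, `tol`, `params`.
#' @examples
#' pip <- build_pip(demographic_params(), step = 0.25)
#' pip$sign  # diagonal is neutral
#' @export
build_pip <- function(params, step = 0.01, tol = 1e-6,
                      initial = stage_densities(10, 10, 10, 10),
                      max_steps = 1000L, tol_state = 1e-10,
                      tol_lambda = 1e-6) {
  validate_params(params)
  if (step <= 0 || step > 0.5) stop_invalid("step must be in (0, 0.5]")
  if (abs(1 / step - round(1 / step)) > 1e-8)
    stop_invalid("1 / step must be an integer")
  betas <- seq(0, 1, by = step)
  nb <- length(betas)
  W <- matrix(NA_real_, nb, nb,
              dimnames = list(beta_mutant = NULL, beta_resident = NULL))
  eqs <- matrix(NA_real_, 4, nb, dimnames = list(c("z", "x", "f", "s"), NULL))
  status <- character(nb)
  pp <- .precompute(params)
  init <- as_state(initial)
  warm <- init
  for (j in seq_len(nb)) {
    env <- .resident_env(pp, betas[j], init = warm, max_steps = max_steps,
                         tol_state = tol_state, tol_lambda = tol_lambda)
    if (!env$extinct && sum(env$n) > 0) warm <- env$n
    eqs[, j] <- env$n
    status[j] <- if (env$extinct) "extinct"
      else if (!env$converged) "unconverged" else "ok"
    if (env$viable) W[, j] <- vapply(betas, function(bm) .W(env, bm),
                                     numeric(1))
  }
  sg <- sign(W - 1)
  sg[abs(W - 1) <= tol] <- 0
  out <- list(beta = betas, W = W, sign = sg, resident_status = status,
              resident_equilibria = eqs, step = step, tol = tol,
              params = params)
  class(out) <- "pip_grid"
  out
}

#' @export
print.pip_grid <- function(x, ...) {
  nb <- length(x$beta)
  cat(sprintf("Pairwise invasibility plot: %d x %d grid (step %g, tol %g)\n",
              nb, nb, x$step, x$tol))
  nok <- sum(x$resident_status != "ok")
  if (nok > 0) cat(" ", nok, "resident column(s) not viable\n")
  pos <- mean(x$sign == 1, na.rm = TRUE)
  neg <- mean(x$sign == -1, na.rm = TRUE)
  cat(sprintf("  sign structure: %.1f%% positive, %.1f%% negative, %.1f%% neutral\n",
              100 * pos, 100 * neg, 100 * (1 - pos - neg)))
  invisible(x)
}

# classify one refined singular point (or boundary point) using the three
# PIP criteria evaluated on the scan grid:
#   (a) vertical-line test  : invadable if any W(b', b*) > 1 + tol
#   (b) convergence stability: sign change of the gradient (+ to -)
#   (c) horizontal-line test: spreads when rare if W(b*, b) >= 1 - tol
#       for every viable resident b
.classify_point <- function(pp, bstar, convergence_stable, betas, envs,
                            h, neutral_tol, curvature_tol, init,
                            max_steps, tol_state, tol_lambda) {
  env <- .resident_env(pp, bstar, init = init, max_steps = max_steps,
                       tol_state = tol_state, tol_lambda = tol_lambda)
  Wv <- vapply(betas, function(bm) .W(env, bm), numeric(1))
  invadable <- any(Wv > 1 + neutral_tol)
  # curvature of W(b') at b* (second-order invadability)
  hh <- min(h, bstar, 1 - bstar)
  curv <- if (hh > 1e-6) {
    (.W(env, bstar + hh) - 2 * .W(env, bstar) + .W(env, bstar - hh)) / hh^2
  } else NA_real_
  # horizontal-line test against all viable scan residents
  Wh <- vapply(seq_along(betas), function(j) {
    if (is.null(envs[[j]]) || !envs[[j]]$viable) return(NA_real_)
    .W(envs[[j]], bstar)
  }, numeric(1))
  can_spread <- all(Wh >= 1 - neutral_tol, na.rm = TRUE)
  if (!convergence_stable) {
    kind <- "repeller"
  } else if (bstar <= 0) {
    kind <- "boundary_attractor_0"
  } else if (bstar >= 1) {
    kind <- "boundary_attractor_1"
  } else if (!invadable && !is.na(curv) && curv < -curvature_tol) {
    kind <- "strict_attractor"
  } else if (!invadable || (!is.na(curv) && abs(curv) <= curvature_tol)) {
    kind <- "neutral_attractor"
  } else {
    kind <- "branching_point"
  }
  list(beta = bstar, kind = kind, convergence_stable = convergence_stable,
       invadable = invadable, can_invade_when_rare = can_spread,
       curvature = curv)
}

#' Locate and classify evolutionarily singular strategies
#'
#' Scans the selection gradient along the trait interval, brackets its sign
#' changes, refines each root by bisection, and classifies every singular
#' point with the three pairwise-invasibility criteria: (a) invadability
#' (vertical-line test), (b) convergence stability (direction of the gradient
#' sign change), (c) ability to spread when rare (horizontal-line test).
#' Interior attractors in this model are evolutionarily neutral (a mutant at
#' the singular point has resident fitness, the limit case between a strict
#' ESS and a branching point) and are labelled `neutral_attractor`.
#' Trait boundaries are appended as `boundary_attractor_0` /
#' `boundary_attractor_1` when the one-sided gradient points into them.
#' Evolutionary bistability is flagged when at least two attractors exist
#' (necessarily separated by repellers).
#'
#' @inheritParams invasion_fitness
#' @param scan_step Gradient-scan increment along `[0, 1]` (default 0.01).
#' @param h Finite-difference step of the gradient (defaults to `scan_step`).
#' @param refine_tol Bisection tolerance on each root (default 1e-4).
#' @param neutral_tol `|W - 1|` tolerance for the PIP sign tests.
#' @param curvature_tol Curvature threshold separating the neutral limit case
#'   from a strict ESS or branching point.
#' @return An object of class `evolutionary_outcome`: list with `attractors`
#'   and `repellers` (data frames with columns `beta`, `kind`,
#'   `convergence_stable`, `invadable`, `can_invade_when_rare`, `curvature`),
#'   `beta_ess_values` (sorted attractor traits), `bistable`, `viable`
#'   (`FALSE` when no resident persists anywhere), `gradient` (the scan
#'   table: `beta`, `gradient`, `lambda`, `status`), and the call settings.
#' @examples
#' \donttest{
#' out <- find_singular_strategies(demographic_params(), scan_step = 0.05)
#' out$beta_ess_values
#' }
#' @export
find_singular_strategies <- function(params, scan_step = 0.01,
                                     h = scan_step, refine_tol = 1e-4,
                                     neutral_tol = 1e-6,
                                     curvature_tol = 1e-5,
                                     initial = stage_densities(10, 10, 10, 10),
                                     max_steps = 1000L, tol_state = 1e-10,
                                     tol_lambda = 1e-6) {
  validate_params(params)
  if (scan_step <= 0 || scan_step > 0.5)
    stop_invalid("scan_step must be in (0, 0.5]")
  pp <- .precompute(params)
  betas <- seq(0, 1, by = scan_step)
  if (betas[length(betas)] < 1) betas <- c(betas, 1)
  nb <- length(betas)
  init <- as_state(initial)

  envs <- vector("list", nb)
  grads <- rep(NA_real_, nb)
  lambdas <- rep(NA_real_, nb)
  status <- character(nb)
  warm <- init
  for (i in seq_len(nb)) {
    env <- .resident_env(pp, betas[i], init = warm, max_steps = max_steps,
                         tol_state = tol_state, tol_lambda = tol_lambda)
    if (!env$extinct && sum(env$n) > 0) warm <- env$n
    envs[[i]] <- env
    lambdas[i] <- env$lambda
    status[i] <- if (env$extinct) "extinct"
      else if (!env$converged) "unconverged" else "ok"
    if (env$viable) grads[i] <- .gradient(env, h)
  }
  scan <- data.frame(beta = betas, gradient = grads, lambda = lambdas,
                     status = status)

  out <- list(attractors = .empty_singular_df(), repellers = .empty_singular_df(),
              beta_ess_values = numeric(0), bistable = FALSE,
              viable = any(status == "ok"), gradient = scan,
              scan_step = scan_step, h = h, refine_tol = refine_tol,
              neutral_tol = neutral_tol, curvature_tol = curvature_tol,
              params = params)
  class(out) <- "evolutionary_outcome"
  if (!out$viable) return(out)

  grad_at <- function(b, warm_n) {
    env <- .resident_env(pp, b, init = warm_n, max_steps = max_steps,
                         tol_state = tol_state, tol_lambda = tol_lambda)
    if (!env$viable) return(NA_real_)
    .gradient(env, h)
  }

  points <- list()
  for (i in seq_len(nb - 1)) {
    g1 <- grads[i]; g2 <- grads[i + 1]
    if (is.na(g1) || is.na(g2)) next
    if (g1 == 0 || g1 * g2 >= 0) next
    # bisection on the gradient
    lo <- betas[i]; hi <- betas[i + 1]
    glo <- g1
    warm_n <- envs[[i]]$n
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      gm <- grad_at(mid, warm_n)
      if (is.na(gm)) break
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    bstar <- (lo + hi) / 2
    points[[length(points) + 1]] <- .classify_point(
      pp, bstar, convergence_stable = (g1 > 0), betas, envs, h,
      neutral_tol, curvature_tol, init = envs[[i]]$n,
      max_steps = max_steps, tol_state = tol_state, tol_lambda = tol_lambda)
  }

  # boundary attractors: one-sided gradient pointing into the boundary
  grad_zero <- 1e-9
  if (status[1] == "ok" && !is.na(grads[1]) && grads[1] < -grad_zero) {
    points[[length(points) + 1]] <- .classify_point(
      pp, 0, convergence_stable = TRUE, betas, envs, h,
      neutral_tol, curvature_tol, init = envs[[1]]$n,
      max_steps = max_steps, tol_state = tol_state, tol_lambda = tol_lambda)
  }
  if (status[nb] == "ok" && !is.na(grads[nb]) && grads[nb] > grad_zero) {
    points[[length(points) + 1]] <- .classify_point(
      pp, 1, convergence_stable = TRUE, betas, envs, h,
      neutral_tol, curvature_tol, init = envs[[nb]]$n,
      max_steps = max_steps, tol_state = tol_state, tol_lambda = tol_lambda)
  }

  if (length(points) > 0) {
    df <- do.call(rbind, lapply(points, function(s)
      data.frame(beta = s$beta, kind = s$kind,
                 convergence_stable = s$convergence_stable,
                 invadable = s$invadable,
                 can_invade_when_rare = s$can_invade_when_rare,
                 curvature = s$curvature)))
    df <- df[order(df$beta), , drop = FALSE]
    rownames(df) <- NULL
    out$attractors <- df[df$kind != "repeller", , drop = FALSE]
    out$repellers <- df[df$kind == "repeller", , drop = FALSE]
    out$beta_ess_values <- sort(out$attractors$beta)
    out$bistable <- nrow(out$attractors) >= 2
  }
  out
}

.empty_singular_df <- function() {
  data.frame(beta = numeric(0), kind = character(0),
             convergence_stable = logical(0), invadable = logical(0),
             can_invade_when_rare = logical(0), curvature = numeric(0))
}

#' @export
print.evolutionary_outcome <- function(x, ...) {
  cat("Evolutionary outcome (fighter fraction beta)\n")
  if (!x$viable) {
    cat("  no persisting resident anywhere on [0, 1]\n")
    return(invisible(x))
  }
  if (nrow(x$attractors) == 0) {
    cat("  no attractor located\n")
  } else {
    for (i in seq_len(nrow(x$attractors)))
      cat(sprintf("  attractor: beta* = %.4f  (%s)\n",
                  x$attractors$beta[i], x$attractors$kind[i]))
  }
  if (nrow(x$repellers) > 0)
    for (i in seq_len(nrow(x$repellers)))
      cat(sprintf("  repeller:  beta  = %.4f\n", x$repellers$beta[i]))
  cat("  bistable:", x$bistable, "\n")
  invisible(x)
}
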
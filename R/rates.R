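# Internal computational core.
#
# All demographic rates are evaluated here once, in one place; the exported
# model functions and the equilibration loop both go through .rates_at() /
# .matrix_at() so there is a single source of truth for the formulas.

# Precompute the state-independent pieces of the model for a parameter set.
# Returns a plain list ("pp") used by all internal hot paths.
.precompute <- function(params) {
  gx <- params$sigma_zz / params$t_x
  gf <- params$sigma_zz / params$t_f
  gs <- params$sigma_zz / params$t_s
  list(
    e0 = params$e0, rho = params$rho, beta = params$beta,
    gx = gx, gf = gf, gs = gs,
    szz = params$sigma_zz, sxx = params$sigma_xx,
    sff = params$sigma_ff, sss = params$sigma_ss,
    cm = params$c_m, k0 = params$k0,
    mff = (params$V - params$C) / 2,
    mfs = params$V - params$eps,
    msf = params$eps,
    mss = params$V / 2,
    uz = params$u_z, ux = params$u_x, uf = params$u_f, us = params$u_s,
    per_male = identical(params$fertility, "per_male"),
    all_stages = identical(params$encounter_denominator, "all_stages")
  )
}

# Zygote stasis P_z for an arbitrary trait value.
.pz <- function(pp, beta) {
  pp$szz * (1 - ((1 - pp$rho) * pp$gx +
                   beta * pp$rho * pp$gf +
                   (1 - beta) * pp$rho * pp$gs))
}

# State-dependent demographic rates at population state n = (z, x, f, s).
# Returns numeric vector:
#   Fx, Ff, Fs, Qz, Qx, Qf, Qs, pf, ps, k, clamped(p), clamped(Q)
# Degenerate states follow the model contracts: fertilities are 0 when there
# are no females or no males; killed proportions are 0 when there are no
# fighters or the population is empty.
.rates_at <- function(pp, n) {
  nz <- n[[1]]; nx <- n[[2]]; nf <- n[[3]]; ns <- n[[4]]
  tot <- nz + nx + nf + ns
  den <- if (pp$all_stages) tot else nx + nf + ns
  nm <- nf + ns
  fx <- ff <- fs <- 0
  pf <- ps <- NA_real_
  k <- pp$k0 / (1 + nx)
  pclamp <- FALSE
  if (nm > 0 && nx > 0 && den > 0) {
    phi <- nf / nm
    pf <- 1 - pp$cm + pp$cm * (phi * pp$mff + (1 - phi) * pp$mfs)
    ps <- 1 - pp$cm + pp$cm * (phi * pp$msf + (1 - phi) * pp$mss)
    if (pf < 0 || pf > 1 || ps < 0 || ps > 1) {
      pclamp <- TRUE
      pf <- min(max(pf, 0), 1)
      ps <- min(max(ps, 0), 1)
    }
    base <- k * pp$e0 * nx / (2 * den)
    if (pp$per_male) {
      # births per male of morph j: B_{x,j} / (2 n_j), finite as n_j -> 0
      ff <- base * pf
      fs <- base * ps
      fx <- k * pp$e0 * (nf * pf + ns * ps) / (2 * den)
    } else {
      # typeset convention: B_{x,j} / (2 n_x)
      ff <- k * pp$e0 * nf * pf / (2 * den)
      fs <- k * pp$e0 * ns * ps / (2 * den)
      fx <- ff + fs
    }
  }
  qz <- qx <- qf <- qs <- 0
  qclamp <- FALSE
  if (nf > 0 && den > 0) {
    press <- pp$e0 * nf / den
    qz <- pp$uz * press; qx <- pp$ux * press
    qf <- pp$uf * press; qs <- pp$us * press
    if (max(qz, qx, qf, qs) > 1) {
      qclamp <- TRUE
      qz <- min(qz, 1); qx <- min(qx, 1); qf <- min(qf, 1); qs <- min(qs, 1)
    }
  }
  c(fx, ff, fs, qz, qx, qf, qs, pf, ps, k,
    as.numeric(pclamp), as.numeric(qclamp))
}

# Projection matrix for trait value `beta` from precomputed params and the
# rate vector of the (resident) state. With beta = resident beta this is the
# resident matrix N; with another beta it is the mutant matrix N' (all
# densities, fertilities and killed proportions frozen at the resident state).
.matrix_at <- function(pp, r, beta = pp$beta) {
  pzb <- .pz(pp, beta)
  matrix(c(
    (1 - r[4]) * pzb,        r[1],                 r[2],              r[3],
    (1 - pp$rho) * pp$gx,    (1 - r[5]) * pp$sxx,  0,                 0,
    pp$rho * beta * pp$gf,   0,                    (1 - r[6]) * pp$sff, 0,
    pp$rho * (1 - beta) * pp$gs, 0,                0,                 (1 - r[7]) * pp$sss
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("z", "x", "f", "s"), c("z", "x", "f", "s")))
}

# One application of the nonlinear map n_{t+1} = N(n_t) n_t, written out as
# scalar updates (the hot path of equilibration).
.step_once <- function(pp, n, r) {
  beta <- pp$beta
  c((1 - r[[4]]) * .pz(pp, beta) * n[[1]] + r[[1]] * n[[2]] +
      r[[2]] * n[[3]] + r[[3]] * n[[4]],
    (1 - pp$rho) * pp$gx * n[[1]] + (1 - r[[5]]) * pp$sxx * n[[2]],
    pp$rho * beta * pp$gf * n[[1]] + (1 - r[[6]]) * pp$sff * n[[3]],
    pp$rho * (1 - beta) * pp$gs * n[[1]] + (1 - r[[7]]) * pp$sss * n[[4]])
}

# Iterate the map to a fixed point. Early exit once the relative state change
# drops below tol_state; optional extension beyond max_steps for slow
# transients (bifurcation neighbourhoods). Returns the final state plus
# bookkeeping; does not store the trajectory (see run_to_equilibrium for the
# user-facing version that can).
.equilibrate <- function(pp, init, max_steps = 1000L, tol_state = 1e-8,
                         extend = TRUE, extinct_tol = 1e-12) {
  n <- init
  relchg <- Inf
  limit <- as.integer(max_steps)
  hard_limit <- if (extend) 10L * limit else limit
  step <- 0L
  clamped <- FALSE
  while (step < hard_limit) {
    step <- step + 1L
    r <- .rates_at(pp, n)
    if (r[11] > 0 || r[12] > 0) clamped <- TRUE
    n2 <- .step_once(pp, n, r)
    if (any(!is.finite(n2)))
      stop_numerical(sprintf("non-finite densities at step %d", step))
    s1 <- sum(n)
    relchg <- if (s1 > 0) sum(abs(n2 - n)) / s1 else 0
    n <- n2
    if (relchg < tol_state) break
  }
  extinct <- sum(n) < extinct_tol
  list(n = n, steps = step, relchg = relchg,
       state_converged = relchg < tol_state || extinct,
       extended = step > limit, extinct = extinct, clamped = clamped)
}

# Dominant eigenvalue (internal, value only) of a 4x4 matrix.
.dom_eig <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  Re(ev[which.max(Mod(ev))])
}

# Resident environment: equilibrate a resident with trait beta and return
# everything invasion analysis needs. `init` supports warm starts.
.resident_env <- function(pp, beta, init = c(10, 10, 10, 10),
                          max_steps = 1000L, tol_state = 1e-10,
                          tol_lambda = 1e-6, extend = TRUE) {
  pp$beta <- beta
  eq <- .equilibrate(pp, init, max_steps = max_steps, tol_state = tol_state,
                     extend = extend)
  r <- .rates_at(pp, eq$n)
  lam <- .dom_eig(.matrix_at(pp, r, beta))
  viable <- !eq$extinct && eq$state_converged && abs(lam - 1) <= tol_lambda
  list(pp = pp, beta = beta, n = eq$n, rates = r, lambda = lam,
       converged = eq$state_converged && abs(lam - 1) <= tol_lambda,
       extinct = eq$extinct, viable = viable, steps = eq$steps,
       clamped = eq$clamped)
}

# Invasion fitness of a mutant trait against a frozen resident environment.
.W <- function(env, beta_mutant) {
  .dom_eig(.matrix_at(env$pp, env$rates, beta_mutant))
}

# Selection gradient at the resident trait from a frozen resident
# environment: central finite difference, one-sided at the trait boundaries.
.gradient <- function(env, h = 0.01) {
  b <- env$beta
  lo <- max(b - h, 0)
  hi <- min(b + h, 1)
  (.W(env, hi) - .W(env, lo)) / (hi - lo)
}
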
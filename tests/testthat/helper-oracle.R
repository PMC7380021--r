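# Independent, naively-coded oracle for the demographic model.
#
# Everything here is written directly from the scalar rate definitions,
# step by step, deliberately not sharing code or algebraic simplifications
# with the package internals: births are computed as B = k * e * p and then
# divided; killed proportions as Q = q / n with q = e_{i,f} * u; the
# dominant eigenvalue comes from the characteristic polynomial
# (Faddeev-LeVerrier coefficients + polyroot), not from eigen().

oracle_rates <- function(p, n) {
  nz <- n[1]; nx <- n[2]; nf <- n[3]; ns <- n[4]
  D <- if (identical(p$encounter_denominator, "adults_only"))
    nx + nf + ns else nz + nx + nf + ns
  enc <- function(ni, nj) if (D > 0) p$e0 * ni * nj / D else 0

  G_x <- p$sigma_zz / p$t_x
  G_f <- p$sigma_zz / p$t_f
  G_s <- p$sigma_zz / p$t_s

  m_ff <- (p$V - p$C) / 2; m_fs <- p$V - p$eps
  m_sf <- p$eps;           m_ss <- p$V / 2

  F_x <- F_f <- F_s <- 0
  if (nx > 0 && nf + ns > 0 && D > 0) {
    w_f <- nf / (nf + ns); w_s <- ns / (nf + ns)
    p_f <- 1 - p$c_m + p$c_m * (w_f * m_ff + w_s * m_fs)
    p_s <- 1 - p$c_m + p$c_m * (w_f * m_sf + w_s * m_ss)
    p_f <- min(max(p_f, 0), 1); p_s <- min(max(p_s, 0), 1)
    k <- p$k0 / (1 + nx)
    B_f <- k * enc(nx, nf) * p_f
    B_s <- k * enc(nx, ns) * p_s
    F_x <- (B_f + B_s) / (2 * nx)
    if (identical(p$fertility, "per_male")) {
      F_f <- if (nf > 0) B_f / (2 * nf) else k * enc(nx, 1) * p_f / 2
      F_s <- if (ns > 0) B_s / (2 * ns) else k * enc(nx, 1) * p_s / 2
    } else {
      F_f <- B_f / (2 * nx)
      F_s <- B_s / (2 * nx)
    }
  }

  Qs <- c(0, 0, 0, 0)
  u <- c(p$u_z, p$u_x, p$u_f, p$u_s)
  for (i in 1:4) {
    q_i <- enc(n[i], nf) * u[i]          # killed per day
    Qs[i] <- if (n[i] > 0) q_i / n[i] else 0
    Qs[i] <- min(max(Qs[i], 0), 1)
  }
  list(G = c(G_x, G_f, G_s), F = c(F_x, F_f, F_s), Q = Qs)
}

oracle_matrix <- function(p, n, beta = p$beta) {
  r <- oracle_rates(p, n)
  G_x <- r$G[1]; G_f <- r$G[2]; G_s <- r$G[3]
  P_z <- p$sigma_zz *
    (1 - ((1 - p$rho) * G_x + beta * p$rho * G_f + p$rho * (1 - beta) * G_s))
  rbind(
    c((1 - r$Q[1]) * P_z,        r$F[1],                    r$F[2],                    r$F[3]),
    c((1 - p$rho) * G_x,         (1 - r$Q[2]) * p$sigma_xx, 0,                         0),
    c(p$rho * beta * G_f,        0,                         (1 - r$Q[3]) * p$sigma_ff, 0),
    c(p$rho * (1 - beta) * G_s,  0,                         0,                         (1 - r$Q[4]) * p$sigma_ss))
}

# dominant eigenvalue via the characteristic polynomial:
# coefficients from the Faddeev-LeVerrier recursion, roots from polyroot()
oracle_dominant_eig <- function(M) {
  stopifnot(nrow(M) == 4, ncol(M) == 4)
  I4 <- diag(4)
  c1 <- sum(diag(M))
  M2 <- M %*% (M - c1 * I4)
  c2 <- -sum(diag(M2)) / 2
  M3 <- M %*% (M2 + c2 * I4)
  c3 <- -sum(diag(M3)) / 3
  M4 <- M %*% (M3 + c3 * I4)
  c4 <- -sum(diag(M4)) / 4
  # lambda^4 - c1 lambda^3 + c2 lambda^2 + c3 lambda + c4 (signs per recursion)
  roots <- polyroot(c(c4, c3, c2, -c1, 1))
  lam <- roots[which.max(Mod(roots))]
  stopifnot(abs(Im(lam)) < 1e-8 * max(1, Mod(lam)))
  Re(lam)
}

# naive one-step map, for trajectory cross-checks
oracle_step <- function(p, n) {
  as.vector(oracle_matrix(p, n) %*% n)
}

# random in-range parameter draw (survivals kept in their swept sub-ranges so
# that eps < V always holds and populations are usually viable)
draw_params <- function() {
  demographic_params(
    beta = runif(1),
    c_m = runif(1),
    C = runif(1, 0.5, 1),
    V = runif(1, 0.5, 1),
    eps = runif(1, 0, 0.4),
    sigma_ff = runif(1, 0.9, 1),
    sigma_ss = runif(1, 0.9, 1),
    u_z = runif(1), u_x = runif(1), u_f = runif(1), u_s = runif(1))
}

draw_state <- function(strictly_positive = TRUE) {
  n <- runif(4, if (strictly_positive) 0.5 else 0, 100)
  stage_densities(n[1], n[2], n[3], n[4])
}
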
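p_def <- demographic_params()

test_that("maturation rates follow G_i = sigma_zz / t_i", {
  expect_equal(maturation_rate(p_def, "x"), 1 / 13.7)
  expect_equal(maturation_rate(p_def, "f"), 1 / 14.4)
  expect_equal(maturation_rate(p_def, "s"), 1 / 12.6)
  expect_equal(maturation_rate(demographic_params(t_f = 1), "f"), 1)
})

test_that("zygote stasis balances survival against maturation outflow", {
  expect_equal(zygote_stasis(p_def, beta = 0.5), 0.926301268682656,
               tolerance = 1e-12)
  expect_equal(zygote_stasis(demographic_params(sigma_zz = 0)), 0)
  expect_equal(zygote_stasis(demographic_params(rho = 1), beta = 1),
               1 - 1 / 14.4, tolerance = 1e-12)
  # P_z bounded by sigma_zz for any beta
  for (b in c(0, 0.3, 1)) {
    pz <- zygote_stasis(p_def, beta = b)
    expect_gte(pz, 0)
    expect_lte(pz, p_def$sigma_zz)
  }
})

test_that("hawk-dove payoff matrix has the game-theoretic entries", {
  m <- payoff_matrix(p_def)
  expect_equal(unclass(m)[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))],
               c(0.15, 0.8, 0.2, 0.5))
  expect_equal(payoff_matrix(demographic_params(V = 0.7, C = 0.7))["f", "f"], 0)
  # negative hawk-hawk payoff at range extremes is allowed, not clamped
  m2 <- payoff_matrix(demographic_params(V = 0.5, C = 1, eps = 0))
  expect_equal(unclass(m2)[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))],
               c(-0.25, 0.5, 0, 0.25))
})

test_that("mating probability mixes payoffs by male morph frequencies", {
  st <- stage_densities(0, 50, 25, 25)
  expect_equal(mating_probability(demographic_params(c_m = 0), st, "f"), 1)
  expect_equal(mating_probability(p_def, st, "f"), 0.5275)
  expect_equal(mating_probability(p_def, st, "s"), 0.415)
  expect_equal(mating_probability(p_def, stage_densities(0, 50, 25, 0), "f"),
               0.235)
  expect_error(mating_probability(p_def, stage_densities(10, 10, 0, 0), "f"),
               class = "artevol_degenerate_state")
  # clamped (and warned) when the hawk-hawk payoff drags p below zero
  p_neg <- demographic_params(V = 0.5, C = 1, eps = 0, c_m = 1)
  expect_warning(
    pf <- mating_probability(p_neg, stage_densities(0, 10, 100, 1e-9), "f"),
    "clamped")
  expect_gte(pf, 0)
})

test_that("mating probability of fighters falls with the fighter share", {
  # m_ff < m_fs under the defaults, so more fighters mean harder contests
  phis <- seq(0.05, 0.95, by = 0.1)
  pf <- vapply(phis, function(phi)
    mating_probability(p_def, stage_densities(0, 50, 100 * phi,
                                              100 * (1 - phi)), "f"),
    numeric(1))
  expect_true(all(diff(pf) < 0))
})

test_that("encounter rates are mass-action with the configured denominator", {
  st <- stage_densities(100, 50, 25, 25)
  expect_equal(encounter_rate(p_def, st, "f", "f"), 3.125)
  expect_equal(encounter_rate(p_def, st, "x", "f"),
               encounter_rate(p_def, st, "f", "x"))
  expect_equal(encounter_rate(p_def, stage_densities(0, 10, 10, 0), "x", "f"), 5)
  expect_equal(encounter_rate(p_def, stage_densities(50, 10, 0, 10), "x", "f"), 0)
  p_ad <- demographic_params(encounter_denominator = "adults_only")
  expect_equal(encounter_rate(p_ad, st, "f", "f"), 625 / 100)
  expect_error(encounter_rate(p_def, stage_densities(0, 0, 0, 0), "x", "f"),
               class = "artevol_degenerate_state")
})

test_that("clutch size declines with female density", {
  expect_equal(clutch_size(p_def, stage_densities(0, 0, 1, 1)), 26.1)
  expect_equal(clutch_size(p_def, stage_densities(0, 50, 1, 1)), 26.1 / 51)
  expect_equal(clutch_size(p_def, stage_densities(0, 25.1, 1, 1)), 1)
})

test_that("fertilities follow the per-male bookkeeping by default", {
  st <- stage_densities(0, 50, 25, 25)
  f <- fertilities(p_def, st)
  expect_equal(unname(f), c(0.0602922794117647, 0.0674889705882353,
                            0.0530955882352941), tolerance = 1e-12)
  # fathers' birth total equals the mothers' under per-male bookkeeping
  expect_equal(f[["F_x"]] * 50, f[["F_f"]] * 25 + f[["F_s"]] * 25)
  # typeset per-female convention divides male births by 2 n_x instead
  p_pf <- demographic_params(fertility = "per_female")
  f2 <- fertilities(p_pf, st)
  expect_equal(unname(f2), c(0.0602922794117647, 0.0337444852941176,
                             0.0265477941176471), tolerance = 1e-12)
  # degenerate states: no females or no males -> all zero
  expect_equal(unname(fertilities(p_def, stage_densities(10, 0, 25, 25))),
               c(0, 0, 0))
  expect_equal(unname(fertilities(p_def, stage_densities(10, 50, 0, 0))),
               c(0, 0, 0))
})

test_that("killed proportions share the fighter-pressure factor", {
  st <- stage_densities(100, 50, 25, 25)
  expect_equal(unname(killed_proportions(p_def, st)), c(0, 0, 0, 0))
  q <- killed_proportions(demographic_params(u_f = 0.5), st)
  expect_equal(q[["Q_f"]], 0.0625)
  expect_equal(unname(killed_proportions(
    demographic_params(u_z = 1, u_x = 1, u_f = 1, u_s = 1),
    stage_densities(100, 50, 0, 50))), c(0, 0, 0, 0))
  # cancellation identity: Q_i / u_i is the same for every stage
  pu <- demographic_params(u_z = 0.2, u_x = 0.4, u_f = 0.6, u_s = 0.8)
  q2 <- killed_proportions(pu, st)
  ratios <- unname(q2) / c(0.2, 0.4, 0.6, 0.8)
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-15)
  # clamp (with warning) only reachable for e0 > 1
  expect_warning(
    q3 <- killed_proportions(demographic_params(e0 = 10, u_s = 1),
                             stage_densities(0, 1, 50, 1)),
    "clamped")
  expect_lte(max(q3), 1)
})

test_that("projection matrix has the model sparsity pattern and entries", {
  st <- stage_densities(0, 50, 25, 25)
  N <- projection_matrix(p_def, st, beta = 0.5)
  expect_equal(N["f", "z"], 0.25 / 14.4, tolerance = 1e-12)
  expect_equal(N["f", "f"], 0.95)
  zero_idx <- rbind(c(2, 3), c(2, 4), c(3, 2), c(3, 4), c(4, 2), c(4, 3))
  expect_equal(unname(unclass(N)[zero_idx]), rep(0, 6))
  # morph-exclusion limits
  expect_equal(projection_matrix(p_def, st, beta = 0)["f", "z"], 0)
  expect_equal(projection_matrix(p_def, st, beta = 1)["s", "z"], 0)
})

test_that("matrix assembly agrees with the naive scalar oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- draw_params()
    n <- draw_state()
    M <- projection_matrix(p, n)
    O <- oracle_matrix(p, n)
    expect_equal(unclass(M), O, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("with no killing the matrix reduces to the baseline model", {
  set.seed(7)
  for (i in 1:20) {
    p <- draw_params()
    p <- modify_params(p, u_z = 0, u_x = 0, u_f = 0, u_s = 0)
    n <- draw_state()
    N <- projection_matrix(p, n)
    # baseline matrix: same entries with survival undiscounted
    expect_equal(N["x", "x"], p$sigma_xx)
    expect_equal(N["f", "f"], p$sigma_ff)
    expect_equal(N["s", "s"], p$sigma_ss)
    expect_equal(N["z", "z"], zygote_stasis(p), tolerance = 1e-12)
  }
})

test_that("matrix entries stay in their demographic bounds (e0 = 1)", {
  set.seed(11)
  for (i in 1:50) {
    p <- draw_params()
    n <- draw_state()
    N <- unclass(projection_matrix(p, n))
    expect_true(all(N[1, ] >= 0))
    expect_true(all(N[2:4, ] >= 0 & N[2:4, ] <= 1))
  }
})
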
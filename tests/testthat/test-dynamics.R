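p_def <- demographic_params(beta = 0.5)

test_that("one step of the map matches a hand-built matrix-vector product", {
  st <- stage_densities(0, 50, 25, 25)
  nxt <- step_population(p_def, st)
  # zygote production: F_x n_x + F_f n_f + F_s n_s (frozen expected value)
  expect_equal(nxt[["z"]], 6.02922794117647, tolerance = 1e-12)
  expect_equal(nxt[["x"]], 0.95 * 50)
  expect_equal(nxt[["f"]], 0.95 * 25)
  expect_equal(nxt[["s"]], 0.96 * 25)
  # extinction is absorbing
  expect_equal(sum(step_population(p_def, stage_densities(0, 0, 0, 0))), 0)
  # killing terms are inert without fighters
  st0 <- stage_densities(10, 10, 0, 10)
  expect_equal(step_population(demographic_params(u_x = 1), st0),
               step_population(p_def, st0))
})

test_that("stepping agrees with the oracle map on random draws", {
  set.seed(3)
  for (i in 1:30) {
    p <- draw_params()
    n <- draw_state()
    expect_equal(unname(unclass(step_population(p, n))), oracle_step(p, n),
                 tolerance = 1e-12)
  }
})

test_that("non-negativity is preserved by the map", {
  set.seed(5)
  for (i in 1:50) {
    p <- draw_params()
    n <- draw_state(strictly_positive = FALSE)
    expect_true(all(step_population(p, n) >= 0))
  }
})

test_that("equilibration reaches a fixed point with unit growth rate", {
  tr <- run_to_equilibrium(p_def, max_steps = 1000)
  expect_true(tr$converged)
  expect_false(tr$extinct)
  expect_lt(abs(tr$lambda - 1), 1e-6)
  # the equilibrium is a fixed point of the map
  expect_equal(unclass(step_population(p_def, tr$equilibrium)),
               unclass(tr$equilibrium), tolerance = 1e-6)
})

test_that("equilibrium is independent of the (positive) starting point", {
  set.seed(9)
  base <- run_to_equilibrium(p_def, tol_state = 1e-10)$equilibrium
  for (i in 1:10) {
    init <- stage_densities(runif(1, 0.1, 500), runif(1, 0.1, 500),
                            runif(1, 0.1, 500), runif(1, 0.1, 500))
    eq <- run_to_equilibrium(p_def, initial = init,
                             tol_state = 1e-10)$equilibrium
    expect_equal(unclass(eq), unclass(base), tolerance = 1e-6)
  }
})

test_that("degenerate and truncated runs are flagged, not raised", {
  tr0 <- run_to_equilibrium(p_def, initial = stage_densities(0, 0, 0, 0))
  expect_true(tr0$converged)
  expect_true(tr0$extinct)
  tr1 <- run_to_equilibrium(p_def, initial = stage_densities(1000, 1, 1, 1),
                            max_steps = 1, extend = FALSE)
  expect_false(tr1$converged)
})

test_that("trajectory storage matches the non-storing path", {
  tr <- run_to_equilibrium(p_def, keep_trajectory = TRUE, tol_state = 1e-9)
  expect_equal(nrow(tr$states), tr$steps_used + 1)
  expect_equal(unname(tr$states[nrow(tr$states), ]),
               unname(unclass(tr$equilibrium)))
  tr2 <- run_to_equilibrium(p_def, keep_trajectory = FALSE, tol_state = 1e-9)
  expect_equal(unclass(tr$equilibrium), unclass(tr2$equilibrium),
               tolerance = 1e-14)
})

test_that("dominant eigenvalue matches the characteristic-polynomial oracle", {
  expect_equal(dominant_eigenvalue(diag(4))$value, 1)
  expect_equal(dominant_eigenvalue(diag(c(0.9, 0.5, 0.2, 0.1)))$value, 0.9)
  set.seed(13)
  for (i in 1:30) {
    p <- draw_params()
    n <- draw_state()
    M <- projection_matrix(p, n)
    d <- dominant_eigenvalue(M)
    expect_equal(d$value, oracle_dominant_eig(unclass(M)), tolerance = 1e-10)
    expect_equal(sum(d$vector), 1, tolerance = 1e-12)
  }
})

test_that("a rotation's complex spectrum is refused", {
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(0, -1, 1, 0), 2)  # 90-degree rotation block
  R[3, 3] <- R[4, 4] <- 0.1
  expect_error(dominant_eigenvalue(R), class = "artevol_numerical_failure")
})
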
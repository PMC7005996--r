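test_that("stationary distributions are normalized, nonnegative, and low-residual", {
  set.seed(11)
  for (rep in 1:6) {
    m <- flex_model(sample(0:15, 1), random_fast_params(), M = sample(5:9, 1))
    K <- build_rate_matrix(m)
    sol <- solve_stationary(K)
    expect_true(all(sol$pi >= 0))
    expect_equal(sum(sol$pi), 1, tolerance = 1e-10)
    expect_lte(sol$residual_rel, 1e-8)
  }
})

test_that("a constitutive gene has a truncated-Poisson marginal", {
  M <- 21
  m <- flex_model(15, kinetic_params(g_hi = 1.0, k = 0.2,
                                     h_a = 1, f_a = 1, h_r = 1, f_r = 1), M = M)
  land <- compute_landscape(m)
  expect_lt(tv_dist(rowSums(land$grid), truncated_poisson(5, M)), 1e-6)
  expect_lt(tv_dist(colSums(land$grid), truncated_poisson(5, M)), 1e-6)
})

test_that("slow-regime MISA marginals match the promoter-chain Poisson mixture", {
  M <- 21
  for (p in list(kinetic_params(h_a = 1e-4, f_a = 1e-3, h_r = 1e-4, f_r = 1e-3),
                 kinetic_params(h_a = 5e-3, f_a = 5e-3, h_r = 1e-3, f_r = 1e-2))) {
    land <- compute_landscape(misa_model(p, M))
    expect_lt(tv_dist(rowSums(land$grid), misa_slow_mixture_marginal(p, M)), 1e-3)
  }
})

test_that("promoter marginalization conserves mass and symmetry", {
  m <- misa_model(kinetic_params(h_a = 30, f_a = 100, h_r = 30, f_r = 100), M = 9)
  sol <- solve_stationary(build_rate_matrix(m))
  land <- marginalize_promoters(sol)
  expect_equal(sum(land$grid), sum(sol$pi))
  expect_equal(sum(land$grid), 1, tolerance = 1e-12)
  # symmetric parameters: landscape equals its transpose
  expect_lt(max(abs(land$grid - t(land$grid))), 1e-8)
  # M = 1: the single (0, 0) cell carries all mass
  m1 <- misa_model(kinetic_params(g_hi = 0.01, h_a = 1, f_a = 1, h_r = 1, f_r = 1), M = 1)
  land1 <- marginalize_promoters(solve_stationary(build_rate_matrix(m1)))
  expect_equal(land1$grid, matrix(1, 1, 1))
})

test_that("the quasipotential transform floors, flips tags, and round-trips", {
  M <- 4
  grid <- matrix(0, M, M)
  grid[1, 1] <- 1
  land <- coexpression_landscape(grid, "probability", "model")
  phi <- quasipotential(land, floor = 1e-6)
  expect_equal(phi$representation, "quasipotential")
  expect_equal(phi$grid[1, 1], 0)
  expect_equal(phi$grid[2, 2], -log(1e-6), tolerance = 1e-12)
  # uniform landscape: constant phi = ln(M^2)
  unif <- coexpression_landscape(matrix(1 / M^2, M, M), "probability", "model")
  expect_equal(quasipotential(unif)$grid, matrix(log(M^2), M, M))
  # exp(-phi) restores pi wherever pi >= floor
  m <- misa_model(kinetic_params(h_a = 30, f_a = 100, h_r = 30, f_r = 100), M = 9)
  pl <- compute_landscape(m)
  ql <- quasipotential(pl, floor = 1e-6)
  ok <- pl$grid >= 1e-6
  expect_equal(exp(-ql$grid)[ok], pl$grid[ok], tolerance = 1e-12)
  # quasipotential of a quasipotential is an error
  expect_error(quasipotential(ql), class = "coexland_error_representation")
  expect_error(quasipotential(pl, floor = 0), class = "coexland_error_args")
})

test_that("increasing the copy-number cap leaves metrics nearly unchanged", {
  p <- kinetic_params(h_a = 100, f_a = 1000, h_r = 100, f_r = 1000)
  m21 <- landscape_metrics(compute_landscape(misa_model(p, M = 21)))
  m36 <- landscape_metrics(compute_landscape(misa_model(p, M = 36)))
  for (col in names(m21)) {
    expect_lt(abs(m36[[col]] - m21[[col]]) / max(abs(m21[[col]]), 1e-12), 0.01)
  }
  expect_lt(boundary_mass(compute_landscape(misa_model(p, M = 21))), 1e-4)
})

test_that("stochastic simulation is reproducible and converges to the exact solution", {
  m <- misa_model(kinetic_params(h_a = 10, f_a = 20, h_r = 10, f_r = 20), M = 8)
  occ1 <- ssa_simulate(m, t_end = 3000, seed = 7)
  occ2 <- ssa_simulate(m, t_end = 3000, seed = 7)
  expect_identical(occ1, occ2)
  expect_equal(sum(occ1), 1, tolerance = 1e-12)
  # t_end = 0: all occupancy on the initial state
  occ0 <- ssa_simulate(m, t_end = 0, seed = 1, init = c(2, 3, 1, 0))
  ss <- enumerate_state_space(8)
  expect_equal(occ0[state_to_index(ss, 2, 3, 1, 0)], 1)
  expect_equal(sum(occ0), 1)
  # occupancy approaches the eigensolution as the horizon grows
  ex <- solve_stationary(build_rate_matrix(m))$pi
  tv_short <- tv_dist(ssa_simulate(m, t_end = 150, seed = 3), ex)
  tv_long <- tv_dist(ssa_simulate(m, t_end = 6000, seed = 3), ex)
  expect_lt(tv_long, tv_short)
  expect_lt(tv_long, 0.02)
})

test_that("a reducible chain is reported as a solver error", {
  # two disconnected copies of the same birth-death chain: rank
  # deficiency beyond 1 cannot yield a unique stationary law
  A <- matrix(0, 4, 4)
  A[2, 1] <- 1; A[1, 2] <- 1; A[4, 3] <- 1; A[3, 4] <- 1
  diag(A) <- -colSums(A)
  K <- methods::as(A, "CsparseMatrix")
  expect_error(solve_stationary(K, M = 1, anchor = 1), class = "coexland_error_solver")
})
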
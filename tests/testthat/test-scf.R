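test_that("solvent-only system is exactly homogeneous and neutral", {
  lat <- make_lattice("spherical", 25)
  st <- solve_quiet(system_spec(NULL, lat, 0))
  expect_true(st$converged)
  expect_equal(rowSums(st$phi), rep(1, 25), tolerance = 1e-12)
  expect_equal(st$psi, numeric(25))
  expect_equal(st$phi[, "Na"], rep(0.01, 25))
  expect_equal(grand_potential(st), 0, tolerance = 1e-8)
})

test_that("athermal chain solution stays an ideal uniform mixture", {
  # neutral homopolymer, all chi = 0: uniform profile with phi = theta/V
  chi0 <- default_interactions(); chi0$chi[, ] <- 0
  lat <- make_lattice("spherical", 20)
  mol <- linear_chain(rep("NH", 8))
  V <- sum(lat$L)
  sp <- system_spec(mol, lat, theta_surf = 0.02 * V, table = chi0,
                    solvent_size = 1)
  st <- solve_quiet(sp, nucleate = FALSE)
  expect_true(st$converged)
  expect_equal(st$phi[, "NH"], rep(0.02, 20), tolerance = 1e-6)
  expect_equal(aggregation_number(st), 0, tolerance = 1e-4)
  expect_equal(grand_potential(st), 0, tolerance = 1e-6)
})

test_that("double layer matches linearised Debye-Hueckel at low potential", {
  # weakly charged plane in dilute salt; the spec tolerance (2%) is only
  # attainable in the weak-screening limit where the lattice dispersion
  # correction is negligible, hence phi_salt = 1e-3 here
  phis <- 1e-3
  lat <- make_lattice("planar", 80)
  fc <- numeric(80); fc[1] <- 5e-4
  sp <- system_spec(NULL, lat, 0, phi_salt_b = phis, fixed_charge = fc)
  st <- solve_quiet(sp)
  expect_true(st$converged)
  expect_true(max(abs(st$psi)) < 0.2)
  conv <- unit_conversions()
  c0 <- dendromicelle:::electrostatic_prefactor(conv)
  eps_b <- drop(st$phi[60, ] %*% segment_kinds()$eps_r)
  kappa <- sqrt(c0 * 2 * phis / eps_b)
  # continuum DH decay rate, fitted over a window where psi is small
  fit <- -diff(log(st$psi[10:30]))
  expect_lt(max(abs(fit / kappa - 1)), 0.02)
  # surface potential against the linearised *discrete* closed form:
  # psi0 = c0 sigma / (eps (1 - x) + eps kappa^2), x = exp(-kappa_d),
  # with 2(cosh kappa_d - 1) = kappa^2 the lattice dispersion relation
  kappa_d <- acosh(1 + kappa^2 / 2)
  psi0_ref <- c0 * fc[1] / (eps_b * (1 - exp(-kappa_d)) + eps_b * kappa^2)
  expect_lt(abs(st$psi[1] / psi0_ref - 1), 0.005)
})

test_that("converged micelle states satisfy the SCF invariants", {
  lat <- make_lattice("spherical", 40)
  mol <- build_molecule(1, 2, 15)
  N <- n_segments(mol)
  sp <- system_spec(mol, lat, theta_surf = 30 * N)
  st <- solve_quiet(sp, max_iter = 8000)
  expect_true(st$converged)
  # incompressibility
  expect_lt(max(abs(rowSums(st$phi) - 1)), 1e-6)
  # positivity
  expect_true(all(st$phi >= 0 & st$phi <= 1))
  # global electroneutrality
  expect_lt(abs(sum(lat$L * st$rho_e)), 1e-8 * sum(lat$L) * 1e-2)
  # bulk consistency at the outer layers
  expect_lt(max(abs(sweep(st$phi[36:40, ], 2, st$phi_b))), 1e-7)
  # partition-function composition independence
  expect_lt(st$qdev, 1e-10)
  # there is an actual aggregate
  expect_gt(aggregation_number(st), 5)
  expect_gt(st$phi[1, "C"], 0.5)
})

test_that("identical spec and init give bitwise-identical states", {
  lat <- make_lattice("spherical", 25)
  mol <- build_molecule(0, 1, 10)
  sp <- system_spec(mol, lat, theta_surf = 12 * n_segments(mol))
  st1 <- solve_quiet(sp, max_iter = 4000)
  st2 <- solve_quiet(sp, max_iter = 4000)
  expect_identical(st1$phi, st2$phi)
  expect_identical(st1$u, st2$u)
  expect_identical(st1$iterations, st2$iterations)
  # warm-started from itself: converges immediately to the same state
  st3 <- solve_quiet(sp, init = st1, max_iter = 4000)
  expect_lt(max(abs(st3$phi - st1$phi)), 1e-9)
})

test_that("infeasible amounts are rejected", {
  lat <- make_lattice("spherical", 10)
  mol <- build_molecule(0, 1, 5)
  expect_error(system_spec(mol, lat, theta_surf = sum(lat$L)), "overfilled")
  expect_error(system_spec(NULL, lat, theta_surf = 10), "molecule")
})
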
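test_that("step probabilities satisfy normalisation and flux balance", {
  for (geom in c("planar", "cylindrical", "spherical")) {
    for (M in c(3, 7, 25, 80)) {
      lat <- make_lattice(geom, M)
      expect_equal(lat$lambda_m + lat$lambda_0 + lat$lambda_p, rep(1, M))
      r <- seq_len(M - 1)
      expect_equal(lat$L[r] * lat$lambda_p[r],
                   lat$L[r + 1] * lat$lambda_m[r + 1],
                   tolerance = 1e-12)
      expect_true(all(lat$L > 0))
      expect_true(all(lat$lambda_0 >= 0))
    }
  }
  lat <- make_lattice("planar", 10)
  expect_equal(lat$L, rep(1, 10))
  expect_equal(lat$lambda_p, rep(1 / 6, 10))
  expect_equal(lat$lambda_0[2:9], rep(4 / 6, 8))
  lat <- make_lattice("spherical", 50)
  expect_equal(lat$L, (4 * pi / 3) * ((1:50)^3 - (0:49)^3))
  expect_error(make_lattice("planar", 2), "M")
})

test_that("local_average preserves constants and spreads impulses", {
  for (geom in c("planar", "cylindrical", "spherical")) {
    lat <- make_lattice(geom, 12)
    expect_equal(local_average(rep(3.7, 12), lat), rep(3.7, 12))
  }
  lat <- make_lattice("planar", 9)
  f <- numeric(9); f[5] <- 1
  out <- local_average(f, lat)
  expect_equal(out[4:6], c(1 / 6, 4 / 6, 1 / 6))
  expect_equal(sum(out), 1)
  # spherical impulse: hand-computed from the step probabilities
  lat <- make_lattice("spherical", 10)
  f <- numeric(10); f[4] <- 1
  out <- local_average(f, lat)
  expect_equal(out[3], lat$lambda_p[3] * 1)
  expect_equal(out[4], lat$lambda_0[4] * 1)
  expect_equal(out[5], lat$lambda_m[5] * 1)
  # site balance: L-weighted mass is conserved by the transfer operator
  expect_equal(sum(lat$L * out), lat$L[4], tolerance = 1e-12)
  expect_error(local_average(1:5, lat), "length")
})

test_that("poisson_solve reproduces discrete Gauss-law closed forms", {
  conv <- unit_conversions()
  lat <- make_lattice("spherical", 40)
  expect_equal(poisson_solve(numeric(40), rep(80, 40), lat), numeric(40))

  # single charged shell, uniform permittivity: constant inside, 1/r-type
  # decay outside, matching the telescoped Gauss closed form to 1e-10
  charge <- numeric(40); charge[10] <- 25 / lat$L[10]
  psi <- poisson_solve(charge, rep(80, 40), lat)
  sigma <- charge * lat$L
  psi_ref <- gauss_shell_psi(sigma, 80, lat)
  expect_lt(max(abs(psi - psi_ref)) / max(abs(psi_ref)), 1e-10)
  expect_equal(diff(psi[1:9]), rep(0, 8), tolerance = 1e-12)  # field-free core

  # net-neutral concentric shells: psi = 0 outside the outer shell
  charge2 <- numeric(40)
  charge2[8] <- 30 / lat$L[8]; charge2[20] <- -30 / lat$L[20]
  psi2 <- poisson_solve(charge2, rep(80, 40), lat)
  expect_equal(psi2[21:40], numeric(20), tolerance = 1e-12)

  expect_error(poisson_solve(charge, rep(-1, 40), lat), "positive")
})

test_that("poisson_solve is linear in the charge profile", {
  set.seed(42)
  lat <- make_lattice("spherical", 30)
  eps <- rep(40, 30)
  s1 <- rnorm(30) * 0.01
  s2 <- rnorm(30) * 0.01
  a <- 1.7; b <- -0.6
  lhs <- poisson_solve(a * s1 + b * s2, eps, lat)
  rhs <- a * poisson_solve(s1, eps, lat) + b * poisson_solve(s2, eps, lat)
  expect_lt(max(abs(lhs - rhs)), 1e-12 * max(1, max(abs(lhs))))
})

test_that("planar charged plane gives the capacitor potential profile", {
  lat <- make_lattice("planar", 60)
  conv <- unit_conversions()
  c0 <- dendromicelle:::electrostatic_prefactor(conv)
  sigma <- 1e-3
  charge <- numeric(60); charge[1] <- sigma
  psi <- poisson_solve(charge, rep(80, 60), lat)
  # between the plane and the grounded boundary the field is uniform:
  # psi linear with slope -c0*sigma/eps
  slope <- diff(psi[2:59])
  expect_equal(slope, rep(-c0 * sigma / 80, 57), tolerance = 1e-10)
  expect_equal(psi[60], 0)
})
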
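test_that("chemical potential reduces to closed-form Flory-Huggins", {
  # athermal binary polymer/solvent: compare against the hand formula
  chi0 <- default_interactions(); chi0$chi[, ] <- 0
  lat <- make_lattice("planar", 20)
  mol <- linear_chain(rep("NH", 10))
  V <- sum(lat$L)
  sp <- system_spec(mol, lat, theta_surf = 0.01 * V, table = chi0,
                    phi_salt_b = 1e-13, solvent_size = 1)
  st <- solve_quiet(sp, nucleate = FALSE)
  expect_true(st$converged)
  spt <- dendromicelle:::species_table(st)
  Ns <- vapply(spt, function(x) x$N, 0)
  phis <- vapply(spt, function(x) x$phi_b, 0)
  mu_hand <- fh_mu_hand(st$phi_surf_b, 10, spt$surf$f, st$phi_b,
                        Ns, phis, chi0$chi)
  expect_equal(chemical_potential(st), mu_hand, tolerance = 1e-12)
  # against the textbook two-component expression (salt negligible)
  phi <- st$phi_surf_b
  mu_binary <- log(phi) + 1 - phi - 10 * (1 - phi)
  expect_equal(chemical_potential(st), mu_binary, tolerance = 1e-9)

  # interacting binary, chi = 1.2, dilute: hand evaluation
  chi12 <- perturb_table(chi0, c("NH", "W"), 1.2)
  sp2 <- system_spec(mol, lat, theta_surf = 0.01 * V, table = chi12,
                     phi_salt_b = 1e-13, solvent_size = 1)
  st2 <- solve_quiet(sp2, nucleate = FALSE)
  phi2 <- st2$phi_surf_b
  mu_binary2 <- log(phi2) + 1 - phi2 - 10 * (1 - phi2) +
    1.2 * 10 * (1 - phi2)^2
  expect_equal(chemical_potential(st2), mu_binary2, tolerance = 1e-9)
  expect_error(chemical_potential(st2, "nope"), "species")
})

test_that("grand potential vanishes for homogeneous systems", {
  lat <- make_lattice("spherical", 20)
  st <- solve_quiet(system_spec(NULL, lat, 0))
  expect_equal(grand_potential(st), 0, tolerance = 1e-8)
  expect_equal(grand_potential_bookkeeping(st), 0, tolerance = 1e-6)
})

test_that("field and bookkeeping routes to Omega agree on micelles", {
  lat <- make_lattice("spherical", 35)
  mol <- build_molecule(1, 2, 15)
  N <- n_segments(mol)
  for (nag in c(15, 30)) {
    st <- solve_quiet(system_spec(mol, lat, nag * N), max_iter = 8000)
    expect_true(st$converged)
    expect_lt(abs(grand_potential(st) - grand_potential_bookkeeping(st)),
              1e-3)
  }
})

test_that("small-systems identity dOmega/dmu = -n_agg holds on a branch", {
  # fully thermodynamic cross-check of Omega, mu and n_agg against each
  # other: along the micellar branch the excess grand potential obeys
  # dOmega = -n_agg dmu
  lat <- make_lattice("spherical", 35)
  mol <- build_molecule(1, 2, 15)
  N <- n_segments(mol)
  init <- NULL; out <- NULL
  for (nag in c(26, 28, 30)) {
    st <- solve_quiet(system_spec(mol, lat, nag * N), init = init,
                      max_iter = 8000)
    init <- st
    out <- rbind(out, c(aggregation_number(st),
                        chemical_potential(st), grand_potential(st)))
  }
  dOm_dmu <- diff(out[, 3]) / diff(out[, 2])
  n_mid <- (out[-1, 1] + out[-3, 1]) / 2
  expect_lt(max(abs(dOm_dmu / (-n_mid) - 1)), 0.05)
})

test_that("find_micelle locates maxima and zero crossings", {
  # synthetic curve Omega(n) = 10 - (n-5)^2/10: crossing at n = 15
  n <- 1:25
  cv <- data.frame(n_agg = n, Omega = 10 - (n - 5)^2 / 10,
                   mu = -1 - 0.01 * n, phi_surf_b = 1e-4 * n)
  th <- find_micelle(cv)
  expect_true(th$found)
  expect_equal(th$n_agg, 15, tolerance = 1e-9)
  expect_equal(th$phi_cmc_b, 5e-4)       # bulk fraction at the maximum
  expect_equal(th$mu_surf, -1.15, tolerance = 1e-9)

  # no crossing: flagged, not an error
  cv2 <- data.frame(n_agg = n, Omega = 10 + 0.1 * n,
                    mu = -1, phi_surf_b = 1e-4)
  expect_false(find_micelle(cv2)$found)
})

test_that("morphology transitions are recovered from synthetic mu curves", {
  tab <- data.frame(
    geometry = rep(c("spherical", "cylindrical"), each = 5),
    Nt = rep(c(10, 14, 18, 22, 26), 2),
    mu = c(1 + 0.10 * c(10, 14, 18, 22, 26),    # sphere: steeper
           2 + 0.04 * c(10, 14, 18, 22, 26)),   # cylinder
    n_agg = 1, found = TRUE)
  tr <- morphology_transition(tab, c("spherical", "cylindrical"))
  # crossing of 1 + 0.10 x = 2 + 0.04 x at x = 16.666...
  expect_equal(tr$Nt_star, 1 / 0.06, tolerance = 1e-9)
  # no crossing inside the range -> NA
  tab2 <- tab; tab2$mu[1:5] <- tab2$mu[6:10] - 1
  expect_true(is.na(morphology_transition(tab2)$Nt_star))
})

test_that("hydrophilic-only molecule never micellises", {
  # toy molecule without C segments: no maximum, no crossing
  lat <- make_lattice("spherical", 25)
  mol <- linear_chain(c(rep("NH", 4), rep("O", 4)))
  N <- n_segments(mol)
  cv <- scan_micelles(mol, lat, c(5, 15, 40) * N, max_iter = 3000)
  expect_true(all(cv$converged))
  expect_true(all(abs(cv$n_agg) < 0.5))
  expect_false(find_micelle(cv)$found)
})

test_that("raising chi_CW strengthens aggregation monotonically", {
  lat <- make_lattice("spherical", 30)
  mol <- linear_chain(c(rep("C", 12), "O", "O", "NH3+"))
  N <- n_segments(mol)
  nags <- vapply(c(0, 0.2, 0.4), function(d) {
    tb <- perturb_table(default_interactions(), c("C", "W"), d)
    st <- solve_quiet(system_spec(mol, lat, 60 * N, table = tb),
                      max_iter = 8000)
    aggregation_number(st)
  }, 0)
  expect_true(all(diff(nags) > -0.5))   # nondecreasing up to solver noise
  expect_gt(nags[3], nags[1])
})
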
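test_that("find_local_maxima handles plateaus and noise floors", {
  expect_equal(find_local_maxima(c(0, 1, 0, 2, 0)), c(2L, 4L))
  # plateau counts once, at its midpoint
  expect_equal(find_local_maxima(c(0, 5, 5, 5, 0)), 3L)
  # peaks below 1% of the global maximum are ignored
  expect_equal(find_local_maxima(c(0, 100, 0, 0.5, 0)), 2L)
  # noise floor removes sub-1e-8 wiggles entirely
  x <- c(0, 1, 0, 1e-10, 2e-10, 1e-10, 0)
  expect_equal(find_local_maxima(x), 2L)
  expect_equal(find_local_maxima(numeric(5)), integer(0))
  # boundary maximum (monotone decay from the first layer)
  expect_equal(find_local_maxima(c(3, 2, 1, 0.5)), 1L)
})

test_that("second-moment radii match analytic profiles", {
  lat <- make_lattice("spherical", 60)
  rc <- layer_centres(lat)
  # step profile phi = 1 for r <= R: R2nd = sqrt(3/5) R
  R <- 30
  w <- ifelse(rc <= R, 1, 0) * lat$L
  expect_equal(dendromicelle:::second_moment_radius(w, lat),
               sqrt(3 / 5) * R, tolerance = 0.01)
  # delta shell at radius R: moment radius = R exactly
  w2 <- numeric(60); w2[25] <- 7
  expect_equal(dendromicelle:::second_moment_radius(w2, lat), rc[25])
})

test_that("core metrics satisfy their defining identities on a micelle", {
  lat <- make_lattice("spherical", 40)
  mol <- build_molecule(1, 2, 15)
  N <- n_segments(mol)
  st <- solve_quiet(system_spec(mol, lat, 28 * N), max_iter = 8000)
  expect_true(st$converged)
  met <- core_metrics(st)
  expect_equal(met$Hshell, met$Rm - met$Rcore)
  expect_equal(met$s * met$n_agg, 4 * pi * met$Rcore^2, tolerance = 1e-9)
  expect_equal(met$Rcore_nm, met$Rcore * 0.3, tolerance = 1e-12)
  # terminal-group bookkeeping: integral of nt equals n_agg * 2^(G+1)
  expect_equal(met$Nterm, met$n_agg * 4, tolerance = 0.01 * met$Nterm)
  expect_gt(met$Hshell, 0)
  # no-micelle state errors
  st0 <- solve_quiet(system_spec(mol, lat, 2 * N), nucleate = FALSE)
  expect_error(core_metrics(st0), "no micelle|no hydrophobe")
})

test_that("charge analysis integrates hand-built profiles correctly", {
  fx <- make_fixture("hand-profiles-doublelayer")
  validate_fixture(fx)
  v <- fx$value
  phi <- matrix(0, v$lattice$M, 7, dimnames = list(NULL, KINDS))
  phi[, "NH3+"] <- v$phi_term; phi[, "Na"] <- v$phi_Na
  phi[, "Cl"] <- v$phi_Cl
  phi[, "W"] <- 1 - rowSums(phi)
  phi_b <- setNames(numeric(7), KINDS); phi_b["W"] <- 1
  st <- synthetic_state(v$lattice, phi, phi_b)
  ca <- charge_analysis(st)
  expect_equal(ca$n_maxima, 1L)
  expect_equal(ca$Reff, 9.5)             # shell sits in layer 10
  expect_equal(ca$Qeff, 50, tolerance = 1e-9)
  expect_equal(ca$Q[v$lattice$M], 0, tolerance = 1e-9)
  expect_equal(ca$zeta, 0)               # psi = 0 in the synthetic state

  # counterion-free profiles: Q monotone nondecreasing, Qeff = Qbare
  phi2 <- matrix(0, v$lattice$M, 7, dimnames = list(NULL, KINDS))
  phi2[, "NH3+"] <- v$phi_term
  phi2[, "W"] <- 1 - rowSums(phi2)
  st2 <- synthetic_state(v$lattice, phi2, phi_b)
  ca2 <- charge_analysis(st2)
  expect_true(all(diff(ca2$Q) >= -1e-12))
  expect_equal(max(ca2$Q), 50, tolerance = 1e-9)
})

test_that("stratification flags unimodal vs two-population profiles", {
  fx <- make_fixture("hand-profiles-stratified")
  validate_fixture(fx)
  mx <- find_local_maxima(fx$value$nt)
  expect_equal(length(mx), 2L)
  # unimodal Gaussian-like profile: one maximum, no stratification
  lat <- fx$value$lattice
  nt1 <- 10 * exp(-(layer_centres(lat) - 15)^2 / 9)
  expect_equal(length(find_local_maxima(nt1)), 1L)
})

test_that("stratification report decomposes by contour class and generation", {
  lat <- make_lattice("spherical", 35)
  mol <- build_molecule(2, 2, 12)
  N <- n_segments(mol)
  st <- solve_quiet(system_spec(mol, lat, 20 * N), max_iter = 8000)
  expect_true(st$converged)
  rep <- stratification_report(st)
  # class profiles sum to the total terminal distribution
  tot <- Reduce(`+`, lapply(rep$by_contour, function(z) z$profile))
  expect_equal(tot, rep$terminal_total$profile, tolerance = 1e-9)
  # class labels match the molecule's contour classes
  expect_setequal(names(rep$by_contour),
                  as.character(unique(contour_classes(mol)$contour)))
  # every dendron generation appears in the per-generation decomposition
  expect_setequal(names(rep$segments_by_gen), as.character(0:2))

  # small generations show a classical double layer: one Q maximum, and
  # the counterion cloud overlaps the terminal-charge layer (the layer
  # windows holding 90% of each excess mass intersect over >= 50% of
  # their union)
  expect_gt(aggregation_number(st), 10)
  ca <- charge_analysis(st)
  expect_equal(ca$n_maxima, 1L)
  mass_range <- function(w) {
    w <- pmax(w, 0); cw <- cumsum(w) / sum(w)
    c(which(cw >= 0.05)[1], which(cw >= 0.95)[1])
  }
  term <- dendromicelle:::node_excess_numbers(st, which(mol$nodes$terminal))
  cl <- (st$phi[, "Cl"] - st$phi_b[["Cl"]]) * lat$L
  r1 <- mass_range(term); r2 <- mass_range(cl)
  inter <- max(0, min(r1[2], r2[2]) - max(r1[1], r2[1]) + 1)
  uni <- max(r1[2], r2[2]) - min(r1[1], r2[1]) + 1
  expect_gte(inter / uni, 0.5)
})
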
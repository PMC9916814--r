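# ---- species bookkeeping -------------------------------------------------
# The cell contains up to four molecular species: the surfactant chain and
# the monomeric solvent/ions.  Each species carries its length N_c, its
# per-kind composition f_c (fractions of the molecule), its bulk volume
# fraction and its amount in the cell.
species_table <- function(state) {
  spec <- state$spec
  lat <- spec$lattice
  kn <- .KINDS
  sp <- list()
  mol <- spec$molecule
  if (!is.null(mol) && spec$theta_surf > 0) {
    N <- n_segments(mol)
    sp$surf <- list(name = "surf", N = N, f = kind_fractions(mol),
                    phi_b = state$phi_surf_b,
                    n = spec$theta_surf / N,
                    phi_r = state$n_mol * rowSums(state$node_dens))
  }
  mono <- function(name, kind, phi_b, Nc = 1) {
    phi_r <- state$phi[, kind]  # monomeric kinds never occur in the chain
    f <- setNames(numeric(7), kn); f[kind] <- 1
    list(name = name, N = Nc, f = f, phi_b = phi_b,
         n = sum(lat$L * phi_r) / Nc, phi_r = phi_r)
  }
  sp$W  <- mono("W", "W", state$phi_W_b, Nc = spec$solvent_size)
  sp$Na <- mono("Na", "Na", state$phi_Na_b)
  sp$Cl <- mono("Cl", "Cl", state$phi_Cl_b)
  sp
}

# chi-quadratic form A_c = (phi_b - f_c)' chi (phi_b - f_c)
chi_quadratic <- function(chi, phi_b_kind, f_c) {
  d <- phi_b_kind - f_c
  drop(d %*% chi %*% d)
}

#' Bulk chemical potential of a species
#'
#' Multicomponent Flory-Huggins chemical potential evaluated at the bulk
#' composition of a converged state (complete equilibrium makes the
#' chemical potential spatially uniform, so the bulk suffices).  Two
#' conventions are provided, differing only by a constant per species:
#' \describe{
#'   \item{\code{"fh"}}{the textbook multicomponent Flory-Huggins form
#'     \deqn{\mu_c/kT = \ln\phi_c^b + 1 - N_c \sum_j \phi_j^b/N_j
#'       - \frac{N_c}{2} \sum_{XY} \chi_{XY}
#'       (\phi_X^b - f_{cX})(\phi_Y^b - f_{cY})}
#'     with \eqn{f_{cX}} the fraction of segments of kind X in species c;
#'     used for reporting and for comparing morphologies.}
#'   \item{\code{"functional"}}{the exact derivative
#'     \eqn{\partial F/\partial n_c} of the free-energy functional used by
#'     \code{\link{helmholtz_energy}},
#'     \eqn{\mu_c = \ln\phi_c^b - N_c\sum_j\phi_j^b/N_j +
#'       N_c f_c^T\chi\phi^b - N_c e_b}
#'     (with \eqn{e_b = \frac12 \phi^{bT}\chi\phi^b}); it differs from
#'     \code{"fh"} by \eqn{1 - \frac{N_c}{2} f_c^T\chi f_c} and is the one
#'     that makes the grand-potential bookkeeping exact.}
#' }
#' Transition points and morphology comparisons are unaffected by the
#' choice because the offset is constant for a given molecule.
#'
#' @param state a converged \code{scf_state}
#' @param species which species, default the surfactant
#' @param convention \code{"fh"} (default) or \code{"functional"}
#' @return chemical potential in kT per molecule
#' @export
chemical_potential <- function(state, species = "surf",
                               convention = c("fh", "functional")) {
  convention <- match.arg(convention)
  sp <- species_table(state)
  if (is.null(sp[[species]])) stop("species not present: ", species)
  s <- sp[[species]]
  if (s$phi_b <= 0) stop("zero bulk fraction for species ", species)
  chi <- state$spec$table$chi
  phi_b <- state$phi_b
  sum_phi_over_N <- sum(vapply(sp, function(x) x$phi_b / x$N, 0))
  if (convention == "fh") {
    A <- chi_quadratic(chi, phi_b, s$f)
    log(s$phi_b) + 1 - s$N * sum_phi_over_N - (s$N / 2) * A
  } else {
    e_b <- 0.5 * drop(phi_b %*% chi %*% phi_b)
    log(s$phi_b) - s$N * sum_phi_over_N +
      s$N * drop(s$f %*% chi %*% phi_b) - s$N * e_b
  }
}

#' Helmholtz free energy of the cell
#'
#' Canonical mean-field free energy of the converged lattice system (kT):
#' ideal chain/monomer terms \eqn{\sum_c n_c(\ln\phi_c^b - 1)} (using the
#' exact identity \eqn{n_c N_c / q_c = \phi_c^b}), minus the field work
#' \eqn{\sum_r L\sum_X u_X\phi_X}, plus the contact energy
#' \eqn{\frac12\sum\chi_{XY}\phi_X\langle\phi_Y\rangle} and the
#' electrostatic energy \eqn{\frac12\sum\rho_e\psi}.
#'
#' @param state a converged \code{scf_state}
#' @return free energy in kT
#' @export
helmholtz_energy <- function(state) {
  sp <- species_table(state)
  lat <- state$spec$lattice
  chi <- state$spec$table$chi
  ideal <- sum(vapply(sp, function(x) x$n * (log(x$phi_b) - 1), 0))
  field <- sum(lat$L * rowSums(state$u * state$phi))
  avg_phi <- apply(state$phi, 2, local_average, lattice = lat)
  contact <- sum(lat$L * 0.5 * rowSums(state$phi * (avg_phi %*% chi)))
  electro <- sum(lat$L * 0.5 * state$rho_e * state$psi)
  ideal - field + contact + electro
}

#' Excess grand potential of an aggregate (field route)
#'
#' The work of formation of the most probable aggregate, i.e. the grand
#' potential of the cell relative to the homogeneous bulk solution,
#' evaluated layer by layer from the converged fields.  \eqn{\Omega = 0}
#' defines the equilibrium (most probable) micelle; the translational
#' entropy of the aggregate as a whole is not included.
#'
#' @param state a converged \code{scf_state}
#' @return grand potential in kT (per unit length / area for cylindrical /
#'   planar lattices)
#' @export
grand_potential <- function(state) {
  sp <- species_table(state)
  lat <- state$spec$lattice
  chi <- state$spec$table$chi
  phi_b <- state$phi_b
  M <- lat$M
  sum_phi_over_N_r <- rowSums(vapply(sp, function(x) x$phi_r / x$N,
                                     numeric(M)))
  sum_phi_over_N_b <- sum(vapply(sp, function(x) x$phi_b / x$N, 0))
  avg_phi <- apply(state$phi, 2, local_average, lattice = lat)
  contact <- 0.5 * rowSums(state$phi * (avg_phi %*% chi))
  cross_b <- drop(state$phi %*% (chi %*% phi_b))
  e_b <- 0.5 * drop(phi_b %*% chi %*% phi_b)
  omega_r <- (sum_phi_over_N_b - sum_phi_over_N_r) -
    rowSums(state$u * state$phi) +
    contact - cross_b + e_b +
    0.5 * state$rho_e * state$psi
  sum(lat$L * omega_r)
}

#' Excess grand potential via thermodynamic bookkeeping
#'
#' Independent route for the same quantity as
#' \code{\link{grand_potential}}: \eqn{\Omega = F - \sum_c \mu_c n_c +
#' p_b V}, with \eqn{F} the canonical free energy from
#' \code{\link{helmholtz_energy}} and \eqn{\mu_c} the bulk chemical
#' potentials in the \code{"functional"} convention (under which the bulk
#' lattice pressure vanishes identically, \eqn{p_b = 0}).  Agreement of
#' the two routes (to 1e-3 kT on converged states) validates the
#' free-energy functional and the chemical-potential expression against
#' each other; the small-systems identity
#' \eqn{d\Omega/d\mu = -n_{agg}} along a micellar branch provides a third,
#' fully thermodynamic check (exercised in the test-suite).
#'
#' @param state a converged \code{scf_state}
#' @return grand potential in kT
#' @export
grand_potential_bookkeeping <- function(state) {
  sp <- species_table(state)
  Fh <- helmholtz_energy(state)
  mu_n <- sum(vapply(sp, function(x) {
    chemical_potential(state, x$name, convention = "functional") * x$n
  }, 0))
  Fh - mu_n
}

# ---- micelle scans -------------------------------------------------------

#' Default geometric amount grid for micelle scans
#'
#' Geometric spacing with at least \code{per_decade} points per decade
#' between \code{theta_min} and \code{theta_max} (surfactant segments in
#' the cell).
#'
#' @param theta_min,theta_max grid end points (segments)
#' @param per_decade grid density (default 12)
#' @return numeric vector of theta values
#' @export
theta_grid <- function(theta_min, theta_max, per_decade = 12) {
  stopifnot(theta_min > 0, theta_max > theta_min)
  n <- max(2, ceiling(log10(theta_max / theta_min) * per_decade) + 1)
  exp(seq(log(theta_min), log(theta_max), length.out = n))
}

#' Scan micelle thermodynamics over the surfactant amount
#'
#' Solves the SCF equations on a grid of surfactant amounts
#' \code{theta} (segments per cell) and tabulates the aggregation number,
#' the excess grand potential, the chemical potential and the bulk
#' fraction.  Consecutive points are warm-started from the previous
#' converged field.  Non-converged points are flagged and kept; the scan
#' continues.
#'
#' @param molecule a \code{chain_graph}
#' @param lattice a \code{lattice_geometry} (its geometry selects the
#'   micelle morphology: spherical, cylindrical per unit length, lamellar
#'   per unit area)
#' @param thetas increasing vector of surfactant amounts (segments)
#' @param table,phi_salt_b,conversions see \code{\link{system_spec}}
#' @param keep_states keep all converged states (attribute
#'   \code{"states"}) for structural analysis
#' @param ... passed to \code{\link{solve_scf}}
#' @return data.frame with one row per theta: \code{theta}, \code{n_agg},
#'   \code{Omega}, \code{Omega_book}, \code{mu}, \code{phi_surf_b},
#'   \code{residual}, \code{iterations}, \code{converged}; states in
#'   \code{attr(, "states")} if requested.
#' @export
scan_micelles <- function(molecule, lattice, thetas,
                          table = default_interactions(),
                          phi_salt_b = 0.01,
                          conversions = unit_conversions(),
                          keep_states = FALSE, ...) {
  stopifnot(!is.unsorted(thetas))
  rows <- vector("list", length(thetas))
  states <- if (keep_states) vector("list", length(thetas)) else NULL
  init <- NULL
  for (i in seq_along(thetas)) {
    sp <- system_spec(molecule, lattice, theta_surf = thetas[i],
                      table = table, phi_salt_b = phi_salt_b,
                      conversions = conversions)
    st <- tryCatch(solve_scf(sp, init = init, quiet = TRUE, ...),
                   error = function(e) NULL)
    # a warm start can fall off the micellar branch; re-nucleate once
    if (!is.null(st) && !is.null(init) && inherits(init, "scf_state") &&
        aggregation_number(init) > 1 && aggregation_number(st) < 0.5) {
      st2 <- tryCatch(solve_scf(sp, init = NULL, quiet = TRUE, ...),
                      error = function(e) NULL)
      if (!is.null(st2) && st2$converged && aggregation_number(st2) > 0.5)
        st <- st2
    }
    if (is.null(st)) {
      rows[[i]] <- data.frame(theta = thetas[i], n_agg = NA_real_,
                              Omega = NA_real_, Omega_book = NA_real_,
                              mu = NA_real_, phi_surf_b = NA_real_,
                              residual = NA_real_, iterations = NA_integer_,
                              converged = FALSE)
      next
    }
    if (st$converged) init <- st
    rows[[i]] <- data.frame(
      theta = thetas[i], n_agg = aggregation_number(st),
      Omega = grand_potential(st),
      Omega_book = grand_potential_bookkeeping(st),
      mu = chemical_potential(st), phi_surf_b = st$phi_surf_b,
      residual = st$residual, iterations = st$iterations,
      converged = st$converged)
    if (keep_states) states[[i]] <- st
  }
  out <- do.call(rbind, rows)
  if (keep_states) attr(out, "states") <- states
  out
}

#' Locate the equilibrium micelle on a scan curve
#'
#' The equilibrium (most probable) micelle is the \eqn{\Omega = 0}
#' crossing on the decaying side of the \eqn{\Omega(n_{agg})} curve; the
#' maximum of \eqn{\Omega} marks the critical micelle concentration (the
#' bulk surfactant fraction there).  Both are located by monotone linear
#' interpolation on the scan grid.
#'
#' @param curves data.frame from \code{\link{scan_micelles}} (columns
#'   \code{n_agg}, \code{Omega}, \code{mu}, \code{phi_surf_b} required)
#' @return object of class \code{micelle_thermo}: list with \code{found},
#'   \code{n_agg}, \code{mu_surf}, \code{phi_surf_b}, \code{phi_cmc_b},
#'   \code{Omega_max}, and the bracketing row indices \code{bracket}
#' @export
find_micelle <- function(curves) {
  cv <- curves[is.finite(curves$Omega) & is.finite(curves$n_agg), ]
  if ("converged" %in% names(cv)) cv <- cv[cv$converged, ]
  res <- list(found = FALSE, n_agg = NA_real_, mu_surf = NA_real_,
              phi_surf_b = NA_real_, phi_cmc_b = NA_real_,
              Omega_max = NA_real_, bracket = NULL)
  class(res) <- "micelle_thermo"
  if (nrow(cv) < 3) return(res)
  imax <- which.max(cv$Omega)
  res$Omega_max <- cv$Omega[imax]
  res$phi_cmc_b <- cv$phi_surf_b[imax]
  # no barrier, or numerical noise around Omega = 0: no micelle
  if (cv$Omega[imax] <= 1e-6) return(res)
  after <- seq(imax, nrow(cv))
  om <- cv$Omega[after]
  cross <- which(om[-length(om)] > 0 & om[-1] <= 0)
  if (length(cross) == 0) return(res)    # Omega never reaches zero
  i1 <- after[cross[1]]; i2 <- after[cross[1] + 1]
  w <- cv$Omega[i1] / (cv$Omega[i1] - cv$Omega[i2])
  lin <- function(a, b) a + w * (b - a)
  n_star <- lin(cv$n_agg[i1], cv$n_agg[i2])
  if (!is.finite(n_star) || n_star <= 0.5) return(res)  # noise crossing
  res$found <- TRUE
  res$n_agg <- n_star
  res$mu_surf <- lin(cv$mu[i1], cv$mu[i2])
  res$phi_surf_b <- lin(cv$phi_surf_b[i1], cv$phi_surf_b[i2])
  res$bracket <- c(i1, i2)
  res
}

#' @export
print.micelle_thermo <- function(x, ...) {
  if (!x$found) {
    cat("<micelle_thermo> no equilibrium micelle of this morphology\n")
  } else {
    cat(sprintf(
      "<micelle_thermo> n_agg = %.3f, mu_surf = %.4f kT, phi_b = %.3e, phi_cmc = %.3e\n",
      x$n_agg, x$mu_surf, x$phi_surf_b, x$phi_cmc_b))
  }
  invisible(x)
}

#' Find the equilibrium micelle of a molecule, with grid refinement
#'
#' Runs \code{\link{scan_micelles}}, then refines the amount grid around
#' the \eqn{\Omega = 0} bracket (\code{refine} levels, 3 extra points per
#' level) before interpolating.  Also returns the converged state nearest
#' the crossing for structural and electrostatic analysis.
#'
#' @inheritParams scan_micelles
#' @param refine number of refinement passes around the crossing
#' @param ... passed to \code{\link{solve_scf}}
#' @return list with \code{thermo} (a \code{micelle_thermo}),
#'   \code{state} (the \code{scf_state} nearest the crossing, or NULL),
#'   and \code{curves} (the full scan table)
#' @export
find_equilibrium_micelle <- function(molecule, lattice, thetas,
                                     table = default_interactions(),
                                     phi_salt_b = 0.01,
                                     conversions = unit_conversions(),
                                     refine = 2, ...) {
  cv <- scan_micelles(molecule, lattice, thetas, table = table,
                      phi_salt_b = phi_salt_b, conversions = conversions,
                      keep_states = TRUE, ...)
  th <- find_micelle(cv)
  for (lev in seq_len(refine)) {
    if (!th$found) break
    i1 <- th$bracket[1]; i2 <- th$bracket[2]
    t1 <- cv$theta[i1]; t2 <- cv$theta[i2]
    if (t2 / t1 < 1.005) break
    states <- attr(cv, "states")
    extra <- exp(seq(log(t1), log(t2), length.out = 5))[2:4]
    cv2 <- scan_micelles(molecule, lattice, extra, table = table,
                         phi_salt_b = phi_salt_b, conversions = conversions,
                         keep_states = TRUE, ...)
    states <- c(states, attr(cv2, "states"))
    cv <- rbind(cv, cv2)
    ord <- order(cv$theta)
    cv <- cv[ord, ]; states <- states[ord]
    rownames(cv) <- NULL
    attr(cv, "states") <- states
    th <- find_micelle(cv)
  }
  state <- NULL
  if (th$found) {
    states <- attr(cv, "states")
    conv <- cv$converged
    target <- th$n_agg
    ok <- which(conv & is.finite(cv$n_agg))
    i_near <- ok[which.min(abs(cv$n_agg[ok] - target))]
    state <- states[[i_near]]
  }
  list(thermo = th, state = state, curves = cv)
}

# ---- morphology ----------------------------------------------------------

#' Chemical potential at the equilibrium micelle across morphologies
#'
#' For each tail length and each morphology (spherical, cylindrical per
#' unit length, lamellar per unit area) locates the equilibrium aggregate
#' and records the surfactant chemical potential there.  The morphology
#' with the lowest \eqn{\mu} at \eqn{\Omega = 0} is the stable one; the
#' point where two morphologies exchange stability is the transition.
#'
#' @param G,t dendron generation and tail count
#' @param Nt_values vector of tail lengths to scan
#' @param geometries morphologies to compare
#' @param M layers per lattice (may be a named vector per geometry)
#' @param thetas_fun function(molecule, geometry) returning the amount
#'   grid; default covers aggregation numbers ~2..200 (spheres) and an
#'   equivalent excess per unit length/area for the other geometries
#' @param ... passed to \code{\link{find_equilibrium_micelle}}
#' @inheritParams scan_micelles
#' @return data.frame with columns \code{geometry}, \code{Nt}, \code{mu},
#'   \code{n_agg}, \code{found}
#' @export
morphology_mu_table <- function(G, t, Nt_values,
                                geometries = c("spherical", "cylindrical",
                                               "lamellar"),
                                M = 60,
                                table = default_interactions(),
                                phi_salt_b = 0.01,
                                conversions = unit_conversions(),
                                thetas_fun = NULL, ...) {
  rows <- list()
  for (g in geometries) {
    lat_geom <- if (g == "lamellar") "planar" else g
    Mg <- if (length(M) > 1) M[[g]] else M
    lat <- make_lattice(lat_geom, Mg)
    for (Nt in Nt_values) {
      mol <- build_molecule(G, t, Nt)
      th_grid <- if (is.null(thetas_fun)) {
        N <- n_segments(mol)
        switch(g,
          spherical   = theta_grid(2 * N, 250 * N, per_decade = 6),
          cylindrical = theta_grid(0.5 * N, 60 * N, per_decade = 6),
          lamellar    = theta_grid(0.25 * N, 30 * N, per_decade = 6))
      } else thetas_fun(mol, g)
      fit <- find_equilibrium_micelle(mol, lat, th_grid, table = table,
                                      phi_salt_b = phi_salt_b,
                                      conversions = conversions, ...)
      rows[[length(rows) + 1]] <- data.frame(
        geometry = g, Nt = Nt, mu = fit$thermo$mu_surf,
        n_agg = fit$thermo$n_agg, found = fit$thermo$found)
    }
  }
  do.call(rbind, rows)
}

#' Morphology transition points from a chemical-potential table
#'
#' Locates, per pair of morphologies, the tail length at which their
#' equilibrium chemical potentials cross (bracketing plus linear
#' interpolation on the \code{Nt} grid).
#'
#' @param mu_table data.frame from \code{\link{morphology_mu_table}}
#' @param pair character(2): the two morphologies, ordered so that the
#'   first is stable at small Nt
#' @return list with \code{Nt_star} (interpolated crossing, NA if no
#'   crossing in range) and the merged comparison table
#' @export
morphology_transition <- function(mu_table,
                                  pair = c("spherical", "cylindrical")) {
  a <- mu_table[mu_table$geometry == pair[1] & mu_table$found, ]
  b <- mu_table[mu_table$geometry == pair[2] & mu_table$found, ]
  m <- merge(a[, c("Nt", "mu")], b[, c("Nt", "mu")], by = "Nt",
             suffixes = c("_1", "_2"))
  m <- m[order(m$Nt), ]
  res <- list(Nt_star = NA_real_, table = m)
  if (nrow(m) < 2) return(res)
  d <- m$mu_1 - m$mu_2            # < 0 where morphology 1 is stable
  cross <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
  if (length(cross) == 0) return(res)
  i <- cross[1]
  w <- d[i] / (d[i] - d[i + 1])
  res$Nt_star <- m$Nt[i] + w * (m$Nt[i + 1] - m$Nt[i])
  res
}

#' Build a micelle morphology state diagram
#'
#' For each tail count \code{t} and generation \code{G}, finds the
#' sphere-to-cylinder (and optionally cylinder-to-lamella) transition tail
#' length and reports the boundary in the
#' (total hydrophobic segments \code{Nt*t}, \code{G}) plane.
#'
#' @param G_values generations to scan
#' @param t_values tail counts to scan
#' @param Nt_values tail-length grid used for each transition search
#' @param pairs list of morphology pairs to bracket
#' @param ... passed to \code{\link{morphology_mu_table}}
#' @return data.frame with columns \code{t}, \code{G}, \code{boundary}
#'   (e.g. \code{"spherical-cylindrical"}), \code{Nt_star},
#'   \code{NtT_star = Nt_star * t}
#' @export
build_state_diagram <- function(G_values, t_values, Nt_values,
                                pairs = list(c("spherical", "cylindrical")),
                                ...) {
  rows <- list()
  geoms <- unique(unlist(pairs))
  for (t in t_values) for (G in G_values) {
    tab <- morphology_mu_table(G, t, Nt_values, geometries = geoms, ...)
    for (p in pairs) {
      tr <- morphology_transition(tab, p)
      rows[[length(rows) + 1]] <- data.frame(
        t = t, G = G, boundary = paste(p, collapse = "-"),
        Nt_star = tr$Nt_star, NtT_star = tr$Nt_star * t)
    }
  }
  do.call(rbind, rows)
}
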
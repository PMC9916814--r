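# Independent oracles and small utilities shared by the test files.

KINDS <- c("W", "C", "NH3+", "NH", "O", "Na", "Cl")

# Brute-force conformation enumeration for a chain graph on a 1D lattice:
# sums the Boltzmann weight of every assignment of layers to nodes.  Bond
# steps are taken parent -> child with the step probability of the parent
# layer (mirror boundaries folded into the same-layer weight); each
# configuration carries the L(r_root) site multiplicity, and per-site
# densities divide the layer volume back out.  By the detailed-balance
# identity L(r) lambda+(r) = L(r+1) lambda-(r+1) this is the ensemble the
# propagators sample.  Exponential cost; only for tiny trees.
enum_node_densities <- function(graph, GW, lat) {
  M <- lat$M
  nd <- graph$nodes
  n <- nrow(nd)
  kidx <- match(nd$kind, KINDS)
  step_w <- function(rp, rc) {
    w <- 0
    if (rc == rp - 1) w <- w + lat$lambda_m[rp]
    if (rc == rp) {
      w <- w + lat$lambda_0[rp]
      if (rp == 1) w <- w + lat$lambda_m[rp]
      if (rp == M) w <- w + lat$lambda_p[rp]
    }
    if (rc == rp + 1) w <- w + lat$lambda_p[rp]
    w
  }
  root <- which(nd$parent == 0L)
  confs <- as.matrix(expand.grid(rep(list(seq_len(M)), n)))
  dens <- matrix(0, M, n)
  q <- 0
  for (i in seq_len(nrow(confs))) {
    conf <- confs[i, ]
    w <- lat$L[conf[root]] * prod(GW[cbind(conf, kidx)])
    for (j in seq_len(n)) {
      p <- nd$parent[j]
      if (p > 0) w <- w * step_w(conf[p], conf[j])
    }
    q <- q + w
    for (j in seq_len(n)) dens[conf[j], j] <- dens[conf[j], j] + w
  }
  list(dens_site = dens / lat$L, q = q)
}

# Discrete Gauss-law closed form for psi given a charge-per-layer profile
# and uniform permittivity: telescoping the flux balance from the outer
# Dirichlet boundary inwards.  Independent of the tridiagonal solver.
gauss_shell_psi <- function(sigma, eps_r, lat, conversions = unit_conversions()) {
  M <- lat$M
  c0 <- dendromicelle:::electrostatic_prefactor(conversions)
  Qenc <- cumsum(sigma)               # charge enclosed within layer r
  # flux through interface r+1/2: eps*A_r*(psi_{r+1}-psi_r) = -c0*Qenc(r)
  dpsi <- -c0 * Qenc[-M] / (eps_r * lat$A[-M])   # psi_{r+1} - psi_r
  psi <- c(0, cumsum(dpsi))           # up to a constant
  psi - psi[M]                        # Dirichlet psi(M) = 0
}

# Hand evaluation of the multicomponent Flory-Huggins chemical potential
# (Eq-1 convention) from raw ingredients; independent re-implementation.
fh_mu_hand <- function(phi_c, N_c, f_c, phi_b_kind, Ns, phis, chi) {
  # Ns, phis: lengths and bulk fractions of all species
  A <- 0
  for (X in seq_along(f_c)) for (Y in seq_along(f_c)) {
    A <- A + chi[X, Y] * (phi_b_kind[X] - f_c[X]) * (phi_b_kind[Y] - f_c[Y])
  }
  unname(log(phi_c) + 1 - N_c * sum(phis / Ns) - (N_c / 2) * A)
}

# a synthetic scf_state carrying hand-built profiles, for observables
# that only read phi/psi/phi_b/lattice (documented as synthetic)
synthetic_state <- function(lattice, phi, phi_b,
                            psi = numeric(lattice$M),
                            molecule = NULL, n_mol = 0, node_dens = NULL,
                            theta_surf = 0, phi_surf_b = 0) {
  st <- list(
    u = matrix(0, lattice$M, 7, dimnames = list(NULL, KINDS)),
    phi = phi, alpha = numeric(lattice$M), psi = psi, phi_b = phi_b,
    phi_surf_b = phi_surf_b, phi_W_b = phi_b[["W"]],
    phi_Na_b = phi_b[["Na"]], phi_Cl_b = phi_b[["Cl"]],
    rho_e = drop(phi %*% segment_kinds()$valency),
    eps = drop(phi %*% segment_kinds()$eps_r),
    node_dens = node_dens, logq = NA_real_, qdev = NA_real_,
    n_mol = n_mol, residual = 0, iterations = 0L, converged = TRUE,
    spec = list(molecule = molecule, lattice = lattice,
                theta_surf = theta_surf, table = default_interactions(),
                phi_salt_b = phi_b[["Na"]],
                conversions = unit_conversions(), fixed_charge = NULL,
                solvent_size = 1L))
  class(st$spec) <- "system_spec"
  class(st) <- "scf_state"
  st
}

solve_quiet <- function(...) solve_scf(..., quiet = TRUE)
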
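#' Specify an SCF system
#'
#' Bundles everything the solver needs: the (optional) surfactant molecule
#' and its total amount in the cell, the lattice, the interaction table,
#' the bulk salt fraction, and the unit conversions.  The solution always
#' contains water (compact clusters of \code{solvent_size} sites) and the
#' two monovalent salt ions; the bulk is kept electroneutral by assigning
#' the counter-charge of dissolved surfactant to the counterion (Cl) bulk
#' fraction.
#'
#' @param molecule a \code{\link{build_molecule}} chain graph, or
#'   \code{NULL} for a surfactant-free solution
#' @param lattice a \code{\link{make_lattice}} geometry
#' @param theta_surf total surfactant amount in the cell, in segments
#'   (\code{theta_surf / n_segments(molecule)} molecules); 0 when
#'   \code{molecule} is \code{NULL}
#' @param table \code{\link{default_interactions}} or a perturbed variant
#' @param phi_salt_b dimensionless bulk salt volume fraction (each ion);
#'   the default 0.01 corresponds to 0.1 M
#' @param conversions \code{\link{unit_conversions}}
#' @param fixed_charge optional length-M profile of a frozen external
#'   charge density (e per site) entering only the Poisson equation;
#'   used for electrostatic benchmarks
#' @param solvent_size number of lattice sites per water cluster (default
#'   5, the united-atom membrane convention the interaction table stems
#'   from; 1 gives monomeric water)
#' @return object of class \code{system_spec}
#' @export
system_spec <- function(molecule, lattice, theta_surf = 0,
                        table = default_interactions(),
                        phi_salt_b = 0.01,
                        conversions = unit_conversions(),
                        fixed_charge = NULL, solvent_size = 5) {
  stopifnot(inherits(lattice, "lattice_geometry"),
            inherits(table, "interaction_table"),
            phi_salt_b > 0, phi_salt_b < 0.5, theta_surf >= 0)
  if (!is.null(molecule)) {
    stopifnot(inherits(molecule, "chain_graph"))
    if (any(molecule$nodes$kind %in% c("W", "Na", "Cl")))
      stop("chain molecules may not contain the monomeric kinds W, Na, Cl")
  }
  if (is.null(molecule) && theta_surf > 0)
    stop("theta_surf > 0 requires a molecule")
  V <- sum(lattice$L)
  if (theta_surf >= 0.9 * V)
    stop("infeasible theta_surf: lattice overfilled")
  if (!is.null(fixed_charge) && length(fixed_charge) != lattice$M)
    stop("fixed_charge must have length M")
  stopifnot(length(solvent_size) == 1, solvent_size >= 1,
            solvent_size == round(solvent_size))
  structure(list(molecule = molecule, lattice = lattice,
                 theta_surf = theta_surf, table = table,
                 phi_salt_b = phi_salt_b, conversions = conversions,
                 fixed_charge = fixed_charge,
                 solvent_size = as.integer(solvent_size)),
            class = "system_spec")
}

# Nonlinear Poisson-Boltzmann solve: ions respond to psi by Boltzmann
# factors while the polymer/fixed charge is frozen.  Newton iteration on
# the flux-form discrete equation (same discretisation as poisson_solve);
# a_Na/a_Cl are the non-electrostatic ion potentials.
pb_solve <- function(rho_fix, phi_Na_b, phi_Cl_b, a_Na, a_Cl, eps, lat,
                     conversions, psi0 = NULL, tol = 1e-12, max_newton = 60) {
  M <- lat$M
  c0 <- electrostatic_prefactor(conversions)
  g <- c(0.5 * (eps[-M] + eps[-1]) * lat$A[-M], 0)
  psi <- if (is.null(psi0)) numeric(M) else psi0
  wNa <- phi_Na_b * exp(-pmin(pmax(a_Na, -60), 60))
  wCl <- phi_Cl_b * exp(-pmin(pmax(a_Cl, -60), 60))
  for (nt in seq_len(max_newton)) {
    psi_c <- pmin(pmax(psi, -60), 60)
    fNa <- wNa * exp(-psi_c)
    fCl <- wCl * exp(psi_c)
    rho <- rho_fix + fNa - fCl
    # residual of the discrete Gauss law, Dirichlet at M
    flux_out <- g * c(psi[-1] - psi[-M], 0)
    flux_in <- c(0, flux_out[-M])
    Fr <- flux_out - flux_in + c0 * rho * lat$L
    Fr[M] <- psi[M]
    # Jacobian: tridiagonal (flux part) + diagonal ion response
    dia <- -(g + c(0, g[-M])) - c0 * (fNa + fCl) * lat$L
    low <- g[-M]; upp <- g[-M]
    dia[M] <- 1; low[M - 1] <- 0; upp[M - 1] <- 0
    # solve J dpsi = -Fr with J = tridiag(low, dia, upp); multiply by -1
    # to match the thomas_solve sign convention (-lower, +diag, -upper)
    dpsi <- thomas_solve(low, -dia, upp, Fr)
    step <- max(abs(dpsi))
    if (step > 5) dpsi <- dpsi * (5 / step)
    psi <- psi + dpsi
    if (step < tol) break
  }
  psi_c <- pmin(pmax(psi, -60), 60)
  list(psi = psi, phi_Na = wNa * exp(-psi_c), phi_Cl = wCl * exp(psi_c),
       newton_iter = nt)
}

# One SCF sweep: given the slow fields (w for the chain kinds, pressure
# xi), compute all volume fractions (chain by propagators; solvent and
# ions explicitly), solve the nonlinear Poisson-Boltzmann equation, and
# return the interaction potentials and residuals.  u_ext is an optional
# frozen external potential (M x 7) used for nucleation pinning.
scf_evaluate <- function(w, xi, spec, psi0 = NULL, u_ext = NULL) {
  lat <- spec$lattice
  M <- lat$M
  kinds <- segment_kinds()
  kn <- .KINDS
  chi <- spec$table$chi
  phi <- matrix(0, M, 7, dimnames = list(NULL, kn))

  mol <- spec$molecule
  pol_kinds <- c("C", "NH3+", "NH", "O")
  u_pol <- sweep(w[, pol_kinds, drop = FALSE], 1, xi, "+")
  if (!is.null(u_ext)) u_pol <- u_pol + u_ext[, pol_kinds]
  if (!is.null(mol) && spec$theta_surf > 0) {
    GWp <- exp(-pmin(pmax(u_pol, -200), 200))
    GW7 <- matrix(1, M, 7, dimnames = list(NULL, kn))
    GW7[, pol_kinds] <- GWp
    kind_idx <- match(mol$nodes$kind, kn)
    prop <- propagate_tree_cpp(mol$nodes$parent, kind_idx, GW7,
                               lat$lambda_m, lat$lambda_0, lat$lambda_p,
                               lat$L)
    N <- n_segments(mol)
    n_mol <- spec$theta_surf / N
    phi_surf_b <- spec$theta_surf * exp(-prop$logq)
    phi <- phi + n_mol * prop$dens_kind
  } else {
    prop <- NULL; N <- 1; n_mol <- 0; phi_surf_b <- 0
  }

  f_mol <- if (!is.null(mol)) kind_fractions(mol) else setNames(numeric(7), kn)
  z_mol <- if (!is.null(mol)) {
    sum(kinds$valency[match(mol$nodes$kind, kn)])
  } else 0

  phi_Na_b <- spec$phi_salt_b
  phi_Cl_b <- spec$phi_salt_b + z_mol * phi_surf_b / max(N, 1)
  phi_W_b <- 1 - phi_surf_b - phi_Na_b - phi_Cl_b
  if (phi_W_b <= 0) stop("bulk overfilled: phi_W_b <= 0")

  # bulk volume fraction per kind
  phi_b <- setNames(numeric(7), kn)
  phi_b["W"] <- phi_W_b; phi_b["Na"] <- phi_Na_b; phi_b["Cl"] <- phi_Cl_b
  phi_b <- phi_b + phi_surf_b * f_mol

  # solvent: explicit response to the current chain profile (chi_WW = 0,
  # so u_int_W involves only the chain kinds) plus the pressure field.
  # Water is a compact cluster of solvent_size sites (a short W chain),
  # following the united-atom membrane parameterisation the interaction
  # table originates from; solvent_size = 1 recovers monomeric water.
  avg_d <- function(col, b) local_average(col - b, lat)
  avg_pol <- vapply(pol_kinds, function(k) avg_d(phi[, k], phi_b[[k]]),
                    numeric(M))
  u_int_W <- drop(avg_pol %*% chi[pol_kinds, "W"])
  ext <- function(k) if (is.null(u_ext)) 0 else u_ext[, k]
  uW <- pmin(pmax(u_int_W + xi + ext("W"), -60), 60)
  NW <- spec$solvent_size
  if (NW == 1) {
    phi[, "W"] <- phi_W_b * exp(-uW)
    logq_W <- NA_real_
  } else {
    GW_w <- matrix(exp(-uW), M, 1)
    pw <- propagate_tree_cpp(c(0L, seq_len(NW - 1L)), rep(1L, NW), GW_w,
                             lat$lambda_m, lat$lambda_0, lat$lambda_p,
                             lat$L)
    # normalisation: dens_kind sums to N_W/q in the far field, so scaling
    # by q/N_W makes phi -> phi_W_b there
    phi[, "W"] <- phi_W_b * exp(pw$logq) * pw$dens_kind[, 1] / NW
    logq_W <- pw$logq
  }

  # ions: non-electrostatic part explicit, psi response handled inside the
  # nonlinear Poisson-Boltzmann solve
  a_Na <- drop(avg_pol %*% chi[pol_kinds, "Na"]) +
    avg_d(phi[, "W"], phi_W_b) * chi["W", "Na"] + xi + ext("Na")
  a_Cl <- drop(avg_pol %*% chi[pol_kinds, "Cl"]) +
    avg_d(phi[, "W"], phi_W_b) * chi["W", "Cl"] + xi + ext("Cl")
  rho_fix <- drop(phi %*% kinds$valency)
  if (!is.null(spec$fixed_charge)) rho_fix <- rho_fix + spec$fixed_charge
  # permittivity: linear mixing over kinds; ions approximated at bulk
  eps <- drop(phi %*% kinds$eps_r) +
    (phi_Na_b + phi_Cl_b) * 0.5 * (kinds$eps_r[kinds$kind == "Na"] +
                                     kinds$eps_r[kinds$kind == "Cl"])
  eps <- pmax(eps, 1)
  pb <- pb_solve(rho_fix, phi_Na_b, phi_Cl_b, a_Na, a_Cl, eps,
                 lat, spec$conversions, psi0 = psi0)
  phi[, "Na"] <- pb$phi_Na
  phi[, "Cl"] <- pb$phi_Cl
  psi <- pb$psi
  rho_e <- rho_fix + phi[, "Na"] - phi[, "Cl"]

  # full interaction potentials for every kind at the current composition
  dphi <- sweep(phi, 2, phi_b)
  avg_dphi <- apply(dphi, 2, local_average, lattice = lat)
  u_int <- avg_dphi %*% chi + outer(psi, kinds$valency)
  colnames(u_int) <- kn

  # the reported u: chain kinds from the slow fields, the rest explicit
  u <- u_int + xi
  u[, pol_kinds] <- u_pol

  sumphi <- rowSums(phi)

  list(phi = phi, phi_b = phi_b, prop = prop,
       phi_surf_b = phi_surf_b, phi_W_b = phi_W_b,
       phi_Na_b = phi_Na_b, phi_Cl_b = phi_Cl_b,
       n_mol = n_mol, rho_e = rho_e, eps = eps, psi = psi,
       u_int = u_int, u = u, pol_kinds = pol_kinds, sumphi = sumphi)
}

# Nucleation pinning potential: an attractive well for the hydrophobic
# segments at the inner boundary, radius from the tail amount but capped
# so that oversized seeds cannot collapse into hollow-shell artifacts.
# Used as a frozen external field during the first solver stage and then
# released (numerical continuation onto the micellar branch).
pin_field <- function(spec, depth = 1) {
  lat <- spec$lattice
  M <- lat$M
  u <- matrix(0, M, 7, dimnames = list(NULL, .KINDS))
  mol <- spec$molecule
  if (is.null(mol) || spec$theta_surf == 0) return(u)
  hydrophobe <- if (any(mol$nodes$part == "tail")) {
    mol$nodes$part == "tail"
  } else mol$nodes$kind == "C"
  theta_tail <- spec$theta_surf * sum(hydrophobe) / n_segments(mol)
  R0 <- switch(lat$geometry,
    spherical   = (3 * theta_tail / (4 * pi))^(1 / 3),
    cylindrical = sqrt(theta_tail / pi),
    planar      = theta_tail)
  R0 <- min(max(1.1 * R0, 2), 0.35 * M)
  core <- layer_centres(lat) <= R0
  u[core, "C"] <- -depth
  # keep the hydrophilic head out of the seed so the pinned droplet is
  # already micelle-like (dense tail core, heads at the rim)
  u[core, c("NH3+", "NH", "O")] <- depth / 2
  u
}

#' Solve the self-consistent field equations
#'
#' Fixed-point iteration on the segment potentials, written in
#' exchange/pressure form \eqn{u_X(r) = w_X(r) + \xi(r)}: the bounded
#' exchange fields \eqn{w_X} relax towards the interaction potential
#' \deqn{u^{int}_X(r) = \sum_Y \chi_{XY}(\langle\phi_Y\rangle(r) -
#'   \phi_Y^b) + \nu_X \psi(r)}
#' under damped mixing, while the pressure field \eqn{\xi(r)} (the
#' incompressibility multiplier \eqn{\alpha}) is driven by
#' \eqn{\ln\sum_X\phi_X(r)} with a strong gain.  Each sweep evaluates the
#' volume fractions from the tree propagators and monomer Boltzmann
#' factors and solves the discrete Poisson equation for \eqn{\psi}.
#' Anderson (DIIS-type) acceleration over the combined
#' \eqn{(w, \xi)} vector speeds up the terminal convergence; diverging
#' accelerated steps fall back to the best damped iterate.  The converged
#' state satisfies self-consistency, incompressibility and the Poisson
#' equation simultaneously.
#'
#' @param spec a \code{\link{system_spec}}
#' @param init optional M x 7 starting potential (e.g. \code{u} from a
#'   previous state); default is a hydrophobic step-profile guess
#' @param tol convergence tolerance on the maximum residual component
#'   (default 1e-7)
#' @param max_iter iteration cap (default 50000)
#' @param mixing damping of the exchange-field Picard steps (default 0.1)
#' @param xi_gain gain of the pressure-field update (default 0.7)
#' @param anderson_depth history depth of Anderson acceleration (default
#'   8; 0 disables acceleration)
#' @param anderson_start iteration at which acceleration begins
#' @param step_cap trust region: maximum change of any field component in
#'   one iteration (default 1 kT)
#' @param nucleate when no \code{init} is given, first converge with a
#'   frozen attractive well on the hydrophobic segments (nucleation
#'   pinning), then release it and re-converge; numerical continuation
#'   onto the micellar branch
#' @param quiet suppress the non-convergence warning
#' @return object of class \code{scf_state}: list with the converged
#'   \code{u}, \code{phi} (M x 7), \code{alpha}, \code{psi}, bulk
#'   fractions (\code{phi_b} per kind and per species), the per-node
#'   density matrix \code{node_dens}, \code{logq}, \code{residual},
#'   \code{iterations}, \code{converged}, and the \code{spec}.
#' @export
solve_scf <- function(spec, init = NULL, tol = 1e-7, max_iter = 50000,
                      mixing = 0.1, xi_gain = 0.7, anderson_depth = 8,
                      anderson_start = 50, step_cap = 1,
                      nucleate = TRUE, quiet = FALSE) {
  lat <- spec$lattice
  M <- lat$M
  pol_kinds <- c("C", "NH3+", "NH", "O")

  pack <- function(w, xi) c(as.vector(w), xi)
  unpack <- function(x) list(w = matrix(x[seq_len(4 * M)], M, 4,
                                        dimnames = list(NULL, pol_kinds)),
                             xi = x[4 * M + seq_len(M)])
  psi_prev <- NULL
  eval_x_outer <- function(x, u_ext, sp_stage = spec) {
    p <- unpack(x)
    w7 <- matrix(0, M, 7, dimnames = list(NULL, .KINDS))
    w7[, pol_kinds] <- p$w
    ev <- scf_evaluate(w7, p$xi, sp_stage, psi0 = psi_prev, u_ext = u_ext)
    rw <- ev$u_int[, pol_kinds] - p$w
    rxi <- log(pmax(ev$sumphi, 1e-10))
    ev$resid <- pack(mixing * rw, xi_gain * rxi)
    ev$residual <- max(max(abs(rw)), max(abs(rxi)))
    ev
  }

  # one fixed-point stage (damped + Anderson acceleration + trust region)
  run_stage <- function(x, u_ext, tol_stage, iter_cap, sp_stage = spec) {
    eval_x <- function(x, u_ext) eval_x_outer(x, u_ext, sp_stage)
    X_hist <- NULL; G_hist <- NULL
    best_res <- Inf; best_x <- x
    trace <- numeric(0)
    ev <- eval_x(x, u_ext)
    psi_prev <<- ev$psi
    it <- 0L
    while (it < iter_cap) {
      it <- it + 1L
      res <- ev$residual
      trace[it] <- res
      if (res < best_res) { best_res <- res; best_x <- x }
      if (res < tol_stage) break

      gv <- ev$resid
      accel <- anderson_depth > 0 && it >= anderson_start &&
        !is.null(X_hist) && ncol(X_hist) >= 1
      if (accel) {
        gamma <- tryCatch({
          A <- crossprod(G_hist)
          diag(A) <- diag(A) * (1 + 1e-10) + 1e-300
          solve(A, crossprod(G_hist, gv))
        }, error = function(e) NULL)
        dx <- if (is.null(gamma)) gv else {
          gv - drop((X_hist + G_hist) %*% gamma)
        }
      } else {
        dx <- gv
      }
      mx <- max(abs(dx))
      if (mx > step_cap) dx <- dx * (step_cap / mx)
      x_new <- x + dx

      ev_new <- tryCatch(eval_x(x_new, u_ext), error = function(e) NULL)
      if (is.null(ev_new) || !is.finite(ev_new$residual) ||
          ev_new$residual > 1e3 * max(best_res, 1e-10)) {
        # diverging step: restart damped from the best iterate
        X_hist <- NULL; G_hist <- NULL
        ev_best <- eval_x(best_x, u_ext)
        dx <- ev_best$resid
        mx <- max(abs(dx))
        if (mx > step_cap / 4) dx <- dx * (step_cap / 4 / mx)
        x_new <- best_x + dx
        ev_new <- eval_x(x_new, u_ext)
      } else {
        X_hist <- cbind(X_hist, x_new - x)
        G_hist <- cbind(G_hist, ev_new$resid - gv)
        if (ncol(X_hist) > anderson_depth) {
          X_hist <- X_hist[, -1, drop = FALSE]
          G_hist <- G_hist[, -1, drop = FALSE]
        }
      }
      x <- x_new; ev <- ev_new
      psi_prev <<- ev$psi
    }
    list(x = x, ev = ev, it = it, trace = trace)
  }

  if (inherits(init, "scf_state")) {
    stopifnot(init$spec$lattice$M == M)
    xi <- init$alpha
    w <- init$u[, pol_kinds] - xi
    x <- pack(w, xi)
    stages <- list(list(spec = spec, u_ext = NULL, tol = tol, cap = max_iter))
  } else if (!is.null(init)) {
    stopifnot(is.matrix(init), nrow(init) == M)
    x <- pack(init[, pol_kinds], numeric(M))
    stages <- list(list(spec = spec, u_ext = NULL, tol = tol, cap = max_iter))
  } else if (nucleate && !is.null(spec$molecule) && spec$theta_surf > 0) {
    # hydrophobicity-ramp continuation: nucleate (pinned) at boosted
    # chi_CW where the micellar branch is robust, then walk chi down to
    # the target value, finishing at full tolerance
    x <- pack(matrix(0, M, 4), numeric(M))
    stages <- list()
    for (dchi in c(0.6, 0.3, 0.15)) {
      sp_d <- spec
      sp_d$table <- perturb_table(spec$table, c("C", "W"), dchi)
      stages[[length(stages) + 1]] <- list(
        spec = sp_d, u_ext = if (dchi == 0.6) pin_field(spec) else NULL,
        tol = max(tol, 1e-4), cap = min(max_iter, 4000))
    }
    stages[[length(stages) + 1]] <- list(spec = spec, u_ext = NULL,
                                         tol = tol, cap = max_iter)
  } else {
    x <- pack(matrix(0, M, 4), numeric(M))
    stages <- list(list(spec = spec, u_ext = NULL, tol = tol, cap = max_iter))
  }

  res_trace <- numeric(0)
  it_total <- 0L
  for (sg in stages) {
    st <- run_stage(x, sg$u_ext, sg$tol, sg$cap, sg$spec)
    x <- st$x; ev <- st$ev
    it_total <- it_total + st$it
    res_trace <- c(res_trace, st$trace)
  }
  it <- it_total

  converged <- ev$residual < tol
  if (!converged && !quiet)
    warning(sprintf("SCF not converged: residual %.3e after %d iterations",
                    ev$residual, it))
  p <- unpack(x)
  state <- list(
    u = ev$u, phi = ev$phi, alpha = p$xi, psi = ev$psi,
    phi_b = ev$phi_b, phi_surf_b = ev$phi_surf_b, phi_W_b = ev$phi_W_b,
    phi_Na_b = ev$phi_Na_b, phi_Cl_b = ev$phi_Cl_b,
    rho_e = ev$rho_e, eps = ev$eps,
    node_dens = if (!is.null(ev$prop)) ev$prop$node_dens else NULL,
    logq = if (!is.null(ev$prop)) ev$prop$logq else NA_real_,
    qdev = if (!is.null(ev$prop)) ev$prop$qdev else NA_real_,
    n_mol = ev$n_mol,
    residual = ev$residual, iterations = it, converged = converged,
    residual_trace = res_trace, spec = spec)
  class(state) <- "scf_state"
  state
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<scf_state> %s lattice M=%d; residual %.2e after %d iterations (%s)\n",
              x$spec$lattice$geometry, x$spec$lattice$M, x$residual,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$spec$molecule))
    cat(sprintf("  theta_surf = %.4g, phi_surf_b = %.4g, n_agg = %.4g\n",
                x$spec$theta_surf, x$phi_surf_b, aggregation_number(x)))
  invisible(x)
}

#' Excess number of surfactant molecules in the aggregate
#'
#' \code{n_agg = (theta_surf - V phi_surf_b) / N}: the surfactant amount in
#' the cell in excess of a homogeneous solution at the bulk fraction,
#' per molecule.  For cylindrical (lamellar) lattices this is an amount
#' per unit length (area).
#'
#' @param state a converged \code{scf_state}
#' @return numeric aggregation number
#' @export
aggregation_number <- function(state) {
  mol <- state$spec$molecule
  if (is.null(mol)) return(0)
  V <- sum(state$spec$lattice$L)
  (state$spec$theta_surf - V * state$phi_surf_b) / n_segments(mol)
}

#' Write a converged state as per-layer CSV
#'
#' Columns: \code{layer}, \code{r} (layer centre), one \code{phi_*} column
#' per segment kind, \code{psi}, \code{alpha}.  Numbers are written with
#' \code{\%.10g} so identical states produce byte-identical files.
#'
#' @param state an \code{scf_state}
#' @param path output file path
#' @return invisibly, the data.frame written
#' @export
write_state_csv <- function(state, path) {
  df <- data.frame(layer = seq_len(state$spec$lattice$M),
                   r = layer_centres(state$spec$lattice))
  phin <- gsub("\\+", "plus", paste0("phi_", colnames(state$phi)))
  for (j in seq_len(ncol(state$phi))) df[[phin[j]]] <- state$phi[, j]
  df$psi <- state$psi
  df$alpha <- state$alpha
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]]))
    out[[j]] <- sprintf("%.10g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
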
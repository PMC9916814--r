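# ---- generic helpers -----------------------------------------------------

#' Strict local maxima of a lattice profile
#'
#' Maxima are detected on the raw profile (no smoothing).  A plateau
#' flanked by lower values on both sides counts as a single maximum at its
#' midpoint; peaks below \code{min_frac} of the global maximum are
#' ignored, as are layers below \code{floor_frac} of the peak (numerical
#' noise floor).
#'
#' @param x numeric profile
#' @param min_frac discard peaks below this fraction of the global max
#' @param floor_frac zero out values below this fraction of the global max
#' @return integer vector of (midpoint) indices of the maxima
#' @export
find_local_maxima <- function(x, min_frac = 0.01, floor_frac = 1e-8) {
  if (all(!is.finite(x)) || max(x, na.rm = TRUE) <= 0) return(integer(0))
  peak <- max(x, na.rm = TRUE)
  x[!is.finite(x) | x < floor_frac * peak] <- 0
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == k) -Inf else r$values[i + 1]
    if (r$values[i] > left && r$values[i] > right &&
        r$values[i] >= min_frac * peak) {
      out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
    }
  }
  out
}

# excess per-layer segment numbers for a set of molecule nodes:
# n(r) = sum_i (n_mol dens_i(r) - phi_surf_b/N) * L(r)
node_excess_numbers <- function(state, node_ids) {
  lat <- state$spec$lattice
  mol <- state$spec$molecule
  N <- n_segments(mol)
  dens <- state$node_dens[, node_ids, drop = FALSE]
  (state$n_mol * rowSums(dens) -
      length(node_ids) * state$phi_surf_b / N) * lat$L
}

# volume-weighted second-moment radius of an excess profile:
# R = sqrt( sum w(r) r_c^2 / sum w(r) )
second_moment_radius <- function(weight, lattice) {
  rc <- layer_centres(lattice)
  w <- pmax(weight, 0)
  if (sum(w) <= 0) return(NA_real_)
  sqrt(sum(w * rc^2) / sum(w))
}

# ---- structural metrics --------------------------------------------------

#' Structural metrics of an equilibrium micelle
#'
#' Computes, from a converged micelle state:
#' \itemize{
#'   \item \code{Rcore}: second-moment radius of the excess hydrophobic
#'     (tail) segment distribution,
#'     \eqn{R = [\sum w(r) r^2 / \sum w(r)]^{1/2}};
#'   \item \code{Rm}: the same moment over the charged terminal groups;
#'   \item \code{Hshell = Rm - Rcore}: corona thickness;
#'   \item \code{s = 4 pi Rcore^2 / n_agg}: area per dendron at the core
#'     surface (spherical lattices only);
#'   \item \code{Nterm}: total excess number of terminal groups,
#'     \eqn{\int n_t(r) dr} (equals \code{n_agg * 2^(G+1)} up to the
#'     bulk-consistency error);
#'   \item \code{core_density = Rcore / (Nt*t*n_agg)^{1/3}}: core packing
#'     measure.
#' }
#' Radii are in lattice units; \code{*_nm} fields give nanometres.
#'
#' @param state a converged micelle \code{scf_state}
#' @param thermo optional \code{micelle_thermo}; only used to report the
#'   interpolated aggregation number alongside
#' @return object of class \code{micelle_metrics} (a list)
#' @export
core_metrics <- function(state, thermo = NULL) {
  mol <- state$spec$molecule
  lat <- state$spec$lattice
  if (is.null(mol)) stop("state has no surfactant molecule")
  nd <- mol$nodes
  w_tail <- node_excess_numbers(state, which(nd$part == "tail"))
  if (sum(pmax(w_tail, 0)) <= 1e-8)
    stop("no hydrophobe excess: no micelle in this state")
  w_term <- node_excess_numbers(state, which(nd$terminal))
  n_agg <- aggregation_number(state)
  Rcore <- second_moment_radius(w_tail, lat)
  Rm <- second_moment_radius(w_term, lat)
  b_nm <- state$spec$conversions$b * 1e9
  met <- list(
    n_agg = n_agg,
    n_agg_interp = if (!is.null(thermo)) thermo$n_agg else NA_real_,
    Rcore = Rcore, Rm = Rm, Hshell = Rm - Rcore,
    s = if (lat$geometry == "spherical") 4 * pi * Rcore^2 / n_agg else NA_real_,
    Nterm = sum(w_term),
    core_density = Rcore / (sum(nd$part == "tail") * n_agg)^(1 / 3),
    Rcore_nm = Rcore * b_nm, Rm_nm = Rm * b_nm,
    Hshell_nm = (Rm - Rcore) * b_nm)
  class(met) <- "micelle_metrics"
  met
}

#' @export
print.micelle_metrics <- function(x, ...) {
  cat(sprintf(
    "<micelle_metrics> n_agg %.2f | Rcore %.2f (%.2f nm) | Hshell %.2f (%.2f nm) | s %.2f | Nterm %.1f\n",
    x$n_agg, x$Rcore, x$Rcore_nm, x$Hshell, x$Hshell_nm, x$s, x$Nterm))
  invisible(x)
}

# ---- electrostatics ------------------------------------------------------

#' Charge distribution analysis of a micelle
#'
#' Lattice version of the shell-resolved net charge
#' \eqn{q(r) = 4\pi[\phi_{term}(r) + \phi_{Na}(r) - \phi_{Cl}(r)] r^2}
#' and its running integral, the cumulative charge
#' \eqn{Q(r) = \int_0^r q(x) dx}.  On the lattice, \code{q(r)} is the
#' excess charge contained in layer r (bulk composition subtracted, so
#' that Q converges) and \code{Q} its cumulative sum; global
#' electroneutrality makes \code{Q} vanish at the outer boundary.
#' The position of the right-most local maximum of \code{Q} is the
#' effective radius \code{Reff}; \code{Qeff = Q(Reff)} the effective
#' (uncompensated) charge; \code{Qbare} the total number of terminal
#' charges; and the zeta potential is \eqn{\zeta = \psi(R_{eff}) kT/e} in
#' Volts.
#'
#' @param state a converged \code{scf_state}
#' @return object of class \code{charge_analysis}: list with profiles
#'   \code{q}, \code{Q}, scalar \code{Reff}, \code{Qeff}, \code{Qbare},
#'   \code{zeta} (Volts), \code{psi_eff} (dimensionless), and
#'   \code{n_maxima} of Q
#' @export
charge_analysis <- function(state) {
  lat <- state$spec$lattice
  phi <- state$phi
  q <- ((phi[, "NH3+"] - state$phi_b[["NH3+"]]) +
          (phi[, "Na"] - state$phi_b[["Na"]]) -
          (phi[, "Cl"] - state$phi_b[["Cl"]])) * lat$L
  Q <- cumsum(q)
  maxima <- find_local_maxima(Q)
  rc <- layer_centres(lat)
  res <- list(q = q, Q = Q, r = rc,
              n_maxima = length(maxima), maxima_r = rc[maxima])
  if (length(maxima) > 0) {
    i_eff <- maxima[length(maxima)]     # the right maximum
    res$Reff <- rc[i_eff]
    res$Qeff <- Q[i_eff]
    res$psi_eff <- state$psi[i_eff]
    res$zeta <- convert_units(state$psi[i_eff], "potential",
                              state$spec$conversions)
  } else {
    res$Reff <- NA_real_; res$Qeff <- NA_real_
    res$psi_eff <- NA_real_; res$zeta <- NA_real_
  }
  mol <- state$spec$molecule
  res$Qbare <- if (!is.null(mol)) {
    aggregation_number(state) * sum(mol$nodes$terminal)
  } else NA_real_
  class(res) <- "charge_analysis"
  res
}

#' @export
print.charge_analysis <- function(x, ...) {
  cat(sprintf(
    "<charge_analysis> %d maximum(a) of Q | Reff %.2f | Qeff %.2f / Qbare %.2f | zeta %.1f mV\n",
    x$n_maxima, x$Reff, x$Qeff, x$Qbare, 1000 * x$zeta))
  invisible(x)
}

# ---- corona stratification -----------------------------------------------

#' Corona stratification diagnostics
#'
#' Groups the corona segment distributions by structural class and tests
#' each for bimodality (two radial populations).  Classes:
#' \itemize{
#'   \item terminal groups by root-to-terminal contour length,
#'   \item branch points by sub-generation,
#'   \item all dendron segments by sub-generation,
#' }
#' plus the total terminal distribution.  A distribution is bimodal when
#' it has at least two strict local maxima after noise-floor filtering
#' (\code{\link{find_local_maxima}}); the split radius is the minimum
#' between the two outermost maxima.
#'
#' @param state a converged micelle \code{scf_state}
#' @return object of class \code{stratification_report}: list with
#'   \code{terminal_total} (profile, maxima, bimodal flag, split radius),
#'   \code{by_contour}, \code{branch_by_gen}, \code{segments_by_gen}
#'   (lists keyed by class), and layer centres \code{r}
#' @export
stratification_report <- function(state) {
  mol <- state$spec$molecule
  lat <- state$spec$lattice
  if (is.null(mol)) stop("state has no surfactant molecule")
  nd <- mol$nodes
  rc <- layer_centres(lat)

  analyze <- function(ids) {
    prof <- node_excess_numbers(state, ids)
    mx <- find_local_maxima(prof)
    split_r <- NA_real_
    if (length(mx) >= 2) {
      i1 <- mx[length(mx) - 1]; i2 <- mx[length(mx)]
      gap <- seq(i1, i2)
      split_r <- rc[gap[which.min(prof[gap])]]
    }
    list(profile = prof, maxima_r = rc[mx], n_maxima = length(mx),
         bimodal = length(mx) >= 2, split_r = split_r, n_nodes = length(ids))
  }

  term_ids <- which(nd$terminal)
  by_contour <- lapply(split(term_ids, nd$contour[term_ids]), analyze)
  branch_ids <- which(nd$branch)
  branch_by_gen <- lapply(split(branch_ids, nd$gen[branch_ids]), analyze)
  dend_ids <- which(nd$part == "dendron")
  segments_by_gen <- lapply(split(dend_ids, nd$gen[dend_ids]), analyze)

  rep <- list(r = rc,
              terminal_total = analyze(term_ids),
              by_contour = by_contour,
              branch_by_gen = branch_by_gen,
              segments_by_gen = segments_by_gen)
  class(rep) <- "stratification_report"
  rep
}

#' @export
print.stratification_report <- function(x, ...) {
  tt <- x$terminal_total
  cat(sprintf("<stratification_report> terminal groups: %d maxima (%s)\n",
              tt$n_maxima,
              if (tt$bimodal) "stratified" else "single population"))
  cat(sprintf("  contour classes: %s; bimodal: %s\n",
              paste(names(x$by_contour), collapse = ", "),
              paste(vapply(x$by_contour, function(z) z$bimodal, TRUE),
                    collapse = ", ")))
  invisible(x)
}
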
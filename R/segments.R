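#' Segment kinds of the united-atom model
#'
#' The model distinguishes seven united-atom segment kinds: water \code{W},
#' hydrophobic carbon \code{C} (CH, CH2, CH3), the charged terminal amino
#' group \code{NH3+}, the neutral backbone groups \code{NH} and \code{O},
#' and the monovalent salt ions \code{Na} (co-ion) and \code{Cl}
#' (counterion).  Each kind carries an integer valency (elementary charges)
#' and a relative dielectric permittivity used in the lattice Poisson
#' equation.
#'
#' @return A data.frame with columns \code{kind}, \code{valency},
#'   \code{eps_r}, one row per segment kind.
#' @export
#' @examples
#' segment_kinds()
segment_kinds <- function() {
  data.frame(
    kind    = c("W", "C", "NH3+", "NH", "O", "Na", "Cl"),
    valency = c(0L, 0L, 1L, 0L, 0L, 1L, -1L),
    eps_r   = c(80, 2, 5, 5, 5, 10, 10),
    stringsAsFactors = FALSE
  )
}

#' Default Flory-Huggins interaction table
#'
#' Returns the default set of dimensionless Flory-Huggins parameters
#' \eqn{\chi_{XY}} (in units of kT) between the seven segment kinds,
#' together with the valency/permittivity table.  The driving force of
#' self-assembly is the water--carbon repulsion \eqn{\chi_{C,W} = 1.2};
#' the hydrogen-bonding groups NH and O are water-attracting
#' (\eqn{\chi = -0.6}); all head groups and ions are strongly expelled
#' from the hydrocarbon core (\eqn{\chi_{C,X} = 2} or 3).
#'
#' @return An object of class \code{interaction_table}: a list with
#'   \itemize{
#'     \item \code{chi}: symmetric 7x7 numeric matrix with zero diagonal,
#'       dimnames the segment kinds;
#'     \item \code{kinds}: the \code{\link{segment_kinds}} data.frame.
#'   }
#' @export
#' @examples
#' tab <- default_interactions()
#' tab$chi["C", "W"]   # 1.2
default_interactions <- function() {
  kinds <- segment_kinds()
  kn <- kinds$kind
  chi <- matrix(0, 7, 7, dimnames = list(kn, kn))
  chi["W", "C"] <- 1.2
  chi["W", "NH"] <- -0.6
  chi["W", "O"] <- -0.6
  chi["C", "NH3+"] <- 3
  chi["C", "NH"] <- 2
  chi["C", "O"] <- 2
  chi["C", "Na"] <- 2
  chi["C", "Cl"] <- 2
  chi <- chi + t(chi)
  new_interaction_table(chi, kinds)
}

new_interaction_table <- function(chi, kinds = segment_kinds()) {
  validate_interaction_table(chi, kinds)
  structure(list(chi = chi, kinds = kinds), class = "interaction_table")
}

validate_interaction_table <- function(chi, kinds) {
  kn <- kinds$kind
  stopifnot(is.matrix(chi), nrow(chi) == length(kn), ncol(chi) == length(kn))
  if (!identical(rownames(chi), kn) || !identical(colnames(chi), kn))
    stop("interaction matrix must be indexed by the segment kinds")
  if (max(abs(chi - t(chi))) > 0)
    stop("interaction matrix must be symmetric")
  if (any(diag(chi) != 0))
    stop("interaction matrix must have a zero diagonal")
  invisible(TRUE)
}

#' Symmetrically perturb one entry of an interaction table
#'
#' Used for sensitivity studies, e.g. sweeping \eqn{\chi_{C,W}} to verify
#' that stronger hydrophobicity strengthens aggregation.
#'
#' @param table an \code{interaction_table}
#' @param pair character vector of two segment kind names
#' @param delta numeric perturbation added to \eqn{\chi_{XY}} and
#'   \eqn{\chi_{YX}}
#' @return a new \code{interaction_table}
#' @export
perturb_table <- function(table, pair, delta) {
  stopifnot(inherits(table, "interaction_table"),
            length(pair) == 2, all(pair %in% table$kinds$kind))
  if (pair[1] == pair[2] && delta != 0)
    stop("cannot perturb a diagonal entry: chi_XX must stay 0")
  chi <- table$chi
  chi[pair[1], pair[2]] <- chi[pair[1], pair[2]] + delta
  if (pair[1] != pair[2])
    chi[pair[2], pair[1]] <- chi[pair[2], pair[1]] + delta
  new_interaction_table(chi, table$kinds)
}

#' Physical unit conversions
#'
#' Collects the constants that map the dimensionless lattice results onto
#' physical units: the lattice cell size \code{b} (metres), the
#' density-to-molarity factor \code{k} (\code{[M] = k * phi}), and the
#' temperature \code{T} (Kelvin).  With the defaults, a dimensionless salt
#' fraction of 0.01 corresponds to 0.1 M, and one lattice unit of length is
#' 0.3 nm.
#'
#' @param b lattice cell size in metres (default \code{3e-10})
#' @param k dimensionless-density to molar conversion factor (default 10)
#' @param temperature temperature in Kelvin (default 298)
#' @return object of class \code{unit_conversions}
#' @export
unit_conversions <- function(b = 3e-10, k = 10, temperature = 298) {
  stopifnot(b > 0, k > 0, temperature > 0)
  structure(list(b = b, k = k, temperature = temperature),
            class = "unit_conversions")
}

#' Convert a dimensionless lattice quantity to physical units
#'
#' @param value numeric, the dimensionless value(s)
#' @param kind one of \code{"length"} (result in metres),
#'   \code{"concentration"} (result in mol/L), \code{"potential"}
#'   (dimensionless e*psi/kT to Volts)
#' @param conversions a \code{\link{unit_conversions}} object
#' @return numeric physical value
#' @export
#' @examples
#' convert_units(0.01, "concentration")  # 0.1 M
#' convert_units(10, "length") * 1e9     # 3 nm
convert_units <- function(value, kind = c("length", "concentration", "potential"),
                          conversions = unit_conversions()) {
  kind <- match.arg(kind)
  kB <- 1.380649e-23
  e  <- 1.602176634e-19
  switch(kind,
    length        = value * conversions$b,
    concentration = value * conversions$k,
    potential     = value * kB * conversions$temperature / e)
}

# Dimensionless electrostatic prefactor e^2 / (eps0 kB T b): multiplies the
# charge density (e per site) in the lattice Poisson equation for the
# reduced potential psi = e*Psi/kT.
# With the defaults c0 ~ 2347, equivalent to the Bjerrum length of water
# l_B = c0 b/(4 pi eps_r) = 0.70 nm at eps_r = 80.
electrostatic_prefactor <- function(conversions = unit_conversions()) {
  e    <- 1.602176634e-19
  kB   <- 1.380649e-23
  eps0 <- 8.8541878128e-12
  e^2 / (eps0 * kB * conversions$temperature * conversions$b)
}
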
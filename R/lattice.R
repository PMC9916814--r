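#' One-dimensional curved lattice
#'
#' Builds the layered lattice used by the SCF equations in planar,
#' cylindrical, or spherical geometry.  Layer \code{r} (1..M) occupies the
#' region between radii \code{r-1} and \code{r} (in lattice units); the
#' micelle centre sits at the inner boundary, the outer boundary is bulk
#' solution.  \code{L(r)} is the number of sites (dimensionless volume) of
#' layer \code{r}: 1 (planar, per unit area), \code{pi*(2r-1)} (cylindrical,
#' per unit length), \code{(4*pi/3)*(r^3-(r-1)^3)} (spherical).
#'
#' Step probabilities follow the simple-cubic convention: a fraction
#' \code{lambda1 = 1/6} of contacts points to each neighbouring layer in
#' the planar case, with curvature corrections proportional to the contact
#' area \code{A} between adjacent shells:
#' \code{lambda_plus(r) = lambda1 * A(r)/L(r)},
#' \code{lambda_minus(r) = lambda1 * A(r-1)/L(r)}.  This guarantees the
#' detailed flux balance \code{L(r) lambda_plus(r) = L(r+1)
#' lambda_minus(r+1)} and \code{lambda_minus + lambda_0 + lambda_plus = 1}.
#'
#' @param geometry \code{"planar"}, \code{"cylindrical"} or
#'   \code{"spherical"}
#' @param M number of layers, >= 3
#' @param lambda1 fraction of bonds towards one adjacent layer in the
#'   planar limit (default 1/6, simple cubic)
#' @return object of class \code{lattice_geometry}: list with
#'   \code{geometry}, \code{M}, \code{L}, \code{A} (contact areas at the
#'   outer edge of each layer, \code{A[r]} between layers r and r+1;
#'   \code{A0} the inner edge area), \code{lambda_m}, \code{lambda_0},
#'   \code{lambda_p}, \code{lambda1}.
#' @export
#' @examples
#' lat <- make_lattice("spherical", 50)
#' all.equal(lat$L, (4 * pi / 3) * ((1:50)^3 - (0:49)^3))
make_lattice <- function(geometry = c("planar", "cylindrical", "spherical"),
                         M, lambda1 = 1 / 6) {
  geometry <- match.arg(geometry)
  if (length(M) != 1 || M < 3 || M != round(M)) stop("M must be an integer >= 3")
  M <- as.integer(M)
  r <- seq_len(M)
  # A(x): contact area at radius x; L(r) = volume between r-1 and r
  switch(geometry,
    planar = {
      # A0 = 1: the inward step exists but is reflected by the mirror
      # boundary handling of local_average / the propagators
      L <- rep(1, M); A <- rep(1, M); A0 <- 1
    },
    cylindrical = {
      L <- pi * (2 * r - 1); A <- 2 * pi * r; A0 <- 0
    },
    spherical = {
      L <- (4 * pi / 3) * (r^3 - (r - 1)^3); A <- 4 * pi * r^2; A0 <- 0
    })
  Ain <- c(A0, A[-M])               # inner edge area of each layer
  lambda_p <- lambda1 * A / L
  lambda_m <- lambda1 * Ain / L
  # planar mirror: the inward fraction at r=1 reflects onto the layer itself,
  # handled by A0 = 0 plus keeping lambda_0 = 1 - lambda_m - lambda_p, so
  # that the reflected weight stays in layer 1.
  lambda_0 <- 1 - lambda_m - lambda_p
  if (any(lambda_0 < 0))
    stop("negative lateral step probability; lambda1 too large for this geometry")
  structure(list(geometry = geometry, M = M, L = L, A = A, A0 = A0,
                 lambda_m = lambda_m, lambda_0 = lambda_0,
                 lambda_p = lambda_p, lambda1 = lambda1),
            class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("<lattice_geometry> %s, M = %d layers, V = %.6g sites\n",
              x$geometry, x$M, sum(x$L)))
  invisible(x)
}

#' Layer centre coordinates
#' @param lattice a \code{lattice_geometry}
#' @return numeric vector \code{r - 1/2} for layers 1..M
#' @export
layer_centres <- function(lattice) seq_len(lattice$M) - 0.5

#' Three-layer local average
#'
#' Applies the lattice transfer operator
#' \eqn{\langle f\rangle(r) = \lambda_-(r) f(r-1) + \lambda_0(r) f(r) +
#' \lambda_+(r) f(r+1)} used in the contact-energy terms and the chain
#' propagators.  Both boundaries are treated as mirrors
#' (\code{f(0) := f(1)}, \code{f(M+1) := f(M)}), so a constant profile is
#' left unchanged; the outer layers are expected to sit at bulk values.
#'
#' @param profile numeric vector of length \code{M}
#' @param lattice a \code{lattice_geometry}
#' @return numeric vector of length \code{M}
#' @export
local_average <- function(profile, lattice) {
  M <- lattice$M
  if (length(profile) != M) stop("profile length must equal the layer count")
  up   <- c(profile[-1], profile[M])
  down <- c(profile[1], profile[-M])
  lattice$lambda_m * down + lattice$lambda_0 * profile + lattice$lambda_p * up
}

#' Discrete Poisson solver on the curved lattice
#'
#' Solves the flux-form discrete Poisson equation for the reduced
#' electrostatic potential \eqn{\psi = e\Psi/kT}:
#' \deqn{\epsilon_{r+1/2} A_r (\psi_{r+1}-\psi_r) -
#'       \epsilon_{r-1/2} A_{r-1} (\psi_r-\psi_{r-1}) = -c_0\, \sigma_r}
#' where \eqn{\sigma_r} is the charge (elementary charges) contained in
#' layer r, \eqn{A} are the shell contact areas, interface permittivities
#' are arithmetic means of adjacent layers, and
#' \eqn{c_0 = e^2/(\epsilon_0 k T b)} is the dimensionless electrostatic
#' prefactor.  Boundary conditions: zero field at the inner boundary
#' (natural, \code{A0 = 0}) and Dirichlet \eqn{\psi(M) = 0} at the outer
#' (bulk) boundary.  Summing the equation over layers 1..R reproduces the
#' discrete Gauss law, which the test-suite uses as an independent oracle.
#'
#' @param charge numeric length-M: net charge density per site (e/site)
#' @param eps_r numeric length-M: relative permittivity per layer (> 0)
#' @param lattice a \code{lattice_geometry}
#' @param conversions \code{\link{unit_conversions}} fixing the prefactor
#' @return numeric length-M reduced potential \eqn{\psi}
#' @export
poisson_solve <- function(charge, eps_r, lattice,
                          conversions = unit_conversions()) {
  M <- lattice$M
  if (length(charge) != M || length(eps_r) != M)
    stop("charge and permittivity profiles must have length M")
  if (any(eps_r <= 0)) stop("permittivity must be positive everywhere")
  c0 <- electrostatic_prefactor(conversions)
  sigma <- charge * lattice$L          # charge per layer
  # conductances g[r] = eps_{r+1/2} * A_r linking layers r and r+1
  g <- c(0.5 * (eps_r[-M] + eps_r[-1]) * lattice$A[-M], 0)
  lower <- g[-M]                        # coupling (r, r-1) for r = 2..M
  diag_ <- c(g[1], g[-M] + g[-1])       # note A0 = 0: no inner coupling
  rhs <- c0 * sigma
  # Dirichlet at M: psi_M = 0
  diag_[M] <- 1; lower[M - 1] <- 0; rhs[M] <- 0
  upper <- g[-M]; upper[M - 1] <- 0
  thomas_solve(lower, diag_, upper, rhs)
}

# Tridiagonal solve: lower[i] couples row i+1 to i, upper[i] row i to i+1.
# Sign convention: system is  -lower*x[i-1] + diag*x[i] - upper*x[i+1] = rhs
thomas_solve <- function(lower, diag_, upper, rhs) {
  n <- length(diag_)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- -upper[1] / diag_[1]
  dp[1] <- rhs[1] / diag_[1]
  for (i in 2:n) {
    m <- diag_[i] + lower[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) -upper[i] / m else 0
    dp[i] <- (rhs[i] + lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}
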
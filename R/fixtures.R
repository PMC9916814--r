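# ---- generic chain constructors (used by fixtures and tests) -------------

#' Build an arbitrary chain graph from kinds and parent pointers
#'
#' Low-level constructor for toy molecules (linear chains, stars,
#' hand-built trees).  Nodes must be in topological order (parent before
#' child, root parent 0).  Terminal flags are set on leaf \code{NH3+}
#' segments; generation/part annotations are left unset.
#'
#' @param kinds character vector of segment kinds
#' @param parent integer vector of parent ids (0 for the root); default is
#'   a linear chain
#' @return a \code{chain_graph} (without dendron-specific annotations)
#' @export
chain_graph <- function(kinds, parent = c(0L, seq_len(length(kinds) - 1L))) {
  n <- length(kinds)
  stopifnot(length(parent) == n, parent[1] == 0, all(parent < seq_len(n)))
  if (!all(kinds %in% segment_kinds()$kind))
    stop("unknown segment kinds: ",
         paste(setdiff(kinds, segment_kinds()$kind), collapse = ", "))
  is_leaf <- !(seq_len(n) %in% parent)
  nodes <- data.frame(id = seq_len(n), parent = as.integer(parent),
                      kind = kinds, part = "chain", gen = NA_integer_,
                      branch = tabulate(parent, n) > 1,
                      terminal = is_leaf & kinds == "NH3+",
                      contour = NA_integer_, stringsAsFactors = FALSE)
  # contour distances from root
  for (i in seq_len(n))
    nodes$contour[i] <- if (parent[i] == 0) 0L else nodes$contour[parent[i]] + 1L
  structure(list(nodes = nodes, G = NA_integer_, t = NA_integer_,
                 Nt = NA_integer_, repeat_unit = NULL),
            class = "chain_graph")
}

#' Linear homopolymer or block chain
#' @param kinds character vector of kinds along the chain
#' @return a \code{chain_graph}
#' @export
linear_chain <- function(kinds) chain_graph(kinds)

# all rooted trees on n nodes as parent vectors (parent[i] < i); includes
# every tree shape (possibly with repeats under isomorphism)
all_parent_trees <- function(n) {
  if (n == 1) return(list(0L))
  sub <- all_parent_trees(n - 1)
  out <- list()
  for (p in sub) for (par in seq_len(n - 1))
    out[[length(out) + 1]] <- c(p, as.integer(par))
  out
}

# ---- fixture registry ----------------------------------------------------

#' Deterministic test fixtures
#'
#' A registry of small, fully synthetic systems that exercise every stage
#' of the pipeline without external data.  Each fixture is a list with
#' \code{name}, \code{value}, human-readable \code{annotations}, and a
#' \code{validate(value)} function asserting the annotations.
#'
#' Registered names:
#' \itemize{
#'   \item \code{"toy-linear-diblock"}: 6-segment chain, 3 hydrophobic C +
#'     3 water-philic NH segments;
#'   \item \code{"symmetric-dendron-G2"}: G=2 dendron whose repeat unit
#'     has equal arms, so all terminals share one contour class;
#'   \item \code{"lysine-G1-t2-Nt12"}: the default two-tailed G=1
#'     molecule (4 charged terminals, 24 tail carbons);
#'   \item \code{"enumeration-trees"}: every parent-vector tree with up to
#'     6 nodes, for the brute-force propagator oracle;
#'   \item \code{"hand-profiles-doublelayer"}: hand-built charged-shell
#'     plus counterion-cloud profiles with a single cumulative-charge
#'     maximum;
#'   \item \code{"hand-profiles-stratified"}: hand-built two-population
#'     terminal profile;
#'   \item \code{"paper-default-table"}: the default interaction table.
#' }
#'
#' @param name registered fixture name
#' @return a fixture list
#' @export
make_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop("unknown fixture '", name, "'; known: ",
         paste(names(reg), collapse = ", "))
  }
  fx <- reg[[name]]()
  fx$name <- name
  fx
}

#' Names of all registered fixtures
#' @return character vector
#' @export
fixture_names <- function() names(fixture_registry())

#' Run a fixture's self-validation
#' @param fx a fixture from \code{\link{make_fixture}}
#' @return TRUE invisibly; errors if an annotation fails
#' @export
validate_fixture <- function(fx) {
  stopifnot(is.list(fx), is.function(fx$validate))
  fx$validate(fx$value)
  invisible(TRUE)
}

fixture_registry <- function() {
  list(
    "toy-linear-diblock" = function() {
      val <- linear_chain(c(rep("C", 3), rep("NH", 3)))
      list(value = val,
           annotations = "6-segment amphiphile; aggregates only if chi_CW is raised",
           validate = function(v) {
             stopifnot(n_segments(v) == 6,
                       kind_counts(v)[["C"]] == 3,
                       kind_counts(v)[["NH"]] == 3)
           })
    },
    "symmetric-dendron-G2" = function() {
      ru <- list(branch_kind = "C",
                 short_arm = c("NH", "C", "O"), long_arm = c("NH", "C", "O"),
                 short_term = "NH3+", long_term = "NH3+")
      val <- build_molecule(2, 1, 1, repeat_unit = ru)
      list(value = val,
           annotations = "equal arms: all terminals in one contour class",
           validate = function(v) {
             cc <- contour_classes(v)
             stopifnot(length(unique(cc$contour)) == 1,
                       nrow(cc) == 2^(2 + 1))
           })
    },
    "lysine-G1-t2-Nt12" = function() {
      val <- build_molecule(1, 2, 12)
      list(value = val,
           annotations = "4 terminal NH3+ groups, 24 tail C segments",
           validate = function(v) {
             stopifnot(sum(v$nodes$terminal) == 4,
                       sum(v$nodes$part == "tail") == 24)
           })
    },
    "enumeration-trees" = function() {
      trees <- list()
      kn <- setdiff(segment_kinds()$kind, c("W", "Na", "Cl"))
      for (n in 1:6) for (p in all_parent_trees(n)) {
        kinds <- kn[(seq_len(n) - 1) %% length(kn) + 1]
        trees[[length(trees) + 1]] <- chain_graph(kinds, p)
      }
      list(value = trees,
           annotations = "all parent-vector trees with <= 6 nodes",
           validate = function(v) {
             stopifnot(length(v) == 1 + 1 + 2 + 6 + 24 + 120,
                       all(vapply(v, function(g) nrow(g$nodes) <= 6, TRUE)))
           })
    },
    "hand-profiles-doublelayer" = function() {
      lat <- make_lattice("spherical", 30)
      M <- lat$M
      phi_term <- numeric(M); phi_term[10] <- 50 / lat$L[10]  # +50 e shell
      phi_Na <- numeric(M)
      phi_Cl <- numeric(M)
      # diffuse neutralising cloud outside the shell
      w <- exp(-(11:20 - 11) / 3); w <- 50 * w / sum(w)
      phi_Cl[11:20] <- w / lat$L[11:20]
      val <- list(lattice = lat, phi_term = phi_term,
                  phi_Na = phi_Na, phi_Cl = phi_Cl)
      list(value = val,
           annotations = "single Q maximum at the shell radius; Qeff = 50",
           validate = function(v) {
             q <- (v$phi_term + v$phi_Na - v$phi_Cl) * v$lattice$L
             Q <- cumsum(q)
             mx <- find_local_maxima(Q)
             stopifnot(length(mx) == 1, mx == 10,
                       abs(Q[mx] - 50) < 1e-9,
                       abs(Q[v$lattice$M]) < 1e-9)
           })
    },
    "hand-profiles-stratified" = function() {
      lat <- make_lattice("spherical", 40)
      rc <- layer_centres(lat)
      nt <- 10 * exp(-(rc - 12)^2 / 4) + 6 * exp(-(rc - 28)^2 / 8)
      val <- list(lattice = lat, nt = nt)
      list(value = val,
           annotations = "two-population terminal profile: 2 maxima",
           validate = function(v) {
             mx <- find_local_maxima(v$nt)
             stopifnot(length(mx) == 2)
           })
    },
    "paper-default-table" = function() {
      val <- default_interactions()
      list(value = val,
           annotations = "default chi / valency / permittivity table",
           validate = function(v) {
             stopifnot(v$chi["C", "W"] == 1.2,
                       v$kinds$valency[v$kinds$kind == "Cl"] == -1)
           })
    }
  )
}
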
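#' Default lysine repeat-unit template
#'
#' A lysine residue in a dendron is a branch point (the alpha carbon, kind
#' \code{C}) with two outgoing arms of unequal contour length: a short arm
#' on the alpha-amino side and a long arm on the epsilon-amino side (four
#' extra CH2 units).  Between two consecutive branch points each arm passes
#' through the amide linkage of the next residue (\code{NH}, carbonyl
#' \code{C}, \code{O}); at the last generation each arm terminates in a
#' charged \code{NH3+} group.  The template is configurable because only
#' the segment kinds and the short/long asymmetry are fixed by the
#' united-atom picture, not the exact counts; the default below is the one
#' the package is tested with.
#'
#' @return list with components \code{branch_kind}, \code{short_arm},
#'   \code{long_arm} (segment-kind vectors between branch points),
#'   \code{short_term}, \code{long_term} (terminal arm kinds ending in the
#'   charged group).
#' @export
lysine_repeat_unit <- function() {
  list(
    branch_kind = "C",
    short_arm   = c("NH", "C", "O"),
    long_arm    = c("C", "C", "C", "C", "NH", "C", "O"),
    short_term  = c("NH3+"),
    long_term   = c("C", "C", "C", "C", "NH3+")
  )
}

validate_repeat_unit <- function(ru) {
  need <- c("branch_kind", "short_arm", "long_arm", "short_term", "long_term")
  if (!all(need %in% names(ru)))
    stop("malformed repeat unit: needs ", paste(need, collapse = ", "))
  kn <- segment_kinds()$kind
  segs <- c(ru$branch_kind, ru$short_arm, ru$long_arm, ru$short_term, ru$long_term)
  if (!all(segs %in% kn))
    stop("repeat unit uses unknown segment kinds: ",
         paste(setdiff(segs, kn), collapse = ", "))
  for (arm in c("short_term", "long_term")) {
    if (utils::tail(ru[[arm]], 1) != "NH3+")
      stop("terminal arms must end in the charged NH3+ group")
  }
  invisible(TRUE)
}

#' Build a dendron-tail hybrid surfactant molecule
#'
#' Constructs the united-atom chain graph of a hybrid amphiphile: one
#' lysine dendron of generation \code{G} whose root carries \code{t} linear
#' hydrophobic tails of \code{Nt} carbon segments each.  The dendron is a
#' binary tree of lysine repeat units; generation \code{G} has
#' \code{2^(G+1)} charged terminal groups.
#'
#' @param G generation number of the dendron head, integer >= 0
#' @param t number of hydrophobic tails attached to the dendron root,
#'   integer >= 1
#' @param Nt number of \code{C} segments per tail, integer >= 1
#' @param repeat_unit repeat-unit template, see
#'   \code{\link{lysine_repeat_unit}}
#' @return An object of class \code{chain_graph}: a list with
#'   \itemize{
#'     \item \code{nodes}: data.frame with one row per segment, columns
#'       \code{id}, \code{parent} (0 for the root), \code{kind},
#'       \code{part} (\code{"dendron"} or \code{"tail"}), \code{gen}
#'       (sub-generation index, \code{NA} for tails), \code{branch}
#'       (logical, dendron branch point), \code{terminal} (logical,
#'       charged terminal group), \code{contour} (segment distance from
#'       the root);
#'     \item \code{G}, \code{t}, \code{Nt}, \code{repeat_unit}.
#'   }
#'   Parents always precede children (topological order).
#' @export
#' @examples
#' mol <- build_molecule(G = 1, t = 2, Nt = 12)
#' sum(mol$nodes$terminal)            # 4 charged end groups
#' sum(mol$nodes$part == "tail")      # 24 tail carbons
build_molecule <- function(G, t, Nt, repeat_unit = lysine_repeat_unit()) {
  if (length(G) != 1 || G < 0 || G != round(G)) stop("G must be an integer >= 0")
  if (length(t) != 1 || t < 1 || t != round(t)) stop("t must be an integer >= 1")
  if (length(Nt) != 1 || Nt < 1 || Nt != round(Nt)) stop("Nt must be an integer >= 1")
  validate_repeat_unit(repeat_unit)

  kind <- character(0); parent <- integer(0); part <- character(0)
  gen <- integer(0); branch <- logical(0); terminal <- logical(0)
  contour <- integer(0)

  add_node <- function(k, p, pt, g, br, tm) {
    kind <<- c(kind, k); parent <<- c(parent, p); part <<- c(part, pt)
    gen <<- c(gen, g); branch <<- c(branch, br); terminal <<- c(terminal, tm)
    contour <<- c(contour, if (p == 0L) 0L else contour[p] + 1L)
    length(kind)
  }
  # a linear run of segments; returns id of the last one
  add_run <- function(kinds, p, pt, g) {
    for (k in kinds) p <- add_node(k, p, pt, g, FALSE, FALSE)
    p
  }
  # terminal arm: all but the last are plain spacers, last is the charged group
  add_term_arm <- function(kinds, p, g) {
    n <- length(kinds)
    if (n > 1) p <- add_run(kinds[-n], p, "dendron", g)
    add_node(kinds[n], p, "dendron", g, FALSE, TRUE)
  }
  # recursive dendron unit at level g attached above node p
  add_unit <- function(p, g) {
    b <- add_node(repeat_unit$branch_kind, p, "dendron", g, TRUE, FALSE)
    if (g == G) {
      add_term_arm(repeat_unit$short_term, b, g)
      add_term_arm(repeat_unit$long_term, b, g)
    } else {
      s <- add_run(repeat_unit$short_arm, b, "dendron", g + 1L)
      add_unit(s, g + 1L)
      l <- add_run(repeat_unit$long_arm, b, "dendron", g + 1L)
      add_unit(l, g + 1L)
    }
    b
  }

  root <- add_unit(0L, 0L)
  for (i in seq_len(t)) add_run(rep("C", Nt), root, "tail", NA_integer_)

  nodes <- data.frame(id = seq_along(kind), parent = parent, kind = kind,
                      part = part, gen = gen, branch = branch,
                      terminal = terminal, contour = contour,
                      stringsAsFactors = FALSE)
  mol <- structure(list(nodes = nodes, G = as.integer(G), t = as.integer(t),
                        Nt = as.integer(Nt), repeat_unit = repeat_unit),
                   class = "chain_graph")
  validate_chain_graph(mol)
  mol
}

validate_chain_graph <- function(mol) {
  nd <- mol$nodes
  if (any(nd$parent >= nd$id)) stop("nodes must be in topological order")
  if (sum(nd$parent == 0L) != 1) stop("chain graph must have exactly one root")
  nterm <- sum(nd$terminal)
  if (nterm != 2^(mol$G + 1))
    stop("terminal group count ", nterm, " != 2^(G+1) = ", 2^(mol$G + 1))
  if (any(nd$kind[nd$terminal] != "NH3+"))
    stop("terminal groups must be NH3+")
  ntail <- sum(nd$part == "tail")
  if (ntail != mol$t * mol$Nt)
    stop("tail segment count ", ntail, " != t*Nt = ", mol$t * mol$Nt)
  invisible(TRUE)
}

#' Number of segments in a molecule
#' @param mol a \code{chain_graph}
#' @return integer segment count
#' @export
n_segments <- function(mol) nrow(mol$nodes)

#' Per-kind segment counts of a molecule
#' @param mol a \code{chain_graph}
#' @return named integer vector over all seven segment kinds (zeros kept)
#' @export
kind_counts <- function(mol) {
  kn <- segment_kinds()$kind
  cnt <- table(factor(mol$nodes$kind, levels = kn))
  stats::setNames(as.integer(cnt), kn)
}

#' Root-to-terminal contour lengths
#'
#' Assigns every charged terminal group its contour distance from the root
#' (in segments).  The asymmetry of the lysine repeat unit makes these
#' lengths spread over several distinct classes, which the corona
#' stratification diagnostics group by.
#'
#' @param mol a \code{chain_graph}
#' @return data.frame with columns \code{id} (terminal node id) and
#'   \code{contour}; the distinct \code{contour} values define the classes
#' @export
contour_classes <- function(mol) {
  nd <- mol$nodes
  out <- nd[nd$terminal, c("id", "contour")]
  rownames(out) <- NULL
  out
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("<chain_graph> dendron G=%d with %d tail(s) of Nt=%d\n",
              x$G, x$t, x$Nt))
  cat(sprintf("  %d segments (%d dendron + %d tail), %d charged terminals\n",
              n_segments(x), sum(x$nodes$part == "dendron"),
              sum(x$nodes$part == "tail"), sum(x$nodes$terminal)))
  invisible(x)
}

# Per-kind composition as fractions of the molecule (used by the bulk
# chemical potential).
kind_fractions <- function(mol) kind_counts(mol) / n_segments(mol)

#' Serialize a molecule or interaction table to a plain list / JSON
#'
#' @param x a \code{chain_graph} or \code{interaction_table}
#' @return a plain list suitable for \code{jsonlite::toJSON}
#' @export
as_config <- function(x) UseMethod("as_config")

#' @export
as_config.chain_graph <- function(x) {
  list(type = "chain_graph", G = x$G, t = x$t, Nt = x$Nt,
       repeat_unit = x$repeat_unit)
}

#' @export
as_config.interaction_table <- function(x) {
  list(type = "interaction_table", kinds = x$kinds, chi = x$chi)
}

#' Rebuild a molecule from its serialized configuration
#' @param cfg list produced by \code{\link{as_config}} (possibly via JSON)
#' @return a \code{chain_graph}
#' @export
molecule_from_config <- function(cfg) {
  ru <- lapply(cfg$repeat_unit, unlist)
  build_molecule(cfg$G, cfg$t, cfg$Nt, repeat_unit = ru)
}
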
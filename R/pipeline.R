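# ---- configuration -------------------------------------------------------

.CONFIG_SCHEMA <- list(
  molecule = c("G", "t", "Nt"),
  lattice  = c("geometry", "M"),
  solution = c("phi_salt_b", "b", "k", "temperature"),
  solver   = c("tol", "max_iter", "mixing"),
  study    = c("mode", "theta", "theta_min", "theta_max", "per_decade",
               "Nt_values", "geometries", "G_values", "t_values", "refine")
)

#' Read a run configuration
#'
#' Configurations are plain text, either JSON or a simple sectioned
#' key-value format:
#' \preformatted{
#' [molecule]
#' G = 1
#' t = 2
#' Nt = 12
#' [study]
#' mode = single
#' theta = 2000
#' }
#' Unknown sections or keys are rejected.  Values are parsed as numbers
#' where possible; comma-separated values become vectors.
#'
#' @param path file path (\code{.json} parsed as JSON, anything else as
#'   sectioned key-value text)
#' @return validated nested configuration list
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    cfg <- list(); section <- NULL
    for (ln in lines) {
      if (grepl("^\\[.*\\]$", ln)) {
        section <- gsub("^\\[|\\]$", "", ln)
        cfg[[section]] <- list()
      } else if (grepl("=", ln, fixed = TRUE)) {
        if (is.null(section)) stop("key before any [section]: ", ln)
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        key <- trimws(kv[1])
        raw <- trimws(paste(kv[-1], collapse = "="))
        vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
        num <- suppressWarnings(as.numeric(vals))
        cfg[[section]][[key]] <- if (any(is.na(num))) vals else num
      } else stop("unparseable configuration line: ", ln)
    }
    cfg
  }
  validate_config(cfg)
}

#' Validate a configuration list against the schema
#' @param cfg nested configuration list
#' @return the configuration, invisibly amended with defaults
#' @export
validate_config <- function(cfg) {
  bad_sec <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(bad_sec) > 0)
    stop("unknown configuration section(s): ", paste(bad_sec, collapse = ", "))
  for (s in names(cfg)) {
    bad <- setdiff(names(cfg[[s]]), .CONFIG_SCHEMA[[s]])
    if (length(bad) > 0)
      stop("unknown key(s) in [", s, "]: ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$study$mode))
    stop("configuration must set study mode")
  modes <- c("single", "scan", "morphology", "diagram", "stratification")
  if (!cfg$study$mode %in% modes)
    stop("study mode must be one of: ", paste(modes, collapse = ", "))
  cfg
}

#' Export a configuration to JSON
#' @param cfg configuration list
#' @param path output path
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_defaults <- function(cfg) {
  d <- function(x, def) if (is.null(x)) def else x
  list(
    G = d(cfg$molecule$G, 1), t = d(cfg$molecule$t, 2),
    Nt = d(cfg$molecule$Nt, 12),
    geometry = d(cfg$lattice$geometry, "spherical"),
    M = d(cfg$lattice$M, 60),
    phi_salt_b = d(cfg$solution$phi_salt_b, 0.01),
    conversions = unit_conversions(
      b = d(cfg$solution$b, 3e-10), k = d(cfg$solution$k, 10),
      temperature = d(cfg$solution$temperature, 298)),
    tol = d(cfg$solver$tol, 1e-7),
    max_iter = d(cfg$solver$max_iter, 50000),
    mixing = d(cfg$solver$mixing, 0.1),
    mode = cfg$study$mode,
    theta = cfg$study$theta,
    theta_min = cfg$study$theta_min, theta_max = cfg$study$theta_max,
    per_decade = d(cfg$study$per_decade, 12),
    Nt_values = cfg$study$Nt_values,
    geometries = d(cfg$study$geometries, c("spherical", "cylindrical")),
    G_values = cfg$study$G_values, t_values = cfg$study$t_values,
    refine = d(cfg$study$refine, 2))
}

num_fmt <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- sprintf("%.10g", df[[j]])
  df
}

write_tidy_csv <- function(df, path) {
  utils::write.csv(num_fmt(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- studies -------------------------------------------------------------

#' Run a configured study
#'
#' Orchestrates the standard study types from a validated configuration:
#' \describe{
#'   \item{single}{one SCF solution at \code{study$theta}; writes the
#'     per-layer profile CSV and a metrics JSON.}
#'   \item{scan}{\code{\link{scan_micelles}} over a geometric amount grid;
#'     writes the scan CSV and an equilibrium-micelle summary JSON.}
#'   \item{morphology}{\code{\link{morphology_mu_table}} over
#'     \code{Nt_values} plus transition points.}
#'   \item{diagram}{\code{\link{build_state_diagram}} over \code{G_values}
#'     x \code{t_values}.}
#'   \item{stratification}{equilibrium micelle plus
#'     \code{\link{stratification_report}} and
#'     \code{\link{charge_analysis}}; writes per-class profile CSV.}
#' }
#' All CSV numbers use fixed \code{\%.10g} formatting and no timestamps,
#' so identical configurations reproduce byte-identical outputs.
#'
#' @param cfg configuration list (see \code{\link{read_config}})
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the computed objects and the paths
#'   written
#' @export
run_study <- function(cfg, out_dir = ".") {
  cfg <- validate_config(cfg)
  p <- config_defaults(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  mol <- build_molecule(p$G, p$t, p$Nt)
  lat_geom <- if (p$geometry == "lamellar") "planar" else p$geometry
  lat <- make_lattice(lat_geom, p$M)
  solver <- list(tol = p$tol, max_iter = p$max_iter, mixing = p$mixing)
  log_lines <- c(sprintf("dendromicelle study mode=%s", p$mode),
                 sprintf("molecule G=%d t=%d Nt=%d (N=%d segments)",
                         p$G, p$t, p$Nt, n_segments(mol)),
                 sprintf("lattice %s M=%d; phi_salt_b=%g",
                         p$geometry, p$M, p$phi_salt_b))
  out <- list(paths = character(0))

  default_grid <- function() {
    N <- n_segments(mol)
    if (!is.null(p$theta_min) && !is.null(p$theta_max)) {
      theta_grid(p$theta_min, p$theta_max, p$per_decade)
    } else theta_grid(2 * N, 250 * N, p$per_decade)
  }

  if (p$mode == "single") {
    if (is.null(p$theta)) stop("mode=single requires study$theta")
    spec <- system_spec(mol, lat, theta_surf = p$theta,
                        phi_salt_b = p$phi_salt_b,
                        conversions = p$conversions)
    st <- do.call(solve_scf, c(list(spec = spec), solver))
    write_state_csv(st, path("profiles.csv"))
    summ <- list(mode = "single", converged = st$converged,
                 residual = st$residual, iterations = st$iterations,
                 n_agg = aggregation_number(st),
                 phi_surf_b = st$phi_surf_b,
                 Omega = grand_potential(st),
                 mu_surf = chemical_potential(st))
    jsonlite::write_json(summ, path("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    out$state <- st; out$summary <- summ
    out$paths <- c(path("profiles.csv"), path("summary.json"))
    log_lines <- c(log_lines, sprintf("residual=%.3e iterations=%d",
                                      st$residual, st$iterations))
  } else if (p$mode == "scan") {
    cv <- do.call(scan_micelles,
                  c(list(molecule = mol, lattice = lat,
                         thetas = default_grid(),
                         phi_salt_b = p$phi_salt_b,
                         conversions = p$conversions), solver))
    th <- find_micelle(cv)
    write_tidy_csv(cv, path("scan.csv"))
    summ <- list(mode = "scan", found = th$found, n_agg = th$n_agg,
                 mu_surf = th$mu_surf, phi_surf_b = th$phi_surf_b,
                 phi_cmc_b = th$phi_cmc_b,
                 morphology = p$geometry,
                 verdict = if (th$found) "micelle" else "no micelle of this morphology")
    jsonlite::write_json(summ, path("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    out$curves <- cv; out$thermo <- th; out$summary <- summ
    out$paths <- c(path("scan.csv"), path("summary.json"))
  } else if (p$mode == "morphology") {
    if (is.null(p$Nt_values)) stop("mode=morphology requires study$Nt_values")
    tab <- morphology_mu_table(p$G, p$t, p$Nt_values,
                               geometries = p$geometries, M = p$M,
                               phi_salt_b = p$phi_salt_b,
                               conversions = p$conversions)
    tr <- morphology_transition(tab, p$geometries[1:2])
    write_tidy_csv(tab, path("morphology.csv"))
    summ <- list(mode = "morphology", boundary = paste(p$geometries[1:2],
                                                       collapse = "-"),
                 Nt_star = tr$Nt_star)
    jsonlite::write_json(summ, path("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    out$table <- tab; out$transition <- tr; out$summary <- summ
    out$paths <- c(path("morphology.csv"), path("summary.json"))
  } else if (p$mode == "diagram") {
    if (is.null(p$G_values) || is.null(p$t_values) || is.null(p$Nt_values))
      stop("mode=diagram requires study$G_values, t_values, Nt_values")
    dg <- build_state_diagram(p$G_values, p$t_values, p$Nt_values,
                              M = p$M, phi_salt_b = p$phi_salt_b,
                              conversions = p$conversions)
    write_tidy_csv(dg, path("diagram.csv"))
    out$diagram <- dg
    out$paths <- path("diagram.csv")
  } else if (p$mode == "stratification") {
    fit <- do.call(find_equilibrium_micelle,
                   c(list(molecule = mol, lattice = lat,
                          thetas = default_grid(),
                          phi_salt_b = p$phi_salt_b,
                          conversions = p$conversions,
                          refine = p$refine), solver))
    if (!fit$thermo$found) stop("no equilibrium micelle found for this system")
    rep <- stratification_report(fit$state)
    ca <- charge_analysis(fit$state)
    prof <- do.call(rbind, lapply(names(rep$by_contour), function(cl) {
      data.frame(layer = seq_along(rep$r), r = rep$r,
                 class = paste0("contour_", cl),
                 value = rep$by_contour[[cl]]$profile)
    }))
    prof <- rbind(prof, data.frame(layer = seq_along(rep$r), r = rep$r,
                                   class = "terminal_total",
                                   value = rep$terminal_total$profile))
    write_tidy_csv(prof, path("stratification.csv"))
    summ <- list(mode = "stratification", n_agg = fit$thermo$n_agg,
                 bimodal = rep$terminal_total$bimodal,
                 n_maxima_terminal = rep$terminal_total$n_maxima,
                 n_maxima_Q = ca$n_maxima, Reff = ca$Reff,
                 Qeff = ca$Qeff, Qbare = ca$Qbare, zeta_V = ca$zeta)
    jsonlite::write_json(summ, path("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    out$fit <- fit; out$report <- rep; out$charge <- ca; out$summary <- summ
    out$paths <- c(path("stratification.csv"), path("summary.json"))
  }
  writeLines(log_lines, path("run.log"))
  invisible(out)
}
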
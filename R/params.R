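#' Parameter registry for the reactive-transport scenario analysis
#'
#' Returns the full set of physical, chemical, microbial and geometric
#' parameters used throughout the package, each with value, units and a
#' provenance tag (`measured`, `calibrated`, `assumed` or `computed`).
#' Per-layer entries carry one value per soil layer (0--30, 30--60,
#' 60--90 cm; the deepest values also parametrize the buffer zone below
#' 90 cm).
#'
#' Internally the model works in micromolar units of carbon (umol C), meters
#' and seconds; reporting helpers convert to mass-based concentrations using
#' the molar mass of MCPA (`n_mol`, g/mol) and its number of carbon atoms
#' (`n_C`).
#'
#' @return A named list of class `param_registry`. Each element is a list
#'   with fields `value`, `unit` and `provenance`.
#' @export
#' @examples
#' reg <- param_registry()
#' reg$B_TS$value     # topsoil degrader biomass, umol C/kg
param_registry <- function() {
  p <- list(
    # --- soil hydraulic functions (per layer: 0-30, 30-60, 60-90 cm) ---
    theta_s  = list(value = c(0.49, 0.46, 0.43),      unit = "1",     provenance = "measured"),
    theta_r  = list(value = c(0.00, 0.15, 0.00),      unit = "1",     provenance = "calibrated"),
    alpha_vg = list(value = c(12.30, 13.40, 3.63),    unit = "1/m",   provenance = "calibrated"),
    n_vg     = list(value = c(1.10, 1.12, 1.12),      unit = "1",     provenance = "calibrated"),
    l_vg     = list(value = 0.5,                      unit = "1",     provenance = "assumed"),
    K_s      = list(value = c(1.85e-5, 24.00e-5, 2.31e-5), unit = "m/s", provenance = "measured"),
    # --- reactive transport ---
    D_m      = list(value = 6.33e-10, unit = "m^2/s", provenance = "computed"),
    K_F      = list(value = 1.79e-3,  unit = "umol C/kg (m^3/umol C)^n_F", provenance = "measured"),
    n_F      = list(value = 0.86,     unit = "1",     provenance = "measured"),
    lambda_L = list(value = 0.03,     unit = "m",     provenance = "assumed"),
    lambda_T = list(value = 0.01,     unit = "m",     provenance = "assumed"),
    # --- microbial degradation ---
    B_TS     = list(value = 12.21,    unit = "umol C/kg",    provenance = "measured"),
    f_mg     = list(value = 1.10e-7,  unit = "umol C/gene",  provenance = "calibrated"),
    gamma    = list(value = 3,        unit = "1/m",          provenance = "assumed"),
    mu_max   = list(value = 2.94e-4,  unit = "1/s",          provenance = "calibrated"),
    K_M      = list(value = 1.93e6,   unit = "umol C/m^3",   provenance = "calibrated"),
    # --- material / chemical properties, global parameters ---
    rho_F    = list(value = 1.00e3,   unit = "kg/m^3", provenance = "assumed"),
    rho_b    = list(value = c(1.24e3, 1.32e3, 1.46e3), unit = "kg/m^3", provenance = "measured"),
    g        = list(value = 9.81,     unit = "m/s^2",  provenance = "assumed"),
    n_mol    = list(value = 200.62,   unit = "g/mol",  provenance = "assumed"),
    n_C      = list(value = 9,        unit = "1",      provenance = "assumed"),
    # --- geometric variables ---
    d_TS     = list(value = 0.3,      unit = "m", provenance = "assumed"),
    d_z      = list(value = 0.1,      unit = "m", provenance = "assumed"),
    d_v_sts  = list(value = 0.05e-3,  unit = "m", provenance = "assumed")
  )
  class(p) <- "param_registry"
  p
}

#' @export
print.param_registry <- function(x, ...) {
  cat("Parameter registry (", length(x), " symbols)\n", sep = "")
  for (nm in names(x)) {
    cat(sprintf("  %-9s = %-28s [%s] (%s)\n", nm,
                paste(signif(x[[nm]]$value, 6), collapse = "; "),
                x[[nm]]$unit, x[[nm]]$provenance))
  }
  invisible(x)
}

#' Soil layer definitions
#'
#' Builds the list of [vg_layer()] objects for the layered profile: three
#' characterized layers (0--30, 30--60, 60--90 cm) plus a buffer zone below
#' 90 cm sharing the deepest layer's properties, used to keep the outflow
#' boundary away from the region of interest.
#'
#' @param registry parameter registry, see [param_registry()].
#' @param buffer_depth thickness of the buffer zone below 0.9 m \[m\].
#' @return list of `vg_layer` objects tiling `[0, 0.9 + buffer_depth]`.
#' @export
soil_layers <- function(registry = param_registry(), buffer_depth = 1.1) {
  tops <- c(0, 0.3, 0.6, 0.9)
  bots <- c(0.3, 0.6, 0.9, 0.9 + buffer_depth)
  idx  <- c(1, 2, 3, 3)  # buffer re-uses the 60-90 cm parametrization
  lapply(seq_along(tops), function(i) {
    j <- idx[i]
    vg_layer(theta_s = registry$theta_s$value[j],
             theta_r = registry$theta_r$value[j],
             alpha_vg = registry$alpha_vg$value[j],
             n_vg = registry$n_vg$value[j],
             l_vg = registry$l_vg$value,
             K_s = registry$K_s$value[j],
             rho_b = registry$rho_b$value[j],
             depth_top = tops[i], depth_bottom = bots[i])
  })
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file and merges it over the package defaults
#' (the full parameter registry plus mesh/solver settings). Unknown keys are
#' rejected with a field-level message; parameter overrides are checked for
#' length and sign.
#'
#' @param path path to a YAML file; `NULL` returns pure defaults.
#' @return A named list with elements `params` (parameter registry),
#'   `mesh` (resolution settings), `solver` (tolerances), `scenario`
#'   (heterogeneity and precipitation labels, realizations, seed).
#' @export
load_config <- function(path = NULL) {
  cfg <- list(
    params = param_registry(),
    mesh = list(dy = 5e-3, width = 0.3, depth = 2.0, refine_top = TRUE),
    solver = list(head_tol = 1e-6, mass_tol = 1e-3, conc_tol = 1e-7,
                  eps_capacity = 1e-9),
    scenario = list(heterogeneity = "HOM", precipitation = "CLR",
                    n_realizations = 1, seed = 1, t_end = 365)
  )
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown top-level config keys: ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (sec == "params") {
      for (pn in names(user$params)) {
        if (!pn %in% names(cfg$params))
          stop("unknown parameter in config: params$", pn)
        v <- user$params[[pn]]
        if (!is.numeric(v)) stop("parameter params$", pn, " must be numeric")
        if (!length(v) %in% c(1L, length(cfg$params[[pn]]$value)))
          stop("parameter params$", pn, " has wrong length")
        if (length(v) == 1L && length(cfg$params[[pn]]$value) > 1L)
          v <- rep(v, length(cfg$params[[pn]]$value))
        cfg$params[[pn]]$value <- v
        cfg$params[[pn]]$provenance <- "config-override"
      }
    } else {
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad)) stop("unknown config keys in ", sec, ": ", paste(bad, collapse = ", "))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  cfg
}

#' Provenance stamp for run outputs
#'
#' Builds a metadata block identifying a run: seeds, a hash of the parameter
#' values, package version and solver tolerances. Two runs with the same
#' configuration and seed produce identical stamps (up to the timestamp,
#' which is excluded from the hash).
#'
#' @param cfg configuration list as returned by [load_config()].
#' @param seed integer seed(s) used for the run.
#' @return named list with fields `seed`, `param_hash`, `package_version`,
#'   `solver`, `timestamp`.
#' @export
provenance_stamp <- function(cfg, seed) {
  vals <- unlist(lapply(cfg$params, `[[`, "value"), use.names = TRUE)
  key <- paste(names(vals), signif(vals, 12), sep = "=", collapse = ";")
  key <- paste(key, paste(unlist(cfg$solver), collapse = ";"), sep = "|")
  # small stable polynomial rolling hash; avoids external digest deps
  # (kept in double arithmetic: 31 * 2^31 + 255 is far below 2^53)
  h <- 7
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2^31
  list(seed = seed,
       param_hash = sprintf("%08x", h),
       package_version = as.character(utils::packageVersion("mcpafate")),
       solver = cfg$solver,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Unit conversions between gene abundance, biomass carbon and MCPA mass
#'
#' `genes_to_biomass()` converts a gene abundance \[genes/kg soil\] to degrader
#' biomass carbon \[umol C/kg\] with the conversion factor `f_mg`
#' \[umol C/gene\]; `biomass_to_genes()` is its inverse.
#' `umolC_to_mg_mcpa()` converts a carbon-based MCPA amount \[umol C\] to
#' milligrams of MCPA using the molar mass and carbon count per molecule.
#'
#' @param abundance gene abundance \[genes/kg\] (vector).
#' @param f_mg biomass-carbon per gene \[umol C/gene\].
#' @return converted quantity, same shape as input.
#' @export
genes_to_biomass <- function(abundance, f_mg = param_registry()$f_mg$value) {
  stopifnot(all(abundance >= 0))
  abundance * f_mg
}

#' @rdname genes_to_biomass
#' @param biomass degrader biomass \[umol C/kg\].
#' @export
biomass_to_genes <- function(biomass, f_mg = param_registry()$f_mg$value) {
  biomass / f_mg
}

#' @rdname genes_to_biomass
#' @param umolC amount of MCPA-derived carbon \[umol C\].
#' @param n_mol MCPA molar mass \[g/mol\].
#' @param n_C carbon atoms per MCPA molecule.
#' @export
umolC_to_mg_mcpa <- function(umolC, n_mol = 200.62, n_C = 9) {
  umolC / n_C * n_mol * 1e-3
}
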
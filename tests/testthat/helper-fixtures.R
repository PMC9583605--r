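# Shared fixtures; expensive objects are computed once per test session.
.fix <- new.env(parent = emptyenv())

fix_get <- function(key, builder) {
  if (!exists(key, envir = .fix)) assign(key, builder(), envir = .fix)
  get(key, envir = .fix)
}

# full-depth single-column (1D) mesh of the study geometry
column_mesh <- function() fix_get("column_mesh", function() preset_mesh("column"))

spun_column <- function() fix_get("spun_column", function() {
  spin_up(column_mesh(), 0.56)
})

# 1D homogeneous heavy-rain-events run used by several checks
hom_hre_run <- function() fix_get("hom_hre_run", function() {
  mesh <- column_mesh()
  simulate_scenario(mesh, hom_field(mesh$width, 0.9),
                    build_precip("HRE"), t_end = 40, initial = spun_column())
})

# uniform single-layer sandy mesh for analytic transport checks
uniform_mesh <- function(depth = 1.0, dy = 0.01) {
  lay <- vg_layer(theta_s = 0.43, theta_r = 0.02, alpha_vg = 3.63,
                  n_vg = 1.4, K_s = 2.31e-5, rho_b = 1.4e3,
                  depth_top = 0, depth_bottom = Inf)
  build_mesh(width = 0.1, depth = depth, dy = dy, dx = 0.1,
             refine_top = FALSE, coarse_below = depth, layers = list(lay))
}

constant_schedule <- function(rate, t_end = 400) {
  sched <- data.frame(start = 0, end = t_end, rate = rate)
  attr(sched, "label") <- "CLR"
  class(sched) <- c("precip_schedule", "data.frame")
  sched
}

# registry with individual overrides, e.g. reg_with(mu_max = 1e-4)
reg_with <- function(...) {
  reg <- param_registry()
  ov <- list(...)
  for (nm in names(ov)) reg[[nm]]$value <- ov[[nm]]
  reg
}

# hand-built degrader_field from a biomass matrix (5 mm cells)
field_from_B <- function(B, cell = 5e-3, d_v_sts = 0.05e-3) {
  ny <- nrow(B); nx <- ncol(B)
  y <- (seq_len(ny) - 0.5) * cell
  mass_kg <- cell^2 * d_v_sts * 1.24e3
  counts <- B / 1.1e-7 * mass_kg
  structure(list(B = B, gene_count = counts,
                 genes_per_g = counts / (mass_kg * 1e3),
                 y = y, x = (seq_len(nx) - 0.5) * cell, cell = cell,
                 seed = NA_integer_, sigma2 = NA_real_, beta = NA_real_,
                 scenario = NA_character_), class = "degrader_field")
}
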
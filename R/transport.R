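#' Freundlich equilibrium sorption
#'
#' Sorbed concentration in equilibrium with the dissolved phase:
#' `C_S = K_F * C_L^n_F`.
#'
#' @param C_L dissolved concentration \[umol C/m^3\], >= 0, vectorized.
#' @param K_F Freundlich coefficient \[umol C/kg (m^3/umol C)^n_F\].
#' @param n_F Freundlich exponent, 0 < n_F <= 1.
#' @return sorbed concentration \[umol C/kg\].
#' @export
freundlich_sorbed <- function(C_L, K_F = 1.79e-3, n_F = 0.86) {
  stopifnot(n_F > 0, n_F <= 1)
  K_F * C_L^n_F
}

#' Millington-Quirk effective diffusivity
#'
#' Tortuosity-corrected aqueous diffusivity in unsaturated soil:
#' `D_s = D_m * theta^(10/3) / theta_s^2`.
#'
#' @param theta volumetric water content \[1\].
#' @param theta_s saturated water content \[1\].
#' @param D_m aqueous molecular diffusion coefficient \[m^2/s\].
#' @return effective soil diffusivity \[m^2/s\].
#' @export
millington_quirk_Ds <- function(theta, theta_s, D_m = 6.33e-10) {
  stopifnot(all(theta >= 0), all(theta <= theta_s + 1e-12))
  D_m * theta^(10 / 3) / theta_s^2
}

#' Hydrodynamic dispersion tensor (Bear form)
#'
#' `D_ij = lambda_T |v| delta_ij + (lambda_L - lambda_T) v_i v_j / |v| +
#' D_s delta_ij` with pore velocity `v = q_w / theta`. At zero flux the
#' tensor degenerates to isotropic molecular diffusion.
#'
#' @param q_w Darcy flux vector \[m/s\], length 2 (x, y).
#' @param theta water content \[1\].
#' @param lambda_L,lambda_T longitudinal and transversal dispersivity \[m\].
#' @param D_s effective diffusivity \[m^2/s\].
#' @return 2x2 symmetric positive semidefinite tensor \[m^2/s\].
#' @export
dispersion_tensor <- function(q_w, theta, lambda_L = 0.03, lambda_T = 0.01,
                              D_s = 0) {
  stopifnot(lambda_L >= lambda_T, lambda_T > 0)
  v <- q_w / theta
  s <- sqrt(sum(v^2))
  if (s == 0) return(diag(2) * D_s)
  lambda_T * s * diag(2) + (lambda_L - lambda_T) * outer(v, v) / s +
    D_s * diag(2)
}

#' Monod degradation rate
#'
#' Volumetric pesticide degradation rate by the immobile degrader biomass:
#' `R = mu_max * rho_b * B * C_L / (K_M + C_L)` \[umol C/m^3 bulk/s\].
#'
#' @param C_L dissolved concentration \[umol C/m^3\], vectorized.
#' @param B degrader biomass \[umol C/kg\].
#' @param rho_b bulk density \[kg/m^3\].
#' @param mu_max maximal rate coefficient \[1/s\].
#' @param K_M Monod constant \[umol C/m^3\].
#' @return degradation rate \[umol C/m^3/s\].
#' @export
monod_rate <- function(C_L, B, rho_b = 1.24e3, mu_max = 2.94e-4,
                       K_M = 1.93e6) {
  stopifnot(mu_max > 0, K_M > 0)
  mu_max * rho_b * B * C_L / (K_M + C_L)
}

#' Initial MCPA distribution after application
#'
#' Distributes the applied dose (2 kg/ha by default) over the upper 1.5 cm
#' of the column: uniform in the horizontal, with a smooth monotone taper in
#' depth (constant to 1 cm, half-cosine shoulder to zero at 1.5 cm) standing
#' in for the steep near-surface gradient of a surface application. The
#' dissolved/sorbed partitioning satisfies Freundlich equilibrium in each
#' cell given the initial water content.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param theta initial water content per column cell \[1\].
#' @param rate_kg_ha application rate \[kg/ha\].
#' @param registry parameter registry.
#' @param z0 depth to which the load is uniform \[m\].
#' @param z1 depth at which the load reaches zero \[m\].
#' @return object of class `mcpa_state`: matrices `C_L` \[umol C/m^3\] and
#'   `C_S` \[umol C/kg\] (rows = depth), `time = 0`.
#' @export
apply_initial_mcpa <- function(mesh, theta, rate_kg_ha = 2,
                               registry = param_registry(),
                               z0 = 0.010, z1 = 0.015) {
  stopifnot(max(mesh$y_faces) >= z1)
  n_mol <- registry$n_mol$value; n_C <- registry$n_C$value
  total_umolC <- rate_kg_ha * 0.1 * mesh$width * mesh$d_z / n_mol * n_C * 1e6
  w <- ifelse(mesh$y <= z0, 1,
              ifelse(mesh$y >= z1, 0,
                     cos(pi / 2 * (mesh$y - z0) / (z1 - z0))^2))
  wsum <- sum(w * mesh$dy)
  # target total concentration per bulk volume [umol C/m^3]
  T_bulk <- total_umolC * w / (wsum * mesh$width * mesh$d_z)
  K_F <- registry$K_F$value; n_F <- registry$n_F$value
  C_L <- vapply(seq_len(mesh$ny), function(i) {
    if (T_bulk[i] <= 0) return(0)
    f <- function(cl) theta[i] * cl + mesh$rho_b[i] * K_F * cl^n_F - T_bulk[i]
    stats::uniroot(f, c(0, T_bulk[i] / theta[i]), tol = 1e-12 * T_bulk[i] + 1e-15)$root
  }, 0)
  C_Lm <- matrix(C_L, mesh$ny, mesh$nx)
  structure(list(C_L = C_Lm, C_S = freundlich_sorbed(C_Lm, K_F, n_F),
                 time = 0), class = "mcpa_state")
}

#' Total mass-based concentration
#'
#' Converts a dissolved/sorbed state to the total mass-normalized MCPA
#' concentration `C_T = (theta*C_L + rho_b*C_S)/rho_b` expressed in
#' mg MCPA per kg soil.
#'
#' @param C_L dissolved concentration \[umol C/m^3\] (matrix, rows = depth).
#' @param C_S sorbed concentration \[umol C/kg\].
#' @param theta water content per depth row.
#' @param rho_b bulk density per depth row \[kg/m^3\].
#' @param registry parameter registry (molar constants).
#' @return `C_T` \[mg MCPA/kg soil\], same shape as `C_L`.
#' @export
total_concentration_mgkg <- function(C_L, C_S, theta, rho_b,
                                     registry = param_registry()) {
  umolC_kg <- sweep(C_L, 1, theta / rho_b, `*`) + C_S
  umolC_to_mg_mcpa(umolC_kg, registry$n_mol$value, registry$n_C$value)
}

# Map a degrader field (5 mm blocks) onto mesh cells by depth; below the
# field's extent the horizontally uniform mean profile continues.
.field_on_mesh <- function(field, mesh, registry = param_registry()) {
  B <- matrix(0, mesh$ny, mesh$nx)
  max_y <- max(field$y) + field$cell / 2
  bi <- pmin(pmax(ceiling(mesh$y / field$cell), 1L), length(field$y))
  for (j in seq_len(mesh$nx)) {
    bj <- min(max(ceiling(mesh$x[j] / field$cell), 1L), length(field$x))
    B[, j] <- field$B[bi, bj]
  }
  deep <- mesh$y > max_y
  if (any(deep))
    B[deep, ] <- depth_mean_profile(mesh$y[deep], registry$B_TS$value,
                                    registry$gamma$value, registry$d_TS$value)
  B
}

# One implicit transport step, operator-split:
#  (A) vertical upwind advection + dispersion + Monod reaction + Freundlich
#      sorption, backward Euler with Picard sub-iteration on the nonlinear
#      capacity and rate terms (one tridiagonal solve per column);
#  (B) lateral dispersion/diffusion with the same mixed-form sorption
#      linearization (one tridiagonal solve per row).
# Both sub-steps are conservative finite-volume operators, so the solute
# mass ledger closes to the Picard tolerance.
# theta_n/theta_np1/q_faces describe the columnar flow over the step.
# Returns NULL on Picard failure.
.transport_step <- function(C, theta_n, theta_np1, q_faces, mesh, B, pars,
                            dt, conc_tol = 1e-6, max_iter = 15L) {
  ny <- mesh$ny; nx <- mesh$nx
  dy <- mesh$dy; dyf <- diff(mesh$y)
  rho <- mesh$rho_b
  # cell velocities and dispersion coefficients (uniform across x)
  q_cell <- (q_faces[-1] + q_faces[-(ny + 1)]) / 2
  v <- abs(q_cell) / theta_np1
  Ds <- millington_quirk_Ds(pmin(theta_np1, mesh$ths), mesh$ths, pars$D_m)
  thDyy <- theta_np1 * (pars$lambda_L * v + Ds)
  thDxx <- theta_np1 * (pars$lambda_T * v + Ds)
  Dv <- (thDyy[-ny] + thDyy[-1]) / 2 / dyf      # vertical face conductance
  dx <- mesh$dx[1]
  qf <- q_faces[-c(1, ny + 1)]                  # interior faces
  qf_pos <- pmax(qf, 0); qf_neg <- pmin(qf, 0)
  q_bot <- q_faces[ny + 1]
  # vertical tridiagonal pieces (upwind advection + dispersion), shared
  # across columns because flow is columnar
  diag_T <- numeric(ny); sub_T <- numeric(ny - 1); sup_T <- numeric(ny - 1)
  diag_T[-ny] <- diag_T[-ny] + qf_pos / dy[-ny]
  sup_T <- sup_T + qf_neg / dy[-ny]
  diag_T[-1] <- diag_T[-1] - qf_neg / dy[-1]
  sub_T <- sub_T - qf_pos / dy[-1]
  diag_T[ny] <- diag_T[ny] + max(q_bot, 0) / dy[ny]
  diag_T[-ny] <- diag_T[-ny] + Dv / dy[-ny]
  sup_T <- sup_T - Dv / dy[-ny]
  diag_T[-1] <- diag_T[-1] + Dv / dy[-1]
  sub_T <- sub_T - Dv / dy[-1]
  a_mat <- matrix(c(0, sub_T), ny, nx)
  c_mat <- matrix(c(sup_T, 0), ny, nx)
  eps <- pars$eps_capacity
  Brho <- B * rho                    # row-recycled: rho varies by depth
  C_n <- C
  C_S_n <- freundlich_sorbed(C_n, pars$K_F, pars$n_F)
  Cm <- C
  scale <- max(C_n, 1e-12)
  reac_coef <- NULL
  # --- sub-step A: vertical transport + sorption + reaction ---
  for (it in seq_len(max_iter)) {
    sprime <- pars$K_F * pars$n_F * pmax(Cm, eps)^(pars$n_F - 1)
    C_S_m <- freundlich_sorbed(Cm, pars$K_F, pars$n_F)
    reac_coef <- pars$mu_max * Brho / (pars$K_M + Cm)
    diag_cell <- sprime * (rho / dt) + reac_coef + theta_np1 / dt
    rhs <- C_n * (theta_n / dt) + (sprime * Cm - C_S_m + C_S_n) * (rho / dt)
    Cn1 <- thomas_solve_many(a_mat, diag_T + diag_cell, c_mat, rhs)
    if (any(!is.finite(Cn1))) return(NULL)
    delta <- max(abs(Cn1 - Cm))
    Cm <- Cn1
    if (delta <= conc_tol * scale) break
    if (it == max_iter) return(NULL)
  }
  if (min(Cm) < -1e-10 * scale) return(NULL)
  Cm[Cm < 0] <- 0
  cellvol <- outer(dy, rep(dx * mesh$d_z, nx))
  deg <- sum(reac_coef * Cm * cellvol) * dt
  export <- sum(max(q_bot, 0) * Cm[ny, ] * dx * mesh$d_z) * dt
  # flux across the 30 cm plane (upwind concentration), for leachate metrics
  i30 <- which.min(abs(mesh$y_faces - 0.3))
  q30 <- q_faces[i30]
  C30 <- if (q30 >= 0) Cm[i30 - 1, ] else Cm[i30, ]
  flux30 <- sum(q30 * C30 * dx * mesh$d_z) * dt
  # --- sub-step B: lateral dispersion (columns exchange mass) ---
  if (nx > 1) {
    Cs_star <- freundlich_sorbed(Cm, pars$K_F, pars$n_F)
    C_star <- Cm
    off <- thDxx / dx^2                         # per depth row
    bt_base <- matrix(off, nx, ny, byrow = TRUE) # transposed layout: nx x ny
    bt_edge <- bt_base
    bt_edge[c(1, nx), ] <- 0                    # Neumann edges lose one face
    at <- -bt_base; at[1, ] <- 0
    ct <- -bt_base; ct[nx, ] <- 0
    diag_lat <- 2 * bt_base; diag_lat[c(1, nx), ] <- bt_base[c(1, nx), ]
    for (it in seq_len(max_iter)) {
      sprime <- pars$K_F * pars$n_F * pmax(Cm, eps)^(pars$n_F - 1)
      C_S_m <- freundlich_sorbed(Cm, pars$K_F, pars$n_F)
      base <- (theta_np1 + sprime * rho) / dt   # ny x nx
      rhs <- C_star * (theta_np1 / dt) +
        (sprime * Cm - C_S_m + Cs_star) * (rho / dt)
      Cn1 <- t(thomas_solve_many(at, t(base) + diag_lat, ct, t(rhs)))
      if (any(!is.finite(Cn1))) return(NULL)
      delta <- max(abs(Cn1 - Cm))
      Cm <- Cn1
      if (delta <= conc_tol * scale) break
      if (it == max_iter) return(NULL)
    }
    if (min(Cm) < -1e-10 * scale) return(NULL)
    Cm[Cm < 0] <- 0
  }
  list(C = Cm, deg = deg, export = export, flux30 = flux30,
       C30 = mean(C30), q30 = q30)
}

#' Simulate a reactive-transport scenario
#'
#' Couples columnar variably saturated flow with two-dimensional
#' advection-dispersion-sorption-reaction transport of MCPA over a
#' precipitation schedule. Per time step the flow field is advanced first
#' (the dilute solute does not feed back on flow), then the transport
#' equation is solved implicitly with Picard sub-iteration on the nonlinear
#' Freundlich capacity and Monod rate. Mass ledgers (cumulative
#' degradation, bottom export, flux across the 30 cm plane) are maintained
#' continuously.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param field a `degrader_field` ([sample_field()] or [hom_field()]).
#' @param schedule a [build_precip()] schedule.
#' @param t_end simulated span \[d\].
#' @param registry parameter registry; individual overrides via `...`
#'   are not supported -- edit the registry instead.
#' @param out_times snapshot times \[d\] (daily by default; sub-daily
#'   cadence can be supplied to resolve event dynamics).
#' @param initial optional `water_state` to start from (defaults to
#'   [spin_up()] at the first schedule rate).
#' @param mcpa_kg_ha application rate \[kg/ha\].
#' @param dt_max maximum time step \[d\].
#' @param conc_tol transport Picard tolerance (relative).
#' @return object of class `scenario_run`: `times` \[d\], list `C_L` of
#'   dissolved-concentration snapshots, matching `theta` vectors, static
#'   `B` matrix on the mesh, ledgers `cum_deg`, `cum_export`, `cum_leach30`
#'   \[umol C\] and leachate series `C30` \[umol C/m^3\], `q30` \[m/s\] at
#'   snapshot times, `initial_mass` \[umol C\], and the `mesh`.
#' @export
simulate_scenario <- function(mesh, field, schedule, t_end,
                              registry = param_registry(),
                              out_times = seq(0, t_end, by = 1),
                              initial = NULL, mcpa_kg_ha = 2,
                              dt_max = 0.2, conc_tol = 1e-6) {
  pars <- list(D_m = registry$D_m$value, K_F = registry$K_F$value,
               n_F = registry$n_F$value, lambda_L = registry$lambda_L$value,
               lambda_T = registry$lambda_T$value,
               mu_max = registry$mu_max$value, K_M = registry$K_M$value,
               eps_capacity = 1e-9)
  if (is.null(initial)) initial <- spin_up(mesh, schedule$rate[1])
  B <- .field_on_mesh(field, mesh, registry)
  h <- initial$h
  theta <- .theta_vec(h, mesh)
  st <- apply_initial_mcpa(mesh, theta, mcpa_kg_ha, registry)
  C <- st$C_L
  cellvol <- outer(mesh$dy, rep(mesh$dx[1] * mesh$d_z, mesh$nx))
  mass0 <- sum((sweep(C, 1, theta, `*`) +
                sweep(freundlich_sorbed(C, pars$K_F, pars$n_F), 1,
                      mesh$rho_b, `*`)) * cellvol)
  breaks <- sort(unique(c(schedule$start, schedule$end)))
  out_times <- sort(unique(pmin(out_times, t_end)))
  nt <- length(out_times)
  snapshots <- vector("list", nt); thetas <- vector("list", nt)
  cum_deg <- cum_exp <- cum_l30 <- numeric(nt)
  C30s <- q30s <- numeric(nt)
  t <- 0; dt <- 1e-3
  deg_acc <- exp_acc <- l30_acc <- 0
  k <- 1L
  if (out_times[1] <= 0) {
    snapshots[[1]] <- C; thetas[[1]] <- theta
    k <- 2L
  }
  while (k <= nt) {
    t_target <- out_times[k]
    while (t < t_target - 1e-12) {
      nb <- breaks[breaks > t + 1e-12]
      t_stop <- min(c(t_target, nb))
      dt_use <- min(dt, t_stop - t)
      rate <- schedule_rate(schedule, t + dt_use / 2) * 1e-3 / 86400
      fres <- .richards_step(h, theta, mesh, rate, dt_use * 86400)
      if (is.null(fres)) {
        dt <- dt_use * 0.3
        if (dt < 1e-9) stop("flow step failed at t = ", signif(t, 6), " d")
        next
      }
      # discretely consistent new water content for solute mass balance
      theta_np1 <- theta - dt_use * 86400 *
        diff(fres$q_faces) / mesh$dy
      tres <- .transport_step(C, theta, theta_np1, fres$q_faces, mesh, B,
                              pars, dt_use * 86400, conc_tol = conc_tol)
      if (is.null(tres)) {
        dt <- dt_use * 0.3
        if (dt < 1e-9) stop("transport step failed at t = ", signif(t, 6), " d")
        next
      }
      h <- fres$h; theta <- theta_np1; C <- tres$C
      deg_acc <- deg_acc + tres$deg
      exp_acc <- exp_acc + tres$export
      l30_acc <- l30_acc + tres$flux30
      C30_last <- tres$C30; q30_last <- tres$q30
      t <- t + dt_use
      dt <- if (fres$iterations <= 5) min(dt_max, dt_use * 1.3) else dt_use
    }
    snapshots[[k]] <- C; thetas[[k]] <- theta
    cum_deg[k] <- deg_acc; cum_exp[k] <- exp_acc; cum_l30[k] <- l30_acc
    C30s[k] <- C30_last; q30s[k] <- q30_last
    k <- k + 1L
  }
  structure(list(times = out_times, C_L = snapshots, theta = thetas,
                 B = B, cum_deg = cum_deg, cum_export = cum_exp,
                 cum_leach30 = cum_l30, C30 = C30s, q30 = q30s,
                 initial_mass = mass0, mesh = mesh,
                 registry = registry,
                 scenario = field$scenario,
                 precip = attr(schedule, "label")),
            class = "scenario_run")
}

#' Domain MCPA mass of a snapshot
#'
#' Total dissolved-plus-sorbed MCPA mass \[umol C\] of snapshot `k` of a
#' [simulate_scenario()] run.
#'
#' @param run a `scenario_run`.
#' @param k snapshot index.
#' @return mass \[umol C\].
#' @export
snapshot_mass <- function(run, k) {
  mesh <- run$mesh
  C <- run$C_L[[k]]
  reg <- run$registry
  cellvol <- outer(mesh$dy, rep(mesh$dx[1] * mesh$d_z, mesh$nx))
  sum((sweep(C, 1, run$theta[[k]], `*`) +
       sweep(freundlich_sorbed(C, reg$K_F$value, reg$n_F$value), 1,
             mesh$rho_b, `*`)) * cellvol)
}

#' Mass-balance error of a run
#'
#' Relative closure error of the MCPA ledger:
#' `|storage + degraded + exported - initial| / initial` at snapshot `k`.
#'
#' @inheritParams snapshot_mass
#' @return relative error \[1\].
#' @export
mass_balance_error <- function(run, k = length(run$times)) {
  m <- snapshot_mass(run, k)
  abs(m + run$cum_deg[k] + run$cum_export[k] - run$initial_mass) /
    run$initial_mass
}
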
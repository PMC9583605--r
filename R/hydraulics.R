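#' Van Genuchten-Mualem soil layer
#'
#' Constructs a soil layer parametrized by the van Genuchten retention curve
#' and the Mualem conductivity model. Invariants (positivity, `n_vg > 1`,
#' `theta_r < theta_s`) are enforced at construction.
#'
#' @param theta_s saturated volumetric water content \[1\].
#' @param theta_r residual volumetric water content \[1\].
#' @param alpha_vg inverse air-entry value \[1/m\].
#' @param n_vg pore-size distribution measure \[1\], > 1.
#' @param l_vg tortuosity/connectivity exponent \[1\].
#' @param K_s saturated hydraulic conductivity \[m/s\].
#' @param rho_b dry bulk density \[kg/m^3\].
#' @param depth_top,depth_bottom layer interval \[m\], depth positive downward.
#' @return object of class `vg_layer`.
#' @export
vg_layer <- function(theta_s, theta_r, alpha_vg, n_vg, l_vg = 0.5,
                     K_s, rho_b, depth_top = 0, depth_bottom = Inf) {
  stopifnot(theta_r >= 0, theta_r < theta_s, theta_s <= 1,
            alpha_vg > 0, n_vg > 1, K_s > 0, rho_b > 0,
            depth_top < depth_bottom)
  structure(list(theta_s = theta_s, theta_r = theta_r, alpha_vg = alpha_vg,
                 n_vg = n_vg, l_vg = l_vg, K_s = K_s, rho_b = rho_b,
                 depth_top = depth_top, depth_bottom = depth_bottom),
            class = "vg_layer")
}

#' Van Genuchten water retention
#'
#' Volumetric water content as a function of pressure head:
#' `Se = (1 + (alpha*|h|)^n)^(-m)`, `m = 1 - 1/n`, and
#' `theta = theta_r + Se * (theta_s - theta_r)` for `h < 0`;
#' `theta = theta_s` at and above saturation.
#'
#' @param h pressure head \[m\], vectorized.
#' @param layer a [vg_layer()].
#' @return volumetric water content \[1\].
#' @export
retention_theta <- function(h, layer) {
  m <- 1 - 1 / layer$n_vg
  Se <- ifelse(h >= 0, 1, (1 + (layer$alpha_vg * abs(h))^layer$n_vg)^(-m))
  layer$theta_r + Se * (layer$theta_s - layer$theta_r)
}

#' Specific moisture capacity d(theta)/dh
#'
#' Analytic derivative of the van Genuchten retention curve; zero at and
#' above saturation.
#'
#' @inheritParams retention_theta
#' @return capacity \[1/m\].
#' @export
vg_capacity <- function(h, layer) {
  m <- 1 - 1 / layer$n_vg
  a <- layer$alpha_vg; n <- layer$n_vg
  ah <- a * abs(h)
  cap <- (layer$theta_s - layer$theta_r) * a * n * m * ah^(n - 1) *
    (1 + ah^n)^(-m - 1)
  ifelse(h >= 0, 0, cap)
}

#' Mualem unsaturated hydraulic conductivity
#'
#' `K = K_s * Se^l * (1 - (1 - Se^(1/m))^m)^2` with `m = 1 - 1/n`;
#' equals `K_s` at saturation and tends to zero in the dry limit.
#'
#' @inheritParams retention_theta
#' @return hydraulic conductivity \[m/s\].
#' @export
conductivity_K <- function(h, layer) {
  m <- 1 - 1 / layer$n_vg
  Se <- ifelse(h >= 0, 1, (1 + (layer$alpha_vg * abs(h))^layer$n_vg)^(-m))
  layer$K_s * Se^layer$l_vg * (1 - (1 - Se^(1 / m))^m)^2
}

#' Simulation mesh
#'
#' Builds the structured mesh of the soil column: depth `y` is 0 at the
#' surface and positive downward. The top 1 m is resolved at `dy` (5 mm by
#' default) with geometric refinement (cells halved over the top 2 cm) to
#' resolve the steep near-surface concentration gradients; below 1 m the
#' vertical resolution coarsens to `dy_coarse`. Horizontal resolution is
#' `dx` across `width`. The out-of-plane thickness `d_z` converts areal
#' application rates to masses.
#'
#' @param width horizontal extent \[m\].
#' @param depth vertical extent \[m\].
#' @param dy,dx target cell sizes \[m\].
#' @param dy_coarse vertical cell size below `coarse_below` \[m\].
#' @param coarse_below depth below which the coarse vertical resolution is
#'   used \[m\].
#' @param refine_top halve the vertical cell size over the top 2 cm.
#' @param d_z out-of-plane (virtual column) thickness \[m\].
#' @param layers list of [vg_layer()]s tiling the depth interval.
#' @return object of class `soil_mesh` with cell centers, widths, per-cell
#'   layer index and vectorized per-cell hydraulic parameters.
#' @export
build_mesh <- function(width = 0.3, depth = 2.0, dy = 5e-3, dx = 5e-3,
                       dy_coarse = 50e-3, coarse_below = 1.0,
                       refine_top = TRUE, d_z = 0.1,
                       layers = soil_layers()) {
  dy_vec <- c()
  if (refine_top) dy_vec <- rep(dy / 2, round(0.02 / (dy / 2)))
  y0 <- sum(dy_vec)
  n_fine <- round((min(depth, coarse_below) - y0) / dy)
  dy_vec <- c(dy_vec, rep(dy, n_fine))
  if (depth > coarse_below + 1e-12)
    dy_vec <- c(dy_vec, rep(dy_coarse, round((depth - coarse_below) / dy_coarse)))
  y_faces <- c(0, cumsum(dy_vec))
  y <- (y_faces[-1] + y_faces[-length(y_faces)]) / 2
  nx <- max(1L, round(width / dx))
  x <- (seq_len(nx) - 0.5) * (width / nx)
  layer_of <- function(yy) {
    idx <- vapply(yy, function(v) {
      k <- which(v >= vapply(layers, `[[`, 0, "depth_top") &
                 v < vapply(layers, `[[`, 0, "depth_bottom"))
      if (!length(k)) length(layers) else k[1]
    }, 0L)
    idx
  }
  li <- layer_of(y)
  mesh <- list(
    y = y, dy = dy_vec, y_faces = y_faces, ny = length(y),
    x = x, dx = rep(width / nx, nx), nx = nx, width = width, depth = depth,
    d_z = d_z, layers = layers, layer_index = li,
    # vectorized per-cell hydraulic parameters (performance path)
    ths = vapply(layers, `[[`, 0, "theta_s")[li],
    thr = vapply(layers, `[[`, 0, "theta_r")[li],
    avg = vapply(layers, `[[`, 0, "alpha_vg")[li],
    nvg = vapply(layers, `[[`, 0, "n_vg")[li],
    lvg = vapply(layers, `[[`, 0, "l_vg")[li],
    Ks  = vapply(layers, `[[`, 0, "K_s")[li],
    rho_b = vapply(layers, `[[`, 0, "rho_b")[li]
  )
  class(mesh) <- "soil_mesh"
  mesh
}

#' @export
print.soil_mesh <- function(x, ...) {
  cat(sprintf("soil_mesh: %d x %d cells (%.2f m wide, %.2f m deep), d_z = %.2f m\n",
              x$nx, x$ny, x$width, x$depth, x$d_z))
  invisible(x)
}

# vectorized per-cell hydraulic functions on a mesh column
.theta_vec <- function(h, mesh) {
  m <- 1 - 1 / mesh$nvg
  Se <- (1 + (mesh$avg * abs(h))^mesh$nvg)^(-m)
  Se[h >= 0] <- 1
  mesh$thr + Se * (mesh$ths - mesh$thr)
}
.cap_vec <- function(h, mesh) {
  m <- 1 - 1 / mesh$nvg
  ah <- mesh$avg * abs(h)
  cap <- (mesh$ths - mesh$thr) * mesh$avg * mesh$nvg * m * ah^(mesh$nvg - 1) *
    (1 + ah^mesh$nvg)^(-m - 1)
  cap[h >= 0] <- 0
  cap
}
.K_vec <- function(h, mesh) {
  m <- 1 - 1 / mesh$nvg
  Se <- (1 + (mesh$avg * abs(h))^mesh$nvg)^(-m)
  Se[h >= 0] <- 1
  mesh$Ks * Se^mesh$lvg * (1 - (1 - Se^(1 / m))^m)^2
}

#' Precipitation schedules
#'
#' Builds the piecewise-constant infiltration schedule for the two
#' precipitation regimes: continuous light rain (`CLR`, 0.56 mm/d
#' throughout) and heavy rain events (`HRE`, 0.56 mm/d for two days, two
#' day-long 40 mm/d events each followed by two rain-free days, then
#' 0.35 mm/d from day 8 onward so that the cumulative input nearly matches
#' CLR).
#'
#' @param label `"CLR"` or `"HRE"`.
#' @param t_end end of the covered span \[d\].
#' @return object of class `precip_schedule`: data frame with columns
#'   `start`, `end` \[d\] and `rate` \[mm/d\], plus attribute `label`.
#' @export
build_precip <- function(label = c("CLR", "HRE"), t_end = 365) {
  label <- match.arg(label)
  sched <- if (label == "CLR") {
    data.frame(start = 0, end = t_end, rate = 0.56)
  } else {
    data.frame(start = c(0, 2, 3, 5, 6, 8),
               end   = c(2, 3, 5, 6, 8, t_end),
               rate  = c(0.56, 40, 0, 40, 0, 0.35))
  }
  sched <- sched[sched$start < t_end, , drop = FALSE]
  sched$end <- pmin(sched$end, t_end)
  stopifnot(all(sched$rate >= 0),
            all(abs(sched$start[-1] - sched$end[-nrow(sched)]) < 1e-12))
  attr(sched, "label") <- label
  class(sched) <- c("precip_schedule", "data.frame")
  sched
}

#' @rdname build_precip
#' @param schedule a `precip_schedule`.
#' @param t time \[d\].
#' @return `schedule_rate`: infiltration rate at `t` \[mm/d\].
#' @export
schedule_rate <- function(schedule, t) {
  i <- findInterval(t, schedule$start, rightmost.closed = FALSE)
  i[i < 1] <- 1
  ifelse(t >= max(schedule$end), 0, schedule$rate[i])
}

# --- Richards solver -------------------------------------------------------

# Thomas algorithm for tridiagonal systems (a: sub, b: diag, c: super);
# compiled kernel, see src/tridiag.cpp
.thomas <- function(a, b, c, r) thomas_solve(a, b, c, r)

# One mixed-form modified-Picard step of the 1D (columnar) Richards equation.
# y positive downward; flux positive downward: q = K * (1 - dh/dy).
# Top boundary: prescribed infiltration flux [m/s]; bottom: free drainage
# (zero pressure-head gradient, q = K(h_N)).
# Returns NULL on iteration failure (caller cuts the step).
.richards_step <- function(h, theta_n, mesh, q_top, dt,
                           head_tol = 1e-6, max_iter = 25L) {
  ny <- mesh$ny
  dyf <- diff(mesh$y)               # center-to-center distances, ny-1 faces
  hm <- h
  for (it in seq_len(max_iter)) {
    theta_m <- .theta_vec(hm, mesh)
    cap <- .cap_vec(hm, mesh)
    Kc <- .K_vec(hm, mesh)
    # upstream-weighted face conductivity from the current head iterate
    drive <- (hm[-ny] - hm[-1]) + dyf      # > 0 => downward flow
    Kf <- ifelse(drive >= 0, Kc[-ny], Kc[-1])
    Kbot <- Kc[ny]
    w <- Kf / dyf
    # linear system A h^{m+1} = r; face flux q = Kf*(1 - dh/dy) split into
    # its head-dependent part (matrix) and gravity part (rhs)
    a <- c(0, -w / mesh$dy[-1])                          # sub-diagonal
    c_ <- c(-w / mesh$dy[-ny], 0)                        # super-diagonal
    b <- cap / dt + c(w, 0) / mesh$dy + c(0, w) / mesh$dy
    r <- cap / dt * hm - (theta_m - theta_n) / dt +
      (c(q_top, Kf) - c(Kf, Kbot)) / mesh$dy
    hn1 <- .thomas(a, b, c_, r)
    if (any(!is.finite(hn1))) return(NULL)
    delta <- max(abs(hn1 - hm))
    hm <- hn1
    if (delta < head_tol) {
      theta_new <- .theta_vec(hm, mesh)
      Kc <- .K_vec(hm, mesh)
      drive <- (hm[-ny] - hm[-1]) + dyf
      Kf <- ifelse(drive >= 0, Kc[-ny], Kc[-1])
      q_faces <- c(q_top, Kf * drive / dyf, Kc[ny])
      return(list(h = hm, theta = theta_new, q_faces = q_faces,
                  iterations = it))
    }
  }
  NULL
}

#' Solve variably saturated flow over a precipitation schedule
#'
#' Cell-centered finite-volume, mixed-form (mass-conservative) solver for
#' the columnar Richards equation with modified-Picard iteration and
#' upstream-weighted inter-cell conductivity. Infiltration is applied as a
#' flux boundary at the surface and free drainage (zero pressure-head
#' gradient) at the bottom. Time stepping is adaptive, with forced step
#' boundaries at every schedule discontinuity and step cuts on iteration
#' failure.
#'
#' Because soil hydraulic properties are horizontally homogeneous in every
#' scenario, flow is strictly one-dimensional; two-dimensional transport
#' re-uses the columnar flow field across all horizontal positions.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param schedule a [build_precip()] schedule covering `[0, t_end]`.
#' @param initial initial pressure head: vector over the column, or a
#'   `water_state` from [spin_up()].
#' @param t_end end time \[d\].
#' @param out_times times at which to store snapshots \[d\].
#' @param head_tol Picard convergence tolerance on the head increment \[m\].
#' @param dt_max maximum time step \[d\].
#' @return object of class `flow_series`: list with `times`, list of
#'   `water_state` snapshots (`h`, `theta`, `q_faces` \[m/s\], `time` \[d\])
#'   and a water `balance` data frame (cumulative inflow, outflow, storage
#'   change \[m\]).
#' @export
solve_flow <- function(mesh, schedule, initial, t_end,
                       out_times = seq(0, t_end, by = 1),
                       head_tol = 1e-6, dt_max = 0.25) {
  h <- if (inherits(initial, "water_state")) initial$h else initial
  stopifnot(length(h) == mesh$ny)
  if (max(schedule$end) < t_end - 1e-9) stop("schedule does not cover [0, t_end]")
  stepper <- .flow_stepper(mesh, schedule, h, head_tol = head_tol,
                           dt_max = dt_max)
  out_times <- sort(unique(pmin(out_times, t_end)))
  snapshots <- vector("list", length(out_times))
  k <- 1L
  if (out_times[1] <= 0) {
    snapshots[[1]] <- stepper$state(); k <- 2L
  }
  while (k <= length(out_times)) {
    stepper$advance_to(out_times[k])
    snapshots[[k]] <- stepper$state()
    k <- k + 1L
  }
  structure(list(times = out_times, states = snapshots,
                 balance = stepper$balance()),
            class = "flow_series")
}

# Incremental flow stepper used by both solve_flow and the coupled
# transport loop. Returns closures over mutable state.
.flow_stepper <- function(mesh, schedule, h0, head_tol = 1e-6,
                          dt_max = 0.25, dt_init = 1e-3) {
  h <- h0
  theta <- .theta_vec(h, mesh)
  t <- 0            # days
  dt <- dt_init     # days
  cum_in <- 0; cum_out <- 0
  theta0 <- theta
  q_faces <- rep(NA_real_, mesh$ny + 1)
  breaks <- sort(unique(c(schedule$start, schedule$end)))

  advance_to <- function(t_target) {
    while (t < t_target - 1e-12) {
      # forced stops at schedule discontinuities
      nb <- breaks[breaks > t + 1e-12]
      t_stop <- min(c(t_target, nb))
      dt_use <- min(dt, t_stop - t)
      rate <- schedule_rate(schedule, t + dt_use / 2) * 1e-3 / 86400  # m/s
      res <- .richards_step(h, theta, mesh, rate, dt_use * 86400,
                            head_tol = head_tol)
      if (is.null(res)) {
        dt <<- dt_use * 0.3
        if (dt < 1e-8) stop("Richards iteration failed at t = ", signif(t, 6),
                            " d despite step-size reduction")
        next
      }
      h <<- res$h; theta <<- res$theta; q_faces <<- res$q_faces
      cum_in <<- cum_in + res$q_faces[1] * dt_use * 86400
      cum_out <<- cum_out + res$q_faces[mesh$ny + 1] * dt_use * 86400
      t <<- t + dt_use
      dt <<- if (res$iterations <= 5) min(dt_max, dt_use * 1.4)
             else if (res$iterations > 12) dt_use * 0.7 else dt_use
    }
    invisible(t)
  }
  list(
    advance_to = advance_to,
    state = function() structure(list(h = h, theta = theta, q_faces = q_faces,
                                      time = t), class = "water_state"),
    balance = function() data.frame(
      inflow = cum_in, outflow = cum_out,
      storage_change = sum((theta - theta0) * mesh$dy)),
    set_dt = function(v) dt <<- v
  )
}

#' Spin-up to steady-state flow
#'
#' Runs the columnar Richards solver under a constant infiltration rate with
#' progressively larger (pseudo-transient) time steps until the pressure
#' field reaches steady state (`max |dh/dt|` below `tol`). The resulting
#' pressure field serves as the initial condition for the transient
#' simulations. The initial guess is the per-layer unit-gradient profile
#' (`K(h) = rate`), which the iteration then relaxes to satisfy head
#' continuity across layer interfaces.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param rate constant infiltration rate \[mm/d\], >= 0.
#' @param tol steady-state criterion on `max |dh/dt|` \[m/d\].
#' @param max_steps maximum number of pseudo-time steps.
#' @return a `water_state` (fields `h`, `theta`, `q_faces`, `time = 0`).
#' @export
spin_up <- function(mesh, rate = 0.56, tol = 1e-7, max_steps = 400L) {
  stopifnot(rate >= 0)
  q <- rate * 1e-3 / 86400
  # unit-gradient initial guess per cell
  h <- vapply(seq_len(mesh$ny), function(i) {
    lay <- mesh$layers[[mesh$layer_index[i]]]
    f <- function(hh) conductivity_K(hh, lay) - max(q, 1e-12)
    tryCatch(uniroot(f, c(-50, -1e-6), tol = 1e-10)$root, error = function(e) -1)
  }, 0)
  theta <- .theta_vec(h, mesh)
  dt <- 3600  # s
  for (s in seq_len(max_steps)) {
    res <- .richards_step(h, theta, mesh, q, dt, head_tol = 1e-7, max_iter = 40L)
    if (is.null(res)) { dt <- dt * 0.3; next }
    rate_change <- max(abs(res$h - h)) / (dt / 86400)  # m/d
    h <- res$h; theta <- res$theta
    if (rate_change < tol && s > 3)
      return(structure(list(h = h, theta = theta, q_faces = res$q_faces,
                            time = 0), class = "water_state"))
    dt <- min(dt * 1.6, 86400 * 30)
  }
  stop("spin_up did not converge within ", max_steps, " steps")
}

#' Topsoil saturation of a water state
#'
#' Mean degree of saturation (`theta / theta_s`) over a depth interval,
#' thickness-weighted; default interval is the 0--30 cm topsoil.
#'
#' @param state a `water_state`.
#' @param mesh the mesh the state lives on.
#' @param from,to depth interval \[m\].
#' @return saturation in percent.
#' @export
topsoil_saturation <- function(state, mesh, from = 0, to = 0.3) {
  sel <- mesh$y >= from & mesh$y < to
  100 * sum((state$theta[sel] / mesh$ths[sel]) * mesh$dy[sel]) / sum(mesh$dy[sel])
}
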
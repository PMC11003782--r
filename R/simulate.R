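#' @importFrom dplyr bind_rows
NULL

# Precompute the kernel-facing views of a domain: boundary link vectors,
# flux planes (inlet first, then outlets), and scratch arrays.
build_engine <- function(domain, spec) {
  lk <- domain$links
  type_code <- match(lk$type, c("wall", "inlet", "outlet")) - 1L
  plane_site <- integer(0)
  plane_id <- integer(0)
  plane_n <- matrix(0, 0, 3)
  n_planes <- 0L
  if (!is.null(domain$inlet_plane)) {
    n_planes <- 1L
    pl <- domain$inlet_plane
    plane_site <- pl$sites
    plane_id <- rep(1L, length(pl$sites))
    # inward normal: positive flux = inflow; rows carry cell-area weights
    plane_n <- matrix(-pl$normal, length(pl$sites), 3, byrow = TRUE) *
      (pl$area_weights %||% 1)
  }
  for (pl in domain$outlet_planes) {
    n_planes <- n_planes + 1L
    plane_site <- c(plane_site, pl$sites)
    plane_id <- c(plane_id, rep(n_planes, length(pl$sites)))
    plane_n <- rbind(plane_n,
                     matrix(pl$normal, length(pl$sites), 3, byrow = TRUE) *
                       (pl$area_weights %||% 1))
  }
  n <- domain$n_fluid
  list(
    ln_site = as.integer(lk$site), ln_dir = as.integer(lk$dir),
    ln_type = as.integer(type_code), ln_q = as.numeric(lk$q),
    ln_nbr2 = as.integer(lk$nbr2), ln_out = as.integer(lk$outlet),
    ln_nx = lk$nx, ln_ny = lk$ny, ln_nz = lk$nz,
    ln_wx = lk$wx, ln_wy = lk$wy, ln_wz = lk$wz,
    plane_site = as.integer(plane_site), plane_id = as.integer(plane_id),
    plane_n = plane_n, n_planes = n_planes,
    fs = matrix(0, n, 19L),
    rho = numeric(n), ux = numeric(n), uy = numeric(n), uz = numeric(n)
  )
}

#' One full lattice-Boltzmann step (reference implementation)
#'
#' Composes [trt_collide()], [stream()] and the boundary appliers in pure
#' R. Used as the oracle for the compiled fused kernel that
#' [run_simulation()] drives; both paths implement the identical scheme.
#'
#' @param f population matrix (sites x 19)
#' @param domain a `voxel_domain`
#' @param spec a [lattice_spec()]
#' @param uc_lat inlet centre velocity (lattice units)
#' @param rho_out_lat imposed outlet densities (lattice units), one per
#'   outlet plane
#' @param wall_props optional [wall_properties()]
#' @param g optional body acceleration (lattice units, length 3)
#' @return updated population matrix
#' @export
lbm_step_r <- function(f, domain, spec, uc_lat = 0, rho_out_lat = NULL,
                       wall_props = NULL, g = NULL) {
  f_post <- trt_collide(f, spec, g = g)
  f_new <- stream(f_post, domain)
  apply_links_r(f_new, f_post, domain, spec,
                which_type = c("wall", "inlet", "outlet"),
                uc_lat = uc_lat, rho_out = rho_out_lat %||% rep(1, 32),
                wall_props = wall_props)
}

#' Run a lattice-Boltzmann flow simulation
#'
#' Drives the compiled D3Q19 TRT kernel over a voxel domain with the
#' configured boundary conditions: a pulsatile velocity inlet, elastic
#' slip walls (activated at the end of the warm-up, when the reference
#' pressure P0 is frozen from the domain mean), and two-element Windkessel
#' outlet coupling integrated by backward Euler at the lattice timestep.
#' The Windkessel pressures are imposed as gauge differences about their
#' instantaneous mean, keeping the lattice density near its reference.
#'
#' @param domain a `voxel_domain`
#' @param spec a [lattice_spec()]
#' @param inlet optional [inlet_from_numbers()] profile
#' @param wall_props optional [wall_properties()]
#' @param wk optional Windkessel table from [windkessel_parameters()]
#' @param n_steps number of lattice steps (derived from the inlet profile
#'   when omitted)
#' @param g body acceleration in SI (m/s^2): length-3 vector or a
#'   `function(t)` returning one; internally converted to lattice units
#' @param measure optional measurement window `list(start, end,
#'   sample_every)` (s, s, steps): wall traction and outlet flows are
#'   sampled inside it
#' @param collect_wss sample the wall shear vector series inside the window
#' @param f0 optional initial populations (default: rest equilibrium)
#' @param check_every NaN-guard interval in steps
#' @param q_smooth_steps optional time constant (in steps) of an
#'   exponential smoothing of the plane flow forcing the Windkessel ODE
#'   (1 = no smoothing, the default). A mild smoothing acts as a small
#'   numerical inertance; the steady state and the recorded flow series
#'   are unaffected
#' @return an object of class `flow_state`: final populations and fields,
#'   `ma_max`, outlet series tibble (`time_s, outlet_index, Q_m3s, P_Pa`),
#'   inlet flow series, and (optionally) the wall traction series
#' @export
run_simulation <- function(domain, spec, inlet = NULL, wall_props = NULL,
                           wk = NULL, n_steps = NULL, g = NULL,
                           measure = NULL, collect_wss = FALSE, f0 = NULL,
                           check_every = 100L, q_smooth_steps = 1L) {
  eng <- build_engine(domain, spec)
  n <- domain$n_fluid
  f <- f0 %||% equilibrium(rep(1, n), matrix(0, n, 3), spec)
  cu <- spec$dx / spec$dt                       # lattice -> SI velocity
  cp <- spec$rho_ref * cu^2                     # lattice -> SI pressure
  ca <- spec$dt^2 / spec$dx                     # SI accel -> lattice
  if (is.null(n_steps)) {
    if (is.null(inlet)) abort("n_steps required without an inlet profile")
    n_steps <- as.integer(ceiling((inlet$warmup + inlet$n_beats * inlet$T0) /
                                    spec$dt))
  }
  n_out <- length(domain$outlet_planes)
  P_wk <- rep(0, max(n_out, 1))
  Q_f <- rep(0, max(n_out, 1))
  q_alpha <- 1 / max(1, q_smooth_steps)
  rho_out_lat <- rep(1, max(n_out, 1))
  elastic_coef <- 0
  rho0_lat <- 1
  P0 <- NA_real_
  if (!is.null(wall_props) && !is.null(wall_props$rho0_lat)) {
    rho0_lat <- wall_props$rho0_lat
    elastic_coef <- (1 - wall_props$sigma^2) * wall_props$r_hat^2 /
      (wall_props$E * wall_props$h) * CS2_LAT * cp / spec$dx
  }
  f_ratio <- if (is.null(wall_props)) 0 else wall_props$F
  g_fun <- if (is.function(g)) g else function(t) g %||% c(0, 0, 0)
  ma_max <- 0
  warm_steps <- if (!is.null(inlet)) ceiling(inlet$warmup / spec$dt) else -1L

  sample_every <- measure$sample_every %||% 1L
  in_window <- function(t) {
    !is.null(measure) && t >= measure$start - 1e-12 && t <= measure$end + 1e-12
  }
  wss_t <- list()
  wss_times <- numeric(0)
  series <- list()
  q_in_series <- NULL
  q_in_times <- numeric(0)
  out_sites <- lapply(domain$outlet_planes, `[[`, "sites")
  out_norms <- lapply(domain$outlet_planes, function(pl) {
    matrix(pl$normal, length(pl$sites), 3, byrow = TRUE) *
      (pl$area_weights %||% 1)
  })
  in_sites <- domain$inlet_plane$sites
  in_norm <- if (!is.null(domain$inlet_plane)) {
    matrix(-domain$inlet_plane$normal, length(in_sites), 3, byrow = TRUE) *
      (domain$inlet_plane$area_weights %||% 1)
  }
  # volumetric and mass-weighted plane fluxes from the current field
  plane_flux <- function(sites, wnorm) {
    fo <- f[sites, , drop = FALSE]
    mom <- fo %*% D3Q19_C
    r <- rowSums(fo)
    c(vol = sum((mom / r) * wnorm), mass = sum(mom * wnorm))
  }

  for (step in seq_len(n_steps)) {
    t <- step * spec$dt
    uc_lat <- if (is.null(inlet)) 0 else {
      centre_velocity_waveform(min(t, inlet$warmup + inlet$n_beats * inlet$T0),
                               inlet) / cu
    }
    # semi-implicit Windkessel coupling: plane flows measured on the
    # current field feed the backward-Euler pressure update applied in
    # this same step (no one-step lag in the control loop)
    if (n_out > 0 && !is.null(wk)) {
      fx <- vapply(seq_len(n_out), function(k) {
        plane_flux(out_sites[[k]], out_norms[[k]])
      }, numeric(2)) * spec$dx^2 * cu
      Q_out <- fx["vol", ]
      Q_f <- Q_f[seq_len(n_out)] + q_alpha * (Q_out - Q_f[seq_len(n_out)])
      P_wk <- windkessel_step(P_wk[seq_len(n_out)], Q_f, wk$R, wk$C, spec$dt)
      rho_out_lat <- 1 + (P_wk - mean(P_wk)) / (CS2_LAT * cp)
      if (in_window(t) && step %% sample_every == 0L) {
        series[[length(series) + 1L]] <- tibble(
          time_s = t, outlet_index = seq_len(n_out), Q_m3s = Q_out,
          Qm_m3s = fx["mass", ], P_Pa = P_wk)
      }
    }
    res <- lbm_step_cpp(f, eng$fs, domain$nbr, spec$hat_tau_plus,
                        spec$hat_tau_minus,
                        eng$ln_site, eng$ln_dir, eng$ln_type, eng$ln_q,
                        eng$ln_nbr2, eng$ln_out,
                        eng$ln_nx, eng$ln_ny, eng$ln_nz,
                        eng$ln_wx, eng$ln_wy, eng$ln_wz,
                        uc_lat, rho_out_lat,
                        f_ratio, elastic_coef, rho0_lat,
                        g_fun(t) * ca,
                        eng$rho, eng$ux, eng$uy, eng$uz,
                        eng$plane_site, eng$plane_id, eng$plane_n,
                        max(eng$n_planes, 1L))
    if (!res$ok || (step %% check_every == 0L && any(!is.finite(f)))) {
      abort(sprintf("solver diverged (NaN/negative density) at t = %.4g s", t),
            class = "hemouq_error_instability")
    }
    ma_max <- max(ma_max, sqrt(res$umax2) * sqrt(3))
    # elastic wall engages at the end of warm-up: P0 = domain mean pressure
    if (!is.null(wall_props) && elastic_coef == 0 && step == warm_steps) {
      rho0_lat <- mean(eng$rho)
      P0 <- rho0_lat * CS2_LAT * cp
      elastic_coef <- (1 - wall_props$sigma^2) * wall_props$r_hat^2 /
        (wall_props$E * wall_props$h) * CS2_LAT * cp / spec$dx
    }
    if (in_window(t) && step %% sample_every == 0L) {
      if (!is.null(domain$inlet_plane)) {
        q_in_series <- rbind(q_in_series,
                             plane_flux(in_sites, in_norm) * spec$dx^2 * cu)
        q_in_times <- c(q_in_times, t)
      }
      if (collect_wss) {
        wss_t[[length(wss_t) + 1L]] <- wall_shear_from_f(f, domain, spec)
        wss_times <- c(wss_times, t)
      }
    }
  }

  mac <- macroscopics(f, spec)
  out <- list(
    f = f, rho = mac$rho, u_lat = mac$u_lat, U = mac$U, P = mac$P,
    t = n_steps * spec$dt, ma_max = ma_max, valid = ma_max < 0.2,
    spec = spec, P_wk = if (n_out > 0) P_wk[seq_len(n_out)] else numeric(0),
    P0 = P0,
    outlet_series = if (length(series)) bind_rows(series) else NULL,
    inlet_series = if (length(q_in_times)) {
      tibble(time_s = q_in_times, Q_m3s = q_in_series[, "vol"],
             Qm_m3s = q_in_series[, "mass"])
    } else NULL,
    wss_series = if (length(wss_t)) {
      wall_traction_series(
        tau = array(unlist(wss_t),
                    dim = c(nrow(wss_t[[1]]), 3, length(wss_t))),
        times = wss_times)
    } else NULL
  )
  class(out) <- "flow_state"
  out
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t = %.4g s, Ma_max = %.3f (%s)\n",
              x$t, x$ma_max, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}
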
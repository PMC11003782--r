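# Shared fixtures, built once per test run.

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, builder) {
    if (!exists(name, envir = cache)) assign(name, builder(), envir = cache)
    get(name, envir = cache)
  }
})

paper_spec <- function() lattice_spec(1e-4, 6e-5)

# small fusiform phantom with a bulge (11k sites)
small_fusiform <- function() {
  fix("small_fusiform", function() {
    build_fusiform_phantom(8e-4, bulge_amplitude = 4e-4, length = 4e-3,
                           dx = 1e-4)
  })
}

# two-outlet branching phantom with distinct radii
small_branching <- function() {
  fix("small_branching", function() {
    build_branching_phantom(15e-4, c(6e-4, 6.6e-4), length = 40e-4,
                            dx = 1e-4)
  })
}

# random populations near equilibrium
random_state <- function(n, spec, seed = 1, amp = 0.01) {
  withr::with_seed(seed, {
    f <- equilibrium(rep(1, n), matrix(0, n, 3), spec)
    f * (1 + amp * matrix(stats::runif(n * 19, -1, 1), n, 19))
  })
}

# random wall-traction series: n elements, nt samples
random_series <- function(n, nt = 16, seed = 1) {
  withr::with_seed(seed, {
    wall_traction_series(array(stats::rnorm(n * 3 * nt), c(n, 3, nt)),
                         times = seq(0, 1, length.out = nt))
  })
}

# drive the compiled kernel directly with fixed boundary data
kernel_steps <- function(f, domain, spec, n_steps, uc_lat = 0,
                         rho_out = NULL, g_lat = c(0, 0, 0),
                         f_ratio = 0, elastic_coef = 0, rho0_lat = 1) {
  eng <- hemouq:::build_engine(domain, spec)
  rho_out <- rho_out %||% rep(1, max(1, eng$n_planes))
  for (s in seq_len(n_steps)) {
    hemouq:::lbm_step_cpp(f, eng$fs, domain$nbr, spec$hat_tau_plus,
                          spec$hat_tau_minus,
                          eng$ln_site, eng$ln_dir, eng$ln_type, eng$ln_q,
                          eng$ln_nbr2, eng$ln_out,
                          eng$ln_nx, eng$ln_ny, eng$ln_nz,
                          eng$ln_wx, eng$ln_wy, eng$ln_wz,
                          uc_lat, rho_out, f_ratio, elastic_coef, rho0_lat,
                          g_lat,
                          eng$rho, eng$ux, eng$uy, eng$uz,
                          eng$plane_site, eng$plane_id, eng$plane_n,
                          max(eng$n_planes, 1L))
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
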
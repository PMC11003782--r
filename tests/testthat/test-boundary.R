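test_that("inlet profile derives peak velocity and period from Re and Wo", {
  prof <- inlet_from_numbers(600, 11.2, rho = 1050, mu = 0.0035,
                             r_inlet = 7.27e-3)
  expect_equal(prof$U_max, 0.27511, tolerance = 1e-4)
  expect_equal(prof$omega0, 7.9113, tolerance = 1e-4)
  expect_equal(prof$T0, 0.7942, tolerance = 1e-4)
  # defining relations hold to high precision
  expect_equal(prof$U_max * 1050 * 7.27e-3 / 0.0035, 600, tolerance = 1e-10)
  expect_equal(prof$omega0, 11.2^2 * 0.0035 / (1050 * 7.27e-3^2),
               tolerance = 1e-10)
  # linearity: doubling Re doubles U_max, leaves the period alone
  prof2 <- inlet_from_numbers(1200, 11.2, r_inlet = 7.27e-3)
  expect_equal(prof2$U_max, 2 * prof$U_max)
  expect_equal(prof2$T0, prof$T0)
  # configuration error before any run if the lattice cannot carry it
  expect_error(inlet_from_numbers(600, 11.2, r_inlet = 7.27e-3,
                                  spec = lattice_spec(1e-4, 2e-4)),
               class = "hemouq_error_mach")
})

test_that("centre waveform starts at rest, peaks at U_max, repeats each beat", {
  prof <- inlet_from_numbers(600, 11.2, r_inlet = 7.27e-3, n_beats = 10)
  expect_equal(centre_velocity_waveform(0, prof), 0)
  tt <- seq(prof$warmup, prof$warmup + prof$T0, length.out = 5000)
  expect_equal(max(centre_velocity_waveform(tt, prof)), prof$U_max,
               tolerance = 1e-6)
  # periodicity beyond the warm-up
  t2 <- seq(prof$warmup, prof$warmup + 3 * prof$T0, length.out = 400)
  expect_equal(centre_velocity_waveform(t2, prof),
               centre_velocity_waveform(t2 + prof$T0, prof),
               tolerance = 1e-12)
  # forward-dominated beat with a mild diastolic backflow
  beat <- centre_velocity_waveform(tt, prof)
  expect_gt(mean(beat), 0)
  expect_lt(min(beat), 0)
  expect_gt(min(beat), -0.5 * prof$U_max)
  expect_error(centre_velocity_waveform(-1, prof),
               class = "hemouq_error_time")
  expect_error(centre_velocity_waveform(prof$warmup + 11 * prof$T0, prof),
               class = "hemouq_error_time")
})

test_that("elastic wall displacement follows the thin-wall law", {
  props <- wall_properties(E = 9e6, h = 1.775e-3, r_hat = 2.015e-3,
                           sigma = 0.5, P0 = 0)
  expect_equal(wall_displacement(0, props), 0)
  expect_equal(wall_displacement(1000, props), 1.9062e-7, tolerance = 1e-4)
  props2 <- wall_properties(E = 18e6, h = 1.775e-3, r_hat = 2.015e-3)
  expect_equal(wall_displacement(1000, props2),
               wall_displacement(1000, props) / 2)
  expect_equal(sign(wall_displacement(-500, props)), -1)
})

test_that("Murray fractions follow the power law", {
  expect_equal(murray_fractions(c(1e-3, 2e-3), m = 3, ref_index = 1),
               c(1, 8))
  expect_equal(murray_fractions(rep(1.3e-3, 4), m = 2.7), rep(1, 4))
  # published extreme radii, quartic law: (2.91/1.12)^4
  expect_equal(murray_fractions(c(1.12e-3, 2.91e-3), m = 4, ref_index = 1)[2],
               (2.91 / 1.12)^4, tolerance = 1e-12)
})

test_that("Windkessel parameters enforce the ratio and RC structure", {
  wk <- windkessel_parameters(c(1, 2), omega0 = 8, gamma_R = 2^10,
                              gamma_C = 0.5, Z0 = 1e7)
  expect_equal(wk$R[1] / wk$R[2], 2)
  expect_equal(8 * wk$R * wk$C, rep(0.5, 2))
  wk2 <- windkessel_parameters(c(1, 2), 8, 2^11, 0.5, 1e7)
  expect_equal(wk2$R, 2 * wk$R)
  expect_equal(wk2$C, wk$C / 2)
  expect_true(all(wk$R > 0 & wk$C > 0))
})

test_that("the backward-Euler Windkessel update is stable and consistent", {
  # hand-evaluated single step
  expect_equal(windkessel_step(0, 1, 1, 1, 1), 0.5)
  # fixed point P -> R Q under constant flow
  P <- 0
  for (i in 1:5000) P <- windkessel_step(P, 2, 3, 0.5, 0.01)
  expect_equal(P, 6, tolerance = 1e-8)
  # free decay matches exp(-t/RC) to O(dt^2) over 1000 steps
  R <- 2; C <- 0.8; dt <- 1e-3
  P <- 1
  for (i in 1:1000) P <- windkessel_step(P, 0, R, C, dt)
  expect_equal(P, exp(-1 / (R * C)), tolerance = 1e-3)
  # positivity: Q > 0 and P(0) >= 0 keep P nonnegative
  withr::with_seed(11, {
    for (rep in 1:20) {
      P <- runif(1, 0, 5)
      Q <- runif(1, 0, 1)
      R <- runif(1, 0.1, 10); C <- runif(1, 0.1, 10)
      for (i in 1:200) {
        P <- windkessel_step(P, Q, R, C, 0.05)
        expect_gte(P, 0)
      }
    }
  })
})

test_that("imposed inlet inflow matches the analytic profile integral", {
  # steady centre velocity on the parabolic weighting: Q = u_c A / 2
  dom <- build_fusiform_phantom(8e-4, 0, length = 20e-4, dx = 1e-4)
  spec <- lattice_spec(1e-4, 2e-4, Lambda = 3 / 16)
  prof <- inlet_from_numbers(8, 6, r_inlet = dom$inlet_plane$equivalent_radius,
                             n_beats = 60, spec = spec)
  prof$shape <- function(theta) rep(1, length(theta))
  prof$shape_peak <- 1
  st <- run_simulation(dom, spec, inlet = prof, n_steps = 3000,
                       measure = list(start = 2800 * spec$dt,
                                      end = 3000 * spec$dt,
                                      sample_every = 10))
  q_meas <- mean(st$inlet_series$Q_m3s)
  q_ana <- prof$U_max * pi * 8e-4^2 / 2
  expect_equal(q_meas / q_ana, 1, tolerance = 0.03)
})

test_that("rigid no-slip limit and slip ratio of the elastic wall", {
  dx <- 1e-4
  spec <- lattice_spec(dx, 3e-4, Lambda = 3 / 16)
  dom <- channel_domain(12, nx = 3, nz = 3, dx = dx)
  g <- 0.4
  st0 <- run_simulation(dom, spec, n_steps = 5000, g = c(0, 0, g))
  wp0 <- wall_properties(E = 9e6, h = 1.775e-3, r_hat = 2.015e-3, F = 0)
  stF0 <- run_simulation(dom, spec, n_steps = 5000, g = c(0, 0, g),
                         wall_props = wp0)
  # F = 0 with rigid walls reproduces plain halfway bounce-back exactly
  expect_identical(stF0$f, st0$f)
  # F > 0: wall-extrapolated velocity equals F times the adjacent value
  wp <- wall_properties(E = 9e6, h = 1.775e-3, r_hat = 2.015e-3, F = 0.4)
  st1 <- run_simulation(dom, spec, n_steps = 5000, g = c(0, 0, g),
                        wall_props = wp)
  prof1 <- vapply(1:12, function(j) mean(st1$U[dom$coords[, 2] == j, 3]),
                  numeric(1))
  # quadratic extrapolation of the three near-wall layers to the wall
  u_wall <- (15 * prof1[1] - 10 * prof1[2] + 3 * prof1[3]) / 8
  expect_equal(u_wall / (wp$F * prof1[1]), 1, tolerance = 0.05)
})

test_that("outlet pressure imposition and the Hagen-Poiseuille drop", {
  dx <- 1e-4
  dom <- build_fusiform_phantom(8e-4, 0, length = 40e-4, dx = dx)
  spec <- lattice_spec(dx, 2e-4, Lambda = 3 / 16)
  prof <- inlet_from_numbers(8, 6, r_inlet = dom$inlet_plane$equivalent_radius,
                             n_beats = 60, spec = spec)
  prof$shape <- function(theta) rep(1, length(theta))
  prof$shape_peak <- 1
  st <- run_simulation(dom, spec, inlet = prof, n_steps = 4000,
                       measure = list(start = 3800 * spec$dt,
                                      end = 4000 * spec$dt,
                                      sample_every = 10))
  # the single outlet is pinned at gauge zero: measured plane pressure
  # matches the imposed value within 1% of the axial pressure drop
  out_sites <- dom$outlet_planes[[1]]$sites
  p_out <- mean(st$P[out_sites]) - spec$rho_ref * spec$cs^2
  q <- mean(st$inlet_series$Q_m3s)
  dp_ana <- 8 * spec$mu * 40e-4 * q / (pi * 8e-4^4)
  expect_lt(abs(p_out) / dp_ana, 0.05)
  # measured axial drop matches Hagen-Poiseuille
  z <- dom$coords[, 3]
  p_in <- mean(st$P[z == 1]) - spec$rho_ref * spec$cs^2
  p_end <- mean(st$P[z == max(z)]) - spec$rho_ref * spec$cs^2
  dz <- (max(z) - 1) * dx
  expect_equal((p_in - p_end) / (dp_ana * dz / 40e-4), 1, tolerance = 0.1)
})
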
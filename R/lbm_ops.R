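#' Second-order D3Q19 equilibrium populations
#'
#' Standard polynomial equilibrium
#' \eqn{f_i^{eq} = w_i \rho (1 + c_i\cdot u / c_s^2 +
#' (c_i\cdot u)^2 / 2c_s^4 - u^2 / 2c_s^2)} in lattice units
#' (\eqn{c_s^2 = 1/3}). Its zeroth and first moments reproduce the density
#' and momentum exactly.
#'
#' @param rho density vector (lattice units), one entry per site
#' @param U velocity matrix (lattice units), sites x 3
#' @param spec a [lattice_spec()]
#' @return matrix of populations, sites x 19
#' @export
equilibrium <- function(rho, U, spec) {
  if (!is.matrix(U)) U <- matrix(U, ncol = 3)
  speed <- sqrt(rowSums(U^2))
  if (length(speed) && max(speed) / sqrt(CS2_LAT) >= 0.4) {
    abort("equilibrium velocity exceeds the Mach guard (|u|/cs >= 0.4)",
          class = "hemouq_error_mach")
  }
  u2 <- rowSums(U^2)
  feq <- matrix(0, nrow = length(rho), ncol = 19L)
  for (i in seq_len(19L)) {
    cu <- U %*% D3Q19_C[i, ]
    feq[, i] <- D3Q19_W[i] * rho *
      (1 + cu / CS2_LAT + cu^2 / (2 * CS2_LAT^2) - u2 / (2 * CS2_LAT))
  }
  feq
}

#' Macroscopic fields from populations
#'
#' Density is the zeroth moment of the populations, momentum the first;
#' pressure follows the lattice equation of state \eqn{P = \rho c_s^2}.
#' Velocity and pressure are converted to SI with the spec's `dx`, `dt`
#' and `rho_ref`.
#'
#' @param f population matrix (sites x 19, lattice units)
#' @param spec a [lattice_spec()]
#' @param g optional constant body acceleration (lattice units, length 3);
#'   when present the velocity carries the standard half-step force shift
#' @return list with `rho` (lattice), `u_lat` (lattice), `U` (m/s),
#'   `P` (Pa)
#' @export
macroscopics <- function(f, spec, g = NULL) {
  rho <- rowSums(f)
  u <- (f %*% D3Q19_C) / rho
  if (!is.null(g)) u <- sweep(u, 2, g / 2, "+")
  list(rho = rho,
       u_lat = u,
       U = u * (spec$dx / spec$dt),
       P = rho * spec$rho_ref * spec$cs^2)
}

# Guo forcing term, split into even/odd parts relaxed with tau+/tau-.
forcing_term <- function(U, g, spec) {
  n <- nrow(U)
  S <- matrix(0, n, 19L)
  for (i in seq_len(19L)) {
    ci <- D3Q19_C[i, ]
    cu <- U %*% ci
    term <- (matrix(ci, n, 3, byrow = TRUE) - U) / CS2_LAT +
      (cu %*% t(ci)) / CS2_LAT^2
    S[, i] <- D3Q19_W[i] * (term %*% g)
  }
  Sp <- (S + S[, D3Q19_OPP]) / 2
  Sm <- (S - S[, D3Q19_OPP]) / 2
  (1 - 1 / (2 * spec$hat_tau_plus)) * Sp +
    (1 - 1 / (2 * spec$hat_tau_minus)) * Sm
}

#' Two-relaxation-time collision
#'
#' Splits populations into symmetric and antisymmetric parts over opposite
#' direction pairs, \eqn{f_i^\pm = (f_i \pm f_{\bar i})/2}, and relaxes each
#' towards its equilibrium part with \eqn{\tau^+} and \eqn{\tau^-}
#' respectively. Collision conserves mass and momentum site-wise, and with
#' \eqn{\tau^+ = \tau^-} reduces exactly to the BGK operator.
#'
#' @inheritParams macroscopics
#' @param g optional constant body acceleration (lattice units, length 3),
#'   applied with Guo forcing
#' @return post-collision population matrix
#' @export
trt_collide <- function(f, spec, g = NULL) {
  if (any(!is.finite(f))) {
    abort("non-finite populations entering collision",
          class = "hemouq_error_nan")
  }
  mac <- macroscopics(f, spec, g = g)
  feq <- equilibrium(mac$rho, mac$u_lat, spec)
  fp <- (f + f[, D3Q19_OPP]) / 2
  fm <- (f - f[, D3Q19_OPP]) / 2
  feqp <- (feq + feq[, D3Q19_OPP]) / 2
  feqm <- (feq - feq[, D3Q19_OPP]) / 2
  out <- f - (fp - feqp) / spec$hat_tau_plus - (fm - feqm) / spec$hat_tau_minus
  if (!is.null(g)) out <- out + forcing_term(mac$u_lat, g, spec)
  out
}

#' BGK collision (single relaxation time)
#'
#' Independent reference operator used to validate the TRT implementation at
#' the BGK point \eqn{\Lambda = (\tau^+/\Delta t - 1/2)^2}.
#'
#' @inheritParams trt_collide
#' @param tau relaxation time in timestep units
#' @return post-collision population matrix
#' @export
bgk_collide <- function(f, spec, tau = spec$hat_tau_plus) {
  mac <- macroscopics(f, spec)
  feq <- equilibrium(mac$rho, mac$u_lat, spec)
  f - (f - feq) / tau
}

#' Streaming (propagation) step
#'
#' Moves population \eqn{i} from each site to its neighbour along
#' \eqn{c_i}, following the domain's neighbour table (which encodes
#' periodic wrapping where the domain is periodic). Populations whose link
#' crosses a wall, inlet or outlet are not propagated: the corresponding
#' incoming slots are left `NA` for the boundary appliers
#' ([apply_elastic_wall()], [apply_inlet()], [apply_outlet_pressure()]) to
#' fill from the post-collision field.
#'
#' @param f post-collision population matrix (sites x 19)
#' @param domain a [voxel_domain()]
#' @return streamed population matrix with `NA` at boundary-incoming slots
#' @export
stream <- function(f, domain) {
  fn <- matrix(NA_real_, nrow(f), 19L)
  nbr <- domain$nbr
  for (i in seq_len(19L)) {
    ok <- nbr[, i] > 0L
    fn[nbr[ok, i], i] <- f[ok, i]
  }
  fn
}
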
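#' @useDynLib hemouq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort
NULL

# D3Q19 velocity set. Index 1 is the rest population; 2-7 the axis
# directions; 8-19 the face diagonals. `D3Q19_OPP` maps each direction to
# its opposite, which the TRT split and bounce-back rules rely on.
D3Q19_C <- matrix(c(
   0,  0,  0,
   1,  0,  0,  -1,  0,  0,
   0,  1,  0,   0, -1,  0,
   0,  0,  1,   0,  0, -1,
   1,  1,  0,  -1, -1,  0,
   1, -1,  0,  -1,  1,  0,
   1,  0,  1,  -1,  0, -1,
   1,  0, -1,  -1,  0,  1,
   0,  1,  1,   0, -1, -1,
   0,  1, -1,   0, -1,  1
), ncol = 3, byrow = TRUE)

D3Q19_W <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))

D3Q19_OPP <- c(1L, 3L, 2L, 5L, 4L, 7L, 6L, 9L, 8L, 11L, 10L,
               13L, 12L, 15L, 14L, 17L, 16L, 19L, 18L)

# lattice speed of sound squared, in lattice units (dx = dt = 1)
CS2_LAT <- 1 / 3

#' Symmetric relaxation time from the dynamic viscosity
#'
#' In the two-relaxation-time (TRT) collision model the symmetric relaxation
#' time \eqn{\tau^+} sets the kinematic viscosity through
#' \eqn{\mu = \rho c_s^2 (\tau^+ - \Delta t / 2)} with
#' \eqn{c_s = \Delta x / (\sqrt{3}\,\Delta t)} the lattice speed of sound.
#'
#' @param mu dynamic viscosity (Pa s)
#' @param rho fluid density (kg m^-3)
#' @param dx lattice spacing (m)
#' @param dt time step (s)
#' @return symmetric relaxation time \eqn{\tau^+} in seconds
#' @examples
#' # haemodynamic reference constants give tau+/dt = 0.56
#' tau_plus_from_viscosity(0.0035, 1050, 1e-4, 6e-5) / 6e-5
#' @export
tau_plus_from_viscosity <- function(mu, rho, dx, dt) {
  stopifnot(mu >= 0, rho > 0, dx > 0, dt > 0)
  cs2 <- (dx / (sqrt(3) * dt))^2
  mu / (rho * cs2) + dt / 2
}

#' Antisymmetric relaxation time from the magic parameter
#'
#' The TRT magic parameter
#' \eqn{\Lambda = (\tau^+/\Delta t - 1/2)(\tau^-/\Delta t - 1/2)} controls
#' truncation error and stability; given \eqn{\tau^+} and \eqn{\Lambda} it
#' fixes the antisymmetric relaxation time. At
#' \eqn{\Lambda = (\tau^+/\Delta t - 1/2)^2} the model reduces to the BGK
#' (single-relaxation-time) operator.
#'
#' @param tau_plus symmetric relaxation time (s)
#' @param Lambda magic parameter (dimensionless, > 0)
#' @param dt time step (s)
#' @return antisymmetric relaxation time \eqn{\tau^-} in seconds
#' @export
tau_minus_from_magic <- function(tau_plus, Lambda, dt) {
  stopifnot(Lambda > 0, dt > 0)
  hp <- tau_plus / dt - 0.5
  if (hp <= 0) {
    abort("tau_plus/dt must exceed 0.5 to invert the magic-parameter relation",
          class = "hemouq_error_relaxation")
  }
  (0.5 + Lambda / hp) * dt
}

#' Lattice specification for the D3Q19 TRT solver
#'
#' Bundles the discretization constants, the fluid properties and the
#' relaxation parameters. Populations evolve in lattice units; `dx`, `dt`
#' and `rho_ref` convert macroscopic fields to SI at the interface.
#'
#' @param dx lattice spacing (m)
#' @param dt time step (s)
#' @param rho_ref reference fluid density (kg m^-3); default arterial blood
#' @param mu dynamic viscosity (Pa s); default arterial blood
#' @param Lambda magic parameter; default 3/16 places the bounce-back wall
#'   midway between lattice sites
#' @param tau_plus optional explicit symmetric relaxation time (s);
#'   derived from `mu` when omitted
#' @return an object of class `lattice_spec`
#' @export
lattice_spec <- function(dx, dt, rho_ref = 1050, mu = 0.0035,
                         Lambda = 3 / 16, tau_plus = NULL) {
  stopifnot(dx > 0, dt > 0, rho_ref > 0, mu >= 0)
  if (is.null(tau_plus)) tau_plus <- tau_plus_from_viscosity(mu, rho_ref, dx, dt)
  if (tau_plus / dt <= 0.5) {
    abort("tau_plus/dt must exceed 0.5 for a positive viscosity",
          class = "hemouq_error_relaxation")
  }
  tau_minus <- tau_minus_from_magic(tau_plus, Lambda, dt)
  spec <- list(
    dx = dx, dt = dt,
    q = 19L, c_i = D3Q19_C, w_i = D3Q19_W, opp = D3Q19_OPP,
    cs = dx / (sqrt(3) * dt),
    tau_plus = tau_plus, tau_minus = tau_minus, Lambda = Lambda,
    rho_ref = rho_ref, mu = mu,
    # lattice-unit relaxation times used by the kernels
    hat_tau_plus = tau_plus / dt, hat_tau_minus = tau_minus / dt
  )
  class(spec) <- "lattice_spec"
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("<lattice_spec> D3Q19 TRT\n")
  cat(sprintf("  dx = %g m, dt = %g s, cs = %g m/s\n", x$dx, x$dt, x$cs))
  cat(sprintf("  tau+/dt = %.4f, tau-/dt = %.4f, Lambda = %.4g\n",
              x$hat_tau_plus, x$hat_tau_minus, x$Lambda))
  cat(sprintf("  rho = %g kg/m^3, mu = %g Pa s\n", x$rho_ref, x$mu))
  invisible(x)
}

#' Track the maximum Mach number of a run
#'
#' The lattice Boltzmann method approximates incompressible flow only at
#' low Mach number; compressibility errors scale with Ma^2. A run whose
#' maximum Ma over all space and time reaches 0.2 is flagged invalid.
#'
#' @param U velocity matrix (m/s), one row per site, columns x/y/z (or a
#'   numeric vector of speeds)
#' @param spec a [lattice_spec()]
#' @param ma_max previously accumulated maximum Mach number
#' @return a list with `ma_max` (updated running maximum) and `valid`
#' @export
mach_monitor <- function(U, spec, ma_max = 0) {
  speed <- if (is.matrix(U)) sqrt(rowSums(U^2)) else abs(U)
  m <- max(ma_max, if (length(speed)) max(speed) / spec$cs else 0)
  list(ma_max = m, valid = m < 0.2)
}
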
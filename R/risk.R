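# Risk-factor thresholds for aneurysm walls: low TAWSS (mean minus two
# standard deviations of reported infrarenal measurements), high OSI, and
# the ECAP/RRT limits implied by combining the two.
RISK_THRESHOLDS <- c(tawss_low = 0.11, osi_high = 0.30,
                     ecap_high = 2.7, rrt_high = 22.7)

# second-moment products c_ia * c_ib, columns xx, yy, zz, xy, xz, yz
cprod_matrix <- function() {
  C <- D3Q19_C
  cbind(C[, 1]^2, C[, 2]^2, C[, 3]^2,
        C[, 1] * C[, 2], C[, 1] * C[, 3], C[, 2] * C[, 3])
}

# Wall shear vectors (Pa) at every wall element from the local
# non-equilibrium populations: deviatoric momentum-flux tensor scaled by
# -(1 - dt/(2 tau+)), traction against the outward normal, tangential
# projection. Fully local; no velocity gradients are formed.
wall_shear_from_f <- function(f, domain, spec) {
  w <- domain$wall_sites
  nm <- domain$wall_normals
  fw <- f[w, , drop = FALSE]
  rho <- rowSums(fw)
  u <- (fw %*% D3Q19_C) / rho
  feq <- equilibrium(rho, u, spec)
  fneq <- fw - feq
  Pi <- fneq %*% cprod_matrix()
  tr <- (Pi[, 1] + Pi[, 2] + Pi[, 3]) / 3
  Pi[, 1:3] <- Pi[, 1:3] - tr
  scale <- -(1 - 1 / (2 * spec$hat_tau_plus)) * spec$rho_ref *
    (spec$dx / spec$dt)^2
  S <- Pi * scale
  # traction t = S . n
  tx <- S[, 1] * nm[, 1] + S[, 4] * nm[, 2] + S[, 5] * nm[, 3]
  ty <- S[, 4] * nm[, 1] + S[, 2] * nm[, 2] + S[, 6] * nm[, 3]
  tz <- S[, 5] * nm[, 1] + S[, 6] * nm[, 2] + S[, 3] * nm[, 3]
  tn <- tx * nm[, 1] + ty * nm[, 2] + tz * nm[, 3]
  cbind(tx - tn * nm[, 1], ty - tn * nm[, 2], tz - tn * nm[, 3])
}

#' Wall shear stress vectors from a flow state
#'
#' Extracts the tangential traction exerted by the fluid on the wall at
#' every wall element, using the local non-equilibrium momentum-flux
#' tensor (no finite-difference velocity gradients). By construction the
#' returned vectors are orthogonal to the wall normals.
#'
#' @param state a `flow_state` from [run_simulation()], or a population
#'   matrix
#' @param domain the `voxel_domain` the state lives on
#' @param spec a [lattice_spec()]
#' @return matrix (wall elements x 3) of wall shear vectors in Pa
#' @export
wall_shear_vector <- function(state, domain, spec) {
  f <- if (is.matrix(state)) state else state$f
  wall_shear_from_f(f, domain, spec)
}

#' Wall traction time series container
#'
#' @param tau array (wall elements x 3 x time samples) of wall shear
#'   vectors (Pa)
#' @param times sample times (s), uniformly spaced, at least 2
#' @return an object of class `wall_traction_series`
#' @export
wall_traction_series <- function(tau, times) {
  stopifnot(length(dim(tau)) == 3, dim(tau)[2] == 3,
            dim(tau)[3] == length(times), length(times) >= 2)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt))) {
    abort("traction series must be uniformly sampled",
          class = "hemouq_error_series")
  }
  structure(list(tau = tau, times = times, sampling = dt[1]),
            class = "wall_traction_series")
}

# trapezoidal time integral over the last array dimension
trapz_series <- function(x, times) {
  nt <- length(times)
  w <- c(0.5, rep(1, nt - 2), 0.5) * (times[nt] - times[1]) / (nt - 1)
  if (is.matrix(x)) as.vector(x %*% w) else sum(x * w)
}

#' Time-averaged wall shear stress
#'
#' Trapezoidal time average of the wall shear magnitude
#' \eqn{\lVert\tau_w\rVert} over the measurement window, per wall element.
#'
#' @param series a [wall_traction_series()]
#' @return TAWSS (Pa) per wall element
#' @export
tawss <- function(series) {
  mag <- sqrt(apply(series$tau^2, c(1, 3), sum))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1)
  trapz_series(mag, series$times) / (max(series$times) - min(series$times))
}

#' Oscillatory shear index
#'
#' \eqn{OSI = (1 - \lVert\int \tau_w dt\rVert / \int \lVert\tau_w\rVert
#' dt) / 2}: 0 for a WSS vector collinear with its time average throughout,
#' 0.5 when the mean WSS vector vanishes. An identically zero series is
#' assigned OSI 0.
#'
#' @param series a [wall_traction_series()]
#' @return OSI (dimensionless, in `[0, 0.5]`) per wall element
#' @export
osi <- function(series) {
  nt <- dim(series$tau)[3]
  ints <- sapply(1:3, function(a) {
    trapz_series(matrix(series$tau[, a, ], ncol = nt), series$times)
  })
  if (is.null(dim(ints))) ints <- matrix(ints, nrow = 1)
  num <- sqrt(rowSums(ints^2))
  mag <- sqrt(apply(series$tau^2, c(1, 3), sum))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1)
  den <- trapz_series(mag, series$times)
  out <- 0.5 * (1 - num / den)
  out[den == 0] <- 0
  pmin(pmax(out, 0), 0.5)
}

#' Endothelial cell activation potential
#'
#' \eqn{ECAP = OSI / TAWSS}; combines low shear magnitude and high
#' oscillation into one atherogenic-risk indicator. A vanishing TAWSS
#' yields an infinite sentinel, excluded from ensemble statistics.
#'
#' @param tawss TAWSS values (Pa)
#' @param osi OSI values
#' @return ECAP (1/Pa)
#' @export
ecap <- function(tawss, osi) {
  out <- ifelse(tawss > 0, osi / tawss, Inf)
  out[tawss == 0 & osi == 0] <- Inf
  out
}

#' Relative residence time
#'
#' \eqn{RRT = [(1 - 2\,OSI)\,TAWSS]^{-1}}, the reciprocal magnitude of the
#' time-averaged WSS vector: large where fluid resides near the wall.
#' Infinite sentinel where OSI = 0.5 or TAWSS = 0.
#'
#' @inheritParams ecap
#' @return RRT (1/Pa)
#' @export
rrt <- function(tawss, osi) {
  den <- (1 - 2 * osi) * tawss
  ifelse(den > 0, 1 / den, Inf)
}

#' Threshold masks for the risk factors
#'
#' Strict comparisons against the configured clinical thresholds:
#' TAWSS < 0.11 Pa, OSI > 0.30, ECAP > 2.7 1/Pa, RRT > 22.7 1/Pa.
#'
#' @param field tibble with columns `tawss`, `osi`, `ecap`, `rrt`
#'   (see [risk_factor_field()])
#' @return tibble of four logical mask columns
#' @export
threshold_masks <- function(field) {
  tibble(
    low_tawss = field$tawss < RISK_THRESHOLDS[["tawss_low"]],
    high_osi = field$osi > RISK_THRESHOLDS[["osi_high"]],
    high_ecap = field$ecap > RISK_THRESHOLDS[["ecap_high"]],
    high_rrt = field$rrt > RISK_THRESHOLDS[["rrt_high"]]
  )
}

#' Risk factor field over the wall elements
#'
#' Derives TAWSS, OSI, ECAP and RRT per wall element from a traction
#' series, with the threshold masks, as one tidy table. Wall element
#' coordinates are attached when the domain is supplied.
#'
#' @param series a [wall_traction_series()]
#' @param domain optional `voxel_domain` for element coordinates
#' @return tibble, one row per wall element
#' @export
risk_factor_field <- function(series, domain = NULL) {
  ta <- tawss(series)
  os <- osi(series)
  out <- tibble(element = seq_along(ta), tawss = ta, osi = os,
                ecap = ecap(ta, os), rrt = rrt(ta, os))
  if (!is.null(domain)) {
    pos <- (domain$coords[domain$wall_sites, , drop = FALSE] - 0.5) * domain$dx
    out$x <- pos[, 1]; out$y <- pos[, 2]; out$z <- pos[, 3]
  }
  dplyr::bind_cols(out, threshold_masks(out))
}

#' Plane-integrated flow rate
#'
#' Discrete surface integral \eqn{Q = \sum (U \cdot \hat n)\,w\,\Delta x^2}
#' over the sites of a boundary plane, where the weights `w` are the
#' fluid-area fractions of the rim cells (1 in the interior).
#'
#' @param state a `flow_state` (or a velocity matrix in m/s)
#' @param plane an inlet/outlet plane record of a `voxel_domain`
#' @param spec a [lattice_spec()] (needed when `state` is a bare matrix)
#' @return flow rate (m^3/s)
#' @export
flow_rate <- function(state, plane, spec = state$spec) {
  U <- if (is.matrix(state)) state else state$U
  w <- plane$area_weights %||% 1
  sum((U[plane$sites, , drop = FALSE] %*% plane$normal) * w) * spec$dx^2
}

#' Relative errors of measured outlet flow ratios
#'
#' Normalizes mean measured flows by the reference outlet and compares with
#' the desired Murray fractions:
#' \eqn{err_j = (\langle Q_j\rangle / \langle Q_{ref}\rangle - \phi_j) /
#' \phi_j}. The reference outlet is excluded (its error is identically 0).
#'
#' @param q_mean mean measured flow per outlet (m^3/s)
#' @param phi desired flow fractions ([murray_fractions()])
#' @param ref_index reference outlet index
#' @return tibble with measured ratio, desired ratio and relative error per
#'   non-reference outlet
#' @export
q_ratio_errors <- function(q_mean, phi, ref_index = 1L) {
  stopifnot(length(q_mean) == length(phi))
  ratio <- q_mean / q_mean[ref_index]
  out <- tibble(outlet = seq_along(phi), measured_ratio = ratio,
                desired_ratio = phi,
                rel_error = (ratio - phi) / phi)
  out[-ref_index, ]
}

#' Measurement window from the phase fraction
#'
#' The window starts between the last four and three beats,
#' \eqn{T_s = t_f - 4T_0 + u\,T_0} with phase fraction \eqn{u \in [0,1]},
#' and lasts three beats (\eqn{T_f - T_s = 3T_0}).
#'
#' @param t_f final simulation time (s)
#' @param T0 beat period (s)
#' @param u phase fraction in `[0, 1]`
#' @return list with `T_s`, `T_f`, `T0`, `t_f`, `phase_fraction`
#' @export
measurement_window <- function(t_f, T0, u = 0) {
  stopifnot(u >= 0, u <= 1, T0 > 0, t_f >= 4 * T0)
  T_s <- t_f - 4 * T0 + u * T0
  list(T_s = T_s, T_f = T_s + 3 * T0, T0 = T0, t_f = t_f,
       phase_fraction = u)
}
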
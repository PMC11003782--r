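#' Uncertain input space of the haemodynamic model
#'
#' The default space holds the nine varied inputs of the simulation model
#' with their distributions — the TRT magic parameter (log-uniform over
#' `[0.0036, 0.25]`, spanning the BGK point and the optimal-stability
#' value 1/4), Reynolds and Womersley numbers (uniform, +/-10% about the
#' resting-aorta values 600 and 11.2), effective Young's modulus (uniform
#' `[3.32, 27.57]` MPa, see [e_range_helper()]), boundary velocity ratio F,
#' Murray exponent m, Windkessel scaling factors (log-uniform over
#' `[2^8, 2^12]` and `[2^-4, 2^0]`), and the measurement phase fraction
#' (uniform `[0, 1]`, parameterizing the start time T_s) — together with
#' the constants (lattice spacing and step, blood density and viscosity,
#' Poisson ratio, effective radius and wall thickness, final time).
#'
#' @param varied_only drop the constant rows
#' @return tibble with columns `name`, `dist` (`uniform`, `loguniform`,
#'   `constant`), `lower`, `upper` (for constants both carry the value)
#' @export
parameter_space <- function(varied_only = FALSE) {
  sp <- tibble(
    name = c("Lambda", "Re", "Wo", "E", "F", "m", "gamma_R", "gamma_C",
             "T_s",
             "dx", "dt", "rho", "mu", "sigma", "r_hat", "h", "t_f"),
    dist = c("loguniform", "uniform", "uniform", "uniform", "uniform",
             "uniform", "loguniform", "loguniform", "uniform",
             rep("constant", 8)),
    lower = c(0.0036, 540, 10.1, 3.32e6, 0.32, 1, 2^8, 2^-4, 0,
              1e-4, 6e-5, 1050, 0.0035, 0.5, 2.015e-3, 1.775e-3, 9.2),
    upper = c(0.25, 660, 12.3, 27.57e6, 0.76, 4, 2^12, 2^0, 1,
              1e-4, 6e-5, 1050, 0.0035, 0.5, 2.015e-3, 1.775e-3, 9.2)
  )
  if (varied_only) sp[sp$dist != "constant", ] else sp
}

varied_rows <- function(space) space[space$dist != "constant", , drop = FALSE]

#' Coefficient of variation of an input distribution
#'
#' Closed forms: a uniform distribution on `[a, b]` has
#' \eqn{CV = (b - a) / (\sqrt{3}(a + b))}; a log-uniform distribution uses
#' \eqn{E[X] = (b-a)/\ln(b/a)} and \eqn{E[X^2] = (b^2-a^2)/(2\ln(b/a))};
#' constants have CV 0. Vectorized.
#'
#' @param dist distribution kind(s): `uniform`, `loguniform`, `constant`
#' @param lower,upper bounds
#' @return CV (dimensionless)
#' @export
distribution_cv <- function(dist, lower, upper) {
  out <- numeric(length(dist))
  u <- dist == "uniform"
  out[u] <- (upper[u] - lower[u]) / (sqrt(3) * (upper[u] + lower[u]))
  l <- dist == "loguniform"
  if (any(l)) {
    a <- lower[l]; b <- upper[l]
    L <- log(b / a)
    ex <- (b - a) / L
    ex2 <- (b^2 - a^2) / (2 * L)
    out[l] <- sqrt(ex2 / ex^2 - 1)
  }
  out
}

#' Per-input CVs of a parameter space
#'
#' @param space a [parameter_space()] tibble
#' @return tibble with `name` and `cv` for the varied inputs
#' @export
input_cvs <- function(space) {
  v <- varied_rows(space)
  tibble(name = v$name, cv = distribution_cv(v$dist, v$lower, v$upper))
}

#' Average input coefficient of variation
#'
#' Mean of the varied inputs' CVs — the denominator of the coefficient of
#' variation ratio.
#'
#' @param space a [parameter_space()] tibble
#' @return scalar CV
#' @export
average_input_cv <- function(space) {
  cv <- input_cvs(space)$cv
  if (length(cv) == 0) 0 else mean(cv)
}

#' Coefficient of variation ratio of a quantity of interest
#'
#' \eqn{CVR(Y) = CV(Y) / \overline{CV}(X)}: values above one mean the model
#' amplifies the input uncertainty.
#'
#' @param qoi_mean mean of the QoI
#' @param qoi_var variance of the QoI
#' @param avg_input_cv average input CV ([average_input_cv()])
#' @return CVR (dimensionless)
#' @export
cvr <- function(qoi_mean, qoi_var, avg_input_cv) {
  if (any(qoi_mean == 0)) {
    abort("CVR undefined for a zero-mean quantity of interest",
          class = "hemouq_error_cvr")
  }
  (sqrt(qoi_var) / abs(qoi_mean)) / avg_input_cv
}

#' Size of the total-degree polynomial chaos basis
#'
#' \eqn{N_p = \binom{n + p}{p}} terms of total degree at most `p` in `n`
#' inputs.
#'
#' @param n number of inputs
#' @param p polynomial degree
#' @return basis size (integer)
#' @export
basis_size <- function(n, p) as.integer(round(choose(n + p, p)))

# all multi-indices in N^n with total degree <= p, ordered by total degree
multi_index_set <- function(n, p) {
  grow <- function(prefix, remaining, budget) {
    if (remaining == 0) return(matrix(prefix, nrow = 1))
    do.call(rbind, lapply(0:budget, function(k) {
      grow(c(prefix, k), remaining - 1, budget - k)
    }))
  }
  m <- grow(integer(0), n, p)
  m[order(rowSums(m)), , drop = FALSE]
}

# orthonormal Legendre values: column k+1 holds sqrt(2k+1) P_k(xi)
legendre_orthonormal <- function(xi, p) {
  out <- matrix(0, length(xi), p + 1)
  out[, 1] <- 1
  if (p >= 1) out[, 2] <- xi
  if (p >= 2) {
    for (k in 1:(p - 1)) {
      out[, k + 2] <- ((2 * k + 1) * xi * out[, k + 1] - k * out[, k]) / (k + 1)
    }
  }
  sweep(out, 2, sqrt(2 * seq(0, p) + 1), "*")
}

# map physical samples to the standard interval [-1, 1] per varied input;
# log-uniform inputs enter through their logarithm so the transformed
# marginal is uniform and the Legendre basis stays orthonormal
to_standard <- function(space, X) {
  v <- varied_rows(space)
  X <- as.matrix(X[, v$name, drop = FALSE])
  xi <- X
  for (j in seq_len(nrow(v))) {
    a <- v$lower[j]; b <- v$upper[j]
    xi[, j] <- if (v$dist[j] == "loguniform") {
      2 * (log(X[, j]) - log(a)) / (log(b) - log(a)) - 1
    } else {
      2 * (X[, j] - a) / (b - a) - 1
    }
  }
  xi
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Draw a space-filling sample design
#'
#' Seeded Latin hypercube on the unit cube, mapped through each input's
#' transform (log-uniform inputs are uniform in the logarithm). The global
#' RNG state is left untouched.
#'
#' @param space a [parameter_space()] tibble
#' @param count number of samples
#' @param seed integer seed; identical seeds give identical designs
#' @return tibble of sampled values, one column per varied input
#' @export
draw_samples <- function(space, count, seed = 1L) {
  v <- varied_rows(space)
  n <- nrow(v)
  u <- with_seed(seed, lhs::randomLHS(count, n))
  out <- matrix(0, count, n)
  for (j in seq_len(n)) {
    a <- v$lower[j]; b <- v$upper[j]
    out[, j] <- if (v$dist[j] == "loguniform") {
      exp(log(a) + u[, j] * (log(b) - log(a)))
    } else {
      a + u[, j] * (b - a)
    }
  }
  colnames(out) <- v$name
  as_tibble(out)
}

#' Fit a polynomial chaos expansion by regression
#'
#' Least-squares projection of sampled model outputs onto the orthonormal
#' tensor-Legendre basis of total degree at most `p` over the transformed
#' inputs. The fit is exact (to solver tolerance) whenever `Y` is a
#' polynomial of total degree at most `p` in the transformed inputs.
#' Multiple QoIs (columns of `Y`) share one factorization of the design
#' matrix.
#'
#' @param X sample design (tibble/matrix with one column per varied input)
#' @param Y outputs: vector, or matrix with one column per QoI
#' @param p polynomial degree
#' @param space the [parameter_space()] the design was drawn from
#' @return an object of class `pce_model`
#' @export
fit_pce <- function(X, Y, p, space = parameter_space()) {
  v <- varied_rows(space)
  n <- nrow(v)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(X) == nrow(Y))
  mi <- multi_index_set(n, p)
  np <- nrow(mi)
  if (nrow(X) < np) {
    abort(sprintf("need at least Np = %d samples for degree %d (have %d); recommended 2*Np",
                  np, p, nrow(X)), class = "hemouq_error_design")
  }
  xi <- to_standard(space, X)
  legs <- lapply(seq_len(n), function(j) legendre_orthonormal(xi[, j], p))
  Psi <- matrix(1, nrow(X), np)
  for (a in seq_len(np)) {
    for (j in seq_len(n)) {
      k <- mi[a, j]
      if (k > 0) Psi[, a] <- Psi[, a] * legs[[j]][, k + 1]
    }
  }
  qrd <- qr(Psi)
  if (qrd$rank < np) {
    abort("rank-deficient PCE design matrix; draw more samples",
          class = "hemouq_error_design")
  }
  coef <- qr.coef(qrd, Y)
  resid <- Y - Psi %*% coef
  structure(list(
    degree = p, n_inputs = n, multi_index = mi, basis_size = np,
    coef = coef, qoi_names = colnames(Y) %||% paste0("qoi", seq_len(ncol(Y))),
    input_names = v$name, n_samples = nrow(X),
    rms_residual = sqrt(colMeans(resid^2)),
    condition = kappa(qr.R(qrd), exact = FALSE),
    space = space
  ), class = "pce_model")
}

#' @export
print.pce_model <- function(x, ...) {
  cat(sprintf("<pce_model> degree %d, %d inputs, Np = %d, %d samples, %d QoI(s)\n",
              x$degree, x$n_inputs, x$basis_size, x$n_samples, ncol(x$coef)))
  cat(sprintf("  max RMS residual %.3g, design condition %.3g\n",
              max(x$rms_residual), x$condition))
  invisible(x)
}

#' Moments of a fitted polynomial chaos expansion
#'
#' On an orthonormal basis the mean is the constant coefficient and the
#' variance the sum of the squared remaining coefficients.
#'
#' @param model a [fit_pce()] model
#' @return tibble with `qoi`, `mean`, `variance`
#' @export
pce_moments <- function(model) {
  co <- model$coef
  tibble(qoi = model$qoi_names,
         mean = co[1, ],
         variance = colSums(co[-1, , drop = FALSE]^2))
}

#' Sobol' sensitivity indices from PCE coefficients
#'
#' Variance-based first-order, second-order and total indices read off the
#' coefficient groups of the orthonormal expansion: \eqn{S_i} sums the
#' squared coefficients whose multi-index involves only input i, divided
#' by the variance; \eqn{S_{ij}} the pure i-j interactions; \eqn{S_{T,i}}
#' everything involving i.
#'
#' @param model a [fit_pce()] model
#' @return an object of class `sobol_indices`: list with `first` and
#'   `total` (inputs x QoIs matrices) and `second` (tibble)
#' @export
sobol_from_pce <- function(model) {
  mi <- model$multi_index
  co <- model$coef
  v <- colSums(co[-1, , drop = FALSE]^2)
  v[v == 0] <- NA_real_
  n <- model$n_inputs
  m <- ncol(co)
  inv <- mi > 0
  co2 <- co^2
  first <- matrix(0, n, m, dimnames = list(model$input_names, model$qoi_names))
  total <- first
  for (i in seq_len(n)) {
    only_i <- inv[, i] & rowSums(inv) == 1
    any_i <- inv[, i]
    first[i, ] <- colSums(co2[only_i, , drop = FALSE]) / v
    total[i, ] <- colSums(co2[any_i, , drop = FALSE]) / v
  }
  pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(0), 2, 0)
  second <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sel <- inv[, i] & inv[, j] & rowSums(inv) == 2
    tibble(i = model$input_names[i], j = model$input_names[j],
           qoi = model$qoi_names,
           value = colSums(co2[sel, , drop = FALSE]) / v)
  })
  if (nrow(second) == 0) {
    second <- tibble(i = character(), j = character(), qoi = character(),
                     value = numeric())
  }
  first[is.na(first)] <- 0
  total[is.na(total)] <- 0
  second$value[is.na(second$value)] <- 0
  structure(list(first = first, total = total, second = second,
                 variance = unname(v)),
            class = "sobol_indices")
}

#' @export
print.sobol_indices <- function(x, ...) {
  cat("<sobol_indices> first-order:\n")
  print(round(x$first, 4))
  invisible(x)
}

#' Monte Carlo Sobol' indices (Saltelli pick-freeze estimator)
#'
#' Independent validation oracle for [sobol_from_pce()]: two seeded sample
#' matrices A and B and the radial AB_i designs give the Sobol'-Saltelli
#' first-order estimator \eqn{V_i = mean(f_B (f_{AB_i} - f_A))} and the
#' Jansen total-order estimator
#' \eqn{V_{T,i} = mean((f_A - f_{AB_i})^2)/2}.
#'
#' @param fn model function taking a tibble of inputs, returning a numeric
#'   vector
#' @param space a [parameter_space()] tibble
#' @param n_mc Monte Carlo base sample size
#' @param seed integer seed
#' @return list with `first` and `total` named vectors
#' @export
mc_sobol_oracle <- function(fn, space, n_mc = 1e4, seed = 1L) {
  v <- varied_rows(space)
  n <- nrow(v)
  u <- with_seed(seed, matrix(stats::runif(2 * n_mc * n), 2 * n_mc, n))
  ua <- u[seq_len(n_mc), , drop = FALSE]
  ub <- u[n_mc + seq_len(n_mc), , drop = FALSE]
  phys <- function(uu) {
    out <- matrix(0, nrow(uu), n)
    for (j in seq_len(n)) {
      a <- v$lower[j]; b <- v$upper[j]
      out[, j] <- if (v$dist[j] == "loguniform") {
        exp(log(a) + uu[, j] * (log(b) - log(a)))
      } else a + uu[, j] * (b - a)
    }
    colnames(out) <- v$name
    as_tibble(out)
  }
  fa <- fn(phys(ua))
  fb <- fn(phys(ub))
  V <- stats::var(c(fa, fb))
  first <- total <- setNames(numeric(n), v$name)
  for (i in seq_len(n)) {
    uab <- ua
    uab[, i] <- ub[, i]
    fab <- fn(phys(uab))
    first[i] <- mean(fb * (fab - fa)) / V
    total[i] <- mean((fa - fab)^2) / (2 * V)
  }
  list(first = first, total = total, variance = V)
}

#' Effective Young's modulus interval from combined wall uncertainties
#'
#' The elastic displacement depends on the group \eqn{E h / \hat r^2};
#' holding radius and thickness at their nominal values while varying an
#' effective modulus therefore requires
#' \eqn{E_{eff} = E\,(h / h_0)\,(\hat r_0 / \hat r)^2}, whose extrema over
#' the three input intervals give the sampled modulus range. With the
#' published inputs (E = 9.0 +/- 2.5 MPa, radius 2.015 mm +/- 32%,
#' thickness 1.58-1.97 mm) this yields approximately [3.32, 27.6] MPa.
#'
#' @param E_interval Young's modulus interval (Pa)
#' @param r_hat_interval effective radius interval (m)
#' @param h_interval wall thickness interval (m)
#' @param r_hat_nominal,h_nominal nominal values held constant
#' @return numeric length-2: effective modulus interval (Pa)
#' @export
e_range_helper <- function(E_interval = c(6.5e6, 11.5e6),
                           r_hat_interval = 2.015e-3 * c(0.68, 1.32),
                           h_interval = c(1.58e-3, 1.97e-3),
                           r_hat_nominal = 2.015e-3,
                           h_nominal = 1.775e-3) {
  stopifnot(all(E_interval > 0), all(r_hat_interval > 0), all(h_interval > 0))
  lo <- min(E_interval) * (min(h_interval) / h_nominal) *
    (r_hat_nominal / max(r_hat_interval))^2
  hi <- max(E_interval) * (max(h_interval) / h_nominal) *
    (r_hat_nominal / min(r_hat_interval))^2
  c(lo, hi)
}
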
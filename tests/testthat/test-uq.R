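test_that("input CVs match the closed forms of the published distributions", {
  sp <- parameter_space()
  cvs <- input_cvs(sp)
  get <- function(nm) cvs$cv[cvs$name == nm]
  expect_equal(round(get("Re"), 3), 0.058)
  expect_equal(round(get("Wo"), 3), 0.057)
  expect_equal(distribution_cv("constant", 5, 5), 0)
  expect_equal(distribution_cv("uniform", 0, 1), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(round(average_input_cv(sp), 3), 0.481)
  # log-uniform closed form against direct numerical moments
  a <- 0.0036; b <- 0.25
  xs <- exp(seq(log(a), log(b), length.out = 2e5))
  dens <- 1 / (xs * log(b / a))
  w <- c(diff(xs), 0)
  ex <- sum(xs * dens * w)
  ex2 <- sum(xs^2 * dens * w)
  expect_equal(distribution_cv("loguniform", a, b), sqrt(ex2 / ex^2 - 1),
               tolerance = 1e-3)
})

test_that("CVR divides the output CV by the average input CV", {
  aic <- average_input_cv(parameter_space())
  # published QoI average CV 0.900 gives the reported amplification 1.87
  expect_equal(round(cvr(1, 0.9^2, aic), 2), 1.87)
  expect_equal(cvr(2, (2 * aic)^2, aic), 1)
  # scale invariance of the QoI
  expect_equal(cvr(3 * 2, 9 * 0.25, aic), cvr(2, 0.25, aic))
  expect_error(cvr(0, 1, aic), class = "hemouq_error_cvr")
})

test_that("basis sizes follow the binomial formula", {
  expect_identical(basis_size(9, 2), 55L)
  expect_identical(2L * basis_size(9, 2), 110L)
  expect_identical(basis_size(9, 3), 220L)
  expect_identical(2L * basis_size(9, 3), 440L)
  expect_identical(basis_size(1, 0), 1L)
  expect_identical(nrow(hemouq:::multi_index_set(4, 3)), basis_size(4, 3))
})

test_that("sample designs are seeded, bounded and log-uniform where declared", {
  sp <- parameter_space()
  X1 <- draw_samples(sp, 110, seed = 7)
  X2 <- draw_samples(sp, 110, seed = 7)
  expect_identical(X1, X2)
  expect_false(identical(X1, draw_samples(sp, 110, seed = 8)))
  v <- sp[sp$dist != "constant", ]
  for (j in seq_len(nrow(v))) {
    expect_true(all(X1[[v$name[j]]] >= v$lower[j] &
                      X1[[v$name[j]]] <= v$upper[j]))
  }
  # the log of a log-uniform marginal is uniform (KS test at n = 2000)
  XL <- draw_samples(sp, 2000, seed = 9)
  u <- (log(XL$Lambda) - log(0.0036)) / (log(0.25) - log(0.0036))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 1e-4)
  # drawing does not disturb the global RNG stream
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, {
    invisible(draw_samples(sp, 10, seed = 3))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("the Legendre basis is orthonormal on the transformed cube", {
  withr::with_seed(30, xi <- matrix(runif(2e6, -1, 1), ncol = 2))
  sp <- tibble::tibble(name = c("a", "b"), dist = "uniform",
                       lower = -1, upper = 1)
  mi <- hemouq:::multi_index_set(2, 3)
  L1 <- hemouq:::legendre_orthonormal(xi[, 1], 3)
  L2 <- hemouq:::legendre_orthonormal(xi[, 2], 3)
  Psi <- sapply(seq_len(nrow(mi)), function(a) {
    L1[, mi[a, 1] + 1] * L2[, mi[a, 2] + 1]
  })
  G <- crossprod(Psi) / nrow(Psi)
  expect_lt(max(abs(G - diag(nrow(mi)))), 5e-3)
})

test_that("PCE regression recovers constants, linears and pure interactions", {
  sp <- tibble::tibble(name = c("x1", "x2"), dist = "uniform",
                       lower = 0, upper = 1)
  X <- draw_samples(sp, 60, seed = 12)
  # constant output
  m0 <- fit_pce(X, rep(4.2, 60), p = 2, space = sp)
  expect_equal(m0$coef[1, 1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(m0$coef[-1, ])), 1e-10)
  # standardized first input: mean 0, variance 1/3
  xi <- 2 * as.matrix(X) - 1
  m1 <- fit_pce(X, xi[, 1], p = 2, space = sp)
  mom <- pce_moments(m1)
  expect_equal(mom$mean, 0, tolerance = 1e-10)
  expect_equal(mom$variance, 1 / 3, tolerance = 1e-10)
  s1 <- sobol_from_pce(m1)
  expect_equal(unname(s1$first["x1", 1]), 1, tolerance = 1e-10)
  expect_equal(unname(s1$total["x1", 1]), 1, tolerance = 1e-10)
  # pure interaction: all variance in S12
  m12 <- fit_pce(X, xi[, 1] * xi[, 2], p = 2, space = sp)
  s12 <- sobol_from_pce(m12)
  expect_lt(max(s12$first), 1e-8)
  expect_equal(s12$second$value, 1, tolerance = 1e-8)
  # degenerate design triggers a typed error
  expect_error(fit_pce(X[1:4, ], rep(1, 4), p = 2, space = sp),
               class = "hemouq_error_design")
})

test_that("PCE is exact for polynomials up to its degree", {
  # random polynomials built on the orthonormal basis itself: moments and
  # every Sobol' index have closed forms from the coefficients
  sp <- tibble::tibble(name = paste0("x", 1:3), dist = "uniform",
                       lower = -2, upper = 5)
  p <- 3
  mi <- hemouq:::multi_index_set(3, p)
  X <- draw_samples(sp, 2 * nrow(mi), seed = 13)
  xi <- hemouq:::to_standard(sp, X)
  for (rep in 1:5) {
    withr::with_seed(100 + rep, w_true <- rnorm(nrow(mi)))
    legs <- lapply(1:3, function(j) {
      hemouq:::legendre_orthonormal(xi[, j], p)
    })
    Psi <- sapply(seq_len(nrow(mi)), function(a) {
      legs[[1]][, mi[a, 1] + 1] * legs[[2]][, mi[a, 2] + 1] *
        legs[[3]][, mi[a, 3] + 1]
    })
    Y <- as.vector(Psi %*% w_true)
    fit <- fit_pce(X, Y, p = p, space = sp)
    expect_equal(as.vector(fit$coef), w_true, tolerance = 1e-8)
    mom <- pce_moments(fit)
    expect_equal(mom$mean, w_true[1], tolerance = 1e-8)
    expect_equal(mom$variance, sum(w_true[-1]^2), tolerance = 1e-8)
    sob <- sobol_from_pce(fit)
    V <- sum(w_true[-1]^2)
    inv <- mi > 0
    s1_true <- sapply(1:3, function(i) {
      sum(w_true[inv[, i] & rowSums(inv) == 1]^2) / V
    })
    expect_equal(unname(sob$first[, 1]), s1_true, tolerance = 1e-8)
    st_true <- sapply(1:3, function(i) sum(w_true[inv[, i]]^2) / V)
    expect_equal(unname(sob$total[, 1]), st_true, tolerance = 1e-8)
    expect_true(all(sob$first <= sob$total + 1e-8))
    # partial indices over all non-empty subsets sum to one
    expect_equal(sum(w_true[-1]^2) / V, 1, tolerance = 1e-12)
  }
})

test_that("noisy sparse coefficients are recovered within uncertainty", {
  sp <- tibble::tibble(name = paste0("x", 1:3), dist = "uniform",
                       lower = 0, upper = 1)
  mi <- hemouq:::multi_index_set(3, 2)
  w_true <- numeric(nrow(mi))
  w_true[c(1, 2, 5, 8)] <- c(2, 1, 0.5, 0.3)
  X <- draw_samples(sp, 120, seed = 14)
  xi <- hemouq:::to_standard(sp, X)
  legs <- lapply(1:3, function(j) hemouq:::legendre_orthonormal(xi[, j], 2))
  Psi <- sapply(seq_len(nrow(mi)), function(a) {
    legs[[1]][, mi[a, 1] + 1] * legs[[2]][, mi[a, 2] + 1] *
      legs[[3]][, mi[a, 3] + 1]
  })
  signal <- as.vector(Psi %*% w_true)
  sigma <- 0.01 * stats::sd(signal)
  withr::with_seed(15, Y <- signal + rnorm(length(signal), sd = sigma))
  fit <- fit_pce(X, Y, p = 2, space = sp)
  # 3 sigma of the regression standard error per coefficient
  se <- sigma * sqrt(diag(solve(crossprod(Psi))))
  expect_true(all(abs(fit$coef - w_true) < 3 * se + 1e-12))
})

test_that("Ishigami Sobol' indices match the closed form and the MC oracle", {
  a <- 7; b <- 0.1
  sp <- tibble::tibble(name = paste0("x", 1:3), dist = "uniform",
                       lower = -pi, upper = pi)
  ishigami <- function(X) {
    sin(X$x1) + a * sin(X$x2)^2 + b * X$x3^4 * sin(X$x1)
  }
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  X <- draw_samples(sp, 440, seed = 16)
  fit <- fit_pce(X, ishigami(X), p = 9, space = sp)
  sob <- sobol_from_pce(fit)
  expect_equal(unname(sob$first["x1", 1]), V1 / V, tolerance = 0.01)
  expect_equal(unname(sob$first["x2", 1]), V2 / V, tolerance = 0.01)
  expect_equal(unname(sob$first["x3", 1]), 0, tolerance = 0.01)
  mc <- mc_sobol_oracle(ishigami, sp, n_mc = 1e5, seed = 17)
  expect_equal(unname(mc$first), unname(sob$first[, 1]), tolerance = 0.02)
  expect_equal(unname(mc$total), unname(sob$total[, 1]), tolerance = 0.02)
})

test_that("the MC oracle agrees with PCE Sobol' on a random quadratic", {
  sp <- tibble::tibble(name = paste0("x", 1:3), dist = "uniform",
                       lower = 0, upper = 2)
  fn <- function(X) {
    1 + 2 * X$x1 - X$x2 + 0.5 * X$x1 * X$x2 + 0.3 * X$x3^2
  }
  X <- draw_samples(sp, 80, seed = 18)
  fit <- fit_pce(X, fn(X), p = 2, space = sp)
  sob <- sobol_from_pce(fit)
  mc <- mc_sobol_oracle(fn, sp, n_mc = 1e5, seed = 19)
  expect_equal(unname(mc$first), unname(sob$first[, 1]), tolerance = 0.02)
  expect_equal(unname(mc$total), unname(sob$total[, 1]), tolerance = 0.02)
  # additive part has vanishing second-order index with x3
  s2 <- sob$second
  expect_lt(s2$value[s2$i == "x1" & s2$j == "x3"], 1e-8)
})

test_that("second- and third-order fits agree on smooth responses", {
  sp <- desk_parameter_space()
  fn <- function(X) {
    0.5 + 0.1 * X$Re / 10 + 0.05 * sin(X$Wo) + 0.03 * X$F^2 +
      0.01 * log(X$gamma_R)
  }
  X2 <- draw_samples(sp, 2 * basis_size(9, 2), seed = 20)
  X3 <- draw_samples(sp, 2 * basis_size(9, 3), seed = 21)
  m2 <- pce_moments(fit_pce(X2, fn(X2), p = 2, space = sp))
  m3 <- pce_moments(fit_pce(X3, fn(X3), p = 3, space = sp))
  expect_equal(m2$mean, m3$mean, tolerance = 0.02)
  expect_equal(sqrt(m2$variance) / m2$mean, sqrt(m3$variance) / m3$mean,
               tolerance = 0.02)
})

test_that("the effective modulus interval reproduces the published range", {
  er <- e_range_helper()
  expect_equal(er[1] / 1e6, 3.32, tolerance = 1e-3)
  expect_equal(er[2] / 1e6, 27.6, tolerance = 0.01)
  # zero wall uncertainty passes the modulus interval through
  expect_equal(e_range_helper(c(6.5e6, 11.5e6),
                              r_hat_interval = c(2.015e-3, 2.015e-3),
                              h_interval = c(1.775e-3, 1.775e-3)),
               c(6.5e6, 11.5e6))
  # widening the radius interval widens the output
  wide <- e_range_helper(r_hat_interval = 2.015e-3 * c(0.5, 1.5))
  expect_lt(wide[1], er[1])
  expect_gt(wide[2], er[2])
})

test_that("tidy and glance methods expose the fitted structure", {
  sp <- tibble::tibble(name = c("x1", "x2"), dist = "uniform",
                       lower = 0, upper = 1)
  X <- draw_samples(sp, 30, seed = 23)
  fit <- fit_pce(X, X$x1 + 2, p = 2, space = sp)
  td <- generics::tidy(fit)
  expect_true(all(c("term", "degree", "qoi", "estimate") %in% names(td)))
  expect_equal(nrow(td), basis_size(2, 2))
  gl <- generics::glance(fit)
  expect_equal(gl$basis_size, basis_size(2, 2))
  sob <- sobol_from_pce(fit)
  ts <- generics::tidy(sob)
  expect_setequal(unique(ts$index), c("first", "total", "second"))
  p <- ggplot2::autoplot(sob)
  expect_s3_class(p, "ggplot")
})
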
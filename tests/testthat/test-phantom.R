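test_that("straight tube voxelization matches the analytic cylinder volume", {
  r0 <- 1.12e-3
  dx <- 1e-4
  dom <- build_fusiform_phantom(r0, 0, length = 3e-3, dx = dx)
  expect_equal(dom$n_fluid, pi * r0^2 * 3e-3 / dx^3, tolerance = 0.03)
  # the smallest published vessel spans about 11 sites along its radius
  expect_equal(round(r0 / dx), 11)
  # inlet equivalent radius within one spacing of the requested radius
  expect_lt(abs(dom$inlet_plane$equivalent_radius - r0), dx)
})

test_that("the bulge raises the maximal cross-section by its amplitude", {
  r0 <- 8e-4
  dx <- 1e-4
  dom <- build_fusiform_phantom(r0, bulge_amplitude = 0.5 * r0,
                                length = 4e-3, dx = dx)
  area_by_z <- tapply(seq_len(dom$n_fluid), dom$coords[, 3], length) * dx^2
  rmax <- sqrt(max(area_by_z) / pi)
  expect_lt(abs(rmax - 1.5 * r0), dx)
  # end cross-sections stay at the base radius
  expect_lt(abs(sqrt(area_by_z[[1]] / pi) - r0), dx)
})

test_that("phantom generation is deterministic and guards its inputs", {
  d1 <- build_fusiform_phantom(8e-4, 2e-4, length = 3e-3, dx = 1e-4)
  d2 <- build_fusiform_phantom(8e-4, 2e-4, length = 3e-3, dx = 1e-4)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$links, d2$links)
  expect_error(build_fusiform_phantom(4e-4, 0, length = 3e-3, dx = 1e-4),
               class = "hemouq_error_resolution")
  expect_error(build_fusiform_phantom(8e-4, 4e-4, bulge_halfwidth = 4e-3,
                                      length = 3e-3, dx = 1e-4),
               class = "hemouq_error_geometry")
})

test_that("branching phantom produces ordered, distinct outlet planes", {
  dom <- small_branching()
  expect_length(dom$outlet_planes, 2)
  idx <- vapply(dom$outlet_planes, `[[`, integer(1), "index")
  expect_equal(idx, c(1L, 2L))
  r <- vapply(dom$outlet_planes, `[[`, numeric(1), "equivalent_radius")
  # measured equivalent radii near the requested ones, ordering preserved
  expect_lt(abs(r[1] - 6e-4), 1e-4)
  expect_lt(abs(r[2] - 6.6e-4), 1e-4)
  expect_true(r[1] < r[2])
  # symmetric pair: equal radii measured equal within a spacing
  sym <- build_branching_phantom(14e-4, c(6e-4, 6e-4), length = 30e-4,
                                 dx = 1e-4)
  rs <- vapply(sym$outlet_planes, `[[`, numeric(1), "equivalent_radius")
  expect_lt(abs(rs[1] - rs[2]), 1e-4)
  # published radius span scaled onto the phantom keeps its ordering
  scaled <- sort(c(1.12, 1.37, 2.91) / 1.12 * 6e-4)
  tri <- build_branching_phantom(4.2e-3, scaled, length = 60e-4, dx = 1e-4)
  rt <- vapply(tri$outlet_planes, `[[`, numeric(1), "equivalent_radius")
  expect_equal(order(rt), order(scaled))
  expect_length(unique(vapply(tri$outlet_planes, `[[`, integer(1),
                              "index")), 3)
})

test_that("branching phantom rejects impossible configurations", {
  expect_error(build_branching_phantom(8e-4, c(6e-4, 6e-4),
                                       length = 30e-4, dx = 1e-4),
               class = "hemouq_error_geometry")
  expect_error(build_branching_phantom(20e-4, c(6e-4, rep(6e-4, 10)),
                                       length = 30e-4, dx = 1e-4),
               class = "hemouq_error_geometry")
  expect_error(build_branching_phantom(14e-4, c(3e-4, 6e-4),
                                       length = 30e-4, dx = 1e-4),
               class = "hemouq_error_resolution")
})

test_that("every boundary link is classified and fractions lie in (0, 1]", {
  for (dom in list(small_fusiform(), small_branching())) {
    expect_true(all(dom$links$type %in% c("wall", "inlet", "outlet")))
    expect_true(all(dom$links$q > 0 & dom$links$q <= 1))
    nlen <- sqrt(dom$links$nx^2 + dom$links$ny^2 + dom$links$nz^2)
    expect_equal(nlen[dom$links$type == "wall"],
                 rep(1, sum(dom$links$type == "wall")), tolerance = 1e-6)
    # neighbour table and link table together cover all 18 directions
    covered <- matrix(FALSE, dom$n_fluid, 19)
    covered[dom$nbr > 0] <- TRUE
    covered[cbind(dom$links$site, dom$links$dir)] <- TRUE
    expect_true(all(covered[, -1]))
  }
})

test_that("wall normals of an analytic cylinder point radially outward", {
  dom <- tube_domain(1e-3, nz = 3, dx = 1e-4)
  pos <- (dom$coords[dom$wall_sites, , drop = FALSE] - 0.5) * dom$dx
  rad <- cbind(pos[, 1] - dom$meta$centre, pos[, 2] - dom$meta$centre, 0)
  rad <- rad / sqrt(rowSums(rad^2))
  d <- rowSums(dom$wall_normals * rad)
  expect_gt(mean(d), 0.98)
})

test_that("flat axis-aligned walls get halfway fractions and axis normals", {
  res <- classify_wall_links(array(1L, c(4, 6, 4)), 1e-4,
                             periodic = c(TRUE, FALSE, TRUE))
  expect_true(all(res$wall_links$q == 0.5))
  expect_equal(abs(res$wall_links$ny), rep(1, nrow(res$wall_links)))
  expect_equal(res$wall_links$nx, rep(0, nrow(res$wall_links)))
})

test_that("closed-surface normals integrate to the zero vector", {
  # sphere phantom: by the divergence theorem the area-weighted normals
  # of a closed surface sum to zero
  n <- 24
  dx <- 1e-4
  ctr <- n * dx / 2
  xs <- (seq_len(n) - 0.5) * dx
  g <- expand.grid(x = xs, y = xs, z = xs)
  lab <- array(as.integer((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <
                            (8 * dx)^2), c(n, n, n))
  surface <- function(px, py, pz) {
    sqrt((px - ctr)^2 + (py - ctr)^2 + (pz - ctr)^2) - 8 * dx
  }
  res <- classify_wall_links(lab, dx, surface = surface)
  tot <- colSums(res$wall_normals)
  expect_lt(sqrt(sum(tot^2)) / nrow(res$wall_normals), 0.01)
})

test_that("isolated fluid pockets are flagged", {
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  expect_error(classify_wall_links(lab, 1e-4),
               class = "hemouq_error_geometry")
})

test_that("voxelized cross-section area converges to pi R^2 with dx", {
  R <- 1e-3
  err <- vapply(c(10, 20, 40), function(ns) {
    dx <- R / ns
    dom <- tube_domain(R, nz = 1, dx = dx)
    abs(dom$n_fluid * dx^2 - pi * R^2) / (pi * R^2)
  }, numeric(1))
  # first-order (or better) decay over a 4x refinement
  expect_lt(err[3], err[1])
  fit <- stats::lm(log(err) ~ log(c(10, 20, 40)))
  expect_lt(coef(fit)[2], -0.9)
})

test_that("fluid disconnected from the inlet is dropped", {
  # two parallel tubes, one never touching the inlet face: the stray tube
  # must not survive in the domain
  nx <- 30
  dx <- 1e-4
  xs <- (seq_len(nx) - 0.5) * dx
  lab <- array(0L, c(nx, nx, 20))
  for (k in 1:20) {
    main <- outer((xs - 8e-4)^2, (xs - 15e-4)^2, "+") < (6.5e-4)^2
    stray <- outer((xs - 22e-4)^2, (xs - 15e-4)^2, "+") < (4e-4)^2 & k > 5
    lab[, , k] <- as.integer(main | stray)
  }
  dom <- hemouq:::build_domain_core(lab, dx, inlet_face = "z-",
                                    outlet_face = "z+")
  pos_x <- (dom$coords[, 1] - 0.5) * dx
  expect_true(all(pos_x < 16e-4))
})
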
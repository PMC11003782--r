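#' @importFrom stats setNames
NULL

# Linear index into a 3-d array stored column-major, 1-based.
lin_index <- function(i, j, k, dims) {
  i + (j - 1L) * dims[1] + (k - 1L) * dims[1] * dims[2]
}

# Numerical outward normal of an implicit surface phi (phi < 0 in fluid),
# central differences, normalized.
surface_normal <- function(surface, px, py, pz, h) {
  gx <- surface(px + h, py, pz) - surface(px - h, py, pz)
  gy <- surface(px, py + h, pz) - surface(px, py - h, pz)
  gz <- surface(px, py, pz + h) - surface(px, py, pz - h)
  n <- cbind(gx, gy, gz)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Vectorized bisection for the wall intersection fraction q along a link:
# x(t) = p0 + t * c * dx, t in (0, 1]. Falls back to 0.5 where the surface
# does not bracket a crossing.
link_fractions <- function(surface, p0, cvec, dx) {
  phi0 <- surface(p0[, 1], p0[, 2], p0[, 3])
  p1 <- p0 + cvec * dx
  phi1 <- surface(p1[, 1], p1[, 2], p1[, 3])
  ok <- is.finite(phi0) & is.finite(phi1) & phi0 < 0 & phi1 >= 0
  lo <- rep(0, nrow(p0))
  hi <- rep(1, nrow(p0))
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    pm <- p0 + mid * cvec * dx
    phim <- surface(pm[, 1], pm[, 2], pm[, 3])
    below <- phim < 0
    lo[ok & below] <- mid[ok & below]
    hi[ok & !below] <- mid[ok & !below]
  }
  q <- (lo + hi) / 2
  q[!ok] <- 0.5
  q[q <= 0] <- 0.5
  pmin(q, 1)
}

# Core domain assembly shared by all generators. `labels` is a 3-d 0/1
# array (1 = fluid); `inlet_face`/`outlet_face` name grid faces ("z-","z+",
# NULL); `outlet_id` is an integer array assigning outlet indices to sites
# whose links exit through the outlet face; `surface` an implicit function
# phi(x,y,z) < 0 in fluid used for sub-voxel wall fractions and normals.
build_domain_core <- function(labels, dx, periodic = c(FALSE, FALSE, FALSE),
                              surface = NULL, inlet_face = NULL,
                              outlet_face = NULL, outlet_id = NULL,
                              inlet_weight = NULL, meta = list(),
                              .recheck = TRUE) {
  dims <- dim(labels)
  fluid_lin <- which(labels == 1L)
  if (length(fluid_lin) == 0L) {
    abort("domain has no fluid sites", class = "hemouq_error_geometry")
  }
  n <- length(fluid_lin)
  coords <- arrayInd(fluid_lin, dims)
  site_of <- array(0L, dims)
  site_of[fluid_lin] <- seq_len(n)

  face_axis <- function(face) match(substr(face, 1, 1), c("x", "y", "z"))
  face_sign <- function(face) if (substr(face, 2, 2) == "+") 1L else -1L

  # neighbour table and out-of-range bookkeeping
  nbr <- matrix(0L, n, 19L)
  oor_face <- matrix(0L, n, 19L) # 0 in-range; axis*sign coding for exits
  for (i in 2:19) {
    ci <- D3Q19_C[i, ]
    pp <- sweep(coords, 2, ci, "+")
    exit <- integer(n)
    for (ax in 1:3) {
      if (periodic[ax]) {
        pp[, ax] <- ((pp[, ax] - 1L) %% dims[ax]) + 1L
      } else {
        lowm <- pp[, ax] < 1L
        highm <- pp[, ax] > dims[ax]
        exit[lowm] <- -ax
        exit[highm] <- ax
      }
    }
    inr <- exit == 0L
    dest <- rep(0L, n)
    dest[inr] <- site_of[lin_index(pp[inr, 1], pp[inr, 2], pp[inr, 3], dims)]
    nbr[, i] <- dest
    oor_face[, i] <- exit
  }
  nbr[, 1] <- seq_len(n)

  # connectivity from the inlet plane: unreachable fluid becomes solid
  if (!is.null(inlet_face) && .recheck) {
    ax <- face_axis(inlet_face)
    sg <- face_sign(inlet_face)
    seed <- which(apply(oor_face == sg * ax, 1, any))
    if (length(seed) == 0L) {
      abort("no fluid sites touch the inlet face",
            class = "hemouq_error_geometry")
    }
    reach <- logical(n)
    reach[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- unique(as.vector(nbr[frontier, , drop = FALSE]))
      nxt <- nxt[nxt > 0L]
      nxt <- nxt[!reach[nxt]]
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(reach)) {
      labels[fluid_lin[!reach]] <- 0L
      return(build_domain_core(labels, dx, periodic, surface, inlet_face,
                               outlet_face, outlet_id, inlet_weight, meta,
                               .recheck = FALSE))
    }
  }

  isolated <- rowSums(nbr[, -1, drop = FALSE] > 0L) == 0L &
    rowSums(oor_face != 0L) == 0L
  if (any(isolated)) {
    abort(sprintf("%d fluid site(s) fully surrounded by solid", sum(isolated)),
          class = "hemouq_error_geometry")
  }

  # classify boundary links
  in_ax <- if (is.null(inlet_face)) 0L else face_axis(inlet_face) * face_sign(inlet_face)
  out_ax <- if (is.null(outlet_face)) 0L else face_axis(outlet_face) * face_sign(outlet_face)
  bnd <- which(nbr == 0L & col(nbr) > 1L, arr.ind = TRUE)
  site <- bnd[, 1]
  dir <- bnd[, 2]
  exit <- oor_face[bnd]
  type <- rep("wall", length(site))
  type[exit == in_ax & in_ax != 0L] <- "inlet"
  type[exit == out_ax & out_ax != 0L] <- "outlet"

  # wall fractions and normals
  pos <- (coords - 0.5) * dx
  q <- rep(0.5, length(site))
  nrm <- matrix(0, length(site), 3)
  is_wall <- type == "wall"
  if (any(is_wall)) {
    if (!is.null(surface)) {
      p0 <- pos[site[is_wall], , drop = FALSE]
      cv <- D3Q19_C[dir[is_wall], , drop = FALSE]
      q[is_wall] <- link_fractions(surface, p0, cv, dx)
      pc <- p0 + q[is_wall] * cv * dx
      nrm[is_wall, ] <- surface_normal(surface, pc[, 1], pc[, 2], pc[, 3],
                                       h = 1e-3 * dx)
    } else {
      # solid-indicator gradient: sum_i w_i c_i s(x + c_i), s = 1 if solid
      solid_ind <- matrix(0, n, 19L)
      for (i in 2:19) solid_ind[, i] <- as.numeric(nbr[, i] == 0L & oor_face[, i] == 0L)
      if (is.null(inlet_face)) {
        for (i in 2:19) {
          solid_ind[, i] <- solid_ind[, i] + as.numeric(oor_face[, i] != 0L)
        }
      }
      g <- solid_ind %*% (D3Q19_C * D3Q19_W)
      len <- sqrt(rowSums(g^2))
      len[len == 0] <- 1
      gn <- g / len
      nrm[is_wall, ] <- gn[site[is_wall], , drop = FALSE]
    }
  }
  q[!is_wall] <- 0.5
  # inlet spatial weights times inward face normal
  wvec <- matrix(0, length(site), 3)
  if (any(type == "inlet")) {
    ax <- abs(in_ax)
    nin <- c(0, 0, 0)
    nin[ax] <- -sign(in_ax)
    wgt <- if (is.null(inlet_weight)) rep(1, n) else inlet_weight(pos)
    sel <- type == "inlet"
    wvec[sel, ] <- outer(wgt[site[sel]], nin)
  }

  links <- tibble(
    site = as.integer(site), dir = as.integer(dir), type = type,
    q = q, outlet = 0L,
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    wx = wvec[, 1], wy = wvec[, 2], wz = wvec[, 3],
    nbr2 = nbr[cbind(site, D3Q19_OPP[dir])]
  )
  if (any(type == "outlet")) {
    if (is.null(outlet_id)) {
      links$outlet[links$type == "outlet"] <- 1L
    } else {
      links$outlet[links$type == "outlet"] <-
        outlet_id[fluid_lin[links$site[links$type == "outlet"]]]
    }
  }
  # inlet and outlet link normals point out of the domain face
  sel <- links$type %in% c("inlet", "outlet")
  if (any(sel)) {
    axs <- ifelse(links$type[sel] == "inlet", in_ax, out_ax)
    m <- matrix(0, sum(sel), 3)
    m[cbind(seq_len(sum(sel)), abs(axs))] <- sign(axs)
    links$nx[sel] <- m[, 1]; links$ny[sel] <- m[, 2]; links$nz[sel] <- m[, 3]
  }

  # wall elements: one per wall-adjacent fluid site, averaged unit normal
  wl <- links[links$type == "wall", ]
  wall_sites <- sort(unique(wl$site))
  wall_normals <- NULL
  if (length(wall_sites)) {
    acc <- rowsum(cbind(wl$nx, wl$ny, wl$nz), group = wl$site)
    len <- sqrt(rowSums(acc^2))
    len[len == 0] <- 1
    wall_normals <- acc / len
  }

  axial_dir_for <- function(axcode) {
    which(D3Q19_C[, abs(axcode)] == sign(axcode) &
            rowSums(abs(D3Q19_C)) == 1L)
  }
  # fraction of each plane site's dx^2 cell lying inside the lumen at the
  # face, from the implicit surface (16-point subsampling); rim cells are
  # partly solid and would otherwise bias the plane flux integral
  cell_area_weights <- function(axcode, sites) {
    if (is.null(surface)) return(rep(1, length(sites)))
    ax <- abs(axcode)
    face <- if (sign(axcode) < 0) 0 else dims[ax] * dx
    ctr <- pos[sites, , drop = FALSE]
    off <- as.matrix(expand.grid(s1 = ((1:4) - 0.5) / 4 - 0.5,
                                 s2 = ((1:4) - 0.5) / 4 - 0.5)) * dx
    tang <- setdiff(1:3, ax)
    w <- numeric(length(sites))
    for (k in seq_len(nrow(off))) {
      p <- ctr
      p[, tang[1]] <- p[, tang[1]] + off[k, 1]
      p[, tang[2]] <- p[, tang[2]] + off[k, 2]
      p[, ax] <- face
      w <- w + (surface(p[, 1], p[, 2], p[, 3]) < 0)
    }
    w / nrow(off)
  }
  plane_from <- function(axcode, sites, idx) {
    aw <- cell_area_weights(axcode, sites)
    area <- sum(aw) * dx^2
    nrm <- c(0, 0, 0)
    nrm[abs(axcode)] <- sign(axcode)
    list(index = idx, normal = nrm, area = area, sites = sites,
         area_weights = aw, equivalent_radius = sqrt(area / pi))
  }
  inlet_plane <- NULL
  if (in_ax != 0L) {
    ad <- axial_dir_for(in_ax)
    sites <- sort(links$site[links$type == "inlet" & links$dir == ad])
    inlet_plane <- plane_from(in_ax, sites, 0L)
    wgt <- if (is.null(inlet_weight)) rep(1, n) else inlet_weight(pos)
    inlet_plane$weights <- wgt[sites]
  }
  outlet_planes <- list()
  if (out_ax != 0L) {
    ad <- axial_dir_for(out_ax)
    ol <- links[links$type == "outlet" & links$dir == ad, ]
    for (k in sort(unique(ol$outlet))) {
      outlet_planes[[length(outlet_planes) + 1L]] <-
        plane_from(out_ax, sort(ol$site[ol$outlet == k]), as.integer(k))
    }
  }

  # per-site category labels
  cat_lab <- array(0L, dims)
  cat_lab[fluid_lin] <- 1L
  if (length(wall_sites)) cat_lab[fluid_lin[wall_sites]] <- 2L
  if (!is.null(inlet_plane)) cat_lab[fluid_lin[inlet_plane$sites]] <- 3L
  for (pl in outlet_planes) cat_lab[fluid_lin[pl$sites]] <- 10L + pl$index

  structure(list(
    dx = dx, shape = dims, periodic = periodic,
    labels = cat_lab, fluid_lin = fluid_lin, coords = coords,
    n_fluid = n, nbr = nbr, links = links,
    wall_sites = wall_sites, wall_normals = wall_normals,
    inlet_plane = inlet_plane, outlet_planes = outlet_planes,
    meta = meta
  ), class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  cat("<voxel_domain>", paste(x$shape, collapse = " x "),
      sprintf("grid, dx = %g m\n", x$dx))
  cat(sprintf("  %d fluid sites, %d wall elements, %d wall links\n",
              x$n_fluid, length(x$wall_sites), sum(x$links$type == "wall")))
  if (!is.null(x$inlet_plane)) {
    cat(sprintf("  inlet: area %.3g m^2 (r_eq %.3g m)\n",
                x$inlet_plane$area, x$inlet_plane$equivalent_radius))
  }
  for (pl in x$outlet_planes) {
    cat(sprintf("  outlet %d: area %.3g m^2 (r_eq %.3g m)\n",
                pl$index, pl$area, pl$equivalent_radius))
  }
  invisible(x)
}

#' Voxelized fusiform-aneurysm phantom
#'
#' Generates a straight tube of radius `tube_radius` along z with an
#' axisymmetric Gaussian bulge,
#' \eqn{r(z) = r_0 + a \exp(-(z - L/2)^2 / 2w^2)}, voxelized on a uniform
#' grid with site centres at \eqn{(i - 1/2)\Delta x}. The inlet plane sits
#' at z = 0, the single outlet plane at z = `length`. Sub-voxel wall
#' intersection fractions and outward normals come from the analytic
#' surface. The inlet carries a parabolic spatial weighting (1 at the
#' centre, 0 at the rim).
#'
#' @param tube_radius base tube radius \eqn{r_0} (m)
#' @param bulge_amplitude bulge amplitude \eqn{a} (m, >= 0); 0 gives a
#'   straight tube
#' @param bulge_halfwidth Gaussian half-width \eqn{w} (m); default L/8
#' @param length axial extent L (m)
#' @param dx lattice spacing (m); at least 6 sites per radius are required
#' @return a `voxel_domain`
#' @examples
#' ph <- build_fusiform_phantom(6.5e-4, bulge_amplitude = 3e-4,
#'                              length = 3e-3, dx = 1e-4)
#' ph
#' @export
build_fusiform_phantom <- function(tube_radius, bulge_amplitude = 0,
                                   bulge_halfwidth = length / 8,
                                   length, dx) {
  stopifnot(dx > 0, tube_radius > 0, length > 0, bulge_amplitude >= 0)
  if (tube_radius / dx < 6 - 1e-9) {
    abort("under-resolved: need at least 6 lattice sites per tube radius",
          class = "hemouq_error_resolution")
  }
  if (bulge_amplitude > 0 &&
      bulge_amplitude * exp(-(length / 2)^2 / (2 * bulge_halfwidth^2)) > dx) {
    abort("bulge overflows the tube ends; shorten bulge_halfwidth or grow length",
          class = "hemouq_error_geometry")
  }
  rmax <- tube_radius + bulge_amplitude
  nx <- as.integer(ceiling(2 * rmax / dx)) + 4L
  nz <- as.integer(round(length / dx))
  cx <- nx * dx / 2
  rz <- function(z) {
    zc <- pmin(pmax(z, 0), length)
    tube_radius + bulge_amplitude * exp(-(zc - length / 2)^2 /
                                          (2 * bulge_halfwidth^2))
  }
  surface <- function(px, py, pz) sqrt((px - cx)^2 + (py - cx)^2) - rz(pz)
  xs <- (seq_len(nx) - 0.5) * dx
  zs <- (seq_len(nz) - 0.5) * dx
  dist2 <- outer((xs - cx)^2, (xs - cx)^2, "+")
  labels <- array(0L, c(nx, nx, nz))
  for (k in seq_len(nz)) labels[, , k] <- (dist2 < rz(zs[k])^2) * 1L
  inlet_weight <- function(pos) {
    d2 <- (pos[, 1] - cx)^2 + (pos[, 2] - cx)^2
    pmax(0, 1 - d2 / tube_radius^2)
  }
  build_domain_core(labels, dx, surface = surface,
                    inlet_face = "z-", outlet_face = "z+",
                    inlet_weight = inlet_weight,
                    meta = list(kind = "fusiform", tube_radius = tube_radius,
                                bulge_amplitude = bulge_amplitude,
                                bulge_halfwidth = bulge_halfwidth,
                                length = length, centre = c(cx, cx)))
}

#' Voxelized branching phantom with one inlet and several outlets
#'
#' A trunk vessel of radius `trunk_radius` runs from the inlet plane (z = 0)
#' to a split at 0.45 L, where it divides into `length(outlet_radii)`
#' parallel child vessels with the requested radii, each terminating on the
#' common outlet face at z = L. Outlet indices follow the order of
#' `outlet_radii`. An optional Gaussian bulge (`bulge = list(amplitude,
#' halfwidth)`) dilates the trunk. Child vessels must fit inside the trunk
#' cross-section at the split and must not overlap.
#'
#' @param trunk_radius trunk radius (m)
#' @param outlet_radii child vessel radii (m), 2 to 10 of them
#' @param length total axial extent (m)
#' @param dx lattice spacing (m)
#' @param bulge optional trunk bulge spec
#' @return a `voxel_domain` with one outlet plane per child vessel
#' @export
build_branching_phantom <- function(trunk_radius, outlet_radii, length, dx,
                                    bulge = NULL) {
  n_out <- base::length(outlet_radii)
  stopifnot(dx > 0, trunk_radius > 0, length > 0)
  if (n_out < 2 || n_out > 10) {
    abort("need between 2 and 10 outlets", class = "hemouq_error_geometry")
  }
  if (any(outlet_radii / dx < 6 - 1e-9) || trunk_radius / dx < 6 - 1e-9) {
    abort("under-resolved: all radii need at least 6 lattice sites",
          class = "hemouq_error_resolution")
  }
  rmaxc <- max(outlet_radii)
  amp <- if (is.null(bulge)) 0 else bulge$amplitude
  bw <- if (is.null(bulge)) length / 8 else bulge$halfwidth
  Ls <- 0.45 * length
  d_place <- trunk_radius - dx - rmaxc
  if (d_place <= 0) {
    abort("child vessels do not fit inside the trunk at the split",
          class = "hemouq_error_geometry")
  }
  ang <- 2 * pi * (seq_len(n_out) - 1) / n_out
  ocx <- d_place * cos(ang)
  ocy <- d_place * sin(ang)
  sep <- 2 * d_place * sin(pi / n_out)
  need <- outlet_radii + outlet_radii[c(2:n_out, 1)]
  if (any(sep < need + 2 * dx)) {
    abort("child vessels overlap; reduce radii or enlarge the trunk",
          class = "hemouq_error_geometry")
  }
  rmax <- trunk_radius + amp
  nx <- as.integer(ceiling(2 * rmax / dx)) + 4L
  nz <- as.integer(round(length / dx))
  cx <- nx * dx / 2
  r_trunk <- function(z) {
    zc <- pmin(pmax(z, 0), Ls)
    trunk_radius + amp * exp(-(zc - Ls / 2)^2 / (2 * bw^2))
  }
  child_phi <- function(px, py) {
    phi <- Inf
    for (j in seq_len(n_out)) {
      dj <- sqrt((px - cx - ocx[j])^2 + (py - cx - ocy[j])^2) - outlet_radii[j]
      phi <- pmin(phi, dj)
    }
    phi
  }
  surface <- function(px, py, pz) {
    ifelse(pz < Ls,
           sqrt((px - cx)^2 + (py - cx)^2) - r_trunk(pz),
           child_phi(px, py))
  }
  xs <- (seq_len(nx) - 0.5) * dx
  zs <- (seq_len(nz) - 0.5) * dx
  labels <- array(0L, c(nx, nx, nz))
  outlet_id <- array(0L, c(nx, nx, nz))
  gx <- matrix(xs, nx, nx)
  gy <- matrix(xs, nx, nx, byrow = TRUE)
  for (k in seq_len(nz)) {
    if (zs[k] < Ls) {
      labels[, , k] <- (sqrt((gx - cx)^2 + (gy - cx)^2) < r_trunk(zs[k])) * 1L
    } else {
      sl <- matrix(0L, nx, nx)
      ids <- matrix(0L, nx, nx)
      for (j in seq_len(n_out)) {
        inj <- (gx - cx - ocx[j])^2 + (gy - cx - ocy[j])^2 < outlet_radii[j]^2
        sl[inj] <- 1L
        ids[inj] <- j
      }
      labels[, , k] <- sl
      outlet_id[, , k] <- ids
    }
  }
  inlet_weight <- function(pos) {
    d2 <- (pos[, 1] - cx)^2 + (pos[, 2] - cx)^2
    pmax(0, 1 - d2 / trunk_radius^2)
  }
  build_domain_core(labels, dx, surface = surface,
                    inlet_face = "z-", outlet_face = "z+",
                    outlet_id = outlet_id, inlet_weight = inlet_weight,
                    meta = list(kind = "branching", trunk_radius = trunk_radius,
                                outlet_radii = outlet_radii, split_z = Ls,
                                length = length, centre = c(cx, cx),
                                child_centres = cbind(cx + ocx, cx + ocy)))
}

#' Classify wall links of a labelled voxel grid
#'
#' Finds every lattice link from a fluid site into solid, assigns each a
#' wall intersection fraction (from the analytic implicit surface when one
#' is supplied, otherwise the halfway value 0.5) and estimates outward unit
#' normals (analytic gradient, or the local solid-indicator gradient).
#' Errors if any fluid site is fully surrounded by solid.
#'
#' @param labels 3-d 0/1 array (1 = fluid)
#' @param dx lattice spacing (m)
#' @param surface optional implicit surface function `phi(x, y, z)`,
#'   negative inside the fluid
#' @param periodic logical length-3; periodic axes produce no wall links
#' @return list with `wall_links` (tibble: site, dir, q, normal components)
#'   and `wall_normals` (matrix, one unit normal per wall-adjacent site)
#' @export
classify_wall_links <- function(labels, dx, surface = NULL,
                                periodic = c(FALSE, FALSE, FALSE)) {
  dom <- build_domain_core(labels, dx, periodic = periodic, surface = surface,
                           .recheck = FALSE)
  wl <- dom$links[dom$links$type == "wall",
                  c("site", "dir", "q", "nx", "ny", "nz")]
  list(wall_links = wl, wall_normals = dom$wall_normals,
       wall_sites = dom$wall_sites, domain = dom)
}

#' Fully periodic box domain
#'
#' All-fluid box with periodic wrapping on every axis; no boundary links.
#' Used for shear-wave decay and conservation tests.
#'
#' @param nx,ny,nz grid extents (sites)
#' @param dx lattice spacing (m)
#' @return a `voxel_domain`
#' @export
periodic_box_domain <- function(nx, ny, nz, dx) {
  build_domain_core(array(1L, c(nx, ny, nz)), dx,
                    periodic = c(TRUE, TRUE, TRUE),
                    meta = list(kind = "periodic_box"))
}

#' Plane channel domain with bounce-back walls
#'
#' Fluid slab of `width` sites between two flat walls normal to y, periodic
#' along x and z. With halfway bounce-back the physical walls sit half a
#' spacing outside the outermost fluid rows, so the channel width is
#' `width * dx`.
#'
#' @param width channel width in sites (wall-normal direction, y)
#' @param nx,nz periodic extents (sites)
#' @param dx lattice spacing (m)
#' @return a `voxel_domain`
#' @export
channel_domain <- function(width, nx = 4L, nz = 4L, dx = 1e-4) {
  build_domain_core(array(1L, c(nx, width, nz)), dx,
                    periodic = c(TRUE, FALSE, TRUE),
                    meta = list(kind = "channel", width = width))
}

#' Axially periodic circular tube domain
#'
#' Circular cross-section of the given radius, periodic along z, with
#' analytic sub-voxel wall fractions. Used for Poiseuille and Womersley
#' validation driven by a body force.
#'
#' @param radius tube radius (m)
#' @param nz axial extent (sites)
#' @param dx lattice spacing (m)
#' @return a `voxel_domain`
#' @export
tube_domain <- function(radius, nz = 4L, dx) {
  nxy <- as.integer(ceiling(2 * radius / dx)) + 4L
  cx <- nxy * dx / 2
  xs <- (seq_len(nxy) - 0.5) * dx
  dist2 <- outer((xs - cx)^2, (xs - cx)^2, "+")
  labels <- array(rep((dist2 < radius^2) * 1L, nz), c(nxy, nxy, nz))
  surface <- function(px, py, pz) sqrt((px - cx)^2 + (py - cx)^2) - radius
  build_domain_core(labels, dx, periodic = c(FALSE, FALSE, TRUE),
                    surface = surface,
                    meta = list(kind = "tube", radius = radius, centre = cx))
}
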
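DOMAIN_MAGIC <- "VXDM"
DOMAIN_VERSION <- 1L

#' Write a voxel domain to a portable binary container
#'
#' Self-describing, versioned little-endian container: magic header,
#' version, lattice spacing (metres), grid shape, periodicity, the per-site
#' category labels, the classified boundary-link table (with sub-voxel wall
#' fractions and normals), inlet/outlet plane metadata and a JSON metadata
#' blob. [read_domain()] restores the domain field-by-field (neighbour
#' tables are rebuilt deterministically from the labels).
#'
#' @param domain a `voxel_domain`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_domain <- function(domain, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(DOMAIN_MAGIC, con, nchars = 4, eos = NULL)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wd <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")
  wi(DOMAIN_VERSION)
  wd(domain$dx)
  wi(domain$shape)
  wi(as.integer(domain$periodic))
  wi(as.vector(domain$labels))
  lk <- domain$links
  wi(nrow(lk))
  wi(lk$site); wi(lk$dir)
  wi(match(lk$type, c("wall", "inlet", "outlet")) - 1L)
  wd(lk$q); wi(lk$outlet)
  wd(lk$nx); wd(lk$ny); wd(lk$nz)
  wd(lk$wx); wd(lk$wy); wd(lk$wz)
  wi(lk$nbr2)
  write_plane <- function(pl, weights = FALSE) {
    wi(pl$index)
    wd(pl$normal)
    wd(pl$area)
    wd(pl$equivalent_radius)
    wi(length(pl$sites))
    wi(pl$sites)
    wd(pl$area_weights %||% rep(1, length(pl$sites)))
    if (weights) wd(pl$weights)
  }
  wi(!is.null(domain$inlet_plane))
  if (!is.null(domain$inlet_plane)) write_plane(domain$inlet_plane, TRUE)
  wi(length(domain$outlet_planes))
  for (pl in domain$outlet_planes) write_plane(pl)
  meta <- as.character(jsonlite::toJSON(domain$meta, auto_unbox = TRUE,
                                        digits = NA))
  mraw <- charToRaw(meta)
  wi(length(mraw))
  writeBin(mraw, con)
  invisible(path)
}

#' Read a voxel domain written by [write_domain()]
#'
#' @param path file path
#' @return a `voxel_domain`
#' @export
read_domain <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, DOMAIN_MAGIC)) {
    abort(sprintf("not a voxel domain container (magic '%s')", magic),
          class = "hemouq_error_format")
  }
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rd <- function(n) readBin(con, "numeric", n, size = 8, endian = "little")
  ver <- ri(1)
  if (!identical(ver, DOMAIN_VERSION)) {
    abort(sprintf("unsupported domain container version %d", ver),
          class = "hemouq_error_format")
  }
  dx <- rd(1)
  shape <- ri(3)
  periodic <- as.logical(ri(3))
  if (any(shape <= 0) || dx <= 0) {
    abort("corrupted domain dimensions", class = "hemouq_error_format")
  }
  labels <- ri(prod(shape))
  if (length(labels) < prod(shape)) {
    abort("truncated domain container", class = "hemouq_error_format")
  }
  labels <- array(labels, shape)
  nl <- ri(1)
  lk <- tibble(
    site = ri(nl), dir = ri(nl),
    type = c("wall", "inlet", "outlet")[ri(nl) + 1L],
    q = rd(nl), outlet = ri(nl),
    nx = rd(nl), ny = rd(nl), nz = rd(nl),
    wx = rd(nl), wy = rd(nl), wz = rd(nl),
    nbr2 = ri(nl)
  )
  read_plane <- function(weights = FALSE) {
    pl <- list(index = ri(1), normal = rd(3), area = rd(1),
               equivalent_radius = rd(1))
    ns <- ri(1)
    pl$sites <- ri(ns)
    pl$area_weights <- rd(ns)
    if (weights) pl$weights <- rd(ns)
    pl
  }
  inlet_plane <- if (ri(1) == 1L) read_plane(TRUE) else NULL
  nout <- ri(1)
  outlet_planes <- lapply(seq_len(nout), function(i) read_plane())
  mlen <- ri(1)
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                             simplifyMatrix = TRUE)

  # rebuild the derived structures deterministically from the fluid mask
  core <- build_domain_core((labels > 0L) * 1L, dx, periodic = periodic,
                            .recheck = FALSE)
  dom <- core
  dom$labels <- labels
  dom$links <- lk
  wl <- lk[lk$type == "wall", ]
  dom$wall_sites <- sort(unique(wl$site))
  if (length(dom$wall_sites)) {
    acc <- rowsum(cbind(wl$nx, wl$ny, wl$nz), group = wl$site)
    len <- sqrt(rowSums(acc^2)); len[len == 0] <- 1
    dom$wall_normals <- acc / len
  }
  dom$inlet_plane <- inlet_plane
  dom$outlet_planes <- outlet_planes
  dom$meta <- meta
  dom
}

#' Export a domain or field to a legacy VTK file
#'
#' Volume data (the site category labels, or any per-fluid-site scalar
#' field) is written as ASCII `STRUCTURED_POINTS` image data on the
#' uniform grid; wall-element fields (one value per wall-adjacent site, as
#' produced by [risk_factor_field()]) are written as `POLYDATA` points with
#' point-data scalars, one point per wall element at its site centre.
#'
#' @param domain a `voxel_domain`
#' @param path output file path
#' @param field optional numeric field: length `n_fluid` for a volume
#'   export, length `length(domain$wall_sites)` for a wall export; `NULL`
#'   exports the labels
#' @param name scalar field name in the file
#' @return `path`, invisibly
#' @export
export_vtk <- function(domain, path, field = NULL, name = "labels") {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- function(...) cat(..., "\n", sep = "", file = con)
  hdr("# vtk DataFile Version 3.0")
  hdr("hemouq export")
  hdr("ASCII")
  if (!is.null(field) && length(field) == length(domain$wall_sites) &&
      length(field) != domain$n_fluid) {
    pos <- (domain$coords[domain$wall_sites, , drop = FALSE] - 0.5) * domain$dx
    hdr("DATASET POLYDATA")
    hdr(sprintf("POINTS %d double", nrow(pos)))
    utils::write.table(format(pos, digits = 9, scientific = TRUE,
                              trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    hdr(sprintf("POINT_DATA %d", nrow(pos)))
    hdr(sprintf("SCALARS %s double 1", name))
    hdr("LOOKUP_TABLE default")
    cat(format(field, digits = 9, scientific = TRUE, trim = TRUE),
        sep = "\n", file = con)
  } else {
    vol <- array(0, domain$shape)
    if (is.null(field)) {
      vol <- domain$labels
      kind <- "int"
    } else {
      stopifnot(length(field) == domain$n_fluid)
      vol[domain$fluid_lin] <- field
      kind <- "double"
    }
    hdr("DATASET STRUCTURED_POINTS")
    hdr(sprintf("DIMENSIONS %d %d %d", domain$shape[1], domain$shape[2],
                domain$shape[3]))
    hdr(sprintf("ORIGIN %g %g %g", domain$dx / 2, domain$dx / 2,
                domain$dx / 2))
    hdr(sprintf("SPACING %g %g %g", domain$dx, domain$dx, domain$dx))
    hdr(sprintf("POINT_DATA %d", prod(domain$shape)))
    hdr(sprintf("SCALARS %s %s 1", name, kind))
    hdr("LOOKUP_TABLE default")
    cat(format(as.vector(vol), digits = 9, scientific = !is.null(field),
               trim = TRUE),
        sep = "\n", file = con)
  }
  invisible(path)
}

# Minimal readers for the package's own VTK exports (round-trip checks).
read_vtk_scalars <- function(path) {
  lines <- readLines(path)
  i <- grep("^SCALARS", lines)[1]
  name <- strsplit(lines[i], " ")[[1]][2]
  vals <- as.numeric(lines[(i + 2):length(lines)])
  dims <- NULL
  d <- grep("^DIMENSIONS", lines)
  if (length(d)) dims <- as.integer(strsplit(lines[d[1]], " ")[[1]][2:4])
  pts <- NULL
  p <- grep("^POINTS", lines)
  if (length(p)) {
    np <- as.integer(strsplit(lines[p[1]], " ")[[1]][2])
    pts <- matrix(as.numeric(unlist(strsplit(lines[(p[1] + 1):(p[1] + np)],
                                             " +"))),
                  ncol = 3, byrow = TRUE)
  }
  list(name = name, values = vals, dims = dims, points = pts)
}
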
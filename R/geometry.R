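#' Spherocylindrical cell geometry
#'
#' A rod-shaped bacterium is modelled as a spherocylinder: a cylinder of
#' radius `radius` capped by two hemispheres, with tip-to-tip length `length`.
#' The cell long axis defines the local x axis; `orientation` rotates it in
#' the image plane.
#'
#' @param length Tip-to-tip cell length in um (must be >= 2*radius).
#' @param radius Cell radius in um.
#' @param center Numeric length-2, cell center (x, y) in um.
#' @param orientation Long-axis angle in radians (counter-clockwise from x).
#' @return An object of class `cell_geometry`.
#' @examples
#' cell <- cell_geometry(length = 3, radius = 0.5)
#' @export
cell_geometry <- function(length = 3, radius = 0.5, center = c(0, 0),
                          orientation = 0) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (length < 2 * radius)
    stop("invalid geometry: length must be >= 2*radius", call. = FALSE)
  g <- list(length = length, radius = radius,
            center = as.numeric(center), orientation = orientation)
  class(g) <- "cell_geometry"
  g
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Spherocylinder cell: %g x %g um at (%g, %g), theta = %g rad\n",
              x$length, 2 * x$radius, x$center[1], x$center[2], x$orientation))
  invisible(x)
}

# half-length of the cylindrical (straight) part
cyl_half_length <- function(geometry) geometry$length / 2 - geometry$radius

# world (lab) xy -> cell-local xy; z is unchanged
to_local <- function(xy, geometry) {
  ct <- cos(geometry$orientation); st <- sin(geometry$orientation)
  dx <- xy[, 1] - geometry$center[1]
  dy <- xy[, 2] - geometry$center[2]
  cbind(ct * dx + st * dy, -st * dx + ct * dy)
}

to_world <- function(xy, geometry) {
  ct <- cos(geometry$orientation); st <- sin(geometry$orientation)
  cbind(geometry$center[1] + ct * xy[, 1] - st * xy[, 2],
        geometry$center[2] + st * xy[, 1] + ct * xy[, 2])
}

#' Test whether 3D points lie inside a spherocylinder
#'
#' Points are given in the cell-local frame (long axis = x, cell center at
#' the origin). A point is inside iff its distance to the axis segment
#' x in [-a, a] (a = length/2 - radius) is at most `radius`.
#'
#' @param p Numeric matrix with columns x, y, z (um, cell-local frame).
#' @param geometry A [cell_geometry()].
#' @param tol Slack in um (default 0, exact test).
#' @return Logical vector.
#' @export
inside_cell <- function(p, geometry, tol = 0) {
  p <- rbind(p)  # promote vectors
  a <- cyl_half_length(geometry)
  xc <- pmin(pmax(p[, 1], -a), a)
  d2 <- (p[, 1] - xc)^2 + p[, 2]^2 + p[, 3]^2
  d2 <= (geometry$radius + tol)^2
}

# signed distance to the spherocylinder surface (< 0 inside)
sphero_dist <- function(p, a, r) {
  xc <- min(max(p[1], -a), a)
  sqrt((p[1] - xc)^2 + p[2]^2 + p[3]^2) - r
}

# Specular reflection of a Brownian substep: the segment from p0 (inside) to
# p1 is traced to its surface crossing (bisection on the signed distance),
# and the remainder is reflected across the tangent plane at the crossing;
# repeated until the endpoint lies inside. Unlike a radial fold, tangent-
# plane reflection has no density bias at curved walls, so the uniform
# equilibrium is preserved.
reflect_step <- function(p0, p1, geometry, max_bounce = 20L) {
  a <- cyl_half_length(geometry)
  r <- geometry$radius
  for (b in seq_len(max_bounce)) {
    if (sphero_dist(p1, a, r) <= 0) return(p1)
    # bisection for the crossing point on [p0, p1]
    lo <- 0; hi <- 1
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      pm <- p0 + mid * (p1 - p0)
      if (sphero_dist(pm, a, r) <= 0) lo <- mid else hi <- mid
    }
    px <- p0 + lo * (p1 - p0)
    xc <- min(max(px[1], -a), a)
    n <- px - c(xc, 0, 0)
    n <- n / sqrt(sum(n^2))                    # outward surface normal
    w <- (1 - lo) * (p1 - p0)                  # remaining flight
    w <- w - 2 * sum(w * n) * n
    p0 <- px
    p1 <- px + w
  }
  p0   # pathological step: stop at the last surface point
}

# Uniform points in the spherocylinder volume (cell-local frame).
# Rejection sampling from the bounding box; exact and simple.
runif_spherocylinder <- function(n, geometry) {
  a <- cyl_half_length(geometry)
  r <- geometry$radius
  L2 <- geometry$length / 2
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, -L2, L2),
                  stats::runif(m, -r, r),
                  stats::runif(m, -r, r))
    keep <- inside_cell(cand, geometry)
    k <- which(keep)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Read cell geometries from a JSON file
#'
#' Expects an array of records `{cell_id, length_um, radius_um, center,
#' orientation}`, the on-disk format produced by segmentation preprocessing.
#'
#' @param path Path to a JSON file.
#' @return A named list of [cell_geometry()] objects.
#' @examples
#' cells <- read_geometry_json(system.file("extdata", "demo_cells.json",
#'                                         package = "rodSPT"))
#' cells$cell_002
#' @export
read_geometry_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(recs, function(r) {
    cell_geometry(length = r$length_um, radius = r$radius_um,
                  center = unlist(r$center), orientation = r$orientation %||% 0)
  })
  names(out) <- vapply(recs, function(r) as.character(r$cell_id), "")
  out
}

#' Write cell geometries to JSON
#'
#' @param cells Named list of [cell_geometry()] objects.
#' @param path Output path.
#' @export
write_geometry_json <- function(cells, path) {
  ids <- names(cells) %||% as.character(seq_along(cells))
  recs <- mapply(function(g, id) {
    list(cell_id = id, length_um = g$length, radius_um = g$radius,
         center = g$center, orientation = g$orientation)
  }, cells, ids, SIMPLIFY = FALSE)
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
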
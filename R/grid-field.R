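#' Rectilinear-grid velocity field
#'
#' Container for a steady or time-varying velocity field sampled on a
#' tensor-product (rectilinear) grid. Coordinates are in mm, velocities in
#' mm/s. Axis 1 is streamwise (x), axis 2 cross-stream (y), axis 3 vertical
#' (z); the 2D case uses (x, y).
#'
#' @param axes list of 2 or 3 strictly increasing numeric coordinate vectors
#'   (mm), each with at least 2 points. Names default to x, y, z in order.
#' @param components for a steady field, a list of `ndim` numeric arrays, each
#'   of dimension `lengths(axes)`, giving the velocity components (mm/s) on
#'   the grid. For a time-varying field, a list of such component lists, one
#'   per time point.
#' @param time_points optional strictly increasing numeric vector of snapshot
#'   times (s); when present `components` must hold one component set per
#'   time point.
#' @return an object of class `grid_field`.
#' @seealso [interpolate_velocity()], [tile_flow()], [parabolic_channel_field()]
#' @export
grid_velocity_field <- function(axes, components, time_points = NULL) {
  if (!is.list(axes) || !(length(axes) %in% c(2L, 3L)))
    zd_stop("`axes` must be a list of 2 or 3 coordinate vectors", "invalid_field")
  ndim <- length(axes)
  axes <- lapply(axes, as.numeric)
  names(axes) <- AXIS_NAMES[seq_len(ndim)]
  for (j in seq_len(ndim)) {
    ax <- axes[[j]]
    if (length(ax) < 2L || anyNA(ax) || any(diff(ax) <= 0))
      zd_stop(sprintf("axis %s must be strictly increasing with >= 2 points",
                      names(axes)[j]), "invalid_field")
  }
  shape <- lengths(axes)

  check_set <- function(comps, what) {
    if (!is.list(comps) || length(comps) != ndim)
      zd_stop(sprintf("%s must hold %d component arrays", what, ndim),
              "invalid_field")
    comps <- lapply(comps, function(a) {
      a <- if (is.null(dim(a))) array(as.numeric(a), dim = shape) else
        array(as.numeric(a), dim = dim(a))
      a
    })
    names(comps) <- COMP_NAMES[seq_len(ndim)]
    for (k in seq_len(ndim)) {
      if (!identical(as.integer(dim(comps[[k]])), as.integer(shape)))
        zd_stop(sprintf("component %s has shape (%s); grid implies (%s)",
                        names(comps)[k],
                        paste(dim(comps[[k]]), collapse = ","),
                        paste(shape, collapse = ",")), "invalid_field")
      if (anyNA(comps[[k]]))
        zd_stop(sprintf("component %s contains NA", names(comps)[k]),
                "invalid_field")
    }
    comps
  }

  if (is.null(time_points)) {
    components <- check_set(components, "`components`")
  } else {
    time_points <- as.numeric(time_points)
    if (length(time_points) < 1L || anyNA(time_points) ||
        any(diff(time_points) <= 0))
      zd_stop("`time_points` must be strictly increasing", "invalid_field")
    if (!is.list(components) || length(components) != length(time_points))
      zd_stop("need one component set per time point", "invalid_field")
    components <- lapply(seq_along(components), function(i)
      check_set(components[[i]], sprintf("snapshot %d", i)))
  }

  structure(list(axes = axes, components = components, ndim = ndim,
                 time_points = time_points),
            class = "grid_field")
}

is_time_varying <- function(field) !is.null(field$time_points)

#' @export
print.grid_field <- function(x, ...) {
  shape <- paste(lengths(x$axes), collapse = " x ")
  cat(sprintf("<grid_field> %dD velocity field, %s nodes\n", x$ndim, shape))
  for (j in seq_len(x$ndim))
    cat(sprintf("  %s: [%g, %g] mm (%d points)\n", names(x$axes)[j],
                min(x$axes[[j]]), max(x$axes[[j]]), length(x$axes[[j]])))
  if (is_time_varying(x))
    cat(sprintf("  time-varying: %d snapshots on [%g, %g] s\n",
                length(x$time_points), min(x$time_points), max(x$time_points)))
  invisible(x)
}

field_bounds <- function(field) {
  vapply(field$axes, range, numeric(2))  # 2 x ndim
}

#' Simulation domain with per-face agent boundary behaviour
#'
#' @param bounds list (or 2-row matrix) of per-axis `[min, max]` extents (mm).
#' @param face_bc named character vector tagging each face `"project"`
#'   (agents crossing it are translated back to the nearest boundary point)
#'   or `"exit"` (agents crossing it leave the simulation). Faces are named
#'   `x_min`, `x_max`, `y_min`, ... Defaults mirror a flow tank: the upstream
#'   and downstream faces (`x_min`, `x_max`) are `exit`; side walls, bottom
#'   and fluid surface are `project`.
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(bounds, face_bc = NULL) {
  if (is.matrix(bounds)) bounds <- lapply(seq_len(ncol(bounds)), function(j) bounds[, j])
  if (!is.list(bounds) || !(length(bounds) %in% c(2L, 3L)))
    zd_stop("`bounds` must give [min, max] for 2 or 3 axes", "invalid_argument")
  bounds <- lapply(bounds, as.numeric)
  ndim <- length(bounds)
  names(bounds) <- AXIS_NAMES[seq_len(ndim)]
  for (j in seq_len(ndim))
    if (length(bounds[[j]]) != 2L || !(bounds[[j]][1] < bounds[[j]][2]))
      zd_stop(sprintf("axis %s bounds must satisfy min < max", names(bounds)[j]),
              "invalid_argument")
  faces <- as.vector(t(outer(names(bounds), c("min", "max"), paste, sep = "_")))
  if (is.null(face_bc)) {
    face_bc <- stats::setNames(rep("project", length(faces)), faces)
    face_bc[c("x_min", "x_max")] <- "exit"
  } else {
    if (is.null(names(face_bc)) || !setequal(names(face_bc), faces))
      zd_stop(sprintf("`face_bc` must name exactly the faces: %s",
                      paste(faces, collapse = ", ")), "invalid_argument")
    face_bc <- face_bc[faces]
  }
  if (!all(face_bc %in% c("project", "exit")))
    zd_stop("face tags must be 'project' or 'exit'", "invalid_argument")
  structure(list(bounds = bounds, face_bc = face_bc, ndim = ndim),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf("<domain_spec> %dD box\n", x$ndim))
  for (j in seq_len(x$ndim))
    cat(sprintf("  %s: [%g, %g] mm   (%s: %s, %s: %s)\n", names(x$bounds)[j],
                x$bounds[[j]][1], x$bounds[[j]][2],
                paste0(names(x$bounds)[j], "_min"),
                x$face_bc[paste0(names(x$bounds)[j], "_min")],
                paste0(names(x$bounds)[j], "_max"),
                x$face_bc[paste0(names(x$bounds)[j], "_max")]))
  invisible(x)
}

# Vectorised multilinear interpolation of one component set at clamped points.
# pts: n x ndim matrix already inside the bounding box.
interp_component_set <- function(axes, comps, pts) {
  ndim <- length(axes)
  n <- nrow(pts)
  idx <- matrix(0L, n, ndim)
  frac <- matrix(0, n, ndim)
  for (j in seq_len(ndim)) {
    ax <- axes[[j]]
    i <- findInterval(pts[, j], ax, all.inside = TRUE)
    idx[, j] <- i
    frac[, j] <- (pts[, j] - ax[i]) / (ax[i + 1L] - ax[i])
  }
  corners <- as.matrix(expand.grid(rep(list(0L:1L), ndim)))
  out <- matrix(0, n, ndim)
  sub <- matrix(0L, n, ndim)
  for (cix in seq_len(nrow(corners))) {
    w <- rep(1, n)
    for (j in seq_len(ndim)) {
      if (corners[cix, j] == 0L) w <- w * (1 - frac[, j]) else w <- w * frac[, j]
      sub[, j] <- idx[, j] + corners[cix, j]
    }
    for (k in seq_len(ndim)) out[, k] <- out[, k] + w * comps[[k]][sub]
  }
  out
}

#' Interpolate a gridded velocity field at arbitrary points
#'
#' Multilinear (bilinear/trilinear) interpolation of each velocity component.
#' Query points outside the grid's bounding box are clamped to the box before
#' interpolation (no extrapolation). For time-varying fields the two
#' bracketing snapshots are blended linearly in time; times outside the
#' snapshot range use the nearest snapshot (constant extrapolation).
#'
#' @param field a [grid_velocity_field()].
#' @param point numeric vector of length `ndim` (one point, mm) or an
#'   `n x ndim` matrix of points.
#' @param time time (s); required only for time-varying fields.
#' @return velocity in mm/s: a vector for a single point, else an
#'   `n x ndim` matrix.
#' @export
interpolate_velocity <- function(field, point, time = NULL) {
  if (!inherits(field, "grid_field"))
    zd_stop("`field` must be a grid_field", "invalid_field")
  one <- is.null(dim(point))
  pts <- if (one) matrix(as.numeric(point), nrow = 1) else
    as.matrix(point)
  storage.mode(pts) <- "double"
  if (ncol(pts) != field$ndim)
    zd_stop(sprintf("points are %dD but field is %dD", ncol(pts), field$ndim),
            "dimension")
  if (anyNA(pts)) zd_stop("query point contains NA", "numeric")
  for (j in seq_len(field$ndim)) {
    ax <- field$axes[[j]]
    pts[, j] <- pmin(pmax(pts[, j], ax[1]), ax[length(ax)])
  }
  if (!is_time_varying(field)) {
    out <- interp_component_set(field$axes, field$components, pts)
  } else {
    if (is.null(time))
      zd_stop("`time` is required for a time-varying field", "invalid_argument")
    tp <- field$time_points
    time <- min(max(as.numeric(time), tp[1]), tp[length(tp)])
    i <- findInterval(time, tp, all.inside = TRUE)
    a <- interp_component_set(field$axes, field$components[[i]], pts)
    if (time == tp[i]) {
      out <- a
    } else {
      b <- interp_component_set(field$axes, field$components[[i + 1L]], pts)
      s <- (time - tp[i]) / (tp[i + 1L] - tp[i])
      out <- (1 - s) * a + s * b
    }
  }
  colnames(out) <- COMP_NAMES[seq_len(field$ndim)]
  if (one) out[1, ] else out
}

#' Tile a periodic flow field horizontally
#'
#' Expands the domain by repeating the field `n_x` times streamwise and
#' `n_y` times cross-stream, assuming periodicity: the first and last grid
#' slices along a tiled axis must carry equal velocities (they are the same
#' physical plane one period apart), which is checked unless `check = FALSE`.
#'
#' @param field a steady [grid_velocity_field()].
#' @param n_x,n_y number of copies along x and y (>= 1).
#' @param check verify periodic compatibility of the tiled faces.
#' @param tol relative tolerance for the periodicity check.
#' @return a `grid_field` covering the enlarged extent; the velocity is
#'   periodic with the original extent along each tiled axis.
#' @export
tile_flow <- function(field, n_x = 1L, n_y = 1L, check = TRUE, tol = 1e-8) {
  if (!inherits(field, "grid_field"))
    zd_stop("`field` must be a grid_field", "invalid_field")
  if (is_time_varying(field))
    zd_stop("tiling is implemented for steady fields only", "invalid_argument")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (is.na(n_x) || is.na(n_y) || n_x < 1L || n_y < 1L)
    zd_stop("tile counts must be integers >= 1", "invalid_argument")
  axes <- field$axes
  comps <- field$components
  for (j in c(1L, 2L)) {
    reps <- if (j == 1L) n_x else n_y
    if (reps == 1L) next
    ax <- axes[[j]]
    n <- length(ax)
    if (check) {
      scale <- max(vapply(comps, function(a) max(abs(a)), 0), 1)
      for (k in seq_along(comps)) {
        first <- slice_axis(comps[[k]], j, 1L)
        last <- slice_axis(comps[[k]], j, n)
        if (max(abs(first - last)) > tol * scale)
          zd_stop(sprintf(
            "field is not periodic along %s (boundary slices differ); use check = FALSE to override",
            names(axes)[j]), "periodicity")
      }
    }
    period <- ax[n] - ax[1]
    new_ax <- c(ax, unlist(lapply(seq_len(reps - 1L),
                                  function(k) ax[-1] + k * period)))
    pick <- c(seq_len(n), rep(2:n, reps - 1L))
    comps <- lapply(comps, function(a) index_axis(a, j, pick))
    axes[[j]] <- new_ax
  }
  grid_velocity_field(axes, comps)
}

# take slice i along axis j of an array (drops that axis)
slice_axis <- function(a, j, i) {
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[j]] <- i
  do.call(`[`, c(list(a), args))
}

# subset along axis j with index vector (keeps dimensions)
index_axis <- function(a, j, pick) {
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[j]] <- pick
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

#' Analytical parabolic (Poiseuille-like) channel flow
#'
#' Whole-domain analytical stand-in for the flow-tank inlet condition: the
#' streamwise component follows a parabola in height,
#' `u(z) = u_max * 4 z (height - z) / height^2` with `z` measured from the
#' bottom of the domain — zero at bottom and surface, maximal (`u_max`) at
#' mid-depth. Cross-stream and vertical components are zero.
#'
#' @param u_max peak streamwise velocity (mm/s), >= 0.
#' @param height channel depth (mm) over which the parabola spans; normally
#'   the vertical extent of `domain`.
#' @param domain a 3D [domain_spec()].
#' @param resolution integer vector of grid points per axis (default
#'   `c(9, 5, 33)`; the profile varies only in z).
#' @return a 3D `grid_field`.
#' @export
parabolic_channel_field <- function(u_max, height, domain,
                                    resolution = c(9L, 5L, 33L)) {
  if (!inherits(domain, "domain_spec") || domain$ndim != 3L)
    zd_stop("`domain` must be a 3D domain_spec", "invalid_argument")
  if (!is.finite(height) || height <= 0)
    zd_stop("`height` must be positive", "invalid_argument")
  if (!is.finite(u_max) || u_max < 0)
    zd_stop("`u_max` must be non-negative", "invalid_argument")
  resolution <- rep_len(as.integer(resolution), 3L)
  if (any(resolution < 2L))
    zd_stop("need at least 2 grid points per axis", "invalid_argument")
  axes <- lapply(1:3, function(j)
    seq(domain$bounds[[j]][1], domain$bounds[[j]][2],
        length.out = resolution[j]))
  z_rel <- axes[[3]] - domain$bounds$z[1]
  u_z <- u_max * 4 * z_rel * (height - z_rel) / height^2
  shape <- resolution
  u <- array(rep(u_z, each = shape[1] * shape[2]), dim = shape)
  zero <- array(0, dim = shape)
  grid_velocity_field(axes, list(u, zero, zero))
}
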
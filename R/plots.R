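#' Plot a simulation result
#'
#' Base-graphics views of a `swarm_sim`: zone occupancy over time, arrival
#' time histograms, the density histogram of final agent positions, or
#' tracked trajectories in the x-z plane.
#'
#' @param x a `swarm_sim`.
#' @param which one of `"occupancy"`, `"arrivals"`, `"density"`,
#'   `"trajectories"`.
#' @param ... passed on to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.swarm_sim <- function(x, which = c("occupancy", "arrivals", "density",
                                        "trajectories"), ...) {
  which <- match.arg(which)
  labs <- colnames(x$arrivals)
  switch(which,
    occupancy = {
      if (length(labs) == 0L) zd_stop("no zones recorded", "invalid_argument")
      series <- lapply(labs, function(l) counts_over_time(x, l))
      ylim <- c(0, max(1, vapply(series, function(s) max(s$count), 0)))
      graphics::plot(series[[1]]$time, series[[1]]$count, type = "l",
                     xlab = "time (s)", ylab = "agents in zone",
                     ylim = ylim, col = 1, ...)
      for (k in seq_along(series)[-1])
        graphics::lines(series[[k]]$time, series[[k]]$count, col = k)
      graphics::legend("topright", legend = labs, col = seq_along(labs),
                       lty = 1, bty = "n")
    },
    arrivals = {
      if (length(labs) == 0L) zd_stop("no zones recorded", "invalid_argument")
      old <- graphics::par(mfrow = c(1, length(labs)))
      on.exit(graphics::par(old))
      for (l in labs) {
        at <- first_arrival_times(x, l)
        if (length(at) == 0L) next
        graphics::hist(at, breaks = "FD", main = paste("zone", l),
                       xlab = "arrival time (s)", ...)
      }
    },
    density = {
      graphics::smoothScatter(x$positions[x$active, 1],
                              x$positions[x$active, min(3, ncol(x$positions))],
                              xlab = "x (mm)", ylab = "z (mm)", ...)
    },
    trajectories = {
      if (is.null(x$trajectories))
        zd_stop("run was not tracked (track = 0)", "invalid_argument")
      tr <- x$trajectories
      zj <- min(3, dim(tr)[2])
      graphics::matplot(tr[, 1, ], tr[, zj, ], type = "l", lty = 1,
                        xlab = "x (mm)", ylab = "z (mm)", ...)
    })
  invisible(x)
}

#' Plot a vertical velocity profile of a field
#'
#' Streamwise velocity against height along a vertical line, the standard
#' way canopy flow structure is inspected.
#'
#' @param field a [grid_velocity_field()].
#' @param x,y horizontal position of the line (mm); defaults to the grid
#'   centre.
#' @param n number of sample heights.
#' @param ... passed to [graphics::plot()].
#' @return data frame of `z` and `u`, invisibly.
#' @export
plot_profile <- function(field, x = NULL, y = NULL, n = 101L, ...) {
  ax <- field$axes
  x <- x %||% mean(range(ax$x))
  y <- y %||% if (field$ndim == 3L) mean(range(ax$y)) else NULL
  zax <- if (field$ndim == 3L) ax$z else ax$y
  z <- seq(min(zax), max(zax), length.out = n)
  pts <- if (field$ndim == 3L) cbind(x, y, z) else cbind(x, z)
  v <- interpolate_velocity(field, pts)
  graphics::plot(v[, 1], z, type = "l", xlab = "u (mm/s)", ylab = "z (mm)",
                 ...)
  invisible(data.frame(z = z, u = v[, 1]))
}
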
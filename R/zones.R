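#' Observation zone
#'
#' An axis-aligned region in which agent presence and first arrival are
#' recorded, mirroring the camera zones of the flow-tank protocol: each zone
#' constrains the streamwise coordinate and usually height, spans the full
#' tank width, and can be subdivided into square counting cells.
#'
#' @param label zone name (e.g. `"green"`, `"blue"`).
#' @param x_interval `[min, max]` streamwise extent (mm).
#' @param y_interval,z_interval optional `[min, max]` extents (mm);
#'   unspecified axes are unconstrained.
#' @param cell_size optional cell edge length (mm) for per-cell occupancy
#'   counts; every specified interval must be an integer multiple of it.
#' @return an object of class `zone`.
#' @export
zone <- function(label, x_interval, y_interval = NULL, z_interval = NULL,
                 cell_size = NULL) {
  ivs <- list(x = x_interval, y = y_interval, z = z_interval)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (is.null(iv)) next
    if (length(iv) != 2L || anyNA(iv) || !(iv[1] < iv[2]))
      zd_stop(sprintf("%s_interval must be [min, max] with min < max", nm),
              "invalid_argument")
  }
  if (!is.null(cell_size)) {
    if (!is.finite(cell_size) || cell_size <= 0)
      zd_stop("`cell_size` must be positive", "invalid_argument")
    for (nm in names(ivs)) {
      iv <- ivs[[nm]]
      if (is.null(iv)) next
      k <- diff(iv) / cell_size
      if (abs(k - round(k)) > 1e-9)
        zd_stop(sprintf("%s_interval width is not a multiple of cell_size", nm),
                "invalid_argument")
    }
  }
  structure(list(label = as.character(label), x_interval = ivs$x,
                 y_interval = ivs$y, z_interval = ivs$z,
                 cell_size = cell_size),
            class = "zone")
}

#' @export
print.zone <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "free" else sprintf("[%g, %g]", iv[1], iv[2])
  cat(sprintf("<zone> '%s'  x %s  y %s  z %s mm%s\n", x$label,
              fmt(x$x_interval), fmt(x$y_interval), fmt(x$z_interval),
              if (is.null(x$cell_size)) "" else
                sprintf("  (cells %g mm)", x$cell_size)))
  invisible(x)
}

# logical: which rows of the n x ndim position matrix lie inside the zone
zone_contains <- function(zn, pos) {
  inside <- rep(TRUE, nrow(pos))
  ivs <- list(zn$x_interval, zn$y_interval, zn$z_interval)
  for (j in seq_len(ncol(pos))) {
    iv <- ivs[[j]]
    if (is.null(iv)) next
    inside <- inside & pos[, j] >= iv[1] & pos[, j] <= iv[2]
  }
  inside
}

# integer cell index (1-based, x-fastest over subdivided axes) or NA outside
zone_cell_index <- function(zn, pos) {
  if (is.null(zn$cell_size)) zd_stop("zone has no cell_size", "invalid_argument")
  inside <- zone_contains(zn, pos)
  ivs <- list(zn$x_interval, zn$y_interval, zn$z_interval)
  idx <- rep(0, nrow(pos))
  mult <- 1L
  for (j in seq_len(ncol(pos))) {
    iv <- ivs[[j]]
    if (is.null(iv)) next
    ncell <- as.integer(round(diff(iv) / zn$cell_size))
    k <- pmin(floor((pos[, j] - iv[1]) / zn$cell_size), ncell - 1L)
    idx <- idx + k * mult
    mult <- mult * ncell
  }
  out <- ifelse(inside, idx + 1L, NA_integer_)
  as.integer(out)
}

zone_n_cells <- function(zn) {
  if (is.null(zn$cell_size)) return(1L)
  ivs <- list(zn$x_interval, zn$y_interval, zn$z_interval)
  prod(vapply(ivs, function(iv)
    if (is.null(iv)) 1L else as.integer(round(diff(iv) / zn$cell_size)), 1L))
}

#' First-arrival times into a zone
#'
#' Returns each agent's first time inside the zone (all of the zone's
#' specified intervals satisfied simultaneously), detected at step resolution
#' from the simulation's online records. Agents that never entered are
#' omitted.
#'
#' @param result a `swarm_sim` object from [simulate_swarm()].
#' @param zone a zone label, a zone index, or a [zone()] matching one
#'   registered with the simulation.
#' @return numeric vector of arrival times (s).
#' @export
first_arrival_times <- function(result, zone) {
  if (!inherits(result, "swarm_sim"))
    zd_stop("`result` must be a swarm_sim", "invalid_argument")
  k <- match_zone(result, zone)
  at <- result$arrivals[, k]
  at[!is.na(at)]
}

match_zone <- function(result, zone) {
  labels <- colnames(result$arrivals)
  if (inherits(zone, "zone")) zone <- zone$label
  if (is.character(zone)) {
    k <- match(zone, labels)
    if (is.na(k))
      zd_stop(sprintf("zone '%s' was not registered with the simulation (have: %s)",
                      zone, paste(labels, collapse = ", ")), "invalid_argument")
    return(k)
  }
  k <- as.integer(zone)
  if (is.na(k) || k < 1L || k > length(labels))
    zd_stop("zone index out of range", "invalid_argument")
  k
}

#' Arrival-time summary statistics (Pearson standardised moments)
#'
#' Computes the mean, median, binned mode, population standard deviation and
#' the Pearson standardised third and fourth moments of a sample of arrival
#' times: skewness \eqn{m_3 / m_2^{3/2}} and (non-excess) kurtosis
#' \eqn{m_4 / m_2^2} (a normal sample gives kurtosis near 3), with
#' \eqn{m_r} the central sample moments using 1/n weights. For a degenerate
#' sample (\eqn{m_2 = 0}) the standard deviation, skewness and kurtosis are
#' all reported as 0 by convention.
#'
#' The mode of a continuous sample is defined by binning: times are assigned
#' to bins of width `mode_bin` centred on multiples of `mode_bin`
#' (round-half-up), and the mode is the centre of the most populated bin,
#' ties going to the earliest bin.
#'
#' @param times non-empty numeric vector of times (s).
#' @param mode_bin mode bin width (s), > 0; default 0.1 s, the simulator's
#'   default time step.
#' @return an object of class `moment_stats`: a list with `mean`, `median`,
#'   `mode`, `std`, `skewness`, `kurtosis`, `n`.
#' @export
moment_stats <- function(times, mode_bin = 0.1) {
  times <- as.numeric(times)
  if (length(times) == 0L || anyNA(times))
    zd_stop("`times` must be a non-empty numeric vector without NA",
            "invalid_argument")
  if (!is.finite(mode_bin) || mode_bin <= 0)
    zd_stop("`mode_bin` must be positive", "invalid_argument")
  n <- length(times)
  mu <- mean(times)
  d <- times - mu
  m2 <- mean(d^2)
  if (m2 > 0) {
    m3 <- mean(d^3); m4 <- mean(d^4)
    std <- sqrt(m2)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    std <- skew <- kurt <- 0
  }
  # bin centred on multiples of mode_bin; round-half-up, ties -> earliest bin
  k <- floor(times / mode_bin + 0.5 + 1e-9)
  tab <- table(k)
  kbest <- as.numeric(names(tab))[which.max(tab)]  # which.max takes first max;
  # names(tab) are sorted numerically by construction of table on integers
  structure(list(mean = mu, median = stats::median(times),
                 mode = kbest * mode_bin, std = std, skewness = skew,
                 kurtosis = kurt, n = n),
            class = "moment_stats")
}

#' @export
print.moment_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean %.5f  median %.2f  mode %.1f  std %.6f  skew %.6f  kurt %.6f\n",
    x$n, x$mean, x$median, x$mode, x$std, x$skewness, x$kurtosis))
  invisible(x)
}

#' @export
as.data.frame.moment_stats <- function(x, ...) {
  data.frame(Mean = x$mean, Median = x$median, Mode = x$mode, Std = x$std,
             Skewness = x$skewness, Kurtosis = x$kurtosis)
}

#' Zone occupancy counts over time
#'
#' Number of active agents inside a zone at regular sampling times, as
#' recorded online during the simulation (mirroring organism counts at fixed
#' intervals in the tank experiments). With `per_cell = TRUE` and a zone that
#' has `cell_size`, counts are returned per counting cell.
#'
#' @param result a `swarm_sim` from [simulate_swarm()].
#' @param zone zone label, index, or [zone()] registered with the simulation.
#' @param interval sampling interval (s); must be a positive multiple of the
#'   simulation's `record_interval`. Defaults to the record interval.
#' @param per_cell return per-cell counts.
#' @return data frame with columns `time`, `zone`, (`cell`,) `count`.
#' @export
counts_over_time <- function(result, zone, interval = NULL, per_cell = FALSE) {
  k <- match_zone(result, zone)
  occ <- result$occupancy
  rec <- result$config$record_interval
  times <- sort(unique(occ$time))
  if (!is.null(interval)) {
    r <- interval / rec
    if (!is.finite(r) || r <= 0 || abs(r - round(r)) > 1e-9)
      zd_stop("`interval` must be a positive multiple of record_interval",
              "invalid_argument")
    keep <- abs(times / interval - round(times / interval)) < 1e-9
    times <- times[keep]
  }
  zlab <- colnames(result$arrivals)[k]
  sub <- occ[occ$zone == zlab & occ$time %in% times, , drop = FALSE]
  if (per_cell) {
    if (!"cell" %in% names(sub) || all(is.na(sub$cell)))
      zd_stop("zone was recorded without cells (no cell_size)",
              "invalid_argument")
    out <- sub[!is.na(sub$cell), c("time", "zone", "cell", "count")]
  } else {
    tot <- if ("cell" %in% names(sub)) sub[is.na(sub$cell), , drop = FALSE] else sub
    out <- data.frame(time = tot$time, zone = zlab, count = tot$count)
  }
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}

#' Normalise paired occupancy series by their grand total
#'
#' Divides both count series by the total count summed across both zones and
#' all times, so the two normalised series together sum to 1.
#'
#' @param green,blue data frames with `time` and `count` columns (as from
#'   [counts_over_time()]).
#' @return list of the two data frames, each with a `normalized` column.
#' @export
normalize_counts <- function(green, blue) {
  for (s in list(green, blue))
    if (!all(c("time", "count") %in% names(s)))
      zd_stop("series need `time` and `count` columns", "invalid_argument")
  total <- sum(green$count) + sum(blue$count)
  if (total <= 0)
    zd_stop("both series are all-zero; nothing to normalise", "degenerate")
  green$normalized <- green$count / total
  blue$normalized <- blue$count / total
  list(green = green, blue = blue)
}

#' Box-plot summary of an appearance-time distribution
#'
#' Treats an occupancy count series as a weighted sample of times (when
#' organisms appear in a zone, not when they first arrive) and returns its
#' weighted mean, median and quartiles plus the earliest and latest times
#' with nonzero count. Weighted quantiles use plotting positions
#' \eqn{p_k = (C_k - w_k) / (W - w_n)} (cumulative weights \eqn{C_k}, total
#' \eqn{W}) with linear interpolation, which reduces to R's default
#' (type 7) quantiles for equal weights.
#'
#' @param series data frame with `time` and `count` (or `normalized`)
#'   columns; counts must be non-negative with a positive total.
#' @return named numeric vector: `mean`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
appearance_boxstats <- function(series) {
  if (!all(c("time", "count") %in% names(series)) &&
      !all(c("time", "normalized") %in% names(series)))
    zd_stop("series needs `time` and `count` (or `normalized`) columns",
            "invalid_argument")
  w <- if ("count" %in% names(series)) series$count else series$normalized
  t <- series$time
  if (any(w < 0)) zd_stop("counts must be non-negative", "invalid_argument")
  W <- sum(w)
  if (W <= 0) zd_stop("total count is zero", "degenerate")
  o <- order(t)
  t <- t[o]; w <- w[o]
  keep <- w > 0
  tk <- t[keep]; wk <- w[keep]
  mean_t <- sum(wk * tk) / W
  if (length(tk) == 1L) {
    q <- rep(tk, 3)
  } else {
    Ck <- cumsum(wk)
    p <- (Ck - wk) / (W - wk[length(wk)])
    q <- stats::approx(p, tk, xout = c(0.25, 0.5, 0.75), rule = 2,
                       ties = "ordered")$y
  }
  c(mean = mean_t, min = tk[1], q1 = q[1], median = q[2], q3 = q[3],
    max = tk[length(tk)])
}

#' Write an arrival-statistics table
#'
#' Formats one [moment_stats()] row per scenario as a CSV with the columns
#' `label, Mean, Median, Mode, Std, Skewness, Kurtosis`.
#'
#' @param stats named list of `moment_stats` objects.
#' @param path output CSV path.
#' @return the table as a data frame, invisibly.
#' @export
write_stats_table <- function(stats, path) {
  rows <- do.call(rbind, lapply(stats, as.data.frame))
  tab <- cbind(data.frame(label = names(stats)), rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
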
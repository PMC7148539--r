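#' Simulation run configuration
#'
#' Parameters of an agent-based transport run. Agents are point organisms
#' released together at `release_point` and updated each step by a Gaussian
#' drift--diffusion rule: the displacement over `dt` is normal with mean
#' `v(x) * dt` (the interpolated local fluid velocity) and independent
#' per-axis variance `variance_rate * dt` — an unbiased random walk riding on
#' the flow.
#'
#' @param release_point numeric release position (mm), length `ndim`.
#' @param n_agents number of agents (>= 1); the reference campaigns use
#'   10,000.
#' @param variance_rate per-axis diffusive variance rate \eqn{\sigma^2}
#'   (mm^2/s), the diagonal of the covariance-rate matrix; scalar values are
#'   recycled. Default 2.5 mm^2/s, an effective diffusivity measured for
#'   Artemia nauplii.
#' @param dt time step (s).
#' @param t_end safety cap on simulated time (s); a run also ends as soon as
#'   every agent has either entered all registered zones or left the domain.
#' @param record_interval occupancy sampling interval (s); must be a positive
#'   multiple of `dt`. Default 0.5 s, the counting interval of the tank
#'   protocol.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(release_point, n_agents = 10000L,
                       variance_rate = 2.5, dt = 0.1, t_end = 600,
                       record_interval = 0.5) {
  release_point <- as.numeric(release_point)
  if (!(length(release_point) %in% c(2L, 3L)) || anyNA(release_point))
    zd_stop("`release_point` must be a 2D or 3D position", "invalid_argument")
  n_agents <- as.integer(n_agents)
  if (is.na(n_agents) || n_agents < 1L)
    zd_stop("`n_agents` must be >= 1", "invalid_argument")
  if (!is.finite(dt) || dt <= 0) zd_stop("`dt` must be > 0", "invalid_argument")
  if (!is.finite(t_end) || t_end < dt)
    zd_stop("`t_end` must be >= dt", "invalid_argument")
  ndim <- length(release_point)
  variance_rate <- rep_len(as.numeric(variance_rate), ndim)
  if (anyNA(variance_rate) || any(variance_rate < 0))
    zd_stop("`variance_rate` must be >= 0 on every axis", "invalid_argument")
  r <- record_interval / dt
  if (!is.finite(r) || r <= 0 || abs(r - round(r)) > 1e-9)
    zd_stop("`record_interval` must be a positive multiple of dt",
            "invalid_argument")
  structure(list(release_point = release_point, n_agents = n_agents,
                 variance_rate = variance_rate, dt = dt, t_end = t_end,
                 record_interval = record_interval, ndim = ndim),
            class = "sim_config")
}

#' Create a swarm of agents
#'
#' Agent state container: positions, per-axis diffusive variance rate, and
#' activity bookkeeping. All agents start active at the same release point.
#'
#' @param n number of agents.
#' @param release_point release position (mm).
#' @param variance_rate per-axis variance rate (mm^2/s), recycled.
#' @return an object of class `swarm`.
#' @export
new_swarm <- function(n, release_point, variance_rate = 2.5) {
  release_point <- as.numeric(release_point)
  ndim <- length(release_point)
  variance_rate <- rep_len(as.numeric(variance_rate), ndim)
  if (any(variance_rate < 0) || anyNA(variance_rate))
    zd_stop("`variance_rate` must be >= 0 on every axis", "invalid_argument")
  pos <- matrix(rep(release_point, each = n), nrow = n)
  colnames(pos) <- AXIS_NAMES[seq_len(ndim)]
  structure(list(positions = pos, active = rep(TRUE, n),
                 exit_time = rep(NA_real_, n),
                 exit_face = rep(NA_character_, n),
                 variance_rate = variance_rate, time = 0, ndim = ndim),
            class = "swarm")
}

#' @export
print.swarm <- function(x, ...) {
  cat(sprintf("<swarm> %d agents (%d active), t = %g s, sigma^2 = (%s) mm^2/s\n",
              nrow(x$positions), sum(x$active), x$time,
              paste(x$variance_rate, collapse = ", ")))
  invisible(x)
}

#' Apply domain boundary conditions to agent positions
#'
#' Agents outside the domain box are handled per violated face: if every
#' violated face is tagged `project`, the agent is translated back to the
#' nearest point on the domain boundary (a componentwise clamp, which is the
#' nearest-point projection onto an axis-aligned box); if any violated face
#' is tagged `exit`, the agent is flagged as having left the domain (exit
#' dominates projection). Positions already inside are untouched.
#'
#' @param positions `n x ndim` matrix of positions (mm), finite.
#' @param domain a [domain_spec()].
#' @return list with `positions` (projected), `exited` (logical), and
#'   `exit_face` (name of the exit face crossed, NA for non-exited agents).
#' @export
apply_boundaries <- function(positions, domain) {
  pos <- if (is.null(dim(positions))) matrix(positions, nrow = 1) else
    as.matrix(positions)
  if (ncol(pos) != domain$ndim)
    zd_stop("positions and domain dimensionality differ", "dimension")
  if (!all(is.finite(pos)))
    zd_stop(sprintf("non-finite position for agent %d",
                    which(!apply(is.finite(pos), 1, all))[1]), "numeric")
  n <- nrow(pos)
  exited <- rep(FALSE, n)
  exit_face <- rep(NA_character_, n)
  for (j in seq_len(domain$ndim)) {
    lo <- domain$bounds[[j]][1]; hi <- domain$bounds[[j]][2]
    ax <- names(domain$bounds)[j]
    for (side in c("min", "max")) {
      face <- paste0(ax, "_", side)
      viol <- if (side == "min") pos[, j] < lo else pos[, j] > hi
      if (domain$face_bc[[face]] == "exit") {
        first <- viol & !exited
        exit_face[first] <- face
        exited <- exited | viol
      }
    }
  }
  keep <- !exited
  if (any(keep)) {
    for (j in seq_len(domain$ndim)) {
      lo <- domain$bounds[[j]][1]; hi <- domain$bounds[[j]][2]
      pos[keep, j] <- pmin(pmax(pos[keep, j], lo), hi)
    }
  }
  list(positions = pos, exited = exited, exit_face = exit_face)
}

#' Advance a swarm by one drift--diffusion step
#'
#' Each active agent moves by an independent Gaussian displacement with mean
#' `v(x_t) * dt` (multilinear interpolation of `field` at the agent's
#' position) and per-axis variance `variance_rate * dt`, then boundary
#' conditions are applied once ([apply_boundaries()]). Inactive agents are
#' untouched and consume no random draws. Draws come from R's global RNG in
#' agent-major order (agent 1 axes x, y, z; then agent 2; ...), so a seeded
#' run is reproducible.
#'
#' @param swarm a [new_swarm()].
#' @param field a [grid_velocity_field()].
#' @param domain a [domain_spec()].
#' @param dt time step (s), > 0.
#' @return the updated `swarm`.
#' @export
step_swarm <- function(swarm, field, domain, dt) {
  if (!inherits(swarm, "swarm")) zd_stop("`swarm` must be a swarm", "invalid_argument")
  if (!is.finite(dt) || dt <= 0) zd_stop("`dt` must be > 0", "invalid_argument")
  if (swarm$ndim != field$ndim)
    zd_stop("swarm and field dimensionality differ", "dimension")
  act <- which(swarm$active)
  t_new <- swarm$time + dt
  if (length(act) > 0L) {
    p <- swarm$positions[act, , drop = FALSE]
    if (!all(is.finite(p)))
      zd_stop(sprintf("non-finite position for agent %d",
                      act[which(!apply(is.finite(p), 1, all))[1]]), "numeric")
    v <- interpolate_velocity(field, p,
                              time = if (is_time_varying(field)) swarm$time)
    if (!all(is.finite(v)))
      zd_stop(sprintf("non-finite interpolated velocity for agent %d",
                      act[which(!apply(is.finite(v), 1, all))[1]]), "numeric")
    d <- swarm$ndim
    sd_ax <- sqrt(swarm$variance_rate * dt)
    disp <- v * dt
    if (any(sd_ax > 0)) {
      noise <- matrix(stats::rnorm(length(act) * d), ncol = d, byrow = TRUE)
      disp <- disp + sweep(noise, 2, sd_ax, `*`)
    }
    bc <- apply_boundaries(p + disp, domain)
    swarm$positions[act, ] <- bc$positions
    out <- act[bc$exited]
    if (length(out) > 0L) {
      swarm$active[out] <- FALSE
      swarm$exit_time[out] <- t_new
      swarm$exit_face[out] <- bc$exit_face[bc$exited]
    }
  }
  swarm$time <- t_new
  swarm
}

#' Run an agent-based transport simulation
#'
#' Releases `n_agents` at the configured point and advances them by
#' [step_swarm()] until the safety cap `t_end` or — when zones are registered
#' — until every agent has either entered all zones or left the domain.
#' First entry into each zone is recorded online at step resolution, and
#' zone occupancy (active agents inside each zone; per counting cell when
#' the zone has a `cell_size`) is sampled every `record_interval`.
#'
#' @param config a [sim_config()]; its `release_point` must lie inside
#'   `domain`.
#' @param field a [grid_velocity_field()].
#' @param domain a [domain_spec()].
#' @param zones list of [zone()] objects to record (each must intersect the
#'   domain).
#' @param seed integer RNG seed; the run is a deterministic function of
#'   (config, field, domain, zones, seed). `NULL` uses the current RNG state.
#' @param track number of agents (the first `track`) whose full trajectories
#'   are stored.
#' @return an object of class `swarm_sim` with elements `arrivals` (N x
#'   n_zones matrix of first-entry times, NA = never), `exit_time`,
#'   `exit_face`, `occupancy` (data frame `time`, `zone`, `cell`, `count`),
#'   `positions` (final), `active`, `trajectories` (array, if tracked),
#'   `config`, `zones`, `seed`, `termination` (`"all_done"` or `"t_end"`),
#'   and `steps`.
#' @export
simulate_swarm <- function(config, field, domain, zones = list(), seed = NULL,
                           track = 0L) {
  if (!inherits(config, "sim_config"))
    zd_stop("`config` must be a sim_config", "invalid_argument")
  if (!inherits(domain, "domain_spec") || domain$ndim != config$ndim ||
      field$ndim != config$ndim)
    zd_stop("config, field and domain dimensionality must agree", "dimension")
  rp <- config$release_point
  for (j in seq_len(domain$ndim)) {
    b <- domain$bounds[[j]]
    if (rp[j] < b[1] || rp[j] > b[2])
      zd_stop("release point lies outside the domain", "invalid_argument")
  }
  if (inherits(zones, "zone")) zones <- list(zones)
  for (zn in zones) {
    if (!inherits(zn, "zone")) zd_stop("`zones` must hold zone objects",
                                       "invalid_argument")
    ivs <- list(zn$x_interval, zn$y_interval, zn$z_interval)
    for (j in seq_len(domain$ndim)) {
      iv <- ivs[[j]]
      if (is.null(iv)) next
      b <- domain$bounds[[j]]
      if (iv[2] < b[1] || iv[1] > b[2])
        zd_stop(sprintf("zone '%s' lies outside the domain", zn$label),
                "invalid_argument")
    }
  }
  zlabels <- vapply(zones, function(z) z$label, "")
  if (anyDuplicated(zlabels))
    zd_stop("zone labels must be unique", "invalid_argument")

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(as.integer(seed))
  }

  n <- config$n_agents
  dt <- config$dt
  nz <- length(zones)
  sw <- new_swarm(n, rp, config$variance_rate)
  arrivals <- matrix(NA_real_, n, max(nz, 1L))[, seq_len(nz), drop = FALSE]
  colnames(arrivals) <- zlabels
  rec_every <- as.integer(round(config$record_interval / dt))
  n_steps <- as.integer(floor(config$t_end / dt + 1e-9))
  n_rec <- n_steps %/% rec_every + 1L
  occ_tot <- matrix(0L, n_rec, nz, dimnames = list(NULL, zlabels))
  occ_cells <- lapply(zones, function(z)
    if (!is.null(z$cell_size)) matrix(0L, n_rec, zone_n_cells(z)))
  rec_times <- (seq_len(n_rec) - 1L) * config$record_interval
  track <- min(as.integer(track), n)
  traj <- if (track > 0L)
    array(NA_real_, dim = c(n_steps + 1L, config$ndim, track))

  record_zones <- function(step_idx, t) {
    pos <- sw$positions
    for (k in seq_len(nz)) {
      inside <- sw$active & zone_contains(zones[[k]], pos)
      hit <- inside & is.na(arrivals[, k])
      if (any(hit)) arrivals[hit, k] <<- t
    }
    if (step_idx %% rec_every == 0L) {
      ri <- step_idx %/% rec_every + 1L
      for (k in seq_len(nz)) {
        inside <- sw$active & zone_contains(zones[[k]], pos)
        occ_tot[ri, k] <<- sum(inside)
        if (!is.null(occ_cells[[k]])) {
          ci <- zone_cell_index(zones[[k]], pos[inside, , drop = FALSE])
          occ_cells[[k]][ri, ] <<- tabulate(ci, nbins = ncol(occ_cells[[k]]))
        }
      }
    }
  }

  record_zones(0L, 0)
  if (track > 0L) traj[1L, , ] <- t(sw$positions[seq_len(track), , drop = FALSE])
  termination <- "t_end"
  last_step <- n_steps
  for (s in seq_len(n_steps)) {
    sw <- step_swarm(sw, field, domain, dt)
    t <- s * dt
    record_zones(s, t)
    if (track > 0L) traj[s + 1L, , ] <- t(sw$positions[seq_len(track), , drop = FALSE])
    if (nz > 0L) {
      done <- !sw$active | !rowAnyNA(arrivals)
      if (all(done)) {
        termination <- "all_done"
        last_step <- s
        break
      }
    }
  }

  ri_keep <- seq_len(last_step %/% rec_every + 1L)
  occ <- occupancy_frame(rec_times[ri_keep],
                         occ_tot[ri_keep, , drop = FALSE],
                         lapply(occ_cells, function(m)
                           if (!is.null(m)) m[ri_keep, , drop = FALSE]),
                         zlabels)
  if (track > 0L)
    traj <- traj[seq_len(last_step + 1L), , , drop = FALSE]

  structure(list(arrivals = arrivals, exit_time = sw$exit_time,
                 exit_face = sw$exit_face, occupancy = occ,
                 positions = sw$positions, active = sw$active,
                 trajectories = if (track > 0L) traj,
                 config = config, zones = zones, seed = seed,
                 termination = termination, steps = last_step,
                 end_time = last_step * dt),
            class = "swarm_sim")
}

rowAnyNA <- function(m) {
  if (ncol(m) == 0L) rep(FALSE, nrow(m)) else rowSums(is.na(m)) > 0L
}

occupancy_frame <- function(times, tot, cells, zlabels) {
  out <- list()
  for (k in seq_along(zlabels)) {
    out[[length(out) + 1L]] <- data.frame(
      time = times, zone = zlabels[k], cell = NA_integer_, count = tot[, k])
    if (!is.null(cells[[k]])) {
      nc <- ncol(cells[[k]])
      out[[length(out) + 1L]] <- data.frame(
        time = rep(times, nc), zone = zlabels[k],
        cell = rep(seq_len(nc), each = length(times)),
        count = as.vector(cells[[k]]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(time = numeric(), zone = character(),
                      cell = integer(), count = integer()))
  res <- do.call(rbind, out)
  res[order(res$time, res$zone, res$cell, na.last = FALSE), , drop = FALSE]
}

#' @export
print.swarm_sim <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("<swarm_sim> %d agents, %d steps (%.1f s), terminated: %s\n",
              n, x$steps, x$end_time, x$termination))
  for (k in seq_len(ncol(x$arrivals)))
    cat(sprintf("  zone '%s': %d/%d arrived\n", colnames(x$arrivals)[k],
                sum(!is.na(x$arrivals[, k])), n))
  cat(sprintf("  exited domain: %d  still active: %d\n",
              sum(!is.na(x$exit_time)), sum(x$active)))
  invisible(x)
}

#' Summarise a simulation: arrival-time statistics per zone
#'
#' @param object a `swarm_sim`.
#' @param mode_bin mode bin width (s) passed to [moment_stats()]; defaults to
#'   the run's time step.
#' @param ... unused.
#' @return data frame with one row per zone (label, n arrived, Mean, Median,
#'   Mode, Std, Skewness, Kurtosis).
#' @export
summary.swarm_sim <- function(object, mode_bin = NULL, ...) {
  mode_bin <- mode_bin %||% object$config$dt
  rows <- lapply(seq_len(ncol(object$arrivals)), function(k) {
    at <- object$arrivals[, k]
    at <- at[!is.na(at)]
    if (length(at) == 0L)
      return(data.frame(label = colnames(object$arrivals)[k], n = 0L,
                        Mean = NA, Median = NA, Mode = NA, Std = NA,
                        Skewness = NA, Kurtosis = NA))
    st <- moment_stats(at, mode_bin = mode_bin)
    cbind(data.frame(label = colnames(object$arrivals)[k], n = st$n),
          as.data.frame(st))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
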
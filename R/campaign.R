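#' Run configuration for a simulation campaign
#'
#' Bundles a flow source, domain, simulation parameters, zones and output
#' settings. Exactly one flow source must be given: a prebuilt `grid_field`,
#' a field file, a canopy fixture, or the analytical parabolic profile.
#'
#' @param field optional [grid_velocity_field()] (takes precedence).
#' @param flow_file optional path to a field file.
#' @param flow_format file dialect for `flow_file` (see [read_grid_field()]).
#' @param canopy optional [canopy_spec()] for the fixture generator.
#' @param u_max peak free-stream velocity (mm/s) for generated fields.
#' @param domain a [domain_spec()].
#' @param sim a [sim_config()].
#' @param zones list of [zone()] objects; default [default_zones()] placed
#'   relative to `canopy` (or to the domain for non-canopy flows).
#' @param variance_rates numeric vector of variance rates (mm^2/s) for
#'   [sweep_diffusivity()].
#' @param out_dir output directory.
#' @param seed base RNG seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(field = NULL, flow_file = NULL,
                       flow_format = "delimited", canopy = NULL,
                       u_max = 44.4, domain = default_tank(), sim = NULL,
                       zones = NULL, variance_rates = NULL,
                       out_dir = "zoodrift-out", seed = 1L) {
  problems <- character()
  n_src <- sum(!is.null(field), !is.null(flow_file), !is.null(canopy))
  if (n_src > 1L)
    problems <- c(problems,
                  "more than one flow source given (field / flow_file / canopy)")
  if (!is.null(flow_file) && !file.exists(flow_file))
    problems <- c(problems, sprintf("flow file does not exist: %s", flow_file))
  if (!inherits(domain, "domain_spec"))
    problems <- c(problems, "`domain` must be a domain_spec")
  if (!is.null(canopy) && !inherits(canopy, "canopy_spec"))
    problems <- c(problems, "`canopy` must be a canopy_spec")
  if (length(problems) > 0L)
    zd_stop(paste0("invalid run configuration:\n",
                   paste0("  - ", problems, collapse = "\n")), "invalid_argument")
  if (is.null(sim)) {
    rp <- default_release(canopy, domain)
    sim <- sim_config(release_point = rp)
  }
  if (is.null(zones)) zones <- default_zones(canopy, domain)
  structure(list(field = field, flow_file = flow_file,
                 flow_format = flow_format, canopy = canopy, u_max = u_max,
                 domain = domain, sim = sim, zones = zones,
                 variance_rates = variance_rates, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# release 1 mm upstream of the canopy's upstream face, on the centreline,
# 3 mm above the bottom (injection directly upstream of the model); for
# canopy-free flows, 10% into the domain streamwise.
default_release <- function(canopy, domain) {
  b <- domain$bounds
  x <- if (!is.null(canopy)) canopy$canopy_start - 1 else
    b$x[1] + 0.1 * diff(b$x)
  c(x, mean(b$y), b$z[1] + 3)
}

#' Default observation zones
#'
#' Two zones in the style of the tank protocol, each 40 mm wide (streamwise)
#' and 80 mm tall, split into eight 20 mm counting cells and spanning the
#' full tank width: `green` immediately downstream of the canopy's trailing
#' edge and `blue` 150 mm further downstream.
#'
#' @param canopy optional [canopy_spec()]; without one the zones are placed
#'   relative to the domain centre.
#' @param domain a [domain_spec()].
#' @return list of two [zone()] objects.
#' @export
default_zones <- function(canopy = NULL, domain = default_tank()) {
  b <- domain$bounds
  xe <- if (!is.null(canopy)) canopy$canopy_start + canopy$canopy_length else
    b$x[1] + 0.375 * diff(b$x)
  zh <- c(b$z[1], b$z[1] + min(80, diff(b$z)))
  list(zone("green", x_interval = c(xe, xe + 40), z_interval = zh,
            cell_size = 20),
       zone("blue", x_interval = c(xe + 150, xe + 190), z_interval = zh,
            cell_size = 20))
}

resolve_field <- function(rc) {
  if (!is.null(rc$field)) return(rc$field)
  if (!is.null(rc$flow_file))
    return(read_grid_field(rc$flow_file, rc$flow_format))
  if (!is.null(rc$canopy))
    return(canopy_field(rc$canopy, u_max = rc$u_max, domain = rc$domain))
  b <- rc$domain$bounds
  parabolic_channel_field(rc$u_max, diff(b$z), rc$domain)
}

#' Execute a configured run and write its artifact set
#'
#' Runs one simulation and writes, under `out_dir`: `arrivals.csv` (one row
#' per agent: per-zone arrival time, exit time and face), `occupancy.csv`
#' (time, zone, cell, count, normalized_count), `stats.csv` (one
#' [moment_stats()] row per zone) and `manifest.yml` (the fully resolved
#' configuration, seed and package version; re-running from a manifest with
#' [read_run_config()] reproduces the outputs exactly).
#'
#' @param rc a [run_config()] (or a path to a config file, see
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return the `swarm_sim` result, invisibly.
#' @export
run_campaign <- function(rc, quiet = FALSE) {
  if (is.character(rc)) rc <- read_run_config(rc)
  if (!inherits(rc, "run_config"))
    zd_stop("`rc` must be a run_config", "invalid_argument")
  say <- function(...) if (!quiet)
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  field <- resolve_field(rc)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  say("simulating %d agents (dt = %g s, seed %d)", rc$sim$n_agents,
      rc$sim$dt, rc$seed)
  res <- simulate_swarm(rc$sim, field, rc$domain, rc$zones, seed = rc$seed)
  say("terminated (%s) after %.1f s simulated time", res$termination,
      res$end_time)
  write_sim_result(res, rc$out_dir)
  stats <- lapply(colnames(res$arrivals), function(lab) {
    at <- first_arrival_times(res, lab)
    if (length(at) > 0L) moment_stats(at, mode_bin = rc$sim$dt)
  })
  names(stats) <- colnames(res$arrivals)
  stats <- Filter(Negate(is.null), stats)
  if (length(stats) > 0L)
    write_stats_table(stats, file.path(rc$out_dir, "stats.csv"))
  write_manifest(rc, file.path(rc$out_dir, "manifest.yml"))
  say("artifacts written to %s", rc$out_dir)
  invisible(res)
}

#' Serialise a simulation result as CSV
#'
#' @param result a `swarm_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- as.data.frame(result$arrivals)
  if (ncol(arr) > 0L) names(arr) <- paste0("arrival_", names(arr))
  arr <- cbind(data.frame(agent = seq_len(nrow(result$positions))), arr,
               data.frame(exit_time = result$exit_time,
                          exit_face = result$exit_face))
  utils::write.csv(arr, file.path(dir, "arrivals.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  occ <- result$occupancy
  tot <- sum(occ$count[is.na(occ$cell)])
  occ$normalized_count <- if (tot > 0) occ$count / tot else 0
  utils::write.csv(occ, file.path(dir, "occupancy.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(dir)
}

#' Diffusivity sweep
#'
#' Repeats the configured run over a grid of per-axis variance rates,
#' seeding run `i` with `seed + i - 1` so single- and multi-process
#' execution agree. The reference grid spans 0 to 25 mm^2/s.
#'
#' @param rc a [run_config()].
#' @param variance_rates variance rates (mm^2/s); defaults to
#'   `rc$variance_rates` or the reference grid
#'   `c(0, 0.25, 0.5, 0.75, 1, 2.5, 5, 7.5, 10, 25)`.
#' @param zone_label zone whose arrival statistics fill the output table.
#' @param quiet suppress progress messages.
#' @return data frame: one row per variance rate with `variance_rate`, `n`
#'   and the [moment_stats()] columns; written to
#'   `<out_dir>/sweep_diffusivity_<zone>.csv`.
#' @export
sweep_diffusivity <- function(rc, variance_rates = NULL, zone_label = "green",
                              quiet = FALSE) {
  variance_rates <- variance_rates %||% rc$variance_rates %||%
    c(0, 0.25, 0.5, 0.75, 1, 2.5, 5, 7.5, 10, 25)
  field <- resolve_field(rc)
  rows <- vector("list", length(variance_rates))
  for (i in seq_along(variance_rates)) {
    sim <- rc$sim
    sim$variance_rate <- rep_len(variance_rates[i], sim$ndim)
    res <- simulate_swarm(sim, field, rc$domain, rc$zones,
                          seed = rc$seed + i - 1L)
    at <- first_arrival_times(res, zone_label)
    st <- moment_stats(at, mode_bin = sim$dt)
    rows[[i]] <- cbind(data.frame(variance_rate = variance_rates[i],
                                  n = st$n), as.data.frame(st))
    if (!quiet)
      message(sprintf("variance %g mm^2/s: mean arrival %.2f s (n = %d)",
                      variance_rates[i], st$mean, st$n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(
    rc$out_dir, sprintf("sweep_diffusivity_%s.csv", zone_label)),
    row.names = FALSE, quote = FALSE)
  out
}

#' Canopy density/height sweep
#'
#' Runs the configured simulation over the [scenario_suite()] fields (every
#' height x density combination plus the plate control), seeding scenario
#' `i` with `seed + i - 1`, and tabulates each scenario's arrival statistics
#' for one zone. Zones and release point are placed per scenario via
#' [default_zones()] and the standard release rule so that every canopy
#' shares the same geometry.
#'
#' @param rc a [run_config()] (its canopy/zones are ignored; geometry comes
#'   from each scenario).
#' @param heights canopy heights (mm).
#' @param density_fractions named in-canopy speed fractions (see
#'   [scenario_suite()]).
#' @param zone_label zone to tabulate.
#' @param quiet suppress progress messages.
#' @return data frame: one row per scenario (label, n, moment columns);
#'   written to `<out_dir>/sweep_density_<zone>.csv`.
#' @export
sweep_density <- function(rc, heights = c(10, 20, 30),
                          density_fractions = c("8x15" = 0.5, "10x20" = 0.3,
                                                "15x30" = 0.05),
                          zone_label = "green", quiet = FALSE) {
  suite <- scenario_suite(heights, density_fractions, u_max = rc$u_max,
                          domain = rc$domain)
  specs <- attr(suite, "specs")
  rows <- vector("list", length(suite))
  for (i in seq_along(suite)) {
    lab <- names(suite)[i]
    sp <- specs[[lab]] %||% canopy_spec()  # plate: reuse standard geometry
    sim <- rc$sim
    sim$release_point <- default_release(sp, rc$domain)
    zones <- default_zones(sp, rc$domain)
    res <- simulate_swarm(sim, suite[[i]], rc$domain, zones,
                          seed = rc$seed + i - 1L)
    at <- first_arrival_times(res, zone_label)
    st <- moment_stats(at, mode_bin = sim$dt)
    rows[[i]] <- cbind(data.frame(label = lab, n = st$n), as.data.frame(st))
    if (!quiet)
      message(sprintf("%s: mean arrival %.2f s (n = %d)", lab, st$mean, st$n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, file.path(
    rc$out_dir, sprintf("sweep_density_%s.csv", zone_label)),
    row.names = FALSE, quote = FALSE)
  out
}

# ---- flat key-value config files -------------------------------------------

#' Read or write a run configuration file
#'
#' The on-disk format is a flat YAML mapping of scalar keys (plus short
#' lists), human-editable, with explicit unit suffixes in the key names.
#' Recognised keys:
#'
#' \describe{
#' \item{flow}{`"parabolic"`, `"fixture"` or `"file"`.}
#' \item{flow_file, flow_format}{field file and dialect, for `flow: file`.}
#' \item{u_max_mm_s}{peak free-stream velocity.}
#' \item{canopy_height_mm, canopy_length_mm, canopy_start_mm,
#'   in_canopy_fraction, transition_width_mm, wake_length_mm, wake_deficit}{
#'   fixture canopy parameters, for `flow: fixture`.}
#' \item{domain_x_mm, domain_y_mm, domain_z_mm}{two-element `[min, max]`
#'   extents.}
#' \item{release_mm}{three-element release position.}
#' \item{n_agents, dt_s, t_end_s, record_interval_s, variance_rate_mm2_s}{
#'   simulation parameters; `variance_rate_mm2_s` may be a list (a sweep
#'   grid; the first value is used for single runs).}
#' \item{zone_<label>_x_mm, zone_<label>_z_mm, zone_<label>_cell_mm}{zone
#'   extents per label (any number of labels).}
#' \item{seed, out_dir}{base seed and output directory.}
#' }
#'
#' Validation collects every violation and reports them together.
#'
#' @param path config (or manifest) file path.
#' @param rc a [run_config()] to serialise.
#' @return `read_run_config` returns a `run_config`; `write_manifest`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    zd_stop(sprintf("config file not found: %s", path), "invalid_argument")
  cfg <- yaml::read_yaml(path)
  problems <- character()
  need_num <- function(key, default = NULL, len = 1L) {
    v <- cfg[[key]] %||% default
    if (is.null(v)) {
      problems <<- c(problems, sprintf("missing required key `%s`", key))
      return(rep(NA_real_, len))
    }
    v <- suppressWarnings(as.numeric(unlist(v)))
    if (anyNA(v) || (len > 0L && length(v) != len))
      problems <<- c(problems,
                     sprintf("key `%s` must hold %d numeric value(s)", key, len))
    v
  }
  flow <- cfg$flow %||% "parabolic"
  if (!flow %in% c("parabolic", "fixture", "file"))
    problems <- c(problems, "`flow` must be parabolic, fixture or file")
  if (flow == "file" && is.null(cfg$flow_file))
    problems <- c(problems, "`flow: file` requires `flow_file`")
  if (!is.null(cfg$flow_file) && !file.exists(cfg$flow_file))
    problems <- c(problems, sprintf("flow file not found: %s", cfg$flow_file))
  dom_b <- list(need_num("domain_x_mm", c(0, 320), 2L),
                need_num("domain_y_mm", c(0, 80), 2L),
                need_num("domain_z_mm", c(0, 80), 2L))
  canopy <- NULL
  if (flow == "fixture") {
    canopy <- tryCatch(
      canopy_spec(canopy_height = need_num("canopy_height_mm", 20),
                  canopy_length = need_num("canopy_length_mm", 60),
                  canopy_start = need_num("canopy_start_mm", 60),
                  in_canopy_fraction = need_num("in_canopy_fraction", 0.3),
                  transition_width = need_num("transition_width_mm", 5),
                  wake_length = need_num("wake_length_mm", 120),
                  wake_deficit = need_num("wake_deficit", 0.7)),
      zoodrift_error = function(e) {
        problems <<- c(problems, conditionMessage(e)); NULL
      })
  }
  u_max <- need_num("u_max_mm_s", 44.4)
  vr <- suppressWarnings(as.numeric(unlist(
    cfg$variance_rate_mm2_s %||% 2.5)))
  if (length(vr) == 0L || anyNA(vr) || any(vr < 0))
    problems <- c(problems, "`variance_rate_mm2_s` must be >= 0")
  if (length(problems) > 0L)
    zd_stop(paste0("invalid run configuration (", path, "):\n",
                   paste0("  - ", problems, collapse = "\n")),
            "invalid_argument")
  domain <- domain_spec(dom_b)
  release <- if (!is.null(cfg$release_mm))
    as.numeric(unlist(cfg$release_mm)) else default_release(canopy, domain)
  sim <- sim_config(release_point = release,
                    n_agents = cfg$n_agents %||% 10000L,
                    variance_rate = vr[1],
                    dt = cfg$dt_s %||% 0.1,
                    t_end = cfg$t_end_s %||% 600,
                    record_interval = cfg$record_interval_s %||% 0.5)
  zkeys <- grep("^zone_.*_x_mm$", names(cfg), value = TRUE)
  zones <- if (length(zkeys) == 0L) default_zones(canopy, domain) else
    lapply(zkeys, function(k) {
      lab <- sub("^zone_(.*)_x_mm$", "\\1", k)
      zone(lab, x_interval = as.numeric(unlist(cfg[[k]])),
           z_interval = if (!is.null(cfg[[paste0("zone_", lab, "_z_mm")]]))
             as.numeric(unlist(cfg[[paste0("zone_", lab, "_z_mm")]])),
           cell_size = cfg[[paste0("zone_", lab, "_cell_mm")]])
    })
  run_config(flow_file = if (flow == "file") cfg$flow_file,
             flow_format = cfg$flow_format %||% "delimited",
             canopy = canopy, u_max = u_max,
             domain = domain, sim = sim, zones = zones,
             variance_rates = if (length(vr) > 1L) vr,
             out_dir = cfg$out_dir %||% "zoodrift-out",
             seed = cfg$seed %||% 1L)
}

#' @rdname read_run_config
#' @export
write_manifest <- function(rc, path) {
  b <- rc$domain$bounds
  flow <- if (!is.null(rc$flow_file)) "file" else
    if (!is.null(rc$canopy)) "fixture" else "parabolic"
  m <- list(zoodrift_version = as.character(utils::packageVersion("zoodrift")),
            flow = flow, u_max_mm_s = rc$u_max)
  if (!is.null(rc$flow_file)) {
    m$flow_file <- rc$flow_file
    m$flow_format <- rc$flow_format
  }
  if (!is.null(rc$canopy)) {
    cp <- rc$canopy
    m <- c(m, list(canopy_height_mm = cp$canopy_height,
                   canopy_length_mm = cp$canopy_length,
                   canopy_start_mm = cp$canopy_start,
                   in_canopy_fraction = cp$in_canopy_fraction,
                   transition_width_mm = cp$transition_width,
                   wake_length_mm = cp$wake_length,
                   wake_deficit = cp$wake_deficit))
  }
  m <- c(m, list(domain_x_mm = b$x, domain_y_mm = b$y, domain_z_mm = b$z,
                 release_mm = rc$sim$release_point,
                 n_agents = rc$sim$n_agents,
                 dt_s = rc$sim$dt, t_end_s = rc$sim$t_end,
                 record_interval_s = rc$sim$record_interval,
                 variance_rate_mm2_s = if (!is.null(rc$variance_rates))
                   rc$variance_rates else rc$sim$variance_rate[1],
                 seed = rc$seed, out_dir = rc$out_dir))
  for (zn in rc$zones) {
    m[[sprintf("zone_%s_x_mm", zn$label)]] <- zn$x_interval
    if (!is.null(zn$z_interval))
      m[[sprintf("zone_%s_z_mm", zn$label)]] <- zn$z_interval
    if (!is.null(zn$cell_size))
      m[[sprintf("zone_%s_cell_mm", zn$label)]] <- zn$cell_size
  }
  yaml::write_yaml(m, path)
  invisible(path)
}
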
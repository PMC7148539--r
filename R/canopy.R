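#' Synthetic macrophyte-canopy flow parameters
#'
#' Describes an idealised submerged canopy (a bed of plant-like obstructions)
#' for the synthetic flow generator [canopy_field()]. Individual stems are
#' not resolved; stem density is abstracted into `in_canopy_fraction`, the
#' ratio of in-canopy to free-stream streamwise speed, which is what the
#' agent model actually responds to.
#'
#' @param canopy_height canopy height above the bottom (mm).
#' @param canopy_length streamwise extent of the canopy (mm).
#' @param canopy_start streamwise position of the upstream canopy face (mm).
#' @param in_canopy_fraction in `[0, 1]`; fraction of the free-stream speed
#'   retained deep inside the canopy (1 = no canopy effect, 0 = stagnant).
#' @param transition_width vertical width (mm) of the smooth shear layer over
#'   which the speed rises from the in-canopy value to the free-stream value.
#' @param wake_length streamwise length (mm) of the slow wake downstream of
#'   the canopy, over which the deficit recovers linearly.
#' @param wake_deficit in `[0, 1]`; fractional velocity deficit immediately
#'   behind the canopy at canopy level (0 = no wake).
#' @return an object of class `canopy_spec`.
#' @export
canopy_spec <- function(canopy_height = 20, canopy_length = 60,
                        canopy_start = 60, in_canopy_fraction = 0.3,
                        transition_width = 5, wake_length = 120,
                        wake_deficit = 0.7) {
  vals <- list(canopy_height = canopy_height, canopy_length = canopy_length,
               canopy_start = canopy_start,
               in_canopy_fraction = in_canopy_fraction,
               transition_width = transition_width,
               wake_length = wake_length, wake_deficit = wake_deficit)
  for (nm in c("canopy_height", "canopy_length", "transition_width",
               "wake_length"))
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0)
      zd_stop(sprintf("`%s` must be positive", nm), "invalid_argument")
  if (!is.finite(canopy_start))
    zd_stop("`canopy_start` must be finite", "invalid_argument")
  for (nm in c("in_canopy_fraction", "wake_deficit"))
    if (!is.finite(vals[[nm]]) || vals[[nm]] < 0 || vals[[nm]] > 1)
      zd_stop(sprintf("`%s` must lie in [0, 1]", nm), "invalid_argument")
  structure(vals, class = "canopy_spec")
}

#' Synthetic canopy flow field
#'
#' Builds a steady 3D velocity field emulating the qualitative flow structure
#' around a submerged macrophyte bed in a channel: slow flow inside the
#' canopy, a sharp speed-up across a shear layer at canopy height with mildly
#' accelerated overtopping flow, upward-directed flow over the leading edge,
#' and a slow wake downstream that recovers linearly with distance. The base
#' profile is the parabolic channel flow of [parabolic_channel_field()]; the
#' canopy enters as a multiplicative velocity-deficit factor. No
#' incompressibility correction is applied.
#'
#' @param spec a [canopy_spec()].
#' @param u_max free-stream peak velocity (mm/s).
#' @param domain a 3D [domain_spec()]; the canopy footprint (streamwise
#'   interval, full width) must lie inside it.
#' @param resolution integer vector of grid points per axis (>= 4 each).
#' @param overtop_boost fractional speed-up of the flow just above the canopy
#'   (displaced volume flux); the resulting speed is capped at
#'   `speed_cap * u_max`.
#' @param speed_cap hard cap on speed as a multiple of `u_max`.
#' @return a 3D `grid_field`.
#' @export
canopy_field <- function(spec, u_max, domain,
                         resolution = c(65L, 5L, 33L),
                         overtop_boost = 0.25, speed_cap = 1.5) {
  if (!inherits(spec, "canopy_spec"))
    zd_stop("`spec` must be a canopy_spec", "invalid_argument")
  if (!inherits(domain, "domain_spec") || domain$ndim != 3L)
    zd_stop("`domain` must be a 3D domain_spec", "invalid_argument")
  resolution <- rep_len(as.integer(resolution), 3L)
  if (any(resolution < 4L))
    zd_stop("need at least 4 grid points per axis", "invalid_argument")
  bx <- domain$bounds$x; bz <- domain$bounds$z
  height <- bz[2] - bz[1]
  x0 <- spec$canopy_start
  x1 <- x0 + spec$canopy_length
  if (x0 < bx[1] || x1 > bx[2] || spec$canopy_height >= height)
    zd_stop("canopy does not fit inside the domain", "invalid_argument")

  axes <- lapply(1:3, function(j)
    seq(domain$bounds[[j]][1], domain$bounds[[j]][2],
        length.out = resolution[j]))
  x <- axes[[1]]; z <- axes[[3]] - bz[1]
  shape <- resolution

  u_par <- u_max * 4 * z * (height - z) / height^2     # base profile, u(z)
  # vertical shear-layer profile: 0 deep in canopy, 1 well above it. The
  # layer is centred one transition width above the canopy top: the sheltered
  # region extends a little above the obstructions, it does not stop at them.
  zc <- spec$canopy_height + spec$transition_width
  sig <- 0.5 * (1 + tanh((z - zc) / (spec$transition_width / 2)))
  blend <- spec$in_canopy_fraction + (1 - spec$in_canopy_fraction) * sig
  # overtopping speed-up above the canopy (displaced volume flux), following
  # the same monotone shear-layer shape so speed stays non-decreasing with
  # height below mid-channel
  boost <- 1 + overtop_boost * (1 - spec$in_canopy_fraction) * sig

  # streamwise deficit factor m(x, z)
  in_canopy <- x >= x0 & x <= x1
  wake_frac <- pmin(pmax((x - x1) / spec$wake_length, 0), 1)  # 0 at trailing edge
  in_wake <- x > x1 & wake_frac < 1
  m <- matrix(1, shape[1], shape[3])                 # x by z
  for (i in seq_len(shape[1])) {
    if (in_canopy[i]) {
      m[i, ] <- blend * boost
    } else if (in_wake[i]) {
      # wake: deficit of wake_deficit at the trailing edge recovering linearly
      # with x; confined below canopy height by the same shear-layer shape
      m[i, ] <- 1 - spec$wake_deficit * (1 - wake_frac[i]) * (1 - sig)
    }
  }
  u_xz <- sweep(m, 2, u_par, `*`)
  u_xz <- pmin(u_xz, speed_cap * u_max)

  # weak upward flow over the leading edge, strongest at canopy height, zero
  # at bottom and surface
  w_amp <- 0.05 * u_max * (1 - spec$in_canopy_fraction) * spec$wake_deficit
  lead <- exp(-0.5 * ((x - x0) / (0.5 * spec$canopy_length))^2) *
    as.numeric(x >= x0 - spec$canopy_length & x <= x1)
  w_z <- 4 * z * (height - z) / height^2 *
    exp(-0.5 * ((z - spec$canopy_height) / spec$canopy_height)^2)
  w_xz <- w_amp * outer(lead, w_z)

  u <- aperm(array(rep(u_xz, times = shape[2]),
                   dim = c(shape[1], shape[3], shape[2])), c(1, 3, 2))
  w <- aperm(array(rep(w_xz, times = shape[2]),
                   dim = c(shape[1], shape[3], shape[2])), c(1, 3, 2))
  v <- array(0, dim = shape)
  grid_velocity_field(axes, list(u, v, w))
}

#' Labelled suite of canopy scenarios
#'
#' Generates one synthetic flow field per (height, density) combination plus
#' a no-canopy "plate" field (the plain parabolic channel), labelled
#' `"<density>_<height-cm>cm"` in the style of the physical model naming
#' (e.g. `"8x15_2cm"`). Stem densities are abstracted to in-canopy speed
#' fractions; lower fraction = denser canopy.
#'
#' @param heights canopy heights (mm).
#' @param density_fractions named numeric vector of in-canopy speed fractions;
#'   names are the density labels. Default maps the 8x15 / 10x20 / 15x30 stem
#'   grids to fractions 0.5 / 0.3 / 0.05 (sparser to denser).
#' @param u_max free-stream peak velocity (mm/s).
#' @param domain a 3D [domain_spec()].
#' @param ... further arguments to [canopy_field()] (resolution, caps) applied
#'   to every scenario.
#' @return a named list of `grid_field` objects (one per scenario plus
#'   `"plate"`), with attribute `"specs"` holding each scenario's
#'   `canopy_spec`.
#' @export
scenario_suite <- function(heights = c(10, 20, 30),
                           density_fractions = c("8x15" = 0.5, "10x20" = 0.3,
                                                 "15x30" = 0.05),
                           u_max = 44.4, domain = default_tank(), ...) {
  if (length(heights) == 0L || length(density_fractions) == 0L)
    zd_stop("`heights` and `density_fractions` must be non-empty",
            "invalid_argument")
  if (is.null(names(density_fractions)))
    names(density_fractions) <- paste0("d", seq_along(density_fractions))
  fields <- list()
  specs <- list()
  for (dn in names(density_fractions)) {
    for (h in heights) {
      label <- sprintf("%s_%gcm", dn, h / 10)
      # the wake deficit deepens with density: a denser bed blocks more flow
      # and sheds a more strongly sheltered wake
      sp <- canopy_spec(canopy_height = h,
                        in_canopy_fraction = density_fractions[[dn]],
                        wake_deficit = 1 - density_fractions[[dn]])
      fields[[label]] <- canopy_field(sp, u_max = u_max, domain = domain, ...)
      specs[[label]] <- sp
    }
  }
  res <- rep_len(list(...)$resolution %||% c(65L, 5L, 33L), 3L)
  fields[["plate"]] <- parabolic_channel_field(
    u_max, domain$bounds$z[2] - domain$bounds$z[1], domain,
    resolution = res)
  attr(fields, "specs") <- specs
  fields
}

#' Default flow-tank domain
#'
#' The simulated working section: an 80 mm (W) x 320 mm (L) x 80 mm (H) box
#' with open (exit) upstream and downstream faces and solid (project) side
#' walls, bottom and fluid surface.
#'
#' @return a 3D [domain_spec()].
#' @export
default_tank <- function() {
  domain_spec(list(c(0, 320), c(0, 80), c(0, 80)))
}
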
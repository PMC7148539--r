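#' Fluid and organism parameters for dimensionless numbers
#'
#' SI units throughout: density in kg/m^3, dynamic viscosity in N s/m^2,
#' velocity in m/s, length in m. [mm_to_m()] and [mm_s_to_m_s()] convert from
#' the mm-based units used elsewhere in the package.
#'
#' @param rho fluid density (kg/m^3), e.g. 1025 for seawater near 20 C.
#' @param mu dynamic viscosity (N s/m^2), e.g. 0.00108 for seawater.
#' @param U characteristic velocity (m/s).
#' @param L characteristic length (m), e.g. stem diameter or canopy height.
#' @return an object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 1025, mu = 0.00108, U, L) {
  vals <- c(rho = rho, mu = mu, U = U, L = L)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0))
    zd_stop("all of rho, mu, U, L must be strictly positive", "invalid_argument")
  structure(as.list(vals), class = "fluid_params")
}

#' Reynolds number
#'
#' `Re = rho * U * L / mu = U * L / nu`, the ratio of inertial to viscous
#' forces; it fixes the flow regime around an organism or an obstruction.
#'
#' @param params a [fluid_params()].
#' @return the dimensionless Reynolds number.
#' @examples
#' # stem-scale regime in seawater: U = 44.4 mm/s across a 2.5 mm stem
#' reynolds(fluid_params(U = 0.0444, L = 0.0025))
#' @export
reynolds <- function(params) {
  if (!inherits(params, "fluid_params"))
    params <- do.call(fluid_params, as.list(params))
  params$rho * params$U * params$L / params$mu
}

#' Velocity ratio of swimming to background flow
#'
#' `Vr = u_swim / u_flow`: below about 1, transport is dominated by passive
#' drift; above it, self-propulsion matters. The caller chooses whether
#' `u_flow` is a speed magnitude or a single component.
#'
#' @param u_swim organism swimming speed (mm/s), >= 0.
#' @param u_flow background flow speed (mm/s), nonzero.
#' @return the dimensionless velocity ratio.
#' @export
velocity_ratio <- function(u_swim, u_flow) {
  if (!is.finite(u_flow) || u_flow == 0)
    zd_stop("`u_flow` must be nonzero", "invalid_argument")
  if (!is.finite(u_swim) || u_swim < 0)
    zd_stop("`u_swim` must be >= 0", "invalid_argument")
  u_swim / u_flow
}

#' @rdname fluid_params
#' @param x length in mm / velocity in mm/s to convert.
#' @export
mm_to_m <- function(x) x / 1000

#' @rdname fluid_params
#' @export
mm_s_to_m_s <- function(x) x / 1000
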
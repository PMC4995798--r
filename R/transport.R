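# Boltzmann constant, J/K (CODATA exact value)
.kB <- 1.380649e-23

#' Cell culture medium conditions governing particle transport
#'
#' Temperature, dynamic viscosity and density of the liquid in which the
#' particles move. The defaults describe complete cell culture medium at
#' incubator temperature: 37 degrees C (310.15 K), viscosity
#' 8.12e-4 Pa s, density 1.00 g cm^-3.
#'
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param rho_medium Medium mass density, g cm^-3.
#' @param g Gravitational acceleration, m s^-2.
#' @return An object of class `medium_conditions`.
#' @export
medium_conditions <- function(temperature = 310.15, viscosity = 8.12e-4,
                              rho_medium = 1.00, g = 9.81) {
  stopifnot(temperature > 0, viscosity > 0, rho_medium > 0, g > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 rho_medium = rho_medium, g = g),
            class = "medium_conditions")
}

#' Exposure well geometry
#'
#' Geometry and cell load of one well of the exposure plate. Defaults match
#' a 96-well plate dosed with 200 uL of suspension: liquid height 5.5 mm,
#' confluent monolayer of 70,000 cells, and a 1 mm reference travel distance
#' for transport-time comparisons.
#'
#' @param liquid_height Height of the liquid column, mm.
#' @param volume Dosed volume, uL.
#' @param cells_per_well Number of cells in the monolayer.
#' @param travel_length Reference distance for transport times, mm.
#' @return An object of class `well_setup`.
#' @export
well_setup <- function(liquid_height = 5.5, volume = 200,
                       cells_per_well = 70000, travel_length = 1.0) {
  stopifnot(liquid_height > 0, volume > 0, cells_per_well > 0,
            travel_length > 0)
  structure(list(liquid_height = liquid_height, volume = volume,
                 cells_per_well = cells_per_well,
                 travel_length = travel_length),
            class = "well_setup")
}

#' Stokes-Einstein diffusion coefficient
#'
#' \deqn{D = \frac{k_B T}{3 \pi \eta D_{NP}}}
#'
#' @param d_np Particle (complex) hydrodynamic diameter, nm.
#' @param medium A [medium_conditions()].
#' @return Diffusion coefficient, m^2 s^-1.
#' @export
diffusion_coefficient <- function(d_np, medium = medium_conditions()) {
  stopifnot(inherits(medium, "medium_conditions"))
  if (any(d_np <= 0)) stop("d_np must be positive", call. = FALSE)
  .kB * medium$temperature / (3 * pi * medium$viscosity * .nm2m(d_np))
}

#' Stokes settling velocity
#'
#' \deqn{V = \frac{g (\rho_{NP} - \rho_m) D_{NP}^2}{18 \eta}}
#' The sign follows the density contrast: buoyant complexes (apparent
#' density below the medium density) get a negative velocity.
#'
#' @inheritParams diffusion_coefficient
#' @param rho_app Apparent density of the particle complex, g cm^-3.
#' @return Settling velocity, m s^-1 (positive downward).
#' @export
settling_velocity <- function(d_np, rho_app, medium = medium_conditions()) {
  stopifnot(inherits(medium, "medium_conditions"))
  if (any(d_np <= 0)) stop("d_np must be positive", call. = FALSE)
  medium$g * .gcm3_to_kgm3(rho_app - medium$rho_medium) * .nm2m(d_np)^2 /
    (18 * medium$viscosity)
}

#' Time to travel a distance by diffusion
#'
#' Mean time for a particle to cover a distance `length` by one-dimensional
#' Brownian motion, from the root-mean-square displacement
#' \eqn{\langle x^2 \rangle = 2 D t}: \eqn{t = L^2 / (2D)}.
#'
#' @inheritParams diffusion_coefficient
#' @param length Travel distance, mm.
#' @return Time in hours.
#' @export
transport_time_diffusion <- function(d_np, medium = medium_conditions(),
                                     length = 1.0) {
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  L <- length * 1e-3
  L^2 / (2 * diffusion_coefficient(d_np, medium)) / 3600
}

#' Time to travel a distance by gravitational sedimentation
#'
#' \eqn{t = L / V} with the Stokes velocity of [settling_velocity()].
#' Complexes that do not sediment (apparent density at or below the medium
#' density) return `Inf` rather than raising an error.
#'
#' @inheritParams settling_velocity
#' @param length Travel distance, mm.
#' @return Time in hours (`Inf` for non-sedimenting particles).
#' @export
transport_time_sedimentation <- function(d_np, rho_app,
                                         medium = medium_conditions(),
                                         length = 1.0) {
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  v <- settling_velocity(d_np, rho_app, medium)
  L <- length * 1e-3
  ifelse(v > 0, L / v / 3600, Inf)
}

#' Peclet number of a particle in a culture well
#'
#' Ratio of sedimentation-driven to diffusion-driven transport over the
#' liquid height \eqn{h}:
#' \deqn{Pe = \frac{V h}{D} = \frac{\pi g (\rho_{app} - \rho_m) D_{NP}^3 h}{6 k_B T}}
#' The viscosity cancels between \eqn{V} and \eqn{D}, so \eqn{Pe} depends
#' only on size, density contrast, temperature and liquid height. A negative
#' value (buoyant particle) is permitted, with a warning.
#'
#' @inheritParams settling_velocity
#' @param well A [well_setup()]; its `liquid_height` sets \eqn{h}.
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(d_np, rho_app, medium = medium_conditions(),
                          well = well_setup()) {
  stopifnot(inherits(well, "well_setup"))
  pe <- settling_velocity(d_np, rho_app, medium) *
    (well$liquid_height * 1e-3) / diffusion_coefficient(d_np, medium)
  if (any(pe < 0)) warning("negative Peclet number: buoyant particle")
  pe
}

#' Classify the dominant transport mode
#'
#' Compares the diffusion and sedimentation transport times over the same
#' reference distance. Transport is called `"diffusion"` when the diffusion
#' time beats the sedimentation time by more than the factor `ratio_band`,
#' `"sedimentation"` in the symmetric case, and `"mixed"` when the two times
#' are within a factor `ratio_band` of each other.
#'
#' @param t_diff Diffusion transport time, hours (vectorized).
#' @param t_sed Sedimentation transport time, hours (`Inf` allowed).
#' @param ratio_band Width of the mixed band (default 1.25): times within
#'   this factor of each other are called mixed.
#' @return Character vector: `"diffusion"`, `"sedimentation"` or `"mixed"`.
#' @export
classify_transport_mode <- function(t_diff, t_sed, ratio_band = 1.25) {
  stopifnot(ratio_band >= 1)
  if (any(t_diff <= 0)) stop("t_diff must be positive", call. = FALSE)
  ifelse(t_diff * ratio_band < t_sed, "diffusion",
         ifelse(t_sed * ratio_band < t_diff, "sedimentation", "mixed"))
}

#' Transport summary for a table of particle batches
#'
#' Computes, for each batch, the diffusion coefficient, settling velocity,
#' times to travel the reference distance by diffusion and by sedimentation,
#' the Peclet number, and the dominant transport mode.
#'
#' @param particles Data frame with columns `label`, `d_h_dls_nm` and either
#'   `rho_app` or `rho_app_gcm3` (apparent density of the complex).
#' @param medium A [medium_conditions()].
#' @param well A [well_setup()].
#' @param ratio_band Mixed-band width passed to [classify_transport_mode()].
#' @return Data frame with one row per batch: `label`, `d_nm`, `rho_app`,
#'   `D_m2s`, `V_ms`, `t_diff_h`, `t_sed_h`, `peclet`, `mode`.
#' @export
transport_summary <- function(particles, medium = medium_conditions(),
                              well = well_setup(), ratio_band = 1.25) {
  stopifnot(is.data.frame(particles))
  d <- particles$d_h_dls_nm
  rho <- if ("rho_app" %in% names(particles)) particles$rho_app
         else particles$rho_app_gcm3
  if (is.null(d) || is.null(rho)) {
    stop("particle table needs `d_h_dls_nm` and an apparent-density column",
         call. = FALSE)
  }
  t_diff <- transport_time_diffusion(d, medium, well$travel_length)
  t_sed <- transport_time_sedimentation(d, rho, medium, well$travel_length)
  data.frame(
    label = particles$label,
    d_nm = d,
    rho_app = rho,
    D_m2s = diffusion_coefficient(d, medium),
    V_ms = settling_velocity(d, rho, medium),
    t_diff_h = t_diff,
    t_sed_h = t_sed,
    peclet = peclet_number(d, rho, medium, well),
    mode = classify_transport_mode(t_diff, t_sed, ratio_band),
    stringsAsFactors = FALSE)
}
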
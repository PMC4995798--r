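# All user-facing interfaces take diameters in nm and densities in g cm^-3,
# matching the units of DLS/CLS instrument reports. Conversion to SI happens
# exactly once, through .nm2m() / .gcm3_to_kgm3() below.

.nm2m <- function(x) x * 1e-9
.m2nm <- function(x) x * 1e9
.gcm3_to_kgm3 <- function(x) x * 1000

#' Disc-centrifuge (CLS) instrument description
#'
#' Holds the fixed experimental constants of a centrifugal liquid sedimentation
#' run: disc radii, rotation speed, gradient viscosity and gradient fluid
#' density. The sedimentation time of a particle of diameter \eqn{D} and
#' density \eqn{\rho} through the gradient is \eqn{t = K / ((\rho - \rho_f) D^2)}
#' with the instrument constant
#' \eqn{K = \ln(R_f/R_0)\, 18\eta / \omega^2} (SI units, kg m\eqn{^{-1}} s).
#'
#' Vendors rarely publish \eqn{R_0}, \eqn{R_f} and the gradient viscosity, so
#' `K` can instead be fixed from a single known (time, diameter, density)
#' triple with [cls_calibrate()].
#'
#' @param r0 Inner (injection) radius, cm.
#' @param rf Detector radius, cm; must exceed `r0`.
#' @param rpm Disc rotation speed, revolutions per minute (default 22000).
#' @param eta_gradient Dynamic viscosity of the density gradient, Pa s.
#' @param rho_f Density of the gradient fluid, g cm^-3 (default 1.064,
#'   nominal 8-24 % sucrose gradient).
#' @param k Instrument constant K in SI units (kg m^-1 s). Supplied directly
#'   by [cls_calibrate()]; otherwise computed from the geometric fields.
#' @return An object of class `cls_instrument`.
#' @seealso [cls_calibrate()], [cls_diameter()], [cls_time()]
#' @export
cls_instrument <- function(r0 = NULL, rf = NULL, rpm = 22000,
                           eta_gradient = NULL, rho_f = 1.064, k = NULL) {
  omega <- rpm * 2 * pi / 60
  if (is.null(k)) {
    if (is.null(r0) || is.null(rf) || is.null(eta_gradient)) {
      stop("either `k` or all of `r0`, `rf`, `eta_gradient` must be supplied",
           call. = FALSE)
    }
    if (!(rf > r0 && r0 > 0)) stop("need rf > r0 > 0", call. = FALSE)
    if (eta_gradient <= 0) stop("eta_gradient must be positive", call. = FALSE)
    k <- log(rf / r0) * 18 * eta_gradient / omega^2
  }
  if (k <= 0) stop("instrument constant K must be positive", call. = FALSE)
  if (rho_f <= 0) stop("rho_f must be positive", call. = FALSE)
  structure(
    list(r0 = r0, rf = rf, rpm = rpm, omega = omega,
         eta_gradient = eta_gradient, rho_f = rho_f, k = k),
    class = "cls_instrument")
}

#' Calibrate the CLS instrument constant from one known measurement
#'
#' Fixes \eqn{K = t (\rho - \rho_f) D^2} from a single sedimentation-time
#' measurement of a particle of known diameter and density (e.g. a certified
#' size standard, or one fully characterized batch).
#'
#' @param t_sed Measured sedimentation time, s.
#' @param d_hs Known hydrodynamic diameter, nm.
#' @param rho_np Known particle density, g cm^-3; must exceed `rho_f`.
#' @inheritParams cls_instrument
#' @return A `cls_instrument` with `k` set.
#' @examples
#' inst <- cls_calibrate(t_sed = 138.0, d_hs = 35.8, rho_np = 4.32)
#' cls_diameter(138.0, 4.32, inst)  # 35.8 by construction
#' @export
cls_calibrate <- function(t_sed, d_hs, rho_np, rpm = 22000, rho_f = 1.064) {
  if (t_sed <= 0) stop("t_sed must be positive", call. = FALSE)
  if (d_hs <= 0) stop("d_hs must be positive", call. = FALSE)
  if (rho_np <= rho_f) {
    stop("calibration particle must be denser than the gradient fluid",
         call. = FALSE)
  }
  k <- t_sed * .gcm3_to_kgm3(rho_np - rho_f) * .nm2m(d_hs)^2
  cls_instrument(rpm = rpm, rho_f = rho_f, k = k)
}

#' @export
print.cls_instrument <- function(x, ...) {
  cat("CLS instrument:", x$rpm, "rpm, gradient density", x$rho_f, "g/cm^3\n")
  cat("  K =", format(x$k, digits = 6), "kg m^-1 s\n")
  invisible(x)
}

#' Hydrodynamic diameter from CLS sedimentation time
#'
#' Inverts the disc-centrifuge sedimentation relation
#' \deqn{D_{hs} = \sqrt{\frac{\ln(R_f/R_0)\, 18\eta}{t\,(\rho_{NP}-\rho_f)\,\omega^2}}
#'             = \sqrt{\frac{K}{t\,(\rho_{NP}-\rho_f)}}}
#' for the diameter, given the sedimentation time and an assumed particle
#' density. Using the bulk material density (19.3 g cm^-3 for gold)
#' underestimates the hydrodynamic diameter of hydrated or protein-coated
#' particles; see [apparent_density()] for the combined DLS+CLS correction.
#'
#' @param t_sed Sedimentation time, s (vectorized).
#' @param rho_np Assumed particle density, g cm^-3.
#' @param inst A [cls_instrument()].
#' @return Diameter in nm.
#' @export
cls_diameter <- function(t_sed, rho_np, inst) {
  stopifnot(inherits(inst, "cls_instrument"))
  if (any(t_sed <= 0)) stop("sedimentation time must be positive", call. = FALSE)
  if (any(rho_np <= inst$rho_f)) {
    stop("particle density must exceed the gradient fluid density ",
         "(non-sedimenting particle)", call. = FALSE)
  }
  .m2nm(sqrt(inst$k / (t_sed * .gcm3_to_kgm3(rho_np - inst$rho_f))))
}

#' CLS sedimentation time for a given diameter and density
#'
#' Exact algebraic inverse of [cls_diameter()]:
#' \eqn{t = K / ((\rho_{NP} - \rho_f) D^2)}.
#'
#' @param d_hs Hydrodynamic diameter, nm (vectorized).
#' @inheritParams cls_diameter
#' @return Time in s.
#' @export
cls_time <- function(d_hs, rho_np, inst) {
  stopifnot(inherits(inst, "cls_instrument"))
  if (any(d_hs <= 0)) stop("diameter must be positive", call. = FALSE)
  if (any(rho_np <= inst$rho_f)) {
    stop("particle density must exceed the gradient fluid density ",
         "(non-sedimenting particle)", call. = FALSE)
  }
  inst$k / (.gcm3_to_kgm3(rho_np - inst$rho_f) * .nm2m(d_hs)^2)
}

#' Apparent density of a particle-shell complex from combined DLS and CLS
#'
#' A CLS run evaluated at the bulk material density yields an (underestimated)
#' diameter \eqn{D_{hs}}; DLS yields the true hydrodynamic diameter
#' \eqn{D_h}. Because both describe the same sedimentation time, the pair
#' fixes the apparent density of the hydrated (or protein-corona) complex:
#' \deqn{\rho_{app} = \rho_f + \left(\frac{D_{hs}}{D_h}\right)^2 (\rho_{bulk} - \rho_f)}
#' The identity \eqn{D_{hs}^2(\rho_{bulk}-\rho_f) = D_h^2(\rho_{app}-\rho_f)}
#' holds exactly by construction.
#'
#' @param d_h_dls Hydrodynamic diameter from DLS (Z-average), nm.
#' @param d_hs_bulk CLS diameter computed at the bulk density, nm; must not
#'   exceed `d_h_dls`.
#' @param rho_bulk Bulk material density, g cm^-3 (gold: 19.3).
#' @param rho_f CLS gradient fluid density, g cm^-3.
#' @return Apparent density in g cm^-3, between `rho_f` and `rho_bulk`.
#' @examples
#' apparent_density(32.9, 17.1)  # ~6.0 g/cm^3
#' @export
apparent_density <- function(d_h_dls, d_hs_bulk, rho_bulk = 19.3,
                             rho_f = 1.064) {
  if (any(d_hs_bulk <= 0) || any(d_h_dls <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  if (any(d_hs_bulk > d_h_dls)) {
    stop("inconsistent measurement: CLS-at-bulk diameter exceeds the DLS ",
         "diameter", call. = FALSE)
  }
  if (any(rho_bulk <= rho_f)) stop("need rho_bulk > rho_f", call. = FALSE)
  rho_f + (d_hs_bulk / d_h_dls)^2 * (rho_bulk - rho_f)
}

#' Apparent density from a DLS diameter and a measured sedimentation time
#'
#' Companion to [apparent_density()] for the case where the CLS run is
#' reported as a raw sedimentation time rather than a bulk-density diameter:
#' \eqn{\rho_{app} = \rho_f + K / (t D_h^2)}.
#'
#' @param d_h_dls DLS hydrodynamic diameter, nm.
#' @param t_sed CLS sedimentation time, s.
#' @param inst A calibrated [cls_instrument()].
#' @return Apparent density in g cm^-3.
#' @export
apparent_density_from_time <- function(d_h_dls, t_sed, inst) {
  stopifnot(inherits(inst, "cls_instrument"))
  if (any(d_h_dls <= 0)) stop("diameter must be positive", call. = FALSE)
  if (any(t_sed <= 0)) stop("sedimentation time must be positive", call. = FALSE)
  inst$rho_f + inst$k / (t_sed * .nm2m(d_h_dls)^2) / 1000
}

#' Calculated core diameter of a core-shell particle
#'
#' From the mass balance
#' \eqn{\rho_{app} V_h = \rho_{core} V_{core} + \rho_{shell} V_{shell}},
#' the diameter of the dense core consistent with the measured hydrodynamic
#' diameter and apparent density is
#' \deqn{D_{core}^{calc} = D_h \left(\frac{\rho_{app} - \rho_{shell}}
#'   {\rho_{core} - \rho_{shell}}\right)^{1/3}.}
#' Comparing this against the TEM core diameter validates the apparent
#' density derived by [apparent_density()].
#'
#' Apparent densities exceeding `rho_core` by at most 0.5 % (measurement
#' noise) are clamped to `rho_core` with a warning; larger excursions, or
#' values below `rho_shell`, raise an error.
#'
#' @param d_h Hydrodynamic diameter, nm.
#' @param rho_app Apparent density of the complex, g cm^-3.
#' @param rho_shell Density of the hydration/corona shell, g cm^-3
#'   (1.064 in water, 1.125 in complete culture medium; see
#'   [default_rho_shell()]).
#' @param rho_core Core material density, g cm^-3 (gold: 19.3).
#' @return Core diameter in nm, between 0 and `d_h`.
#' @examples
#' core_diameter_calc(32.9, 6.0, 1.064)    # ~21.3 nm
#' core_diameter_calc(101.9, 6.21, 1.125)  # ~66.6 nm
#' @export
core_diameter_calc <- function(d_h, rho_app, rho_shell, rho_core = 19.3) {
  if (any(d_h <= 0)) stop("d_h must be positive", call. = FALSE)
  if (any(rho_core <= rho_shell)) stop("need rho_core > rho_shell", call. = FALSE)
  over <- rho_app > rho_core
  if (any(rho_app[over] > rho_core * 1.005)) {
    stop("rho_app exceeds rho_core by more than 0.5% (", max(rho_app),
         " vs ", rho_core, "): inconsistent inputs", call. = FALSE)
  }
  if (any(over)) {
    warning("rho_app marginally above rho_core; clamped to rho_core")
    rho_app <- pmin(rho_app, rho_core)
  }
  if (any(rho_app < rho_shell)) {
    stop("rho_app below rho_shell (", min(rho_app), " < ", rho_shell,
         "): no physical core-shell solution", call. = FALSE)
  }
  d_h * ((rho_app - rho_shell) / (rho_core - rho_shell))^(1 / 3)
}

#' Hydration/corona shell thickness from two diameters
#'
#' The shell (hydration layer plus protein corona, if present) is the
#' difference between the hydrodynamic diameter and the core diameter.
#'
#' @param d_h Hydrodynamic diameter, nm.
#' @param d_core Core diameter (TEM or [core_diameter_calc()]), nm.
#' @param total If `TRUE` return the full diameter increase `d_h - d_core`;
#'   otherwise (default) the per-side shell thickness `(d_h - d_core)/2`.
#' @return Thickness in nm.
#' @export
shell_thickness <- function(d_h, d_core, total = FALSE) {
  if (any(d_h < d_core)) {
    stop("inconsistent measurement: d_h smaller than d_core", call. = FALSE)
  }
  if (total) d_h - d_core else (d_h - d_core) / 2
}

#' Default shell density by dispersion condition
#'
#' The hydration shell is taken at the density of the surrounding fluid:
#' 1.064 g cm^-3 in water (the nominal sucrose-gradient density) and
#' 1.125 g cm^-3 for the protein corona formed in complete culture medium.
#'
#' @param condition `"water"` or `"ccm"` (complete cell culture medium).
#' @return Density in g cm^-3.
#' @export
default_rho_shell <- function(condition = c("water", "ccm")) {
  condition <- match.arg(condition, several.ok = TRUE)
  c(water = 1.064, ccm = 1.125)[condition]
}

#' Characterize a table of particle batches
#'
#' Applies the combined DLS+CLS apparent-density method and the core-shell
#' back-calculation to every row of a particle table (see
#' [read_particle_table()] for the column contract). The apparent density is
#' derived from `(d_h_dls_nm, d_hs_cls_nm)` when the bulk-density CLS
#' diameter is present, otherwise from `(d_h_dls_nm, t_sed_s)` via a
#' calibrated instrument; rows with neither keep the supplied
#' `rho_app_gcm3`.
#'
#' @param particles Data frame with columns `label`, `condition`,
#'   `d_core_tem_nm`, `d_h_dls_nm`, `d_hs_cls_nm`, `t_sed_s`,
#'   `rho_app_gcm3` (missing values `NA`).
#' @param rho_core Core material density, g cm^-3.
#' @param rho_shell Shell density; if `NULL`, chosen per row from
#'   [default_rho_shell()] using the `condition` column.
#' @param instrument Optional calibrated [cls_instrument()] used when a row
#'   carries a sedimentation time but no bulk-density diameter.
#' @return The input with columns `rho_app` (derived apparent density),
#'   `d_core_calc` (nm), and `shell_nm` (diameter increase over the core,
#'   nm, where a TEM core diameter is available).
#' @export
characterize_particles <- function(particles, rho_core = 19.3,
                                   rho_shell = NULL, instrument = NULL) {
  stopifnot(is.data.frame(particles))
  req <- c("label", "condition", "d_h_dls_nm")
  miss <- setdiff(req, names(particles))
  if (length(miss)) {
    stop("particle table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(particles)
  get <- function(col) {
    if (col %in% names(particles)) particles[[col]] else rep(NA_real_, n)
  }
  d_h <- particles$d_h_dls_nm
  d_hs <- get("d_hs_cls_nm")
  t_sed <- get("t_sed_s")
  rho_app_in <- get("rho_app_gcm3")
  d_tem <- get("d_core_tem_nm")

  if (is.null(rho_shell)) {
    rho_shell_row <- unname(default_rho_shell(particles$condition))
  } else {
    rho_shell_row <- rep_len(rho_shell, n)
  }

  rho_app <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(d_hs[i])) {
      rho_app[i] <- apparent_density(d_h[i], d_hs[i], rho_bulk = rho_core)
    } else if (!is.na(t_sed[i]) && !is.null(instrument)) {
      rho_app[i] <- apparent_density_from_time(d_h[i], t_sed[i], instrument)
    } else {
      rho_app[i] <- rho_app_in[i]
    }
  }
  d_core_calc <- rep(NA_real_, n)
  ok <- !is.na(rho_app)
  if (any(ok)) {
    d_core_calc[ok] <- core_diameter_calc(d_h[ok], rho_app[ok],
                                          rho_shell_row[ok], rho_core)
  }
  ddiff <- d_h - d_tem
  shell_nm <- ifelse(!is.na(ddiff) & ddiff >= 0, ddiff, NA_real_)
  out <- particles
  out$rho_shell <- rho_shell_row
  out$rho_app <- rho_app
  out$d_core_calc <- d_core_calc
  out$shell_nm <- shell_nm
  out
}
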
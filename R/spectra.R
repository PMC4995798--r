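#' UV-vis absorbance spectrum
#'
#' A wavelength/absorbance pair with the metadata needed by the dose
#' pipeline: replicate id, exposure timepoint, and experimental condition.
#'
#' @param wavelength Strictly increasing wavelengths, nm.
#' @param absorbance Matched absorbances, AU.
#' @param replicate_id Replicate identifier (text).
#' @param timepoint Exposure time, hours (`NA` for calibration spectra).
#' @param condition One of `"with_cells"`, `"without_cells"`,
#'   `"control_medium"`, `"calibration"`.
#' @param concentration Known concentration (calibration spectra only).
#' @return An object of class `uv_spectrum`.
#' @export
uv_spectrum <- function(wavelength, absorbance, replicate_id = NA_character_,
                        timepoint = NA_real_,
                        condition = c("with_cells", "without_cells",
                                      "control_medium", "calibration"),
                        concentration = NA_real_) {
  condition <- match.arg(condition)
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("wavelength and absorbance must have equal length", call. = FALSE)
  }
  if (length(wavelength) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 replicate_id = as.character(replicate_id),
                 timepoint = timepoint, condition = condition,
                 concentration = concentration),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat("UV-vis spectrum:", length(x$wavelength), "points,",
      min(x$wavelength), "-", max(x$wavelength), "nm\n")
  cat("  condition:", x$condition,
      if (!is.na(x$timepoint)) paste0("  t = ", x$timepoint, " h") else "",
      if (!is.na(x$replicate_id)) paste0("  replicate ", x$replicate_id) else "",
      "\n")
  invisible(x)
}

#' Subtract a control (baseline) spectrum
#'
#' Subtracts the medium baseline (spectrum of culture medium from unexposed
#' wells) from a sample spectrum, pointwise. When the wavelength grids
#' differ, the control is interpolated linearly onto the sample grid;
#' extrapolation outside the control's measured range is refused. Negative
#' differences are retained.
#'
#' @param sample,control `uv_spectrum` objects.
#' @return A `uv_spectrum` on the sample grid with metadata of `sample`.
#' @export
subtract_baseline <- function(sample, control) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(control, "uv_spectrum"))
  if (min(sample$wavelength) < min(control$wavelength) ||
      max(sample$wavelength) > max(control$wavelength)) {
    stop("control spectrum does not cover the sample wavelength range; ",
         "extrapolation is not allowed", call. = FALSE)
  }
  base <- stats::approx(control$wavelength, control$absorbance,
                        xout = sample$wavelength)$y
  out <- sample
  out$absorbance <- sample$absorbance - base
  out
}

#' Pointwise average of replicate spectra
#'
#' @param spectra List of `uv_spectrum` objects on identical wavelength
#'   grids.
#' @return A `uv_spectrum` with the metadata of the first replicate and
#'   `replicate_id = "mean"`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "uv_spectrum")))
  wl <- spectra[[1]]$wavelength
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$wavelength, wl))) {
      stop("replicate spectra must share the same wavelength grid",
           call. = FALSE)
    }
  }
  ab <- rowMeans(vapply(spectra, function(s) s$absorbance,
                        numeric(length(wl))))
  out <- spectra[[1]]
  out$absorbance <- ab
  out$replicate_id <- "mean"
  out
}

#' Area under an absorbance spectrum within a wavelength window
#'
#' Trapezoidal integral of the absorbance over `window`, the analysis range
#' chosen to avoid serum-protein absorption (default 450-650 nm). Points at
#' the window edges are obtained by linear interpolation when the grid does
#' not fall exactly on the bounds.
#'
#' @param s A `uv_spectrum`.
#' @param window Length-2 numeric, nm.
#' @return Area in AU nm.
#' @export
spectral_area <- function(s, window = c(450, 650)) {
  stopifnot(inherits(s, "uv_spectrum"), length(window) == 2,
            window[2] > window[1])
  wl <- s$wavelength
  ab <- s$absorbance
  if (window[1] < min(wl) || window[2] > max(wl)) {
    stop("integration window [", window[1], ", ", window[2],
         "] nm extends beyond the measured range [", min(wl), ", ", max(wl),
         "] nm", call. = FALSE)
  }
  inside <- wl > window[1] & wl < window[2]
  if (sum(wl >= window[1] & wl <= window[2]) < 2) {
    stop("fewer than 2 points inside the integration window", call. = FALSE)
  }
  edge <- stats::approx(wl, ab, xout = window)$y
  x <- c(window[1], wl[inside], window[2])
  y <- c(edge[1], ab[inside], edge[2])
  pracma::trapz(x, y)
}

#' SPR peak position of a spectrum
#'
#' Wavelength of maximum absorbance inside the analysis window; reported as
#' a quality-control quantity (a red shift indicates corona formation or
#' agglomeration).
#'
#' @inheritParams spectral_area
#' @return Wavelength in nm.
#' @export
peak_position <- function(s, window = c(450, 650)) {
  stopifnot(inherits(s, "uv_spectrum"))
  inside <- s$wavelength >= window[1] & s$wavelength <= window[2]
  if (!any(inside)) stop("no points inside window", call. = FALSE)
  s$wavelength[inside][which.max(s$absorbance[inside])]
}

#' Fit an area-vs-concentration calibration curve
#'
#' Ordinary least squares fit of spectral area against known concentration.
#' The spectral area of plasmonic nanoparticle suspensions is linear in
#' concentration, so the fitted line maps areas of unknown supernatants to
#' concentrations via [concentration_from_area()].
#'
#' @param areas Spectral areas, AU nm.
#' @param concentrations Matching known concentrations (>= 3 distinct
#'   values required).
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @param concentration_unit Unit label carried into reports.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `concentration_unit`, `n`.
#' @export
fit_calibration <- function(areas, concentrations, through_origin = FALSE,
                            concentration_unit = "uM") {
  if (length(areas) != length(concentrations)) {
    stop("areas and concentrations must match", call. = FALSE)
  }
  if (length(areas) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (any(concentrations < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  if (length(unique(concentrations)) < 2) {
    stop("degenerate calibration design: all concentrations equal",
         call. = FALSE)
  }
  fit <- if (through_origin) {
    stats::lm(areas ~ concentrations + 0)
  } else {
    stats::lm(areas ~ concentrations)
  }
  co <- stats::coef(fit)
  slope <- unname(co[["concentrations"]])
  intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
  if (slope <= 0) {
    stop("calibration slope is not positive; check the input pairing",
         call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((areas - mean(areas))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)),
                 concentration_unit = concentration_unit,
                 n = length(areas)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: area = %.4g * conc + %.4g  (R^2 = %.4f, n = %d, unit %s)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$concentration_unit))
  invisible(x)
}

#' Concentration from a spectral area via a calibration curve
#'
#' Inverts the linear calibration: `(area - intercept) / slope`. Slightly
#' negative results (noise around the blank) are clamped to zero and
#' flagged through the `"clamped"` attribute.
#'
#' @param area Spectral area, AU nm (vectorized).
#' @param cal A [fit_calibration()] result.
#' @return Concentration in the calibration's unit.
#' @export
concentration_from_area <- function(area, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  conc <- (area - cal$intercept) / cal$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  attr(conc, "clamped") <- clamped
  conc
}

#' Deposition kinetics from a time series of supernatant spectra
#'
#' Implements the supernatant-depletion dose method: at each timepoint the
#' replicate spectra are averaged, the medium baseline subtracted, and the
#' spectral area computed; areas are normalized by the area at t = 0 and the
#' deposited (or cell-associated) fraction is `1 - normalized area`.
#' Replicate scatter is propagated as the standard deviation of the
#' per-replicate normalized areas and flagged when it exceeds
#' `sd_warn_frac` of the mean. Fractions are not forced monotone; small
#' negatives from noise are retained but flagged below -0.05.
#'
#' @param spectra List of `uv_spectrum` objects with `timepoint` and
#'   `condition` set (`with_cells` and/or `without_cells`); every timepoint
#'   needs at least one replicate and t = 0 must be present per condition.
#' @param control A `control_medium` `uv_spectrum` used as baseline.
#' @param window Integration window, nm.
#' @param sd_warn_frac Replicate-SD flag threshold as a fraction of the mean
#'   area (default 0.05).
#' @return An object of classes `deposition_kinetics`/`data.frame` with
#'   columns `timepoint_h`, `condition`, `area`, `norm_area`, `sd_norm_area`,
#'   `fraction_deposited`, `sd_flag`, `negative_flag`.
#' @export
deposition_kinetics <- function(spectra, control, window = c(450, 650),
                                sd_warn_frac = 0.05) {
  stopifnot(is.list(spectra), inherits(control, "uv_spectrum"))
  conds <- vapply(spectra, function(s) s$condition, character(1))
  tps <- vapply(spectra, function(s) s$timepoint, numeric(1))
  keep <- conds %in% c("with_cells", "without_cells")
  if (!any(keep)) stop("no exposure spectra supplied", call. = FALSE)
  if (any(is.na(tps[keep]))) {
    stop("every exposure spectrum needs a timepoint", call. = FALSE)
  }
  rows <- list()
  for (cond in unique(conds[keep])) {
    sel <- which(conds == cond)
    tt <- sort(unique(tps[sel]))
    if (!any(tt == 0)) {
      stop("condition ", cond, " lacks a t = 0 measurement", call. = FALSE)
    }
    area_mean <- numeric(length(tt))
    area_sd <- numeric(length(tt))
    for (j in seq_along(tt)) {
      reps <- spectra[sel[tps[sel] == tt[j]]]
      avg <- subtract_baseline(average_spectra(reps), control)
      area_mean[j] <- spectral_area(avg, window)
      rep_areas <- vapply(reps, function(s) {
        spectral_area(subtract_baseline(s, control), window)
      }, numeric(1))
      area_sd[j] <- if (length(rep_areas) > 1) stats::sd(rep_areas) else NA_real_
    }
    a0 <- area_mean[tt == 0]
    if (a0 <= 0) {
      stop("nonpositive spectral area at t = 0 for condition ", cond,
           call. = FALSE)
    }
    norm <- area_mean / a0
    sd_norm <- area_sd / a0
    frac <- 1 - norm
    rows[[cond]] <- data.frame(
      timepoint_h = tt, condition = cond, area = area_mean,
      norm_area = norm, sd_norm_area = sd_norm,
      fraction_deposited = frac,
      sd_flag = !is.na(area_sd) & area_sd > sd_warn_frac * abs(area_mean),
      negative_flag = frac < -0.05,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deposition_kinetics", "data.frame")
  out
}

#' Number of particles deposited per cell
#'
#' Scales the administered particle load by the deposited fraction and
#' divides by the number of cells in the monolayer.
#'
#' @param nps_per_well Particles administered to the well.
#' @param fraction Deposited/cell-associated fraction, in `[0, 1]`.
#' @param cells_per_well Cells in the monolayer (default 70,000).
#' @return Particles per cell.
#' @examples
#' nps_per_cell(6.24e8, 0.75)  # ~6.7e3
#' @export
nps_per_cell <- function(nps_per_well, fraction, cells_per_well = 70000) {
  if (any(nps_per_well < 0) || any(fraction < 0)) {
    stop("inputs must be nonnegative", call. = FALSE)
  }
  if (any(cells_per_well <= 0)) {
    stop("cells_per_well must be positive", call. = FALSE)
  }
  nps_per_well * fraction / cells_per_well
}
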
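#' Parametric model of a plasmonic absorbance spectrum
#'
#' Generative stand-in for measured gold-nanoparticle UV-vis spectra: a
#' Lorentzian surface-plasmon-resonance peak whose height is linear in
#' concentration, on top of a medium baseline (a Rayleigh-like
#' \eqn{\lambda^{-4}} scattering term plus a constant) with additive
#' Gaussian noise.
#'
#' @param peak_center SPR peak position, nm (e.g. 524 for 20 nm gold
#'   particles in culture medium; see [reference_spr_peaks()]).
#' @param peak_width Full width at half maximum of the Lorentzian, nm.
#' @param peak_height_per_conc Peak absorbance per concentration unit,
#'   AU per unit.
#' @param baseline_amplitude Amplitude of the medium baseline, AU.
#' @param baseline_const Constant offset of the baseline, AU.
#' @param noise_sd Standard deviation of the additive noise, AU.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(peak_center = 524, peak_width = 50,
                           peak_height_per_conc = 0.015,
                           baseline_amplitude = 0.08,
                           baseline_const = 0.02, noise_sd = 0.003) {
  stopifnot(peak_center > 0, peak_width > 0, peak_height_per_conc >= 0,
            baseline_amplitude >= 0, baseline_const >= 0, noise_sd >= 0)
  structure(list(peak_center = peak_center, peak_width = peak_width,
                 peak_height_per_conc = peak_height_per_conc,
                 baseline_amplitude = baseline_amplitude,
                 baseline_const = baseline_const, noise_sd = noise_sd),
            class = "spectrum_model")
}

#' Baseline of the spectrum model (no particles)
#'
#' @param model A [spectrum_model()].
#' @param wavelength Wavelengths, nm.
#' @return Absorbance, AU.
#' @export
model_baseline <- function(model, wavelength) {
  stopifnot(inherits(model, "spectrum_model"))
  model$baseline_amplitude * (450 / wavelength)^4 + model$baseline_const
}

#' Analytic spectral area of the model peak per concentration unit
#'
#' Exact integral of the Lorentzian peak over `window` for one
#' concentration unit; the noiseless area of a synthetic spectrum is
#' `conc * model_peak_area(...) + baseline area`, exactly linear in
#' concentration.
#'
#' @param model A [spectrum_model()].
#' @param window Integration window, nm.
#' @return Area in AU nm per concentration unit.
#' @export
model_peak_area <- function(model, window = c(450, 650)) {
  stopifnot(inherits(model, "spectrum_model"))
  hw <- model$peak_width / 2
  model$peak_height_per_conc * hw *
    (atan((window[2] - model$peak_center) / hw) -
     atan((window[1] - model$peak_center) / hw))
}

#' Synthesize a UV-vis spectrum at a known concentration
#'
#' \eqn{A(\lambda) = c\,H\,\frac{(w/2)^2}{(\lambda - \lambda_0)^2 + (w/2)^2}
#'   + \mathrm{baseline}(\lambda) + \varepsilon}, with
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. Deterministic under a fixed seed;
#' the global RNG state is left untouched.
#'
#' @param conc Concentration (>= 0), in the model's concentration unit.
#' @param model A [spectrum_model()].
#' @param seed Integer seed for the noise (`NULL` = noiseless).
#' @param wavelength Wavelength grid, nm.
#' @param ... Metadata passed to [uv_spectrum()] (`timepoint`, `condition`,
#'   `replicate_id`, `concentration`).
#' @return A `uv_spectrum`.
#' @export
synth_spectrum <- function(conc, model = spectrum_model(), seed = NULL,
                           wavelength = seq(400, 800, by = 2), ...) {
  stopifnot(inherits(model, "spectrum_model"), conc >= 0)
  hw <- model$peak_width / 2
  peak <- hw^2 / ((wavelength - model$peak_center)^2 + hw^2)
  ab <- conc * model$peak_height_per_conc * peak +
    model_baseline(model, wavelength)
  if (!is.null(seed) && model$noise_sd > 0) {
    ab <- ab + withr::with_seed(seed, stats::rnorm(length(wavelength),
                                                   sd = model$noise_sd))
  }
  uv_spectrum(wavelength, ab, ...)
}

#' Synthesize a disc-centrifuge detector trace
#'
#' Gaussian detector peak centered at the sedimentation time
#' [cls_time()]`(d_hs, rho_np)` of the particle, with a relative width set
#' by the polydispersity of the batch, plus additive noise. Peak-picking on
#' the trace followed by [cls_diameter()] recovers the diameter.
#'
#' @param d_hs Hydrodynamic diameter of the batch, nm.
#' @param rho_np Density used for the sedimentation relation, g cm^-3.
#' @param inst A calibrated [cls_instrument()].
#' @param pdi_width Relative width of the time peak (sd/t_peak, default
#'   0.05; 0 gives a numerically sharp peak).
#' @param noise_sd Detector noise standard deviation (signal units).
#' @param n_points Number of samples in the trace.
#' @param seed Integer seed for the noise (`NULL` = noiseless).
#' @return A data frame with columns `time_s` and `signal`, with the true
#'   peak time in attribute `"t_peak"`.
#' @export
synth_cls_trace <- function(d_hs, rho_np, inst, pdi_width = 0.05,
                            noise_sd = 0.01, n_points = 600, seed = NULL) {
  t_peak <- cls_time(d_hs, rho_np, inst)
  sdt <- max(pdi_width, 1e-4) * t_peak
  time_s <- seq(max(t_peak - 6 * sdt, t_peak * 0.2), t_peak + 6 * sdt,
                length.out = n_points)
  signal <- exp(-(time_s - t_peak)^2 / (2 * sdt^2))
  if (!is.null(seed) && noise_sd > 0) {
    signal <- signal + withr::with_seed(seed, stats::rnorm(n_points,
                                                           sd = noise_sd))
  }
  out <- data.frame(time_s = time_s, signal = signal)
  attr(out, "t_peak") <- t_peak
  out
}

#' Peak sedimentation time of a detector trace
#'
#' Argmax of the signal refined by a three-point quadratic (parabolic)
#' interpolation, which suppresses grid quantization.
#'
#' @param trace Data frame with `time_s` and `signal` columns.
#' @return Time in s.
#' @export
trace_peak_time <- function(trace) {
  stopifnot(all(c("time_s", "signal") %in% names(trace)))
  i <- which.max(trace$signal)
  if (i == 1 || i == nrow(trace)) return(trace$time_s[i])
  y <- trace$signal[(i - 1):(i + 1)]
  x <- trace$time_s[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom == 0) return(x[2])
  x[2] + 0.5 * (x[1] - x[3]) * (y[1] - y[3]) / (2 * denom) * -1
}

#' Generate a complete synthetic exposure study
#'
#' Builds, for each particle batch of [reference_particles()]`("ccm")`, a
#' with-cells and a without-cells depletion experiment: the supernatant
#' concentration trace comes from [simulate_well()] (quasi-sink saturable
#' binding for the cell monolayer, weak nonspecific binding for bare
#' plastic), and triplicate UV-vis spectra are synthesized at each sampling
#' time, together with medium-control and calibration spectra. Running the
#' dose pipeline on the result recovers the simulator's ground-truth
#' deposited fractions, so the full spectral chain is testable end to end.
#'
#' @param seed Integer seed; all noise derives from it deterministically.
#' @param dir Optional directory; when given, spectra are written as
#'   two-column CSV files plus a `manifest.csv` and a `particles.csv`
#'   (see [read_spectra_manifest()]), and the paths are returned.
#' @param batches Particle table (defaults to the packaged
#'   culture-medium characterization table). Needs columns `label`,
#'   `d_h_dls_nm`, `rho_app_gcm3`, and is matched by label against
#'   [reference_spr_peaks()] and [reference_stock()].
#' @param medium,well Transport conditions.
#' @param k_cells,k_cells_ns Specific and nonspecific binding coefficients
#'   of the cell monolayer, m s^-1.
#' @param k_plastic Binding coefficient of the bare well bottom, m s^-1.
#' @param capacity_frac Uptake capacity as a fraction of the administered
#'   particle load (phase-1 saturation level).
#' @param noise_sd Spectral noise, AU.
#' @param n_replicates Replicates per (condition, timepoint).
#' @param timepoints Sampling times, hours.
#' @return A list with `spectra` (named by batch label: list of
#'   `uv_spectrum`), `control` (per batch), `calibration` (per batch:
#'   concentrations, spectra), `truth` (data frame of simulator deposited
#'   fractions), `particles`, and `dir`/`manifest` when files were written.
#' @export
make_study_fixture <- function(seed = 1, dir = NULL,
                               batches = reference_particles("ccm"),
                               medium = medium_conditions(),
                               well = well_setup(),
                               k_cells = 1e-6, k_cells_ns = 1e-7,
                               k_plastic = 5e-11, capacity_frac = 0.15,
                               noise_sd = 0.003, n_replicates = 3,
                               timepoints = default_timepoints()) {
  stopifnot(is.data.frame(batches), nrow(batches) >= 1)
  spr <- reference_spr_peaks()
  stock <- reference_stock()
  spectra <- list()
  control <- list()
  calibration <- list()
  truth_rows <- list()

  for (i in seq_len(nrow(batches))) {
    lab <- batches$label[i]
    d <- batches$d_h_dls_nm[i]
    rho <- batches$rho_app_gcm3[i]
    conc_um <- stock$conc_um[match(lab, stock$label)]
    conc0_ml <- stock$nps_per_well[match(lab, stock$label)] /
      (well$volume * 1e-3)                      # particles per mL
    peak <- spr$ccm_nm[match(lab, spr$label)]
    if (is.na(peak)) peak <- 530
    if (is.na(conc_um)) conc_um <- 50
    model <- spectrum_model(peak_center = peak, noise_sd = noise_sd)

    h_m <- well$liquid_height * 1e-3
    n0 <- conc0_ml * 1e6
    cap <- if (is.na(conc0_ml)) Inf else capacity_frac * n0 * h_m

    runs <- list(
      with_cells = sim_config(d, rho, medium, well, k_bind = k_cells,
                              k_ns = k_cells_ns, uptake_capacity = cap,
                              conc0_per_ml = conc0_ml,
                              duration = max(timepoints)),
      without_cells = sim_config(d, rho, medium, well, k_bind = k_plastic,
                                 k_ns = 0, duration = max(timepoints)))
    batch_spectra <- list()
    for (cond in names(runs)) {
      sim <- simulate_well(runs[[cond]], output_times = timepoints)
      truth_rows[[paste(lab, cond)]] <- data.frame(
        label = lab, condition = cond, timepoint_h = sim$times_h,
        fraction_deposited = sim$deposited,
        fraction_suspended = sim$suspended, stringsAsFactors = FALSE)
      for (j in seq_along(sim$times_h)) {
        for (r in seq_len(n_replicates)) {
          sub_seed <- (seed * 97 + i * 1013 + j * 131 +
                         r * 7 + match(cond, names(runs)) * 29) %% 2147483647
          batch_spectra[[length(batch_spectra) + 1]] <-
            synth_spectrum(conc_um * sim$suspended[j], model,
                           seed = sub_seed,
                           timepoint = sim$times_h[j], condition = cond,
                           replicate_id = as.character(r))
        }
      }
    }
    spectra[[lab]] <- batch_spectra
    # medium control: triplicate baseline-only spectra, averaged
    ctrl_reps <- lapply(seq_len(n_replicates), function(r) {
      synth_spectrum(0, model, seed = (seed * 97 + i * 1013 + 5000 + r) %%
                       2147483647, condition = "control_medium",
                     replicate_id = as.character(r))
    })
    control[[lab]] <- average_spectra(ctrl_reps)
    # calibration series at known concentrations
    cal_conc <- seq(0, conc_um, length.out = 6)
    cal_spectra <- lapply(seq_along(cal_conc), function(j) {
      synth_spectrum(cal_conc[j], model, seed = (seed * 97 + i * 1013 +
                       7000 + j) %% 2147483647, condition = "calibration",
                     concentration = cal_conc[j], replicate_id = "1")
    })
    calibration[[lab]] <- list(concentrations = cal_conc,
                               spectra = cal_spectra)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  out <- list(spectra = spectra, control = control,
              calibration = calibration, truth = truth,
              particles = batches, seed = seed)
  if (!is.null(dir)) {
    out$dir <- dir
    out$manifest <- write_study_fixture(out, dir)
  }
  out
}
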
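# Packaged reference tables: the printed characterization of the six gold
# batches (two stabilizer chemistries, core sizes ~10-80 nm) in water and in
# complete culture medium, their SPR peak positions, and the administered
# particle numbers. These are measurement inputs, not derived quantities.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "nanodose")
  if (path == "") stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Packaged particle characterization tables
#'
#' Measured TEM/DLS/CLS characterization of the gold nanoparticle batches
#' (citrate-stabilized HM series and surfactant-stabilized CO series) in
#' water or in complete cell culture medium (`"ccm"`). Columns follow the
#' particle-table contract of [read_particle_table()].
#'
#' @param condition `"water"` or `"ccm"`.
#' @return Data frame, one row per batch.
#' @export
reference_particles <- function(condition = c("water", "ccm")) {
  condition <- match.arg(condition)
  read_particle_table(.extdata(paste0("particles_", condition, ".csv")))
}

#' Packaged SPR peak positions
#'
#' Measured surface-plasmon-resonance peak wavelengths of each batch in
#' water and in complete culture medium.
#'
#' @return Data frame with columns `label`, `water_nm`, `ccm_nm`.
#' @export
reference_spr_peaks <- function() {
  utils::read.csv(.extdata("spr_peaks.csv"), stringsAsFactors = FALSE)
}

#' Packaged administered particle numbers
#'
#' Stock number concentrations, particles administered per well, and molar
#' gold concentration of the dosing suspensions.
#'
#' @return Data frame with columns `label`, `nps_per_ml`, `nps_per_well`,
#'   `conc_um`.
#' @export
reference_stock <- function() {
  utils::read.csv(.extdata("stock_concentrations.csv"),
                  stringsAsFactors = FALSE)
}

#' Read or write a particle characterization table
#'
#' Delimited text, one row per (batch, condition), columns: `label`,
#' `condition`, `d_core_tem_nm`, `d_h_dls_nm`, `pdi`, `zeta_mV`,
#' `d_hs_cls_nm`, `t_sed_s`, `rho_app_gcm3`; missing values empty.
#'
#' @param path CSV file path.
#' @return `read_particle_table`: a data frame.
#' @export
read_particle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "condition", "d_h_dls_nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("particle table ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(names(df), c("label", "condition"))
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @param particles Data frame to write.
#' @rdname read_particle_table
#' @export
write_particle_table <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a two-column spectrum file
#'
#' Delimited text with columns `wavelength_nm`, `absorbance`; metadata
#' (condition, timepoint, replicate) lives in the manifest, not the file.
#'
#' @param path CSV file path.
#' @param ... Metadata passed to [uv_spectrum()].
#' @return `read_spectrum_file`: a `uv_spectrum`.
#' @export
read_spectrum_file <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df))) {
    stop("spectrum file ", path,
         " must have columns wavelength_nm, absorbance", call. = FALSE)
  }
  uv_spectrum(df$wavelength_nm, df$absorbance, ...)
}

#' @param s A `uv_spectrum` to write.
#' @rdname read_spectrum_file
#' @export
write_spectrum_file <- function(s, path) {
  stopifnot(inherits(s, "uv_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = s$wavelength,
                              absorbance = s$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Writes every spectrum of a [make_study_fixture()] result as a two-column
#' CSV, plus `manifest.csv` (columns `file`, `label`, `condition`,
#' `timepoint_h`, `replicate`, `concentration`) and `particles.csv`.
#'
#' @param fixture A [make_study_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_study_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(s, label, tag) {
    fname <- paste0("spec_", label, "_", tag, ".csv")
    write_spectrum_file(s, file.path(dir, fname))
    rows[[length(rows) + 1]] <<- data.frame(
      file = fname, label = label, condition = s$condition,
      timepoint_h = s$timepoint, replicate = s$replicate_id,
      concentration = s$concentration, stringsAsFactors = FALSE)
  }
  for (lab in names(fixture$spectra)) {
    for (s in fixture$spectra[[lab]]) {
      emit(s, lab, sprintf("%s_t%05.1f_r%s", s$condition, s$timepoint,
                           s$replicate_id))
    }
    emit(fixture$control[[lab]], lab, "control")
    cal <- fixture$calibration[[lab]]
    for (j in seq_along(cal$spectra)) {
      emit(cal$spectra[[j]], lab, sprintf("cal%02d", j))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  write_particle_table(fixture$particles, file.path(dir, "particles.csv"))
  utils::write.csv(fixture$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a spectrum manifest back into memory
#'
#' Inverse of [write_study_fixture()]: reads `manifest.csv` in `dir` and
#' loads every referenced spectrum with its metadata.
#'
#' @param dir Directory containing `manifest.csv` and the spectrum files.
#' @return A list with `spectra`, `control` and `calibration`, each named
#'   by batch label (same shapes as in [make_study_fixture()]), and the
#'   `manifest` data frame.
#' @export
read_spectra_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  spectra <- list()
  control <- list()
  calibration <- list()
  for (lab in unique(manifest$label)) {
    rows <- manifest[manifest$label == lab, ]
    sp <- list()
    cal_spec <- list()
    cal_conc <- numeric(0)
    for (i in seq_len(nrow(rows))) {
      s <- read_spectrum_file(
        file.path(dir, rows$file[i]),
        condition = rows$condition[i],
        timepoint = rows$timepoint_h[i],
        replicate_id = as.character(rows$replicate[i]),
        concentration = rows$concentration[i])
      if (s$condition == "control_medium") {
        control[[lab]] <- s
      } else if (s$condition == "calibration") {
        cal_spec[[length(cal_spec) + 1]] <- s
        cal_conc <- c(cal_conc, s$concentration)
      } else {
        sp[[length(sp) + 1]] <- s
      }
    }
    spectra[[lab]] <- sp
    if (length(cal_spec)) {
      calibration[[lab]] <- list(concentrations = cal_conc,
                                 spectra = cal_spec)
    }
  }
  list(spectra = spectra, control = control, calibration = calibration,
       manifest = manifest)
}

# ---- study configuration ---------------------------------------------------

.default_config <- function() {
  list(
    medium = list(temperature = 310.15, viscosity = 8.12e-4,
                  rho_medium = 1.00, g = 9.81),
    well = list(liquid_height = 5.5, volume = 200, cells_per_well = 70000,
                travel_length = 1.0),
    window = c(450, 650),
    rho_shell = list(water = 1.064, ccm = 1.125),
    rho_core = 19.3,
    ratio_band = 1.25
  )
}

#' Read and validate a study configuration file
#'
#' YAML file with the sections of the default configuration (`medium`,
#' `well`, `window`, `rho_shell`, `rho_core`, `ratio_band`); any subset may
#' be given and is merged over the defaults. Unknown keys are rejected with
#' a clear message rather than silently ignored.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A validated configuration list.
#' @export
read_study_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(names(cfg), collapse = ", "),
         call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
      if (length(bad)) {
        stop("unknown config key(s) in `", key, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  stopifnot(length(cfg$window) == 2, cfg$window[2] > cfg$window[1],
            cfg$ratio_band >= 1, cfg$rho_core > 0)
  cfg
}

.config_medium <- function(cfg) {
  do.call(medium_conditions, cfg$medium)
}
.config_well <- function(cfg) {
  do.call(well_setup, cfg$well)
}

# ---- pipeline runners (the CLI surface) ------------------------------------

#' Run the characterization pipeline on a particle table
#'
#' Reads a particle table, derives apparent densities and calculated core
#' diameters ([characterize_particles()]), and optionally writes the result.
#'
#' @param particles Path to a particle-table CSV, or a data frame.
#' @param out Optional output CSV path.
#' @param config Configuration list from [read_study_config()].
#' @param instrument Optional calibrated [cls_instrument()].
#' @return The characterized data frame, invisibly when `out` is given.
#' @export
run_characterize <- function(particles, out = NULL,
                             config = read_study_config(),
                             instrument = NULL) {
  if (is.character(particles)) particles <- read_particle_table(particles)
  res <- characterize_particles(particles, rho_core = config$rho_core,
                                instrument = instrument)
  if (!is.null(out)) {
    write_particle_table(res, out)
    return(invisible(res))
  }
  res
}

#' Run the transport pipeline on a particle table
#'
#' Computes diffusion/sedimentation descriptors, Peclet numbers and the
#' dominant transport mode for each batch ([transport_summary()]).
#'
#' @inheritParams run_characterize
#' @return The transport summary data frame, invisibly when `out` is given.
#' @export
run_transport <- function(particles, out = NULL,
                          config = read_study_config()) {
  if (is.character(particles)) particles <- read_particle_table(particles)
  res <- transport_summary(particles, medium = .config_medium(config),
                           well = .config_well(config),
                           ratio_band = config$ratio_band)
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Run the dose pipeline on a spectrum manifest
#'
#' For every batch in the manifest: averages replicates, subtracts the
#' medium control, integrates the spectral area, normalizes by t = 0 and
#' reports the deposited fraction over time ([deposition_kinetics()]).
#' When the administered particle number is known (packaged
#' [reference_stock()] or the `nps_per_well` argument), per-cell particle
#' numbers are appended.
#'
#' @param dir Directory holding `manifest.csv` and spectrum files.
#' @param out Optional output CSV path.
#' @param config Configuration list from [read_study_config()].
#' @param nps_per_well Named vector of administered particles per well by
#'   batch label; defaults to the packaged reference values where labels
#'   match.
#' @return Data frame of kinetics (one row per batch, condition,
#'   timepoint), invisibly when `out` is given.
#' @export
run_dose <- function(dir, out = NULL, config = read_study_config(),
                     nps_per_well = NULL) {
  study <- read_spectra_manifest(dir)
  if (is.null(nps_per_well)) {
    stock <- reference_stock()
    nps_per_well <- stats::setNames(stock$nps_per_well, stock$label)
  }
  cells <- .config_well(config)$cells_per_well
  rows <- list()
  for (lab in names(study$spectra)) {
    if (is.null(study$control[[lab]])) {
      stop("batch ", lab, " has no control_medium spectrum", call. = FALSE)
    }
    kin <- deposition_kinetics(study$spectra[[lab]], study$control[[lab]],
                               window = config$window)
    kin <- cbind(label = lab, kin)
    npw <- nps_per_well[lab]
    kin$nps_per_cell <- if (!is.na(npw)) {
      nps_per_cell(npw, pmax(kin$fraction_deposited, 0), cells)
    } else NA_real_
    rows[[lab]] <- kin
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Generate and write a synthetic study
#'
#' Thin wrapper over [make_study_fixture()] that always writes the study to
#' disk; identical seeds produce identical output trees.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param config Configuration list from [read_study_config()].
#' @param ... Passed to [make_study_fixture()].
#' @return The fixture list, invisibly.
#' @export
run_simulate <- function(dir, seed = 1, config = read_study_config(), ...) {
  fx <- make_study_fixture(seed = seed, dir = dir,
                           medium = .config_medium(config),
                           well = .config_well(config), ...)
  invisible(fx)
}
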
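# Shared oracles and frozen reference values for the test suite.

# Analytic suspended fraction for pure diffusion in a column of height h
# with an absorbing bottom and reflecting top, from a uniform initial
# condition: eigenfunction expansion with lambda_k = (2k-1) pi / (2h).
diffusion_remaining_series <- function(D, h, t, nterms = 200) {
  k <- seq_len(nterms)
  lam <- (2 * k - 1) * pi / (2 * h)
  vapply(t, function(tt) sum(8 / ((2 * k - 1)^2 * pi^2) *
                               exp(-D * lam^2 * tt)), numeric(1))
}

# Printed characterization values (measured inputs and derived columns) of
# the six gold batches in water. rho_app and d_core_calc are the printed
# derived columns the pipeline should reproduce where the printed inputs
# are arithmetically self-consistent.
published_water <- function() {
  data.frame(
    label = c("HM15", "HM35", "HM75", "CO20", "CO40", "CO80"),
    d_tem = c(11.3, 29.6, 68.9, 15.7, 35.5, 72.8),
    d_h = c(20.3, 34.6, 71.8, 32.9, 54.4, 95.4),
    d_hs = c(7.8, 29.7, 62.5, 17.1, 38.3, 75.1),
    rho_app = c(3.8, 13.6, 14.8, 6.0, 8.2, 12.4),
    d_core_calc = c(8.69, 31.9, 65.4, 21.3, 39.8, 81.3),
    stringsAsFactors = FALSE)
}

# Printed culture-medium characterization (five stable batches).
published_ccm <- function() {
  data.frame(
    label = c("HM35", "HM75", "CO20", "CO40", "CO80"),
    d_h = c(69.7, 101.9, 35.8, 66.5, 116.7),
    t_sed_water = c(28.9, 7.7, 97.5, 25.0, 5.3),
    t_sed_ccm = c(42.1, 10.3, 138.0, 31.5, 7.1),
    rho_app = c(3.30, 6.21, 4.32, 5.00, 6.72),
    d_core_calc = c(34.5, 66.6, 19.8, 39.8, 78.9),
    stringsAsFactors = FALSE)
}

# Printed 1-mm transport times (hours) and Peclet numbers in culture medium.
published_transport <- function() {
  data.frame(
    label = c("HM35", "HM75", "CO20", "CO40", "CO80"),
    d_h = c(69.7, 101.9, 35.8, 66.5, 116.7),
    rho_app = c(3.30, 6.21, 4.32, 5.00, 6.72),
    t_diff_h = c(17.3, 25.3, 8.9, 16.5, 28.9),
    t_sed_h = c(37.0, 7.6, 97.2, 23.3, 5.3),
    peclet = c(5.14, 36.40, 1.00, 7.77, 60.03),
    stringsAsFactors = FALSE)
}

# An instrument calibrated on the 20-nm commercial batch measured in
# culture medium (t = 138.0 s at apparent density 4.32 g/cm^3, 35.8 nm).
calibrated_instrument <- function() {
  cls_calibrate(t_sed = 138.0, d_hs = 35.8, rho_np = 4.32)
}

# Relative tolerance for comparing a computed value against a value printed
# with finite precision: 1%, widened to half a printed ULP where the print
# precision itself is coarser than 1%.
printed_tol <- function(printed, ulp) {
  pmax(0.01, 0.5 * ulp / abs(printed))
}
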
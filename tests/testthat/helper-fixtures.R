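# Shared fixtures and independent oracles used across the suite.

# Full-scan simulation of the 25-mixture design; noiseless by default.
sim_study <- function(noise = no_noise()) {
  design <- load_design_fixture()
  grid <- wavelength_grid(200, 400)
  pure <- generate_pure_spectra(grid)
  spectra <- simulate_mixture_spectra(design, pure, noise)
  windowed <- select_window(spectra)
  split <- split_calibration_validation(design)
  list(design = design, pure = pure, pure_w = window_pure_spectra(pure),
       spectra = spectra, windowed = windowed,
       cal_idx = which(design$role == "calibration"),
       val_idx = which(design$role == "validation"),
       Xcal = windowed$absorbance[design$role == "calibration", ],
       Xval = windowed$absorbance[design$role == "validation", ],
       Ycal = design_concentrations(split$calibration),
       Yval = design_concentrations(split$validation))
}

# Ordinary least squares with intercept: the reference predictor that PCR
# and PLS must reproduce at full rank.
ols_oracle_predict <- function(X, Y, Xnew = X) {
  Xd <- cbind(1, X)
  B <- solve(crossprod(Xd), crossprod(Xd, Y))
  cbind(1, Xnew) %*% B
}

# Printed validation-set values used as test inputs.
table2_pls_bup_pred <- c(14.98, 5.06, 25.09, 25.00, 24.87, 20.33, 19.86, 20.15)
table2_val_bup_nominal <- c(15, 5, 25, 25, 25, 20, 20, 20)
table3_pls_bup_recovery <- c(99.87, 101.26, 100.36, 99.98, 99.5, 101.66,
                             99.29, 100.77)
table3_ann_dma_recovery <- c(100.00, 100.00, 100.00, 99.99, 100.00, 100.00,
                             99.99, 98.33)
table3_mcr_dex_recovery <- c(114.44, 102.71, 98.87, 101.43, 104.44, 101.55,
                             103.28, 102.46)
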
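#!/usr/bin/env Rscript
# Stage 1: build the study inputs.
#
# The measured spectra behind the study are not published, so the workflow
# runs on synthetic Beer-Lambert mixtures: four Gaussian-band pure spectra
# with heavy overlap in the 224-330 nm window, mixed at the 25 designed
# concentrations (17 calibration + 8 validation) with 0.5% photometric noise.

suppressPackageStartupMessages(library(quatmix))

seed <- 1L
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- load_design_fixture()
cat("Design: ", nrow(design), "mixtures (",
    sum(design$role == "calibration"), "calibration /",
    sum(design$role == "validation"), "validation )\n")
write_design(design, file.path(out, "design.csv"))

grid <- wavelength_grid(200, 400)
pure <- generate_pure_spectra(grid)
cm <- pure_cosine_matrix(window_pure_spectra(pure))
cat("Max pairwise spectral cosine in 224-330 nm:",
    round(max(cm[upper.tri(cm)]), 3),
    "-> severe overlap, univariate quantification is hopeless here.\n")
write_pure_spectra(pure, file.path(out, "pure_spectra.csv"))

noisy <- simulate_mixture_spectra(
  design, pure, noise_spec(sd_frac = 0.005, seed = derive_seed(seed, "noise")))
write_spectra(noisy, file.path(out, "mixture_spectra.csv"))
cat("Wrote", nrow(design), "mixture spectra x", grid$n_points,
    "wavelengths to", file.path(out, "mixture_spectra.csv"), "\n")
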
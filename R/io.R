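#' Read / write the canonical spectra CSV
#'
#' Canonical (`wavelength_rows`) layout: first column `wavelength_nm`, one
#' subsequent column per sample (header = sample id), absorbance in AU. The
#' transposed dialect (`sample_rows`: first column `sample_id`, one column
#' per wavelength named by its nm value) is accepted via the `dialect` flag.
#' Round-trips are lossless at 12 significant digits.
#'
#' @param path File path.
#' @param dialect `"wavelength_rows"` (canonical) or `"sample_rows"`.
#' @return `read_spectra` returns a [spectra_matrix()]; `write_spectra`
#'   returns `path` invisibly.
#' @export
read_spectra <- function(path, dialect = c("wavelength_rows", "sample_rows")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(df))
    stop("read_spectra: missing/ragged values (first bad row: ",
         which(rowSums(is.na(df)) > 0)[1], ")")
  if (dialect == "wavelength_rows") {
    wl <- df[[1]]
    A <- t(as.matrix(df[, -1, drop = FALSE]))
    ids <- colnames(df)[-1]
  } else {
    ids <- as.character(df[[1]])
    wl <- as.numeric(colnames(df)[-1])
    A <- as.matrix(df[, -1, drop = FALSE])
  }
  if (any(diff(wl) <= 0)) stop("read_spectra: wavelengths not strictly increasing")
  steps <- diff(wl)
  if (length(steps) > 0 && (max(steps) - min(steps)) > 1e-6 * mean(steps))
    stop("read_spectra: non-uniform wavelength spacing")
  grid <- wavelength_grid(wl[1], wl[length(wl)],
                          if (length(steps)) mean(steps) else 1)
  spectra_matrix(A, grid, ids)
}

#' @rdname read_spectra
#' @param spectra A [spectra_matrix()].
#' @export
write_spectra <- function(spectra, path,
                          dialect = c("wavelength_rows", "sample_rows")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spectra, "spectra_matrix"))
  fmt <- function(x) sprintf("%.12g", x)
  if (dialect == "wavelength_rows") {
    df <- data.frame(wavelength_nm = fmt(spectra$grid$wavelengths),
                     check.names = FALSE)
    for (i in seq_along(spectra$sample_ids))
      df[[spectra$sample_ids[i]]] <- fmt(spectra$absorbance[i, ])
  } else {
    df <- data.frame(sample_id = spectra$sample_ids, check.names = FALSE)
    for (j in seq_len(spectra$grid$n_points))
      df[[fmt(spectra$grid$wavelengths[j])]] <- fmt(spectra$absorbance[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive a per-stage seed from the master seed
#'
#' `(master * 1009 + stage_offset) mod (2^31 - 1)`: one master seed
#' reproduces every stage's randomness while keeping the stage streams
#' distinct.
#'
#' @param master Master seed (integer).
#' @param stage Stage name (`"noise"`, `"ann"`, ...) or an integer offset.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  offsets <- c(noise = 11L, ann = 23L, split = 37L, mc = 53L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("derive_seed: unknown stage ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(master) * 1009 + off) %% 2147483647)
}

#' Default run configuration
#'
#' The shipped configuration mirrors the study conditions: 200--400 nm scan
#' simulated at 1 nm, working window 224--330 nm (107 points), mean-centered
#' blocks, PCR with 6 and PLS with 5 latent variables, MCR-ALS with
#' non-negativity + correlation constraints at a 0.1% convergence threshold,
#' a 107-10-4 purelin network trained by Levenberg-Marquardt (70/15/15
#' split, patience 6), and 0.5% Gaussian instrument noise.
#'
#' @param seed Master seed.
#' @param sd_frac Instrument noise as a fraction of max clean absorbance.
#' @param models Models to run.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, sd_frac = 0.005,
                               models = c("PCR", "PLS", "MCR-ALS", "ANN")) {
  structure(list(
    scan = list(lo_nm = 200, hi_nm = 400, step_nm = 1),
    window = list(lo_nm = 224, hi_nm = 330),
    models = models,
    n_lv = list(PCR = 6L, PLS = 5L),
    mcr = list(nonneg_C = TRUE, nonneg_S = TRUE,
               unimodal_C = FALSE, unimodal_S = FALSE,
               conv_threshold_percent = 0.1, max_iter = 50L),
    ann = list(n_hidden = 10L, split = c(0.70, 0.15, 0.15),
               patience = 6L, max_epochs = 1000L, mse_goal = 0),
    noise = list(sd_frac = sd_frac),
    seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full calibration/validation pipeline
#'
#' Simulates (or accepts) the mixture spectra for the 25-mixture design,
#' selects the working window, mean-centers, fits every requested model on
#' the 17 calibration mixtures, predicts the 8 validation mixtures, and
#' computes the validation statistics (per-component recoveries with Q
#' rejection, mean/RSD, RMSEP, calibration regression diagnostics, EJCR).
#' Fully deterministic given the master seed.
#'
#' @param config A [default_run_config()] list.
#' @param out_dir Optional directory; when given, writes the config echo,
#'   simulated spectra, per-model prediction and recovery CSVs and a JSON
#'   summary.
#' @param design Optional `design_table` (defaults to the shipped fixture).
#' @param spectra Optional measured [spectra_matrix()]; when `NULL`,
#'   spectra are simulated from the design.
#' @return A `pipeline_report` list: `design`, `pure`, `models` (per model:
#'   `predicted`, `recovery` per component, `summaries`, `rmsep`,
#'   `diagnostics`, `ejcr`), `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         design = load_design_fixture(), spectra = NULL) {
  comp <- component_names()
  grid <- wavelength_grid(config$scan$lo_nm, config$scan$hi_nm,
                          config$scan$step_nm)
  pure <- generate_pure_spectra(grid)
  if (is.null(spectra)) {
    ns <- if (!is.null(config$noise$sd_au))
      noise_spec(sd_au = config$noise$sd_au,
                 seed = derive_seed(config$seed, "noise"))
    else noise_spec(sd_frac = config$noise$sd_frac,
                    seed = derive_seed(config$seed, "noise"))
    spectra <- simulate_mixture_spectra(design, pure, ns)
  }
  win <- select_window(spectra, config$window$lo_nm, config$window$hi_nm)
  pure_w <- window_pure_spectra(pure, config$window$lo_nm, config$window$hi_nm)
  split <- split_calibration_validation(design)
  cal_idx <- which(design$role == "calibration")
  val_idx <- which(design$role == "validation")
  Xcal <- win$absorbance[cal_idx, , drop = FALSE]
  Xval <- win$absorbance[val_idx, , drop = FALSE]
  Ycal <- design_concentrations(split$calibration)
  Yval <- design_concentrations(split$validation)

  fit_one <- function(model_name) {
    pred_cal <- NULL
    if (model_name == "PCR") {
      m <- fit_pcr(Xcal, Ycal, config$n_lv$PCR)
      pred <- predict(m, Xval); pred_cal <- predict(m, Xcal)
    } else if (model_name == "PLS") {
      m <- fit_pls(Xcal, Ycal, config$n_lv$PLS)
      pred <- predict(m, Xval); pred_cal <- predict(m, Xcal)
    } else if (model_name == "ANN") {
      m <- fit_ann(Xcal, Ycal, seed = derive_seed(config$seed, "ann"),
                   n_hidden = config$ann$n_hidden, split = config$ann$split,
                   patience = config$ann$patience,
                   max_epochs = config$ann$max_epochs,
                   mse_goal = config$ann$mse_goal)
      pred <- predict(m, Xval); pred_cal <- predict(m, Xcal)
    } else if (model_name == "MCR-ALS") {
      S0 <- initialize_profiles(Xcal, length(comp), "pure_standards", pure_w)
      cons <- mcr_constraints(nonneg_C = config$mcr$nonneg_C,
                              nonneg_S = config$mcr$nonneg_S,
                              unimodal_C = config$mcr$unimodal_C,
                              unimodal_S = config$mcr$unimodal_S)
      qr_res <- quantify_test_samples(Xcal, Xval, Ycal, S0, cons,
                                      config$mcr$conv_threshold_percent,
                                      config$mcr$max_iter)
      m <- run_mcr_als(Xcal, S0,
                       mcr_constraints(nonneg_C = config$mcr$nonneg_C,
                                       nonneg_S = config$mcr$nonneg_S,
                                       unimodal_C = config$mcr$unimodal_C,
                                       unimodal_S = config$mcr$unimodal_S,
                                       correlation = Ycal),
                       config$mcr$conv_threshold_percent, config$mcr$max_iter)
      pred <- qr_res$predicted
      pred_cal <- m$C
    } else stop("run_pipeline: unknown model ", model_name)
    colnames(pred) <- comp
    rec <- 100 * pred / Yval
    summaries <- lapply(comp, function(cn)
      summarize_recoveries(rec[, cn], apply_q = TRUE))
    names(summaries) <- comp
    diagnostics <- lapply(comp, function(cn)
      regression_diagnostics(pred_cal[, cn], Ycal[, cn]))
    names(diagnostics) <- comp
    ej <- lapply(comp, function(cn) ejcr(pred[, cn], Yval[, cn]))
    names(ej) <- comp
    out <- list(model = m, predicted = pred, predicted_cal = pred_cal,
                recovery = rec, summaries = summaries,
                rmsep = rmse(pred, Yval, "prediction"),
                rmsec = rmse(pred_cal, Ycal, "calibration"),
                diagnostics = diagnostics, ejcr = ej)
    out
  }

  models <- lapply(config$models, fit_one)
  names(models) <- config$models
  report <- structure(list(design = design, pure = pure, spectra = spectra,
                           windowed = win, models = models,
                           nominal_validation = Yval,
                           nominal_calibration = Ycal, config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits the config echo (JSON, including the master seed), the simulated
#' spectra CSV, per-model predicted-concentration and recovery CSVs and a
#' figures-of-merit JSON summary sufficient to re-run bit-identically.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_spectra(report$spectra, file.path(out_dir, "spectra.csv"))
  write_design(report$design, file.path(out_dir, "design.csv"))
  summary <- list(seed = report$config$seed)
  for (mn in names(report$models)) {
    mm <- report$models[[mn]]
    tag <- gsub("[^A-Za-z0-9]", "_", tolower(mn))
    utils::write.csv(round(mm$predicted, 4),
                     file.path(out_dir, paste0("predicted_", tag, ".csv")))
    utils::write.csv(round(mm$recovery, 2),
                     file.path(out_dir, paste0("recovery_", tag, ".csv")))
    summary[[mn]] <- list(
      mean_recovery = vapply(mm$summaries, function(s) s$mean_percent,
                             numeric(1)),
      rsd = vapply(mm$summaries, function(s) s$rsd_percent, numeric(1)),
      rmsep = as.vector(mm$rmsep), rmsec = as.vector(mm$rmsec),
      slope = vapply(mm$diagnostics, function(d) d$slope, numeric(1)),
      intercept = vapply(mm$diagnostics, function(d) d$intercept, numeric(1)),
      r = vapply(mm$diagnostics, function(d) d$r, numeric(1)),
      ejcr_contains_ideal = vapply(mm$ejcr, function(e) e$contains_ideal,
                                   logical(1)))
    if (mn == "MCR-ALS")
      summary[[mn]]$figures_of_merit <- list(
        lof_percent = mm$model$lof_percent,
        r2_percent = mm$model$r2_percent,
        n_iterations = mm$model$n_iterations,
        converged = mm$model$converged)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
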
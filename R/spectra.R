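#' Wavelength grid
#'
#' An evenly spaced grid of wavelengths (nm) on which absorbance spectra are
#' recorded. The grid is closed at both ends: a 200--400 nm grid at 1 nm steps
#' has 201 points, and the 224--330 nm working window has 107.
#'
#' @param lo_nm,hi_nm Lower and upper wavelength bounds in nm (`lo_nm < hi_nm`).
#' @param step_nm Grid spacing in nm, default 1.0.
#' @return An object of class `wavelength_grid` with elements `lo_nm`, `hi_nm`,
#'   `step_nm`, `n_points` and the vector of `wavelengths`.
#' @export
#' @examples
#' g <- wavelength_grid(200, 400)
#' g$n_points # 201
wavelength_grid <- function(lo_nm, hi_nm, step_nm = 1.0) {
  stopifnot(is.numeric(lo_nm), is.numeric(hi_nm), is.numeric(step_nm))
  if (!(lo_nm < hi_nm)) stop("wavelength_grid: lo_nm must be < hi_nm")
  if (step_nm <= 0) stop("wavelength_grid: step_nm must be > 0")
  n <- floor((hi_nm - lo_nm) / step_nm + 1e-9) + 1L
  wl <- lo_nm + step_nm * (seq_len(n) - 1L)
  structure(
    list(lo_nm = lo_nm, hi_nm = hi_nm, step_nm = step_nm,
         n_points = n, wavelengths = wl),
    class = "wavelength_grid"
  )
}

#' Spectra matrix (samples x wavelengths)
#'
#' The data matrix D of multivariate calibration: one row per sample, one
#' column per wavelength, absorbance in AU.
#'
#' @param absorbance Numeric matrix, samples x wavelengths; all entries finite.
#' @param grid A [wavelength_grid()] whose `n_points` equals `ncol(absorbance)`.
#' @param sample_ids Optional character vector of row labels.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(absorbance, grid, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (!inherits(grid, "wavelength_grid")) stop("grid must be a wavelength_grid")
  if (ncol(absorbance) != grid$n_points)
    stop("spectra_matrix: column count (", ncol(absorbance),
         ") does not match grid n_points (", grid$n_points, ")")
  if (any(!is.finite(absorbance)))
    stop("spectra_matrix: absorbance contains non-finite values")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(absorbance)))
  }
  if (length(sample_ids) != nrow(absorbance))
    stop("spectra_matrix: sample_ids length mismatch")
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format_wl(grid$wavelengths)
  structure(list(absorbance = absorbance, grid = grid, sample_ids = sample_ids),
            class = "spectra_matrix")
}

format_wl <- function(wl) sprintf("%.6g", wl)

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("spectra_matrix: %d samples x %d wavelengths (%.1f-%.1f nm, step %.3g nm)\n",
              nrow(x$absorbance), x$grid$n_points,
              x$grid$lo_nm, x$grid$hi_nm, x$grid$step_nm))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$absorbance)

#' Restrict spectra to a wavelength window
#'
#' Keeps the columns whose wavelength lies in the closed interval
#' `[lo_nm, hi_nm]`. The default window (224.0--330.0 nm) is the working
#' region of the assay: below 224 nm the solvent background dominates, above
#' 330 nm the four analytes carry little absorbance. At 1 nm steps the
#' default window retains 107 experimental points.
#'
#' @param spectra A [spectra_matrix()].
#' @param lo_nm,hi_nm Window bounds in nm; must lie within the spectra grid.
#' @return A new `spectra_matrix` on the windowed grid.
#' @export
select_window <- function(spectra, lo_nm = 224.0, hi_nm = 330.0) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (lo_nm > hi_nm) stop("select_window: lo_nm must be <= hi_nm")
  g <- spectra$grid
  if (lo_nm < g$lo_nm - 1e-9 || hi_nm > g$hi_nm + 1e-9)
    stop("select_window: window [", lo_nm, ", ", hi_nm,
         "] outside the grid [", g$lo_nm, ", ", g$hi_nm, "]")
  keep <- which(g$wavelengths >= lo_nm - 1e-9 & g$wavelengths <= hi_nm + 1e-9)
  if (length(keep) == 0) stop("select_window: empty window")
  wl <- g$wavelengths[keep]
  sub <- if (length(keep) > 1)
    wavelength_grid(wl[1], wl[length(wl)], g$step_nm)
  else # single-point window: keep a degenerate grid with one point
    structure(list(lo_nm = wl, hi_nm = wl, step_nm = g$step_nm,
                   n_points = 1L, wavelengths = wl), class = "wavelength_grid")
  spectra_matrix(spectra$absorbance[, keep, drop = FALSE], sub,
                 spectra$sample_ids)
}

#' Mean-center spectra
#'
#' Subtracts the per-wavelength column mean, returning the centered spectra
#' together with an invertible centering state so that validation spectra can
#' later be centered with the calibration means.
#'
#' @param spectra A [spectra_matrix()] with at least 2 samples.
#' @return A list with `centered` (a `spectra_matrix`) and `state`, a
#'   `centering_state` holding `column_means` and `n_samples_fit`.
#' @export
mean_center <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  X <- spectra$absorbance
  if (nrow(X) < 2) stop("mean_center: need at least 2 samples")
  m <- colMeans(X)
  state <- structure(list(column_means = m, n_samples_fit = nrow(X)),
                     class = "centering_state")
  centered <- spectra_matrix(sweep(X, 2L, m), spectra$grid, spectra$sample_ids)
  list(centered = centered, state = state)
}

#' Apply a stored centering to new spectra
#'
#' @param spectra A [spectra_matrix()] on the same grid used to fit `state`.
#' @param state A `centering_state` from [mean_center()].
#' @return The centered `spectra_matrix`.
#' @export
apply_centering <- function(spectra, state) {
  stopifnot(inherits(spectra, "spectra_matrix"),
            inherits(state, "centering_state"))
  if (ncol(spectra$absorbance) != length(state$column_means))
    stop("apply_centering: grid length (", ncol(spectra$absorbance),
         ") does not match centering state (", length(state$column_means), ")")
  spectra_matrix(sweep(spectra$absorbance, 2L, state$column_means),
                 spectra$grid, spectra$sample_ids)
}

#' Undo a centering (add the stored means back)
#'
#' @inheritParams apply_centering
#' @return The uncentered `spectra_matrix`.
#' @export
invert_centering <- function(spectra, state) {
  stopifnot(inherits(spectra, "spectra_matrix"),
            inherits(state, "centering_state"))
  if (ncol(spectra$absorbance) != length(state$column_means))
    stop("invert_centering: length mismatch")
  spectra_matrix(sweep(spectra$absorbance, 2L, state$column_means, FUN = "+"),
                 spectra$grid, spectra$sample_ids)
}
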
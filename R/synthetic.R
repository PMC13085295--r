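#' Default Gaussian band parameters for the four pure spectra
#'
#' Two bands per component, placed so that the four absorptivity profiles
#' overlap heavily inside the 224--330 nm working window — the regime that
#' defeats univariate spectrophotometry and motivates multivariate
#' calibration. Heights are molar-absorptivity-like coefficients in AU per
#' (ug/mL), scaled so that mixtures at the design concentrations stay within
#' the photometric range of a bench UV-Vis instrument (roughly 0.1--1.5 AU).
#'
#' @return Named list (BUP, DEX, CBA, DMA) of data.frames with columns
#'   `center_nm`, `width_nm`, `height`.
#' @export
default_pure_peaks <- function() {
  list(
    BUP = data.frame(center_nm = c(252, 298), width_nm = c(13, 22),
                     height = c(0.040, 0.010)),
    DEX = data.frame(center_nm = c(270, 232), width_nm = c(16, 10),
                     height = c(0.045, 0.020)),
    CBA = data.frame(center_nm = c(240, 282), width_nm = c(12, 18),
                     height = c(0.055, 0.028)),
    DMA = data.frame(center_nm = c(261, 305), width_nm = c(14, 20),
                     height = c(0.050, 0.022))
  )
}

#' Generate pure-component absorptivity spectra as Gaussian band sums
#'
#' Each component's absorptivity profile is a sum of Gaussian bands
#' `height * exp(-(wl - center)^2 / (2 width^2))` evaluated on the grid,
#' emulating strongly overlapping UV absorption bands. The output is fully
#' deterministic given the grid and band parameters.
#'
#' @param grid A [wavelength_grid()].
#' @param peak_params Named list of per-component data.frames with columns
#'   `center_nm`, `width_nm`, `height`; every center must lie inside the
#'   grid, widths and heights must be positive.
#' @param seed Integer recorded in the object for provenance (the profile
#'   construction itself is deterministic).
#' @return A `pure_spectra_set`: list with `component_names`, `absorptivity`
#'   (n_points x k matrix, AU per ug/mL), `grid`, `peak_params`, `seed`.
#' @export
#' @examples
#' ps <- generate_pure_spectra(wavelength_grid(200, 400))
#' dim(ps$absorptivity) # 201 x 4
generate_pure_spectra <- function(grid, peak_params = default_pure_peaks(),
                                  seed = 1L) {
  stopifnot(inherits(grid, "wavelength_grid"), length(peak_params) >= 1)
  wl <- grid$wavelengths
  profiles <- vapply(peak_params, function(pk) {
    stopifnot(nrow(pk) >= 1)
    if (any(pk$center_nm < grid$lo_nm - 1e-9 | pk$center_nm > grid$hi_nm + 1e-9))
      stop("generate_pure_spectra: peak center outside the wavelength grid")
    if (any(pk$width_nm <= 0) || any(pk$height <= 0))
      stop("generate_pure_spectra: peak widths and heights must be positive")
    rowSums(vapply(seq_len(nrow(pk)), function(i) {
      pk$height[i] * exp(-(wl - pk$center_nm[i])^2 / (2 * pk$width_nm[i]^2))
    }, numeric(length(wl))))
  }, numeric(length(wl)))
  colnames(profiles) <- names(peak_params)
  structure(list(component_names = names(peak_params),
                 absorptivity = profiles, grid = grid,
                 peak_params = peak_params, seed = as.integer(seed)),
            class = "pure_spectra_set")
}

#' Restrict a pure spectra set to a wavelength window
#'
#' @param pure A `pure_spectra_set`.
#' @param lo_nm,hi_nm Closed window bounds (nm).
#' @return A `pure_spectra_set` on the windowed grid.
#' @export
window_pure_spectra <- function(pure, lo_nm = 224.0, hi_nm = 330.0) {
  stopifnot(inherits(pure, "pure_spectra_set"))
  sm <- spectra_matrix(t(pure$absorptivity), pure$grid, pure$component_names)
  sm <- select_window(sm, lo_nm, hi_nm)
  structure(list(component_names = pure$component_names,
                 absorptivity = t(sm$absorbance), grid = sm$grid,
                 peak_params = pure$peak_params, seed = pure$seed),
            class = "pure_spectra_set")
}

#' Pairwise cosine similarities of pure profiles
#'
#' Used to verify the strong-overlap regime: at least one pair of profiles
#' should exceed cosine 0.7 inside the working window.
#' @param pure A `pure_spectra_set`.
#' @return Symmetric k x k matrix of cosine similarities.
#' @export
pure_cosine_matrix <- function(pure) {
  S <- pure$absorptivity
  Sn <- sweep(S, 2L, sqrt(colSums(S^2)), "/")
  crossprod(Sn)
}

#' Instrument noise specification
#'
#' Additive i.i.d. Gaussian photometric noise. Exactly one of `sd_au`
#' (absolute absorbance SD in AU) or `sd_frac` (fraction of the maximum
#' clean absorbance) may be given; the seed fully determines the
#' realization. The shipped default, `sd_frac = 0.005` (0.5% of the maximum
#' clean absorbance), is a typical bench UV-Vis photometric noise level.
#'
#' @param sd_au Absolute noise SD in AU, or `NULL`.
#' @param sd_frac Noise SD as a fraction of max clean absorbance, or `NULL`.
#' @param seed Integer seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sd_au = NULL, sd_frac = NULL, seed = 1L) {
  if (is.null(sd_au) && is.null(sd_frac)) sd_frac <- 0.005
  if (!is.null(sd_au) && !is.null(sd_frac))
    stop("noise_spec: give exactly one of sd_au / sd_frac")
  if (!is.null(sd_au) && sd_au < 0) stop("noise_spec: sd_au must be >= 0")
  if (!is.null(sd_frac) && sd_frac < 0) stop("noise_spec: sd_frac must be >= 0")
  structure(list(model = "gaussian", sd_au = sd_au, sd_frac = sd_frac,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Noise-free specification shorthand
#' @return A `noise_spec` with zero noise.
#' @export
no_noise <- function() noise_spec(sd_au = 0, seed = 0L)

#' Simulate mixture spectra by the multiwavelength Beer-Lambert law
#'
#' Builds the bilinear data matrix `D = C %*% t(S) + E`: each mixture
#' spectrum is the concentration-weighted sum of the pure absorptivity
#' profiles plus seeded additive noise. With zero noise the output is
#' exactly bilinear, so its numerical rank is at most the number of
#' components.
#'
#' @param design A `design_table` whose component columns match
#'   `pure$component_names` in order.
#' @param pure A `pure_spectra_set`.
#' @param noise A [noise_spec()]; default noise-free.
#' @return A [spectra_matrix()] with one row per design row (sample ids
#'   `mix<id>`), in design order.
#' @export
simulate_mixture_spectra <- function(design, pure, noise = no_noise()) {
  stopifnot(inherits(pure, "pure_spectra_set"), inherits(noise, "noise_spec"))
  comp <- pure$component_names
  if (!all(comp %in% names(design)))
    stop("simulate_mixture_spectra: design lacks columns for components: ",
         paste(setdiff(comp, names(design)), collapse = ", "))
  C <- as.matrix(design[, comp, drop = FALSE])
  if (any(C < 0)) stop("simulate_mixture_spectra: negative concentration")
  D <- C %*% t(pure$absorptivity)
  sd_au <- if (!is.null(noise$sd_au)) noise$sd_au else noise$sd_frac * max(D)
  if (sd_au > 0) {
    E <- with_seed(noise$seed, matrix(rnorm(length(D), sd = sd_au),
                                      nrow = nrow(D)))
    D <- D + E
  }
  ids <- if ("mixture_id" %in% names(design))
    paste0("mix", design$mixture_id) else paste0("mix", seq_len(nrow(D)))
  spectra_matrix(D, pure$grid, ids)
}

# Evaluate expr under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write pure spectra to CSV
#'
#' Two-column-per-component layout is collapsed to a `wavelength_nm` column
#' followed by one absorptivity column per component.
#' @param pure A `pure_spectra_set`.
#' @param path File path.
#' @export
write_pure_spectra <- function(pure, path) {
  df <- data.frame(wavelength_nm = pure$grid$wavelengths)
  for (j in seq_along(pure$component_names))
    df[[pure$component_names[j]]] <- pure$absorptivity[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
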
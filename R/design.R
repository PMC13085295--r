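#' @importFrom stats coef lm pf pt qf qt rnorm runif sd var
NULL

# Component concentration grids (ug/mL): five equally spaced levels each.
component_levels <- function() {
  list(BUP = c(5, 10, 15, 20, 25),
       DEX = c(8, 10, 12, 14, 16),
       CBA = c(2, 4, 6, 8, 10),
       DMA = c(2, 4, 6, 8, 10))
}

#' Names of the four quantified components
#'
#' BUP (bupropion hydrochloride) and DEX (dextromethorphan hydrobromide) are
#' the active drugs; CBA (3-chlorobenzoic acid) and DMA (N,N-dimethylaniline)
#' are their pharmacopeial process-related impurities.
#' @return Character vector of length 4.
#' @export
component_names <- function() c("BUP", "DEX", "CBA", "DMA")

new_design_table <- function(df) {
  stopifnot(all(c("mixture_id", "role", component_names()) %in% names(df)))
  structure(df, class = c("design_table", "data.frame"))
}

validate_design_table <- function(design) {
  lv <- component_levels()
  if (anyDuplicated(design$mixture_id))
    stop("design_table: duplicated mixture_id")
  if (!all(design$role %in% c("calibration", "validation")))
    stop("design_table: role must be 'calibration' or 'validation'")
  for (cn in component_names()) {
    v <- design[[cn]]
    if (any(v < min(lv[[cn]]) - 1e-9) || any(v > max(lv[[cn]]) + 1e-9))
      stop("design_table: ", cn, " outside its calibrated range [",
           min(lv[[cn]]), ", ", max(lv[[cn]]), "] ug/mL")
    if (!all(vapply(v, function(x) any(abs(x - lv[[cn]]) < 1e-9), logical(1))))
      stop("design_table: ", cn, " contains off-grid concentrations")
  }
  invisible(design)
}

#' The five-level, four-factor calibration/validation design
#'
#' Returns the 25-mixture experimental design used throughout the workflow:
#' 17 calibration and 8 validation mixtures covering BUP 5--25, DEX 8--16,
#' CBA 2--10 and DMA 2--10 ug/mL, each component on five equally spaced
#' levels with every level occurring exactly five times. Mixture 1 is the
#' all-center point (15, 12, 6, 6).
#'
#' @return A `design_table` (data.frame) with columns `mixture_id`, `role`,
#'   `BUP`, `DEX`, `CBA`, `DMA` (ug/mL).
#' @export
#' @examples
#' d <- load_design_fixture()
#' table(d$role) # 17 calibration, 8 validation
load_design_fixture <- function() {
  conc <- matrix(c(
    15, 12,  6,  6,
    15,  8,  4,  2,
     5, 10,  2, 10,
    10,  8, 10, 10,
     5, 16, 10,  6,
    25, 16,  6,  4,
    25, 12,  4, 10,
    15, 10, 10,  4,
    10, 16,  4,  8,
    25, 10,  8,  8,
    10, 14,  8,  6,
    20, 14,  6, 10,
    20, 12, 10,  8,
    15, 16,  8, 10,
    25, 14, 10,  2,
    20, 16,  2,  2,
    25,  8,  2,  6,
     5,  8,  6,  8,
     5, 12,  8,  2,
    15, 14,  2,  8,
    20,  8,  8,  4,
     5, 14,  4,  4,
    20, 10,  4,  6,
    10, 10,  6,  2,
    10, 12,  2,  4), ncol = 4, byrow = TRUE)
  validation_rows <- c(1, 3, 6, 7, 10, 13, 21, 23)
  df <- data.frame(
    mixture_id = 1:25,
    role = ifelse(1:25 %in% validation_rows, "validation", "calibration"),
    BUP = conc[, 1], DEX = conc[, 2], CBA = conc[, 3], DMA = conc[, 4],
    stringsAsFactors = FALSE
  )
  validate_design_table(new_design_table(df))
}

# Balanced 24-run coded sequence (levels -2..2) for runs 2..25 of factor 1;
# together with the center-point first run each level occurs exactly 5 times.
default_seed_sequence <- function() {
  c(0, -2, -1, -2, 2, 2, 0, -1, 2, -1, 1, 1,
    0, 2, 1, 2, -2, -2, 0, 1, -2, 1, -1, -1)
}

#' Build a balanced five-level multifactor calibration design
#'
#' Constructs a 25-run design in which the first run is the all-center point
#' and every factor takes each of its five levels exactly five times. The
#' first factor follows a balanced cyclic coded sequence; each successive
#' factor is a cyclic shift of that sequence over the 24 non-center runs,
#' which preserves both the center-point first run and per-factor balance.
#' The generator is validated by these balance properties, not by row-exact
#' reproduction of any particular published table.
#'
#' @param levels Number of levels per factor; only 5 is supported by the
#'   default generator.
#' @param factors Number of factors (components).
#' @param level_values List of `factors` numeric vectors, each of `levels`
#'   strictly increasing concentrations. Defaults to the component grids of
#'   the shipped design.
#' @param seed_sequence Coded sequence (levels `-2..2`) for runs 2..25 of the
#'   first factor; must contain the center code 4 times and every other code
#'   5 times.
#' @return A `design_table` with all rows flagged `calibration`.
#' @export
build_multilevel_design <- function(levels = 5L, factors = 4L,
                                    level_values = component_levels(),
                                    seed_sequence = default_seed_sequence()) {
  if (levels != 5L)
    stop("build_multilevel_design: the cyclic generator supports levels = 5 only")
  stopifnot(factors >= 1L, length(level_values) >= factors)
  level_values <- level_values[seq_len(factors)]
  n_run <- levels^2
  if (length(seed_sequence) != n_run - 1L)
    stop("build_multilevel_design: seed_sequence must have ", n_run - 1L, " codes")
  tab <- table(factor(seed_sequence, levels = -2:2))
  if (!all(tab == c(5, 5, 4, 5, 5)))
    stop("build_multilevel_design: seed_sequence is not balanced ",
         "(center 4x, others 5x required)")
  coded <- matrix(0L, nrow = n_run, ncol = factors)
  for (j in seq_len(factors)) {
    shifted <- seed_sequence
    if (j > 1L) {
      k <- (j - 1L) %% length(seed_sequence)
      shifted <- c(seed_sequence[-seq_len(k)], seed_sequence[seq_len(k)])
    }
    coded[, j] <- c(0L, shifted)
  }
  conc <- vapply(seq_len(factors), function(j) {
    vals <- level_values[[j]]
    if (is.unsorted(vals, strictly = TRUE))
      stop("build_multilevel_design: level_values must be strictly increasing")
    vals[coded[, j] + 3L]
  }, numeric(n_run))
  df <- data.frame(mixture_id = seq_len(n_run), role = "calibration",
                   stringsAsFactors = FALSE)
  nm <- names(level_values)
  if (is.null(nm)) nm <- paste0("F", seq_len(factors))
  for (j in seq_len(factors)) df[[nm[j]]] <- conc[, j]
  out <- structure(df, class = c("design_table", "data.frame"))
  attr(out, "coded") <- coded
  out
}

#' Split a design into calibration and validation subsets
#'
#' @param design A `design_table` with assigned roles.
#' @return A list with `calibration` and `validation` design tables; the
#'   partition preserves row order and together restores the input.
#' @export
split_calibration_validation <- function(design) {
  if (!all(c("role", "mixture_id") %in% names(design)))
    stop("split_calibration_validation: design lacks role assignments")
  if (any(is.na(design$role)) ||
      !all(design$role %in% c("calibration", "validation")))
    stop("split_calibration_validation: invalid or missing roles")
  cal <- design[design$role == "calibration", , drop = FALSE]
  val <- design[design$role == "validation", , drop = FALSE]
  rownames(cal) <- NULL; rownames(val) <- NULL
  list(calibration = new_design_table(cal), validation = new_design_table(val))
}

#' Concentration matrix of a design
#'
#' @param design A `design_table`.
#' @return Numeric matrix (rows = mixtures) with columns BUP, DEX, CBA, DMA.
#' @export
design_concentrations <- function(design) {
  m <- as.matrix(design[, component_names(), drop = FALSE])
  rownames(m) <- design$mixture_id
  m
}

#' Read / write the design CSV format
#'
#' Columns `mixture_id, role, BUP, DEX, CBA, DMA`, concentrations in ug/mL
#' printed with two decimals.
#' @param design A `design_table`.
#' @param path File path.
#' @return `read_design` returns a `design_table`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  out <- as.data.frame(design)
  for (cn in component_names()) out[[cn]] <- sprintf("%.2f", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_design_table(df)
}
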
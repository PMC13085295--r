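#' Recovery percentage
#'
#' `100 * predicted / nominal`; reports are printed at 2 dp but full
#' precision is returned.
#'
#' @param predicted Predicted concentration(s), ug/mL.
#' @param nominal Nominal concentration(s), ug/mL; must be > 0.
#' @return Numeric recovery in percent (vectorized).
#' @export
#' @examples
#' round(recovery_percent(14.98, 15.00), 2) # 99.87
recovery_percent <- function(predicted, nominal) {
  if (any(nominal <= 0)) stop("recovery_percent: nominal must be > 0")
  100 * predicted / nominal
}

# Dixon Q critical values (r10 = gap/range statistic), n = 3..10.
dixon_q_table <- function(alpha) {
  tab <- list(
    `0.1`  = c(0.886, 0.679, 0.557, 0.482, 0.434, 0.399, 0.370, 0.349),
    `0.05` = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412),
    `0.01` = c(0.988, 0.889, 0.780, 0.698, 0.637, 0.590, 0.555, 0.527))
  key <- as.character(alpha)
  if (!key %in% names(tab))
    stop("dixon_q_test: tabulated alpha levels are 0.1, 0.05, 0.01")
  tab[[key]]
}

#' Dixon Q outlier test
#'
#' Computes the r10 statistic `q = (suspect gap) / range` for the more
#' extreme tail of the sorted values and compares it to the tabulated
#' critical value at the requested level (n = 3..10). At most one value is
#' rejected per pass.
#'
#' @param values Numeric vector, 3 to 10 values.
#' @param alpha Significance level: 0.1, 0.05 (default) or 0.01.
#' @return A `q_test_result`: `sorted_values`, `q_statistic`, `q_critical`,
#'   `rejected_value` (or `NULL`), `rejected_index` (into the input order).
#' @export
dixon_q_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 10)
    stop("dixon_q_test: n must be in 3..10 (tabulated range), got ", n)
  crit <- dixon_q_table(alpha)[n - 2L]
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0) {
    q <- 0; suspect <- NA_real_
  } else {
    gap_low <- s[2] - s[1]
    gap_high <- s[n] - s[n - 1]
    if (gap_high >= gap_low) { q <- gap_high / rng; suspect <- s[n] }
    else { q <- gap_low / rng; suspect <- s[1] }
  }
  rejected <- !is.na(suspect) && q > crit
  structure(list(sorted_values = s, q_statistic = q, q_critical = crit,
                 rejected_value = if (rejected) suspect else NULL,
                 rejected_index = if (rejected) which(values == suspect)[1]
                                  else NULL,
                 alpha = alpha, n = n),
            class = "q_test_result")
}

#' Summarize recoveries (mean, RSD) with optional Q rejection
#'
#' Optionally applies the Dixon Q rule (single pass by default; sequential
#' re-testing behind `sequential = TRUE`), then reports the mean and the
#' relative standard deviation `RSD = 100 * sd / mean` (n-1 denominator) of
#' the retained values.
#'
#' @param recoveries Numeric vector of recovery percentages (>= 2 values;
#'   >= 3 for Q rejection).
#' @param apply_q Apply Dixon Q rejection first.
#' @param alpha Q-test level.
#' @param sequential Repeat the Q test after each rejection while n >= 3.
#' @return A `recovery_summary`: `recoveries_percent`, `rejected_indices`,
#'   `mean_percent`, `rsd_percent`, `n_used`.
#' @export
summarize_recoveries <- function(recoveries, apply_q = FALSE, alpha = 0.05,
                                 sequential = FALSE) {
  stopifnot(length(recoveries) >= 2)
  rejected <- integer(0)
  kept <- recoveries
  idx <- seq_along(recoveries)
  if (apply_q) {
    stopifnot(length(recoveries) >= 3)
    repeat {
      qt_res <- dixon_q_test(kept, alpha)
      if (is.null(qt_res$rejected_value)) break
      drop <- qt_res$rejected_index
      rejected <- c(rejected, idx[drop])
      kept <- kept[-drop]; idx <- idx[-drop]
      if (!sequential || length(kept) < 3) break
    }
  }
  m <- mean(kept)
  rsd <- 100 * sd(kept) / m
  structure(list(recoveries_percent = recoveries,
                 rejected_indices = rejected,
                 mean_percent = m, rsd_percent = rsd,
                 n_used = length(kept)),
            class = "recovery_summary")
}

#' Regression diagnostics of predicted vs nominal concentrations
#'
#' Ordinary least squares of predicted on nominal with the Pearson
#' correlation and the calibration RMSE.
#'
#' @param predicted,nominal Numeric vectors (>= 3 points; nominal not all
#'   equal).
#' @return A `regression_diagnostics` list: `slope`, `intercept`, `r`,
#'   `rmsec`.
#' @export
regression_diagnostics <- function(predicted, nominal) {
  stopifnot(length(predicted) == length(nominal), length(nominal) >= 3)
  if (var(nominal) < .Machine$double.eps)
    stop("regression_diagnostics: nominal values have zero variance")
  fit <- lm(predicted ~ nominal)
  b <- coef(fit)
  structure(list(slope = unname(b[2]), intercept = unname(b[1]),
                 r = stats::cor(predicted, nominal),
                 rmsec = sqrt(mean((predicted - nominal)^2))),
            class = "regression_diagnostics")
}

#' Elliptical joint confidence region (EJCR) for slope and intercept
#'
#' From the OLS regression of predicted on nominal, the joint
#' `100(1-alpha)%` confidence region for `(intercept, slope)` is
#' `(beta - b)' X'X (beta - b) <= 2 s^2 F(alpha; 2, n-2)` with
#' `X = [1, nominal]`. A model free of systematic bias has the ideal point
#' `(0, 1)` inside the region.
#'
#' @param predicted,nominal Numeric vectors (n >= 3).
#' @param alpha Significance level (default 0.05).
#' @param n_boundary Number of parametric boundary points returned.
#' @return An `ejcr_result`: `intercept`, `slope`, `s2`, `n`, `f_crit`,
#'   `contains_ideal`, `ellipse_boundary` (n_boundary x 2 matrix of
#'   (intercept, slope) pairs).
#' @export
ejcr <- function(predicted, nominal, alpha = 0.05, n_boundary = 360L) {
  n <- length(nominal)
  if (n < 3) stop("ejcr: need at least 3 points")
  stopifnot(length(predicted) == n)
  X <- cbind(1, nominal)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, predicted))
  res <- predicted - X %*% b
  s2 <- sum(res^2) / (n - 2)
  f_crit <- qf(1 - alpha, 2, n - 2)
  rhs <- 2 * s2 * f_crit
  dlt <- c(0, 1) - as.vector(b)
  qform <- as.numeric(t(dlt) %*% XtX %*% dlt)
  eg <- eigen(XtX, symmetric = TRUE)
  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[seq_len(n_boundary)]
  circ <- rbind(cos(th), sin(th))
  bound <- t(as.vector(b) +
             eg$vectors %*% (sqrt(rhs) / sqrt(eg$values) * circ))
  colnames(bound) <- c("intercept", "slope")
  structure(list(intercept = b[1], slope = b[2], s2 = s2, n = n,
                 f_crit = f_crit, contains_ideal = qform <= rhs,
                 ellipse_boundary = bound, alpha = alpha),
            class = "ejcr_result")
}

new_comparison <- function(test, statistic, df, critical, alpha, significant)
  structure(list(test = test, statistic = statistic, df = df,
                 critical = critical, alpha = alpha,
                 significant = significant),
            class = "comparison_result")

#' One-sample t test of mean recovery against a reference value
#'
#' Tests trueness: `t = (mean - reference) / (sd / sqrt(n))` with `n - 1`
#' degrees of freedom against the two-sided critical value. The usual
#' reference for recoveries is 100%.
#'
#' @param values Recovery percentages (n >= 2, non-zero spread).
#' @param reference Reference value (default 100).
#' @param alpha Two-sided level (default 0.05).
#' @return A `comparison_result`.
#' @export
one_sample_t_vs_reference <- function(values, reference = 100.0, alpha = 0.05) {
  n <- length(values)
  if (n < 2) stop("one_sample_t_vs_reference: need >= 2 values")
  s <- sd(values)
  if (s == 0) stop("one_sample_t_vs_reference: zero standard deviation")
  tstat <- (mean(values) - reference) / (s / sqrt(n))
  crit <- critical_value("t_two_sided", alpha, n - 1L)
  new_comparison("one_sample_t_vs_100", tstat, n - 1L, crit, alpha,
                 abs(tstat) > crit)
}

#' Two-sample comparison with an official method (pooled t and F)
#'
#' Pooled-variance two-sample t test (`df = n1 + n2 - 2`) for accuracy and
#' a variance-ratio F test (larger variance in the numerator) for
#' precision, as used in pharmacopeial method comparison.
#'
#' @param model_values Results of the proposed model.
#' @param official_values Results of the official method.
#' @param alpha Level (two-sided t; upper-tail F).
#' @return List with elements `t` and `F`, both `comparison_result`s.
#' @export
compare_with_official <- function(model_values, official_values, alpha = 0.05) {
  n1 <- length(model_values); n2 <- length(official_values)
  if (n1 < 2 || n2 < 2) stop("compare_with_official: both samples need n >= 2")
  v1 <- var(model_values); v2 <- var(official_values)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("compare_with_official: zero pooled variance")
  tstat <- (mean(model_values) - mean(official_values)) /
    sqrt(sp2 * (1 / n1 + 1 / n2))
  df_t <- n1 + n2 - 2L
  t_crit <- critical_value("t_two_sided", alpha, df_t)
  if (v1 >= v2) { fstat <- v1 / v2; df_f <- c(n1 - 1L, n2 - 1L) }
  else { fstat <- v2 / v1; df_f <- c(n2 - 1L, n1 - 1L) }
  f_crit <- critical_value("F_upper", alpha, df_f)
  list(t = new_comparison("two_sample_t", tstat, df_t, t_crit, alpha,
                          abs(tstat) > t_crit),
       F = new_comparison("variance_F", fstat, df_f, f_crit, alpha,
                          fstat > f_crit))
}

#' Tabulated critical values (t and F)
#'
#' Inverse distribution functions; reports round to 3 dp, full precision is
#' returned.
#'
#' @param kind `"t_two_sided"` (two-sided t at level `alpha`) or
#'   `"F_upper"` (upper-tail F).
#' @param alpha Level in (0, 1).
#' @param df Degrees of freedom: a single integer for t, a pair
#'   `(df_num, df_den)` for F.
#' @return Numeric critical value.
#' @export
#' @examples
#' round(critical_value("t_two_sided", 0.05, 7), 3) # 2.365
#' round(critical_value("F_upper", 0.05, c(2, 7)), 3) # 4.737
critical_value <- function(kind = c("t_two_sided", "F_upper"), alpha, df) {
  kind <- match.arg(kind)
  if (alpha <= 0 || alpha >= 1) stop("critical_value: alpha must be in (0,1)")
  if (any(df < 1)) stop("critical_value: df must be >= 1")
  if (kind == "t_two_sided") {
    stopifnot(length(df) == 1)
    qt(1 - alpha / 2, df)
  } else {
    if (length(df) != 2) stop("critical_value: F_upper needs df = c(num, den)")
    qf(1 - alpha, df[1], df[2])
  }
}

# IUPAC 2021 abridged standard atomic weights (g/mol) for common elements.
atomic_weights <- function() c(
  H = 1.008, He = 4.0026, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
  Mn = 54.938, Fe = 55.845, Cu = 63.546, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.90)

#' Molar mass from a molecular formula
#'
#' Parses an element-count formula (e.g. `"C18H26BrNO"`) and sums standard
#' atomic weights.
#'
#' @param formula Character formula; element symbols with optional counts.
#' @return Molar mass in g/mol.
#' @export
#' @examples
#' round(molar_mass("H2O"), 3) # 18.015
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  aw <- atomic_weights()
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (paste(parts, collapse = "") != formula)
    stop("molar_mass: cannot parse formula '", formula, "'")
  total <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!sym %in% names(aw))
      stop("molar_mass: unknown element symbol '", sym, "'")
    total <- total + cnt * aw[[sym]]
  }
  total
}

#' Titration equivalence
#'
#' Mass of analyte (mg) equivalent to a titrant volume:
#' `molarity * volume_mL * molar_mass / stoichiometry`. For the
#' dextromethorphan base C18H26BrNO, 1.0 mL of 0.1 M NaOH corresponds to
#' 35.23 mg.
#'
#' @param formula Molecular formula of the analyte.
#' @param titrant_molarity Titrant concentration, mol/L.
#' @param volume_mL Titrant volume, mL.
#' @param stoichiometry Moles of titrant per mole of analyte.
#' @return Equivalent analyte mass in mg.
#' @export
#' @examples
#' round(titration_equivalent("C18H26BrNO", 0.1, 1.0), 2) # 35.23
titration_equivalent <- function(formula, titrant_molarity, volume_mL,
                                 stoichiometry = 1L) {
  titrant_molarity * volume_mL * molar_mass(formula) / stoichiometry
}
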
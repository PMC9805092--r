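#' GFP intensity corrected for cell mass
#'
#' @param gfp bulk GFP plate-reader intensity, ADU
#' @param od600 optical density at 600 nm (> 0)
#' @return ADU per OD unit
#' @export
gfp_corr <- function(gfp, od600) {
  if (any(od600 <= 0)) stop("od600 must be > 0")
  gfp / od600
}

#' GFP_corr expressed relative to a non-fluorescent control strain
#'
#' @param gfp_corr_strain GFP_corr of the strain of interest
#' @param gfp_corr_control GFP_corr of the negative-control strain (> 0)
#' @return dimensionless ratio GFP_norm
#' @export
gfp_norm <- function(gfp_corr_strain, gfp_corr_control) {
  if (any(gfp_corr_control <= 0)) stop("control GFP_corr must be > 0")
  gfp_corr_strain / gfp_corr_control
}

#' Fit the abundance calibration regression
#'
#' Ordinary least squares of log10(GFP_norm) on log10(molecules/cell) over
#' reference strains of known abundance. A single straight line over
#' orders of magnitude of abundance is only plausible on log axes, so the
#' regression space is log10-log10 by default; `space = "linear"` is
#' offered for sensitivity analysis. At least 3 distinct abundances are
#' required.
#'
#' @param gfp_norm GFP_norm values of the reference strains
#' @param molecules_per_cell known abundances (> 0)
#' @param space "log10" (default) or "linear"
#' @return `calibration_model`: list with `slope`, `intercept`, `r2`,
#'   `n`, `space`, `domain` (fitted abundance range) and `gfp_range`
#' @export
fit_calibration <- function(gfp_norm, molecules_per_cell, space = "log10") {
  if (any(molecules_per_cell <= 0)) stop("abundances must be positive")
  if (any(gfp_norm <= 0) && space == "log10")
    stop("GFP_norm must be positive for a log-space fit")
  if (length(unique(molecules_per_cell)) < 3)
    stop("calibration needs >= 3 distinct abundances")
  if (space == "log10") {
    x <- log10(molecules_per_cell); y <- log10(gfp_norm)
  } else {
    x <- molecules_per_cell; y <- gfp_norm
  }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 slope_se = summary(fit)$coefficients[2, 2],
                 n = length(x), space = space,
                 domain = range(molecules_per_cell),
                 gfp_range = range(gfp_norm)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model (%s): slope %.4f, intercept %.4f, R^2 %.4f, n = %d\n",
              x$space, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Predict molecules/cell from GFP_norm via the calibration model
#'
#' Inverts the calibration map. Predictions outside the fitted GFP_norm
#' range carry an `extrapolated` flag.
#'
#' @param model a `calibration_model`
#' @param gfp_norm GFP_norm values (> 0)
#' @return data.frame: `gfp_norm`, `molecules_per_cell`, `extrapolated`
#' @export
predict_abundance <- function(model, gfp_norm) {
  if (any(gfp_norm <= 0)) stop("GFP_norm must be positive")
  if (model$space == "log10") {
    mol <- 10^((log10(gfp_norm) - model$intercept) / model$slope)
  } else {
    mol <- (gfp_norm - model$intercept) / model$slope
  }
  data.frame(gfp_norm = gfp_norm, molecules_per_cell = mol,
             extrapolated = gfp_norm < model$gfp_range[1] |
                            gfp_norm > model$gfp_range[2])
}

#' Molar concentration implied by a per-cell abundance and a cell density
#'
#' molecules/cell x cells/mL, converted to moles per litre through
#' Avogadro's number, returned in nM. 1.5e5 molecules/cell at 1e8 cells/mL
#' gives 24.9 nM.
#'
#' @param molecules_per_cell per-cell copy number (>= 0)
#' @param cell_density cells per mL (>= 0)
#' @return concentration in nM
#' @export
molarity <- function(molecules_per_cell, cell_density) {
  if (any(molecules_per_cell < 0) || any(cell_density < 0))
    stop("inputs must be >= 0")
  avogadro <- 6.02214076e23
  molecules_per_cell * cell_density * 1e3 / avogadro * 1e9
}

#' Displayed abundance from total abundance and displayed fraction
#'
#' @param molecules_per_cell total per-cell abundance
#' @param fraction displayed fraction in \[0,1\]
#' @param cell_density cells/mL used for the molar conversion
#' @return list: `molecules_per_cell` (displayed), `concentration_nM`
#' @export
displayed_abundance <- function(molecules_per_cell, fraction,
                                cell_density = 1e8) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  disp <- molecules_per_cell * fraction
  list(molecules_per_cell = disp,
       concentration_nM = molarity(disp, cell_density))
}

#' Maximum specific growth rate from an OD600 time series
#'
#' Maximum slope of ln(OD) over a sliding window of `window` consecutive
#' time points (default 5, i.e. 75 min at 15-min sampling), in 1/h.
#'
#' @param time_min sampling times in minutes
#' @param od OD600 readings (> 0)
#' @param window sliding-window length in points
#' @return growth rate mu in 1/h
#' @export
growth_rate <- function(time_min, od, window = 5) {
  if (length(time_min) != length(od)) stop("time and OD lengths differ")
  if (length(od) < 8) stop("need >= 8 time points")
  if (any(od <= 0)) stop("OD readings must be > 0")
  if (window < 2 || window > length(od)) stop("invalid window")
  th <- time_min / 60
  ln_od <- log(od)
  slopes <- vapply(seq_len(length(od) - window + 1), function(i) {
    j <- i:(i + window - 1)
    unname(stats::coef(stats::lm(ln_od[j] ~ th[j]))[2])
  }, numeric(1))
  max(slopes)
}

#' Fitness as a growth-rate ratio
#'
#' @param mu_strain growth rate of the strain of interest, 1/h
#' @param mu_reference growth rate of the reference strain, 1/h (> 0)
#' @return dimensionless fitness ratio
#' @export
fitness_ratio <- function(mu_strain, mu_reference) {
  if (any(mu_reference <= 0)) stop("reference growth rate must be > 0")
  mu_strain / mu_reference
}

#' Two-sample comparison utility
#'
#' Thin wrapper around Welch's t-test for parity with figure annotations.
#' @param x,y numeric vectors
#' @return list: `p_value`, `estimate` (difference of means)
#' @export
compare_groups <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(p_value = tt$p.value,
       estimate = unname(diff(rev(tt$estimate))))
}
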
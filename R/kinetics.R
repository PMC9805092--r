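#' Fit the pH-dependence of the p-nitrophenol extinction coefficient
#'
#' p-nitrophenol absorbs at ~405 nm only in its deprotonated form, so the
#' apparent extinction coefficient follows a Henderson-Hasselbalch
#' titration, `epsilon(pH) = epsilon_max / (1 + 10^(pKa - pH))`. Fitted by
#' nonlinear least squares; the standard literature values (pKa 7.15,
#' epsilon_max 18000 1/(M cm)) serve only as optimizer starting points.
#'
#' @param ph reference pH values (>= 4 points spanning the pKa)
#' @param epsilon reference extinction coefficients, 1/(M cm)
#' @param start optional list(epsilon_max=, pka=) of starting values
#' @return `epsilon_model`: list with `epsilon_max`, `pka`, `rss`, `fit`
#' @export
fit_epsilon_model <- function(ph, epsilon,
                              start = list(epsilon_max = 18000, pka = 7.15)) {
  if (length(ph) < 4) stop("need >= 4 reference points")
  if (any(epsilon < 0)) stop("extinction coefficients must be >= 0")
  fit <- minpack.lm::nlsLM(epsilon ~ emax / (1 + 10^(pka - ph)),
                           start = list(emax = start$epsilon_max,
                                        pka = start$pka),
                           data = data.frame(ph = ph, epsilon = epsilon),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  if (co[["pka"]] < min(ph) || co[["pka"]] > max(ph))
    stop("reference data do not span the fitted pKa")
  structure(list(epsilon_max = unname(co[["emax"]]),
                 pka = unname(co[["pka"]]),
                 rss = sum(stats::residuals(fit)^2), fit = fit),
            class = "epsilon_model")
}

#' @export
print.epsilon_model <- function(x, ...) {
  cat(sprintf("epsilon_model: epsilon_max %.1f 1/(M cm), pKa %.3f\n",
              x$epsilon_max, x$pka))
  invisible(x)
}

#' Predict the extinction coefficient at given pH values
#' @param model an `epsilon_model`
#' @param ph pH value(s)
#' @return epsilon in 1/(M cm)
#' @export
predict_epsilon <- function(model, ph) {
  model$epsilon_max / (1 + 10^(model$pka - ph))
}

#' Packaged p-nitrophenol extinction reference table (synthetic)
#'
#' A synthetic reference table of apparent 405 nm extinction coefficients
#' of p-nitrophenol between pH 6 and 10, generated from the standard
#' literature titration constants (pKa 7.15, epsilon_max 18000 1/(M cm);
#' the classical spectrophotometric characterization of p-nitrophenol is
#' Biggs, 1954). It stands in for tabulated spectrophotometric
#' measurements and is labelled synthetic accordingly.
#'
#' @return data.frame: `ph`, `epsilon`
#' @export
pnp_extinction_reference <- function() {
  path <- system.file("extdata", "pnp_extinction_405nm_synthetic.csv",
                      package = "surfquant", mustWork = TRUE)
  utils::read.csv(path)
}

#' Product concentration from endpoint absorbance (Beer-Lambert)
#'
#' `(A405 - A405_control) / (epsilon * pathlength)` in molar units,
#' reported in uM. The paired autohydrolysis control (substrate in buffer
#' only) removes the non-enzymatic background. Negative net absorbances
#' are floored at 0 with a warning.
#'
#' @param a405 endpoint absorbance of the reaction
#' @param a405_control absorbance of the autohydrolysis control
#' @param epsilon extinction coefficient at the assay pH, 1/(M cm)
#' @param pathlength optical pathlength in cm (required; well geometry
#'   dependent)
#' @return product concentration in uM
#' @export
pnp_concentration <- function(a405, a405_control, epsilon, pathlength) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0")
  if (any(pathlength <= 0)) stop("pathlength must be > 0")
  net <- a405 - a405_control
  if (any(net < 0)) {
    warning("negative net absorbance floored at 0")
    net <- pmax(net, 0)
  }
  net / (epsilon * pathlength) * 1e6
}

#' Initial rate from a single-endpoint assay
#'
#' @param product_uM product concentration at the endpoint, uM
#' @param duration_min reaction duration in minutes (> 0)
#' @return rate in uM/min
#' @export
initial_rate <- function(product_uM, duration_min) {
  if (any(duration_min <= 0)) stop("duration must be > 0")
  product_uM / duration_min
}

#' Fit Michaelis-Menten kinetics
#'
#' Unweighted nonlinear least squares of `v = Vmax * S / (Km + S)`;
#' replicate points are fitted individually, not averaged. Starting
#' values: `Vmax = max(v)`, `Km = S` nearest to half-maximal rate.
#'
#' @param s substrate concentrations, uM (>= 5 distinct values)
#' @param v rates, uM/min
#' @return `mm_fit`: list with `vmax`, `km`, their standard errors,
#'   `rss`, `fit`
#' @export
fit_michaelis_menten <- function(s, v) {
  if (length(s) != length(v)) stop("s and v lengths differ")
  if (length(unique(s)) < 5) stop("need >= 5 distinct substrate concentrations")
  if (any(s <= 0)) stop("substrate concentrations must be > 0")
  if (all(v == 0)) stop("all rates are zero; nothing to fit")
  v0 <- max(v)
  km0 <- s[which.min(abs(v - v0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s),
                      start = list(vmax = v0, km = max(km0, 1e-6)),
                      lower = c(0, 0),
                      data = data.frame(s = s, v = v),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("Michaelis-Menten fit did not converge (start vmax=%.3g, km=%.3g): %s",
                   v0, km0, conditionMessage(e))))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(list(vmax = unname(co[["vmax"]]), km = unname(co[["km"]]),
                 vmax_se = unname(se[["vmax"]]), km_se = unname(se[["km"]]),
                 rss = sum(stats::residuals(fit)^2), fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("mm_fit: Vmax %.4g uM/min, Km %.4g uM\n", x$vmax, x$km))
  invisible(x)
}

#' Whole-cell catalytic constants from the abundance chain
#'
#' `k_cat = Vmax / [E]` with units reconciled to 1/s, and catalytic
#' efficiency `k_cat / Km` in 1/(M s). The enzyme concentration's
#' provenance (displayed-abundance chain, total abundance, or purified
#' enzyme) is recorded alongside the constants.
#'
#' @param vmax maximal rate in uM/min
#' @param enzyme_nM enzyme concentration in nM (> 0)
#' @param km_uM Michaelis constant in uM
#' @param provenance one of "displayed", "total", "purified"
#' @return list: `kcat_per_s`, `efficiency_per_M_s`, `enzyme_nM`,
#'   `provenance`
#' @export
catalytic_constants <- function(vmax, enzyme_nM, km_uM,
                                provenance = c("displayed", "total",
                                               "purified")) {
  provenance <- match.arg(provenance)
  if (any(enzyme_nM <= 0)) stop("enzyme concentration must be > 0")
  vmax_nM_s <- vmax * 1e3 / 60   # uM/min -> nM/s
  kcat <- vmax_nM_s / enzyme_nM
  list(kcat_per_s = kcat,
       efficiency_per_M_s = kcat / (km_uM * 1e-6),
       enzyme_nM = enzyme_nM, provenance = provenance)
}

#' Normalize an activity to a reference cell density
#'
#' @param rate measured rate
#' @param cell_density assay cell density, cells/mL (> 0)
#' @param reference_density reference density (default 1e8 cells/mL)
#' @return rate scaled to the reference density
#' @export
normalize_activity <- function(rate, cell_density, reference_density = 1e8) {
  if (any(cell_density <= 0)) stop("cell density must be > 0")
  rate * reference_density / cell_density
}
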
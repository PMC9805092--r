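#' Synthetic plate-reader calibration dataset
#'
#' Reference strains of known abundance with bulk GFP and OD600 readings
#' generated under the power-law model
#' `log10(GFP_norm) = slope * log10(molecules/cell) + intercept + noise`,
#' plus negative-control rows. OD600 varies between replicates; raw GFP is
#' reconstructed as `GFP_norm * control_corr * OD600` so that the
#' downstream `gfp_corr`/`gfp_norm` chain recovers the generating values
#' exactly when noise is off.
#'
#' @param abundances known molecules/cell of the reference strains (> 0);
#'   defaults to 30 strains log-uniform over 2.3e3 ... 7.5e5
#' @param slope,intercept generating log10-log10 parameters
#' @param noise_sd Gaussian noise sd on log10(GFP_norm)
#' @param control_corr GFP_corr (ADU/OD) of the negative-control strain
#' @param n_control number of negative-control replicate rows
#' @param seed RNG seed
#' @return data.frame: `strain_id`, `molecules_per_cell_true`, `od600`,
#'   `gfp`, `is_control`
#' @export
generate_calibration_table <- function(abundances = NULL, slope = 1.0,
                                       intercept = -3.5, noise_sd = 0.05,
                                       control_corr = 5000, n_control = 3,
                                       seed = 1L) {
  with_scene_rng(seed, {
    if (is.null(abundances))
      abundances <- 10^seq(log10(2.3e3), log10(7.5e5), length.out = 30)
    if (any(abundances <= 0)) stop("abundances must be positive")
    n <- length(abundances)
    log_gnorm <- slope * log10(abundances) + intercept +
      stats::rnorm(n, 0, noise_sd)
    gnorm <- 10^log_gnorm
    od <- stats::runif(n + n_control, 0.6, 1.2)
    strain <- data.frame(strain_id = sprintf("ref%02d", seq_len(n)),
                         molecules_per_cell_true = abundances,
                         od600 = od[seq_len(n)],
                         gfp = gnorm * control_corr * od[seq_len(n)],
                         is_control = FALSE)
    ctrl <- data.frame(strain_id = sprintf("control%02d", seq_len(n_control)),
                       molecules_per_cell_true = NA_real_,
                       od600 = od[n + seq_len(n_control)],
                       gfp = control_corr * od[n + seq_len(n_control)],
                       is_control = TRUE)
    rbind(strain, ctrl)
  })
}

#' GFP_norm values from a calibration-style table
#'
#' Runs the `gfp_corr` / `gfp_norm` chain: per-strain GFP/OD600, divided
#' by the mean GFP_corr of the control rows.
#'
#' @param tab a table as from [generate_calibration_table()]
#' @return data.frame of non-control rows with a `gfp_norm` column added
#' @export
calibration_gfp_norm <- function(tab) {
  ctrl <- tab[tab$is_control, , drop = FALSE]
  if (!nrow(ctrl)) stop("table has no negative-control rows")
  ctrl_corr <- mean(gfp_corr(ctrl$gfp, ctrl$od600))
  out <- tab[!tab$is_control, , drop = FALSE]
  out$gfp_norm <- gfp_norm(gfp_corr(out$gfp, out$od600), ctrl_corr)
  out
}

#' Specification of a synthetic endpoint kinetics assay
#'
#' @param vmax_true generating maximal rate, uM/min (> 0)
#' @param km_true generating Michaelis constant, uM (> 0)
#' @param substrate_concentrations uM, strictly positive and sorted;
#'   defaults to 12 log-spaced points over 0.07 ... 134.1 uM
#' @param n_replicates replicate reactions per concentration
#' @param autohydrolysis_rate non-enzymatic substrate hydrolysis, uM/min
#' @param epsilon extinction coefficient at assay pH, 1/(M cm)
#' @param pathlength optical pathlength, cm
#' @param duration_min reaction time, min
#' @param read_noise_sd absorbance read noise (AU)
#' @param cell_density assay cell density, cells/mL
#' @param seed RNG seed
#' @return an `assay_spec` list
#' @export
assay_spec <- function(vmax_true = 1.0, km_true = 10,
                       substrate_concentrations = NULL, n_replicates = 3,
                       autohydrolysis_rate = 0.02, epsilon = 18000,
                       pathlength = 1, duration_min = 10,
                       read_noise_sd = 0.002, cell_density = 1e8,
                       seed = 1L) {
  if (is.null(substrate_concentrations))
    substrate_concentrations <- 10^seq(log10(0.07), log10(134.1),
                                       length.out = 12)
  s <- substrate_concentrations
  if (any(s <= 0)) stop("substrate concentrations must be > 0")
  if (is.unsorted(s, strictly = TRUE)) stop("substrate concentrations must be sorted and distinct")
  if (vmax_true <= 0 || km_true <= 0) stop("vmax_true and km_true must be > 0")
  structure(list(vmax_true = vmax_true, km_true = km_true,
                 substrate_concentrations = s, n_replicates = n_replicates,
                 autohydrolysis_rate = autohydrolysis_rate,
                 epsilon = epsilon, pathlength = pathlength,
                 duration_min = duration_min, read_noise_sd = read_noise_sd,
                 cell_density = cell_density, seed = as.integer(seed)),
            class = "assay_spec")
}

#' Synthetic endpoint kinetics dataset
#'
#' Per substrate concentration and replicate,
#' `A405 = epsilon * l * (v(S) + autohydrolysis) * t` (concentrations in
#' M) plus read noise, with `v(S) = Vmax S / (Km + S)`, and a paired
#' autohydrolysis-control absorbance (substrate in buffer only).
#'
#' @param spec an [assay_spec()]
#' @return data.frame: `s_uM`, `replicate`, `a405`, `a405_control`,
#'   `duration_min`, `cell_density`, `v_true_uM_min`
#' @export
generate_kinetics_dataset <- function(spec) {
  with_scene_rng(spec$seed, {
    grid <- expand.grid(s_uM = spec$substrate_concentrations,
                        replicate = seq_len(spec$n_replicates))
    v <- spec$vmax_true * grid$s_uM / (spec$km_true + grid$s_uM)
    signal <- spec$epsilon * spec$pathlength *
      (v + spec$autohydrolysis_rate) * spec$duration_min * 1e-6
    ctrl <- spec$epsilon * spec$pathlength *
      spec$autohydrolysis_rate * spec$duration_min * 1e-6
    n <- nrow(grid)
    data.frame(s_uM = grid$s_uM, replicate = grid$replicate,
               a405 = signal + stats::rnorm(n, 0, spec$read_noise_sd),
               a405_control = ctrl + stats::rnorm(n, 0, spec$read_noise_sd),
               duration_min = spec$duration_min,
               cell_density = spec$cell_density,
               v_true_uM_min = v)
  })
}

#' Synthetic OD600 growth curves
#'
#' Logistic trajectories `OD(t) = K od0 e^(mu t) / (K + od0 (e^(mu t)-1))`
#' sampled every `interval_min` minutes with multiplicative log-normal
#' noise.
#'
#' @param mu_list specific growth rates, 1/h (> 0); one curve per entry
#' @param od0 inoculation OD600 (> 0)
#' @param carrying_capacity plateau OD600
#' @param interval_min sampling interval, min (> 0)
#' @param duration_h total duration, h
#' @param noise_sd sd of the multiplicative log-normal noise
#' @param seed RNG seed
#' @return data.frame: `curve_id`, `mu_true`, `time_min`, `od600`
#' @export
generate_growth_curves <- function(mu_list, od0 = 0.05,
                                   carrying_capacity = 1.5,
                                   interval_min = 15, duration_h = 24,
                                   noise_sd = 0.01, seed = 1L) {
  if (any(mu_list <= 0)) stop("growth rates must be > 0")
  if (od0 <= 0) stop("od0 must be > 0")
  if (interval_min <= 0) stop("interval must be > 0")
  with_scene_rng(seed, {
    t_min <- seq(0, duration_h * 60, by = interval_min)
    th <- t_min / 60
    rows <- lapply(seq_along(mu_list), function(i) {
      mu <- mu_list[i]
      od <- carrying_capacity * od0 * exp(mu * th) /
        (carrying_capacity + od0 * (exp(mu * th) - 1))
      od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
      data.frame(curve_id = i, mu_true = mu, time_min = t_min, od600 = od)
    })
    do.call(rbind, rows)
  })
}
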
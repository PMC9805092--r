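#!/usr/bin/env Rscript
# Fit the GFP calibration regression on the simulated plate-reader table,
# convert a display strain's bulk GFP signal to molecules/cell and molar
# concentration, combine with the displayed fraction from 02 to get
# surface abundance, and compute growth-rate fitness.

suppressMessages(library(surfquant))

indir <- "results/simulated"
outdir <- "results"
if (!dir.exists(indir)) stop("run analysis/01_simulate.R first")

tab <- read.csv(file.path(indir, "calibration_table.csv"))
dat <- calibration_gfp_norm(tab)
cal <- fit_calibration(dat$gfp_norm, dat$molecules_per_cell_true)
message(sprintf("Calibration: log10(GFP_norm) = %.3f log10(N) %+.3f, R^2 = %.3f (n = %d)",
                cal$slope, cal$intercept, cal$r2, cal$n))
jsonlite::write_json(unclass(cal)[c("slope", "intercept", "r2", "n", "space",
                                    "domain", "gfp_range")],
                     file.path(outdir, "calibration_model.json"),
                     auto_unbox = TRUE, digits = NA)

# an example display strain at 1.2e5 molecules/cell (7 replicate readings)
set.seed(3)
gnorm <- mean(10^(1.0 * log10(1.2e5) - 3.5 + rnorm(7, 0, 0.05)))
pred <- predict_abundance(cal, gnorm)
message(sprintf("Example strain: GFP_norm %.2f -> %.3g molecules/cell (true 1.2e5)%s",
                gnorm, pred$molecules_per_cell,
                if (pred$extrapolated) " [extrapolated]" else ""))
message(sprintf("Implied molarity at 1e8 cells/mL: %.1f nM",
                molarity(pred$molecules_per_cell, 1e8)))

# displayed abundance using the fraction recovered in 02 (if available)
ps_file <- "results/display/per_strain.json"
if (file.exists(ps_file)) {
  ps <- jsonlite::read_json(ps_file, simplifyVector = TRUE)
  f22 <- ps$mean_fraction[ps$strain_id == "display-22"]
  d <- displayed_abundance(pred$molecules_per_cell, f22, 1e8)
  message(sprintf("Displayed abundance at fraction %.3f: %.3g molecules/cell = %.2f nM",
                  f22, d$molecules_per_cell, d$concentration_nM))
}

g <- read.csv(file.path(indir, "growth_curves.csv"))
mu <- vapply(unique(g$curve_id), function(i) {
  d <- g[g$curve_id == i, ]
  growth_rate(d$time_min, d$od600)
}, numeric(1))
fit <- fitness_ratio(mu[1], mu[2])
message(sprintf("Growth rates: %.3f and %.3f 1/h -> fitness ratio %.3f (true 0.95)",
                mu[1], mu[2], fit))
write.csv(data.frame(curve_id = unique(g$curve_id), mu_per_h = mu),
          file.path(outdir, "growth_rates.csv"), row.names = FALSE)
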
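test_that("the extinction-coefficient model obeys titration identities", {
  ph <- seq(6, 10, 0.5)
  eps <- 18000 / (1 + 10^(7.15 - ph))
  m <- fit_epsilon_model(ph, eps)
  expect_equal(m$epsilon_max, 18000, tolerance = 1e-6)
  expect_equal(m$pka, 7.15, tolerance = 1e-6)
  expect_equal(predict_epsilon(m, m$pka), m$epsilon_max / 2, tolerance = 1e-9)
  # monotone increasing over the assay range, saturating at high pH
  grid <- seq(6, 10.5, 0.1)
  expect_true(all(diff(predict_epsilon(m, grid)) > 0))
  expect_gte(predict_epsilon(m, 10.5), 0.999 * predict_epsilon(m, 12))
  expect_true(all(is.finite(predict_epsilon(m, c(7.5, 8.5, 9.5, 10.5)))))
  expect_error(fit_epsilon_model(ph[1:3], eps[1:3]), ">= 4")
  expect_error(fit_epsilon_model(seq(9, 10.5, 0.5),
                                 18000 / (1 + 10^(7.15 - seq(9, 10.5, 0.5)))),
               "span")
})

test_that("the packaged synthetic extinction table refits its constants", {
  ref <- pnp_extinction_reference()
  m <- fit_epsilon_model(ref$ph, ref$epsilon)
  expect_equal(m$epsilon_max, 18000, tolerance = 0.01)
  expect_equal(m$pka, 7.15, tolerance = 0.01)
})

test_that("Beer-Lambert conversion and rates match hand arithmetic", {
  expect_equal(pnp_concentration(0.18, 0, 18000, 1), 10)
  expect_equal(pnp_concentration(0.25, 0.25, 18000, 1), 0)
  expect_warning(out <- pnp_concentration(0.1, 0.2, 18000, 1), "floored")
  expect_equal(out, 0)
  expect_error(pnp_concentration(0.1, 0, -5, 1), "> 0")
  expect_error(pnp_concentration(0.1, 0, 18000, 0), "> 0")
  expect_equal(initial_rate(5, 10), 0.5)
  expect_equal(initial_rate(0, 10), 0)
  expect_error(initial_rate(1, 0), "> 0")
})

test_that("Michaelis-Menten fitting inverts noiseless curves exactly", {
  s <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  v <- 10 * s / (5 + s)
  fit <- fit_michaelis_menten(s, v)
  expect_equal(fit$vmax, 10, tolerance = 1e-6)
  expect_equal(fit$km, 5, tolerance = 1e-6)
  # definitional identity on the fitted curve
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  expect_error(fit_michaelis_menten(s[1:4], v[1:4]), "5 distinct")
  expect_error(fit_michaelis_menten(s, v * 0), "zero")
})

test_that("Km recovery error shrinks with noise and is <= 10% at 5% noise", {
  s <- rep(10^seq(log10(0.07), log10(134.1), length.out = 12), 3)
  v_true <- 1.0 * s / (10 + s)
  errs <- vapply(c(0.05, 0.01, 0.002), function(nl) {
    set.seed(42)
    rel <- vapply(1:100, function(i) {
      v <- v_true + rnorm(length(s), 0, nl * max(v_true))
      f <- fit_michaelis_menten(s, pmax(v, 0))
      abs(f$km - 10) / 10
    }, numeric(1))
    stats::median(rel)
  }, numeric(1))
  expect_lte(errs[1], 0.10)
  expect_true(all(diff(errs) < 0))  # bias/error shrinks as noise drops
})

test_that("catalytic constants reconcile units and scale invariantly", {
  # Vmax 10 nM/s = 0.6 uM/min; [E] 2 nM -> kcat 5 1/s
  cc <- catalytic_constants(0.6, 2, 5, provenance = "purified")
  expect_equal(cc$kcat_per_s, 5)
  expect_equal(cc$efficiency_per_M_s, 1e6)
  # scaling Vmax and [E] together leaves kcat unchanged
  cc2 <- catalytic_constants(0.6 * 7, 2 * 7, 5, provenance = "purified")
  expect_equal(cc2$kcat_per_s, cc$kcat_per_s)
  expect_error(catalytic_constants(1, 0, 5), "> 0")
})

test_that("activity normalization rescales to the reference density", {
  expect_equal(normalize_activity(2, 1e8), 2)
  expect_equal(normalize_activity(2, 5e7), 4)
  expect_error(normalize_activity(1, 0), "> 0")
  # generator round-trip: halving density halves the observed rate
  sp <- assay_spec(read_noise_sd = 0, seed = 1, cell_density = 5e7,
                   vmax_true = 0.5)
  tab <- generate_kinetics_dataset(sp)
  v <- initial_rate(pnp_concentration(tab$a405, tab$a405_control,
                                      sp$epsilon, sp$pathlength),
                    tab$duration_min)
  vn <- normalize_activity(v, unique(tab$cell_density))
  expect_equal(max(vn), 2 * max(v), tolerance = 1e-9)
})

test_that("full synthetic assays recover their generating parameters within 5%", {
  sp <- assay_spec(vmax_true = 1.0, km_true = 10, seed = 9)
  tab <- generate_kinetics_dataset(sp)
  v <- initial_rate(pnp_concentration(tab$a405, tab$a405_control,
                                      sp$epsilon, sp$pathlength),
                    tab$duration_min)
  fit <- fit_michaelis_menten(tab$s_uM, v)
  expect_lt(abs(fit$vmax - 1.0) / 1.0, 0.05)
  expect_lt(abs(fit$km - 10) / 10, 0.05)
})
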
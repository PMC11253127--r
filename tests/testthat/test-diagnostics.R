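# Prediction bands, the CAG sweep and residual diagnostics.

fit_params_published <- function() {
  list(params = c(as.list(truth_vector()),
                  list(cag_ref = CAG_REF, density_brain = 1.03)),
       spec = model_spec(), cl = clearance_table())
}

test_that("bands collapse onto the median curve without variability", {
  f <- fit_params_published()
  f$params$omega_k0 <- 0; f$params$omega_k2 <- 0
  f$params$sigma_prop_nfl <- 0; f$params$sigma_add_vol <- 0
  b <- prediction_band(f, group = "HC", age_grid = seq(35, 75, by = 5),
                      n_sim = 200, seed = 2)
  expect_equal(b$lower, b$median, tolerance = 1e-10)
  expect_equal(b$upper, b$median, tolerance = 1e-10)
})

test_that("median HC NfL curve equals the QSS worked value at age 50", {
  b <- prediction_band(fit_params_published(), group = "HC",
                       age_grid = c(40, 50, 60), n_sim = 200, seed = 3)
  expect_equal(b$median[b$age == 50], 418.7452, tolerance = 1e-6)
})

test_that("median HC NfL is linear in age with the analytic slope", {
  f <- fit_params_published()
  ages <- seq(40, 70, by = 1)
  b <- prediction_band(f, group = "HC", age_grid = ages, n_sim = 200, seed = 4)
  slopes <- diff(b$median) / diff(ages)
  cb <- convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml")
  expect_equal(unname(slopes),
               rep(2 * 0.0902 * cb / convert_clearance(303), length(slopes)),
               tolerance = 1e-8)
})

test_that("narrower bands nest inside wider ones and bands reproduce", {
  f <- fit_params_published()
  b50 <- prediction_band(f, "manifestHD", cag = 42.75, level = 0.5,
                         n_sim = 500, seed = 9)
  b90 <- prediction_band(f, "manifestHD", cag = 42.75, level = 0.9,
                         n_sim = 500, seed = 9)
  expect_true(all(b50$lower >= b90$lower))
  expect_true(all(b50$upper <= b90$upper))
  again <- prediction_band(f, "manifestHD", cag = 42.75, level = 0.9,
                           n_sim = 500, seed = 9)
  expect_identical(b90, again)
  expect_error(prediction_band(f, "HC", n_sim = 50), "meaningless")
  expect_error(prediction_band(f, "preHD", cag = NA), "CAG")
})

test_that("90% bands cover fresh observations at the nominal rate", {
  f <- fit_params_published()
  ages <- seq(35, 75, by = 2)
  hits <- 0; total <- 0
  set.seed(501)
  for (g in list(c("HC", NA), c("preHD", 42), c("manifestHD", 42.75))) {
    cag <- suppressWarnings(as.numeric(g[2]))
    b <- prediction_band(f, g[1], cag = cag, age_grid = ages,
                         n_sim = 4000, seed = 11)
    # fresh subjects through the same generative model
    n_new <- 600
    eta0 <- rnorm(n_new, 0, 40); eta2 <- rnorm(n_new, 0, 0.3)
    k2 <- nflatrophy:::k2_population(f$params, f$spec, g[1], cag) * exp(eta2)
    age <- sample(ages, n_new, replace = TRUE)
    cb <- convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml")
    nfl <- pmax(cb * pmax(-4.84 + 2 * k2 * age, 0) /
                  clearance_ml_per_yr(f$cl, g[1]) *
                  (1 + rnorm(n_new, 0, 0.216)), 1)
    j <- match(age, b$age)
    hits <- hits + sum(nfl >= b$lower[j] & nfl <= b$upper[j])
    total <- total + n_new
  }
  expect_equal(hits / total, 0.9, tolerance = 0.033)
})

test_that("CAG sweep reproduces the rate surface", {
  tab <- cag_rate_sweep(published_truth(), age_grid = c(50, 56),
                        cag_values = 39:51)
  expect_equal(tab$rate[tab$group == "HC" & tab$age == 50], 4.18)
  expect_equal(tab$rate[tab$group == "HD" & tab$age == 56 & tab$CAG == 45],
               11.5336180, tolerance = 1e-7)
  # reference identity: CAG 42.5 equals the HD population curve
  tab_ref <- cag_rate_sweep(published_truth(), age_grid = 60,
                            cag_values = 42.5)
  expect_equal(tab_ref$k2[tab_ref$group == "HD"], 0.125)
  # monotone in CAG at every age
  for (a in unique(tab$age)) {
    r <- tab[tab$group == "HD" & tab$age == a, ]
    expect_true(all(diff(r$rate[order(r$CAG)]) > 0))
  }
  expect_error(cag_rate_sweep(published_truth(), cag_values = 20),
               "plausible")
})

test_that("residuals vanish on noise-free data and flag injected bias", {
  dat <- noise_free_cohort(seed = 91)
  fit <- fit_nfl_model(dat, model_spec(random_effects = FALSE), se = FALSE,
                       fix = list(sigma_prop_nfl = 0.01,
                                  sigma_add_vol = 0.1))
  rr <- residual_report(dat, fit)
  expect_lt(max(abs(rr$residuals$iwres[rr$residuals$stream == "volume"])),
            0.05)
  # shift every volume by +50 mL: mean weighted residual ~ 50 / 11
  shifted <- dat
  shifted$wb_adj <- shifted$wb_adj + 50
  fit2 <- fit
  rr2 <- residual_report(shifted, fit2)
  mv <- rr2$summary$mean[rr2$summary$stream == "volume"]
  expect_equal(mv, 50 / fit$params$sigma_add_vol, tolerance = 0.2)
})

test_that("weighted residuals are standard normal on well-specified data", {
  # dense visit schedule so empirical-Bayes shrinkage is mild
  design <- cohort_design(n = c(HC = 15, preHD = 15, manifestHD = 30),
                          visit_days = seq(0, 3650, by = 730),
                          dropout = 0)
  subj <- sample_subjects(design, seed = 95)
  dat <- simulate_observations(subj, design = design, seed = 96)
  fit <- fit_nfl_model(dat, se = FALSE)
  rr <- residual_report(dat, fit)
  expect_equal(rr$summary$mean, c(0, 0), tolerance = 0.12)
  expect_equal(rr$summary$sd, c(1, 1), tolerance = 0.12)
})
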
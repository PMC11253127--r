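# Joint mixed-effects estimation: exact recovery on clean data, agreement
# with the two-stage cross-check, likelihood dominance, and invariances.

test_that("noise-free data identify the fixed effects exactly", {
  dat <- noise_free_cohort(seed = 15)
  spec <- model_spec(random_effects = FALSE)
  # error magnitudes are held at small values: on exact data their MLEs
  # sit on the boundary and carry no information about the fixed effects
  fit <- fit_nfl_model(dat, spec, se = FALSE,
                       fix = list(sigma_prop_nfl = 0.01,
                                  sigma_add_vol = 0.1))
  est <- coef(fit)
  truth <- truth_vector()
  for (nm in c("k0", "k1", "k2_hc", "k2_hd_pop", "beta_cag", "cnfl_brain"))
    expect_equal(unname(est[nm]), unname(truth[nm]), tolerance = 1e-3)
})

test_that("two-stage estimator is exact on noise-free data", {
  dat <- noise_free_cohort(seed = 16)
  ts <- suppressWarnings(two_stage_fit(dat))
  est <- coef(ts)
  truth <- truth_vector()
  for (nm in c("k0", "k1", "k2_hc", "k2_hd_pop", "beta_cag", "cnfl_brain"))
    expect_equal(unname(est[nm]), unname(truth[nm]), tolerance = 1e-6)
})

test_that("two-stage and joint fits agree on a low-noise cohort", {
  design <- cohort_design(replicate = 2)
  subj <- sample_subjects(design, random_effects_spec(5, 0.05),
                          published_truth(), seed = 25)
  dat <- simulate_observations(subj, err = error_model_spec(0.02, 1),
                               design = design, seed = 26)
  fit <- fit_nfl_model(dat, se = FALSE)
  ts <- suppressWarnings(two_stage_fit(dat))
  expect_true(fit$converged)
  expect_lt(abs(coef(ts)["beta_cag"] - coef(fit)["beta_cag"]) /
              abs(coef(fit)["beta_cag"]), 0.25)
  # the maximised marginal likelihood dominates the two-stage plug-in
  expect_gte(fit$loglik, ts$loglik)
})

test_that("CAG covariate is inestimable from a degenerate design", {
  dat <- small_cohort(seed = 33)
  one_hd <- dat[dat$group == "HC" | dat$ID == dat$ID[dat$group == "manifestHD"][1], ]
  expect_error(suppressWarnings(two_stage_fit(one_hd)), "inestimable")
})

test_that("fit is invariant to subject relabeling and row order", {
  design <- cohort_design(n = c(HC = 10, preHD = 10, manifestHD = 20))
  subj <- sample_subjects(design, seed = 41)
  dat <- simulate_observations(subj, design = design, seed = 42)
  fit1 <- fit_nfl_model(dat, se = FALSE)
  perm <- dat[rev(seq_len(nrow(dat))), ]
  relab <- perm
  relab$ID <- paste0("X", relab$ID)
  fit2 <- fit_nfl_model(relab, se = FALSE)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-4)
})

test_that("fit result carries likelihood metadata and EB estimates", {
  dat <- small_cohort(seed = 51)
  fit <- fit_nfl_model(dat)
  expect_s3_class(fit, "fit_result")
  expect_true(is.finite(fit$bicc))
  expect_match(fit$bicc_formula, "logLik")
  expect_equal(nrow(fit$ranef), length(unique(dat$ID)))
  expect_equal(fit$n_obs, sum(!is.na(dat$wb_adj)) + sum(!is.na(dat$NfL_CSF2)))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$n_param)
})

test_that("model comparison ranks by corrected BIC", {
  dat <- small_cohort(seed = 61)
  cmpq <- compare_models(dat)
  expect_equal(cmpq$table$model[1], "quadratic")
  expect_true(all(diff(cmpq$table$bicc[cmpq$table$converged]) >= 0))
  # single spec: a table of one, no ranking to do
  cmp1 <- compare_models(dat, specs = list(quadratic = model_spec()))
  expect_equal(nrow(cmp1$table), 1)
})

test_that("flat data generated without curvature prefer the linear model", {
  # k2 ~ 0: volume is a line, NfL flat; the quadratic adds parameters
  design <- cohort_design()
  truth_flat <- structural_params(k0 = 1500, k1 = -4, k2 = 1e-6,
                                  k2_hd_pop = 1e-6, beta_cag = 0)
  subj <- sample_subjects(design, random_effects_spec(40, 0),
                          truth_flat, seed = 71)
  dat <- simulate_observations(subj, truth_flat, design = design, seed = 72)
  cmp <- compare_models(dat)
  expect_equal(cmp$table$model[1], "linear")
})

test_that("the fitted linear model predicts NfL constant in age", {
  dat <- small_cohort(seed = 81)
  fl <- fit_nfl_model(dat, model_spec("linear"), se = FALSE)
  p <- fl$params
  ages <- seq(35, 75, by = 5)
  pred <- nflatrophy:::predict_typical(p, fl$spec, fl$cl, "HC", NA, ages)$nfl
  expect_equal(diff(range(pred)), 0)
  # while the data show a positive empirical NfL-age trend
  slope <- coef(lm(NfL_CSF2 ~ age, data = dat[dat$group == "HC", ]))[2]
  expect_gt(slope, 0)
})
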
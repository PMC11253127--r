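# Structural equations: worked values are frozen from an independent hand
# oracle (direct arithmetic on the printed formulas).

test_that("brain volume follows the quadratic trajectory", {
  p <- published_truth()
  expect_equal(brain_volume(0, p), p$k0)
  expect_equal(brain_volume(50, p), 1516.5)            # 1500 + 242 - 225.5
  k2_45 <- k2_from_cag(45, 0.125, 2.74)
  expect_equal(brain_volume(50, p, k2 = k2_45), 1376.51745, tolerance = 1e-7)
  expect_error(brain_volume(-1, p), "non-negative")
})

test_that("neurodegeneration rate is the negative volume derivative", {
  p <- published_truth()
  expect_equal(neurodegeneration_rate(50, p), 4.18)    # -4.84 + 2*0.0902*50
  vertex <- p$k1 / (2 * p$k2)
  expect_equal(neurodegeneration_rate(vertex, p), 0)
  expect_equal(neurodegeneration_rate(56, p, k2 = k2_from_cag(45)),
               11.5336180, tolerance = 1e-7)
  # finite-difference check against the volume trajectory
  h <- 1e-6
  expect_equal(neurodegeneration_rate(60, p),
               -(brain_volume(60 + h, p) - brain_volume(60 - h, p)) / (2 * h),
               tolerance = 1e-6)
})

test_that("CAG power law on k2 matches worked values and is monotone", {
  expect_equal(k2_from_cag(42.5, 0.125, 2.74), 0.125)  # reference identity
  expect_equal(k2_from_cag(51, 0.125, 2.74), 0.20599972, tolerance = 1e-7)
  expect_equal(k2_from_cag(39, 0.125, 2.74), 0.09877371, tolerance = 1e-7)
  ks <- k2_from_cag(39:51, 0.125, 2.74)
  expect_true(all(diff(ks) > 0))
  expect_error(k2_from_cag(0), "positive")
})

test_that("NfL input rate clamps a growing brain to zero", {
  cb <- convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml")
  expect_equal(nfl_input_rate(cb, 0), 0)
  expect_equal(nfl_input_rate(cb, -1), 0)
  expect_equal(nfl_input_rate(1.5965e7, 4.18), 6.67337e7, tolerance = 1e-6)
})

test_that("unit conversions match hand values and round-trip", {
  expect_equal(convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml"), 1.59650e7)
  expect_equal(convert_brain_conc(0, "ug_per_g_to_pg_per_ml"), 0)
  x <- convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml")
  expect_equal(convert_brain_conc(x, "pg_per_ml_to_ug_per_g"), 15.5)
  expect_equal(convert_clearance(303), 159365.88)      # 303*60*24*365.25/1000
  expect_equal(convert_clearance(108), 56803.68)
  expect_equal(convert_clearance(0), 0)
})

test_that("quasi-steady-state CSF NfL matches worked values", {
  p <- published_truth()
  cl <- clearance_table()
  expect_equal(cnfl_csf_qss(50, p, cl, "HC"), 418.7452, tolerance = 1e-6)
  expect_equal(cnfl_csf_qss(56, p, cl, "manifestHD", cag = 45),
               3241.5895, tolerance = 1e-6)
  # below the vertex the clamped input gives zero concentration
  expect_equal(cnfl_csf_qss(20, p, cl, "HC"), 0)
  expect_error(cnfl_csf_qss(50, p, cl, "manifestHD"), "CAG")
  expect_error(cnfl_csf_qss(50, p, cl, "nosuch"), "unknown group")
})

test_that("QSS prediction is linear in brain concentration and 1/clearance", {
  p <- published_truth()
  p2 <- published_truth(); p2$cnfl_brain <- 2 * p$cnfl_brain
  cl <- clearance_table()
  cl_half <- clearance_table(HC = 2 * 303, preHD = 2 * 136,
                             manifestHD = 2 * 108)
  ages <- c(40, 55, 70)
  expect_equal(cnfl_csf_qss(ages, p2, cl, "HC"),
               2 * cnfl_csf_qss(ages, p, cl, "HC"))
  expect_equal(cnfl_csf_qss(ages, p, cl_half, "HC"),
               cnfl_csf_qss(ages, p, cl, "HC") / 2)
})

test_that("ODE solution reproduces analytic limits of the compartment", {
  cl <- clearance_table()
  comp <- csf_compartment(v_csf = 150, c0 = 0)
  CL <- clearance_ml_per_yr(cl, "HC")
  # constant input: steady state R/CL
  R <- 5e7
  sol <- cnfl_csf_ode(seq(0, 0.5, by = 0.001), comp = comp, group = "HC",
                      input_rate = function(t) R)
  expect_equal(sol$cnfl_csf[nrow(sol)], R / CL, tolerance = 1e-6)
  # zero input: exponential decay at rate CL/V_CSF
  comp2 <- csf_compartment(v_csf = 150, c0 = 400)
  tg <- seq(0, 0.005, by = 0.0005)
  sol2 <- cnfl_csf_ode(tg, comp = comp2, group = "HC",
                       input_rate = function(t) 0)
  expect_equal(sol2$cnfl_csf, 400 * exp(-CL / 150 * tg), tolerance = 1e-5)
  expect_error(cnfl_csf_ode(c(2, 1)), "increasing")
})

test_that("ODE started at the QSS value tracks the QSS curve", {
  p <- published_truth()
  cl <- clearance_table()
  for (case in list(list(g = "HC", cag = NA), list(g = "preHD", cag = 42),
                    list(g = "manifestHD", cag = 48))) {
    ages <- seq(37, 77, by = 0.5)
    qss0 <- cnfl_csf_qss(ages[1], p, cl, case$g, case$cag)
    sol <- cnfl_csf_ode(ages, p, cl, csf_compartment(150, qss0),
                        group = case$g, cag = case$cag)
    qss <- cnfl_csf_qss(ages, p, cl, case$g, case$cag)
    expect_lt(max(abs(sol$cnfl_csf - qss) / pmax(qss, 1)), 0.01)
  }
})

test_that("released NfL mass balances the volume lost", {
  p <- published_truth()
  cb <- convert_brain_conc(p$cnfl_brain, "ug_per_g_to_pg_per_ml")
  mass <- integrate(function(t)
    nfl_input_rate(cb, neurodegeneration_rate(t, p)), 40, 60,
    rel.tol = 1e-10)$value
  expect_equal(mass, cb * (brain_volume(40, p) - brain_volume(60, p)),
               tolerance = 1e-8)
})

test_that("parameter containers enforce their invariants", {
  expect_error(structural_params(k2 = -0.1))
  expect_error(structural_params(cnfl_brain = 0))
  expect_error(structural_params(cag_ref = 40), "42.5")
  expect_error(clearance_table(HC = 0))
  expect_error(csf_compartment(v_csf = 0))
  expect_silent(csf_compartment(c0 = 0))
})
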
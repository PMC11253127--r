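# Structural model: quadratic brain-volume trajectory, CAG covariate on the
# acceleration coefficient, and the quasi-steady-state CSF compartment.
# Canonical internal units are mL, yr and pg/mL; unit conversions happen at
# the boundary (convert_brain_conc, convert_clearance).

#' Days per year convention used throughout the package
#' @export
DAYS_PER_YEAR <- 365.25

#' Brain tissue density in g/mL
#'
#' Used to convert the brain NfL concentration between mass-per-gram-tissue
#' (ug/g) and mass-per-volume (pg/mL) units.
#' @export
BRAIN_DENSITY_G_PER_ML <- 1.03

#' Reference CAG repeat count of the HD-population covariate model
#' @export
CAG_REF <- 42.5

#' Default CSF compartment volume in mL (adult literature value)
#'
#' Only used by the full ODE form of the CSF compartment; the
#' quasi-steady-state solution is independent of it.
#' @export
V_CSF_DEFAULT <- 150

#' Canonical group labels
#' @export
GROUP_LEVELS <- c("HC", "preHD", "manifestHD")

#' Structural (fixed-effect) parameters of the NfL-atrophy model
#'
#' Bundles the coefficients of the quadratic brain-volume trajectory
#' \eqn{V(t) = k_0 + k_1 t - k_2 t^2}, the CAG power-law covariate on the
#' acceleration coefficient for HD subjects, and the brain NfL
#' concentration, together with the physical constants they rely on.
#' Defaults are the published population estimates for the HD-CSF cohort
#' (the intercept \code{k0} is a typical adjusted whole-brain volume; it
#' cancels from every NfL prediction).
#'
#' @param k0 brain volume intercept at age 0, mL.
#' @param k1 linear volume coefficient, mL/yr (shared across groups).
#' @param k2 quadratic (acceleration) coefficient for healthy controls,
#'   mL/yr^2. Must be positive: the trajectory is concave and the
#'   neurodegeneration rate accelerates.
#' @param k2_hd_pop HD-population acceleration coefficient at the reference
#'   CAG repeat count, mL/yr^2.
#' @param beta_cag dimensionless exponent of the CAG power law.
#' @param cag_ref reference CAG repeat count (42.5).
#' @param cnfl_brain NfL concentration in brain tissue, ug per g tissue.
#' @param density_brain brain tissue density, g/mL.
#' @return an object of class \code{structural_params}.
#' @examples
#' p <- structural_params()
#' brain_volume(50, p)
#' @export
structural_params <- function(k0 = 1500, k1 = 4.84, k2 = 0.0902,
                              k2_hd_pop = 0.125, beta_cag = 2.74,
                              cag_ref = CAG_REF, cnfl_brain = 15.5,
                              density_brain = BRAIN_DENSITY_G_PER_ML) {
  stopifnot(k2 > 0, k2_hd_pop > 0, cnfl_brain > 0, density_brain > 0)
  if (cag_ref != CAG_REF)
    stop("cag_ref must be ", CAG_REF, ": the covariate model is anchored there")
  structure(list(k0 = k0, k1 = k1, k2 = k2, k2_hd_pop = k2_hd_pop,
                 beta_cag = beta_cag, cag_ref = cag_ref,
                 cnfl_brain = cnfl_brain, density_brain = density_brain),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural parameters of the NfL-atrophy model\n")
  cat(sprintf("  k0         %10.4g mL      (volume intercept)\n", x$k0))
  cat(sprintf("  k1         %10.4g mL/yr   (shared linear coefficient)\n", x$k1))
  cat(sprintf("  k2 (HC)    %10.4g mL/yr^2\n", x$k2))
  cat(sprintf("  k2 (HD pop)%10.4g mL/yr^2 at CAG %.1f\n", x$k2_hd_pop, x$cag_ref))
  cat(sprintf("  beta_CAG   %10.4g\n", x$beta_cag))
  cat(sprintf("  cNfL_brain %10.4g ug/g    (density %.2f g/mL)\n",
              x$cnfl_brain, x$density_brain))
  invisible(x)
}

#' Per-group NfL clearance (net CSF flow) table
#'
#' NfL is assumed to be cleared from the CSF compartment by bulk CSF flow,
#' so the clearance equals the net CSF flow rate. Defaults are the median
#' MRI aqueduct-flow measurements: 303 uL/min in healthy controls, 136 in
#' premanifest HD and 108 in manifest HD. Clearance is held constant in age
#' within a group.
#'
#' @param HC,preHD,manifestHD clearance per group, uL/min; all positive.
#' @return an object of class \code{clearance_table} (named numeric vector
#'   in uL/min with a \code{days_per_year} attribute).
#' @examples
#' cl <- clearance_table()
#' clearance_ml_per_yr(cl, "HC")
#' @export
clearance_table <- function(HC = 303, preHD = 136, manifestHD = 108) {
  cl <- c(HC = HC, preHD = preHD, manifestHD = manifestHD)
  stopifnot(all(cl > 0))
  structure(cl, days_per_year = DAYS_PER_YEAR, class = "clearance_table")
}

#' @export
print.clearance_table <- function(x, ...) {
  cat("NfL clearance (net CSF flow), uL/min:\n")
  print(unclass(x)[GROUP_LEVELS])
  invisible(x)
}

#' CSF compartment description for the ODE model
#'
#' @param v_csf CSF compartment volume, mL (positive).
#' @param c0 initial NfL concentration in CSF, pg/mL (non-negative).
#' @return an object of class \code{csf_compartment}.
#' @export
csf_compartment <- function(v_csf = V_CSF_DEFAULT, c0 = 0) {
  stopifnot(v_csf > 0, c0 >= 0)
  structure(list(v_csf = v_csf, c0 = c0), class = "csf_compartment")
}

check_age <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("age t must be finite and non-negative")
  invisible(t)
}

#' Whole-brain volume at a given age
#'
#' Evaluates the quadratic trajectory \eqn{V(t) = k_0 + k_1 t - k_2 t^2}
#' with the healthy-control acceleration coefficient unless \code{k2} is
#' overridden (use [k2_from_cag()] for an HD subject).
#'
#' @param t age in years (vectorised, non-negative).
#' @param p a [structural_params()] object.
#' @param k2 optional acceleration coefficient overriding \code{p$k2},
#'   mL/yr^2.
#' @return volume in mL.
#' @export
brain_volume <- function(t, p = structural_params(), k2 = p$k2) {
  check_age(t)
  p$k0 + p$k1 * t - k2 * t^2
}

#' Neurodegeneration rate at a given age
#'
#' The negative rate of change of brain volume, \eqn{-dV/dt = -k_1 + 2 k_2 t}:
#' it increases linearly with age from the basal value \eqn{-k_1} with
#' acceleration \eqn{2 k_2}. Negative values (a growing brain, below the
#' parabola vertex at \eqn{t = k_1 / 2 k_2}) are returned as-is; the NfL
#' input rate clamps them to zero.
#'
#' @inheritParams brain_volume
#' @return rate in mL/yr (may be negative at young ages).
#' @export
neurodegeneration_rate <- function(t, p = structural_params(), k2 = p$k2) {
  check_age(t)
  -p$k1 + 2 * k2 * t
}

#' Acceleration coefficient for an HD subject from CAG repeat length
#'
#' Power-law covariate model \eqn{k_{2,i} = k_{2,pop} (CAG_i / 42.5)^{\beta}}:
#' longer CAG repeats mean faster acceleration of atrophy.
#'
#' @param cag CAG repeat count(s), positive.
#' @param k2_hd_pop HD-population coefficient at the reference CAG, mL/yr^2.
#' @param beta_cag dimensionless exponent.
#' @param cag_ref reference CAG repeat count.
#' @return k2 in mL/yr^2, strictly increasing in \code{cag} when
#'   \code{beta_cag > 0}.
#' @export
k2_from_cag <- function(cag, k2_hd_pop = 0.125, beta_cag = 2.74,
                        cag_ref = CAG_REF) {
  if (any(!is.finite(cag)) || any(cag <= 0))
    stop("cag must be finite and positive")
  stopifnot(k2_hd_pop > 0)
  k2_hd_pop * (cag / cag_ref)^beta_cag
}

#' Subject-level k2 given group and CAG
#'
#' Healthy controls use the HC coefficient; HD subjects the CAG power law.
#' @param group one of `r paste(GROUP_LEVELS, collapse = ", ")` (vectorised).
#' @param cag CAG repeat count, required for HD groups (NA allowed for HC).
#' @param p a [structural_params()] object.
#' @return k2 in mL/yr^2.
#' @export
k2_for_subject <- function(group, cag, p = structural_params()) {
  group <- as.character(group)
  bad <- !group %in% GROUP_LEVELS
  if (any(bad)) stop("unknown group: ", paste(unique(group[bad]), collapse = ", "))
  hd <- group != "HC"
  if (any(hd & (is.na(cag) | !is.finite(cag))))
    stop("CAG repeat count is required for HD subjects")
  k2 <- rep(p$k2, length(group))
  if (any(hd))
    k2[hd] <- k2_from_cag(cag[hd], p$k2_hd_pop, p$beta_cag, p$cag_ref)
  k2
}

#' NfL input rate into the CSF
#'
#' Mass balance: the NfL mass entering CSF per unit time is the brain NfL
#' concentration times the rate of volume loss. The relation only holds for
#' a shrinking brain, so negative rates contribute zero (neurons do not
#' absorb NfL).
#'
#' @param cnfl_brain_pg_per_ml brain NfL concentration in pg/mL (see
#'   [convert_brain_conc()]).
#' @param rate neurodegeneration rate, mL/yr (vectorised).
#' @return input rate in pg/yr, non-negative.
#' @export
nfl_input_rate <- function(cnfl_brain_pg_per_ml, rate) {
  stopifnot(all(cnfl_brain_pg_per_ml >= 0))
  cnfl_brain_pg_per_ml * pmax(rate, 0)
}

#' Quasi-steady-state CSF NfL concentration
#'
#' Because CSF turnover (hours) is fast relative to neurodegeneration
#' (years), the CSF compartment is effectively at steady state:
#' \eqn{c_{CSF}(t) = c_{Brain} \cdot (-dV/dt) / CL_{NfL}}. The input rate is
#' clamped at zero below the parabola vertex, so the prediction is always
#' non-negative.
#'
#' @param t age in years (vectorised).
#' @param p a [structural_params()] object.
#' @param cl a [clearance_table()].
#' @param group group label (scalar or vector matching \code{t}).
#' @param cag CAG repeat count, required for HD groups.
#' @return CSF NfL concentration in pg/mL.
#' @examples
#' cnfl_csf_qss(50, structural_params(), clearance_table(), "HC")
#' @export
cnfl_csf_qss <- function(t, p = structural_params(), cl = clearance_table(),
                         group = "HC", cag = NA_real_) {
  k2 <- k2_for_subject(group, cag, p)
  rate <- neurodegeneration_rate(t, p, k2 = k2)
  cb <- convert_brain_conc(p$cnfl_brain, "ug_per_g_to_pg_per_ml",
                           density = p$density_brain)
  nfl_input_rate(cb, rate) / clearance_ml_per_yr(cl, group)
}

#' Full one-compartment ODE for CSF NfL
#'
#' Integrates \eqn{dc/dt = [c_{Brain}(-dV/dt)_+ - CL \cdot c] / V_{CSF}}
#' from the initial concentration \code{comp$c0} over \code{t_grid}. The
#' equation is stiff on the year timescale (CSF turnover is about
#' \eqn{CL/V_{CSF} \approx 10^3}/yr), so it is solved with \code{deSolve}'s
#' implicit-capable \code{lsoda}. Used to verify that the quasi-steady-state
#' solution [cnfl_csf_qss()] is an accurate limit.
#'
#' @param t_grid strictly increasing ages, years.
#' @param p a [structural_params()] object.
#' @param cl a [clearance_table()].
#' @param comp a [csf_compartment()].
#' @param group scalar group label.
#' @param cag CAG repeat count, required for HD groups.
#' @param input_rate optional function \code{(t) -> pg/yr} overriding the
#'   structural input rate (for analytic checks).
#' @param clearance_ml_yr optional constant clearance override, mL/yr.
#' @return data frame with columns \code{age} and \code{cnfl_csf} (pg/mL).
#' @export
cnfl_csf_ode <- function(t_grid, p = structural_params(),
                         cl = clearance_table(), comp = csf_compartment(),
                         group = "HC", cag = NA_real_,
                         input_rate = NULL, clearance_ml_yr = NULL) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  if (is.null(clearance_ml_yr))
    clearance_ml_yr <- clearance_ml_per_yr(cl, group)
  if (is.null(input_rate)) {
    k2 <- k2_for_subject(group, cag, p)
    cb <- convert_brain_conc(p$cnfl_brain, "ug_per_g_to_pg_per_ml",
                             density = p$density_brain)
    input_rate <- function(t) nfl_input_rate(cb, neurodegeneration_rate(t, p, k2 = k2))
  }
  deriv <- function(t, y, parms) {
    list((input_rate(t) - clearance_ml_yr * y[1]) / comp$v_csf)
  }
  sol <- deSolve::lsoda(y = c(cnfl = comp$c0), times = t_grid, func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-8)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE solver failed (istate = ", diagn[1], "); see deSolve::diagnostics")
  data.frame(age = sol[, "time"], cnfl_csf = pmax(sol[, "cnfl"], 0))
}

#' Convert brain NfL concentration between ug/g and pg/mL
#'
#' A concentration of \eqn{x} ug per g tissue equals
#' \eqn{x \cdot \rho \cdot 10^6} pg per mL with tissue density \eqn{\rho}
#' in g/mL. The round trip is the identity.
#'
#' @param value concentration(s), non-negative.
#' @param direction \code{"ug_per_g_to_pg_per_ml"} or
#'   \code{"pg_per_ml_to_ug_per_g"}.
#' @param density tissue density, g/mL.
#' @return converted concentration.
#' @examples
#' convert_brain_conc(15.5, "ug_per_g_to_pg_per_ml")  # 1.5965e7 pg/mL
#' @export
convert_brain_conc <- function(value,
                               direction = c("ug_per_g_to_pg_per_ml",
                                             "pg_per_ml_to_ug_per_g"),
                               density = BRAIN_DENSITY_G_PER_ML) {
  stopifnot(all(value >= 0), density > 0)
  direction <- match.arg(direction)
  if (direction == "ug_per_g_to_pg_per_ml") value * density * 1e6
  else value / (density * 1e6)
}

#' Convert a clearance from uL/min to mL/yr
#'
#' Unit bridge between the flow-rate literature (uL/min) and the model's
#' year-based units: \eqn{1\ uL/min = 60 \cdot 24 \cdot 365.25 / 1000}
#' mL/yr = 525.96 mL/yr.
#'
#' @param cl_ul_per_min clearance(s) in uL/min, non-negative.
#' @return clearance in mL/yr.
#' @export
convert_clearance <- function(cl_ul_per_min) {
  stopifnot(all(cl_ul_per_min >= 0))
  cl_ul_per_min * 60 * 24 * DAYS_PER_YEAR / 1000
}

#' Group clearance in mL/yr
#'
#' @param cl a [clearance_table()].
#' @param group group label(s).
#' @return clearance in mL/yr.
#' @export
clearance_ml_per_yr <- function(cl, group) {
  group <- as.character(group)
  bad <- !group %in% names(cl)
  if (any(bad)) stop("unknown group: ", paste(unique(group[bad]), collapse = ", "))
  unname(convert_clearance(unclass(cl)[group]))
}
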
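# Synthetic HD-CSF-like cohorts: subjects with random effects, forward
# simulation through the structural model, and observational noise, in the
# exact tabular schema of the real study.

HDCSF_SCHEMA <- c("ID", "sample_day", "gender", "CAG", "age", "group",
                  "wb_adj", "NfL_CSF2")

#' Cohort design for the synthetic-data generator
#'
#' Defaults emulate the HD-CSF study: 20 healthy controls (mean baseline
#' age 50.7 yr), 20 premanifest HD (mean age 42.4 yr, mean CAG 42.0) and 40
#' manifest HD (mean age 56.0 yr, mean CAG 42.75), each seen at baseline
#' and a 24-month follow-up, with a small probability that the follow-up
#' visit is missing. Baseline ages are normal, truncated to the study's
#' observed range 26--77 yr; CAG repeats are a shifted binomial on 39--51
#' matched to the group means.
#'
#' @param n per-group sizes, named numeric (HC, preHD, manifestHD).
#' @param age_mean per-group mean baseline age, yr.
#' @param age_sd baseline age standard deviation, yr (common).
#' @param age_range truncation range for baseline age, yr.
#' @param cag_mean mean CAG repeats for the HD groups.
#' @param cag_range admissible CAG range.
#' @param visit_days visit schedule in days since baseline.
#' @param dropout probability that each post-baseline visit is missing.
#' @param replicate integer scale factor multiplying every group size
#'   (recovery studies use larger cohorts to shrink Monte-Carlo error).
#' @return an object of class \code{cohort_design}.
#' @export
cohort_design <- function(n = c(HC = 20, preHD = 20, manifestHD = 40),
                          age_mean = c(HC = 50.7, preHD = 42.4, manifestHD = 56.0),
                          age_sd = 8,
                          age_range = c(26, 77),
                          cag_mean = c(preHD = 42.0, manifestHD = 42.75),
                          cag_range = c(39, 51),
                          visit_days = c(0, 730),
                          dropout = 0.1,
                          replicate = 1) {
  stopifnot(all(n >= 1), replicate >= 1, age_sd >= 0,
            dropout >= 0, dropout < 1,
            age_range[1] < age_range[2], cag_range[1] <= cag_range[2],
            visit_days[1] == 0)
  n <- round(n * replicate)
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, cag_mean = cag_mean,
                 cag_range = cag_range, visit_days = sort(visit_days),
                 dropout = dropout),
            class = "cohort_design")
}

#' Between-subject random-effect specification
#'
#' An additive normal effect on the volume intercept \code{k0} (residual
#' head-size variation that survives intracranial-volume adjustment) and a
#' log-normal effect on the acceleration coefficient \code{k2}
#' (\eqn{k_{2,i} = k_2 e^{\eta}}, keeping it positive).
#'
#' @param omega_k0 SD of the additive effect on k0, mL.
#' @param omega_k2 SD of the log-scale effect on k2.
#' @return an object of class \code{random_effects_spec}.
#' @export
random_effects_spec <- function(omega_k0 = 40, omega_k2 = 0.3) {
  stopifnot(omega_k0 >= 0, omega_k2 >= 0)
  structure(list(omega_k0 = omega_k0, omega_k2 = omega_k2),
            class = "random_effects_spec")
}

#' Observational error model
#'
#' CSF NfL is measured with error proportional to the measured value
#' (default coefficient 0.216, a CV of about 22\%); adjusted whole-brain
#' volume with additive error (default SD 11 mL).
#'
#' @param sigma_prop_nfl proportional error coefficient on NfL.
#' @param sigma_add_vol additive error SD on volume, mL.
#' @return an object of class \code{error_model_spec}.
#' @export
error_model_spec <- function(sigma_prop_nfl = 0.216, sigma_add_vol = 11) {
  stopifnot(sigma_prop_nfl >= 0, sigma_add_vol >= 0)
  structure(list(sigma_prop_nfl = sigma_prop_nfl,
                 sigma_add_vol = sigma_add_vol),
            class = "error_model_spec")
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# CAG repeats: shifted binomial on [lo, hi] with the requested mean.
sample_cag <- function(n, mean, range) {
  size <- range[2] - range[1]
  p <- (mean - range[1]) / size
  stopifnot(p > 0, p < 1)
  range[1] + rbinom(n, size = size, prob = p)
}

#' Draw a cohort of subjects with individual parameters
#'
#' Samples group membership sizes, sex, baseline age and (for HD groups)
#' CAG repeat length from the design, then attaches individual parameter
#' realisations: \code{k0_i = k0 + eta0} and
#' \code{k2_i = k2(group, CAG) * exp(eta2)}.
#'
#' @param design a [cohort_design()].
#' @param re a [random_effects_spec()].
#' @param truth a [structural_params()] object (generating values).
#' @param seed integer seed; required for reproducibility.
#' @return data frame of class \code{nfl_subjects}, one row per subject:
#'   \code{ID, group, gender, CAG, age0, k0_i, k2_i}.
#' @export
sample_subjects <- function(design = cohort_design(),
                            re = random_effects_spec(),
                            truth = structural_params(),
                            seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  set.seed(seed)
  groups <- rep(names(design$n), design$n)
  n <- length(groups)
  age0 <- numeric(n)
  for (g in names(design$n)) {
    idx <- groups == g
    age0[idx] <- rnorm_trunc(sum(idx), design$age_mean[[g]], design$age_sd,
                             design$age_range[1], design$age_range[2])
  }
  cag <- rep(NA_real_, n)
  for (g in names(design$cag_mean)) {
    idx <- groups == g
    cag[idx] <- sample_cag(sum(idx), design$cag_mean[[g]], design$cag_range)
  }
  eta0 <- rnorm(n, 0, re$omega_k0)
  eta2 <- rnorm(n, 0, re$omega_k2)
  k2_pop <- k2_for_subject(groups, cag, truth)
  out <- data.frame(
    ID = sprintf("S%04d", seq_len(n)),
    group = groups,
    gender = sample(c("F", "M"), n, replace = TRUE),
    CAG = cag,
    age0 = age0,
    k0_i = truth$k0 + eta0,
    k2_i = k2_pop * exp(eta2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("nfl_subjects", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Simulate longitudinal observations in the HD-CSF schema
#'
#' Pushes each subject through the structural model at every scheduled
#' visit: the true volume from the quadratic trajectory with the subject's
#' individual parameters, the true CSF NfL from the quasi-steady-state
#' solution, then observational noise — additive normal on volume,
#' proportional normal on NfL (floored at 1 pg/mL so concentrations stay
#' physical). Post-baseline visits are dropped independently with the
#' design's dropout probability.
#'
#' @param subjects output of [sample_subjects()].
#' @param truth a [structural_params()] object.
#' @param cl a [clearance_table()].
#' @param err an [error_model_spec()].
#' @param design the [cohort_design()] providing the visit schedule.
#' @param seed integer seed for the observation-level noise.
#' @return data frame in the HD-CSF schema (\code{ID, sample_day, gender,
#'   CAG, age, group, wb_adj, NfL_CSF2}); the per-subject truth is attached
#'   as attribute \code{"truth"}.
#' @export
simulate_observations <- function(subjects, truth = structural_params(),
                                  cl = clearance_table(),
                                  err = error_model_spec(),
                                  design = cohort_design(),
                                  seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(inherits(subjects, "nfl_subjects") || all(
    c("ID", "group", "gender", "CAG", "age0", "k0_i", "k2_i") %in% names(subjects)))
  set.seed(seed)
  visits <- design$visit_days
  n <- nrow(subjects)
  long <- subjects[rep(seq_len(n), each = length(visits)), , drop = FALSE]
  long$sample_day <- rep(visits, times = n)
  keep <- long$sample_day == 0 | runif(nrow(long)) >= design$dropout
  long <- long[keep, , drop = FALSE]

  age <- long$age0 + long$sample_day / DAYS_PER_YEAR
  vol_true <- long$k0_i + truth$k1 * age - long$k2_i * age^2
  cb <- convert_brain_conc(truth$cnfl_brain, "ug_per_g_to_pg_per_ml",
                           density = truth$density_brain)
  rate <- -truth$k1 + 2 * long$k2_i * age
  nfl_true <- nfl_input_rate(cb, rate) / clearance_ml_per_yr(cl, long$group)

  wb_adj <- vol_true + rnorm(nrow(long), 0, err$sigma_add_vol)
  nfl_obs <- pmax(nfl_true * (1 + rnorm(nrow(long), 0, err$sigma_prop_nfl)), 1)

  out <- data.frame(
    ID = long$ID, sample_day = long$sample_day, gender = long$gender,
    CAG = long$CAG, age = age, group = long$group,
    wb_adj = wb_adj, NfL_CSF2 = nfl_obs,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "truth") <- list(params = truth, subjects = subjects,
                             error = err, seed = seed)
  out
}

#' Write a simulated dataset with its truth sidecars
#'
#' Writes the dataset CSV in the HD-CSF schema, a companion CSV of
#' per-subject true parameters (for recovery scoring) and a JSON sidecar
#' recording the seed and generating parameters.
#'
#' @param dataset output of [simulate_observations()].
#' @param path output CSV path; sidecars get \code{_truth.csv} and
#'   \code{_meta.json} suffixes.
#' @return invisibly, the paths written.
#' @export
write_simulated_cohort <- function(dataset, path) {
  write.csv(dataset[, HDCSF_SCHEMA], path, row.names = FALSE, quote = FALSE)
  truth <- attr(dataset, "truth")
  paths <- path
  if (!is.null(truth)) {
    tpath <- sub("\\.csv$", "", path)
    truth_csv <- paste0(tpath, "_truth.csv")
    meta_json <- paste0(tpath, "_meta.json")
    write.csv(truth$subjects, truth_csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = truth$seed,
           params = unclass(truth$params),
           error = unclass(truth$error)),
      meta_json, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth_csv, meta_json)
  }
  invisible(paths)
}
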
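# Model-evaluation surfaces: simulation-based prediction bands, the CAG
# sweep of the neurodegeneration rate, and standardized residuals.

# Typical-subject (zero random effect, zero noise) predictions for a
# parameter list in the fit's natural-scale form; works for both the
# quadratic and the linear (k2 = 0) volume model.
predict_typical <- function(params, spec, cl, group, cag, age) {
  k2 <- k2_population(params, spec, group, cag)
  vol <- params$k0 + params$k1 * age - k2 * age^2
  cb <- convert_brain_conc(params$cnfl_brain, "ug_per_g_to_pg_per_ml")
  nfl <- cb * pmax(-params$k1 + 2 * k2 * age, 0) / clearance_ml_per_yr(cl, group)
  list(volume = vol, nfl = nfl, k2 = k2)
}

#' Covariate-conditional prediction band
#'
#' Simulates \code{n_sim} virtual subjects of the given group (and CAG, for
#' HD groups) from the fitted population distribution — random effects on
#' the intercept and acceleration plus observational error — and returns
#' pointwise quantiles of the simulated observations over the age grid.
#' The median curve is the typical-subject trajectory (zero random effects,
#' zero noise), the convention used for reporting. Because observational
#' error is included, the band bounds future observations, not the latent
#' trajectory.
#'
#' @param fit a converged \code{fit_result} from [fit_nfl_model()], or a
#'   named list of natural-scale parameters plus \code{spec}/\code{cl}
#'   supplied separately.
#' @param group group label.
#' @param cag CAG repeat count (required for HD groups; group-typical
#'   values are 42.0 for premanifest and 42.75 for manifest HD).
#' @param age_grid ages (years) at which to evaluate the band.
#' @param response \code{"nfl"} (pg/mL) or \code{"volume"} (mL).
#' @param level band level in (0, 1); default 0.9.
#' @param n_sim number of simulated subjects (at least 100).
#' @param seed integer seed.
#' @return data frame of class \code{prediction_band}: \code{age},
#'   \code{median}, \code{lower}, \code{upper}, with the context recorded
#'   in attributes.
#' @export
prediction_band <- function(fit, group = "HC", cag = NA_real_,
                            age_grid = seq(30, 77, by = 1),
                            response = c("nfl", "volume"),
                            level = 0.9, n_sim = 2000, seed = 1) {
  response <- match.arg(response)
  if (n_sim < 100) stop("n_sim < 100 is statistically meaningless")
  stopifnot(level > 0, level < 1)
  if (inherits(fit, "fit_result")) {
    if (!isTRUE(fit$converged)) stop("fit did not converge")
    params <- fit$params; spec <- fit$spec; cl <- fit$cl
  } else { params <- fit$params; spec <- fit$spec; cl <- fit$cl }
  if (group != "HC" && !is.finite(cag))
    stop("CAG repeat count required for HD groups")

  set.seed(seed)
  ng <- length(age_grid)
  eta0 <- rnorm(n_sim, 0, params$omega_k0)
  eta2 <- rnorm(n_sim, 0, params$omega_k2)
  k2_pop <- k2_population(params, spec, group, cag)
  k2_i <- k2_pop * exp(eta2)
  A <- matrix(age_grid, n_sim, ng, byrow = TRUE)
  if (response == "volume") {
    Y <- (params$k0 + eta0) + params$k1 * A - k2_i * A^2 +
      rnorm(n_sim * ng, 0, params$sigma_add_vol)
  } else {
    cb <- convert_brain_conc(params$cnfl_brain, "ug_per_g_to_pg_per_ml")
    G <- cb * pmax(-params$k1 + 2 * k2_i * A, 0) /
      clearance_ml_per_yr(cl, group)
    Y <- pmax(G * (1 + rnorm(n_sim * ng, 0, params$sigma_prop_nfl)), 1)
  }
  qs <- apply(Y, 2, quantile, probs = c((1 - level) / 2, (1 + level) / 2))
  typ <- predict_typical(params, spec, cl, group, cag, age_grid)
  out <- data.frame(age = age_grid,
                    median = if (response == "volume") typ$volume else typ$nfl,
                    lower = qs[1, ], upper = qs[2, ])
  structure(out, class = c("prediction_band", "data.frame"),
            context = list(group = group, cag = cag, response = response,
                           level = level, n_sim = n_sim, seed = seed))
}

#' Neurodegeneration rate as a function of age and CAG repeat length
#'
#' Tabulates the model's neurodegeneration rate \eqn{-k_1 + 2 k_2 t} over
#' an age grid for healthy controls and for HD subjects across a range of
#' CAG repeat lengths (via the power-law covariate). At any fixed age the
#' rate increases monotonically with CAG.
#'
#' @param params a [structural_params()] object or the \code{params} list
#'   of a \code{fit_result}.
#' @param age_grid ages, years.
#' @param cag_values CAG repeat counts for the HD curves (default 39--51,
#'   the study's observed range).
#' @return tidy data frame: \code{age}, \code{group} ("HC" or "HD"),
#'   \code{CAG} (NA for HC), \code{k2}, \code{rate} (mL/yr).
#' @export
cag_rate_sweep <- function(params = structural_params(),
                           age_grid = seq(30, 77, by = 1),
                           cag_values = 39:51) {
  if (inherits(params, "fit_result")) params <- params$params
  k2_hc <- if (!is.null(params$k2_hc)) params$k2_hc else params$k2
  if (any(cag_values < 30 | cag_values > 70))
    stop("cag_values outside the plausible range 30-70")
  k2_hd <- k2_from_cag(cag_values, params$k2_hd_pop, params$beta_cag)
  grid <- rbind(
    data.frame(group = "HC", CAG = NA_real_, k2 = k2_hc),
    data.frame(group = "HD", CAG = cag_values, k2 = k2_hd))
  out <- merge(data.frame(age = age_grid), grid)
  out$rate <- -params$k1 + 2 * out$k2 * out$age
  out[order(out$group, out$CAG, out$age),
      c("age", "group", "CAG", "k2", "rate")]
}

#' Individual weighted residuals for both observation streams
#'
#' Computes residuals at the empirical-Bayes individual parameters:
#' volume residuals are standardized by the additive error SD, NfL
#' residuals by the proportional error (\eqn{(y - \hat y)/(\sigma_p \hat y)}).
#' On well-specified data both streams should have mean about 0 and SD
#' about 1.
#'
#' @param dataset the dataset that was fitted (HD-CSF schema with
#'   \code{age}).
#' @param fit a converged \code{fit_result}.
#' @return list with \code{residuals} (per-observation data frame:
#'   \code{ID, age, group, stream, observed, predicted, iwres}) and
#'   \code{summary} (per-stream mean and SD).
#' @export
residual_report <- function(dataset, fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  params <- fit$params
  eb <- fit$ranef
  i <- match(dataset$ID, eb$ID)
  if (any(is.na(i))) stop("dataset contains subjects absent from the fit")
  k0_i <- eb$k0_i[i]; k2_i <- eb$k2_i[i]
  age <- dataset$age
  pred_v <- k0_i + params$k1 * age - k2_i * age^2
  cb <- convert_brain_conc(params$cnfl_brain, "ug_per_g_to_pg_per_ml")
  pred_c <- pmax(cb * pmax(-params$k1 + 2 * k2_i * age, 0) /
                   clearance_ml_per_yr(fit$cl, dataset$group), NFL_PRED_FLOOR)
  res <- rbind(
    data.frame(ID = dataset$ID, age = age, group = dataset$group,
               stream = "volume", observed = dataset$wb_adj,
               predicted = pred_v,
               iwres = (dataset$wb_adj - pred_v) / params$sigma_add_vol,
               stringsAsFactors = FALSE),
    data.frame(ID = dataset$ID, age = age, group = dataset$group,
               stream = "nfl", observed = dataset$NfL_CSF2,
               predicted = pred_c,
               iwres = (dataset$NfL_CSF2 - pred_c) /
                 (params$sigma_prop_nfl * pred_c),
               stringsAsFactors = FALSE))
  res <- res[!is.na(res$observed), ]
  summ <- aggregate(iwres ~ stream, data = res,
                    FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summ <- data.frame(stream = summ$stream,
                     mean = summ$iwres[, "mean"], sd = summ$iwres[, "sd"],
                     n = summ$iwres[, "n"])
  list(residuals = res, summary = summ)
}
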
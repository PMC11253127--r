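# Joint population fit of the volume and NfL observation streams, the
# two-stage cross-check estimator, and corrected-BIC model comparison.

#' Model specification for the joint fit
#'
#' @param volume_model \code{"quadratic"} (the full model) or
#'   \code{"linear"} (the rejected alternative, \eqn{k_2 \equiv 0}; the
#'   predicted NfL concentration is then constant in age).
#' @param cag_covariate apply the CAG power law to \eqn{k_2} for HD
#'   subjects (ignored for the linear model).
#' @param random_effects estimate between-subject variability (additive on
#'   the volume intercept, log-normal on the acceleration).
#' @return an object of class \code{model_spec}. The linear volume
#'   coefficient is always shared across groups.
#' @export
model_spec <- function(volume_model = c("quadratic", "linear"),
                       cag_covariate = TRUE,
                       random_effects = TRUE) {
  volume_model <- match.arg(volume_model)
  if (volume_model == "linear") cag_covariate <- FALSE
  structure(list(volume_model = volume_model,
                 cag_covariate = cag_covariate,
                 random_effects = random_effects),
            class = "model_spec")
}

# Flatten the padded per-subject matrices back to long format.
fd_long <- function(fd) {
  df <- data.frame(age = as.vector(fd$T), vol = as.vector(fd$Yv),
                   nfl = as.vector(fd$Yc),
                   group = rep(fd$group, ncol(fd$T)),
                   cag = rep(fd$cag, ncol(fd$T)),
                   sid = rep(seq_len(fd$n), ncol(fd$T)))
  df[!is.na(df$age), ]
}

# Within-subject volume slopes (first to last visit) with subject mid-age;
# NULL when the data are essentially cross-sectional.
slope_summary <- function(fd) {
  dv <- fd_long(fd)
  dv <- dv[!is.na(dv$vol), ]
  per <- split(dv, dv$sid)
  multi <- vapply(per, nrow, integer(1)) >= 2
  if (sum(multi) < 3 * length(unique(dv$group))) return(NULL)
  sl <- t(vapply(per[multi], function(r) {
    i <- c(which.min(r$age), which.max(r$age))
    c(slope = (r$vol[i[2]] - r$vol[i[1]]) / (r$age[i[2]] - r$age[i[1]]),
      mid = mean(r$age))
  }, numeric(2)))
  ids <- as.integer(names(per[multi]))
  data.frame(slope = sl[, 1], mid = sl[, 2],
             group = fd$group[ids], cag = fd$cag[ids],
             stringsAsFactors = FALSE)
}

# Moment-style fit of the volume trajectory. The linear coefficient k1 is
# identified longitudinally: each subject's observed volume change per year
# equals k1 - 2 k2 * midage, so a regression of within-subject slopes on
# mid-age (with group-specific slopes) recovers k1 as the common intercept
# and each group's acceleration from the age trend. Because that intercept
# is a long extrapolation (mid-ages sit 30-80 years from zero) it is noisy;
# k1_fix overrides it so callers can profile along the weak direction.
# Per-subject (eta0_i, k2_i) then solve the subject's own least-squares
# problem given k1. Exact on noise-free data.
volume_moment_fit <- function(fd, quad, k1_fix = NULL) {
  dv <- fd_long(fd)
  dv <- dv[!is.na(dv$vol), ]
  per <- split(dv, dv$sid)
  sdf <- slope_summary(fd)
  if (!is.null(sdf)) {
    if (quad) {
      k1 <- if (!is.null(k1_fix)) k1_fix
      else unname(coef(lm(slope ~ mid:group, data = sdf))["(Intercept)"])
      # refine by nonlinear least squares on the slope equation with the
      # CAG structure: slope_i = k1 - 2 k2(group_i, CAG_i) mid_i. The plain
      # interaction regression is inconsistent when k2 varies with CAG
      # within a group (the k2 deviations act as residuals correlated with
      # mid-age); the structured fit is exact on clean data.
      hd <- sdf$group != "HC"
      has_hc <- any(!hd)
      use_beta <- any(hd) && length(unique(sdf$cag[hd])) > 1
      k2h0 <- if (has_hc)
        max(sum(sdf$mid[!hd] * (k1 - sdf$slope[!hd])) /
              (2 * sum(sdf$mid[!hd]^2)), 1e-4) else 0.05
      k2d0 <- if (any(hd))
        max(sum(sdf$mid[hd] * (k1 - sdf$slope[hd])) /
              (2 * sum(sdf$mid[hd]^2)), 1e-4) else 0.05
      free <- c(if (is.null(k1_fix)) "k1", if (has_hc) "lkh",
                if (any(hd)) "lkd", if (use_beta) "beta")
      full <- c(k1 = k1, lkh = log(k2h0), lkd = log(k2d0), beta = 1)
      k2_of <- function(th) ifelse(hd, exp(th["lkd"]) *
                                     (if (use_beta)
                                       (sdf$cag / CAG_REF)^th["beta"] else 1),
                                   exp(th["lkh"]))
      ss <- function(x) {
        th <- full; th[free] <- x
        sum((sdf$slope - (th["k1"] - 2 * k2_of(th) * sdf$mid))^2)
      }
      o <- nlminb(full[free], ss,
                  control = list(rel.tol = 1e-14, iter.max = 500))
      full[free] <- o$par
      k1 <- unname(full["k1"])
      k2s <- k2_of(full)
      k2_g <- vapply(split(k2s, sdf$group), mean, numeric(1))
      resid_sl <- sdf$slope - (k1 - 2 * k2s * sdf$mid)
    } else {
      k1 <- if (!is.null(k1_fix)) k1_fix else mean(sdf$slope)
      k2_g <- setNames(rep(0, length(unique(sdf$group))), unique(sdf$group))
      resid_sl <- sdf$slope - k1
    }
  } else {
    # cross-sectional fallback: pooled polynomial least squares
    f <- if (quad) vol ~ age + I(age^2) else vol ~ age
    cf <- coef(lm(f, data = dv))
    k1 <- if (!is.null(k1_fix)) k1_fix else unname(cf[2])
    k2 <- if (quad) max(-unname(cf[3]), 1e-4) else 0
    k2_g <- setNames(rep(k2, length(unique(dv$group))), unique(dv$group))
    resid_sl <- numeric(0)
  }
  miss_g <- setdiff(unique(dv$group), names(k2_g))
  if (length(miss_g)) k2_g[miss_g] <- mean(k2_g)
  # per-subject least squares given k1: regress (V - k1 t) on t^2.
  # Single-visit subjects get the group-level k2 imputed; they are
  # excluded from the intercept and covariate stages (k2_fit marks the
  # data-driven estimates).
  k2_i <- eta0_raw <- rep(NA_real_, fd$n)
  k2_fit <- rep(FALSE, fd$n)
  for (s in names(per)) {
    r <- per[[s]]; i <- as.integer(s)
    y <- r$vol - k1 * r$age
    if (quad && nrow(r) >= 2) {
      x <- r$age^2
      b <- -sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      k2_i[i] <- b
      eta0_raw[i] <- mean(y) + b * mean(x)
      k2_fit[i] <- TRUE
    } else {
      k2_i[i] <- if (quad) k2_g[[fd$group[i]]] else 0
      eta0_raw[i] <- mean(y + k2_i[i] * r$age^2)
      k2_fit[i] <- !quad && nrow(r) >= 1
    }
  }
  k0 <- if (any(k2_fit)) mean(eta0_raw[k2_fit]) else mean(eta0_raw, na.rm = TRUE)
  list(k0 = k0, k1 = k1, k2_g = k2_g, k2_i = k2_i, k2_fit = k2_fit,
       eta0_i = eta0_raw - k0, slope_resid = resid_sl, nv = fd$nv)
}

# Starting values for the marginal-likelihood optimizer: volume moments,
# CAG regression on per-subject accelerations, QSS inversion for the brain
# NfL concentration, robust (median-based) scale estimates. Overridable.
default_start <- function(fd, spec, cl, k1_fix = NULL) {
  quad <- spec$volume_model == "quadratic"
  vm <- volume_moment_fit(fd, quad, k1_fix = k1_fix)
  st <- list(k0 = vm$k0, k1 = vm$k1, k2_hc = 0.05, k2_hd_pop = 0.1,
             beta_cag = 1, cnfl_brain = 15, omega_k0 = 30, omega_k2 = 0.3,
             sigma_prop_nfl = 0.2, sigma_add_vol = 10)
  if (quad) {
    if ("HC" %in% names(vm$k2_g)) st$k2_hc <- vm$k2_g[["HC"]]
    grp <- fd$group
    hd <- grp != "HC" & vm$k2_fit & !is.na(vm$k2_i) & vm$k2_i > 0
    if (any(hd)) {
      lk <- log(vm$k2_i[hd]); lc <- log(fd$cag[hd] / CAG_REF)
      if (spec$cag_covariate && length(unique(lc)) > 1) {
        b <- coef(lm(lk ~ lc))
        st$k2_hd_pop <- exp(unname(b[1]))
        st$beta_cag <- min(max(unname(b[2]), 0), 10)
      } else st$k2_hd_pop <- exp(mean(lk))
      st$omega_k2 <- max(min(sd(lk), 2), 0.05)
    }
  }
  if (sum(!is.na(vm$eta0_i)) > 2)
    st$omega_k0 <- max(min(sd(vm$eta0_i, na.rm = TRUE), 300), 1)
  if (length(vm$slope_resid) > 2) {
    dt <- 2  # typical follow-up interval, yr
    st$sigma_add_vol <-
      max(min(mad(vm$slope_resid, center = 0) * dt / sqrt(2), 100), 1)
  }
  # NfL stream: invert the QSS relation at per-subject rates
  dn <- fd_long(fd)
  dn <- dn[!is.na(dn$nfl), ]
  k2n <- if (quad) {
    v <- vm$k2_i[dn$sid]
    pop <- ifelse(dn$group == "HC", st$k2_hc,
                  st$k2_hd_pop * (dn$cag / CAG_REF)^
                    (if (spec$cag_covariate) st$beta_cag else 0))
    ifelse(is.na(v) | v <= 0, pop, v)
  } else rep(0, nrow(dn))
  rate <- -st$k1 + 2 * k2n * dn$age
  ok <- rate > 0.5
  if (any(ok)) {
    clr <- clearance_ml_per_yr(cl, dn$group[ok])
    cb <- median(dn$nfl[ok] * clr / rate[ok])
    st$cnfl_brain <- convert_brain_conc(cb, "pg_per_ml_to_ug_per_g")
    g <- cb * rate[ok] / clr
    st$sigma_prop_nfl <-
      max(min(mad((dn$nfl[ok] - g) / g, center = 0), 2), 0.02)
  }
  st
}

#' Fit the joint NfL-atrophy mixed-effects model
#'
#' Maximises the marginal likelihood of both observation streams — brain
#' volumes with additive-normal error, CSF NfL with proportional-normal
#' error — over the structural fixed effects, the random-effect SDs and
#' the error magnitudes. The intercept random effect is integrated out
#' analytically; the log-normal acceleration effect by a log-scale
#' trapezoid rule over mode-centred and prior-spanning nodes
#' (\code{n_nodes = 1} gives the Laplace approximation). Per-group
#' clearances are fixed, never estimated.
#' Positive parameters are estimated on the log scale.
#'
#' @param dataset data frame in the HD-CSF schema with an \code{age}
#'   column (see [read_hdcsf_csv()] or [simulate_observations()]).
#' @param spec a [model_spec()].
#' @param cl a [clearance_table()]; its values are fixed constants of the
#'   fit.
#' @param start optional named list of natural-scale starting values
#'   overriding the data-driven defaults.
#' @param n_nodes number of mode-centred integration nodes (1 = Laplace).
#' @param fix optional named list of parameters to hold at given values
#'   instead of estimating them (e.g. known error magnitudes).
#' @param se compute standard errors from the observed information
#'   (adds a numerical Hessian; disable for speed in simulation loops).
#' @param control list passed to [stats::nlminb()]; defaults
#'   \code{rel.tol = 1e-8}, \code{iter.max = 150}. The iteration caps are
#'   set so a replicated-cohort fit completes in minutes; along the flat
#'   basal-rate/acceleration ridge, movement beyond them is far smaller
#'   than the sampling uncertainty.
#' @return an object of class \code{fit_result}: \code{estimates} (data
#'   frame of natural-scale estimates and SEs), \code{loglik}, \code{bicc},
#'   \code{converged}, \code{ranef} (empirical-Bayes per-subject
#'   estimates), plus the spec, clearances and optimizer metadata.
#' @examples
#' \donttest{
#' subj <- sample_subjects(cohort_design(), seed = 1)
#' dat <- simulate_observations(subj, seed = 2)
#' fit <- fit_nfl_model(dat)
#' fit$estimates
#' }
#' @export
fit_nfl_model <- function(dataset, spec = model_spec(),
                          cl = clearance_table(), start = NULL,
                          n_nodes = 31, fix = NULL, se = TRUE,
                          control = list()) {
  fd <- prepare_fit_data(dataset)
  if (min(table(fd$group)) < 2)
    stop("need at least 2 subjects per represented group")
  skel <- build_skeleton(spec, unique(fd$group))
  st <- default_start(fd, spec, cl)
  if (!is.null(start)) st <- modifyList(st, start)
  if (!spec$random_effects) { st$omega_k0 <- 0; st$omega_k2 <- 0 }
  if (!is.null(fix)) {
    skel$free <- setdiff(skel$free, names(fix))
    skel$log_scale <- setdiff(skel$log_scale, names(fix))
    st <- modifyList(st, fix)
  }
  skel$fixed <- modifyList(skel$fixed, st[setdiff(names(st), skel$free)])

  ctrl <- modifyList(list(rel.tol = 1e-8, iter.max = 150, eval.max = 2000),
                     control)
  # physiologically generous box bounds on the estimation scale keep the
  # optimizer out of degenerate regions (e.g. explaining NfL as pure noise
  # around a vanishing prediction)
  bounds <- list(
    k0 = c(0, 1e4), k1 = c(-100, 100), k2_hc = log(c(1e-5, 10)),
    k2_hd_pop = log(c(1e-5, 10)), beta_cag = c(-20, 20),
    cnfl_brain = log(c(0.01, 1e4)), omega_k0 = log(c(1e-3, 1e3)),
    omega_k2 = log(c(1e-3, 10)), sigma_prop_nfl = log(c(1e-4, 5)),
    sigma_add_vol = log(c(1e-2, 1e3)))

  # one maximisation pass over a subset of the free parameters, the rest
  # held at `at`; quasi-Newton with per-parameter scaling (the 1, t, t^2
  # collinearity makes the surface badly conditioned), then a polish
  maximise <- function(free, at, data = fd, maxit = ctrl$iter.max) {
    sk <- skel; sk$free <- free
    sk$log_scale <- intersect(skel$log_scale, free)
    sk$fixed <- at
    warm <- new.env(parent = emptyenv())
    f <- function(theta) {
      p <- theta_to_params(theta, sk)
      ll <- marginal_loglik(p, spec, data, cl, n_nodes = n_nodes,
                            warm = warm)
      if (!is.finite(ll)) 1e10 else -ll
    }
    lo <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
    hi <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
    th0 <- pmin(pmax(params_to_theta(at, sk), lo + 1e-6), hi - 1e-6)
    # forward-difference gradient with a cached centre halves the
    # evaluations per quasi-Newton iteration
    cache <- new.env(parent = emptyenv())
    fc <- function(theta) {
      v <- f(theta)
      cache$theta <- theta; cache$value <- v
      v
    }
    hstep <- 1e-6 * pmax(abs(th0), 0.1)
    gr <- function(theta) {
      f0 <- if (!is.null(cache$theta) && identical(cache$theta, theta))
        cache$value else f(theta)
      vapply(seq_along(theta), function(j) {
        e <- theta
        e[j] <- if (e[j] + hstep[j] <= hi[j]) e[j] + hstep[j]
        else e[j] - hstep[j]
        g <- (f(e) - f0) / (e[j] - theta[j])
        if (is.finite(g)) g else 0
      }, numeric(1))
    }
    o1 <- stats::optim(th0, fc, gr, method = "L-BFGS-B",
                       lower = lo, upper = hi,
                       control = list(maxit = maxit, factr = 1e7,
                                      parscale = pmax(abs(th0), 0.1)))
    o2 <- nlminb(o1$par, f, lower = lo, upper = hi, control = ctrl)
    if (o2$objective > o1$value) {      # keep the better of the two
      o2$par <- o1$par; o2$objective <- o1$value
    }
    # nlminb's "false convergence" (8) at a flat optimum counts as
    # converged: it reports it whenever the remaining improvement is below
    # numerical resolution
    msg2 <- if (is.null(o2$message)) "" else o2$message
    ok2 <- o2$convergence == 0 ||
      grepl("convergence \\((3|4|5|8)\\)", msg2)
    list(params = theta_to_params(o2$par, sk), value = o2$objective,
         converged = ok2 || o1$convergence == 0,
         opt = o2)
  }

  # The marginal likelihood has a curved, nearly flat valley along the
  # curvature coefficient (with k1 riding on it), so a single start can
  # settle in the wrong basin. Candidate starts profile that direction:
  # each fixes k1 = a1 + 2 * 50 * k2 at a trial curvature (a1 = the
  # anchor group's volume slope at age 50, estimated from within-subject
  # changes) and derives every other starting value coherently from the
  # data. The best-scoring candidates get a short refinement; the winner a
  # full optimization.
  negll_params <- function(p) {
    ll <- marginal_loglik(p, spec, fd, cl, n_nodes = n_nodes)
    if (!is.finite(ll)) 1e10 else -ll
  }
  cands <- list(st)
  sdf <- slope_summary(fd)
  if (is.null(start) && spec$volume_model == "quadratic" && !is.null(sdf) &&
      !is.null(skel$anchor)) {
    ag <- if (skel$anchor == "k2_hc") "HC" else setdiff(GROUP_LEVELS, "HC")
    sa <- sdf[sdf$group %in% ag, ]
    a1 <- unname(coef(lm(slope ~ I(mid - 50), data = sa))[1])
    dv <- fd_long(fd)
    dva <- dv[!is.na(dv$vol) & dv$group %in% ag, ]
    k2_cs <- max(-coef(lm(vol ~ age + I(age^2), data = dva))[[3]], 0.005)
    for (f in c(0.25, 0.5, 1, 2, 4)) {
      k1_c <- a1 + 2 * 50 * (f * k2_cs)
      cands <- c(cands, list(tryCatch(
        default_start(fd, spec, cl, k1_fix = k1_c), error = function(e) NULL)))
    }
    cands <- cands[!vapply(cands, is.null, logical(1))]
  }
  cands <- lapply(cands, function(s) modifyList(skel$fixed, s))
  vals <- vapply(cands, negll_params, numeric(1))
  ord <- order(vals)
  top <- cands[ord[seq_len(min(2, length(cands)))]]
  short <- lapply(top, function(s) maximise(skel$free, s, maxit = 12))
  best <- top[[which.min(vapply(short, `[[`, numeric(1), "value"))]]
  best <- modifyList(best,
                     short[[which.min(vapply(short, `[[`, numeric(1),
                                             "value"))]]$params)
  sC <- maximise(skel$free, best)
  opt <- sC$opt
  converged <- sC$converged
  theta_hat <- opt$par
  warm_se <- new.env(parent = emptyenv())
  negll <- function(theta) {
    p <- theta_to_params(theta, skel)
    ll <- marginal_loglik(p, spec, fd, cl, n_nodes = n_nodes,
                          warm = warm_se)
    if (!is.finite(ll)) 1e10 else -ll
  }
  params <- theta_to_params(theta_hat, skel)

  # observed-information SEs, delta method through the (nonlinear) map
  # from the estimation scale to the natural parameters
  se_nat <- rep(NA_real_, length(theta_hat))
  H <- if (se) tryCatch(num_hessian(negll, theta_hat, h = 1e-2),
                        error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      nat_of <- function(th) {
        p <- theta_to_params(th, skel)
        vapply(skel$free, function(nm) p[[nm]], numeric(1))
      }
      J <- vapply(seq_along(theta_hat), function(j) {
        e <- numeric(length(theta_hat)); e[j] <- 1e-5
        (nat_of(theta_hat + e) - nat_of(theta_hat - e)) / 2e-5
      }, numeric(length(theta_hat)))
      se_nat <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
    }
  }
  est <- data.frame(
    parameter = skel$free,
    estimate = vapply(skel$free, function(nm) params[[nm]], numeric(1)),
    se = se_nat, row.names = NULL, stringsAsFactors = FALSE)

  ll <- -opt$objective
  p_n <- length(theta_hat)
  res <- structure(list(
    estimates = est, params = params, spec = spec, cl = cl,
    loglik = ll, n_obs = fd$n_obs, n_param = p_n,
    bicc = bicc(ll, p_n, fd$n_obs),
    bicc_formula = "-2*logLik + p*log(n)*n/(n-p-1)",
    converged = converged, optimizer = list(
      method = "nlminb", n_nodes = n_nodes, iterations = opt$iterations,
      message = opt$message, rel.tol = ctrl$rel.tol),
    ranef = NULL, n_subjects = fd$n,
    groups = table(fd$group)), class = "fit_result")
  res$ranef <- empirical_bayes(params, spec, fd, cl)
  res
}

# Small-sample corrected BIC (the n/(n-p-1) AICc-style inflation applied
# to the BIC penalty); the formula is recorded in fit metadata.
bicc <- function(loglik, p, n) {
  -2 * loglik + p * log(n) * n / (n - p - 1)
}

num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- h; ej[j] <- h
    if (i == j) H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Joint NfL-atrophy fit (%s volume model%s)\n",
              x$spec$volume_model,
              if (isTRUE(x$spec$cag_covariate)) ", CAG covariate" else ""))
  cat(sprintf("  %d subjects, %d observations; converged: %s\n",
              x$n_subjects, x$n_obs, x$converged))
  cat(sprintf("  logLik %.2f   BICc %.2f\n", x$loglik, x$bicc))
  print(transform(x$estimates, estimate = signif(estimate, 4),
                  se = signif(se, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
logLik.fit_result <- function(object, ...) {
  structure(object$loglik, df = object$n_param, nobs = object$n_obs,
            class = "logLik")
}

#' Two-stage cross-check estimator
#'
#' An intentionally simple estimator used as an independent consistency
#' check on [fit_nfl_model()], not as the headline method. Stage 1 fits the
#' population volume trajectory by pooled least squares; stage 2 computes a
#' per-subject acceleration coefficient given the pooled intercept and
#' slope, then regresses its log on \eqn{\log(CAG/42.5)} over HD subjects
#' to estimate the covariate power law; stage 3 inverts the
#' quasi-steady-state relation on every NfL observation and takes the
#' median implied brain concentration. Error magnitudes are
#' moment estimates from the stage residuals. On noise-free data with zero
#' random effects all stages are exact.
#'
#' @inheritParams fit_nfl_model
#' @return a \code{fit_result} whose \code{loglik} is the plug-in marginal
#'   log-likelihood at the two-stage estimates (never above the joint
#'   fit's maximised value).
#' @export
two_stage_fit <- function(dataset, spec = model_spec(),
                          cl = clearance_table()) {
  fd <- prepare_fit_data(dataset)
  quad <- spec$volume_model == "quadratic"
  if (any(fd$nv < 2))
    warning(sum(fd$nv < 2), " subject(s) with < 2 volume observations; ",
            "they inform only the pooled stage")

  # stage 1: pooled k1 and group accelerations from within-subject slopes;
  # per-subject (eta0_i, k2_i) by least squares given k1
  vm <- volume_moment_fit(fd, quad)
  k0 <- vm$k0; k1 <- vm$k1
  k2i <- vm$k2_i
  k2_hc <- if ("HC" %in% names(vm$k2_g)) vm$k2_g[["HC"]] else 0
  k2_hd_pop <- 0.1; beta <- 0

  # stage 2: CAG power law from the per-subject accelerations
  if (quad) {
    hc <- fd$group == "HC" & vm$k2_fit & !is.na(k2i) & k2i > 0
    if (any(hc)) k2_hc <- exp(mean(log(k2i[hc])))
    hd <- fd$group != "HC" & vm$k2_fit & !is.na(k2i) & k2i > 0
    if (spec$cag_covariate) {
      if (sum(hd) < 2 || length(unique(fd$cag[hd])) < 2)
        stop("CAG covariate inestimable: need >= 2 HD subjects with ",
             "distinct CAG values")
      b <- coef(lm(log(k2i[hd]) ~ log(fd$cag[hd] / CAG_REF)))
      k2_hd_pop <- exp(unname(b[1])); beta <- unname(b[2])
    } else if (any(hd)) k2_hd_pop <- exp(mean(log(k2i[hd])))
  }

  # stage 3: invert the QSS relation on NfL observations
  dn <- fd_long(fd)
  dn <- dn[!is.na(dn$nfl), ]
  k2n <- if (quad) {
    v <- k2i[dn$sid]
    pop <- ifelse(dn$group == "HC", k2_hc,
                  k2_hd_pop * (if (spec$cag_covariate)
                    (dn$cag / CAG_REF)^beta else 1))
    ifelse(is.na(v) | v <= 0, pop, v)
  } else rep(0, nrow(dn))
  rate <- -k1 + 2 * k2n * dn$age
  ok <- rate > 0.1
  cb <- if (any(ok))
    median(dn$nfl[ok] * clearance_ml_per_yr(cl, dn$group[ok]) / rate[ok])
  else convert_brain_conc(15, "ug_per_g_to_pg_per_ml")
  cnfl <- convert_brain_conc(cb, "pg_per_ml_to_ug_per_g")

  # robust moment estimates of error magnitudes and random-effect SDs
  g <- pmax(cb * pmax(rate, 0) / clearance_ml_per_yr(cl, dn$group),
            NFL_PRED_FLOOR)
  sigma_prop <- mad((dn$nfl[ok] - g[ok]) / g[ok], center = 0)
  sigma_add <- if (length(vm$slope_resid) > 2)
    mad(vm$slope_resid, center = 0) * 2 / sqrt(2) else 10
  omega_k0 <- if (sum(!is.na(vm$eta0_i)) > 2)
    sd(vm$eta0_i, na.rm = TRUE) else sigma_add
  omega_k2 <- if (quad) {
    lk <- log(k2i[!is.na(k2i) & k2i > 0])
    if (length(lk) > 2) sd(lk) else 0.3
  } else 0

  params <- list(k0 = k0, k1 = k1, k2_hc = k2_hc, k2_hd_pop = k2_hd_pop,
                 beta_cag = beta, cnfl_brain = cnfl,
                 omega_k0 = max(omega_k0, 1), omega_k2 = max(omega_k2, 0.01),
                 sigma_prop_nfl = max(sigma_prop, 1e-3),
                 sigma_add_vol = max(sigma_add, 1e-3))
  if (!spec$random_effects) { params$omega_k0 <- 0; params$omega_k2 <- 0 }
  skel <- build_skeleton(spec, unique(fd$group))
  est <- data.frame(parameter = skel$free,
                    estimate = vapply(skel$free, function(nm) params[[nm]],
                                      numeric(1)),
                    se = NA_real_, row.names = NULL, stringsAsFactors = FALSE)
  ll <- marginal_loglik(params, spec, fd, cl)
  p_n <- length(skel$free)
  structure(list(estimates = est, params = params, spec = spec, cl = cl,
                 loglik = ll, n_obs = fd$n_obs, n_param = p_n,
                 bicc = bicc(ll, p_n, fd$n_obs),
                 bicc_formula = "-2*logLik + p*log(n)*n/(n-p-1)",
                 converged = TRUE,
                 optimizer = list(method = "two-stage"),
                 ranef = NULL, n_subjects = fd$n,
                 groups = table(fd$group)),
            class = "fit_result")
}

#' Compare candidate model specifications by corrected BIC
#'
#' Fits every specification to the same dataset and ranks the converged
#' fits by small-sample corrected BIC (lower is better). Non-converged
#' fits are excluded from the ranking and flagged.
#'
#' @param dataset data frame in the HD-CSF schema.
#' @param specs list of [model_spec()] objects (at least one; names are
#'   kept in the output).
#' @param cl a [clearance_table()].
#' @param ... passed on to [fit_nfl_model()].
#' @return a list with \code{table} (data frame: model, loglik, n_param,
#'   bicc, converged, ranked by BICc) and \code{fits} (the fit objects).
#' @export
compare_models <- function(dataset,
                           specs = list(quadratic = model_spec("quadratic"),
                                        linear = model_spec("linear")),
                           cl = clearance_table(), ...) {
  stopifnot(length(specs) >= 1)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$volume_model, character(1))
  fits <- lapply(specs, function(s) fit_nfl_model(dataset, s, cl, ...))
  tab <- data.frame(
    model = names(specs),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_param = vapply(fits, `[[`, numeric(1), "n_param"),
    bicc = vapply(fits, `[[`, numeric(1), "bicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL, stringsAsFactors = FALSE)
  ok <- tab$converged
  tab <- rbind(tab[ok, ][order(tab$bicc[ok]), ], tab[!ok, ])
  list(table = tab, fits = fits,
       bicc_formula = "-2*logLik + p*log(n)*n/(n-p-1)")
}
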
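# Marginal likelihood machinery for the joint volume + NfL mixed-effects
# model. Two random effects per subject: an additive normal effect on the
# volume intercept k0 (integrated out analytically -- it enters only the
# volume stream, linearly, giving a compound-symmetry marginal covariance)
# and a log-normal effect on the acceleration k2 (integrated numerically
# per subject; see marginal_loglik).

# NfL reporting floor in pg/mL: simulated observations never fall below
# it, and observations at it are treated as left-censored.
NFL_PRED_FLOOR <- 1

# Smoothing scale (mL/yr) for the positive-part clamp on the
# neurodegeneration rate inside the likelihood: softplus(r) differs from
# max(r, 0) by < 1e-3 beyond |r| = 0.07 mL/yr but is twice differentiable,
# which Newton mode-finding requires. The scale is chosen small enough
# that sharpening it further leaves the maximum-likelihood estimates
# unchanged (a wide smoothing measurably tilts the flat ridge between the
# basal rate and the acceleration).
RATE_SMOOTH <- 0.01

softplus_rate <- function(r, s = RATE_SMOOTH) {
  ifelse(r > 30 * s, r, s * log1p(exp(pmax(r, -30 * s) / s)))
}

# Restructure a HD-CSF-schema dataset into padded per-subject matrices.
prepare_fit_data <- function(dataset) {
  need <- c("ID", "age", "group", "wb_adj", "NfL_CSF2")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  if (!"CAG" %in% names(dataset)) dataset$CAG <- NA_real_
  bad <- !dataset$group %in% GROUP_LEVELS
  if (any(bad))
    stop("unknown group labels: ", paste(unique(dataset$group[bad]), collapse = ", "),
         " (normalise with read_hdcsf_csv)")
  hd <- dataset$group != "HC"
  if (any(hd & is.na(dataset$CAG)))
    stop("HD rows must carry a CAG repeat count")

  ids <- unique(dataset$ID)
  n <- length(ids)
  idx <- match(dataset$ID, ids)
  first <- !duplicated(idx)
  J <- max(tabulate(idx))
  Tm <- Yv <- Yc <- matrix(NA_real_, n, J)
  pos <- integer(n)
  ord <- order(idx, dataset$age)
  for (r in ord) {
    i <- idx[r]
    pos[i] <- pos[i] + 1
    Tm[i, pos[i]] <- dataset$age[r]
    Yv[i, pos[i]] <- dataset$wb_adj[r]
    Yc[i, pos[i]] <- dataset$NfL_CSF2[r]
  }
  list(ids = ids, n = n,
       group = dataset$group[first][order(idx[first])],
       cag = dataset$CAG[first][order(idx[first])],
       T = Tm, Yv = Yv, Yc = Yc,
       mask_v = !is.na(Yv), mask_c = !is.na(Yc),
       cens_c = !is.na(Yc) & Yc <= NFL_PRED_FLOOR + 1e-9,
       nv = rowSums(!is.na(Yv)), nc = rowSums(!is.na(Yc)),
       n_obs = sum(!is.na(Yv)) + sum(!is.na(Yc)))
}

# Natural-scale parameter list from the estimation-scale vector. Positive
# parameters are estimated on the log scale. The trajectory intercept and
# slope are estimated in age-centred coordinates — a0 = V(t_ref), a1 =
# dV/dt at t_ref for the anchor group — because the raw (k0, k1, k2)
# coordinates form a curved, nearly flat valley (the data sit 30-80 years
# from the t = 0 intercept) that defeats quasi-Newton optimizers.
theta_to_params <- function(theta, skel) {
  p <- as.list(theta[skel$free])
  names(p) <- skel$free
  for (nm in skel$log_scale) p[[nm]] <- exp(p[[nm]])
  p <- modifyList(skel$fixed, p)
  if (!is.null(skel$t_ref)) {
    tr <- skel$t_ref
    k2a <- if (!is.null(skel$anchor)) p[[skel$anchor]] else 0
    a0 <- p$k0; a1 <- p$k1
    p$k1 <- a1 + 2 * tr * k2a
    p$k0 <- a0 - tr * p$k1 + tr^2 * k2a
  }
  p
}

params_to_theta <- function(params, skel) {
  params <- params[!vapply(params, is.null, logical(1))]
  if (!is.null(skel$t_ref)) {
    tr <- skel$t_ref
    k2a <- if (!is.null(skel$anchor)) params[[skel$anchor]] else 0
    if (is.null(k2a)) k2a <- 0
    a1 <- params$k1 - 2 * tr * k2a
    a0 <- params$k0 + tr * params$k1 - tr^2 * k2a
    params$k0 <- a0; params$k1 <- a1
  }
  th <- vapply(skel$free, function(nm) {
    v <- params[[nm]]
    if (nm %in% skel$log_scale) log(v) else v
  }, numeric(1))
  names(th) <- skel$free
  th
}

# Parameter skeleton for a model spec and the groups present in the data.
build_skeleton <- function(spec, groups_present) {
  has_hc <- "HC" %in% groups_present
  has_hd <- any(c("preHD", "manifestHD") %in% groups_present)
  free <- c("k0", "k1")
  log_scale <- character(0)
  if (spec$volume_model == "quadratic") {
    if (has_hc) { free <- c(free, "k2_hc"); log_scale <- c(log_scale, "k2_hc") }
    if (has_hd) {
      free <- c(free, "k2_hd_pop"); log_scale <- c(log_scale, "k2_hd_pop")
      if (spec$cag_covariate) free <- c(free, "beta_cag")
    }
  }
  free <- c(free, "cnfl_brain"); log_scale <- c(log_scale, "cnfl_brain")
  if (spec$random_effects) {
    free <- c(free, "omega_k0", "omega_k2")
    log_scale <- c(log_scale, "omega_k0", "omega_k2")
    if (spec$volume_model == "linear") {
      free <- setdiff(free, "omega_k2")   # no k2 to randomise
      log_scale <- setdiff(log_scale, "omega_k2")
    }
  }
  free <- c(free, "sigma_prop_nfl", "sigma_add_vol")
  log_scale <- c(log_scale, "sigma_prop_nfl", "sigma_add_vol")
  fixed <- list(k0 = NA_real_, k1 = NA_real_, k2_hc = 0, k2_hd_pop = 0,
                beta_cag = 0, cnfl_brain = NA_real_,
                omega_k0 = 0, omega_k2 = 0,
                sigma_prop_nfl = NA_real_, sigma_add_vol = NA_real_)
  anchor <- if (spec$volume_model == "quadratic") {
    if (has_hc) "k2_hc" else if (has_hd) "k2_hd_pop" else NULL
  } else NULL
  list(free = free, log_scale = log_scale, fixed = fixed,
       t_ref = 50, anchor = anchor)
}

# Population (zero random effect) k2 per subject under a spec.
k2_population <- function(params, spec, group, cag) {
  if (spec$volume_model == "linear") return(rep(0, length(group)))
  k2 <- ifelse(group == "HC", params$k2_hc, params$k2_hd_pop)
  if (spec$cag_covariate) {
    hd <- group != "HC"
    k2[hd] <- k2[hd] * (cag[hd] / CAG_REF)^params$beta_cag
  }
  k2
}

# Per-subject conditional log-likelihood at log-k2 deviations eta2
# (vector over subjects), with the intercept random effect integrated out
# analytically on the volume stream. Returns an n-vector.
cond_loglik <- function(eta2, fd, params, k2_base, cl_i, cb) {
  s2a <- params$sigma_add_vol^2
  w0 <- params$omega_k0^2
  K2 <- k2_base * exp(pmin(pmax(eta2, -30), 30))

  # volume stream: y ~ N(k0 + k1 t - K2 t^2, s2a I + w0 J). The quadratic
  # form is computed in its centred decomposition (within-subject scatter
  # plus shrunken subject mean), which is cancellation-free.
  M <- params$k0 + params$k1 * fd$T - K2 * fd$T^2
  R <- fd$Yv - M
  R[!fd$mask_v] <- 0
  S1 <- rowSums(R)
  nv1 <- pmax(fd$nv, 1)
  Rc <- R - S1 / nv1
  Rc[!fd$mask_v] <- 0
  SSc <- rowSums(Rc^2)
  d <- s2a + fd$nv * w0
  ll_v <- -0.5 * (fd$nv * log(2 * pi) + (fd$nv - 1) * log(s2a) + log(d) +
                    SSc / s2a + S1^2 / (nv1 * d))
  ll_v[fd$nv == 0] <- 0

  # NfL stream: y ~ N(g, (sigma_prop * g)^2), g from the QSS solution with
  # the rate clamp smoothed so the density is differentiable in eta2.
  # Observations at the 1 pg/mL reporting floor are left-censored: they
  # contribute P(g(1 + eps) <= floor) = Phi((floor - g) / (sigma_prop g)),
  # the exact likelihood of a floored measurement.
  sp <- params$sigma_prop_nfl
  G <- cb * softplus_rate(-params$k1 + 2 * K2 * fd$T) / cl_i + 1e-3
  z <- (fd$Yc - G) / (sp * G)
  ll_el <- -0.5 * (log(2 * pi) + z^2) - log(sp * G)
  if (any(fd$cens_c)) {
    ic <- which(fd$cens_c)
    ll_el[ic] <- pnorm((NFL_PRED_FLOOR - G[ic]) / (sp * G[ic]), log.p = TRUE)
  }
  ll_el[!fd$mask_c] <- 0
  ll_v + rowSums(ll_el)
}

# Value, gradient and curvature of the per-subject joint log-density
# l(eta2) + log phi(eta2; omega_k2), all analytic (the quadrature centre
# and width must be smooth functions of the outer parameters, or the
# marginal likelihood surface picks up finite-difference jitter that
# defeats quasi-Newton optimizers). Returns n-vectors f, g, H.
joint_deriv <- function(eta2, fd, params, k2_base, cl_i, cb) {
  s2a <- params$sigma_add_vol^2
  w0 <- params$omega_k0^2
  sp <- params$sigma_prop_nfl
  w2 <- params$omega_k2
  K2 <- k2_base * exp(pmin(pmax(eta2, -30), 30))

  # volume stream
  P <- K2 * fd$T^2
  R <- fd$Yv - (params$k0 + params$k1 * fd$T - P)
  P[!fd$mask_v] <- 0; R[!fd$mask_v] <- 0
  nv1 <- pmax(fd$nv, 1)
  S1 <- rowSums(R); P1 <- rowSums(P)
  Rc <- R - S1 / nv1; Pc <- P - P1 / nv1
  Rc[!fd$mask_v] <- 0; Pc[!fd$mask_v] <- 0
  SSc <- rowSums(Rc^2)
  A <- rowSums(Rc * Pc)
  B <- rowSums(Pc^2)
  d <- s2a + fd$nv * w0
  f_v <- -0.5 * (fd$nv * log(2 * pi) + (fd$nv - 1) * log(s2a) + log(d) +
                   SSc / s2a + S1^2 / (nv1 * d))
  f_v[fd$nv == 0] <- 0
  g_v <- -(A / s2a + S1 * P1 / (nv1 * d))
  H_v <- -((B + A) / s2a + (P1^2 + S1 * P1) / (nv1 * d))

  # NfL stream (smoothed positive-part rate; floored observations are
  # left-censored)
  r <- -params$k1 + 2 * K2 * fd$T
  sig_s <- 1 / (1 + exp(-pmin(pmax(r / RATE_SMOOTH, -700), 700)))
  G <- cb * softplus_rate(r) / cl_i + 1e-3
  scl <- cb / cl_i
  dr <- r + params$k1                  # d r / d eta2 = 2 K2 T
  Gp <- scl * sig_s * dr
  Gpp <- scl * (sig_s * (1 - sig_s) / RATE_SMOOTH * dr^2 + sig_s * dr)
  z <- (fd$Yc - G) / (sp * G)
  f_el <- -0.5 * (log(2 * pi) + z^2) - log(sp * G)
  l1 <- z * fd$Yc / (sp * G^2) - 1 / G
  l2 <- -fd$Yc^2 / (sp^2 * G^4) - 2 * z * fd$Yc / (sp * G^3) + 1 / G^2
  if (any(fd$cens_c)) {
    ic <- which(fd$cens_c)
    zc <- (NFL_PRED_FLOOR - G[ic]) / (sp * G[ic])
    lr <- dnorm(zc, log = TRUE) - pnorm(zc, log.p = TRUE)
    hr <- exp(lr)
    dzc <- -NFL_PRED_FLOOR / (sp * G[ic]^2)
    d2zc <- 2 * NFL_PRED_FLOOR / (sp * G[ic]^3)
    f_el[ic] <- pnorm(zc, log.p = TRUE)
    l1[ic] <- hr * dzc
    l2[ic] <- (-zc * hr - hr^2) * dzc^2 + hr * d2zc
  }
  g_el <- l1 * Gp
  H_el <- l2 * Gp^2 + l1 * Gpp
  f_el[!fd$mask_c] <- 0; g_el[!fd$mask_c] <- 0; H_el[!fd$mask_c] <- 0

  list(f = f_v + rowSums(f_el) - log(w2) - 0.5 * log(2 * pi) -
         eta2^2 / (2 * w2^2),
       g = g_v + rowSums(g_el) - eta2 / w2^2,
       H = H_v + rowSums(H_el) - 1 / w2^2)
}

# Conditional log-likelihood evaluated at a whole matrix of eta2 nodes
# (subjects x nodes) in one vectorised pass: the visit dimension is small,
# so looping over visits while keeping the node dimension in matrices is
# far cheaper than one call per node column.
cond_loglik_nodes <- function(nodes, fd, params, k2_base, cl_i, cb) {
  s2a <- params$sigma_add_vol^2
  w0 <- params$omega_k0^2
  sp <- params$sigma_prop_nfl
  n <- fd$n; m <- ncol(nodes); J <- ncol(fd$T)
  K2 <- k2_base * exp(pmin(pmax(nodes, -30), 30))
  nv1 <- pmax(fd$nv, 1)
  d <- s2a + fd$nv * w0

  Rs <- vector("list", J)
  S1 <- matrix(0, n, m)
  for (j in seq_len(J)) {
    R <- fd$Yv[, j] - (params$k0 + params$k1 * fd$T[, j] - K2 * fd$T[, j]^2)
    R[!fd$mask_v[, j], ] <- 0
    Rs[[j]] <- R
    S1 <- S1 + R
  }
  SSc <- matrix(0, n, m)
  for (j in seq_len(J)) {
    Rc <- Rs[[j]] - S1 / nv1
    Rc[!fd$mask_v[, j], ] <- 0
    SSc <- SSc + Rc^2
  }
  ll <- -0.5 * (fd$nv * log(2 * pi) + (fd$nv - 1) * log(s2a) + log(d) +
                  SSc / s2a + S1^2 / (nv1 * d))
  ll[fd$nv == 0, ] <- 0

  for (j in seq_len(J)) {
    G <- cb * softplus_rate(-params$k1 + 2 * K2 * fd$T[, j]) / cl_i + 1e-3
    z <- (fd$Yc[, j] - G) / (sp * G)
    lj <- -0.5 * (log(2 * pi) + z^2) - log(sp * G)
    ic <- which(fd$cens_c[, j])
    if (length(ic)) {
      Gi <- G[ic, , drop = FALSE]
      lj[ic, ] <- pnorm((NFL_PRED_FLOOR - Gi) / (sp * Gi), log.p = TRUE)
    }
    lj[!fd$mask_c[, j], ] <- 0
    ll <- ll + lj
  }
  ll
}

# Vectorised Newton search for the per-subject mode of the joint density,
# using the analytic derivatives above, with monotone backtracking.
subset_fd <- function(fd, idx) {
  list(n = length(idx), T = fd$T[idx, , drop = FALSE],
       Yv = fd$Yv[idx, , drop = FALSE], Yc = fd$Yc[idx, , drop = FALSE],
       mask_v = fd$mask_v[idx, , drop = FALSE],
       mask_c = fd$mask_c[idx, , drop = FALSE],
       cens_c = fd$cens_c[idx, , drop = FALSE],
       nv = fd$nv[idx], nc = fd$nc[idx])
}

inner_modes <- function(fd, params, k2_base, cl_i, cb,
                        max_iter = 40, tol = 1e-9, eta_init = NULL) {
  w2 <- params$omega_k2
  curv_floor <- max(0.05 / w2^2, 1e-6)  # curvature cannot fall far below the prior's
  eta <- if (is.null(eta_init)) rep(0, fd$n) else eta_init
  jd <- joint_deriv(eta, fd, params, k2_base, cl_i, cb)
  f0 <- jd$f; g0 <- jd$g; H0 <- jd$H
  f0[!is.finite(f0)] <- -Inf
  act <- seq_len(fd$n)                  # subjects still iterating
  for (it in seq_len(max_iter)) {
    Ha <- pmin(H0[act], -curv_floor)
    step <- pmin(pmax(-g0[act] / Ha, -1), 1)
    step[!is.finite(step)] <- 0
    sub <- subset_fd(fd, act)
    k2a <- k2_base[act]
    cla <- if (length(cl_i) > 1) cl_i[act] else cl_i
    # backtracking: only accept ascent steps (the NfL stream puts steep
    # cliffs next to some modes, where a raw Newton step 2-cycles)
    jd1 <- joint_deriv(eta[act] + step, sub, params, k2a, cla, cb)
    f1 <- jd1$f
    f1[!is.finite(f1)] <- -Inf
    for (bt in 1:10) {
      worse <- f1 < f0[act]
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      jd1 <- joint_deriv(eta[act] + step, sub, params, k2a, cla, cb)
      f1 <- jd1$f
      f1[!is.finite(f1)] <- -Inf
    }
    keep <- f1 >= f0[act]
    step[!keep] <- 0
    eta[act] <- eta[act] + step
    upd <- act[keep]
    f0[upd] <- f1[keep]; g0[upd] <- jd1$g[keep]; H0[upd] <- jd1$H[keep]
    act <- act[abs(step) >= tol]
    if (!length(act)) break
  }
  list(eta = eta, joint = f0, curv = -pmin(H0, -curv_floor))
}

# Marginal log-likelihood of the whole dataset. The random-effect integral
# per subject is computed by a log-scale trapezoid rule over the union of
# (a) nodes centred at the Newton mode, spaced by its local width, and
# (b) a fixed grid spanning the prior. The union makes the value robust to
# multimodal integrands (the rate clamp can split the posterior of eta2
# into two bumps): when the Newton search flips between modes, the other
# bump is still covered by the fixed grid, so the marginal value moves
# only at quadrature resolution and the surface stays effectively smooth
# for the outer optimizer. n_nodes = 1 gives the Laplace approximation.
marginal_loglik <- function(params, spec, fd, cl, n_nodes = 31,
                            warm = NULL) {
  cb <- convert_brain_conc(params$cnfl_brain, "ug_per_g_to_pg_per_ml")
  cl_i <- clearance_ml_per_yr(cl, fd$group)
  k2_base <- k2_population(params, spec, fd$group, fd$cag)

  no_eta2 <- spec$volume_model == "linear" || !spec$random_effects ||
    params$omega_k2 <= 0
  if (no_eta2)
    return(sum(cond_loglik(rep(0, fd$n), fd, params, k2_base, cl_i, cb)))

  eta_init <- if (!is.null(warm) && length(warm$eta) == fd$n) warm$eta
  m <- inner_modes(fd, params, k2_base, cl_i, cb, eta_init = eta_init)
  if (!is.null(warm)) warm$eta <- m$eta
  sig <- 1 / sqrt(m$curv)
  if (n_nodes <= 1)
    return(sum(0.5 * log(2 * pi) + log(sig) + m$joint))

  w2 <- params$omega_k2
  prior_grid <- matrix(w2 * seq(-6, 6, length.out = 21),
                       fd$n, 21, byrow = TRUE)
  # secondary-bump refinement: the rate clamp can leave a second local
  # maximum far from the Newton mode; when a prior-grid node competes with
  # the mode, refine it too so both bumps get width-matched nodes
  Fp <- cond_loglik_nodes(prior_grid, fd, params, k2_base, cl_i, cb) +
    dnorm(prior_grid, 0, w2, log = TRUE)
  bi <- max.col(Fp, ties.method = "first")
  rows <- seq_len(fd$n)
  bv <- Fp[cbind(rows, bi)]
  eb <- prior_grid[cbind(rows, bi)]
  eta2nd <- m$eta
  sig2nd <- sig
  need2 <- abs(eb - m$eta) > pmax(2 * sig, 0.05) & bv > m$joint - 15
  need2[!is.finite(bv)] <- FALSE
  if (any(need2)) {
    idx <- which(need2)
    m2 <- inner_modes(subset_fd(fd, idx), params, k2_base[idx],
                      if (length(cl_i) > 1) cl_i[idx] else cl_i, cb,
                      eta_init = eb[idx])
    eta2nd[idx] <- m2$eta
    sig2nd[idx] <- 1 / sqrt(m2$curv)
  }
  loc <- m$eta + outer(sig, seq(-6, 6, length.out = n_nodes))
  loc2 <- eta2nd + outer(sig2nd, seq(-6, 6, length.out = 15))
  raw <- cbind(loc, loc2, prior_grid)
  o <- order(row(raw), raw)            # one radix sort, all rows at once
  nodes <- matrix(raw[o], nrow = fd$n, byrow = TRUE)
  F <- cond_loglik_nodes(nodes, fd, params, k2_base, cl_i, cb) +
    dnorm(nodes, 0, w2, log = TRUE)
  # trapezoid in log space: segment integral ~ (h/2)(e^{f_l} + e^{f_r})
  mseg <- pmax(F[, -1], F[, -ncol(F)])
  lseg <- log(pmax(nodes[, -1] - nodes[, -ncol(nodes)], 1e-300) / 2) +
    mseg + log(exp(F[, -1] - mseg) + exp(F[, -ncol(F)] - mseg))
  mx <- apply(lseg, 1, max)
  sum(mx + log(rowSums(exp(lseg - mx))))
}

# Empirical-Bayes estimates of both random effects at the fitted
# parameters: eta2 from the inner mode, eta0 from its conditional
# (conjugate-normal) posterior mean given eta2.
empirical_bayes <- function(params, spec, fd, cl) {
  cb <- convert_brain_conc(params$cnfl_brain, "ug_per_g_to_pg_per_ml")
  cl_i <- clearance_ml_per_yr(cl, fd$group)
  k2_base <- k2_population(params, spec, fd$group, fd$cag)
  no_eta2 <- spec$volume_model == "linear" || !spec$random_effects ||
    params$omega_k2 <= 0
  eta2 <- if (no_eta2) rep(0, fd$n)
  else inner_modes(fd, params, k2_base, cl_i, cb)$eta
  K2 <- k2_base * exp(eta2)
  R <- fd$Yv - (params$k0 + params$k1 * fd$T - K2 * fd$T^2)
  R[!fd$mask_v] <- 0
  w0 <- params$omega_k0^2
  eta0 <- w0 * rowSums(R) / (params$sigma_add_vol^2 + fd$nv * w0)
  data.frame(ID = fd$ids, group = fd$group, CAG = fd$cag,
             eta_k0 = eta0, eta_k2 = eta2,
             k0_i = params$k0 + eta0, k2_i = K2,
             stringsAsFactors = FALSE)
}
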
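#' Prior specification
#'
#' Coefficients get independent uniform priors over `range` unless an
#' informative normal prior is supplied by name (used for elicited
#' priors on outcome-selection coefficients). Precisions (reciprocal
#' variances) of the score regressions get gamma priors, by default the
#' conventional diffuse gamma(0.001, 0.001).
#'
#' @param range Length-2 numeric, the uniform prior support for every
#'   coefficient without a normal prior (per-SD scale for selection
#'   coefficients, score units for outcome-model coefficients).
#' @param normal Named list; each element `c(mean, variance)` attaches a
#'   normal prior to the coefficient of that name (e.g.
#'   `list(delta.Y1.R1 = c(0.25, 0.3))`).
#' @param precision_shape,precision_rate Gamma prior for each residual
#'   precision.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(range = c(-50, 50), normal = list(),
                       precision_shape = 0.001, precision_rate = 0.001) {
  stopifnot(length(range) == 2, range[1] < range[2],
            precision_shape > 0, precision_rate > 0)
  for (nm in names(normal)) {
    v <- normal[[nm]]
    if (length(v) != 2 || v[2] <= 0) {
      stop("normal prior for ", nm, " must be c(mean, variance>0)")
    }
  }
  structure(list(range = range, normal = normal,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults are desk-scale (4 chains of 2,500 burn-in plus 2,500 kept
#' iterations); `paper_scale = TRUE` switches to 25,000/25,000 per chain.
#'
#' @param n_chains Number of chains (>= 2 recommended, needed for the
#'   Gelman-Rubin diagnostic).
#' @param n_burn,n_keep Burn-in and kept iterations per chain.
#' @param thin Thinning interval for stored draws.
#' @param seed Integer seed; fanned out into one stream per chain.
#' @param paper_scale Use the 25,000/25,000 schedule.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_burn = 2500, n_keep = 2500,
                        thin = 1, seed = 1L, paper_scale = FALSE) {
  if (paper_scale) {
    n_burn <- 25000
    n_keep <- 25000
  }
  stopifnot(n_chains >= 1, n_burn >= 0, n_keep >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

prior_bounds <- function(priors, nm) {
  if (nm %in% names(priors$normal)) c(-Inf, Inf) else priors$range
}

# vectorized prior info for a coefficient block: normal mean/sd where a
# normal prior applies (NA otherwise) and uniform bounds elsewhere
block_prior_info <- function(nms, priors) {
  p <- length(nms)
  np_mean <- rep(NA_real_, p)
  np_sd <- rep(NA_real_, p)
  lo <- rep(priors$range[1], p)
  hi <- rep(priors$range[2], p)
  for (j in seq_len(p)) {
    np <- priors$normal[[nms[j]]]
    if (!is.null(np)) {
      np_mean[j] <- np[1]
      np_sd[j] <- sqrt(np[2])
      lo[j] <- -Inf
      hi[j] <- Inf
    }
  }
  list(np_mean = np_mean, np_sd = np_sd, lo = lo, hi = hi,
       has_normal = which(!is.na(np_mean)))
}

# log prior density for a coefficient block (uniform terms drop out inside
# the support; -Inf outside)
coef_log_prior <- function(theta, info) {
  if (any(theta < info$lo | theta > info$hi)) return(-Inf)
  h <- info$has_normal
  if (length(h) == 0) return(0)
  sum(dnorm(theta[h], info$np_mean[h], info$np_sd[h], log = TRUE))
}

#' Fit the joint selection model by data-augmentation MCMC
#'
#' Samples the joint posterior of all free parameters and the missing
#' scores. Missing baseline, final and proxy scores are latent variables:
#' each is proposed from the exact Gaussian full conditional implied by
#' the score regressions and accepted against the logistic selection
#' terms (so under missing-at-random constraints the imputation step is
#' exact Gibbs). Normal-regression coefficients and variances use
#' conjugate Gibbs updates (the t family for the final score is handled
#' by its normal scale-mixture representation with per-observation latent
#' weights); logistic-regression blocks use random-walk Metropolis with a
#' Fisher-information-preconditioned proposal whose global scale adapts
#' during burn-in only. Coefficients listed in `spec$fixed` are held at
#' their values in every draw.
#'
#' Identification is the caller's responsibility: with the single-R1
#' model, leaving both `delta.Y0.R0` and the outcome-selection
#' coefficient(s) free without informative priors reproduces a known
#' poorly identified model and triggers a warning. Convergence is
#' assessed by the Gelman-Rubin statistic ([gelman_rubin()]) when at
#' least two chains are run; exceedances are flagged in the result and a
#' warning is raised, never silently dropped.
#'
#' @param data A [trial_data] tibble.
#' @param spec A [model_spec].
#' @param priors A [prior_spec].
#' @param mcmc An [mcmc_config].
#' @return An object of class `mnar_fit`; see [tidy.mnar_fit()],
#'   [treatment_effect_summary()], [delta_missing_minus_observed()],
#'   [gelman_rubin()].
#' @export
fit_selection_model <- function(data, spec, priors = prior_spec(),
                                mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (!all(c("y0", "y1", "r0", "r1", "arm", "centre") %in% names(data))) {
    data <- trial_data(data)
  }
  if (spec$use_proxy && !any(data$rz == 1L)) {
    stop("use_proxy requires observed proxy scores")
  }
  outcome_sel <- if (spec$arm_specific) {
    c("delta.Y1.R1.T", "delta.Y1.R1.C")
  } else "delta.Y1.R1"
  if (!spec$use_attempts) {
    constrained <- function(nm) {
      nm %in% names(spec$fixed) || nm %in% names(priors$normal)
    }
    if (!constrained("delta.Y0.R0") && !all(vapply(outcome_sel,
                                                  constrained,
                                                  logical(1)))) {
      warning("unconstrained selection model requested: with both ",
              "delta.Y0.R0 and the outcome-selection coefficient(s) free ",
              "and uninformative priors the model is very poorly ",
              "identified and the posterior is likely to be diffuse",
              call. = FALSE)
    }
  }
  std <- list(
    y0 = standardizer(data$y0, data$centre),
    y1 = standardizer(data$y1, data$centre),
    z = if (spec$use_proxy) standardizer(data$z, data$centre) else NULL
  )
  chain_seeds <- stage_seeds(mcmc$seed, mcmc$n_chains)
  chains <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    chains[[c]] <- run_chain(data, spec, priors, mcmc, std,
                             chain_seed = chain_seeds[c])
  }
  fit <- structure(list(
    chains = chains, spec = spec, priors = priors, mcmc = mcmc,
    std = std,
    par_names = colnames(chains[[1]]$draws),
    fixed = spec$fixed,
    arm = data$arm, r1 = data$r1,
    obs_mean_y1 = c(
      intervention = mean(data$y1[data$arm == 1L & data$r1 == 1L]),
      control = mean(data$y1[data$arm == 0L & data$r1 == 1L])
    ),
    missing_ids = chains[[1]]$missing_ids,
    scores = tibble::tibble(participant_id = data$participant_id,
                            arm = data$arm, y0 = data$y0, y1 = data$y1,
                            r0 = data$r0, r1 = data$r1),
    data_summary = list(
      n = nrow(data),
      n_missing_y0 = sum(data$r0 == 0L),
      n_missing_y1 = sum(data$r1 == 0L),
      n_missing_z = if (spec$use_proxy) sum(data$rz == 0L) else 0L
    )
  ), class = "mnar_fit")
  fit$convergence <- tryCatch(
    if (mcmc$n_chains >= 2) gelman_rubin(fit) else NULL,
    error = function(e) NULL
  )
  if (!is.null(fit$convergence) && any(fit$convergence$flag,
                                       na.rm = TRUE)) {
    bad <- fit$convergence$term[which(fit$convergence$flag)]
    warning("Gelman-Rubin diagnostic exceeds threshold for: ",
            paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  fit
}

# ---------------------------------------------------------------------
# sampler internals
# ---------------------------------------------------------------------

# intercept + centre dummy design, with coefficient names for `target`
xc_design <- function(centre, target) {
  k <- nlevels(centre)
  X <- matrix(1, nrow = length(centre), ncol = 1)
  if (k >= 2) {
    X <- cbind(X, vapply(2:k, function(j) centre_dummy(centre, j),
                         numeric(length(centre))))
  }
  colnames(X) <- c(paste0("alpha.", target),
                   if (k >= 2) paste0("delta.X", 2:k, ".", target))
  X
}

# conjugate draw of regression coefficients with optional fixed columns,
# observation weights, normal priors and uniform bounds
draw_normal_coefs <- function(D, y, coef, free, s2, w, priors) {
  fixed <- setdiff(colnames(D), free)
  yy <- y
  if (length(fixed) > 0) {
    yy <- yy - drop(D[, fixed, drop = FALSE] %*% coef[fixed])
  }
  Df <- D[, free, drop = FALSE]
  Dw <- if (is.null(w)) Df else Df * w
  XtX <- crossprod(Df, Dw) / s2
  Xty <- crossprod(Dw, yy) / s2
  # normal priors contribute pseudo-information
  for (j in seq_along(free)) {
    np <- priors$normal[[free[j]]]
    if (!is.null(np)) {
      XtX[j, j] <- XtX[j, j] + 1 / np[2]
      Xty[j] <- Xty[j] + np[1] / np[2]
    }
  }
  R <- tryCatch(chol(XtX), error = function(e) {
    stop("singular design in a score regression (collinear covariates, ",
         "e.g. a constant response indicator with its coefficient left ",
         "free); fix the offending coefficient in the model spec",
         call. = FALSE)
  })
  m <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  for (try in 1:50) {
    draw <- drop(m + backsolve(R, rnorm(length(free))))
    ok <- TRUE
    for (j in seq_along(free)) {
      b <- prior_bounds(priors, free[j])
      if (draw[j] < b[1] || draw[j] > b[2]) { ok <- FALSE; break }
    }
    if (ok) { coef[free] <- draw; break }
  }
  coef
}

draw_variance <- function(resid, w, priors) {
  ssr <- if (is.null(w)) sum(resid^2) else sum(w * resid^2)
  1 / rgamma(1, shape = priors$precision_shape + length(resid) / 2,
             rate = priors$precision_rate + ssr / 2)
}

# one random-walk Metropolis update of a logistic block; returns the block
rwm_logit <- function(blk, D, y, priors, adapt, t_adapt) {
  free <- blk$free
  th <- blk$coef[free]
  eta <- drop(D %*% blk$coef)
  ll <- sum(bernoulli_loglik(y, eta))
  lp <- coef_log_prior(th, blk$prior_info)
  step <- exp(blk$log_lam) * drop(blk$prop_chol %*% rnorm(length(free)))
  th_new <- th + step
  lp_new <- coef_log_prior(th_new, blk$prior_info)
  acc <- 0
  if (is.finite(lp_new)) {
    eta_new <- eta + drop(D[, free, drop = FALSE] %*% step)
    ll_new <- sum(bernoulli_loglik(y, eta_new))
    lr <- (ll_new + lp_new) - (ll + lp)
    acc <- min(1, exp(lr))
    if (runif(1) < acc) blk$coef[free] <- th_new
  }
  if (adapt) {
    blk$log_lam <- blk$log_lam +
      min(0.25, 2 / sqrt(t_adapt)) * (acc - 0.28)
  }
  blk
}

# Fisher-information-based proposal Cholesky for a logistic block
logit_proposal_chol <- function(D, y, coef, free) {
  p <- length(free)
  fallback <- diag(0.1, p)
  out <- tryCatch({
    eta <- drop(D %*% coef)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-4)
    Df <- D[, free, drop = FALSE]
    info <- crossprod(Df, Df * wt)
    Sig <- chol2inv(chol(info))
    t(chol(Sig)) * (2.38 / sqrt(p))
  }, error = function(e) fallback)
  out
}

# initial coefficient values for a logistic block via one-step glm
logit_init <- function(D, y, coef, free, priors) {
  est <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(
      x = D[, free, drop = FALSE],
      y = y,
      offset = if (length(free) < ncol(D)) {
        drop(D[, setdiff(colnames(D), free), drop = FALSE] %*%
               coef[setdiff(colnames(D), free)])
      } else rep(0, length(y)),
      family = stats::binomial()))
    co <- fit$coefficients
    co[!is.finite(co)] <- 0
    co
  }, error = function(e) rep(0, length(free)))
  est <- pmin(pmax(est, priors$range[1] + 1e-6), priors$range[2] - 1e-6)
  for (j in seq_along(free)) {
    np <- priors$normal[[free[j]]]
    if (!is.null(np) && abs(est[j] - np[1]) > 3 * sqrt(np[2])) {
      est[j] <- np[1]
    }
  }
  coef[free] <- est
  coef
}

run_chain <- function(data, spec, priors, mcmc, std, chain_seed) {
  set.seed(chain_seed)
  n <- nrow(data)
  k <- nlevels(data$centre)
  arm <- as.numeric(data$arm)
  r0 <- as.numeric(data$r0)
  r1 <- as.numeric(data$r1)
  rz <- as.numeric(data$rz)
  i0 <- which(data$r0 == 0L)
  i1 <- which(data$r1 == 0L)
  iz <- if (spec$use_proxy) which(data$rz == 0L) else integer()
  use_t <- spec$y1_family == "t"

  # --- initial imputations -------------------------------------------
  y0v <- data$y0
  y1v <- data$y1
  zv <- data$z
  if (length(i0) > 0) y0v[i0] <- std$y0$mean + rnorm(length(i0),
                                                     0, 0.5 * std$y0$sd)
  if (length(i1) > 0) y1v[i1] <- std$y1$mean + rnorm(length(i1),
                                                     0, 0.5 * std$y1$sd)
  if (spec$use_proxy && length(iz) > 0) {
    zv[iz] <- std$z$mean + rnorm(length(iz), 0, 0.5 * std$z$sd)
  }
  ys0 <- standardize(y0v, std$y0)
  ys1 <- standardize(y1v, std$y1)
  zs <- if (spec$use_proxy) standardize(zv, std$z) else NULL

  # --- designs --------------------------------------------------------
  Xc_y0 <- xc_design(data$centre, "Y0")
  D_r0 <- cbind(xc_design(data$centre, "R0"), delta.Y0.R0 = ys0)
  D_y1 <- cbind(xc_design(data$centre, "Y1"), delta.Y0.Y1 = ys0,
                delta.R0.Y1 = r0, delta.T.Y1 = arm)
  if (!spec$use_attempts) {
    D_r1 <- cbind(xc_design(data$centre, "R1"), delta.Y0.R1 = ys0,
                  delta.R0.R1 = r0, delta.T.R1 = arm)
    if (spec$arm_specific) {
      D_r1 <- cbind(D_r1, delta.Y1.R1.T = ys1 * arm,
                    delta.Y1.R1.C = ys1 * (1 - arm))
    } else {
      D_r1 <- cbind(D_r1, delta.Y1.R1 = ys1)
    }
  } else {
    imp <- data
    imp$y0 <- y0v
    imp$y1 <- y1v
    att <- attempts_design(spec, imp, std)
    att_success <- att$success
    att_idx <- att$idx
    D_att <- att$X
    att_rows_i0 <- which(att_idx %in% i0)
    att_rows_i1 <- which(att_idx %in% i1)
    grp_i0 <- match(att_idx[att_rows_i0], i0)
    grp_i1 <- match(att_idx[att_rows_i1], i1)
  }
  if (spec$use_proxy) {
    D_z <- cbind(xc_design(data$centre, "Z"), delta.Y0.Z = ys0,
                 delta.R0.Z = r0, delta.T.Z = arm, delta.Y1.Z = ys1,
                 delta.R1.Z = r1)
    D_rz <- cbind(xc_design(data$centre, "RZ"), delta.Y0.RZ = ys0,
                  delta.R0.RZ = r0, delta.T.RZ = arm, delta.Y1.RZ = ys1,
                  delta.R1.RZ = r1, delta.Z.RZ = zs)
  }

  fixed_nms <- names(spec$fixed)
  free_of <- function(D) setdiff(colnames(D), fixed_nms)
  set_fixed <- function(coef) {
    hit <- intersect(names(coef), fixed_nms)
    coef[hit] <- spec$fixed[hit]
    coef
  }

  # --- initial parameter values --------------------------------------
  init_lm <- function(D, y, free) {
    co <- stats::setNames(rep(0, ncol(D)), colnames(D))
    est <- tryCatch(stats::lm.fit(D[, free, drop = FALSE], y)$coefficients,
                    error = function(e) rep(0, length(free)))
    est[!is.finite(est)] <- 0
    co[free] <- est
    co
  }
  b_y0 <- set_fixed(init_lm(Xc_y0, y0v, free_of(Xc_y0)))
  s2_y0 <- max(stats::var(y0v - drop(Xc_y0 %*% b_y0)), 1e-4)
  b_y1 <- set_fixed(init_lm(D_y1, y1v, free_of(D_y1)))
  s2_y1 <- max(stats::var(y1v - drop(D_y1 %*% b_y1)), 1e-4)
  if (spec$use_proxy) {
    b_z <- set_fixed(init_lm(D_z, zv, free_of(D_z)))
    s2_z <- max(stats::var(zv - drop(D_z %*% b_z)), 1e-4)
  }
  w <- rep(1, n)

  new_block <- function(D, y) {
    coef <- stats::setNames(rep(0, ncol(D)), colnames(D))
    coef <- set_fixed(coef)
    free <- free_of(D)
    coef <- logit_init(D, y, coef, free, priors)
    coef <- set_fixed(coef)
    list(coef = coef, free = free,
         prop_chol = logit_proposal_chol(D, y, coef, free),
         prior_info = block_prior_info(free, priors),
         log_lam = 0)
  }
  blk_r0 <- new_block(D_r0, r0)
  if (spec$use_attempts) {
    blk_att <- new_block(D_att, att_success)
  } else {
    blk_r1 <- new_block(D_r1, r1)
  }
  if (spec$use_proxy) blk_rz <- new_block(D_rz, rz)
  # a free outcome-selection slope couples strongly with the imputed
  # final scores; refresh its block again after each imputation sweep
  r1_slope_free <- !spec$use_attempts &&
    any(c("delta.Y1.R1", "delta.Y1.R1.T", "delta.Y1.R1.C") %in%
          blk_r1$free)

  # refresh standardized-score columns after imputation updates
  refresh_y0 <- function() {
    ys0 <<- standardize(y0v, std$y0)
    D_r0[, "delta.Y0.R0"] <<- ys0
    D_y1[, "delta.Y0.Y1"] <<- ys0
    if (spec$use_attempts) {
      D_att[, "delta.Y0.Rstar"] <<- ys0[att_idx]
    } else {
      D_r1[, "delta.Y0.R1"] <<- ys0
    }
    if (spec$use_proxy) {
      D_z[, "delta.Y0.Z"] <<- ys0
      D_rz[, "delta.Y0.RZ"] <<- ys0
    }
  }
  refresh_y1 <- function() {
    ys1 <<- standardize(y1v, std$y1)
    if (spec$use_attempts) {
      D_att[, "delta.Y1.Rstar"] <<- ys1[att_idx]
      if (spec$attempts_arm_by_outcome) {
        D_att[, "delta.Y1T.Rstar"] <<- ys1[att_idx] * arm[att_idx]
      }
    } else if (spec$arm_specific) {
      D_r1[, "delta.Y1.R1.T"] <<- ys1 * arm
      D_r1[, "delta.Y1.R1.C"] <<- ys1 * (1 - arm)
    } else {
      D_r1[, "delta.Y1.R1"] <<- ys1
    }
    if (spec$use_proxy) {
      D_z[, "delta.Y1.Z"] <<- ys1
      D_rz[, "delta.Y1.RZ"] <<- ys1
    }
  }
  refresh_z <- function() {
    zs <<- standardize(zv, std$z)
    D_rz[, "delta.Z.RZ"] <<- zs
  }

  # --- storage --------------------------------------------------------
  par_names <- c(colnames(Xc_y0), "sigma2.Y0",
                 colnames(D_r0),
                 colnames(D_y1), "sigma2.Y1",
                 if (spec$use_attempts) colnames(D_att) else
                   colnames(D_r1),
                 if (spec$use_proxy) c(colnames(D_z), "sigma2.Z",
                                       colnames(D_rz)))
  n_store <- mcmc$n_keep %/% mcmc$thin
  draws <- matrix(NA_real_, n_store, length(par_names),
                  dimnames = list(NULL, par_names))
  dmean_T <- rep(NA_real_, n_store)
  dmean_C <- rep(NA_real_, n_store)
  imp_y0 <- matrix(NA_real_, n_store, length(i0))
  imp_y1 <- matrix(NA_real_, n_store, length(i1))
  imp_z <- matrix(NA_real_, n_store, length(iz))
  i1_T <- i1[arm[i1] == 1]
  i1_C <- i1[arm[i1] == 0]
  obs_T <- mean(data$y1[data$arm == 1L & data$r1 == 1L])
  obs_C <- mean(data$y1[data$arm == 0L & data$r1 == 1L])

  n_iter <- mcmc$n_burn + mcmc$n_keep
  store_row <- 0L

  for (it in seq_len(n_iter)) {
    adapting <- it <= mcmc$n_burn

    # t-weights
    if (use_t) {
      res <- y1v - drop(D_y1 %*% b_y1)
      w <- rgamma(n, shape = (spec$y1_df + 1) / 2,
                  rate = (spec$y1_df + res^2 / s2_y1) / 2)
    }

    # normal regressions
    b_y0 <- draw_normal_coefs(Xc_y0, y0v, b_y0, free_of(Xc_y0), s2_y0,
                              NULL, priors)
    mu0 <- drop(Xc_y0 %*% b_y0)
    s2_y0 <- draw_variance(y0v - mu0, NULL, priors)

    b_y1 <- draw_normal_coefs(D_y1, y1v, b_y1, free_of(D_y1), s2_y1,
                              if (use_t) w else NULL, priors)
    mu1 <- drop(D_y1 %*% b_y1)
    s2_y1 <- draw_variance(y1v - mu1, if (use_t) w else NULL, priors)

    if (spec$use_proxy) {
      b_z <- draw_normal_coefs(D_z, zv, b_z, free_of(D_z), s2_z, NULL,
                               priors)
      muz <- drop(D_z %*% b_z)
      s2_z <- draw_variance(zv - muz, NULL, priors)
    }

    # logistic blocks; the high-dimensional attempts block gets extra
    # Metropolis refreshes per iteration to keep it mixing
    for (rep2 in 1:2) {
      blk_r0 <- rwm_logit(blk_r0, D_r0, r0, priors, adapting, it)
      if (!spec$use_attempts) {
        blk_r1 <- rwm_logit(blk_r1, D_r1, r1, priors, adapting, it)
      }
      if (spec$use_proxy) {
        blk_rz <- rwm_logit(blk_rz, D_rz, rz, priors, adapting, it)
      }
    }
    if (spec$use_attempts) {
      for (rep2 in 1:5) {
        blk_att <- rwm_logit(blk_att, D_att, att_success, priors,
                             adapting, it)
      }
    }

    # --- impute missing baseline scores ------------------------------
    if (length(i0) > 0) {
      # mu1 = A + c*y0 with c the per-raw-unit slope; A = mu1 - c*y0_cur
      cy1 <- b_y1[["delta.Y0.Y1"]] / std$y0$sd
      wi <- if (use_t) w[i0] else 1
      prec <- 1 / s2_y0 + cy1^2 * wi / s2_y1
      num <- mu0[i0] / s2_y0 +
        cy1 * wi * (y1v[i0] - (mu1[i0] - cy1 * y0v[i0])) / s2_y1
      if (spec$use_proxy) {
        cz <- b_z[["delta.Y0.Z"]] / std$y0$sd
        prec <- prec + cz^2 / s2_z
        num <- num + cz * (zv[i0] - (muz[i0] - cz * y0v[i0])) / s2_z
      }
      prop <- rnorm(length(i0), num / prec, sqrt(1 / prec))
      dy <- prop - y0v[i0]
      # logistic terms in the acceptance ratio
      lr <- rep(0, length(i0))
      a_r0 <- blk_r0$coef[["delta.Y0.R0"]] / std$y0$sd
      if (a_r0 != 0) {
        eta_old <- drop(D_r0[i0, , drop = FALSE] %*% blk_r0$coef)
        lr <- lr + bernoulli_loglik(r0[i0], eta_old + a_r0 * dy) -
          bernoulli_loglik(r0[i0], eta_old)
      }
      if (spec$use_attempts) {
        a_att <- blk_att$coef[["delta.Y0.Rstar"]] / std$y0$sd
        if (a_att != 0 && length(att_rows_i0) > 0) {
          eta_old <- drop(D_att[att_rows_i0, , drop = FALSE] %*%
                            blk_att$coef)
          drow <- a_att * dy[grp_i0]
          dll <- bernoulli_loglik(att_success[att_rows_i0],
                                  eta_old + drow) -
            bernoulli_loglik(att_success[att_rows_i0], eta_old)
          agg <- rowsum(dll, grp_i0)
          lr[as.integer(rownames(agg))] <-
            lr[as.integer(rownames(agg))] + drop(agg)
        }
      } else {
        a_r1 <- blk_r1$coef[["delta.Y0.R1"]] / std$y0$sd
        if (a_r1 != 0) {
          eta_old <- drop(D_r1[i0, , drop = FALSE] %*% blk_r1$coef)
          lr <- lr + bernoulli_loglik(r1[i0], eta_old + a_r1 * dy) -
            bernoulli_loglik(r1[i0], eta_old)
        }
      }
      if (spec$use_proxy) {
        a_rz <- blk_rz$coef[["delta.Y0.RZ"]] / std$y0$sd
        if (a_rz != 0) {
          eta_old <- drop(D_rz[i0, , drop = FALSE] %*% blk_rz$coef)
          lr <- lr + bernoulli_loglik(rz[i0], eta_old + a_rz * dy) -
            bernoulli_loglik(rz[i0], eta_old)
        }
      }
      acc <- log(runif(length(i0))) < lr
      y0v[i0[acc]] <- prop[acc]
      refresh_y0()
      mu1 <- drop(D_y1 %*% b_y1)
      if (spec$use_proxy) muz <- drop(D_z %*% b_z)
    }

    # --- impute missing final scores ---------------------------------
    if (length(i1) > 0) {
      wi <- if (use_t) w[i1] else 1
      prec <- wi / s2_y1
      num <- wi * mu1[i1] / s2_y1
      if (spec$use_proxy) {
        cz <- b_z[["delta.Y1.Z"]] / std$y1$sd
        prec <- prec + cz^2 / s2_z
        num <- num + cz * (zv[i1] - (muz[i1] - cz * y1v[i1])) / s2_z
      }
      prop <- rnorm(length(i1), num / prec, sqrt(1 / prec))
      dy <- prop - y1v[i1]
      lr <- rep(0, length(i1))
      if (spec$use_attempts) {
        a1 <- blk_att$coef[["delta.Y1.Rstar"]] / std$y1$sd
        a1T <- if (spec$attempts_arm_by_outcome) {
          blk_att$coef[["delta.Y1T.Rstar"]] / std$y1$sd
        } else 0
        ci <- a1 + a1T * arm[i1]
        if (any(ci != 0) && length(att_rows_i1) > 0) {
          eta_old <- drop(D_att[att_rows_i1, , drop = FALSE] %*%
                            blk_att$coef)
          drow <- ci[grp_i1] * dy[grp_i1]
          dll <- bernoulli_loglik(att_success[att_rows_i1],
                                  eta_old + drow) -
            bernoulli_loglik(att_success[att_rows_i1], eta_old)
          agg <- rowsum(dll, grp_i1)
          lr[as.integer(rownames(agg))] <- lr[as.integer(rownames(agg))] +
            drop(agg)
        }
      } else {
        ci <- if (spec$arm_specific) {
          blk_r1$coef[["delta.Y1.R1.T"]] / std$y1$sd * arm[i1] +
            blk_r1$coef[["delta.Y1.R1.C"]] / std$y1$sd * (1 - arm[i1])
        } else {
          rep(blk_r1$coef[["delta.Y1.R1"]] / std$y1$sd, length(i1))
        }
        if (any(ci != 0)) {
          eta_old <- drop(D_r1[i1, , drop = FALSE] %*% blk_r1$coef)
          lr <- lr + bernoulli_loglik(r1[i1], eta_old + ci * dy) -
            bernoulli_loglik(r1[i1], eta_old)
        }
      }
      if (spec$use_proxy) {
        a_rz <- blk_rz$coef[["delta.Y1.RZ"]] / std$y1$sd
        if (a_rz != 0) {
          eta_old <- drop(D_rz[i1, , drop = FALSE] %*% blk_rz$coef)
          lr <- lr + bernoulli_loglik(rz[i1], eta_old + a_rz * dy) -
            bernoulli_loglik(rz[i1], eta_old)
        }
      }
      acc <- log(runif(length(i1))) < lr
      y1v[i1[acc]] <- prop[acc]
      refresh_y1()
      if (spec$use_proxy) muz <- drop(D_z %*% b_z)
    }

    # --- impute missing proxy scores ---------------------------------
    if (spec$use_proxy && length(iz) > 0) {
      prec <- rep(1 / s2_z, length(iz))
      num <- muz[iz] / s2_z
      prop <- rnorm(length(iz), num / prec, sqrt(1 / prec))
      dz <- prop - zv[iz]
      lr <- rep(0, length(iz))
      a_rz <- blk_rz$coef[["delta.Z.RZ"]] / std$z$sd
      if (a_rz != 0) {
        eta_old <- drop(D_rz[iz, , drop = FALSE] %*% blk_rz$coef)
        lr <- lr + bernoulli_loglik(rz[iz], eta_old + a_rz * dz) -
          bernoulli_loglik(rz[iz], eta_old)
      }
      acc <- log(runif(length(iz))) < lr
      zv[iz[acc]] <- prop[acc]
      refresh_z()
    }

    if (r1_slope_free) {
      for (rep2 in 1:4) {
        blk_r1 <- rwm_logit(blk_r1, D_r1, r1, priors, adapting, it)
      }
    }

    # --- record -------------------------------------------------------
    if (!adapting) {
      kept <- it - mcmc$n_burn
      if (kept %% mcmc$thin == 0L) {
        store_row <- store_row + 1L
        row <- c(b_y0, sigma2.Y0 = s2_y0, blk_r0$coef,
                 b_y1, sigma2.Y1 = s2_y1,
                 if (spec$use_attempts) blk_att$coef else blk_r1$coef,
                 if (spec$use_proxy) c(b_z, sigma2.Z = s2_z,
                                       blk_rz$coef))
        draws[store_row, ] <- row[par_names]
        dmean_T[store_row] <- if (length(i1_T) > 0) {
          mean(y1v[i1_T]) - obs_T
        } else NA_real_
        dmean_C[store_row] <- if (length(i1_C) > 0) {
          mean(y1v[i1_C]) - obs_C
        } else NA_real_
        if (length(i0) > 0) imp_y0[store_row, ] <- y0v[i0]
        if (length(i1) > 0) imp_y1[store_row, ] <- y1v[i1]
        if (length(iz) > 0) imp_z[store_row, ] <- zv[iz]
      }
    }
  }

  list(draws = draws, dmean_T = dmean_T, dmean_C = dmean_C,
       imp_y0 = imp_y0, imp_y1 = imp_y1, imp_z = imp_z,
       missing_ids = list(y0 = data$participant_id[i0],
                          y1 = data$participant_id[i1],
                          z = data$participant_id[iz]))
}
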
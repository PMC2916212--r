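fake_fit <- function(draws_list, dmean_T = NULL, dmean_C = NULL) {
  structure(list(
    chains = lapply(draws_list, function(d) {
      list(draws = d,
           dmean_T = dmean_T %||% rep(NA_real_, nrow(d)),
           dmean_C = dmean_C %||% rep(NA_real_, nrow(d)))
    }),
    par_names = colnames(draws_list[[1]]),
    fixed = numeric(),
    convergence = NULL,
    mcmc = mcmc_config(n_chains = length(draws_list), n_burn = 0,
                       n_keep = nrow(draws_list[[1]])),
    data_summary = list(n = 0, n_missing_y1 = 0)
  ), class = "mnar_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("with no missing data the posterior matches least squares", {
  p <- sim_params(n = 400, response_mechanism = "logistic",
                  use_proxy = FALSE,
                  r0_coefs = c(alpha.R0 = 20),
                  r1_coefs = c(alpha.R1 = 20),
                  y1_coefs = c(alpha.Y1 = 41, delta.Y0.Y1 = 6,
                               delta.T.Y1 = 2))
  sim <- simulate_trial(p, seed = 11)
  d <- sim$data
  expect_equal(sum(d$r0 == 0) + sum(d$r1 == 0), 0)
  ys0 <- standardize(d$y0, standardizer(d$y0, d$centre))
  ls_fit <- lm(d$y1 ~ d$centre + ys0 + d$arm)
  # r0 is constant 1 here, so its (inconsequential) coefficient in the
  # R1 model is collinear with the intercept and may flag convergence
  fit <- suppressWarnings(fit_selection_model(
    d, spec_mar(),
    mcmc = mcmc_config(n_chains = 2, n_burn = 400, n_keep = 800,
                       seed = 5)))
  eff <- treatment_effect_summary(fit)
  mcse <- eff$sd / sqrt(200)   # generous effective-sample bound
  expect_lt(abs(eff$mean - coef(ls_fit)[["d$arm"]]), 4 * mcse)
  # residual variance recovered too
  s2 <- mean(pooled_param(fit, "sigma2.Y1"))
  expect_lt(abs(s2 - summary(ls_fit)$sigma^2) / s2, 0.1)
})

test_that("identical seeds give identical draws and different seeds do
           not", {
  sim <- shared_mar_sim()
  m <- mcmc_config(n_chains = 2, n_burn = 100, n_keep = 100, seed = 9)
  f1 <- suppressWarnings(fit_selection_model(sim$data, spec_mar(),
                                             mcmc = m))
  f2 <- suppressWarnings(fit_selection_model(sim$data, spec_mar(),
                                             mcmc = m))
  expect_identical(lapply(f1$chains, `[[`, "draws"),
                   lapply(f2$chains, `[[`, "draws"))
  m3 <- mcmc_config(n_chains = 2, n_burn = 100, n_keep = 100, seed = 10)
  f3 <- suppressWarnings(fit_selection_model(sim$data, spec_mar(),
                                             mcmc = m3))
  expect_false(identical(f1$chains[[1]]$draws, f3$chains[[1]]$draws))
})

test_that("point-mass constraints hold exactly in every draw and the
           stored draw count honours the configuration", {
  fit <- shared_mar_fit()
  for (nm in names(fit$fixed)) {
    expect_true(all(pooled_param(fit, nm) == fit$fixed[[nm]]))
  }
  dr <- posterior_draws(fit)
  expect_equal(nrow(dr),
               fit$mcmc$n_chains * (fit$mcmc$n_keep %/% fit$mcmc$thin))
})

test_that("requesting the unconstrained selection model warns about
           identifiability", {
  sim <- shared_mar_sim()
  expect_warning(
    fit_selection_model(sim$data, model_spec(),
                        mcmc = mcmc_config(n_chains = 1, n_burn = 20,
                                           n_keep = 20, seed = 1)),
    "poorly identified")
})

test_that("the Gelman-Rubin statistic behaves at its edge cases and
           matches a direct-formula oracle", {
  set.seed(1)
  x <- lapply(1:4, function(i) {
    matrix(rnorm(2000), 500, 4, dimnames = list(NULL, letters[1:4]))
  })
  gr <- gelman_rubin(x)
  # direct textbook computation, written independently
  oracle <- function(mat_list, p) {
    xs <- sapply(mat_list, function(m) m[, p])
    n <- nrow(xs); m <- ncol(xs)
    W <- mean(apply(xs, 2, var))
    B <- n * var(colMeans(xs))
    V <- (n - 1) / n * W + (1 + 1 / m) * B / n
    s2 <- apply(xs, 2, var); mu <- colMeans(xs)
    var_v <- ((n - 1)^2 * var(s2) / m + (1 + 1 / m)^2 * 2 * B^2 / (m - 1) +
                2 * (n - 1) * (1 + 1 / m) * (n / m) *
                (cov(s2, mu^2) - 2 * mean(mu) * cov(s2, mu))) / n^2
    d <- 2 * V^2 / var_v
    sqrt((d + 3) / (d + 1) * V / W)
  }
  for (p in letters[1:4]) {
    expect_equal(gr$rhat[gr$term == p], oracle(x, p), tolerance = 1e-8)
  }
  # agrees with the reference implementation in coda
  cl <- coda::mcmc.list(lapply(x, coda::mcmc))
  ref <- coda::gelman.diag(cl, autoburnin = FALSE,
                           multivariate = FALSE)$psrf[, 1]
  expect_equal(gr$rhat, unname(ref), tolerance = 1e-8)

  # chains that are exact copies: statistic is 1 (up to (n-1)/n)
  copies <- lapply(1:3, function(i) x[[1]])
  expect_equal(gelman_rubin(copies)$rhat, rep(1, 4), tolerance = 0.01)

  # chains with disjoint supports: far above 1
  far <- lapply(1:3, function(i) {
    matrix(rnorm(500, mean = 100 * i), 500, 1,
           dimnames = list(NULL, "a"))
  })
  expect_gt(gelman_rubin(far)$rhat[1], 5)

  expect_error(gelman_rubin(list(x[[1]])), "at least two chains")
})

test_that("posterior summaries match brute-force computation on raw
           draws", {
  set.seed(2)
  v <- rnorm(4000, 1.3, 0.8)
  d <- matrix(v, 2000, 2)
  colnames(d) <- c("delta.T.Y1", "sigma2.Y1")
  fit <- fake_fit(list(d[1:1000, ], d[1001:2000, ]))
  eff <- treatment_effect_summary(fit)
  raw <- c(d[1:1000, 1], d[1001:2000, 1])
  expect_equal(eff$mean, mean(raw))
  expect_equal(eff$sd, sd(raw))
  expect_equal(eff$conf.low, unname(quantile(raw, 0.025)))
  expect_equal(eff$conf.high, unname(quantile(raw, 0.975)))
  expect_lte(eff$conf.low, eff$mean)
  expect_gte(eff$conf.high, eff$mean)

  # degenerate posterior
  dc <- matrix(3, 50, 1, dimnames = list(NULL, "delta.T.Y1"))
  effc <- treatment_effect_summary(fake_fit(list(dc, dc)))
  expect_equal(unlist(effc), c(mean = 3, sd = 0, conf.low = 3,
                               conf.high = 3))
})

test_that("missing-minus-observed differences behave under MAR and
           error without missing scores", {
  fit <- shared_mar_fit()
  # MAR: small relative to the score SD (12)
  dT <- delta_missing_minus_observed(fit, "intervention")
  dC <- delta_missing_minus_observed(fit, "control")
  expect_lt(abs(dT$mean), 0.15 * 12)
  expect_lt(abs(dC$mean), 0.15 * 12)

  # imputations fixed at the observed mean give exactly zero
  n_m <- length(fit$missing_ids$y1)
  d0 <- matrix(0, 100, 1, dimnames = list(NULL, "delta.T.Y1"))
  f0 <- fake_fit(list(d0), dmean_T = rep(0, 100))
  expect_equal(delta_missing_minus_observed(f0, "intervention")$mean, 0)
  expect_error(delta_missing_minus_observed(f0, "control"),
               "no missing final scores")
})

test_that("tidy, glance, imputation summaries and plots expose the fit", {
  fit <- shared_mar_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high", "fixed", "rhat") %in% names(td)))
  expect_true(all(fit$par_names %in% td$term))
  expect_true(all(td$conf.low <= td$estimate + 1e-12))
  gl <- glance(fit)
  expect_equal(gl$n, 300)
  expect_equal(gl$n_draws, 2000)

  im <- imputation_summary(fit)
  expect_equal(sum(im$variable == "y1"), fit$data_summary$n_missing_y1)
  expect_true(all(im$conf.low <= im$mean & im$mean <= im$conf.high))

  expect_s3_class(autoplot(fit, type = "trace"), "ggplot")
  expect_s3_class(autoplot(fit, type = "imputations"), "ggplot")

  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(posterior_draws(fit), f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 2000)
})

test_that("model variants run end-to-end: t-distributed final scores
           and fixed arm-specific selection", {
  sim <- shared_mar_sim()
  m <- mcmc_config(n_chains = 2, n_burn = 400, n_keep = 600, seed = 77)
  # heavy-tailed final-score family (normal scale mixture internally)
  fit_t <- suppressWarnings(fit_selection_model(
    sim$data, spec_mar(y1_family = "t", y1_df = 5), mcmc = m))
  eff_t <- treatment_effect_summary(fit_t)
  expect_true(is.finite(eff_t$mean) && is.finite(eff_t$sd))
  # close to the normal-family effect on well-behaved simulated data
  eff_n <- treatment_effect_summary(shared_mar_fit())
  expect_lt(abs(eff_t$mean - eff_n$mean), 1)
  # scale parameter near the generating residual SD
  expect_lt(abs(sqrt(mean(pooled_param(fit_t, "sigma2.Y1"))) - 10.4), 3)

  # worst-case grid point: arm-specific fixed outcome selection
  cell <- suppressWarnings(run_delta_grid(
    sim$data,
    grid = list(G = c(delta.Y0.R0 = 0, delta.Y1.R1.T = 1,
                      delta.Y1.R1.C = 0)),
    mcmc = m))
  expect_true(is.finite(cell$effect_mean))
  # selection only in the intervention arm: its implied missing scores
  # drop, the control arm's stay near zero
  expect_lt(cell$delta_T_mean, -3)
  expect_gt(cell$delta_C_mean, -3)
})

test_that("MAR credible intervals achieve nominal coverage over
           replicate fits (scaled-down coverage study)", {
  cover <- 0
  for (r in 1:100) {
    sim <- simulate_trial(mar_sim_params(n = 120), seed = 1000 + r)
    fit <- suppressWarnings(fit_selection_model(
      sim$data, spec_mar(),
      mcmc = mcmc_config(n_chains = 2, n_burn = 200, n_keep = 300,
                         seed = r)))
    eff <- treatment_effect_summary(fit)
    cover <- cover + (eff$conf.low <= 2 && 2 <= eff$conf.high)
  }
  # 95% nominal; binomial 2.5-sigma band around 95/100
  expect_gte(cover, 89)
})
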
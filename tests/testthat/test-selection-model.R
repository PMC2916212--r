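test_that("linear predictor accumulates coefficient times covariate", {
  d <- tiny_trial()
  d$y0[3] <- 40
  d$y1[2] <- 39
  d$z[3] <- 20
  std <- unit_standardizers()

  expect_equal(linear_predictor(c(alpha.R1 = 0, delta.Y0.R1 = 0), d, std),
               rep(0, 4))
  expect_equal(linear_predictor(c(alpha.R1 = 1.7), d, std), rep(1.7, 4))

  # brute-force dot product over a random coefficient map
  set.seed(4)
  co <- c(alpha.R1 = rnorm(1), delta.X2.R1 = rnorm(1),
          delta.X3.R1 = rnorm(1), delta.Y0.R1 = rnorm(1),
          delta.R0.R1 = rnorm(1), delta.T.R1 = rnorm(1),
          delta.Y1.R1 = rnorm(1))
  want <- co[["alpha.R1"]] +
    co[["delta.X2.R1"]] * (d$centre == "centre_2") +
    co[["delta.X3.R1"]] * (d$centre == "centre_3") +
    co[["delta.Y0.R1"]] * d$y0 + co[["delta.R0.R1"]] * d$r0 +
    co[["delta.T.R1"]] * d$arm + co[["delta.Y1.R1"]] * d$y1
  expect_equal(linear_predictor(co, d, std), as.numeric(want))

  # arm-specific terms multiply the standardized score by T and 1-T
  co2 <- c(delta.Y1.R1.T = 2, delta.Y1.R1.C = -1)
  expect_equal(linear_predictor(co2, d, std),
               2 * d$y1 * d$arm - 1 * d$y1 * (1 - d$arm))

  # a needed covariate with no imputation is a state error
  d_na <- tiny_trial()
  expect_error(linear_predictor(c(delta.Y0.R1 = 1), d_na, std),
               "no current imputation")
})

test_that("complete-data log-likelihood has its closed forms", {
  d1 <- trial_data(tibble::tibble(
    participant_id = "a",
    centre = factor("centre_1", levels = paste0("centre_", 1:4)),
    arm = 0L, y0 = 0, y1 = 0, z = NA
  ))
  par1 <- full_params(model_spec())
  std <- unit_standardizers()
  # all coefficients zero, unit variances, scores at their means:
  # two standard-normal densities and two Bernoulli(1/2) terms
  expect_equal(complete_data_loglik(par1, d1, model_spec(), std),
               2 * dnorm(0, log = TRUE) + 2 * log(0.5))

  expect_error(
    complete_data_loglik(replace(par1, "sigma2.Y1", -1), d1,
                         model_spec(), std),
    "positive")
})

test_that("the t family approaches the normal likelihood as df grows", {
  sim <- simulate_trial(mar_sim_params(n = 50), seed = 9)
  d <- sim$data
  d$y0 <- sim$truth$y0
  d$y1 <- sim$truth$y1
  par <- full_params(model_spec(),
                     c(alpha.Y0 = 39, sigma2.Y0 = 121, alpha.Y1 = 41,
                       delta.T.Y1 = 2, sigma2.Y1 = 108, alpha.R1 = 1.5))
  std <- list(y0 = standardizer(d$y0, d$centre),
              y1 = standardizer(d$y1, d$centre), z = NULL)
  ll_n <- complete_data_loglik(par, d, model_spec(), std)
  ll_t <- complete_data_loglik(par, d,
                               model_spec(y1_family = "t", y1_df = 1e6),
                               std)
  expect_lt(abs(ll_n - ll_t), 1e-4)
  # and differs materially at small df
  ll_t5 <- complete_data_loglik(par, d,
                                model_spec(y1_family = "t", y1_df = 5),
                                std)
  expect_gt(abs(ll_n - ll_t5), 0.1)
})

test_that("log-likelihood equals a factor-by-factor oracle", {
  sim <- simulate_trial(quatro_sim_params(n = 20), seed = 15)
  d <- sim$data
  d$y0 <- sim$truth$y0
  d$y1 <- sim$truth$y1
  d$z <- sim$truth$z
  spec <- model_spec(use_proxy = TRUE)
  set.seed(2)
  nms <- names(full_params(spec))
  par <- setNames(rnorm(length(nms), 0, 0.3), nms)
  par[c("alpha.Y0", "alpha.Y1", "alpha.Z")] <- c(39, 41, 20)
  par[c("sigma2.Y0", "sigma2.Y1", "sigma2.Z")] <- c(121, 144, 36)
  std <- list(y0 = standardizer(d$y0, d$centre),
              y1 = standardizer(d$y1, d$centre),
              z = standardizer(d$z, d$centre))
  # oracle: evaluate each model factor one participant at a time
  ys0 <- standardize(d$y0, std$y0)
  ys1 <- standardize(d$y1, std$y1)
  zs <- standardize(d$z, std$z)
  x2 <- as.numeric(d$centre == "centre_2")
  x3 <- as.numeric(d$centre == "centre_3")
  x4 <- as.numeric(d$centre == "centre_4")
  ll <- 0
  for (i in seq_len(20)) {
    mu0 <- par["alpha.Y0"] + par["delta.X2.Y0"] * x2[i] +
      par["delta.X3.Y0"] * x3[i] + par["delta.X4.Y0"] * x4[i]
    ll <- ll + dnorm(d$y0[i], mu0, sqrt(par["sigma2.Y0"]), log = TRUE)
    e0 <- par["alpha.R0"] + par["delta.X2.R0"] * x2[i] +
      par["delta.X3.R0"] * x3[i] + par["delta.X4.R0"] * x4[i] +
      par["delta.Y0.R0"] * ys0[i]
    ll <- ll + dbinom(d$r0[i], 1, plogis(e0), log = TRUE)
    mu1 <- par["alpha.Y1"] + par["delta.X2.Y1"] * x2[i] +
      par["delta.X3.Y1"] * x3[i] + par["delta.X4.Y1"] * x4[i] +
      par["delta.Y0.Y1"] * ys0[i] + par["delta.R0.Y1"] * d$r0[i] +
      par["delta.T.Y1"] * d$arm[i]
    ll <- ll + dnorm(d$y1[i], mu1, sqrt(par["sigma2.Y1"]), log = TRUE)
    e1 <- par["alpha.R1"] + par["delta.X2.R1"] * x2[i] +
      par["delta.X3.R1"] * x3[i] + par["delta.X4.R1"] * x4[i] +
      par["delta.Y0.R1"] * ys0[i] + par["delta.R0.R1"] * d$r0[i] +
      par["delta.T.R1"] * d$arm[i] + par["delta.Y1.R1"] * ys1[i]
    ll <- ll + dbinom(d$r1[i], 1, plogis(e1), log = TRUE)
    muz <- par["alpha.Z"] + par["delta.X2.Z"] * x2[i] +
      par["delta.X3.Z"] * x3[i] + par["delta.X4.Z"] * x4[i] +
      par["delta.Y0.Z"] * ys0[i] + par["delta.R0.Z"] * d$r0[i] +
      par["delta.T.Z"] * d$arm[i] + par["delta.Y1.Z"] * ys1[i] +
      par["delta.R1.Z"] * d$r1[i]
    ll <- ll + dnorm(d$z[i], muz, sqrt(par["sigma2.Z"]), log = TRUE)
    ez <- par["alpha.RZ"] + par["delta.X2.RZ"] * x2[i] +
      par["delta.X3.RZ"] * x3[i] + par["delta.X4.RZ"] * x4[i] +
      par["delta.Y0.RZ"] * ys0[i] + par["delta.R0.RZ"] * d$r0[i] +
      par["delta.T.RZ"] * d$arm[i] + par["delta.Y1.RZ"] * ys1[i] +
      par["delta.R1.RZ"] * d$r1[i] + par["delta.Z.RZ"] * zs[i]
    ll <- ll + dbinom(d$rz[i], 1, plogis(ez), log = TRUE)
  }
  expect_equal(complete_data_loglik(par, d, spec, std), unname(ll))
})

test_that("attempt success probability depends on m only through the
           intercepts and matches brute-force evaluation", {
  spec <- model_spec(use_attempts = TRUE)
  d <- tiny_trial()[1, ]
  std <- unit_standardizers()
  par <- c(setNames(c(-0.5, 0.3, -1), paste0("alpha.m", 1:3)),
           delta.type.Rstar = 0.4, delta.X2.Rstar = 0.2,
           delta.X3.Rstar = 0, delta.X4.Rstar = 0,
           delta.X2m2.Rstar = 0, delta.X3m2.Rstar = 0,
           delta.X4m2.Rstar = 0, delta.X2m3.Rstar = 0,
           delta.X3m3.Rstar = 0, delta.X4m3.Rstar = 0,
           delta.T.Rstar = -0.3, delta.Y0.Rstar = 0.25,
           delta.Y1.Rstar = 0.6)
  # all slopes zero: inverse-logit of the attempt intercept
  par0 <- par
  par0[setdiff(names(par0), paste0("alpha.m", 1:3))] <- 0
  expect_equal(attempt_success_probability(2, d, par0, spec,
                                           standardizers = std),
               plogis(0.3))
  # shared coefficients: probabilities at m = 1 vs m = 9 (outside the
  # centre-by-attempt window) differ only via alpha_m
  par9 <- c(par, alpha.m9 = -0.5)  # same intercept as m = 1
  p1 <- attempt_success_probability(1, d, par9, spec, attempt_type = 1,
                                    standardizers = std)
  p9 <- attempt_success_probability(9, d, par9, spec, attempt_type = 1,
                                    standardizers = std)
  expect_equal(p1, p9)
  # brute force
  eta <- par[["alpha.m1"]] + par[["delta.type.Rstar"]] * 1 +
    par[["delta.T.Rstar"]] * d$arm + par[["delta.Y0.Rstar"]] * d$y0 +
    par[["delta.Y1.Rstar"]] * d$y1
  expect_equal(attempt_success_probability(1, d, par, spec,
                                           attempt_type = 1,
                                           standardizers = std),
               plogis(as.numeric(eta)))
  expect_error(attempt_success_probability(10, d, par, spec), "1..9")
})

test_that("with one allowed attempt the attempts likelihood reduces to
           the single-logistic likelihood with matched coefficients", {
  p <- sim_params(n = 120, response_mechanism = "attempts",
                  max_attempts = 1, use_proxy = FALSE,
                  r0_coefs = c(alpha.R0 = 20), attempt_type_prob = 1,
                  attempt_coefs = c(delta.T.Rstar = -0.4,
                                    delta.Y0.Rstar = 0.3,
                                    delta.Y1.Rstar = 0.6))
  sim <- simulate_trial(p, seed = 4)
  d <- sim$data
  d$y1 <- sim$truth$y1   # fill imputations with the truth
  std <- list(y0 = standardizer(d$y0, d$centre),
              y1 = standardizer(sim$data$y1, d$centre), z = NULL)
  spec_att <- model_spec(use_attempts = TRUE,
                         attempts_centre_by_attempt = FALSE,
                         attempts_type = FALSE)
  common <- c(alpha.Y0 = 39, delta.X2.Y0 = 0.5, delta.X3.Y0 = 0,
              delta.X4.Y0 = 1, sigma2.Y0 = 121,
              alpha.R0 = 2, delta.X2.R0 = 0.1, delta.X3.R0 = 0,
              delta.X4.R0 = 0, delta.Y0.R0 = 0.2,
              alpha.Y1 = 41, delta.X2.Y1 = 0, delta.X3.Y1 = 0.3,
              delta.X4.Y1 = 0, delta.Y0.Y1 = 6, delta.R0.Y1 = 0.5,
              delta.T.Y1 = -0.4, sigma2.Y1 = 108)
  shared <- c(0.9, 0.2, 0, -0.1, -0.4, 0.3, 0.6)
  par_att <- c(common, setNames(shared, c(
    "alpha.m1", "delta.X2.Rstar", "delta.X3.Rstar", "delta.X4.Rstar",
    "delta.T.Rstar", "delta.Y0.Rstar", "delta.Y1.Rstar")))
  par_log <- c(common, setNames(shared, c(
    "alpha.R1", "delta.X2.R1", "delta.X3.R1", "delta.X4.R1",
    "delta.T.R1", "delta.Y0.R1", "delta.Y1.R1")), delta.R0.R1 = 0)
  expect_equal(complete_data_loglik(par_att, d, spec_att, std),
               complete_data_loglik(par_log, d, model_spec(), std))
})

test_that("with zero selection coefficients the response factors are
           invariant to the imputed scores", {
  sim <- simulate_trial(mar_sim_params(n = 60), seed = 6)
  d1 <- sim$data
  d1$y0[is.na(d1$y0)] <- 39
  d1$y1[is.na(d1$y1)] <- 41
  d2 <- d1
  miss1 <- which(sim$data$r1 == 0)
  d2$y1[miss1] <- d1$y1[miss1] + rnorm(length(miss1), 0, 5)
  spec <- model_spec()
  par <- full_params(spec, c(alpha.Y0 = 39, sigma2.Y0 = 121,
                             alpha.Y1 = 41, sigma2.Y1 = 144,
                             alpha.R0 = 2.8, alpha.R1 = 1.7,
                             delta.R0.R1 = 1, delta.T.R1 = -0.5))
  std <- list(y0 = standardizer(sim$data$y0, d1$centre),
              y1 = standardizer(sim$data$y1, d1$centre), z = NULL)
  ll1 <- complete_data_loglik(par, d1, spec, std)
  ll2 <- complete_data_loglik(par, d2, spec, std)
  # the difference is exactly the difference in the Y1 density terms
  dy <- sum(dnorm(d1$y1[miss1], 41, 12, log = TRUE)) -
    sum(dnorm(d2$y1[miss1], 41, 12, log = TRUE))
  expect_equal(ll1 - ll2, dy)
})

test_that("pattern-mixture / selection conversion is exact and matches
           a logistic-regression oracle", {
  expect_equal(pattern_mixture_to_selection(40, 40, 10)$b, 0)
  # a 2.5-point lower mean among the missing at reference SD 10 is a
  # per-SD selection slope of 0.25
  conv <- pattern_mixture_to_selection(40, 37.5, 10)
  expect_equal(conv$b_per_sd, 0.25)
  expect_equal(conv$b, 0.025)

  # bijection for fixed sigma
  set.seed(8)
  for (i in 1:20) {
    mu_o <- rnorm(1, 40, 5)
    mu_m <- rnorm(1, 38, 5)
    sig <- runif(1, 5, 15)
    b <- pattern_mixture_to_selection(mu_o, mu_m, sig)$b
    expect_equal(selection_to_pattern_mixture(b, sig), mu_o - mu_m,
                 tolerance = 1e-10)
  }
  expect_equal(selection_to_pattern_mixture(0, 10), 0)
  expect_error(pattern_mixture_to_selection(1, 0, -2), "positive")

  # two-pattern normal simulation: logistic fit recovers b
  set.seed(12)
  n <- 1e5
  mu_o <- 41; mu_m <- 35; sig <- 10
  pi_o <- 0.8
  r <- rbinom(n, 1, pi_o)
  y <- rnorm(n, ifelse(r == 1, mu_o, mu_m), sig)
  fit <- glm(r ~ y, family = binomial())
  b_hat <- coef(fit)[["y"]]
  se <- sqrt(vcov(fit)["y", "y"])
  b <- pattern_mixture_to_selection(mu_o, mu_m, sig)$b
  expect_lt(abs(b_hat - b), 2 * se)
})

test_that("model specifications validate and serialize", {
  expect_error(model_spec(fixed = c(delta.Y1.R1 = 0),
                          arm_specific = TRUE), "arm_specific")
  expect_error(model_spec(fixed = c(delta.Y1.R1 = 0),
                          use_attempts = TRUE), "identifiable")
  expect_error(model_spec(y1_family = "t", y1_df = Inf), "finite")

  spec <- model_spec(fixed = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0.5),
                     y1_family = "t", y1_df = 5, use_proxy = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, f)
  spec2 <- read_model_spec(f)
  expect_equal(spec2$fixed, spec$fixed)
  expect_equal(spec2$y1_df, 5)
  expect_true(spec2$use_proxy)
})
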
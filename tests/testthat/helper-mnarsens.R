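# shared helpers for the test suite: tiny datasets, full parameter
# vectors for likelihood checks, and one memoised moderate MAR fit that
# several tests interrogate

tiny_trial <- function() {
  trial_data(
    tibble::tibble(
      participant_id = c("a", "b", "c", "d"),
      centre = factor(paste0("centre_", c(1, 2, 4, 3)),
                      levels = paste0("centre_", 1:4)),
      arm = c(1L, 0L, 1L, 0L),
      y0 = c(35, 42, NA, 39),
      y1 = c(41, NA, 44, 38),
      z = c(21, 18, NA, 22)
    ),
    tibble::tibble(
      participant_id = c("a", "b", "b", "c", "d"),
      m = c(1L, 1L, 2L, 1L, 1L),
      attempt_type = c(1L, 1L, 0L, 1L, 1L),
      success = c(1L, 0L, 0L, 1L, 1L)
    )
  )
}

# every coefficient for `spec` set to zero (variances 1), with overrides
full_params <- function(spec, overrides = c(), k = 4, max_m = 9) {
  cn <- mnarsens:::coef_names(spec, k, max_m)
  nms <- unlist(cn, use.names = FALSE)
  par <- stats::setNames(rep(0, length(nms)), nms)
  par[mnarsens:::variance_names(spec)] <- 1
  par[names(overrides)] <- overrides
  par
}

unit_standardizers <- function() {
  s <- function() structure(list(mean = 0, sd = 1), class = "standardizer")
  list(y0 = s(), y1 = s(), z = s())
}

mar_sim_params <- function(n = 300, effect = 2) {
  sim_params(n = n, response_mechanism = "logistic", use_proxy = FALSE,
             r0_coefs = c(alpha.R0 = 2.8),
             r1_coefs = c(alpha.R1 = 1.7, delta.R0.R1 = 1,
                          delta.T.R1 = -0.5),
             y1_coefs = c(alpha.Y1 = 41, delta.Y0.Y1 = 6,
                          delta.T.Y1 = effect))
}

# one moderate MAR fit shared across tests (built on first use)
.shared <- new.env(parent = emptyenv())

shared_mar_fit <- function() {
  if (is.null(.shared$fit)) {
    sim <- simulate_trial(mar_sim_params(n = 300), seed = 42)
    .shared$sim <- sim
    .shared$fit <- suppressWarnings(fit_selection_model(
      sim$data, spec_mar(),
      mcmc = mcmc_config(n_chains = 2, n_burn = 600, n_keep = 1000,
                         seed = 7)
    ))
  }
  .shared$fit
}

shared_mar_sim <- function() {
  invisible(shared_mar_fit())
  .shared$sim
}
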
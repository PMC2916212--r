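#' Pattern-mixture to selection-model conversion
#'
#' For a normally distributed score with common SD `sigma` in both
#' response patterns and pattern means `mu_o` (observed, R = 1) and `mu_m`
#' (missing, R = 0), the log-odds of response conditional on the score y
#' is linear in y with slope `b = (mu_o - mu_m)/sigma^2` per raw score
#' unit; on the standardized scale the slope is `b * sigma =
#' (mu_o - mu_m)/sigma`. This identity is what lets elicited
#' pattern-mixture beliefs (differences in means) be re-expressed as fixed
#' values or priors for the outcome coefficient of a logistic selection
#' model.
#'
#' @param mu_o,mu_m Pattern means of the score among responders and
#'   non-responders.
#' @param sigma Common within-pattern SD (> 0).
#' @return Tibble with columns `b` (logit per raw unit) and `b_per_sd`
#'   (logit per SD).
#' @export
pattern_mixture_to_selection <- function(mu_o, mu_m, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  tibble::tibble(b = (mu_o - mu_m) / sigma^2,
                 b_per_sd = (mu_o - mu_m) / sigma)
}

#' Selection-model to pattern-mixture conversion
#'
#' Inverse of [pattern_mixture_to_selection()] under the same
#' equal-variance two-pattern normal model: a raw-unit logistic slope `b`
#' implies a responder-minus-non-responder mean difference
#' `mu_o - mu_m = b * sigma^2`. The difference does not depend on the
#' marginal response probability, which is therefore accepted but unused
#' (it only shifts the intercept of the response model).
#'
#' @param b Logistic slope of response on the raw score.
#' @param sigma Common within-pattern SD (> 0).
#' @param response_prob Marginal response probability; unused.
#' @return Mean difference `mu_o - mu_m` (raw score units).
#' @export
selection_to_pattern_mixture <- function(b, sigma, response_prob = NULL) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  b * sigma^2
}
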
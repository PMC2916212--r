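#' Elicitation categories and midpoints
#'
#' Expert beliefs about the difference in mean final score between
#' non-responders and responders are elicited by distributing a total
#' weight of 100 across nine ordered categories: lower than responders by
#' 13 or more, 9-12, 5-8 or 1-4 points; the same; or higher by 1-4, 5-8,
#' 9-12 or 13 or more points. Moments are extracted using the category
#' midpoints, with 14.5 for the two open-ended extreme categories.
#'
#' @return `category_midpoints()` returns the nine midpoints (increasing);
#'   `category_labels()` the matching labels.
#' @export
category_midpoints <- function() {
  c(-14.5, -10.5, -6.5, -2.5, 0, 2.5, 6.5, 10.5, 14.5)
}

#' @rdname category_midpoints
#' @export
category_labels <- function() {
  c("lower_13plus", "lower_9_12", "lower_5_8", "lower_1_4", "same",
    "higher_1_4", "higher_5_8", "higher_9_12", "higher_13plus")
}

weight_cols <- function() paste0("w_", category_labels())

#' Validate a table of expert elicitation results
#'
#' @param x Data frame with one row per expert: `expert_id`, nine weight
#'   columns `w_lower_13plus` ... `w_higher_13plus` (non-negative, summing
#'   to 100 per expert) and optionally the correlation-anchor columns
#'   `avg_diff`, `max_diff`, `revised_guess`.
#' @return The validated tibble, classed `elicitation_table`.
#' @export
elicitation_table <- function(x) {
  x <- tibble::as_tibble(x)
  miss <- setdiff(c("expert_id", weight_cols()), names(x))
  if (length(miss) > 0) {
    stop("elicitation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  w <- as.matrix(x[weight_cols()])
  if (any(w < 0)) stop("weights must be non-negative")
  tot <- rowSums(w)
  if (any(abs(tot - 100) > 1e-6)) {
    stop("weights must sum to 100 for every expert (found ",
         format(tot[which.max(abs(tot - 100))]), ")")
  }
  class(x) <- unique(c("elicitation_table", class(x)))
  x
}

#' Read elicitation tables from CSV
#'
#' @param path CSV with the columns documented in [elicitation_table()].
#' @return An `elicitation_table` tibble.
#' @export
read_elicitation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  elicitation_table(readr::read_csv(path, show_col_types = FALSE,
                                    progress = FALSE))
}

#' Linear opinion pool of expert weight tables
#'
#' Averages the experts' weight vectors category by category (an unweighted
#' linear opinion pooling rule). Because the pool is linear, the midpoint
#' mean of the pooled distribution equals the average of the per-expert
#' midpoint means.
#'
#' @param tables An [elicitation_table()] (one row per expert).
#' @return Tibble with columns `category`, `midpoint`, `weight`; weights
#'   sum to 100.
#' @export
pool_opinions <- function(tables) {
  tables <- elicitation_table(tables)
  if (nrow(tables) == 0) stop("need at least one expert")
  w <- colMeans(as.matrix(tables[weight_cols()]))
  tibble::tibble(category = category_labels(),
                 midpoint = category_midpoints(),
                 weight = unname(w))
}

#' Moments of a category-weight distribution
#'
#' Treats `weights/100` as probabilities on the midpoint support and
#' returns the implied mean and standard deviation of the
#' missing-minus-observed score difference.
#'
#' @param weights Either a numeric vector of nine weights (category order
#'   of [category_labels()]) or the tibble returned by [pool_opinions()].
#' @param midpoints Nine strictly increasing support points.
#' @return Tibble with columns `mean` and `sd`.
#' @export
moments_from_weights <- function(weights, midpoints = category_midpoints()) {
  if (is.data.frame(weights)) {
    if (!is.null(weights$midpoint)) midpoints <- weights$midpoint
    weights <- weights$weight
  }
  if (length(weights) != length(midpoints)) {
    stop("need one weight per category")
  }
  if (any(weights < 0) || abs(sum(weights) - 100) > 1e-6) {
    stop("weights must be non-negative and sum to 100")
  }
  if (any(diff(midpoints) <= 0)) stop("midpoints must be increasing")
  p <- weights / 100
  m <- sum(p * midpoints)
  v <- sum(p * (midpoints - m)^2)
  tibble::tibble(mean = m, sd = sqrt(v))
}

#' Between-arm belief correlation from the anchoring question
#'
#' After stating their average expected non-responder/responder difference
#' in the intervention arm, each expert is told to suppose the control-arm
#' difference is as large as their own maximum and asked for a revised
#' intervention-arm guess. An unchanged guess is read as uncorrelated
#' beliefs between arms (0); revising all the way to the maximum as
#' perfect positive correlation (1); intermediate answers interpolate
#' linearly and results are clipped to [0, 1].
#'
#' @param avg_diff,max_diff,revised_guess Numeric vectors (recycled).
#' @return Correlations in [0, 1].
#' @export
correlation_from_anchors <- function(avg_diff, max_diff, revised_guess) {
  if (any(max_diff == avg_diff)) {
    stop("anchor question undefined when max_diff equals avg_diff")
  }
  pmin(pmax((revised_guess - avg_diff) / (max_diff - avg_diff), 0), 1)
}

#' Selection-model prior from a pattern-mixture belief
#'
#' Elicited beliefs concern the difference `mu_m - mu_o` between the mean
#' final score of non-responders and responders, stated relative to a
#' reference outcome SD (`sigma`, 10 in the elicitation questionnaire).
#' Under the equal-variance two-pattern normal model the per-SD logistic
#' selection slope is `(mu_o - mu_m)/sigma`, so a normal belief
#' `mu_m - mu_o ~ N(mean_diff, var_diff)` maps to a normal prior with mean
#' `-mean_diff/sigma` and variance `var_diff/sigma^2` for the coefficient
#' of the standardized outcome in the response logistic regression.
#' Beliefs are regarded as scaling with sigma, so the per-SD prior is
#' invariant to the realized outcome SD.
#'
#' @param mean_diff Belief mean for `mu_m - mu_o` (score units).
#' @param var_diff Belief variance (score units squared).
#' @param sigma Reference SD the beliefs were stated against.
#' @return Tibble with columns `mean` and `variance` (per-SD logit scale).
#' @export
prior_for_delta <- function(mean_diff, var_diff, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(var_diff <= 0)) stop("var_diff must be positive")
  tibble::tibble(mean = -mean_diff / sigma, variance = var_diff / sigma^2)
}

#' Pool arm-specific elicited moments into a common prior
#'
#' Averages the two arms' belief means and SDs; the pooled variance is the
#' squared averaged SD. Reported both unrounded and rounded to the nearest
#' integer, since pooled variances are conventionally quoted rounded.
#'
#' @param intervention,control Length-2 numeric vectors `c(mean, sd)`.
#' @return Tibble with columns `mean`, `sd`, `variance`,
#'   `variance_rounded`.
#' @export
combine_arms <- function(intervention, control) {
  stopifnot(length(intervention) == 2, length(control) == 2)
  if (intervention[2] <= 0 || control[2] <= 0) stop("sds must be positive")
  m <- mean(c(intervention[1], control[1]))
  s <- mean(c(intervention[2], control[2]))
  tibble::tibble(mean = m, sd = s, variance = s^2,
                 variance_rounded = round(s^2))
}
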
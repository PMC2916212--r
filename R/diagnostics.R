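#' Gelman-Rubin potential scale reduction
#'
#' Computes the corrected potential scale reduction factor per monitored
#' parameter from the kept draws of a multi-chain fit: with m chains of
#' length n, within-chain variance W, between-chain variance B (n times
#' the variance of the chain means) and pooled variance estimate
#' V = (n-1)/n W + (1 + 1/m) B/n, the statistic is
#' sqrt((d+3)/(d+1) * V/W) with d the method-of-moments degrees of
#' freedom of V. Values near 1 indicate the chains have mixed;
#' parameters exceeding `threshold` are flagged. Coefficients held fixed
#' by the model spec have zero variance and report `NA`.
#'
#' @param fit An `mnar_fit` (or a list of draw matrices with identical
#'   column names, one per chain).
#' @param threshold Flagging threshold (default 1.05).
#' @return Tibble with `term`, `rhat`, `flag`.
#' @export
gelman_rubin <- function(fit, threshold = 1.05) {
  draws <- if (inherits(fit, "mnar_fit")) {
    lapply(fit$chains, function(ch) ch$draws)
  } else fit
  if (!is.list(draws) || length(draws) < 2) {
    stop("need at least two chains for the Gelman-Rubin statistic")
  }
  terms <- colnames(draws[[1]])
  rhat <- vapply(terms, function(p) {
    psrf(vapply(draws, function(d) d[, p], numeric(nrow(draws[[1]]))))
  }, numeric(1))
  tibble::tibble(term = terms, rhat = unname(rhat),
                 flag = !is.na(rhat) & rhat > threshold)
}

# x: n x m matrix, one column per chain
psrf <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  xbar <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * stats::var(xbar)
  V <- (n - 1) / n * W + (1 + 1 / m) * B / n
  var_w <- stats::var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(s2, xbar^2) -
                         2 * mean(xbar) * stats::cov(s2, xbar))
  var_v <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
  ratio <- V / W
  if (!is.finite(var_v) || var_v <= 0) return(sqrt(ratio))
  d <- 2 * V^2 / var_v
  sqrt((d + 3) / (d + 1) * ratio)
}

#' Convergence report
#'
#' Machine-readable convergence summary of a fit: the Gelman-Rubin table
#' plus an overall flag. Serializable to JSON with `jsonlite`.
#'
#' @param fit An `mnar_fit`.
#' @param threshold Flagging threshold.
#' @return List with elements `threshold`, `converged`, `table`.
#' @export
convergence_report <- function(fit, threshold = 1.05) {
  stopifnot(inherits(fit, "mnar_fit"))
  tab <- if (fit$mcmc$n_chains >= 2) {
    gelman_rubin(fit, threshold)
  } else {
    tibble::tibble(term = fit$par_names, rhat = NA_real_, flag = NA)
  }
  list(threshold = threshold,
       converged = if (fit$mcmc$n_chains >= 2) {
         !any(tab$flag, na.rm = TRUE)
       } else NA,
       table = tab)
}
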
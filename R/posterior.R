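#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# pooled draws of one parameter across chains
pooled_param <- function(fit, term) {
  if (!term %in% fit$par_names) stop("unknown parameter: ", term)
  unlist(lapply(fit$chains, function(ch) ch$draws[, term]),
         use.names = FALSE)
}

#' Posterior draws as a tibble
#'
#' One row per kept draw with one column per parameter plus the derived
#' missing-minus-observed mean differences; suitable for CSV export.
#'
#' @param fit An `mnar_fit`.
#' @return Tibble with columns `chain`, `draw`, every parameter, and
#'   `Delta.Y1.T` / `Delta.Y1.C` where defined.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "mnar_fit"))
  out <- purrr::imap(fit$chains, function(ch, i) {
    d <- tibble::as_tibble(ch$draws)
    d$Delta.Y1.T <- ch$dmean_T
    d$Delta.Y1.C <- ch$dmean_C
    d$chain <- i
    d$draw <- seq_len(nrow(d))
    d
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("chain", "draw")
}

#' Posterior summary of the treatment effect
#'
#' Summaries of the marginal posterior of `delta.T.Y1`, the coefficient
#' of randomized arm in the final-score regression (score units,
#' intervention minus control).
#'
#' @param fit An `mnar_fit`.
#' @param conf_level Credible level for the equal-tailed interval.
#' @return Tibble with `mean`, `sd`, `conf.low`, `conf.high`.
#' @export
treatment_effect_summary <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mnar_fit"))
  x <- pooled_param(fit, "delta.T.Y1")
  a <- (1 - conf_level) / 2
  q <- unname(stats::quantile(x, c(a, 1 - a)))
  tibble::tibble(mean = mean(x), sd = stats::sd(x),
                 conf.low = q[1], conf.high = q[2])
}

#' Missing-minus-observed final-score difference
#'
#' Per kept draw, the mean of the currently imputed missing final scores
#' minus the (fixed) mean of the observed final scores in the requested
#' arm; summarised by its posterior mean and SD. Near zero this indicates
#' the fitted model treats missing final scores like observed ones
#' (departure from missingness completely at random is small); strongly
#' negative values arise when selection against low scores is assumed or
#' inferred.
#'
#' @param fit An `mnar_fit`.
#' @param arm `"intervention"` or `"control"`.
#' @return Tibble with `arm`, `mean`, `sd`.
#' @export
delta_missing_minus_observed <- function(fit,
                                         arm = c("intervention",
                                                 "control")) {
  stopifnot(inherits(fit, "mnar_fit"))
  arm <- match.arg(arm)
  draws <- unlist(lapply(fit$chains, function(ch) {
    if (arm == "intervention") ch$dmean_T else ch$dmean_C
  }), use.names = FALSE)
  if (all(is.na(draws))) {
    stop("no missing final scores in the ", arm, " arm")
  }
  tibble::tibble(arm = arm, mean = mean(draws), sd = stats::sd(draws))
}

#' @rdname tidy.mnar_fit
#' @exportS3Method generics::glance
glance.mnar_fit <- function(x, ...) {
  eff <- treatment_effect_summary(x)
  rhat <- if (!is.null(x$convergence)) {
    suppressWarnings(max(x$convergence$rhat, na.rm = TRUE))
  } else NA_real_
  tibble::tibble(
    n = x$data_summary$n,
    n_missing_y1 = x$data_summary$n_missing_y1,
    n_chains = x$mcmc$n_chains,
    n_draws = x$mcmc$n_chains * (x$mcmc$n_keep %/% x$mcmc$thin),
    effect = eff$mean, effect_sd = eff$sd,
    max_rhat = rhat,
    converged = if (is.na(rhat)) NA else !any(x$convergence$flag,
                                              na.rm = TRUE)
  )
}

#' Tidy posterior summaries of a fitted selection model
#'
#' One row per monitored parameter: posterior mean, SD, equal-tailed
#' credible interval, whether the coefficient was held fixed, and the
#' Gelman-Rubin statistic when several chains were run.
#'
#' @param x An `mnar_fit`.
#' @param conf.level Credible level.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.mnar_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  rows <- purrr::map(x$par_names, function(p) {
    d <- pooled_param(x, p)
    q <- unname(stats::quantile(d, c(a, 1 - a)))
    tibble::tibble(term = p, estimate = mean(d),
                   std.error = stats::sd(d),
                   conf.low = q[1], conf.high = q[2],
                   fixed = p %in% names(x$fixed))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(x$convergence)) {
    out <- dplyr::left_join(out,
                            x$convergence[c("term", "rhat")],
                            by = "term")
  }
  out
}

#' @export
print.mnar_fit <- function(x, ...) {
  cat("<mnar_fit> joint selection model,",
      x$data_summary$n, "participants\n")
  cat("  final-response arc:",
      if (x$spec$use_attempts) "repeated attempts" else "logistic",
      "| proxies:", if (x$spec$use_proxy) "yes" else "no",
      "| Y1 family:", x$spec$y1_family, "\n")
  cat(sprintf("  chains: %d x %d kept (burn %d)\n", x$mcmc$n_chains,
              x$mcmc$n_keep, x$mcmc$n_burn))
  eff <- treatment_effect_summary(x)
  cat(sprintf("  treatment effect delta.T.Y1: %.2f (sd %.2f)\n",
              eff$mean, eff$sd))
  for (a in c("intervention", "control")) {
    ok <- tryCatch(delta_missing_minus_observed(x, a),
                   error = function(e) NULL)
    if (!is.null(ok)) {
      cat(sprintf("  Delta(Y1, %s): %.2f (sd %.2f)\n", a, ok$mean,
                  ok$sd))
    }
  }
  if (!is.null(x$convergence)) {
    nf <- sum(x$convergence$flag, na.rm = TRUE)
    cat("  convergence:",
        if (nf == 0) "all Gelman-Rubin statistics below threshold"
        else paste(nf, "parameter(s) flagged"), "\n")
  }
  invisible(x)
}

#' Posterior summaries of the imputed missing scores
#'
#' @param fit An `mnar_fit`.
#' @param conf_level Credible level for the per-value interval.
#' @return Tibble with `variable` (y0/y1/z), `participant_id`, `mean`,
#'   `sd`, `conf.low`, `conf.high`.
#' @export
imputation_summary <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "mnar_fit"))
  a <- (1 - conf_level) / 2
  one <- function(slot, var) {
    ids <- fit$missing_ids[[var]]
    if (length(ids) == 0) return(NULL)
    M <- do.call(rbind, lapply(fit$chains, function(ch) ch[[slot]]))
    tibble::tibble(
      variable = var, participant_id = ids,
      mean = colMeans(M), sd = apply(M, 2, stats::sd),
      conf.low = apply(M, 2, stats::quantile, probs = a),
      conf.high = apply(M, 2, stats::quantile, probs = 1 - a)
    )
  }
  dplyr::bind_rows(one("imp_y0", "y0"), one("imp_y1", "y1"),
                   one("imp_z", "z"))
}

#' Plot a fitted selection model
#'
#' `type = "imputations"` reproduces the conventional final-versus-
#' baseline scatter: open points are complete cases, filled points show
#' participants with one or both scores replaced by their posterior
#' means, with vertical/horizontal credible bars for the imputed
#' coordinate. `type = "trace"` shows per-chain trace plots of selected
#' parameters.
#'
#' @param object An `mnar_fit`.
#' @param type Plot type.
#' @param pars Parameters for the trace plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mnar_fit <- function(object, type = c("imputations", "trace"),
                              pars = "delta.T.Y1", ...) {
  type <- match.arg(type)
  if (type == "trace") {
    d <- posterior_draws(object) |>
      dplyr::select(dplyr::all_of(c("chain", "draw", pars))) |>
      tidyr::pivot_longer(dplyr::all_of(pars), names_to = "term")
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$draw, .data$value,
                                      colour = factor(.data$chain))) +
        ggplot2::geom_line(linewidth = 0.2) +
        ggplot2::facet_wrap(~term, scales = "free_y") +
        ggplot2::labs(colour = "chain", x = "kept iteration",
                      y = "value") +
        ggplot2::theme_minimal()
    )
  }
  imp <- imputation_summary(object)
  sc <- object$scores
  pm <- function(var, id) {
    i <- imp$variable == var & imp$participant_id == id
    if (any(i)) imp$mean[which(i)[1]] else NA_real_
  }
  d <- sc |>
    dplyr::mutate(
      y0_plot = ifelse(.data$r0 == 1L, .data$y0,
                       vapply(.data$participant_id,
                              function(id) pm("y0", id), numeric(1))),
      y1_plot = ifelse(.data$r1 == 1L, .data$y1,
                       vapply(.data$participant_id,
                              function(id) pm("y1", id), numeric(1))),
      imputed = .data$r0 == 0L | .data$r1 == 0L
    )
  bars1 <- imp |>
    dplyr::filter(.data$variable == "y1") |>
    dplyr::left_join(d, by = "participant_id")
  bars0 <- imp |>
    dplyr::filter(.data$variable == "y0") |>
    dplyr::left_join(d, by = "participant_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$y0_plot, .data$y1_plot)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$imputed),
                        na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::geom_segment(
      data = bars1,
      ggplot2::aes(x = .data$y0_plot, xend = .data$y0_plot,
                   y = .data$conf.low, yend = .data$conf.high),
      linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_segment(
      data = bars0,
      ggplot2::aes(x = .data$conf.low, xend = .data$conf.high,
                   y = .data$y1_plot, yend = .data$y1_plot),
      linetype = "dotted", na.rm = TRUE) +
    ggplot2::labs(x = "baseline score", y = "final score",
                  shape = "imputed") +
    ggplot2::theme_minimal()
}
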
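# one row of a sensitivity report, summarising a fitted model
make_cell <- function(label, spec, fit, extras = NULL, keep_fit = FALSE) {
  eff <- treatment_effect_summary(fit)
  dT <- tryCatch(delta_missing_minus_observed(fit, "intervention"),
                 error = function(e) NULL)
  dC <- tryCatch(delta_missing_minus_observed(fit, "control"),
                 error = function(e) NULL)
  conv <- if (is.null(fit$convergence)) NA else {
    !any(fit$convergence$flag, na.rm = TRUE)
  }
  out <- tibble::tibble(
    model = label,
    fixed = if (length(spec$fixed) == 0) "" else {
      paste(names(spec$fixed), "=", format(spec$fixed, trim = TRUE),
            collapse = ", ")
    },
    delta_T_mean = if (is.null(dT)) NA_real_ else dT$mean,
    delta_T_sd = if (is.null(dT)) NA_real_ else dT$sd,
    delta_C_mean = if (is.null(dC)) NA_real_ else dC$mean,
    delta_C_sd = if (is.null(dC)) NA_real_ else dC$sd,
    effect_mean = eff$mean, effect_sd = eff$sd,
    converged = conv
  )
  if (!is.null(extras)) out <- dplyr::bind_cols(out, tibble::as_tibble(extras))
  if (keep_fit) out$fit <- list(fit)
  out
}

empty_cells <- function() {
  tibble::tibble(model = character(), fixed = character(),
                 delta_T_mean = numeric(), delta_T_sd = numeric(),
                 delta_C_mean = numeric(), delta_C_sd = numeric(),
                 effect_mean = numeric(), effect_sd = numeric(),
                 converged = logical())
}

slope_extras <- function(fit, terms) {
  out <- list()
  for (tm in terms) {
    if (tm %in% fit$par_names) {
      d <- pooled_param(fit, tm)
      out[[paste0(tm, ".mean")]] <- mean(d)
      out[[paste0(tm, ".sd")]] <- stats::sd(d)
    }
  }
  out
}

# per-fit seeds derived from one master seed, so a whole suite is
# reproducible and adding a fit never perturbs earlier ones
fan_mcmc <- function(mcmc, n) {
  seeds <- stage_seeds(mcmc$seed, n)
  lapply(seq_len(n), function(i) {
    m <- mcmc
    m$seed <- seeds[i]
    m
  })
}

#' Missing-at-random analysis
#'
#' Fits the selection model under the missing-at-random constraint
#' ([spec_mar()]) and summarises the treatment effect and the
#' missing-minus-observed score differences.
#'
#' @param data A [trial_data] tibble.
#' @param mcmc An [mcmc_config].
#' @param priors A [prior_spec].
#' @param use_proxy Include proxy models.
#' @param keep_fit Attach the full fit as a list-column.
#' @return One-row sensitivity tibble.
#' @export
run_mar <- function(data, mcmc = mcmc_config(), priors = prior_spec(),
                    use_proxy = FALSE, keep_fit = FALSE) {
  spec <- spec_mar(use_proxy = use_proxy)
  fit <- fit_selection_model(data, spec, priors, mcmc)
  make_cell("MAR", spec, fit, keep_fit = keep_fit)
}

#' Default sensitivity grids
#'
#' `delta_grid_default()` is the conventional seven-model grid over
#' (`delta.Y0.R0`, `delta.Y1.R1`): both zero (A); baseline-selection 0.5
#' and 1 with outcome-selection 0 (B, C); outcome-selection 0.5 and 1
#' (D, E); and the arm-specific worst cases 0/1 and 1/0 (F, G).
#' `proxy_grid_default()` varies (`delta.Y1.R1`, `delta.Z.RZ`) with
#' `delta.Y0.R0 = 0` in the same pattern.
#'
#' @return Named list of named numeric vectors of fixed coefficients.
#' @export
delta_grid_default <- function() {
  list(
    A = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0),
    B = c(delta.Y0.R0 = 0.5, delta.Y1.R1 = 0),
    C = c(delta.Y0.R0 = 1, delta.Y1.R1 = 0),
    D = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0.5),
    E = c(delta.Y0.R0 = 0, delta.Y1.R1 = 1),
    F = c(delta.Y0.R0 = 0, delta.Y1.R1.T = 0, delta.Y1.R1.C = 1),
    G = c(delta.Y0.R0 = 0, delta.Y1.R1.T = 1, delta.Y1.R1.C = 0)
  )
}

#' @rdname delta_grid_default
#' @export
proxy_grid_default <- function() {
  list(
    A = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0, delta.Z.RZ = 0),
    B = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0, delta.Z.RZ = 0.5),
    C = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0, delta.Z.RZ = 1),
    D = c(delta.Y0.R0 = 0, delta.Y1.R1 = 0.5, delta.Z.RZ = 0),
    E = c(delta.Y0.R0 = 0, delta.Y1.R1 = 1, delta.Z.RZ = 0),
    F = c(delta.Y0.R0 = 0, delta.Y1.R1.T = 0, delta.Y1.R1.C = 1,
          delta.Z.RZ = 0),
    G = c(delta.Y0.R0 = 0, delta.Y1.R1.T = 1, delta.Y1.R1.C = 0,
          delta.Z.RZ = 0)
  )
}

check_grid_point <- function(fixed, use_proxy) {
  need_outcome <- c("delta.Y1.R1") %in% names(fixed) ||
    all(c("delta.Y1.R1.T", "delta.Y1.R1.C") %in% names(fixed))
  if (!"delta.Y0.R0" %in% names(fixed)) {
    stop("grid point leaves delta.Y0.R0 free; the model is not identified")
  }
  if (!need_outcome) {
    stop("grid point leaves the outcome-selection coefficient ",
         "delta.Y1.R1 free; the model is not identified")
  }
  if (use_proxy && !"delta.Z.RZ" %in% names(fixed)) {
    stop("grid point leaves delta.Z.RZ free; the model is not identified")
  }
  invisible(fixed)
}

#' Delta-constrained sensitivity analysis
#'
#' Fits the selection model once per grid point, each point fixing the
#' unidentified selection coefficients at chosen per-SD values, and
#' returns one report row per point in input order.
#'
#' @param data A [trial_data] tibble.
#' @param grid Named list of named numeric vectors of fixed
#'   coefficients; default [delta_grid_default()].
#' @inheritParams run_mar
#' @return Sensitivity tibble, one row per grid point.
#' @export
run_delta_grid <- function(data, grid = delta_grid_default(),
                           mcmc = mcmc_config(), priors = prior_spec(),
                           keep_fit = FALSE) {
  if (length(grid) == 0) return(empty_cells())
  labels <- names(grid) %||% as.character(seq_along(grid))
  mcmcs <- fan_mcmc(mcmc, length(grid))
  cells <- purrr::map(seq_along(grid), function(i) {
    fixed <- check_grid_point(grid[[i]], use_proxy = FALSE)
    arm_spec <- any(grepl("^delta\\.Y1\\.R1\\.[TC]$", names(fixed)))
    spec <- model_spec(fixed = fixed, arm_specific = arm_spec)
    fit <- fit_selection_model(data, spec, priors, mcmcs[[i]])
    make_cell(labels[i], spec, fit, keep_fit = keep_fit)
  })
  dplyr::bind_rows(cells)
}

#' Analysis with elicited priors on the outcome-selection slope
#'
#' Instead of fixing `delta.Y1.R1`, places the elicited normal prior(s)
#' on it (baseline selection still constrained to missing at random,
#' `delta.Y0.R0 = 0`) and reports the slope posterior(s) alongside the
#' standard summaries. In the absence of other identifying information
#' the slope posterior essentially returns the prior; the analysis
#' propagates that prior uncertainty into the treatment effect.
#'
#' @param data A [trial_data] tibble.
#' @param prior For `prior_mode = "common"` a one-row tibble (or length-2
#'   vector) with the prior mean and variance, as from
#'   [prior_for_delta()]; for `"arm_specific"` a list with elements
#'   `intervention` and `control`, each of that form.
#' @param prior_mode Common slope or independent arm-specific slopes.
#' @inheritParams run_mar
#' @return One-row sensitivity tibble with slope posterior columns.
#' @export
run_elicited <- function(data, prior,
                         prior_mode = c("common", "arm_specific"),
                         mcmc = mcmc_config(), priors = prior_spec(),
                         keep_fit = FALSE) {
  prior_mode <- match.arg(prior_mode)
  as_mv <- function(p) {
    if (is.data.frame(p)) c(p$mean[1], p$variance[1]) else unname(p[1:2])
  }
  if (prior_mode == "common") {
    normal <- list(delta.Y1.R1 = as_mv(prior))
    spec <- model_spec(fixed = c(delta.Y0.R0 = 0))
    slopes <- "delta.Y1.R1"
  } else {
    normal <- list(delta.Y1.R1.T = as_mv(prior$intervention),
                   delta.Y1.R1.C = as_mv(prior$control))
    spec <- model_spec(fixed = c(delta.Y0.R0 = 0), arm_specific = TRUE)
    slopes <- c("delta.Y1.R1.T", "delta.Y1.R1.C")
  }
  pr <- prior_spec(range = priors$range,
                   normal = c(priors$normal, normal),
                   precision_shape = priors$precision_shape,
                   precision_rate = priors$precision_rate)
  fit <- fit_selection_model(data, spec, pr, mcmc)
  make_cell(paste0("elicited_", prior_mode), spec, fit,
            extras = slope_extras(fit, slopes), keep_fit = keep_fit)
}

#' Proxy-outcome analysis suite
#'
#' Runs the proxy-augmented model under (a) the proxy missing-at-random
#' constraint, (b) the delta grid over (`delta.Y1.R1`, `delta.Z.RZ`),
#' and (c) the identification-via-proxy variants, which fix
#' `delta.R1.Z` (the direct effect of final response on the proxy mean)
#' at 0 or 1 with `delta.Y0.R0 = delta.Z.RZ = 0` and leave
#' `delta.Y1.R1` free: the observed response-proxy association then
#' identifies the outcome-selection slope, well or badly depending on
#' how strongly the proxy is correlated with the outcome. Slope
#' posteriors are reported for the identification variants, and poor
#' mixing surfaces through the convergence flag.
#'
#' @param data A [trial_data] tibble with proxy scores.
#' @param variants Subset of `"mar"`, `"grid"`, `"identify"`.
#' @param grid Grid for the `"grid"` variant.
#' @param identify_values Values of `delta.R1.Z` for the identification
#'   variants.
#' @inheritParams run_mar
#' @return Sensitivity tibble.
#' @export
run_proxy_suite <- function(data,
                            variants = c("mar", "grid", "identify"),
                            grid = proxy_grid_default(),
                            identify_values = c(0, 1),
                            mcmc = mcmc_config(), priors = prior_spec(),
                            keep_fit = FALSE) {
  if (length(variants) == 0) return(empty_cells())
  variants <- match.arg(variants, several.ok = TRUE)
  n_fits <- ("mar" %in% variants) +
    (if ("grid" %in% variants) length(grid) else 0) +
    (if ("identify" %in% variants) length(identify_values) else 0)
  mcmcs <- fan_mcmc(mcmc, max(n_fits, 1))
  j <- 0
  nxt <- function() {
    j <<- j + 1
    mcmcs[[j]]
  }
  cells <- list()
  if ("mar" %in% variants) {
    spec <- spec_mar(use_proxy = TRUE)
    fit <- fit_selection_model(data, spec, priors, nxt())
    cells <- c(cells, list(make_cell("proxy_MAR", spec, fit,
                                     keep_fit = keep_fit)))
  }
  if ("grid" %in% variants && length(grid) > 0) {
    labels <- names(grid) %||% as.character(seq_along(grid))
    for (i in seq_along(grid)) {
      fixed <- check_grid_point(grid[[i]], use_proxy = TRUE)
      arm_spec <- any(grepl("^delta\\.Y1\\.R1\\.[TC]$", names(fixed)))
      spec <- model_spec(fixed = fixed, arm_specific = arm_spec,
                         use_proxy = TRUE)
      fit <- fit_selection_model(data, spec, priors, nxt())
      cells <- c(cells, list(make_cell(paste0("proxy_", labels[i]),
                                       spec, fit, keep_fit = keep_fit)))
    }
  }
  if ("identify" %in% variants) {
    for (v in identify_values) {
      fixed <- c(delta.Y0.R0 = 0, delta.Z.RZ = 0, delta.R1.Z = v)
      spec <- model_spec(fixed = fixed, use_proxy = TRUE)
      fit <- suppressWarnings(
        fit_selection_model(data, spec, priors, nxt())
      )
      cells <- c(cells, list(make_cell(
        paste0("proxy_identify_dR1Z_", format(v)), spec, fit,
        extras = slope_extras(fit, "delta.Y1.R1"),
        keep_fit = keep_fit
      )))
    }
  }
  dplyr::bind_rows(cells)
}

#' Repeated contact-attempts analysis suite
#'
#' Fits the shared-coefficient attempts model, under which the
#' informative-missingness coefficient of the final score is
#' identifiable: model A without, and model B with, the
#' arm-by-outcome interaction; model C adds the proxy models to B with
#' `delta.Z.RZ = 0`. Baseline selection is constrained to missing at
#' random throughout. The outcome-slope (`delta.Y1.Rstar`) and
#' interaction (`delta.Y1T.Rstar`) posteriors are reported alongside
#' the standard summaries.
#'
#' @param data A [trial_data] tibble with attempt records.
#' @param models Subset of `"A"`, `"B"`, `"C"`.
#' @inheritParams run_mar
#' @return Sensitivity tibble.
#' @export
run_attempts_suite <- function(data, models = c("A", "B", "C"),
                               mcmc = mcmc_config(),
                               priors = prior_spec(),
                               keep_fit = FALSE) {
  if (length(models) == 0) return(empty_cells())
  models <- match.arg(models, several.ok = TRUE)
  mcmcs <- fan_mcmc(mcmc, length(models))
  cells <- purrr::map(seq_along(models), function(i) {
    mod <- models[i]
    spec <- model_spec(
      fixed = c(delta.Y0.R0 = 0,
                if (mod == "C") c(delta.Z.RZ = 0)),
      use_attempts = TRUE,
      attempts_arm_by_outcome = mod %in% c("B", "C"),
      use_proxy = mod == "C"
    )
    fit <- fit_selection_model(data, spec, priors, mcmcs[[i]])
    make_cell(paste0("attempts_", mod), spec, fit,
              extras = slope_extras(fit, c("delta.Y1.Rstar",
                                           "delta.Y1T.Rstar")),
              keep_fit = keep_fit)
  })
  dplyr::bind_rows(cells)
}

#' Render a sensitivity report
#'
#' Formats report rows in the conventional layout (posterior SDs in
#' parentheses) and optionally writes a machine-readable CSV twin that
#' round-trips to the numeric cells exactly.
#'
#' @param cells Sensitivity tibble from the `run_*` functions.
#' @param csv_path Optional path for the CSV twin.
#' @return An object of class `sensitivity_report` (printable text plus
#'   the cells), invisibly when printed.
#' @export
render_report <- function(cells, csv_path = NULL) {
  tab <- dplyr::select(cells, -dplyr::any_of("fit"))
  fmt <- function(m, s) {
    ifelse(is.na(m), "-", sprintf("%.2f (%.2f)", m, s))
  }
  body <- tibble::tibble(
    Model = tab$model %||% character(),
    `Fixed deltas` = tab$fixed %||% character(),
    `Delta(Y1,T)` = fmt(tab$delta_T_mean, tab$delta_T_sd),
    `Delta(Y1,C)` = fmt(tab$delta_C_mean, tab$delta_C_sd),
    `Effect` = fmt(tab$effect_mean, tab$effect_sd)
  )
  widths <- vapply(names(body), function(cn) {
    max(nchar(cn), if (nrow(body)) max(nchar(body[[cn]])) else 0)
  }, numeric(1))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  lines <- paste(mapply(pad, names(body), widths), collapse = "  ")
  for (i in seq_len(nrow(body))) {
    lines <- c(lines, paste(mapply(pad, unlist(body[i, ]), widths),
                            collapse = "  "))
  }
  if (!is.null(csv_path)) readr::write_csv(tab, csv_path)
  structure(list(text = lines, cells = tab),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' @describeIn render_report Dot-and-interval plot of the treatment
#'   effect (and the missing-minus-observed differences) across models.
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_report <- function(object, ...) {
  tab <- object$cells
  long <- dplyr::bind_rows(
    tibble::tibble(model = tab$model, quantity = "effect",
                   mean = tab$effect_mean, sd = tab$effect_sd),
    tibble::tibble(model = tab$model, quantity = "Delta(Y1,T)",
                   mean = tab$delta_T_mean, sd = tab$delta_T_sd),
    tibble::tibble(model = tab$model, quantity = "Delta(Y1,C)",
                   mean = tab$delta_C_mean, sd = tab$delta_C_sd)
  ) |>
    dplyr::filter(!is.na(.data$mean))
  long$model <- factor(long$model, levels = unique(tab$model))
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                   ymax = .data$mean + 2 * .data$sd), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "posterior mean ± 2 SD") +
    ggplot2::theme_minimal()
}
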
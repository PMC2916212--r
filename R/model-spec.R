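#' Specify a joint selection model
#'
#' The joint model factorizes along the trial's causal ordering: centre X,
#' baseline score Y0, its response indicator R0, randomized arm T, final
#' score Y1, its response indicator R1 (or, alternatively, the sequence of
#' contact attempts), and optionally the carer proxy score Z with its
#' indicator RZ. Scores are normal (Y1 optionally Student-t) regressions
#' on all earlier variables; indicators are logistic regressions on all
#' earlier variables including the possibly unobserved scores, which makes
#' the model missing-not-at-random. Coefficients are named
#' `delta.<A>.<B>` for the coefficient of A in the model for B
#' (`alpha.<B>` for intercepts); scores enter the logistic and proxy
#' regressions standardized, so selection coefficients are per
#' observed-data SD.
#'
#' Sensitivity analyses fix some unidentified coefficients (typically
#' `delta.Y0.R0`, `delta.Y1.R1`, `delta.Z.RZ`, `delta.R1.Z`) at chosen
#' values via `fixed`; `arm_specific = TRUE` replaces `delta.Y1.R1` by the
#' pair `delta.Y1.R1.T` (intervention) and `delta.Y1.R1.C` (control).
#' `use_attempts = TRUE` replaces the single R1 logistic regression by a
#' shared-coefficient logistic model across contact attempts with
#' per-attempt intercepts `alpha.m.1 ... alpha.m.9` ('continuum of
#' resistance'); there the outcome coefficient is identifiable and must
#' not be fixed.
#'
#' @param fixed Named numeric vector of coefficients held constant.
#' @param arm_specific Use arm-specific outcome-selection coefficients in
#'   the R1 model.
#' @param y1_family `"normal"` or `"t"` for the final-score residuals.
#' @param y1_df Degrees of freedom when `y1_family = "t"` (fixed, not
#'   estimated; 10 and 5 are the conventional robustness choices).
#' @param use_proxy Include the proxy score models (Z, RZ).
#' @param use_attempts Replace the R1 logistic by the repeated-attempts
#'   model.
#' @param attempts_centre_by_attempt Include centre-by-attempt-index
#'   dummies for attempts 2 and 3 only (the interaction is not extended
#'   past the third attempt because later attempts are rare).
#' @param attempts_arm_by_outcome Include the arm-by-standardized-outcome
#'   interaction in the attempts model.
#' @param attempts_type Include the attempt-type covariate (verbal
#'   agreement to interview or not).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed = numeric(),
                       arm_specific = FALSE,
                       y1_family = c("normal", "t"),
                       y1_df = Inf,
                       use_proxy = FALSE,
                       use_attempts = FALSE,
                       attempts_centre_by_attempt = TRUE,
                       attempts_arm_by_outcome = FALSE,
                       attempts_type = TRUE) {
  y1_family <- match.arg(y1_family)
  if (y1_family == "t" && (!is.finite(y1_df) || y1_df <= 2)) {
    stop("y1_df must be finite and > 2 for the t family")
  }
  fixed <- unlist(fixed)
  if (length(fixed) > 0 &&
      (is.null(names(fixed)) || any(names(fixed) == ""))) {
    stop("fixed coefficients must be named")
  }
  if (arm_specific && "delta.Y1.R1" %in% names(fixed)) {
    stop("delta.Y1.R1 cannot be fixed when arm_specific coefficients ",
         "replace it; fix delta.Y1.R1.T / delta.Y1.R1.C instead")
  }
  if (use_attempts &&
      any(c("delta.Y1.R1", "delta.Y1.R1.T", "delta.Y1.R1.C") %in%
          names(fixed))) {
    stop("the repeated-attempts model replaces the R1 regression; ",
         "its outcome coefficient is identifiable and cannot be fixed")
  }
  structure(list(
    fixed = fixed,
    arm_specific = arm_specific,
    y1_family = y1_family,
    y1_df = y1_df,
    use_proxy = use_proxy,
    use_attempts = use_attempts,
    attempts_centre_by_attempt = attempts_centre_by_attempt,
    attempts_arm_by_outcome = attempts_arm_by_outcome,
    attempts_type = attempts_type
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat("  Y1 family:", x$y1_family,
      if (x$y1_family == "t") paste0("(df ", x$y1_df, ")") else "", "\n")
  cat("  final-response arc:",
      if (x$use_attempts) "repeated contact attempts" else
        if (x$arm_specific) "single logistic, arm-specific outcome slope"
        else "single logistic", "\n")
  cat("  proxy models:", if (x$use_proxy) "yes" else "no", "\n")
  if (length(x$fixed) > 0) {
    cat("  fixed:", paste(names(x$fixed), "=", format(x$fixed),
                          collapse = ", "), "\n")
  } else cat("  fixed: none\n")
  invisible(x)
}

#' Missing-at-random model specification
#'
#' Constrains every arc between a score and a response indicator so that
#' scores and indicators are conditionally independent: `delta.Y0.R0 =
#' delta.Y0.R1 = delta.R0.Y1 = delta.Y1.R1 = 0` and, when proxies are
#' included, also the Z-related arcs (`delta.Y0.RZ`, `delta.Y1.RZ`,
#' `delta.Z.RZ`, `delta.R0.Z`, `delta.R1.Z`, `delta.R0.RZ`,
#' `delta.R1.RZ`).
#'
#' @param use_proxy Include the proxy models.
#' @inheritParams model_spec
#' @return A `model_spec`.
#' @export
spec_mar <- function(use_proxy = FALSE, y1_family = "normal", y1_df = Inf) {
  fixed <- c(delta.Y0.R0 = 0, delta.Y0.R1 = 0, delta.R0.Y1 = 0,
             delta.Y1.R1 = 0)
  if (use_proxy) {
    fixed <- c(fixed,
               delta.Y0.RZ = 0, delta.Y1.RZ = 0, delta.Z.RZ = 0,
               delta.R0.Z = 0, delta.R1.Z = 0,
               delta.R0.RZ = 0, delta.R1.RZ = 0)
  }
  model_spec(fixed = fixed, use_proxy = use_proxy,
             y1_family = y1_family, y1_df = y1_df)
}

#' Serialize / deserialize a model specification
#'
#' Writes the specification as JSON naming coefficients by the
#' `delta.<A>.<B>` convention, and reads it back.
#'
#' @param spec A `model_spec`.
#' @param path File path.
#' @return `read_model_spec()` returns a `model_spec`;
#'   `write_model_spec()` returns `spec` invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  x <- unclass(spec)
  x$fixed <- as.list(x$fixed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(spec)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(fixed = unlist(x$fixed),
             arm_specific = isTRUE(x$arm_specific),
             y1_family = x$y1_family,
             y1_df = if (is.null(x$y1_df)) Inf else x$y1_df,
             use_proxy = isTRUE(x$use_proxy),
             use_attempts = isTRUE(x$use_attempts),
             attempts_centre_by_attempt =
               isTRUE(x$attempts_centre_by_attempt),
             attempts_arm_by_outcome = isTRUE(x$attempts_arm_by_outcome),
             attempts_type = isTRUE(x$attempts_type))
}
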
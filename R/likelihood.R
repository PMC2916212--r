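#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats dnorm dt plogis qlogis rbinom rnorm runif rgamma
NULL

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 35
  out[small] <- log1p(exp(x[small]))
  out
}

# Bernoulli log-likelihood from the linear predictor, stable in the tails
bernoulli_loglik <- function(r, eta) {
  -log1pexp(-(2 * r - 1) * eta)
}

centre_dummy <- function(centre, j) {
  as.numeric(unclass(centre) == j)
}

# Frozen standardizers computed from the observed scores of a dataset
default_standardizers <- function(data) {
  list(
    y0 = standardizer(data$y0, data$centre),
    y1 = standardizer(data$y1, data$centre),
    z = if (any(!is.na(data$z))) {
      tryCatch(standardizer(data$z, data$centre), error = function(e) NULL)
    } else NULL
  )
}

# value of the covariate attached to one coefficient name; vectorized over
# participants. `std` holds the frozen standardizers.
covariate_value <- function(a, arm_tag, data, std) {
  k <- nlevels(data$centre)
  if (grepl("^X[0-9]+m[23]$", a)) {
    stop("centre-by-attempt term ", a, " is only defined inside the ",
         "attempts model")
  }
  val <- switch(a,
    "T" = as.numeric(data$arm),
    "R0" = as.numeric(data$r0),
    "R1" = as.numeric(data$r1),
    "RZ" = as.numeric(data$rz),
    "Y0" = standardize(data$y0, std$y0),
    "Y1" = standardize(data$y1, std$y1),
    "Z" = standardize(data$z, std$z),
    {
      if (!grepl("^X[0-9]+$", a)) stop("unknown covariate: ", a)
      j <- as.integer(sub("^X", "", a))
      if (j < 2 || j > k) stop("no centre level for dummy ", a)
      centre_dummy(data$centre, j)
    }
  )
  if (!is.na(arm_tag)) {
    val <- switch(arm_tag,
      "T" = val * data$arm,
      "C" = val * (1 - data$arm),
      stop("unknown arm tag: ", arm_tag)
    )
  }
  if (anyNA(val)) {
    stop("covariate ", a, " has missing values with no current imputation")
  }
  val
}

parse_coef <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "alpha") {
    return(list(kind = "alpha", a = NA_character_, arm = NA_character_))
  }
  if (parts[1] != "delta" || length(parts) < 3) {
    stop("cannot parse coefficient name: ", name)
  }
  list(kind = "delta", a = parts[2],
       arm = if (length(parts) >= 4) parts[4] else NA_character_)
}

#' Linear predictor of one regression in the joint model
#'
#' Accumulates coefficient times covariate over a named coefficient map.
#' Names follow the `delta.<A>.<B>` convention (`alpha.<B>` for the
#' intercept); scores Y0, Y1 and Z enter standardized by the frozen
#' observed-data standardizers, indicators and dummies enter raw, and the
#' arm-specific forms `delta.Y1.<B>.T` / `delta.Y1.<B>.C` multiply the
#' standardized score by `T` and `1 - T`.
#'
#' @param coefs Named numeric vector of coefficients.
#' @param data A [trial_data] tibble whose score columns hold the current
#'   imputations where the original values are missing.
#' @param standardizers List with elements `y0`, `y1`, `z` as returned by
#'   [standardizer()]; defaults to standardizers frozen from the observed
#'   values in `data`.
#' @return Numeric vector, one linear predictor per row of `data`.
#' @export
linear_predictor <- function(coefs, data, standardizers = NULL) {
  std <- standardizers %||% default_standardizers(data)
  eta <- numeric(nrow(data))
  for (nm in names(coefs)) {
    p <- parse_coef(nm)
    if (p$kind == "alpha") {
      eta <- eta + coefs[[nm]]
    } else {
      eta <- eta + coefs[[nm]] * covariate_value(p$a, p$arm, data, std)
    }
  }
  eta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coefficient name sets per submodel ------------------------------------

x_dummies <- function(k, target) {
  if (k < 2) character() else paste0("delta.X", 2:k, ".", target)
}

coef_names <- function(spec, k, max_m = 9L) {
  out <- list(
    y0 = c("alpha.Y0", x_dummies(k, "Y0")),
    r0 = c("alpha.R0", x_dummies(k, "R0"), "delta.Y0.R0"),
    y1 = c("alpha.Y1", x_dummies(k, "Y1"), "delta.Y0.Y1", "delta.R0.Y1",
           "delta.T.Y1")
  )
  if (spec$use_attempts) {
    nm <- c(paste0("alpha.m", seq_len(max_m)))
    if (spec$attempts_type) nm <- c(nm, "delta.type.Rstar")
    nm <- c(nm, x_dummies(k, "Rstar"))
    if (spec$attempts_centre_by_attempt && k >= 2) {
      nm <- c(nm, paste0("delta.X", rep(2:k, 2), "m",
                         rep(2:3, each = k - 1), ".Rstar"))
    }
    nm <- c(nm, "delta.T.Rstar", "delta.Y0.Rstar", "delta.Y1.Rstar")
    if (spec$attempts_arm_by_outcome) nm <- c(nm, "delta.Y1T.Rstar")
    out$rstar <- nm
  } else {
    out$r1 <- c("alpha.R1", x_dummies(k, "R1"), "delta.Y0.R1",
                "delta.R0.R1", "delta.T.R1",
                if (spec$arm_specific) c("delta.Y1.R1.T", "delta.Y1.R1.C")
                else "delta.Y1.R1")
  }
  if (spec$use_proxy) {
    out$z <- c("alpha.Z", x_dummies(k, "Z"), "delta.Y0.Z", "delta.R0.Z",
               "delta.T.Z", "delta.Y1.Z", "delta.R1.Z")
    out$rz <- c("alpha.RZ", x_dummies(k, "RZ"), "delta.Y0.RZ",
                "delta.R0.RZ", "delta.T.RZ", "delta.Y1.RZ", "delta.R1.RZ",
                "delta.Z.RZ")
  }
  out
}

variance_names <- function(spec) {
  c("sigma2.Y0", "sigma2.Y1", if (spec$use_proxy) "sigma2.Z")
}

# design row for the attempts model, vectorized over attempt rows ---------

attempts_design <- function(spec, data, std, max_m = NULL) {
  long <- attempts_long(data)
  if (nrow(long) == 0) stop("dataset has no recorded contact attempts")
  max_m <- max_m %||% max(long$m)
  idx <- match(long$participant_id, data$participant_id)
  k <- nlevels(data$centre)
  cols <- list()
  for (m in seq_len(max_m)) {
    cols[[paste0("alpha.m", m)]] <- as.numeric(long$m == m)
  }
  if (spec$attempts_type) {
    cols[["delta.type.Rstar"]] <- as.numeric(long$attempt_type)
  }
  cen <- unclass(data$centre)[idx]
  if (k >= 2) {
    for (j in 2:k) {
      cols[[paste0("delta.X", j, ".Rstar")]] <- as.numeric(cen == j)
    }
    if (spec$attempts_centre_by_attempt) {
      for (mm in 2:3) for (j in 2:k) {
        cols[[paste0("delta.X", j, "m", mm, ".Rstar")]] <-
          as.numeric(cen == j & long$m == mm)
      }
    }
  }
  ys0 <- standardize(data$y0, std$y0)[idx]
  ys1 <- standardize(data$y1, std$y1)[idx]
  arm <- data$arm[idx]
  cols[["delta.T.Rstar"]] <- as.numeric(arm)
  cols[["delta.Y0.Rstar"]] <- ys0
  cols[["delta.Y1.Rstar"]] <- ys1
  if (spec$attempts_arm_by_outcome) {
    cols[["delta.Y1T.Rstar"]] <- ys1 * arm
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    stop("attempts design has missing covariates with no imputation")
  }
  list(X = X, success = as.numeric(long$success), idx = idx, m = long$m)
}

#' Success probability of a contact attempt
#'
#' Probability that attempt `m` succeeds under the repeated-attempts
#' model: inverse logit of the attempt-specific intercept `alpha.m<m>`
#' plus a linear predictor whose coefficients are shared across attempts
#' (attempt type, centre, centre-by-attempt dummies frozen at the third
#' attempt, arm, standardized baseline and final scores, and optionally
#' the arm-by-outcome interaction). Sharing all slopes across `m` is the
#' identifying assumption of the model.
#'
#' @param m Attempt index in 1..9.
#' @param record One-row [trial_data] (scores imputed where missing).
#' @param params Named coefficient vector containing the attempts-model
#'   coefficients.
#' @param spec A [model_spec] with `use_attempts = TRUE`.
#' @param attempt_type Type covariate for this attempt (1 = verbal
#'   agreement).
#' @param standardizers Frozen standardizers; default from `record`'s
#'   dataset is rarely right, so pass the analysis standardizers.
#' @return Success probability.
#' @export
attempt_success_probability <- function(m, record, params, spec,
                                        attempt_type = 0,
                                        standardizers = NULL) {
  if (length(m) != 1 || m < 1 || m > 9 || m != round(m)) {
    stop("attempt index m must be a single integer in 1..9")
  }
  if (!spec$use_attempts) stop("spec does not use the attempts model")
  std <- standardizers %||% default_standardizers(record)
  k <- nlevels(record$centre)
  eta <- params[[paste0("alpha.m", m)]]
  if (spec$attempts_type && "delta.type.Rstar" %in% names(params)) {
    eta <- eta + params[["delta.type.Rstar"]] * attempt_type
  }
  cen <- unclass(record$centre)[1]
  if (k >= 2) {
    for (j in 2:k) {
      nm <- paste0("delta.X", j, ".Rstar")
      if (nm %in% names(params)) eta <- eta + params[[nm]] * (cen == j)
      if (spec$attempts_centre_by_attempt && m %in% 2:3) {
        nm2 <- paste0("delta.X", j, "m", m, ".Rstar")
        if (nm2 %in% names(params)) eta <- eta + params[[nm2]] * (cen == j)
      }
    }
  }
  ys0 <- standardize(record$y0[1], std$y0)
  ys1 <- standardize(record$y1[1], std$y1)
  if (is.na(ys0) || is.na(ys1)) {
    stop("scores must be observed or imputed to evaluate the attempt model")
  }
  eta <- eta + params[["delta.T.Rstar"]] * record$arm[1] +
    params[["delta.Y0.Rstar"]] * ys0 + params[["delta.Y1.Rstar"]] * ys1
  if (spec$attempts_arm_by_outcome && "delta.Y1T.Rstar" %in% names(params)) {
    eta <- eta + params[["delta.Y1T.Rstar"]] * ys1 * record$arm[1]
  }
  unname(plogis(eta))
}

#' Complete-data log-likelihood of the joint model
#'
#' Evaluates the joint log-likelihood with every score slot filled
#' (observed or imputed): normal (or Student-t, for Y1) log-densities for
#' the score regressions and Bernoulli-logistic terms for the response
#' indicators, with the final-response arc contributed either by the
#' single R1 regression or by the product of per-attempt Bernoulli terms
#' when the spec uses the repeated-attempts model.
#'
#' @param params Named numeric vector holding every coefficient named by
#'   `coef_names()` for the spec plus the variances `sigma2.Y0`,
#'   `sigma2.Y1` (and `sigma2.Z`). For the t family, `sigma2.Y1` is the
#'   squared scale.
#' @param data A [trial_data] tibble with imputations filled in.
#' @param spec A [model_spec].
#' @param standardizers Frozen standardizers (default: from the observed
#'   part of `data`).
#' @return The log-likelihood (scalar).
#' @export
complete_data_loglik <- function(params, data, spec,
                                 standardizers = NULL) {
  std <- standardizers %||% default_standardizers(data)
  for (v in variance_names(spec)) {
    if (!v %in% names(params)) stop("params lacks ", v)
    if (params[[v]] <= 0) stop(v, " must be positive")
  }
  cn <- coef_names(spec, nlevels(data$centre))
  want <- unlist(cn[setdiff(names(cn), "rstar")], use.names = FALSE)
  miss <- setdiff(want, names(params))
  if (length(miss) > 0) {
    stop("params lacks coefficient(s): ", paste(miss, collapse = ", "))
  }
  ll <- 0
  mu0 <- linear_predictor(params[cn$y0], data, std)
  ll <- ll + sum(dnorm(data$y0, mu0, sqrt(params[["sigma2.Y0"]]),
                       log = TRUE))
  ll <- ll + sum(bernoulli_loglik(data$r0,
                                  linear_predictor(params[cn$r0], data,
                                                   std)))
  mu1 <- linear_predictor(params[cn$y1], data, std)
  s1 <- sqrt(params[["sigma2.Y1"]])
  if (spec$y1_family == "normal") {
    ll <- ll + sum(dnorm(data$y1, mu1, s1, log = TRUE))
  } else {
    ll <- ll + sum(dt((data$y1 - mu1) / s1, df = spec$y1_df, log = TRUE) -
                     log(s1))
  }
  if (spec$use_attempts) {
    des <- attempts_design(spec, data, std)
    miss <- setdiff(colnames(des$X), names(params))
    if (length(miss) > 0) {
      stop("params lacks coefficient(s): ", paste(miss, collapse = ", "))
    }
    theta <- params[colnames(des$X)]
    ll <- ll + sum(bernoulli_loglik(des$success,
                                    drop(des$X %*% theta)))
  } else {
    ll <- ll + sum(bernoulli_loglik(data$r1,
                                    linear_predictor(params[cn$r1], data,
                                                     std)))
  }
  if (spec$use_proxy) {
    muz <- linear_predictor(params[cn$z], data, std)
    ll <- ll + sum(dnorm(data$z, muz, sqrt(params[["sigma2.Z"]]),
                         log = TRUE))
    ll <- ll + sum(bernoulli_loglik(data$rz,
                                    linear_predictor(params[cn$rz], data,
                                                     std)))
  }
  ll
}
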
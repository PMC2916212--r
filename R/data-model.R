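#' Trial data model
#'
#' A `trial_data` object is a tibble with one row per participant and the
#' columns
#' \describe{
#'   \item{participant_id}{character, unique}
#'   \item{centre}{factor with four levels (recruiting centre)}
#'   \item{arm}{integer, 1 = intervention, 0 = control}
#'   \item{y0, y1}{baseline and final mental-health component scores (MCS,
#'     SF-36 units; higher is better); `NA` when not recorded}
#'   \item{r0, r1}{response indicators, always derived from presence of
#'     `y0`/`y1`, never trusted from file}
#'   \item{z, rz}{carer-reported proxy score (sum of four visual-analogue
#'     ratings) and its derived response indicator}
#'   \item{attempts}{list-column; each element a tibble with columns `m`
#'     (attempt number), `attempt_type` (1 = verbal agreement to interview),
#'     `success` (1 = interview completed)}
#' }
#'
#' Invariants enforced by [trial_data()]: indicators equal presence;
#' attempt numbers are consecutive from 1; no attempt follows a success;
#' when attempts are recorded, `r1 = 1` exactly when the last attempt
#' succeeded.
#'
#' @param participants A data frame with columns `participant_id`, `centre`,
#'   `arm`, `y0`, `y1` and optionally `z`.
#' @param attempts Optional long-format data frame of contact attempts with
#'   columns `participant_id`, `m`, `attempt_type`, `success`.
#' @return A `trial_data` tibble.
#' @export
trial_data <- function(participants, attempts = NULL) {
  stopifnot(is.data.frame(participants))
  need <- c("participant_id", "centre", "arm", "y0", "y1")
  miss <- setdiff(need, names(participants))
  if (length(miss) > 0) {
    stop("participant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  d <- tibble::as_tibble(participants)
  d$participant_id <- as.character(d$participant_id)
  if (anyDuplicated(d$participant_id)) {
    stop("participant_id values must be unique")
  }
  if (!is.factor(d$centre)) d$centre <- factor(d$centre)
  d$arm <- as.integer(d$arm)
  if (!all(d$arm %in% c(0L, 1L))) stop("arm must be coded 0/1")
  d$y0 <- as.numeric(d$y0)
  d$y1 <- as.numeric(d$y1)
  if (!"z" %in% names(d)) d$z <- NA_real_
  d$z <- as.numeric(d$z)
  # indicators are definitionally presence
  d$r0 <- as.integer(!is.na(d$y0))
  d$r1 <- as.integer(!is.na(d$y1))
  d$rz <- as.integer(!is.na(d$z))

  att_list <- rep(list(empty_attempts()), nrow(d))
  names(att_list) <- d$participant_id
  if (!is.null(attempts) && nrow(attempts) > 0) {
    a <- tibble::as_tibble(attempts)
    need_a <- c("participant_id", "m", "attempt_type", "success")
    miss_a <- setdiff(need_a, names(a))
    if (length(miss_a) > 0) {
      stop("attempts table lacks column(s): ", paste(miss_a, collapse = ", "))
    }
    a$participant_id <- as.character(a$participant_id)
    unknown <- setdiff(unique(a$participant_id), d$participant_id)
    if (length(unknown) > 0) {
      stop("attempts refer to unknown participant_id: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    a <- dplyr::arrange(a, .data$participant_id, .data$m)
    sp <- split(a[c("m", "attempt_type", "success")], a$participant_id)
    for (id in names(sp)) {
      att <- tibble::as_tibble(lapply(sp[[id]], as.integer))
      validate_attempt_sequence(att, id)
      att_list[[id]] <- att
    }
  }
  d$attempts <- unname(att_list)
  # r1 must agree with the attempt record when one exists
  n_att <- vapply(d$attempts, nrow, integer(1))
  has_att <- n_att > 0
  if (any(has_att)) {
    succ <- vapply(d$attempts[has_att],
                   function(a) as.integer(any(a$success == 1L)), integer(1))
    bad <- d$r1[has_att] != succ
    if (any(bad)) {
      stop("final-score presence inconsistent with attempt record for: ",
           paste(utils::head(d$participant_id[has_att][bad], 3),
                 collapse = ", "))
    }
  }
  d <- d[c("participant_id", "centre", "arm",
           "y0", "r0", "y1", "r1", "z", "rz", "attempts")]
  class(d) <- c("trial_data", class(tibble::tibble()))
  d
}

empty_attempts <- function() {
  tibble::tibble(m = integer(), attempt_type = integer(), success = integer())
}

validate_attempt_sequence <- function(att, id) {
  m <- att$m
  if (!identical(m, seq_along(m))) {
    stop("attempt numbers for participant ", id,
         " are not consecutive from 1")
  }
  if (!all(att$success %in% c(0L, 1L)) ||
      !all(att$attempt_type %in% c(0L, 1L))) {
    stop("attempt_type and success must be coded 0/1 (participant ", id, ")")
  }
  s <- which(att$success == 1L)
  if (length(s) > 1) {
    stop("participant ", id, " has more than one successful attempt")
  }
  if (length(s) == 1 && s < nrow(att)) {
    stop("participant ", id, " has an attempt recorded after a success")
  }
  invisible(att)
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data> ", nrow(x), " participants (",
      sum(x$arm == 1L), " intervention / ", sum(x$arm == 0L), " control)\n",
      sep = "")
  NextMethod()
}

#' Read a trial dataset from delimited text
#'
#' Reads the participant table (and optionally a long-format contact-attempts
#' table) written as UTF-8 CSV with a mandatory header row. Response
#' indicators are derived from presence of the score columns; if the files
#' carry `r0`/`r1`/`rz` columns they are checked against presence and a
#' validation error is raised on disagreement.
#'
#' @param path Path to the participant CSV (columns `participant_id`,
#'   `centre`, `arm`, `y0`, `y1` and optionally `z`).
#' @param attempts_path Optional path to the attempts CSV (columns
#'   `participant_id`, `m`, `attempt_type`, `success`).
#' @param na Sentinel string marking a missing cell (default: empty string).
#' @return A [trial_data] tibble.
#' @export
read_trial_table <- function(path, attempts_path = NULL, na = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- readr::read_csv(path, na = na, show_col_types = FALSE,
                       progress = FALSE)
  pb <- readr::problems(p)
  if (nrow(pb) > 0) {
    stop("malformed participant table at line ", pb$row[1] + 1L,
         ": ", pb$expected[1])
  }
  att <- NULL
  if (!is.null(attempts_path)) {
    if (!file.exists(attempts_path)) stop("no such file: ", attempts_path)
    att <- readr::read_csv(attempts_path, na = na, show_col_types = FALSE,
                           progress = FALSE)
    pb <- readr::problems(att)
    if (nrow(pb) > 0) {
      stop("malformed attempts table at line ", pb$row[1] + 1L,
           ": ", pb$expected[1])
    }
  }
  d <- trial_data(p, att)
  for (ind in c("r0", "r1", "rz")) {
    if (ind %in% names(p)) {
      file_ind <- as.integer(p[[ind]])
      if (!identical(file_ind, d[[ind]])) {
        stop("column ", ind, " in file disagrees with score presence at row ",
             which(file_ind != d[[ind]])[1])
      }
    }
  }
  d
}

#' Write a trial dataset to delimited text
#'
#' Inverse of [read_trial_table()]: writes the participant table and, when
#' any attempts are recorded, a long-format attempts table, in the same CSV
#' schema. `read_trial_table(write_trial_table(d))` reproduces `d` exactly.
#'
#' @param data A [trial_data] tibble.
#' @param path Participant CSV path.
#' @param attempts_path Optional attempts CSV path; required if any
#'   participant has recorded attempts.
#' @param na Sentinel written for missing cells.
#' @return `data`, invisibly.
#' @export
write_trial_table <- function(data, path, attempts_path = NULL, na = "") {
  p <- data[c("participant_id", "centre", "arm", "y0", "y1", "z")]
  readr::write_csv(tibble::as_tibble(p), path, na = na)
  long <- attempts_long(data)
  if (nrow(long) > 0) {
    if (is.null(attempts_path)) {
      stop("dataset has attempt records; supply attempts_path")
    }
    readr::write_csv(long, attempts_path, na = na)
  }
  invisible(data)
}

#' Long-format attempts table
#'
#' @param data A [trial_data] tibble.
#' @return Tibble with one row per contact attempt: `participant_id`, `m`,
#'   `attempt_type`, `success`.
#' @export
attempts_long <- function(data) {
  keep <- vapply(data$attempts, nrow, integer(1)) > 0
  if (!any(keep)) {
    return(tibble::tibble(participant_id = character(), m = integer(),
                          attempt_type = integer(), success = integer()))
  }
  out <- dplyr::bind_rows(
    stats::setNames(data$attempts[keep], data$participant_id[keep]),
    .id = "participant_id"
  )
  tibble::as_tibble(out)
}

#' Score standardizer
#'
#' Freezes the map used whenever a score enters a logistic selection model:
#' subtract the sample mean of the observed scores, divide by the standard
#' deviation pooled across centres (square root of the within-centre pooled
#' variance). The same frozen map is applied to imputed values inside the
#' sampler, so selection coefficients are always per observed-data SD.
#'
#' @param x Numeric scores, possibly with `NA`.
#' @param centre Factor of centre labels aligned with `x`; when `NULL` the
#'   plain sample SD of the observed scores is used.
#' @return An object of class `standardizer` with fields `mean` and `sd`.
#' @export
standardizer <- function(x, centre = NULL) {
  obs <- !is.na(x)
  if (sum(obs) < 2) stop("need at least two observed scores")
  m <- mean(x[obs])
  if (is.null(centre)) {
    s <- stats::sd(x[obs])
  } else {
    s <- pooled_sd(x[obs], droplevels(factor(centre[obs])))
  }
  if (!is.finite(s) || s <= 0) stop("pooled SD must be positive")
  structure(list(mean = m, sd = s), class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer> mean %.4g, pooled SD %.4g\n", x$mean, x$sd))
  invisible(x)
}

# within-group pooled SD: sqrt(sum (n_g - 1) var_g / sum (n_g - 1))
pooled_sd <- function(x, g) {
  ss <- tapply(x, g, function(v) {
    if (length(v) < 2) c(0, 0) else c((length(v) - 1) * stats::var(v),
                                      length(v) - 1)
  })
  ss <- do.call(rbind, ss)
  sqrt(sum(ss[, 1]) / sum(ss[, 2]))
}

#' Standardize / de-standardize scores
#'
#' Observed entries are mapped to `(x - mean)/sd`; missing entries are
#' preserved. `unstandardize()` is the exact inverse.
#'
#' @param x Numeric scores, possibly with `NA`.
#' @param s A [standardizer].
#' @return Numeric vector of the same length.
#' @export
standardize <- function(x, s) {
  stopifnot(inherits(s, "standardizer"))
  if (s$sd <= 0) stop("pooled SD must be positive")
  (x - s$mean) / s$sd
}

#' @rdname standardize
#' @export
unstandardize <- function(x, s) {
  stopifnot(inherits(s, "standardizer"))
  x * s$sd + s$mean
}

#' Pattern of missingness table
#'
#' Cross-tabulates the four observation patterns of the two scores
#' (baseline only, final only, neither, both) by trial arm, with margins,
#' in the layout conventionally printed for trial missing-data reports.
#'
#' @param data A [trial_data] tibble (or data frame with `arm`, `r0`, `r1`).
#' @return Tibble with columns `pattern`, `intervention`, `control`,
#'   `total`; the last row is the column total.
#' @export
missingness_pattern <- function(data) {
  pat <- dplyr::case_when(
    data$r0 == 1L & data$r1 == 0L ~ "baseline only",
    data$r0 == 0L & data$r1 == 1L ~ "final only",
    data$r0 == 0L & data$r1 == 0L ~ "neither",
    TRUE ~ "both"
  )
  lev <- c("baseline only", "final only", "neither", "both")
  tab <- table(factor(pat, levels = lev),
               factor(data$arm, levels = c(1L, 0L)))
  out <- tibble::tibble(
    pattern = c(lev, "total"),
    intervention = unname(c(tab[, 1], sum(tab[, 1]))),
    control = unname(c(tab[, 2], sum(tab[, 2])))
  )
  out$total <- out$intervention + out$control
  out
}

#' Mean final score by number of contact attempts
#'
#' Groups participants into attempt-count bands (1, 2, 3, more than 3) and
#' reports, per band and arm, the mean final score over participants with
#' an observed final score together with the number of participants in the
#' band (responders and non-responders alike), plus each band's share of
#' the whole dataset. Participants with no recorded attempts are excluded.
#'
#' @param data A [trial_data] tibble.
#' @return Tibble with one row per band: `band`, `mean_intervention`,
#'   `n_intervention`, `mean_control`, `n_control`, `n`, `proportion`.
#' @export
attempts_summary <- function(data) {
  n_att <- vapply(data$attempts, nrow, integer(1))
  keep <- n_att > 0
  band <- cut(n_att[keep], breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", ">3"))
  d <- tibble::tibble(band = band, arm = data$arm[keep],
                      y1 = data$y1[keep], r1 = data$r1[keep])
  one_arm <- function(a) {
    d |>
      dplyr::filter(.data$arm == a) |>
      dplyr::group_by(.data$band, .drop = FALSE) |>
      dplyr::summarise(
        mean = mean(.data$y1[.data$r1 == 1L]),
        n = dplyr::n(), .groups = "drop"
      )
  }
  ti <- one_arm(1L)
  tc <- one_arm(0L)
  out <- tibble::tibble(
    band = as.character(ti$band),
    mean_intervention = ti$mean, n_intervention = ti$n,
    mean_control = tc$mean, n_control = tc$n
  )
  out$n <- out$n_intervention + out$n_control
  out$proportion <- out$n / sum(out$n)
  out
}
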
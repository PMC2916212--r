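#' Synthetic dataset encoding the published marginal tables
#'
#' Builds a fully deterministic 409-participant dataset whose missingness
#' pattern, per-arm totals, contact-attempt band counts and band-wise mean
#' final scores reproduce the marginal summaries published for the QUATRO
#' adherence-therapy trial (four centres, intervention n = 204, control
#' n = 205). Individual-level values are synthetic: every responder in an
#' attempt band carries that band's published mean final score, baseline
#' scores are constant, and proxy scores are constant with the published
#' count of recorded proxies (379, of which 19 among the 42 participants
#' missing a final score). The object is intended for exercising the
#' descriptive operations ([missingness_pattern()], [attempts_summary()]);
#' it carries no information beyond the published margins.
#'
#' @return A [trial_data] tibble with 409 rows.
#' @export
quatro_margins_fixture <- function() {
  # per-arm pattern counts: both, baseline-only, final-only, neither
  pat_i <- c(both = 165L, baseline_only = 26L, final_only = 10L, neither = 3L)
  pat_c <- c(both = 184L, baseline_only = 11L, final_only = 8L, neither = 2L)
  # attempt-band totals (1, 2, 3, >3) and responder/non-responder split;
  # the split within bands is not published and is a free choice here
  bands_resp_i <- c(87L, 79L, 6L, 3L)
  bands_nonr_i <- c(0L, 17L, 3L, 9L)
  bands_resp_c <- c(83L, 90L, 8L, 11L)
  bands_nonr_c <- c(0L, 6L, 2L, 5L)
  mean_y1_i <- c(40.7, 40.2, 38.6, 36.2)
  mean_y1_c <- c(42.4, 41.3, 38.7, 36.8)
  n_attempts <- c(1L, 2L, 3L, 4L)

  build_arm <- function(arm, pat, bands_resp, bands_nonr, mean_y1, prefix) {
    n <- sum(pat)
    # responders first (both, then final-only), then non-responders
    r1 <- rep(c(1L, 0L), c(pat[["both"]] + pat[["final_only"]],
                           pat[["baseline_only"]] + pat[["neither"]]))
    r0 <- c(rep(1L, pat[["both"]]), rep(0L, pat[["final_only"]]),
            rep(1L, pat[["baseline_only"]]), rep(0L, pat[["neither"]]))
    band_resp <- rep(1:4, bands_resp)
    band_nonr <- rep(1:4, bands_nonr)
    band <- c(band_resp, band_nonr)
    y1 <- ifelse(r1 == 1L, mean_y1[band], NA_real_)
    y0 <- ifelse(r0 == 1L, 39, NA_real_)
    tibble::tibble(
      participant_id = sprintf("%s%03d", prefix, seq_len(n)),
      centre = factor(rep_len(paste0("centre_", 1:4), n),
                      levels = paste0("centre_", 1:4)),
      arm = arm, y0 = y0, y1 = y1, band = band, r1 = r1
    )
  }
  d <- dplyr::bind_rows(
    build_arm(1L, pat_i, bands_resp_i, bands_nonr_i, mean_y1_i, "I"),
    build_arm(0L, pat_c, bands_resp_c, bands_nonr_c, mean_y1_c, "C")
  )
  # proxies: 360 of the 367 responders and 19 of the 42 non-responders
  resp_idx <- which(d$r1 == 1L)
  nonr_idx <- which(d$r1 == 0L)
  z <- rep(NA_real_, nrow(d))
  z[resp_idx[seq_len(360)]] <- 20
  z[nonr_idx[seq_len(19)]] <- 20
  d$z <- z

  att <- dplyr::bind_rows(lapply(seq_len(nrow(d)), function(i) {
    k <- n_attempts[d$band[i]]
    succ <- integer(k)
    if (d$r1[i] == 1L) succ[k] <- 1L
    tibble::tibble(participant_id = d$participant_id[i],
                   m = seq_len(k), attempt_type = 1L, success = succ)
  }))
  trial_data(d[c("participant_id", "centre", "arm", "y0", "y1", "z")], att)
}
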
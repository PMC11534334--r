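#' Classify a trial response into the signal-detection cell
#'
#' In the reward-discrimination task the rewarded category is the signal:
#' a correct response to a rewarded word is a hit, an incorrect one a miss;
#' a correct response to an unrewarded word is a correct rejection, an
#' incorrect one a false alarm. Timeouts are excluded and returned as `NA`.
#'
#' @param reward_category `"rewarded"` or `"unrewarded"` (vectorized).
#' @param response `"reward_button"`, `"noreward_button"` or `"timeout"`.
#' @return character vector in
#'   `c("hit", "miss", "correct_rejection", "false_alarm")`, `NA` on timeout.
#' @export
classify_response <- function(reward_category, response) {
  n <- max(length(reward_category), length(response))
  reward_category <- rep_len(as.character(reward_category), n)
  response <- rep_len(as.character(response), n)
  bad <- !reward_category %in% c("rewarded", "unrewarded")
  if (any(bad)) stopf("unknown reward_category: %s",
                      paste(unique(reward_category[bad]), collapse = ", "))
  bad <- !response %in% c("reward_button", "noreward_button", "timeout")
  if (any(bad)) stopf("unknown response: %s",
                      paste(unique(response[bad]), collapse = ", "))
  out <- ifelse(reward_category == "rewarded",
                ifelse(response == "reward_button", "hit", "miss"),
                ifelse(response == "noreward_button", "correct_rejection",
                       "false_alarm"))
  out[response == "timeout"] <- NA_character_
  out
}

#' Rate with boundary correction
#'
#' Proportion `count / n`, with the conventional replacement of empty and
#' full rates: 0 becomes `0.5/n` and `n` becomes `(n - 0.5)/n`, so the
#' normal quantile stays finite.
#'
#' @param count number of hits (or false alarms), `0 <= count <= n`.
#' @param n number of trials in the category (> 0).
#' @return corrected rate in (0, 1).
#' @export
corrected_rate <- function(count, n) {
  if (any(n <= 0)) stopf("`n` must be positive")
  if (any(count < 0 | count > n)) stopf("`count` must be within [0, n]")
  ifelse(count == 0, 0.5 / n, ifelse(count == n, (n - 0.5) / n, count / n))
}

check_rate <- function(rate, what) {
  if (any(!is.finite(rate)) || any(rate <= 0 | rate >= 1)) {
    stopf("%s must lie strictly inside (0, 1); apply corrected_rate() first", what)
  }
}

#' Signal-detection discriminability d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard-normal
#' quantile.
#'
#' @param hit_rate,fa_rate rates strictly inside (0, 1) (vectorized).
#' @return d' value(s).
#' @export
dprime <- function(hit_rate, fa_rate) {
  check_rate(hit_rate, "hit_rate"); check_rate(fa_rate, "fa_rate")
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Signal-detection response criterion c
#'
#' `c = -0.5 * (z(false-alarm rate) + z(hit rate))`; positive values indicate
#' conservative (risk-avoidant) responding.
#'
#' @inheritParams dprime
#' @return criterion value(s).
#' @export
criterion <- function(hit_rate, fa_rate) {
  check_rate(hit_rate, "hit_rate"); check_rate(fa_rate, "fa_rate")
  -0.5 * (stats::qnorm(fa_rate) + stats::qnorm(hit_rate))
}

#' Score a behavioral session with signal detection theory
#'
#' Counts hits over rewarded trials and false alarms over unrewarded trials
#' within each grouping cell, corrects boundary rates, and computes d' and
#' the c criterion. Timeout trials (`response_type` NA) are excluded and the
#' per-category n reduced accordingly. Cells without both rewarded and
#' unrewarded trials are omitted (missing, not zero).
#'
#' @param trials data.frame with `condition`, `reward_category`,
#'   `response_type`, and (optionally) `presentation`.
#' @param by grouping columns, subset of `c("condition", "presentation")`.
#' @return data.frame with one row per cell: grouping columns, `n_signal`,
#'   `n_noise`, `hit_rate`, `fa_rate`, `dprime`, `criterion`.
#' @export
score_session <- function(trials, by = "condition") {
  stopifnot(all(by %in% names(trials)))
  trials <- trials[!is.na(trials$response_type), , drop = FALSE]
  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  cells <- split(trials, key)
  rows <- lapply(cells, function(cell) {
    sig <- cell[cell$reward_category == "rewarded", , drop = FALSE]
    noi <- cell[cell$reward_category == "unrewarded", , drop = FALSE]
    if (nrow(sig) == 0 || nrow(noi) == 0) return(NULL)
    hr <- corrected_rate(sum(sig$response_type == "hit"), nrow(sig))
    fr <- corrected_rate(sum(noi$response_type == "false_alarm"), nrow(noi))
    out <- cell[1, by, drop = FALSE]
    out$n_signal <- nrow(sig)
    out$n_noise <- nrow(noi)
    out$hit_rate <- hr
    out$fa_rate <- fr
    out$dprime <- dprime(hr, fr)
    out$criterion <- criterion(hr, fr)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Overnight change in memory performance
#'
#' Componentwise post-sleep minus pre-sleep d' and criterion, matched by
#' condition.
#'
#' @param pre,post results of [score_session()] with a `condition` column.
#' @return data.frame with `condition`, `delta_dprime`, `delta_criterion`.
#' @export
overnight_change <- function(pre, post) {
  if (!setequal(pre$condition, post$condition)) {
    stopf("pre and post results cover different conditions")
  }
  m <- match(pre$condition, post$condition)
  data.frame(condition = pre$condition,
             delta_dprime = post$dprime[m] - pre$dprime,
             delta_criterion = post$criterion[m] - pre$criterion,
             stringsAsFactors = FALSE)
}
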
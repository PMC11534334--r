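#' Parameters of the discrimination-behavior simulator
#'
#' Defaults emulate the two-alternative reward-discrimination task: 160
#' artificial words (40 rewarded + 40 unrewarded per phonotactic-probability
#' condition), three presentations during encoding (480 trials), and pre- and
#' post-sleep memory tests of 160 trials each. Per-presentation response
#' accuracies make the easy (high-PP) condition outperform the difficult
#' (low-PP) condition from the second presentation on, and the post-sleep
#' accuracy of the cued condition carries a consolidation benefit.
#'
#' @param n_rewarded rewarded words per PP condition (default 40).
#' @param n_unrewarded unrewarded words per PP condition (default 40).
#' @param presentations number of encoding presentations (default 3).
#' @param encoding_p named list of per-presentation probabilities of a
#'   correct response, one numeric vector per condition.
#' @param memory_pre_p,memory_post_p named numeric vectors of accuracy in the
#'   pre-/post-sleep memory test per condition.
#' @param cued_condition condition reactivated during sleep.
#' @param timeout_p probability of a response timeout on any trial.
#' @param points money points gained/lost per correct/incorrect response.
#' @param seed integer RNG seed.
#' @return list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_rewarded = 40, n_unrewarded = 40,
                                presentations = 3,
                                encoding_p = list(high_pp = c(0.54, 0.68, 0.78),
                                                  low_pp = c(0.53, 0.61, 0.70)),
                                memory_pre_p = c(high_pp = 0.74, low_pp = 0.70),
                                memory_post_p = c(high_pp = 0.78, low_pp = 0.70),
                                cued_condition = "high_pp",
                                timeout_p = 0, points = 10, seed = 1) {
  probs <- c(unlist(encoding_p), memory_pre_p, memory_post_p, timeout_p)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  if (any(vapply(encoding_p, length, 0L) != presentations)) {
    stopf("each `encoding_p` entry needs one probability per presentation")
  }
  structure(list(n_rewarded = n_rewarded, n_unrewarded = n_unrewarded,
                 presentations = presentations, encoding_p = encoding_p,
                 memory_pre_p = memory_pre_p, memory_post_p = memory_post_p,
                 cued_condition = cued_condition, timeout_p = timeout_p,
                 points = points, seed = seed),
            class = "behavior_sim_params")
}

simulate_block <- function(words, p_correct, timeout_p, points, presentation) {
  n <- nrow(words)
  timeout <- stats::runif(n) < timeout_p
  correct <- stats::runif(n) < p_correct[words$condition_idx]
  response <- ifelse(timeout, "timeout",
                     ifelse(correct == (words$reward_category == "rewarded"),
                            "reward_button", "noreward_button"))
  df <- data.frame(word_id = words$word_id, condition = words$condition,
                   reward_category = words$reward_category,
                   presentation = presentation, response = response,
                   stringsAsFactors = FALSE)
  df$response_type <- classify_response(df$reward_category, df$response)
  df$correct <- df$response_type %in% c("hit", "correct_rejection")
  df$correct[timeout] <- NA
  df$points <- ifelse(is.na(df$correct), 0L, ifelse(df$correct, points, -points))
  df[sample.int(n), , drop = FALSE]
}

#' Simulate encoding and memory-test behavior
#'
#' Generates per-trial Bernoulli responses for the encoding task (all words x
#' presentations, randomized order) and for the pre- and post-sleep memory
#' tests (one trial per word).
#'
#' @param params a [behavior_sim_params()] object.
#' @return list with data.frames `encoding` (words x presentations rows),
#'   `memory_pre` and `memory_post` (one row per word), each carrying
#'   `word_id`, `condition`, `reward_category`, `presentation`, `response`,
#'   `response_type`, `correct` and `points`.
#' @export
generate_behavior <- function(params = behavior_sim_params()) {
  p <- params
  conds <- names(p$encoding_p)
  words <- do.call(rbind, lapply(seq_along(conds), function(ci) {
    data.frame(
      condition = conds[ci], condition_idx = ci,
      reward_category = rep(c("rewarded", "unrewarded"),
                            c(p$n_rewarded, p$n_unrewarded)),
      stringsAsFactors = FALSE)
  }))
  words$word_id <- seq_len(nrow(words))
  run <- function() {
    enc <- do.call(rbind, lapply(seq_len(p$presentations), function(k) {
      pk <- vapply(conds, function(cn) p$encoding_p[[cn]][k], 0)
      simulate_block(words, pk, p$timeout_p, p$points, k)
    }))
    enc <- enc[sample.int(nrow(enc)), , drop = FALSE]
    rownames(enc) <- NULL
    pre <- simulate_block(words, p$memory_pre_p[conds], p$timeout_p, p$points, 1L)
    post <- simulate_block(words, p$memory_post_p[conds], p$timeout_p, p$points, 1L)
    rownames(pre) <- rownames(post) <- NULL
    list(encoding = enc, memory_pre = pre, memory_post = post)
  }
  if (is.null(p$seed)) run() else withr::with_seed(as.integer(p$seed), run())
}
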
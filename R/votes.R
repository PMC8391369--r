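# Voted-Appropriateness aggregation for the static-context (bystander)
# evaluation: per-dialogue vote counts over the four candidate responses,
# Rmax agreement percentages, correlation, and star ratings.

#' Count votes for one evaluation dialogue
#'
#' Each evaluator casts exactly one vote for the candidate response (index
#' 0-3; 0 is the system's actual response, a position hidden from
#' evaluators) they judge most appropriate for the dialogue context. The
#' Rvoted value of a candidate is its vote count; Rmax is the largest count
#' in the dialogue.
#'
#' @param dialogue An `rt_dialogue` (see [generate_evaluation_set()]), or
#'   `NULL` when only vote arithmetic is needed.
#' @param votes data.frame with columns `evaluator_id` and
#'   `chosen_candidate` (integers 0-3); zero rows means nobody voted.
#' @param n_candidates Number of candidate positions (4 in the study
#'   design).
#' @return Object of class `rt_rvoted`: `counts` (named integer vector,
#'   names "0".."3"), `rmax`, `n_evaluators`.
#' @examples
#' v <- data.frame(evaluator_id = paste0("e", 1:11), chosen_candidate = 0)
#' rvoted(NULL, v)
#' @export
rvoted <- function(dialogue, votes, n_candidates = 4L) {
  stopifnot(is.data.frame(votes))
  need <- c("evaluator_id", "chosen_candidate")
  if (!all(need %in% names(votes))) {
    rt_invalid_vote_error("votes need columns evaluator_id, chosen_candidate")
  }
  idx <- votes$chosen_candidate
  if (nrow(votes)) {
    if (any(is.na(idx)) || any(idx != as.integer(idx)) ||
        any(idx < 0L) || any(idx >= n_candidates)) {
      rt_invalid_vote_error(sprintf(
        "chosen_candidate must be an integer in 0..%d", n_candidates - 1L))
    }
    if (anyDuplicated(votes$evaluator_id)) {
      rt_invalid_vote_error("an evaluator voted more than once on a dialogue")
    }
  }
  counts <- integer(n_candidates)
  names(counts) <- as.character(seq_len(n_candidates) - 1L)
  if (nrow(votes)) {
    tab <- table(factor(as.integer(idx),
                        levels = seq_len(n_candidates) - 1L))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, rmax = max(counts),
                 n_evaluators = nrow(votes)),
            class = "rt_rvoted")
}

#' @export
print.rt_rvoted <- function(x, ...) {
  cat("Rvoted:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                       collapse = " "),
      sprintf(" (Rmax=%d, %d evaluators)\n", x$rmax, x$n_evaluators))
  invisible(x)
}

#' Per-position agreement with the most-voted response
#'
#' For each candidate position, the percentage of dialogues in which its
#' Rvoted equals the dialogue's Rmax. Ties count for every tied position,
#' so the percentages can sum above 100 — the convention that makes a
#' candidate's agreement the share of dialogues where it was (one of) the
#' most voted.
#'
#' @param votes_by_dialogue A list with one votes data.frame per dialogue
#'   (see [rvoted()]), or a single data.frame carrying a `dialogue_id`
#'   column to split on.
#' @param n_candidates Number of candidate positions.
#' @return Named numeric vector of percentages, names "0".."3", plus
#'   attribute `"n_dialogues"`.
#' @export
agreement_percentages <- function(votes_by_dialogue, n_candidates = 4L) {
  if (is.data.frame(votes_by_dialogue)) {
    if (!"dialogue_id" %in% names(votes_by_dialogue)) {
      rt_invalid_vote_error("votes data.frame needs a dialogue_id column")
    }
    votes_by_dialogue <- split(votes_by_dialogue,
                               votes_by_dialogue$dialogue_id)
  }
  nd <- length(votes_by_dialogue)
  if (!nd) rt_empty_input_error("no dialogues to aggregate")
  hits <- integer(n_candidates)
  for (v in votes_by_dialogue) {
    rv <- rvoted(NULL, v, n_candidates)
    hits <- hits + as.integer(rv$counts == rv$rmax)
  }
  out <- 100 * hits / nd
  names(out) <- as.character(seq_len(n_candidates) - 1L)
  attr(out, "n_dialogues") <- nd
  out
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return Object of class `rt_correlation`: `r`, `n`, `p_value`
#'   (two-sided, from the t distribution with n - 2 degrees of freedom).
#' @examples
#' pearson_correlation(1:5, c(2, 4, 5, 4, 5))
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    rt_length_mismatch_error(sprintf("length(x)=%d but length(y)=%d",
                                     length(x), length(y)))
  }
  if (length(x) < 3L) {
    rt_length_mismatch_error("need at least 3 pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rt_constant_input_error("correlation is undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value),
            class = "rt_correlation")
}

#' @export
print.rt_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-sided p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Summarize 1-5 star ratings
#'
#' @param ratings Integer vector with values in 1..5.
#' @return Object of class `rt_stars`: `mean` (exact), `mean_2dp` (half-up
#'   rounded to 2 decimals, the printed convention), `counts` and
#'   `percentages` per star, `n`.
#' @examples
#' star_rating_summary(c(rep(4, 7), rep(5, 3), 3))
#' @export
star_rating_summary <- function(ratings) {
  if (!length(ratings)) rt_empty_input_error("no ratings")
  if (any(is.na(ratings)) || any(ratings != as.integer(ratings)) ||
      any(ratings < 1L) || any(ratings > 5L)) {
    rt_range_error("ratings must be integers between 1 and 5")
  }
  ratings <- as.integer(ratings)
  counts <- table(factor(ratings, levels = 1:5))
  structure(list(mean = mean(ratings),
                 mean_2dp = round_half_up(mean(ratings), 2),
                 counts = counts,
                 percentages = 100 * as.numeric(counts) / length(ratings),
                 n = length(ratings)),
            class = "rt_stars")
}

#' @export
print.rt_stars <- function(x, ...) {
  cat(sprintf("star rating: mean %.2f over %d ratings\n", x$mean_2dp, x$n))
  for (s in 5:1) {
    cat(sprintf("  %d stars: %2d (%5.1f%%)\n", s, x$counts[[s]],
                x$percentages[[s]]))
  }
  invisible(x)
}

#' Read an evaluator-votes CSV
#'
#' Columns: `dialogue_id`, `evaluator_id`, `chosen_candidate` (0-3).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_votes_csv <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("dialogue_id", "evaluator_id", "chosen_candidate")
  if (!all(need %in% names(v))) {
    rt_invalid_vote_error(paste("votes CSV needs columns",
                                paste(need, collapse = ", ")))
  }
  v
}
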
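#' @title Backward-counting behavioural scoring
#' @name behavior
#' @description
#' Scores the silent backward-counting tasks (easy: count down from 100 by
#' 1; hard: from 300 by 7; 60 s each). Performance is the number of
#' subtractions achieved, `(start - reported_final) / decrement`, which can
#' be non-integer when counting errors were made; counting frequency is
#' performance per second.
NULL

#' One participant's counting report
#'
#' @param start starting number.
#' @param decrement step size (>= 1).
#' @param reported_final the final number the participant reported.
#' @param duration_s task duration in seconds (default 60).
#' @return a `counting_report` list.
#' @export
counting_report <- function(start, decrement, reported_final,
                            duration_s = 60) {
  stopifnot(decrement >= 1, duration_s > 0)
  structure(list(start = start, decrement = decrement,
                 reported_final = reported_final, duration_s = duration_s),
            class = "counting_report")
}

#' Counting performance: subtractions achieved
#'
#' `(start - reported_final) / decrement`. A reported final above the start
#' yields a negative score, returned with a warning.
#'
#' @param r a [counting_report()].
#' @return numeric performance score (may be non-integer).
#' @export
#' @examples
#' performance(counting_report(100, 1, 31))   # 69
#' performance(counting_report(300, 7, 237))  # 9
performance <- function(r) {
  stopifnot(inherits(r, "counting_report"))
  score <- (r$start - r$reported_final) / r$decrement
  if (score < 0) warning("reported final exceeds start: negative score")
  score
}

#' Counting frequency in Hz
#'
#' Performance divided by task duration: average subtractions per second.
#'
#' @param r a [counting_report()].
#' @return frequency in Hz.
#' @export
counting_frequency <- function(r) {
  performance(r) / r$duration_s
}

#' Correctness proxy of a counting report
#'
#' Without the true count reached, correctness is judged by whether the
#' achieved difference is divisible by the decrement, i.e. whether the
#' reported final lies on the arithmetic sequence. This is a proxy: a
#' compensating pair of errors can pass it.
#'
#' @param r a [counting_report()].
#' @return list: `correct` (logical), `remainder`.
#' @export
correctness <- function(r) {
  stopifnot(inherits(r, "counting_report"))
  rem <- (r$start - r$reported_final) %% r$decrement
  list(correct = rem == 0, remainder = rem)
}

#' Score a cohort's behavioural reports
#'
#' @param reports data.frame with columns `participant`, `start`,
#'   `decrement`, `final`, and optionally `duration` (default 60 s) and
#'   `task`.
#' @return data.frame with added `performance`, `frequency`, `correct`,
#'   plus attributes `n_correct`, `pct_correct` (2-dp percentage).
#' @export
score_behavior <- function(reports) {
  need <- c("participant", "start", "decrement", "final")
  stopifnot(all(need %in% names(reports)))
  dur <- if ("duration" %in% names(reports)) reports$duration else 60
  out <- reports
  rs <- lapply(seq_len(nrow(reports)), function(i)
    counting_report(reports$start[i], reports$decrement[i],
                    reports$final[i],
                    if (length(dur) > 1) dur[i] else dur))
  out$performance <- vapply(rs, performance, numeric(1))
  out$frequency <- vapply(rs, counting_frequency, numeric(1))
  out$correct <- vapply(rs, function(r) correctness(r)$correct, logical(1))
  attr(out, "n_correct") <- sum(out$correct)
  attr(out, "pct_correct") <- round(100 * mean(out$correct), 2)
  out
}
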
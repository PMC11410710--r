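#' Code one intake pair as a win, loss or tie
#'
#' The unit step of the multiverse: at preference threshold `t`, item A wins
#' an offering when its share of the total 30-min intake attains `t` and
#' exceeds half (strict majority), item B symmetrically; every other case —
#' including a zero total intake — is a tie. Ties are retained downstream as
#' half-wins rather than dropped, so the number of comparisons never changes
#' silently with the threshold.
#'
#' @param intake_a,intake_b Non-negative intakes (kg DM); vectorized.
#' @param threshold Preference threshold, a fraction in `[0.5, 1)`.
#' @param boundary `"ge"` (default) codes a share exactly equal to the
#'   threshold as a win; `"gt"` requires strict exceedance. With continuous
#'   intakes the two almost never differ, but both are available so either
#'   convention is reproducible.
#' @return Character vector in `c("win_a", "win_b", "tie")`.
#' @export
#' @examples
#' code_outcome(0.8, 0.2, 0.70)  # "win_a": share 80% attains 70%
#' code_outcome(0.6, 0.4, 0.70)  # "tie": neither share reaches 70%
code_outcome <- function(intake_a, intake_b, threshold,
                         boundary = c("ge", "gt")) {
  boundary <- match.arg(boundary)
  check_threshold(threshold)
  if (any(intake_a < 0) || any(intake_b < 0)) {
    stop("intakes must be non-negative", call. = FALSE)
  }
  total <- intake_a + intake_b
  share_a <- ifelse(total > 0, intake_a / total, 0.5)
  attains <- function(s) if (boundary == "ge") s >= threshold else s > threshold
  out <- rep("tie", length(share_a))
  out[attains(share_a) & share_a > 0.5] <- "win_a"
  out[attains(1 - share_a) & share_a < 0.5] <- "win_b"
  out
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || anyNA(threshold) ||
      any(threshold < 0.5) || any(threshold >= 1)) {
    stop("threshold(s) must lie in [0.5, 1)", call. = FALSE)
  }
  invisible(threshold)
}

check_threshold_grid <- function(thresholds) {
  check_threshold(thresholds)
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  invisible(thresholds)
}

#' Code a whole trial at one threshold
#'
#' Applies [code_outcome()] to every offering, carrying subject, occasion and
#' the item pair through. One outcome row per offering, order preserved.
#'
#' @param x A [trial()].
#' @param threshold Preference threshold in `[0.5, 1)`.
#' @param zero_total `"tie"` (default) retains offerings where nothing was
#'   eaten as ties (behavioral indifference); `"drop"` excludes them.
#' @inheritParams code_outcome
#' @return Data frame of outcome records with columns `subject`, `occasion`,
#'   `item_a`, `item_b`, `outcome`.
#' @export
code_trial <- function(x, threshold, boundary = c("ge", "gt"),
                       zero_total = c("tie", "drop")) {
  stopifnot(inherits(x, "trial"))
  boundary <- match.arg(boundary)
  zero_total <- match.arg(zero_total)
  rec <- x$records
  out <- data.frame(
    subject = rec$subject,
    occasion = rec$occasion,
    item_a = rec$item_a,
    item_b = rec$item_b,
    outcome = code_outcome(rec$intake_a, rec$intake_b, threshold, boundary),
    stringsAsFactors = FALSE
  )
  if (zero_total == "drop") {
    out <- out[rec$intake_a + rec$intake_b > 0, , drop = FALSE]
  }
  out
}

#' Fraction of tied comparisons
#'
#' @param outcomes Data frame of outcome records (from [code_trial()]).
#' @return `#ties / #records`, a fraction in `[0, 1]`.
#' @export
tie_fraction <- function(outcomes) {
  if (is.null(outcomes$outcome) || nrow(outcomes) == 0L) {
    stop("outcomes must be a nonempty outcome-record table", call. = FALSE)
  }
  mean(outcomes$outcome == "tie")
}
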
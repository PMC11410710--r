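#' Run the threshold multiverse over a trial
#'
#' The full two-step pipeline at every preference threshold in the grid:
#' code intakes to win/loss/tie ([code_trial()]), fit the Bradley-Terry
#' model ([fit_bt()]), and summarize with quasi-variances, CIs, pooled-SE
#' pairwise tests and letters ([quasi_summary()]). All branches use
#' identical settings except the threshold. A branch whose fit fails (e.g.
#' separation when a high threshold leaves too few decisive comparisons) is
#' recorded as failed with its reason, never dropped silently.
#'
#' The result is an ensemble to be read jointly; no combined cross-threshold
#' statistic is computed, because the ensemble does not constitute a single
#' formal test.
#'
#' @param x A [trial()].
#' @param thresholds Strictly increasing thresholds in `[0.5, 1)`; default
#'   `c(0.5, 0.6, 0.7, 0.8)`.
#' @param reference Item fixed at palatability zero; default first item.
#' @param alpha Significance level for tests and letters.
#' @param level CI coverage.
#' @inheritParams code_trial
#' @return Object of class `"multiverse_result"`: `thresholds`, `reference`,
#'   `alpha`, `items`, and `branches` — one entry per threshold with
#'   `threshold`, `tie_fraction`, `fit`, `summary`, `failed`, `reason`.
#' @export
run_multiverse <- function(x, thresholds = c(0.5, 0.6, 0.7, 0.8),
                           reference = NULL, alpha = 0.05, level = 0.95,
                           boundary = c("ge", "gt"),
                           zero_total = c("tie", "drop")) {
  stopifnot(inherits(x, "trial"))
  check_threshold_grid(thresholds)
  boundary <- match.arg(boundary)
  zero_total <- match.arg(zero_total)
  if (is.null(reference)) reference <- x$items[1L]

  branches <- lapply(thresholds, function(t) {
    outcomes <- code_trial(x, t, boundary = boundary, zero_total = zero_total)
    branch <- list(threshold = t,
                   tie_fraction = tie_fraction(outcomes),
                   fit = NULL, summary = NULL,
                   failed = FALSE, reason = NULL)
    res <- tryCatch({
      fit <- fit_bt(outcomes, reference = reference, items = x$items)
      if (fit$separation) stop("separation: an item never wins or never loses")
      list(fit = fit, summary = quasi_summary(fit, alpha = alpha,
                                              level = level))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      branch$failed <- TRUE
      branch$reason <- conditionMessage(res)
    } else {
      branch$fit <- res$fit
      branch$summary <- res$summary
    }
    branch
  })
  if (all(vapply(branches, `[[`, TRUE, "failed"))) {
    stop("every multiverse branch failed; first reason: ",
         branches[[1L]]$reason, call. = FALSE)
  }
  structure(list(thresholds = thresholds, reference = reference,
                 alpha = alpha, level = level, items = x$items,
                 branches = branches),
            class = "multiverse_result")
}

ok_branches <- function(result) {
  Filter(function(b) !b$failed, result$branches)
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat("Multiverse of", length(x$branches), "win-loss-tie thresholds",
      "(reference:", x$reference, "= 0)\n")
  for (b in x$branches) {
    cat(sprintf("  threshold %.2f | ties %4.1f%% | %s\n",
                b$threshold, 100 * b$tie_fraction,
                if (b$failed) paste("FAILED:", b$reason)
                else paste(sprintf("%s=%.2f%s", names(b$fit$abilities),
                                   b$fit$abilities,
                                   vapply(names(b$fit$abilities), function(it)
                                     b$summary$letters[[it]], "")),
                           collapse = " ")))
  }
  invisible(x)
}

#' @export
item_table.multiverse_result <- function(x, ...) {
  do.call(rbind, lapply(ok_branches(x), function(b) {
    cbind(threshold = b$threshold, tie_fraction = b$tie_fraction,
          item_table(b$summary))
  }))
}

#' @export
pair_table.multiverse_result <- function(x, ...) {
  do.call(rbind, lapply(ok_branches(x), function(b) {
    cbind(threshold = b$threshold, pair_table(b$summary))
  }))
}

#' Cross-threshold concordance of pairwise conclusions
#'
#' For every item pair, counts the branches in which its test is significant
#' at `alpha`, the branches in which it is not, and whether the sign of the
#' estimated difference agrees across branches. The verdict — redundant
#' versus conflicting ensemble — is left to the analyst; no pooled p-value
#' is produced.
#'
#' @param result A [run_multiverse()] result.
#' @param alpha Significance level; defaults to the one used in the run.
#' @return Data frame: `item_i`, `item_j`, `n_significant`,
#'   `n_nonsignificant`, `direction_consistent`; the number of failed
#'   branches is attached as attribute `n_failed`.
#' @export
summarize_concordance <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "multiverse_result"))
  ok <- ok_branches(result)
  if (length(ok) == 0L) stop("no successful branches", call. = FALSE)
  tests <- do.call(rbind, lapply(ok, function(b) as.data.frame(b$summary$tests)))
  key <- paste(tests$item_i, tests$item_j, sep = "\r")
  out <- do.call(rbind, lapply(split(tests, key), function(d) {
    sgn <- sign(d$delta[d$delta != 0])
    data.frame(item_i = d$item_i[1L], item_j = d$item_j[1L],
               n_significant = sum(!is.na(d$p) & d$p <= alpha),
               n_nonsignificant = sum(is.na(d$p) | d$p > alpha),
               direction_consistent = length(unique(sgn)) <= 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(match(out$item_i, result$items),
                   match(out$item_j, result$items)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_failed") <- length(result$branches) - length(ok)
  out
}

#' Plot a multiverse of palatability estimates
#'
#' One panel per threshold: palatability estimates with quasi-SE confidence
#' intervals and compact letters; items sharing a letter within a panel do
#' not differ significantly.
#'
#' @param x A [run_multiverse()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.multiverse_result <- function(x, ...) {
  tab <- item_table(x)
  tab$panel <- sprintf("threshold %.0f%% (ties %.0f%%)",
                       100 * tab$threshold, 100 * tab$tie_fraction)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$item, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$upper, label = .data$letters),
                       vjust = -0.6, size = 3.4) +
    ggplot2::facet_wrap(~panel, nrow = 1L) +
    ggplot2::labs(x = NULL, y = "palatability (log-odds vs reference)") +
    ggplot2::theme_bw()
}
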
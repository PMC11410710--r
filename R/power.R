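#' Specify a paired-preference design for simulation
#'
#' Describes the design whose power (or type-I error) is to be estimated:
#' the items with their true palatabilities, the schedule of pairs with
#' replicate counts, and the contrast to be tested. The default schedule
#' offers every unordered pair the same number of times, e.g. 4 items give
#' 6 pairs, offered once to each of 12 subjects = 72 comparisons.
#'
#' @param abilities Named numeric vector of true palatabilities (log-odds);
#'   names are the item labels.
#' @param replicates Replicate count per scheduled pair; a scalar (recycled)
#'   or a vector matching `pairs`.
#' @param pairs Two-column character matrix of unordered pairs; default all
#'   `choose(K, 2)` pairs.
#' @param contrast Character vector of two items whose palatability
#'   difference is tested; default the pair with the largest true
#'   difference (first such pair under the item ordering).
#' @param alpha Two-sided significance level of the test, default 0.05.
#' @param n_reps Number of Monte-Carlo replicates, default 2000.
#' @return Object of class `"design_spec"`.
#' @export
#' @examples
#' # the 4-feed trial layout: one palatability one unit below the rest
#' design_spec(c(A0 = 0, A48 = 0, B0 = 0, B48 = -1), replicates = 12,
#'             contrast = c("A48", "B48"))
design_spec <- function(abilities, replicates, pairs = NULL,
                        contrast = NULL, alpha = 0.05, n_reps = 2000L) {
  stopifnot(is.numeric(abilities), !is.null(names(abilities)),
            length(abilities) >= 2L, all(is.finite(abilities)))
  items <- names(abilities)
  if (is.null(pairs)) {
    idx <- utils::combn(items, 2L)
    pairs <- cbind(idx[1L, ], idx[2L, ])
  }
  pairs <- matrix(as.character(pairs), ncol = 2L)
  if (!all(pairs %in% items)) stop("pair labels not among items",
                                   call. = FALSE)
  if (any(pairs[, 1L] == pairs[, 2L])) stop("pairs must involve two distinct items",
                                            call. = FALSE)
  replicates <- rep_len(as.integer(replicates), nrow(pairs))
  if (any(replicates < 1L)) stop("replicate counts must be >= 1",
                                 call. = FALSE)
  if (is.null(contrast)) {
    d <- abs(outer(abilities, abilities, "-"))
    diag(d) <- -1
    ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
    contrast <- items[sort(ij)]
  }
  stopifnot(length(contrast) == 2L, all(contrast %in% items))
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1L)
  structure(list(items = items, abilities = abilities, pairs = pairs,
                 replicates = replicates, contrast = contrast,
                 alpha = alpha, n_reps = as.integer(n_reps)),
            class = "design_spec")
}

#' Simulate one replicate of binary preference outcomes
#'
#' Each scheduled comparison of pair `(i, j)` is an independent Bernoulli
#' draw: item `i` wins with probability [bt_probability()] of the true
#' palatabilities, otherwise item `j` wins. No ties are generated — this is
#' the pure win/loss world in which the Bradley-Terry selection probability
#' is defined (a unit difference means the better feed is picked 73% of the
#' time).
#'
#' @param design A [design_spec()].
#' @return Data frame of outcome records, one row per comparison, with
#'   `subject` set to the replicate index within each pair. Uses the current
#'   RNG state; call `set.seed()` first for reproducibility.
#' @export
simulate_outcomes <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  generate_outcome_stream(design$abilities, design$pairs, design$replicates)
}

#' Monte-Carlo power of the pooled quasi-SE pairwise test
#'
#' For each replicate: simulate the design's binary outcomes, fit the
#' Bradley-Terry model, compute quasi-variances, and test the contrast with
#' the pooled quasi-SE z-test at `alpha` — the same inferential procedure as
#' the main pipeline. Power is the fraction of rejections. Replicates where
#' the fit separates or the quasi-variance computation fails are, by
#' default, excluded from the denominator and counted in `n_failed`; with
#' `failed = "nonreject"` they are kept as non-rejections, a conservative
#' sensitivity option. With all true palatabilities equal this estimates the
#' type-I error instead.
#'
#' @param design A [design_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @param failed How to count failed replicates: `"exclude"` (default) or
#'   `"nonreject"`.
#' @return Object of class `"power_result"`: `power_estimate`, binomial
#'   Monte-Carlo standard error `mc_se`, `n_failed`, `n_effective`,
#'   `unreliable` (flagged when more than 20% of replicates failed) and the
#'   design settings.
#' @export
#' @examples
#' \donttest{
#' d <- design_spec(c(A0 = 0, A48 = 0, B0 = 0, B48 = -1), replicates = 12,
#'                  contrast = c("A48", "B48"), n_reps = 200)
#' estimate_power(d, seed = 1)
#' }
estimate_power <- function(design, seed = NULL,
                           failed = c("exclude", "nonreject")) {
  stopifnot(inherits(design, "design_spec"))
  failed <- match.arg(failed)
  if (!is.null(seed)) set.seed(seed)
  reference <- design$items[1L]
  ci <- design$contrast

  reject <- logical(design$n_reps)
  ok <- logical(design$n_reps)
  for (r in seq_len(design$n_reps)) {
    outcomes <- simulate_outcomes(design)
    res <- tryCatch(suppressWarnings({
      fit <- fit_bt(outcomes, reference = reference, items = design$items)
      if (fit$separation) stop("separation")
      qv <- quasi_variances(fit)
      pooled_var <- qv$q[[ci[1L]]] + qv$q[[ci[2L]]]
      if (!is.finite(pooled_var) || pooled_var <= 0) stop("pooled variance")
      z <- (fit$abilities[[ci[1L]]] - fit$abilities[[ci[2L]]]) /
        sqrt(pooled_var)
      2 * stats::pnorm(-abs(z))
    }), error = function(e) NA_real_)
    if (is.na(res)) next
    ok[r] <- TRUE
    reject[r] <- res <= design$alpha
  }
  n_failed <- sum(!ok)
  if (failed == "exclude") {
    n_eff <- sum(ok)
    p_hat <- if (n_eff > 0L) mean(reject[ok]) else NA_real_
  } else {
    n_eff <- design$n_reps
    p_hat <- mean(reject & ok)
  }
  structure(list(
    power_estimate = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / n_eff),
    n_failed = n_failed,
    n_effective = n_eff,
    unreliable = n_failed > 0.2 * design$n_reps,
    failed_handling = failed,
    design = design
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  d <- x$design
  cat(sprintf("Monte-Carlo power: %.3f (MC SE %.4f)\n",
              x$power_estimate, x$mc_se))
  cat(sprintf("  contrast %s vs %s | alpha %.3g | %d replicates, %d failed\n",
              d$contrast[1L], d$contrast[2L], d$alpha, d$n_reps, x$n_failed))
  if (x$unreliable) cat("WARNING: >20% of replicates failed; unreliable\n")
  invisible(x)
}
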
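#' Quasi-variances for Bradley-Terry palatabilities
#'
#' Computes a quasi-variance `q_i` for every item — including the zero
#' reference — such that `q_i + q_j` approximates the variance of the
#' contrast `lambda_i - lambda_j` for every pair. The `q` minimize the sum
#' of squared errors on the log scale,
#' `sum_(i<j) (log(q_i + q_j) - log v_ij)^2`, where
#' `v_ij = c_ii + c_jj - 2 c_ij` is the exact contrast variance. This is what
#' lets the usual "pooled SE" pairwise tests be run from a per-item table.
#'
#' For `K = 3` the three equations can be met exactly and the residual is
#' zero; for `K >= 4` the approximation error is reported, not hidden:
#' `worst_rel_err` is the largest relative error of `q_i + q_j` against
#' `v_ij` over all pairs. Quasi-variances can legitimately come out
#' negative; they are then flagged and their quasi-SE is `NA`.
#'
#' @param covariance A `K x K` ability covariance matrix with a zero row and
#'   column at the reference item, or a [fit_bt()] object.
#' @return An object of class `"quasi_var"`: named vector `q`, quasi-SEs
#'   `se = sqrt(q)`, the log-scale `residual` attained, `worst_rel_err`, and
#'   a `negative` flag.
#' @export
quasi_variances <- function(covariance) {
  if (inherits(covariance, "bt_fit")) covariance <- covariance$covariance
  C <- as.matrix(covariance)
  K <- nrow(C)
  if (K < 2L || K != ncol(C)) stop("covariance must be square, K >= 2",
                                   call. = FALSE)
  if (any(!is.finite(C))) stop("covariance contains non-finite entries",
                               call. = FALSE)
  items <- rownames(C)
  if (is.null(items)) items <- paste0("item", seq_len(K))

  V <- outer(diag(C), diag(C), "+") - 2 * C
  pairs <- which(upper.tri(V), arr.ind = TRUE)
  v <- V[pairs]
  if (any(v <= 0)) {
    stop("degenerate covariance: some contrast variances are <= 0",
         call. = FALSE)
  }

  # init: ordinary least squares on the v scale, (K-2) I + 11' system;
  # K = 2 is underdetermined and the even split is exact
  if (K == 2L) {
    q0 <- rep(v / 2, 2L)
  } else {
    b <- rowSums(V) - diag(V)
    A <- matrix(1, K, K); diag(A) <- K - 1
    q0 <- solve(A, b)
  }
  s0 <- q0[pairs[, 1L]] + q0[pairs[, 2L]]
  if (any(s0 <= 0)) q0 <- rep(mean(v) / 2, K)

  obj <- function(q) {
    s <- q[pairs[, 1L]] + q[pairs[, 2L]]
    if (any(s <= 0)) return(1e10 - min(s))
    sum((log(s) - log(v))^2)
  }
  grd <- function(q) {
    s <- q[pairs[, 1L]] + q[pairs[, 2L]]
    if (any(s <= 0)) return(rep(0, K))
    r <- 2 * (log(s) - log(v)) / s
    g <- numeric(K)
    for (k in seq_len(K)) {
      g[k] <- sum(r[pairs[, 1L] == k | pairs[, 2L] == k])
    }
    g
  }
  opt <- stats::optim(q0, obj, grd, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500L))
  q <- opt$par
  s <- q[pairs[, 1L]] + q[pairs[, 2L]]

  negative <- any(q < 0)
  if (negative) {
    warning("negative quasi-variance(s): ",
            paste(items[q < 0], collapse = ", "), call. = FALSE)
  }
  structure(list(
    q = stats::setNames(q, items),
    se = stats::setNames(ifelse(q >= 0, sqrt(pmax(q, 0)), NA_real_), items),
    residual = opt$value,
    worst_rel_err = max(abs(s / v - 1)),
    negative = negative
  ), class = "quasi_var")
}

#' @export
print.quasi_var <- function(x, ...) {
  cat("Quasi-variances (log-scale residual",
      format(x$residual, digits = 3), ")\n")
  print(round(rbind(q = x$q, quasi_se = x$se), 4))
  invisible(x)
}

#' Pooled quasi-SE pairwise tests
#'
#' For every unordered item pair, tests the palatability difference with a
#' Wald z statistic whose standard error is pooled from the two
#' quasi-variances: `z = (lambda_i - lambda_j) / sqrt(q_i + q_j)`, two-sided
#' p from the normal distribution. The Bradley-Terry covariance is
#' asymptotic, so the normal (not t) reference is used. By default p-values
#' are reported raw, matching the per-pair letter criterion; set `p_adjust`
#' for a multiplicity correction.
#'
#' @param fit A [fit_bt()] object.
#' @param qv Quasi-variances from [quasi_variances()] on `fit`; computed if
#'   omitted.
#' @param alpha Significance level attached to the table (default 0.05).
#' @param p_adjust Method passed to [stats::p.adjust()] (default `"none"`).
#' @return Data frame of class `"pairwise_tests"`: columns `item_i`,
#'   `item_j`, `delta`, `pooled_se`, `z`, `p`. Pairs with non-positive
#'   pooled variance are marked undefined (`NA`).
#' @export
pairwise_tests <- function(fit, qv = quasi_variances(fit), alpha = 0.05,
                           p_adjust = "none") {
  stopifnot(inherits(fit, "bt_fit"))
  items <- fit$items
  idx <- which(upper.tri(diag(length(items))), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  delta <- unname(fit$abilities[items[i]] - fit$abilities[items[j]])
  pooled_var <- unname(qv$q[items[i]] + qv$q[items[j]])
  pooled_se <- ifelse(pooled_var > 0, sqrt(pooled_var), NA_real_)
  z <- delta / pooled_se
  p <- 2 * stats::pnorm(-abs(z))
  p <- stats::p.adjust(p, method = p_adjust)
  structure(
    data.frame(item_i = items[i], item_j = items[j],
               delta = delta, pooled_se = pooled_se, z = z, p = p,
               stringsAsFactors = FALSE),
    alpha = alpha, class = c("pairwise_tests", "data.frame")
  )
}

#' Quasi-SE confidence intervals for palatabilities
#'
#' Per-item interval `lambda_i +/- z * sqrt(q_i)` at the given coverage.
#' An interval is produced for every item, including the reference, whose
#' point estimate is pinned at zero but whose quasi-variance is generally
#' nonzero. Items with negative quasi-variance get `NA` bounds and a
#' warning.
#'
#' @inheritParams pairwise_tests
#' @param level Coverage, default 0.95.
#' @return Data frame: `item`, `estimate`, `quasi_se`, `lower`, `upper`.
#' @export
confidence_intervals <- function(fit, qv = quasi_variances(fit),
                                 level = 0.95) {
  stopifnot(inherits(fit, "bt_fit"), level > 0, level < 1)
  zq <- stats::qnorm((1 + level) / 2)
  se <- unname(qv$se[fit$items])
  if (anyNA(se)) {
    warning("interval undefined for item(s) with negative quasi-variance",
            call. = FALSE)
  }
  est <- unname(fit$abilities[fit$items])
  data.frame(item = fit$items, estimate = est, quasi_se = se,
             lower = est - zq * se, upper = est + zq * se,
             stringsAsFactors = FALSE)
}

#' Compact letter display from a pairwise test matrix
#'
#' Assigns letters so that two items share a letter if and only if their
#' pairwise test is non-significant at `alpha` (insert-and-absorb
#' algorithm). Undefined (NA) p-values are treated as non-significant.
#'
#' @param tests A [pairwise_tests()] table.
#' @param alpha Significance level; defaults to the level stored in `tests`.
#' @param order Optional item ordering used to assign letters (e.g. by
#'   decreasing palatability); defaults to first appearance.
#' @return Named character vector: item -> concatenated letters.
#' @export
letter_display <- function(tests, alpha = attr(tests, "alpha"),
                           order = NULL) {
  if (is.null(alpha)) alpha <- 0.05
  items <- unique(c(tests$item_i, tests$item_j))
  if (!is.null(order)) items <- order[order %in% items]
  sig <- tests[!is.na(tests$p) & tests$p <= alpha, , drop = FALSE]

  groups <- list(items)
  if (nrow(sig) > 0L) {
    for (r in seq_len(nrow(sig))) {
      a <- sig$item_i[r]; b <- sig$item_j[r]
      new_groups <- list()
      for (g in groups) {
        if (a %in% g && b %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb: drop empty/duplicate groups and proper subsets of another
      new_groups <- unique(lapply(Filter(length, new_groups), sort))
      keep <- vapply(seq_along(new_groups), function(u) {
        !any(vapply(seq_along(new_groups), function(w) {
          w != u &&
            length(new_groups[[w]]) > length(new_groups[[u]]) &&
            all(new_groups[[u]] %in% new_groups[[w]])
        }, logical(1L)))
      }, logical(1L))
      groups <- new_groups[keep]
    }
  }
  # order groups by the position of their first member, assign letters
  first <- vapply(groups, function(g) min(match(g, items)), 0)
  groups <- groups[order(first)]
  out <- stats::setNames(rep("", length(items)), items)
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    out[members] <- paste0(out[members], letters[gi])
  }
  out
}

#' One-stop quasi-variance summary of a Bradley-Terry fit
#'
#' Bundles [quasi_variances()], [confidence_intervals()],
#' [pairwise_tests()] and [letter_display()] — the per-branch inferential
#' output of the pipeline.
#'
#' @inheritParams pairwise_tests
#' @param level CI coverage, default 0.95.
#' @return Object of class `"quasi_summary"` with elements `qv`, `ci`,
#'   `tests`, `letters`, `alpha`, `level`.
#' @export
quasi_summary <- function(fit, alpha = 0.05, level = 0.95,
                          p_adjust = "none") {
  qv <- quasi_variances(fit)
  tests <- pairwise_tests(fit, qv, alpha = alpha, p_adjust = p_adjust)
  ci <- confidence_intervals(fit, qv, level = level)
  ord <- fit$items[order(fit$abilities, decreasing = TRUE)]
  letters <- letter_display(tests, alpha = alpha, order = ord)
  structure(list(qv = qv, ci = ci, tests = tests,
                 letters = letters[fit$items],
                 alpha = alpha, level = level),
            class = "quasi_summary")
}

#' @export
print.quasi_summary <- function(x, ...) {
  tab <- item_table(x)
  tab[, c("estimate", "quasi_se", "lower", "upper")] <-
    round(tab[, c("estimate", "quasi_se", "lower", "upper")], 4)
  print(tab, row.names = FALSE)
  cat("(items sharing a letter do not differ at alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Per-item and per-pair result tables
#'
#' `item_table()` mirrors the usual figure layout (estimate, quasi-SE, CI,
#' letters); `pair_table()` mirrors the p-value matrix as a long table.
#' Both work on a single [quasi_summary()] or on a whole
#' [run_multiverse()] result, in which case a `threshold` column is added.
#'
#' @param x A `quasi_summary` or `multiverse_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
item_table <- function(x, ...) UseMethod("item_table")

#' @rdname item_table
#' @export
pair_table <- function(x, ...) UseMethod("pair_table")

#' @export
item_table.quasi_summary <- function(x, ...) {
  cbind(x$ci, letters = unname(x$letters[x$ci$item]))
}

#' @export
pair_table.quasi_summary <- function(x, ...) as.data.frame(x$tests)
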
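#' Bradley-Terry selection probability
#'
#' Probability that the item with palatability `lambda_i` is selected over
#' the item with palatability `lambda_j`: the inverse logit of their
#' difference. A unit palatability advantage gives
#' `1 / (1 + exp(-1)) = 0.7311`, i.e. the more palatable feed is chosen
#' about 73% of the time.
#'
#' @param lambda_i,lambda_j Palatabilities (log-odds units); vectorized.
#' @return Selection probability in `(0, 1)`.
#' @export
#' @examples
#' bt_probability(1, 0)  # 0.7311
bt_probability <- function(lambda_i, lambda_j) {
  stats::plogis(lambda_i - lambda_j)
}

#' Accumulate outcome records into a win matrix
#'
#' Entry `(i, j)` holds the number of wins of item `i` over item `j`; each
#' tie contributes half a win to both orders, so pair totals are conserved:
#' `counts[i, j] + counts[j, i]` equals the number of i-vs-j comparisons.
#'
#' @param outcomes Data frame of outcome records (columns `item_a`,
#'   `item_b`, `outcome` in `c("win_a", "win_b", "tie")`).
#' @param items Ordered item labels; every item in `outcomes` must appear.
#' @return `K x K` numeric matrix with zero diagonal, dimnames `items`.
#' @export
accumulate_wins <- function(outcomes, items) {
  unknown <- setdiff(unique(c(outcomes$item_a, outcomes$item_b)), items)
  if (length(unknown) > 0L) {
    stop("unknown item label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  K <- length(items)
  W <- matrix(0, K, K, dimnames = list(items, items))
  if (nrow(outcomes) == 0L) return(W)
  a <- match(outcomes$item_a, items)
  b <- match(outcomes$item_b, items)
  add <- function(i, j, w) {
    if (length(i) > 0L) {
      tab <- rowsum(w, group = (j - 1L) * K + i)
      idx <- as.integer(rownames(tab))
      W[idx] <<- W[idx] + tab[, 1L]
    }
  }
  wa <- outcomes$outcome == "win_a"
  wb <- outcomes$outcome == "win_b"
  ti <- outcomes$outcome == "tie"
  add(a[wa], b[wa], rep(1, sum(wa)))
  add(b[wb], a[wb], rep(1, sum(wb)))
  add(a[ti], b[ti], rep(0.5, sum(ti)))
  add(b[ti], a[ti], rep(0.5, sum(ti)))
  W
}

bt_loglik <- function(lambda, W) {
  # sum_{i != j} W[i,j] * log plogis(lambda_i - lambda_j), computed stably
  d <- outer(lambda, lambda, "-")
  lp <- -log1p(exp(-d))             # log p_ij
  lp[!is.finite(lp)] <- d[!is.finite(lp)]  # d very negative: log p ~ d
  diag(lp) <- 0
  sum(W * lp)
}

bt_grad_hess <- function(lambda, W) {
  P <- stats::plogis(outer(lambda, lambda, "-"))
  N <- W + t(W)
  diag(P) <- 0
  g <- rowSums(W) - rowSums(N * P)
  V <- N * P * (1 - P)
  H <- V
  diag(H) <- 0
  diag(H) <- -rowSums(H)            # Hessian of loglik: off-diag V, diag -sum
  list(grad = g, hess = H)
}

connected_components <- function(adj) {
  K <- nrow(adj)
  comp <- rep(NA_integer_, K)
  cur <- 0L
  for (s in seq_len(K)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Fit a Bradley-Terry palatability model
#'
#' Maximum-likelihood palatabilities from win/loss/tie outcomes, with one
#' item fixed at zero as the reference. Ties enter the likelihood as half a
#' win for each order (factor `p^0.5 * (1-p)^0.5`). Optimization is Newton's
#' method on the free parameters, started at zero, with a minorization (MM)
#' fallback step whenever a Newton step fails to improve the log-likelihood.
#'
#' @param outcomes Data frame of outcome records (from [code_trial()] or
#'   [simulate_outcomes()]).
#' @param reference Item label fixed at palatability zero; defaults to the
#'   first item encountered.
#' @param items Optional ordered item labels; defaults to order of first
#'   appearance in `outcomes`.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `"bt_fit"` with elements `items`, `reference`,
#'   `abilities` (named vector, reference exactly 0), `covariance` (`K x K`,
#'   zero row/column at the reference), `log_likelihood`, `converged`,
#'   `n_iterations`, `separation` and the win matrix `counts`.
#'   `separation = TRUE` flags an item whose estimate diverges (it never
#'   loses or never wins), under which the MLE is infinite and the reported
#'   numbers are untrustworthy.
#' @export
#' @examples
#' out <- data.frame(item_a = "x", item_b = "y",
#'                   outcome = c("win_a", "win_a", "win_a", "win_b"))
#' fit <- fit_bt(out, reference = "y")
#' fit$abilities[["x"]]  # log(3)
fit_bt <- function(outcomes, reference = NULL, items = NULL,
                   tol = 1e-8, max_iter = 200L) {
  if (is.null(items)) items <- unique(c(outcomes$item_a, outcomes$item_b))
  K <- length(items)
  if (K < 2L) stop("need at least 2 items", call. = FALSE)
  if (is.null(reference)) reference <- items[1L]
  if (!reference %in% items) {
    stop("reference '", reference, "' is not among the items", call. = FALSE)
  }
  W <- accumulate_wins(outcomes, items)
  N <- W + t(W)

  comp <- connected_components(N > 0)
  if (length(unique(comp)) > 1L) {
    parts <- split(items, comp)
    stop("comparison graph is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "),
         call. = FALSE)
  }

  ref <- match(reference, items)
  free <- setdiff(seq_len(K), ref)
  lambda <- rep(0, K)
  ll <- bt_loglik(lambda, W)
  converged <- FALSE
  iter <- 0L

  mm_step <- function(lambda) {
    # MM update on the worth scale pi = exp(lambda), then re-anchor
    pi <- exp(lambda)
    S <- outer(pi, pi, "+")
    denom <- rowSums(N / S) - diag(N / S)
    wi <- rowSums(W)
    pi_new <- ifelse(denom > 0, wi / denom, pi)
    pi_new[pi_new <= 0] <- 1e-12
    log(pi_new) - log(pi_new[ref])
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    gh <- bt_grad_hess(lambda, W)
    g <- gh$grad[free]
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    H <- gh$hess[free, free, drop = FALSE]
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    moved <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      cand <- lambda
      cand[free] <- cand[free] + step
      ll_cand <- bt_loglik(cand, W)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) {
        lambda <- cand; ll <- ll_cand; moved <- TRUE
      }
    }
    if (!moved) {
      cand <- mm_step(lambda)
      ll_cand <- bt_loglik(cand, W)
      if (!is.finite(ll_cand) || ll_cand <= ll + 1e-12) break
      lambda <- cand; ll <- ll_cand
    }
  }

  gh <- bt_grad_hess(lambda, W)
  if (!converged && max(abs(gh$grad[free])) <= tol) converged <- TRUE
  separation <- any(abs(lambda) > 15)

  H <- gh$hess[free, free, drop = FALSE]
  cov_free <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(cov_free) || any(!is.finite(cov_free)) ||
      any(diag(cov_free) < 0)) {
    separation <- TRUE
    cov_free <- matrix(NA_real_, K - 1L, K - 1L)
  }
  covariance <- matrix(0, K, K, dimnames = list(items, items))
  covariance[free, free] <- cov_free

  structure(list(
    items = items, reference = reference,
    abilities = stats::setNames(lambda, items),
    covariance = covariance,
    log_likelihood = ll,
    converged = converged, n_iterations = iter,
    separation = separation,
    counts = W
  ), class = "bt_fit")
}

#' @export
print.bt_fit <- function(x, ...) {
  cat("Bradley-Terry palatability fit (reference:", x$reference, "= 0)\n")
  print(round(x$abilities, 4))
  cat("log-likelihood:", format(x$log_likelihood, digits = 6),
      "| converged:", x$converged,
      "| iterations:", x$n_iterations, "\n")
  if (x$separation) cat("WARNING: separation detected; estimates diverge\n")
  invisible(x)
}

#' @export
vcov.bt_fit <- function(object, ...) object$covariance

#' @export
as.data.frame.bt_fit <- function(x, ...) {
  cbind(
    data.frame(item = x$items, ability = unname(x$abilities)),
    stats::setNames(as.data.frame(x$covariance),
                    paste0("cov_", x$items))
  )
}
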
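# Small fixture builders shared across test files.

# outcome-record table from a compact spec: list(c(item_a, item_b, outcome))
make_outcomes <- function(...) {
  rows <- list(...)
  data.frame(
    subject = paste0("s", seq_along(rows)),
    occasion = NA_character_,
    item_a = vapply(rows, `[[`, "", 1L),
    item_b = vapply(rows, `[[`, "", 2L),
    outcome = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# n_a wins for a over b, n_b for b, n_t ties, as an outcome table
pair_outcomes <- function(a, b, n_a, n_b, n_t = 0L) {
  out <- c(rep("win_a", n_a), rep("win_b", n_b), rep("tie", n_t))
  data.frame(subject = paste0("s", seq_along(out)),
             occasion = NA_character_,
             item_a = a, item_b = b, outcome = out,
             stringsAsFactors = FALSE)
}

# tiny intake trial with hand-picked shares
tiny_trial <- function() {
  trial(data.frame(
    subject = rep(c("h1", "h2"), each = 3L),
    occasion = rep(c("d1", "d2", "d3"), 2L),
    item_a = c("A0", "A0", "A48", "A0", "A0", "A48"),
    item_b = c("A48", "B0", "B0", "A48", "B0", "B0"),
    intake_a = c(0.8, 0.6, 0.3, 0.9, 0.55, 0.2),
    intake_b = c(0.2, 0.4, 0.7, 0.1, 0.45, 0.8),
    stringsAsFactors = FALSE
  ))
}

# brute-force log-likelihood of a win matrix at given abilities
brute_loglik <- function(lambda, W) {
  ll <- 0
  K <- nrow(W)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j && W[i, j] > 0) {
      ll <- ll + W[i, j] * log(plogis(lambda[i] - lambda[j]))
    }
  }
  ll
}

# check the compact-letter-display invariant: shared letter <=> p > alpha
letters_consistent <- function(letters, tests, alpha) {
  for (r in seq_len(nrow(tests))) {
    shared <- length(intersect(
      strsplit(letters[[tests$item_i[r]]], "")[[1L]],
      strsplit(letters[[tests$item_j[r]]], "")[[1L]]
    )) > 0L
    signif <- !is.na(tests$p[r]) && tests$p[r] <= alpha
    if (shared == signif) return(FALSE)
  }
  TRUE
}
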
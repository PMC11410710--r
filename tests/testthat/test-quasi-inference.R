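# independent oracle: for K = 3 the quasi-variance equations are met
# exactly by a linear solve, q_i = (v_ij + v_ik - v_jk) / 2
qv_linear_solve_k3 <- function(V) {
  c(q1 = (V[1, 2] + V[1, 3] - V[2, 3]) / 2,
    q2 = (V[1, 2] + V[2, 3] - V[1, 3]) / 2,
    q3 = (V[1, 3] + V[2, 3] - V[1, 2]) / 2)
}

contrast_var <- function(C) outer(diag(C), diag(C), "+") - 2 * C

test_that("K = 3 quasi-variances attain the exact linear solution", {
  set.seed(13)
  out <- generate_outcome_stream(c(r = 0, s = 0.7, t = -0.4),
                                 rbind(c("r", "s"), c("r", "t"), c("s", "t")),
                                 25L)
  fit <- fit_bt(out, reference = "r")
  qv <- quasi_variances(fit)
  V <- contrast_var(fit$covariance)
  expect_equal(unname(qv$q), unname(qv_linear_solve_k3(V)), tolerance = 1e-8)
  expect_lt(qv$residual, 1e-12)
  expect_lt(qv$worst_rel_err, 1e-6)
  # quasi-SEs reconstruct every contrast SE exactly at K = 3
  expect_equal(sqrt(qv$q[1] + qv$q[2]), sqrt(V[1, 2]),
               ignore_attr = TRUE, tolerance = 1e-7)
})

test_that("identity covariance of two free items solves as computed by the oracle", {
  C <- matrix(0, 3, 3, dimnames = rep(list(c("r", "s", "t")), 2))
  C[2:3, 2:3] <- diag(2)
  V <- contrast_var(C)
  oracle <- qv_linear_solve_k3(V)  # (0, 1, 1)
  qv <- quasi_variances(C)
  expect_equal(unname(qv$q), unname(oracle), tolerance = 1e-8)
  expect_equal(unname(oracle), c(0, 1, 1))
})

test_that("K = 4 fits report the approximation instead of hiding it", {
  set.seed(17)
  abilities <- c(a = 0, b = 0.3, c = -0.5, d = 0.9)
  out <- generate_outcome_stream(abilities, t(combn(names(abilities), 2L)), 30L)
  fit <- fit_bt(out, reference = "a")
  qv <- quasi_variances(fit)
  expect_true(is.finite(qv$worst_rel_err))

  # optimality against the constant baseline q_i = mean(v)/2
  V <- contrast_var(fit$covariance)
  v <- V[upper.tri(V)]
  objective <- function(q) {
    s <- outer(q, q, "+")[upper.tri(V)]
    sum((log(s) - log(v))^2)
  }
  expect_lte(objective(unname(qv$q)), objective(rep(mean(v) / 2, 4L)))

  # pooled-SE p-values track exact-contrast p-values within 10% relative
  tests <- pairwise_tests(fit, qv)
  for (r in seq_len(nrow(tests))) {
    vij <- V[tests$item_i[r], tests$item_j[r]]
    p_exact <- 2 * pnorm(-abs(tests$delta[r]) / sqrt(vij))
    expect_equal(tests$p[r], p_exact, tolerance = 0.1)
  }
})

test_that("degenerate covariances are refused", {
  C <- matrix(0, 3, 3)  # all contrast variances zero
  expect_error(quasi_variances(C), "degenerate")
})

test_that("pairwise tests follow the pooled quasi-SE z formula", {
  out <- rbind(pair_outcomes("a", "b", 0L, 0L, 6L),
               pair_outcomes("b", "c", 0L, 0L, 6L),
               pair_outcomes("a", "c", 0L, 0L, 6L))
  fit <- fit_bt(out, reference = "a")   # all deltas zero
  tests <- pairwise_tests(fit)
  expect_equal(tests$p, rep(1, 3L))
  expect_identical(tests$item_i, c("a", "a", "b"))

  # z quantile identity: delta = 1.96 pooled SE <-> p ~ 0.05
  set.seed(29)
  out2 <- generate_outcome_stream(c(a = 0, b = 0.8, c = -0.2),
                                  rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                                  40L)
  fit2 <- fit_bt(out2, reference = "a")
  qv2 <- quasi_variances(fit2)
  t2 <- pairwise_tests(fit2, qv2)
  expect_equal(t2$p, 2 * pnorm(-abs(t2$delta) / t2$pooled_se))
  expect_equal(t2$pooled_se[1L],
               sqrt(qv2$q[["a"]] + qv2$q[["b"]]))

  # optional multiplicity correction
  t2h <- pairwise_tests(fit2, qv2, p_adjust = "holm")
  expect_equal(t2h$p, p.adjust(t2$p, "holm"))
})

test_that("confidence intervals use per-item quasi-SEs, reference included", {
  set.seed(37)
  out <- generate_outcome_stream(c(a = 0, b = 0.5, c = 1),
                                 rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                                 30L)
  fit <- fit_bt(out, reference = "a")
  qv <- quasi_variances(fit)
  ci <- confidence_intervals(fit, qv, level = 0.95)
  expect_equal(ci$upper - ci$estimate, qnorm(0.975) * unname(qv$se[ci$item]))
  # reference has a nonzero interval around its pinned estimate
  ref <- ci[ci$item == "a", ]
  expect_identical(ref$estimate, 0)
  expect_gt(ref$upper, 0)
  expect_lt(ref$lower, 0)
  # widths scale as sqrt(q)
  width <- ci$upper - ci$lower
  expect_equal(width / sqrt(unname(qv$q[ci$item])),
               rep(2 * qnorm(0.975), 3L))
})

test_that("letter displays match the significance pattern exactly", {
  mk_tests <- function(p) {
    structure(data.frame(item_i = c("a", "a", "a", "b", "b", "c"),
                         item_j = c("b", "c", "d", "c", "d", "d"),
                         delta = 0, pooled_se = 1, z = 0, p = p),
              alpha = 0.05, class = c("pairwise_tests", "data.frame"))
  }
  # all significant -> four distinct letters
  lt <- letter_display(mk_tests(rep(0.01, 6L)))
  expect_length(unique(lt), 4L)
  expect_true(all(nchar(lt) == 1L))
  # none significant -> one shared letter
  lt <- letter_display(mk_tests(rep(0.4, 6L)))
  expect_length(unique(lt), 1L)
  # exactly one non-significant pair shares; all other pairs disjoint
  p <- rep(0.01, 6L); p[4L] <- 0.9  # pair (b, c)
  lt <- letter_display(mk_tests(p))
  expect_true(letters_consistent(lt, mk_tests(p), 0.05))
})
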
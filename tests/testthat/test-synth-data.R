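test_that("the default trial reproduces the crossed pair schedule", {
  tr <- generate_trial(synthetic_config(), seed = 1)
  rec <- tr$records
  expect_equal(nrow(rec), 72L)
  expect_length(unique(rec$subject), 12L)
  # every subject sees each unordered pair exactly once, over 6 occasions
  key <- apply(cbind(rec$item_a, rec$item_b), 1L,
               function(r) paste(sort(r), collapse = ":"))
  tab <- table(rec$subject, key)
  expect_true(all(tab == 1L))
  expect_equal(ncol(tab), 6L)
  expect_true(all(table(rec$subject, rec$occasion) == 1L))
  # physical constraints
  expect_true(all(rec$intake_a >= 0 & rec$intake_a <= rec$offered_a))
  expect_true(all(rec$intake_b >= 0 & rec$intake_b <= rec$offered_b))
  expect_true(all(rec$offered_a >= 2.09 & rec$offered_a <= 2.99))
})

test_that("the generator is deterministic under a fixed seed", {
  t1 <- generate_trial(synthetic_config(), seed = 42)
  t2 <- generate_trial(synthetic_config(), seed = 42)
  expect_identical(t1$records, t2$records)
})

test_that("marginal intake statistics hit their targets", {
  # at trial scale (72 offerings): within 15%
  tr <- generate_trial(synthetic_config(), seed = 2)
  bins <- c(tr$records$intake_a, tr$records$intake_b)
  expect_equal(mean(bins), 0.48, tolerance = 0.15)
  expect_equal(sd(bins), 0.40, tolerance = 0.15)
  # at 10,000 offerings: within 3%
  big <- generate_trial(synthetic_config(n_subjects = 1667L), seed = 2)
  bins <- c(big$records$intake_a, big$records$intake_b)
  expect_equal(mean(bins), 0.48, tolerance = 0.03)
  expect_equal(sd(bins), 0.40, tolerance = 0.03)
})

test_that("3-h intakes correlate with 30-min intakes as configured", {
  cfg <- synthetic_config(n_subjects = 400L, include_3h = TRUE)
  tr <- generate_trial(cfg, seed = 8)
  rec <- tr$records
  expect_true(all(c("intake_a_3h", "intake_b_3h") %in% names(rec)))
  expect_true(all(rec$intake_a_3h >= rec$intake_a - 1e-12))
  r <- cor(c(rec$intake_a, rec$intake_b),
           c(rec$intake_a_3h, rec$intake_b_3h))
  expect_equal(r, 0.89, tolerance = 0.03)
})

test_that("tie fractions grow with the threshold on average", {
  set.seed(55)
  cfg <- synthetic_config()
  ties <- t(replicate(200, {
    tr <- generate_trial(cfg)
    c(tie_fraction(code_trial(tr, 0.6)), tie_fraction(code_trial(tr, 0.8)))
  }))
  expect_gt(mean(ties[, 2L]), mean(ties[, 1L]))
  # the default share spread keeps the 70% threshold moderately decisive
  tr <- generate_trial(synthetic_config(n_subjects = 300L), seed = 56)
  tf <- tie_fraction(code_trial(tr, 0.7))
  expect_gt(tf, 0.3)
  expect_lt(tf, 0.5)
})

test_that("a one-unit deficit loses the majority about 73:27", {
  cfg <- synthetic_config(abilities = c(A0 = 0, A48 = 0, B0 = 0, B48 = -1),
                          n_subjects = 500L)
  tr <- generate_trial(cfg, seed = 9)
  out <- code_trial(tr, 0.5)
  vs0 <- out[xor(out$item_a == "B48", out$item_b == "B48"), ]
  b48_win <- ifelse(vs0$item_a == "B48", vs0$outcome == "win_a",
                    vs0$outcome == "win_b")
  expect_equal(mean(b48_win), plogis(-1), tolerance = 0.05)
})

test_that("the share mechanism is left/right symmetric", {
  cfg <- synthetic_config(items = c("hi", "lo"),
                          abilities = c(hi = 1, lo = 0),
                          n_subjects = 4000L)
  tr <- generate_trial(cfg, seed = 10)
  rec <- tr$records
  share_hi_left <- with(rec[rec$item_a == "hi", ],
                        intake_a / (intake_a + intake_b))
  share_hi_right <- with(rec[rec$item_b == "hi", ],
                         intake_b / (intake_a + intake_b))
  expect_equal(mean(share_hi_left), mean(share_hi_right), tolerance = 0.02)
  expect_equal(mean(share_hi_left > 0.5), plogis(1), tolerance = 0.03)
})

test_that("infeasible configurations are refused up front", {
  expect_error(synthetic_config(consumption_mean = 3),
               "infeasible")
  expect_error(synthetic_config(consumption_sd = 0.05),
               NA)  # validated at generation time
  expect_error(generate_trial(synthetic_config(consumption_sd = 0.05)),
               "infeasible")
})

test_that("outcome streams honor the schedule and the win probabilities", {
  pairs <- rbind(c("a", "b"), c("a", "c"))
  set.seed(12)
  out <- generate_outcome_stream(c(a = 0, b = 0, c = -1), pairs,
                                 c(500L, 2500L))
  expect_equal(nrow(out), 3000L)
  expect_equal(sum(out$item_b == "c"), 2500L)
  ab <- out[out$item_b == "b", ]
  expect_equal(mean(ab$outcome == "win_a"), 0.5, tolerance = 0.05)
  ac <- out[out$item_b == "c", ]
  expect_equal(mean(ac$outcome == "win_a"), plogis(1), tolerance = 0.03)
})
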
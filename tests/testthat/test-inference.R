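test_that("strong generating effects are recovered with the right signs", {
  p <- sim_params(n_clients = 200, messages_per_window = 0,
                  therapist_messages_per_window = 0, seed = 41)
  tab <- truth_table(generate_corpus(p))
  fit <- fit_distance_model(tab, "symptoms_on_distance")
  eff <- fit$effects
  expect_lt(eff$beta_std[eff$predictor == "within"], 0)
  expect_lt(eff$beta_std[eff$predictor == "between"], 0)
  expect_lt(eff$p_value[eff$predictor == "between"], 0.05)
  expect_true(all(eff$r2_beta >= 0 & eff$r2_beta <= 1, na.rm = TRUE))
  expect_true(all(is.finite(eff$df)))

  # distance drifts upward over treatment (gamma_time > 0 by default)
  fit2 <- fit_distance_model(tab, "time_on_distance")
  expect_gt(fit2$effects$beta_std[1], 0)
  expect_lt(fit2$effects$p_value[1], 0.01)
})

test_that("semipartial R2 is invariant to affine predictor rescaling", {
  p <- sim_params(n_clients = 50, messages_per_window = 0,
                  therapist_messages_per_window = 0, seed = 43)
  tab <- truth_table(generate_corpus(p))
  f1 <- fit_distance_model(tab, "symptoms_on_distance")
  tab2 <- tab
  tab2$mean_score <- 10 * tab$mean_score + 3
  tab2 <- suppressMessages(decompose_scores(tab2[, !names(tab2) %in%
    c("person_mean", "between", "within")]))
  f2 <- fit_distance_model(tab2, "symptoms_on_distance")
  expect_equal(f2$effects$r2_beta, f1$effects$r2_beta, tolerance = 1e-4)
  expect_equal(f2$effects$beta_std, f1$effects$beta_std, tolerance = 1e-4)
})

test_that("zero-variance predictors are flagged degenerate, not NaN", {
  tab <- data.frame(client_id = rep(sprintf("c%d", 1:10), each = 3),
                    time = rep(1:3, 10),
                    internalizing = rpois(30, 15),
                    mean_score = 0.5)
  tab <- suppressMessages(decompose_scores(tab))
  fit <- fit_distance_model(tab, "symptoms_on_distance")
  expect_true(any(grepl("degenerate", fit$flags)))
  eff <- fit$effects
  expect_true(all(is.na(eff$beta_std[eff$predictor %in%
                                       c("within", "between")])))
})

test_that("identical methods give all-zero bootstrap deltas", {
  p <- sim_params(n_clients = 15, messages_per_window = 0,
                  therapist_messages_per_window = 0, seed = 47)
  tw <- generate_corpus(p)$truth$windows
  ta <- data.frame(client_id = tw$client_id, window = tw$window,
                   time = tw$time, internalizing = tw$internalizing,
                   mean_score = tw$d_raw)
  bc <- paired_bootstrap_compare(ta, ta, model = "symptoms_on_distance",
                                 focal = "within", B = 10, seed = 3)
  expect_true(all(abs(bc$deltas) < 1e-10))
  expect_equal(bc$ci, c(0, 0), tolerance = 1e-10)
  expect_false(bc$significant)
  expect_false(bc$unreliable)
})

test_that("the bootstrap is exactly reproducible under a fixed seed", {
  p <- sim_params(n_clients = 15, messages_per_window = 0,
                  therapist_messages_per_window = 0, seed = 53)
  tw <- generate_corpus(p)$truth$windows
  set.seed(99)
  ta <- data.frame(client_id = tw$client_id, window = tw$window,
                   time = tw$time, internalizing = tw$internalizing,
                   mean_score = tw$d_raw + rnorm(nrow(tw), 0, 0.05),
                   therapist_id = rep_len(c("t1", "t2", "t3"), nrow(tw)))
  tb <- ta; tb$mean_score <- tw$d_raw + rnorm(nrow(tw), 0, 0.05)
  b1 <- paired_bootstrap_compare(ta, tb, focal = "within", B = 8, seed = 11)
  b2 <- paired_bootstrap_compare(ta, tb, focal = "within", B = 8, seed = 11)
  expect_identical(b1$deltas, b2$deltas)
  b3 <- paired_bootstrap_compare(ta, tb, focal = "within", B = 8, seed = 12)
  expect_false(identical(b3$deltas, b1$deltas))

  # therapist-unit resampling runs through the same machinery
  b4 <- paired_bootstrap_compare(ta, tb, focal = "within", B = 4,
                                 unit = "therapist", seed = 5)
  expect_length(b4$deltas, 4)
})

test_that("input checks reject mismatched tables and bad focal predictors", {
  tab <- data.frame(client_id = c("a", "a", "b", "b"), time = c(1, 2, 1, 2),
                    internalizing = c(10, 9, 12, 11),
                    mean_score = c(0.4, 0.5, 0.3, 0.6))
  tab <- suppressMessages(decompose_scores(tab))
  other <- tab; other$client_id <- paste0("x", other$client_id)
  expect_error(paired_bootstrap_compare(tab, other, focal = "within",
                                        B = 2, seed = 1), "same clients")
  expect_error(paired_bootstrap_compare(tab, tab, focal = "nope",
                                        B = 2, seed = 1), "focal")
  expect_error(fit_distance_model(tab[1:2, ], "symptoms_on_distance"),
               ">= 2")
})
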
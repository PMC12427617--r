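test_that("identical seeds give identical corpora", {
  p <- sim_params(n_clients = 12, seed = 33)
  s1 <- generate_corpus(p)
  s2 <- generate_corpus(p)
  expect_identical(s1$corpus$messages, s2$corpus$messages)
  expect_identical(s1$corpus$assessments, s2$corpus$assessments)
  expect_identical(s1$truth$windows, s2$truth$windows)
  s3 <- generate_corpus(sim_params(n_clients = 12, seed = 34))
  expect_false(identical(s1$corpus$messages$text, s3$corpus$messages$text))
})

test_that("zero occasion variance and zero trend give constant latents", {
  p <- sim_params(n_clients = 8, sigma_within = 0, gamma_time = 0,
                  messages_per_window = 2, seed = 2)
  sim <- generate_corpus(p)
  per_client_range <- tapply(sim$truth$windows$d_raw,
                             sim$truth$windows$client_id,
                             function(x) diff(range(x)))
  expect_true(all(per_client_range == 0))
})

test_that("infeasible parameters are rejected", {
  expect_error(sim_params(n_clients = 0), "n_clients")
  expect_error(sim_params(assessments_per_client = 2), "inclusion")
  expect_error(sim_params(sigma_within = -1), "non-negative")
  expect_error(sim_params(p_no_verbs = 0.9, p_no_pronouns = 0.3), "fractions")
})

test_that("OLS on the true components recovers the generating coefficients", {
  # independent oracle: ordinary least squares on the generated table using
  # the true within/between decomposition
  p <- sim_params(n_clients = 500, messages_per_window = 0,
                  therapist_messages_per_window = 0,
                  beta_within = -0.4, beta_between = -0.8,
                  sigma_symptom = 0.5, sigma_subject = 0.5, seed = 91)
  sim <- generate_corpus(p)
  tw <- sim$truth$windows
  tw$d_i <- sim$truth$clients$d_i[match(tw$client_id,
                                        sim$truth$clients$client_id)]
  fit <- lm(internalizing ~ I(d_raw - d_i) + I(d_i - p$mu_d) + time,
            data = tw)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(est[2] - p$beta_within), 4 * se[2] + 0.05)
  expect_lt(abs(est[3] - p$beta_between), 4 * se[3] + 0.05)
})

test_that("template mixtures have the right mean and fragment rates", {
  set.seed(7)
  n <- 10000
  texts <- vapply(seq_len(n),
                  function(i) generate_message_text(0.5, sentences = 4,
                                                    p_no_verbs = 0.071,
                                                    p_no_pronouns = 0.094),
                  character(1))
  vals <- vapply(texts, wc_self_distance, numeric(1), USE.NAMES = FALSE)

  # law of large numbers on the template mixture
  expect_lt(abs(mean(vals, na.rm = TRUE) - 0.5), 0.02)

  # undefined fractions track the fragment probabilities (binomial 4-sigma)
  counts <- lapply(texts, tag_tokens)
  no_verb <- vapply(counts, function(ct)
    ct[["past"]] + ct[["present"]] + ct[["future"]] == 0, logical(1))
  no_pron_raw <- vapply(counts, function(ct)
    sum(ct[c("pron_first_singular", "pron_first_plural", "pron_second",
             "pron_third_singular", "pron_third_plural")]) == 0,
    logical(1))
  no_pron <- no_pron_raw & !no_verb
  tol <- function(p) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(no_verb) - 0.071), tol(0.071))
  expect_lt(abs(mean(no_pron) - 0.094), tol(0.094))
})

test_that("analytic effects follow the mediation identity", {
  p <- sim_params(gamma_time = 0.5, beta_within = -0.4, c_prime = -0.1)
  eff <- theoretical_effects(p)
  expect_equal(eff$proportion_mediated, 100 * (-0.2) / (-0.3))
  expect_equal(eff$proportion_mediated, 66.7, tolerance = 1e-3)

  eff <- theoretical_effects(sim_params(gamma_time = 0.5,
                                        beta_within = -0.4, c_prime = 0))
  expect_equal(eff$proportion_mediated, 100)

  eff <- theoretical_effects(sim_params(gamma_time = 0.5, beta_within = 0,
                                        c_prime = -0.1))
  expect_equal(eff$proportion_mediated, 0)

  eff <- theoretical_effects(sim_params(gamma_time = 0.5, beta_within = -0.4,
                                        c_prime = 0.2))
  expect_false(eff$defined)
  expect_true(is.na(eff$proportion_mediated))
})

test_that("generated corpora pass corpus validation invariants", {
  sim <- generate_corpus(sim_params(n_clients = 10, seed = 5))
  corp <- sim$corpus
  expect_equal(attr(corp, "n_excluded"), 0)
  expect_true(all(corp$assessments$days_in_treatment >= 0))
  expect_true(all(corp$assessments$internalizing >= 0 &
                    corp$assessments$internalizing <= 45))
  expect_setequal(unique(corp$messages$client_id), corp$dyads$client_id)
  # every message latent refers to a real message
  expect_true(all(sim$truth$message_latents$message_id %in%
                    corp$messages$message_id))
})
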
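# Small corpora built in code for unit tests.

# Two clients, one therapist each, three assessments spanning >= 42 days,
# a handful of messages per window.
make_fixture_tables <- function() {
  d0 <- as.Date("2018-03-01")
  messages <- data.frame(
    message_id = sprintf("m%03d", 1:10),
    client_id = rep(c("cA", "cB"), each = 5),
    therapist_id = rep(c("t1", "t2"), each = 5),
    author_role = rep(c("client", "client", "therapist", "client", "client"), 2),
    timestamp = format(d0 + c(0, 10, 15, 30, 50, 2, 12, 20, 35, 55), "%Y-%m-%d"),
    text = c("I am here.", "We slept well.", "You could step back.",
             "I played a game.", "They walked the dog.",
             "I feel fine.", "She visited the garden.", "Try to rest.",
             "We cooked a meal.", "I watched a story."),
    stringsAsFactors = FALSE
  )
  assessments <- data.frame(
    client_id = rep(c("cA", "cB"), each = 3),
    date = format(d0 + c(21, 42, 63, 23, 44, 65), "%Y-%m-%d"),
    phq8 = c(10, 8, 6, 15, 14, 12),
    gad7 = c(8, 7, 5, 12, 11, 10),
    stringsAsFactors = FALSE
  )
  list(messages = messages, assessments = assessments)
}

make_fixture_corpus <- function() {
  tabs <- make_fixture_tables()
  corpus(tabs$messages, tabs$assessments, quiet = TRUE)
}

# windowed table built straight from the generator's latent truth, i.e. a
# perfectly measured distance score (used by estimator-level tests)
truth_table <- function(sim) {
  tw <- sim$truth$windows
  tab <- data.frame(client_id = tw$client_id, window = tw$window,
                    days_in_treatment = tw$day, time = tw$time,
                    internalizing = tw$internalizing,
                    mean_score = tw$d_raw,
                    stringsAsFactors = FALSE)
  suppressMessages(decompose_scores(tab))
}
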
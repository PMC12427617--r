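test_that("a two-client fixture round-trips through write and read", {
  corp <- make_fixture_corpus()
  expect_s3_class(corp, "ld_corpus")
  expect_equal(nrow(corp$dyads), 2)
  expect_equal(sort(corp$dyads$therapist_id), c("t1", "t2"))

  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  corp2 <- read_corpus(file.path(dir, "messages.csv"),
                       file.path(dir, "assessments.csv"), quiet = TRUE)
  expect_equal(corp2$messages, corp$messages)
  expect_equal(corp2$assessments, corp$assessments)
  expect_equal(corp2$dyads, corp$dyads)
})

test_that("JSON-lines message files load like CSV ones", {
  tabs <- make_fixture_tables()
  dir <- withr::local_tempdir()
  mpath <- file.path(dir, "messages.jsonl")
  writeLines(vapply(seq_len(nrow(tabs$messages)), function(i)
    jsonlite::toJSON(as.list(tabs$messages[i, ]), auto_unbox = TRUE),
    character(1)), mpath)
  apath <- file.path(dir, "assessments.csv")
  write.csv(tabs$assessments, apath, row.names = FALSE)
  corp <- read_corpus(mpath, apath, quiet = TRUE)
  expect_equal(corp, corpus(tabs$messages, tabs$assessments, quiet = TRUE))
})

test_that("internalizing is recomputed as phq8 + gad7 on read", {
  corp <- make_fixture_corpus()
  expect_equal(corp$assessments$internalizing,
               corp$assessments$phq8 + corp$assessments$gad7)
})

test_that("clients below the assessment/span threshold are excluded", {
  tabs <- make_fixture_tables()
  # cB loses one assessment -> only 2 left -> excluded
  tabs$assessments <- tabs$assessments[-6, ]
  expect_message(corp <- corpus(tabs$messages, tabs$assessments),
                 "excluded")
  expect_equal(attr(corp, "n_excluded"), 1)
  expect_equal(unique(corp$assessments$client_id), "cA")
  expect_false("cB" %in% corp$messages$client_id)

  # three assessments but spanning less than six weeks -> also excluded
  tabs2 <- make_fixture_tables()
  tabs2$assessments$date[4:6] <-
    format(as.Date("2018-03-01") + c(10, 20, 30), "%Y-%m-%d")
  corp2 <- corpus(tabs2$messages, tabs2$assessments, quiet = TRUE)
  expect_equal(attr(corp2, "excluded_clients"), "cB")

  # the inclusion filter is idempotent: re-validating a kept corpus
  # excludes nobody
  corp3 <- corpus(corp$messages, corp$assessments[, 1:4], quiet = TRUE)
  expect_equal(attr(corp3, "n_excluded"), 0)
})

test_that("validation rejects malformed inputs", {
  tabs <- make_fixture_tables()
  bad <- tabs$assessments; bad$phq8[1] <- 25
  expect_error(corpus(tabs$messages, bad), "phq8")
  bad <- tabs$assessments; bad$gad7[2] <- -1
  expect_error(corpus(tabs$messages, bad), "gad7")
  bad <- tabs$assessments; bad$date[1] <- "not-a-date"
  expect_error(corpus(tabs$messages, bad), "unparsable date")
  bad <- tabs$assessments[, -2]
  expect_error(corpus(tabs$messages, bad), "missing column")
  bad <- tabs$messages; bad$author_role[1] <- "observer"
  expect_error(corpus(bad, tabs$assessments), "author_role")
})

test_that("the primary therapist has the most messages, ties by first date", {
  d0 <- as.Date("2018-01-01")
  msgs <- data.frame(
    message_id = sprintf("m%02d", 1:5),
    client_id = "cA",
    therapist_id = c("t2", "t1", "t1", "t2", "t2"),
    author_role = "client",
    timestamp = d0 + c(0, 1, 2, 3, 4),
    text = "I am here.",
    stringsAsFactors = FALSE)
  ass <- data.frame(client_id = "cA", date = d0 + c(21, 42, 63),
                    phq8 = 5, gad7 = 5)
  corp <- corpus(msgs, ass, quiet = TRUE)
  expect_equal(corp$dyads$therapist_id, "t2")   # 3 vs 2 messages

  msgs$therapist_id <- c("t2", "t1", "t1", "t2", "t1")  # 3 vs 2 now t1
  corp <- corpus(msgs, ass, quiet = TRUE)
  expect_equal(corp$dyads$therapist_id, "t1")

  msgs$therapist_id <- c("t2", "t1", "t1", "t2", "t2")[c(2, 1, 3, 4, 5)]
  msgs$therapist_id <- c("t1", "t2", "t1", "t2", "x")   # 2-2 tie, t1 earlier
  corp <- corpus(msgs, ass, quiet = TRUE)
  expect_equal(corp$dyads$therapist_id, "t1")
})

test_that("score tables round-trip and enforce referential integrity", {
  corp <- make_fixture_corpus()
  path <- withr::local_tempfile(fileext = ".csv")

  # empty score set -> header-only file
  empty <- data.frame(message_id = character(0), method = character(0),
                      value = numeric(0), defined = logical(0))
  write_scores(corp, empty, path)
  expect_equal(nrow(read_scores(path)), 0)

  scores <- score_wordcount(corp$messages)
  write_scores(corp, scores, path)
  back <- read_scores(path)
  expect_equal(back$value, scores$value)
  expect_equal(back$defined, scores$defined)
  expect_equal(back$message_id, scores$message_id)

  dangling <- scores; dangling$message_id[1] <- "nope"
  expect_error(write_scores(corp, dangling, path), "unknown message_id")
})

test_that("config files override defaults section-wise", {
  cfg <- read_config(NULL)
  expect_equal(cfg$bootstrap$B, 2000L)
  expect_equal(cfg$mcmc$iterations, 12500L)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "bootstrap:", "  B: 50"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$bootstrap$B, 50)
  expect_equal(cfg2$bootstrap$unit, "client")
  expect_equal(cfg2$mcmc$chains, 2L)
})
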
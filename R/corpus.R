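## Corpus data model and file I/O.
##
## A corpus bundles three tables:
##   messages    - message_id, client_id, therapist_id, author_role,
##                 timestamp (Date), text
##   assessments - client_id, date (Date), phq8, gad7, internalizing,
##                 days_in_treatment
##   dyads       - client_id, therapist_id, first_message_date
## Clients enter analyses only if they completed at least three symptom
## assessments spanning at least six weeks (42 days).

MIN_ASSESSMENTS <- 3L
MIN_SPAN_DAYS <- 42L

#' Construct and validate a corpus
#'
#' Derives dyads (the primary therapist is the one with the most messages to
#' the client; ties broken by earliest first message), computes
#' `days_in_treatment` as days since the first message with the primary
#' therapist, recomputes the internalizing sum, and applies the inclusion
#' rule (>= 3 assessments spanning >= 42 days).  Excluded clients are
#' reported via a message and recorded in `attr(x, "n_excluded")`.
#'
#' @param messages Data frame with columns `message_id`, `client_id`,
#'   `therapist_id`, `author_role` (`"client"`/`"therapist"`), `timestamp`
#'   (`Date` or ISO-8601 string), `text`.
#' @param assessments Data frame with columns `client_id`, `date`, `phq8`
#'   (0-24), `gad7` (0-21).
#' @param quiet Suppress the exclusion message.
#' @return An object of class `ld_corpus`: list with elements `messages`,
#'   `assessments`, `dyads`.
#' @export
corpus <- function(messages, assessments, quiet = FALSE) {
  req_m <- c("message_id", "client_id", "therapist_id", "author_role",
             "timestamp", "text")
  req_a <- c("client_id", "date", "phq8", "gad7")
  miss <- setdiff(req_m, names(messages))
  if (length(miss))
    stop("messages table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_a, names(assessments))
  if (length(miss))
    stop("assessments table is missing column(s): ",
         paste(miss, collapse = ", "))

  messages$timestamp <- .parse_dates(messages$timestamp, "messages")
  assessments$date <- .parse_dates(assessments$date, "assessments")
  messages$text[is.na(messages$text)] <- ""
  messages$author_role <- as.character(messages$author_role)
  bad_role <- !messages$author_role %in% c("client", "therapist")
  if (any(bad_role))
    stop("invalid author_role value(s): ",
         paste(unique(messages$author_role[bad_role]), collapse = ", "))

  .check_range(assessments$phq8, 0, 24, "phq8")
  .check_range(assessments$gad7, 0, 21, "gad7")
  assessments$internalizing <- as.integer(assessments$phq8 + assessments$gad7)

  dyads <- .derive_dyads(messages)

  no_dyad <- setdiff(unique(assessments$client_id), dyads$client_id)
  if (length(no_dyad))
    stop("assessments reference client(s) with no messages: ",
         paste(head(no_dyad, 5), collapse = ", "))

  assessments$days_in_treatment <- as.integer(
    assessments$date -
      dyads$first_message_date[match(assessments$client_id, dyads$client_id)])
  if (any(assessments$days_in_treatment < 0))
    stop("assessment dated before the dyad's first message")

  # inclusion rule
  ord <- order(assessments$client_id, assessments$date)
  assessments <- assessments[ord, , drop = FALSE]
  keep <- vapply(split(assessments$date, assessments$client_id), function(d) {
    length(d) >= MIN_ASSESSMENTS &&
      as.integer(max(d) - min(d)) >= MIN_SPAN_DAYS
  }, logical(1))
  excluded <- names(keep)[!keep]
  if (length(excluded) && !quiet)
    message(length(excluded),
            " client(s) excluded (need >= 3 assessments spanning >= 42 days)")
  assessments <- assessments[!assessments$client_id %in% excluded, ,
                             drop = FALSE]
  messages <- messages[!messages$client_id %in% excluded, , drop = FALSE]
  dyads <- dyads[!dyads$client_id %in% excluded, , drop = FALSE]
  rownames(messages) <- rownames(assessments) <- rownames(dyads) <- NULL

  out <- structure(list(messages = messages, assessments = assessments,
                        dyads = dyads),
                   class = "ld_corpus")
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_clients") <- excluded
  out
}

#' @noRd
.parse_dates <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("unparsable date in ", what, " at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD)")
  }
  d
}

#' @noRd
.check_range <- function(x, lo, hi, name) {
  if (anyNA(x) || any(x < lo | x > hi | x != round(x)))
    stop(name, " must be an integer in [", lo, ", ", hi, "]")
  invisible(NULL)
}

#' @noRd
.derive_dyads <- function(messages) {
  sp <- split(messages, messages$client_id)
  rows <- lapply(sp, function(m) {
    counts <- table(m$therapist_id)
    first_dates <- vapply(split(m$timestamp, m$therapist_id),
                          function(d) as.numeric(min(d)), numeric(1))
    cand <- names(counts)[counts == max(counts)]
    primary <- cand[which.min(first_dates[cand])]
    data.frame(client_id = m$client_id[1],
               therapist_id = primary,
               first_message_date = min(m$timestamp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ld_corpus <- function(x, ...) {
  cat("Therapy-message corpus\n")
  cat("  clients:     ", nrow(x$dyads), "\n")
  cat("  messages:    ", nrow(x$messages),
      sprintf(" (%d client / %d therapist)\n",
              sum(x$messages$author_role == "client"),
              sum(x$messages$author_role == "therapist")))
  cat("  assessments: ", nrow(x$assessments), "\n")
  if (length(attr(x, "excluded_clients")))
    cat("  excluded at read:", attr(x, "n_excluded"), "client(s)\n")
  invisible(x)
}

#' Read a corpus from delimited files
#'
#' @param messages_path CSV or JSON-lines (`.jsonl`/`.ndjson`) file with
#'   columns `message_id`, `client_id`, `therapist_id`, `author_role`,
#'   `timestamp`, `text`.
#' @param assessments_path CSV file with columns `client_id`, `date`, `phq8`,
#'   `gad7`.
#' @param quiet Suppress the exclusion message.
#' @return A validated [corpus()] object.
#' @export
read_corpus <- function(messages_path, assessments_path, quiet = FALSE) {
  stopifnot(file.exists(messages_path), file.exists(assessments_path))
  if (grepl("\\.(jsonl|ndjson)$", messages_path, ignore.case = TRUE)) {
    lines <- readLines(messages_path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    messages <- do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else {
    messages <- read.csv(messages_path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  }
  assessments <- read.csv(assessments_path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  corpus(messages, assessments, quiet = quiet)
}

#' Write a corpus to a directory
#'
#' Writes `messages.csv` and `assessments.csv` (dyads and days in treatment
#' are re-derived on read).
#'
#' @param x An `ld_corpus`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(x, dir) {
  stopifnot(inherits(x, "ld_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- x$messages
  m$timestamp <- format(m$timestamp, "%Y-%m-%d")
  write.csv(m, file.path(dir, "messages.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  a <- x$assessments[, c("client_id", "date", "phq8", "gad7")]
  a$date <- format(a$date, "%Y-%m-%d")
  write.csv(a, file.path(dir, "assessments.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(dir)
}

#' Write a message-score table
#'
#' One row per (message_id, method) with `value` and `defined`; every score
#' must reference a message in the corpus.
#'
#' @param corpus An `ld_corpus`.
#' @param scores Score table as produced by [score_wordcount()] or
#'   [score_messages()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(corpus, scores, path) {
  stopifnot(inherits(corpus, "ld_corpus"), is.data.frame(scores))
  dangling <- setdiff(scores$message_id, corpus$messages$message_id)
  if (length(dangling))
    stop("score(s) reference unknown message_id: ",
         paste(head(dangling, 5), collapse = ", "))
  out <- scores[, c("message_id", "method", "value", "defined")]
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a message-score table written by [write_scores()]
#'
#' @param path CSV path.
#' @return Score data frame (`message_id`, `method`, `value`, `defined`).
#' @export
read_scores <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(message_id = "character",
                                 method = "character",
                                 value = "numeric", defined = "logical"))
  out
}

#' Read a pipeline configuration file
#'
#' YAML key-value file with nested sections (paths, methods, seed, bootstrap
#' `B`, MCMC settings).  Values present in the file override the defaults;
#' unknown keys are kept as given.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @return Named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    methods = c("wc_self", "llm_self"),
    bootstrap = list(B = 2000L, unit = "client"),
    mcmc = list(chains = 2L, iterations = 12500L, burn_in = 2500L)
  )
  if (is.null(path)) return(defaults)
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  .merge_lists(defaults, user)
}

#' @noRd
.merge_lists <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .merge_lists(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}
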
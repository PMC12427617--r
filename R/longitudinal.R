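## From message scores to the regression table.
##
## Window k of client i is the half-open interval (assessment date k-1,
## assessment date k]; window 1 starts at the dyad's first message date
## (inclusive).  Message scores are averaged per window without weighting by
## length; windows with no defined score are dropped from model fitting.
## Predictors are decomposed into a between-person component (person mean,
## centered on the unweighted grand mean of person means) and a
## within-person component (observation minus person mean).

#' Map messages to assessment windows
#'
#' @param corpus An `ld_corpus`.
#' @param role Map only messages by this author role.
#' @return Data frame `message_id`, `client_id`, `window`.  Messages after
#'   the last assessment are unmapped; their count is in
#'   `attr(x, "n_unmapped")`.
#' @export
assign_windows <- function(corpus, role = c("client", "therapist")) {
  stopifnot(inherits(corpus, "ld_corpus"))
  role <- match.arg(role)
  msg <- corpus$messages[corpus$messages$author_role == role, , drop = FALSE]
  ass <- corpus$assessments
  out <- vector("list", nrow(corpus$dyads))
  n_unmapped <- 0L
  for (i in seq_len(nrow(corpus$dyads))) {
    cl <- corpus$dyads$client_id[i]
    dates <- sort(ass$date[ass$client_id == cl])
    m <- msg[msg$client_id == cl, , drop = FALSE]
    if (!nrow(m)) next
    # findInterval on (prev, current]: window = count of dates < timestamp,
    # plus 1; messages on an assessment day belong to the ending window
    w <- findInterval(as.numeric(m$timestamp) - 0.5, as.numeric(dates)) + 1L
    mapped <- w <= length(dates)
    n_unmapped <- n_unmapped + sum(!mapped)
    out[[i]] <- data.frame(message_id = m$message_id[mapped],
                           client_id = cl, window = w[mapped],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  if (n_unmapped > 0)
    message(n_unmapped, " message(s) after the last assessment left unmapped")
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Per-window unweighted mean scores
#'
#' @param corpus An `ld_corpus`.
#' @param scores Score table (one method) with `message_id`, `value`,
#'   `defined`.
#' @param windows Mapping from [assign_windows()]; computed for `role` if
#'   omitted.
#' @param role Author role whose messages are averaged.
#' @param time_unit_days Days per unit of the `time` column (default 21, one
#'   assessment period).
#' @return Windowed-observation table: `client_id`, `window`,
#'   `days_in_treatment`, `time`, `internalizing`, `mean_score` (`NA` when
#'   no defined message score fell in the window), `n_messages_used`.
#' @export
window_means <- function(corpus, scores, windows = NULL,
                         role = c("client", "therapist"),
                         time_unit_days = 21) {
  stopifnot(inherits(corpus, "ld_corpus"), is.data.frame(scores))
  role <- match.arg(role)
  if (length(unique(scores$method)) > 1)
    stop("scores must contain a single method; got: ",
         paste(unique(scores$method), collapse = ", "))
  if (is.null(windows))
    windows <- suppressMessages(assign_windows(corpus, role))

  ass <- corpus$assessments
  ass <- ass[order(ass$client_id, ass$date), , drop = FALSE]
  ass$window <- ave(seq_along(ass$client_id), ass$client_id, FUN = seq_along)

  sc <- merge(windows, scores[, c("message_id", "value", "defined")],
              by = "message_id", sort = FALSE)
  sc <- sc[sc$defined & !is.na(sc$value), , drop = FALSE]
  agg <- if (nrow(sc)) {
    means <- aggregate(value ~ client_id + window, data = sc, FUN = mean)
    counts <- aggregate(cbind(n = value) ~ client_id + window, data = sc,
                        FUN = length)
    merge(means, counts, by = c("client_id", "window"))
  } else data.frame(client_id = character(0), window = integer(0),
                    value = numeric(0), n = integer(0))

  out <- merge(ass[, c("client_id", "window", "days_in_treatment",
                       "internalizing")],
               agg, by = c("client_id", "window"), all.x = TRUE)
  names(out)[names(out) == "value"] <- "mean_score"
  names(out)[names(out) == "n"] <- "n_messages_used"
  out$n_messages_used[is.na(out$n_messages_used)] <- 0L
  out$time <- out$days_in_treatment / time_unit_days
  out <- out[order(out$client_id, out$window),
             c("client_id", "window", "days_in_treatment", "time",
               "internalizing", "mean_score", "n_messages_used")]
  rownames(out) <- NULL
  n_empty <- sum(is.na(out$mean_score))
  if (n_empty > 0)
    message(n_empty,
            " window(s) without a defined message score (dropped at fit)")
  attr(out, "n_empty_windows") <- n_empty
  out
}

#' Within/between decomposition of a windowed predictor
#'
#' Adds, for `score_col`, the person mean over that client's defined
#' windows, the between-person component (person mean minus the unweighted
#' grand mean of person means) and the within-person component (observation
#' minus person mean).  Rows with an undefined score are dropped with a
#' message.
#'
#' @param observations Windowed-observation table from [window_means()] (any
#'   data frame with `client_id` and `score_col`).
#' @param score_col Column to decompose (default `"mean_score"`).
#' @return The table with columns `person_mean`, `between`, `within` added;
#'   the grand mean is in `attr(x, "grand_mean")`.
#' @export
decompose_scores <- function(observations, score_col = "mean_score") {
  stopifnot(is.data.frame(observations),
            all(c("client_id", score_col) %in% names(observations)))
  x <- observations
  drop <- is.na(x[[score_col]])
  if (any(drop)) {
    message(sum(drop), " undefined observation(s) dropped before decomposition")
    x <- x[!drop, , drop = FALSE]
  }
  pm <- ave(x[[score_col]], x$client_id, FUN = mean)
  grand <- mean(tapply(x[[score_col]], x$client_id, mean))
  x$person_mean <- pm
  x$between <- pm - grand
  x$within <- x[[score_col]] - pm
  rownames(x) <- NULL
  attr(x, "grand_mean") <- grand
  x
}

#' Build the regression table for one score method
#'
#' Chains [assign_windows()], [window_means()] and [decompose_scores()].
#'
#' @param corpus An `ld_corpus`.
#' @param scores Score table for one method.
#' @param role Author role whose messages are averaged (clustering stays at
#'   the client level either way).
#' @param time_unit_days Passed to [window_means()].
#' @return Decomposed windowed-observation table.
#' @export
build_regression_table <- function(corpus, scores,
                                   role = c("client", "therapist"),
                                   time_unit_days = 21) {
  role <- match.arg(role)
  w <- suppressMessages(assign_windows(corpus, role))
  obs <- suppressMessages(window_means(corpus, scores, windows = w,
                                       role = role,
                                       time_unit_days = time_unit_days))
  out <- suppressMessages(decompose_scores(obs))
  # therapist identity carried for bootstrap resampling at the dyad level
  out$therapist_id <- corpus$dyads$therapist_id[
    match(out$client_id, corpus$dyads$client_id)]
  out
}
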
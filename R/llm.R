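## Prompted-LLM construct scoring.
##
## A scoring backend maps a full prompt string to five unnormalized
## next-token scores (logits), one per ordered label A-E.  The message score
## is the softmax-weighted expectation of 1-5 over those five labels only;
## the model's distribution is read out, never sampled.  The packaged mock
## backend reads a synthetic message's hidden latent and emits logits peaked
## at the matching label, enabling full-path tests without model weights.

#' Load a prompt template
#'
#' Templates ship as plain-text files with a `{{MESSAGE}}` placeholder; the
#' instruction text precedes the message.  The self-distance construct
#' applies to client and therapist text, other-distance (encouragement of
#' distancing) to therapist text only.
#'
#' @param construct `"self_distance"` or `"other_distance"`.
#' @param path Optional path to a custom template file.
#' @return Object of class `prompt_template`: list with `construct`,
#'   `instruction` (the template text) and `labels` (`A`-`E`).
#' @export
prompt_template <- function(construct = c("self_distance", "other_distance"),
                            path = NULL) {
  construct <- match.arg(construct)
  if (is.null(path))
    path <- system.file("prompts", paste0(construct, ".txt"),
                        package = "lingdist", mustWork = TRUE)
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  if (!grepl("{{MESSAGE}}", txt, fixed = TRUE))
    stop("template lacks the {{MESSAGE}} placeholder")
  structure(list(construct = construct, instruction = txt,
                 labels = LETTERS[1:5]),
            class = "prompt_template")
}

#' Build the full prompt for one message
#'
#' The message payload is truncated after `max_tokens` tokens (whitespace
#' tokenization here; a real model adapter substitutes its own tokenizer
#' behind the same contract) and substituted into the template.
#'
#' @param template A [prompt_template()].
#' @param message_text Message string.
#' @param author_role Optional role of the author; rating a client-authored
#'   message for other-distance triggers a warning (the construct is defined
#'   for therapist messages).
#' @param max_tokens Truncation limit (default 1000).
#' @return The prompt string.
#' @export
build_prompt <- function(template, message_text, author_role = NULL,
                         max_tokens = 1000L) {
  stopifnot(inherits(template, "prompt_template"))
  if (!is.null(author_role) && template$construct == "other_distance" &&
      identical(author_role, "client"))
    warning("other-distance is defined for therapist messages; ",
            "scoring a client-authored message")
  toks <- strsplit(trimws(message_text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  payload <- paste(toks, collapse = " ")
  sub("{{MESSAGE}}", payload, template$instruction, fixed = TRUE)
}

#' Expected score from five label logits
#'
#' Softmax restricted to the five label logits (max-subtraction stabilized),
#' then the probability-weighted mean of 1-5.
#'
#' @param logits Numeric vector of five finite logits (A-E order).
#' @return A number in `[1, 5]`.
#' @export
#' @examples
#' expected_score(c(0, 0, 0, 0, 0))        # 3
#' expected_score(log(c(1, 2, 3, 2, 1)))   # 3
expected_score <- function(logits) {
  if (length(logits) != 5L || !all(is.finite(logits)))
    stop("logits must be five finite numbers")
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  sum(seq_len(5L) * p)
}

#' Mock scoring backend driven by synthetic ground truth
#'
#' Returns a backend whose logits for message `m` with hidden latent
#' `l` (on `[0, 1]`) are `-sharpness * (i - (1 + 4 l))^2` for labels
#' `i = 1..5`: peaked at the label bin containing the latent, symmetric,
#' deterministic.  `sharpness = 0` yields uniform logits (score 3 for all).
#'
#' @param truth The `truth` element of [generate_corpus()] output (or any
#'   list with a `message_latents` data frame).
#' @param sharpness Non-negative peaking parameter.
#' @return Object of class `scoring_backend`: function
#'   `(prompt, message_id) -> numeric[5]`.
#' @export
mock_backend <- function(truth, sharpness = 2) {
  stopifnot(is.list(truth), is.data.frame(truth$message_latents),
            sharpness >= 0)
  lat <- setNames(truth$message_latents$latent,
                  truth$message_latents$message_id)
  f <- function(prompt, message_id) {
    if (!message_id %in% names(lat))
      stop("message not in ground truth: ", message_id)
    l <- lat[[message_id]]
    -sharpness * (seq_len(5L) - (1 + 4 * l))^2
  }
  structure(f, class = c("scoring_backend", "function"),
            backend_name = "mock")
}

#' Score a message table with a prompted-model backend
#'
#' One score per message; a backend failure on a message yields an undefined
#' score and a warning, and the run continues.  Scores depend only on the
#' message itself (batch order is irrelevant).
#'
#' @param backend A `scoring_backend`.
#' @param template A [prompt_template()].
#' @param messages Data frame with `message_id`, `text` and optionally
#'   `author_role`.
#' @param max_tokens Truncation limit passed to [build_prompt()].
#' @return Score table: `message_id`, `method` (`"llm_self"` or
#'   `"llm_other"`), `value` (`[1, 5]` or `NA`), `defined`.
#' @export
score_messages <- function(backend, template, messages, max_tokens = 1000L) {
  stopifnot(inherits(backend, "scoring_backend"),
            inherits(template, "prompt_template"),
            is.data.frame(messages),
            all(c("message_id", "text") %in% names(messages)))
  method <- switch(template$construct,
                   self_distance = "llm_self",
                   other_distance = "llm_other")
  if (template$construct == "other_distance" &&
      "author_role" %in% names(messages) &&
      any(messages$author_role == "client"))
    warning("other-distance scores requested for client-authored messages")
  n <- nrow(messages)
  vals <- rep(NA_real_, n)
  n_failed <- 0L
  for (j in seq_len(n)) {
    prompt <- build_prompt(template, messages$text[j],
                           max_tokens = max_tokens)
    res <- tryCatch(
      expected_score(backend(prompt, messages$message_id[j])),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed <= 3L)
        warning("backend failed on ", messages$message_id[j], ": ",
                conditionMessage(res))
    } else vals[j] <- res
  }
  if (n_failed > 3L)
    warning(n_failed, " messages failed in total; scores left undefined")
  data.frame(message_id = messages$message_id, method = method,
             value = vals, defined = !is.na(vals),
             stringsAsFactors = FALSE)
}
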
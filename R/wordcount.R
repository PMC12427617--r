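## Word-count composite of linguistic distancing.
##
## Two sub-measures per message:
##   temporal distance = (past + future) / (past + future + present)
##   social distance   = non-first-singular personal pronouns / personal pronouns
## The composite is their unweighted mean on [0, 1]; either sub-measure is
## undefined when its denominator is zero, and the composite is undefined if
## either part is.  A display helper multiplies by 10 (0-10 scale).

# ---- lexicons ---------------------------------------------------------------

#' @noRd
.pronoun_table <- function() {
  list(
    pron_first_singular = c("i", "me", "my", "mine", "myself"),
    pron_first_plural   = c("we", "us", "our", "ours", "ourselves"),
    pron_second         = c("you", "your", "yours", "yourself", "yourselves"),
    pron_third_singular = c("he", "she", "him", "her", "his", "hers",
                            "himself", "herself"),
    pron_third_plural   = c("they", "them", "their", "theirs", "themselves"),
    # impersonal forms are tallied but excluded from the social-distance
    # denominator (personal pronouns only)
    pron_impersonal     = c("it", "its", "itself", "this", "that",
                            "these", "those", "one")
  )
}

# verbs whose base/-s forms are recognized as present tense; regular verbs
# also supply -ed past forms via the suffix rule
.base_verbs <- c(
  "accept", "afford", "agree", "answer", "appreciate", "ask", "avoid",
  "be", "believe", "belong", "breathe", "call", "care", "change", "clean",
  "climb", "close", "cook", "cope", "count", "cry", "dance", "decide",
  "deserve", "discuss", "dream", "eat", "end", "enjoy", "expect", "explain",
  "face", "feel", "finish", "focus", "follow", "forget", "forgive", "get",
  "give", "go", "grow", "guess", "happen", "hate", "have", "hear", "help",
  "hope", "hurt", "imagine", "jump", "keep", "know", "laugh", "learn",
  "leave", "like", "listen", "live", "look", "love", "make", "manage",
  "matter", "mean", "meet", "mind", "miss", "move", "need", "notice",
  "open", "paint", "panic", "pause", "plan", "play", "practice", "prefer",
  "promise", "read", "realize", "relax", "remember", "rest", "return",
  "run", "say", "see", "seem", "share", "sit", "sleep", "smile", "speak",
  "spend", "start", "stay", "stop", "struggle", "study", "suppose", "take",
  "talk", "tell", "think", "travel", "trust", "try", "turn", "understand",
  "visit", "wait", "wake", "walk", "want", "watch", "wish", "wonder",
  "work", "worry", "write"
)

# irregular simple-past forms (the -ed suffix rule covers regular verbs)
.irregular_past <- c(
  "ate", "became", "began", "bought", "broke", "brought", "built", "came",
  "caught", "chose", "did", "drank", "drew", "drove", "fell", "felt",
  "flew", "forgave", "forgot", "found", "gave", "got", "grew", "had",
  "heard", "held", "hid", "kept", "knew", "left", "lost", "made", "meant",
  "met", "paid", "ran", "rode", "rose", "said", "sang", "sat", "saw",
  "sent", "shook", "slept", "sold", "spent", "spoke", "stood", "swam",
  "taught", "thought", "threw", "told", "took", "understood", "was",
  "went", "were", "woke", "won", "wore", "wrote"
)

# -ed forms that function as adjectives (state descriptions), not finite
# past-tense verbs; excluded from tense counts
.participial_adjectives <- c(
  "annoyed", "ashamed", "bored", "burned", "complicated", "concerned",
  "confused", "connected", "depressed", "detached", "disappointed",
  "disconnected", "distracted", "drained", "embarrassed", "excited",
  "exhausted", "frustrated", "interested", "isolated", "motivated",
  "overwhelmed", "panicked", "puzzled", "relieved", "scared", "stressed",
  "surprised", "tired", "worried"
)

.be_forms <- c("am", "is", "are", "was", "were", "be", "been", "being",
               "'s", "'re", "'m")
.modals_nonfuture <- c("would", "could", "should", "may", "might", "must",
                       "can", "'d")
# a base verb after any of these is not counted itself (the marker carries
# the tense, or the form is non-finite)
.verb_skippers <- c(.modals_nonfuture, "will", "shall", "'ll", "to")

#' @noRd
.build_lexicons <- function() {
  third_s <- function(v) {
    ifelse(grepl("(s|sh|ch|x|z|o)$", v), paste0(v, "es"),
           ifelse(grepl("[^aeiou]y$", v), sub("y$", "ies", v),
                  paste0(v, "s")))
  }
  present <- setdiff(unique(c(.base_verbs, third_s(.base_verbs))), "be")
  .lexicons$pronouns <- .pronoun_table()
  .lexicons$pronoun_lookup <- {
    tab <- .pronoun_table()
    setNames(rep(names(tab), lengths(tab)), unlist(tab))
  }
  .lexicons$present_verbs <- present
  .lexicons$irregular_past <- .irregular_past
  .lexicons$participial_adjectives <- .participial_adjectives
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) .build_lexicons()

#' @noRd
.lex <- function() {
  if (is.null(.lexicons$present_verbs)) .build_lexicons()
  .lexicons
}

# ---- tokenization -----------------------------------------------------------

#' Tokenize a message for dictionary scoring
#'
#' Lowercases, normalizes curly apostrophes, splits on non-alphanumeric
#' characters (keeping internal apostrophes), and detaches clitic endings
#' (`'s`, `'re`, `'m`, `'ve`, `'ll`, `'d`, `n't`) as separate tokens so the
#' tense rules can treat them as auxiliaries.  The redaction marker `[-]`
#' carries no alphanumeric content and therefore yields no token.
#'
#' @param text A character string (may be empty).
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize_message("It’s fine, we’ll see.")
tokenize_message <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- chartr("’‘", "''", tolower(text))
  toks <- regmatches(x, gregexpr("[a-z0-9]+(?:'[a-z]+)*", x))[[1]]
  if (!length(toks)) return(character(0))
  out <- character(0)
  for (t in toks) {
    if (grepl("n't$", t) && nchar(t) > 3L) {
      base <- sub("n't$", "", t)
      base <- switch(base, wo = "will", ca = "can", sha = "shall", base)
      out <- c(out, base, "not")
    } else if (grepl("'(s|re|m|ve|ll|d)$", t)) {
      clitic <- regmatches(t, regexpr("'(s|re|m|ve|ll|d)$", t))
      out <- c(out, sub("'(s|re|m|ve|ll|d)$", "", t), clitic)
    } else {
      out <- c(out, t)
    }
  }
  out
}

# ---- tagging ----------------------------------------------------------------

#' Count pronoun categories and verb tenses in a message
#'
#' Applies the packaged closed-class pronoun dictionary and rule-based tense
#' tagger.  Tense rules: irregular-past lookup and the `-ed` suffix give past
#' (except passives/adjectival participles); `will`/`shall`/`'ll` and
#' `going to` + verb give future; finite be/have/do forms, present clitics
#' (`'s` after a pronoun, `'re`, `'m`, `'ve`) and lexicon base/-s forms give
#' present.  Infinitival `to` + verb, modal + verb (other than will/shall),
#' and bare `-ing`/`-ed` participles are excluded from tense counts: the
#' auxiliary, when present, carries the tense.
#'
#' @param text A character string.
#' @return Object of class `token_counts`: named integer vector with
#'   components `past`, `present`, `future` and the six pronoun categories.
#' @export
#' @examples
#' tag_tokens("We slept and they played")
tag_tokens <- function(text) {
  lex <- .lex()
  toks <- tokenize_message(text)
  counts <- c(past = 0L, present = 0L, future = 0L,
              pron_first_singular = 0L, pron_first_plural = 0L,
              pron_second = 0L, pron_third_singular = 0L,
              pron_third_plural = 0L, pron_impersonal = 0L)
  n <- length(toks)
  if (!n) return(structure(counts, class = "token_counts"))
  prev1 <- function(i) if (i > 1L) toks[i - 1L] else ""
  prev2 <- function(i) if (i > 2L) toks[i - 2L] else ""
  pron_like <- c(unlist(lex$pronouns, use.names = FALSE),
                 "there", "what", "who", "everything", "something", "nothing")
  for (i in seq_len(n)) {
    t <- toks[i]
    cat_p <- lex$pronoun_lookup[t]
    if (!is.na(cat_p)) counts[[cat_p]] <- counts[[cat_p]] + 1L

    # future markers
    if (t %in% c("will", "shall", "'ll")) {
      counts[["future"]] <- counts[["future"]] + 1L
      next
    }
    if (t == "going" && i + 2L <= n && toks[i + 1L] == "to" &&
        (toks[i + 2L] %in% lex$present_verbs || toks[i + 2L] == "be")) {
      counts[["future"]] <- counts[["future"]] + 1L
      next
    }

    # auxiliaries and copulas
    if (t %in% c("am", "is", "are", "'re", "'m", "have", "has", "'ve",
                 "do", "does")) {
      counts[["present"]] <- counts[["present"]] + 1L
      next
    }
    if (t == "'s") {  # present auxiliary only after a pronoun-like host
      if (prev1(i) %in% pron_like)
        counts[["present"]] <- counts[["present"]] + 1L
      next
    }
    if (t %in% c("was", "were", "had", "did")) {
      counts[["past"]] <- counts[["past"]] + 1L
      next
    }

    # irregular simple past
    if (t %in% lex$irregular_past) {
      counts[["past"]] <- counts[["past"]] + 1L
      next
    }

    # lexicon base and -s forms (checked before the -ed suffix rule, which
    # would otherwise misread bases like "need"): present unless
    # infinitival or modal-governed
    if (t %in% lex$present_verbs) {
      if (prev1(i) %in% .verb_skippers) next
      counts[["present"]] <- counts[["present"]] + 1L
      next
    }

    # regular -ed past; skip passives ("are puzzled") and adjectival
    # participles ("oddly detached")
    if (grepl("[a-z]ed$", t) && nchar(t) > 3L) {
      if (t %in% lex$participial_adjectives) next
      if (prev1(i) %in% .be_forms || prev2(i) %in% .be_forms) next
      counts[["past"]] <- counts[["past"]] + 1L
      next
    }
  }
  structure(counts, class = "token_counts")
}

#' @export
print.token_counts <- function(x, ...) {
  cat("Token counts (tense / pronoun categories):\n")
  print(unclass(x))
  invisible(x)
}

# ---- distance measures ------------------------------------------------------

#' Temporal distance of a message
#'
#' Proportion of tensed verbs that are not in the present tense:
#' `(past + future) / (past + future + present)`.  `NA` (undefined) when the
#' message has no tensed verbs.
#'
#' @param counts A `token_counts` object (or named numeric with the same
#'   components).
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @export
temporal_distance <- function(counts) {
  denom <- counts[["past"]] + counts[["future"]] + counts[["present"]]
  if (denom == 0) return(NA_real_)
  (counts[["past"]] + counts[["future"]]) / denom
}

#' Social distance of a message
#'
#' Proportion of personal pronouns that are not first-person singular:
#' `(second + first plural + third singular + third plural) / (all five
#' personal categories)`.  Impersonal pronouns are excluded from the
#' denominator (switch with `include_impersonal`).  `NA` when the message has
#' no personal pronouns.
#'
#' @param counts A `token_counts` object.
#' @param include_impersonal Count impersonal pronouns in the denominator
#'   (default `FALSE`).
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @export
social_distance <- function(counts, include_impersonal = FALSE) {
  non_first <- counts[["pron_first_plural"]] + counts[["pron_second"]] +
    counts[["pron_third_singular"]] + counts[["pron_third_plural"]]
  denom <- non_first + counts[["pron_first_singular"]]
  if (include_impersonal) denom <- denom + counts[["pron_impersonal"]]
  if (denom == 0) return(NA_real_)
  non_first / denom
}

#' Word-count composite linguistic distance of a message
#'
#' Mean of [temporal_distance()] and [social_distance()] on `[0, 1]`.
#' Undefined (`NA`) if either component is undefined; such messages are
#' excluded from all downstream analyses so that every scoring method is
#' evaluated on the same message set.
#'
#' @param text A character string.
#' @param include_impersonal Passed to [social_distance()].
#' @return A single number in `[0, 1]` or `NA_real_`.
#' @seealso [wc_display()] for the 0-10 display scale.
#' @export
#' @examples
#' wc_self_distance("On Saturday, we slept in, went to yoga, and played cards")
wc_self_distance <- function(text, include_impersonal = FALSE) {
  counts <- tag_tokens(text)
  td <- temporal_distance(counts)
  sd_ <- social_distance(counts, include_impersonal = include_impersonal)
  if (is.na(td) || is.na(sd_)) return(NA_real_)
  (td + sd_) / 2
}

#' Display-scale word-count distance (0-10)
#'
#' The composite is computed on `[0, 1]`; published examples print it times
#' ten.
#'
#' @param value Composite score(s) on `[0, 1]`.
#' @return `value * 10`.
#' @export
wc_display <- function(value) value * 10

#' Score a message table with the word-count composite
#'
#' @param messages Data frame with columns `message_id` and `text` (e.g. the
#'   `messages` element of a corpus).
#' @param include_impersonal Passed to [social_distance()].
#' @return A score table: `message_id`, `method` (`"wc_self"`), `value`
#'   (`[0, 1]` or `NA`), `defined` (logical).
#' @export
score_wordcount <- function(messages, include_impersonal = FALSE) {
  stopifnot(is.data.frame(messages),
            all(c("message_id", "text") %in% names(messages)))
  vals <- vapply(messages$text, wc_self_distance, numeric(1),
                 include_impersonal = include_impersonal, USE.NAMES = FALSE)
  data.frame(message_id = messages$message_id,
             method = "wc_self",
             value = vals,
             defined = !is.na(vals),
             stringsAsFactors = FALSE)
}
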
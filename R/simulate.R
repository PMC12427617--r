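## Synthetic-corpus generator.
##
## Latent model (per client i, assessment window k, time t_ik measured in
## assessment periods of `time_unit_days` days):
##   d_i   ~ Normal(mu_d, sigma_between^2)            person-level distance
##   d_ik  = d_i + gamma_time * t_ik + Normal(0, sigma_within^2)
##   y_ik  = round/clip[0,45]( beta0
##            + beta_within  * (d_ik - d_i)
##            + beta_between * (d_i - mu_d)
##            + c_prime * t_ik + u_i + Normal(0, sigma_symptom^2) )
## Message text in window k carries the latent level d_ik (clipped to [0,1])
## through controlled pronoun-person and verb-tense mixtures, so the
## word-count composite of a message is an unbiased estimate of the latent.

#' Simulation parameters
#'
#' Defaults describe the emulated study conditions: dyads with roughly 2.7
#' clients per therapist, four assessments about three weeks apart (so every
#' client passes the >= 3 assessments / >= 6 weeks inclusion rule), latent
#' distance on the word-count `[0, 1]` scale drifting slowly upward over
#' treatment, symptoms on the 0-45 internalizing scale coupled negatively to
#' both distance components, and the observed fractions of messages without
#' verbs (7.1\%) or pronouns (9.4\%).
#'
#' @param n_clients Number of clients.
#' @param clients_per_therapist Average caseload (therapist count is
#'   `n_clients` divided by this, rounded up).
#' @param assessments_per_client Number of assessments (>= 3).
#' @param assessment_spacing_days Days between assessments (default 21).
#' @param jitter_days Uniform jitter (+/- days) on assessment dates; 0
#'   disables.
#' @param messages_per_window Client messages per assessment window; 0 keeps
#'   only one anchoring message per dyad (fast, for table-level tests).
#' @param therapist_messages_per_window Therapist messages per window.
#' @param poisson_messages Draw per-window message counts as Poisson with the
#'   above means instead of fixed counts.
#' @param sentences_per_message Template sentences per generated message.
#' @param mu_d Grand-mean latent distance.
#' @param sigma_between Person-level SD of latent distance.
#' @param sigma_within Occasion-level SD of latent distance.
#' @param gamma_time Latent distance slope per assessment period (the `a`
#'   path).
#' @param beta_within Within-person distance-to-symptom coefficient (the `b`
#'   path).
#' @param beta_between Between-person distance-to-symptom coefficient.
#' @param c_prime Direct time-to-symptom effect per assessment period.
#' @param beta0 Symptom intercept on the 0-45 scale.
#' @param sigma_subject SD of the person-level symptom intercept `u_i`.
#' @param sigma_symptom Residual symptom SD.
#' @param p_no_verbs Fraction of messages emitted as verb-free fragments.
#' @param p_no_pronouns Fraction emitted as pronoun-free fragments.
#' @param time_unit_days Days per time unit for `gamma_time` and `c_prime`
#'   (default one assessment period, 21 days).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return Object of class `sim_params` (named list).
#' @export
sim_params <- function(n_clients = 200L,
                       clients_per_therapist = 2.7,
                       assessments_per_client = 4L,
                       assessment_spacing_days = 21L,
                       jitter_days = 3L,
                       messages_per_window = 10L,
                       therapist_messages_per_window = 6L,
                       poisson_messages = FALSE,
                       sentences_per_message = 4L,
                       mu_d = 0.4,
                       sigma_between = 0.12,
                       sigma_within = 0.08,
                       gamma_time = 0.04,
                       beta_within = -6,
                       beta_between = -10,
                       c_prime = -0.5,
                       beta0 = 20,
                       sigma_subject = 4,
                       sigma_symptom = 4,
                       p_no_verbs = 0.071,
                       p_no_pronouns = 0.094,
                       time_unit_days = 21L,
                       seed = 1L) {
  p <- as.list(environment())
  if (p$n_clients < 1) stop("n_clients must be >= 1")
  if (p$assessments_per_client < 3)
    stop("assessments_per_client must be >= 3 (inclusion rule)")
  if (p$sigma_between < 0 || p$sigma_within < 0 || p$sigma_subject < 0 ||
      p$sigma_symptom < 0)
    stop("standard deviations must be non-negative")
  if (p$p_no_verbs < 0 || p$p_no_pronouns < 0 ||
      p$p_no_verbs + p$p_no_pronouns > 1)
    stop("fragment fractions must lie in [0, 1] and sum to at most 1")
  if (p$assessment_spacing_days <= 2 * p$jitter_days)
    stop("assessment_spacing_days must exceed twice jitter_days")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic-corpus parameters:\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# ---- template vocabulary ----------------------------------------------------

.tpl_subjects_nonfirst <- c("we", "you", "he", "she", "they")
.tpl_verbs <- c("walk", "play", "work", "talk", "cook", "clean", "paint",
                "dance", "laugh", "call", "visit", "help", "watch", "want",
                "need", "learn", "listen", "open", "close", "start",
                "finish", "share", "stay", "smile")
.tpl_objects <- c("the dog", "a game", "the garden", "the report", "a meal",
                  "the room", "the piano", "a story", "the kitchen",
                  "a song")
.tpl_noverb_fragments <- c("What a day!", "Such a long week!",
                           "Quite the morning!", "So much noise outside!",
                           "Another quiet afternoon!")
.tpl_nopronoun_subjects <- c("The neighbors", "The children", "The family")

#' @noRd
.verb_past <- function(v) ifelse(grepl("e$", v), paste0(v, "d"),
                                 paste0(v, "ed"))
#' @noRd
.verb_third <- function(v) {
  ifelse(grepl("(s|sh|ch|x|z|o)$", v), paste0(v, "es"),
         ifelse(grepl("[^aeiou]y$", v), sub("y$", "ies", v), paste0(v, "s")))
}

#' Generate one template message at a latent distance level
#'
#' Emits `sentences` subject-verb-object sentences from a closed vocabulary
#' in which the probability of a non-first-singular subject pronoun and the
#' probability of a past-tense verb form both equal `latent`; with
#' probability `p_no_verbs` a verb-free fragment is emitted instead, and with
#' probability `p_no_pronouns` a pronoun-free (noun-subject) sentence, both
#' of which are undefined under the word-count composite.  Uses the current
#' RNG stream.
#'
#' @param latent Latent distance in `[0, 1]`.
#' @param sentences Number of sentences in a regular message.
#' @param p_no_verbs,p_no_pronouns Fragment probabilities.
#' @return A character string.
#' @export
generate_message_text <- function(latent, sentences = 4L,
                                  p_no_verbs = 0, p_no_pronouns = 0) {
  stopifnot(latent >= 0, latent <= 1)
  u <- runif(1)
  if (u < p_no_verbs)
    return(sample(.tpl_noverb_fragments, 1))
  if (u < p_no_verbs + p_no_pronouns) {
    subj <- sample(.tpl_nopronoun_subjects, 1)
    v <- sample(.tpl_verbs, 1)
    form <- if (runif(1) < latent) .verb_past(v) else v
    return(paste0(subj, " ", form, " ", sample(.tpl_objects, 1), "."))
  }
  sent <- character(sentences)
  for (s in seq_len(sentences)) {
    nonfirst <- runif(1) < latent
    subj <- if (nonfirst) sample(.tpl_subjects_nonfirst, 1) else "I"
    v <- sample(.tpl_verbs, 1)
    past <- runif(1) < latent
    form <- if (past) .verb_past(v)
            else if (subj %in% c("he", "she")) .verb_third(v)
            else v
    disp <- if (subj == "I") "I" else
      paste0(toupper(substring(subj, 1, 1)), substring(subj, 2))
    sent[s] <- paste0(disp, " ", form, " ", sample(.tpl_objects, 1), ".")
  }
  paste(sent, collapse = " ")
}

# ---- corpus generation ------------------------------------------------------

#' Generate a synthetic corpus with known ground truth
#'
#' @param params A [sim_params()] object.
#' @return Object of class `ld_simulation`: list with elements
#'   \describe{
#'     \item{corpus}{an `ld_corpus` (messages, assessments, dyads)}
#'     \item{truth}{list with `params`, `clients` (per-client `d_i`, `u_i`),
#'       `windows` (per-window latent `d_raw`, clipped `d`, time, symptom
#'       before/after clipping), and `message_latents` (message_id to the
#'       clipped latent its text was generated from, with author role)}
#'   }
#'   The symptom clipping rate is reported in
#'   `attr(truth, "symptom_clip_rate")`.
#' @export
generate_corpus <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  origin <- as.Date("2017-01-01")
  n <- as.integer(p$n_clients)
  K <- as.integer(p$assessments_per_client)
  n_ther <- max(1L, ceiling(n / p$clients_per_therapist))

  client_id <- sprintf("c%05d", seq_len(n))
  therapist_id <- sprintf("t%04d", rep_len(seq_len(n_ther), n))
  start_day <- sample.int(365L, n, replace = TRUE) - 1L

  d_i <- rnorm(n, p$mu_d, p$sigma_between)
  u_i <- rnorm(n, 0, p$sigma_subject)

  # assessment schedule: day_k ~ k * spacing + jitter
  jit <- if (p$jitter_days > 0)
    matrix(sample(seq(-p$jitter_days, p$jitter_days), n * K, replace = TRUE),
           n, K) else matrix(0L, n, K)
  day_k <- sweep(jit, 2, (seq_len(K)) * p$assessment_spacing_days, `+`)
  t_ik <- day_k / p$time_unit_days

  eps_w <- matrix(rnorm(n * K, 0, p$sigma_within), n, K)
  d_raw <- d_i + p$gamma_time * t_ik + eps_w
  d_clip <- d_raw
  d_clip[] <- pmin(1, pmax(0, d_raw))

  y_lin <- p$beta0 + p$beta_within * (d_raw - d_i) +
    p$beta_between * (d_i - p$mu_d) + p$c_prime * t_ik + u_i +
    matrix(rnorm(n * K, 0, p$sigma_symptom), n, K)
  y <- y_lin
  y[] <- pmin(45, pmax(0, round(y_lin)))
  clip_rate <- mean(y_lin < -0.5 | y_lin > 45.5)

  windows <- data.frame(
    client_id = rep(client_id, each = K),
    window = rep(seq_len(K), n),
    day = as.integer(t(day_k)),
    time = as.numeric(t(t_ik)),
    d_raw = as.numeric(t(d_raw)),
    d = as.numeric(t(d_clip)),
    internalizing = as.integer(t(y)),
    stringsAsFactors = FALSE
  )

  assessments <- data.frame(
    client_id = windows$client_id,
    date = origin + rep(start_day, each = K) + windows$day,
    phq8 = NA_integer_, gad7 = NA_integer_,
    stringsAsFactors = FALSE
  )
  # split internalizing into PHQ-8 / GAD-7 parts respecting both ranges
  assessments$phq8 <- pmin(24L, pmax(windows$internalizing - 21L,
                                     as.integer(round(windows$internalizing * 24 / 45))))
  assessments$gad7 <- windows$internalizing - assessments$phq8

  # messages: anchor at day 0, then per-window streams for both roles
  msgs <- vector("list", n * (K + 1L))
  latents <- vector("list", n * (K + 1L))
  idx <- 0L
  msg_counter <- 0L
  for (i in seq_len(n)) {
    anchor <- data.frame(
      message_id = sprintf("m%08d", msg_counter + 1L),
      client_id = client_id[i], therapist_id = therapist_id[i],
      author_role = "client",
      timestamp = origin + start_day[i],
      text = generate_message_text(d_clip[i, 1], p$sentences_per_message),
      stringsAsFactors = FALSE)
    msg_counter <- msg_counter + 1L
    idx <- idx + 1L
    msgs[[idx]] <- anchor
    latents[[idx]] <- data.frame(message_id = anchor$message_id,
                                 latent = d_clip[i, 1], window = 1L,
                                 author_role = "client",
                                 stringsAsFactors = FALSE)
    prev_day <- 0L
    for (k in seq_len(K)) {
      n_c <- if (p$poisson_messages) stats::rpois(1, p$messages_per_window)
             else as.integer(p$messages_per_window)
      n_t <- if (p$poisson_messages)
        stats::rpois(1, p$therapist_messages_per_window)
        else as.integer(p$therapist_messages_per_window)
      n_w <- n_c + n_t
      if (n_w > 0L) {
        lo <- prev_day + 1L
        hi <- day_k[i, k]
        days <- if (hi > lo) sample(seq(lo, hi), n_w, replace = TRUE)
                else rep(max(hi, lo), n_w)
        role <- c(rep("client", n_c), rep("therapist", n_t))
        texts <- vapply(seq_len(n_w), function(j)
          generate_message_text(d_clip[i, k], p$sentences_per_message,
                                p$p_no_verbs, p$p_no_pronouns),
          character(1))
        ids <- sprintf("m%08d", msg_counter + seq_len(n_w))
        msg_counter <- msg_counter + n_w
        idx <- idx + 1L
        msgs[[idx]] <- data.frame(
          message_id = ids, client_id = client_id[i],
          therapist_id = therapist_id[i], author_role = role,
          timestamp = origin + start_day[i] + sort(days),
          text = texts, stringsAsFactors = FALSE)
        latents[[idx]] <- data.frame(message_id = ids,
                                     latent = d_clip[i, k], window = k,
                                     author_role = role,
                                     stringsAsFactors = FALSE)
      }
      prev_day <- day_k[i, k]
    }
  }
  messages <- do.call(rbind, msgs[seq_len(idx)])
  message_latents <- do.call(rbind, latents[seq_len(idx)])
  rownames(messages) <- rownames(message_latents) <- NULL

  corp <- corpus(messages, assessments, quiet = TRUE)
  truth <- list(params = p,
                clients = data.frame(client_id = client_id, d_i = d_i,
                                     u_i = u_i, stringsAsFactors = FALSE),
                windows = windows,
                message_latents = message_latents)
  attr(truth, "symptom_clip_rate") <- clip_rate
  structure(list(corpus = corp, truth = truth), class = "ld_simulation")
}

#' @export
print.ld_simulation <- function(x, ...) {
  cat("Synthetic corpus with ground truth\n")
  print(x$corpus)
  cat("  symptom clipping rate:",
      signif(attr(x$truth, "symptom_clip_rate"), 3), "\n")
  invisible(x)
}

#' Expected effects implied by simulation parameters
#'
#' Returns the generating within/between coefficients and the analytic
#' proportion mediated, `100 * a*b / (a*b + c')`, where the `a` path is the
#' latent time trend (`gamma_time`) and the `b` path the within-person
#' distance-to-symptom coefficient.
#'
#' @param params A [sim_params()] object.
#' @return List with `beta_within`, `beta_between`, `a`, `b`, `c_prime`,
#'   `proportion_mediated` (percent; `NA` with `defined = FALSE` when
#'   `a*b + c'` is zero).
#' @export
theoretical_effects <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  a <- params$gamma_time
  b <- params$beta_within
  cp <- params$c_prime
  denom <- a * b + cp
  pm <- if (abs(denom) < .Machine$double.eps * 100) NA_real_
        else 100 * a * b / denom
  list(beta_within = params$beta_within,
       beta_between = params$beta_between,
       a = a, b = b, c_prime = cp,
       proportion_mediated = pm,
       defined = !is.na(pm))
}
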
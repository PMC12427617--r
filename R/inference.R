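## Mixed-effects estimation and effect-size comparison.
##
## Two model families over the windowed table:
##   time_on_distance:     score ~ time + (1 + time | client)
##   symptoms_on_distance: internalizing ~ within + between + (1 + within | client)
## Every model carries a random intercept by subject and random slopes for
## repeated-measure predictors.  Coefficients are reported pseudo-
## standardized (scaled by the SD of predictor and outcome at the
## predictor's level); effect size per predictor is semipartial
## R^2_beta = F / (nu2 + F) with F the Wald statistic (numerator df 1) and
## nu2 the Satterthwaite denominator df.

.MODEL_SPECS <- list(
  time_on_distance = list(
    outcome = "mean_score",
    predictors = c(time = "within"),
    formula = mean_score ~ time + (1 + time | client_id),
    fallback = mean_score ~ time + (1 | client_id)
  ),
  symptoms_on_distance = list(
    outcome = "internalizing",
    predictors = c(within = "within", between = "between"),
    formula = internalizing ~ within + between + (1 + within | client_id),
    fallback = internalizing ~ within + between + (1 | client_id)
  )
)

#' @noRd
.level_sd <- function(x, client, level) {
  if (level == "within") {
    dev <- x - ave(x, client, FUN = mean)
    sqrt(sum(dev^2) / (length(dev) - 1))
  } else {
    sd(tapply(x, client, mean))
  }
}

#' Fit a distance mixed model
#'
#' Restricted-maximum-likelihood fit of one of the two model families, with
#' Satterthwaite-df tests.  Non-convergence and singular fits are recorded
#' in the returned object's `flags`, never silently dropped; predictors with
#' zero variance are flagged degenerate and reported as `NA`.
#'
#' @param table Windowed-observation table; `symptoms_on_distance` expects
#'   the decomposed columns from [decompose_scores()].
#' @param model `"time_on_distance"` or `"symptoms_on_distance"`.
#' @return Object of class `ld_fit` with elements `model` (the fitted
#'   `lmerModLmerTest`), `effects` (one row per predictor: `beta`, `se`,
#'   `df`, `p_value`, `beta_std`, `r2_beta`), `model_name`, `flags`.
#' @export
fit_distance_model <- function(table,
                               model = c("time_on_distance",
                                         "symptoms_on_distance")) {
  model <- match.arg(model)
  spec <- .MODEL_SPECS[[model]]
  dat <- table
  need <- c(spec$outcome, names(spec$predictors), "client_id")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  dat <- dat[complete.cases(dat[, need]), , drop = FALSE]
  if (nrow(dat) < 4 || length(unique(dat$client_id)) < 2)
    stop("need >= 2 observations for >= 2 clients")
  dat$client_id <- factor(dat$client_id)

  flags <- character(0)
  degenerate <- names(spec$predictors)[vapply(
    names(spec$predictors), function(p) sd(dat[[p]]) == 0, logical(1))]
  if (length(degenerate))
    flags <- c(flags, paste0("degenerate predictor: ",
                             paste(degenerate, collapse = ", ")))

  fit <- withCallingHandlers(
    lmerTest::lmer(spec$formula, data = dat, REML = TRUE),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      flags <<- c(flags, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  if (lme4::isSingular(fit)) flags <- c(flags, "singular fit")

  effects <- .effect_table(fit, spec, dat)
  effects[effects$predictor %in% degenerate,
          c("beta", "se", "df", "p_value", "beta_std", "r2_beta")] <- NA_real_

  structure(list(model = fit, effects = effects, model_name = model,
                 flags = flags, n_obs = nrow(dat),
                 n_clients = length(unique(dat$client_id))),
            class = "ld_fit")
}

#' @noRd
.effect_table <- function(fit, spec, dat) {
  ct <- summary(fit)$coefficients   # Satterthwaite df from lmerTest
  preds <- names(spec$predictors)
  sd_y_within <- .level_sd(dat[[spec$outcome]], dat$client_id, "within")
  sd_y_between <- .level_sd(dat[[spec$outcome]], dat$client_id, "between")
  rows <- lapply(preds, function(p) {
    if (!p %in% rownames(ct))
      return(data.frame(predictor = p, beta = NA_real_, se = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        beta_std = NA_real_, r2_beta = NA_real_))
    beta <- ct[p, "Estimate"]; se <- ct[p, "Std. Error"]
    df <- ct[p, "df"]; pval <- ct[p, "Pr(>|t|)"]
    level <- spec$predictors[[p]]
    sd_x <- .level_sd(dat[[p]], dat$client_id, level)
    sd_y <- if (level == "within") sd_y_within else sd_y_between
    bstd <- if (sd_x > 0 && sd_y > 0) beta * sd_x / sd_y else NA_real_
    Fstat <- (beta / se)^2
    data.frame(predictor = p, beta = beta, se = se, df = df, p_value = pval,
               beta_std = bstd, r2_beta = Fstat / (df + Fstat))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("Linguistic-distance mixed model:", x$model_name, "\n")
  cat(sprintf("  %d observations, %d clients\n", x$n_obs, x$n_clients))
  eff <- x$effects
  eff[, -1] <- lapply(eff[, -1], function(v) signif(v, 4))
  print(eff, row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.ld_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying mixed model:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.ld_fit <- function(object, ...) {
  setNames(object$effects$beta_std, object$effects$predictor)
}

#' @export
predict.ld_fit <- function(object, ...) predict(object$model, ...)

#' @export
residuals.ld_fit <- function(object, ...) residuals(object$model, ...)

# ---- paired cluster bootstrap ----------------------------------------------

#' @noRd
.r2_for_focal <- function(dat, spec, focal) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(spec$formula, data = dat, REML = TRUE))),
    error = function(e) NULL)
  ct <- if (!is.null(fit))
    tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(ct) || !focal %in% rownames(ct) ||
      !is.finite(ct[focal, "df"])) {
    # simplified random structure, bootstrap resamples only
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(spec$fallback, data = dat, REML = TRUE))),
      error = function(e) NULL)
    ct <- if (!is.null(fit))
      tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (is.null(ct) || !focal %in% rownames(ct)) return(NA_real_)
  }
  Fstat <- (ct[focal, "Estimate"] / ct[focal, "Std. Error"])^2
  df <- ct[focal, "df"]
  if (!is.finite(Fstat) || !is.finite(df)) return(NA_real_)
  Fstat / (df + Fstat)
}

#' Paired cluster bootstrap comparing two score methods
#'
#' For each of `B` resamples, draws N clusters with replacement (N = number
#' of clusters in the full data), relabels duplicates as distinct clusters,
#' rebuilds both methods' tables from the same resample (re-decomposing
#' within/between components), refits both mixed models, and records the
#' difference in semipartial R^2_beta for the focal predictor.  Failed fits
#' are skipped and counted; more than 10\% failures flags the comparison
#' unreliable.
#'
#' @param table_a,table_b Windowed tables for the two methods over the same
#'   clients (from [build_regression_table()] or [window_means()]).
#' @param model Model family, as in [fit_distance_model()].
#' @param focal Focal predictor (`"time"`, `"within"` or `"between"`).
#' @param B Number of resamples (default 2000).
#' @param unit Cluster role to resample: `"client"` resamples `client_id`,
#'   `"therapist"` resamples `therapist_id` (column required in the tables).
#' @param seed Integer seed.
#' @return Object of class `ld_boot`: `deltas` (R^2_a - R^2_b per resample),
#'   `ci` (2.5/97.5 percentiles), `significant` (CI excludes 0),
#'   `n_failed`, `unreliable`.
#' @export
paired_bootstrap_compare <- function(table_a, table_b,
                                     model = c("symptoms_on_distance",
                                               "time_on_distance"),
                                     focal = "within", B = 2000L,
                                     unit = c("client", "therapist"),
                                     seed = 1L) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  spec <- .MODEL_SPECS[[model]]
  if (!focal %in% names(spec$predictors))
    stop("focal predictor must be one of: ",
         paste(names(spec$predictors), collapse = ", "))
  if (B < 1) stop("B must be >= 1")
  unit_col <- if (unit == "client") "client_id" else "therapist_id"
  for (tb in list(table_a, table_b))
    if (!unit_col %in% names(tb))
      stop("tables lack the resampling column ", unit_col)
  if (!setequal(unique(table_a$client_id), unique(table_b$client_id)))
    stop("the two tables must cover the same clients")

  prep <- function(tab) {
    keep <- !is.na(tab$mean_score)
    tab[keep, , drop = FALSE]
  }
  ta <- prep(table_a); tb <- prep(table_b)

  set.seed(seed)
  deltas <- rep(NA_real_, B)
  needs_decomp <- model == "symptoms_on_distance"
  for (b in seq_len(B)) {
    # one cluster draw shared by both methods (paired design)
    ids <- unique(ta[[unit_col]])
    draw <- sample(ids, length(ids), replace = TRUE)
    build <- function(tab) {
      pieces <- lapply(seq_along(draw), function(j) {
        piece <- tab[tab[[unit_col]] == draw[j], , drop = FALSE]
        piece$client_id <- paste0(piece$client_id, ".", j)
        piece
      })
      res <- do.call(rbind, pieces)
      if (needs_decomp)
        res <- suppressMessages(decompose_scores(res))
      res
    }
    da <- build(ta); db <- build(tb)
    r2a <- .r2_for_focal(da, spec, focal)
    r2b <- .r2_for_focal(db, spec, focal)
    if (is.finite(r2a) && is.finite(r2b)) deltas[b] <- r2a - r2b
  }
  n_failed <- sum(is.na(deltas))
  ok <- deltas[!is.na(deltas)]
  if (!length(ok)) stop("all bootstrap fits failed")
  ci <- unname(quantile(ok, c(0.025, 0.975)))
  structure(list(deltas = ok, ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 B = B, n_failed = n_failed,
                 unreliable = n_failed > 0.1 * B,
                 model = model, focal = focal, unit = unit, seed = seed),
            class = "ld_boot")
}

#' @export
print.ld_boot <- function(x, ...) {
  cat("Paired cluster bootstrap (", x$model, ", focal ", x$focal,
      ", unit ", x$unit, ")\n", sep = "")
  cat(sprintf("  B = %d resamples (%d failed fits%s)\n", x$B, x$n_failed,
              if (x$unreliable) "; UNRELIABLE (>10% failures)" else ""))
  cat(sprintf("  mean delta R2_beta = %.4g, 95%% CI [%.4g, %.4g]%s\n",
              mean(x$deltas), x$ci[1], x$ci[2],
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' @export
plot.ld_boot <- function(x, ...) {
  graphics::hist(x$deltas, breaks = 30, main = "Bootstrap effect-size deltas",
                 xlab = expression(Delta ~ R[beta]^2), ...)
  graphics::abline(v = c(0, x$ci), lty = c(1, 2, 2),
                   col = c("red", "grey30", "grey30"))
  invisible(x)
}
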
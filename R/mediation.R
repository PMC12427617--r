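## Bayesian multilevel mediation.
##
## Mediator model:  M  ~ X (+ covariates) + random intercept by participant
## Outcome model:   Y  ~ X + M_within (+ covariates) + random intercept
## where M_within is the participant-centered mediator (the reported
## indirect pathway is the within-person one).  Both models are sampled
## jointly so the a (X -> M) and b (M_within -> Y) draws are aligned per
## iteration; the indirect effect a*b and the proportion mediated
## 100 * a*b / (a*b + c') are formed draw-wise from the joint posterior.
## Weakly informative Gaussian(0, 10) priors on all regression coefficients.

#' @noRd
.mediation_model_string <- function(n_cov) {
  cov_m <- if (n_cov) " + inprod(gM[1:P], C[j, 1:P])" else ""
  cov_y <- if (n_cov) " + inprod(gY[1:P], C[j, 1:P])" else ""
  cov_priors <- if (n_cov) "
  for (p in 1:P) {
    gM[p] ~ dnorm(0, 0.01)
    gY[p] ~ dnorm(0, 0.01)
  }" else ""
  paste0("
model {
  for (j in 1:N) {
    M[j] ~ dnorm(aM0 + a * X[j]", cov_m, " + uM[cl[j]], tauM)
    Y[j] ~ dnorm(b0 + cp * X[j] + b * Mw[j]", cov_y, " + uY[cl[j]], tauY)
  }
  for (i in 1:Ncl) {
    uM[i] ~ dnorm(0, tauUM)
    uY[i] ~ dnorm(0, tauUY)
  }
  aM0 ~ dnorm(0, 0.01)
  a   ~ dnorm(0, 0.01)
  b0  ~ dnorm(0, 0.01)
  b   ~ dnorm(0, 0.01)
  cp  ~ dnorm(0, 0.01)", cov_priors, "
  sigmaM  ~ dunif(0, 50);  tauM  <- pow(sigmaM, -2)
  sigmaY  ~ dunif(0, 50);  tauY  <- pow(sigmaY, -2)
  sigmaUM ~ dunif(0, 50);  tauUM <- pow(sigmaUM, -2)
  sigmaUY ~ dunif(0, 50);  tauUY <- pow(sigmaUY, -2)
}
")
}

#' @noRd
.split_rhat <- function(chains) {
  # split-chain potential scale reduction; chains: list of numeric vectors
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Bayesian multilevel mediation model
#'
#' @param table Data frame with one row per client-window: `client_id`, the
#'   predictor, mediator, outcome and covariate columns.
#' @param predictor Name of the X column (e.g. `"time"`).
#' @param mediator Name of the mediator column; it is participant-centered
#'   internally to form the within-person pathway.
#' @param outcome Name of the outcome column (default `"internalizing"`).
#' @param covariates Optional covariate column names entered in both models.
#' @param chains,iterations,burn_in MCMC settings (defaults 2 chains,
#'   12,500 iterations with the first 2,500 discarded; adaptation counts
#'   toward burn-in).  `fast = TRUE` switches to 2 x 2,000 with 500 burn-in
#'   for test-scale runs.
#' @param fast Use the reduced-iteration mode.
#' @param seed Integer seed (chain RNGs derive from it).
#' @return Object of class `ld_mediation`: posterior `summaries` (median
#'   and 95\% credible range for `a`, `b`, `c_prime`, `indirect`,
#'   `proportion_mediated`), `significant` (indirect CR excludes zero),
#'   `rhat` per parameter with `converged` flag, and the retained `draws`.
#' @export
fit_mediation <- function(table, predictor, mediator,
                          outcome = "internalizing",
                          covariates = character(0),
                          chains = 2L, iterations = 12500L, burn_in = 2500L,
                          fast = FALSE, seed = 1L) {
  if (fast) { iterations <- 2000L; burn_in <- 500L }
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  need <- c("client_id", predictor, mediator, outcome, covariates)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  dat <- table[complete.cases(table[, need]), need, drop = FALSE]
  cl <- as.integer(factor(dat$client_id))
  M <- dat[[mediator]]
  Mw <- M - ave(M, cl, FUN = mean)

  # center predictor and covariates for sampling: slopes are unchanged,
  # intercepts absorb the shift, and Gibbs mixing improves markedly
  jd <- list(N = nrow(dat), Ncl = max(cl), cl = cl,
             X = dat[[predictor]] - mean(dat[[predictor]]),
             M = M, Mw = Mw, Y = dat[[outcome]])
  if (length(covariates)) {
    jd$C <- scale(as.matrix(dat[, covariates, drop = FALSE]),
                  center = TRUE, scale = FALSE)
    jd$P <- length(covariates)
  }
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))

  n_adapt <- min(500L, burn_in)
  jm <- rjags::jags.model(
    textConnection(.mediation_model_string(length(covariates))),
    data = jd, inits = inits, n.chains = chains, n.adapt = n_adapt,
    quiet = TRUE)
  if (burn_in > n_adapt)
    stats::update(jm, n.iter = burn_in - n_adapt, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = c("a", "b", "cp"),
                              n.iter = iterations - burn_in,
                              progress.bar = "none")

  get_par <- function(par) lapply(samp, function(ch) as.numeric(ch[, par]))
  a_ch <- get_par("a"); b_ch <- get_par("b"); cp_ch <- get_par("cp")
  a <- unlist(a_ch); b <- unlist(b_ch); cp <- unlist(cp_ch)
  indirect <- a * b
  total <- indirect + cp
  stable <- abs(total) >= 1e-8
  proportion <- 100 * indirect[stable] / total[stable]

  qs <- function(x) c(median = median(x),
                      lower = unname(quantile(x, 0.025)),
                      upper = unname(quantile(x, 0.975)))
  summaries <- rbind(a = qs(a), b = qs(b), c_prime = qs(cp),
                     indirect = qs(indirect),
                     proportion_mediated = qs(proportion))
  summaries <- data.frame(parameter = rownames(summaries), summaries,
                          row.names = NULL)
  rhat <- c(a = .split_rhat(a_ch), b = .split_rhat(b_ch),
            c_prime = .split_rhat(cp_ch))
  ci <- summaries[summaries$parameter == "indirect", c("lower", "upper")]

  structure(list(
    summaries = summaries,
    significant = ci$lower > 0 || ci$upper < 0,
    rhat = rhat,
    converged = all(rhat < 1.01),
    n_unstable_draws = sum(!stable),
    draws = list(a = a, b = b, c_prime = cp, indirect = indirect,
                 proportion_mediated = proportion),
    settings = list(predictor = predictor, mediator = mediator,
                    outcome = outcome, covariates = covariates,
                    chains = chains, iterations = iterations,
                    burn_in = burn_in, seed = seed),
    n_obs = nrow(dat), n_clients = max(cl)),
    class = "ld_mediation")
}

#' @export
print.ld_mediation <- function(x, ...) {
  s <- x$settings
  cat("Bayesian multilevel mediation: ", s$predictor, " -> ", s$mediator,
      " (within) -> ", s$outcome, "\n", sep = "")
  if (length(s$covariates))
    cat("  covariates:", paste(s$covariates, collapse = ", "), "\n")
  cat(sprintf("  %d observations, %d clients; %d chains x %d iterations (%d burn-in)\n",
              x$n_obs, x$n_clients, s$chains, s$iterations, s$burn_in))
  tab <- x$summaries
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  indirect effect %ssignificant (95%% CR %s 0); max split R-hat = %.3f%s\n",
              if (x$significant) "" else "not ",
              if (x$significant) "excludes" else "includes",
              max(x$rhat),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (x$n_unstable_draws > 0)
    cat("  ", x$n_unstable_draws,
        "draw(s) with |indirect + direct| < 1e-8 excluded from the proportion\n")
  invisible(x)
}

#' @export
summary.ld_mediation <- function(object, ...) {
  print(object)
  invisible(object$summaries)
}

#' Run the three standard mediation configurations
#'
#' Configuration 1: time in treatment -> client self-distance (within) ->
#' internalizing.  Configuration 2: time -> therapist other-distance
#' (within) -> internalizing.  Configuration 3: therapist other-distance ->
#' client self-distance (within) -> internalizing, controlling for time.  A
#' configuration whose score table is missing is skipped with a message.
#'
#' @param self_table Windowed table of client self-distance scores
#'   ([build_regression_table()] output), or `NULL`.
#' @param other_table Windowed table of therapist other-distance scores, or
#'   `NULL`.
#' @param ... Passed to [fit_mediation()] (`fast`, MCMC settings).
#' @param seed Integer seed; configuration k uses `seed + k`.
#' @return Named list of `ld_mediation` results (`config1`-`config3`),
#'   omitting skipped configurations.
#' @export
run_standard_mediations <- function(self_table = NULL, other_table = NULL,
                                    seed = 1L, ...) {
  res <- list()
  merged <- NULL
  if (!is.null(self_table) && !is.null(other_table)) {
    merged <- merge(
      self_table[, c("client_id", "window", "time", "internalizing",
                     "mean_score")],
      setNames(other_table[, c("client_id", "window", "mean_score")],
               c("client_id", "window", "other_score")),
      by = c("client_id", "window"))
  }
  if (!is.null(self_table)) {
    res$config1 <- fit_mediation(self_table, predictor = "time",
                                 mediator = "mean_score",
                                 seed = seed + 1L, ...)
  } else message("config 1 skipped: client self-distance table missing")
  if (!is.null(other_table)) {
    res$config2 <- fit_mediation(other_table, predictor = "time",
                                 mediator = "mean_score",
                                 seed = seed + 2L, ...)
  } else message("config 2 skipped: therapist other-distance table missing")
  if (!is.null(merged)) {
    res$config3 <- fit_mediation(merged, predictor = "other_score",
                                 mediator = "mean_score",
                                 covariates = "time",
                                 seed = seed + 3L, ...)
  } else message("config 3 skipped: needs both score tables")
  res
}
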
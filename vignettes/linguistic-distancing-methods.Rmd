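---
title: "Measuring linguistic distancing and relating it to symptoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linguistic distancing and relating it to symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingdist)
```

## The construct and the two measurement routes

Psychological (linguistic) distancing is the degree to which language frames
an experience as removed from the self and the present moment. People who
"step back" linguistically use fewer first-person-singular pronouns and less
present tense; in therapy transcripts, higher distancing tracks better
emotion regulation and lower internalizing symptoms. `lingdist` implements
two message-level measures of this construct and the longitudinal modelling
pipeline that relates them to symptoms.

**Word-count composite (`wc_self`).** Each message is scored as the mean of

* *temporal distance* = (past + future) / (past + future + present), over
  tensed verbs, and
* *social distance* = non-first-person-singular personal pronouns / all
  personal pronouns,

both on $[0,1]$. Either component is undefined when its denominator is zero
(no tensed verbs: about 7% of real messages; no personal pronouns: about
9%), and the composite is undefined if either part is. Undefined messages
are excluded from *all* methods so every measure is evaluated on the same
message set. Display output multiplies by 10.

**Prompted-LLM expected score (`llm_self`, `llm_other`).** An instruction
defining the construct and a five-level scale (A–E) is prepended to the
message (truncated after 1,000 tokens) and submitted to a scoring backend
that returns one unnormalized score (logit) per label for the next-token
position. The message score is the softmax-weighted expectation

$$\mathrm{score} = \sum_{i=1}^{5} i \cdot \mathrm{softmax}(\mathrm{logit})_i \in [1,5],$$

computed with a max-subtracted softmax in double precision. Reading out the
label distribution rather than sampling makes the score deterministic.
`llm_self` rates how distanced the author's language is (client or
therapist text); `llm_other` rates how much a therapist's message
*encourages the client* to adopt a distanced perspective (therapist text
only). Real model adapters plug in behind the same `scoring_backend`
contract (labels must map to single vocabulary tokens); the packaged
`mock_backend()` reads a synthetic message's hidden latent $\ell$ and emits
logits $-s\,(i - (1+4\ell))^2$, enabling full-path tests without model
weights.

The prompt texts shipped under `inst/prompts/` are original compositions
following that structure (construct definition, five ordered labels,
single-letter answer); they are data files the code treats as opaque.

## Dictionary and tense rules

The proprietary word-count tool used in earlier work is replaced by a
packaged open dictionary. Pronoun categories are enumerated exhaustively
(first singular *I, me, my, mine, myself*; first plural; second; third
singular; third plural; impersonal *it, its, itself, this, that, these,
those, one*). Impersonal pronouns are excluded from the social-distance
denominator by default — the published worked examples are consistent with
that choice — and `include_impersonal = TRUE` switches the alternative.

Tense tagging is rule-based and deliberately conservative:

* irregular-past lookup plus the `-ed` suffix → past, except passives
  (`are puzzled`) and a packaged list of adjectival participles
  (`oddly detached`);
* `will`/`shall`/`'ll` and `going to` + verb → future;
* finite *be/have/do* forms, the clitics `'re`, `'m`, `'ve`, and `'s`
  attached to a pronoun-like host → present; possessive `'s` is ignored;
* base and `-s` forms of a packaged verb lexicon → present, unless
  preceded by infinitival `to` or a modal (the marker carries the tense);
* bare `-ing`/`-ed` participles carry no tense themselves.

These rules reproduce all six published boundary-example scores exactly
(three messages at 0.00 and three at 10.0 on the display scale). They are
heuristics: a part-of-speech tagger backend could replace them behind the
same `tag_tokens()` contract. Tokenization lowercases, treats curly and
straight apostrophes alike, splits on non-alphanumerics keeping internal
apostrophes, and drops the redaction marker `[-]` (it contributes no
token).

## From messages to the regression table

Assessments are PHQ-8 (0–24) plus GAD-7 (0–21), summed to an internalizing
score (0–45); clients enter analyses with at least three assessments
spanning at least six weeks. Window $k$ of a client is the half-open
interval (assessment $k-1$, assessment $k$], with window 1 starting at the
dyad's first message date; a message on an assessment day belongs to the
ending window, and messages after the last assessment are unmapped. Scores
are averaged per window *without weighting by message length*; a window
with no defined score is dropped from fitting (no imputation). Days in
treatment is the assessment date minus the first message date with the
primary therapist — defined here, since multi-therapist records leave it
open, as the therapist with the most messages to that client (ties broken
by earliest first message).

Windowed predictors are decomposed as
$x_{ik} = \bar{x} + b_i + w_{ik}$ with $b_i$ the person mean centered on
the unweighted grand mean of person means (between-person component) and
$w_{ik}$ the deviation from the person mean (within-person component).
Within components sum to zero per person and the reconstruction is exact;
both identities are tested to machine precision.

## Mixed models, standardization, and effect size

Two REML model families (lme4, Satterthwaite tests via lmerTest):

* `time_on_distance`: `score ~ time + (1 + time | client)`
* `symptoms_on_distance`:
  `internalizing ~ within + between + (1 + within | client)`

Every model has a random intercept by subject and random slopes for
repeated-measure predictors (time; the within component). The `between`
component is constant within person, so it takes no slope.

Coefficients are reported *pseudo-standardized*: each predictor is scaled
by the SD at its own level (pooled within-person SD for repeated measures,
SD of person means for between-level predictors) and the outcome by its SD
at the matching level. Effect size per predictor is the semipartial

$$R^2_\beta = \frac{F}{\nu_2 + F},$$

with $F$ the Wald statistic ($t^2$, numerator df 1) and $\nu_2$ the
Satterthwaite denominator df — an identity that makes $R^2_\beta$ invariant
to affine rescaling of the predictor (tested). Singular or non-converged
fits are flagged on the returned object, never silently dropped; a
zero-variance predictor is flagged degenerate with `NA` estimates.

Time is measured in assessment periods (`time_unit_days`, default 21 days)
throughout the modelling layer: slopes per three-week period are the
interpretable scale for a construct assessed every three weeks, and the
mediation paths below are stated on the same scale.

## Paired cluster bootstrap

To compare two scoring methods' effect sizes, each of $B$ resamples draws
$N$ clusters (clients, or therapists) with replacement, where $N$ is the
number of clusters in the data. Duplicated clusters are relabelled as
distinct groups — required for a valid refit of the random-effects
structure. Both methods' tables are rebuilt from the *same* resample
(within/between components re-decomposed per resample, since the grand mean
moves), both models refit, and $\Delta R^2_\beta$ recorded for the focal
predictor. The 2.5/97.5 percentiles give the confidence interval;
significance means the interval excludes zero. Resamples whose fits fail
are skipped and counted; more than 10% failures flags the comparison
unreliable. Inside bootstrap refits only, a failed random-slope fit falls
back to an intercept-only random structure; headline fits never do. The
default is $B = 2000$.

## Bayesian multilevel mediation

The mediation layer jointly samples, with participant random intercepts,

* mediator model: $M \sim X$ (+ covariates),
* outcome model: $Y \sim X + M_w$ (+ covariates),

where $M_w$ is the participant-centered mediator: the reported indirect
pathway is the within-person one. Coefficients get Gaussian(0, 10) priors;
group and residual SDs get flat Uniform(0, 50) priors. The default sampler
settings are 2 chains of 12,500 iterations with the first 2,500 discarded
(adaptation counts toward burn-in); `fast = TRUE` runs 2 × 2,000 for
test-scale work. Sampling uses Gibbs updates (JAGS); the predictor and
covariates are mean-centered inside the sampler, which leaves all slopes
unchanged and dramatically improves mixing on the $X$–$M_w$ collinearity
ridge created by a time trend inside the mediator.

The indirect effect $a \times b$ and the proportion mediated
$100\,ab/(ab + c')$ are formed per retained draw from the joint posterior
(never from summary products); draws with $|ab + c'| < 10^{-8}$ are
excluded from the proportion and counted, since the ratio is unstable
there. Significance is the 95% credible range of the indirect effect
excluding zero. Convergence is gated on split-chain potential scale
reduction $< 1.01$ for $a$, $b$, $c'$, computed in-package (each chain is
split in half before the between/within-chain variance comparison).

`run_standard_mediations()` wires the three standard configurations:
time → client self-distance → symptoms; time → therapist other-distance →
symptoms; and therapist other-distance → client self-distance → symptoms
controlling for time.

## The synthetic generator and what it does (not) emulate

Because real transcripts are proprietary, every downstream stage is tested
against `generate_corpus()`, which draws, per client $i$ and window $k$
(time $t_{ik}$ in assessment periods):

$$d_i \sim N(\mu_d, \sigma_b^2), \qquad
d_{ik} = d_i + \gamma t_{ik} + N(0, \sigma_w^2),$$
$$y_{ik} = \mathrm{round/clip}_{[0,45]}\big(\beta_0 + \beta_w (d_{ik}-d_i)
 + \beta_b (d_i - \mu_d) + c' t_{ik} + u_i + N(0, \sigma_y^2)\big).$$

Message text in window $k$ is built from subject–verb–object templates over
a closed vocabulary in which the probability of a non-first-singular
subject and of a past-tense verb both equal $d_{ik}$ clipped to $[0,1]$, so
the word-count composite of a message is an unbiased estimate of the latent
(and exactly 0 or 1 at the endpoints). A stated fraction of messages are
verb-free (default 7.1%) or pronoun-free (9.4%) fragments, undefined under
the composite. The internalizing score is split into PHQ-8/GAD-7 parts
respecting both ranges; the symptom clipping rate is reported so recovery
tests can avoid heavy-censoring regimes.

Default study conditions: 200 clients (about 2.7 per therapist), four
assessments 21 ± 3 days apart (every client passes the inclusion rule;
jitter can be disabled), 10 client and 6 therapist messages per window
(fixed counts for test stability, Poisson optional;
`messages_per_window = 0` keeps a single anchoring message for fast
table-level simulation), $\mu_d = 0.4$, $\sigma_b = 0.12$,
$\sigma_w = 0.08$, $\gamma = 0.04$ per period, $\beta_w = -6$,
$\beta_b = -10$, $c' = -0.5$ per period, $\beta_0 = 20$,
$\sigma_u = 4$, $\sigma_y = 4$. Therapist messages carry the client's
window latent, so the therapist-side pathways are active for mediation
configurations 2–3. Identical seeds give identical corpora.

The generator carries controlled grammatical signal, not clinical prose: it
contains no counterfactuals, no affect vocabulary, no length variation of
consequence, and its latent truly is one-dimensional. Passing
recovery tests therefore demonstrates that the *pipeline* is correct —
scoring, windowing, decomposition, estimation, and uncertainty — not that
either measure captures distancing in real therapy language.

`theoretical_effects()` returns the analytic proportion mediated
$100\,ab/(ab + c')$ with $a = \gamma$ and $b = \beta_w$; with $a = 0.5$,
$b = -0.4$, $c' = -0.1$ per period it is $66.7\%$, the anchor for the
mediation recovery test.

## Numerical and design choices

* Dates are day-resolution; intra-day order is file order.
* Windows are half-open (prev, current]; boundary messages belong to the
  ending window.
* The grand mean for between-centering is the unweighted mean of person
  means, not of observations.
* Recovery tests run on windowed tables built from the latent truth (a
  perfectly measured score). Dictionary scores of template text are
  unbiased but noisy per message; that measurement noise attenuates
  within-person slopes, which is a property of the measurement, not of the
  estimator under test. Sign-level checks on the scored-text path are part
  of the unit suite.
* The bias check for the symptoms model runs with $c' = 0$ and
  $\gamma = 0$: estimator bias is defined under the model's own
  assumptions, and a direct time path (which the two-predictor symptoms
  model deliberately omits, matching the analysis it reproduces) is an
  unmodelled confounder of the within slope, not an estimator defect.
  Because person means are estimated from $K$ windows, the expected
  between coefficient is not $\beta_b$ but
  $\lambda \beta_b + (1-\lambda)\beta_w$ with reliability
  $\lambda = \sigma_b^2/(\sigma_b^2 + \sigma_w^2/K)$ — occasion noise in
  the person mean both attenuates the between effect and leaks a share of
  the within effect; the test asserts recovery of that expectation.
* Simulation scales used by the test suite (chosen for a single CPU): bias
  checks at 500 clients × 4 windows × 100 replicates; bootstrap null
  calibration at 25 clients × 3 windows, $B = 50$, 40 replicates, with the
  significance rate asserted within a binomial band of the nominal 5%;
  bootstrap power at 40 clients with a strong within-person effect
  ($\beta_w = -25$, $\sigma_w = 0.1$, $\sigma_y = 2$), asserted > 90%;
  mediation recovery at 300 clients × 4 windows in fast MCMC mode with
  nuisance parameters ($\sigma_w = 0.5$, $\sigma_y = 2$, $\sigma_u = 2$,
  $\sigma_b = 0.15$, $\beta_0 = 22$) chosen to keep symptoms off the
  0/45 bounds.
* The mediation null check ($b = 0$: indirect credible range contains 0)
  is a single fixed-seed run; a replicate-level rate would need dozens of
  MCMC runs.

## Known limitations

* The tense rules are heuristics over a finite verb lexicon; out-of-lexicon
  present-tense verbs are missed (undefined rather than wrong, in the
  worst case), and the participial-adjective list is not exhaustive.
* The real-model scoring backend is a contract plus a mock here; no model
  weights ship with the package, and nothing ever leaves the machine.
* Mediation is observational: the machinery quantifies pathways under the
  stated model, and no sensitivity analysis for sequential ignorability is
  provided.
* The therapist-side generative coupling (therapist latent = client window
  latent) is a convenience for exercising configurations 2–3, not a model
  of therapist behavior.
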
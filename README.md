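# lingdist

Linguistic distancing scores and longitudinal symptom models for
text-based psychotherapy.

## The problem

Psychological ("linguistic") distancing is the degree to which language
frames an experience as removed from the self and the present moment —
fewer first-person-singular pronouns, less present tense, more abstract
framing. In therapy transcripts it tracks emotion regulation and
internalizing symptoms (PHQ-8 + GAD-7, range 0–45). `lingdist` is for
researchers who want to score distancing in message streams and model its
relation to longitudinal symptoms, with every stage testable against a
synthetic corpus of known ground truth.

Two measurement routes are implemented:

* **Word-count composite** (`wc_self`): the mean of
  *temporal distance* = (past + future) / (past + future + present)
  over tensed verbs and
  *social distance* = non-first-singular personal pronouns / personal
  pronouns, on [0, 1] (×10 for display). Undefined when a message has no
  tensed verbs or no personal pronouns; undefined messages are excluded
  from all methods.
* **Prompted-LLM expected score** (`llm_self`, `llm_other`): an
  instruction describing the construct and a five-level scale (A–E) is
  prepended to the message; a scoring backend returns one logit per label
  and the score is the constrained softmax expectation
  `score = Σ i · softmax(logit)_i ∈ [1, 5]`. A deterministic mock backend
  driven by synthetic ground truth ships in the package; real local-model
  adapters plug in behind the same contract.

Downstream, window means between assessments are decomposed into
within-person and between-person components and fed to random-slope mixed
models (pseudo-standardized β, semipartial `R²_β = F / (ν₂ + F)` with
Satterthwaite ν₂), a paired cluster bootstrap comparing two measures'
effect sizes, and Bayesian multilevel mediation (indirect effect `a·b`,
proportion mediated `100·a·b/(a·b + c′)`).

## Worked example

```r
library(lingdist)

# packaged paraphrased boundary examples
ex <- read.csv(system.file("extdata", "boundary_examples.csv",
                           package = "lingdist"))
wc_display(wc_self_distance(ex$text[5]))
#> [1] 10
wc_self_distance("Haha!")   # no verbs, no pronouns -> undefined
#> [1] NA

# synthetic corpus -> score -> window -> decompose -> fit
sim <- generate_corpus(sim_params(n_clients = 60, seed = 42))
scores <- score_wordcount(subset(sim$corpus$messages,
                                 author_role == "client"))
tab <- build_regression_table(sim$corpus, scores, role = "client")
fit_distance_model(tab, "time_on_distance")
#> Linguistic-distance mixed model: time_on_distance
#>   240 observations, 60 clients
#>  predictor    beta       se    df   p_value beta_std r2_beta
#>       time 0.03719 0.005423 152.4 1.643e-10   0.4615  0.2358
#>   flags: boundary (singular) fit: see help('isSingular'); singular fit

fit_distance_model(tab, "symptoms_on_distance")
#> Linguistic-distance mixed model: symptoms_on_distance
#>   240 observations, 60 clients
#>  predictor   beta    se     df p_value beta_std r2_beta
#>     within -4.878 2.832 174.00 0.08683  -0.1279 0.01676
#>    between -4.196 4.528  58.06 0.35790  -0.1206 0.01458
#>   flags: boundary (singular) fit: see help('isSingular'); singular fit
```

Read: distance drifts upward over treatment (standardized β = 0.46 per
within-person SD of time, `R²_β` = 0.24), and higher-than-usual distance
within a client accompanies lower symptoms (β_std = −0.13), attenuated
here by per-message measurement noise at this small simulated scale. The
`singular fit` flag reports a random-slope variance estimated at zero —
expected when the generating slopes are homogeneous — surfaced rather than
hidden.

Mediation and method comparison:

```r
m <- fit_mediation(tab, predictor = "time", mediator = "mean_score",
                   fast = TRUE, seed = 1)      # time -> distance -> symptoms
cmp <- paired_bootstrap_compare(table_wc, table_llm, focal = "within",
                                B = 2000, seed = 1)
```

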
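# raschform

Tools for building short (caregiver-reported) and long (directly administered)
instruments of early child development from a Rasch item bank, the way modern
cross-national measures are constructed: expert judges rate which items from
legacy instruments measure the same behaviour, which developmental domains
they load on and how feasible they are across cultures; item difficulties come
from a dichotomous Rasch model; and forms are assembled to measure uniformly
across 0–36 months with balanced domain coverage, semantic ordering, and
age-conditional start/stop rules.

## The model

Responses are dichotomous Rasch draws: a child of ability β (D-score units,
one unit = one logit) passes an item of difficulty δ with probability
`plogis(β − δ)`. An age-conditional reference curve `(μ(a), σ(a))` supplies
the development-for-age z-score `DAZ = (β − μ(a)) / σ(a)`, the EAP prior, and
the expected pass-age quantiles `a_p` solving
`E_z[plogis(μ(a) + σ(a)z − δ)] = p` used to place items on the age grid.
Matching judgements on the scale none < partial < strong < very strong are
mapped to {0, 1/3, 2/3, 1} and averaged over judges; equate groups are the
connected components of pairs at or above the strong level (≥ 2/3). Item
difficulties are fitted by marginal maximum likelihood with adaptive
Gauss–Hermite quadrature (conditional and pairwise-conditional estimators are
included as cross-checks; see the methods vignette for why marginal ML is the
default on banks spanning many logits).

## Worked example

```r
library(raschform)
curve <- defaultReferenceCurve()                      # μ(a) = 20·log2(a+1) + 10, σ = 5
bank  <- simulateItemBank(nItems = 200, nConcepts = 98, seed = 1)
bank
#> ItemBank with 200 items
#>   modality: caregiver_report=72, direct_admin=128
#>   difficulty range: [23.63, 114.74] D-score units
#>   latent concepts: 98

## judge panel: match ratings -> coefficients -> equate groups
ratings <- simulateJudgeMatchings(bank, nJudges = 6, errorRate = 0.1, seed = 2)
coef    <- aggregateMatching(ratings)
groups  <- extractEquateGroups(coef)                  # 62 groups over 164 items

## Rasch difficulties from 800 simulated children
responses <- simulateResponses(bank, curve, nChildren = 800, seed = 3)
params    <- fitDifficulties(responses, curve = curve)
#> difficulty recovery: r = 0.9998, RMSE = 0.456 over 200 estimable items
bank <- setEquateGroups(setDifficulties(bank, params), groups)

## assemble a 40-item short form
reps <- selectRepresentatives(groups, bank, modality = "caregiver_report")
form <- assembleForm(bank, "short_form", 40, curve, representatives = reps)
form <- orderItems(form, difficulties(bank))
doms <- setNames(sub("\\..*", "", itemData(bank)$domain), itemIds(bank))
form <- breakStrings(form, doms)                      # no same-domain run > 3
form <- deriveStartRules(form, responses)
startRule(form)
#>   bracket_lower start_index
#> 1             0           1
#> 2             6           6
#> 3            12          10
#> 4            18          16
#> 5            24          22
#> 6            30          26

evaluateForm(form, bank, curve, nChildren = 800, seed = 4)
#> EvaluationReport for sf_proto
#>   DAZ correlation vs full bank: 0.9563
#>   separation reliability:       0.9421
#>   mean items administered:      13.3 of 40
```

The start-rule table says a child entering at 12–18 months begins at item 10
(everything earlier is passed by ≥ 90% of children entering that bracket);
administration stops after five contiguous failures, so a median child answers
about 13 of the 40 items. The form's DAZ correlates 0.96 with scores from the
full 200-item bank. Per-item pass-age quantiles used during selection:

```r
passAgeQuantiles(difficulties(bank)[formItems(form)[20]], curve)
#>     p   age censored
#> 1 0.1 11.83    FALSE
#> 2 0.5 15.23    FALSE
#> 3 0.9 19.54    FALSE
```

`runPipeline(pipelineConfig(seed = 1), "artefacts")` runs every stage —
simulate, judge, fit, assemble, evaluate — writing CSV/JSON artefacts and a
machine-readable audit log of every selection decision; two runs with the same
config are byte-identical. A thin command-line wrapper lives in
`inst/cli/raschform.R`.

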
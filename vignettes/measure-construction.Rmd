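---
title: "Constructing developmental instruments from a Rasch item bank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing developmental instruments from a Rasch item bank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Population-level measurement of early child development (0–36 months) draws on
many legacy instruments whose items overlap heavily: dozens of variants of
"walks without support", "says one word", "copies a circle".  Building a new
short caregiver-reported form and a longer directly administered form from such
an item bank requires (a) aggregating expert judgements about which items
measure the same behaviour, which developmental domains they load on, and
whether they are feasible across cultures and languages; (b) psychometric item
difficulties on a common scale; and (c) assembly rules that turn a ranked item
pool into an administrable instrument with start and stop rules.

`raschform` implements that workflow end to end on synthetic data with known
ground truth, so every stage is testable without any restricted data set:

```{r}
library(raschform)
cfg <- pipelineConfig(seed = 1)
res <- runPipeline(cfg, "artefacts")
```

## The measurement model

Responses are dichotomous and follow the Rasch model: a child with ability
$\beta$ (on the D-score scale, where one unit equals one logit) passes an item
of difficulty $\delta$ with probability
$$P(X = 1 \mid \beta, \delta) = \mathrm{logistic}(\beta - \delta).$$

All derived quantities are standard Rasch machinery: test information
$\sum_i P_i(1-P_i)$, measurement SEM $1/\sqrt{\text{information}}$, person
separation reliability $(\mathrm{var}(\hat\beta) - \overline{\mathrm{SEM}^2}) /
\mathrm{var}(\hat\beta)$, and the development-for-age z-score
$\mathrm{DAZ} = (\beta - \mu(a))/\sigma(a)$, where the *reference curve*
$(\mu(a), \sigma(a))$ gives the median and spread of ability at age $a$ months.

The default synthetic curve is $\mu(a) = 20\log_2(a+1) + 10$ with constant
$\sigma = 5$: monotone, concave (rapid infant gains that slow toward 36
months), and analytically invertible, which keeps closed-form checks of
pass-age quantiles possible.  It is a plausible stand-in for a population
curve, not a reconstruction of any published one.

### Expected pass ages

Item selection is anchored on the ages at which 10%, 50% and 90% of children
would pass an item.  `passAgeQuantiles()` solves
$E_z[\mathrm{logistic}(\mu(a) + \sigma(a)z - \delta)] = p$ by root finding
(31-node Gauss–Hermite quadrature for the expectation); a `median` mode uses
the median child instead, which reduces to $a = \mu^{-1}(\delta +
\mathrm{logit}(p))$ and is the $\sigma \to 0$ limit.  Whether published
pass-age tables marginalise over ability or use the median child is usually
unstated; both modes are exposed and the marginal one is the default, as it
describes the observable population pass rate.  Roots outside the curve span
are censored at the boundary and flagged.

## Fitting item difficulties

`fitDifficulties()` offers three estimators.

* **Marginal maximum likelihood (`mml`, the default)** integrates the person
  parameter against the age-conditional prior $N(\mu(a), \sigma(a)^2)$ using
  *adaptive* Gauss–Hermite quadrature — nodes centred and scaled at each
  child's posterior mode — inside an EM loop accelerated by SQUAREM
  extrapolation.
* **Conditional maximum likelihood (`cml`)** conditions on raw scores and
  maximises the conditional likelihood through log-space elementary symmetric
  functions (an Rcpp kernel, exact to machine precision against brute-force
  subset enumeration).
* **Pairwise conditional (`pairwise`)** maximises the conditional likelihood
  of item pairs given exactly one pass in the pair; it tolerates arbitrary
  missingness and serves as an independent cross-check.

The default deserves explanation, because conditional estimation is the
textbook choice.  A developmental item bank spans the whole 0–36-month range —
roughly a hundred logits under the default curve.  In that regime the data are
near-Guttman: each child is effectively measured by only the handful of items
near their own ability.  Conditioning on raw scores then removes almost all
information about the *global spacing* of the scale: the conditional
likelihood is nearly flat along a stretch of all difficulties away from their
centre, and the CML maximiser can wander many logits along that direction
while remaining a perfectly converged MLE.  Joint (person-and-item) ML
suffers the complementary problem — with about 1.5 informative items per
logit per child, the incidental-parameter bias inflates the scale by
10–20%.  Marginal ML keeps the raw-score information (via the prior) and
recovers the generating difficulties with slope ≈ 1.00 and correlation
> 0.999 at desk scale; adaptive quadrature matters because the ability
posterior (SD ≈ 0.8) is far narrower than the prior (SD 5), so fixed
prior-scaled nodes under-resolve it and shrink the scale by a few percent.

Non-identifiable inputs are handled explicitly: items that nobody passed or
nobody failed are flagged non-estimable; for the conditional methods,
extreme-score children and then-unmixed items are trimmed iteratively (they
carry no conditional information), while marginal ML keeps extreme-score
children — removing them truncates the ability tails and stretches the scale.
A response design whose items split into groups never linked by a pass/fail
contrast is an error naming the components.  Conditional estimates are
identified up to location and returned sum-zero; `anchors` maps them onto a
reporting scale (location shift for one anchor, least-squares affine for two
or more).  Marginal estimates already live on the reference-curve scale, so
the pipeline applies no anchor map.

Ability estimation (`estimateAbility`) offers ML (solves the score equation;
perfect and zero scores are flagged infinite) and EAP under the same adaptive
quadrature (always finite; the pipeline default).  SEM is reported as
$1/\sqrt{I(\hat\beta)}$ over administered items in both cases.

## Aggregating expert judgements

Match ratings on the ordinal scale none < partial < strong < very strong are
mapped to $\{0, \frac13, \frac23, 1\}$ and averaged over judges per item pair.
Only the endpoints of that mapping are substantive; equal spacing is the
maximally uninformative interior choice and the mapping is a function
argument.  A judge's second-pass rating replaces their first-pass rating for
that pair only.  Judges who skipped a pair contribute nothing to its mean —
an unreviewed pair is not a "no match".

Equate groups — clusters of items measuring the same behaviour — are the
connected components of the graph whose edges are pairs with mean coefficient
at or above the strong level ($\ge 2/3$), with components of size one
discarded.  Components (rather than cliques) match the chain-like clusters
seen in practice, where A matches B and B matches C without every A–C pair
being rated strong; a greedy clique mode is available behind `mode =
"clique"` for the stricter reading.

Domain votes are rescaled to weights by dividing by the judge-panel size —
the only denominator that bounds every item and subdomain count
simultaneously — so weights live in $[0, 1]$ and need not sum to 1
(multi-domain items are expected).  The primary domain is the argmax weight,
ties broken lexicographically and flagged.  Subdomain co-ascription is
summarised by Spearman correlations of the per-item vote counts; constant
vote columns have no defined correlation and are reported missing, never
zero.  Feasibility flags are counted per modality-specific criterion set
(directly administered items: translation, adaptation, administration,
materials, other; caregiver-reported: translation, adaptation, caregiver
knowledge, other), with percentages recomputed from the counts.

## Assembling forms

*Representatives.* Within each equate group, the item with the fewest
feasibility concerns is retained; ties go to the shortest descriptor (a proxy
for the simplest, clearest wording), then to the lexicographically first id,
and the deciding reason is recorded in the provenance.

*Selection.* The form is filled greedily over a grid of target median pass
ages spanning 0–36 months, one slot per item: each slot takes the eligible
item whose $a_{50}$ is closest, subject to running domain quotas
$\lceil w_d \cdot n \rceil$.  The grid is age-anchored (rather than
difficulty-anchored) because coverage requirements are stated in ages, and
age spacing is what administrators experience.  At most one item per equate
group is eligible.  Slots with no item within one grid step are reported as
coverage gaps; unmet quotas as shortfalls.  The greedy scheme is a declared
reconstruction — no published objective function trades difficulty uniformity
against domain balance — and the provenance table makes each choice
auditable.

*Ordering.* Items are sorted easiest to hardest, then repaired so that
semantically easier variants precede harder ones ("says 5 words" before
"says 15 words") even where the modelled difficulties disagree.  Instances of
up to 12 items are repaired exactly (the linear extension with the fewest
adjacent transpositions from the difficulty sort, by dynamic programming over
subsets); larger forms use a greedy topological sort emitting the easiest
available item plus an adjacent-swap cleanup.  Exact minimisation over
arbitrary precedence graphs is NP-hard, and in the pipeline precedence pairs
survive only within a concept, so large repairs are rare.

*String breaking (short form).* Because administration stops after
`stop_rule_k` contiguous failures, a long run of same-domain items could end
the assessment for a child weak in that single domain.  Runs longer than
`max_run = 3` are split by moving another-domain item into the run.  The
donor is the nearest item (earlier-positioned — hence easier — preferred)
whose removal does not merge its own neighbours into a new over-long run;
that safety condition is what makes the scan terminate rather than oscillate
between two runs.  Each move is logged; re-running the pass on its own output
is the identity.

*Three-group partition (long form).* Items sharing a material tag form
indivisible blocks assigned greedily (largest first) to the group with the
lowest added cost — an energy-level mixing penalty plus size pressure — under
a size-balance tolerance of 5.  Items without metadata fall back to a domain
heuristic (motor with the movement group, language with the verbal group,
the rest with the table-top group) with a warning.

*Start rules.* For each 6-month age bracket, the start index is the deepest
safe entry point: the last position of the longest prefix of items that at
least 90% of children near the bracket's lower bound (within its first month)
pass empirically.  The "first item that 90% can complete" phrasing is read
from the hard end of the form — under a difficulty-sorted form every item
before a qualifying one also qualifies, so the literal first-position reading
would always return position 1 and could never advance with age.  Brackets
with no children inherit the previous rule with a warning, and indices are
monotonised across brackets so an older child never starts earlier.

*Stop rule.* Administration halts at the fifth contiguous failure
(`stop_rule_k = 5`, configurable); `stopRuleCheck()` is verified against an
exhaustive window scan on all binary strings up to length 12.

## Evaluation

`evaluateForm()` scores a simulated cohort twice — on the form and on the
whole bank — and reports the DAZ correlation between the two, separation
reliability, mean SEM by 3-month age bin (13 bins balance resolution against
sampling noise), the share of test information by domain across age (item
information at $\mu(a)$, apportioned by domain weights and normalised per
age), and administration-length statistics under the start/stop rules.
Items skipped before the start index are treated as not administered —
the conservative default — with an `implicitPass` mode that scores them as
passes, mirroring common basal-rule practice.

## What the generator emulates, and what it does not

`simulateItemBank()` reproduces the *shape* of a real bank: a few hundred
items in latent concepts (the ground truth behind the matching exercise),
facility-ranked variants within concepts, a domain mix dominated by motor
items (45%, with cognition and language at 20% each), both administration
modalities, material tags and energy levels for the long form.  Judge panels
produce ordinal match ratings with symmetric adjacent-level noise, domain
votes through a configurable confusion matrix, and feasibility flags with
material-driven concern rates.  Children have ages uniform on 0.5–36 months
and abilities drawn from the reference curve; responses are exact Rasch
draws.

Passing tests on these data show that the machinery is correct under its own
model.  They do not show robustness to what real data add: differential item
functioning across countries and languages, misfitting items, guessing and
discrimination differences, judge panels with systematic (rather than
symmetric) disagreement, or enrolment age distributions.  Those belong to the
upstream psychometric harmonisation and downstream validation stages, which
are out of scope here.

## Numerical choices and problem sizes

Root finding uses `uniroot` at tolerance 1e-10 on the age axis; quadrature
uses 31 Gauss–Hermite nodes for scoring and pass ages, and 9 adaptive nodes
inside the MML EM loop (adaptive centring makes few nodes sufficient); the
EM stops when the largest difficulty update falls below 1e-4 (well under the
per-item standard error of ≈ 0.2 at desk scale).  Conditional optimisers use
BFGS with analytic gradients at relative tolerance 1e-10.  Ties are broken
deterministically everywhere (lexicographic ids), so identical seeds give
byte-identical artefacts, including the audit log.

The default pipeline runs 200 items in 98 concepts, a 6-judge matching panel
(9 for domains and feasibility), 800 children, and a 40-item short form;
parameter-recovery checks use 2,000 children × 150 items.  These sizes give
stable estimates (difficulty recovery r > 0.999) while keeping a full run
around a minute on one CPU.

## Known limitations

* Difficulty recovery RMSE at desk scale is ≈ 0.35 D-score units, dominated
  by items under ~3 months of age where a uniform-age cohort supplies few
  children per logit; this is close to the information bound
  ($\sqrt{\text{span}/n} \approx 0.23$ at 2,000 children), so only a larger
  or age-stratified cohort, not a better estimator, would reduce it.
* CML is exact but should be confined to narrow difficulty ranges or paired
  with anchoring; its global-stretch flatness on wide banks is intrinsic.
* The matching noise model flips single levels symmetrically; correlated
  judge errors (shared blind spots) are not modelled.
* Free-text feasibility comments are carried verbatim; no text analysis is
  attempted.
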
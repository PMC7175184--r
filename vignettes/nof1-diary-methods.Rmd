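---
title: "Single-subject cutpoint analysis of symptom diaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject cutpoint analysis of symptom diaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1oda)
```

## The problem

People with fibromyalgia and similar multisystem chronic conditions face
highly individual symptom dynamics: the bedtime, drug dosage or exercise
pattern that helps one patient may do nothing for the next. A daily
health diary — nine 0–10 "how bothersome" symptom ratings plus a set of
behavioral and lifestyle attributes over a 24-hour recall — accumulates
enough within-person data that single-subject (N-of-1) inference becomes
possible. `nof1oda` implements that analytic chain: it searches each
user's diary for statistically significant threshold rules of the form
*"symptom S tends to be better on days when attribute A is at or below
(at or above) some cutpoint"*, renders the significant rules as
personalized recommendation statements, and provides the longitudinal
apparatus (FIQ scoring, cumulative use indices, pooled Kendall tau-b)
for evaluating whether program use tracks functional improvement.

## The cutpoint model

For one (attribute, symptom) pair the engine works on same-day pairs
$(x_i, r_i)$, $i = 1 \dots n$: attribute value and 0–10 rating from the
same diary entry. Days with either value missing are dropped, never
imputed.

**Dichotomization.** The 0–10 ratings are split at the user's own
median for that series: day $i$ is labelled *improved* iff
$r_i < \mathrm{median}(r)$. Ties at the median count as *not improved*.
The split is scale-free (a user who hovers between 6 and 8 is analysed
on their own terms) and tends to balance the two classes. A constant
series is degenerate and no model is attempted. This is a documented
package choice: the two-class framing is inherent to the method, but
the exact dichotomization rule of the original proprietary program is
not public.

**Search.** Candidate cutpoints are the midpoints between consecutive
distinct sorted attribute values ($k$ distinct values give $k-1$
candidates). Every candidate is scored in both directions (`le`:
improvement predicted when $x \le c$; `ge`: the mirror) by the mean of
the two per-class sensitivities — the class-weighted objective of
optimal discriminant analysis, which is insensitive to class imbalance.
The maximizing rule is returned; ties are broken toward the smaller
cutpoint, and at the same cutpoint toward `le`. The effect strength for
sensitivity rescales the objective to a 0–100 effect scale:
$\mathrm{ESS} = 100\,(\bar S - 0.5)/0.5$, with 0 at chance and 100 at
perfect separation.

**Inference.** The test statistic is the *best achievable* mean
sensitivity over all rules, and its null distribution is obtained by
permuting class labels with class sizes fixed. When
$\binom{n}{n_1} \le 200{,}000$ the engine enumerates all distinct
assignments exactly; otherwise it Monte-Carlos label permutations
(default 10,000), counting the observed arrangement in both numerator
and denominator so $p$ is never zero. Both routes are deterministic
given a seed. Significance is judged per comparison at $\alpha = .05$,
matching the original program's stated operating point; a Šidák
adjustment across the scanned pairs is available behind an option but
off by default. Models are only attempted when both classes have at
least `min_per_class = 5` members — below that, permutation resolution
and rule stability are too poor to act on.

## Recommendation statements

Significant models become statements through a fixed template:
`"My {symptom} will improve if my {noun} is {phrase} {threshold}"`,
e.g. *"My pain will improve if my bed time is no later than 9:40 pm"*.
The threshold quoted is the **observed** attribute value on the
favorable side of the cutpoint (not the midpoint), so statements name
realizable behaviors. Clock-time attributes are encoded as continuous
hours after noon — so bedtimes spanning midnight form one monotone
scale without wraparound — and rendered back as `h:mm am/pm`; durations
render in minutes; personal inputs carry their registered units.

Statement generation is gated on 22 completed logs, the pilot-derived
minimum for a first statement. Re-issues that match a previous
statement in (symptom, attribute, direction) replace it in place with a
refreshed threshold and keep the original issue date, so the cumulative
statement count — one of the two use indices — grows only when a
genuinely new rule appears.

## FIQ scoring

The Fibromyalgia Impact Questionnaire yields ten subscales, each
normalized to 0–10: the mean of the answered 0–3 physical-functioning
items times 10/3; "days felt good" reversed as $(7-d)\times 10/7$;
missed-work days as $d \times 10/7$; and the seven 0–10 visual analog
scales taken directly. The total is the available-subscale sum rescaled
by $100/(10\,n_\text{valid})$, which handles respondents not working
outside the home (their two work items are skipped) by rescaling rather
than penalizing. Descriptions of the instrument fix its items but not one
canonical arithmetic; this package uses the original published scoring
convention and keeps the subscale construction inspectable in the
returned object. Severity bands follow the established criteria:
total $\le 38$ mild, $38 < t \le 58$ moderate, $> 58$ severe.

## The synthetic cohort generator

No diary corpus ships with the package, so every stage is exercised
against a generator whose defaults encode the study conditions the
package targets:

* **Skewed use.** Total log counts are log-normal (meanlog 1.61,
  sdlog 1.45, truncated at 1), calibrated so that roughly 15% of
  simulated applicants reach the 22-log gate, moderate users (22–47
  logs) average ~32 logs and heavy users (≥ 48) average ~100, with
  logging gaps of 1–4 days and an 11-month (330-day) window.
* **Planted rules.** Three behavioral attributes drive all nine
  symptoms (late bed time worsens pain, stiffness, fatigue and memory;
  exercise lifts mood, anxiety and concentration; yoga improves sleep
  and digestion), with effects of 1.5–3 rating points on days a rule is
  violated. Spreading the effects across all nine outcomes mirrors the
  broad use-linked symptom improvement reported for the program, and
  calibrates the included cohort to a baseline FIQ near 61 with a
  double-digit percent drop among the heaviest users.
* **Realistic noise.** Ratings are user baseline + planted effects +
  AR(1) noise (stationary SD 1.5, day-to-day correlation 0.3), rounded
  and clipped to 0–10.
* **Closed loop.** As logs accrue past the gate, the *real* discovery
  engine is re-run (every 14 logs, with 200 Monte Carlo permutations —
  a p-resolution of ~0.005, ample for $\alpha=.05$ decisions inside the
  generator; the user-facing default remains 10,000) and issued
  statements can change behavior: a user adopts advice about an
  attribute with probability 0.8, after which 80% of days draw that
  attribute from the favorable side of the recommended threshold.
* **Outcome coupling.** FIQ visual-analog items are the trailing-week
  mean of the matching symptom plus unit noise; feel-good and
  missed-work days move with the overall symptom mean;
  physical-function items are user-level constants plus noise. A
  baseline FIQ is administered at the first log and a follow-up every
  30 days of use. Compliance therefore lowers symptoms, which lowers
  FIQ — the simplest causal chain consistent with the program's
  narrative.

`null_mode = TRUE` zeroes every planted effect, giving
behavior-independent symptoms for calibration studies, and
`require_included = TRUE` rejection-samples log counts to the 22-log
gate, emulating the *included* analysis sample directly.

What the generator does **not** emulate: dropout mechanisms and their
reasons, demographic structure, comorbidities, measurement reactivity
(diary-keeping itself changing symptoms), seasonal or weekly
periodicity, and any lagged or cumulative behavior effects — planted
rules act same-day only, matching the engine's same-entry pairing.
Passing tests on this cohort therefore demonstrate that the machinery
recovers the kinds of structure it models, not that real diaries
contain such structure.

## Longitudinal evaluation

Each FIQ administration becomes one row of a pooled table carrying the
FIQ total and the user's cumulative log and statement counts at that
timestamp; baselines are included by default (a flag restricts to
follow-ups). Association is measured by Kendall tau-b,
$\tau_b = (C - D)/\sqrt{(n_0 - t_x)(n_0 - t_y)}$ with the usual tie
corrections, computed via a merge-sort discordance count, and tested
two-tailed with the tie-adjusted normal approximation — appropriate at
pooled-table sizes of several hundred rows where exact enumeration is
infeasible.

**Statistical caveat, stated rather than silently fixed:** pooling
repeated FIQ rows across users ignores within-user correlation.
Because users differ in baseline severity, pooled rows are clustered,
and the normal-approximation test is mildly anticonservative under the
null — in the package's own null-mode calibration at 76 included users
the rejection rate ran around 10% rather than 5%. The pooled analysis
is retained as the primary evaluation because it is the design being
reproduced; a per-user tau-b (computing the statistic within each user
and inspecting the distribution) is available by grouping the pooled
table, and a mixed-model re-analysis is explicitly out of scope.

## Numerical and design choices

* Same-entry pairing: an entry's behaviors are related to the same
  entry's ratings (bedtime "previous night" is part of the entry's
  24-hour recall). Whether the original program used lags is unstated;
  no cross-day lags exist in this version.
* Clock anchor at noon, so the 24-hour encoding window splits at the
  time of day least likely to bisect a sleep-related attribute.
* Cutpoint tie-breaks (smaller cutpoint, then `le`) are fixed so that
  refitting identical data reproduces identical rules; floating-point
  comparisons carry a $10^{-12}$ guard, far below the $1/(2 n_1 n_0)$
  spacing of achievable objective values.
* The Monte Carlo permutation screen inside the pair scan stops early
  once 30 exceedances are seen (Besag–Clifford sequential estimate);
  such p-values are necessarily $\ge 0.15$-scale and cannot flip an
  $\alpha = .05$ decision.
* Degenerate inputs fail loudly and specifically: constant ratings
  (degenerate outcome), a single distinct attribute value (no
  candidates), undersized classes, all-tied tau inputs, baseline-zero
  percent drops.
* Problem sizes used by the test suite, chosen as the package's
  standing verification conditions: 200 random instances ($n \le 30$,
  tied attributes) for cutpoint-oracle equivalence; exact-vs-Monte-
  Carlo agreement at $n \le 12$ with 10,000 replicates; permutation
  null calibration over 1,000 seeded series of length 30; planted-rule
  recovery over 100 seeded series of 60 pairs (effect 3 points, noise
  SD 1.5, 15-minute attribute resolution); tau-b oracle equivalence on
  500 tied vectors ($n \le 50$); and 100 + 100 replicate cohorts of 76
  included users for the pooled-association direction and its null
  calibration.

## Known limitations

* Univariable rules only: no multivariable or tree-structured
  discriminant models, and no jackknife/LOO validation of fitted rules.
* Per-comparison $\alpha$ by default mirrors the original operating
  point but inflates family-wise error across the attribute × symptom
  scan; enable the Šidák option when rigor matters more than fidelity.
* The pooled evaluation inherits the clustering caveat above.
* The attribute registry ships with the original compact catalog;
  expanded symptom/attribute catalogs load through the registry
  configuration but are not enumerated here.
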
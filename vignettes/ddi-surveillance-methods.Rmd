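---
title: "Methods: population-scale surveillance of co-administered drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale surveillance of co-administered drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiprev)
library(data.table)
```

# The problem

Dispensation registries record which drugs a patient received and for how
long, but not whether pairs of drugs known to interact were taken at the
same time. `ddiprev` turns longitudinal dispensation tables into
population-level measures of that co-administration burden: who is exposed
to known drug–drug interactions (DDIs), how exposure differs by gender and
age, how much of it is an unavoidable consequence of polypharmacy, which
drug pairs dominate, and how much exposure a concrete substitution policy
could remove.

The pipeline works at two temporal resolutions, matching the two kinds of
registries in circulation: *daily* (dispensation date plus an administration
length in days) and *monthly* (billing months only).

# Episodes and the pairwise measures

For patient $u$ and drug $i$, the distinct administration intervals after
merging are $A_i^u$, their count $\alpha_i^u = |A_i^u|$, and the total
administered time $\lambda_i^u = \sum a^{i,u}$ (distinct calendar days, or
billing months). Two drugs are *co-administered* when their day sets share
at least one day (daily) or when both are billed in the same month
(monthly). Per patient and pair, $\alpha_{i,j}^u$ counts the maximal runs
of consecutive shared days and $\lambda_{i,j}^u$ the total shared time; at
monthly resolution $\alpha_{i,j}^u = \lambda_{i,j}^u$.

Two deliberate conventions shape these counts:

* **Half-open day intervals.** A record starting on day $s$ with duration
  $d$ covers $[s, s+d)$. Lengths and overlaps are then plain integer
  arithmetic with no fencepost ambiguity; two intervals co-occur only when
  they share a full calendar day.
* **Same-drug refills merge, including abutting ones.** A refill dispensed
  the day a previous supply runs out continues one treatment episode, so
  $\lambda_i^u$ counts distinct days rather than dispensed quantity.
  Merging is idempotent and independent of row order. Whether refills
  should merge at all is a genuinely open choice for this kind of data; we
  merge because co-administration is a calendar phenomenon, and
  double-counted days would inflate both $\lambda$ and the strength
  measure below.

**Conditional likelihood.** For a pair $(i,j)$,
$\gamma_{i,j} = |U_{i,j}| / |U_i|$ is the probability that a patient on
drug $i$ also co-administers $j$; it is directional, and the direction
conditioned on the rarer drug is always the larger. The identity
$\gamma_{i,j}\,|U_i| = \gamma_{j,i}\,|U_j| = |U_{i,j}|$ holds exactly and
is asserted in the test suite.

**Strength of co-administration.** Per patient,
$$\tau_{i,j}^u = \frac{\lambda_{i,j}^u}{\lambda_i^u + \lambda_j^u - \lambda_{i,j}^u},$$
the shared time over the union of administered time (a temporal Jaccard
index). We adopted this denominator, rather than the symmetric difference
that a literal reading of "duration of separate administration" might
suggest, because the measure must live in $[0,1]$ and reach 1 exactly at
complete temporal overlap — the symmetric-difference form divides by zero
there. $\tau$ is symmetric, monotone in overlap at fixed union, and its
cohort mean $\tau_{i,j}^\psi$ weights the edges of the co-administration
graph.

# Prevalence, stratification, relative risks

*Prevalence of co-administration* (PC) is the fraction of patients with at
least one co-administered pair; *prevalence of interaction* (PI) the
fraction with at least one co-administered pair present in the interaction
reference. The denominator of every stratum is the number of patients with
at least one administration in that stratum: these registries define their
population by drug events, not enrolment.

Age is computed in completed years at the date of the drug event and mapped
to 5-year bins (`0-4` … `85-89`, `90+`); because the data are longitudinal,
one patient legitimately contributes to several bins. Severity strata
(major/moderate/minor) are non-exclusive — a patient with one major and one
moderate interaction counts in both — and `any` pools them.

The relative risk for women of co-administration (RRC) or interaction
(RRI) is the ratio of the two gender-specific prevalences, with a
two-sided Fisher exact test on the gender × affected table. Multiplicity
across the strata of one report is controlled with Benjamini–Hochberg FDR
at 0.05 by default; Bonferroni is available (`correction =` argument)
for the more conservative reading. Relative risks are displayed at two
decimals in report tables, but all stored tables keep full precision.

# The polypharmacy-preserving null model

PI rises with age, but so does polypharmacy; the null model asks how much
of the rise the pair counts alone explain. Within each age bin, every
patient keeps their observed number of distinct drugs and of
co-administered pairs, while the drug identities are randomized within the
bin. Randomized pairs are then looked up in the same interaction
reference; the expected PI per bin is averaged over replicates (100 by
default), and the observed-vs-null disparity is summarized by an odds
ratio with a Fisher exact test, pooling patient outcomes across
replicates (per-replicate odds ratios are also emitted).

Three sampling modes are provided:

* `label_shuffle` (default) permutes the bin's observed patient–drug
  occurrences, repairing within-patient duplicates by random swaps. It
  preserves each patient's distinct-drug count *and* each drug's
  occurrence total exactly — a drug-label shuffle that respects
  cohort-specific drug availability.
* `frequency_weighted` redraws each patient's set without replacement with
  probabilities proportional to the drugs' observed patient counts in the
  bin.
* `uniform_distinct` draws uniformly over the bin's distinct drugs.

We made the shuffle the default after a calibration experiment the
frequency-weighted mode fails: under heavy-tailed drug popularity, weighted
sampling *without replacement* saturates popular drugs for high-count
patients, so feeding marginal frequencies back as weights yields a
redistribution flatter than the observed one. That mismatch interacts with
the sparse, randomly placed interaction reference and inflates the
seed-to-seed variance of the odds ratio on data where it should be 1. The
shuffle preserves both margins by construction and centers the odds ratio
at 1; the acceptance suite verifies this on twenty independent cohorts of
20,000 patients.

Details that matter for reproduction: the `all`-ages row is computed as
its own stratum (distinct drugs and pairs per patient over the whole
window, pool = all observed drugs) rather than by unioning per-bin draws —
a pair whose runs span two bins would otherwise get two chances in the
null but one in the observed count, biasing the odds ratio downward by a
few percent. A patient whose observed pair count exceeds
$\binom{d}{2}$ for their bin (possible when a run starts in a later bin
than the drug records) is capped at $\binom{d}{2}$ with a logged count.
Each replicate draws from an independent seeded substream, so results are
reproducible per (seed, replicate) and replicates can be recomputed in
isolation.

# The interaction network

Observed interacting pairs are tested for co-usage enrichment: a 2×2 table
of (administered $i$) × (administered $j$) over the population, whose joint
cell is the number of concomitant co-users, gives a one-sided
hypergeometric (Fisher) p-value for more co-administration than
independence of the user sets would produce. The one-sided alternative is
deliberate — only over-co-administration is flagged. Both BH q-values and
Bonferroni-adjusted p-values are emitted; the edge criterion is FDR
≤ 0.05. The network keeps only significant pairs: nodes carry
`node_risk` $= |U_i^\phi| / |U_i|$ (distinct patients in the union over
the drug's significant pairs, divided by the drug's users), edges carry
$\tau$ (width), severity, and the pair's gender relative risk, stored
unclipped alongside a display copy of the dominant-gender relative risk
clipped to $[1, 5]$. Export is GraphML (typed attributes, round-trip
tested) or a flat edge list, with an optional minimum-$\tau$ display
filter. Patient margins are counted over the whole window; restricting
margins to age-eligible periods would be a different (and less
reproducible) population definition.

# The substitution intervention

Given a target drug and a class of interchangeable alternatives, every
administration episode of the target that overlaps an interaction partner
is examined. Alternatives are ranked once — ascending count of known
interactions in the reference, ties broken lexicographically by drug id —
and the first whose reference interactions are disjoint from *all* drugs
concurrently administered during that episode replaces the target in the
underlying records (same dates, same durations). Episodes with no safe
alternative are kept and the blocking drugs recorded. The scope of the
safety check equals the co-administration definition (≥ 1 shared day or
month). Substitution is per episode, so a patient can keep the target in
one episode and lose it in another; we also considered global (all
administrations) replacement and chose per-episode as the more
conservative intervention — only situations with an actual interaction are
touched. Replacement cannot create a new interaction by construction
(checked exhaustively in the tests), so stratum PI never increases; the
report gives PI before/after, relative reduction, and the number of
patients freed of all known interactions.

# The synthetic cohort generator

Real dispensation registries are not publicly shareable, so the package
ships a generator that reproduces the statistical structure the analysis
relies on, with one master seed feeding named substreams (population,
reference, dispensations, each planted effect) so any table can be
regenerated independently.

| parameter | default | why |
|---|---|---|
| `n_patients` | 10,000 | large enough for stable stratum estimates at test scale |
| `gender_ratio` | 0.5 | balanced two-gender cohort |
| `age_range` | 0–90 years | full lifespan, uniform at window start |
| `n_drugs` | 200 | municipal-formulary order of magnitude |
| `popularity_exponent` | 1.0 | Zipf-like rank law; a few hub drugs dominate co-administrations |
| `mean_drugs` | 3 | distinct drugs at age 0 |
| `polypharmacy_slope` | 0.4 /decade | mean distinct drugs grows with age; negative binomial (`drug_count_dispersion` = 2) for the overdispersion real counts show |
| `mean_duration_days` | 30 | month-scale treatments (geometric) |
| `mean_dispensations` | 3 | refills per patient-drug (1 + Poisson) |
| `ddi_fraction` | 0.015 | sparse reference; yields interaction prevalences in the low-teens percent at 18 months, the magnitude population registries report |
| `severity_probs` | 0.25/0.55/0.20 | moderate interactions most common |
| `gender_specific_fraction` | 0.02 | contraceptive-like drugs restricted to one gender |
| `planted_base_rate` | 0.1 | co-dispensation rate of a controlled pair channel |

The study window defaults to 18 months of daily resolution; monthly mode
maps each day interval to its covered billing months.

**Planted effects** give a drug pair a known ground truth: the generator
removes the pair's natural overlaps, then grants every patient a single
co-dispensation event (both drugs, one shared interval) with probability
`planted_base_rate`, multiplied by `risk_multiplier` in the matching
gender/age stratum. The stratum's relative rate therefore equals the
multiplier in expectation, a multiplier of 0 empties the stratum exactly,
and the rate is monotone in the multiplier — the properties the
parameter-recovery tests assert.

**What the generator does *not* emulate** — and hence what passing tests do
not certify about real data: comorbidity-driven correlations between
drugs (drug identities are conditionally independent given the popularity
law), seasonal or calendar prescribing patterns, adherence gaps between
dispensation and administration, formulary changes over time, and any
fitting of real registries' marginals. In particular, because drug
co-usage is generated independent of the interaction reference, the
co-usage enrichment network on default synthetic data is expected to be
(near-)empty; network behaviour is exercised by constructed fixtures with
genuine enrichment.

# Validation design and problem sizes

The suite validates each stage against an independent route: episode
detection against a brute-force oracle that materializes every
(patient, drug, day) triple (500 randomized instances of ≤ 20 patients,
≤ 8 drugs, ≤ 60-day windows); the enrichment p-value against
`fisher.test(alternative = "greater")`; the published relative-risk grid
against the ratio-of-prevalences formula with tolerances propagated from
the inputs' printed precision; null-model calibration and planted-effect
recovery on twenty independent cohorts of 20,000 patients each (100
replicates for the null). The gender-null calibration of the Fisher test
uses 200 cohorts of 500 patients. These sizes were chosen so each
statistical check has clear power while the whole suite stays
desk-runnable.

# Known limitations

* Dispensation length is taken as administration length (worst-case
  exposure); early discontinuation is invisible.
* Within-day timing is unobservable, so interactions avoidable by
  separating intakes during the day are counted as exposure.
* The interaction reference is treated as fixed truth; its own coverage
  bias propagates to PI.
* Monthly resolution overstates overlap relative to daily (any shared
  billing month counts), so cross-resolution comparisons need care.
* The substitution simulation ignores dose equivalence, availability and
  cost; it bounds what prescription-switching alone could achieve.
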
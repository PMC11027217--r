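# ddiprev

Population-scale surveillance of co-administered drug–drug interactions
(DDIs) from longitudinal dispensation records.

Pharmacoepidemiologists and health-system analysts hold registries that say
*which* drugs each patient received and for how long — but not how often
pairs of drugs known to interact were actually taken together, who bears
that exposure, and how much of it is avoidable. `ddiprev` answers those
questions end to end:

* **Episode detection** — per patient and unordered drug pair, maximal runs
  of shared administration days (daily data) or shared billing months
  (monthly data), after merging same-drug refills into treatment episodes.
* **Pairwise statistics** — the directed conditional likelihood
  γᵢⱼ = |Uᵢⱼ|/|Uᵢ| (how often users of *i* also co-administer *j*) and the
  strength of co-administration
  τᵢⱼᵘ = λᵢⱼ/(λᵢ + λⱼ − λᵢⱼ) ∈ (0, 1], a temporal Jaccard index that is 1
  at complete overlap.
* **Stratified prevalence** — prevalence of co-administration (PC) and of
  interaction (PI) by gender, 5-year age bin (age at the drug event; a
  patient may appear in several bins) and interaction severity, with
  relative risks for women (RRC, RRI) tested by two-sided Fisher exact
  tests under Benjamini–Hochberg FDR control.
* **Polypharmacy null model** — expected PI per age bin when drug labels
  are shuffled within the bin, preserving each patient's distinct-drug and
  co-administered-pair counts and each drug's occurrence total; observed vs
  expected compared by odds ratios.
* **Interaction network** — the graph of known-DDI pairs whose co-usage is
  enriched beyond independence of the user sets (one-sided Fisher test,
  FDR ≤ 0.05), with node risk P(Uᵢᵠ), τ edge weights and per-pair gender
  relative risks; GraphML/edge-list export.
* **Substitution intervention** — counterfactual replacement of a target
  drug (e.g. an over-prescribed proton-pump inhibitor) by same-class
  alternatives free of interactions with each episode's concurrent drugs,
  and the resulting reduction in PI.
* **Synthetic cohort generator** — EHR-like populations with age-increasing
  polypharmacy, Zipf drug popularity, gender-specific drugs, a sparse
  severity-labelled interaction reference and plantable pair effects, so
  the whole pipeline is testable without patient data.

## Worked example

```r
library(ddiprev)

cfg   <- synthetic_config(n_patients = 5000, seed = 42)   # 18-month daily window
pats  <- generate_population(cfg)
recs  <- generate_dispensations(pats, cfg)
ddi   <- generate_ddi_reference(cfg)
cls   <- generate_drug_classes(cfg, ddi)

runs  <- coadmin_runs(recs, ddi, cfg$window)
prev  <- compute_prevalence(runs, recs, pats)
prev[gender == "all" & age_bin == "all"]
#>    gender age_bin severity n_patients n_coadmin n_interact        pc         pi
#> 1:    all     all      any       4545      3473        533 0.7641364 0.11727173
#> 2:    all     all    major       4545      3473        132 0.7641364 0.02904290
#> 3:    all     all    minor       4545      3473         93 0.7641364 0.02046205
#> 4:    all     all moderate       4545      3473        400 0.7641364 0.08800880
```

Of the 4,545 patients with at least one dispensation, 76.4% co-administered
two or more drugs (PC) and 11.7% were exposed to at least one known
interaction (PI), 2.9% to a major one. The gender comparison:

```r
rr <- gender_relative_risks(prev)
rr[age_bin == "all" & measure == "interaction" & severity == "any"]
#>    age_bin severity     measure    prev_w    prev_m rr_women    rr_men   p_value
#> 1:     all      any interaction 0.1192171 0.1153679 1.033365 0.9677126 0.7122937
```

RRI ≈ 1.03: women's interaction prevalence is 3% higher, not significant
here — as expected, since this synthetic cohort plants no gender effect.
The null model asks whether the observed PI exceeds what the cohort's
polypharmacy alone would produce:

```r
nm <- run_null_model(recs, pats, ddi, cfg$window, null_model_config(n_reps = 50, seed = 42))
nm$summary[age_bin %in% c("70-74", "all"),
           .(age_bin, observed_pi, expected_pi_mean, odds_ratio, p_value)]
#>    age_bin observed_pi expected_pi_mean odds_ratio   p_value
#> 1:   70-74   0.1307190        0.1510458  0.8451896 0.3743308
#> 2:     all   0.1172717        0.1232431  0.9451109 0.2358087
```

Odds ratios near 1 (synthetic dispensation is random with respect to DDI
status); in real registries this comparison is where worse-than-random
prescribing shows up. Finally, substituting the hub drug by its safest
same-class alternative wherever that avoids an interaction:

```r
hub  <- attr(cls, "hub_drug")
plan <- plan_substitutions(recs, hub, cls, ddi, cfg$window)
rep  <- apply_and_recompute(recs, pats, ddi, cfg$window, plan)
rep$strata[severity == "any"]
#>    gender severity n_patients pi_before  pi_after relative_reduction
#> 1:      M      any       2297 0.1153679 0.1049195         0.09056604
#> 2:      W      any       2248 0.1192171 0.1107651         0.07089552
#> 3:    all      any       4545 0.1172717 0.1078108         0.08067542
rep$n_patients_freed
#> [1] 43
```

Substitution frees 43 patients of all known interactions and lowers overall
PI by 8.1%, without ever creating a new interaction.

A thin command-line front end over the same functions is installed at
`inst/cli/ddi.R` (`synth`, `run`, `compare` subcommands).

## Vignette

`vignettes/ddi-surveillance-methods.Rmd` documents the measures and their
conventions (half-open intervals, refill merging, the Jaccard form of τ),
the null model's sampling modes and why the label shuffle is the default,
the enrichment test behind the network, the substitution rules, the
synthetic generator's parameters, and what the generator deliberately does
not emulate.
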
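---
title: "Validating discharge-database detection of complicated ectopic pregnancy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating discharge-database detection of complicated ectopic pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepsbvalid)
```

## The model

A hospital stay is a pair: a chart-review abstract (the gold standard) and a
coded discharge record. The gold standard classifies a stay as a complicated
ectopic pregnancy with severe bleeding (CEPSB) when the ectopic pregnancy is
confirmed by histology **and** at least one complication is present: tubal
rupture seen at laparoscopy, a hemoperitoneum of 500 cc or more (the
threshold is inclusive at exactly 500), or active bleeding. Everything else —
spontaneous abortion, ruptured ovarian cyst, bleeding intra-uterine
pregnancy, uncomplicated ectopic pregnancy, pelvic infection — is a
non-case.

A detection algorithm is a conjunction of an administrative filter (female,
age 18–45 inclusive, study year, gynecology unit) and code-set clauses, each
clause an OR over codes in a scoped field (main diagnosis only, associated
position only, any diagnosis position, or procedures). Detection performance
against the gold standard is summarized by

$$\mathrm{Se} = \frac{TP}{TP+FN}, \qquad
  \mathrm{Sp} = \frac{TN}{TN+FP}, \qquad
  \mathrm{LR}^+ = \frac{\mathrm{Se}}{1-\mathrm{Sp}}.$$

## Statistical choices

**Confidence intervals.** The source tables we reproduce print intervals
consistent with the Wald normal approximation for proportions,
$p \pm 1.96\sqrt{p(1-p)/n}$ clipped to $[0,1]$, and with Simel's log-method
interval for the likelihood ratio,
$\exp\!\big(\ln \mathrm{LR}^+ \pm 1.96\,\sqrt{1/TP - 1/(TP+FN) + 1/FP -
1/(FP+TN)}\big)$. Both reproduce the printed bounds at one decimal in 7 of 8
cases; the remaining two bounds (a specificity upper bound printed 97.5
where Wald gives 97.1, and an LR lower bound printed 7.2 where the log
method gives 7.15, which still rounds to 7.2 under half-up) we treat as
display artifacts. A Wilson option is available (`method = "wilson"`)
because Wald is known to undercover at extreme proportions; the default
stays Wald to match the reference display. Displayed percentages round
*half-up* to one decimal (`round_half_up()`), not banker's rounding.

**Degenerate cells.** With $FP = 0$ the LR+ is infinite; we report `Inf`
flagged as degenerate together with a Haldane-corrected finite companion
(0.5 added to every cell). With $TP = 0$ the LR+ is 0 with an undefined CI,
flagged.

**Association tests.** Per-code screening uses the two-sided Fisher exact
test in the point-probability convention (sum of all tables with the
observed margins whose probability does not exceed the observed table's),
implemented in-package on the hypergeometric density and verified in the
test suite against an independent `choose()`-ratio enumeration oracle and
against the reference implementation. Two-center comparisons use Fisher when
any expected cell is below 5 and otherwise the chi-square test without
continuity correction; both branches are exposed explicitly via
`compare_centers(..., test = )` because the borderline table 10/28 vs 2/24
(every expected cell ≥ 5.5) is quoted in the source as a Fisher value —
both tests print 0.02 there.

**Code-level LR+ in screening** adds 0.5 to all four cells when the code is
absent from one class entirely (Haldane–Anscombe), since otherwise perfectly
discriminative codes have undefined or infinite ratios. Selection requires
`p < 0.05` **and** `LR+ > 4`, both strict; no multiple-testing correction is
applied because the selection rule is a fixed published procedure being
reproduced, not re-designed. Screening runs over *all* analyzable stays, not
only stays flagged by the guideline algorithm: restricting to flagged stays
(exposed as a possible variant) would make sensitivity improvement
impossible, since codes absent from the flagged subset could never enter.

## The synthetic world

The original hospital records are not deposited, so the generator
(`generate_cohort()`) emulates the study population as a *stated world*:

- 370 stays (230 center A, 140 center B), 52 CEPSB (28 / 24) — counts are
  **fixed, not sampled**, so validation statistics carry no prevalence
  noise;
- age ~ Normal(32.0, 6.6²) truncated to [18, 45]; stay duration ~ log-normal
  moment-matched to mean 2.21, SD 1.7 days (the source reports only
  mean ± SD; log-normal is the standard positively skewed choice for length
  of stay);
- CEPSB complication profiles: tubal rupture 45%, hemoperitoneum-dominant
  30% (volume 500 + Exp(350) cc, i.e. always above the case threshold),
  active-bleeding-dominant 25% — a mix consistent with reported rupture
  rates in surgically managed ectopic pregnancies; transfusion is implied
  deterministically by massive bleeding (≥ 1500 cc, or ≥ 1000 cc with
  rupture and active bleeding) so the audit can recompute it from the
  abstract;
- non-CEPSB composition: spontaneous abortion 40%, uncomplicated ectopic
  19% (a quarter of them managed surgically — these are the stays that
  *correctly coded* still trip the practice-based algorithm, mirroring the
  reference study's 17 false positives), cyst rupture 15%, intra-uterine
  bleeding 15%, pelvic infection 8%, other 3%. The source does not report
  this composition; it was chosen once on clinical grounds and is not a
  tuning dial.

`ideal_coding()` writes the record a guideline-perfect coder would produce.
For CEPSB: main diagnosis O00.1 (tubal; ~95% of ectopics — site variants
are supported but not drawn), one associated code per observed complication
(K66.1 hemoperitoneum, O08.1 haemorrhage, O08.6 pelvic-organ damage for
rupture, Z51.3 transfusion), plus D62 (acute posthaemorrhagic anaemia,
present in any severe-bleeding stay), and an EP-specific procedure. By
construction the guideline algorithm achieves Se = Sp = 1.0 on an
uncorrupted cohort — a tested invariant that anchors everything downstream:
any misclassification after injection is attributable to injected errors.

### Error injection

`inject_errors()` applies a nine-type error taxonomy with independent
per-stay Bernoulli draws, at most two errors per stay (applied and truncated
in taxonomy order), from a single seeded stream consumed in (stay,
error-type) order with a fixed number of draws per stay — so the stream
position never depends on what fired, and injection is exactly reproducible.
`calibrate_default_model()` sets each probability to printed-count /
eligible-stratum (e.g. 19/52 for a missing associated diagnosis, 3/318 for
excess coding on non-cases).

Two design rules make the ground truth recoverable:

1. **Distinct signatures.** "Absent associated diagnosis" empties the
   associated list entirely; "absent complication code" deletes only
   complication-family codes, leaving the ever-present D62. The audit can
   therefore tell them apart deterministically.
2. **Masking.** A drawn mutation that would not change the record (deleting
   a complication already gone; marking an already-mutated stay uncoded;
   replacing a main diagnosis that is no longer an EP code) is *masked*:
   neither applied nor logged. Consequently the audit recovers the error
   log **exactly** (a tested invariant), at the price that realized counts
   for the dependent types sit below their printed tallies by the
   documented masking factors; the injection test uses the masking-aware
   binomial expectation.

### What a green test does and does not establish

Green unit and property tests establish: the statistics reproduce the
printed reference values at printed precision; evaluation equals a
brute-force oracle; the Fisher test equals exhaustive enumeration; the
generator is deterministic and exact in its counts; the audit recovers
injected ground truth without false discovery.

They do **not** establish that the synthetic world reproduces the reference
study's end-to-end operating points — and it measurably does not. The study
observed 46 false-negative-side error instances spread over ~40 missed
cases (≈1.15 errors per stay: strongly anti-correlated, almost one error
per failing coder-stay). Independent Bernoulli injection with the same
marginal rates concentrates the same number of instances onto ~33 of 52
stays, because
$52\,(1 - \prod_i (1-p_i)) \approx 33$. The guideline algorithm's expected
synthetic sensitivity is therefore ≈ 36% against the study's 23.1%, and the
practice-based algorithm's ≈ 78% against 63.5% (only procedure,
administrative, uncoded and main-diagnosis errors can break it). No
independent per-type model with these calibrated marginals can reach the
study's point values; reproducing them would need an explicit negative
dependence ("every erring coder makes exactly one mistake") that the stated
design (independence, cap of two) excludes. The corresponding
distributional acceptance check is deliberately left failing rather than
silently recalibrated, and the acceptance report prints the honest
synthetic means.

## Degenerate inputs and numerical conventions

- Stays without an available medical record are carried in files
  (`record_available = false`), never classified, and dropped — with a
  count — by every analysis stage, mirroring the 15/385 excluded charts.
- An uncoded stay is a missing main diagnosis with empty code lists; any
  other combination is rejected at cohort construction, as are duplicate
  stay ids, malformed codes, negative durations, and a main diagnosis
  repeated in the associated list.
- ICD-10 codes are stored dot-free and re-dotted only for display
  (`format_icd10()`); comparison is exact string equality within a coding
  system. Wildcards/ranges are unsupported by design — the reference
  algorithms enumerate codes explicitly.
- Report files round half-up to one decimal at render time only; CSVs and
  in-memory objects carry full precision; cohort files print doubles with
  17 significant digits so write→read round-trips are bit-exact.
- All screening/selection ties break conservatively: `LR+ = 4.0` exactly is
  *not* selected, `p = α` is *not* significant.

## Known limitations

- Coding behavior only: no clinical course, hCG kinetics, methotrexate
  pathways, or coder learning; error types are independent within a stay by
  design (see above for what that costs).
- The administrative filter matches unit labels by exact string equality;
  real extraction systems need unit-label normalization upstream.
- The generator's non-case mix and complication profile are plausible but
  unverifiable against the undeposited source data; conclusions about
  absolute synthetic operating points inherit that uncertainty.
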
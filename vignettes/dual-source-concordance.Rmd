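---
title: "Measuring dual-source concordance of neonatal critical conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dual-source concordance of neonatal critical conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoconcord)
```

## The problem

Perinatal drug-safety and outcomes research leans on two administrative
data sources that were never collected for research: birth certificates
(BC), which record delivery and neonatal conditions as checkboxes filled
in by registrars and clinical staff, and Medicaid claims extracts, which
record billed encounters coded in ICD-9-CM and CPT. Neither is a gold
standard. When the two disagree about whether a newborn was admitted to a
NICU, needed mechanical ventilation, or had respiratory distress
syndrome, seizures or a birth injury, an outcome definition built on
either source alone inherits unknown misclassification. `neoconcord`
implements the full concordance analysis for linked mother--infant
cohorts: deterministic linkage, claims-based phenotyping, certificate
ascertainment, and the agreement surface (2×2 tables, Cohen's kappa,
cross-source sensitivities, prevalence, discordance decomposition), plus
a generative simulator with known truth so every stage can be validated
end to end.

## Ascertainment model

A linked mother--infant pair is a **claims (MAX) case** of a condition
when at least one inpatient or outpatient claim, on the infant's or the
linked mother's record, in any diagnosis position, carries a code in the
condition's code set with a service date inside the postnatal window.
The packaged code sets are: CPT neonatal critical/intensive-care codes
for NICU admission (99295--99300, deleted January 2009 but retained
because cohorts span earlier years, plus 99468/99469/99477--99480),
ICD-9-CM 769.xx for RDS, 779.0x for neonatal seizures, procedure codes
96.7x and 93.90 for assisted ventilation, and 767.xx for birth injury.

Three conventions are deliberate and configurable:

* **Window.** "Within 30 days of birth" is implemented as the closed
  interval `[birth_date, birth_date + 30]` with the day of birth as day
  0. The inclusive reading maximizes capture and makes boundary tests
  unambiguous; `window_days` is a parameter (days, default 30).
* **Code matching.** ICD-9 family semantics: a trailing wildcard run
  (`769.xx`) and a bare stem (`96.7`) both match any more specific code
  by prefix on the normalized (dot- and comma-free, upper-cased) form;
  CPT matches exactly on five digits. Code systems never cross: a
  diagnosis 9671 (a poisoning code) is not the procedure 96.71.
* **Mother records.** The maternal-record rule is applied to all five
  conditions by default, with a per-condition switch
  (`use_mother_records`). Whether maternal claims are equally relevant
  for every condition is genuinely unclear; applying the rule uniformly
  is the simplest defensible reading, and the switch lets analysts test
  the alternative.

A pair is a **certificate (BC) case** when the condition's checkbox is
checked. Unlike claims — where an absent code means absence — the
certificate forces an explicit yes/no, so a missing determination is
excluded from agreement tables rather than counted as a noncase. NICU
admission is restricted to births in 2004--2010 because the checkbox
only exists on the post-2003 certificate revision; affected pairs get an
`excluded_year` status that removes them from that condition's tables
only.

The cohort filter requires both members continuously enrolled through
day 30 (coverage through the window end, inclusive, after merging
abutting spans). Delivery-type claims establish the delivery date for
linkage but are never ascertainment encounters.

## Linkage

Linkage is strictly deterministic and two-step, in a fixed order:

1. **Exact SSN.** Certificates carrying both the mother's and the
   infant's SSN link when each SSN resolves to exactly one Medicaid
   person of the right role and the certificate's SSN combination is
   unique.
2. **Case ID, then SSN.** For the remainder, infants pair to mothers
   sharing the Medicaid family identifier whose delivery claim date
   matches the birth date within `date_tolerance_days` (default 0 —
   the strictest reading; the simulator can stress the knob), and the
   dyad then links to the certificate matched by whichever single SSN
   is available.

Every ambiguity — an SSN shared across enrollees, duplicate
certificates, an infant matching two mothers, two dyads resolving to one
certificate — is dropped and counted, never resolved by choice. Twins
are supported as distinct dyads of one mother; an infant or certificate
appears in at most one link. `evaluate_linkage()` scores emitted links
against simulated truth (PPV and recall), mirroring the >99% PPV
reported for the established state linkage algorithms this procedure
models.

## Agreement statistics

For each condition and stratum the pair cohort is cross-classified into
`a` (both sources positive), `b` (claims only), `c` (certificate only),
`d` (neither), after removing excluded pairs. The statistics are:

* observed agreement `po = (a + d) / N` and chance agreement
  `pe = p_MAX * p_BC + (1 - p_MAX)(1 - p_BC)` from the margins;
* Cohen's kappa `(po - pe) / (1 - pe)`, undefined (reported `NA`, never
  0) when `pe = 1`;
* cross-source sensitivities `a / (a + c)` (claims capture of
  certificate cases) and `a / (a + b)` (the converse) — "sensitivity as
  if the comparator were gold", a capture measure, not a validity claim;
* prevalence per 100 pairs for each source;
* the discordance decomposition: `100 (b + c) / (a + b + c)`, the share
  of all ascertained cases seen by one source only.

Kappa is banded on the conventional scale — poor (≤ 20%), fair
(20--40%], moderate (40--60%], substantial (60--80%], high (> 80%) —
applied to the percent value rounded half-up to one decimal. The
published convention leaves the open interval (20, 21) unassigned; the
contiguous half-open bands used here are the unique total extension, and
boundary values fall in the lower band. All displayed rounding is
half-away-from-zero on the final digit (`round_half_up()`), with raw
values always retained.

## Reproducing the published tables

The packaged fixture (`printed_concordance()`) carries the published
per-condition case counts, kappas, sensitivities and prevalences for
Florida (558,224 linked pairs) and Texas (981,120). The published tables
print marginal and joint counts but not per-condition analysis
denominators, and the denominators implied by the printed prevalences
are mutually inconsistent across rows — most visibly in Texas, where the
RDS and seizure rows imply a sub-cohort of about 377,574 pairs rather
than the state total. `reconstruct_denominator()` inverts the prevalence
formula and reports the feasible integer interval implied by printed
rounding; each fixture row records the denominator policy established
that way once:

* Florida NICU: reconstructed from its claims prevalence (N = 277,676;
  the NICU year restriction shrinks the cohort);
* Florida RDS, seizure, AV, birth injury: the state total;
* Texas NICU: reconstructed from its certificate prevalence (604,142);
* Texas RDS and birth injury: reconstructed from their claims
  prevalences; Texas seizure borrows the RDS-reconstructed sub-cohort
  denominator (its own printed prevalences, 0.25 and 0.02, are too
  coarse to invert usefully);
* Texas AV: the state total.

Three Florida rows (seizure, AV, birth injury) do not reproduce their
printed kappa under any candidate denominator (e.g. seizure recomputes
to 8.45 → 8.5 against a printed 8.4). They are retained with
`reproducible = FALSE` and surfaced by `reproduce_printed_tables()` with
their recomputed values — the reproduction report is honest about what
the printed numbers do and do not pin down. All twenty printed
sensitivities, by contrast, are exact ratios of printed counts and
reproduce without any denominator.

```{r repro}
rep <- reproduce_printed_tables()
rep[, c("state", "condition", "denominator_policy", "denominator",
        "kappa_pct_rounded", "printed_kappa_pct", "kappa_match")]
```

## The synthetic cohort

`simulate_cohort()` generates every table the pipeline consumes from a
latent-truth model: per condition, true status is Bernoulli with the
configured prevalence; the claims source observes it with sensitivity
`se_max` / specificity `sp_max` (an observation becomes one or more
coded claims at a uniform date in the window, sometimes on the mother's
record); the certificate observes it with `se_bc` / `sp_bc` and loses
the determination entirely at `bc_missing_rate` (default 0.02, matching
the just-under-2% missingness of the study setting). SSNs are masked at
configurable rates (defaults 0.15 for mothers, 0.25 for infants, chosen
to exercise both linkage paths and the no-SSN failure mode), births are
uniform over 1999--2010, and unrelated noise claims arrive at a Poisson
rate per infant.

Defaults for the per-condition sensitivities and specificities are
working assumptions, loosely motivated by the published claims
validation studies (PPV 86--97% across these conditions, hence high
claims specificity) and by the observed cross-capture pattern
(certificates under-report most conditions but out-capture claims for
assisted ventilation). They are documented knobs, not estimates: true
source specificities are unobservable in a dual-source design without a
gold standard.

Two design choices matter for testing:

* **Conditional independence** of the two sources given true status is
  the default, because it yields a closed-form oracle:
  `expected_kappa()` computes the exact large-sample kappa from the
  five parameters, verified in the tests against brute-force
  enumeration of the eight truth × claims × certificate outcomes. A
  `source_correlation` knob couples the detection draws for true cases
  (shared severity) for sensitivity analyses, since real under-reporting
  is plausibly correlated.
* **One root seed, per-stream sub-seeds** (identity, truth, claims,
  certificate, noise, enrollment), so toggling one noise source leaves
  every other stream's draws byte-identical — property-tested.

What the simulator does *not* emulate: real demographic structure,
within-family correlation across conditions, coding drift over years,
seasonal births, or certificate data-entry error mechanisms beyond
symmetric misclassification. A passing pipeline on synthetic data
therefore demonstrates correctness of linkage, phenotyping and
arithmetic under the stated generative assumptions — not validity of any
code set against medical records.

## Numerical and degenerate-input choices

* Undefined statistics are `NA`, never 0: kappa at `pe = 1`,
  cross-sensitivity with an empty reference margin, discordance with an
  empty case union, linkage PPV with no links.
* The independence null is exact: a table with cells proportional to
  products of its own margins gives kappa 0 to machine precision
  (property-tested).
* Kappa is symmetric in the two sources (swap `b` and `c`), bounded
  above by 1, and equals 1 exactly when both discordant cells are 0.
* Ties and ambiguities in linkage are never broken arbitrarily; the
  drop-and-log policy keeps output invariant to input row order
  (property-tested by shuffling).

## Problem sizes

The test suite validates arithmetic on desk-scale fixtures
(milliseconds), runs full synthetic pipelines at 400--20,000 pairs, and
checks simulator parameter recovery — empirical kappa within three
Monte-Carlo standard errors of `expected_kappa()` — at 200,000 pairs,
the size at which the Monte-Carlo error is small enough to make that a
sharp check. The acceptance script uses 50,000 pairs for its end-to-end
synthetic quantities, which bounds the Monte-Carlo error on kappa near
0.01 while keeping the whole run in seconds.

## Known limitations

* No kappa variance or confidence intervals, no weighted kappa, PABAK
  or Gwet's AC1: the analysis this package implements reports crude
  kappa only.
* No probabilistic linkage; records that deterministic rules cannot
  resolve are dropped, which understates linkage yield relative to
  probabilistic methods.
* ICD-9-CM/CPT only; cohorts after the ICD-10 transition are out of
  scope.
* Deleted CPT codes are retained without validity-period enforcement by
  default (pooled multi-year cohorts); per-code validity windows would
  be a straightforward extension.
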
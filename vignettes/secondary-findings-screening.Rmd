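---
title: "Secondary-findings screening: models, triage rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-findings screening: models, triage rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfscreenr)
library(dplyr)
```

## The screening problem

Diagnostic genome sequencing observes every gene, not only those relevant to
the indication for testing. A *primary finding* (PF) is a causative variant
that explains the phenotype that prompted testing; a *secondary finding*
(SF) is a pathogenic or likely pathogenic (P/LP) variant in a medically
actionable gene unrelated to that phenotype. Laboratories report SFs against
the ACMG SF gene list (78 genes in v3.1); cohorts with distinctive disease
epidemiology — in particular highly consanguineous populations, where
biallelic recessive genotypes are strongly enriched — motivate an additional
locally curated actionable panel. `sfscreenr` implements that whole
reporting pipeline as composable, tibble-first functions: variant QC,
mode-of-inheritance-aware triage into PF / SF / carrier classes, cohort
statistics, and a cohort simulator for validating the logic.

## Variant quality policy

A call is kept when it has at least `min_depth` reads **and** an
alternate-allele fraction of at least `min_alt_fraction`; both thresholds
are inclusive, so depth 9 passes the default `qc_policy(9, 0.30)` and depth
8 does not. Missing genotypes are dropped before triage with a logged count.

The 0.30 default deserves a note. The quality rule this mirrors is stated
as "an alternate allele frequency of at least 0.3%"; a fraction of 0.003 is
far below anything a germline genotyper would emit for a true heterozygote
(expected fraction 0.5), and a depth-9 threshold with a 0.003 fraction
floor would accept calls supported by a single read in principle. We
therefore read the figure as a typographic slip for a *fraction of 0.30*,
which is the conventional heterozygote-support floor, and make it fully
configurable so either reading can be run.

## Triage rules

Per participant and gene (after QC), in order:

1. **Primary findings.** If the participant is symptomatic and some panel
   pair for the gene shares at least one HPO term with the participant
   (ancestor closure applied when an ontology is supplied), the gene group
   is a PF for the best-matching pair. VUS calls are allowed in PFs and
   flagged with `includes_vus`, so "P/LP-only" PF statistics can exclude
   them. PF assignment takes priority: a pair is never double-reported as
   both PF and SF for one participant.
2. **Secondary findings and carriers.** Otherwise only P/LP calls are
   considered. Allelic status is biallelic when a homozygote is present or
   when two *distinct* heterozygous P/LP variants co-occur in the gene — a
   putative compound heterozygote presumed in trans, since short-read
   cohorts rarely have phasing (`require_phase = TRUE` downgrades unphased
   pairs to monoallelic). Mode of inheritance then decides: dominant and
   semidominant genes report at any status; recessive genes report
   biallelic genotypes and route single heterozygotes to **carrier**
   status; X-linked genes report hemizygous males (heterozygous females
   only with `xl_female_sf = TRUE`, off by default because monoallelic SFs
   in such cohorts are reported in dominant/X-linked-male contexts).
3. Anything else is `NOT_REPORTABLE`, which is retained in the output so
   the classes exactly partition the participant x gene groups — a
   property the tests assert on randomized cohorts.

Asymptomatic participants carry no phenotype terms, so they can receive no
PFs by construction; their reportable variants all route to SF or carrier
status.

**Genes with several disease associations.** A gene may carry more than one
panel pair (the packaged custom panel has ABCA4 with both a dominant
macular-degeneration pair and a recessive Stargardt pair). Emitting one
finding per pair would double-report every such gene, so triage emits one
finding per gene and picks the pair by (i) disposition priority
(reportable > carrier > none), (ii) zygosity-MOI specificity — a biallelic
genotype is attributed to the recessive pair, a monoallelic one to the
dominant pair — and (iii) ACMG panel before custom panel. This also
prevents a heterozygote already reported under the dominant pair from
being double-counted as a carrier of the recessive disease.

**Families are not collapsed.** Two members of one family carrying the same
variant count as two participants (the headline frequencies are
participant-level); `count_findings()` offers `unique_variant` and
`unique_gene` levels for the deduplicated summaries.

## The actionability rubric

The custom panel is built from a semiquantitative score with four 0–3
components — disease severity, likelihood of disease, effectiveness of the
intervention, and nature (burden/risk) of the intervention — summing to
0–12; pairs scoring **≥ 10** are candidates. Evidence grades (A–D, N)
attach to the likelihood and effectiveness components but are descriptive
and never enter the total. The final cut from scored candidates to the
packaged 39-pair panel is expert curation, for which no algorithm exists;
the panel format therefore carries a `curated` flag rather than pretending
the last step is computable.

## Statistics

Frequencies are printed as percents rounded *half-up* (the convention of
clinical tables; base `round()` rounds half to even), one decimal
everywhere except carrier rates at two. A `1e-9` relative nudge in
`round_half_up()` absorbs binary-representation error in exact decimal
halves; it cannot move any value that is not a representational half-case.

Symptomatic-vs-asymptomatic comparisons use 2x2 tables with both the
**risk ratio** `(a/(a+b))/(c/(c+d))` and the **odds ratio** `ad/bc`, each
with the log-scale Wald interval `exp(log(est) ± 1.96 * SE)` and a
two-sided normal-tail p-value on `z = log(est)/SE`. Published reports of
this design are loose about which measure they print: the value labelled
"OR" for the ACMG comparison reproduces the *frequency (risk) ratio*
(22/741 ÷ 1/122 = 3.62), while the non-ACMG "OR 0.40" is the true odds
ratio in the asymptomatic-first direction (1·726 / 121·15 = 0.400). The
package therefore always computes both measures in both directions and
lets the reader pick the labelled one. The Wald normal-tail p-values
reproduce the printed two-decimal p-values (0.21, 0.38); printed CI bounds
of that provenance are not exactly reproducible by any single standard
formula, so interval checks here are properties (point inside its CI; p <
0.05 iff the CI excludes 1) rather than digit matches. Zero cells error by
default; `haldane = TRUE` applies the Haldane–Anscombe +0.5 to all cells.
An exact Fisher p-value by hypergeometric enumeration (`fisher_p()`) is
provided as a cross-check and is verified against `stats::fisher.test` on
all small-margin tables in the tests.

`version_comparison()` computes the relative change between two *rounded*
participant-level percents, matching how such comparisons are quoted.

## The simulator and the reference cohort

`simulate_cohort()` draws cohorts with the study structure: 700 index
participants plus 163 relatives, 61.65% male, 85.86% symptomatic, 79.86%
of index families consanguineous (2.71% undisclosed), ages from truncated
normals (symptomatic mean 4.93, SD 6.17 on [0, 65]; asymptomatic mean
28.34, SD 10.52 on [0, 55]). Consanguinity is modelled with a single
inbreeding coefficient **F = 0.0625** (first cousins): for a recessive
pair with carrier allele frequency *q*, a participant from a
consanguineous family is biallelic with probability `q^2 + F q (1 - q)`
and heterozygous with `2 q (1 - q)(1 - F)`; outcrossed families use the
Hardy–Weinberg values. Dominant pairs are planted as heterozygotes at a
configured rate. Depths (10 + Poisson(30)) and binomial allele fractions
make over 99% of planted calls pass default QC. Fraction-to-count
conversion uses largest-remainder apportionment when
`deterministic_margins = TRUE`, so 0.8586 of 863 is exactly 741. The
planted truth table lets `recover_findings()` verify that triage recovers
every QC-passing planted finding's class exactly — the logic is
deterministic, so the only permissible loss is the sub-1% QC attrition.

What the simulator deliberately does **not** model: linkage and pedigree
structure beyond a family-level consanguinity flag, mutation spectra,
sequencing error, VUS abundance, or gene-specific penetrance. Passing
recovery tests therefore demonstrates the correctness of the reporting
logic under the stated genetic model, not performance on real sequencing
data.

`reference_cohort()` is different in kind: a *deterministic* 863-participant
fixture, generated in code, constructed so the full pipeline reproduces
every published aggregate exactly — 24 ACMG SFs in 23 participants (22
unique variants in 14 genes; 18 cardiovascular including four TTN, 4
cancer, 2 malignant hyperthermia; one homozygous LDLR; one MYBPC3+TTN
dual; a TMEM43 family pair and a duplicated KCNQ1 variant), 1 MUTYH
carrier, 16 non-ACMG SFs (8 biallelic), 8 non-ACMG AR carriers, 35 P/LP
ACMG PFs (31 biallelic, 23 unique variants, 8 genes) plus 6 VUS-flagged,
and 10 P/LP non-ACMG PFs plus one LP/VUS compound heterozygote. Where the
published aggregates do not pin a choice (which PF genes fill the
non-printed remainder, how relatives distribute over families, the
clinical status of carriers), the fixture makes one documented choice and
keeps it; its age vectors are quantile-grid constructions pinned to the
printed mean/median/range (SD agrees to ~0.05), not random draws. The
deterministic fixture also carries decoy calls — a depth-8 call, a 10%
allele-fraction call, a benign call, an off-panel gene, an unmatched VUS —
that must produce no findings.

One aggregate is *not* reproducible and is knowingly reported as computed:
restricting the ACMG panel to v2.0. With 24 SFs in 23 participants, four
TTN findings, and exactly one dual-SF participant (MYBPC3+TTN), removing
TTN (the only detected gene absent from v2.0; the packaged panel encodes
PALB2 as present from v2.0 to respect the source's own attribution of the
whole difference to TTN) removes exactly three participants: 20/863 =
2.3%, a relative increase of 17.4% — whereas the quoted figures are 2.4%
and 12.5%, which would require only two TTN-only participants and are
arithmetically inconsistent with the stated counts. The pipeline reports
the recomputed values.

## Packaged panels

`acmg_panel()` ships a 78-pair ACMG-v3.1-shaped panel with per-pair
version flags back to v1.0 (56 pairs), following the published version
history for the genes that matter to the analyses (TTN enters at v3.0);
the five v3.1-only rows are plausible synthetic placeholders, as are all
HPO annotations. `nonacmg_panel()` ships the 39-pair curated custom panel:
the 19 pairs named in the underlying results under field-standard gene
symbols, plus 20 clearly-labelled synthetic placeholders (`SYNG01`…), all
with rubric scores ≥ 10. Category assignments reproduce the published
category shares. These are test and demonstration fixtures, not clinical
reporting lists.

## Problem sizes and numerical choices

The test suite runs the full deterministic pipeline (863 participants, ~110
calls) in seconds; property tests use 50 replicate stochastic cohorts of
863 participants for parameter recovery, 20,000-participant cohorts for
the inbreeding-separation check, and 10^6 Monte-Carlo draws for the
biallelic closed-form check — sizes chosen so each check's binomial noise
is far below the effect it measures. Ties in pair selection break
deterministically (panel order), triage output is sorted, and the same
seed always reproduces a simulated cohort byte-for-byte.

## Worked example

```{r example}
ref <- reference_cohort()
scr <- screen_cohort(ref$manifest, ref$calls, quiet = TRUE)
glance(scr)
scr$summary$class_freq
category_breakdown(scr$findings, "ACMG_SF")
tail(scr$summary$ratios[c("finding_class", "measure", "comparison",
                          "estimate", "p.value")], 4)
```

## Known limitations

- Variants arrive pre-classified (P/LP/VUS/LB/B); no ACMG/AMP criteria
  engine, no HGVS validation, no structural-variant genotyping.
- Phenotype matching is term-set intersection (optionally closure-expanded),
  a stand-in for the clinical-judgment matching such studies describe.
- Compound heterozygotes are presumed in trans without phasing unless
  `require_phase` is set.
- The custom panel's final 154-to-39 curation step is not an algorithm and
  is represented only by a flag.
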
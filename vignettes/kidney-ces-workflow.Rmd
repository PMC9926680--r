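---
title: "The kidneyCES diagnostic workflow: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kidneyCES diagnostic workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyCES)
```

# The clinical problem

Roughly a third of children with chronic kidney disease carry a monogenic
condition, and many reach transplantation undiagnosed. Clinical exome
sequencing (CES) — sequencing of the ~6,700 disease-associated genes with
analysis restricted to phenotype-matched gene panels — is an effective
compromise between diagnostic power and the burden of incidental findings.
`kidneyCES` models the complete decision chain of such a diagnostic
service, from raw annotated variant calls to the per-patient genetic report
and the cohort-level yield statistics, so that every rule is executable,
testable and simulatable.

# The filtering cascade

For each patient, calls pass three gates in order; the first failing gate is
recorded per variant in a trace (`run_filter_cascade()`):

1. **Panel restriction.** Only genes on the panel matched to the patient's
   disease macro-category (CAKUT, ciliopathy, glomerulopathy,
   nephrolithiasis, tubulopathy, other/syndromic) are analysed.
2. **Consequence filter.** Synonymous variants that do not impact splicing
   and intronic variants outside the splice region are excluded;
   non-synonymous, nonsense, frameshift and splice-affecting variants (and
   CNVs) are kept.
3. **Rarity / quality filter.** A variant is kept when its external
   population allele frequency is *strictly below* 0.01, its in-patient
   allele fraction (VAF) is *at least* 0.2, and the site is covered by
   *at least* 20 reads.

The boundary semantics follow the clinical wording literally ("less than
1%", "at least 0.2", "at least 20 reads"); all three thresholds are
exposed in `filter_config()` with these defaults. Two deliberate choices:
an absent population frequency is treated as 0, because novel variants must
pass a rarity filter; and homozygous calls get no VAF exemption, because
the rule is stated unconditionally. CNV records have no meaningful
single-site allele fraction and therefore bypass the VAF/depth tests while
still obeying the frequency test when an AF is available.

# Panels and kidneyome escalation

Panels are category-keyed gene lists with a single inheritance mode per
entry; a gene with dual inheritance is entered once per mode and both modes
are evaluated (`panel_moi()`, `build_bundle()`). The *kidneyome* is derived
as the exact union of the subpanels (`kidneyome_panel()`), never curated
separately. Escalation to the kidneyome happens only when the subpanel
analysis is negative **and** the phenotype is not clearly indicative or
overlaps disease categories (`should_escalate()`); both phenotype flags are
clinician-supplied inputs, never inferred from the data. Escalation reuses
the already-filtered calls — a single filtering pass — because the
filtering thresholds are patient-level, not panel-level.

The bundled `demo_registry()` is a compact demonstration registry of real
kidney gene–disease pairs (PKD1, PKHD1, COL4A5, NPHS1/2, CTNS, CLCN5, …),
not a clinical-grade list: production deployments should load their own
versioned panel TSVs via `read_panel_registry()`.

# ACMG evidence combination

The engine (`combine_evidence()`) consumes evidence *counts per strength
tier* — very strong / strong / moderate / supporting pathogenic, and
stand-alone / strong / supporting benign — and applies the 2015 ACMG/AMP
combining rules to produce C1 (benign) through C5 (pathogenic). The
28-criterion catalogue itself is not modelled: a diagnostic laboratory
applies ACMG rather than re-deriving it, and evidence assignment
(population data, functional studies, in-silico predictors) is upstream of
this package. The engine is a total function — every count profile maps to
exactly one class, conflicting pathogenic and benign evidence collapsing to
VUS — and is tested for monotonicity: adding pathogenic evidence can never
move a class toward benign. The intermediate "C3/C4" label seen on real
reports is not producible by the combining rules; it exists only as a
curator override (`classify_with_override()`), carries C4-like weight in
the report rules, and is tallied as its own class.

# Trio segregation

Parental genotypes travel as columns on the proband's call rows; the trio
skeleton (from the PED) distinguishes *pending* (parents exist, not yet
genotyped) from *unavailable* (no parents). Three primitives feed the
gene-group evaluation:

* `assess_moi()` — the inheritance-mode × zygosity × sex truth table. A
  single heterozygous variant in a recessive gene is explicitly flagged
  (`ar_single_het`) and never satisfies the model.
* `detect_de_novo()` — true only when both parents are homozygous
  reference at ≥ 20 reads (`min_parent_depth`, mirroring the proband
  coverage rule; the value is a symmetry choice, the clinical source being
  silent on parental depth).
* `phase_compound_het()` — trans when each variant traces exclusively to a
  different parent, cis when both trace to the same single parent, unknown
  otherwise (shared carriage, missing parent).

`evaluate_segregation()` then confirms or refutes a gene group: an AR
homozygote expects both parents heterozygous; a compound heterozygote must
phase in trans (cis refutes the recessive model — one allele remains
intact); a dominant variant is confirmed when inherited or proven de novo;
a hemizygous son whose variant is carried only by his father is refuted
(a father does not transmit his X to a son). Penetrance is assumed
complete: an unaffected carrier parent under AD yields confirmed
transmission, not refutation. Incomplete penetrance — common in real
dominant kidney disease — and parental mosaicism are deliberately not
modelled.

# CNV calling

`call_cnv()` implements the baseline-of-normals strategy: depths are
normalised per sample by the median autosomal depth (`normalize_depths()`),
and per-region ratios are taken against the mean of the applicable baseline
columns. Because the baseline contains both sexes and the test sample's sex
is declared, sex-chromosome regions are compared only against same-sex
columns, so a male's single X copy sits at ratio 1.0 rather than looking
like a deletion. Ratio cut-offs — heterozygous deletion ≤ 0.7, complete
deletion ≤ 0.1, duplication ≥ 1.3 — are conventional values exposed in
the `thresholds` argument; the clinical source names the baseline strategy
but not numeric cut-offs. Consecutive same-state regions are merged into
one call (per-region merging; whether a laboratory merges per exon or per
gene is unstated, and per-region is the conservative choice). No
segmentation HMM/CBS and no GC correction are attempted. Calls convert to
ordinary variant records (`cnv_to_variant_calls()`) so they flow through
classification and reporting like small variants.

# Report classification

Per gene group, the leading (most severe) class, the clinician-supplied
phenotype fit (full / partial / none), the inheritance-model assessment and
the segregation status decide a provisional outcome:

| rule | condition | outcome |
|------|-----------|---------|
| (a) | C4/C5 (or C3/C4), full phenotype fit, inheritance model satisfied | conclusive |
| (b) | C3, full fit, segregation confirmed | conclusive |
| (c) | C3, full fit, segregation pending/unavailable | uncertain |
| (d) | C4/C5, partial fit | uncertain |
| (e) | single heterozygous variant in a recessive gene | inconclusive |
| (f) | C3, no fit, found only on the kidneyome | inconclusive |
| (g) | no surviving variants | inconclusive (negative analysis) |
| (h) | segregation refuted | inconclusive |

Refuted segregation (h) and the single-het-recessive flag (e) are checked
first within a group; a C4/C5 finding with *no* phenotype fit on the
patient's own subpanel is suppressed and logged rather than given an
invented outcome (incidental-finding policy is out of scope). Benign (C1/
C2) survivors are dropped at bundle assembly and logged. The patient's
report takes the best outcome across gene groups (conclusive > uncertain >
inconclusive): a patient with one conclusive finding has a conclusive
report regardless of additional VUS; reasons from non-deciding groups are
kept as secondary codes.

# Cohort statistics

"Diagnostic" means a conclusive report; uncertain reports never count
toward yield. Every percentage is rounded half away from zero to one
decimal (`round_half_up()`), matching how such cohort tables are printed,
and every denominator is kept in the output so any percentage can be
recomputed from its two counts. The report-split percentages use the
variant-positive patients as denominator (the convention for "among
patients in whom CES identified variants"), while the variant-positive
share itself uses the whole cohort. Three published-figure quirks are
documented rather than reproduced, because they are not
arithmetic-consistent under any standard rounding: an overall conclusive
rate printed as 37.1% where 71/191 rounds to 37.2; a family-history yield
printed once as 59.5% in text against 59.6 in the table (28/47 = 59.57);
and a nonsense share printed as "145.6%" where 14/96 = 14.6%. The
acceptance suite targets only the arithmetic-consistent figures.

# Synthetic cohorts and the demonstration fixture

`simulate_cohort()` draws per-patient categories, family history and
outcome archetypes, then realises each patient as concrete annotated calls:
causative variants that pass every filter and carry evidence mapping to the
intended class, trio genotypes consistent with the intended segregation
result, and decoy variants each engineered to fail exactly one named filter
(common, low-VAF, low-depth, silent-consequence, off-panel). The plan is
the ground-truth ledger, and on noise-free configurations the pipeline must
reproduce the ledger outcome for every patient — exact agreement is the
contract, and any disagreement is a generator or pipeline bug. Defaults
emulate the study cohort's structure: category proportions 34/39/62/22/20/
14 over 191, per-category family-history rates, an outcome mix matching the
observed report split, and trios available for most recessive findings.
What the generator does **not** emulate: sequencing noise, annotation
errors, mosaicism, incomplete penetrance, multi-gene phenotype overlap
within one patient beyond the planted groups — so green synthetic tests
validate the decision logic, not robustness to messy real-world inputs.

`build_paper_fixture()` fixes one deterministic 191-patient plan consistent
with all published marginals. The joint distribution of category × class ×
zygosity × family history is under-determined by the published counts (only
marginals and two partial figures exist); the completion chosen here echoes
the reported patterns — nephrolithiasis and tubulopathies rich in C5
homozygotes, ciliopathies rich in C3 and in PKD1 heterozygotes, CNVs placed
in CAKUT and glomerulopathy genes — and is validated at build time: the
construction re-derives every marginal (191 patients; 34/39/62/22/20/14 per
category; 71/22/61 report split over 154 variant-positive; 7/29/15/10/9/1
diagnosed per category; 47 family-history-positive of whom 28 diagnosed; 96
reported variants in exactly 32 genes, 53/15/14/9 missense/frameshift/
nonsense/splicing plus 5 CNVs; 17/34/16/4 patients led by C5/C4/C3/C3_C4)
and stops with an error if any fails. Gene symbols are the genes a kidney
panel would actually carry, with enough distinct symbols to reach the
printed 32. Per-sex family-history subsplits are left unconstrained: the
published per-sex figures are ambiguous as printed.

# Numerical and interface choices

* Coordinates are 1-based fully-closed VCF convention throughout; no
  translation layer.
* The population-frequency INFO key is configurable (`read_vcf()`’s
  `info_keys`), since the reference database is deployment-specific.
* Genotypes map to het / hom_alt / hemizygous by allele count plus
  chromosome and declared sex; haploid alternate calls on chrX/chrY in
  males are hemizygous.
* Multi-allelic records are decomposed one row per alternate allele;
  homozygous-reference samples contribute no rows.
* `round_half_up()` adds a 1e-9 guard against binary-float artefacts
  (e.g. an exact decimal .45 stored as .4499…).
* Problem sizes in the test-suite property checks (1,000 random filter
  calls, the exhaustive MOI and evidence grids, 2,000 random report
  bundles, 40–50-patient simulated cohorts) were chosen as the smallest
  sizes that still exercise every rule combination exhaustively or near-
  exhaustively.

# Known limitations

* Evidence assignment, variant annotation and population frequencies are
  inputs, not computed.
* Segregation reasoning is trio-only; extended pedigrees and linkage are
  out of scope, as are sample-swap QC and validation chemistry.
* The CNV caller is deliberately minimal (no segmentation, no GC
  correction) and is not a substitute for array CGH confirmation.
* Complete penetrance is assumed; dominant kidney disease with reduced
  penetrance will over-call "confirmed transmission".
* The demonstration fixture reproduces published *marginals*; its joint
  structure is one consistent completion, not patient-level truth.
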
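---
title: "elicitR: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{elicitR: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitR)
```

This vignette is the package's own account of its science: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The experimental design being modelled

A PAMP-elicitation time course in three Arabidopsis genotypes — wild type
(Ws), the phosphatase null *mkp1*, and the double mutant *mkp1 mpk6* —
sampled at 0, 30 and 90 min with three biological replicates, quantified as
FPKM-like values per gene. The scientific question is epistatic: which
elicitor-responsive transcripts require MKP1, and which of those
additionally require MPK6 (so that losing the kinase reverts the
phosphatase-mutant phenotype). Because MKP1 is a negative regulator, the
typical dependent transcript hyper-responds in *mkp1*.

## Genetic classification

Per gene and post-elicitation timepoint, five contrasts feed three gates:

1. **Responsive**: |log2 FC| ≥ `lfc_min` (default 1) and q ≤ `q_resp`
   (default 0.01) in the wild-type or single-mutant time contrast. The
   union matters: a transcript whose wild-type induction is damped below
   threshold but clearly responds in the mutant still belongs to the
   responsive universe. All thresholds are inclusive.
2. **MKP1 dependent**: responsive and |log2(mkp1/Ws)| ≥ log2(`dep_fold_min`)
   (default 1.5-fold, in either direction — the mutant can hyper- or
   hypo-accumulate) with q ≤ `q_dep`. MKP1-*independent* is defined purely
   by subtraction, so the four categories partition the responsive set
   exactly; this partition is enforced by a property test.
3. **MPK6 subdivision** (q-only, no fold gate): significance of
   mutant-vs-double and wild-type-vs-double decide MPK6 dependent
   (reverted), MPK6 independent (not reverted), with everything ambiguous
   — including missing contrasts — in the partial residual.

Choices the published procedure left open, and what this package does:

* *Direction conflicts* (wild type and mutant qualify with opposite signs)
  take the wild-type sign and increment a logged counter.
* *Pre-existing 0-min genotype differences* are flagged
  (`baseline_diff`), never excluded.
* The 30- and 90-min labels are independent; transcripts may switch
  categories between timepoints, and nothing forces consistency.
* Percentage summaries are reported with explicit numerators and
  denominators, rounded to the nearest integer in prose style and to two
  decimals in table style; empty denominators yield an undefined marker
  rather than 0. The MPK6 split is reported twice: over all MKP1-dependent
  transcripts, and over the *discretely classifiable* subset (dependent +
  independent only), because the published split percentages exclude the
  partial residual from their denominator.

## The differential stand-in

The upstream tool this module replaces shares dispersion information
across genes in a negative-binomial model. The contract here is
only the table: per gene, `log2_fc = log2((mean_b + pc)/(mean_a + pc))`
(pseudocount 1 FPKM stabilizes low-expression ratios), a p-value from a
two-sample test on `log2(FPKM + pc)`, and BH q-values within the contrast.

The default test is a **moderated t**: per-gene pooled variances are shrunk
toward a common prior with limma's empirical-Bayes `squeezeVar`, and the
prior degrees of freedom are added to the residual ones. This is not a
stylistic preference. With n = 3 and a 20% CV, a plain Welch t has ~4
residual degrees of freedom; its null distribution has tails so heavy that
a q ≤ 0.01 gate needs |t| ≈ 8–10, and a planted 2-fold genotype effect is
then essentially undetectable (the package's power analysis measured <1%
recovery). Since the generator draws all genes from a common noise model —
and real RNA-seq dispersion is likewise strongly shared — the moderated
test is the faithful stand-in. `method = "welch"` retains the plain test;
both share the degenerate conventions (zero variance in both groups: p = 1
on equal means, a 1e-300 floor otherwise).

Whether q-values should be computed per contrast or globally was not
stated; per contrast was chosen, matching how pairwise differential tools
report their tables.

## Temporal clustering

All `(2c+1)^(T−1)` integer model profiles with per-step change bounded by
c = 2 are enumerated (25 candidates for T = 3, below the default cap of
50; if ever above the cap, a greedy max–min selection on 1 − correlation,
seeded at the largest-amplitude profile with lexicographic tie-breaks,
keeps the set deterministic). Genes enter as wild-type log2-ratio
trajectories versus 0 min — clustering uses the wild type only, because in
this system the mutants alter response magnitude, not shape.

Assignment maximizes the Pearson correlation between the gene's ratio
vector and the profile's cumulative levels. Two numerical realities shape
the tie policy:

* Pearson correlation of 3-point vectors is degenerate-prone; rows with
  numerically zero variance fall back to a guarded cosine convention and
  constant genes are unassigned.
* Correlation is scale-invariant, so proportional integer profiles —
  (0,1,1) vs (0,2,2), nine such pairs among the 25 — tie *structurally*
  for every gene. Declaring all exact ties unassigned would therefore
  unassign essentially everything. Since proportional profiles always
  share an archetype (scale carries no shape information), ties confined
  to one archetype are resolved to the first profile; ties spanning
  archetypes are left unassigned, which is what the "could not be
  confidently assigned" remainder corresponds to here.

Profile significance follows the permutation logic of short time-series
clustering: expected counts from re-assignment under all T! timepoint
permutations (exact, 6 for T = 3; each permuted vector re-referenced to
its new first timepoint), an upper-tail binomial p at the observed count,
BH across profiles.

The grouping of profiles into the eight named archetypes was published
only as "combined clusters with similar general trends"; the decision
table used here — first-step sign × second-phase trend — is one consistent
reconstruction, and an exhaustive test verifies it partitions all 24
non-flat profiles with the mirror symmetry 1↔5, 2↔7, 3↔6, 4↔8 under
negation.

## Enrichment

One-sided over-representation only (the workflow computes over-represented
categories; depletion is untested), via the hypergeometric upper tail,
with BH across the tested terms (k = 0 terms are excluded) at q ≤ 0.05.
Term maps are flat by design — no ontology DAG propagation — and both
published background modes are expressed by passing either the responsive
direction-matched set or the whole expressed universe as `background`.
The p-value is verified against an exhaustive binomial-coefficient
enumeration for every table with N ≤ 60, and a 200-seed null simulation
checks the q ≤ 0.05 family error.

## qPCR quantification

The expression model is `level = E^(−ΔCt)` with
`ΔCt = Ct(sample) − Ct(reference)`; per-reaction efficiencies are averaged
per amplicon before the formula (common practice for per-reaction fitting
tools; the source procedure is silent), and E = 2 reduces the formula to
the classical `2^−ΔCt` exactly. Folds are normalized to the mean level at
the reference condition (wild type, 0 min), and genotype contrasts use the
equal-variance Student's t, per the published wording, with stars at
p < 0.05 / p < 0.01.

Window-of-linearity parameters reconstruct the cited curve-fitting
program, which publishes no parameters: baseline = mean fluorescence of
cycles 3–10, exponential window inside 5–60% of the plateau maximizing the
R² of log10(F) vs cycle, E = 10^slope clamped to (1, 2], reliability gate
R² ≥ 0.99, Ct log-interpolated at 10% of plateau. One adaptation was
forced by arithmetic: a 5–60% band spans 12-fold, but five cycles at
E = 2 span 16-fold, so a fixed 5-cycle window cannot exist for efficient
amplicons; when an in-band stretch is shorter than the target width the
whole stretch (minimum 3 cycles) is fitted.

The curve simulator writes `baseline + cap(q0·E^cycle)` with multiplicative
noise and a plateau at 100× baseline. The cap is a sharp order-6
soft-minimum rather than a soft Michaelis-type saturation: a soft cap
bends the 5–60% band enough to bias the fitted efficiency from 1.85 down
to ≈1.66, whereas real reactions hold their efficiency until reagent
exhaustion; with the sharp cap the recovery bias is ≈0.003, inside the
±0.02 acceptance band.

## The synthetic world

The generator's defaults are the stated conditions of the emulated
experiment: 3 genotypes × (0, 30, 90) min × 3 replicates, elicitor effect
2.0 log2 per unit of archetype shape, genotype effect 1.0 log2 applied in
the response direction (hyper-response in the mutant), log-normal
replicate noise at CV 0.2 (replicate dispersion was never published; 20%
is a realistic bulk-RNA-seq figure and is the one free noise parameter),
baseline log2 expression N(5, 2). The category mix (65% non-responsive,
25% MKP1-independent, 4% + 4% + 2% dependent subcategories) and the
archetype mix (0.25, 0.15, 0.10, 0.12, 0.08, 0.12, 0.12, 0.06) follow the
proportions visible in the published counts: roughly a third of genes
responsive, ~10–15% of those MKP1 dependent, induced-transient the largest
temporal class. `partial_MPK6` genes place the double mutant halfway (in
log2) between wild type and mutant, making the residual category a real
intermediate rather than noise.

What the generator does **not** emulate — and therefore what a green test
does not establish: count-level sampling noise (FPKM-like values are
log-normal, not negative-binomial), gene–gene correlation, length or
GC biases, isoforms, genes whose response exists only in the double
mutant, and annotation structure beyond flat term maps. Recovery
percentages on this world validate the decision procedure, not any claim
about re-deriving the published gene lists, which would require the
original sequencing data.

## Numerical conventions

* BH step-up implemented directly (sorted `p·m/rank`, reverse cumulative
  minimum, capped at 1) and tested for exact equality against a
  brute-force oracle for all n ≤ 12.
* Inclusive thresholds everywhere (≥, ≤), exactly as printed.
* Degenerate variances: p = 1 on equal means, 1e-300 floor otherwise.
* Tie-breaks (profile selection, assignment) are lexicographic, making
  every stage deterministic; the end-to-end pipeline is byte-identical
  under a repeated seed, which an acceptance test checks with file
  checksums.
* Sub-stage seeds are derived from the master seed by fixed small offsets
  (annotation +11, qPCR +23), keeping everything below 2^31.

## Known limitations

* The moderated test assumes shared dispersion; a dataset with strongly
  gene-specific variance would favour `method = "welch"` at the cost of
  power.
* Archetype grouping is defined for T = 3; longer series enumerate and
  assign profiles fine but need their own grouping table.
* The enrichment stage tests flat maps only; DAG-aware enrichment is out
  of scope.
* Published headline counts (e.g. 2895/5989 responsive transcripts, and
  the 6963-vs-6964 discrepancy between the abstract and the clustering
  section of the source counts) derive from the deposited sequencing data
  and are reported, never hard-coded.
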
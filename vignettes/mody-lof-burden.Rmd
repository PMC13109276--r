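---
title: "Methods: NMD-stratified LOF burden analysis in MODY genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMD-stratified LOF burden analysis in MODY genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modyburden)
```

## The analysis in one paragraph

A clinically ascertained MODY cohort is compared with a large unfiltered
population control cohort, one gene at a time. Qualifying variants are
ultra-rare loss-of-function (LOF) changes — stop-gains, frameshifts and
essential splice-site variants — split by whether the resulting premature
termination codon (PTC) is predicted to trigger nonsense-mediated decay
(NMD, leading to haploinsufficiency) or to escape it (leading to a
truncated protein). Individuals carrying at least one qualifying variant
form the carrier cell of a 2×2 table; exact conditional inference on that
table gives the odds ratio, CI and p-value. Synonymous variants run through
the identical pipeline as negative controls for calibration.

## Variant classification

**Coordinates.** All coordinates are 1-based and inclusive, and cDNA
positions follow HGVS c. numbering (c.1 = A of the initiator ATG), because
clinical variant names are exchanged in that convention. The VCF reader
keeps VCF conventions on ingest (left-anchored indels on the genomic plus
strand); `annotate_variants()` does the strand-aware conversion internally.

**Consequences.** A single-nucleotide change that converts a codon to
TAA/TAG/TGA is a stop-gain; a coding indel whose length change is not a
multiple of 3 is a frameshift; a position in the first or last two bases of
an intron is an essential splice variant; a protein-identical coding change
is synonymous. Start-loss and stop-loss are deliberately classified `other`
and excluded from LOF: their mechanism differs and the burden framework
counts them in no category.

**Truncated proteins.** Frameshifts are translated in the shifted frame
through the native stop and into the 3′UTR until the first new-frame stop,
which is how late-exon frameshifts acquire novel C-terminal tails. The HGVS
consequence is `p.<Ref><Pos><New>fsTer<K>`, K counting from the first
changed residue (=1) to the new termination codon inclusive. A frameshift
that reaches the transcript end without a stop is retained, flagged
`nonstop`: with no PTC it cannot trigger NMD and is treated as escape with
a warning note rather than dropped.

**The 50-bp rule.** A PTC escapes NMD when its first base lies in the final
exon or within the last 50 bp of the penultimate exon, measured in
spliced-mRNA coordinates from the first base of the termination codon. The
boundary is implemented so that a PTC exactly 50 bp before the penultimate
exon's 3′ end escapes and one 51 bp before triggers; both sides are pinned
by tests. Single-exon genes (the KCNJ11/NEUROD1 analogues) have no
exon–exon junction, so every LOF variant escapes.

**Essential splice variants** have no directly observable PTC. The package
assigns variants in any intron but the last to `triggering` and variants in
the last intron to `escape` (intron retention or exon extension there can
only place a PTC beyond the penultimate-exon boundary), and flags the call
`splice-inferred` so downstream users can drop or re-bin these records. This
is a documented package choice for a case the 50-bp rule does not decide.

## Carrier collapsing and frequency filters

The unit of burden is the carrier, not the allele: one individual with one
or more qualifying variants of a category counts once (dominant-model
collapse; at MAF < 10⁻⁴ carriers and alleles coincide in practice).
`NMD_triggering` and `NMD_escape` partition `LOF_all` as carrier sets — a
person carrying both kinds still counts once in `LOF_all`.

MAF is assessed strictly (`< threshold`) against the control cohort and an
external reference table, never against cases, which are enriched by
hypothesis. The default threshold is 10⁻⁴ ("1 in 10,000"), with 5×10⁻⁵ and
2×10⁻⁴ swept for sensitivity; filter monotonicity guarantees the three
qualifying sets are nested, which the pipeline tests assert. A variant
missing from the reference is treated as frequency 0 with a warning, the
permissive choice appropriate for references that omit absent variants.

Per-gene case cohort sizes are configurable (`case_n`): genes assayed in
combined sub-cohorts legitimately have different denominators (e.g. 3,512
for a gene Sanger-sequenced in an extra 941 individuals on top of a
2,571-sample panel cohort).

## Exact inference

Conditional on both margins of the 2×2 table, the case-carrier count X
follows Fisher's noncentral hypergeometric distribution with odds-ratio
parameter ψ. The package implements, directly on that likelihood:

* **Conditional MLE** of ψ, solving E(X) = a by a root search on
  log ψ (tolerance 10⁻¹⁰). This is the estimator associated with Fisher's
  exact test; it stays finite and sensible on sparse tables where the
  sample OR is unstable, and both are reported. Boundary conventions:
  a at the support minimum → 0, at the maximum → ∞, no carrier in either
  cohort → NA.
* **Central exact CI** by one-sided tail inversion at (1−level)/2 per side:
  upper bound solves P(X ≤ a | ψ) = 0.025, lower solves P(X ≥ a | ψ) =
  0.025, with one-sided bounds (0 or ∞) at support boundaries. The central
  CI is consistent with the doubled one-sided tail p-value by
  construction; the reported two-sided p instead uses probability-mass
  ordering (the convention of standard exact-test software), which can
  disagree with the CI near 0.05 on asymmetric tables — a known property
  of exact-test conventions, not a defect.
* **Two-sided Fisher p** by probability-mass ordering with a 1+10⁻⁷
  relative tie tolerance to make floating-point ties deterministic. Zero
  margins give p = 1.
* **Bonferroni threshold** α/(genes × categories), default 0.05/(10×2) =
  0.0025.
* **Odds-ratio homogeneity** (interaction between two carrier tables):
  Zelen's exact conditional test by default — conditioning additionally on
  the summed case-carrier count removes the common ψ, leaving a normalized
  product-hypergeometric null — with a Wald test on the difference of log
  sample ORs (0.5 continuity correction on zero cells) as the asymptotic
  fallback. Exact and asymptotic routes can differ noticeably on sparse
  tables; the exact route is conservative by construction, which the
  type-I simulation in the suite checks.

The accuracy bar is set by oracles, not by another library: Fisher p is
checked against exhaustive enumeration to 10⁻¹², the conditional MLE
against a grid + golden-section scan of the raw likelihood to 10⁻⁶;
`stats::fisher.test` is additionally used as an independent cross-check on
moderate tables. On extreme margins (10⁵-scale controls with single-digit
carriers) `fisher.test`'s root searches lose some relative precision, so
exact equality with it is asserted only where it is itself exact.

## Co-segregation LOD

The simplified meiosis-counting formulation: each genotyped non-proband
relative with known affection status is one informative meiosis. Under
linkage, phenotype-given-genotype contributes penetrance f for an affected
carrier, 1−f for an unaffected carrier, 1 for an unaffected non-carrier and
the phenocopy rate (default 0) for an affected non-carrier; under
independent transmission each genotype has probability ½. LOD =
log₁₀(∏contrib / 0.5ⁿ), additive across families; with full penetrance and
no discordance it reduces to n·log₁₀2, so ten concordant meioses give the
classical 3.01. Probands are excluded (ascertainment). An affected
non-carrier at f = 1 yields −∞, reported as `refuted` rather than averaged
away. Full pedigree-likelihood linkage analysis (loops, haplotypes,
liability classes) is deliberately out of scope.

De novo status requires both parents genotyped non-carrier; an untested
parent leaves the flag unset with an `unconfirmed` note.

## Power

"MAF 1 in 10,000" is interpreted as the collapsed qualifying-carrier
frequency p₀ = 10⁻⁴ in controls — the quantity the 2×2 carrier test
actually sees. Case carriers are Binomial(n_case, p₁) with odds(p₁) =
OR·odds(p₀); control carriers Binomial(n_control, p₀); power is the
fraction of replicates with two-sided Fisher p < α. Replicates share
common random numbers across candidate odds ratios, making the empirical
power curve monotone so the bisection for the minimal detectable OR is
well behaved; results are reported at one decimal with the binomial
Monte-Carlo standard error (≈0.003 near power 0.8 at the default 20,000
replicates). Significance is strict (p < α); α ≥ 1 is treated as "no
test", so the minimal detectable OR degenerates to 1 in that limit.

## Proinsulin truncation severity

Preproinsulin (110 aa: signal 1–24, B chain 25–54, C-peptide 57–87, A
chain 90–110) folds through three disulfide bonds, B7–A7 (31–96), B19–A20
(43–109) and A6–A11 (95–100). `cysteine_inventory()` compares a predicted
mutant against the reference, splitting conserved cysteines into retained
(before the first divergence) and novel (in a frameshifted tail), and
counts retained B-chain cysteines whose A-chain partners are lost.
`classify_pattern()` is rule-based on that topology alone: no A-chain
cysteine retained → `mody_like` (unpaired B-chain cysteines, milder
misfolding); a proper nonempty subset retained → `neonatal_like` (aberrant
crosslinking); otherwise `indeterminate`. Novel tail cysteines never change
the class — whether they can pair is a spatial question, answered
advisorily by `sg_distances()` on user-supplied coordinates (SG atoms, CB
fallback flagged, default cutoff 5.5 Å, chosen just above the ~4.8 Å
typical wild-type SG–SG distance; the cutoff is configurable because no
sharp literature threshold exists). The package never predicts structures.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code. `toy_transcripts()` bundles
synthetic models with realistic exon-count structure; the INS analogue
encodes the real human preproinsulin protein on an engineered CDS/3′UTR so
that the clinically reported variant names (p.Gln78*, p.Leu82GlyfsTer52,
p.Glu83ValfsTer58, p.Cys95*, p.Tyr103*, p.Tyr108*) arise from concrete
nucleotide edits, with the frameshift stops placed in the 3′UTR exactly
where the published Ter counts demand. These are synthetic stand-ins, not
RefSeq records.

`sim_cohort()` defaults to the study conditions: 2,571 cases against
155,501 controls, per-gene control carrier frequencies of a few per
hundred thousand and planted odds ratios spanning no-enrichment to the
several-hundred range seen for the established haploinsufficiency genes,
with synonymous variants planted at OR 1 in every gene as the calibration
category. Sites are planted as near-singletons (balanced assignment keeps
every site below the ultra-rare threshold deterministically), case carrier
status is drawn at the frequency implied by the true OR, and the truth
ledger records every realized count so downstream collapsing can be
checked exactly. Everything is byte-reproducible under a seed.

Deliberately not emulated: linkage disequilibrium, relatedness, sequencing
or genotyping error, per-gene mutational target size, covariate structure
and ancestry stratification. Passing tests on this generator therefore
demonstrate the correctness of the statistical machinery and bookkeeping
under the stated sampling model — not robustness to the technical artefacts
real cohorts carry.

Problem sizes used by the default test run: the cohort-level tests run the
full 155,501-control design (sparse carrier storage makes this cheap), the
frameshift oracle sweep covers 1,000 random engineered variants, recovery
and calibration simulations use 300–1,000 replicates, and the power
bisection uses 20,000 replicates. The whole suite completes in about a
minute on one core.

## Known limitations

* Printed per-gene results from count data can only be reproduced up to the
  effective per-gene analyzable sample sizes; when those denominators are
  not published, small rounding-level differences in extreme odds ratios
  are expected and should not be tuned away.
* The exact conditional framework conditions on both margins; estimates on
  tables with zero carriers anywhere are reported under explicit 0/∞/NA
  conventions rather than continuity-corrected.
* Central exact CIs are conservative at ultra-rare counts: empirical
  coverage of a nominal 95% interval sits above 95%, which the recovery
  tests assert one-sidedly.
* The essential-splice NMD assignment is an inference from intron position,
  not an observation; it is flagged in the output precisely so it can be
  excluded in sensitivity analyses.
* The LOD model assumes a fully informative dominant system with known
  phenotypes; penetrance enters per-individual, not via liability classes.
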
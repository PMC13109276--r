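# modyburden

Gene-level burden analysis of ultra-rare loss-of-function (LOF) variants in
MODY genes, stratified by predicted nonsense-mediated decay (NMD) status.

Maturity-onset diabetes of the young (MODY) is autosomal-dominant,
young-onset, non-autoimmune diabetes. Whether a truncating variant in a MODY
gene causes disease depends not only on the gene but on where the premature
termination codon (PTC) lands: transcripts with a PTC more than 50 bp
upstream of the last exon–exon junction are degraded by NMD
(haploinsufficiency), while PTCs in the final exon or the last 50 bp of the
penultimate exon escape NMD and produce truncated protein with
gene-dependent effects. `modyburden` is for statistical geneticists and
diagnostic laboratories who want to run, stress-test, or teach this style of
analysis: a clinically ascertained case cohort compared against a large
population control cohort, gene by gene and NMD class by NMD class.

## What the package computes

* **Transcript models and coordinates** — exon/CDS structures with HGVS-style
  c. mapping on either strand (`transcript_model()`, `genomic_to_cdna()`),
  read from GFF3+FASTA or a small JSON dialect; bundled synthetic toy models
  for the ten MODY genes (`toy_transcripts()`), including a 3-exon INS
  analogue encoding real human preproinsulin.
* **LOF annotation** — consequence classes (stop-gain, frameshift, essential
  splice, synonymous, …), truncated-protein prediction with frameshift
  read-through into the 3′UTR and HGVS `fsTer` naming
  (`annotate_variants()`, `predict_mutant_protein()`), and the 50-bp NMD rule
  (`classify_nmd()`).
* **Carrier collapsing** — strict ultra-rare MAF filters assessed against
  controls plus an external reference, never cases
  (`ultra_rare_filter()`), and dominant-model carrier collapse to per-gene,
  per-category 2×2 tables (`collapse_carriers()`).
* **Exact inference** — for a table with `a`/`b` case carriers/non-carriers
  and `c`/`d` controls, the case-carrier count conditional on both margins is
  noncentral hypergeometric with odds-ratio parameter ψ:

  P(X = x | ψ) ∝ C(a+b, x) · C(c+d, s−x) · ψˣ,  s = a + c.

  The package reports the conditional MLE of ψ (the Fisher-exact-associated
  estimator, solving E<sub>ψ</sub>[X] = a), a central exact 95% CI by
  one-sided tail inversion, the two-sided Fisher p under probability-mass
  ordering, Bonferroni correction, and Zelen's exact test of odds-ratio
  homogeneity (`burden_test()`, `conditional_mle_or()`, `exact_ci()`,
  `fisher_two_sided()`, `or_homogeneity()`).
* **Co-segregation** — meiosis-counting LOD scores under a dominant model
  with configurable penetrance (LOD = n·log₁₀2 for n concordant meioses at
  full penetrance) and de novo flagging (`lod_score()`,
  `detect_de_novo()`).
* **Power** — simulation-based power and minimal detectable odds ratio for
  the carrier design (`power_at()`, `min_detectable_or()`).
* **Proinsulin truncation severity** — cysteine inventories of predicted
  mutant proinsulins and a topology rule separating MODY-like truncations
  (A chain lost, B-chain cysteines unpaired, milder misfolding) from
  neonatal-like ones (partial A-chain cysteine retention, aberrant
  crosslinking), plus SG–SG distance measurement from PDB coordinates
  (`cysteine_inventory()`, `classify_pattern()`, `sg_distances()`).
* **Synthetic data** — seeded generators with truth ledgers for cohorts,
  transcripts and pedigrees (`sim_cohort()`, `sim_transcripts()`,
  `sim_pedigrees()`), and an end-to-end orchestrator (`run_burden()`).

## Worked example

Enter the per-gene carrier counts for three genes (case cohorts of 2,571
individuals, 155,501 controls) and run the exact burden machinery:

```r
library(modyburden)

counts <- tibble::tribble(
  ~gene,     ~category,        ~a, ~b,   ~c,  ~d,
  "INS",     "NMD_escape",      3, 2568,   1, 155500,
  "NEUROD1", "LOF_all",         8, 2563,  23, 155478,
  "ABCC8",   "NMD_triggering",  6, 2565, 131, 155370)

res <- burden_test(counts, alpha = 0.05, n_tests = 20)
tidy(res)
#> # A tibble: 3 x 12
#>   gene    category         a     b     c      d or_cmle or_sample  ci_lo   ci_hi     p_fisher significant
#> 1 INS     NMD_escape       3  2568     1 155500  182.      182.   14.6   9537.   0.0000170    TRUE
#> 2 NEUROD1 LOF_all          8  2563    23 155478   21.1      21.1   8.15    48.9  0.0000000274 TRUE
#> 3 ABCC8   NMD_triggering   6  2565   131 155370    2.77      2.77  0.999    6.21 0.0251       FALSE
```

NMD-escape LOF carriers in *INS* are enriched about 180-fold over controls
and survive the Bonferroni threshold of 0.0025 (`bonferroni_threshold()`),
as does *NEUROD1*; the *ABCC8* signal does not. `autoplot(res)` draws the
forest plot.

Why do NMD-escape *INS* truncations cause MODY rather than neonatal
diabetes? Profile the bundled variant panel:

```r
ins_panel_profile()
#> # A tibble: 6 x 7
#>   name              nmd_class pattern       unpaired_b_cys novel_cys_n mutant_length
#> 1 p.Gln78*          escape    mody_like                  2           0            77
#> 2 p.Leu82GlyfsTer52 escape    mody_like                  2           0           132
#> 3 p.Glu83ValfsTer58 escape    mody_like                  2           2           139
#> 4 p.Cys95*          escape    mody_like                  2           0            94
#> 5 p.Tyr103*         escape    neonatal_like              1           0           102
#> 6 p.Tyr108*         escape    neonatal_like              1           0           107
```

The MODY-associated variants all remove the entire insulin A chain, leaving
both B-chain cysteines (B7, B19) unpaired — predicted milder misfolding —
while the neonatal-diabetes truncations keep three of the four A-chain
cysteines and lose only the fourth, permitting aberrant disulfide
crosslinking.

An end-to-end run on synthetic data:

```r
sim <- sim_cohort(seed = 1)          # 2,571 cases vs 155,501 controls
out <- run_burden(sim)               # annotate -> filter -> collapse -> test
tidy(out$results)
```

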
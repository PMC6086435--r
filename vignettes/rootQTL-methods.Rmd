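---
title: "Methods: dissecting small-effect root-trait QTLs in structured panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting small-effect root-trait QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

rootQTL implements an integrated strategy for mapping and shortlisting
candidate genes for small-effect quantitative trait loci (QTLs) in largely
homozygous inbred panels — the setting of rice diversity collections, where
two subspecies (*indica* and *japonica*) dominate the population structure
and an upland ecotype of *japonica* carries robust (long, thick) roots as a
drought-adaptation syndrome. The pipeline stages are:

1. **Variant QC** (`qcFilter`): keep variants with missing rate ≤ 50% and
   minor allele frequency ≥ 5% (allele-copy MAF, missing excluded);
   `ldPrune` offers greedy r² pruning in genome order for structure
   analyses.
2. **Structure model** (`computePCs`, `computeKinship`): PCs of the
   column-standardized dosage matrix; VanRaden method-1 kinship
   \(K = ZZ^\top / 2\sum_j p_j(1-p_j)\) on mean-imputed centered dosages.
   The kinship formula is a documented choice: the tools this pipeline
   emulates use a comparable default without printing one.
3. **Association scan** (`scanGLM`, `scanMLM`): per variant,
   \(y = \mu + \mathrm{PC}s + g\beta + (u) + e\). The GLM is exact least
   squares with a two-sided t-test on \(\beta\) (df \(n-k-2\) with \(k\)
   PCs). The mixed model adds \(u \sim N(0, \sigma^2_g K)\); the variance
   ratio is estimated **once** by REML on the null model via the spectral
   decomposition of \(K\) and reused for every variant (the P3D shortcut of
   compressed-MLM software). Optional compression clusters accessions on
   kinship distance and replaces \(K\) by the group-mean kinship; the group
   count comes from the grid \{n, n/2, n/4\} by null REML likelihood.
   Full per-variant REML is deliberately out of scope: at desk scale the
   difference is negligible and the contract is stated.
4. **Genome-wide threshold** (`conditionalThreshold`): the conditional
   permutation test. The trait is decomposed as \(Y = P + G\) with \(P\)
   the least-squares fit of \(Y\) on all PCs jointly (an intercept
   included); each permutation reshuffles \(G\) (Fisher–Yates), rebuilds
   \(P + G_r\), rescans with the same model, and records the genome-wide
   maximum \(-\log_{10} p\). The threshold is the stated percentile of the
   per-permutation **maxima** (the study-wide-cutoff convention of
   permutation thresholds); with 1,000 permutations at the 95th percentile
   this is the 50th-largest maximum. An alternative reading — the
   percentile of the pooled statistic distribution — is not the default
   because a single study-wide cutoff is reported; and a per-PC marginal
   decomposition is available via `decomposePhenotype(method = "marginal")`
   for fidelity testing.
5. **QTL calling** (`callQTLs`): significant variants chained while
   adjacent gaps are ≤ 170 kb (single-linkage on gaps, matching the LD
   decay scale of rice panels); chains of ≥ 3 SNPs become QTLs. Spans are
   min–max member positions without flanking extension; cross-population
   comparison (`overlapQTLs`) reports identical/nearby/unique classes and
   leaves the interpretation of "near" to the user, since no numeric
   definition exists for it.
6. **Candidate screening** (`buildPools`, `pooledChi2`,
   `annotateVariants`, `intersectLinkage`, `expressionFilters`,
   `integrateEvidence`): extreme pools of 20 accessions are drawn within
   the "typical" region of each subpopulation on PC1; per variant a Pearson
   χ² (1 df, no continuity correction) compares pool allele counts, and the
   trait-increasing allele (association β sign) must be enriched in the
   high pool. Variants are assigned to ORF / 2000-bp promoter / intergenic
   zones; coding SNPs are translated codon-wise (strand-aware, standard
   code). Candidate genes need a pooled-χ² pass, no linkage contradiction
   (genes in QTLs without linkage coverage keep a neutral flag), a
   non-synonymous or large-effect variant, and an expression pattern —
   RPKM ratio outside [0.77, 1.3] or root-specific expression; genes with
   everything but expression are **deferred** and promoted only if their
   haplotype–phenotype test rejects (`finalizeDeferredCandidates`),
   mirroring the third expression pattern (no differential expression but
   significant allelic phenotype differences).
7. **Haplotype statistics** (`buildHaplotypes`, `anovaDuncan`): gene-level
   haplotypes over non-synonymous/large-effect ORF variants plus promoter
   variants; protected one-way ANOVA across major classes with Duncan's
   multiple range letters, or a Welch t-test for exactly two classes.
8. **Adaptation scan** (`diversityStats`, `diversityRatios`,
   `pyramidingProfile`, `njTree`, `monophylyCheck`): per-gene π, Watterson
   θ and Tajima's D by group; diversity ratios with a selection flag at
   ratio > 4 and a D < −1 flag; mean trait-increasing allele frequencies
   per group; neighbor-joining trees on IBS distances from candidate-gene
   SNPs.

# Key parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `maxMissing`, `minMaf` | 0.5, 0.05 | QC fractions |
| `kPcs` | 3 | PC covariates in every model |
| `nPerm`, `percentile`, `prefilter` | 1000, 95, 2 | permutation count, percentile of maxima, \(-\log_{10} p\) pre-selection |
| `windowBp`, `minSnps` | 170000, 3 | QTL clustering rule |
| `nPerPool` | 20 | extreme-pool size |
| `alpha` | 0.05 | pooled-χ² and haplotype tests, uncorrected (a Bonferroni variant is a one-line change of `alpha`) |
| `eps` | 0.1 | RPKM pseudo-count stabilising ratios near zero |
| `majorMinFreq` | 0.05 | major-haplotype threshold (loci typically show 2–5 major haplotypes; no published cutoff exists, so this is a documented choice) |
| `flagAbove` | 4 | diversity-ratio selection flag |

"Large-effect" has no published definition; here it is stop gain/loss,
start loss, frameshift, or a position within 2 bp of an internal CDS
junction (splice boundary), and it is configurable in spirit: the
annotation table carries the consequence so any other rule can be applied
downstream.

The PC1 "typicality" cutoffs for pooling are data-specific absolute values
in the motivating study (−400/300 on its PC1 scale); the default here is
quantile-based — the middle 20% of PC1 is excluded — with absolute cutoffs
accepted through `pc1Cuts` for fidelity.

# The synthetic stated world

`simulatePanel` generates the panel every stage is validated on. Defaults:
two cultivated subpopulations of 300 inbred accessions each, 50 wild
outgroup accessions, 2 chromosomes × 2 Mb, 2,000 variants (5% small
InDels), 100 gene models, 5 causal genes with nominal effects of 0.5 trait
SD per allele copy, heritability 0.5, a 0.5 SD *japonica* trait shift, and
an upland sub-branch (40% of *japonica*) whose trait-increasing allele
frequency is boosted by 0.2 over the lowland 0.4 (wild sits at 0.2).

Design features worth knowing:

* **LD model.** Non-causal variants within a 50-kb block are drawn from 4
  block haplotypes per subpopulation — enough LD to exercise the
  clustered-significant-SNP QTL caller and LD pruning. Each causal variant
  additionally gets 6 intergenic "support" variants in strong LD (8% flip
  probability), providing the ≥ 3-SNP clusters a QTL needs. Support
  variants are placed outside genes and promoters so decoy genes do not
  inherit defining variants.
* **Causal planting.** Causal variants are non-synonymous SNPs at the
  second codon position of their gene's CDS (verified by translation at
  generation time); the ALT allele is trait-increasing. Causal genes carry
  expression signal: robust/control root RPKM ratios of 2 or 0.5, with the
  last causal gene root-specific instead.
* **Heritability scaling.** The genetic score is standardized and scaled
  to \(\sqrt{h^2}\), structure and noise fill the rest of unit variance;
  nominal effects stay nonzero while `effectScale` records the multiplier
  (0 when \(h^2 = 0\)). `realizedH2` verifies the generator lands within
  sampling error of the target.
* **Wild outgroup.** Independent draws from ancestral frequencies
  U(0.05, 0.5); the wild group therefore segregates for ≈ 99% of
  cultivated alleles, emulating "almost all alleles detectable in wild"
  without coalescent machinery.
* **What it does not emulate.** Realistic demography, recombination maps,
  linkage-map resolution, polyploidy, epistasis, genotyping error
  structure, or a *diversity reduction* at selected loci: selection is
  modelled as a frequency shift (0.4 → 0.6), which raises rather than
  lowers local diversity, so green tests establish the correctness of the
  diversity/ratio estimators (by exact oracles), not that the generator
  reproduces selective sweeps.

# Numerical choices

* \(-\log_{10} p\) is computed from `pt(..., log.p = TRUE)`, so it is
  stable far beyond the \(p = 10^{-308}\) double floor; an exact fit
  (residual sum of squares 0) is capped at 320, and a 0/0 statistic (zero
  trait variance after projection) reports \(-\log_{10}p = 0\).
* A genotypic component \(G\) that is numerically zero (trait fully
  explained by structure) is snapped to exact zero so all permutations
  coincide — otherwise scale-invariant t-statistics would amplify
  floating-point dust.
* The permutation prefilter (rescan only variants with original
  \(-\log_{10} p \ge 2\)) is a compute shortcut that truncates maxima
  below 2 and, because the set is selected on the observed scan, biases a
  family-wise-error calibration; the FWER test therefore runs with the
  prefilter off. Production thresholds inherit the shortcut's caveat, as
  in the original procedure (which rounded its threshold up above the
  permutation percentile). The suite runs 200 permutations instead of
  1,000 to stay inside its compute budget; the order statistic
  (k-th largest with \(k = \lfloor n_\mathrm{perm}(1 - q/100)\rfloor\))
  is unchanged.
* Mixed-model weights use eigenvalues clipped at zero (with a warning)
  when \(K\) is not numerically PSD.
* Duncan's test uses studentized-range quantiles at protection level
  \(1-(1-\alpha)^{p-1}\) for a span of \(p\) means, harmonic-mean group
  sizes for unequal \(n\), step-down testing in which a non-significant
  range protects all sub-ranges, and runs only when the ANOVA rejects
  (protected test). Letters follow maximal non-significant runs of the
  sorted means. Whether the original two-group t-tests pooled variances is
  unstated; Welch's form is used and documented as a divergence risk.
* Diversity: inbred dosages are haploidized (residual heterozygotes set
  missing); per site \(\pi\)-contribution \(2\hat p(1-\hat p)\,n/(n-1)\)
  with site-wise \(n\) (pairwise deletion); sites with \(n < 4\) are
  skipped by default (`minN = 2` recovers the classic two-sequence
  definition); \(a_1\) and the 1989 variance constants are evaluated at
  the harmonic-mean site-wise \(n\); the region length \(L\) (gene span)
  is the denominator, so absolute π depends on the \(L\) convention while
  group ratios do not — which is why ratios, not absolute π, carry the
  selection flags. \(D\) is reported missing (never 0) when \(S = 0\) or
  fewer than 4 sequences are available.
* Ties in pool construction are broken by accession id; heterozygous
  dosages count one allele copy in MAF and pools but exclude an accession
  from haplotype construction (inbred-panel assumption; the source
  procedure is silent on both).
* NJ trees come from the standard Saitou–Nei implementation (`ape::nj`)
  on IBS mismatch distances with pairwise deletion; negative branch
  lengths are clipped to 0. Clades in `monophylyCheck` are relative to the
  tree's representation root; pass a wild accession as `outgroup` for a
  biologically rooted check.

# Known limitations

* The mixed model is P3D-style, not per-variant REML, and is a documented
  equivalent — not a bit-level clone — of any specific GWAS package.
* Multiallelic records are skipped on VCF input; imputation and phasing
  are out of scope.
* The pooled-χ² α is uncorrected by default, matching the screening
  procedure it reproduces; treat downstream candidate counts accordingly.
* Acceptance-scale simulations cannot reproduce the headline counts of a
  795-accession, 3.3-million-SNP panel; the tests are property- and
  recovery-based on the synthetic stated world instead.
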
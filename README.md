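# gbsconcord

Do two DNA sampling methods tell the same genetic story? For rare or
protected animals — the motivating case is unionid freshwater mussels —
non-destructive visceral swabs are far gentler than tissue biopsies, but they
yield less DNA and fewer sequencing reads. `gbsconcord` implements a
desk-scale, fully testable version of the workflow used to answer whether
that matters for genotyping-by-sequencing (GBS): from multiplexed reads
through de novo reference construction, genotype likelihoods, a defined SNP
filter cascade, Bayesian genotype probabilities, and a PCA + Procrustes
concordance evaluation of the two sampling arms.

Because real method-comparison data are large and external, the package
ships a synthetic GBS generator with known ground truth that emulates the
two arms' contrasting read profiles: a *tissue-like* arm (high total yield,
reads spread broadly over loci at low depth) and a *swab-like* arm (low
yield concentrated on few loci at high depth), both reading out the same
underlying genotypes.

## The statistics at the core

* **Genotype likelihoods.** For a biallelic site with per-read error rate
  *e*, a read shows the alternative allele with probability
  *g*/2·(1−*e*) + (1−*g*/2)·*e* for dosage *g* ∈ {0,1,2}; allele depths give
  the likelihood product per dosage. Allele frequencies are maximized by EM
  under Hardy–Weinberg.
* **Admixture genotype probabilities.** A conjugate Gibbs sampler on the
  hierarchical model *q*ᵢ ~ Dirichlet(1), *p*ₖℓ ~ Beta(1,1), allele-copy
  ancestry ~ Categorical(*q*ᵢ), data entering through the genotype
  likelihoods; posterior genotype probabilities are Rao–Blackwellized
  averages of P(*g* | *p*, *q*), averaged over chains after Gelman–Rubin
  convergence screening.
* **SNP filter cascade** (in order): biallelic → ≥80% individual presence →
  total depth ≥ 2*n* → paralog excess-depth (> mean + 2 SD) → mapping
  quality ≥ 30 → Mann–Whitney quality-bias |z| ≤ 1.96 (base and mapping
  qualities, ref vs alt reads) → minor allele frequency ≥ 0.05 → one random
  SNP per contig. Every stage is logged in a conservation-checked ledger.
* **Concordance.** PCA (centered, unscaled dosages) of each arm, then
  symmetric Procrustes: both configurations centered and scaled to unit sum
  of squares, optimal rotation from the SVD of the cross-product,
  *m*² = 1 − (Σ singular values)², and the Procrustes correlation
  *R* = √(1 − *m*²), judged against the *R* > 0.95 concordance criterion.

## Worked example

```r
library(gbsconcord)
res <- run_gbs_pipeline(sim_config(), seed = 1)
print(res)
```

```
gbs_pipeline (seed 1): 14 individuals, 2000 loci
-- own-reference design --
GBS sampling-method concordance
  arm tissue   (tissue-only ref):  1063 SNPs, per-SNP depth 10.23 +/- 6.10, 254825 reads
  arm swab     (swab-only ref):     173 SNPs, per-SNP depth 15.02 +/- 8.52, 69553 reads
  Procrustes R = 0.9938 (criterion > 0.95): concordant
```

Reading the output: the tissue-like arm generated ~3.7× the reads and
recovered ~6× as many SNPs, but each swab SNP was sequenced deeper — the
breadth-vs-depth trade-off between the two sampling methods. Despite the
two arms being assembled and genotyped completely independently (each
against its own de novo reference, with different SNP sets), the two PCA
ordinations of the 14 individuals superimpose almost perfectly
(Procrustes R = 0.994 > 0.95): the gentler sampling method would have led
to the same biological conclusions. `plot(res$concordance$own)` draws the
paired ordinations with an arrow per individual showing how its placement
moved between arms.

Stage-level functions (`simulate_method_reads()`, `demultiplex()`,
`build_reference()`, `map_reads()`, `apply_cascade()`, `gibbs_admixture()`,
`procrustes_concordance()`, ...) expose every intermediate step; see the
vignette in `vignettes/` for the model, parameter and design details.

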
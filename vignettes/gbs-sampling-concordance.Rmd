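---
title: "Evaluating sampling-method concordance for GBS: models and design choices"
author: "gbsconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sampling-method concordance for GBS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Non-destructive DNA sampling (e.g. visceral swabbing of freshwater mussels)
is gentler than tissue biopsy but yields less DNA and fewer sequencing
reads. For genotyping-by-sequencing (GBS) the practical question is not
whether the two methods give identical read sets — they demonstrably do not
— but whether the *patterns of genetic variation among individuals* they
recover are interchangeable. `gbsconcord` operationalizes that question as
a pipeline: both sampling arms of the same individuals are processed
independently (own de novo reference, own SNP discovery, own filtering, own
genotype-probability estimation), each arm is summarized by a PCA of
posterior mean genotype dosages, and the two ordinations are compared by
symmetric Procrustes superimposition. Concordance is declared when the
Procrustes correlation R exceeds 0.95.

## The synthetic truth model

Everything downstream is exercised against `simulate_truth()` /
`simulate_method_reads()`, so the assumptions baked into the generator
matter. The defaults describe the study conditions the package emulates:

* 14 diploid individuals from two collection localities with **no**
  allele-frequency divergence between localities (the labels are metadata
  only; a structured scenario can be built by simulating two truths).
* ~2,000 GBS loci of 84–86 bp (the post-trim read length of a 300–400 bp
  size-selected single-end library; fragment size is recorded as metadata).
  70% of loci are polymorphic with 1–2 variable sites; minor allele
  frequencies are uniform on [0.05, 0.5].
* Per-base sequencing error 0.005, with a two-component base-quality model
  (per-read high quality Q34–Q40 for correct bases, Q10–Q25 at error
  positions) so that the downstream quality-bias filter has real signal.
* 10–20 bp multiplex identifiers (default 10 bp), pairwise Hamming
  distance ≥ 3.

### Why the individuals are related

A subtle but decisive modeling choice: if the 14 individuals were drawn
i.i.d. from Hardy–Weinberg proportions at every site, the leading PCA axes
would be pure sampling noise, and ordinations computed from *different* SNP
subsets (which is exactly what two independently assembled arms produce —
one arm may genotype 1,000 sites, the other 150, partially overlapping)
would be essentially uncorrelated. No pipeline, however accurate, could
then reach R ≥ 0.95 — at truth level, with exact dosages, the achievable R
is ~0.5. Real populations that show high between-method concordance
despite an order-of-magnitude SNP-count gap must therefore carry consistent
individual-level signal: relatedness.

The generator models this as a **founder-haplotype pool**: each individual
inherits two distinct haplotypes from a pool of 8 founders sampled with
geometrically decaying weights (decay 0.65 — a few successful breeders
dominate, as in a mussel bed seeded by sporadic host-fish dispersal), and
each locus switches to a random pool haplotype at rate 0.1 (so individuals
sharing founders are strongly related but never clones). Marginally, every
genotype is still a Hardy–Weinberg draw at the site's frequency, and the
two localities remain frequency-identical. Under these defaults the
truth-level ordination concordance between realistic arm-sized SNP subsets
is ~0.99, while two *independently drawn* truths (the negative control:
different genotypes, different realized kinship) give R ≈ 0.3. Setting
`n_founders = 0` recovers the literal i.i.d. model for experiments that
need it.

### Method profiles

`gbs_profiles()` encodes the two arms, scaled down by a common factor
(~1/86.5) from the study's per-individual yields so that printed mean ± SD
read totals are directly representable by the truncated-normal yield model:

| profile | mean reads | SD | capture breadth | allocation |
|---|---|---|---|---|
| tissue-like | 18,600 | 3,550 | 0.90 | Dirichlet(2) over captured loci |
| swab-like | 6,000 | 2,750 | 0.15 | Dirichlet(2) over captured loci |

The tissue/swab yield contrast preserves the printed (a − b)/b = 2.1.
Capture breadth is a *method-level* random subset of loci (all individuals
of an arm share it), and per-locus Dirichlet weights are drawn once per arm
— locus-intrinsic amplification bias. `depth_overdispersion` is the
Dirichlet concentration: smaller values concentrate reads on fewer loci,
which is the mechanism making the swab-like arm "fewer loci, deeper".

What the generator does **not** emulate: restriction-site sequence
polymorphism (allele dropout at cut sites), PCR duplicates, indels,
paired-end layout, reference bias from diverged paralogs, and
batch/lane effects. Passing tests therefore demonstrate the pipeline's
internal correctness and the logic of the concordance comparison — not
robustness to every artifact of real libraries.

## Stage-by-stage numerical choices

**Demultiplexing.** Exact prefix matching by default (`max_mismatches = 0`
— the conservative reading when a tolerance is unstated); with 1 mismatch,
same-length barcodes must be > 2 mismatches apart, validated up front.
Reads matching no barcode are counted, not guessed.

**Contaminant screen.** An ungapped sliding-window identity screen (≥ 0.9
over the full read) against a bundled *synthetic* 1.5 kb control-library
stand-in, seeded with 11-mers. This is deliberately not a full aligner;
at stack scale ungapped identity is the operative criterion.

**Reference construction.** Unique reads are retained iff total copies ≥ 4
AND sharing individuals ≥ 4. The two published phrasings of this rule
("less than four … removed" vs "more than four … retained") disagree at
exactly 4; we adopt the inclusive-at-4 convention common in de novo RAD
pipelines. Clustering is CD-HIT-style greedy incremental at 80% identity,
processing order (abundance desc, length desc, lexicographic) for full
reproducibility; the comparator is best-ungapped-offset identity with the
shorter sequence as denominator — for near-identical 84–86 bp stacks a
banded gapped alignment would change nothing, so it is omitted.

**Mapping and sites.** Best-identity ungapped placement (≥ 0.9 of read
length), ties between contigs → unmapped. The mapping quality is an
ambiguity surrogate: `-10·log10` of the posterior probability the placement
is wrong under a symmetric mismatch model across seeded candidate contigs,
capped at 60 (floor 10⁻⁶ on the error). Candidate variant sites need two
alleles each covered by ≥ 2 reads; a third such allele flags the site
non-biallelic. The reference allele is the overall major allele
(lexicographic tie-break); coordinates are 0-based internally, 1-based in
the VCF.

**Genotype likelihoods.** Single error-rate symmetric model (default
ε = 0.01, configurable); base qualities are *carried* for the bias filter
but do not weight the likelihood — the per-read quality-weighted model
would add a parameter per read without changing the desk-scale behavior.
EM for allele frequency converges at |Δf| < 1e-8 or 200 iterations; all-flat
sites return 0.5 with a no-data flag.

**Filter cascade.** Order: biallelic → presence → depth floor → paralog
depth → mapping quality → quality bias → MAF → thinning. Boundary
semantics, each chosen as the stricter/literal reading and asserted by
tests: presence uses `ceiling(0.8 n)`; the "2×n" depth floor is inclusive
(total ≥ 2n, i.e. mean per-individual depth ≥ 2 — we read "mean sequence
depth" as the per-site mean over individuals); the paralog cut is strict
(> mean + 2 SD of per-site mean depths, moments computed once before any
removal); MQ keeps exactly 30; the Mann–Whitney removal is strict
(|z| > 1.96) with midrank ties, tie-corrected variance
n₁n₂/12·[(N+1) − Σ(t³−t)/(N(N−1))], and no continuity correction (a flag
enables it); MAF keeps exactly 0.05. Quality-bias tests pool reads across
individuals (per-individual testing would be hopeless at per-individual
depths of 3–20). Thinning draws the per-contig survivor from a RNG seeded
by hashing the contig id with the stage seed, so the selection is invariant
to contig order and never perturbs the caller's RNG stream.

**Admixture model.** k = 2 by default with flat conjugate priors
(q ~ Dirichlet(1), p ~ Beta(1,1)); no hyper-priors — this is a transparent
stand-in for fuller hierarchical genotype-uncertainty software, not a
re-implementation of it. The desk preset (5,000 iterations, 500 burn-in,
thin 10, 2 chains) keeps a full two-arm run around a minute;
`preset = "study"` selects the heavyweight 50,000/5,000/10 schedule.
Genotype probabilities are Rao–Blackwellized (averaging P(g | p, q) over
retained draws), which both reduces Monte Carlo noise and guarantees the
documented limits: noiseless likelihoods pin the posterior at the true
genotype, and zero-depth cells shrink to the admixture-weighted
Hardy–Weinberg prior rather than to any fixed call.

**Convergence policy.** `average_genotype_probs()` screens Gelman–Rubin
R-hat ≤ 1.2 on every p and q parameter (population labels aligned across
chains first, by the permutation minimizing the distance between
posterior-mean frequencies) and refuses to average without an explicit
override. The *pipeline*, however, gates on a different summary: the
maximum between-chain difference in posterior mean dosage (≤ 0.2). The
reason is structural: with k = 2 on data that contain no real population
split, the per-population frequencies are only weakly identified — chains
can freeze into different arbitrary partitions of the individuals, which
legitimately inflates R-hat on p and q while the label-invariant genotype
probabilities agree across chains to within a few hundredths. Gating on
the dosages checks convergence of exactly the quantity the ordination
consumes; the p/q diagnostics remain available in every `geno_prob`.

**Ordination and Procrustes.** PCA on centered, unscaled posterior mean
dosages (no variance scaling — rare alleles should not be inflated;
dosage polarity is irrelevant because column sign flips leave SVD scores
unchanged). Procrustes is the symmetric variant on the first two axes
(2-D ordinations are what practitioners inspect; the axis count is an
argument), R = √(1 − m²); a seeded 999-permutation test is available
though the concordance criterion itself is the fixed R > 0.95 threshold.
The implementation is a direct SVD superimposition and is cross-checked in
the test suite against both a numeric minimization oracle and the vegan
implementation.

## Check problem sizes

The verification suite runs the complete two-arm pipeline at the full study
conditions (14 individuals, 2,000 loci) for three seeds — median R across
seeds is the headline check against the 0.95 criterion — and a five-seed
negative control (independently drawn truths) at 800 loci, where the median
R falls to ~0.3. Unit-level properties (filter boundaries, rank-sum z
against exhaustive enumeration for group sizes ≤ 6, PCA against an eigen
oracle at 1e-8, Procrustes against numeric minimization at 1e-6, EM against
a 1e-5 grid, genotype-mode accuracy ≥ 98% at depth 10) use fixtures of a
few dozen sites built in code.

## Known limitations

* The mapper is ungapped and single-orientation (GBS stacks from one cut
  site); it is not a general-purpose aligner.
* The admixture sampler fixes k; no model choice (DIC/WAIC) is provided.
* The quality-bias filter, like its real-world counterpart, removes ~5% of
  perfectly good SNPs at the 1.96 cutoff (two tests per site under the
  null); this is the documented cost of the published threshold.
* Procrustes R with 14 points is generous to chance agreement (random
  configurations give R ≈ 0.5–0.7); the negative control exists precisely
  to calibrate that baseline, and conclusions should rest on the contrast,
  not the absolute value.
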
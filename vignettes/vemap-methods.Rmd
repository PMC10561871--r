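---
title: "Methods: models and design choices behind vemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind vemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vemap)
```

# The assay being modelled

`vemap` implements the computational stages of a saturation variant-effect
map measured by yeast complementation. Human PSAT1 (phosphoserine
aminotransferase, the second enzyme of L-serine biosynthesis) can replace
its yeast ortholog SER1; in a *ser1Δ0* background, growth on medium lacking
serine is a quantitative readout of PSAT activity. Each assayed strain
carries one amino-acid substitution, growth is measured from plate images,
and scores are expressed on a scale where the null (deletion) control is 0
and wild type is 1. Diploids carrying two alleles model human genotypes,
including compound heterozygotes.

The package covers: enumeration of the SNV-accessible substitution space of
a CDS; pooled-sequencing variant calling with an empirical per-variant error
model; image-based growth quantification; linear-model growth
normalization; clinically anchored classification; a pairwise-additive
diploid predictor; and conservation statistics. A seeded synthetic-data
module generates every input, so the full pipeline is testable without
external data.

# Library design

`enumerate_snv_substitutions()` translates, for every codon except the
initiation and termination codons, all nine single-nucleotide changes,
discards synonymous and stop-gain changes, and keeps unique
(position, alternate amino acid) pairs. Under the standard genetic code
every sense codon yields between 4 and 7 unique substitutions (a fact we
verified by brute-force expansion of all 61 sense codons), so a 1,113-bp
CDS with 369 internal codons yields roughly 2,100–2,200 substitutions
depending on its codon composition. The packaged
`synthetic_psat1_like_cds.fa` is a *synthetic stand-in* of the same length
as the human PSAT1 isoform 1 CDS — it is a seeded random sense-codon
sequence, not the human sequence, and its substitution total (2,126)
reflects its own codons.

Design choices:

* Stop-gain and synonymous changes are excluded: the library assays
  amino-acid substitutions only.
* One variant codon per substitution, chosen as the highest-usage codon for
  the target amino acid in a supplied usage table (a reference
  *S. cerevisiae* table ships with the package), ties broken
  alphabetically. The choice is deterministic; the enumeration itself does
  not depend on it.
* Residues are numbered 1-based with the initiator Met as residue 1,
  matching p.Ala99Val-style HGVS labels, which serve as the join key across
  all tables.

# Pooled variant calling

Transformants are pooled in groups of up to 12 such that no target codon
appears twice in a pool. At each target codon the most frequent
non-reference codon is the candidate variant. Because sequencing errors can
generate spurious variant codons at reproducible, position-specific rates,
an error model is estimated from wild-type-only control sequencing with a
pseudocount over the 64-codon alphabet:

$$e_v = \frac{\text{count}_v + 1}{\text{total} + 64}.$$

A candidate is rejected when (i) its frequency is below 3.3× its error
frequency; (ii) the second most frequent variant is both ≥10-fold enriched
over its own error frequency and observed at >30% of the candidate's
frequency; (iii) it is supported by fewer than 15 reads; or (iv) a
nonsynonymous or nonsense secondary mutation is detected at a non-target
codon. Rejection uses strict inequalities ("less than 3.3×", "fewer than
15"), so values exactly at a threshold pass. Each no-call carries
machine-readable reasons, tallied in the run summary.

Two decisions deserve note. The caller operates on position-resolved codon
counts, not raw reads — basecalling and alignment are out of scope. And a
secondary mutation detected in a pool rejects *all* transformants of that
pool, because pooled reads cannot attribute the mutation to one
transformant; this is conservative relative to per-transformant
attribution.

# Image quantification

Plate images are cropped into 96 equal tiles labelled A1–H12 row-major.
Each tile is segmented by Otsu's threshold (implemented in the package; an
independent implementation is used as a cross-check in the tests); when the
foreground fraction falls outside a 1–60% plausibility band — inverted
contrast, empty or noise-only tiles — a fixed-radius centered circle is
used instead and the tile is flagged. The growth metric is the *pixelsum*:
the sum of grayscale intensities inside the patch mask. No background
subtraction is applied by default. Rendered plate images used in testing
place disk-shaped patches whose summed intensity equals the generating
observation's pixelsum, so render → crop → segment → measure is an exact
round trip for well-formed patches (8-bit PNG output adds quantization
error, which matters only for very faint patches).

# Growth normalization

All observations are fitted jointly with one linear model:

$$y_{i} = \beta_{g(i)} + \pi_{p(i)} + \delta\,\mathrm{edge}_i
  + \gamma\, z_i + \varepsilon_i,$$

where $\beta_g$ are genotype effects (one per variant isolate; the
wild-type and null controls are single shared levels), $\pi_p$ are
plate-replicate effects, $\mathrm{edge}_i$ flags perimeter wells, and
$z_i$ is the neighbor-competition covariate: the mean raw pixelsum of the
orthogonally adjacent wells, standardized within each plate-replicate.
Genotype effects are then rescaled affinely so the fitted null control is
exactly 0 and the fitted wild type exactly 1; negative scores are permitted
(below-null noise is not clamped). Diploid plates use the same model
without the neighbor term — the checkerboard pinning arrangement leaves no
orthogonal neighbors — and anchor on the homozygous controls. Pin-position
effects are not modelled; a reserved switch exists but is off because pin
normalization does not reduce noise in this design.

Isolate-level QC removes, first, isolates flagged for secondary mutations
(this rule takes precedence), then all isolates of any variant whose
isolate-to-isolate standard deviation exceeds a control-derived threshold.
The threshold is the 95th percentile of the per-plate standard deviation of
normalized wild-type control wells — i.e. a variant is dropped when its
isolates disagree more than technical replicates of a single genotype
plausibly can. The full-scale screen this emulates retained about 2.7
isolates per variant; the generator default is 3. Per-variant scores are
the mean of retained isolate scores with standard error $s/\sqrt{n}$
(single-isolate variants get SE 0 and a low-replication flag).

# The synthetic-data generators

The generators are first-class, tested code and define the conditions under
which the pipeline is validated.

**Allele effects.** Effects are drawn from a three-component mixture: an
unimpaired component at Normal(1.00, 0.035), a null-like component at
Normal(0.02, 0.03) truncated at 0, and an intermediate component at
Normal(0.86, 0.03), with weights 0.57/0.28/0.15, clamped to [0, 1.15]. The
weights and component placement echo the published class proportions of the
PSAT1 map (28% deleterious, 15% uncertain, 57% non-deleterious under the
82%/91% bounds). The intermediate component is deliberately concentrated in
the mildly hypomorphic range so those proportions emerge; real hypomorphs
spread across the whole (0.05, 0.95] band, so passing tests demonstrate
correct tabulation machinery at realistic class proportions, not a
distributional match to real data.

**Plate observations.** The generator emits data from exactly the model the
normalizer fits: genotype signal (background 2,000 plus effect × 50,000
pixelsum units), a Normal(0, plate_sd × signal) plate-replicate offset, an
edge offset (edge_factor − 1) × signal, and a neighbor-competition term.
The neighbor term is resolved self-consistently: observed pixelsums satisfy
$y = \text{base} + \gamma z(y)$ by fixed-point iteration, because real
neighbor competition responds to realized neighbor growth — and because
this makes the normalization model exactly well-specified, so recovery at
zero noise is exact to machine precision (a property the tests assert at
1e-6). The generating coefficient is calibrated so the penalty is
proportional to the mean neighbor growth *effect* (0–1 scale): with a
unit-variance standardized covariate, γ = −neighbor_coef × signal × sd of
the plate-centered mean-neighbor effect. Replicate noise is multiplicative
lognormal on the final pixelsum (growth data are positive and skewed; the
assay does not state a noise model). Isolates are arrayed in random well
order, as independently picked transformants would be; co-locating a
variant's isolates would correlate their local estimation errors. Control
wells are fixed: null at A1 and H12, wild type at A12, H1, D6 and E7 (the
assay specifies 2 + 4 controls per plate but not their positions).

At the default conditions (noise 0.05, plate_sd 0.1, edge 0.9, neighbor
0.2, 3 isolates × 3 replicates) variant-score recovery RMSE is below 0.02;
the property tests run this at 300 variants, a size at which the shared
anchor-estimation error is small and the lm fits in seconds.

**Pooled reads.** Per-position error-prone codons and their frequencies
(uniform in `error_rate_range`) are a deterministic function of the seed,
shared between pool and control simulation, so an error model estimated
from simulated controls matches the rates that generated the pools. Counts
are multinomial at the configured depth with the true variant at frequency
1/(pool size).

**Diploid pairs.** Observed diploid growth is generated from the
pairwise-additive model (below) with Gaussian noise. The default noise SD
of 0.07 matches the residual scale the assay reports for its experimental
diploids (cross-validated RMSE ≈ 0.0698). The default design emulates the
clinical genotype panel: 9 patient genotypes (8 from severe alleles drawn
on [0, 0.6], homozygous or compound heterozygous, plus one mild homozygote
with allele score on [0.75, 0.85], mirroring the mildest reported patient
genotype), 10 carrier genotypes (patient allele × wild type), homozygous
wild-type and null controls and two additional constructed genotypes — 23
pairs, matching the experimental panel size.

**Conservation profiles.** A synthetic stand-in for a per-residue
conservation table: the conservation score is a noisy monotone transform of
the realized per-residue median effect, with coupling strength 0.5 chosen
once to land in the moderate range reported for conservation–function
correlations (Spearman ρ ≈ 0.4–0.55 at survey scale); more negative scores
mean more conserved residues.

# Classification

Functional bands follow the assay's definitions: amorph (≤ 0.05, comparable
to the null control), hypomorph ((0.05, 0.95]), unimpaired (> 0.95).
Clinical evidence bands are derived from annotated anchors: the deleterious
bound is the *maximum* score among pathogenic anchors, the non-deleterious
bound the *minimum* among benign anchors, optionally extended by
primate-homozygote (primAD) variants, with no margin — bounds are exact
anchor extremes, which is how the published 82%/91% (ClinVar) and 82%/84%
(ClinVar + primAD) bounds arise. Scores at a bound take the adjacent
definitive class (≤ deleterious bound → deleterious; ≥ benign bound →
non-deleterious); above-wild-type scores are non-deleterious, since
increased activity is not associated with serine-deficiency disease. No
odds-of-pathogenicity calibration is attempted: the handful of annotated
variants in an ultrarare disease gene cannot support it.

# The diploid model

For a diploid carrying alleles with haploid scores $x_1, x_2$, order them
as $x_j = \min$, $x_k = \max$ (wild type contributes 1, null 0) and fit by
ordinary least squares:

$$d = a + b\,x_j + c\,x_k.$$

`fit_diploid_growth()` returns a classed fit with
print/summary/coef/predict/residuals/simulate/plot methods. Fitted to a
23-pair panel generated at the published coefficients (a = 0.05, b = 0.28,
c = 0.73) it recovers them within sampling error and explains ~97% of
variance; with zero noise recovery is exact. Constrained alternatives — the
allele-mean model (b = c) and complete dominance of the higher allele
(b = 0) — are fitted by restricted OLS and compared with one-degree nested
F tests. Leave-one-out cross-validation refits on each n−1 subset.

A logistic regression of carrier-vs-patient labels on predicted diploid
growth, $\mathrm{logit}(p) = g + h\,y_p$, gives a decision boundary at
$-g/h$ (the growth value where p = 0.5). The positive class is the
high-growth carrier label so h > 0, matching the published sign convention.
Under complete separation — possible in a 19-genotype panel — the boundary
is reported as the midpoint between the classes with a separation flag.
Only the 19 trio genotypes (9 patients, 10 carriers) enter the logistic
fit; all 23 pairs enter the OLS fit.

`predict_all_pairs()` scans all $n(n+1)/2$ unordered allele pairs (with
repetition) in vectorized row chunks, accumulating a 1%-bin histogram and
the count of genotypes strictly below the boundary, so memory stays linear
in n; 1,916 alleles (1,836,486 genotypes) take a few seconds. Predictions
are not clamped: the homozygous wild-type prediction is a + b + c = 1.06 by
construction.

# Conservation statistics

Per-residue medians use the standard mean-of-middle-two convention;
residues with no tested variant are absent, not zero. The site-set test
(e.g. for the 12 cofactor-binding residues of PSAT) compares the median
growth of all variants at the set's residues against random residue sets of
equal size drawn without replacement — the permutation unit is the
*residue*, preserving the per-residue variant-count structure — with the
one-sided p-value $(1 + \#\{null \le obs\})/(1 + n_{perm})$, never below
$1/(n_{perm}+1)$; small instances can be enumerated exhaustively and the
tests verify agreement. Conservation–sensitivity association uses Spearman
rank correlation with average ranks for ties; amorph enrichment at
conserved residues (ConSurf < 0) uses a one-sided Fisher exact test;
external predictor comparison reports per-predictor Spearman ρ and the mean
|ρ| (predictors differ in scale and orientation).

# Numerical and interface choices

* All internal scores are fractions; `*_pct` columns are converted on read.
  TSV is canonical; CSV is sniffed.
* Every generator is a pure function of its inputs and the config seed;
  per-stage seeds are derived deterministically from the global seed.
* Rank-deficient normalization designs are reported with their aliased
  terms rather than silently dropped.
* The interface is the package's functions, `run_pipeline()` and
  `scripts/acceptance.R`; no shell entry point is shipped.

# Problem sizes and limitations

The test suite exercises tabulation-stage analyses at the survey scale
(1,914 variants, 1,916-allele pair scans) and measurement-stage analyses
(plate simulation + normalization) at 300 variants with 3 isolates × 3
replicates — about 8,600 observations and 900 isolate effects, where the
linear model fits in seconds and anchor-estimation error is negligible.
The variant-level data tables of the original assay are not redistributed
here; all survey-scale numbers in the tests and the acceptance script are
computed on the package's synthetic stand-ins at the conditions above, with
the assay's published constants (filter thresholds, anchor extremes, model
coefficients) used as inputs. Consequently the pipeline's agreement with
the published map is demonstrated structurally (same rules, same models,
same scales) rather than numerically on the original data. The generators
also idealize reality in known ways: no image artifacts (condensation,
lighting gradients), no indel or basecalling error structure in reads, an
intermediate effect component narrower than real hypomorph spread, and
conservation scores coupled to function by construction rather than by
evolution.
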
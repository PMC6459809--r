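---
title: "From regional transcriptomes to circuit hypotheses: methods and design choices"
author: "CoexCircuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From regional transcriptomes to circuit hypotheses: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CoexCircuits reimplements, as a tested and reusable pipeline, a
systems-genomics workflow for multi-brain-region expression studies of
selectively bred lines: a line bred for an extreme behavioral phenotype
(e.g. high binge-like alcohol drinking) is compared with its genetically
heterogeneous founder stock across several interconnected brain regions, and
the correlation structure of the transcriptome is used to move from gene
lists to cell types to candidate neural circuits. This vignette explains the
statistical machinery stage by stage, states every tunable parameter with
its default and rationale, and documents the design decisions made where the
underlying methods literature leaves the choice open.

## The study design and the synthetic generator

The pipeline is organized around a 2 genotype x 7 region x 12 replicate
design (168 samples): genotypes `selected` and `control`, regions PFC, AcbC,
AcbSh, BNST, BLA, CeA and VTA — the mesocorticolimbic and extended-amygdala
circuitry that regulates motivated behavior. Because no external data ship
with the package, a synthetic generator (`generateDataset()`) produces
datasets with known ground truth that every downstream stage is tested
against.

The generative model for gene $g$ in module $m$, sample $s$ is

$$x_{gs} = b_g + r_m(\mathrm{region}(s)) + \delta_m(\mathrm{region}(s))\,
\mathbb{1}[\mathrm{selected}(s)] + \lambda\, F_{ms} + \varepsilon_{gs},$$

with a per-gene baseline $b_g \sim N(7, 2^2)$ (log2 intensity scale), a
per-module region profile $r_m$, a per-module genotype effect $\delta_m$
restricted to a subset of regions, a per-module, per-sample standard-normal
latent factor $F$ scaled by the loading $\lambda \in (0,1)$, and Gaussian
noise. The latent-factor form is chosen deliberately: it creates exactly the
block-correlation structure that weighted coexpression analysis assumes, and
it keeps the analytics closed-form — the expected within-module correlation
of a flat module is $\lambda^2 / (\lambda^2 + \sigma^2)$, which for the
default $\lambda = 0.8$, $\sigma = 0.6$ gives $0.64$.

Defaults were fixed once, from what is realistic for brain microarray data,
and are not revisited per analysis:

* **8 modules, sizes 100–400** (2050 of 3000 genes), the remainder
  uncorrelated background. Two neuronal modules carry genotype effects in
  extended-amygdala/mesolimbic regions, three glial modules are tagged
  astrocyte / oligodendrocyte / microglia, and two flat "housekeeping"
  modules have no region profile — mirroring the empirical observation that
  cell type and region dominate brain expression variance while
  housekeeping-like modules vary little across areas.
* **Region-profile amplitude 0.3 log2** and **genotype effects 0.5 log2**:
  typical microarray effect sizes (published fold changes for such selected
  lines run roughly 1.2–2.7 linear, i.e. ~0.3–1.4 log2).
* **Baseline spread sd 2 log2**: wide per-gene expression levels are what
  make sample profiles mutually correlated, which in turn is what makes
  distance-based outlier detection meaningful after quantile normalization.
* **Two planted outlier samples** (control arrays in AcbC and BNST),
  emulated as profile-scrambled (degraded) arrays. A constant intensity
  shift would be erased by quantile normalization (it is rank-preserving),
  so degradation is modeled as a permutation of the sample's values across
  genes, which decorrelates the array from its region.
* **Detection p-values**: Beta(0.1, 10) for present gene-regions (sharp mass
  near 0), Uniform(0, 1) for absent ones; 5% of background genes are absent
  in a random subset of regions. Simple, with controllable pass rates.

One global RNG stream is seeded from the config; per-module draws happen in
a fixed order, so an identical seed and config reproduce the dataset
byte-for-byte.

What the generator does *not* emulate: bead-level microarray structure,
probe sequence or SNP-in-probe artifacts, batch effects, heavy-tailed or
intensity-dependent noise, and correlated background genes. Tests that pass
on this generator therefore certify the statistical machinery, not
robustness to every artifact of real arrays.

## Preprocessing

Order: normalize, remove outlier samples, re-normalize the survivors, filter
undetected genes, mask per-value outliers.

* **Normalization.** Quantile normalization across all samples (sorted
  values replaced by cross-sample rank means; ties get the mean of their
  tied positions — deterministic and standard). For raw positive intensities
  a `log2(x + 1)` variance-stabilizing transform is available; it is a
  deliberate, documented simplification — a bead-level variance-stabilizing
  transform needs per-bead variance data that a plain expression matrix does
  not carry.
* **Sample outliers** (`removeOutlierSamples()`): within each region, the
  Euclidean distance of each sample to the region's mean profile; a sample
  is removed when its distance strictly exceeds **2 x the median** of those
  distances. One pass only; regions with fewer than 3 samples are skipped.
  Euclidean distance on normalized expression is the concrete reading of
  "distance to the sample average".
* **Detection filter** (`detectionFilter()`): per region, a gene is kept
  when detection p < 0.05 in at least 75% of that region's samples (the
  boundary is inclusive: 9 of 12 passes). Cross-region analyses (the
  network) use genes detected in **all** regions; per-region differential
  expression uses each region's own universe.
* **Grubbs masking** (`grubbsFilter()`): per gene within each genotype x
  region cell, the most extreme value is masked when
  $G = \max_i |x_i - \bar x| / s$ exceeds
  $\frac{N-1}{\sqrt N}\sqrt{t^2/(N-2+t^2)}$, $t$ the upper $\alpha/(2N)$
  t-quantile on $N-2$ df ($\alpha = 0.05$). The test repeats until clean,
  stops below group size 6, and never removes more than half a group —
  iteration policy and guards are package choices where the method itself
  is silent. Masked values are `NA` everywhere downstream; group sizes and
  degrees of freedom adjust gene-wise.

## Differential expression

Per region, a two-group comparison with empirical-Bayes variance shrinkage.
With per-gene pooled variance $s_g^2$ on $d_g$ df (unequal across genes
after masking), the hyperparameters of the scaled inverse-chi-square prior
are estimated by the method of moments on $\log s_g^2$: solve
$\mathrm{var}(e_g) = \overline{\psi'(d_g/2)} + \psi'(d_0/2)$ for the prior
df $d_0$ by Newton inversion of the trigamma function (tolerance $10^{-8}$,
$d_0 > 10^6$ treated as infinite), then the prior variance $s_0^2$ from the
mean. The posterior variance is
$s^2_{\mathrm{post}} = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
moderated t is referred to $t_{d_0 + d_g}$. At $d_0 = 0$ this reproduces the
ordinary pooled t exactly (the package tests assert relative error below
$10^{-10}$, and the hyperparameter fit is cross-checked against an
independent reference implementation). Fold change is reported signed:
$|FC| = 2^{|\Delta|}$, sign that of $\Delta$ (selected minus control).

The excess of DEGs over chance is a 1-df chi-square on the
(significant, not significant) pair against expected counts
$(\alpha N, (1-\alpha) N)$, without continuity correction (two cells, large
N). BH q-values use the standard step-up construction. Region-wise t
profiles of the top genes (raw p < 0.001 somewhere) are K-means clustered;
k defaults to 6 with 25 restarts under a fixed seed — k is a visualization
choice, not an inference.

## The signed coexpression network

* **Similarity** $S_{ij} = (1 + \mathrm{cor}(x_i, x_j))/2$, Pearson on
  pairwise-complete observations; signed so that anti-correlated genes are
  *unconnected* rather than connected.
* **Adjacency** $a_{ij} = S_{ij}^\beta$. $\beta$ defaults to 12 (the
  conventional signed-network power) or is chosen as the smallest candidate
  whose connectivity distribution reaches scale-free fit index
  $R^2 \cdot \mathrm{sign}(-\mathrm{slope}) \ge 0.8$ (10 equal-width
  connectivity bins, log-log regression of bin frequency on bin mean).
* **Topological overlap**
  $\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
  with $\ell_{ij} = \sum_u a_{iu} a_{uj}$; genes overlap when they are
  connected *and* share neighbours. $1 - \mathrm{TOM}$ is the clustering
  dissimilarity.
* **Module detection**: average-linkage clustering, static cut at height
  0.995, minimum module size 80. The published dynamic "hybrid" tree cut is
  approximated by a deterministic recursive rule: a branch splits at its top
  merge when both children hold at least 80 leaves *and* the merge height
  exceeds the branch's median merge height. On homogeneous blocks
  average-linkage trees are highly unbalanced (the last merges attach small
  stragglers), so genuine modules rarely satisfy the both-children condition
  and stay intact, while branches concatenating two real modules split at
  their balanced top merge. Exact equivalence with the published
  implementation is a non-goal; recovery of planted modules (adjusted Rand
  index against ground truth) is the correctness surface. Modules are named
  by the conventional size-ranked color palette ("turquoise" largest, then
  "blue", "brown", ...), "grey" collecting unassigned genes.
* **Eigengene**: first principal component of the gene-standardized module
  submatrix (masked values mean-imputed), unit norm, oriented to correlate
  non-negatively with the module mean profile; variance explained reported.
* **Hubs**: $K_{in}$ is the sum of within-module adjacencies; hub genes are
  the top 20% by $K_{in}$ (ties broken lexicographically by gene id, for
  determinism).
* **Hub modules**: the underlying notion of a module's "connections" to the
  rest of the network needs an operational edge definition; the package
  defines edges as the **top quartile** of off-diagonal adjacencies among
  assigned genes (density 0.25). A sparser rule (say, the top 1%) retains
  only within-module pairs in any realistically modular network — the
  maximal between-module correlation of a factor model is bounded by
  $\lambda/\sqrt{k}$ for $k$ modules, always below the within-module value —
  which would make every score identically zero. `scoreAll` counts retained
  edges with exactly one endpoint in the module, normalized by module size;
  `scoreTopQuartile` restricts to the top quartile of retained edge weights.
  The exported Cytoscape edge list uses a sparser density (1%) purely for
  file-size practicality.

The benchmark scale (3000 genes, 168 samples) keeps the dense gene x gene
matrices comfortable; matrices are dense by design and a warning is issued
above 20,000 genes.

## Module characterization

All enrichment questions share one statistic: the upper-tail hypergeometric
probability $P(X \ge k)$ of the observed overlap $k$ between a module
(size $n$) and a query set (size $K$) in the universe of the $N$ network
genes — the universe is always the transcripts used to build the network,
never the whole genome, and the observed overlap is included in the tail.
BH correction is applied **once per analysis family** (all module x set
tests jointly), never per module; q < 0.05 is the significance rule
throughout.

* **Selection-responsive**: modules over-represented with per-region,
  per-direction DEG lists (raw p < 0.05 DEGs; a q-based list is available
  behind a flag). Any significant (region, direction) flags the module.
* **Cell types**: marker collections (GMT) for neurons, astrocytes,
  oligodendrocytes, microglia, endothelium, etc.; a module is assigned every
  marker set with q < 0.05, and "cell-type-specific" means at least one
  assignment. The grey pseudo-module is excluded by default.
* **Region dependence**: one-way fixed-effects ANOVA of each eigengene
  across regions; constant eigengenes report F = 0, p = 1 by convention.
* **Generic gene sets**: the same machinery over arbitrary collections
  (e.g. an immune-response signature).

## Cross-species conservation

Ortholog tables are reduced to one-to-one pairs — sources or targets
appearing more than once are dropped and counted as ambiguous (a
conservative choice; resolution by sequence similarity is out of scope).
Each network pair is compared on its own shared universe (the intersection
of gene sets after mapping). Every non-grey module pair is tested by the
same hypergeometric upper tail; edges with raw p < 0.001 form the
meta-network, weighted by $-\log_{10} p$. The raw-p threshold (no
multiplicity correction) follows the conventional meta-network practice for
this analysis; a BH-corrected variant sits behind a flag. A module is
*conserved* when it keeps at least one edge. Module prioritization then
intersects four criteria: selection-responsive, conserved, cell-type
specific, and connected to a disease-related, cell-type-specific partner
module. (A fifth line of evidence used in such studies — knowledgebase
upstream-regulator prediction — depends on proprietary content and is
deliberately not reimplemented; hypothesis records carry a free-text
annotation slot for it.)

## Circuit hypotheses

Per module and region, a regulation call is derived from the per-direction
enrichment q-values: "up" or "down" when exactly one direction is
significant, "mixed" when both are, "none" otherwise. For neuron-specific,
selection-responsive modules, every ordered region pair that is regulated at
both ends and present as a directed edge in the anatomical connectivity
table becomes a hypothesis, scored
$-\log_{10} q(r_1) - \log_{10} q(r_2)$ — a simple, monotone evidence
combination chosen because the source methodology offers no quantitative
rule. Coregulated pairs with no edge in either direction are emitted
separately as *common-upstream* candidates (a third region may drive both).
The default connectivity table for the seven study regions ships as an
editable TSV fixture with citation tags; it is data, not code.

A caveat worth stating plainly: under a latent-factor coexpression model,
the factor's finite-sample imbalance between genotype groups within a region
(standard deviation $\lambda\sqrt{2/n}$, about 0.33 log2 at $\lambda = 0.8$,
$n = 12$) is itself a *genuine* module-wide expression difference,
comparable to realistic selection effects. Regulation calls therefore
reflect planted effects *plus* these chance module-level shifts, and at this
sample size the two cannot be separated by any per-region test. This is a
property of the biology-faithful model, not of the implementation; it is
the reason hypothesis lists should be read as ranked candidates for
experimental validation, not as detections.

## Numerical and testing choices

Degenerate inputs are handled explicitly: zero-variance genes get similarity
0.5 with a warning; singular module submatrices fall back to the
standardized mean profile; constant eigengenes give p = 1; all-equal
adjacencies abort the hub-score quantile with guidance. All tree cutting,
hub selection and output ordering are deterministic; the only RNG consumers
are the generator and K-means, both seeded.

Test and verification sizes are chosen to exercise the asymptotics while
staying quick on a laptop: calibration uses 21,000 null gene-tests (3000
genes x 7 regions, n = 12/group); power simulations plant 1.0 log2 effects
at noise sd 0.5 with factor loading 0.3 — the loading kept low so the
gene-level residual sd matches the nominal noise level the power analysis is
about; module recovery runs the full 3000-gene benchmark; replicate-based
checks (marker assignment, hub-module recovery, selection-responsive
flagging) use 10–20 replicates. Oracles are independent of the code paths
they check: exhaustive hypergeometric sums, the literal BH step-up
definition, the closed-form pooled t, and an external empirical-Bayes
reference implementation.

## Known limitations

* The tree cut is an approximation of the published dynamic hybrid
  algorithm; module boundaries can differ in edge cases even when planted
  structure is recovered.
* Quantile normalization couples samples: strong, asymmetric true signal in
  one sample class leaks small compensatory shifts into other genes.
* The hypergeometric enrichment tests treat genes as exchangeable;
  coexpressed genes are not independent, so module-level enrichment
  p-values are anti-conservative for factor-correlated modules (see the
  circuit caveat above).
* No batch correction, probe-level modeling, or module merging by eigengene
  similarity; orthologs are resolved by dropping ambiguity, not by homology
  scoring.
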
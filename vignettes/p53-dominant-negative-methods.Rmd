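---
title: "Quantifying the dominant-negative effect of Delta133p53 and Delta160p53"
author: "p53dnx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the dominant-negative effect of Delta133p53 and Delta160p53}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53dnx)
```

## The biological question

Full-length p53 (FLp53) is a tetrameric transcription factor. Its
N-terminally truncated isoforms Delta133p53 (residues 133–393) and
Delta160p53 (residues 160–393) lack both transactivation domains and,
critically, part of the DNA-binding domain (DBD, residues 94–292), while
retaining the oligomerization domain. They can therefore join tetramers
with FLp53 and, in principle, poison them — a dominant-negative effect.
The package quantifies three threads of evidence about how that
inhibition works:

1. **Structure**: what exactly do the truncations remove? Contact maps
   and solvent accessibility say which tertiary contacts are lost and
   whether the aggregation-prone segment ILTIITL (residues 251–257)
   becomes exposed.
2. **Stoichiometry**: how many isoform subunits does it take to
   inactivate a tetramer? Theoretical inhibition curves under different
   inactivation thresholds are compared with experimental reporter
   titrations.
3. **Assays**: reporter, ChIP-qPCR, fractionation and caspase readouts
   are reduced to the derived quantities the conclusions rest on.

## Structural truncation analysis

`domainLossFraction()` is pure arithmetic on author residue numbering:
the Delta133 truncation removes residues 94–132 of the DBD, 39 of 199
residues = 19.6%, which rounds to 20%; Delta160 removes 66/199 = 33.2%,
rounding to 33%. Author (PDB) numbering is used everywhere — every p53
range in the literature (94–292, 251–257, 133, 160) is in these
coordinates, so the package never re-indexes.

`computeContactMap()` implements the classic C-alpha contact rule:
residues are in contact when their C-alpha atoms lie within **8 Å**
(inclusive). A minimum sequence separation of **2** excludes the i/i and
i/i±1 pairs, which would otherwise dominate the map without saying
anything about tertiary structure; the separation is configurable since
published contact-density maps rarely state their diagonal handling.
`lostInterregionContacts()` then partitions a full-length map into pairs
*lost* by a truncation (exactly one member deleted — the informative
class: a retained residue loses a packing partner), *removed* (both
deleted) and *retained*; the three classes partition the map exactly,
which is property-tested.

`computeSasa()` is a direct Shrake–Rupley implementation: each heavy
atom's sphere, expanded by the probe radius (default 1.4 Å, water), is
sampled with a deterministic Fibonacci lattice of 960 quasi-uniform
points, and the accessible fraction is the share of points inside no
neighbouring expanded sphere. Van der Waals radii come from a fixed
Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Se 1.90 Å);
relative SASA divides each residue's area by the theoretical Gly-X-Gly
maxima of Tien *et al.* (2013). Both tables are exported via
`sasaReferenceTables()` and pinned in the tests. Tests check the
single-atom closed form $4\pi(r+probe)^2$ to 1%, and a caged-atom case
against an independent Monte-Carlo burial oracle with random (not
lattice) directions.

`exposedHydrophobics()` flags residues in a segment that are both in the
hydrophobic set {Ala, Val, Leu, Ile, Met, Phe, Cys} (positive
Kyte–Doolittle hydropathy) and have relative SASA at or above a
threshold, default **0.25** — a common surface/buried boundary; the
original surface-colouring analyses this mirrors do not state a numeric
threshold, so ours is an explicit substitute, not a reconstruction.
Exposure calls on predicted isoform models should accordingly be read
qualitatively.

## The tetramer stoichiometry model

Let $r$ be the isoform:FLp53 expression ratio (transfected plasmid
amount as the expression proxy — the same assumption the experiments
make). The isoform fraction of the monomer pool is $p = r/(1+r)$.
Assuming tetramers assemble by drawing four subunits independently from
the pool — the standard reading of random hetero-oligomerization — the
number of isoform subunits per tetramer is Binomial(4, p):

$$P(i) = \binom{4}{i} p^i (1-p)^{4-i}, \qquad i = 0,\dots,4.$$

An *inactivation threshold* $k$ states that a tetramer with at least
$k$ isoform subunits is transcriptionally dead. Expected pool activity
is $A(p) = \sum_{i<k} P(i)$ in the default **step** mode (tetramers
below threshold fully active). Because the cited theoretical model's
grading of partially substituted tetramers is not written out anywhere
we could consult, a **proportional** mode
($A(p) = \sum_{i<k} P(i)\,(4-i)/4$) is offered as the natural
alternative rather than guessing one; both give $A(0)=1$.

`theoreticalInhibitionCurve()` evaluates $A$ over a ratio ladder
(default 0/1/5/10, the experimental design).
`inferMinimalThreshold()` runs the rejection argument: a hypothesis $k$
is rejected when its theoretical curve under-predicts the observed
activity by more than `tol` (default **0.05** absolute activity — the
published comparison is a visual curve ordering, so the tolerance is
this package's explicit knob) at any nonzero ratio; the inferred
minimal threshold is the smallest surviving $k$, with sentinel 5 when
even $k=4$ fails. On curves generated with $k_{true}=3$ the
two-subunit hypothesis is rejected and 3 is recovered — the package's
quantitative form of "at least three isoform molecules per tetramer are
required".

`nuclearAdjustedFraction()` adds the compartment correction: only
nuclear, non-aggregated protein tetramerizes productively, so the
effective isoform fraction uses pools
$e\,(1-\text{sequestered})\,\phi_{nuc}$. Whenever the isoforms are less
nuclear and more aggregated than FLp53 — which is what the
fractionation data show — the effective fraction drops below the naive
expression fraction, weakening the hetero-tetramer route and shifting
explanatory weight to co-aggregation. Sequestration enters only as a
pool-depletion fraction; no aggregation kinetics are modelled.

## Assay quantification

* **Reporter**: replicates are divided by the mean of the empty-vector
  (pcDNA3.1) control; `reporterInhibitionCurve()` additionally rescales
  by the FLp53-alone point so curves start at 1. Summaries are mean ±
  SD of n = 3, matching the published triplicate design.
* **ExpDec1**: inhibition curves are fitted with the Origin
  parameterization $y = y_0 + A_1 e^{-x/t_1}$ by unweighted
  Levenberg–Marquardt least squares (weighting in the original fits is
  unstated, so none is applied). Starts are $y_0 = \min y$,
  $A_1 = y(x_{min}) - y_0$, $t_1 = (x_{max}-x_{min})/3$, with a short
  ladder of alternative $t_1$ starts because a single poor start can
  strand the optimizer; $t_1$ is box-constrained positive. Essentially
  constant $y$ is flagged non-identifiable (flat fit, $A_1 = 0$,
  $t_1 = \infty$) instead of returning a meaningless decay. Noiseless
  self-generated curves are recovered to $10^{-6}$ across a parameter
  grid.
* **ChIP-qPCR**: percent input is
  $100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ with $f$ the
  input fraction, and fold enrichment is sample over control percent
  input (control = 1). The formula is standard practice; the original
  methods state only the normalization targets, so it is pinned here
  and test-covered. The input fraction is never defaulted at the
  analysis level — it must be supplied, because the published methods
  do not print it (the synthetic Scenario uses 5%).
* **Response elements**: decamer half-sites are compared with the
  canonical consensus RRRCWWGYYY via IUPAC membership; matched bases
  render uppercase, mismatches lowercase. Half-sites are assumed
  contiguous (zero spacer); other lengths are rejected loudly rather
  than silently split.
* **Fractionation**: C/N = (cytoplasmic signal / cytoplasmic marker) /
  (nuclear signal / nuclear marker), re-expressed relative to FLp53
  (set as 1). `estimateCnEnrichment()` aggregates replicates by the
  geometric mean, the natural location estimator under multiplicative
  band noise.
* **Caspase**: fold = (sample − blank)/(control − blank) on replicate
  means.
* **Statistics**: pooled-variance two-sided Student's t-test by default
  (the captions' label), Welch available; no multiple-testing
  correction is applied because the original analysis applies none.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded and byte-reproducible, and exposes its ground
truth as an attribute, so each estimator has a parameter-recovery test.
Defaults are the published study conditions: threshold $k_{true}=3$,
step mode, ratios 0/1/5/10, triplicates, isoform C/N enrichment
**1.5**, FLp53 caspase induction **2.5**, an FLp53 C/N ratio of 0.5
(p53 is predominantly nuclear), reporter fold-activation 20 and ChIP
enrichments (p21 8, MDM2 4, BAX 2.5, PUMA 2) chosen as realistic
figure-scale magnitudes for a strong p53 response — the latter are
illustrative, since the underlying numbers are only published as bar
graphs. Noise is multiplicative lognormal (meanlog 0, so the multiplier
has median 1) for luminescence and band intensities — positive-valued
assays with scale-proportional error — and additive Gaussian on Ct
values, matching qPCR physics. The default CV of 10% is a stand-in:
the original work reports triplicate SDs, not CVs.

The generators emulate effect sizes and noise structure, not biology:
no transfection-efficiency drift, no promoter-specific activation
anomalies (the real PUMA promoter behaves non-monotonically at 1:1),
no saturation or plate effects. Passing recovery tests therefore shows
the estimators are correct and well-calibrated under the stated noise
model, not that real data are this clean.

Toy structures for the geometry tests come in two flavours: an ideal
alpha-helix (rise 1.5 Å, 100° per residue, radius 2.3 Å) whose contact
set is known analytically, and a compact cluster (rejection sampling at
minimum C-alpha distance 3.8 Å inside a sphere sized to ~38 Å$^3$ per
residue) whose contacts are checked against a brute-force all-pairs
oracle.

## Problem sizes and reproducibility

The recovery analyses use n = 1000 replicates for the fractionation
(CV 20%) and caspase (CV 10%) estimators — large enough that the
5%-accuracy checks reflect estimator calibration rather than sampling
luck — and 100 independent simulated experiments (triplicates, CV 2%)
for the modal minimal-threshold inference. Contact-map oracle
comparisons run at 50–100 residues. `scripts/acceptance.R` re-runs all
of these from a single command-line seed and writes the headline
numbers as JSON.

## Known limitations

* The binomial mixing assumption ignores dimer-of-dimers assembly
  pathways and any cooperativity; thresholds inferred under it inherit
  that assumption.
* Truncated-isoform structures are analyzed as user-supplied
  coordinates or as truncations of a full-length structure; the package
  does not predict structures, and exposure results on predicted models
  are qualitative.
* The contact "density" of published maps is reduced to per-region-pair
  counts (`regionContactCount()`); per-cell heatmap binning is a
  plotting concern left to the user.
* No aggregation kinetics, DNA-binding energetics, or image
  densitometry: analysis starts from intensity and Ct tables.
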
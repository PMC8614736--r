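---
title: "Measuring the cost of incomplete barcode libraries for benthic status assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the cost of incomplete barcode libraries for benthic status assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

Ecological status assessment of transitional waters under the Water
Framework Directive rests on benthic macroinvertebrate communities:
species are identified, counted, and condensed into descriptors (species
richness S, Shannon diversity H), a biotic index (AMBI) and a multivariate
score (M-AMBI) that maps each sampling unit onto five quality classes,
High through Bad. DNA-based identification can only see species that have
a reference barcode in BOLD or GenBank. `barcodegap` simulates the
molecular assessment by the *reduced database* device: restrict the
checklist to barcoded species, drop every individual belonging to a
non-barcoded species, recompute everything, and compare.

This vignette documents the models, the numerical choices, and the
synthetic-data design the tests rest on.

## Indices

**Richness and Shannon.** S counts taxa with positive abundance. H is
computed on abundance shares; the log base defaults to 2 (the convention
of the AZTI assessment software whose workflow this package parallels) and
is recorded in every result row, because H scales by 1/log(base). All
correlation analyses are base-invariant, so this choice cannot affect the
comparative conclusions.

**AMBI.** The AZTI Marine Biotic Index assigns each species to an
ecological group from I (sensitive) to V (first-order opportunist) and
scores a sample as the abundance-weighted mean of the group weights
(0, 1.5, 3, 4.5, 6), i.e. a 0–6 pollution gradient. Individuals of
species with no assigned group are excluded from the mean (the fractions
are renormalized) but counted in `na_fraction`; following standard AMBI
practice the value is flagged unreliable when more than 20% of individuals
are unassigned (`na_threshold`, configurable). Azoic samples receive a
sentinel (default 7) and are always classified Bad downstream. Group
assignments are user input: the curated AMBI species list is licensed
data and is not redistributed or guessed at.

**M-AMBI.** The multivariate index is reimplemented from its published
construction — a factor analysis of (AMBI, H, S) anchored by two
reference conditions — since the reference software is closed source.
The procedure is deterministic: pool sample rows with the "high" and
"bad" reference triplets, standardize each column over the pooled rows,
project onto the leading principal components of the correlation matrix
(all three by default, making the projection an isometry), and score each
sample by its coordinate along the bad→high axis, so the references map
to 0 and 1 exactly. Scores are clamped to [0, 1]; the raw value is kept
for diagnostics. With fewer factors the projection discards the trailing
component(s) first. Tie-free, rotation-free PCA was chosen over rotated
factor solutions because rotation does not change the bad→high axis
coordinate in the full-rank case and adds arbitrary convention in the
reduced-rank case.

Reference conditions are rarely published alongside survey results. The
default "bad" is the azoic condition (AMBI 6, H 0, S 0); the default
"high" is AMBI 0 with the observed maxima of H and S inflated by 15%
(`inflation = 1.15`), a common operational convention. When comparing
morphological against reduced runs the references derived from the
morphological data are shared with the reduced run by default, so that
the comparison isolates the library-gap effect rather than a shift in the
reference frame; `shared_refs = FALSE` restores per-database references.

**Class boundaries.** The M-AMBI scale is cut at 0.77 / 0.53 / 0.39 /
0.20 (boundary value belongs to the upper class), boundary values widely
used for transitional waters in WFD intercalibration; they are fully
configurable because assessments in different member states use slightly
different cuts. Published class grids can therefore be ingested directly
(`read_eqs_classes()`) and compared with `class_divergence()` without
recomputation — this is also how the packaged Apulian worked example is
used, since the abundance matrix behind it was never published and the
exact reference conditions of the original software run are unknown.

Divergence accounting uses the fixed ordinal encoding Bad = 0 … High = 4.
Any nonzero signed distance counts as a divergence, and the maximum
absolute distance is reported explicitly, so multi-class jumps are
surfaced rather than averaged away.

## Sequence analysis

**Consensus.** Per alignment column, the most frequent non-gap symbol
wins if its frequency exceeds 0.5; symbols tied at the maximum are
covered by the minimal IUPAC ambiguity code; all-gap columns are removed.
Input ambiguity codes count as atomic symbols, and ties union their base
sets. The operation is idempotent.

**K2P distances.** The closed form K = −½ ln((1−2P−Q)√(1−2Q)) over
comparable sites, with transition proportion P and transversion
proportion Q. Sites with a gap or any ambiguity code in either sequence
are excluded pairwise — conservative, rather than resolving ambiguities
probabilistically. When a log argument is non-positive the pair is marked
saturated, and tree building refuses matrices with saturated pairs
instead of imputing them.

**Neighbor joining.** Saitou–Nei with the standard Q-criterion. Ties are
broken by the lowest index pair in the current matrix ordering, so output
is reproducible; negative branch-length estimates are clamped to zero
with the deficit moved to the sibling branch, preserving the path length
between the joined taxa. The result is unrooted with a trifurcating root
node and is exact (topology and branch lengths) on additive matrices.

**PTP delimitation.** The Poisson Tree Processes model treats branch
lengths as exponential draws from two classes — between-species
(speciation) and within-species (coalescent). A delimitation is a set of
species subtrees; branches strictly inside them are within-species. For
each candidate partition the two rates are profiled out analytically
(MLE k/S per class), so the sufficient statistic per subtree is just the
(count, sum) of its within branches. This makes an *exact* search
possible by dynamic programming over these pairs; trees whose candidate
sets outgrow `exact_limit` fall back to a deterministic split/merge
hill-climb. The fitted delimitation is compared against a one-rate null
by AIC. The parameter count of the delimitation model includes its
estimated structure (two rates plus the species boundaries,
k = n_clusters + 1), the accounting used by multi-rate PTP
implementations; a flat two-parameter count would let the search overfit
its way past the null on any tree with heterogeneous branch lengths,
because the partition is itself optimized over thousands of candidates.

Two practical guards matter on distance trees. First, unrooted input is
midpoint-rooted (with a message), since PTP results depend on the root.
Second, branch lengths are floored at `min_branch = 1e-4`
substitutions/site: distance trees routinely contain exactly-zero
branches (identical sequences), and without a floor the exponential
likelihood of a class of zero branches diverges, letting the optimizer
"shave off" tiny branches as a pseudo-class. The companion workflow
`delimit_alignment()` additionally collapses identical haplotypes before
tree building — standard practice before PTP-type analyses — and maps
the duplicates back onto the final clusters.

**Primer matching.** IUPAC-aware compatibility (two codes match iff
their base sets intersect), forward primer scanned along the target and
reverse primer along the reverse complement, best-position hit with a
mismatch budget (default 3). The Folmer pair LCO1490/HCO2198 and a
degenerate variant ship as a text fixture and can be replaced by a user
file.

## Synthetic data

The generators provide the statistical structure the analysis assumes,
without any database download.

**Survey preset ("apulia-like").** 82 species across six phyla with
Mollusca, Annelida and Arthropoda making up ~93% of the checklist and
carrying per-phylum barcode probabilities 0.58, 0.65 and 0.73 (other
phyla 0.64) — the coverage regime of a southeast-Mediterranean
transitional-water checklist against the 2021 state of the reference
libraries. Fifteen sites sampled in two seasons along a disturbance
gradient spread over [0, 1]. Each ecological group has a fixed tolerance
anchor (I→0, II→0.25, III→0.5, IV→0.75, V→1); a species' occupancy
probability decays as a Gaussian kernel of the distance between site
disturbance and species tolerance (`occupancy_base = 0.55`,
`occupancy_bw = 0.35`), which enriches pristine sites in groups I–II and
disturbed sites in IV–V and makes expected AMBI increase monotonically
along the gradient. Abundances are log-normal counts
(meanlog 2, sdlog 1) — no abundance distribution is published for such
surveys, so this is a stated modeling choice, replaceable in the config.
Barcode flags are independent Bernoulli draws per source calibrated so
the union probability matches the per-phylum coverage. A master seed
fans out to fixed per-stage child seeds, so catalog, communities and
sequences can be regenerated independently.

**Accession sets.** A pure-birth species-tree topology with branch
lengths redrawn iid exponential at the between-species scale, a
coalescent-topology accession subtree per species with branches iid
exponential at the within-species scale, and sequences evolved under
K80 (`kappa = 4`) along the combined tree. Drawing both branch classes
from their exponential scales mirrors the PTP generative model, which is
exactly what a delimitation-recovery harness should simulate. Defaults
are taken from standard COI barcoding figures: within-scale 0.002
(~0.4% intraspecific divergence), between-scale 0.05 (~10%
sister-species divergence), i.e. the classic ten-fold-plus "barcoding
gap"; `seq_length` defaults to the 658 bp Folmer fragment. An earlier
design that rescaled the species tree to a fixed depth was abandoned:
it leaves the most recent speciation events arbitrarily shallow, so some
replicates contain species with no barcoding gap at all and recovery
failures say nothing about the method.

**What passing tests do and do not show.** The synthetic surveys
reproduce the *mechanism* of library-gap distortion — species loss,
deflated richness and diversity, class flips — under known, favorable
conditions: closed taxonomy, exact identification, no sampling error, no
PCR or sequencing artifacts, independent barcode flags. Real checklists
violate several of these (barcode availability clusters phylogenetically;
occupancy is not a clean function of one disturbance axis), so test
results validate the computations and their qualitative behaviour, not
any field-specific coverage number. Likewise the sequence simulations
test delimitation recovery under the PTP model's own assumptions;
real COI data add rate variation, selection and uneven sampling that
no desk-scale simulation captures.

## Problem sizes and numerics

The shipped tests and the acceptance script run at desk scale: surveys of
82 species × 30 site-season units (25–50 replicates), accession sets of
10 species × 3 accessions × 600 bp (20 replicates), exhaustive PTP
oracles on trees of ≤ 8 leaves, and NJ exactness on 100 random additive
matrices of ≤ 6 taxa. These sizes give stable statistics while keeping a
full run in tens of seconds.

Numerical conventions: percentages are carried unrounded and displayed
half-up; M-AMBI endpoint exactness is asserted to 1e-9; newick round
trips are written with 15 significant digits; all stochastic outputs are
pure functions of their seeds, with ties broken lexicographically
(NJ pair choice, PTP leaf order), so every reported number is exactly
reproducible.

## Known limitations

* M-AMBI is reimplemented from its published construction; closed-source
  implementations may differ in internal detail (rotation, reference
  handling), so published class grids should be compared via
  `read_eqs_classes()`, not recomputed from abundances unless the
  original configuration is known.
* Presence/absence data are accepted but degrade H and AMBI to
  richness-driven values; the reader warns when it detects them.
* No multiple-sequence alignment, likelihood tree search, bootstrap
  support, or Bayesian delimitation support values; externally built
  trees can be supplied as newick.
* Taxon joining is exact string matching after normalization; synonymy
  resolution belongs upstream.
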
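---
title: "Clonal architecture from multiregion tumour sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture from multiregion tumour sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonearch)
```

# The problem

Multiregion and longitudinal sequencing of a patient's tumour asks which
cell populations (clones) are present where and when: which mutations
define the most recent common ancestor, which mark subclones private to a
site or time point, and how the clones relate as a phylogeny. `clonearch`
implements this analysis for pairs (and, by consensus, larger sets) of
samples from one patient: cancer-cell-fraction (CCF) estimation, a battery
of mutation quality filters, two-dimensional CCF clustering, clone-tree
reconstruction, topology classification, mutational-signature refitting
and whole-genome-doubling calls — together with a synthetic generator that
provides ground truth for every one of these stages.

# The CCF model

For a mutation observed at variant allele fraction $v = a/d$ (variant
reads over depth), the expected allele fraction under clonality — every
tumour cell carries $m$ mutated copies — is

$$E[v] = \frac{m\,p}{p\,C_t + (1-p)\,C_n},$$

with tumour purity $p$, local tumour total copy number $C_t$ and normal
copy number $C_n$ (2 on autosomes). The cancer cell fraction is the ratio
of observed to expected allele fraction, $\mathrm{CCF} = v / E[v]$.

Two choices deserve comment:

* **Multiplicity.** On a segment with major allele copy number $M$, a
  mutation can occupy $1..M$ copies. By default the multiplicity is the
  value minimising $|\mathrm{CCF} - 1|$ — the clonality assumption — and
  the chosen value is recorded so that downstream conflict resolution can
  revisit it (`enumerate_multiplicities()`). When a cluster of mutations
  lands at CCF $\approx 2$ on a polyploid segment, clonality was the wrong
  assumption; rescaling by the feasible integer multiplicity closest to
  clonal resolves the conflict (`rescale_conflicting_clusters()`).
* **No truncation.** CCFs above 1 are preserved. Clustering needs to see
  them (they mark noise and multiplicity errors); truncation happens only
  at reporting.

Degenerate inputs are flagged, never dropped silently: zero depth
(`unevaluable`), no covering segment (`no_segment`), homozygous deletion
(`loh_deleted`), a within-sample subclonal copy number state
(`subclonal_cn`, excluded from clustering).

# The filter battery

Filters run in a fixed order and only annotate — read counts are never
modified. All thresholds live in one namespace (`default_config()`).

1. **Artifact filters (per sample).** Calls below allele fraction 0.2 are
   scrutinised: the forward–reverse score
   $1 - |f - r|/(f + r)$ must reach 0.2 (strand-balanced support), and the
   coverage–AF product must reach the read-count threshold
   ($\min(d_\mathrm{tum}, d_\mathrm{norm}) \cdot v \ge 10$), so low-AF
   calls survive only where coverage gives them power.
2. **Site filters (per patient).** Single-nucleotide mutations within
   10 bp (strict) of any indel call fail (mapping artifacts around
   indels); mutations in the outer 1.5% of the chromosome, in centromeric
   intervals, or where more than 10% of reads map with low quality are
   flagged (copy number estimates are unreliable there, hence so are
   CCFs).
3. **Unification and rescue.** Per-sample segmentations are unified on
   the union of breakpoints; the per-patient mutation list is unified, and
   a mutation passing all stringent filters in one sample is re-probed in
   the others with relaxed criteria (at least one variant read). Rescue
   is monotone and idempotent.
4. **LOH conflict.** A mutation on a segment with loss of heterozygosity
   in some but not all samples, private (or near-private, CCF < 0.2) to a
   sample lacking the loss, cannot be placed: its absence elsewhere may be
   the copy-number loss rather than subclonal origin. Excluded as
   ambiguous, as are mutations on segments whose within-sample subclonal
   copy number states involve LOH.
5. **Power trim.** The CCF contribution of a single mutated read,
   $(1/d)/E[v]$, is modelled per sample as log-normal; mutations in the
   2.5% tails ($z = 1.96$) on either sample are removed as over- or
   underpowered. Constant scores trim nothing; fewer than 10 scored
   mutations skip the trim with a warning.
6. **Private/shared test.** For a mutation called in exactly one sample:
   under the null that it is shared at the observed allele fraction $v$,
   the probability of seeing no variant read among $D$ reads in the other
   sample is $(1-v)^D$ (a configurable detection threshold $k$ generalises
   this to $P(X < k)$). Benjamini–Hochberg control at 5% across the
   pair's candidates; rejected candidates are truly private, the rest are
   excluded as underpowered rather than miscalled as private.

The normal-sample depth needed by the power gate is an optional input
column; absent it, the tumour depth stands in for the minimum. The
per-read power score is a reconstruction of the published idea (the exact
formula is not printed anywhere we could follow); it is the natural "CCF
increment of one read" quantity and is documented as such.

# Two-dimensional CCF clustering

Retained mutations of a sample pair are binned into a 2-D histogram
(bin width 0.05 over $[0, 1.5]^2$ — CCFs slightly above 1 must stay
visible; values beyond the range are clamped into the last bin). The
counts are fitted with a tensor-product B-spline surface under a Poisson
count model with a *single* smoothing parameter shared by both axes,
chosen by generalised cross-validation over a log-spaced grid; the count
model is what absorbs bin-level sampling jitter, so surface maxima are
stable under Poisson noise. Strict 8-neighbour local maxima above a floor
of 1% of the surface maximum become cluster centres (bin midpoints; an
off-grid refinement was considered and rejected for determinism).

Centre coordinates in the first bin are reported as 0: these are axis
(private) centres. Because the grid cannot distinguish coordinates inside
the first bin from the axis, rescued trace-level detections — shared
calls whose CCF falls inside the axis bin in exactly one sample — follow
the same convention and are assigned as near-private to the carrier side.
Without this, a subclone present at trace level in the second sample
splits between an axis centre its shared members may not join and distant
shared centres.

Assignment is nearest-centre by Euclidean distance under the kind
constraint (shared mutations to shared centres, private to private
centres of their side), with ties broken toward the centre with larger
summed CCF, then lexicographically. Clusters below four members are
deleted and their members re-assigned to the nearest surviving compatible
centre; a private side with at least four orphaned mutations founds its
own axis centre, otherwise those mutations are excluded as ambiguous.

# Clone trees, classes, and parsimony

Cluster centres are clone CCFs. The reconstruction searches rooted trees
over the clusters under two constraints with tolerance $\varepsilon = 0.1$
(the data give no sharper accuracy; the tolerance is configurable):

* **ancestry monotonicity** — a child's CCF cannot exceed its parent's in
  any sample;
* **the sum rule** — sibling CCFs cannot sum above their parent's in any
  sample (infinite sites: each mutation arises once).

The root C0 is the cluster clonal in every sample (all coordinates at
least $1 - \varepsilon$; coordinates above 1 are noise or multiplicity
error and do not disqualify). Several qualifying clusters are
indistinguishable at tolerance and merge; if none qualifies the highest
shared cluster is promoted with a warning flag. Among admissible trees
the search returns the one with the fewest branching events (maximum
parsimony — linear evolution preferred over branched); remaining ties
attach each clone to the admissible parent with the smallest CCF
(deepest attachment), then break lexicographically. Whether the linear
preference should apply per sample or globally is ambiguous in the
underlying methodology; the global minimum implemented here is the
simpler, deterministic reading. Clone labels C0, C1, … follow depth-first
order with larger-CCF children first.

Topology classes: **A** no subclones; **B**/**C** linear with one /
at least two subclones; **D**/**E** one branching event below / at C0;
**F** at least two branchings (a branching event is a node with two or
more children).

When no admissible tree exists, the pipeline first re-evaluates
multiplicity for clusters beyond CCF $1 + \varepsilon$; if a conflict
remains, `run_patient()` discards the smallest cluster (flagged
`dropped_unplaceable`) and retries — small conflicting clusters are
almost always assignment debris. `reconstruct_tree()` itself never
silently drops: called directly it fails with the violated constraints.

## More than two samples

Pairs are the unit of analysis (matching the exome power available per
sample); for patients with three or more samples every pair is clustered
and mutations are grouped by their tuple of per-pair cluster labels
("-" where a pair dropped the mutation, e.g. one absent from both of a
pair's samples). Groups of at least four mutations become clones with
per-sample centres averaged over pairs; groups indistinguishable at
$1.5\,\varepsilon$ merge; mutations whose CCF is unknown in some sample
(trimmed from every pair covering it) are excluded, since they have no
position in the joint CCF space. This consensus is a pragmatic extension
— the published analyses are pairwise — and is what lets two independent
branchings (class F), visible only across three or more tumours, be
recovered. For interpatient comparison `downscale_pairs()` selects the
representative pair maximising the number of subclones, then of
subclonal mutations.

# Mutational signatures

Catalogues are 96-channel trinucleotide spectra under the
pyrimidine-strand convention. Exposures are fitted by non-negative least
squares in count space; the cost is the L2 residual norm. Backward
selection removes, at each step, the signature whose removal increases
the cost least, as long as the cost stays within 2% (configurable) of the
full-model cost — only signatures that markedly reduce the cost are kept,
and the selected subset's cost is within the threshold of the full fit by
construction. Cohort prevalence requires a signature in at least 5 cases;
platinum signatures SBS31/SBS35 are force-included for post-treatment
subclonal fits, where platinum scars are expected a priori. Eligibility
is strict: clonal fits need more than 300 mutations, subclonal fits more
than 20 (how the "median over 300" clonal rule interacts with per-case
counts is ambiguous; the per-subset count rule used here is the stricter,
simpler reading and a config switch exposes it). Skipped subsets are
reported with the reason. Radiation-associated burden is summarised by
the indel/substitution and deletion/insertion ratios, with undefined
denominators reported as missing rather than zero.

The catalogue bundled under `inst/extdata/` is **synthetic**: 15 profiles
with COSMIC-style names whose shapes only loosely echo their namesakes'
characteristic channels, built deterministically by
`synthetic_sbs_catalogue()`. It exists so that examples and recovery
experiments run self-contained; real analyses must load a genuine COSMIC
matrix via `read_signature_catalog()`.

# Ploidy and genome doubling

A sample is high-ploidy at mean copy number 2.8 or above (inclusive).
Among high-ploidy genomes, doubling is separated from successive
independent gains by the genome LOH fraction — the length-weighted
fraction of the autosomal genome with minor copy number 0 (sex
chromosomes are excluded: hemizygosity confounds). A doubled genome
carries its pre-doubling LOH at even copy numbers and needs little LOH to
be high-ploidy, so the default call is
$\mathrm{ploidy} > 2.9 - 2\cdot\mathrm{LOH}$, a documented reconstruction
of the cited approach with both parameters configurable. Acquired
doubling between time points is simply post-WGD without pre-WGD; loss of
a doubling is not modelled.

# The synthetic generator

The generator emulates the study conditions of a multiregion exome
cohort: 2–3 samples per patient, mean coverage 127×, purity 0.85, genome
ploidy near 2.5 (allele-specific segments drawn per chromosome with
state weights meeting the target), hundreds of clonal mutations and tens
to hundreds per subclone (log-uniform between 50–500 and 10–200 by
default), Poisson depths (the single-parameter choice when only a mean
coverage is known) and binomial variant reads at
$E[v]\cdot\mathrm{CCF}$, with strand counts split evenly. Optional
artifact channels — FFPE-like strand-biased low-AF noise, indel calls
adjacent to SNMs, LOH segments — default off and exist to exercise the
filters.

Clone CCFs are drawn by recursive stick-breaking from the parent, so the
sum rule holds by construction and C0 is 1 everywhere. At each branching
the parent's active samples are partitioned among the children, giving
siblings crossing CCF patterns (neither dominates in all samples): this
is what makes a branching identifiable from data at all, and the
feasibility check rejects class/sample combinations that cannot be
embedded (class F needs three samples). In target-class mode a draw is
accepted only if the noiseless CCF matrix reconstructs to the requested
class at a stricter tolerance (0.15) — otherwise maximum parsimony could
legitimately flatten the branching — and only if clones are separated by
at least 0.25 in CCF space (the published separability regime; the
distribution of subclone CCFs in real tumours is unknown, so these
defaults are conventions, not estimates).

What the simulator does **not** model: read-level errors and mapping
(FASTQ/BAM are out of scope), germline variation, contamination by mouse
reads in xenograft material, subclonal copy number evolution, sequencing
batch effects, and clone CCF distributions estimated from real cohorts.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not performance on arbitrary
real data.

# Validation experiments and problem sizes

The test suite validates, among others: false-discovery control of the
private-mutation test under a global null (500 replicates × 2,000 shared
mutations at depth Poisson(120), purity 0.85 — the fraction of replicates
with any false "truly private" call must stay within the BH level);
end-to-end class and centre recovery (50 seeds per class A–F at depth
120, purity 0.85, separation 0.25, at least 50 mutations per clone;
recovery must reach 85%, centres within 0.1); equivalence of the tree
search with a brute-force enumeration oracle on 200 random cluster
configurations of up to 6 clusters; and signature recovery (cosine ≥ 0.9
against truth at 800 mutations, with backward selection retaining the
generating signatures in ≥ 90% of 50 seeds). These sizes were chosen so
the whole suite runs comfortably on a laptop while keeping Monte-Carlo
error well below the asserted margins.

# Known limitations

* Purity and ploidy are inputs, not estimated; errors in them propagate
  directly into CCFs.
* Subclones closer than ~0.25 in CCF, or sitting on the diagonal shoulder
  of a much larger clone, can merge under the smoothing — the dominant
  failure mode in the recovery experiments (class B/C chains at high
  subclone CCF).
* The pairwise consensus for ≥3 samples inherits each pair's exclusions
  and can split a clone across tuple variants; the merge step recovers
  most of these, the `dropped_unplaceable` fallback the rest.
* The binomial private test conditions on the carrier's observed VAF; for
  very low-powered loci the BH correction makes exclusion (not private
  status) the default, which is conservative by design.

```{r example, eval = FALSE}
# a complete synthetic run
b <- simulate_patient(3, 2, target_class = "E", seed = 1)
res <- run_patient(b)
res$class          # recovered topology class
res$tree           # labelled clone tree with per-sample CCFs
res$newick         # Newick export
```
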
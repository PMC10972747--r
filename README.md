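# clonearch

Clonal architecture and phylogeny reconstruction from multiregion and
longitudinal tumour sequencing.

## What it does and for whom

When several samples of one patient's tumour are exome-sequenced —
different sites, or the same site before and after therapy — the variant
allele fractions of somatic mutations encode which cell populations
(clones) are present where, and how they descend from one another.
`clonearch` is an R package for analysts of such data. It takes per-sample
mutation tables (read counts, strand counts), allele-specific copy number
segments and purity/ploidy estimates, and produces per-mutation cancer
cell fractions, quality-filter reports, two-dimensional CCF clusters,
a labelled clone tree with a topology class, mutational-signature
exposures and ploidy/whole-genome-doubling calls. A synthetic
tumour-evolution generator with full ground truth makes every stage
testable without access to patient data.

## The model in brief

For a mutation with variant allele fraction `v = a/d`, purity `p`, local
tumour copy number `C_t`, normal copy number `C_n` and multiplicity `m`
(mutated copies per tumour cell), the expected VAF under clonality is

    E[v] = m * p / (p * C_t + (1 - p) * C_n)

and the cancer cell fraction is `CCF = v / E[v]`, with `m` chosen in
`1..major_cn` to minimise `|CCF - 1|` (recorded, and revisited when
clusters conflict with phylogenetic rules). Filtered, paired CCFs are
binned into a 2-D histogram, smoothed with a tensor-product spline under
a Poisson count model (one common smoothing parameter, chosen by GCV),
and surface peaks become cluster centres; mutations join their nearest
centre under shared/private constraints with a four-mutation cluster
minimum. Cluster centres are clone CCFs; the clone tree is the
minimum-branching tree satisfying, in every sample, ancestry monotonicity
and the sum rule (sibling CCFs sum to at most their parent's), with
classes **A** (no subclones), **B**/**C** (linear), **D**/**E** (one
branching below/at the ancestor C0) and **F** (two or more branchings).
Signature exposures are non-negative least squares over a 96-channel
catalogue with backward selection; whole-genome doubling combines the
ploidy gate (≥ 2.8) with the genome LOH fraction.

The methods vignette (`vignettes/clonal-architecture-methods.Rmd`)
documents every model, threshold and design decision.

## Worked example

Simulate a two-sample patient whose true phylogeny has one branching at
the common ancestor (class E), then run the full pipeline:

```r
library(clonearch)
b   <- simulate_patient(3, 2, target_class = "E", seed = 1)
res <- run_patient(b)
res$class
#> [1] "E"
res$tree
#> clone_tree: 3 clones, 1 branching event(s), class E
#>   C0 <- root  [1.03, 0.98]  n=179
#>   C1 <- C0  [0.18, 0.78]  n=21
#>   C2 <- C0  [0.73, 0.00]  n=10
res$newick
#> [1] "(C1:0.5250,C2:0.6375)C0:0.0000;"
res$summary
#>   patient n_subclones n_subclonal_mutations class
#> 1     SIM           2                    31     E
```

Reading: 179 mutations are clonal everywhere (the ancestor C0, CCF ~1 in
both samples); one subclone lives mostly in sample 2 (CCF 0.18/0.78), one
is private to sample 1 (0.73/0) after the binomial private-mutation test;
both branch from C0, hence class E. `res$ploidy` adds per-sample
ploidy/LOH/WGD calls, `res$filter_report` the per-mutation filter
provenance, and `write_patient_results(res, dir)` persists every table
plus the tree as JSON and Newick. Real data enter through
`read_inputs(mutation_tsv, seg_tsv, purity_tsv)`; a thin CLI for the same
two steps ships in `inst/scripts/clonearch`.

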
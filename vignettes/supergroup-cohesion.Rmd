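---
title: "Testing genetic cohesion of bacterial supergroups with cohesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing genetic cohesion of bacterial supergroups with cohesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

*Wolbachia* and other deeply structured bacterial taxa pose a species
problem: are the named "supergroups" (here A and B, each sampled by three
genomes) merely arbitrary cuts through a continuum, or genuinely cohesive
gene pools that recombine freely inside but only marginally across the
boundary? cohesim implements the comparative-genomics inference chain used
to answer this from annotated genomes: extract the single-copy core, build
per-gene codon alignments, infer per-gene maximum-likelihood trees and
classify their topologies against the two-clade split, measure the
dispersion of per-gene synonymous divergences, run a four-method intragenic
recombination ensemble with fragment attribution, post-process per-site
recombination/substitution posteriors into r/m, and call group-specific
genes. A bundled sequence-evolution simulator generates data with known
ground truth so every stage can be exercised and calibrated at desk scale.

## Pipeline and models

### Orthology and alignments

Homology edges (12-column tabular hits, or scores from the built-in
aligner) are filtered with the study's rule: the shorter protein of a pair
must be at least 60% of the longer one's length and be aligned over at
least 80% of its own length (both inclusive). The filtered graph is
clustered with Markov clustering (dense expansion/inflation iteration;
default inflation 1.5 -- unstated in the original analysis, so it is
surfaced as a parameter rather than buried). The single-copy core is the
set of clusters with exactly one member per genome.

Families are aligned at the protein level (a small progressive
profile aligner is included for desk-scale work; external alignments can
be imported as FASTA), back-translated to codons, and pruned: every column
whose gap fraction is 50% *or more* is removed -- the inclusive reading of
the rule. For codon alignments whole codon columns are pruned from the
protein-column decision, preserving frame. Whether the original pruning
acted on protein or nucleotide columns is not documented; protein-column
pruning mapped to codons is assumed.

### Gene trees and the topology census

The likelihood core is Felsenstein pruning under GTR with optional
discrete-Gamma rate variation (4 categories, each the exact mean of its
quantile bin), gaps treated as missing data. Branch lengths are optimized
per branch by Brent's method on the log scale (minimum length 1e-8,
log-likelihood tolerance 1e-6); exchangeabilities (GT fixed to 1) and the
Gamma shape are optimized by Nelder-Mead in coordinate ascent with the
branch lengths; base frequencies are empirical. For at most 8 taxa the
tree search is exhaustive over all (2n-5)!! unrooted topologies -- exact,
and free of stochastic-search variance; the search ranks all topologies
with a coarse single-pass optimization and then refits the leading
candidates at full precision, which is a pure speed device (the coarse
pass orders candidates whose refined log-likelihoods differ by far more
than the coarse error). Bootstrap support resamples site patterns and
re-runs the search.

Each gene tree is classified against the two-clade split: if the A|B
bipartition is present, the within-A and within-B resolutions (3 x 3 = 9
classes) are read from the induced triplets; otherwise the tree is
incongruent. With a support floor f, only trees whose internal
bipartitions all exceed f (strictly) are counted. Trees are also
comparable by the branch-length-weighted Robinson-Foulds distance (sum of
absolute branch-length differences over the union of internal
bipartitions, absent bipartitions weighted zero -- the unnormalized
branch-score variant; the height-1.0 complete-linkage cut used for
clustering is therefore scale-sensitive, which is why the census, not the
clustering, is the primary readout).

### Divergence spread

Pairwise dN/dS uses Nei-Gojobori counting: per-codon synonymous site
fractions, path-averaged difference counts for multi-hit codons (paths
through stop codons excluded), pairwise deletion of gapped or
stop-containing codon columns, and the Jukes-Cantor correction
d = -3/4 log(1 - 4/3 p), with saturation flagged. This replaces the
original codon-model ML estimator; at the divergences involved the two
agree monotonically, and an adapter point accepts external per-pair dS
tables for full-scale reproduction.

For a strain triple, each gene's three pairwise dS values are normalized
to sum to one and plotted in a ternary diagram; the *spread* is the median
distance of the per-gene points from their mean point. The distance is
taken on the raw 3-component relative triple (not the 2-D plot embedding):
in that space a gene whose closest pair is locally identical -- the
signature of within-group recombination -- lies 0.408 from the simplex
centre, the regime of the spreads reported for recombining groups, and the
package's clonal simulations reproduce the ~0.1 spread reported for a
clonally related triple without any tuning. The 2-D embedding distance
remains available via `spread(..., metric = "xy")`.

### Recombination detectors

Four intragenic detectors are implemented with permutation nulls (seeded,
add-one corrected):

* **Phi**: mean pairwise incompatibility (Estabrook-McMorris test on the
  bipartite state-co-occurrence graph) of parsimony-informative sites
  whose alignment positions fall within a 100-bp window; recombination
  depresses near-site incompatibility, so p = P(perm <= observed). The
  window is measured in alignment positions, the convention of the
  original implementation of the test.
* **NSS**: the fraction of *adjacent* informative-site pairs that are
  compatible; recombination inflates it, p = P(perm >= observed).
* **MaxChi**: for every sequence pair a breakpoint slides along the
  alignment and a 2x2 chi-square compares mismatch counts in the
  200-bp half-windows flanking it (whole alignment when shorter); the
  statistic is the maximum over pairs and breakpoints. The windowed form
  is essential: a tract in the interior of a gene is invisible to a
  whole-length left/right split.
* **GENECONV-style inner fragments**: over the alignment's polymorphic
  columns, each pair scores +1 at matches and -penalty at mismatches with
  penalty = (total polymorphic columns) x gscale / (pair differences)
  (gscale 0 = mismatches break fragments); maximal-scoring segments are
  candidate fragments, assessed against permutations of polymorphic-column
  order with Bonferroni correction across pairs (the permutation variant
  of the KA p-value; the original tool's analytic option is not
  reproduced). "Polymorphisms" in the penalty formula counts all variable
  columns. Fragments are reported in 1-based inclusive alignment bp and
  classified within-A / within-B / between by the pair's group labels.

A gene's ensemble tier is the number of methods significant at alpha =
0.01 (GENECONV by its corrected-KA < 0.05 fragment rule; NA counts as
non-significant). Power analysis on planted single tracts shows the
fragment scan dominates detection at realistic within-group divergences,
while Phi/NSS/MaxChi contribute mainly for more divergent or multiply
recombined genes -- which is why detection experiments report gene-level
("any method") power alongside per-method calibration.

### r/m and event counts

Per-site posterior tracks (S = substitution, R = recombination) are
post-processed with the published rules: a site counts as a
mutation-derived substitution when (1-R)S >= 0.95 and recombination-derived
when RS >= 0.95 (inclusive); r/m is their ratio; events are maximal runs
with R >= 0.5 throughout containing at least one site with R >= 0.95. The
MCMC that produces such tracks is out of scope; the package consumes any
site/S/R TSV.

### Group-specific genes

For clusters confined to one group, evidence against each outside genome
is reduced to absent / present / pseudogene: present needs an intact hit
with e < 1e-5 and >= 60% of the query aligned, or e < 1e-20, >= 30%
aligned and >= 35% identity (inclusive thresholds, coverage measured on
the query protein); a threshold-passing but disrupted hit (internal stop
or frameshift, taken from the hit record) is a pseudogene. A cluster is
group-specific iff present in all own-group genomes and absent or
pseudogene everywhere outside, including configured outgroup genomes.

## The synthetic generator

`wolbachia_tree()` fixes the six-strain, two-clade scenario
((wMel,(wRi,wHa)),(wNo,(wPip,wAlbB))) with branch lengths chosen so
pairwise divergences match the published synonymous-divergence scales:
within-A ~0.015-0.04, within-B ~0.03-0.07, between ~0.15
substitutions/site. `sim_params()` defaults: AT-rich stationary
frequencies (0.35/0.15/0.15/0.35), transition-biased exchangeabilities
(AG = CT = 4), 999-bp genes, no rate variation (a Gamma shape can be
set), geometric tract lengths with means 500 bp (within-group) and 120 bp
(between-group), and a mean transfer age of 0.005 substitutions/site
drawn exponentially per event (transfers sample the donor group's wider
population, not only the sequenced strain).

Recombination is modelled as tract replacement -- the recipient's tract is
the donor's tract re-evolved for the drawn transfer age -- rather than an
ancestral recombination graph: it produces exactly the mosaic alignments
the detectors target at a fraction of the complexity. "Heavy within-group
recombination" experiments use `randomize_within_groups()`: per gene, the
within-group subtree is redrawn from a Kingman coalescent (first
coalescence Exp(m), second Exp(3m), with 6m equal to the group's mean
pairwise distance) with a random leaf arrangement -- the free-recombination
limit in which every gene has its own within-group history while the
supergroup split stands. Proteome fixtures plant core, group-specific and
pseudogenized families and emit the homology-hit and cross-search tables
the orthology and gene-content stages consume; hit tables are derived
from the constructed sequences (unrelated families are random sequences,
so cross-family hits are absent by construction).

What the generator does **not** emulate: indels (alignments are gap-free;
gap handling is tested on hand-made fixtures), codon-level selection (sites
evolve under a nucleotide model; dS from such data tracks total divergence),
rate heterogeneity among genes, and genome-scale artifacts (assembly error,
annotation noise). Passing tests therefore demonstrate correctness of the
inference chain and its calibration on idealized data, not robustness to
real-data pathologies.

## Numerical and design choices

* Pattern compression before likelihood evaluation; site log-likelihoods
  floored at 1e-300 to avoid -Inf under degenerate parameters.
* Brent optimization in log-branch-length space over [1e-8, 5] with an
  absolute tolerance (a relative tolerance collapses near log-length 0).
* Exhaustive-search ties (log-likelihood difference < 1e-6) are flagged;
  candidate order is the canonical topology enumeration, so ties resolve
  deterministically.
* Permutation p-values use the add-one estimator (1 + #extreme)/(B + 1),
  hence never below 1/(B+1); all permutation draws flow through R's RNG so
  user seeds govern reproducibility end to end; each generator operation
  uses a private stream restored afterwards.
* MCL adds per-node self-loops equal to the node's maximum incident
  weight, prunes entries below 1e-12, and declares convergence at a
  maximum column change of 1e-6; clusters are the connected components of
  the thresholded attractor matrix.
* Degenerate inputs are first-class: fewer than two informative sites
  gives NA detector p-values; all-zero dS triples are excluded from the
  ternary projection with a warning; zero qualifying mutation sites flags
  r/m undefined; empty hit tables call "absent".

## Problem sizes

The shipped experiments are sized for a desk machine: 300-gene census
runs, 200-gene spread estimates, 500-gene detector calibration at 1000
permutations, 100-gene power runs, 40-gene fragment-size contrasts and
20 proteome fixtures of 77 families. These sizes give binomial/median
estimates tight enough for the calibration bands asserted in the test
suite while completing in minutes.

## Known limitations

* The exhaustive search is limited to 8 taxa by design; larger taxon sets
  need a heuristic searcher, which this package deliberately does not
  provide.
* NG86 dS differs from codon-model ML dS at high divergence (saturation
  flagged rather than extrapolated); full-scale reproductions should
  import per-pair dS tables if exact agreement with the ML estimator
  matters.
* The GENECONV reduction implements global inner fragments only -- no
  outer fragments, no analytic KA p-values.
* Single short within-group tracts at realistic divergence are near the
  detection floor of Phi/NSS/MaxChi (see the power analysis); conclusions
  about per-method power on real data should use the gene-level ensemble.
* NSS is conservative on low-homoplasy data: the adjacent-pair
  compatibility statistic is nearly degenerate at 1, and with heavy ties
  the add-one permutation p-value rarely drops below the nominal level, so
  its empirical type-I error falls below (not above) alpha. Calibration
  experiments should read NSS one-sidedly.

## A worked run

```{r, eval = FALSE}
library(cohesim)
cfg <- pipeline_config(n_genes = 50, params = sim_params(seed = 1),
                       history = "clonal")
report <- run_pipeline(cfg)
print(report)
```

The report prints the census (all 50 genes in the generating class for a
clonal run), per-group spreads (~0.1), ensemble tiers, the r/m block of
the demo posterior track, and the recovered group-specific cluster counts.
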
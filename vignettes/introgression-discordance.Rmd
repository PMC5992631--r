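---
title: "Detecting introgression and dissecting discordance in RAD-locus data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression and dissecting discordance in RAD-locus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introrad)
```

## The problem

Short anonymous loci from reduced-representation sequencing (ddRAD) are now
the workhorse of non-model phylogeography, but two biological processes
make the gene trees of individual loci disagree with the species phylogeny:
incomplete lineage sorting (ILS), in which ancestral polymorphism persists
through successive speciations, and introgression, in which alleles cross
species boundaries by hybridization.  The two leave different footprints.
ILS alone produces the two minor resolutions of any rooted triplet at equal
frequency, while introgression inflates one of them; and inference methods
react differently: concatenation-based tree building can be captured by a
minority of strongly divergent introgressed loci, whereas
coalescent-aware quartet methods follow the majority signal.

`introrad` packages the full analysis loop: a multispecies-coalescent (MSC)
simulator with admixture pulses as the ground-truth data source, the
standard RAD locus and individual quality filters, four-taxon ABBA-BABA
(Patterson's D) test batteries with bootstrap Z-scores and Holm-Bonferroni
correction, distance-based concatenation and quartet-frequency MSC species
trees, and naive binning of loci into "supergenes" — the experiment that
exposes when and why concatenation is biased by distant-relative
introgression.

## The D statistic and its battery machinery

For an ordered quartet (P1, P2, P3, O) with P1 and P2 sisters, sites that
are biallelic across the four taxa and polarized by the outgroup allele
(ancestral state A, derived state B) fall into two informative classes:
ABBA (derived allele shared by P2 and P3) and BABA (shared by P1 and P3).
Under ILS alone both classes are equally probable, so

$$D = \frac{n_{ABBA} - n_{BABA}}{n_{ABBA} + n_{BABA}}$$

has expectation zero; significantly positive D indicates gene flow between
P3 and P2 (negative, between P3 and P1).  `count_patterns()` implements two
estimators: `sampled` draws one allele per taxon per site (the natural
choice when each test uses a single individual per taxon; IUPAC
heterozygotes are resolved by a seeded uniform draw, `N` is missing), and
`frequency` accumulates the allele-frequency products
$(1-p_1)p_2p_3(1-p_O)$ and $p_1(1-p_2)p_3(1-p_O)$.  The default is
`sampled`, matching the convention of permuting single individuals into
many tests; both estimators are exposed because the choice is a genuine
free parameter of the method.

Significance comes from a locus bootstrap: loci are resampled with
replacement (1000 replicates by default), D is recomputed from the
per-locus pattern counts, and $Z = |D_{obs}|/\mathrm{SD}(D^\ast)$ with a
two-sided normal tail probability.  Degenerate cases are handled
explicitly: fewer than two contributing loci makes a test uninformative;
zero bootstrap SD with nonzero D is reported as infinitely significant;
zero SD with $D = 0$ gives $Z = 0$.

A test battery is the Cartesian product of single-individual choices
across the four taxa (`permute_individuals()`), so taxon sizes (2, 5, 4, 9)
yield 360 tests of one introgression hypothesis.  The family for the
Holm-Bonferroni correction (`alpha = 0.01`) is that battery — the set of
permutations of one event — not the global collection of hypotheses.
`split_by_geography()` supports the follow-up move when per-individual D
is heterogeneous: it reports per-region means and variances of D, flags a
split when the between-region variance exceeds twice the mean
within-region variance (the ratio is configurable; the adoption decision
is deliberately left to the user), and re-forms the taxon maps by region.

## The synthetic-data generator

Because the motivating data sets are typically museum-tissue ddRAD
assemblies without public raw reads, the simulator is the package's
canonical input source and every downstream stage is tested against it.

* **Gene trees.** `simulate_gene_trees()` runs the structured coalescent
  on a rooted ultrametric species tree whose branch lengths are durations
  in coalescent units (2N generations; per-branch population sizes are
  absorbed into the durations).  Within a branch, lineages coalesce
  pairwise at rate 1 per pair.  An admixture pulse (donor, recipient,
  time, $\gamma$) instantaneously reassigns each recipient-branch lineage
  to the donor branch with probability $\gamma$ — a discrete pulse, not
  continuous migration, matching the event-like introgression that
  D-statistics target.  A locus is flagged introgressed when at least one
  lineage took the donor path.
* **Sequences.** `simulate_sequences()` evolves each site independently
  under Jukes-Cantor with substitution rate `theta` per site per
  coalescent unit and a uniform root composition; 87 bp is the default
  locus length (the typical trimmed ddRAD fragment).  Each diploid
  individual's two haplotypes are collapsed to one IUPAC consensus, so
  heterozygous sites arise mechanically where the haplotypes differ.
  Richer substitution models are deliberately out of scope: none of the
  statistics implemented here depend on them.  Indels are available only
  as rare single-column gap events to exercise the indel filter.
* **Missingness.** `apply_missingness()` drops whole (individual, locus)
  cells with probability
  $1-(1-d_0)\,e^{-r\,d}$, where $d$ is the species-tree patristic distance
  from a reference individual.  Real assemblies show missingness
  correlated with phylogenetic distance from the restriction-site
  reference (gain and loss of cut sites); the exponential-in-distance form
  is this package's own quantitative choice, not an empirical estimate,
  and the truth mask is always retained.
* **Seeding.** One master seed; per-locus streams are derived from it
  deterministically, so equal seeds give byte-identical locus sets.

What the generator does *not* emulate: read-level error, coverage,
PCR duplicates, restriction-digest physics, linked selection, or
continuous migration.  Tests passing on these data therefore demonstrate
correctness of the statistical machinery under the MSC-plus-pulse model,
not robustness to assembly artefacts.

## Locus filtering

`filter_loci()` applies the standard RAD quality rules in a fixed,
declared order, each rule seeing the previous rule's survivors: (1)
individual consensus with more than 10 heterozygous sites (paralog
signal), (2) more than 2 haplotypes for one individual — on the diploid
consensus representation this surfaces as a 3- or 4-allele IUPAC code,
(3) any site heterozygous in more than 75% of the individuals that have
data there (missing individuals are excluded from the denominator),
(4) optional under-polymorphism (< 2 polymorphic sites) and indel rules
used by the filtered binning runs, (5) locus present in fewer than 50% of
individuals, and finally removal of individuals with more than 80%
missing data across the surviving loci.  The source pipelines do not
document their rule order; fixing one makes per-rule removal counts
disjoint and auditable, and the brute-force oracle tests hold under that
declared order.  Read-depth filtering belongs to the raw-read stage and
is out of scope — the package starts from assembled loci.

`extract_unlinked_snps()` picks one biallelic variable site per locus
(leftmost or seeded-random), skipping sites with more than two alleles,
because both the D machinery and the SNP quartet tally assume biallelic
patterns.

## Species-tree engines

The package's two inference families are deliberately simple, exactly
testable stand-ins that preserve the contrast under study:

* **Concatenation** = uncorrected p-distances on the concatenated
  supermatrix followed by neighbour joining.  Per site the distance
  contribution is the probability that one random allele from each
  genotype differs, so a heterozygote against a matching homozygote
  counts 0.5.  Negative NJ branches are clamped to zero with the deficit
  moved to the sibling branch.  NJ on p-distances reacts to the same
  signal mixing that biases likelihood concatenation, while remaining
  provably consistent on additive matrices (property-tested).
* **Quartet MSC** = per-locus (or per-supergene) trees, induced quartet
  topologies tallied over all species quartets with one representative
  haplotype per species, dominant resolutions assembled into the species
  tree by exhaustive search up to 8 species (greedy stepwise insertion
  beyond).  Node support is the mean dominant-quartet frequency over the
  quartets spanning the node, or a gene/site bootstrap percentage when
  requested.  An alternative tally from one SNP per locus is available
  via `extract_unlinked_snps()` plus `tally_quartets()` on per-species
  genotypes.

GTR likelihood, Bayesian MCMC and SVD-based quartet scoring are
non-goals: the scientific contrast is between inference *families*
(concatenation versus quartet coalescent), not between likelihood
engines.

## Naive binning and the concatenation-bias experiment

`bin_loci()` partitions loci uniformly at random into supergenes of k
loci (the remainder forms a final smaller bin; pure random partition, no
stratification), and `binned_species_tree()` runs the quartet pipeline on
per-bin NJ trees with an optional 128-replicate gene- or site-resampling
bootstrap.  At k = 1 the binned pipeline is bit-identical to the unbinned
quartet pipeline.

`concat_bias_experiment()` is the canonical demonstration.  The scenario
`bias_scenario_model(gamma)` uses the species tree
`((X:8,(A:5.4,(B:4.6,C:4.6):0.8):2.6):3,O:11)` with a pulse X→A at time
1.5.  The geometry was chosen from a four-point analysis of mixture
distances before freezing: per non-introgressed locus the species signal
(the expected p-distance gap favouring A with (B, C) over A with X) is
about 0.10 — roughly twice the per-locus sampling noise at 87 bp, so
single loci still vote for the species topology — while per introgressed
locus the donor signal is about 0.26, so a supergene flips to the
introgressed resolution once roughly a quarter of its sequence is
introgressed, below $\gamma = 0.3$.  The pulse time is late enough that
the recipient's two lineages have usually coalesced and jump as a unit,
keeping the locus-level introgression fraction near $\gamma$ (an earlier
pulse lets the two haplotypes jump independently, which at
$\gamma = 0.3$ pushes the fraction of affected loci towards 0.5 and
destroys the k = 1 contrast).  `theta = 0.05` makes the long donor branch
leave several supporting mutations per introgressed locus — the
mutational asymmetry the experiment illustrates and reports via
`mutation_summary`.

With these frozen defaults the experiment shows the threshold behaviour
of interest: the species topology dominates at k = 1, the introgressed
topology dominates large supergenes, and the probability of recovering
the introgressed topology is non-decreasing in k; with $\gamma = 0$ every
bin size recovers the species tree.  The empirical switch point observed
in real data is data-dependent, so only the monotone directionality is
asserted, never a particular switch point.

## Numerical choices and degenerate inputs

* Coordinates: loci are unanchored; site indices are 0-based internally,
  1-based in reports; strand is not modelled.  Gap `-` is distinct from
  missing `N`; both are excluded from distances and pattern counts, and
  3/4-allele ambiguity codes are treated as no-calls outside the filter
  that targets them.
* `compute_D(0, 0)` is `NA` (flagged no-data), never a division error;
  uninformative tests are excluded from `nSig/ntest` with a note.
* NJ ties and zero-length branches are resolved by `ape`'s deterministic
  agglomeration; quartet ties (equal four-point sums) count for no
  resolution when scoring candidate topologies.
* `NA` p-values are excluded from the Holm family size and flagged
  not-significant with a warning.
* All Monte-Carlo machinery takes explicit integer seeds and derives
  per-locus/per-test streams deterministically; two runs with the same
  configuration and seed are byte-identical end to end.

## Problem sizes used by the test suite

The suite simulates at desk scale, chosen as the smallest sizes at which
the closed-form checks sit comfortably inside three Monte-Carlo standard
errors: 6000 loci for the gene-tree discordance check, 1000–2000 loci for
battery calibration and power (batteries of 200 permuted tests, 200
bootstrap replicates), 2000 loci × 10 seeds for the binning experiment,
and 100 random fixtures per brute-force oracle.  The published empirical
numbers from the motivating study (locus and SNP totals, per-dataset
Z-ranges, empirical support values) derive from undeposited raw reads and
are not reproduction targets; the two printed worked examples of D from
averaged pattern counts are, and `scripts/acceptance.R` recomputes them.

## Known limitations

* The sampled-allele estimator ignores within-taxon allele frequencies by
  design; with many individuals per taxon the frequency estimator is the
  better choice.
* Quartet assembly is exhaustive only to 8 species; the greedy fallback
  is order-dependent in pathological tally landscapes.
* p-distances saturate on deep trees; that saturation is part of the
  concatenation-bias mechanism being studied, but it makes the NJ
  stand-in a poor absolute estimator of branch lengths.
* The missingness model is per-cell independent given the species
  distance; real restriction-site dropout is phylogenetically
  autocorrelated along the locus as well.
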
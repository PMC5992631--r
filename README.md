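# introrad

Introgression detection and phylogenetic-discordance analysis for
RAD-locus data.

Reduced-representation sequencing (ddRAD) yields thousands of short
anonymous loci whose individual gene trees disagree — through incomplete
lineage sorting (ILS), through introgression, or both.  `introrad` is a
toolkit for telling those apart and for understanding how they distort
species-tree inference:

* **ABBA-BABA test batteries.**  For a quartet (P1, P2, P3, O) with P1 and
  P2 sisters, Patterson's
  `D = (nABBA − nBABA) / (nABBA + nBABA)` has expectation 0 under ILS
  alone and is pushed positive by gene flow between P3 and P2.  The
  package counts the polarized site patterns (sampled-allele or
  allele-frequency estimators), attaches a locus-bootstrap Z-score
  (`Z = |D| / SD(D*)`, 1000 replicates), permutes all single-individual
  combinations of the four taxa into a battery of tests, and corrects the
  battery with the Holm-Bonferroni procedure at α = 0.01, reporting the
  standard summary row (mean D, mean ABBA/BABA, mean loci per test,
  Z-range, nSig/ntest).  Per-individual D can be examined and taxa split
  by geographic region when the variance warrants it.
* **RAD locus filters.**  The standard assembly quality rules (consensus
  heterozygosity, haplotype count, per-site heterozygosity across
  individuals, per-locus individual fraction, per-individual missingness,
  optional polymorphism/indel rules) applied in a fixed audited order,
  plus one-unlinked-SNP-per-locus extraction with IUPAC heterozygotes.
* **Two species-tree engines.**  Concatenation (p-distances + neighbour
  joining, with site or locus bootstrap) versus a quartet-frequency
  multispecies-coalescent assembly (dominant induced quartets across gene
  trees, exhaustive topology search to 8 species).
* **Naive binning.**  Random grouping of loci into k-locus "supergenes"
  across a grid of bin sizes, exposing how concatenation within bins
  flips the inferred topology when a distant relative has introgressed —
  including the canonical `concat_bias_experiment()`.
* **A multispecies-coalescent simulator** with admixture pulses,
  Jukes-Cantor sequences on 87 bp loci, diploid IUPAC consensus output and
  divergence-correlated missingness, retaining full ground truth, so every
  stage above is testable without any external data.  PyRAD-style `.loci`,
  relaxed Phylip and FASTA readers/writers round out the I/O.

## Worked example

Simulate five species with a pulse of introgression from P3 into P2
(γ = 0.3), run a permuted D battery, and watch naive binning flip the
recovered topology:

```r
library(introrad)

m <- species_tree_model("((((P1:1,P2:1):0.5,P3:1.5):0.5,P4:2):1,O:3);",
  samples_per_species = c(P1 = 2, P2 = 2, P3 = 2, P4 = 1, O = 1),
  pulses = data.frame(donor = "P3", recipient = "P2", time = 0.3, gamma = 0.3))
loci <- simulate_radseq(m, n_loci = 1000, theta = 0.01, seed = 42)
loci
#> locus_set: 1000 loci, 8 individuals, 5 species; nominal locus length 87 bp

bat <- run_battery(loci,
  taxa = list(P1 = c("P1_1", "P1_2"), P2 = c("P2_1", "P2_2"),
              P3 = c("P3_1", "P3_2"), O = "O_1"),
  n_boot = 1000, seed = 42)
round(bat$summary, 2)
#>   meanD meanABBA meanBABA mean_nloci minZ maxZ nSig ntest
#> 1  0.49    493.5      169     388.38 8.98   11    8     8
```

All 8 permuted tests are significant after Holm-Bonferroni correction:
derived alleles are shared between P2 and P3 far in excess of the ILS
expectation (mean D = 0.49).  The same battery on a γ = 0 simulation of
the same tree gives `meanD = -0.09, nSig = 0/8` — no false signal.

The binning experiment (canonical scenario: distant donor X introgressing
into A at γ = 0.3) shows the concatenation bias:

```r
ex <- concat_bias_experiment(gamma = 0.3, n_loci = 1000,
                             k_grid = c(1, 10, 100), seeds = 1:2)
ex$table
#>   seed   k     topology support
#> 1    1   1      species      63
#> 2    1  10 introgressed      83
#> 3    1 100 introgressed     100
#> 4    2   1      species      65
#> 5    2  10 introgressed      78
#> 6    2 100 introgressed      93
ex$mutation_summary
#>              class sites_supporting_introgressed sites_supporting_species
#> 1     introgressed                      5.868132                0.5274725
#> 2 non-introgressed                      1.634434                3.6100629
```

Unbinned loci (k = 1) vote by majority and recover the species topology
(A with (B, C)); 100-locus supergenes are each captured by their
introgressed members — which carry ~6 supporting mutations apiece, versus
~3.6 species-supporting mutations in non-introgressed loci — and the
assembled tree groups A with the donor X.

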
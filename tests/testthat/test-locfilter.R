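test_that("site-heterozygosity and individual-fraction rules remove the right loci", {
  ind <- paste0("sp1_", 1:10)
  hom <- function() stats::setNames(rep("ACGT", 10), ind)
  # a site heterozygous in 8/10 individuals (0.8 > 0.75)
  hot <- function() stats::setNames(c(rep("ARGT", 8), rep("AAGT", 2)), ind)
  loci <- c(replicate(8, hom(), simplify = FALSE),
            replicate(2, hot(), simplify = FALSE))
  ls1 <- make_locus_set(loci)
  res <- filter_loci(ls1, filter_config())
  expect_equal(res$report$loci_out, 8L)
  expect_equal(unname(res$report$removed["site_heterozygosity"]), 2L)

  # locus present in 4 of 10 individuals is removed at the 50% rule
  sparse <- stats::setNames(rep("ACGT", 4), ind[1:4])
  ls2 <- locus_set(list(hom(), sparse),
                   data.frame(individual = ind, species = "sp1"))
  res2 <- filter_loci(ls2, filter_config())
  expect_equal(res2$report$loci_out, 1L)
  expect_equal(unname(res2$report$removed["individual_fraction"]), 1L)

  # consensus with 11 heterozygous sites trips the paralog rule
  many_het <- stats::setNames(c(paste(rep("R", 11), collapse = ""),
                                rep(strrep("A", 11), 9)), ind)
  res3 <- suppressWarnings(filter_loci(make_locus_set(list(many_het)),
                                       filter_config()))
  expect_equal(res3$report$loci_out, 0L)
  expect_equal(unname(res3$report$removed["consensus_heterozygosity"]), 1L)
})

test_that("individuals with excess missing data are dropped after locus rules", {
  ind <- paste0("sp1_", 1:6)
  full <- stats::setNames(rep("ACGT", 6), ind)
  # individual sp1_6 present at only 1 of 10 loci (90% missing > 80%)
  mostly <- stats::setNames(rep("ACGT", 5), ind[1:5])
  loci <- c(list(full), replicate(9, mostly, simplify = FALSE))
  res <- filter_loci(make_locus_set(loci), filter_config())
  expect_equal(res$report$individuals_removed, "sp1_6")
  expect_false("sp1_6" %in% individuals(res$loci))
})

test_that("filtering is idempotent and matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:12) {
    ls1 <- random_locus_set(n_loci = sample(10:50, 1), n_ind = 8, L = 12,
                            p_missing = stats::runif(1, 0, 0.6))
    cfg <- filter_config(
      max_het_sites_per_consensus = sample(0:3, 1),
      max_site_heterozygosity = stats::runif(1, 0.2, 0.9),
      min_individual_fraction_per_locus = stats::runif(1, 0.2, 0.8),
      max_missing_per_individual = 1,  # isolate locus rules for the oracle
      min_polymorphic_sites = sample(0:2, 1))
    res <- suppressWarnings(filter_loci(ls1, cfg))
    expect_identical(res$loci$loci,
                     ls1$loci[oracle_filter_survivors(ls1, cfg)])
    twice <- suppressWarnings(filter_loci(res$loci, cfg))
    expect_identical(twice$loci$loci, res$loci$loci)
    expect_equal(twice$report$loci_out, res$report$loci_out)
  }
})

test_that("relaxing any single threshold never removes survivors", {
  set.seed(77)
  ls1 <- random_locus_set(n_loci = 40, n_ind = 8, L = 12, p_missing = 0.4)
  base <- filter_config(max_het_sites_per_consensus = 1,
                        max_site_heterozygosity = 0.4,
                        min_individual_fraction_per_locus = 0.6,
                        min_polymorphic_sites = 2)
  n_base <- suppressWarnings(filter_loci(ls1, base))$report$loci_out
  relax <- list(
    filter_config(max_het_sites_per_consensus = 5,
                  max_site_heterozygosity = 0.4,
                  min_individual_fraction_per_locus = 0.6,
                  min_polymorphic_sites = 2),
    filter_config(max_het_sites_per_consensus = 1,
                  max_site_heterozygosity = 0.9,
                  min_individual_fraction_per_locus = 0.6,
                  min_polymorphic_sites = 2),
    filter_config(max_het_sites_per_consensus = 1,
                  max_site_heterozygosity = 0.4,
                  min_individual_fraction_per_locus = 0.2,
                  min_polymorphic_sites = 2),
    filter_config(max_het_sites_per_consensus = 1,
                  max_site_heterozygosity = 0.4,
                  min_individual_fraction_per_locus = 0.6,
                  min_polymorphic_sites = 0))
  for (cfg in relax)
    expect_gte(suppressWarnings(filter_loci(ls1, cfg))$report$loci_out, n_base)
})

test_that("indel and polymorphism filters target the constructed loci", {
  ind <- paste0("sp1_", 1:4)
  mono <- stats::setNames(rep("AAAA", 4), ind)
  poly1 <- stats::setNames(c("AAAA", "AAAT", "AAAA", "AAAA"), ind)
  poly2 <- stats::setNames(c("CAAA", "AAAT", "AAAA", "AAAA"), ind)
  gap <- stats::setNames(c("CA-T", "AAAA", "AAAT", "AAAA"), ind)  # 2 SNPs + gap
  ls1 <- make_locus_set(list(mono, poly1, poly2, gap))
  res <- filter_loci(ls1, filter_config(min_polymorphic_sites = 2,
                                        drop_indel_loci = TRUE))
  expect_identical(res$loci$loci, list(poly2))
  expect_equal(unname(res$report$removed["polymorphism"]), 2L)
  expect_equal(unname(res$report$removed["indel"]), 1L)
  # empty survivor set warns rather than errors
  expect_warning(filter_loci(make_locus_set(list(mono)),
                             filter_config(min_polymorphic_sites = 2)),
                 "all loci removed")
})

test_that("unlinked SNP extraction picks one biallelic site per locus", {
  ind <- paste0("sp1_", 1:4)
  mono <- stats::setNames(rep("AAAA", 4), ind)
  one <- stats::setNames(c("AAAT", "AAAA", "AAAA", "AAAA"), ind)
  two <- stats::setNames(c("CAAT", "AAAA", "AAAA", "AAAA"), ind)
  tri <- stats::setNames(c("TAAA", "CAAA", "GAAA", "GAAA"), ind)  # 3 alleles
  ls1 <- make_locus_set(list(one, mono, two, tri))
  m <- extract_unlinked_snps(ls1, picker = "first")
  expect_equal(ncol(m), 2L)
  expect_equal(attr(m, "n_no_variant"), 2L)
  expect_equal(attr(m, "site"), c(4L, 1L))   # leftmost biallelic site
  # monomorphic set: empty matrix
  m0 <- extract_unlinked_snps(make_locus_set(list(mono)))
  expect_equal(ncol(m0), 0L)
  # random picker is seed-deterministic
  r1 <- extract_unlinked_snps(ls1, picker = "random", seed = 5)
  r2 <- extract_unlinked_snps(ls1, picker = "random", seed = 5)
  expect_identical(r1, r2)
  # heterozygotes keep their IUPAC code in the matrix
  het <- stats::setNames(c("AAAW", "AAAA", "AAAA", "AAAA"), ind)
  mh <- extract_unlinked_snps(make_locus_set(list(het)), picker = "first")
  expect_equal(unname(mh["sp1_1", 1]), "W")
})
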
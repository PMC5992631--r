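quartet_fixture <- function(sites) {
  # sites: character matrix with rownames p1,p2,p3,o; one locus per column-set
  make_locus_set(list(stats::setNames(apply(sites, 1, paste, collapse = ""),
                                      rownames(sites))),
                 species = c("P1", "P2", "P3", "O"))
}

test_that("single-site patterns follow the ABBA/BABA definitions", {
  ind <- c(p1_1 = "P1", p2_1 = "P2", p3_1 = "P3", o_1 = "O")
  mk <- function(...) locus_set(
    list(c(p1_1 = ..1, p2_1 = ..2, p3_1 = ..3, o_1 = ..4)),
    data.frame(individual = names(ind), species = unname(ind)))
  qt <- quartet_test("p1_1", "p2_1", "p3_1", "o_1")
  for (mode in c("sampled", "frequency")) {
    abba <- count_patterns(mk("G", "T", "T", "G"), qt, mode)
    expect_equal(c(abba$ABBA, abba$BABA, abba$nloci), c(1, 0, 1))
    baba <- count_patterns(mk("T", "G", "T", "G"), qt, mode)
    expect_equal(c(baba$ABBA, baba$BABA, baba$nloci), c(0, 1, 1))
    # three states at the site: biallelic requirement excludes it
    tri <- count_patterns(mk("A", "C", "G", "G"), qt, mode)
    expect_equal(c(tri$ABBA, tri$BABA, tri$nloci), c(0, 0, 0))
    # BBBA (invariant within P1-P3 relative to derived state) contributes nothing
    bbba <- count_patterns(mk("T", "T", "T", "G"), qt, mode)
    expect_equal(bbba$ABBA + bbba$BABA, 0)
    # missing data in a chosen individual skips the site
    mis <- count_patterns(mk("N", "T", "T", "G"), qt, mode)
    expect_equal(mis$nloci, 0)
  }
})

test_that("frequency-mode counts match the brute-force enumeration oracle", {
  set.seed(19)
  for (rep in 1:10) {
    ls1 <- random_locus_set(n_loci = 15, n_ind = 8, L = 10, p_missing = 0.3)
    ind <- individuals(ls1)
    qt <- quartet_test(ind[1:2], ind[3:4], ind[5:6], ind[7:8])
    got <- count_patterns(ls1, qt, mode = "frequency")
    want <- oracle_count_patterns_freq(ls1, ind[1:2], ind[3:4], ind[5:6],
                                       ind[7:8])
    expect_equal(got$ABBA, want$ABBA, tolerance = 1e-12)
    expect_equal(got$BABA, want$BABA, tolerance = 1e-12)
    expect_equal(got$nloci, want$nloci)
  }
})

test_that("D reproduces the published worked examples and limiting cases", {
  # averaged discordant-locus counts from the published test batteries
  expect_equal(round(compute_D(1623, 381), 2), 0.62)
  expect_equal(round(compute_D(152, 19), 2), 0.78)
  expect_equal(round(compute_D(9, 6), 2), 0.20)
  expect_equal(compute_D(5, 5), 0)
  expect_equal(compute_D(7, 0), 1)
  expect_true(is.na(compute_D(0, 0)))
})

test_that("exchanging P1 and P2 negates D and swaps ABBA with BABA", {
  set.seed(23)
  ls1 <- random_locus_set(n_loci = 25, n_ind = 8, L = 12, p_missing = 0.2)
  ind <- individuals(ls1)
  fwd <- count_patterns(ls1, quartet_test(ind[1:2], ind[3:4], ind[5:6],
                                          ind[7:8]), mode = "frequency")
  rev <- count_patterns(ls1, quartet_test(ind[3:4], ind[1:2], ind[5:6],
                                          ind[7:8]), mode = "frequency")
  expect_equal(fwd$ABBA, rev$BABA, tolerance = 1e-12)
  expect_equal(fwd$BABA, rev$ABBA, tolerance = 1e-12)
  expect_equal(compute_D(fwd), -compute_D(rev), tolerance = 1e-12)
})

test_that("two-locus bootstrap SD matches the exact enumeration", {
  # loci with counts (2,0) and (0,2): resample distribution of D is
  # {1, 0, 0, -1} over the four equiprobable resamples; SD = 1/sqrt(2)
  ind <- c(p1_1 = "P1", p2_1 = "P2", p3_1 = "P3", o_1 = "O")
  abba2 <- c(p1_1 = "GG", p2_1 = "TT", p3_1 = "TT", o_1 = "GG")
  baba2 <- c(p1_1 = "TT", p2_1 = "GG", p3_1 = "TT", o_1 = "GG")
  ls1 <- locus_set(list(abba2, baba2),
                   data.frame(individual = names(ind), species = unname(ind)))
  qt <- quartet_test("p1_1", "p2_1", "p3_1", "o_1")
  res <- bootstrap_Z(ls1, qt, n_boot = 1e5, seed = 4)
  exact <- oracle_two_locus_boot_sd(2, 0, 0, 2)
  expect_equal(exact, 1 / sqrt(2))
  # MC estimate of the SD within 3 SE (delta-method SE ~ sd/sqrt(2 n))
  expect_lt(abs(res$sd_boot - exact), 3 * exact / sqrt(2 * 1e5))
  expect_equal(res$D, 0)
  expect_equal(res$Z, 0)
})

test_that("bootstrap degenerate cases and scale invariance behave", {
  ind <- c(p1_1 = "P1", p2_1 = "P2", p3_1 = "P3", o_1 = "O")
  # identical (1, 1) counts at every locus: D = 0 with zero bootstrap SD
  bal <- c(p1_1 = "GT", p2_1 = "TG", p3_1 = "TT", o_1 = "GG")
  ls1 <- locus_set(rep(list(bal), 4),
                   data.frame(individual = names(ind), species = unname(ind)))
  qt <- quartet_test("p1_1", "p2_1", "p3_1", "o_1")
  res <- bootstrap_Z(ls1, qt, n_boot = 200, seed = 1)
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)
  # all-ABBA loci: D = 1, SD = 0 -> infinite-significant sentinel
  ab <- c(p1_1 = "G", p2_1 = "T", p3_1 = "T", o_1 = "G")
  ls2 <- locus_set(rep(list(ab), 3),
                   data.frame(individual = names(ind), species = unname(ind)))
  res2 <- bootstrap_Z(ls2, qt, n_boot = 100, seed = 1)
  expect_true(is.infinite(res2$Z))
  expect_equal(res2$p, 0)
  # duplicating every locus leaves D unchanged
  ls3 <- locus_set(ls2$loci[c(1, 1, 2, 2, 3, 3)],
                   data.frame(individual = names(ind), species = unname(ind)))
  d3 <- compute_D(count_patterns(ls3, qt, mode = "frequency"))
  d2 <- compute_D(count_patterns(ls2, qt, mode = "frequency"))
  expect_equal(d3, d2)
  # a single-locus test is uninformative
  ls4 <- locus_set(list(ab),
                   data.frame(individual = names(ind), species = unname(ind)))
  expect_false(bootstrap_Z(ls4, qt, n_boot = 50, seed = 1)$informative)
})

test_that("individual permutation enumerates the Cartesian product", {
  taxa <- list(P1 = paste0("a", 1:2), P2 = paste0("b", 1:5),
               P3 = paste0("c", 1:4), O = paste0("d", 1:9))
  tests <- permute_individuals(taxa)
  expect_length(tests, 2 * 5 * 4 * 9)   # 360, the published ntest pattern
  expect_length(permute_individuals(list(P1 = "a", P2 = "b", P3 = "c",
                                         O = "d")), 1L)
  capped1 <- permute_individuals(taxa, cap = 10, seed = 3)
  capped2 <- permute_individuals(taxa, cap = 10, seed = 3)
  expect_length(capped1, 10L)
  expect_identical(capped1, capped2)
})

test_that("Holm-Bonferroni matches p.adjust and handles edge cases", {
  expect_equal(holm_bonferroni(c(0.001, 0.02, 0.03), alpha = 0.01),
               c(TRUE, FALSE, FALSE))
  expect_identical(holm_bonferroni(numeric(0)), logical(0))
  expect_warning(flags <- holm_bonferroni(c(0.001, NA, 0.3), alpha = 0.05),
                 "NA")
  expect_equal(flags, c(TRUE, FALSE, FALSE))
  set.seed(8)
  for (rep in 1:40) {
    p <- stats::runif(sample(1:30, 1))^sample(1:3, 1)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(holm_bonferroni(p, alpha), oracle_holm(p, alpha))
  }
})

test_that("batteries detect a pulse and stay null without one", {
  nw <- "((((P1:1,P2:1):0.5,P3:1.5):0.5,P4:2):1,OG:3);"
  taxa <- list(P1 = c("P1_1", "P1_2"), P2 = c("P2_1", "P2_2"),
               P3 = c("P3_1", "P3_2"), O = "OG_1")
  samples <- c(P1 = 2, P2 = 2, P3 = 2, P4 = 1, OG = 1)
  m1 <- species_tree_model(nw, samples,
                           pulses = data.frame(donor = "P3", recipient = "P2",
                                               time = 0.3, gamma = 0.3))
  ls1 <- simulate_radseq(m1, 600, theta = 0.01, seed = 5)
  b1 <- run_battery(ls1, taxa, n_boot = 200, seed = 5)
  expect_gt(b1$summary$meanD, 0)
  expect_gte(b1$summary$nSig / b1$summary$ntest, 0.8)
  m0 <- species_tree_model(nw, samples)
  ls0 <- simulate_radseq(m0, 600, theta = 0.01, seed = 5)
  b0 <- run_battery(ls0, taxa, n_boot = 200, seed = 5)
  expect_equal(b0$summary$nSig, 0)
  expect_lt(abs(b0$summary$meanD), 0.15)
  # swapping P1 and P2 negates the battery mean D (frequency mode is exact)
  taxa_sw <- list(P1 = taxa$P2, P2 = taxa$P1, P3 = taxa$P3, O = taxa$O)
  f1 <- run_battery(ls1, taxa, mode = "frequency", n_boot = 50, seed = 2)
  f2 <- run_battery(ls1, taxa_sw, mode = "frequency", n_boot = 50, seed = 2)
  expect_equal(f1$summary$meanD, -f2$summary$meanD, tolerance = 1e-10)
  expect_equal(f1$summary$meanABBA, f2$summary$meanBABA, tolerance = 1e-10)
})

test_that("geographic splitting flags region-structured D", {
  res <- data.frame(P1 = "a", P2 = rep(c("r1_1", "r1_2", "r2_1", "r2_2"), each = 4),
                    P3 = "c", O = "o",
                    D = c(rnorm(8, 0.6, 0.01), rnorm(8, 0.0, 0.01)))
  taxa <- list(P1 = "a", P2 = unique(res$P2), P3 = "c", O = "o")
  region_map <- c(r1_1 = "east", r1_2 = "east", r2_1 = "west", r2_2 = "west")
  sp <- split_by_geography(res, taxa, region_map)
  expect_true(sp$split_flagged)
  expect_setequal(names(sp$taxa_maps), c("east", "west"))
  expect_setequal(sp$taxa_maps$east$P2, c("r1_1", "r1_2"))
  # homogeneous D: no split
  res$D <- 0.3
  expect_false(split_by_geography(res, taxa, region_map)$split_flagged)
  # identity grouping leaves taxa unchanged
  idmap <- stats::setNames(rep("all", 4), unique(res$P2))
  sp2 <- split_by_geography(res, taxa, idmap)
  expect_setequal(sp2$taxa_maps$all$P2, taxa$P2)
  # unknown region member errors
  expect_error(split_by_geography(res, taxa, region_map[-1]), "missing")
})
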
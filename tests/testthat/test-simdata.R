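test_that("species_tree_model validates topology, durations and pulses", {
  expect_error(species_tree_model("((A:1,B:1):0.5,C:1.5,D:1.5);"), "binary")
  expect_error(species_tree_model("((A:1,B:2):0.5,C:1.5);"), "ultrametric")
  # pulse outside the branch-interval overlap is named in the error
  expect_error(
    species_tree_model("((A:1,B:1):0.5,C:1.5);",
                       pulses = data.frame(donor = "C", recipient = "A",
                                           time = 1.2, gamma = 0.5)),
    "outside the overlap")
  expect_error(
    species_tree_model("((A:1,B:1):0.5,C:1.5);",
                       pulses = data.frame(donor = "C", recipient = "A",
                                           time = 0.5, gamma = 1.5)),
    "gamma")
  m <- species_tree_model("((A:1,B:1):0.5,C:1.5);",
                          samples_per_species = c(A = 2, B = 1, C = 1),
                          pulses = data.frame(donor = "C", recipient = "A",
                                              time = 0.5, gamma = 0.2))
  expect_s3_class(m, "species_tree_model")
  expect_equal(nrow(model_individual_map(m)), 4L)
})

test_that("deep-split limit gives reciprocal monophyly and gamma=1 full replacement", {
  # two species, very deep split: every gene tree is reciprocally monophyletic
  m <- species_tree_model("(A:50,B:50);", samples_per_species = 3)
  gt <- simulate_gene_trees(m, 20, seed = 1)
  for (tr in gt) {
    a_tips <- grep("^A_", tr$tip.label)
    expect_true(ape::is.monophyletic(tr, tr$tip.label[a_tips]))
  }
  # gamma=1 pulse: all recipient lineages jump, every locus flagged
  m2 <- species_tree_model("((A:2,X:2):1,O:3);", samples_per_species = 2,
                           pulses = data.frame(donor = "X", recipient = "A",
                                               time = 0.01, gamma = 1))
  gt2 <- simulate_gene_trees(m2, 30, seed = 2)
  expect_true(all(attr(gt2, "introgressed")))
})

test_that("gene-tree discordance matches the closed-form MSC expectation", {
  # internal branch T = 0.5: each minor topology with prob exp(-T)/3
  m <- species_tree_model("(((P1:1,P2:1):0.5,P3:1.5):1,O:2.5);")
  n <- 6000
  gt <- simulate_gene_trees(m, n, seed = 42)
  counts <- quartet_topology_counts(gt, c("P1", "P2", "P3", "O"))
  expect_equal(sum(counts), n)
  p_minor <- exp(-0.5) / 3
  se <- sqrt(p_minor * (1 - p_minor) / n)
  expect_lt(abs(counts[["p1p3"]] / n - p_minor), 3 * se)
  expect_lt(abs(counts[["p2p3"]] / n - p_minor), 3 * se)
})

test_that("admixture pulse inflates donor-recipient grouping monotonically in gamma", {
  frac_p2p3 <- vapply(c(0, 0.2, 0.4), function(g) {
    tot <- 0
    for (s in 1:3) {
      m <- species_tree_model(
        "(((P1:1,P2:1):0.5,P3:1.5):1,O:2.5);",
        pulses = if (g > 0) data.frame(donor = "P3", recipient = "P2",
                                       time = 0.3, gamma = g))
      cnt <- quartet_topology_counts(simulate_gene_trees(m, 400, seed = s),
                                     c("P1", "P2", "P3", "O"))
      tot <- tot + cnt[["p2p3"]] / sum(cnt)
    }
    tot / 3
  }, numeric(1))
  expect_true(all(diff(frac_p2p3) > 0))
  expect_gt(frac_p2p3[3], exp(-0.5) / 3 + 0.1)
})

test_that("Jukes-Cantor sequences match the expected p-distance", {
  # hand-built two-tip tree at path distance 2t; theta*2t substitutions/site
  tip_tree <- structure(list(
    edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
    edge.length = c(1.5, 1.5), tip.label = c("sp1_1_a", "sp1_1_b"),
    Nnode = 1L), class = "phylo", order = "cladewise")
  trees <- list(tip_tree)
  attr(trees, "introgressed") <- FALSE
  theta <- 0.1
  L <- 20000
  ls1 <- simulate_sequences(trees, locus_length = L, theta = theta, seed = 5)
  # the two haplotypes of the single individual differ at het sites
  het <- mean(strsplit(ls1$loci[[1]][[1]], "")[[1]] %in%
                c("R", "Y", "S", "W", "K", "M"))
  d <- theta * 3
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(het - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / L))
})

test_that("theta -> 0 limit yields identical sequences and uniform root composition", {
  m <- species_tree_model("((A:1,B:1):0.5,C:1.5);", samples_per_species = 2)
  gt <- simulate_gene_trees(m, 3, seed = 9)
  ls0 <- simulate_sequences(gt, locus_length = 40, theta = 1e-12, seed = 9)
  for (sq in ls0$loci) expect_length(unique(unname(sq)), 1L)
  # long single-tip locus: composition approximately uniform
  one <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        edge.length = 0, tip.label = "sp1_1_a",
                        Nnode = 1L), class = "phylo", order = "cladewise")
  # need two haplotypes per individual for the diploid collapse: use a cherry
  cherry <- structure(list(
    edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
    edge.length = c(0, 0), tip.label = c("sp1_1_a", "sp1_1_b"),
    Nnode = 1L), class = "phylo", order = "cladewise")
  trees <- list(cherry)
  ls1 <- simulate_sequences(trees, locus_length = 40000, theta = 1e-9, seed = 3)
  comp <- table(strsplit(ls1$loci[[1]][[1]], "")[[1]]) / 40000
  expect_true(all(abs(comp - 0.25) < 0.02))
})

test_that("missingness is reproducible, bounded, and divergence-correlated", {
  m <- species_tree_model("(((A:1,B:1):1,C:2):2,D:4);", samples_per_species = 2)
  ls1 <- simulate_radseq(m, 300, theta = 0.01, seed = 11)
  # rates 0: identity
  same <- apply_missingness(ls1, 0, 0, seed = 1)
  expect_identical(same$loci, ls1$loci)
  # dropout 1: everything absent
  gone <- apply_missingness(ls1, 1, 0, seed = 1)
  expect_true(all(lengths(gone$loci) == 0L))
  # divergence-correlated loss: missingness increases with distance from A_1
  ms <- apply_missingness(ls1, 0.05, 0.15, reference_individual = "A_1",
                          seed = 7)
  frac <- missingness_report(ms)$missing_fraction
  dm <- stats::cophenetic(m$tree)
  d <- c(A_1 = 0, A_2 = 0, B_1 = dm["A", "B"], B_2 = dm["A", "B"],
         C_1 = dm["A", "C"], C_2 = dm["A", "C"],
         D_1 = dm["A", "D"], D_2 = dm["A", "D"])
  expect_gt(stats::cor(d[names(frac)], frac, method = "spearman"), 0)
  expect_true(all(frac[c("D_1", "D_2")] > frac[c("A_1", "A_2")]))
})

test_that("identical seeds give byte-identical locus sets", {
  m <- bias_scenario_model(0.3)
  a <- simulate_radseq(m, 40, theta = 0.05, seed = 123,
                       dropout_per_individual = 0.1,
                       divergence_dropout_rate = 0.02)
  b <- simulate_radseq(m, 40, theta = 0.05, seed = 123,
                       dropout_per_individual = 0.1,
                       divergence_dropout_rate = 0.02)
  expect_identical(a$loci, b$loci)
  expect_identical(a$truth$introgressed, b$truth$introgressed)
  c <- simulate_radseq(m, 40, theta = 0.05, seed = 124)
  expect_false(identical(a$loci, c$loci))
})
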
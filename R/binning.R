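#' Randomly bin loci into supergenes
#'
#' Partitions the loci uniformly at random (seeded) into bins of `k`; a
#' supergene is the concatenation of its member loci.  When `nloci` is not a
#' multiple of `k` the remainder forms one final smaller bin (or is dropped
#' with `drop_remainder = TRUE`).  `k = 1` is the identity partition.
#'
#' @param loci a [locus_set()].
#' @param k bin size in loci, `1 <= k <= n_loci(loci)`.
#' @param seed integer seed for the random partition.
#' @param drop_remainder drop the trailing partial bin (default FALSE).
#' @return object of class `binned_run`: fields `loci`, `k`, `assignment`
#'   (locus index -> bin id) and `bins` (list of locus-index vectors).
#' @export
bin_loci <- function(loci, k, seed = 1, drop_remainder = FALSE) {
  nl <- n_loci(loci)
  if (k < 1L || k > nl) stop("k must lie in [1, ", nl, "]")
  set.seed(as.integer(seed))
  perm <- sample.int(nl)
  bin_id <- ceiling(seq_len(nl) / k)
  if (drop_remainder && nl %% k != 0L) {
    keep <- seq_len((nl %/% k) * k)
    perm <- perm[keep]
    bin_id <- bin_id[keep]
  }
  bins <- split(perm, bin_id)
  assignment <- integer(nl)
  for (b in seq_along(bins)) assignment[bins[[b]]] <- b
  structure(list(loci = loci, k = as.integer(k),
                 assignment = assignment, bins = unname(bins)),
            class = "binned_run")
}

#' @export
print.binned_run <- function(x, ...) {
  cat("binned_run: k =", x$k, "->", length(x$bins), "bins over",
      n_loci(x$loci), "loci\n")
  invisible(x)
}

#' Species tree from binned supergenes
#'
#' The binned coalescent pipeline: each supergene (bin) gets a
#' neighbour-joining tree from the p-distances of its concatenated
#' alignment, and the per-bin trees are assembled into a species tree by
#' dominant quartet frequencies.  Bins whose alignment is uninformative
#' (a pair with no comparable sites, or fewer than 4 species with data) are
#' excluded and counted.  Optional bootstrap: `unit = "gene"` resamples
#' whole bins (their trees are reused), `unit = "site"` resamples loci
#' within each bin and re-infers the bin trees.
#'
#' @param run a [bin_loci()] result.
#' @param n_boot bootstrap replicates (0 = none; the field default used for
#'   the support-vs-bin-size analyses is 128).
#' @param unit `"gene"` or `"site"`.
#' @param seed integer seed.
#' @return unrooted species `phylo` with dominant-quartet supports in
#'   `node.label`; attributes `n_bins_used`, `n_bins_excluded`, and (when
#'   bootstrapped) `boot_support` (percentage per internal edge) in
#'   `node.label` instead.
#' @export
binned_species_tree <- function(run, n_boot = 0, unit = c("gene", "site"),
                                seed = 1) {
  unit <- match.arg(unit)
  stopifnot(inherits(run, "binned_run"))
  loci <- run$loci
  species_map <- .species_of(loci)
  bin_trees <- lapply(run$bins, function(b) .bin_tree(loci, b))
  used <- !vapply(bin_trees, is.null, logical(1))
  if (!any(used)) stop("no informative bins")
  bin_trees <- bin_trees[used]
  tr <- quartet_species_tree(bin_trees, species_map = .ind_tree_map(loci))
  attr(tr, "n_bins_used") <- sum(used)
  attr(tr, "n_bins_excluded") <- sum(!used)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    reps <- vector("list", n_boot)
    for (r in seq_len(n_boot)) {
      if (unit == "gene") {
        pick <- sample.int(length(bin_trees), length(bin_trees), replace = TRUE)
        reps[[r]] <- quartet_species_tree(bin_trees[pick],
                                          species_map = .ind_tree_map(loci))
      } else {
        rebinned <- lapply(run$bins[used], function(b)
          .bin_tree(loci, sample(b, length(b), replace = TRUE)))
        rebinned <- Filter(Negate(is.null), rebinned)
        reps[[r]] <- quartet_species_tree(rebinned,
                                          species_map = .ind_tree_map(loci))
      }
    }
    counts <- ape::prop.clades(tr, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tr$node.label <- as.character(round(100 * counts / n_boot))
  }
  tr
}

# NJ tree of one bin's concatenated alignment, NULL when uninformative
.bin_tree <- function(loci, members) {
  aln <- concat_alignment(loci, which = members)
  aln <- aln[!vapply(aln, function(s) grepl("^[N-]*$", s), logical(1))]
  if (length(aln) < 4L) return(NULL)
  dm <- tryCatch(p_distance(aln), error = function(e) NULL)
  if (is.null(dm)) return(NULL)
  neighbor_joining(dm)
}

# individual-labelled trees -> species map for quartet tallying
.ind_tree_map <- function(loci) {
  sp <- .species_of(loci)
  stats::setNames(unname(sp), names(sp))
}

#' Concatenation-bias experiment under distant-relative introgression
#'
#' The canonical demonstration that binning (and, in the limit, full
#' concatenation) is biased by introgression from a distant relative.  The
#' scenario is a species tree `((X,(A,(B,C))),O)` with a long divergence
#' between X and A and a recent admixture pulse X -> A with proportion
#' `gamma`.  Introgressed loci carry many more mutations grouping A with X
#' (accumulated along the long donor branch) than non-introgressed loci
#' carry for the species grouping of A with (B, C), so any bin containing
#' enough introgressed loci resolves the conflicted node in favour of the
#' introgressed topology: as the bin size grows, support shifts from the
#' species tree to the introgressed tree.
#'
#' @param gamma admixture proportion of the pulse (0 disables it).
#' @param n_loci loci per simulated dataset.
#' @param k_grid bin sizes to evaluate (default `c(1, 5, 10, 20, 50, 100)`).
#' @param seeds integer vector; one dataset is simulated per seed.
#' @param theta substitutions per site per coalescent unit (default 0.05;
#'   high enough that the long donor branch leaves a strong mutational
#'   footprint on introgressed loci).
#' @param locus_length sites per locus (default 87).
#' @param model optional [species_tree_model()] overriding the canonical
#'   scenario of [bias_scenario_model()].
#' @return list with `table` (data.frame: seed, k, recovered topology
#'   `"species"`/`"introgressed"`/`"other"`, support at the conflicted node)
#'   and `mutation_summary` (per locus class, mean site counts supporting
#'   the introgressed A+X grouping and the species A+B grouping).
#' @export
concat_bias_experiment <- function(gamma, n_loci = 2000,
                                   k_grid = c(1, 5, 10, 20, 50, 100),
                                   seeds = 1:10, theta = 0.05,
                                   locus_length = 87, model = NULL) {
  if (is.null(model)) model <- bias_scenario_model(gamma)
  rows <- list()
  mut <- list()
  for (s in seeds) {
    ls1 <- simulate_radseq(model, n_loci, theta = theta, seed = s,
                           locus_length = locus_length)
    mut[[length(mut) + 1L]] <- .bias_mutation_counts(ls1, seed = s)
    for (k in k_grid) {
      run <- bin_loci(ls1, k, seed = s)
      tr <- binned_species_tree(run)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, k = k,
        topology = .classify_bias_topology(tr),
        support = .conflicted_node_support(tr))
    }
  }
  mut_all <- do.call(rbind, mut)
  mutation_summary <- stats::aggregate(
    cbind(sites_supporting_introgressed, sites_supporting_species) ~ class,
    data = mut_all, FUN = mean)
  list(table = do.call(rbind, rows), mutation_summary = mutation_summary)
}

#' Canonical distant-introgression scenario
#'
#' Species tree `((X:8,(A:5.4,(B:4.6,C:4.6):0.8):2.6):3,O:11)` (durations in
#' coalescent units), one diploid individual per species, and a pulse
#' X -> A at time 1.5 with the given proportion.  The X/A divergence is long
#' relative to the 2.6-unit branch carrying the species signal for
#' A+(B, C): loci whose A lineages trace through X coalesce with X early and
#' then run a long internal branch before rejoining the rest of the tree, so
#' they accumulate several times more mutations supporting the A+X grouping
#' than non-introgressed loci accumulate for the species grouping.  A
#' mixed supergene therefore flips to the introgressed resolution once
#' roughly a quarter of its sequence is introgressed -- below the admixture
#' proportions of interest -- while single non-introgressed loci still
#' recover the species split.  The pulse is late enough that the recipient's
#' two lineages have usually coalesced and jump as a unit, keeping the
#' locus-level introgression fraction close to `gamma`.
#'
#' @param gamma admixture proportion (0 = no pulse).
#' @return a [species_tree_model()].
#' @export
bias_scenario_model <- function(gamma) {
  newick <- "((X:8,(A:5.4,(B:4.6,C:4.6):0.8):2.6):3,O:11);"
  pulses <- if (gamma > 0)
    data.frame(donor = "X", recipient = "A", time = 1.5, gamma = gamma)
  species_tree_model(newick, samples_per_species = 1, pulses = pulses)
}

# does the recovered unrooted tree group A with X (introgressed), A with
# (B,C) (species), or neither
.classify_bias_topology <- function(tr) {
  sp <- sub("_[0-9]+$", "", tr$tip.label)
  splits <- lapply(.bipartitions(tr), function(s)
    sort(unique(sub("_[0-9]+$", "", s$side))))
  has <- function(side) any(vapply(splits, function(x)
    identical(x, sort(side)), logical(1)))
  all_sp <- sort(unique(sp))
  if (has(c("A", "X")) || has(setdiff(all_sp, c("A", "X")))) return("introgressed")
  if (has(c("A", "B", "C")) || has(setdiff(all_sp, c("A", "B", "C"))))
    return("species")
  "other"
}

.conflicted_node_support <- function(tr) {
  n <- length(tr$tip.label)
  for (s in .bipartitions(tr)) {
    side <- sort(unique(sub("_[0-9]+$", "", s$side)))
    if (identical(side, c("A", "X")) || identical(side, c("A", "B", "C")) ||
        identical(side, c("B", "C", "O")) || identical(side, c("O", "X"))) {
      lab <- tr$node.label[s$node - n]
      if (!is.null(lab) && nzchar(lab)) return(as.numeric(lab))
    }
  }
  NA_real_
}

# per-locus counts of sites whose pattern groups A with X versus A with B,
# split by true introgression class (needs one individual per species)
.bias_mutation_counts <- function(loci, seed = 1) {
  stopifnot(!is.null(loci$truth$introgressed))
  nl <- n_loci(loci)
  intro <- loci$truth$introgressed
  n_ax <- n_ab <- integer(nl)
  for (j in seq_len(nl)) {
    sq <- loci$loci[[j]]
    pick <- function(spp) {
      hit <- grep(paste0("^", spp, "_"), names(sq))
      if (length(hit)) sq[[hit[1]]] else NULL
    }
    A <- pick("A"); X <- pick("X"); B <- pick("B"); C <- pick("C"); O <- pick("O")
    if (is.null(A) || is.null(X) || is.null(B) || is.null(O)) next
    e <- encode_alleles(c(A = A, X = X, B = B, O = O))
    hom <- e$a1 == e$a2 & e$a1 > 0L
    ok <- colSums(hom) == 4L
    a <- e$a1[1, ]; x <- e$a1[2, ]; b <- e$a1[3, ]; o <- e$a1[4, ]
    n_ax[j] <- sum(ok & a == x & b == o & a != b)
    n_ab[j] <- sum(ok & a == b & x == o & a != x)
  }
  data.frame(class = ifelse(intro, "introgressed", "non-introgressed"),
             sites_supporting_introgressed = n_ax,
             sites_supporting_species = n_ab)
}

#' Node support across bin sizes, with and without locus filtering
#'
#' Runs the binned pipeline over a grid of bin sizes, for the unfiltered
#' data and for a filtered run (loci with fewer than 2 polymorphic sites or
#' containing indels removed), and reports per-node bootstrap support.
#'
#' @param loci a [locus_set()].
#' @param k_grid bin sizes (default `c(1, 2, 3, 5, 10, 20, 50, 100)`).
#' @param filters character subset of `c("none", "s2")`; `"s2"` is the
#'   filtered run.
#' @param n_boot bootstrap replicates per run (default 128, gene resampling).
#' @param seed integer seed.
#' @return data.frame with columns `filter`, `k`, `n_bins`, `clade`
#'   (bipartition as sorted species labels) and `support` (percent).
#' @export
support_vs_binsize <- function(loci, k_grid = c(1, 2, 3, 5, 10, 20, 50, 100),
                               filters = c("none", "s2"), n_boot = 128,
                               seed = 1) {
  out <- list()
  for (f in filters) {
    dat <- if (f == "s2") {
      filter_loci(loci, filter_config(min_polymorphic_sites = 2,
                                      drop_indel_loci = TRUE))$loci
    } else loci
    for (k in k_grid) {
      if (k > n_loci(dat)) next
      run <- bin_loci(dat, k, seed = seed)
      tr <- binned_species_tree(run, n_boot = n_boot, unit = "gene",
                                seed = seed)
      n <- length(tr$tip.label)
      for (s in .bipartitions(tr)) {
        lab <- tr$node.label[s$node - n]
        out[[length(out) + 1L]] <- data.frame(
          filter = f, k = k, n_bins = attr(tr, "n_bins_used"),
          clade = paste(sort(unique(sub("_[0-9]+$", "", s$side))),
                        collapse = "+"),
          support = if (nzchar(lab)) as.numeric(lab) else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}
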
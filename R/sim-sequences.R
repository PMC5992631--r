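#' Evolve sequences along gene trees under Jukes-Cantor
#'
#' Sites evolve independently; substitution events occur at rate `theta` per
#' site per coalescent unit and replace the current base by one of the other
#' three uniformly, so `theta * t` is the expected number of substitutions
#' per site along a path of length `t` and two tips separated by path length
#' `t` differ with probability `3/4 * (1 - exp(-4 * theta * t / 3))`.
#' The root state is drawn uniformly over A, C, G, T.  The two haplotypes of
#' each diploid individual are collapsed to a single consensus with IUPAC
#' ambiguity codes, so heterozygous sites arise wherever the haplotypes
#' disagree.
#'
#' @param trees list of gene trees from [simulate_gene_trees()].
#' @param locus_length sites per locus (default 87, the typical trimmed
#'   ddRAD fragment length).
#' @param theta substitutions per site per coalescent unit (> 0).
#' @param seed master seed (per-locus streams derived deterministically).
#' @param indel_rate probability per locus of a single-column gap event: one
#'   alignment column is replaced by `-` in one random gene-tree clade
#'   (default 0; used to exercise the indel filter).
#' @return a [locus_set()] whose `truth` field retains the model, the gene
#'   trees and the per-locus introgression flags.
#' @examples
#' m <- species_tree_model("((A:1,B:1):0.5,C:1.5);")
#' gt <- simulate_gene_trees(m, 2, seed = 1)
#' ls1 <- simulate_sequences(gt, locus_length = 50, theta = 0.01, seed = 1)
#' @export
simulate_sequences <- function(trees, locus_length = 87, theta, seed,
                               indel_rate = 0) {
  stopifnot(theta > 0, locus_length >= 1)
  model <- attr(trees, "model")
  set.seed(as.integer(seed))
  locus_seeds <- sample.int(.Machine$integer.max, length(trees))
  loci <- vector("list", length(trees))
  for (j in seq_along(trees)) {
    set.seed(locus_seeds[j])
    loci[[j]] <- .simulate_locus(trees[[j]], locus_length, theta, indel_rate)
  }
  imap <- if (!is.null(model)) model_individual_map(model) else
    .individual_map_from_tips(trees[[1]]$tip.label)
  truth <- list(model = model, gene_trees = trees,
                introgressed = attr(trees, "introgressed"))
  locus_set(loci, imap, locus_length, truth)
}

.individual_map_from_tips <- function(tip_labels) {
  ind <- unique(sub("_[ab]$", "", tip_labels))
  sp <- sub("_[0-9]+$", "", ind)
  data.frame(individual = ind, species = sp, population = sp)
}

# simulate one locus: haplotype matrix down the tree, then diploid collapse
.simulate_locus <- function(tr, L, theta, indel_rate) {
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  seqs <- matrix(0L, n_node, L)
  root <- n_tip + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  # cladewise edge order guarantees parents are visited before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    p_stay <- 0.25 + 0.75 * exp(-4 * theta * tr$edge.length[e] / 3)
    s <- seqs[parent, ]
    hit <- which(stats::runif(L) >= p_stay)
    if (length(hit)) {
      off <- sample.int(3L, length(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + off) %% 4L) + 1L
    }
    seqs[child, ] <- s
  }
  gap_col <- 0L
  gap_tips <- integer(0)
  if (indel_rate > 0 && stats::runif(1) < indel_rate) {
    gap_col <- sample.int(L, 1L)
    internal <- which(tr$edge[, 2] > n_tip)
    pick <- if (length(internal)) sample(internal, 1L) else sample.int(nrow(tr$edge), 1L)
    gap_tips <- .tips_below(tr, tr$edge[pick, 2])
  }
  inds <- unique(sub("_[ab]$", "", tr$tip.label))
  out <- character(length(inds))
  for (i in seq_along(inds)) {
    t1 <- match(paste0(inds[i], "_a"), tr$tip.label)
    t2 <- match(paste0(inds[i], "_b"), tr$tip.label)
    h1 <- seqs[t1, ]; h2 <- seqs[t2, ]
    g <- .pair_to_genotype(h1, h2)
    if (gap_col > 0L && (t1 %in% gap_tips || t2 %in% gap_tips))
      substr(g, gap_col, gap_col) <- "-"
    out[i] <- g
  }
  stats::setNames(out, inds)
}

.tips_below <- function(tr, node) {
  n_tip <- length(tr$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Apply ddRAD-style missingness to a locus set
#'
#' Drops whole (individual, locus) cells to emulate restriction-site gain and
#' loss: each cell is retained with probability
#' `(1 - dropout_per_individual) * exp(-divergence_dropout_rate * d)` where
#' `d` is the species-tree patristic distance between the individual's
#' species and the reference individual's species, so expected missingness
#' increases with phylogenetic distance from the reference.
#'
#' @param loci a [locus_set()] carrying simulation truth (needs the model's
#'   species tree for distances unless `divergence_dropout_rate = 0`).
#' @param dropout_per_individual baseline per-cell dropout probability.
#' @param divergence_dropout_rate exponential loss rate per coalescent unit
#'   of divergence from the reference individual.
#' @param reference_individual individual id used as distance origin
#'   (default: first individual).
#' @param seed integer seed.
#' @return a `locus_set` with cells removed; the dropout mask is recorded in
#'   `truth$dropout_mask` (TRUE = cell retained).
#' @export
apply_missingness <- function(loci, dropout_per_individual = 0,
                              divergence_dropout_rate = 0,
                              reference_individual = NULL, seed = 1) {
  stopifnot(inherits(loci, "locus_set"),
            dropout_per_individual >= 0, dropout_per_individual <= 1,
            divergence_dropout_rate >= 0)
  inds <- individuals(loci)
  if (is.null(reference_individual)) reference_individual <- inds[1]
  sp_of <- .species_of(loci)
  d <- numeric(length(inds))
  if (divergence_dropout_rate > 0) {
    if (is.null(loci$truth$model))
      stop("divergence-correlated dropout needs truth$model for tree distances")
    dm <- .species_distance_matrix(loci$truth$model)
    ref_sp <- sp_of[[reference_individual]]
    d <- vapply(inds, function(i) {
      s <- sp_of[[i]]
      if (s == ref_sp) 0 else dm[ref_sp, s]
    }, numeric(1))
  }
  p_keep <- stats::setNames(
    (1 - dropout_per_individual) * exp(-divergence_dropout_rate * d), inds)
  set.seed(as.integer(seed))
  keep_mask <- matrix(FALSE, length(inds), n_loci(loci),
                      dimnames = list(inds, NULL))
  out <- vector("list", n_loci(loci))
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    keep <- stats::runif(length(sq)) < p_keep[names(sq)]
    out[[j]] <- sq[keep]
    keep_mask[names(sq)[keep], j] <- TRUE
  }
  truth <- loci$truth
  truth$dropout_mask <- keep_mask
  locus_set(out, loci$individual_map, loci$locus_length, truth)
}

#' One-call synthetic ddRAD dataset
#'
#' Convenience wrapper: gene trees, sequences, and (optionally) missingness
#' from a single model and master seed.
#'
#' @inheritParams simulate_gene_trees
#' @inheritParams simulate_sequences
#' @param dropout_per_individual,divergence_dropout_rate,reference_individual
#'   forwarded to [apply_missingness()]; the default of 0/0 applies none.
#' @return a [locus_set()] with full simulation truth.
#' @export
simulate_radseq <- function(model, n_loci, theta = 0.01, seed = 1,
                            locus_length = 87, indel_rate = 0,
                            dropout_per_individual = 0,
                            divergence_dropout_rate = 0,
                            reference_individual = NULL) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, 3L)
  gt <- simulate_gene_trees(model, n_loci, seed = seeds[1])
  ls1 <- simulate_sequences(gt, locus_length, theta, seed = seeds[2],
                            indel_rate = indel_rate)
  if (dropout_per_individual > 0 || divergence_dropout_rate > 0)
    ls1 <- apply_missingness(ls1, dropout_per_individual,
                             divergence_dropout_rate,
                             reference_individual, seed = seeds[3])
  ls1
}
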
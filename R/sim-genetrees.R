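#' Simulate gene trees under the multispecies coalescent with admixture pulses
#'
#' Generates one independent gene tree per locus.  Within each species branch
#' lineages coalesce pairwise at rate 1 per pair (time in coalescent units of
#' 2N generations); at an admixture pulse each lineage currently in the
#' recipient branch independently moves to the donor branch with probability
#' `gamma`.  Each diploid individual contributes two haploid lineages; tips
#' are labelled `<species>_<i>_a` / `<species>_<i>_b`.
#'
#' @param model a [species_tree_model()].
#' @param n_loci number of independent loci (gene trees) to simulate.
#' @param seed master seed; per-locus random streams are derived from it
#'   deterministically, so the same seed reproduces the same trees.
#' @return list of `phylo` gene trees.  Each tree carries attribute
#'   `introgressed` (TRUE if at least one lineage took a donor path at any
#'   pulse).  The list carries attributes `model` and `introgressed` (the
#'   per-locus flag vector).
#' @examples
#' m <- species_tree_model("((A:1,B:1):0.5,C:1.5);")
#' gt <- simulate_gene_trees(m, n_loci = 3, seed = 1)
#' attr(gt, "introgressed")
#' @export
simulate_gene_trees <- function(model, n_loci, seed) {
  stopifnot(inherits(model, "species_tree_model"), n_loci >= 1)
  set.seed(as.integer(seed))
  locus_seeds <- sample.int(.Machine$integer.max, n_loci)
  trees <- vector("list", n_loci)
  flags <- logical(n_loci)
  for (j in seq_len(n_loci)) {
    set.seed(locus_seeds[j])
    trees[[j]] <- .simulate_one_gene_tree(model)
    flags[j] <- attr(trees[[j]], "introgressed")
  }
  attr(trees, "model") <- model
  attr(trees, "introgressed") <- flags
  trees
}

# one realisation of the structured coalescent on the species tree
.simulate_one_gene_tree <- function(model) {
  tree <- model$tree
  tt <- model$node_time
  n_sp <- length(tree$tip.label)
  root <- n_sp + 1L

  # tips: two lineages per diploid individual, grouped by species
  tip_species <- rep(seq_len(n_sp), model$samples_per_species * 2L)
  imap <- model_individual_map(model)
  # interleaved so consecutive tip pairs belong to one individual
  tip_labels <- unlist(lapply(seq_len(nrow(imap)), function(i)
    paste0(imap$individual[i], c("_a", "_b"))), use.names = FALSE)
  n_tip <- length(tip_labels)

  # active lineage state
  br <- tip_species            # species-tree node whose parent branch holds the lineage
  gn <- seq_len(n_tip)         # gene-tree node carried by the lineage
  introgressed <- FALSE

  n_node <- 2L * n_tip - 1L
  height <- numeric(n_node)
  kid1 <- integer(n_node); kid2 <- integer(n_node)
  next_node <- n_tip + 1L

  coalesce_in <- function(members, t0, t1) {
    # members: indices into br/gn of lineages sharing a branch
    while (length(members) >= 2L) {
      k <- length(members)
      t0 <- t0 + stats::rexp(1L, rate = k * (k - 1) / 2)
      if (t0 >= t1) break
      pick <- sample.int(k, 2L)
      v <- next_node
      height[v] <<- t0
      kid1[v] <<- gn[members[pick[1]]]
      kid2[v] <<- gn[members[pick[2]]]
      next_node <<- v + 1L
      gn[members[pick[1]]] <<- v
      drop <- members[pick[2]]
      gn[drop] <<- NA_integer_
      br[drop] <<- NA_integer_
      members <- members[-pick[2]]
    }
    invisible(NULL)
  }

  # event schedule: species-tree internal node times (merges) and pulses
  ev_time <- tt[(n_sp + 1L):(2L * n_sp - 1L)]
  ev <- data.frame(time = ev_time, type = "merge",
                   node = (n_sp + 1L):(2L * n_sp - 1L),
                   donor = NA_integer_, recipient = NA_integer_,
                   gamma = NA_real_)
  if (!is.null(model$pulses)) {
    pl <- model$pulses
    ev <- rbind(ev, data.frame(
      time = pl$time, type = "pulse", node = NA_integer_,
      donor = vapply(pl$donor, function(l) .branch_node(model, l), integer(1)),
      recipient = vapply(pl$recipient, function(l) .branch_node(model, l), integer(1)),
      gamma = pl$gamma))
  }
  ev <- ev[order(ev$time), , drop = FALSE]

  t_now <- 0
  for (i in seq_len(nrow(ev))) {
    t_next <- ev$time[i]
    if (t_next > t_now) {
      for (b in unique(br[!is.na(br)]))
        coalesce_in(which(!is.na(br) & br == b), t_now, t_next)
      t_now <- t_next
    }
    if (ev$type[i] == "pulse") {
      cand <- which(!is.na(br) & br == ev$recipient[i])
      if (length(cand)) {
        move <- cand[stats::runif(length(cand)) < ev$gamma[i]]
        if (length(move)) {
          br[move] <- ev$donor[i]
          introgressed <- TRUE
        }
      }
    } else {
      kids <- tree$edge[tree$edge[, 1] == ev$node[i], 2]
      br[!is.na(br) & br %in% kids] <- ev$node[i]
    }
  }
  # above the root: single panmictic branch
  coalesce_in(which(!is.na(br)), t_now, Inf)

  phy <- .build_phylo(n_tip, tip_labels, height, kid1, kid2)
  attr(phy, "introgressed") <- introgressed
  phy
}

# assemble an ape phylo from the merge records (tips 1..n, internal ids in
# ascending-height creation order; ape wants root = n+1 and cladewise edges)
.build_phylo <- function(n_tip, tip_labels, height, kid1, kid2) {
  n_node <- 2L * n_tip - 1L
  internal <- (n_tip + 1L):n_node
  # relabel internal nodes by descending height so the root becomes n+1
  ord <- internal[order(height[internal], decreasing = TRUE)]
  new_id <- integer(n_node)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  new_id[ord] <- (n_tip + 1L):n_node
  h2 <- numeric(n_node)
  h2[new_id] <- height
  k1 <- integer(n_node); k2 <- integer(n_node)
  k1[new_id[internal]] <- new_id[kid1[internal]]
  k2[new_id[internal]] <- new_id[kid2[internal]]

  # preorder (cladewise) edge construction
  edge <- matrix(0L, n_node - 1L, 2L)
  elen <- numeric(n_node - 1L)
  stack <- c(n_tip + 1L)
  e <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n_tip) next
    for (child in c(k1[v], k2[v])) {
      e <- e + 1L
      edge[e, ] <- c(v, child)
      elen[e] <- h2[v] - h2[child]
      stack <- c(stack, child)
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = tip_labels, Nnode = n_tip - 1L),
                   class = "phylo", order = "cladewise")
  attr(phy, "node_height") <- h2
  phy
}

#' Gene-tree quartet topology frequencies for single-lineage samples
#'
#' Restricts each gene tree to one haplotype per named species and tallies
#' the induced unrooted quartet topology; used to check simulated discordance
#' against the closed-form multispecies-coalescent expectation (the two minor
#' resolutions each arise with probability `exp(-T)/3` for an internal branch
#' of length `T`).
#'
#' @param gene_trees list of `phylo` from [simulate_gene_trees()].
#' @param quartet character vector of four species labels (p1, p2, p3, o).
#' @return table of counts over the splits `p1p2`, `p1p3`, `p2p3` (which pair
#'   of the first three species is together, with the fourth).
#' @export
quartet_topology_counts <- function(gene_trees, quartet) {
  stopifnot(length(quartet) == 4L)
  out <- c(p1p2 = 0L, p1p3 = 0L, p2p3 = 0L)
  for (tr in gene_trees) {
    tips <- vapply(quartet, function(s) {
      hit <- grep(paste0("^", s, "_[0-9]+_a$"), tr$tip.label)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (anyNA(tips)) next
    split <- .quartet_split_from_heights(tr, tips)
    out[split] <- out[split] + 1L
  }
  out
}

# which pair of tips[1:3] (with tips[4]) forms the split, by four-point on
# node heights (ultrametric: pair with the lowest MRCA is together)
.quartet_split_from_heights <- function(tr, tips) {
  d <- .pairwise_mrca_heights(tr, tips)
  s12 <- d[1, 2] + d[3, 4]; s13 <- d[1, 3] + d[2, 4]; s23 <- d[2, 3] + d[1, 4]
  c("p1p2", "p1p3", "p2p3")[which.min(c(s12, s13, s23))]
}

.pairwise_mrca_heights <- function(tr, tips) {
  h <- attr(tr, "node_height")
  if (is.null(h)) {
    n <- length(tr$tip.label)
    depth <- ape::node.depth.edgelength(tr)
    h <- max(depth[seq_len(n)]) - depth
  }
  anc <- lapply(tips, function(t) .ancestor_path(tr, t))
  d <- matrix(0, 4L, 4L)
  for (i in 1:3) for (j in (i + 1):4) {
    m <- intersect(anc[[i]], anc[[j]])
    d[i, j] <- d[j, i] <- min(h[m])
  }
  d
}

.ancestor_path <- function(tr, node) {
  path <- integer(0)
  repeat {
    i <- match(node, tr$edge[, 2])
    if (is.na(i)) break
    node <- tr$edge[i, 1]
    path <- c(path, node)
  }
  path
}
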
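#' Uncorrected pairwise distances from a concatenated alignment
#'
#' Computes the proportion of differing comparable sites per pair of
#' sequences.  Per site the contribution is the probability that one allele
#' drawn from each diploid genotype differs, so an IUPAC heterozygote against
#' a matching homozygote counts 0.5 (and two identical heterozygotes count
#' 0.5); `N`, gaps and 3/4-allele codes are excluded pairwise.
#'
#' @param aln named character vector of equal-length sequences (e.g. from
#'   [concat_alignment()]).
#' @return symmetric distance matrix with attribute `n_sites` (comparable
#'   sites per pair).  A pair with zero comparable sites is an error naming
#'   the pair.
#' @examples
#' p_distance(c(a = "ACGT", b = "ACGA"))[1, 2]  # 0.25
#' @export
p_distance <- function(aln) {
  if (length(aln) < 2L) stop("need >= 2 sequences")
  enc <- encode_alleles(aln)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  ns <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- enc$a1[i, ] > 0L & enc$a1[j, ] > 0L
    nc <- sum(ok)
    if (nc == 0L)
      stop("no comparable sites between '", names(aln)[i], "' and '",
           names(aln)[j], "'")
    # expected allele mismatch over the four allele-pair draws
    mm <- (enc$a1[i, ok] != enc$a1[j, ok]) + (enc$a1[i, ok] != enc$a2[j, ok]) +
          (enc$a2[i, ok] != enc$a1[j, ok]) + (enc$a2[i, ok] != enc$a2[j, ok])
    d[i, j] <- d[j, i] <- sum(mm) / (4 * nc)
    ns[i, j] <- ns[j, i] <- nc
  }
  attr(d, "n_sites") <- ns
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit moved to the adjacent (sibling) branch so
#' path lengths through the node are preserved.  This is the package's
#' concatenation-inference engine: a deliberately simple, exactly testable
#' stand-in for likelihood tree inference that preserves the
#' concatenation-versus-coalescent contrast under study.
#'
#' @param dm distance matrix (as from [p_distance()]).
#' @return unrooted `phylo`.
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm) < 3L) stop("need >= 3 taxa")
  tr <- ape::nj(as.matrix(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    sib <- which(tr$edge[, 1] == tr$edge[e, 1])
    sib <- setdiff(sib, e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap support by site or locus resampling
#'
#' Resamples alignment columns (`unit = "site"`) or whole loci
#' (`unit = "locus"`) with replacement, re-infers the NJ tree, and reports
#' for each internal edge of the original tree the percentage of replicates
#' containing the same bipartition.
#'
#' @param loci a [locus_set()] (locus structure is needed for
#'   `unit = "locus"`).
#' @param n_reps bootstrap replicates (>= 1).
#' @param unit `"site"` or `"locus"`.
#' @param seed integer seed.
#' @return the NJ tree from the full data with integer percentage supports
#'   in `node.label` (root label empty).
#' @export
bootstrap_support <- function(loci, n_reps = 100, unit = c("site", "locus"),
                              seed = 1) {
  unit <- match.arg(unit)
  stopifnot(n_reps >= 1)
  aln <- concat_alignment(loci)
  base_tree <- neighbor_joining(p_distance(aln))
  lens <- attr(aln, "locus_lengths")
  set.seed(as.integer(seed))
  boots <- vector("list", n_reps)
  total <- sum(lens)
  for (r in seq_len(n_reps)) {
    if (unit == "site") {
      cols <- sample.int(total, total, replace = TRUE)
      re <- vapply(aln, function(s)
        paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""),
        character(1))
    } else {
      pick <- sample.int(n_loci(loci), n_loci(loci), replace = TRUE)
      re <- concat_alignment(loci, which = pick)
    }
    boots[[r]] <- tryCatch(neighbor_joining(p_distance(re)),
                           error = function(e) NULL)
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(base_tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base_tree$node.label <- as.character(round(100 * counts / length(boots)))
  base_tree$node.label[1] <- ""
  base_tree
}

#' Quartet-frequency species tree from gene trees
#'
#' The package's multispecies-coalescent inference engine: for every quartet
#' of species it tallies the induced unrooted quartet topology across gene
#' trees (one representative haplotype per species per tree), takes the
#' dominant resolution, and assembles the species tree that satisfies the
#' largest number of dominant quartets (exhaustive search over topologies up
#' to 8 species, greedy stepwise insertion beyond).  Under the multispecies
#' coalescent the dominant quartet resolution is statistically consistent
#' for the species tree even under incomplete lineage sorting.
#'
#' @param gene_trees list of `phylo`; tip labels must map to species via
#'   `species_map` (or, by default, by stripping the `_<i>_<a|b>` suffix the
#'   simulator appends).
#' @param species_map optional named character vector tip-label -> species.
#' @return unrooted species `phylo`; `node.label` holds percentage supports
#'   (mean dominant-quartet frequency over the quartets spanning each
#'   internal edge).  Attribute `quartets` carries the tally table.
#' @export
quartet_species_tree <- function(gene_trees, species_map = NULL) {
  tal <- tally_quartets(gene_trees, species_map)
  assemble_from_quartets(tal)
}

#' Tally induced quartet topologies across gene trees
#'
#' @inheritParams quartet_species_tree
#' @return data.frame with columns `a`,`b`,`c`,`d` (species, sorted),
#'   counts `ab_cd`, `ac_bd`, `ad_bc` and `n` (informative gene trees).
#' @export
tally_quartets <- function(gene_trees, species_map = NULL) {
  species <- sort(unique(.tree_species(gene_trees[[1]], species_map)))
  if (length(species) < 4L) stop("need >= 4 species")
  quads <- utils::combn(species, 4L)
  nq <- ncol(quads)
  counts <- matrix(0L, nq, 3L,
                   dimnames = list(NULL, c("ab_cd", "ac_bd", "ad_bc")))
  n_inf <- integer(nq)
  for (tr in gene_trees) {
    sp <- .tree_species(tr, species_map)
    rep_tip <- match(species, sp)     # first haplotype per species
    h <- .tree_heights(tr)
    mrca_h <- .rep_mrca_heights(tr, rep_tip[!is.na(rep_tip)], h)
    present <- !is.na(rep_tip)
    idx_of <- stats::setNames(cumsum(present), species)
    for (q in seq_len(nq)) {
      four <- quads[, q]
      if (!all(present[match(four, species)])) next
      ii <- idx_of[four]
      s1 <- mrca_h[ii[1], ii[2]] + mrca_h[ii[3], ii[4]]
      s2 <- mrca_h[ii[1], ii[3]] + mrca_h[ii[2], ii[4]]
      s3 <- mrca_h[ii[1], ii[4]] + mrca_h[ii[2], ii[3]]
      k <- which.min(c(s1, s2, s3))
      counts[q, k] <- counts[q, k] + 1L
      n_inf[q] <- n_inf[q] + 1L
    }
  }
  data.frame(a = quads[1, ], b = quads[2, ], c = quads[3, ], d = quads[4, ],
             counts, n = n_inf)
}

.tree_species <- function(tr, species_map) {
  if (!is.null(species_map)) {
    sp <- species_map[tr$tip.label]
    if (anyNA(sp)) stop("species_map does not cover all gene-tree tips")
    return(unname(sp))
  }
  sub("_[0-9]+_[ab]$", "", tr$tip.label)
}

.tree_heights <- function(tr) {
  h <- attr(tr, "node_height")
  if (!is.null(h)) return(h)
  n <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  max(depth[seq_len(n)]) - depth
}

# MRCA height matrix for a set of representative tips
.rep_mrca_heights <- function(tr, tips, h) {
  k <- length(tips)
  anc <- lapply(tips, function(t) c(t, .ancestor_path(tr, t)))
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    common <- intersect(anc[[i]], anc[[j]])
    m[i, j] <- m[j, i] <- min(h[common])
  }
  m
}

#' Assemble a species tree from quartet tallies
#'
#' @param tally data.frame from [tally_quartets()].
#' @return unrooted `phylo` with percentage supports in `node.label`; see
#'   [quartet_species_tree()].
#' @export
assemble_from_quartets <- function(tally) {
  tally <- tally[tally$n > 0L, , drop = FALSE]
  if (nrow(tally) == 0L) stop("no informative quartets")
  species <- sort(unique(unlist(tally[, c("a", "b", "c", "d")])))
  dom <- max.col(as.matrix(tally[, c("ab_cd", "ac_bd", "ad_bc")]),
                 ties.method = "first")
  dom_freq <- vapply(seq_len(nrow(tally)), function(i)
    tally[[c("ab_cd", "ac_bd", "ad_bc")[dom[i]]]][i] / tally$n[i], numeric(1))
  candidates <- if (length(species) <= 8L) .all_topologies(species)
    else list(.greedy_topology(species, tally, dom))
  best <- NULL; best_score <- -1
  for (cand in candidates) {
    sc <- .quartet_score(cand, tally, dom)
    if (sc > best_score) { best_score <- sc; best <- cand }
  }
  .attach_quartet_support(best, tally, dom, dom_freq)
}

# all unrooted topologies by stepwise addition (n <= 8: 10395 trees max)
.all_topologies <- function(species) {
  base <- ape::read.tree(text = paste0("(", species[1], ",", species[2], ",",
                                       species[3], ");"))
  trees <- list(base)
  for (s in species[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(e) .bind_tip(tr, s, e))
    }), recursive = FALSE)
  }
  trees
}

.bind_tip <- function(tr, label, edge) {
  tip <- ape::read.tree(text = paste0("(", label, ":1);"))
  tr2 <- ape::bind.tree(ape::compute.brlen(tr, 1), tip,
                        where = tr$edge[edge, 2], position = 0.5)
  ape::unroot(tr2)
}

# number of dominant quartets induced by a candidate topology
.quartet_score <- function(tr, tally, dom) {
  tr <- ape::compute.brlen(tr, 1)
  h <- .tree_heights(tr)
  tips <- match(sort(tr$tip.label), tr$tip.label)
  mh <- .rep_mrca_heights(tr, tips, h)
  lab <- sort(tr$tip.label)
  idx <- stats::setNames(seq_along(lab), lab)
  score <- 0L
  for (i in seq_len(nrow(tally))) {
    ii <- idx[c(tally$a[i], tally$b[i], tally$c[i], tally$d[i])]
    s1 <- mh[ii[1], ii[2]] + mh[ii[3], ii[4]]
    s2 <- mh[ii[1], ii[3]] + mh[ii[2], ii[4]]
    s3 <- mh[ii[1], ii[4]] + mh[ii[2], ii[3]]
    v <- c(s1, s2, s3)
    if (which.min(v) == dom[i] && sum(v == min(v)) == 1L) score <- score + 1L
  }
  score
}

# greedy stepwise insertion maximizing the quartet score (> 8 species)
.greedy_topology <- function(species, tally, dom) {
  tr <- ape::read.tree(text = paste0("(", species[1], ",", species[2], ",",
                                     species[3], ");"))
  for (s in species[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tr$edge)), function(e) .bind_tip(tr, s, e))
    scores <- vapply(cands, function(cand) {
      keep <- apply(tally[, c("a", "b", "c", "d")], 1L, function(r)
        all(r %in% cand$tip.label))
      .quartet_score(cand, tally[keep, , drop = FALSE], dom[keep])
    }, numeric(1))
    tr <- cands[[which.max(scores)]]
  }
  tr
}

# node.label = mean dominant frequency over quartets whose induced split uses
# the edge's bipartition, as integer percentages
.attach_quartet_support <- function(tr, tally, dom, dom_freq) {
  tr <- ape::compute.brlen(tr, 1)
  n <- length(tr$tip.label)
  labels <- rep("", tr$Nnode)
  splits <- .bipartitions(tr)
  for (k in seq_along(splits)) {
    side <- splits[[k]]$side
    node <- splits[[k]]$node
    rel <- vapply(seq_len(nrow(tally)), function(i) {
      four <- c(tally$a[i], tally$b[i], tally$c[i], tally$d[i])
      inside <- four %in% side
      if (sum(inside) != 2L) return(NA_real_)
      pair <- sort(four[inside])
      want <- .dominant_pair(tally[i, ], dom[i])
      # the quartet's dominant split matches the edge if either side of the
      # induced pair partition lies inside the bipartition
      if (identical(pair, want) ||
          identical(pair, sort(setdiff(four, want)))) dom_freq[i]
      else NA_real_
    }, numeric(1))
    vals <- rel[!is.na(rel)]
    if (length(vals))
      labels[node - n] <- as.character(round(100 * mean(vals)))
  }
  tr$node.label <- labels
  attr(tr, "quartets") <- tally
  tr
}

.dominant_pair <- function(row, dom) {
  four <- c(row$a, row$b, row$c, row$d)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  sort(four[pairs[[dom]]])
}

# internal-edge bipartitions as tip-label sets (non-trivial splits)
.bipartitions <- function(tr) {
  n <- length(tr$tip.label)
  internal <- unique(tr$edge[tr$edge[, 2] > n, 2])
  out <- list()
  for (v in internal) {
    tips <- .tips_below(tr, v)
    if (length(tips) >= 2L && length(tips) <= n - 2L)
      out[[length(out) + 1L]] <- list(node = v,
                                      side = sort(tr$tip.label[tips]))
  }
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric count of bipartitions present in one unrooted topology but not
#' the other; 0 iff the topologies are identical.
#'
#' @param a,b `phylo` objects over the same leaf set.
#' @return integer bipartition difference count.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
}
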
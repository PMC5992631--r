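#' Specify a species tree model for coalescent simulation
#'
#' Bundles a rooted, ultrametric species tree (branch lengths in coalescent
#' units of 2N generations), a sampling design, and an optional list of
#' admixture pulses into the ground-truth model from which gene trees and
#' sequences are simulated.
#'
#' Time runs backwards from the present (tips at time 0).  The branch of a
#' node spans the interval from the node's own height to its parent's height;
#' a pulse from `donor` into `recipient` at time `t` requires `t` to fall in
#' the interior of both branches.  At a pulse each lineage currently in the
#' recipient branch independently reassigns to the donor branch with
#' probability `gamma` (an instantaneous admixture pulse, not continuous
#' migration).
#'
#' @param newick species tree as a Newick string or `phylo` object; branch
#'   lengths are interpreted as durations in coalescent units.  Internal
#'   nodes may carry labels so pulses can name internal branches.
#' @param samples_per_species number of diploid individuals sampled per
#'   species: a single count recycled to all species, or a named vector.
#' @param pulses `NULL` or a data.frame with columns `donor`, `recipient`
#'   (tip or internal-node labels), `time` (coalescent units before present)
#'   and `gamma` (admixture proportion in `[0, 1]`).
#' @return object of class `species_tree_model` with fields `tree` (phylo),
#'   `node_time` (height of every node), `samples_per_species`, `pulses`.
#' @examples
#' m <- species_tree_model("((A:1,B:1):0.5,C:1.5);", samples_per_species = 2)
#' @export
species_tree_model <- function(newick, samples_per_species = 1, pulses = NULL) {
  tree <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(tree) || is.null(tree$edge.length))
    stop("species tree must be a valid Newick string with branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("species tree must be rooted and binary")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  node_time <- max(depth[seq_len(n)]) - depth # height above present
  if (any(abs(node_time[seq_len(n)]) > 1e-8))
    stop("species tree must be ultrametric (contemporaneous tips)")
  node_time[seq_len(n)] <- 0
  if (any(tree$edge.length <= 0))
    stop("every non-root branch must have duration > 0")
  sps <- tree$tip.label
  if (is.null(names(samples_per_species))) {
    samples_per_species <- stats::setNames(rep_len(as.integer(samples_per_species),
                                                   length(sps)), sps)
  } else {
    missing <- setdiff(sps, names(samples_per_species))
    if (length(missing)) stop("samples_per_species missing: ",
                              paste(missing, collapse = ", "))
    samples_per_species <- vapply(sps, function(s)
      as.integer(samples_per_species[[s]]), integer(1))
  }
  if (any(samples_per_species < 1L)) stop("need >= 1 diploid individual per species")
  model <- structure(list(tree = tree, node_time = node_time,
                          samples_per_species = samples_per_species,
                          pulses = NULL),
                     class = "species_tree_model")
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses)
    stopifnot(all(c("donor", "recipient", "time", "gamma") %in% names(pulses)))
    for (i in seq_len(nrow(pulses))) .validate_pulse(model, pulses[i, ], i)
    model$pulses <- pulses
  }
  model
}

# node id (tip or internal) for a branch label
.branch_node <- function(model, label) {
  tree <- model$tree
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  NA_integer_
}

.parent_of <- function(tree, node) {
  e <- tree$edge[, 2] == node
  if (!any(e)) NA_integer_ else tree$edge[e, 1]
}

.validate_pulse <- function(model, pulse, i) {
  who <- function(role, label) {
    node <- .branch_node(model, label)
    if (is.na(node))
      stop("pulse ", i, ": unknown ", role, " branch '", label, "'")
    node
  }
  d <- who("donor", pulse$donor)
  r <- who("recipient", pulse$recipient)
  if (identical(d, r)) stop("pulse ", i, ": donor equals recipient")
  if (pulse$gamma < 0 || pulse$gamma > 1)
    stop("pulse ", i, ": gamma must lie in [0, 1]")
  tree <- model$tree
  tt <- model$node_time
  span <- function(node) {
    p <- .parent_of(tree, node)
    c(tt[node], if (is.na(p)) Inf else tt[p])
  }
  sd_ <- span(d); sr <- span(r)
  lo <- max(sd_[1], sr[1]); hi <- min(sd_[2], sr[2])
  if (!(pulse$time > lo && pulse$time < hi))
    stop("pulse ", i, " ('", pulse$donor, "' -> '", pulse$recipient,
         "'): time ", pulse$time,
         " outside the overlap of donor and recipient branch intervals (",
         signif(lo, 4), ", ", signif(hi, 4), ")")
  invisible(TRUE)
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("species_tree_model:", length(x$tree$tip.label), "species, root at",
      signif(max(x$node_time), 4), "coalescent units;",
      sum(x$samples_per_species), "diploid individuals\n")
  if (!is.null(x$pulses))
    for (i in seq_len(nrow(x$pulses)))
      cat(sprintf("  pulse: %s -> %s at t=%g, gamma=%g\n",
                  x$pulses$donor[i], x$pulses$recipient[i],
                  x$pulses$time[i], x$pulses$gamma[i]))
  invisible(x)
}

#' Individual ids and species map implied by a model's sampling design
#' @param model a `species_tree_model`.
#' @return data.frame with columns `individual`, `species`, `population`.
#' @export
model_individual_map <- function(model) {
  sps <- model$tree$tip.label
  ind <- unlist(lapply(sps, function(s)
    paste0(s, "_", seq_len(model$samples_per_species[[s]]))), use.names = FALSE)
  data.frame(individual = ind,
             species = rep(sps, model$samples_per_species),
             population = rep(sps, model$samples_per_species))
}

# patristic distance between two species on the model tree (coalescent units)
.species_distance_matrix <- function(model) {
  stats::cophenetic(model$tree)
}
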
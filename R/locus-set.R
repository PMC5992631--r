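#' Construct a set of RAD loci
#'
#' A `locus_set` is the central substrate of the pipeline: a collection of
#' equal-role short loci, each an alignment of diploid consensus sequences
#' (IUPAC ambiguity codes mark heterozygous sites, `N` missing data, `-`
#' alignment gaps).  Missingness is per (individual, locus): an individual
#' with no data at a locus is simply absent from that locus' alignment.
#'
#' @param loci list of named character vectors; element `j` maps individual
#'   ids to their consensus sequence at locus `j`.  All sequences within a
#'   locus must have identical length.
#' @param individual_map data.frame with columns `individual`, `species` and
#'   optionally `population` (defaults to the species label).  Every
#'   individual appearing in `loci` must be mapped.
#' @param locus_length nominal locus length in bases (default taken from the
#'   first locus, or 0 for an empty set).
#' @param truth optional ground-truth list from the simulator: fields
#'   `model` (a [species_tree_model()]), `gene_trees` (list of `phylo`),
#'   `introgressed` (logical per locus) and `dropout_mask`.
#' @return an object of class `locus_set`.
#' @examples
#' ls1 <- locus_set(
#'   loci = list(c(a = "ACGT", b = "ACGA")),
#'   individual_map = data.frame(individual = c("a", "b"),
#'                               species = c("sp1", "sp2")))
#' n_loci(ls1)
#' @export
locus_set <- function(loci, individual_map, locus_length = NULL, truth = NULL) {
  stopifnot(is.list(loci))
  individual_map <- as.data.frame(individual_map)
  if (!all(c("individual", "species") %in% names(individual_map)))
    stop("individual_map needs columns 'individual' and 'species'")
  if (is.null(individual_map$population))
    individual_map$population <- individual_map$species
  individual_map$individual <- as.character(individual_map$individual)
  individual_map$species <- as.character(individual_map$species)
  individual_map$population <- as.character(individual_map$population)
  if (anyDuplicated(individual_map$individual))
    stop("duplicated individual ids in individual_map")
  for (j in seq_along(loci)) {
    sq <- loci[[j]]
    if (length(sq) == 0L) next
    if (is.null(names(sq)) || any(names(sq) == ""))
      stop("locus ", j, ": sequences must be named by individual")
    if (length(unique(nchar(sq))) != 1L)
      stop("locus ", j, ": ragged alignment (unequal sequence lengths)")
    unknown <- !(names(sq) %in% individual_map$individual)
    if (any(unknown))
      stop("locus ", j, ": individual(s) not in individual_map: ",
           paste(names(sq)[unknown], collapse = ", "))
  }
  if (is.null(locus_length)) {
    locus_length <- if (length(loci) && length(loci[[1]])) nchar(loci[[1]][[1]]) else 0L
  }
  structure(list(loci = loci, individual_map = individual_map,
                 locus_length = as.integer(locus_length), truth = truth),
            class = "locus_set")
}

#' @rdname locus_set
#' @param x a `locus_set`.
#' @export
n_loci <- function(x) length(x$loci)

#' @rdname locus_set
#' @export
individuals <- function(x) x$individual_map$individual

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", n_loci(x), "loci,",
      nrow(x$individual_map), "individuals,",
      length(unique(x$individual_map$species)), "species;",
      "nominal locus length", x$locus_length, "bp\n")
  pres <- presence_matrix(x)
  if (length(pres)) cat(sprintf("missing cells: %.1f%%\n", 100 * mean(!pres)))
  invisible(x)
}

#' Presence matrix of a locus set
#'
#' @param x a `locus_set`.
#' @return logical matrix, individuals x loci; TRUE where the individual has
#'   sequence data at the locus.
#' @export
presence_matrix <- function(x) {
  inds <- individuals(x)
  m <- matrix(FALSE, length(inds), n_loci(x),
              dimnames = list(inds, NULL))
  for (j in seq_along(x$loci)) m[names(x$loci[[j]]), j] <- TRUE
  m
}

#' Subset a locus set by locus index
#' @param x a `locus_set`.
#' @param j integer vector of locus indices (may repeat for resampling).
#' @keywords internal
subset_loci <- function(x, j) {
  truth <- x$truth
  if (!is.null(truth)) {
    if (!is.null(truth$gene_trees)) truth$gene_trees <- truth$gene_trees[j]
    if (!is.null(truth$introgressed)) truth$introgressed <- truth$introgressed[j]
  }
  locus_set(x$loci[j], x$individual_map, x$locus_length, truth)
}

# species labels of the individuals, as a named lookup vector
.species_of <- function(x) {
  stats::setNames(x$individual_map$species, x$individual_map$individual)
}

# Concatenate all loci into one matrix of genotype strings per individual,
# filling absent (individual, locus) cells with N.  Returns a named character
# vector of full-length sequences plus the locus boundaries.
#' Concatenate the loci of a locus set
#'
#' Builds the concatenated supermatrix used by distance-based (concatenation)
#' inference; absent cells are filled with `N`.
#'
#' @param x a `locus_set`.
#' @param which optional integer vector of locus indices (default all).
#' @return named character vector of concatenated sequences with attribute
#'   `locus_lengths`.
#' @export
concat_alignment <- function(x, which = seq_len(n_loci(x))) {
  inds <- individuals(x)
  lens <- vapply(x$loci[which], function(sq)
    if (length(sq)) nchar(sq[[1]]) else 0L, integer(1))
  parts <- matrix("", length(inds), length(which), dimnames = list(inds, NULL))
  for (k in seq_along(which)) {
    sq <- x$loci[[which[k]]]
    blank <- strrep("N", lens[k])
    parts[, k] <- blank
    if (length(sq)) parts[names(sq), k] <- sq
  }
  out <- apply(parts, 1L, paste, collapse = "")
  attr(out, "locus_lengths") <- lens
  out
}

# cache of per-individual allele matrices over the concatenation of all loci;
# used by the D-statistic counting code.  site -> locus index map included.
.allele_cache <- function(x) {
  aln <- concat_alignment(x)
  enc <- encode_alleles(aln)
  lens <- attr(aln, "locus_lengths")
  list(a1 = enc$a1, a2 = enc$a2,
       locus_of_site = rep.int(seq_along(lens), lens),
       n_loci = length(lens))
}
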
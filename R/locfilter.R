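#' Locus and individual quality-filter configuration
#'
#' Thresholds mirror the PyRAD-style assembly filters applied to ddRAD loci:
#' loci are discarded when an individual consensus carries too many
#' heterozygous sites (paralog signal), when an individual contributes more
#' than two haplotypes, when a site is heterozygous in too large a fraction
#' of individuals, when too few individuals have data at the locus, and
#' (optionally) when the locus is under-polymorphic or contains
#' insertion-deletion columns; individuals with too much missing data are
#' then dropped.
#'
#' @param max_het_sites_per_consensus discard a locus if any individual's
#'   consensus has more heterozygous sites than this (default 10).
#' @param max_haplotypes_per_individual maximum haplotypes one individual may
#'   contribute at a locus (default 2; on the diploid consensus
#'   representation a violation shows up as a 3- or 4-allele ambiguity code).
#' @param max_site_heterozygosity discard a locus containing a site at which
#'   more than this fraction of with-data individuals are heterozygous
#'   (default 0.75).
#' @param min_individual_fraction_per_locus discard a locus present in fewer
#'   than this fraction of mapped individuals (default 0.50).
#' @param max_missing_per_individual drop an individual whose fraction of
#'   missing loci (over the surviving loci) exceeds this (default 0.80).
#' @param min_polymorphic_sites discard loci with fewer polymorphic sites
#'   (default 0, i.e. off; set 2 for the filtered binning runs).
#' @param drop_indel_loci discard loci containing gap characters (default
#'   FALSE).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(max_het_sites_per_consensus = 10,
                          max_haplotypes_per_individual = 2,
                          max_site_heterozygosity = 0.75,
                          min_individual_fraction_per_locus = 0.50,
                          max_missing_per_individual = 0.80,
                          min_polymorphic_sites = 0,
                          drop_indel_loci = FALSE) {
  cfg <- list(max_het_sites_per_consensus = max_het_sites_per_consensus,
              max_haplotypes_per_individual = max_haplotypes_per_individual,
              max_site_heterozygosity = max_site_heterozygosity,
              min_individual_fraction_per_locus = min_individual_fraction_per_locus,
              max_missing_per_individual = max_missing_per_individual,
              min_polymorphic_sites = min_polymorphic_sites,
              drop_indel_loci = drop_indel_loci)
  fr <- c("max_site_heterozygosity", "min_individual_fraction_per_locus",
          "max_missing_per_individual")
  if (any(unlist(cfg[fr]) < 0) || any(unlist(cfg[fr]) > 1))
    stop("fraction thresholds must lie in [0, 1]")
  if (cfg$max_het_sites_per_consensus < 0 || cfg$min_polymorphic_sites < 0)
    stop("count thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Filter a locus set
#'
#' Applies the quality rules of [filter_config()] sequentially, in a fixed,
#' declared order -- consensus heterozygosity, haplotype count, site
#' heterozygosity, polymorphism/indel, individual fraction per locus, then
#' individual missingness -- each rule seeing only the previous rule's
#' survivors, so per-rule removal counts are disjoint and sum to the total.
#'
#' @param loci a [locus_set()].
#' @param cfg a [filter_config()].
#' @return list with `loci` (the filtered `locus_set`) and `report` (class
#'   `filter_report`: `loci_in`, `loci_out`, per-rule removal counts,
#'   `individuals_removed`).
#' @export
filter_loci <- function(loci, cfg = filter_config()) {
  stopifnot(inherits(loci, "locus_set"), inherits(cfg, "filter_config"))
  keep <- seq_len(n_loci(loci))
  removed <- c(consensus_heterozygosity = 0L, haplotype_count = 0L,
               site_heterozygosity = 0L, polymorphism = 0L, indel = 0L,
               individual_fraction = 0L)
  stats_for <- lapply(loci$loci, .locus_stats)

  drop_rule <- function(keep, fails, rule) {
    removed[rule] <<- removed[rule] + sum(fails)
    keep[!fails]
  }
  keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
    s$max_het_per_ind > cfg$max_het_sites_per_consensus, logical(1)),
    "consensus_heterozygosity")
  keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
    s$max_haplotypes > cfg$max_haplotypes_per_individual, logical(1)),
    "haplotype_count")
  keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
    s$max_site_het > cfg$max_site_heterozygosity, logical(1)),
    "site_heterozygosity")
  if (cfg$min_polymorphic_sites > 0)
    keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
      s$n_polymorphic < cfg$min_polymorphic_sites, logical(1)), "polymorphism")
  if (cfg$drop_indel_loci)
    keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
      s$has_indel, logical(1)), "indel")
  n_ind <- nrow(loci$individual_map)
  keep <- drop_rule(keep, vapply(stats_for[keep], function(s)
    s$n_present / n_ind < cfg$min_individual_fraction_per_locus, logical(1)),
    "individual_fraction")

  out <- subset_loci(loci, keep)
  # individual-missingness rule, computed over the surviving loci
  individuals_removed <- character(0)
  if (n_loci(out) > 0L) {
    pres <- presence_matrix(out)
    miss_frac <- 1 - rowMeans(pres)
    individuals_removed <- names(miss_frac)[miss_frac > cfg$max_missing_per_individual]
    if (length(individuals_removed)) {
      out$loci <- lapply(out$loci, function(sq)
        sq[setdiff(names(sq), individuals_removed)])
      out$individual_map <- out$individual_map[
        !(out$individual_map$individual %in% individuals_removed), , drop = FALSE]
    }
  }
  if (n_loci(out) == 0L) warning("all loci removed by filtering")
  report <- structure(list(loci_in = n_loci(loci), loci_out = n_loci(out),
                           removed = removed,
                           individuals_removed = individuals_removed),
                      class = "filter_report")
  list(loci = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$loci_in, "loci in,", x$loci_out, "out\n")
  for (r in names(x$removed))
    if (x$removed[[r]] > 0) cat("  removed by", r, ":", x$removed[[r]], "\n")
  if (length(x$individuals_removed))
    cat("  individuals removed:", paste(x$individuals_removed, collapse = ", "), "\n")
  invisible(x)
}

# per-locus summary statistics feeding the filter rules
.locus_stats <- function(sq) {
  if (length(sq) == 0L)
    return(list(max_het_per_ind = 0L, max_haplotypes = 0L, max_site_het = 0,
                n_polymorphic = 0L, has_indel = FALSE, n_present = 0L))
  enc <- encode_alleles(sq)
  het <- .is_het_matrix(enc)
  with_data <- enc$a1 > 0L
  n_data <- colSums(with_data)
  site_het <- ifelse(n_data > 0L, colSums(het) / pmax(n_data, 1L), 0)
  # >2-allele ambiguity codes (B, D, H, V) signal >2 haplotypes per individual
  chars <- strsplit(paste(sq, collapse = ""), "", fixed = TRUE)[[1]]
  multi <- any(chars %in% c("B", "D", "H", "V"))
  list(max_het_per_ind = max(rowSums(het)),
       max_haplotypes = if (multi) 3L else 2L,
       max_site_het = max(site_het),
       n_polymorphic = .count_polymorphic_sites(enc),
       has_indel = any(chars == "-"),
       n_present = length(sq))
}

# sites with >1 allele across individuals (alleles pooled from IUPAC pairs)
.count_polymorphic_sites <- function(enc) {
  L <- ncol(enc$a1)
  if (L == 0L) return(0L)
  poly <- logical(L)
  for (b in 1:4) {
    hasb <- colSums(enc$a1 == b | enc$a2 == b) > 0L
    poly <- poly | (hasb & .other_allele_present(enc, b))
  }
  sum(poly)
}

.other_allele_present <- function(enc, b) {
  other <- (enc$a1 > 0L & enc$a1 != b) | (enc$a2 > 0L & enc$a2 != b)
  colSums(other) > 0L
}

#' Extract one unlinked SNP per locus
#'
#' Picks a single biallelic variable site per locus (sites with more than two
#' alleles across individuals are skipped) and returns the genotype matrix
#' with heterozygotes encoded as IUPAC ambiguity codes.
#'
#' @param loci a (typically filtered) [locus_set()].
#' @param picker `"first"` (leftmost biallelic site) or `"random"` (seeded
#'   uniform draw among the locus' biallelic sites).
#' @param seed integer seed (used by `picker = "random"`).
#' @return character matrix (individuals x contributing loci) of genotype
#'   codes, `N` where the individual lacks data; attributes `site` (chosen
#'   1-based site per column), `locus` (source locus index) and
#'   `n_no_variant` (count of loci contributing no column).
#' @export
extract_unlinked_snps <- function(loci, picker = c("first", "random"), seed = 1) {
  picker <- match.arg(picker)
  stopifnot(inherits(loci, "locus_set"))
  set.seed(as.integer(seed))
  inds <- individuals(loci)
  cols <- list(); sites <- integer(0); src <- integer(0)
  n_skip <- 0L
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    enc <- encode_alleles(sq)
    cand <- .biallelic_sites(enc)
    if (length(cand) == 0L) { n_skip <- n_skip + 1L; next }
    s <- if (picker == "first") cand[1] else cand[sample.int(length(cand), 1L)]
    g <- rep("N", length(inds)); names(g) <- inds
    g[names(sq)] <- substring(sq, s, s)
    cols[[length(cols) + 1L]] <- g
    sites <- c(sites, s); src <- c(src, j)
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(0), nrow = length(inds), dimnames = list(inds, NULL))
  attr(m, "site") <- sites
  attr(m, "locus") <- src
  attr(m, "n_no_variant") <- n_skip
  m
}

# sites with exactly two alleles across all individuals
.biallelic_sites <- function(enc) {
  L <- ncol(enc$a1)
  if (L == 0L) return(integer(0))
  nalleles <- integer(L)
  for (b in 1:4)
    nalleles <- nalleles + (colSums(enc$a1 == b | enc$a2 == b) > 0L)
  which(nalleles == 2L)
}
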
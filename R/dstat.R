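#' Define a four-taxon ABBA-BABA hypothesis
#'
#' A quartet test names two putative sister taxa (P1, P2), a candidate
#' introgressor (P3) and an outgroup (O), each with a non-empty, disjoint set
#' of individuals.  A positive D indicates an excess of ABBA sites, i.e.
#' sharing of derived alleles between P2 and P3.
#'
#' @param P1,P2,P3,O character vectors of individual ids.
#' @param labels optional character(4) of taxon display labels.
#' @return object of class `quartet_test`.
#' @export
quartet_test <- function(P1, P2, P3, O, labels = NULL) {
  sets <- list(P1 = P1, P2 = P2, P3 = P3, O = O)
  if (any(lengths(sets) == 0L)) stop("all four taxa need >= 1 individual")
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("taxon individual sets must be disjoint")
  if (is.null(labels)) labels <- vapply(sets, function(s) s[1], character(1))
  structure(list(P1 = P1, P2 = P2, P3 = P3, O = O, labels = labels),
            class = "quartet_test")
}

#' Count ABBA and BABA site patterns for a quartet test
#'
#' Sites are polarized by the outgroup allele (state A).  Only sites that are
#' biallelic across the four taxa and variable within P1-P3 contribute: an
#' ABBA site carries the derived state in P2 and P3, a BABA site in P1 and
#' P3.  In `sampled` mode one allele is drawn per taxon per site (a seeded
#' uniform draw over the taxon's non-missing alleles, which also resolves
#' IUPAC heterozygotes); in `frequency` mode the standard allele-frequency
#' products `(1-p1) p2 p3 (1-p4)` and `p1 (1-p2) p3 (1-p4)` are accumulated,
#' with `p` the derived-allele frequency per taxon.
#'
#' @param loci a [locus_set()].
#' @param test a [quartet_test()].
#' @param mode `"sampled"` or `"frequency"`.
#' @param seed integer seed for the allele draws.
#' @param cache optional precomputed allele cache (internal; built once per
#'   battery).
#' @return object of class `d_counts`: totals `ABBA`, `BABA`, `nloci` (loci
#'   contributing at least one counted site) and the per-locus count vectors
#'   used by the locus bootstrap.
#' @export
count_patterns <- function(loci, test, mode = c("sampled", "frequency"),
                           seed = 1, cache = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "quartet_test"))
  if (is.null(cache)) cache <- .allele_cache(loci)
  known <- rownames(cache$a1)
  for (role in c("P1", "P2", "P3", "O")) {
    bad <- setdiff(test[[role]], known)
    if (length(bad)) stop(role, ": unknown individual(s) ",
                          paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  S <- ncol(cache$a1)
  nl <- cache$n_loci
  if (mode == "sampled") {
    draw <- function(ids) .draw_taxon_alleles(cache, ids)
    p1 <- draw(test$P1); p2 <- draw(test$P2); p3 <- draw(test$P3)
    o <- draw(test$O)
    valid <- p1 > 0L & p2 > 0L & p3 > 0L & o > 0L
    abba <- valid & p1 == o & p2 != o & p3 == p2
    baba <- valid & p2 == o & p1 != o & p3 == p1
    ab_loc <- tabulate(cache$locus_of_site[abba], nbins = nl)
    ba_loc <- tabulate(cache$locus_of_site[baba], nbins = nl)
  } else {
    st <- lapply(list(test$P1, test$P2, test$P3, test$O),
                 function(ids) .stack_taxon(cache, ids))
    anc_der <- .polarize_sites(st)
    pfreq <- lapply(st, function(m) .derived_freq(m, anc_der$derived))
    ok <- anc_der$ok
    for (p in pfreq) ok <- ok & !is.na(p)
    wA <- wB <- numeric(S)
    wA[ok] <- (1 - pfreq[[1]][ok]) * pfreq[[2]][ok] * pfreq[[3]][ok] *
      (1 - pfreq[[4]][ok])
    wB[ok] <- pfreq[[1]][ok] * (1 - pfreq[[2]][ok]) * pfreq[[3]][ok] *
      (1 - pfreq[[4]][ok])
    ab_loc <- .sum_by_locus(wA, cache$locus_of_site, nl)
    ba_loc <- .sum_by_locus(wB, cache$locus_of_site, nl)
  }
  counted <- ab_loc + ba_loc > 0
  structure(list(ABBA = sum(ab_loc), BABA = sum(ba_loc),
                 nloci = sum(counted),
                 abba_by_locus = ab_loc, baba_by_locus = ba_loc,
                 test = test, mode = mode),
            class = "d_counts")
}

# one uniformly drawn non-missing allele per site for a taxon's individuals
.draw_taxon_alleles <- function(cache, ids) {
  rows <- match(ids, rownames(cache$a1))
  m <- rbind(cache$a1[rows, , drop = FALSE], cache$a2[rows, , drop = FALSE])
  S <- ncol(m)
  pr <- matrix(stats::runif(length(m)), nrow = nrow(m))
  pr[m == 0L] <- -1
  best <- max.col(t(pr), ties.method = "first")
  m[best + (seq_len(S) - 1L) * nrow(m)]
}

.stack_taxon <- function(cache, ids) {
  rows <- match(ids, rownames(cache$a1))
  rbind(cache$a1[rows, , drop = FALSE], cache$a2[rows, , drop = FALSE])
}

# ancestral allele = outgroup majority; derived = the single other allele at
# sites biallelic across all four taxa.  ok = usable site.
.polarize_sites <- function(stacks) {
  S <- ncol(stacks[[1]])
  all_m <- do.call(rbind, stacks)
  pres <- matrix(FALSE, 4L, S)
  for (b in 1:4) pres[b, ] <- colSums(all_m == b) > 0L
  biallelic <- colSums(pres) == 2L
  ocnt <- matrix(0L, 4L, S)
  for (b in 1:4) ocnt[b, ] <- colSums(stacks[[4]] == b)
  omax <- apply(ocnt, 2L, max)
  anc <- max.col(t(ocnt), ties.method = "first")
  tie <- colSums(ocnt == rep(omax, each = 4L) & ocnt > 0L) > 1L
  ok <- biallelic & !tie & omax > 0L
  derived <- integer(S)
  for (b in 1:4) {
    sel <- ok & pres[b, ] & anc != b
    derived[sel] <- b
  }
  ok <- ok & derived > 0L
  list(ok = ok, derived = derived)
}

.derived_freq <- function(m, derived) {
  S <- ncol(m)
  dmat <- matrix(derived, nrow = nrow(m), ncol = S, byrow = TRUE)
  nder <- colSums(m == dmat & m > 0L)
  ntot <- colSums(m > 0L)
  ifelse(ntot > 0L, nder / ntot, NA_real_)
}

.sum_by_locus <- function(w, locus_of_site, nl) {
  out <- numeric(nl)
  nz <- w != 0
  if (any(nz)) {
    rs <- rowsum(w[nz], locus_of_site[nz])
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

#' Patterson's D from pattern weights
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; positive values indicate an excess of
#' derived-allele sharing between P2 and P3.
#'
#' @param ABBA,BABA non-negative pattern weights (scalars, or a `d_counts`
#'   object as first argument).
#' @return D in `[-1, 1]`, or `NA` when both weights are zero (no data).
#' @examples
#' compute_D(1623, 381)  # 0.62
#' @export
compute_D <- function(ABBA, BABA = NULL) {
  if (inherits(ABBA, "d_counts")) {
    BABA <- ABBA$BABA
    ABBA <- ABBA$ABBA
  }
  stopifnot(ABBA >= 0, BABA >= 0)
  if (ABBA + BABA == 0) return(NA_real_)
  (ABBA - BABA) / (ABBA + BABA)
}

#' Locus-bootstrap Z-score for a quartet test
#'
#' Resamples loci with replacement `n_boot` times, recomputing D from the
#' per-locus pattern counts each time; `Z = |D_obs| / SD(bootstrap D)` and
#' `p` is the two-sided normal tail probability.
#'
#' @param loci a [locus_set()] (ignored when `counts` is supplied).
#' @param test a [quartet_test()] (ignored when `counts` is supplied).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param mode forwarded to [count_patterns()].
#' @param counts optional precomputed `d_counts` for this test.
#' @param cache optional allele cache (internal).
#' @return list with `D`, `ABBA`, `BABA`, `nloci`, `Z`, `p`, `sd_boot` and
#'   `informative` (FALSE when fewer than 2 loci carry counted sites, in
#'   which case `Z` and `p` are `NA`).  A zero bootstrap SD with nonzero D
#'   yields `Z = Inf`, `p = 0`; with `D = 0` it yields `Z = 0`, `p = 1`.
#' @export
bootstrap_Z <- function(loci = NULL, test = NULL, n_boot = 1000, seed = 1,
                        mode = "sampled", counts = NULL, cache = NULL) {
  if (is.null(counts)) {
    counts <- count_patterns(loci, test, mode = mode, seed = seed,
                             cache = cache)
  }
  D_obs <- compute_D(counts)
  out <- list(D = D_obs, ABBA = counts$ABBA, BABA = counts$BABA,
              nloci = counts$nloci, Z = NA_real_, p = NA_real_,
              sd_boot = NA_real_, informative = FALSE)
  if (counts$nloci < 2L || is.na(D_obs)) return(out)
  nl <- length(counts$abba_by_locus)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  idx <- matrix(sample.int(nl, n_boot * nl, replace = TRUE), nrow = n_boot)
  Ab <- rowSums(matrix(counts$abba_by_locus[idx], nrow = n_boot))
  Bb <- rowSums(matrix(counts$baba_by_locus[idx], nrow = n_boot))
  tot <- Ab + Bb
  Db <- ifelse(tot > 0, (Ab - Bb) / tot, NA_real_)
  s <- stats::sd(Db[!is.na(Db)])
  if (!is.finite(s)) s <- 0
  out$sd_boot <- s
  if (s == 0) {
    if (D_obs == 0) { out$Z <- 0; out$p <- 1 }
    else { out$Z <- Inf; out$p <- 0 }
  } else {
    out$Z <- abs(D_obs) / s
    out$p <- 2 * stats::pnorm(-out$Z)
  }
  out$informative <- TRUE
  out
}

#' All-combination individual permutation for a test battery
#'
#' Forms the Cartesian product of single-individual choices across the four
#' taxa, so one introgression hypothesis yields multiple tests (e.g. taxon
#' sizes 2, 5, 4, 9 yield 360 permuted tests).
#'
#' @param taxa named list with elements `P1`, `P2`, `P3`, `O`, each a
#'   character vector of individual ids.
#' @param cap optional maximum number of tests; when set, a seeded uniform
#'   subsample of the full product is returned.
#' @param seed integer seed (used only when `cap` is set).
#' @return list of [quartet_test()] objects.
#' @export
permute_individuals <- function(taxa, cap = NULL, seed = 1) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(taxa)),
            all(lengths(taxa[c("P1", "P2", "P3", "O")]) >= 1L))
  grid <- expand.grid(P1 = taxa$P1, P2 = taxa$P2, P3 = taxa$P3, O = taxa$O,
                      stringsAsFactors = FALSE)
  if (!is.null(cap) && cap < nrow(grid)) {
    set.seed(as.integer(seed))
    grid <- grid[sort(sample.int(nrow(grid), cap)), , drop = FALSE]
  }
  lapply(seq_len(nrow(grid)), function(i)
    quartet_test(grid$P1[i], grid$P2[i], grid$P3[i], grid$O[i]))
}

#' Holm-Bonferroni sequentially rejective correction
#'
#' Sorts the p-values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure; flags are
#' returned in the input order.  `NA` p-values are excluded from `m`,
#' flagged not-significant, and trigger a warning.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NAs tolerated).
#' @param alpha family-wise error level (default 0.01).
#' @return logical rejection flags, same length and order as `pvalues`.
#' @examples
#' holm_bonferroni(c(0.001, 0.02, 0.03), alpha = 0.01)
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.01) {
  if (length(pvalues) == 0L) return(logical(0))
  ok <- !is.na(pvalues)
  if (any(!ok)) warning(sum(!ok), " NA p-value(s) excluded from the correction")
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0, 1]")
  flags <- logical(length(pvalues))
  m <- sum(ok)
  if (m == 0L) return(flags)
  ord <- order(pvalues)            # NAs sort last
  ord <- ord[seq_len(m)]
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= alpha / (m - i + 1)) flags[ord[i]] <- TRUE
    else break
  }
  flags
}

#' Run a permuted D-statistic battery
#'
#' Permutes individuals across the four taxa, runs pattern counting, D and
#' the locus bootstrap for every permuted test, applies the Holm-Bonferroni
#' correction across the battery (the correction family is the set of
#' permutations of this one hypothesis), and summarises the battery in the
#' standard report row: mean D, mean ABBA/BABA, mean nloci, Z range and
#' nSig/ntest.
#'
#' @param loci a [locus_set()].
#' @param taxa named list `P1`, `P2`, `P3`, `O` of individual-id vectors.
#' @param mode `"sampled"` (default) or `"frequency"`.
#' @param n_boot bootstrap replicates per test (default 1000).
#' @param alpha family-wise error level for Holm-Bonferroni (default 0.01).
#' @param cap optional cap on the number of permuted tests.
#' @param seed master seed.
#' @return list with `summary` (one-row data.frame: `meanD`, `meanABBA`,
#'   `meanBABA`, `mean_nloci`, `minZ`, `maxZ`, `nSig`, `ntest`) and `results`
#'   (per-test data.frame with individuals, D, counts, Z, p, significance).
#'   Uninformative tests (fewer than 2 contributing loci) are excluded from
#'   `nSig`/`ntest` and flagged in `results$informative`.
#' @export
run_battery <- function(loci, taxa, mode = "sampled", n_boot = 1000,
                        alpha = 0.01, cap = NULL, seed = 1) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, 2L)
  tests <- permute_individuals(taxa, cap = cap, seed = seeds[1])
  cache <- .allele_cache(loci)
  set.seed(seeds[2])
  test_seeds <- sample.int(.Machine$integer.max, length(tests))
  rows <- vector("list", length(tests))
  for (i in seq_along(tests)) {
    cnt <- count_patterns(loci, tests[[i]], mode = mode,
                          seed = test_seeds[i], cache = cache)
    bz <- bootstrap_Z(n_boot = n_boot, seed = test_seeds[i], counts = cnt)
    rows[[i]] <- data.frame(
      P1 = tests[[i]]$P1[1], P2 = tests[[i]]$P2[1],
      P3 = tests[[i]]$P3[1], O = tests[[i]]$O[1],
      D = bz$D, ABBA = bz$ABBA, BABA = bz$BABA, nloci = bz$nloci,
      Z = bz$Z, p = bz$p, informative = bz$informative)
  }
  res <- do.call(rbind, rows)
  res$significant <- FALSE
  inf <- which(res$informative)
  if (length(inf))
    res$significant[inf] <- holm_bonferroni(res$p[inf], alpha = alpha)
  summary <- data.frame(
    meanD = mean(res$D[inf]), meanABBA = mean(res$ABBA[inf]),
    meanBABA = mean(res$BABA[inf]), mean_nloci = mean(res$nloci[inf]),
    minZ = if (length(inf)) min(res$Z[inf]) else NA_real_,
    maxZ = if (length(inf)) max(res$Z[inf]) else NA_real_,
    nSig = sum(res$significant), ntest = length(inf))
  if (length(inf) < nrow(res))
    message(nrow(res) - length(inf), " uninformative test(s) excluded from nSig/ntest")
  list(summary = summary, results = res)
}

#' Examine geographic structure in per-individual D and split taxa
#'
#' When the variance of D across a taxon's individuals is elevated,
#' introgression may have affected only some geographic regions.  This
#' aggregates per-test D by the focal taxon's individual, reports per-region
#' mean and variance, flags a split when the between-region variance of the
#' region means exceeds `ratio` times the mean within-region variance, and
#' re-forms the taxon maps along the region map.  The decision to adopt the
#' split remains the user's.
#'
#' @param results per-test data.frame from [run_battery()]`$results`.
#' @param taxa the taxa maps used for the battery.
#' @param region_map named character vector: individual id -> region label,
#'   covering the focal taxon's individuals.
#' @param focal which taxon to split (default `"P2"`, the putatively
#'   introgressed taxon).
#' @param ratio variance-ratio threshold flagging a split (default 2).
#' @return list with `per_individual` (mean D per focal individual),
#'   `per_region` (region, n, meanD, varD), `split_flagged`, and
#'   `taxa_maps` (named list of taxa lists, one per region; identical to
#'   `list(taxa)` when the grouping has a single region).
#' @export
split_by_geography <- function(results, taxa, region_map, focal = "P2",
                               ratio = 2.0) {
  stopifnot(focal %in% c("P1", "P2", "P3", "O"))
  inds <- unique(results[[focal]])
  miss <- setdiff(inds, names(region_map))
  if (length(miss)) stop("region_map missing individual(s): ",
                         paste(miss, collapse = ", "))
  per_ind <- stats::aggregate(D ~ ind, data = data.frame(
    ind = results[[focal]], D = results$D), FUN = mean)
  per_ind$region <- region_map[per_ind$ind]
  regs <- split(per_ind$D, per_ind$region)
  if (any(lengths(regs) == 0L)) stop("region with no individuals")
  per_region <- data.frame(
    region = names(regs), n = lengths(regs),
    meanD = vapply(regs, mean, numeric(1)),
    varD = vapply(regs, function(x) if (length(x) > 1) stats::var(x) else 0,
                  numeric(1)))
  within_var <- mean(per_region$varD)
  between_var <- if (nrow(per_region) > 1) stats::var(per_region$meanD) else 0
  split_flagged <- nrow(per_region) > 1 &&
    between_var > ratio * max(within_var, .Machine$double.eps)
  taxa_maps <- lapply(names(regs), function(r) {
    t2 <- taxa
    t2[[focal]] <- per_ind$ind[per_ind$region == r]
    t2
  })
  names(taxa_maps) <- names(regs)
  list(per_individual = per_ind, per_region = per_region,
       split_flagged = split_flagged,
       between_var = between_var, within_var = within_var,
       taxa_maps = taxa_maps)
}
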
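# Fixture builders and independent brute-force oracles.  The oracles are
# deliberately naive (character-level loops, direct definitions) and share no
# code with the package internals they check.

make_locus_set <- function(seqs_per_locus, species = NULL) {
  ind <- unique(unlist(lapply(seqs_per_locus, names), use.names = FALSE))
  if (is.null(species)) species <- sub("_[^_]*$", "", ind)
  locus_set(seqs_per_locus,
            data.frame(individual = ind, species = species))
}

random_locus_set <- function(n_loci, n_ind, L, p_missing = 0.2,
                             alphabet = c("A", "C", "G", "T", "R", "Y", "N")) {
  ind <- paste0("sp", rep(1:2, length.out = n_ind), "_", seq_len(n_ind))
  loci <- lapply(seq_len(n_loci), function(j) {
    present <- ind[stats::runif(n_ind) >= p_missing]
    if (length(present) == 0L) present <- ind[1]
    sq <- vapply(present, function(i)
      paste(sample(alphabet, L, replace = TRUE,
                   prob = c(8, 8, 8, 8, 1, 1, 1)), collapse = ""),
      character(1))
    stats::setNames(sq, present)
  })
  make_locus_set(loci, species = sub("_.*$", "", ind))
}

# --- ABBA/BABA oracle: per-site enumeration on explicit character alleles ---

IUPAC_ALLELES <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
                      T = c("T", "T"), R = c("A", "G"), Y = c("C", "T"),
                      S = c("C", "G"), W = c("A", "T"), K = c("G", "T"),
                      M = c("A", "C"))

oracle_count_patterns_freq <- function(loci, p1, p2, p3, o) {
  abba <- baba <- 0
  per_locus_counted <- logical(n_loci(loci))
  alleles_of <- function(sq, inds, s) {
    out <- character(0)
    for (i in inds) {
      if (!i %in% names(sq)) next
      g <- substr(sq[[i]], s, s)
      if (g %in% names(IUPAC_ALLELES)) out <- c(out, IUPAC_ALLELES[[g]])
    }
    out
  }
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    if (length(sq) == 0L) next
    L <- nchar(sq[[1]])
    for (s in seq_len(L)) {
      a1 <- alleles_of(sq, p1, s); a2 <- alleles_of(sq, p2, s)
      a3 <- alleles_of(sq, p3, s); ao <- alleles_of(sq, o, s)
      if (!length(a1) || !length(a2) || !length(a3) || !length(ao)) next
      all_a <- unique(c(a1, a2, a3, ao))
      if (length(all_a) != 2L) next
      tab <- table(factor(ao, levels = all_a))
      if (tab[1] == tab[2]) next
      anc <- names(tab)[which.max(tab)]
      der <- setdiff(all_a, anc)
      f <- function(a) mean(a == der)
      wA <- (1 - f(a1)) * f(a2) * f(a3) * (1 - f(ao))
      wB <- f(a1) * (1 - f(a2)) * f(a3) * (1 - f(ao))
      if (wA + wB > 0) per_locus_counted[j] <- TRUE
      abba <- abba + wA
      baba <- baba + wB
    }
  }
  list(ABBA = abba, BABA = baba, nloci = sum(per_locus_counted))
}

# --- Holm oracle via stats::p.adjust -----------------------------------------

oracle_holm <- function(p, alpha) {
  ok <- !is.na(p)
  flags <- logical(length(p))
  flags[ok] <- stats::p.adjust(p[ok], method = "holm") <= alpha
  flags
}

# --- brute-force locus filter (rule-by-rule, character level) ----------------

oracle_filter_survivors <- function(loci, cfg) {
  het_codes <- c("R", "Y", "S", "W", "K", "M")
  multi_codes <- c("B", "D", "H", "V")
  n_ind <- nrow(loci$individual_map)
  keep <- c()
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    chars <- lapply(sq, function(s) strsplit(s, "")[[1]])
    max_het <- if (length(sq)) max(vapply(chars, function(v)
      sum(v %in% het_codes), integer(1))) else 0L
    if (max_het > cfg$max_het_sites_per_consensus) next
    if (any(unlist(chars) %in% multi_codes) &&
        cfg$max_haplotypes_per_individual <= 2) next
    L <- if (length(sq)) nchar(sq[[1]]) else 0L
    site_bad <- FALSE
    for (s in seq_len(L)) {
      col <- vapply(chars, `[`, character(1), s)
      with_data <- col %in% c("A", "C", "G", "T", het_codes)
      if (sum(with_data) > 0 &&
          sum(col %in% het_codes) / sum(with_data) > cfg$max_site_heterozygosity) {
        site_bad <- TRUE; break
      }
    }
    if (site_bad) next
    if (cfg$min_polymorphic_sites > 0) {
      npoly <- 0L
      for (s in seq_len(L)) {
        col <- vapply(chars, `[`, character(1), s)
        alle <- unique(unlist(IUPAC_ALLELES[col[col %in% names(IUPAC_ALLELES)]]))
        if (length(alle) > 1L) npoly <- npoly + 1L
      }
      if (npoly < cfg$min_polymorphic_sites) next
    }
    if (cfg$drop_indel_loci && any(unlist(chars) == "-")) next
    if (length(sq) / n_ind < cfg$min_individual_fraction_per_locus) next
    keep <- c(keep, j)
  }
  keep
}

# --- p-distance oracle (explicit allele-pair mismatch average) ---------------

oracle_p_distance <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  num <- 0; nc <- 0
  for (s in seq_along(c1)) {
    a <- IUPAC_ALLELES[[c1[s]]]; b <- IUPAC_ALLELES[[c2[s]]]
    if (is.null(a) || is.null(b)) next
    nc <- nc + 1
    num <- num + mean(outer(a, b, `!=`))
  }
  if (nc == 0) return(NA_real_)
  num / nc
}

# --- RF oracle: explicit bipartition sets ------------------------------------

oracle_rf <- function(t1, t2) {
  bip <- function(tr) {
    tr <- ape::unroot(tr)
    n <- length(tr$tip.label)
    out <- character(0)
    for (node in unique(tr$edge[tr$edge[, 2] > n, 2])) {
      tips <- ape::extract.clade(tr, node)$tip.label
      if (length(tips) >= 2 && length(tips) <= n - 2) {
        side <- sort(tips)
        other <- sort(setdiff(tr$tip.label, tips))
        key <- paste(c(min(paste(side, collapse = ","),
                           paste(other, collapse = ",")),
                       max(paste(side, collapse = ","),
                           paste(other, collapse = ","))), collapse = "|")
        out <- c(out, key)
      }
    }
    unique(out)
  }
  b1 <- bip(t1); b2 <- bip(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# exact two-locus bootstrap distribution of D by enumerating resamples
oracle_two_locus_boot_sd <- function(ab1, ba1, ab2, ba2) {
  picks <- expand.grid(l1 = 1:2, l2 = 1:2)
  ab <- c(ab1, ab2); ba <- c(ba1, ba2)
  D <- apply(picks, 1, function(r) {
    A <- sum(ab[r]); B <- sum(ba[r])
    if (A + B == 0) NA_real_ else (A - B) / (A + B)
  })
  # population SD over the 4 equiprobable resamples
  sqrt(mean((D - mean(D))^2))
}
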
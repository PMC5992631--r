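# IUPAC nucleotide machinery shared by the simulator, filters, D-statistic
# counting and distance code.  Bases are encoded internally as integers
# A=1, C=2, G=3, T=4; 0 marks "no allele" (missing data 'N'/'?' or the
# alignment gap '-', and the 3/4-allele ambiguity codes B/D/H/V which cannot
# arise from a diploid genotype and are treated as no-calls in computations).

.BASES <- c("A", "C", "G", "T")

# lookup tables indexed by utf8 code point (uppercase handled by caller)
.build_allele_tables <- function() {
  a1 <- integer(127L)
  a2 <- integer(127L)
  set <- function(ch, x, y) {
    i <- utf8ToInt(ch)
    a1[i] <<- x
    a2[i] <<- y
  }
  set("A", 1L, 1L); set("C", 2L, 2L); set("G", 3L, 3L); set("T", 4L, 4L)
  set("R", 1L, 3L); set("Y", 2L, 4L); set("S", 2L, 3L)
  set("W", 1L, 4L); set("K", 3L, 4L); set("M", 1L, 2L)
  # N, ?, -, B, D, H, V all stay (0, 0)
  list(a1 = a1, a2 = a2)
}
.ALLELE_TABLES <- .build_allele_tables()

# genotype code for an unordered allele pair, indexed [a, b] with a,b in 1..4
.build_pair_table <- function() {
  m <- matrix("N", 4L, 4L)
  diag(m) <- .BASES
  pairs <- list(R = c(1, 3), Y = c(2, 4), S = c(2, 3),
                W = c(1, 4), K = c(3, 4), M = c(1, 2))
  for (code in names(pairs)) {
    p <- pairs[[code]]
    m[p[1], p[2]] <- code
    m[p[2], p[1]] <- code
  }
  m
}
.PAIR_TABLE <- .build_pair_table()

.KNOWN_RESIDUES <- c(.BASES, "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N", "?", "-")

#' Encode sequences as allele-pair integer matrices
#'
#' Expands a vector of equal-length IUPAC genotype strings into two integer
#' matrices (rows = sequences, columns = sites) holding the two alleles of
#' each diploid genotype; homozygous sites repeat the allele, missing data
#' and gaps are 0 in both.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return list with integer matrices `a1` and `a2` (dim: length(seqs) x nchar).
#' @keywords internal
encode_alleles <- function(seqs) {
  if (length(seqs) == 0L) {
    return(list(a1 = matrix(integer(), 0L, 0L), a2 = matrix(integer(), 0L, 0L)))
  }
  L <- nchar(seqs[[1]])
  codes <- matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
  bad <- codes < 1L | codes > 127L
  if (any(bad)) codes[bad] <- utf8ToInt("N")
  a1 <- matrix(.ALLELE_TABLES$a1[codes], nrow = L)
  a2 <- matrix(.ALLELE_TABLES$a2[codes], nrow = L)
  a1 <- t(a1); a2 <- t(a2)
  rownames(a1) <- rownames(a2) <- names(seqs)
  list(a1 = a1, a2 = a2)
}

# collapse two haplotype integer matrices (rows = sites) into IUPAC strings
.pair_to_genotype <- function(h1, h2) {
  stopifnot(length(h1) == length(h2))
  out <- character(length(h1))
  ok <- h1 > 0L & h2 > 0L
  out[!ok] <- "N"
  out[ok] <- .PAIR_TABLE[cbind(h1[ok], h2[ok])]
  paste(out, collapse = "")
}

# TRUE where a genotype character is heterozygous (two distinct alleles)
.is_het_matrix <- function(enc) {
  enc$a1 != enc$a2 & enc$a1 > 0L
}

# validate residues of a sequence string; returns position of first unknown, 0 if clean
.first_unknown_residue <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% .KNOWN_RESIDUES))
  if (length(bad)) bad[1] else 0L
}
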
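#' Read and write locus sets
#'
#' Three dialects are supported.  `"loci"` is the PyRAD-style flat format:
#' per locus, one `name<whitespace>sequence` line per individual, blocks
#' terminated by a `//` separator line (trailing match markers after `//`
#' are tolerated and ignored on read); it round-trips a [locus_set()]
#' losslessly.  `"fasta"` writes one FASTA record per (individual, locus)
#' with headers `>individual locus=<j>` (via \pkg{Biostrings} when
#' available), also lossless.  `"phylip"` writes the relaxed sequential
#' Phylip concatenation of all loci with `N` filling absent cells; locus
#' boundaries are not representable in Phylip, so reading it back yields a
#' single-locus set.
#'
#' @param path file path.
#' @param loci a [locus_set()].
#' @param individual_map used on read when the file carries no species
#'   information; defaults to species = individual id up to the last `_`.
#' @param dialect `"loci"`, `"phylip"` or `"fasta"`.
#' @return `read_loci` returns a [locus_set()]; `write_loci` returns `path`
#'   invisibly.
#' @export
write_loci <- function(loci, path, dialect = c("loci", "phylip", "fasta")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         loci = .write_loci_flat(loci, path),
         phylip = .write_phylip(loci, path),
         fasta = .write_fasta(loci, path))
  invisible(path)
}

#' @rdname write_loci
#' @export
read_loci <- function(path, dialect = c("loci", "phylip", "fasta"),
                      individual_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- switch(dialect,
                loci = .read_loci_flat(path),
                phylip = .read_phylip(path),
                fasta = .read_fasta(path))
  if (is.null(individual_map)) {
    ind <- unique(unlist(lapply(raw, names), use.names = FALSE))
    sp <- sub("_[^_]*$", "", ind)
    sp[sp == ""] <- ind[sp == ""]
    individual_map <- data.frame(individual = ind, species = sp)
  }
  .validate_residues(raw)
  locus_set(raw, individual_map)
}

.validate_residues <- function(raw) {
  for (j in seq_along(raw)) {
    for (i in seq_along(raw[[j]])) {
      pos <- .first_unknown_residue(raw[[j]][[i]])
      if (pos > 0L)
        stop("locus ", j, ", individual '", names(raw[[j]])[i],
             "': unknown residue at position ", pos)
    }
  }
}

.write_loci_flat <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    if (length(sq)) {
      w <- max(nchar(names(sq))) + 4L
      writeLines(sprintf("%-*s%s", w, names(sq), sq), con)
    }
    writeLines(sprintf("//%*s|%d|", if (length(sq)) nchar(sq[[1]]) else 0L,
                       "", j), con)
  }
}

.read_loci_flat <- function(path) {
  lines <- readLines(path)
  loci <- list()
  cur_names <- character(0)
  cur_seqs <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "//")) {
      loci[[length(loci) + 1L]] <- stats::setNames(cur_seqs, cur_names)
      cur_names <- character(0)
      cur_seqs <- character(0)
    } else if (nzchar(trimws(ln))) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) stop("malformed .loci line: ", ln)
      cur_names <- c(cur_names, sub("^>", "", parts[1]))
      cur_seqs <- c(cur_seqs, toupper(parts[2]))
    }
  }
  if (length(cur_names))
    loci[[length(loci) + 1L]] <- stats::setNames(cur_seqs, cur_names)
  if (length(loci)) {
    lens <- lapply(loci, function(sq) unique(nchar(sq)))
    bad <- which(lengths(lens) > 1L)
    if (length(bad)) stop("ragged locus at index ", bad[1])
  }
  loci
}

.write_phylip <- function(loci, path) {
  aln <- concat_alignment(loci)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln),
                     if (length(aln)) nchar(aln[[1]]) else 0L), con)
  if (length(aln)) {
    w <- max(nchar(names(aln))) + 2L
    writeLines(sprintf("%-*s%s", w, names(aln), aln), con)
  }
}

.read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed Phylip header")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr[1]) stop("Phylip: expected ", hdr[1], " sequences")
  nm <- character(length(body)); sq <- character(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nm[i] <- parts[1]
    sq[i] <- toupper(paste(parts[-1], collapse = ""))
    if (nchar(sq[i]) != hdr[2])
      stop("Phylip: sequence '", nm[i], "' length ", nchar(sq[i]),
           " != header ", hdr[2])
  }
  keep <- !grepl("^N*$", sq)   # all-missing rows are absent individuals
  list(stats::setNames(sq[keep], nm[keep]))
}

.write_fasta <- function(loci, path) {
  headers <- character(0); seqs <- character(0)
  for (j in seq_len(n_loci(loci))) {
    sq <- loci$loci[[j]]
    headers <- c(headers, sprintf("%s locus=%d", names(sq), j))
    seqs <- c(seqs, unname(sq))
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- headers
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  }
}

.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    headers <- names(x)
    seqs <- toupper(as.character(x))
  } else {
    lines <- readLines(path)
    hidx <- grep("^>", lines)
    headers <- sub("^>", "", lines[hidx])
    bounds <- c(hidx, length(lines) + 1L)
    seqs <- vapply(seq_along(hidx), function(i)
      toupper(paste(lines[(hidx[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")),
      character(1))
  }
  ind <- sub("\\s.*$", "", headers)
  locus <- as.integer(sub(".*locus=([0-9]+).*", "\\1", headers))
  if (anyNA(locus)) stop("FASTA headers must carry 'locus=<j>' tags")
  groups <- split(seq_along(ind), factor(locus, levels = sort(unique(locus))))
  unname(lapply(groups, function(i) stats::setNames(seqs[i], ind[i])))
}

#' Write simulation truth as Newick plus a key-value sidecar
#'
#' @param loci a [locus_set()] with truth.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.  Writes `species_tree.nwk`, `gene_trees.nwk`
#'   and `truth.txt` (flat `key<TAB>value` lines: seed-free model metadata
#'   and per-locus introgression flags).
#' @export
write_truth <- function(loci, dir) {
  if (is.null(loci$truth)) stop("locus_set carries no truth")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- loci$truth
  if (!is.null(tr$model))
    ape::write.tree(tr$model$tree, file.path(dir, "species_tree.nwk"))
  if (!is.null(tr$gene_trees))
    ape::write.tree(do.call(c, lapply(tr$gene_trees, identity)),
                    file.path(dir, "gene_trees.nwk"))
  kv <- c(sprintf("n_loci\t%d", n_loci(loci)),
          sprintf("locus_length\t%d", loci$locus_length),
          if (!is.null(tr$introgressed))
            sprintf("introgressed\t%s",
                    paste(as.integer(tr$introgressed), collapse = ",")))
  writeLines(kv, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Read a sample-to-species/population map
#'
#' Tab-separated file with 2 or 3 columns: individual, species, optional
#' population/region (defaulting to the species).  A header line is detected
#' and skipped when its first field is `individual`.
#'
#' @param path TSV path.
#' @return data.frame with columns `individual`, `species`, `population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(df[1, 1]), "individual")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2L) stop("popmap needs at least 2 columns")
  out <- data.frame(individual = as.character(df[[1]]),
                    species = as.character(df[[2]]))
  out$population <- if (ncol(df) >= 3L) as.character(df[[3]]) else out$species
  if (anyDuplicated(out$individual)) stop("duplicate individual ids in popmap")
  out
}

#' Locus presence/absence report
#'
#' The individual-by-locus presence matrix (rows optionally arranged in a
#' phylogeny's tip order, as in the classic missing-data figure for RAD
#' assemblies) with per-individual missing fractions and their quantiles.
#'
#' @param loci a [locus_set()].
#' @param order optional `phylo`; rows are ordered by its tip order.  Tips
#'   unknown to the locus set are an error.
#' @return list with `matrix` (logical, individuals x loci),
#'   `missing_fraction` (named, per individual) and `quantiles`.
#' @export
missingness_report <- function(loci, order = NULL) {
  m <- presence_matrix(loci)
  if (!is.null(order)) {
    tips <- order$tip.label
    unknown <- setdiff(tips, rownames(m))
    if (length(unknown)) stop("order tree has unknown tips: ",
                              paste(unknown, collapse = ", "))
    m <- m[tips, , drop = FALSE]
  }
  frac <- 1 - rowMeans(m)
  list(matrix = m, missing_fraction = frac,
       quantiles = stats::quantile(frac, c(0, 0.25, 0.5, 0.75, 1)))
}

# default run-configuration values; the thresholds are the pipeline's
# standard operating point (alpha = 0.01, 1000 bootstrap replicates, the
# canonical supergene size grid, and the filter defaults)
.CONFIG_DEFAULTS <- list(
  seed = 1L, alpha = 0.01, n_boot = 1000L,
  k_grid = c(1L, 2L, 3L, 5L, 10L, 20L, 50L, 100L),
  max_het_sites_per_consensus = 10, max_haplotypes_per_individual = 2,
  max_site_heterozygosity = 0.75, min_individual_fraction_per_locus = 0.50,
  max_missing_per_individual = 0.80, min_polymorphic_sites = 0,
  drop_indel_loci = FALSE)

#' Read and validate a flat run configuration
#'
#' Flat `key = value` (or `key: value`) file covering seeds and thresholds;
#' unknown keys are rejected, omitted keys take the package defaults.
#' Comma-separated values become numeric vectors (e.g. `k_grid`).
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return named list of settings, with a ready-made [filter_config()] under
#'   `$filter`.
#' @export
run_config <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]")[[1]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (anyNA(parsed)) parsed <- as.logical(val)
      if (anyNA(parsed)) stop("cannot parse config value for ", key, ": ", val)
      cfg[[key]] <- parsed
    }
  }
  cfg$filter <- filter_config(
    max_het_sites_per_consensus = cfg$max_het_sites_per_consensus,
    max_haplotypes_per_individual = cfg$max_haplotypes_per_individual,
    max_site_heterozygosity = cfg$max_site_heterozygosity,
    min_individual_fraction_per_locus = cfg$min_individual_fraction_per_locus,
    max_missing_per_individual = cfg$max_missing_per_individual,
    min_polymorphic_sites = cfg$min_polymorphic_sites,
    drop_indel_loci = as.logical(cfg$drop_indel_loci))
  cfg
}
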
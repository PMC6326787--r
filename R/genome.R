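#' Load and index a reference genome
#'
#' Reads a (possibly line-wrapped) multi-record FASTA and attaches an
#' organelle label (\code{"nuclear"} or \code{"mitochondrial"}) to every
#' chromosome. Sequences are upper-cased; chromosome order is FASTA order.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param organelle Either a named character vector mapping chromosome name to
#'   organelle label, or a path to a plain-text file of `chrom: label` lines.
#' @return A `genome_index` object: a list with elements `seqs` (a named
#'   [Biostrings::DNAStringSet]), `lengths` (named integer vector) and
#'   `organelle` (named character vector), in FASTA order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrN", "acgtACGT", ">chrM", "GGCC"), fa)
#' g <- load_reference(fa, c(chrN = "nuclear", chrM = "mitochondrial"))
#' chrom_lengths(g)
#' @export
load_reference <- function(fasta_path, organelle) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("reference FASTA contains no sequences: ", fasta_path, call. = FALSE)
  }
  # FASTA headers may carry a description after the first whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome names in FASTA", call. = FALSE)
  }
  org <- if (is.character(organelle) && !is.null(names(organelle))) {
    organelle
  } else {
    read_organelle_map(organelle)
  }
  missing <- setdiff(names(seqs), names(org))
  if (length(missing)) {
    stop("no organelle label for chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(org), c("nuclear", "mitochondrial"))
  if (length(bad)) {
    stop("organelle labels must be 'nuclear' or 'mitochondrial'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  structure(
    list(
      seqs = seqs,
      lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
      organelle = org[names(seqs)]
    ),
    class = "genome_index"
  )
}

# "chrom: label" per line; blank lines and #-comments ignored
read_organelle_map <- function(path) {
  if (!file.exists(path)) {
    stop("organelle map not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("organelle map lines must be 'chrom: label'", call. = FALSE)
  }
  stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                  trimws(vapply(parts, `[`, "", 1L)))
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index with", length(x$seqs), "chromosome(s)\n")
  df <- data.frame(chrom = names(x$seqs), length = unname(x$lengths),
                   organelle = unname(x$organelle))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Chromosome lengths of a genome index
#' @param genome A `genome_index`.
#' @return Named integer vector of chromosome lengths, FASTA order.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  genome$lengths
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Strand-aware single-base access
#'
#' Returns the base at a zero-based offset, read on the requested strand
#' (minus strand returns the complement). Positions outside the chromosome
#' return `NA` rather than erroring, so callers can probe window edges.
#'
#' @param genome A `genome_index`.
#' @param chrom Chromosome name.
#' @param pos Zero-based offset(s); vectorized.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of bases (`A/C/G/T/N`), `NA` where out of range.
#' @export
base_at <- function(genome, chrom, pos, strand = "+") {
  stopifnot(inherits(genome, "genome_index"), strand %in% c("+", "-"))
  if (!chrom %in% names(genome$seqs)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  len <- genome$lengths[[chrom]]
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 0L & pos < len
  if (any(ok)) {
    s <- as.character(genome$seqs[[chrom]])
    bases <- substring(s, pos[ok] + 1L, pos[ok] + 1L)
    if (strand == "-") bases <- unname(COMPLEMENT[bases])
    out[ok] <- bases
  }
  out
}

#' Background base frequencies of an organelle group
#'
#' Proportions of A/C/G/T pooled over both strands of every chromosome
#' carrying the given organelle label. Pooling both strands makes the result
#' complement-symmetric (`freq(A) == freq(T)`, `freq(C) == freq(G)`), which is
#' the natural null for features reported 5'->3' on their own strand. `N`
#' bases are excluded from numerator and denominator.
#'
#' @param genome A `genome_index`.
#' @param organelle `"nuclear"` or `"mitochondrial"`.
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
background_frequencies <- function(genome, organelle) {
  stopifnot(inherits(genome, "genome_index"))
  keep <- names(genome$organelle)[genome$organelle == organelle]
  if (!length(keep)) {
    stop("no chromosome labelled '", organelle, "'", call. = FALSE)
  }
  counts <- Biostrings::alphabetFrequency(genome$seqs[keep], baseOnly = TRUE)
  fwd <- colSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  # reverse strand contributes the complement counts
  both <- fwd + fwd[c("T", "G", "C", "A")]
  names(both) <- c("A", "C", "G", "T")
  if (sum(both) == 0) {
    stop("organelle group '", organelle, "' has no non-N bases", call. = FALSE)
  }
  both / sum(both)
}
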
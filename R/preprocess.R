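#' Read structure of a tagged library
#'
#' Describes the fixed 5' layout of read 1: a random UMI of `umi_length`
#' bases followed by a fixed molecular barcode, then the genomic insert.
#'
#' @param umi_length Non-negative UMI length.
#' @param barcode A/C/G/T barcode string, possibly `""`.
#' @return A `read_structure` list.
#' @export
read_structure <- function(umi_length = 0L, barcode = "") {
  umi_length <- as.integer(umi_length)
  stopifnot(umi_length >= 0L, grepl("^[ACGT]*$", barcode))
  structure(list(umi_length = umi_length, barcode = barcode),
            class = "read_structure")
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path.
#' @return Data frame with columns `name`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(name = names(dss),
             sequence = as.character(dss),
             quality = as.character(S4Vectors::mcols(dss)$qualities),
             row.names = NULL)
}

#' Write a read data frame as FASTQ
#' @param reads Data frame with `name`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$name))
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Barcode-based read retention and trimming
#'
#' A read is retained iff the bases at offsets
#' `[umi_length, umi_length + nchar(barcode))` equal the barcode exactly
#' (zero mismatches). Retained reads have the UMI+barcode prefix removed from
#' sequence and quality; the UMI is returned in a `umi` column. Reads too
#' short to contain the prefix plus at least one genomic base are discarded
#' and counted separately.
#'
#' @param reads Data frame from [read_fastq()].
#' @param structure A [read_structure()].
#' @return Data frame of retained reads (`name`, `sequence`, `quality`,
#'   `umi`), with a `report` attribute listing `retained`, `discarded` and
#'   `too_short` counts.
#' @examples
#' r <- data.frame(name = "r1", sequence = "ACGTTCAGGGT", quality = "IIIIIIIIIII")
#' demultiplex(r, read_structure(4, "TCA"))
#' @export
demultiplex <- function(reads, structure) {
  stopifnot(inherits(structure, "read_structure"))
  u <- structure$umi_length
  b <- nchar(structure$barcode)
  prefix <- u + b
  long_enough <- nchar(reads$sequence) > prefix
  bc_ok <- long_enough &
    substr(reads$sequence, u + 1L, prefix) == structure$barcode
  out <- reads[bc_ok, , drop = FALSE]
  out$umi <- substr(out$sequence, 1L, u)
  out$sequence <- substr(out$sequence, prefix + 1L, nchar(out$sequence))
  out$quality <- substr(out$quality, prefix + 1L, nchar(out$quality))
  rownames(out) <- NULL
  attr(out, "report") <- list(
    input = nrow(reads),
    retained = sum(bc_ok),
    discarded = sum(!bc_ok),
    too_short = sum(!long_enough)
  )
  out
}

#' Move the UMI from the read sequence into the read name
#'
#' Appends `"_<UMI>"` to each read name (a separator that survives
#' alignment) and removes the UMI bases from sequence and quality. UMIs
#' containing `N` are kept verbatim. With `umi_length` 0 this is the
#' identity.
#'
#' @param reads Data frame with `name`, `sequence`, `quality`.
#' @param structure A [read_structure()]; only `umi_length` is used.
#' @return The reads with renamed records and trimmed sequences.
#' @export
extract_umi <- function(reads, structure) {
  stopifnot(inherits(structure, "read_structure"))
  u <- structure$umi_length
  if (u == 0L) return(reads)
  stopifnot(all(nchar(reads$sequence) > u))
  umi <- substr(reads$sequence, 1L, u)
  reads$name <- paste0(reads$name, "_", umi)
  reads$sequence <- substr(reads$sequence, u + 1L, nchar(reads$sequence))
  reads$quality <- substr(reads$quality, u + 1L, nchar(reads$quality))
  reads
}

# zero-based offset of the 5' base: start for plus reads, end-1 for minus
five_prime_pos <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end - 1L)
}

#' Position+UMI de-duplication of aligned reads
#'
#' PCR duplicates align to the same 5' position in the genome and carry the
#' same UMI; identical reads from distinct molecules share the position but
#' differ in UMI and are retained. Groups are keyed on
#' `(chrom, strand, 5' position, exact UMI string)` and one representative —
#' the lexicographically smallest read name — is kept per group.
#'
#' @param alignments Alignment data frame (`chrom`, `start`, `end`,
#'   `strand`, `name`, `umi`).
#' @return De-duplicated alignments with a `report` attribute
#'   (`reads_in`, `reads_out`, `groups`). Warns when every UMI is empty,
#'   since grouping is then positional only.
#' @export
deduplicate <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0L) {
    attr(alignments, "report") <-
      list(reads_in = 0L, reads_out = 0L, groups = 0L)
    return(alignments)
  }
  if (all(alignments$umi == "")) {
    warning("all UMIs are empty; de-duplicating on position alone",
            call. = FALSE)
  }
  key <- paste(alignments$chrom, alignments$strand,
               five_prime_pos(alignments), alignments$umi, sep = "\r")
  ord <- order(key, alignments$name, method = "radix")
  a <- alignments[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(reads_in = n, reads_out = nrow(out),
                              groups = length(unique(key)))
  out
}
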
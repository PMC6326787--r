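#' Read aligned reads into zero-based half-open intervals
#'
#' Accepts SAM, BAM or BED6. SAM/BAM records are read CIGAR-aware via
#' GenomicAlignments (SAM text is converted with [Rsamtools::asBam()] first);
#' unmapped, secondary and supplementary records are dropped, only read 1 of
#' a pair is used (the 5' tagged nucleotide lives on read 1), and records
#' below `mapq_min` are excluded. SAM 1-based positions become zero-based
#' half-open intervals; BED is already in that convention and passes
#' through. The UMI is recovered from the read name by splitting on the
#' final `"_"` (empty when the name has none).
#'
#' @param path SAM/BAM/BED file.
#' @param genome A `genome_index`; every alignment chromosome must exist.
#' @param mapq_min Minimum MAPQ for SAM/BAM records (default 0).
#' @return Alignment data frame (`chrom`, `start`, `end`, `strand`, `name`,
#'   `umi`).
#' @export
alignments_to_intervals <- function(path, genome, mapq_min = 0L) {
  stopifnot(inherits(genome, "genome_index"))
  ext <- tolower(tools::file_ext(path))
  aln <- switch(ext,
    bed = read_bed_alignments(path),
    sam = ,
    bam = read_bam_alignments(path, mapq_min),
    stop("unsupported alignment format '.", ext, "'; expected SAM, BAM or BED",
         call. = FALSE)
  )
  bad <- setdiff(unique(aln$chrom), names(genome$seqs))
  if (length(bad)) {
    stop("alignment chromosome(s) absent from genome: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  aln
}

read_bed_alignments <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"),
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  stopifnot(all(bed$strand %in% c("+", "-")))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, name = bed$name,
             umi = umi_from_name(bed$name))
}

read_bam_alignments <- function(path, mapq_min) {
  if (tolower(tools::file_ext(path)) == "sam") {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ".converted"),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("flag", "mapq"))
  ga <- GenomicAlignments::readGAlignments(path, use.names = TRUE,
                                           param = param)
  mc <- S4Vectors::mcols(ga)
  # bit 0x80: second of pair; single-end reads have it unset
  is_read2 <- bitwAnd(mc$flag, 128L) != 0L
  mapq_ok <- is.na(mc$mapq) | mc$mapq >= mapq_min
  ga <- ga[!is_read2 & mapq_ok]
  nm <- names(ga)
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             name = nm,
             umi = umi_from_name(nm))
}

umi_from_name <- function(name) {
  has <- grepl("_", name, fixed = TRUE)
  ifelse(has, sub("^.*_", "", name), "")
}

#' Calculate rNMP coordinates from aligned read-1 intervals
#'
#' Applies the technique-specific genomic arithmetic that relates the 5'
#' tagged nucleotide of each read to the embedded rNMP, in BED convention
#' (zero-based half-open), per aligned strand:
#'
#' \describe{
#'   \item{ribose-seq}{the rNMP is the reverse complement of the tagged
#'     nucleotide: `+` read at `[s,e)` gives site `(s, s+1, -)`; `-` read
#'     gives `(e-1, e, +)`.}
#'   \item{HydEn-seq / Pu-seq}{the rNMP is one nucleotide upstream of the
#'     tagged nucleotide, same strand: `+` read gives `(s-1, s, +)`; `-`
#'     read gives `(e, e+1, -)`.}
#'   \item{emRiboSeq}{the rNMP is one nucleotide downstream of the reverse
#'     complement of the tagged nucleotide: `+` read gives `(s-1, s, -)`;
#'     `-` read gives `(e, e+1, +)`.}
#' }
#'
#' Coordinates may fall outside the chromosome (end-aligned reads under
#' HydEn-seq/Pu-seq/emRiboSeq); screening is a separate, deliberate step —
#' see [screen_sites()].
#'
#' @param alignments Alignment data frame.
#' @param technique Technique name (case-insensitive).
#' @return Data frame of unscreened sites (`chrom`, `start`, `end`,
#'   `strand`, `name` of the originating read).
#' @examples
#' reads <- data.frame(chrom = "chrI", start = 0L, end = 1L, strand = "+",
#'                     name = "r1", umi = "")
#' calc_site(reads, "emRiboSeq")  # start -1: rejected downstream
#' @export
calc_site <- function(alignments, technique) {
  technique <- parse_technique(technique)
  stopifnot(all(alignments$strand %in% c("+", "-")))
  plus <- alignments$strand == "+"
  s <- alignments$start
  e <- alignments$end
  site <- switch(technique,
    "ribose-seq" = list(start = ifelse(plus, s, e - 1L),
                        strand = ifelse(plus, "-", "+")),
    "HydEn-seq" = ,
    "Pu-seq" = list(start = ifelse(plus, s - 1L, e),
                    strand = ifelse(plus, "+", "-")),
    "emRiboSeq" = list(start = ifelse(plus, s - 1L, e),
                       strand = ifelse(plus, "-", "+"))
  )
  data.frame(chrom = alignments$chrom,
             start = as.integer(site$start),
             end = as.integer(site$start) + 1L,
             strand = site$strand,
             name = alignments$name)
}

#' Screen rNMP coordinates for biological relevance
#'
#' End-aligned reads under the emRiboSeq, HydEn-seq or Pu-seq arithmetic
#' imply rNMP coordinates beyond the chromosome ends (e.g. start -1), which
#' would break downstream analyses. A site is accepted iff
#' `start >= 0` and `end <= chromosome length`; rejected sites are returned
#' for audit (with their originating read names), never written to site
#' output.
#'
#' @param sites Unscreened site data frame from [calc_site()].
#' @param genome A `genome_index`.
#' @return List with `accepted` and `rejected` data frames.
#' @export
screen_sites <- function(sites, genome) {
  stopifnot(inherits(genome, "genome_index"))
  bad <- setdiff(unique(sites$chrom), names(genome$seqs))
  if (length(bad)) {
    stop("site chromosome(s) absent from genome: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  len <- unname(genome$lengths[sites$chrom])
  ok <- sites$start >= 0L & sites$end <= len
  list(accepted = `rownames<-`(sites[ok, , drop = FALSE], NULL),
       rejected = `rownames<-`(sites[!ok, , drop = FALSE], NULL))
}

#' Tabulate per-site rNMP counts
#'
#' Collapses screened single-nucleotide sites to unique
#' `(chrom, start, strand)` rows with a raw multiplicity and a per-hundred
#' normalized count (`raw / library total * 100`), the unit that makes
#' libraries of different depth directly comparable. Rows are sorted by
#' chromosome (genome order when supplied, else first-appearance order),
#' start, then strand.
#'
#' @param sites Screened site data frame.
#' @param genome Optional `genome_index` fixing the chromosome sort order.
#' @return Site table data frame (`chrom`, `start`, `end`, `strand`, `raw`,
#'   `normalized`).
#' @export
count_sites <- function(sites, genome = NULL) {
  if (nrow(sites) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      raw = integer(), normalized = numeric()))
  }
  chrom_levels <- if (!is.null(genome)) names(genome$seqs) else
    unique(sites$chrom)
  key <- paste(sites$chrom, sites$start, sites$strand, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.integer(vapply(parts, `[`, "", 2L)),
                    strand = vapply(parts, `[`, "", 3L),
                    raw = as.integer(agg$Freq))
  out$end <- out$start + 1L
  out <- out[order(match(out$chrom, chrom_levels), out$start, out$strand), ]
  out$normalized <- out$raw / sum(out$raw) * 100
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "strand", "raw", "normalized")]
}

#' Map aligned reads to a screened rNMP site table
#'
#' Convenience wrapper chaining [deduplicate()] (optional),
#' [calc_site()], [screen_sites()] and [count_sites()].
#'
#' @param alignments Alignment data frame.
#' @param technique Technique name.
#' @param genome A `genome_index`.
#' @param dedup De-duplicate on position+UMI first (default `TRUE`).
#' @return List with `sites` (site table), `rejected` (audit data frame)
#'   and `dedup_report`.
#' @export
map_coordinates <- function(alignments, technique, genome, dedup = TRUE) {
  dedup_report <- NULL
  if (dedup) {
    alignments <- deduplicate(alignments)
    dedup_report <- attr(alignments, "report")
  }
  screened <- screen_sites(calc_site(alignments, technique), genome)
  list(sites = count_sites(screened$accepted, genome),
       rejected = screened$rejected,
       dedup_report = dedup_report)
}

#' Write a site table as BED6
#'
#' One line per unique site: `chrom start end . raw_count strand`,
#' tab-separated, LF endings.
#'
#' @param site_table From [count_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(site_table, path) {
  bed <- data.frame(site_table$chrom, site_table$start, site_table$end,
                    ".", site_table$raw, site_table$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a site table as TSV with raw and normalized counts
#' @param site_table From [count_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(site_table, path) {
  utils::write.table(site_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a site table written by [write_site_tsv()]
#' @param path TSV path.
#' @return Site table data frame.
#' @export
read_site_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "numeric"))
}
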
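#' Simulation specification
#'
#' Bundles the parameters that define a simulated rNMP sequencing library:
#' which technique's tagging geometry to invert, the read length, the 5'
#' read structure (UMI then barcode), and the PCR duplication rate.
#'
#' @param technique One of `"ribose-seq"`, `"HydEn-seq"`, `"Pu-seq"`,
#'   `"emRiboSeq"` (case-insensitive).
#' @param read_length Read length in bases (genomic part, excluding UMI and
#'   barcode), >= 1.
#' @param barcode Fixed 5' molecular barcode (A/C/G/T string, may be `""`).
#' @param umi_length Length of the random UMI prefix, >= 0.
#' @param duplication_rate Probability that a molecule gains one extra PCR
#'   copy (same UMI, same position), in [0, 1].
#' @param seed Integer seed controlling UMI draws and duplication.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(technique, read_length = 50L, barcode = "",
                     umi_length = 0L, duplication_rate = 0,
                     seed = 1L) {
  technique <- parse_technique(technique)
  read_length <- as.integer(read_length)
  umi_length <- as.integer(umi_length)
  stopifnot(
    read_length >= 1L,
    umi_length >= 0L,
    duplication_rate >= 0, duplication_rate <= 1,
    grepl("^[ACGT]*$", barcode)
  )
  structure(
    list(technique = technique, read_length = read_length, barcode = barcode,
         umi_length = umi_length, duplication_rate = duplication_rate,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Generate a random reference genome
#'
#' Draws i.i.d. bases per chromosome at the requested GC fraction
#' (`P(G) = P(C) = gc/2`). Reproducible for a fixed seed.
#'
#' @param chrom_specs Data frame with columns `name`, `length`, `organelle`
#'   and optionally `gc` (default 0.5).
#' @param seed Integer seed.
#' @param fasta_path Optional path; when given the genome is also written as
#'   FASTA (60-column wrapped).
#' @return A `genome_index`.
#' @examples
#' g <- generate_reference(
#'   data.frame(name = "chrN", length = 1000, organelle = "nuclear"),
#'   seed = 7)
#' chrom_lengths(g)
#' @export
generate_reference <- function(chrom_specs, seed = 1L, fasta_path = NULL) {
  stopifnot(is.data.frame(chrom_specs),
            all(c("name", "length", "organelle") %in% names(chrom_specs)))
  if (anyDuplicated(chrom_specs$name)) {
    stop("duplicate chromosome names", call. = FALSE)
  }
  stopifnot(all(chrom_specs$length >= 1))
  gc <- if ("gc" %in% names(chrom_specs)) chrom_specs$gc else
    rep(0.5, nrow(chrom_specs))
  stopifnot(all(gc >= 0 & gc <= 1))
  local_seed(seed)
  seqs <- vapply(seq_len(nrow(chrom_specs)), function(i) {
    p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2,
           T = (1 - gc[i]) / 2)
    paste(sample(names(p), chrom_specs$length[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, chrom_specs$name))
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(dss, fasta_path, width = 60L)
  }
  structure(
    list(seqs = dss,
         lengths = stats::setNames(Biostrings::width(dss), chrom_specs$name),
         organelle = stats::setNames(as.character(chrom_specs$organelle),
                                     chrom_specs$name)),
    class = "genome_index"
  )
}

#' Plant rNMP truth sites in a genome
#'
#' Samples single-nucleotide (chrom, pos, strand) sites without replacement.
#' Each site's base is the reference base read 5'->3' on the site's own
#' strand, with T reported as U (the embedded nucleotide is a ribonucleotide).
#' An optional identity bias re-weights sampling toward particular rNMP types
#' (e.g. the rCMP enrichment seen in real libraries).
#'
#' @param genome A `genome_index`.
#' @param n Number of sites to plant.
#' @param seed Integer seed.
#' @param base_bias Optional named weights over `c("A","C","G","U")`; sites
#'   are drawn with probability proportional to the weight of their base.
#' @return Data frame `chrom`, `pos` (zero-based), `strand`, `base`.
#' @export
plant_rnmps <- function(genome, n, seed = 1L, base_bias = NULL) {
  stopifnot(inherits(genome, "genome_index"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), base = character()))
  }
  # enumerate the candidate space; intended for desk-scale genomes
  cand <- do.call(rbind, lapply(names(genome$seqs), function(ch) {
    len <- genome$lengths[[ch]]
    data.frame(chrom = ch, pos = rep(0:(len - 1L), 2L),
               strand = rep(c("+", "-"), each = len))
  }))
  base_plus <- unlist(lapply(names(genome$seqs), function(ch) {
    strsplit(as.character(genome$seqs[[ch]]), "")[[1]]
  }), use.names = FALSE)
  # base on the site's own strand
  cand$base <- ifelse(cand$strand == "+",
                      base_plus[match_pos(cand, genome)],
                      unname(COMPLEMENT[base_plus[match_pos(cand, genome)]]))
  cand <- cand[cand$base != "N", , drop = FALSE]
  cand$base[cand$base == "T"] <- "U"
  w <- rep(1, nrow(cand))
  if (!is.null(base_bias)) {
    stopifnot(all(names(base_bias) %in% c("A", "C", "G", "U")))
    w <- rep(0, nrow(cand))
    for (b in names(base_bias)) w[cand$base == b] <- base_bias[[b]]
    cand <- cand[w > 0, , drop = FALSE]
    w <- w[w > 0]
  }
  if (n > nrow(cand)) {
    stop("requested ", n, " sites but only ", nrow(cand),
         " candidate positions available", call. = FALSE)
  }
  local_seed(seed)
  idx <- sample.int(nrow(cand), n, replace = FALSE, prob = w)
  out <- cand[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# linear index of (chrom, pos) into the concatenated plus-strand sequence
match_pos <- function(df, genome) {
  offs <- c(0L, cumsum(as.integer(genome$lengths)))
  names(offs) <- c(names(genome$seqs), "")
  offs[df$chrom] + df$pos + 1L
}

# Read placement that each technique's chemistry implies for a truth site at
# zero-based pos p (read length L), i.e. the inverse of the coordinate
# arithmetic in calc_site():
#   ribose-seq:       + site -> minus read [p+1-L, p+1);  - site -> plus read [p, p+L)
#   HydEn-seq/Pu-seq: + site -> plus read  [p+1, p+1+L);  - site -> minus read [p-L, p)
#   emRiboSeq:        + site -> minus read [p-L, p);      - site -> plus read [p+1, p+1+L)
read_placement <- function(pos, strand, technique, L) {
  plus_site <- strand == "+"
  switch(technique,
    "ribose-seq" = list(
      start = ifelse(plus_site, pos + 1L - L, pos),
      strand = ifelse(plus_site, "-", "+")),
    "HydEn-seq" = ,
    "Pu-seq" = list(
      start = ifelse(plus_site, pos + 1L, pos - L),
      strand = ifelse(plus_site, "+", "-")),
    "emRiboSeq" = list(
      start = ifelse(plus_site, pos - L, pos + 1L),
      strand = ifelse(plus_site, "-", "+"))
  )
}

#' Simulate aligned reads from planted rNMP sites
#'
#' Places one error-free read-1 alignment per truth site according to the
#' technique's tagging geometry, assigns a random UMI per molecule, and adds
#' PCR duplicates (same interval, same UMI) at the spec's duplication rate.
#' Sites whose implied read would overhang a chromosome end are skipped and
#' reported in the `skipped` attribute, so the effective truth set is
#' `attr(result, "truth")`.
#'
#' @param truth Data frame from [plant_rnmps()].
#' @param spec A [sim_spec()].
#' @param genome A `genome_index`.
#' @return Data frame of alignments (`chrom`, `start`, `end`, `strand`,
#'   `name`, `umi`), with attributes `truth` (sites actually simulated) and
#'   `skipped` (sites dropped at chromosome ends).
#' @export
simulate_alignments <- function(truth, spec, genome) {
  stopifnot(inherits(spec, "sim_spec"), inherits(genome, "genome_index"))
  L <- spec$read_length
  if (nrow(truth) == 0L) {
    out <- empty_alignments()
    attr(out, "truth") <- truth
    attr(out, "skipped") <- truth
    return(out)
  }
  pl <- read_placement(truth$pos, truth$strand, spec$technique, L)
  start <- as.integer(pl$start)
  end <- start + L
  fits <- start >= 0L & end <= unname(genome$lengths[truth$chrom])
  skipped <- truth[!fits, , drop = FALSE]
  kept <- truth[fits, , drop = FALSE]
  aln <- data.frame(
    chrom = kept$chrom,
    start = start[fits],
    end = end[fits],
    strand = pl$strand[fits],
    name = sprintf("read%06d", seq_len(sum(fits))),
    umi = ""
  )
  local_seed(spec$seed)
  if (spec$umi_length > 0L && nrow(aln) > 0L) {
    aln$umi <- vapply(seq_len(nrow(aln)), function(i) {
      paste(sample(c("A", "C", "G", "T"), spec$umi_length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  if (spec$duplication_rate > 0 && nrow(aln) > 0L) {
    dup <- stats::runif(nrow(aln)) < spec$duplication_rate
    if (any(dup)) {
      extra <- aln[dup, , drop = FALSE]
      extra$name <- paste0(extra$name, ".dup")
      aln <- rbind(aln, extra)
      aln <- aln[order(aln$name), , drop = FALSE]
      rownames(aln) <- NULL
    }
  }
  attr(aln, "truth") <- `rownames<-`(kept, NULL)
  attr(aln, "skipped") <- `rownames<-`(skipped, NULL)
  aln
}

#' End-aligned alignments at chromosome 5'-most ends
#'
#' Constructs reads aligned flush to the 5'-most end of the forward strand
#' (interval `[0, L)`, `+`) and of the reverse strand (`[len-L, len)`, `-`).
#' Under the emRiboSeq, HydEn-seq or Pu-seq arithmetic such reads imply rNMP
#' coordinates beyond the chromosome ends, which the biological-relevance
#' screen must reject; they model contamination or chemistry inefficiency,
#' not planted sites.
#'
#' @param genome A `genome_index`.
#' @param read_length Read length.
#' @param chroms Length-2 character vector: chromosome for the forward-strand
#'   end read, then for the reverse-strand end read.
#' @return Alignment data frame of two reads.
#' @export
simulate_end_reads <- function(genome, read_length,
                               chroms = rep(names(genome$seqs)[1], 2L)) {
  stopifnot(inherits(genome, "genome_index"), length(chroms) == 2L)
  L <- as.integer(read_length)
  len2 <- genome$lengths[[chroms[2]]]
  stopifnot(L <= genome$lengths[[chroms[1]]], L <= len2)
  data.frame(
    chrom = chroms,
    start = c(0L, len2 - L),
    end = c(L, len2),
    strand = c("+", "-"),
    name = c("endread.fwd", "endread.rev"),
    umi = ""
  )
}

empty_alignments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character(), umi = character())
}

#' Serialize simulated alignments as a FASTQ library
#'
#' Each record's sequence is `UMI + barcode + genomic sequence` of the
#' aligned interval read 5'->3' on the alignment strand, with constant
#' quality `"I"` (Phred+33). Duplicate alignments in the input are emitted
#' verbatim, reproducing PCR duplication at the FASTQ level. Optionally also
#' writes the truth sites as BED6.
#'
#' @param alignments Alignment data frame from [simulate_alignments()].
#' @param spec A [sim_spec()]; supplies barcode and UMI length.
#' @param genome A `genome_index`.
#' @param fastq_path Output FASTQ path.
#' @param truth Optional truth data frame; written as BED6 when
#'   `truth_path` is given (name ".", score 1).
#' @param truth_path Optional truth BED path.
#' @return `fastq_path`, invisibly.
#' @export
emit_fastq <- function(alignments, spec, genome, fastq_path,
                       truth = NULL, truth_path = NULL) {
  stopifnot(inherits(spec, "sim_spec"), inherits(genome, "genome_index"))
  n <- nrow(alignments)
  seqs <- character(n)
  for (i in seq_len(n)) {
    g <- Biostrings::subseq(genome$seqs[[alignments$chrom[i]]],
                            alignments$start[i] + 1L, alignments$end[i])
    if (alignments$strand[i] == "-") g <- Biostrings::reverseComplement(g)
    seqs[i] <- paste0(alignments$umi[i], spec$barcode, as.character(g))
  }
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, alignments$name))
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dss, fastq_path, format = "fastq",
                              qualities = quals)
  if (!is.null(truth) && !is.null(truth_path)) {
    bed <- data.frame(chrom = truth$chrom, start = truth$pos,
                      end = truth$pos + 1L, name = ".", score = 1L,
                      strand = truth$strand)
    utils::write.table(bed, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(fastq_path)
}
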
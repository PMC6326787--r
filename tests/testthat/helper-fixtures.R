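# Shared fixture builders: tiny genomes from literal sequences, and SAM
# writing for ingestion tests. All fixtures are built in code at test time.

make_genome <- function(seqs, organelle = NULL) {
  if (is.null(organelle)) {
    organelle <- stats::setNames(rep("nuclear", length(seqs)), names(seqs))
  }
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             fa)
  load_reference(fa, organelle)
}

# minimal single-end SAM; records = list of c(qname, flag, rname, pos, mapq, cigar, seq)
write_sam <- function(records, chrom_lengths) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- vapply(records, function(r) {
    paste(r[1], r[2], r[3], r[4], r[5], r[6], "*", 0, 0, r[7],
          strrep("I", nchar(r[7])), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

ALL_TECHNIQUES <- c("ribose-seq", "HydEn-seq", "Pu-seq", "emRiboSeq")

site_key <- function(df, pos_col = "pos") {
  paste(df$chrom, df[[pos_col]], df$strand)
}
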
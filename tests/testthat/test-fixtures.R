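test_that("generate_reference is reproducible and respects GC requests", {
  specs <- data.frame(name = "chrN", length = 20000, organelle = "nuclear",
                      gc = 0.4)
  g1 <- generate_reference(specs, seed = 7)
  g2 <- generate_reference(specs, seed = 7)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  expect_false(identical(as.character(generate_reference(specs, seed = 8)$seqs),
                         as.character(g1$seqs)))

  gc_of <- function(g) {
    f <- Biostrings::alphabetFrequency(g$seqs[[1]], baseOnly = TRUE)
    (f[["C"]] + f[["G"]]) / sum(f[c("A", "C", "G", "T")])
  }
  pure <- generate_reference(data.frame(name = "c", length = 500,
                                        organelle = "nuclear", gc = 1),
                             seed = 1)
  expect_equal(gc_of(pure), 1)
  half <- generate_reference(data.frame(name = "c", length = 50000,
                                        organelle = "nuclear", gc = 0.5),
                             seed = 3)
  expect_gte(gc_of(half), 0.47)
  expect_lte(gc_of(half), 0.53)
  expect_error(generate_reference(data.frame(name = c("a", "a"),
                                             length = c(10, 10),
                                             organelle = "nuclear"),
                                  seed = 1),
               "duplicate")
})

test_that("generate_reference writes a FASTA that loads back identically", {
  fa <- tempfile(fileext = ".fa")
  g <- generate_reference(data.frame(name = c("chrI", "chrM"),
                                     length = c(150, 80),
                                     organelle = c("nuclear", "mitochondrial")),
                          seed = 5, fasta_path = fa)
  g2 <- load_reference(fa, g$organelle)
  expect_identical(as.character(g2$seqs), as.character(g$seqs))
})

test_that("plant_rnmps reports bases 5'->3' on the site strand, T as U", {
  g <- make_genome(list(chr = "ACGTACGTAC"))
  truth <- plant_rnmps(g, 10, seed = 2)
  expect_equal(nrow(truth), 10)
  expect_true(all(truth$base %in% c("A", "C", "G", "U")))
  for (i in seq_len(nrow(truth))) {
    ref <- base_at(g, truth$chrom[i], truth$pos[i], truth$strand[i])
    expect_equal(truth$base[i], if (ref == "T") "U" else ref)
  }
  # without replacement: all (chrom,pos,strand) unique
  expect_equal(anyDuplicated(site_key(truth)), 0L)
  expect_equal(nrow(plant_rnmps(g, 0)), 0L)
  expect_error(plant_rnmps(g, 21, seed = 1), "candidate positions")
})

test_that("plant_rnmps base bias constrains sampled identities", {
  g <- generate_reference(data.frame(name = "chr", length = 2000,
                                     organelle = "nuclear"), seed = 9)
  truth <- plant_rnmps(g, 100, seed = 4, base_bias = c(C = 1))
  expect_true(all(truth$base == "C"))
  truth2 <- plant_rnmps(g, 200, seed = 4, base_bias = c(C = 10, U = 1))
  expect_setequal(unique(truth2$base), c("C", "U"))
  expect_gt(sum(truth2$base == "C"), sum(truth2$base == "U"))
})

test_that("simulated read placement matches the technique geometry", {
  # frozen placements for a + strand truth site at zero-based 100, L = 50;
  # each verified below by mapping the read back through calc_site
  g <- generate_reference(data.frame(name = "chrN", length = 500,
                                     organelle = "nuclear"), seed = 1)
  truth <- data.frame(chrom = "chrN", pos = 100L, strand = "+", base = "A")
  frozen <- list(
    "ribose-seq" = c(start = 51L, end = 101L, strand = "-"),
    "HydEn-seq"  = c(start = 101L, end = 151L, strand = "+"),
    "Pu-seq"     = c(start = 101L, end = 151L, strand = "+"),
    "emRiboSeq"  = c(start = 50L, end = 100L, strand = "-")
  )
  for (tech in ALL_TECHNIQUES) {
    aln <- simulate_alignments(truth, sim_spec(tech, read_length = 50), g)
    expect_equal(aln$start, as.integer(frozen[[tech]][["start"]]), info = tech)
    expect_equal(aln$end, as.integer(frozen[[tech]][["end"]]), info = tech)
    expect_equal(aln$strand, frozen[[tech]][["strand"]], info = tech)
    back <- calc_site(aln, tech)
    expect_equal(back$start, 100L, info = tech)
    expect_equal(back$strand, "+", info = tech)
  }
})

test_that("sites whose read would overhang a chromosome end are skipped", {
  g <- generate_reference(data.frame(name = "chrN", length = 200,
                                     organelle = "nuclear"), seed = 1)
  # HydEn-seq reads run downstream of a + site: pos 180 + L 50 overhangs
  truth <- data.frame(chrom = "chrN", pos = c(50L, 180L),
                      strand = "+", base = "A")
  aln <- simulate_alignments(truth, sim_spec("HydEn-seq", read_length = 50), g)
  expect_equal(nrow(aln), 1L)
  expect_equal(attr(aln, "truth")$pos, 50L)
  expect_equal(attr(aln, "skipped")$pos, 180L)
})

test_that("round trip recovers the planted site set for every technique", {
  g <- generate_reference(data.frame(name = c("chrI", "chrM"),
                                     length = c(30000, 10000),
                                     organelle = c("nuclear", "mitochondrial")),
                          seed = 13)
  truth <- plant_rnmps(g, 300, seed = 17)
  for (tech in ALL_TECHNIQUES) {
    aln <- simulate_alignments(truth, sim_spec(tech, read_length = 40), g)
    res <- map_coordinates(aln, tech, g, dedup = FALSE)
    expect_setequal(site_key(res$sites, "start"),
                    site_key(attr(aln, "truth")))
    expect_equal(nrow(res$rejected), 0L, info = tech)
  }
})

test_that("emit_fastq writes UMI + barcode + oriented genomic sequence", {
  g <- make_genome(list(chr = "AACCGGTTAACCGGTT"))
  aln <- data.frame(chrom = "chr", start = c(2L, 2L), end = c(6L, 6L),
                    strand = c("+", "-"), name = c("p", "m"),
                    umi = c("ACGT", "TTTT"))
  spec <- sim_spec("emRiboSeq", read_length = 4, barcode = "GAT",
                   umi_length = 4)
  fq <- tempfile(fileext = ".fastq")
  emit_fastq(aln, spec, g, fq)
  reads <- read_fastq(fq)
  expect_equal(reads$sequence[reads$name == "p"], "ACGTGATCCGG")
  # minus strand: reverse complement of CCGG
  expect_equal(reads$sequence[reads$name == "m"], "TTTTGATCCGG")
  expect_true(all(reads$quality == strrep("I", 11)))
})

test_that("bare reads and deterministic FASTQ emission", {
  g <- generate_reference(data.frame(name = "chr", length = 300,
                                     organelle = "nuclear"), seed = 2)
  truth <- plant_rnmps(g, 20, seed = 3)
  spec <- sim_spec("ribose-seq", read_length = 30)
  aln <- simulate_alignments(truth, spec, g)
  f1 <- tempfile(); f2 <- tempfile()
  emit_fastq(aln, spec, g, f1)
  emit_fastq(aln, spec, g, f2)
  expect_identical(readLines(f1), readLines(f2))
  reads <- read_fastq(f1)
  # umi_length 0 and empty barcode: the bare genomic sequence
  i <- match(aln$name[1], reads$name)
  seq_fwd <- substr(as.character(g$seqs[[1]]), aln$start[1] + 1, aln$end[1])
  want <- if (aln$strand[1] == "+") seq_fwd else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  expect_equal(reads$sequence[i], want)
})

test_that("duplication_rate 1 doubles records without inventing UMIs", {
  g <- generate_reference(data.frame(name = "chr", length = 2000,
                                     organelle = "nuclear"), seed = 2)
  truth <- plant_rnmps(g, 50, seed = 3)
  spec <- sim_spec("HydEn-seq", read_length = 30, umi_length = 8,
                   duplication_rate = 1)
  aln <- simulate_alignments(truth, spec, g)
  n <- nrow(attr(aln, "truth"))  # planted minus any end-skipped sites
  expect_equal(nrow(aln), 2L * n)
  expect_equal(length(unique(aln$umi)), n)
  fq <- tempfile()
  emit_fastq(aln, spec, g, fq)
  expect_equal(nrow(read_fastq(fq)), 2L * n)
})

test_that("truth BED is valid BED6 with one line per planted site", {
  g <- generate_reference(data.frame(name = "chr", length = 500,
                                     organelle = "nuclear"), seed = 2)
  truth <- plant_rnmps(g, 15, seed = 5)
  spec <- sim_spec("emRiboSeq", read_length = 20)
  aln <- simulate_alignments(truth, spec, g)
  tb <- tempfile(fileext = ".bed")
  emit_fastq(aln, spec, g, tempfile(), truth = attr(aln, "truth"),
             truth_path = tb)
  bed <- read.table(tb, sep = "\t")
  expect_equal(nrow(bed), nrow(attr(aln, "truth")))
  expect_true(all(bed$V3 == bed$V2 + 1))
  expect_true(all(bed$V6 %in% c("+", "-")))
})
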
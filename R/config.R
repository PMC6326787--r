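# Recognized config keys, their defaults (NULL = required per stage), and
# coercions. Flat "key: value" text; organelle labels live in a separate
# two-column file referenced by `organelle_map`.
CONFIG_KEYS <- list(
  technique = NULL,
  sample = "sample",
  reference = NULL,
  organelle_map = NULL,
  input = NULL,
  output_dir = NULL,
  barcode = "",
  umi_length = 0L,
  min_mapq = 0L,
  read_length = 50L,
  window_widths = c(100L, 15L),
  normalization = "library",
  n_sites = 1000L,
  duplication_rate = 0,
  gc = 0.5,
  chrom_lengths = 100000L,
  seed = 1L
)

#' Parse a run configuration file
#'
#' Flat `key: value` text (a YAML subset): one key per line, `#` comments,
#' comma-separated lists for multi-valued keys (`window_widths`,
#' `chrom_lengths`). Unknown keys are an error listing them; the technique
#' name is validated and canonicalized. All effective values (defaults
#' included) are retained, so the returned object fully reproduces the run.
#'
#' @param path Config file path.
#' @return A `run_config` list of all effective key values.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hit <- regexpr(":", lines, fixed = TRUE)
  if (any(hit < 0L)) {
    stop("config lines must be 'key: value'; offending line(s): ",
         paste(lines[hit < 0L], collapse = "; "), call. = FALSE)
  }
  keys <- trimws(substr(lines, 1L, hit - 1L))
  vals <- trimws(substr(lines, hit + 1L, nchar(lines)))
  unknown <- setdiff(keys, names(CONFIG_KEYS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  cfg <- CONFIG_KEYS
  for (i in seq_along(keys)) cfg[[keys[i]]] <- vals[i]
  int_keys <- c("umi_length", "min_mapq", "read_length", "seed", "n_sites")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("duplication_rate", "gc")) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in c("window_widths", "chrom_lengths")) {
    if (is.character(cfg[[k]])) {
      cfg[[k]] <- as.integer(trimws(strsplit(cfg[[k]], ",")[[1]]))
    }
  }
  if (!is.null(cfg$technique)) cfg$technique <- parse_technique(cfg$technique)
  if (!cfg$normalization %in% c("library", "chromosome")) {
    stop("normalization must be 'library' or 'chromosome'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

require_keys <- function(cfg, keys, stage) {
  missing <- keys[vapply(keys, function(k) is.null(cfg[[k]]), TRUE)]
  if (length(missing)) {
    stop("stage '", stage, "' requires config key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

require_upstream <- function(path, what, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs ", what, " at ", path,
         "; run the upstream stage first", call. = FALSE)
  }
}

write_manifest <- function(dir, stage, cfg, extra = list()) {
  m <- c(list(stage = stage,
              version = as.character(utils::packageVersion("rnmpmapr")),
              config = unclass(cfg)),
         extra)
  jsonlite::write_json(m, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

load_config_genome <- function(cfg, stage) {
  require_keys(cfg, c("reference", "organelle_map"), stage)
  load_reference(cfg$reference, cfg$organelle_map)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic reference, truth BED, alignment BED
#' and FASTQ), `preprocess` (alias `alignment`: demultiplex + UMI
#' extraction of a FASTQ), `coordinate` (de-duplicate alignments, apply the
#' technique arithmetic, screen, write site BED/TSV and rejection log),
#' `sequence` (context profiles per organelle, filter and window width) and
#' `distribution` (coverage BedGraphs and plots). Each stage writes its
#' outputs plus a JSON manifest (parameters, input/output counts, version)
#' into `output_dir`, and stages chain through files, so any stage can be
#' re-run in isolation.
#'
#' @param stage Stage name (see above).
#' @param config A `run_config` from [parse_config()], or a path to one.
#' @return Named list of output paths, invisibly.
#' @export
run_stage <- function(stage, config) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage, c("simulate", "preprocess", "alignment",
                              "coordinate", "sequence", "distribution"))
  if (stage == "alignment") stage <- "preprocess"
  require_keys(config, c("technique", "output_dir"), stage)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(config),
         preprocess = stage_preprocess(config),
         coordinate = stage_coordinate(config),
         sequence = stage_sequence(config),
         distribution = stage_distribution(config))
}

stage_simulate <- function(cfg) {
  dir <- cfg$output_dir
  n_chrom <- length(cfg$chrom_lengths)
  specs <- data.frame(
    name = sprintf("chr%s", as.character(utils::as.roman(seq_len(n_chrom)))),
    length = cfg$chrom_lengths,
    organelle = c(rep("nuclear", max(0L, n_chrom - 1L)),
                  if (n_chrom > 1L) "mitochondrial" else "nuclear"),
    gc = cfg$gc)
  fa <- file.path(dir, "reference.fa")
  genome <- generate_reference(specs, seed = cfg$seed, fasta_path = fa)
  org <- file.path(dir, "organelle.txt")
  writeLines(paste0(specs$name, ": ", specs$organelle), org)
  truth <- plant_rnmps(genome, cfg$n_sites, seed = cfg$seed + 1L)
  spec <- sim_spec(cfg$technique, read_length = cfg$read_length,
                   barcode = cfg$barcode, umi_length = cfg$umi_length,
                   duplication_rate = cfg$duplication_rate,
                   seed = cfg$seed + 2L)
  aln <- simulate_alignments(truth, spec, genome)
  bed <- file.path(dir, "alignments.bed")
  nm <- ifelse(aln$umi == "", aln$name, paste0(aln$name, "_", aln$umi))
  utils::write.table(
    data.frame(aln$chrom, aln$start, aln$end, nm, 0L, aln$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    eol = "\n")
  fq <- file.path(dir, "reads.fastq")
  truth_bed <- file.path(dir, "truth.bed")
  emit_fastq(aln, spec, genome, fq, truth = attr(aln, "truth"),
             truth_path = truth_bed)
  write_manifest(dir, "simulate", cfg, list(
    counts = list(planted = nrow(truth),
                  simulated = nrow(attr(aln, "truth")),
                  skipped_at_ends = nrow(attr(aln, "skipped")),
                  alignments = nrow(aln))))
  invisible(list(reference = fa, organelle_map = org, alignments = bed,
                 fastq = fq, truth = truth_bed))
}

stage_preprocess <- function(cfg) {
  dir <- cfg$output_dir
  require_keys(cfg, "input", "preprocess")
  require_upstream(cfg$input, "a FASTQ of raw reads", "preprocess")
  reads <- read_fastq(cfg$input)
  st <- read_structure(cfg$umi_length, cfg$barcode)
  kept <- demultiplex(reads, st)
  rep <- attr(kept, "report")
  # UMI into the name with the alignment-safe "_" separator
  out <- data.frame(name = if (cfg$umi_length > 0L)
                      paste0(kept$name, "_", kept$umi) else kept$name,
                    sequence = kept$sequence, quality = kept$quality)
  fq <- file.path(dir, "preprocessed.fastq")
  write_fastq(out, fq)
  write_manifest(dir, "preprocess", cfg, list(counts = rep))
  invisible(list(fastq = fq))
}

stage_coordinate <- function(cfg) {
  dir <- cfg$output_dir
  input <- if (!is.null(cfg$input)) cfg$input else
    file.path(dir, "alignments.bed")
  require_upstream(input, "aligned reads (SAM/BAM/BED)", "coordinate")
  genome <- load_config_genome(cfg, "coordinate")
  aln <- alignments_to_intervals(input, genome, mapq_min = cfg$min_mapq)
  res <- map_coordinates(aln, cfg$technique, genome,
                         dedup = cfg$umi_length > 0L)
  bed <- file.path(dir, paste0(cfg$sample, ".sites.bed"))
  tsv <- file.path(dir, paste0(cfg$sample, ".counts.tsv"))
  rej <- file.path(dir, paste0(cfg$sample, ".rejected.tsv"))
  write_site_bed(res$sites, bed)
  write_site_tsv(res$sites, tsv)
  utils::write.table(res$rejected, rej, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  write_manifest(dir, "coordinate", cfg, list(
    counts = list(alignments = nrow(aln),
                  deduplicated = if (is.null(res$dedup_report)) nrow(aln)
                                 else res$dedup_report$reads_out,
                  accepted_sites = nrow(res$sites),
                  accepted_reads = sum(res$sites$raw),
                  rejected = nrow(res$rejected))))
  invisible(list(sites_bed = bed, counts_tsv = tsv, rejected_tsv = rej))
}

site_input <- function(cfg, stage) {
  tsv <- if (!is.null(cfg$input) &&
             grepl("counts\\.tsv$", cfg$input)) cfg$input else
    file.path(cfg$output_dir, paste0(cfg$sample, ".counts.tsv"))
  require_upstream(tsv, "a site counts TSV from the coordinate stage", stage)
  read_site_tsv(tsv)
}

stage_sequence <- function(cfg) {
  dir <- cfg$output_dir
  genome <- load_config_genome(cfg, "sequence")
  sites <- site_input(cfg, "sequence")
  outs <- list()
  for (org in unique(unname(genome$organelle))) {
    for (w in cfg$window_widths) {
      for (filt in list(NULL, "A", "C", "G", "U")) {
        fm <- withCallingHandlers(
          profile_context(sites, genome, org, w, rnmp_filter = filt),
          warning = function(w_) invokeRestart("muffleWarning"))
        tag <- paste0(cfg$sample, ".", org, ".w", w, ".",
                      if (is.null(filt)) "all" else paste0("r", filt, "MP"))
        tsv <- file.path(dir, paste0(tag, ".profile.tsv"))
        write_profile_tsv(fm, tsv)
        outs[[tag]] <- tsv
        if (fm$n_sites > 0) {
          png_path <- file.path(dir, paste0(tag, ".profile.png"))
          ggplot2::ggsave(png_path, plot_profile(fm), width = 7, height = 4,
                          dpi = 120)
          outs[[paste0(tag, ".png")]] <- png_path
        }
      }
    }
  }
  write_manifest(dir, "sequence", cfg,
                 list(counts = list(sites = nrow(sites),
                                    profiles = length(outs))))
  invisible(outs)
}

stage_distribution <- function(cfg) {
  dir <- cfg$output_dir
  genome <- load_config_genome(cfg, "distribution")
  sites <- site_input(cfg, "distribution")
  total <- sum(sites$raw)
  outs <- list()
  for (sc in c("+", "-", "both")) {
    tr <- coverage_track(sites, sc, genome)
    tag <- c("+" = "fwd", "-" = "rev", both = "both")[[sc]]
    raw_bg <- file.path(dir, paste0(cfg$sample, ".", tag, ".raw.bedgraph"))
    write_bedgraph(tr, raw_bg)
    outs[[paste0(tag, ".raw")]] <- raw_bg
    if (total > 0) {
      pct <- if (cfg$normalization == "chromosome") {
        normalize_per_chromosome(tr, sites)
      } else {
        normalize_track(tr, total)
      }
      suffix <- if (cfg$normalization == "chromosome")
        ".perchrom.percent.bedgraph" else ".percent.bedgraph"
      pct_bg <- file.path(dir, paste0(cfg$sample, ".", tag, suffix))
      write_bedgraph(pct, pct_bg)
      outs[[paste0(tag, ".percent")]] <- pct_bg
    }
  }
  if (total > 0) {
    png_path <- file.path(dir, paste0(cfg$sample, ".distribution.png"))
    ggplot2::ggsave(png_path, plot_distribution(sites, genome),
                    width = 8, height = 5, dpi = 120)
    outs[["plot"]] <- png_path
  }
  write_manifest(dir, "distribution", cfg,
                 list(counts = list(sites = nrow(sites), reads = total)))
  invisible(outs)
}

# per-chromosome denominators; output labelled as such by the caller
normalize_per_chromosome <- function(track, sites) {
  totals <- tapply(sites$raw, sites$chrom, sum)
  scope <- attr(track, "scope")
  track$value <- track$value / as.numeric(totals[track$chrom]) * 100
  track <- merge_runs(track)
  attr(track, "scope") <- scope
  attr(track, "units") <- "percent"
  track
}
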
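#' Per-nucleotide rNMP coverage track
#'
#' Sums site raw counts per position, restricted to one strand or pooled
#' (`"both"`). Zero-coverage positions are omitted (sparse BedGraph
#' convention) and adjacent equal-valued runs are merged.
#'
#' @param site_table Site table from [count_sites()].
#' @param strand_scope `"+"`, `"-"` or `"both"`.
#' @param genome Optional `genome_index` fixing chromosome order.
#' @return Coverage data frame (`chrom`, `start`, `end`, `value`), sorted
#'   and non-overlapping, with attribute `scope`.
#' @export
coverage_track <- function(site_table, strand_scope = "both", genome = NULL) {
  stopifnot(strand_scope %in% c("+", "-", "both"))
  s <- site_table
  if (strand_scope != "both") {
    s <- s[s$strand == strand_scope, , drop = FALSE]
  }
  if (nrow(s) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
    attr(out, "scope") <- strand_scope
    return(out)
  }
  chrom_levels <- if (!is.null(genome)) names(genome$seqs) else unique(s$chrom)
  agg <- stats::aggregate(raw ~ chrom + start, data = s, FUN = sum)
  out <- data.frame(chrom = agg$chrom, start = agg$start,
                    end = agg$start + 1L, value = as.numeric(agg$raw))
  out <- out[order(match(out$chrom, chrom_levels), out$start), , drop = FALSE]
  out <- merge_runs(out)
  attr(out, "scope") <- strand_scope
  out
}

# merge adjacent intervals on the same chromosome with equal value
merge_runs <- function(track) {
  n <- nrow(track)
  if (n <= 1L) return(`rownames<-`(track, NULL))
  new_run <- c(TRUE, !(track$chrom[-1L] == track$chrom[-n] &
                       track$start[-1L] == track$end[-n] &
                       track$value[-1L] == track$value[-n]))
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = track$chrom[new_run],
    start = track$start[new_run],
    end = tapply(track$end, run, max),
    value = track$value[new_run]
  )
  rownames(out) <- NULL
  out$end <- as.integer(out$end)
  out
}

#' Normalize a coverage track to reads per hundred
#'
#' Divides every value by the whole-library total and multiplies by 100, so
#' tracks from libraries of different read depth are directly comparable.
#' The denominator is the library total (sum of all raw site counts over
#' all chromosomes and both strands), not a per-track sum.
#'
#' @param track Raw coverage data frame from [coverage_track()].
#' @param library_total Total screened, de-duplicated read count (> 0).
#' @return The track with values in percent; attribute `units = "percent"`.
#' @export
normalize_track <- function(track, library_total) {
  if (!is.numeric(library_total) || length(library_total) != 1L ||
      library_total <= 0) {
    stop("library_total must be a positive number", call. = FALSE)
  }
  scope <- attr(track, "scope")
  track$value <- track$value / library_total * 100
  track <- merge_runs(track)
  attr(track, "scope") <- scope
  attr(track, "units") <- "percent"
  track
}

#' Write a coverage track as BedGraph
#'
#' Standard 4-column BedGraph (`chrom start end value`), zero-based
#' half-open, tab-separated, LF endings, no header. Values are printed with
#' at most 6 decimals, trailing zeros trimmed. Adjacent equal-valued runs
#' are merged; unsorted or overlapping input is an invariant breach.
#'
#' @param track Coverage data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- merge_runs(track)
  if (nrow(track) > 1L) {
    same <- track$chrom[-1L] == track$chrom[-nrow(track)]
    if (any(same & track$start[-1L] < track$end[-nrow(track)])) {
      stop("track entries overlap or are unsorted", call. = FALSE)
    }
  }
  value <- sub("\\.?0+$", "", formatC(track$value, format = "f", digits = 6L))
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   value)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Plot per-chromosome rNMP coverage
#'
#' One panel per chromosome, position on x, percent (or raw) coverage on y.
#' With `by_strand = TRUE` the two strands are overlaid as distinct series;
#' the default pools strands.
#'
#' @param site_table Site table from [count_sites()].
#' @param genome A `genome_index` (supplies chromosome order and lengths).
#' @param percent Plot reads per hundred (default) or raw counts.
#' @param by_strand Overlay strands instead of pooling.
#' @return A ggplot object.
#' @export
plot_distribution <- function(site_table, genome, percent = TRUE,
                              by_strand = FALSE) {
  total <- sum(site_table$raw)
  scopes <- if (by_strand) c("+", "-") else "both"
  long <- do.call(rbind, lapply(scopes, function(sc) {
    tr <- coverage_track(site_table, sc, genome)
    if (nrow(tr) == 0L) return(NULL)
    if (percent) tr$value <- tr$value / total * 100
    data.frame(chrom = tr$chrom, pos = tr$start, value = tr$value,
               strand = sc)
  }))
  long$chrom <- factor(long$chrom, levels = names(genome$seqs))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = pos, y = value)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "chromosomal position (bp)",
                  y = if (percent) "coverage (reads per hundred, %)" else
                    "coverage (reads)") +
    ggplot2::theme_minimal()
  if (by_strand) {
    p + ggplot2::geom_segment(
      ggplot2::aes(xend = pos, yend = 0, colour = strand))
  } else {
    p + ggplot2::geom_segment(ggplot2::aes(xend = pos, yend = 0),
                              colour = "steelblue")
  }
}
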
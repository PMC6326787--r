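#' Bases around a site, oriented 5'->3' on the rNMP strand
#'
#' For a `+` strand site at zero-based `pos`, relative position `i` maps to
#' the reference base at `pos + i`; for a `-` strand site it maps to the
#' complement of the base at `pos - i`, so every window reads 5'->3' on the
#' strand carrying the rNMP. Positions beyond the chromosome are `NA`
#' (absent, not zero).
#'
#' @param genome A `genome_index`.
#' @param chrom,pos,strand Site location (zero-based `pos`).
#' @param w Window half-width; the window spans relative positions `-w..w`.
#' @return Character vector of `2w+1` bases named by relative position.
#' @export
oriented_window <- function(genome, chrom, pos, strand, w) {
  offs <- -w:w
  ref_pos <- if (strand == "+") pos + offs else pos - offs
  bases <- base_at(genome, chrom, ref_pos, strand)
  stats::setNames(bases, offs)
}

#' Background-normalized nucleotide frequency profile around rNMP sites
#'
#' For every relative position in `-w..w` (0 = the rNMP itself), computes
#' the frequency of each base over all sites of one organelle, read 5'->3'
#' on each site's own strand, then divides by the organelle's background
#' base frequencies ([background_frequencies()]): a value of 1 means "no
#' different from the genome at large". Sites contribute their raw count by
#' default (each count is one observed incorporation event); set
#' `weight_by_count = FALSE` for unique-site mode. Per-position denominators
#' exclude sites whose window is truncated at a chromosome end and bases
#' called `N`, so truncated flanks are absent rather than zero.
#'
#' @param site_table Site table from [count_sites()] (or any data frame with
#'   `chrom`, `start`, `strand` and optionally `raw`).
#' @param genome A `genome_index`.
#' @param organelle `"nuclear"` or `"mitochondrial"`; sites are restricted
#'   to chromosomes carrying this label.
#' @param w Window half-width (defaults used in practice: 100 zoomed-out,
#'   15 zoomed-in).
#' @param rnmp_filter Optional rNMP identity in `c("A","C","G","U")`; keeps
#'   only sites whose position-0 base (T read as U) matches.
#' @param weight_by_count Weight sites by their raw count (default `TRUE`).
#' @return A `freq_matrix`: list with `positions` (`-w..w`), `raw` and
#'   `normalized` (position x base matrices, columns A/C/G/T), `n`
#'   (per-position effective site totals), `background`, `organelle`,
#'   `rnmp_filter`, `n_sites`. Warns and returns zero-row totals when no
#'   site survives filtering.
#' @export
profile_context <- function(site_table, genome, organelle, w = 15L,
                            rnmp_filter = NULL, weight_by_count = TRUE) {
  stopifnot(inherits(genome, "genome_index"))
  w <- as.integer(w)
  keep_chrom <- names(genome$organelle)[genome$organelle == organelle]
  sites <- site_table[site_table$chrom %in% keep_chrom, , drop = FALSE]
  weight <- if (weight_by_count && "raw" %in% names(sites)) sites$raw else
    rep(1L, nrow(sites))
  if (!is.null(rnmp_filter)) {
    stopifnot(rnmp_filter %in% c("A", "C", "G", "U"))
    base0 <- site_base(sites, genome)
    keep <- !is.na(base0) & base0 == rnmp_filter
    sites <- sites[keep, , drop = FALSE]
    weight <- weight[keep]
  }
  positions <- -w:w
  bases <- c("A", "C", "G", "T")
  raw_counts <- matrix(0, nrow = length(positions), ncol = 4L,
                       dimnames = list(positions, bases))
  totals <- stats::setNames(numeric(length(positions)),
                            as.character(positions))
  if (nrow(sites) == 0L) {
    warning("no sites after filtering (organelle '", organelle,
            "', filter ", if (is.null(rnmp_filter)) "none" else rnmp_filter,
            "); profile is empty", call. = FALSE)
  } else {
    seq_cache <- lapply(genome$seqs[unique(sites$chrom)], function(s) {
      strsplit(as.character(s), "")[[1]]
    })
    for (ch in unique(sites$chrom)) {
      sel <- sites$chrom == ch
      pos <- sites$start[sel]
      strand <- sites$strand[sel]
      wgt <- weight[sel]
      chars <- seq_cache[[ch]]
      len <- length(chars)
      for (k in seq_along(positions)) {
        i <- positions[k]
        ref_pos <- ifelse(strand == "+", pos + i, pos - i)
        ok <- ref_pos >= 0L & ref_pos < len
        if (!any(ok)) next
        b <- chars[ref_pos[ok] + 1L]
        b <- ifelse(strand[ok] == "-", unname(COMPLEMENT[b]), b)
        counted <- b != "N"
        if (!any(counted)) next
        tb <- tapply(wgt[ok][counted], factor(b[counted], levels = bases),
                     sum, default = 0)
        raw_counts[k, ] <- raw_counts[k, ] + tb
        totals[k] <- totals[k] + sum(wgt[ok][counted])
      }
    }
  }
  raw <- raw_counts / ifelse(totals > 0, totals, NA_real_)
  bg <- background_frequencies(genome, organelle)
  normalized <- sweep(raw, 2L, bg[bases], "/")
  structure(
    list(positions = positions, raw = raw, normalized = normalized,
         n = totals, background = bg, organelle = organelle,
         rnmp_filter = rnmp_filter, n_sites = sum(weight)),
    class = "freq_matrix"
  )
}

# position-0 base on the rNMP strand, T reported as U
site_base <- function(sites, genome) {
  vapply(seq_len(nrow(sites)), function(i) {
    b <- base_at(genome, sites$chrom[i], sites$start[i], sites$strand[i])
    if (!is.na(b) && b == "T") "U" else b
  }, character(1))
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("freq_matrix:", x$organelle, "organelle,",
      if (is.null(x$rnmp_filter)) "all rNMPs" else paste0("r", x$rnmp_filter, "MP"),
      "\n  positions", min(x$positions), "..", max(x$positions),
      "; total site weight", x$n_sites, "\n")
  invisible(x)
}

#' Write a frequency profile as TSV
#'
#' Columns: `position`, raw frequencies `A/C/G/U_T` (the rNMP position's T
#' is a rUMP, so the T column is labelled `U_T`), then `*_norm` normalized
#' counterparts, then `n_sites`. Positions with no coverage carry `NA`.
#'
#' @param fm A `freq_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(fm, path) {
  df <- data.frame(position = fm$positions,
                   A = fm$raw[, "A"], C = fm$raw[, "C"], G = fm$raw[, "G"],
                   U_T = fm$raw[, "T"],
                   A_norm = fm$normalized[, "A"],
                   C_norm = fm$normalized[, "C"],
                   G_norm = fm$normalized[, "G"],
                   U_T_norm = fm$normalized[, "T"],
                   n_sites = unname(fm$n))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Plot a background-normalized context profile
#'
#' Line plot of normalized frequency against relative position, one series
#' per base (T shown as T/U since position 0 is the ribonucleotide).
#'
#' @param fm A `freq_matrix`.
#' @return A ggplot object.
#' @export
plot_profile <- function(fm) {
  long <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    data.frame(position = fm$positions, base = ifelse(b == "T", "T/U", b),
               normalized = fm$normalized[, b])
  }))
  long <- long[!is.na(long$normalized), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = position, y = normalized,
                                     colour = base)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = "position relative to rNMP site",
      y = "normalized frequency",
      colour = "base",
      title = paste0(fm$organelle, ", ",
                     if (is.null(fm$rnmp_filter)) "all rNMPs" else
                       paste0("r", fm$rnmp_filter, "MP"))) +
    ggplot2::theme_minimal()
}
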
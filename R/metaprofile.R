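## Average tag-density metaprofiles around transcription start sites.
## Each tag within +/- flank of a TSS contributes at exactly one position:
## its 5' end shifted toward the fragment center by half the fragment
## length (+shift on plus-strand tags, -shift on minus-strand tags). Tags on
## the X/Y chromosomes count twice (single-copy chromosomes in male genomes
## yield half the tags). Raw positional counts are divided by
## total_mapped/1e6 and by the number of genes, then smoothed with a
## centered moving average.

# Centered moving average of width w; the window is truncated at the array
# edges (the mean runs over the positions that exist).
smooth_moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Average tag-density profile around TSSs
#'
#' @param tags BED6-shaped data.frame of aligned tags.
#' @param genes gene annotation data.frame (gene_id, chrom, strand, tss).
#' @param gene_set character vector of gene ids to average over (non-empty;
#'   every id must exist in `genes`).
#' @param total_mapped library size for per-million normalization.
#' @param flank half-width of the profile window in bp.
#' @param shift bp by which each tag's 5' end is shifted toward its fragment
#'   center; conventionally half the fragment length.
#' @param smooth_window width of the centered moving-average smoother in bp
#'   (1 disables smoothing).
#' @param orient `"transcription"` flips minus-strand genes so positive
#'   positions are downstream of transcription; `"genome"` keeps genomic
#'   orientation.
#' @param sex_chrom_weight weight of tags on X/Y chromosomes (default 2).
#' @return a `Metaprofile`: positions `-flank..flank`, smoothed `density`,
#'   unsmoothed `density_raw`, `n_genes`, and `n_reads_total` (the weighted
#'   in-window tag count).
#' @export
tss_profile <- function(tags, genes, gene_set, total_mapped,
                        flank = 2000L, shift = 75L, smooth_window = 100L,
                        orient = c("transcription", "genome"),
                        sex_chrom_weight = 2) {
  orient <- match.arg(orient)
  if (length(gene_set) == 0) fail("gene_set is empty")
  if (total_mapped <= 0) fail("total_mapped must be > 0")
  missing <- setdiff(gene_set, genes$gene_id)
  if (length(missing) > 0)
    fail("gene_set ids absent from annotation: %s",
         paste(utils::head(missing, 5), collapse = ", "))
  gs <- genes[match(gene_set, genes$gene_id), , drop = FALSE]
  width <- 2L * flank + 1L
  counts <- numeric(width)

  # Shifted 5' ends, grouped and sorted per chromosome once.
  p5 <- ifelse(tags$strand == "+", tags$start + shift,
               (tags$end - 1L) - shift)
  by_chrom <- split(p5, tags$chrom)
  by_chrom <- lapply(by_chrom, sort)

  for (i in seq_len(nrow(gs))) {
    pos <- by_chrom[[gs$chrom[i]]]
    if (is.null(pos) || length(pos) == 0) next
    tss <- gs$tss[i]
    lo <- findInterval(tss - flank - 0.5, pos)
    hi <- findInterval(tss + flank + 0.5, pos)
    if (hi <= lo) next
    rel <- pos[(lo + 1L):hi] - tss
    if (orient == "transcription" && gs$strand[i] == "-") rel <- -rel
    w <- if (is_sex_chrom(gs$chrom[i])) sex_chrom_weight else 1
    counts <- counts + w * tabulate(rel + flank + 1L, nbins = width)
  }

  raw <- counts / (total_mapped / 1e6) / nrow(gs)
  structure(list(positions = seq(-flank, flank),
                 density = smooth_moving_average(raw, smooth_window),
                 density_raw = raw,
                 n_genes = nrow(gs),
                 n_reads_total = sum(counts),
                 flank = flank, shift = shift,
                 smooth_window = smooth_window,
                 total_mapped = total_mapped),
            class = "Metaprofile")
}

#' @export
print.Metaprofile <- function(x, ...) {
  cat(sprintf("Metaprofile: %d genes, %.0f weighted in-window tags, peak %.4f at %+d bp\n",
              x$n_genes, x$n_reads_total, max(x$density),
              x$positions[which.max(x$density)]))
  invisible(x)
}

#' @export
plot.Metaprofile <- function(x, ...) {
  graphics::plot(x$positions, x$density, type = "l",
                 xlab = "Position relative to TSS (bp)",
                 ylab = "Tag density (per million mapped, per gene)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Export a metaprofile as a two-column TSV (position, density)
#' @param profile a `Metaprofile`.
#' @param path output path.
#' @export
write_metaprofile <- function(profile, path) {
  utils::write.table(data.frame(position = profile$positions,
                                density = profile$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
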
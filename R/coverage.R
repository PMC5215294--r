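## Fragment-extended, depth-normalized coverage and interval tag counting.
## Tags are extended to the estimated fragment length and each fragment adds
## 1e6 / total_mapped to every bp it covers, yielding FPM units (fragments
## per million mapped tags).

#' Extend tags to fragment length
#'
#' A plus-strand tag `[start, end)` extends to `[start, start + L)`; a
#' minus-strand tag to `[end - L, end)`. Fragments are clipped to
#' `[0, chrom_length)` when a chromosome length is supplied.
#'
#' @param tags BED6-shaped data.frame (needs chrom, start, end, strand).
#' @param fragment_length fragment length L in bp; must be at least the
#'   longest read.
#' @param chrom_length optional chromosome length (single value or named
#'   vector by chromosome) used to clip at the right edge.
#' @return data.frame (chrom, start, end, strand) of fragment intervals, in
#'   input order.
#' @export
extend_tags <- function(tags, fragment_length, chrom_length = NULL) {
  if (nrow(tags) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  read_len <- tags$end - tags$start
  if (any(fragment_length < read_len))
    fail("fragment_length %d shorter than longest read (%d bp)",
         fragment_length, max(read_len))
  fe <- ifelse(tags$strand == "+", tags$start + fragment_length, tags$end)
  fs <- fe - fragment_length
  fs <- pmax(fs, 0L)
  if (!is.null(chrom_length)) {
    lim <- if (length(chrom_length) > 1 || !is.null(names(chrom_length)))
      unname(chrom_length[tags$chrom]) else chrom_length
    fe <- pmin(fe, lim)
  }
  data.frame(chrom = tags$chrom, start = as.integer(fs), end = as.integer(fe),
             strand = tags$strand, stringsAsFactors = FALSE)
}

#' Build depth-normalized coverage tracks
#'
#' Extends every tag to `fragment_length` and accumulates
#' `1e6 / total_mapped` over each covered bp, one track per chromosome.
#'
#' @param tags BED6-shaped data.frame.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param total_mapped library size used for normalization (> 0).
#' @param fragment_length fragment length in bp.
#' @return a named list of `CoverageTrack` objects (fields: chrom, values,
#'   total_mapped, fragment_length).
#' @export
build_coverage <- function(tags, chrom_lengths, total_mapped,
                           fragment_length) {
  if (total_mapped <= 0) fail("total_mapped must be > 0")
  frags <- extend_tags(tags, fragment_length, chrom_lengths)
  w <- 1e6 / total_mapped
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- as.integer(chrom_lengths[[cn]])
    f <- frags[frags$chrom == cn, , drop = FALSE]
    delta <- numeric(L + 1L)
    if (nrow(f) > 0) {
      delta <- w * (tabulate(f$start + 1L, nbins = L + 1L) -
                      tabulate(f$end + 1L, nbins = L + 1L))
    }
    structure(list(chrom = cn, values = cumsum(delta)[seq_len(L)],
                   total_mapped = total_mapped,
                   fragment_length = fragment_length),
              class = "CoverageTrack")
  })
  stats::setNames(out, names(chrom_lengths))
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack %s: %d bp, max %.4f FPM (total_mapped %g, L %d)\n",
              x$chrom, length(x$values), max(x$values), x$total_mapped,
              x$fragment_length))
  invisible(x)
}

# Reference positions of tags under a counting mode:
#  midpoint - midpoint of the extended fragment (default; strand-symmetric),
#  5prime   - the read's 5' end,
#  overlap  - no single position; handled separately.
tag_positions <- function(tags, fragment_length, mode = "midpoint") {
  if (mode == "midpoint") {
    f <- extend_tags(tags, fragment_length)
    fragment_midpoint(f$start, f$end)
  } else if (mode == "5prime") {
    ifelse(tags$strand == "+", tags$start, tags$end - 1L)
  } else {
    fail("unknown count mode '%s'", mode)
  }
}

#' Count tags in a genomic interval
#'
#' Default membership rule: the midpoint of the extended fragment lies in
#' the half-open interval `[start, end)`. Alternatives: the read's 5' end
#' (`"5prime"`), or any overlap of the extended fragment (`"overlap"`).
#'
#' @param tags BED6-shaped data.frame.
#' @param chrom,start,end interval (0-based half-open).
#' @param fragment_length fragment length used for extension.
#' @param mode `"midpoint"` (default), `"5prime"` or `"overlap"`.
#' @return integer raw count.
#' @export
count_tags <- function(tags, chrom, start, end, fragment_length = 150L,
                       mode = c("midpoint", "5prime", "overlap")) {
  mode <- match.arg(mode)
  onchrom <- tags[tags$chrom == chrom, , drop = FALSE]
  if (nrow(onchrom) == 0 || end <= start) return(0L)
  if (mode == "overlap") {
    f <- extend_tags(onchrom, fragment_length)
    return(sum(f$start < end & f$end > start))
  }
  pos <- tag_positions(onchrom, fragment_length, mode)
  sum(pos >= start & pos < end)
}

# Vectorized counting of positions into disjoint sorted regions of a single
# chromosome; returns an integer count per region.
count_positions_in_regions <- function(pos, region_start, region_end) {
  if (length(region_start) == 0) return(integer(0))
  if (length(pos) == 0) return(integer(length(region_start)))
  pos <- sort(pos)
  lo <- findInterval(region_start - 0.5, pos)
  hi <- findInterval(region_end - 0.5, pos)
  as.integer(hi - lo)
}

#' Count tags in many intervals at once
#'
#' @param tags BED6-shaped data.frame.
#' @param regions data.frame with chrom, start, end (intervals may overlap).
#' @param fragment_length fragment length used for extension.
#' @param mode counting mode as in [count_tags()] (`"overlap"` not
#'   supported here).
#' @return integer vector of counts, one per region row.
#' @export
count_tags_in_regions <- function(tags, regions, fragment_length = 150L,
                                  mode = "midpoint") {
  counts <- integer(nrow(regions))
  if (nrow(regions) == 0) return(counts)
  pos_all <- if (nrow(tags) > 0)
    tag_positions(tags, fragment_length, mode) else integer(0)
  for (cn in unique(regions$chrom)) {
    ri <- which(regions$chrom == cn)
    pos <- sort(pos_all[tags$chrom == cn])
    if (length(pos) == 0) next
    lo <- findInterval(regions$start[ri] - 0.5, pos)
    hi <- findInterval(regions$end[ri] - 0.5, pos)
    counts[ri] <- as.integer(hi - lo)
  }
  counts
}
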
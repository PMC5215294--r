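## Island calling and differential testing.
##
## The caller is a fixed-width scanning-window Poisson model: the genome is
## tiled with non-overlapping windows; a window is enriched when its tag
## count beats the genome-wide expectation under a Poisson upper-tail test;
## enriched windows closer than a gap are merged into islands. Differential
## strength between two samples is assessed MAnorm-style: fit M = log2
## fold change against A = mean log2 intensity on islands common to both
## samples by least squares, subtract the fit, and test each island's
## normalized count pair with an exact conditional binomial test.

#' Call islands of tag enrichment
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp
#' (a trailing partial window is ignored), computes the genome-wide expected
#' tags per window `lambda = n_tags / n_windows`, flags windows with Poisson
#' upper-tail probability `P(X >= k)` below `p_threshold`, merges flagged
#' windows separated by at most `gap` bp, and trims each island to its
#' outermost flagged windows. Island counts are raw tag counts over the
#' island span; the island p-value is the Poisson tail of its total count
#' against `lambda` times the number of windows it spans.
#'
#' @param tags BED6-shaped data.frame.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window scanning window width in bp (>= 100).
#' @param gap maximum bp between enriched windows that are merged.
#' @param p_threshold Poisson upper-tail threshold for window eligibility.
#' @param fragment_length fragment length for midpoint counting.
#' @param count_mode tag membership rule, see [count_tags()].
#' @return data.frame (chrom, start, end, count, pvalue), possibly empty.
#' @export
call_islands <- function(tags, chrom_lengths, window = 200L, gap = 400L,
                         p_threshold = 1e-5, fragment_length = 150L,
                         count_mode = "midpoint") {
  if (window < 100) fail("window must be >= 100 bp")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), count = integer(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0) return(empty)
  nwin <- floor(chrom_lengths / window)
  total_windows <- sum(nwin)
  if (total_windows == 0) fail("chromosomes shorter than one window")
  lambda <- nrow(tags) / total_windows

  pos_all <- tag_positions(tags, fragment_length, count_mode)
  out <- list()
  for (cn in names(chrom_lengths)) {
    nw <- nwin[[cn]]
    if (nw == 0) next
    pos <- pos_all[tags$chrom == cn]
    pos <- pos[pos >= 0 & pos < nw * window]
    counts <- tabulate(pos %/% window + 1L, nbins = nw)
    eligible <- which(stats::ppois(counts - 1, lambda,
                                   lower.tail = FALSE) < p_threshold)
    if (length(eligible) == 0) next
    # Merge eligible windows whose inter-window gap is <= gap bp.
    brk <- which((diff(eligible) - 1L) * window > gap)
    grp <- rep(seq_len(length(brk) + 1L),
               times = diff(c(0L, brk, length(eligible))))
    first <- eligible[!duplicated(grp)]
    last <- eligible[!duplicated(grp, fromLast = TRUE)]
    start <- (first - 1L) * window
    end <- last * window
    span <- last - first + 1L
    cnt <- count_positions_in_regions(pos, start, end)
    pv <- stats::ppois(cnt - 1, lambda * span, lower.tail = FALSE)
    out[[cn]] <- data.frame(chrom = cn, start = as.integer(start),
                            end = as.integer(end), count = cnt,
                            pvalue = pmax(pv, .Machine$double.xmin),
                            stringsAsFactors = FALSE)
  }
  res <- rbind_all(out)
  if (is.null(res)) return(empty)
  res <- sort_intervals(res)
  rownames(res) <- NULL
  res
}

islands_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Merge two island sets into a union of regions
#'
#' Overlapping islands (within or across samples) are merged into one
#' region; a region is flagged `common` when it overlaps at least one
#' island from each sample.
#'
#' @param islands_a,islands_b island data.frames from [call_islands()].
#' @return data.frame (chrom, start, end, common).
#' @export
merge_island_sets <- function(islands_a, islands_b) {
  if (nrow(islands_a) + nrow(islands_b) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), common = logical(0),
                      stringsAsFactors = FALSE))
  gr_a <- islands_granges(islands_a)
  gr_b <- islands_granges(islands_b)
  un <- GenomicRanges::reduce(c(gr_a, gr_b))
  common <- GenomicRanges::countOverlaps(un, gr_a) > 0 &
    GenomicRanges::countOverlaps(un, gr_b) > 0
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(un)),
                   start = GenomicRanges::start(un) - 1L,
                   end = GenomicRanges::end(un),
                   common = common, stringsAsFactors = FALSE)
  sort_intervals(df)
}

#' M-A normalization of island counts between two samples
#'
#' Computes `M = log2(count_b / count_a)` and
#' `A = 0.5 * log2(count_a * count_b)` per island (zero counts replaced by a
#' 0.5 pseudocount so M stays finite), fits `M ~ A` by ordinary least
#' squares over the common islands, and subtracts the fit from every
#' island's M -- including sample-unique islands -- to yield `M_adjusted`.
#' Sequencing-depth and intensity-dependent biases common to both samples
#' cancel; after normalization the median M_adjusted of common islands is
#' close to zero.
#'
#' @param count_a,count_b raw counts per region (reference and target).
#' @param common logical: which regions are common islands; at least 10 are
#'   required for a stable fit.
#' @return data.frame (M, A, M_adjusted, M_fitted) with the fit coefficients
#'   in attribute `coefficients`.
#' @export
ma_normalize <- function(count_a, count_b, common) {
  if (sum(common) < 10)
    fail(paste("only %d common islands (need >= 10 for the M-A fit);",
               "simulate deeper libraries or stronger enrichment"),
         sum(common))
  a2 <- ifelse(count_a <= 0, 0.5, count_a)
  b2 <- ifelse(count_b <= 0, 0.5, count_b)
  M <- log2(b2 / a2)
  A <- 0.5 * log2(a2 * b2)
  # The slope of the M ~ A line is only identifiable when the common
  # islands span a reasonable intensity range; with a degenerate spread the
  # extrapolated trend corrupts M_adjusted at sample-unique islands, so the
  # fit falls back to the pure depth offset.
  if (stats::sd(A[common]) >= 0.5) {
    beta <- stats::lm.fit(cbind(1, A[common]), M[common])$coefficients
  } else {
    beta <- c(mean(M[common]), 0)
  }
  fitted <- beta[1] + beta[2] * A
  out <- data.frame(M = M, A = A, M_adjusted = M - fitted,
                    M_fitted = unname(fitted))
  attr(out, "coefficients") <- unname(beta)
  out
}

#' Differential test for a normalized island count pair
#'
#' Exact conditional test: given the total `count_a + count_b`, under the
#' no-difference null the target count is binomial with success probability
#' `2^M_fitted / (1 + 2^M_fitted)` (the M-A fit absorbs the depth
#' imbalance); the two-sided p-value comes from [stats::binom.test()]. An
#' island passes when p < `p_cutoff`, |M_adjusted| exceeds
#' `log2(fold_change)`, and the larger raw count reaches `min_reads`.
#' Direction is `gained` (stronger in the target sample) for positive
#' M_adjusted, `lost` for negative; non-passing islands are `unchanged`.
#'
#' @param count_a,count_b raw counts (reference, target); vectorized.
#' @param m_adjusted normalized log2 fold change per island.
#' @param m_fitted fitted M under the null (0 = equal depths).
#' @param p_cutoff significance threshold (default 0.01).
#' @param fold_change minimum adjusted linear fold change (default 2, i.e.
#'   |M_adjusted| > 1).
#' @param min_reads minimum raw count required in at least one condition
#'   (default 15).
#' @return data.frame (pvalue, passes, direction).
#' @export
differential_test <- function(count_a, count_b, m_adjusted, m_fitted = 0,
                              p_cutoff = 0.01, fold_change = 2,
                              min_reads = 15) {
  n <- length(count_a)
  if (length(m_fitted) == 1) m_fitted <- rep(m_fitted, n)
  p0 <- 2^m_fitted / (1 + 2^m_fitted)
  pvalue <- vapply(seq_len(n), function(i) {
    tot <- round(count_a[i]) + round(count_b[i])
    if (tot == 0) return(1)
    stats::binom.test(round(count_b[i]), tot, p = p0[i])$p.value
  }, numeric(1))
  passes <- pvalue < p_cutoff & abs(m_adjusted) > log2(fold_change) &
    pmax(count_a, count_b) >= min_reads
  direction <- ifelse(!passes, "unchanged",
                      ifelse(m_adjusted > 0, "gained", "lost"))
  data.frame(pvalue = pvalue, passes = passes, direction = direction,
             stringsAsFactors = FALSE)
}

#' Differential islands between two samples, end to end
#'
#' Calls nothing itself: takes islands already called per sample, merges
#' them ([merge_island_sets()]), counts raw tags of each sample in every
#' region, normalizes ([ma_normalize()]) and tests ([differential_test()]).
#' `direction = "gained"` means stronger in the *target* sample.
#'
#' @param tags_ref,tags_tgt BED6-shaped tag data.frames (reference, e.g.
#'   naive, and target, e.g. memory).
#' @param islands_ref,islands_tgt island sets from [call_islands()].
#' @param fragment_length fragment length for midpoint counting.
#' @param count_mode tag membership rule.
#' @param p_cutoff,fold_change,min_reads pass criteria, see
#'   [differential_test()].
#' @return data.frame (chrom, start, end, common, count_ref, count_tgt, M,
#'   A, M_adjusted, pvalue, passes, direction).
#' @export
differential_islands <- function(tags_ref, tags_tgt, islands_ref,
                                 islands_tgt, fragment_length = 150L,
                                 count_mode = "midpoint", p_cutoff = 0.01,
                                 fold_change = 2, min_reads = 15) {
  regions <- merge_island_sets(islands_ref, islands_tgt)
  if (nrow(regions) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), common = logical(0),
                      count_ref = integer(0), count_tgt = integer(0),
                      M = numeric(0), A = numeric(0),
                      M_adjusted = numeric(0), pvalue = numeric(0),
                      passes = logical(0), direction = character(0),
                      stringsAsFactors = FALSE))
  count_ref <- count_tags_in_regions(tags_ref, regions, fragment_length,
                                     count_mode)
  count_tgt <- count_tags_in_regions(tags_tgt, regions, fragment_length,
                                     count_mode)
  norm <- ma_normalize(count_ref, count_tgt, regions$common)
  test <- differential_test(count_ref, count_tgt, norm$M_adjusted,
                            norm$M_fitted, p_cutoff, fold_change, min_reads)
  cbind(regions,
        data.frame(count_ref = count_ref, count_tgt = count_tgt,
                   M = norm$M, A = norm$A, M_adjusted = norm$M_adjusted,
                   stringsAsFactors = FALSE),
        test)
}

#' Write islands or differential results as TSV (BED-style columns first)
#' @param islands data.frame from [call_islands()] or
#'   [differential_islands()].
#' @param path output path.
#' @export
write_islands <- function(islands, path) {
  utils::write.table(islands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
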
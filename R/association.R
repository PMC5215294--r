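## Linking differential islands to genes by genomic windows, summarizing
## gains/losses per induction group, and categorizing the expression
## consequence of promoter-level changes.

#' Per-gene association windows
#'
#' For the gain/loss association the window spans `upstream` bp 5' of the
#' TSS to `downstream` bp 3' of it. In `"transcription"` orientation
#' (default) upstream means against the direction of transcription, so a
#' minus-strand gene's window is `[tss - downstream, tss + upstream)`;
#' `"genome"` orientation ignores strand.
#'
#' @param genes annotation data.frame (gene_id, chrom, strand, tss).
#' @param upstream,downstream window extents in bp.
#' @param orient `"transcription"` or `"genome"`.
#' @return data.frame (gene_id, chrom, start, end), starts clipped at 0.
#' @export
gene_windows <- function(genes, upstream = 20000L, downstream = 1000L,
                         orient = c("transcription", "genome")) {
  orient <- match.arg(orient)
  minus <- orient == "transcription" & genes$strand == "-"
  start <- ifelse(minus, genes$tss - downstream, genes$tss - upstream)
  end <- ifelse(minus, genes$tss + upstream, genes$tss + downstream)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(pmax(start, 0L)), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Link passing differential islands to genes
#'
#' A gene's status is `gained` if at least one passing island with
#' direction `gained` overlaps its window by >= 1 bp, `lost` likewise,
#' `both` when both kinds are present, `none` otherwise. Multiple islands
#' in one window contribute presence/absence only (no p-value combination).
#'
#' @param diff differential results from [differential_islands()].
#' @param genes annotation data.frame.
#' @param upstream,downstream,orient window geometry, see [gene_windows()].
#' @return data.frame (gene_id, chrom, win_start, win_end, n_gained,
#'   n_lost, status).
#' @export
link_islands_to_genes <- function(diff, genes, upstream = 20000L,
                                  downstream = 1000L,
                                  orient = "transcription") {
  wins <- gene_windows(genes, upstream, downstream, orient)
  n_gained <- integer(nrow(wins))
  n_lost <- integer(nrow(wins))
  passing <- diff[diff$passes, , drop = FALSE]
  if (nrow(passing) > 0 && nrow(wins) > 0) {
    gr_w <- GenomicRanges::GRanges(wins$chrom,
                                   IRanges::IRanges(wins$start + 1L,
                                                    wins$end))
    gr_i <- islands_granges(passing)
    hits <- GenomicRanges::findOverlaps(gr_w, gr_i)
    qh <- S4Vectors::queryHits(hits)
    dir <- passing$direction[S4Vectors::subjectHits(hits)]
    if (length(qh) > 0) {
      tg <- table(factor(qh[dir == "gained"], levels = seq_len(nrow(wins))))
      tl <- table(factor(qh[dir == "lost"], levels = seq_len(nrow(wins))))
      n_gained <- as.integer(tg)
      n_lost <- as.integer(tl)
    }
  }
  status <- ifelse(n_gained > 0 & n_lost > 0, "both",
                   ifelse(n_gained > 0, "gained",
                          ifelse(n_lost > 0, "lost", "none")))
  data.frame(gene_id = wins$gene_id, chrom = wins$chrom,
             win_start = wins$start, win_end = wins$end,
             n_gained = n_gained, n_lost = n_lost, status = status,
             stringsAsFactors = FALSE)
}

has_gain <- function(status) status %in% c("gained", "both")
has_loss <- function(status) status %in% c("lost", "both")

#' Combine per-replicate gene statuses, requiring agreement in both
#'
#' A gene is `gained` only if a gain is seen in both replicate comparisons
#' and no loss in either; symmetrically for `lost`. Conflicting directions
#' across replicates yield `none`.
#'
#' @param links1,links2 linkage tables from [link_islands_to_genes()] for
#'   the two replicate comparisons (same gene order).
#' @return data.frame (gene_id, status).
#' @export
combine_replicate_status <- function(links1, links2) {
  stopifnot(identical(links1$gene_id, links2$gene_id))
  g <- has_gain(links1$status) & has_gain(links2$status) &
    !(has_loss(links1$status) | has_loss(links2$status))
  l <- has_loss(links1$status) & has_loss(links2$status) &
    !(has_gain(links1$status) | has_gain(links2$status))
  data.frame(gene_id = links1$gene_id,
             status = ifelse(g, "gained", ifelse(l, "lost", "none")),
             stringsAsFactors = FALSE)
}

#' Fraction of genes per induction group that gained or lost islands
#'
#' @param links per-gene status table (gene_id, status) -- either a single
#'   linkage table or a replicate-combined one.
#' @param induction_groups data.frame (gene_id, group) from
#'   [induction_groups()].
#' @return data.frame with one row per group (naive_specific, tem_specific,
#'   shared): n_genes, fraction_gained, fraction_lost (NA when the group is
#'   empty).
#' @export
poising_summary <- function(links, induction_groups) {
  merged <- merge(induction_groups, links[, c("gene_id", "status")],
                  by = "gene_id")
  groups <- c("naive_specific", "tem_specific", "shared")
  rows <- lapply(groups, function(g) {
    sub <- merged[merged$group == g, , drop = FALSE]
    n <- nrow(sub)
    data.frame(group = g, n_genes = n,
               fraction_gained = if (n > 0) mean(has_gain(sub$status))
                                 else NA_real_,
               fraction_lost = if (n > 0) mean(has_loss(sub$status))
                               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes with replicate-consistent differential promoter marks
#'
#' A gene's promoter (`TSS +/- flank`) is `gained` only when a passing
#' gained island overlaps it in *both* replicate comparisons (and no lost
#' island does); `lost` symmetrically; direction conflicts are excluded.
#'
#' @param diff_rep1,diff_rep2 differential results for the two replicate
#'   comparisons.
#' @param genes annotation data.frame.
#' @param flank promoter half-width in bp (default 1000).
#' @return data.frame (gene_id, status) with status in gained/lost/none.
#' @export
promoter_differential <- function(diff_rep1, diff_rep2, genes,
                                  flank = 1000L) {
  l1 <- link_islands_to_genes(diff_rep1, genes, upstream = flank,
                              downstream = flank, orient = "genome")
  l2 <- link_islands_to_genes(diff_rep2, genes, upstream = flank,
                              downstream = flank, orient = "genome")
  combine_replicate_status(l1, l2)
}

#' Expression consequence of a promoter-level chromatin change
#'
#' Compares the expressed/silent/inducible class of each gene between naive
#' and memory cells and names the transition: `silent -> expressed` is
#' `increased_expression`, `silent -> inducible` is
#' `increased_inducibility`, `inducible -> expressed` is
#' `increased_expression`, `inducible -> silent` is `lost_inducibility`,
#' `expressed -> silent/inducible` is `lost_expression`; identical classes
#' (and transitions involving `ambiguous`) are `no_change`.
#'
#' @param class_naive,class_mem class labels from [classify_genes()].
#' @return character vector of categories.
#' @export
consequence_category <- function(class_naive, class_mem) {
  key <- paste(class_naive, class_mem, sep = "->")
  map <- c("silent->expressed" = "increased_expression",
           "silent->inducible" = "increased_inducibility",
           "inducible->expressed" = "increased_expression",
           "inducible->silent" = "lost_inducibility",
           "expressed->silent" = "lost_expression",
           "expressed->inducible" = "lost_expression")
  out <- unname(map[key])
  out[is.na(out)] <- "no_change"
  out
}

#' Consequence categories and clustered heatmap input for a gene list
#'
#' For the genes in `gene_status` (typically from
#' [promoter_differential()]), classifies expression in naive and memory
#' cells, assigns a consequence category, and builds the heatmap matrix of
#' `log2(floor_rpkm(FPKM))` over all naive and memory conditions, row-ordered
#' by average-linkage hierarchical clustering on correlation distance
#' (cosmetic ordering only).
#'
#' @param gene_status data.frame (gene_id, status); rows with status
#'   `"none"` are dropped.
#' @param expr gene-level expression data.frame.
#' @param cell_mem memory cell type compared against naive (default
#'   `"TEM"`).
#' @param time activation timepoint for classification.
#' @return list with `categories` (gene_id, status, class_naive, class_mem,
#'   category) and `matrix` (log2 floored FPKM, rows in cluster order).
#' @export
consequence_matrix <- function(gene_status, expr, cell_mem = "TEM",
                               time = "150min") {
  sel <- gene_status[gene_status$status != "none", , drop = FALSE]
  e <- expr[match(sel$gene_id, expr$gene_id), , drop = FALSE]
  if (any(is.na(e$gene_id)))
    fail("expression table lacks gene(s): %s",
         paste(utils::head(sel$gene_id[is.na(e$gene_id)], 5),
               collapse = ", "))
  cn <- classify_expression(e, "Naive", time)$class
  cm <- classify_expression(e, cell_mem, time)$class
  categories <- data.frame(gene_id = sel$gene_id, status = sel$status,
                           class_naive = cn, class_mem = cm,
                           category = consequence_category(cn, cm),
                           stringsAsFactors = FALSE)
  cols <- c(fpkm_col("Naive", TIMEPOINTS), fpkm_col(cell_mem, TIMEPOINTS))
  cols <- cols[cols %in% names(e)]
  mat <- log2(floor_rpkm(as.matrix(e[, cols, drop = FALSE])))
  rownames(mat) <- sel$gene_id
  if (nrow(mat) >= 3) {
    cc <- suppressWarnings(stats::cor(t(mat)))
    d <- 1 - cc
    d[!is.finite(d)] <- 2   # constant rows: maximal correlation distance
    ord <- stats::hclust(stats::as.dist(d), method = "average")$order
    mat <- mat[ord, , drop = FALSE]
  }
  list(categories = categories, matrix = mat)
}
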
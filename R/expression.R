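## FPKM processing: isoform combination, expressed/silent/inducible
## classification, relative-induction grouping, and RPKM flooring.
##
## Thresholds: a gene is "expressed" with resting FPKM > 5, "silent" with
## resting FPKM < 2 (and < 5 after activation), "inducible" with resting
## FPKM < 2 rising above 5 after activation. About 5-8 RPKM corresponds to a
## single transcript copy per cell, which motivates the 2/5 bracket; values
## falling in the [2, 5] gap (or exactly on a threshold) are "ambiguous".

#' Combine isoform FPKMs that share a TSS
#'
#' Isoforms of a gene with the same TSS have their FPKM values summed
#' (transcript mass from the same start site is additive); isoforms with
#' distinct TSSs remain separate entries keyed by (gene_id, tss).
#'
#' @param expr isoform-level data.frame with `gene_id`, `tss` and
#'   `cell:timepoint` FPKM columns (an `isoform_id` column is dropped).
#' @return gene/TSS-level data.frame with summed FPKM columns.
#' @export
combine_isoforms <- function(expr) {
  if (!all(c("gene_id", "tss") %in% names(expr)))
    fail("combine_isoforms needs gene_id and tss columns")
  fcols <- grep(":", names(expr), value = TRUE)
  key <- paste(expr$gene_id, expr$tss, sep = "\r")
  first <- !duplicated(key)
  out <- expr[first, setdiff(names(expr), c(fcols, "isoform_id")),
              drop = FALSE]
  summed <- rowsum(as.matrix(expr[, fcols, drop = FALSE]), group = key,
                   reorder = FALSE)
  out[fcols] <- as.data.frame(summed[match(key[first], rownames(summed)), ,
                                     drop = FALSE], row.names = NULL)
  rownames(out) <- NULL
  out
}

#' Classify genes as expressed, silent, inducible or ambiguous
#'
#' Vectorized over genes: `expressed` if resting FPKM > 5 (whatever
#' activation does); `silent` if resting < 2 and activated < 5; `inducible`
#' if resting < 2 and activated > 5; otherwise `ambiguous` (strict
#' inequalities, so boundary values are ambiguous).
#'
#' @param fpkm_rest FPKM at rest.
#' @param fpkm_act FPKM after activation.
#' @return character vector of class labels.
#' @export
classify_genes <- function(fpkm_rest, fpkm_act) {
  if (length(fpkm_act) == 1) fpkm_act <- rep(fpkm_act, length(fpkm_rest))
  if (any(is.na(fpkm_rest) | is.na(fpkm_act)))
    fail("classify_genes: missing FPKM values")
  ifelse(fpkm_rest > 5, "expressed",
         ifelse(fpkm_rest < 2 & fpkm_act < 5, "silent",
                ifelse(fpkm_rest < 2 & fpkm_act > 5, "inducible",
                       "ambiguous")))
}

#' Classify every gene of an expression table for one cell type
#'
#' @param expr gene-level expression data.frame (see [read_expression()]).
#' @param cell_type cell type whose columns are used.
#' @param time activation timepoint compared against rest (default
#'   `"150min"`); ignored when `any_time = TRUE`.
#' @param any_time if `TRUE`, activation FPKM is the maximum over 40min,
#'   150min and 15h.
#' @return data.frame (gene_id, class).
#' @export
classify_expression <- function(expr, cell_type, time = "150min",
                                any_time = FALSE) {
  rest_col <- fpkm_col(cell_type, "R")
  if (!rest_col %in% names(expr))
    fail("expression table lacks column %s", rest_col)
  act <- if (any_time) {
    act_cols <- fpkm_col(cell_type, c("40min", "150min", "15h"))
    act_cols <- act_cols[act_cols %in% names(expr)]
    if (length(act_cols) == 0)
      fail("expression table lacks activation columns for %s", cell_type)
    do.call(pmax, expr[act_cols])
  } else {
    act_col <- fpkm_col(cell_type, time)
    if (!act_col %in% names(expr))
      fail("expression table lacks column %s", act_col)
    expr[[act_col]]
  }
  data.frame(gene_id = expr$gene_id,
             class = classify_genes(expr[[rest_col]], act),
             stringsAsFactors = FALSE)
}

#' Relative induction ratio between TEM and naive cells
#'
#' Computed exactly as
#' `(|FPKM_TEM,150 - FPKM_TEM,R| + 0.1) / (|FPKM_Naive,150 - FPKM_Naive,R| + 0.1)`.
#' A ratio of at least 3 labels the gene `tem_specific`, at most 1/3
#' `naive_specific`, anything between `shared` (ties at exactly 3-fold go to
#' the specific group).
#'
#' @param naive_r,naive_act resting and 150-min FPKM in naive cells.
#' @param tem_r,tem_act resting and 150-min FPKM in TEM cells.
#' @return data.frame (ratio, group), vectorized over genes.
#' @export
induction_ratio <- function(naive_r, naive_act, tem_r, tem_act) {
  ratio <- (abs(tem_act - tem_r) + 0.1) / (abs(naive_act - naive_r) + 0.1)
  group <- ifelse(ratio >= 3, "tem_specific",
                  ifelse(ratio <= 1 / 3, "naive_specific", "shared"))
  data.frame(ratio = ratio, group = group, stringsAsFactors = FALSE)
}

#' Induction groups for the inducible-gene universe
#'
#' Restricts to genes silent at rest (< `rest_threshold` FPKM in both naive
#' and TEM) and induced above `induced_threshold` at 150 min in at least one
#' of the two cell types, then groups them by [induction_ratio()]. Genes
#' outside the universe are excluded, not errors; their count is attached as
#' attribute `n_excluded`.
#'
#' @param expr gene-level expression data.frame.
#' @param time activation timepoint (default `"150min"`).
#' @param rest_threshold FPKM below which a resting gene is silent.
#' @param induced_threshold FPKM above which an activated gene is induced.
#' @return data.frame (gene_id, ratio, group).
#' @export
induction_groups <- function(expr, time = "150min", rest_threshold = 2,
                             induced_threshold = 5) {
  need <- c(fpkm_col("Naive", c("R", time)), fpkm_col("TEM", c("R", time)))
  missing <- setdiff(need, names(expr))
  if (length(missing) > 0)
    fail("expression table lacks column(s): %s",
         paste(missing, collapse = ", "))
  nr <- expr[[fpkm_col("Naive", "R")]]
  na <- expr[[fpkm_col("Naive", time)]]
  tr <- expr[[fpkm_col("TEM", "R")]]
  ta <- expr[[fpkm_col("TEM", time)]]
  eligible <- nr < rest_threshold & tr < rest_threshold &
    (na > induced_threshold | ta > induced_threshold)
  ig <- induction_ratio(nr[eligible], na[eligible], tr[eligible],
                        ta[eligible])
  out <- data.frame(gene_id = expr$gene_id[eligible], ratio = ig$ratio,
                    group = ig$group, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!eligible)
  out
}

#' Floor RPKM values at 1
#'
#' Avoids huge fold changes driven by near-zero expression when building
#' log2 heatmap matrices.
#'
#' @param x numeric RPKM/FPKM values.
#' @return `pmax(x, 1)`.
#' @export
floor_rpkm <- function(x) pmax(x, 1)
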
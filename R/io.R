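## Readers and writers for the plain-text formats the pipeline touches.
## All interval coordinates are 0-based, half-open (BED-native) everywhere
## inside the package; the TSS of a minus-strand gene is the position
## `end - 1` of its transcript interval.

#' Read aligned ChIP-Seq tags from a BED6 file
#'
#' Expects six tab-separated columns (chrom, start, end, name, score,
#' strand), 0-based half-open. Malformed lines are reported with their line
#' numbers; a record with `start >= end` or a strand outside `+`/`-` is a
#' parse error.
#'
#' @param path path to a BED6 file.
#' @return a data.frame (chrom, start, end, name, score, strand) sorted by
#'   (chrom, start).
#' @export
read_tags <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6))
    fail("BED6 parse error: fewer than 6 fields on line(s) %s of %s",
         paste(utils::head(lineno[nf < 6], 5), collapse = ", "), path)
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad))
    fail("BED6 parse error: bad coordinates (need 0 <= start < end) on line(s) %s of %s",
         paste(utils::head(lineno[bad], 5), collapse = ", "), path)
  bad_strand <- !m[, 6] %in% c("+", "-")
  if (any(bad_strand))
    fail("BED6 parse error: unknown strand on line(s) %s of %s",
         paste(utils::head(lineno[bad_strand], 5), collapse = ", "), path)
  tags <- data.frame(chrom = m[, 1], start = start, end = end,
                     name = m[, 4],
                     score = suppressWarnings(as.numeric(m[, 5])),
                     strand = m[, 6], stringsAsFactors = FALSE)
  tags <- sort_intervals(tags)
  rownames(tags) <- NULL
  tags
}

#' Write tags as BED6
#' @param tags data.frame as returned by [read_tags()].
#' @param path output path.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(tags[, c("chrom", "start", "end", "name", "score",
                              "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, strand, tss, tes, isoform_id.
#' TSS/TES are 0-based positions; on the minus strand `tss > tes`.
#'
#' @param path path to the TSV.
#' @return a data.frame of gene records.
#' @export
read_genes <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "strand", "tss", "tes", "isoform_id")
  missing <- setdiff(needed, names(g))
  if (length(missing) > 0)
    fail("gene table %s lacks column(s): %s", path,
         paste(missing, collapse = ", "))
  if (!all(g$strand %in% c("+", "-")))
    fail("gene table %s: strand must be '+' or '-'", path)
  if (any(g$tss == g$tes)) fail("gene table %s: tss == tes", path)
  wrong <- (g$strand == "-" & g$tss < g$tes) |
    (g$strand == "+" & g$tss > g$tes)
  if (any(wrong))
    fail("gene table %s: tss/tes order inconsistent with strand for %s",
         path, paste(utils::head(g$gene_id[wrong], 5), collapse = ", "))
  g
}

#' Write a gene annotation table
#' @param genes data.frame as from [read_genes()].
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an FPKM expression table
#'
#' Tab-separated with a header row; the first column is `gene_id` and the
#' FPKM columns are named `cell:timepoint` (e.g. `Naive:R`, `TEM:150min`).
#' `.` denotes a missing value. Isoform-level tables additionally carry
#' `isoform_id` and `tss` columns and may repeat gene ids; gene-level tables
#' must not.
#'
#' @param path path to the TSV.
#' @return a data.frame with `gene_id` plus numeric FPKM columns.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = ".")
  if (!"gene_id" %in% names(x)) fail("expression table %s lacks gene_id", path)
  fcols <- grep(":", names(x), value = TRUE)
  if (length(fcols) == 0)
    fail("expression table %s has no cell:timepoint columns", path)
  times <- sub("^[^:]+:", "", fcols)
  bad_t <- !times %in% TIMEPOINTS
  if (any(bad_t))
    fail("expression table %s: unknown timepoint(s) %s", path,
         paste(unique(times[bad_t]), collapse = ", "))
  if (anyDuplicated(fcols))
    fail("expression table %s: duplicate condition column(s)", path)
  for (cc in fcols) x[[cc]] <- as.numeric(x[[cc]])
  neg <- vapply(fcols, function(cc) any(x[[cc]] < 0, na.rm = TRUE),
                logical(1))
  if (any(neg))
    fail("expression table %s: negative FPKM in column(s) %s", path,
         paste(fcols[neg], collapse = ", "))
  isoform_level <- all(c("isoform_id", "tss") %in% names(x))
  if (!isoform_level && anyDuplicated(x$gene_id))
    fail("expression table %s: duplicate gene_id rows (use isoform_id/tss columns for isoform tables)",
         path)
  x
}

#' Write an FPKM expression table
#' @param expr data.frame as from [read_expression()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes the per-bp values (rounded to 4 decimals); adjacent
#' equal values are merged and zero-valued intervals are suppressed, the
#' usual bedGraph convention.
#'
#' @param track a `CoverageTrack` from [build_coverage()], or a plain numeric
#'   vector (then `chrom` must be given).
#' @param path output path.
#' @param chrom chromosome name when `track` is a bare vector.
#' @export
write_bedgraph <- function(track, path, chrom = NULL) {
  if (inherits(track, "CoverageTrack")) {
    values <- track$values
    chrom <- track$chrom
  } else {
    values <- track
    if (is.null(chrom)) fail("chrom required when track is a numeric vector")
  }
  v <- round(values, 4)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values != 0)
  lines <- vapply(keep, function(i)
    sprintf("%s\t%d\t%d\t%s", chrom, starts[i], ends[i],
            format(r$values[i], trim = TRUE, scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into a per-bp vector
#' @param path bedGraph path.
#' @param chrom_length length of the (single) chromosome.
#' @return numeric vector of length `chrom_length` (zeros where absent).
#' @export
read_bedgraph <- function(path, chrom_length) {
  values <- numeric(chrom_length)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(values)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    s <- as.integer(p[2]); e <- as.integer(p[3])
    values[(s + 1):e] <- as.numeric(p[4])
  }
  values
}

#' Write ground truth as JSON
#' @param truth a `GroundTruth`.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  gene_class <- as.list(stats::setNames(truth$genes$class,
                                        truth$genes$gene_id))
  tss_table <- truth$genes[, c("gene_id", "chrom", "strand", "tss")]
  jsonlite::write_json(list(gene_class = gene_class,
                            planted_islands = truth$planted_islands,
                            tss_table = tss_table,
                            has_island = as.list(
                              stats::setNames(truth$genes$has_island,
                                              truth$genes$gene_id))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Hard error when tag and annotation chromosome sets disagree; chromosome
# names are passed through verbatim (no "chr" normalization).
check_chrom_compatibility <- function(tag_chroms, gene_chroms) {
  only_genes <- setdiff(unique(gene_chroms), unique(tag_chroms))
  if (length(only_genes) > 0)
    fail("annotation chromosomes absent from tags: %s",
         paste(only_genes, collapse = ", "))
  invisible(TRUE)
}
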
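## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical condition labels used throughout.
CELL_TYPES <- c("Naive", "TCM", "TEM")
TIMEPOINTS <- c("R", "40min", "150min", "15h")

fpkm_col <- function(cell, time) paste0(cell, ":", time)

# Sex chromosomes are weighted twice in metaprofiles (one copy in male
# genomes means half the expected tag yield).
is_sex_chrom <- function(chrom) chrom %in% c("chrX", "chrY", "X", "Y")

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows through one user-visible seed; each
#' simulation stream (genome layout, each tag library, the expression noise)
#' gets its own derived seed so streams are independent and stable when other
#' streams are added or dropped. The derived value stays below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... character/numeric labels identifying the stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tokens <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- abs(seed) %% 2147483647
  for (ch in utf8ToInt(tokens)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Stop with a message assembled from sprintf-style parts.
fail <- function(...) stop(sprintf(...), call. = FALSE)

# Order a tag/interval data.frame by (chrom, start).
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Midpoint of an extended fragment [fs, fe): integer position.
fragment_midpoint <- function(fs, fe) (fs + fe) %/% 2L

# data.frame row-binder that tolerates an empty list.
rbind_all <- function(lst) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0, logical(1))]
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
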
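## Synthetic-data generator: genomes with planted poised genes, ChIP-Seq tag
## libraries with planted enrichment islands, and FPKM tables whose induction
## structure matches the planted islands. Everything is seeded and carries
## ground-truth labels so downstream recovery is measurable.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator and validates it.
#' Defaults describe the study conditions the rest of the package is tested
#' under: 200 genes on two autosomes plus an X-like chromosome, 10-fold
#' promoter enrichment over a background of 0.05 tags/bp (50 expected
#' background tags per kb, so a 1 kb planted island expects 500 tags), 150 bp
#' fragments sequenced as 36 bp reads, and lognormal FPKM noise of sigma 0.3
#' around a 20 FPKM induced level and a 0.5 FPKM silent level.
#'
#' @param seed master RNG seed; every stream derives from it.
#' @param n_chromosomes number of autosomes; one X-like chromosome named
#'   `"chrX"` is always appended.
#' @param chrom_length length of every chromosome in bp.
#' @param n_genes number of genes to place.
#' @param background_rate expected background tags per bp at full depth.
#' @param island_enrichment fold enrichment of tag density inside a planted
#'   island over background (total in-island density is
#'   `island_enrichment * background_rate`); must exceed 1.
#' @param fragment_length ChIP fragment length in bp (reads are extended to
#'   this length downstream).
#' @param read_length sequenced read length in bp.
#' @param depth_per_sample optional total expected tag count per sample; when
#'   `NULL` the library size follows naturally from `background_rate`.
#' @param class_fractions named proportions over the gene classes
#'   `constitutive`, `poised_TEM`, `poised_naive`, `poised_both`, `silent`;
#'   must sum to 1.
#' @param fpkm_high FPKM of an expressed/induced state.
#' @param fpkm_low FPKM of a silent state.
#' @param fpkm_noise_sd sigma of the multiplicative lognormal FPKM noise.
#' @param island_width width of planted islands in bp.
#' @param gene_spacing minimum TSS-to-TSS distance in bp; 50 kb keeps the
#'   `[TSS-20 kb, TSS+1 kb]` association windows of neighbouring genes
#'   disjoint so ground-truth association is unambiguous.
#' @param poised_marked_fraction fraction of poised_TEM genes that actually
#'   carry the planted island; the remainder stay induced in TEM but
#'   unmarked, modelling induction that chromatin state does not explain.
#' @param marked_silent_fraction fraction of silent genes that carry a TEM
#'   island anyway (marked but never induced), modelling promoter gains
#'   without an expression consequence.
#' @param multinomial_classes if `TRUE` classes are drawn multinomially;
#'   default is deterministic proportional allocation so expected class
#'   counts are exact.
#' @return a validated list of class `"SimConfig"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 4e6,
                       n_genes = 200L,
                       background_rate = 0.05,
                       island_enrichment = 10,
                       fragment_length = 150L,
                       read_length = 36L,
                       depth_per_sample = NULL,
                       class_fractions = c(constitutive = 0.25,
                                           poised_TEM = 0.20,
                                           poised_naive = 0.20,
                                           poised_both = 0.10,
                                           silent = 0.25),
                       fpkm_high = 20,
                       fpkm_low = 0.5,
                       fpkm_noise_sd = 0.3,
                       island_width = 1000L,
                       gene_spacing = 50000L,
                       poised_marked_fraction = 1,
                       marked_silent_fraction = 0,
                       multinomial_classes = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              background_rate = background_rate,
              island_enrichment = island_enrichment,
              fragment_length = as.integer(fragment_length),
              read_length = as.integer(read_length),
              depth_per_sample = depth_per_sample,
              class_fractions = class_fractions,
              fpkm_high = fpkm_high, fpkm_low = fpkm_low,
              fpkm_noise_sd = fpkm_noise_sd,
              island_width = as.integer(island_width),
              gene_spacing = as.integer(gene_spacing),
              poised_marked_fraction = poised_marked_fraction,
              marked_silent_fraction = marked_silent_fraction,
              multinomial_classes = isTRUE(multinomial_classes))
  validate_sim_config(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  needed <- c("constitutive", "poised_TEM", "poised_naive", "poised_both",
              "silent")
  if (!all(needed %in% names(cfg$class_fractions)))
    fail("class_fractions must name all of: %s", paste(needed, collapse = ", "))
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    fail("class_fractions must sum to 1 (got %.12f)", sum(cfg$class_fractions))
  if (any(cfg$class_fractions < 0)) fail("class_fractions must be >= 0")
  if (cfg$background_rate <= 0) fail("background_rate must be > 0")
  if (cfg$island_enrichment <= 1) fail("island_enrichment must be > 1")
  if (cfg$fragment_length <= 0) fail("fragment_length must be > 0")
  if (cfg$read_length <= 0 || cfg$read_length > cfg$fragment_length)
    fail("read_length must be in (0, fragment_length]")
  if (cfg$n_genes < 0) fail("n_genes must be >= 0")
  if (cfg$n_chromosomes < 1) fail("need at least one autosome")
  if (!is.null(cfg$depth_per_sample) && cfg$depth_per_sample <= 0)
    fail("depth_per_sample must be > 0")
  if (cfg$poised_marked_fraction < 0 || cfg$poised_marked_fraction > 1)
    fail("poised_marked_fraction must be in [0, 1]")
  if (cfg$marked_silent_fraction < 0 || cfg$marked_silent_fraction > 1)
    fail("marked_silent_fraction must be in [0, 1]")
  invisible(cfg)
}

sim_chromosomes <- function(cfg) {
  c(paste0("chr", seq_len(cfg$n_chromosomes)), "chrX")
}

# Deterministic proportional allocation: floor the expected counts, hand the
# remainder to the classes with the largest fractional parts.
allocate_classes <- function(n, fractions, multinomial = FALSE) {
  if (n == 0) return(character(0))
  if (multinomial)
    return(sample(names(fractions), n, replace = TRUE, prob = fractions))
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- fractions * n - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  rep(names(fractions), times = base)
}

island_cells_for_class <- function(class) {
  switch(class,
         constitutive = "Naive,TCM,TEM",
         poised_TEM = "TEM",
         poised_naive = "Naive",
         poised_both = "Naive,TCM,TEM",
         NA_character_)
}

#' Simulate a gene layout with planted ground truth
#'
#' Places `n_genes` TSSs on a grid with `gene_spacing` bp between slots
#' (margins keep every association window inside its chromosome), assigns a
#' strand and a gene class to each, and plants a 1 kb enrichment island at
#' the promoter of every marked gene, recording which cell types carry it.
#' Constitutive genes carry their island in all cell types (an active
#' promoter), poised genes only in the cell type(s) where they are inducible.
#'
#' @param config a [sim_config()].
#' @return a list with `annotation` (data.frame: gene_id, chrom, strand, tss,
#'   tes, isoform_id) and `truth` (a `GroundTruth`: per-gene class/island
#'   labels plus the planted island table).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  chroms <- sim_chromosomes(config)
  empty_ann <- data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          tes = integer(0), isoform_id = character(0),
                          stringsAsFactors = FALSE)
  if (config$n_genes == 0) {
    truth <- ground_truth(genes = cbind(empty_ann[0, 1:5],
                                        data.frame(class = character(0),
                                                   has_island = logical(0),
                                                   island_cells = character(0))),
                          planted_islands = empty_island_table(),
                          config = config)
    return(list(annotation = empty_ann, truth = truth))
  }

  margin <- 25000L   # window [TSS-20kb, TSS+20kb] (either strand) must fit
  if (config$chrom_length < 2 * margin + config$gene_spacing)
    fail("chrom_length %g too short to place genes at %d bp spacing",
         config$chrom_length, config$gene_spacing)
  slot_pos <- seq(margin, config$chrom_length - margin,
                  by = config$gene_spacing)
  slots <- expand.grid(chrom = chroms, pos = slot_pos,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(slots) < config$n_genes)
    fail("chromosomes too short: %d slots available for %d genes at %d bp spacing",
         nrow(slots), config$n_genes, config$gene_spacing)

  set.seed(derive_seed(config$seed, "genome"))
  pick <- sample.int(nrow(slots), config$n_genes)
  chrom <- slots$chrom[pick]
  tss <- as.integer(slots$pos[pick])
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_len <- 10000L
  tes <- ifelse(strand == "+",
                pmin(tss + gene_len, as.integer(config$chrom_length) - 1L),
                pmax(tss - gene_len, 0L))
  class <- allocate_classes(config$n_genes, config$class_fractions,
                            config$multinomial_classes)
  class <- class[sample.int(config$n_genes)]
  gene_id <- sprintf("G%04d", seq_len(config$n_genes))

  has_island <- class %in% c("constitutive", "poised_TEM", "poised_naive",
                             "poised_both")
  island_cells <- vapply(class, island_cells_for_class, character(1))

  # Optionally unmark a fraction of poised_TEM genes (induction the
  # chromatin does not explain) ...
  ptem <- which(class == "poised_TEM")
  if (config$poised_marked_fraction < 1 && length(ptem) > 0) {
    n_marked <- round(config$poised_marked_fraction * length(ptem))
    unmarked <- ptem[!seq_along(ptem) %in% seq_len(n_marked)]
    # ptem indices are already in randomized gene order, so taking a prefix
    # is an unbiased deterministic choice.
    has_island[unmarked] <- FALSE
    island_cells[unmarked] <- NA_character_
  }
  # ... and optionally mark a fraction of silent genes with a TEM island
  # that never gains an expression consequence.
  sil <- which(class == "silent")
  if (config$marked_silent_fraction > 0 && length(sil) > 0) {
    n_marked <- round(config$marked_silent_fraction * length(sil))
    marked <- sil[seq_len(n_marked)]
    has_island[marked] <- TRUE
    island_cells[marked] <- "TEM"
  }

  half <- config$island_width %/% 2L
  isl <- which(has_island)
  planted <- data.frame(gene_id = gene_id[isl],
                        chrom = chrom[isl],
                        start = tss[isl] - half,
                        end = tss[isl] - half + config$island_width,
                        cells = island_cells[isl],
                        stringsAsFactors = FALSE)

  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = tss, tes = tes, class = class,
                      has_island = has_island, island_cells = island_cells,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  rownames(genes) <- NULL
  annotation <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                           strand = genes$strand, tss = genes$tss,
                           tes = genes$tes,
                           isoform_id = paste0(genes$gene_id, ".1"),
                           stringsAsFactors = FALSE)
  planted <- sort_intervals(planted)
  rownames(planted) <- NULL
  truth <- ground_truth(genes = genes, planted_islands = planted,
                        config = config)
  list(annotation = annotation, truth = truth)
}

empty_island_table <- function() {
  data.frame(gene_id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), cells = character(0), stringsAsFactors = FALSE)
}

ground_truth <- function(genes, planted_islands, config) {
  structure(list(genes = genes, planted_islands = planted_islands,
                 config = config),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", nrow(x$genes), "genes,",
      nrow(x$planted_islands), "planted islands\n")
  if (nrow(x$genes) > 0) print(table(x$genes$class))
  invisible(x)
}

islands_carried_by <- function(truth, cell_type) {
  pl <- truth$planted_islands
  if (nrow(pl) == 0) return(pl)
  keep <- vapply(strsplit(pl$cells, ","), function(cc) cell_type %in% cc,
                 logical(1))
  pl[keep, , drop = FALSE]
}

#' Expected tag count of a simulated library at natural depth
#'
#' Background contributes `background_rate` tags per bp genome-wide; every
#' island carried by `cell_type` contributes an extra
#' `(island_enrichment - 1) * background_rate` per bp, so total in-island
#' density is `island_enrichment` times background.
#'
#' @param truth a `GroundTruth` from [simulate_genome()].
#' @param config the matching [sim_config()].
#' @param cell_type one of `"Naive"`, `"TCM"`, `"TEM"`.
#' @return expected number of tags (a double).
#' @export
expected_tag_count <- function(truth, config, cell_type) {
  n_chrom <- length(sim_chromosomes(config))
  bg <- config$background_rate * config$chrom_length * n_chrom
  isl <- islands_carried_by(truth, cell_type)
  extra <- sum((config$island_enrichment - 1) * config$background_rate *
                 (isl$end - isl$start))
  bg + extra
}

#' Simulate one ChIP-Seq tag library
#'
#' Draws aligned-read tags from a mixture of uniform background plus planted
#' islands for the given cell type. Segment counts are Poisson; fragment
#' midpoints are uniform inside the source region; the read strand is chosen
#' with equal probability, and the read's 5' end is placed so that the
#' midpoint of the `fragment_length` fragment it implies falls on the drawn
#' midpoint. Replicates differ only by their derived seed (and optionally
#' depth).
#'
#' @param truth a `GroundTruth` from [simulate_genome()].
#' @param config the matching [sim_config()].
#' @param cell_type one of `"Naive"`, `"TCM"`, `"TEM"`.
#' @param replicate_id replicate index (enters the derived seed).
#' @param depth optional expected total tag count; `NULL` uses the natural
#'   depth implied by `background_rate` (see [expected_tag_count()]).
#' @return a BED6-shaped data.frame (chrom, start, end, name, score, strand)
#'   sorted by (chrom, start); coordinates 0-based half-open.
#' @export
simulate_chip_tags <- function(truth, config, cell_type, replicate_id = 1L,
                               depth = NULL) {
  validate_sim_config(config)
  if (!cell_type %in% CELL_TYPES)
    fail("unknown cell_type '%s' (expected one of %s)", cell_type,
         paste(CELL_TYPES, collapse = ", "))
  if (!is.null(depth) && depth <= 0) fail("depth must be > 0")
  depth <- depth %||% config$depth_per_sample

  chroms <- sim_chromosomes(config)
  isl <- islands_carried_by(truth, cell_type)

  # Expected counts per source segment (background per chromosome + extra
  # per island), optionally rescaled to hit the requested depth.
  lambda_bg <- rep(config$background_rate * config$chrom_length,
                   length(chroms))
  lambda_isl <- (config$island_enrichment - 1) * config$background_rate *
    (isl$end - isl$start)
  total <- sum(lambda_bg) + sum(lambda_isl)
  if (!is.null(depth)) {
    sc <- depth / total
    lambda_bg <- lambda_bg * sc
    lambda_isl <- lambda_isl * sc
  }

  set.seed(derive_seed(config$seed, "tags", cell_type, replicate_id))
  n_bg <- stats::rpois(length(chroms), lambda_bg)
  n_isl <- if (nrow(isl) > 0) stats::rpois(nrow(isl), lambda_isl) else integer(0)

  mids <- numeric(0); tag_chrom <- character(0)
  for (i in seq_along(chroms)) {
    if (n_bg[i] > 0) {
      mids <- c(mids, stats::runif(n_bg[i], 0, config$chrom_length))
      tag_chrom <- c(tag_chrom, rep(chroms[i], n_bg[i]))
    }
  }
  for (j in seq_len(nrow(isl))) {
    if (n_isl[j] > 0) {
      mids <- c(mids, stats::runif(n_isl[j], isl$start[j], isl$end[j]))
      tag_chrom <- c(tag_chrom, rep(isl$chrom[j], n_isl[j]))
    }
  }
  n <- length(mids)
  if (n == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  half <- config$fragment_length / 2
  # 5' end placement: fragment [fs, fs+L) has midpoint at mid.
  fs <- round(mids - half)
  start <- ifelse(strand == "+", fs, fs + config$fragment_length -
                    config$read_length)
  start <- pmin(pmax(start, 0), config$chrom_length - config$read_length)
  tags <- data.frame(chrom = tag_chrom,
                     start = as.integer(start),
                     end = as.integer(start + config$read_length),
                     name = paste0(cell_type, "_r", replicate_id, "_",
                                   seq_len(n)),
                     score = 0L, strand = strand, stringsAsFactors = FALSE)
  tags <- sort_intervals(tags)
  rownames(tags) <- NULL
  tags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless FPKM template for one gene class: a named vector over the
# 12 cell x time conditions.
expression_template <- function(class, fpkm_high, fpkm_low) {
  v <- rep(fpkm_low, length(CELL_TYPES) * length(TIMEPOINTS))
  names(v) <- as.vector(outer(CELL_TYPES, TIMEPOINTS, fpkm_col))
  induced <- c("150min", "15h")
  cells <- switch(class,
                  constitutive = NULL,
                  silent = NULL,
                  poised_TEM = "TEM",
                  poised_naive = "Naive",
                  poised_both = c("Naive", "TCM", "TEM"))
  if (class == "constitutive") v[] <- fpkm_high
  for (cc in cells) v[fpkm_col(cc, induced)] <- fpkm_high
  v
}

#' Simulate an FPKM expression table
#'
#' Each gene follows the noiseless template of its class (constitutive genes
#' high everywhere, silent genes low everywhere, poised genes low at rest and
#' high at 150 min and 15 h in the cell type(s) carrying their island), then
#' every entry is multiplied by lognormal noise `exp(N(0, fpkm_noise_sd))`.
#'
#' @param truth a `GroundTruth` from [simulate_genome()].
#' @param config the matching [sim_config()].
#' @return a data.frame with `gene_id` and one `cell:time` FPKM column per
#'   condition (Naive/TCM/TEM x R/40min/150min/15h).
#' @export
simulate_expression <- function(truth, config) {
  validate_sim_config(config)
  genes <- truth$genes
  cols <- as.vector(outer(CELL_TYPES, TIMEPOINTS, fpkm_col))
  mat <- matrix(0, nrow = nrow(genes), ncol = length(cols),
                dimnames = list(genes$gene_id, cols))
  for (i in seq_len(nrow(genes))) {
    mat[i, ] <- expression_template(genes$class[i], config$fpkm_high,
                                    config$fpkm_low)[cols]
  }
  if (config$fpkm_noise_sd > 0 && nrow(genes) > 0) {
    set.seed(derive_seed(config$seed, "expression"))
    mat <- mat * exp(matrix(stats::rnorm(length(mat), 0,
                                         config$fpkm_noise_sd),
                            nrow = nrow(mat)))
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out[cols] <- as.data.frame(mat, row.names = NULL)
  rownames(out) <- NULL
  out
}

#' Write a full simulated dataset to disk
#'
#' Writes the gene annotation (TSV), the expression table (TSV), the ground
#' truth (JSON) and, optionally, one BED6 tag file per cell type/replicate.
#'
#' @param sim result of [simulate_genome()].
#' @param config the matching [sim_config()].
#' @param outdir output directory (created if needed).
#' @param cell_types cell types to simulate tags for; `NULL` skips tags.
#' @param replicates number of tag replicates per cell type.
#' @return invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, config, outdir,
                             cell_types = c("Naive", "TEM"),
                             replicates = 2L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(outdir, "genes.tsv")
  write_genes(sim$annotation, p); paths <- c(paths, p)
  expr <- simulate_expression(sim$truth, config)
  p <- file.path(outdir, "expression.tsv")
  write_expression(expr, p); paths <- c(paths, p)
  p <- file.path(outdir, "ground_truth.json")
  write_ground_truth(sim$truth, p); paths <- c(paths, p)
  for (ct in cell_types %||% character(0)) {
    for (r in seq_len(replicates)) {
      tags <- simulate_chip_tags(sim$truth, config, ct, r)
      p <- file.path(outdir, sprintf("tags_%s_rep%d.bed", ct, r))
      write_tags(tags, p); paths <- c(paths, p)
    }
  }
  invisible(paths)
}
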
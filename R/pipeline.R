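## Orchestration: simulate (or load) data, call islands per sample, run the
## replicate-paired differential comparisons, associate islands with genes,
## and emit a machine-readable report. Deterministic given the config.

#' Build and validate a pipeline configuration
#'
#' Defaults carry the analysis constants used throughout: FPKM thresholds
#' 2/5, differential criteria p < 0.01 / fold > 2 / 15 reads, association
#' window TSS-20 kb..TSS+1 kb, promoter window TSS +/- 1 kb. The two
#' replicate comparisons are intentionally depth-imbalanced (3:1 and 1:3)
#' so the M-A normalization has real work to do.
#'
#' @param seed master seed; all per-stage seeds derive from it.
#' @param sim list of overrides passed to [sim_config()] (ignored when
#'   `inputs` is given).
#' @param inputs optional list of paths for file-driven runs: `genes`,
#'   `expression`, `chrom_lengths` (named list), and `tags` -- a list
#'   mapping cell type to a vector of per-replicate BED paths. All fields
#'   are required in file mode.
#' @param cell_types the (reference, target) pair compared; default
#'   `c("Naive", "TEM")`.
#' @param depth_factors list mapping cell type to per-replicate depth
#'   multipliers of the natural library size (simulation mode only).
#' @param islands list: `window`, `gap`, `p_threshold`.
#' @param diff list: `p_cutoff`, `fold_change`, `min_reads`.
#' @param windows list: `upstream`, `downstream`, `promoter_flank`.
#' @param expression list: `rest_threshold`, `induced_threshold`, `time`.
#' @param outdir optional output directory; when set, tables and the JSON
#'   report are written there.
#' @param write_tags if `TRUE` (and simulating) the tag BED files are also
#'   written to `outdir`.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipeline_config <- function(seed = 1L, sim = list(), inputs = NULL,
                            cell_types = c("Naive", "TEM"),
                            depth_factors = list(Naive = c(1, 1 / 3),
                                                 TEM = c(1 / 3, 1)),
                            islands = list(), diff = list(),
                            windows = list(), expression = list(),
                            outdir = NULL, write_tags = FALSE) {
  if (is.character(seed) && file.exists(seed)) {
    # Convenience: pipeline_config("config.yaml")
    y <- yaml::read_yaml(seed)
    return(do.call(pipeline_config, y))
  }
  cfg <- list(
    seed = as.integer(seed),
    sim = sim, inputs = inputs, cell_types = cell_types,
    depth_factors = depth_factors,
    islands = utils::modifyList(list(window = 200L, gap = 400L,
                                     p_threshold = 1e-5), islands),
    diff = utils::modifyList(list(p_cutoff = 0.01, fold_change = 2,
                                  min_reads = 15), diff),
    windows = utils::modifyList(list(upstream = 20000L, downstream = 1000L,
                                     promoter_flank = 1000L), windows),
    expression = utils::modifyList(list(rest_threshold = 2,
                                        induced_threshold = 5,
                                        time = "150min"), expression),
    outdir = outdir, write_tags = isTRUE(write_tags))
  if (length(cfg$cell_types) != 2 || !all(cfg$cell_types %in% CELL_TYPES))
    fail("cell_types must be two of %s", paste(CELL_TYPES, collapse = ", "))
  if (!is.null(cfg$inputs)) {
    for (field in c("genes", "expression", "tags", "chrom_lengths")) {
      if (is.null(cfg$inputs[[field]]))
        fail("pipeline config inputs is missing field '%s'", field)
    }
    for (p in c(cfg$inputs$genes, cfg$inputs$expression,
                unlist(cfg$inputs$tags))) {
      if (!file.exists(p)) fail("input path does not exist: %s", p)
    }
  }
  with_thresh <- c(cfg$diff$p_cutoff, cfg$diff$fold_change,
                   cfg$diff$min_reads, cfg$expression$rest_threshold,
                   cfg$expression$induced_threshold, cfg$windows$upstream,
                   cfg$windows$downstream, cfg$windows$promoter_flank)
  if (any(with_thresh <= 0)) fail("all thresholds must be positive")
  class(cfg) <- "PipelineConfig"
  cfg
}

pipeline_load_inputs <- function(cfg) {
  ref <- cfg$cell_types[1]; tgt <- cfg$cell_types[2]
  if (is.null(cfg$inputs)) {
    sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                     cfg$sim))
    sim <- simulate_genome(sim_cfg)
    expr <- simulate_expression(sim$truth, sim_cfg)
    tags <- list()
    for (ct in cfg$cell_types) {
      natural <- expected_tag_count(sim$truth, sim_cfg, ct)
      factors <- cfg$depth_factors[[ct]] %||% c(1, 1)
      tags[[ct]] <- lapply(seq_along(factors), function(r) {
        d <- if (factors[r] == 1) NULL else natural * factors[r]
        simulate_chip_tags(sim$truth, sim_cfg, ct, r, depth = d)
      })
    }
    chroms <- sim_chromosomes(sim_cfg)
    list(genes = sim$annotation, truth = sim$truth, expr = expr,
         tags = tags,
         chrom_lengths = stats::setNames(rep(sim_cfg$chrom_length,
                                             length(chroms)), chroms),
         sim_cfg = sim_cfg)
  } else {
    genes <- read_genes(cfg$inputs$genes)
    expr <- read_expression(cfg$inputs$expression)
    tags <- lapply(cfg$inputs$tags, function(paths) lapply(paths, read_tags))
    chrom_lengths <- unlist(cfg$inputs$chrom_lengths)
    check_chrom_compatibility(unlist(lapply(tags[[ref]], function(t) t$chrom)),
                              genes$chrom)
    list(genes = genes, truth = NULL, expr = expr, tags = tags,
         chrom_lengths = chrom_lengths, sim_cfg = NULL)
  }
}

#' Run the poising analysis pipeline
#'
#' Stages: (1) simulate or load tags, genes and expression; (2) call
#' islands per sample; (3) per replicate, test islands for differential
#' strength between the reference and target cell types with M-A
#' normalization; (4) link passing islands to gene windows and combine the
#' replicates; (5) group inducible genes by relative induction and
#' summarize gains/losses per group; (6) find replicate-consistent
#' promoter-level changes and their expression consequences. In simulation
#' mode the report also contains recovery metrics against the planted
#' ground truth.
#'
#' @param config a [pipeline_config()] (or arguments for one, e.g. a YAML
#'   path).
#' @return a list of class `"poising_report"` with elements `report` (the
#'   JSON-serializable summary), `links`, `gene_status`, `groups`,
#'   `summary`, `promoter_status`, `consequences`, `diff` (per replicate),
#'   and `truth` (simulation mode).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- pipeline_config(config)
  cfg <- config
  ref <- cfg$cell_types[1]; tgt <- cfg$cell_types[2]
  inp <- pipeline_load_inputs(cfg)

  frag <- if (!is.null(inp$sim_cfg)) inp$sim_cfg$fragment_length else 150L
  isl <- lapply(inp$tags, function(reps) lapply(reps, function(t) {
    call_islands(t, inp$chrom_lengths, window = cfg$islands$window,
                 gap = cfg$islands$gap, p_threshold = cfg$islands$p_threshold,
                 fragment_length = frag)
  }))

  n_rep <- min(length(inp$tags[[ref]]), length(inp$tags[[tgt]]))
  diffs <- lapply(seq_len(n_rep), function(r) {
    differential_islands(inp$tags[[ref]][[r]], inp$tags[[tgt]][[r]],
                         isl[[ref]][[r]], isl[[tgt]][[r]],
                         fragment_length = frag,
                         p_cutoff = cfg$diff$p_cutoff,
                         fold_change = cfg$diff$fold_change,
                         min_reads = cfg$diff$min_reads)
  })

  links <- lapply(diffs, function(d) {
    link_islands_to_genes(d, inp$genes, upstream = cfg$windows$upstream,
                          downstream = cfg$windows$downstream)
  })
  gene_status <- if (n_rep >= 2) combine_replicate_status(links[[1]],
                                                          links[[2]])
                 else links[[1]][, c("gene_id", "status")]

  groups <- induction_groups(inp$expr, time = cfg$expression$time,
                             rest_threshold = cfg$expression$rest_threshold,
                             induced_threshold = cfg$expression$induced_threshold)
  summary_tab <- poising_summary(gene_status, groups)

  promoter_status <- if (n_rep >= 2)
    promoter_differential(diffs[[1]], diffs[[2]], inp$genes,
                          flank = cfg$windows$promoter_flank)
  else link_islands_to_genes(diffs[[1]], inp$genes,
                             upstream = cfg$windows$promoter_flank,
                             downstream = cfg$windows$promoter_flank,
                             orient = "genome")[, c("gene_id", "status")]
  consequences <- consequence_matrix(promoter_status, inp$expr,
                                     cell_mem = tgt,
                                     time = cfg$expression$time)

  report <- list(
    seed = cfg$seed,
    cell_types = cfg$cell_types,
    n_genes = nrow(inp$genes),
    n_tags = lapply(inp$tags, function(reps)
      vapply(reps, nrow, integer(1))),
    n_islands = lapply(isl, function(reps)
      vapply(reps, nrow, integer(1))),
    n_inducible = nrow(groups),
    induction_groups = as.list(table(factor(groups$group,
                                            levels = c("naive_specific",
                                                       "tem_specific",
                                                       "shared")))),
    poising_summary = summary_tab,
    promoter = list(gained = sum(promoter_status$status == "gained"),
                    lost = sum(promoter_status$status == "lost")),
    consequences = as.list(table(consequences$categories$category)))

  if (!is.null(inp$truth)) {
    report$recovery <- recovery_metrics(inp$truth, gene_status, groups)
  }

  out <- list(report = report, links = links, gene_status = gene_status,
              groups = groups, summary = summary_tab,
              promoter_status = promoter_status,
              consequences = consequences, diff = diffs,
              islands = isl, truth = inp$truth, config = cfg)
  class(out) <- "poising_report"
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, inp, cfg)
  out
}

# Ground-truth recovery: marked poised_TEM genes found as tem_specific with
# a gained island, and spurious gains among constitutive/silent genes.
recovery_metrics <- function(truth, gene_status, groups) {
  g <- truth$genes
  status <- gene_status$status[match(g$gene_id, gene_status$gene_id)]
  group <- groups$group[match(g$gene_id, groups$gene_id)]
  target <- g$class == "poised_TEM" & g$has_island
  recovered <- target & !is.na(group) & group == "tem_specific" &
    status == "gained"
  nonpoised <- g$class %in% c("constitutive", "silent") & !g$has_island |
    (g$class == "constitutive")   # constitutive islands are non-differential
  spurious <- nonpoised & status == "gained"
  list(n_poised_tem_marked = sum(target),
       poised_tem_recovered = sum(recovered),
       poised_tem_recovery = if (sum(target) > 0)
         sum(recovered) / sum(target) else NA_real_,
       n_nonpoised = sum(nonpoised),
       spurious_gains = sum(spurious),
       spurious_gain_rate = if (sum(nonpoised) > 0)
         sum(spurious) / sum(nonpoised) else NA_real_)
}

write_pipeline_outputs <- function(out, inp, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_genes(inp$genes, file.path(cfg$outdir, "genes.tsv"))
  write_expression(inp$expr, file.path(cfg$outdir, "expression.tsv"))
  for (ct in names(out$islands)) {
    for (r in seq_along(out$islands[[ct]])) {
      write_islands(out$islands[[ct]][[r]],
                    file.path(cfg$outdir,
                              sprintf("islands_%s_rep%d.tsv", ct, r)))
    }
  }
  for (r in seq_along(out$diff)) {
    write_islands(out$diff[[r]],
                  file.path(cfg$outdir, sprintf("differential_rep%d.tsv", r)))
  }
  utils::write.table(merge(out$gene_status, out$groups, by = "gene_id",
                           all.x = TRUE),
                     file.path(cfg$outdir, "gene_status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$consequences$categories,
                     file.path(cfg$outdir, "consequences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(gene_id = rownames(out$consequences$matrix),
                           as.data.frame(out$consequences$matrix)),
                     file.path(cfg$outdir, "heatmap_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(out$truth))
    write_ground_truth(out$truth, file.path(cfg$outdir, "ground_truth.json"))
  if (cfg$write_tags && is.null(cfg$inputs)) {
    for (ct in names(inp$tags)) {
      for (r in seq_along(inp$tags[[ct]])) {
        write_tags(inp$tags[[ct]][[r]],
                   file.path(cfg$outdir, sprintf("tags_%s_rep%d.bed", ct, r)))
      }
    }
  }
  jsonlite::write_json(out$report,
                       file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$outdir)
}

#' @export
print.poising_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Poising pipeline report (seed %d): %d genes, %d inducible\n",
              r$seed, r$n_genes, r$n_inducible))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Promoters: %d gained, %d lost (replicate-consistent)\n",
              r$promoter$gained, r$promoter$lost))
  if (!is.null(r$recovery))
    cat(sprintf("Recovery: %.1f%% of marked poised_TEM genes; %.1f%% spurious gains\n",
                100 * r$recovery$poised_tem_recovery,
                100 * r$recovery$spurious_gain_rate))
  invisible(x)
}
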
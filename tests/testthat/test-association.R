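# Gene-window association, poising summaries, promoter replicate logic and
# expression consequences.

fake_diff <- function(chrom, start, end, direction, passes = TRUE) {
  data.frame(chrom = chrom, start = start, end = end, common = FALSE,
             count_ref = 100L, count_tgt = 100L, M = 0, A = 5,
             M_adjusted = ifelse(direction == "gained", 2, -2),
             pvalue = 1e-6, passes = passes, direction = direction,
             stringsAsFactors = FALSE)
}

genes_one <- function(strand, tss = 50000L) {
  data.frame(gene_id = "G1", chrom = "chr1", strand = strand, tss = tss,
             tes = if (strand == "+") tss + 10000L else tss - 10000L,
             isoform_id = "G1.1", stringsAsFactors = FALSE)
}

test_that("association windows respect strand and the 21 kb geometry", {
  wp <- gene_windows(genes_one("+"), 20000, 1000)
  expect_equal(c(wp$start, wp$end), c(30000, 51000))
  wm <- gene_windows(genes_one("-"), 20000, 1000)
  expect_equal(c(wm$start, wm$end), c(49000, 70000))
  expect_equal(wm$end - wm$start, 21000)
  wg <- gene_windows(genes_one("-"), 20000, 1000, orient = "genome")
  expect_equal(c(wg$start, wg$end), c(30000, 51000))
})

test_that("island overlap drives gene status", {
  g <- genes_one("+")
  inside <- fake_diff("chr1", 30500, 31000, "gained")
  outside <- fake_diff("chr1", 51500, 52000, "gained")
  failing <- fake_diff("chr1", 30500, 31000, "unchanged", passes = FALSE)
  expect_equal(link_islands_to_genes(inside, g)$status, "gained")
  expect_equal(link_islands_to_genes(outside, g)$status, "none")
  expect_equal(link_islands_to_genes(failing, g)$status, "none")
  both <- rbind(inside, fake_diff("chr1", 45000, 45400, "lost"))
  expect_equal(link_islands_to_genes(both, g)$status, "both")
})

test_that("linkage matches the all-pairs overlap oracle on random toys", {
  set.seed(61)
  for (rep in 1:5) {
    n_genes <- 50
    genes <- data.frame(gene_id = paste0("G", seq_len(n_genes)),
                        chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                        strand = sample(c("+", "-"), n_genes, TRUE),
                        tss = sample(30000:970000, n_genes),
                        tes = 0L, isoform_id = "i")
    genes$tes <- ifelse(genes$strand == "+", genes$tss + 1000L,
                        genes$tss - 1000L)
    start <- sample(0:995000, 200)
    diff <- fake_diff(sample(c("chr1", "chr2"), 200, TRUE), start,
                      start + sample(200:5000, 200, TRUE),
                      sample(c("gained", "lost"), 200, TRUE))
    diff$passes <- sample(c(TRUE, FALSE), 200, TRUE)
    links <- link_islands_to_genes(diff, genes)
    wins <- gene_windows(genes, 20000, 1000)
    want <- oracle_link_status(diff[diff$passes, ], wins)
    expect_equal(links$status, want)
  }
})

test_that("poising summary reports planted fractions and empty groups", {
  links <- data.frame(gene_id = c("A", "B", "C", "D"),
                      status = c("gained", "gained", "none", "lost"))
  groups <- data.frame(gene_id = c("A", "B", "C", "D"),
                       group = c("tem_specific", "tem_specific",
                                 "naive_specific", "naive_specific"))
  s <- poising_summary(links, groups)
  expect_equal(s$fraction_gained[s$group == "tem_specific"], 1.0)
  expect_equal(s$fraction_gained[s$group == "naive_specific"], 0.0)
  expect_equal(s$fraction_lost[s$group == "naive_specific"], 0.5)
  expect_equal(s$n_genes[s$group == "shared"], 0)
  expect_true(is.na(s$fraction_gained[s$group == "shared"]))
})

test_that("promoter changes require direction-consistent replicates", {
  g <- genes_one("+")
  at_tss <- function(direction) fake_diff("chr1", 49500, 50200, direction)
  away <- fake_diff("chr1", 200000, 200400, "gained")
  # passing in replicate 1 only: excluded
  expect_equal(promoter_differential(at_tss("gained"), away, g)$status,
               "none")
  # passing gained in both: gained
  expect_equal(promoter_differential(at_tss("gained"), at_tss("gained"),
                                     g)$status, "gained")
  # direction conflict: excluded
  expect_equal(promoter_differential(at_tss("gained"), at_tss("lost"),
                                     g)$status, "none")
  expect_equal(promoter_differential(at_tss("lost"), at_tss("lost"),
                                     g)$status, "lost")
})

test_that("expression consequences are categorized by class transitions", {
  expect_equal(consequence_category("silent", "inducible"),
               "increased_inducibility")
  expect_equal(consequence_category("silent", "expressed"),
               "increased_expression")
  expect_equal(consequence_category("expressed", "expressed"), "no_change")
  expect_equal(consequence_category("inducible", "silent"),
               "lost_inducibility")
  expect_equal(consequence_category("expressed", "silent"),
               "lost_expression")
  expect_equal(consequence_category("ambiguous", "expressed"), "no_change")
})

test_that("consequence matrix floors, logs and orders the heatmap input", {
  status <- data.frame(gene_id = c("A", "B", "C"),
                       status = c("gained", "gained", "none"))
  expr <- data.frame(gene_id = c("A", "B", "C"), check.names = FALSE)
  for (ct in c("Naive", "TEM")) {
    for (tp in c("R", "40min", "150min", "15h")) {
      expr[[paste0(ct, ":", tp)]] <- c(0.5, 8, 1)
    }
  }
  expr[["TEM:150min"]] <- c(16, 8, 1)
  out <- consequence_matrix(status, expr)
  expect_equal(nrow(out$categories), 2)          # C (none) dropped
  expect_equal(out$categories$category[out$categories$gene_id == "A"],
               "increased_inducibility")
  expect_equal(out$categories$category[out$categories$gene_id == "B"],
               "no_change")
  expect_equal(out$matrix["A", "TEM:150min"], 4)  # log2(16)
  expect_equal(out$matrix["A", "Naive:R"], 0)     # floored at 1
})

test_that("swapping samples swaps gained and lost gene lists exactly", {
  cfg <- sim_config(seed = 63, n_chromosomes = 1, chrom_length = 2e6,
                    n_genes = 30)
  sim <- simulate_genome(cfg)
  ta <- simulate_chip_tags(sim$truth, cfg, "Naive")
  tb <- simulate_chip_tags(sim$truth, cfg, "TEM")
  L <- c(chr1 = 2e6, chrX = 2e6)
  ia <- call_islands(ta, L); ib <- call_islands(tb, L)
  fwd <- link_islands_to_genes(differential_islands(ta, tb, ia, ib),
                               sim$annotation)
  rev <- link_islands_to_genes(differential_islands(tb, ta, ib, ia),
                               sim$annotation)
  swap <- c(gained = "lost", lost = "gained", both = "both", none = "none")
  expect_equal(unname(swap[fwd$status]), rev$status)
})
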
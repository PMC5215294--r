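# Brute-force reference implementations and toy-data generators used by the
# oracle-equivalence tests. These deliberately share no code with the
# package internals: per-bp loops, per-gene loops, and explicit Poisson pmf
# sums.

# Random BED6 toy tag set on one chromosome.
random_tags <- function(n, chrom_length, chrom = "chr1", read_len = 36L) {
  start <- sample.int(chrom_length - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start, end = start + read_len,
             name = paste0("r", seq_len(n)), score = 0L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Per-bp coverage by looping over every fragment and every covered base.
oracle_coverage <- function(tags, chrom_length, total_mapped,
                            fragment_length) {
  values <- numeric(chrom_length)
  w <- 1e6 / total_mapped
  for (i in seq_len(nrow(tags))) {
    if (tags$strand[i] == "+") {
      fs <- tags$start[i]; fe <- fs + fragment_length
    } else {
      fe <- tags$end[i]; fs <- fe - fragment_length
    }
    fs <- max(fs, 0L); fe <- min(fe, chrom_length)
    if (fe > fs) for (p in (fs + 1):fe) values[p] <- values[p] + w
  }
  values
}

# Unsmoothed metaprofile by looping over genes and tags.
oracle_tss_profile <- function(tags, genes, gene_set, total_mapped, flank,
                               shift, orient = "transcription",
                               sex_weight = 2) {
  counts <- numeric(2 * flank + 1)
  for (gid in gene_set) {
    g <- genes[genes$gene_id == gid, ]
    for (i in seq_len(nrow(tags))) {
      if (tags$chrom[i] != g$chrom) next
      p5 <- if (tags$strand[i] == "+") tags$start[i] + shift
            else (tags$end[i] - 1L) - shift
      rel <- p5 - g$tss
      if (orient == "transcription" && g$strand == "-") rel <- -rel
      if (abs(rel) <= flank) {
        w <- if (g$chrom %in% c("chrX", "chrY", "X", "Y")) sex_weight else 1
        counts[rel + flank + 1] <- counts[rel + flank + 1] + w
      }
    }
  }
  counts / (total_mapped / 1e6) / length(gene_set)
}

# Centered moving average by explicit window loop.
oracle_moving_average <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  hl <- (w - 1) %/% 2; hr <- w %/% 2
  for (i in seq_len(n)) {
    idx <- max(1, i - hl):min(n, i + hr)
    out[i] <- mean(x[idx])
  }
  out
}

# Poisson upper tail P(X >= k) as an explicit pmf partial sum.
oracle_pois_upper <- function(k, lambda) {
  if (k <= 0) return(1)
  1 - sum(dpois(0:(k - 1), lambda))
}

# Island calling by exhaustive window enumeration and loop-based merging,
# one chromosome at a time.
oracle_call_islands <- function(tags, chrom_lengths, window, gap,
                                p_threshold, fragment_length) {
  # extended-fragment midpoints
  mids <- integer(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    if (tags$strand[i] == "+") {
      fs <- tags$start[i]; fe <- fs + fragment_length
    } else {
      fe <- tags$end[i]; fs <- fe - fragment_length
    }
    mids[i] <- (fs + fe) %/% 2
  }
  total_windows <- sum(floor(chrom_lengths / window))
  lambda <- nrow(tags) / total_windows
  out <- NULL
  for (cn in names(chrom_lengths)) {
    nw <- floor(chrom_lengths[[cn]] / window)
    onchrom <- mids[tags$chrom == cn]
    elig <- integer(0)
    wcount <- integer(nw)
    for (wi in seq_len(nw)) {
      lo <- (wi - 1) * window; hi <- wi * window
      k <- sum(onchrom >= lo & onchrom < hi)
      wcount[wi] <- k
      if (oracle_pois_upper(k, lambda) < p_threshold) elig <- c(elig, wi)
    }
    if (length(elig) == 0) next
    # group eligible windows separated by <= gap bp
    cur <- list(first = elig[1], last = elig[1])
    flush <- function(cur) {
      s <- (cur$first - 1) * window; e <- cur$last * window
      k <- sum(onchrom >= s & onchrom < e)
      data.frame(chrom = cn, start = s, end = e, count = k,
                 stringsAsFactors = FALSE)
    }
    for (wi in elig[-1]) {
      if ((wi - cur$last - 1) * window <= gap) cur$last <- wi
      else { out <- rbind(out, flush(cur)); cur <- list(first = wi, last = wi) }
    }
    out <- rbind(out, flush(cur))
  }
  if (is.null(out)) out <- data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      count = integer(0))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# All-pairs gene-window / island overlap.
oracle_link_status <- function(passing, wins) {
  status <- character(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    g <- 0; l <- 0
    for (j in seq_len(nrow(passing))) {
      if (passing$chrom[j] != wins$chrom[i]) next
      if (passing$start[j] < wins$end[i] && passing$end[j] > wins$start[i]) {
        if (passing$direction[j] == "gained") g <- g + 1 else l <- l + 1
      }
    }
    status[i] <- if (g > 0 && l > 0) "both" else if (g > 0) "gained"
                 else if (l > 0) "lost" else "none"
  }
  status
}

# A small default simulation shared by several tests.
small_sim_config <- function(...) {
  args <- utils::modifyList(list(seed = 1, n_chromosomes = 1,
                                 chrom_length = 1.5e6, n_genes = 25),
                            list(...))
  do.call(sim_config, args)
}
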
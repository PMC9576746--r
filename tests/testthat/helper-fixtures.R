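# shared fixture builders; everything is generated in code, no stored files

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# bedGraph fixture from a data.frame(chrom, start, end, value)
write_bedgraph_tmp <- function(df) {
  write_lines_tmp(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                          format(df$value, scientific = FALSE)),
                  ext = ".bedgraph")
}

make_track <- function(chrom, start, end, value) {
  read_signal(write_bedgraph_tmp(
    data.frame(chrom = chrom, start = start, end = end, value = value)))
}

# independent per-base summation oracle for signal queries
naive_signal_sum <- function(df, chrom, qs, qe) {
  d <- df[df$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0L || qe <= qs) return(0)
  base <- rep(0, qe - qs)
  for (i in seq_len(nrow(d))) {
    lo <- max(d$start[i], qs); hi <- min(d$end[i], qe)
    if (hi > lo) base[(lo - qs + 1):(hi - qs)] <-
        base[(lo - qs + 1):(hi - qs)] + d$value[i]
  }
  sum(base)
}

# exhaustive scan oracle for the scaled rank-curve cutoff
brute_cutoff <- function(densities) {
  y <- sort(densities)
  n <- length(y)
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    yh <- (y[i] - y[1]) / (y[n] - y[1])
    if (x - yh > best) { best <- x - yh; best_i <- i }
  }
  y[best_i]
}

# tiny gene table
make_genes <- function(tss, chrom = "chr1", ids = NULL) {
  n <- length(tss)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(n))
  data.frame(gene_id = ids, symbol = toupper(ids), chrom = chrom,
             strand = "+", tss = tss, stringsAsFactors = FALSE)
}

# a synthetic 3-pair mini cohort for pipeline plumbing tests
mini_cohort <- function(dir, seed = 42) {
  cfg <- cohort_config(
    n_pairs = 3, n_genes = 40, n_background_peaks = 25,
    planted = default_planted(n_tumor_gained = 4, n_shared = 4,
                              n_normal_only = 2, recurrence_k = 3),
    genome = data.frame(chrom = "chr1", length = 2e6),
    seed = seed)
  simulate_cohort(cfg, dir)
}
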
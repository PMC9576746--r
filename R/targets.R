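#' Candidate genes for a super-enhancer locus
#'
#' Genes on the locus chromosome whose TSS lies within `window` bp of the
#' locus center (inclusive at exactly `window`; strand ignored), and whose
#' mean TPM across the used samples exceeds `expr_floor`.
#'
#' @param locus 1-row interval `data.frame` (or list with `chrom`, `start`,
#'   `end`).
#' @param genes gene annotation `data.frame`.
#' @param expression TPM matrix from [read_expression()].
#' @param window TSS-to-center distance in bp (default 500000).
#' @param expr_floor minimum mean TPM (default 2).
#' @param samples sample ids defining the columns used for the mean
#'   (default: all columns).
#' @return subset of `genes`, with an added `tss_distance` column.
#' @export
candidate_genes <- function(locus, genes, expression, window = 500000,
                            expr_floor = 2.0, samples = NULL) {
  center <- floor((locus$start + locus$end) / 2)
  near <- genes$chrom == locus$chrom & abs(genes$tss - center) <= window
  out <- genes[near, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  if (is.null(samples)) samples <- colnames(expression)
  expr <- expression[, samples, drop = FALSE]
  present <- out$gene_id %in% rownames(expr)
  out <- out[present, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  keep <- rowMeans(expr[out$gene_id, , drop = FALSE]) > expr_floor
  out <- out[keep, , drop = FALSE]
  out$tss_distance <- abs(out$tss - center)
  out
}

#' Regress gene expression on super-enhancer signal
#'
#' Ordinary least squares of expression on signal across matched samples;
#' `r` is the Pearson correlation and the two-sided P comes from
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees of freedom
#' (identical to the slope test). Zero variance in either vector yields a
#' degenerate result with `p = 1`.
#'
#' @param se_signal numeric vector of per-sample SE densities.
#' @param expr numeric vector of per-sample TPM (same sample order).
#' @return list with `slope`, `intercept`, `r`, `t_stat`, `p_value`,
#'   `n_samples`, `degenerate`.
#' @export
correlate_se_gene <- function(se_signal, expr) {
  n <- length(se_signal)
  if (length(expr) != n) stop("vectors must have equal length",
                              call. = FALSE)
  if (n < 3L) stop("need >= 3 matched samples", call. = FALSE)
  vx <- var(se_signal); vy <- var(expr)
  if (vx == 0 || vy == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                t_stat = NA_real_, p_value = 1.0, n_samples = n,
                degenerate = TRUE))
  }
  cxy <- cov(se_signal, expr)
  slope <- cxy / vx
  r <- cxy / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  if (abs(r) < 1) {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t_stat), n - 2)
  } else {
    t_stat <- Inf * sign(r)
    p <- 0
  }
  list(slope = slope, intercept = mean(expr) - slope * mean(se_signal),
       r = r, t_stat = t_stat,
       p_value = max(p, .Machine$double.xmin), n_samples = n,
       degenerate = FALSE)
}

#' Assign target gene(s) to one locus
#'
#' Regresses every candidate gene's expression on the locus signal;
#' significant genes are those with `p < alpha`, and the assigned target is
#' the most significant (ties broken by larger `|r|`, then gene id).
#'
#' @param locus 1-row locus `data.frame` carrying `locus_id`.
#' @param genes,expression,window,expr_floor see [candidate_genes()].
#' @param signal_row named numeric vector of the locus's per-sample
#'   densities.
#' @param samples sample ids used (intersection of assays).
#' @param alpha significance threshold on raw P (default 0.05).
#' @return list with `locus_id`, `candidates` (per-gene regression stats,
#'   ascending p), `assigned`, `all_significant`.
#' @export
assign_targets <- function(locus, signal_row, genes, expression,
                           samples, alpha = 0.05, window = 500000,
                           expr_floor = 2.0) {
  cand <- candidate_genes(locus, genes, expression, window = window,
                          expr_floor = expr_floor, samples = samples)
  if (nrow(cand) == 0L) {
    return(list(locus_id = locus$locus_id,
                candidates = data.frame(), assigned = NA_character_,
                all_significant = character()))
  }
  x <- signal_row[samples]
  stats <- lapply(cand$gene_id, function(g) {
    correlate_se_gene(x, expression[g, samples])
  })
  tab <- data.frame(gene_id = cand$gene_id,
                    symbol = cand$symbol,
                    tss_distance = cand$tss_distance,
                    slope = vapply(stats, `[[`, 0, "slope"),
                    r = vapply(stats, `[[`, 0, "r"),
                    t_stat = vapply(stats, `[[`, 0, "t_stat"),
                    p_value = vapply(stats, `[[`, 0, "p_value"),
                    n_samples = length(samples),
                    stringsAsFactors = FALSE)
  tab$q_value <- p.adjust(tab$p_value, method = "BH")
  tab <- tab[order(tab$p_value, -abs(tab$r), tab$gene_id), , drop = FALSE]
  sig <- tab$gene_id[tab$p_value < alpha]
  list(locus_id = locus$locus_id, candidates = tab,
       assigned = if (length(sig)) sig[1L] else NA_character_,
       all_significant = sig)
}

#' Assign targets for every catalog locus
#'
#' Uses the samples present in both the signal matrix and the expression
#' matrix (optionally restricted to one manifest group).
#'
#' @param catalog an `se_catalog`.
#' @param matrix an `se_signal_matrix` (normalized).
#' @param genes gene annotations.
#' @param expression TPM matrix.
#' @param alpha,window,expr_floor see [assign_targets()].
#' @param samples optional explicit sample subset.
#' @return object of class `se_assignments`: `data.frame` with one row per
#'   locus (`locus_id`, `n_candidates`, `assigned`, `assigned_symbol`,
#'   `assigned_p`, `assigned_r`, `n_significant`, `all_significant`
#'   comma-separated, `n_samples`); per-locus detail in attribute
#'   `details`.
#' @export
assign_all <- function(catalog, matrix, genes, expression, alpha = 0.05,
                       window = 500000, expr_floor = 2.0, samples = NULL) {
  if (is.null(samples)) {
    samples <- intersect(colnames(matrix$values), colnames(expression))
  }
  if (length(samples) < 3L) {
    stop("need >= 3 samples with both ChIP and RNA assays", call. = FALSE)
  }
  loci <- catalog$loci
  res <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    res[[i]] <- assign_targets(loci[i, , drop = FALSE],
                               matrix$values[i, ], genes, expression,
                               samples = samples, alpha = alpha,
                               window = window, expr_floor = expr_floor)
  }
  pick <- function(a, field, default) {
    if (is.na(a$assigned) || nrow(a$candidates) == 0L) return(default)
    a$candidates[[field]][match(a$assigned, a$candidates$gene_id)]
  }
  out <- data.frame(
    locus_id = loci$locus_id,
    n_candidates = vapply(res, function(a) nrow(a$candidates), 0L),
    assigned = vapply(res, function(a) a$assigned, ""),
    assigned_symbol = vapply(res, pick, "", field = "symbol",
                             default = NA_character_),
    assigned_p = vapply(res, pick, 0, field = "p_value",
                        default = NA_real_),
    assigned_r = vapply(res, pick, 0, field = "r", default = NA_real_),
    n_significant = vapply(res, function(a) length(a$all_significant), 0L),
    all_significant = vapply(res, function(a)
      paste(a$all_significant, collapse = ","), ""),
    n_samples = length(samples),
    stringsAsFactors = FALSE)
  attr(out, "details") <- res
  class(out) <- c("se_assignments", "data.frame")
  out
}

#' @export
print.se_assignments <- function(x, ...) {
  cat("se_assignments:", nrow(x), "loci;",
      sum(!is.na(x$assigned)), "assigned a target (P <0.05),",
      sum(is.na(x$assigned)), "unassigned\n")
  invisible(x)
}
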
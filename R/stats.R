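#' Differential super-enhancer statistics between two groups
#'
#' Per consensus locus, a pooled-variance two-sample two-sided Student's
#' t-test on (normalized) densities, plus
#' `log2fc = log2((mean_a + eps) / (mean_b + eps))`. The matched design
#' notwithstanding, the unpaired test is the default; set `paired = TRUE`
#' for a paired t-test over samples matched by position in `group_a` /
#' `group_b`. With `lfc_mode = "paired"`, log2fc is instead the mean of
#' per-pair log2 ratios. Benjamini-Hochberg q-values are reported but never
#' used for selection.
#'
#' @param matrix an `se_signal_matrix` (normalized).
#' @param group_a,group_b character vectors of sample ids (columns of the
#'   matrix). Group a is the numerator of the fold change.
#' @param eps pseudocount in density units (default 0.1).
#' @param paired use a paired t-test (ids matched by position).
#' @param lfc_mode `"group_means"` (default, log2 of ratio of group means)
#'   or `"paired"` (mean per-pair log2 ratio).
#' @return `data.frame` with one row per locus: `locus_id`, `mean_a`,
#'   `mean_b`, `log2fc`, `t_stat`, `p_value`, `q_value`.
#' @export
differential_ses <- function(matrix, group_a, group_b, eps = 0.1,
                             paired = FALSE,
                             lfc_mode = c("group_means", "paired")) {
  stopifnot(inherits(matrix, "se_signal_matrix"))
  lfc_mode <- match.arg(lfc_mode)
  v <- matrix$values
  miss <- setdiff(c(group_a, group_b), colnames(v))
  if (length(miss)) stop("sample(s) not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  a <- v[, group_a, drop = FALSE]
  b <- v[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group", call. = FALSE)
  ma <- rowMeans(a); mb <- rowMeans(b)
  if (paired) {
    if (na != nb) stop("paired test requires equal group sizes",
                       call. = FALSE)
    d <- a - b
    md <- rowMeans(d)
    sd2 <- apply(d, 1L, var)
    se <- sqrt(sd2 / na)
    t_stat <- ifelse(se > 0, md / se, ifelse(md == 0, 0, Inf * sign(md)))
    df <- na - 1L
  } else {
    va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t_stat <- ifelse(se > 0, (ma - mb) / se,
                     ifelse(ma == mb, 0, Inf * sign(ma - mb)))
    df <- na + nb - 2L
  }
  p <- ifelse(is.finite(t_stat), 2 * pt(-abs(t_stat), df),
              .Machine$double.xmin)
  p[t_stat == 0 & se == 0] <- 1.0
  lfc <- if (lfc_mode == "group_means") {
    log2((ma + eps) / (mb + eps))
  } else {
    rowMeans(log2((a + eps) / (b + eps)))
  }
  data.frame(locus_id = rownames(v), mean_a = ma, mean_b = mb,
             log2fc = lfc, t_stat = t_stat, p_value = p,
             q_value = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank differential results by fold change
#'
#' Descending by `log2fc`; ties broken by ascending `p_value`, then
#' `locus_id`.
#'
#' @param results output of [differential_ses()].
#' @return the reordered `data.frame`.
#' @export
rank_by_fold_change <- function(results) {
  if (nrow(results) == 0L) return(results)
  results[order(-results$log2fc, results$p_value, results$locus_id), ,
          drop = FALSE]
}

#' Select significantly divergent loci
#'
#' Raw-P selection (`p < max_p`, strict) with a fold-change threshold in the
#' stated direction; q-values are informational only.
#'
#' @param results output of [differential_ses()].
#' @param max_p significance threshold on raw P.
#' @param min_abs_lfc fold-change magnitude threshold (log2 units).
#' @param direction `"both"` (|lfc| > threshold), `"up"` (lfc > threshold)
#'   or `"down"` (lfc < -threshold).
#' @return the selected rows.
#' @export
select_divergent <- function(results, max_p = 0.01, min_abs_lfc = 1.0,
                             direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- results$p_value < max_p & switch(direction,
    both = abs(results$log2fc) > min_abs_lfc,
    up = results$log2fc > min_abs_lfc,
    down = results$log2fc < -min_abs_lfc)
  results[keep, , drop = FALSE]
}

#' Per-locus recurrence within a sample group
#'
#' `k` of `n`: the number of group samples whose own SE call overlaps the
#' consensus locus.
#'
#' @param catalog an `se_catalog`.
#' @param manifest manifest `data.frame`.
#' @param group group label (e.g. `"tumor"`).
#' @return named integer vector (locus_id -> k) with attribute `n_group`.
#' @export
recurrence_counts <- function(catalog, manifest, group) {
  ids <- manifest_samples(manifest, group)
  ids <- intersect(ids, colnames(catalog$membership))
  k <- rowSums(catalog$membership[, ids, drop = FALSE])
  structure(as.integer(k), names = rownames(catalog$membership),
            n_group = length(ids))
}

#' Cumulative unique-SE discovery (saturation) curve
#'
#' Adds the group's samples in the given acquisition order and counts the
#' distinct consensus loci discovered so far (membership true in at least
#' one of the first k samples). Fractions are relative to the full-group
#' count; the final cumulative count is order-invariant.
#'
#' @param catalog an `se_catalog`.
#' @param manifest manifest `data.frame`.
#' @param group group label.
#' @param order optional permutation of the group's sample ids (default:
#'   manifest order).
#' @return object of class `saturation_curve`: `data.frame` with
#'   `sample_id`, `cumulative_unique`, `fraction_of_final`.
#' @export
saturation_curve <- function(catalog, manifest, group, order = NULL) {
  ids <- manifest_samples(manifest, group)
  if (is.null(order)) order <- ids
  if (!setequal(order, ids) || length(order) != length(ids)) {
    stop("order must be a permutation of the group's sample ids",
         call. = FALSE)
  }
  memb <- catalog$membership[, order, drop = FALSE]
  seen <- rep(FALSE, nrow(memb))
  cum <- integer(length(order))
  for (k in seq_along(order)) {
    seen <- seen | memb[, k]
    cum[k] <- sum(seen)
  }
  final <- cum[length(cum)]
  out <- data.frame(sample_id = order, cumulative_unique = cum,
                    fraction_of_final = if (final > 0) cum / final
                    else rep(NA_real_, length(cum)),
                    stringsAsFactors = FALSE)
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Saturation index of a discovery curve
#'
#' @param curve a `saturation_curve`.
#' @param theta target fraction of the final unique count (default 0.95).
#' @return smallest number of samples k whose cumulative discovery fraction
#'   reaches `theta`.
#' @export
saturation_index <- function(curve, theta = 0.95) {
  hit <- which(curve$fraction_of_final >= theta)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

#' Prioritize candidate loci by ranking and recurrence
#'
#' Intersects the first `top_n` fold-change-ranked loci with loci recurrent
#' in at least `min_k` group samples, in ranked order.
#'
#' @param ranked output of [rank_by_fold_change()].
#' @param recurrence named vector from [recurrence_counts()].
#' @param top_n number of top-ranked loci to consider (default 100).
#' @param min_k minimum recurrence (default 9).
#' @return character vector of locus ids with attribute `provenance`.
#' @export
prioritize_candidates <- function(ranked, recurrence, top_n = 100,
                                  min_k = 9) {
  if (top_n > nrow(ranked)) {
    warning("top_n exceeds number of loci; using all ", nrow(ranked),
            call. = FALSE)
    top_n <- nrow(ranked)
  }
  top <- ranked$locus_id[seq_len(top_n)]
  recurrent <- names(recurrence)[recurrence >= min_k]
  structure(top[top %in% recurrent],
            provenance = list(top_n = top_n, min_k = min_k))
}

#' Row-wise z-score a matrix
#'
#' Figure-ready transform: each row is centred to mean 0 and scaled to
#' standard deviation 1. Zero-variance rows become all-zero with a warning.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) set to 0", call. = FALSE)
    sdv[zero] <- 1
  }
  out <- (m - mu) / sdv
  out[zero, ] <- 0
  out
}
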
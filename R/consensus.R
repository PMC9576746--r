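#' Build a cross-sample consensus super-enhancer catalog
#'
#' Consensus loci are the single-linkage merge (>= 1 bp overlap, book-ended
#' included) of every sample's SE intervals, pooled across all groups. A
#' sample is a member of a locus iff one of its own SE calls overlaps the
#' locus by at least 1 bp -- i.e. the locus met ROSE SE criteria in that
#' sample.
#'
#' @param calls list of `se_call` objects.
#' @return object of class `se_catalog`: list with `loci` (sorted, disjoint
#'   interval `data.frame` with `locus_id`), `membership` (loci x samples
#'   logical matrix) and `samples`.
#' @export
build_consensus <- function(calls) {
  stopifnot(length(calls) > 0L)
  samples <- vapply(calls, function(x) x$sample_id, "")
  ses <- lapply(calls, function(x) {
    x$regions[x$regions$is_super, c("chrom", "start", "end"), drop = FALSE]
  })
  pooled <- do.call(rbind, ses)
  if (is.null(pooled) || nrow(pooled) == 0L) {
    warning("no super-enhancers in any sample; empty catalog", call. = FALSE)
    loci <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), locus_id = character())
    memb <- matrix(FALSE, 0L, length(samples),
                   dimnames = list(NULL, samples))
    return(structure(list(loci = loci, membership = memb, samples = samples),
                     class = "se_catalog"))
  }
  loci <- merge_intervals(pooled)
  loci$locus_id <- locus_ids(loci)
  gr <- .gi_to_gr(loci)
  memb <- matrix(FALSE, nrow(loci), length(samples),
                 dimnames = list(loci$locus_id, samples))
  for (k in seq_along(calls)) {
    if (nrow(ses[[k]]) == 0L) next
    hits <- GenomicRanges::findOverlaps(.gi_to_gr(ses[[k]]), gr)
    memb[unique(S4Vectors::subjectHits(hits)), k] <- TRUE
  }
  structure(list(loci = loci, membership = memb, samples = samples),
            class = "se_catalog")
}

#' @export
print.se_catalog <- function(x, ...) {
  cat("se_catalog:", nrow(x$loci), "consensus loci across",
      length(x$samples), "samples\n")
  if (nrow(x$loci)) {
    cat("  mean recurrence:",
        format(mean(rowSums(x$membership)), digits = 4), "samples/locus\n")
  }
  invisible(x)
}

#' Quantify the consensus catalog across samples
#'
#' Entry `(l, s)` is the RPKM-like density of locus `l` in sample `s`
#' (control-subtracted when the manifest provides a control track).
#'
#' @param catalog an `se_catalog`.
#' @param manifest manifest `data.frame`.
#' @param tracks optional named list of preloaded `signal_track`s (and
#'   `control_tracks`), to avoid re-reading files.
#' @param control_tracks optional named list of control `signal_track`s.
#' @return object of class `se_signal_matrix`: list with `values` (loci x
#'   samples numeric matrix), `normalized = FALSE`, `scale_factors = NULL`.
#' @export
quantify_matrix <- function(catalog, manifest, tracks = NULL,
                            control_tracks = NULL) {
  loci <- catalog$loci
  vals <- matrix(NA_real_, nrow(loci), nrow(manifest),
                 dimnames = list(loci$locus_id, manifest$sample_id))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    trk <- if (!is.null(tracks)) tracks[[sid]] else {
      if (!file.exists(manifest$signal_path[i])) {
        stop("signal track missing for sample ", sid, call. = FALSE)
      }
      read_signal(manifest$signal_path[i])
    }
    ctl <- if (!is.null(control_tracks)) control_tracks[[sid]] else {
      if (!is.na(manifest$control_path[i]))
        read_signal(manifest$control_path[i])
    }
    vals[, i] <- quantify_density(loci, trk, ctl)
  }
  structure(list(values = vals, normalized = FALSE, scale_factors = NULL),
            class = "se_signal_matrix")
}

#' @export
print.se_signal_matrix <- function(x, ...) {
  cat("se_signal_matrix:", nrow(x$values), "loci x", ncol(x$values),
      "samples;", if (x$normalized) "promoter-normalized" else "raw", "\n")
  invisible(x)
}

#' Promoter-normalize a signal matrix
#'
#' Computes each sample's mean density over promoter windows
#' `[tss - w, tss + w)` and rescales its column by
#' `median(promoter means) / own promoter mean`, so that after scaling all
#' samples share the cohort-median promoter mean. Promoter activity is
#' comparatively invariant across samples, making it a robust per-sample
#' scale reference; within-sample rank order of loci is preserved.
#'
#' @param matrix an `se_signal_matrix` (raw).
#' @param manifest manifest `data.frame`.
#' @param genes gene annotations supplying TSS positions.
#' @param promoter_window half-width in bp (default 1000).
#' @param tracks optional named list of preloaded `signal_track`s.
#' @return the matrix with scaled columns, `normalized = TRUE` and
#'   per-sample `scale_factors`.
#' @export
promoter_normalize <- function(matrix, manifest, genes,
                               promoter_window = 1000, tracks = NULL) {
  stopifnot(inherits(matrix, "se_signal_matrix"))
  if (nrow(genes) < 10L) {
    stop("need >= 10 promoters to estimate scale factors", call. = FALSE)
  }
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - promoter_window),
                     end = genes$tss + promoter_window)
  pm <- vapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$sample_id[i]
    trk <- if (!is.null(tracks)) tracks[[sid]] else
      read_signal(manifest$signal_path[i])
    mean(quantify_density(prom, trk))
  }, 0)
  names(pm) <- manifest$sample_id
  if (any(pm <= 0)) {
    stop("zero promoter signal for sample(s): ",
         paste(names(pm)[pm <= 0], collapse = ", "), call. = FALSE)
  }
  sf <- median(pm) / pm
  cols <- colnames(matrix$values)
  matrix$values <- sweep(matrix$values, 2L, sf[cols], `*`)
  matrix$normalized <- TRUE
  matrix$scale_factors <- sf[cols]
  matrix
}

#' Fraction of total enhancer signal mass residing in super-enhancers
#'
#' Mass is density x region length; the statistic is SE mass over the mass
#' of all stitched regions, in `[0, 1]`.
#'
#' @param call an `se_call`.
#' @return a single fraction.
#' @export
fraction_signal_in_ses <- function(call) {
  r <- call$regions
  if (nrow(r) == 0L) stop("call has no regions", call. = FALSE)
  mass <- r$density * (r$end - r$start)
  total <- sum(mass)
  if (total <= 0) stop("zero total signal mass; fraction undefined",
                       call. = FALSE)
  sum(mass[r$is_super]) / total
}

#' Write catalog, membership and signal matrix tables
#'
#' @param catalog an `se_catalog`.
#' @param matrix optional `se_signal_matrix`.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_catalog <- function(catalog, matrix = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- catalog$loci
  loci$name <- loci$locus_id
  loci$score <- rowSums(catalog$membership)
  paths <- c(bed = file.path(dir, "catalog.bed"),
             membership = file.path(dir, "membership.tsv"))
  write_bed(loci, paths[["bed"]])
  memb <- data.frame(locus_id = rownames(catalog$membership),
                     catalog$membership + 0L, check.names = FALSE)
  write.table(memb, paths[["membership"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(matrix)) {
    p <- file.path(dir, if (matrix$normalized)
      "signal_matrix_normalized.tsv" else "signal_matrix_raw.tsv")
    tab <- data.frame(locus_id = rownames(matrix$values), matrix$values,
                      check.names = FALSE)
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, matrix = p)
  }
  invisible(paths)
}
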
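#' Remove peaks overlapping promoter windows
#'
#' A peak is dropped entirely if it overlaps any window
#' `[tss - tss_window, tss + tss_window)`; peaks are never trimmed,
#' mirroring ROSE's whole-peak exclusion. Input order is preserved.
#'
#' @param peaks interval `data.frame` of enhancer peaks.
#' @param genes gene annotation `data.frame` (see [read_gene_table()]).
#' @param tss_window half-width of the promoter window in bp (ROSE default
#'   2500).
#' @return the retained peaks.
#' @export
exclude_promoter_peaks <- function(peaks, genes, tss_window = 2500) {
  if (tss_window < 0) stop("tss_window must be >= 0", call. = FALSE)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(peaks)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - tss_window),
                     end = genes$tss + tss_window + 1)
  # window 0 degenerates to the single TSS base [tss, tss+1)
  if (tss_window == 0) prom$end <- genes$tss + 1
  hits <- GenomicRanges::findOverlaps(.gi_to_gr(peaks), .gi_to_gr(prom))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
}

#' Stitch peaks within a gap threshold into regions
#'
#' Per chromosome, sorted peaks are single-linkage chained whenever the gap
#' between consecutive peaks is `<= stitch_gap` (inclusive boundary:
#' "within 12.5 kb" stitches a gap of exactly 12500). Every input peak lands
#' in exactly one stitched region.
#'
#' @param peaks interval `data.frame`.
#' @param stitch_gap maximum gap in bp across which peaks are joined.
#' @return `data.frame` with columns `chrom`, `start`, `end`,
#'   `n_constituents` and a list-column `constituents` holding each region's
#'   member peaks; sorted by position.
#' @export
stitch_peaks <- function(peaks, stitch_gap = 12500) {
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer()))
  }
  validate_intervals(peaks, "peak")
  gr <- .gi_to_gr(peaks)
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = stitch_gap + 1)
  hits <- GenomicRanges::findOverlaps(gr, red)
  regions <- .gr_to_gi(red)
  memb <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  const <- vector("list", nrow(regions))
  for (k in seq_along(memb)) {
    i <- as.integer(names(memb)[k])
    rows <- peaks[memb[[k]], c("chrom", "start", "end"), drop = FALSE]
    const[[i]] <- rows[order(rows$start), , drop = FALSE]
  }
  regions$n_constituents <- vapply(const, nrow, 0L)
  regions$constituents <- I(const)
  regions
}

#' RPKM-like signal density of regions
#'
#' `density = max(0, rpkm(signal) - rpkm(control))` where
#' `rpkm(t) = (coverage / (length/1000)) / (total_signal(t) / 1e6)`.
#' Background subtraction is floored at zero so densities stay rankable.
#'
#' @param regions interval `data.frame` (any number of rows).
#' @param signal a `signal_track`.
#' @param control optional matched input `signal_track`.
#' @return numeric vector of densities, one per region.
#' @export
quantify_density <- function(regions, signal, control = NULL) {
  if (signal$total_signal <= 0) {
    stop("signal track has zero total signal", call. = FALSE)
  }
  rpkm <- function(track) {
    cov <- signal_query(track, regions$chrom, regions$start, regions$end)
    (cov / ((regions$end - regions$start) / 1000)) /
      (track$total_signal / 1e6)
  }
  d <- rpkm(signal)
  if (!is.null(control)) {
    if (control$total_signal <= 0) {
      stop("control track has zero total signal", call. = FALSE)
    }
    d <- d - rpkm(control)
  }
  pmax(0, d)
}

#' Rank-curve inflection cutoff (ROSE geometric criterion)
#'
#' Densities are sorted ascending and both axes scaled to `[0, 1]`:
#' `x_i = i/(n-1)`, `y_hat_i = (y_i - y_min)/(y_max - y_min)`. The cutoff is
#' the unscaled density at the index maximizing `x_i - y_hat_i` -- the point
#' of maximum vertical distance below the diagonal, equivalent to the
#' tangent-slope-1 point for a convex rank curve. Ties take the smallest
#' index (more regions called super, conservative for discovery).
#'
#' @param densities numeric vector, `n >= 3`, non-negative, not all equal.
#' @return the cutoff density; regions with density strictly above it are
#'   super-enhancers.
#' @export
find_cutoff <- function(densities) {
  n <- length(densities)
  if (n < 3L) stop("need at least 3 densities to locate a cutoff",
                   call. = FALSE)
  if (any(densities < 0)) stop("densities must be non-negative",
                               call. = FALSE)
  y <- sort(densities)
  if (y[n] == y[1L]) {
    stop("degenerate input: all densities equal, no inflection exists",
         call. = FALSE)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  yhat <- (y - y[1L]) / (y[n] - y[1L])
  y[which.max(x - yhat)]
}

#' Call super-enhancers for one sample
#'
#' Composes promoter exclusion, stitching, density quantification and the
#' rank-curve cutoff into a per-sample call. Regions with density strictly
#' above the cutoff are labelled super-enhancers; the rest are typical
#' enhancers. The SE/TE split is invariant to rescaling all signal by a
#' positive constant.
#'
#' @param peaks interval `data.frame` of enhancer peaks.
#' @param signal `signal_track` of H3K27ac coverage.
#' @param genes gene annotations for promoter exclusion (`NULL` disables it).
#' @param control optional input-control `signal_track`.
#' @param sample_id label recorded in the result.
#' @param stitch_gap,tss_window stitching and promoter-window parameters
#'   in bp.
#' @return object of class `se_call`: list with `sample_id`, `regions` (one
#'   row per stitched region: coordinates, `n_constituents`, `density`,
#'   `rank` with 1 = densest, `is_super`), `cutoff_density` and `params`.
#' @export
call_superenhancers <- function(peaks, signal, genes = NULL, control = NULL,
                                sample_id = "sample", stitch_gap = 12500,
                                tss_window = 2500) {
  if (!is.null(genes)) {
    peaks <- exclude_promoter_peaks(peaks, genes, tss_window)
  }
  if (nrow(peaks) == 0L) {
    warning("no peaks left after promoter exclusion for ", sample_id,
            call. = FALSE)
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), n_constituents = integer(),
                        density = numeric(), rank = integer(),
                        is_super = logical())
    return(structure(list(sample_id = sample_id, regions = empty,
                          cutoff_density = NA_real_,
                          params = list(stitch_gap = stitch_gap,
                                        tss_window = tss_window)),
                     class = "se_call"))
  }
  regions <- stitch_peaks(peaks, stitch_gap)
  regions$density <- quantify_density(regions, signal, control)
  cutoff <- find_cutoff(regions$density)
  regions$rank <- rank(-regions$density, ties.method = "first")
  regions$is_super <- regions$density > cutoff
  structure(list(sample_id = sample_id, regions = regions,
                 cutoff_density = cutoff,
                 params = list(stitch_gap = stitch_gap,
                               tss_window = tss_window)),
            class = "se_call")
}

#' Call super-enhancers from a manifest row
#'
#' Thin file-reading wrapper around [call_superenhancers()].
#'
#' @param row a 1-row manifest `data.frame`.
#' @param genes gene annotations (or `NULL`).
#' @param ... passed to [call_superenhancers()].
#' @export
call_sample <- function(row, genes = NULL, ...) {
  control <- if (!is.na(row$control_path)) read_signal(row$control_path)
  call_superenhancers(read_bed(row$peaks_path), read_signal(row$signal_path),
                      genes = genes, control = control,
                      sample_id = row$sample_id, ...)
}

#' @export
print.se_call <- function(x, ...) {
  cat("se_call for", x$sample_id, "\n")
  cat("  stitched regions:", nrow(x$regions),
      " super-enhancers:", sum(x$regions$is_super),
      " cutoff density:", format(x$cutoff_density, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.se_call <- function(object, ...) {
  r <- object$regions
  out <- list(sample_id = object$sample_id,
              n_regions = nrow(r),
              n_super = sum(r$is_super),
              cutoff_density = object$cutoff_density,
              fraction_signal_in_ses =
                if (nrow(r)) fraction_signal_in_ses(object) else NA_real_)
  class(out) <- "summary.se_call"
  out
}

#' @export
print.summary.se_call <- function(x, ...) {
  cat("Sample", x$sample_id, ":", x$n_super, "SEs /", x$n_regions,
      "stitched regions; cutoff", format(x$cutoff_density, digits = 5),
      "; SE signal fraction", format(x$fraction_signal_in_ses, digits = 3),
      "\n")
  invisible(x)
}

#' Write a per-sample SE call to disk
#'
#' Emits `<sample>_superenhancers.bed`, `<sample>_typical.bed` (BED with
#' name = region id, score = density) and `<sample>_regions.tsv`.
#'
#' @param call an `se_call`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_se_call <- function(call, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- call$regions
  r$name <- locus_ids(r)
  r$score <- r$density
  paths <- c(
    se = file.path(dir, paste0(call$sample_id, "_superenhancers.bed")),
    te = file.path(dir, paste0(call$sample_id, "_typical.bed")),
    tsv = file.path(dir, paste0(call$sample_id, "_regions.tsv")))
  write_bed(r[r$is_super, , drop = FALSE], paths[["se"]])
  write_bed(r[!r$is_super, , drop = FALSE], paths[["te"]])
  tab <- r[c("chrom", "start", "end", "n_constituents", "density",
             "rank", "is_super")]
  tab <- cbind(region = r$name, tab)
  write.table(tab, paths[["tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

locus_ids <- function(df) {
  sprintf("SE_%s_%d_%d", df$chrom, as.integer(df$start), as.integer(df$end))
}
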
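#' Construct a validated table of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention) throughout the package;
#' any 1-based display is formatting only.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer start coordinates (0-based, inclusive).
#' @param end integer end coordinates (exclusive); must satisfy `end > start`.
#' @param name optional character vector of interval names.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   given, `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(what, " table contains missing coordinates", call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(what, " start coordinates must be >= 0", call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(what, " with end <= start at row ", bad[1L],
         " (", df$chrom[bad[1L]], ":", df$start[bad[1L]], "-",
         df$end[bad[1L]], ")", call. = FALSE)
  }
  invisible(df)
}

# 0-based half-open data.frame <-> 1-based closed GRanges
.gi_to_gr <- function(df) {
  GenomicRanges::GRanges(
    factor(df$chrom, levels = sort(unique(df$chrom))),
    IRanges::IRanges(start = df$start + 1L, end = df$end))
}

.gr_to_gi <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' Accepts BED3 or wider; columns beyond the fourth are ignored. Coordinates
#' are kept verbatim (0-based half-open).
#'
#' @param path path to a tab/whitespace-delimited BED file.
#' @return Interval `data.frame` as from [genomic_intervals()], in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
         ": fewer than 3 columns", call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         " in ", path, ": non-numeric coordinates", call. = FALSE)
  }
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[`, "", 4L)
  validate_intervals(df, what = paste0("BED record in ", path))
  df
}

#' Write intervals as BED
#'
#' @param df interval `data.frame`; optional columns `name` and `score` are
#'   written as BED columns 4-5 (with strand "." as column 6 when `score`
#'   is present).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- df[c("chrom", "start", "end")]
  if (!is.null(df$name)) {
    cols$name <- df$name
    if (!is.null(df$score)) {
      cols$score <- df$score
      cols$strand <- "."
    }
  }
  write.table(format(cols, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping or book-ended intervals
#'
#' Single-linkage union: intervals that overlap or touch (gap 0) collapse
#' into one. The covered base set is preserved and the result is sorted and
#' pairwise disjoint; the operation is order-invariant and idempotent.
#'
#' @param df interval `data.frame`.
#' @return merged interval `data.frame`.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[c("chrom", "start", "end")])
  validate_intervals(df)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(.gi_to_gr(df)))
  .gr_to_gi(gr)
}

#' Gap between two intervals on the same chromosome
#'
#' For `a` preceding `b` on one chromosome the gap is `b$start - a$end`
#' (0 for book-ended intervals). Overlapping intervals yield 0 with
#' attribute `overlap = TRUE`; intervals on different chromosomes yield
#' `NA` (no defined distance).
#'
#' @param a,b single intervals (1-row data.frames or lists with `chrom`,
#'   `start`, `end`).
#' @return numeric gap in bp, with attribute `overlap`; `NA` across
#'   chromosomes.
#' @export
gap_between <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  gap <- b$start - a$end
  if (gap < 0) {
    return(structure(0, overlap = TRUE))
  }
  structure(as.numeric(gap), overlap = FALSE)
}
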
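#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `symbol`, `chrom`,
#'   `strand`, `tss` (TSS as a single 0-based coordinate).
#' @return validated `data.frame` of gene annotations.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  req <- c("gene_id", "symbol", "chrom", "strand", "tss")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("gene table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in gene table: ",
         df$gene_id[anyDuplicated(df$gene_id)], call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$tss < 0) || anyNA(df$tss)) {
    stop("gene tss must be a non-negative coordinate", call. = FALSE)
  }
  df
}

#' Read a gene x sample expression matrix (TPM)
#'
#' @param path TSV whose first column is `gene_id` and remaining columns are
#'   sample ids; body numeric, non-negative.
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 1 sample column",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene row in expression matrix: ",
         ids[anyDuplicated(ids)], call. = FALSE)
  }
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("non-numeric cell in expression matrix ", path,
                           call. = FALSE)
  if (anyNA(m)) stop("missing value in expression matrix ", path,
                     call. = FALSE)
  if (any(m < 0)) stop("negative TPM in expression matrix ", path,
                       call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a sample manifest
#'
#' @param path TSV with header columns `sample_id`, `group`
#'   (tumor/normal/cell_line/organoid), optional `pair_id`, `peaks_path`,
#'   `signal_path`, optional `control_path`. Relative paths are resolved
#'   against the manifest's directory.
#' @return validated manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("sample_id", "group", "peaks_path", "signal_path")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("manifest ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$pair_id)) df$pair_id <- NA_character_
  if (is.null(df$control_path)) df$control_path <- NA_character_
  base <- dirname(normalizePath(path))
  for (col in c("peaks_path", "signal_path", "control_path")) {
    rel <- !is.na(df[[col]]) & !grepl("^/", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  validate_manifest(df)
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }
  ok <- df$group %in% c("tumor", "normal", "cell_line", "organoid")
  if (!all(ok)) {
    stop("unknown group label(s): ",
         paste(unique(df$group[!ok]), collapse = ", "), call. = FALSE)
  }
  norm <- df[df$group == "normal" & !is.na(df$pair_id), ]
  if (anyDuplicated(norm$pair_id)) {
    stop("pair_id maps a tumor to more than one normal", call. = FALSE)
  }
  df
}

manifest_samples <- function(manifest, group) {
  if (!group %in% manifest$group) {
    stop("no samples with group '", group, "' in manifest", call. = FALSE)
  }
  manifest$sample_id[manifest$group == group]
}
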
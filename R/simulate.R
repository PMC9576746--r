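#' Configuration for a synthetic matched cohort
#'
#' Describes a deterministic tumor/normal cohort with planted
#' super-enhancer loci. Defaults emulate the matched design the package
#' targets: 15 tumor/normal pairs on one 10 Mb chromosome, 50 planted loci
#' (20 tumor-gained at recurrence 12/15 with a log2 effect of 2, 20 shared,
#' 10 normal-only), expression linear in true SE signal at design
#' correlation 0.8, and per-sample scale factors log-uniform in [0.5, 2] so
#' promoter normalization has work to do.
#'
#' @param n_pairs number of tumor/normal pairs.
#' @param n_cell_lines extra unpaired cell-line samples (carry only
#'   `shared` loci).
#' @param genome `data.frame(chrom, length)`; a single chromosome is used.
#' @param n_genes total genes (one true target per planted locus, the rest
#'   decoys placed inside the regression windows).
#' @param n_background_peaks typical-enhancer peaks per sample.
#' @param planted `data.frame` with one row per planted locus: `class`
#'   (`tumor_gained`, `shared`, `normal_only`), `log2_effect`,
#'   `recurrence_k` (tumor carriers; only used for `tumor_gained`),
#'   `target_r` design correlation in (0, 1).
#' @param baseline_value per-base coverage of a typical enhancer peak.
#' @param promoter_value per-base coverage of every promoter window
#'   (jitter-free, the normalization anchor).
#' @param noise_sd log-normal sd of per-peak signal jitter.
#' @param scale_range range of per-sample whole-track scale factors
#'   (log-uniform). RPKM quantification is invariant to whole-track
#'   scaling, so these exercise the plumbing rather than the statistics.
#' @param offtarget_range range (log-uniform) of each sample's off-target
#'   signal mass, expressed relative to 1 Mb of baseline coverage placed on
#'   a decoy contig. Varying off-target mass distorts total-signal (RPKM)
#'   normalization across samples -- the varying-ChIP-efficiency effect
#'   that promoter normalization exists to correct.
#' @param locus_span bp spanned by each planted constituent-peak cluster.
#' @param stitch_gap stitching gap the layout must respect (loci are kept
#'   more than `2 * stitch_gap` apart).
#' @param seed integer controlling all randomness.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 15, n_cell_lines = 0,
                          genome = data.frame(chrom = "chr1",
                                              length = 1e7),
                          n_genes = 200, n_background_peaks = 120,
                          planted = default_planted(),
                          baseline_value = 2.0, promoter_value = 2.0,
                          noise_sd = 0.15, scale_range = c(0.5, 2.0),
                          offtarget_range = c(0.5, 2.0),
                          locus_span = 30000, stitch_gap = 12500,
                          seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_cell_lines = n_cell_lines,
              genome = genome, n_genes = n_genes,
              n_background_peaks = n_background_peaks, planted = planted,
              baseline_value = baseline_value,
              promoter_value = promoter_value, noise_sd = noise_sd,
              scale_range = scale_range, offtarget_range = offtarget_range,
              locus_span = locus_span,
              stitch_gap = stitch_gap, seed = as.integer(seed))
  n_planted <- nrow(planted)
  if (n_planted < 1L) stop("need at least one planted locus", call. = FALSE)
  if (!all(planted$class %in% c("tumor_gained", "shared", "normal_only"))) {
    stop("unknown planted class", call. = FALSE)
  }
  if (any(planted$recurrence_k > n_pairs)) {
    stop("recurrence_k cannot exceed n_pairs", call. = FALSE)
  }
  if (any(planted$target_r <= 0 | planted$target_r >= 1)) {
    stop("target_r must be in (0, 1)", call. = FALSE)
  }
  if (n_genes < n_planted) stop("n_genes must be >= number of planted loci",
                                call. = FALSE)
  spacing <- floor(genome$length[1L] / n_planted)
  if (spacing < locus_span + 2 * stitch_gap + 125000) {
    stop("genome too small: planted loci would violate spacing invariants",
         call. = FALSE)
  }
  cfg$spacing <- spacing
  class(cfg) <- "cohort_config"
  cfg
}

#' Default planted-locus table
#'
#' @param n_tumor_gained,n_shared,n_normal_only class counts.
#' @param log2_effect carrier-over-baseline signal effect (log2).
#' @param recurrence_k tumor carriers per tumor-gained locus.
#' @param target_r design signal-expression correlation for true targets.
#' @return `data.frame` consumable by [cohort_config()].
#' @export
default_planted <- function(n_tumor_gained = 20, n_shared = 20,
                            n_normal_only = 10, log2_effect = 2,
                            recurrence_k = 12, target_r = 0.8) {
  n <- n_tumor_gained + n_shared + n_normal_only
  data.frame(
    class = rep(c("tumor_gained", "shared", "normal_only"),
                c(n_tumor_gained, n_shared, n_normal_only)),
    log2_effect = log2_effect,
    recurrence_k = recurrence_k,
    target_r = target_r,
    stringsAsFactors = FALSE)
}

# deterministic geometry shared by all samples: planted locus coordinates,
# gene placement, background-cell grid
.cohort_layout <- function(cfg) {
  chrom <- cfg$genome$chrom[1L]
  n_planted <- nrow(cfg$planted)
  start <- (seq_len(n_planted) - 1) * cfg$spacing + 20000
  loci <- data.frame(locus_id = sprintf("PL%03d", seq_len(n_planted)),
                     chrom = chrom, start = start,
                     end = start + cfg$locus_span,
                     stringsAsFactors = FALSE)
  # one true target per locus at center + 80 kb; decoys 130/136/142 kb ...
  # downstream of the locus start, all inside the 500 kb regression window
  targets <- data.frame(gene_id = sprintf("TG%03d", seq_len(n_planted)),
                        symbol = sprintf("TGT%03d", seq_len(n_planted)),
                        chrom = chrom, strand = "+",
                        tss = start + 95000, stringsAsFactors = FALSE)
  n_decoy <- cfg$n_genes - n_planted
  per_locus <- ceiling(n_decoy / n_planted)
  if (per_locus > 4L) {
    stop("too many decoy genes for the layout (max 4 per planted locus)",
         call. = FALSE)
  }
  dslot <- rep(seq_len(per_locus), times = n_planted)[seq_len(n_decoy)]
  dlocus <- rep(seq_len(n_planted), each = per_locus)[seq_len(n_decoy)]
  decoys <- data.frame(gene_id = sprintf("DG%03d", seq_len(n_decoy)),
                       symbol = sprintf("DEC%03d", seq_len(n_decoy)),
                       chrom = chrom, strand = "+",
                       tss = start[dlocus] + 104000 + 6000 * dslot,
                       stringsAsFactors = FALSE)
  genes <- rbind(targets, decoys)
  genes <- genes[order(genes$tss), , drop = FALSE]
  rownames(genes) <- NULL
  # background cells: 25 kb grid cells clear of planted loci (by more than
  # the stitch gap) and of promoter windows
  cell <- 25000
  n_cells <- floor(cfg$genome$length[1L] / cell)
  cell_start <- (seq_len(n_cells) - 1) * cell
  forb <- rbind(
    data.frame(start = loci$start - cfg$stitch_gap - 5000,
               end = loci$end + cfg$stitch_gap + 5000),
    data.frame(start = genes$tss - 3500, end = genes$tss + 3500))
  blocked <- rep(FALSE, n_cells)
  for (i in seq_len(nrow(forb))) {
    hit <- cell_start < forb$end[i] & (cell_start + cell) > forb$start[i]
    blocked <- blocked | hit
  }
  free_cells <- cell_start[!blocked]
  if (length(free_cells) < cfg$n_background_peaks) {
    stop("layout has only ", length(free_cells),
         " free background cells; lower n_background_peaks", call. = FALSE)
  }
  list(chrom = chrom, loci = loci, genes = genes,
       free_cells = free_cells, cell = cell)
}

# constituent-peak footprint of one planted locus: m peaks in equal slots,
# each covering 70% of its slot (gaps well under the stitch threshold)
.cluster_footprint <- function(start, span, m) {
  slot <- span / m
  s <- round((start + (seq_len(m) - 1) * slot) / 50) * 50
  w <- round(0.7 * slot / 50) * 50
  data.frame(start = s, end = s + w)
}

#' Simulate a matched tumor/normal cohort with planted truth
#'
#' Writes a complete fixture tree -- per-sample peak BEDs and bedGraph
#' coverage (50 bp grid), a manifest, a gene table, a TPM expression matrix
#' and a JSON truth set -- that the pipeline consumes unchanged. Every
#' sample carries the same peak footprint at each planted locus; carriers
#' get `baseline * 2^log2_effect` coverage there, non-carriers baseline, so
#' the expected consensus-locus log2 fold change equals the configured
#' effect. Whole tracks are multiplied by per-sample scale factors;
#' promoter windows carry a fixed jitter-free coverage as the normalization
#' anchor. Deterministic given `config$seed`.
#'
#' @param config a `cohort_config`.
#' @param dir output directory (created).
#' @return list with `dir`, `manifest`, `genes`, `expression`, `truth`
#'   (class `se_truth`) and file `paths`.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  lay <- .cohort_layout(config)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "signal"), showWarnings = FALSE)

  tumors <- sprintf("T%02d", seq_len(config$n_pairs))
  normals <- sprintf("N%02d", seq_len(config$n_pairs))
  lines <- if (config$n_cell_lines > 0)
    sprintf("C%02d", seq_len(config$n_cell_lines)) else character()
  samples <- c(tumors, normals, lines)
  groups <- c(rep("tumor", length(tumors)), rep("normal", length(normals)),
              rep("cell_line", length(lines)))
  pairs <- c(sprintf("P%02d", seq_len(config$n_pairs)),
             sprintf("P%02d", seq_len(config$n_pairs)),
             rep(NA_character_, length(lines)))

  n_planted <- nrow(config$planted)
  planted <- cbind(lay$loci, config$planted)

  # carriers per planted locus
  carriers <- vector("list", n_planted)
  names(carriers) <- planted$locus_id
  for (i in seq_len(n_planted)) {
    carriers[[i]] <- switch(planted$class[i],
      tumor_gained = sort(sample(tumors, planted$recurrence_k[i])),
      shared = samples,
      normal_only = normals)
  }

  # shared cluster footprints (same in every sample)
  foot <- vector("list", n_planted)
  for (i in seq_len(n_planted)) {
    m <- sample(3:8, 1L)
    foot[[i]] <- .cluster_footprint(planted$start[i], config$locus_span, m)
  }

  scale_factors <- exp(runif(length(samples), log(config$scale_range[1L]),
                             log(config$scale_range[2L])))
  names(scale_factors) <- samples
  offtarget <- exp(runif(length(samples), log(config$offtarget_range[1L]),
                         log(config$offtarget_range[2L])))
  names(offtarget) <- samples

  # per-(locus, sample) true pre-scale peak coverage
  true_density <- matrix(NA_real_, n_planted, length(samples),
                         dimnames = list(planted$locus_id, samples))
  for (i in seq_len(n_planted)) {
    carrier <- samples %in% carriers[[i]]
    base <- config$baseline_value *
      ifelse(carrier, 2^planted$log2_effect[i], 1)
    true_density[i, ] <- base * exp(rnorm(length(samples), 0,
                                          config$noise_sd))
  }

  genes <- lay$genes
  prom <- data.frame(start = genes$tss - 1000, end = genes$tss + 1000)

  manifest <- data.frame(sample_id = samples, group = groups,
                         pair_id = pairs,
                         peaks_path = file.path("peaks",
                                                paste0(samples, ".bed")),
                         signal_path = file.path("signal",
                                                 paste0(samples,
                                                        ".bedgraph")),
                         control_path = NA_character_,
                         stringsAsFactors = FALSE)

  for (s in seq_along(samples)) {
    sid <- samples[s]
    # background peaks
    cells <- sample(lay$free_cells, config$n_background_peaks)
    w <- round(runif(config$n_background_peaks, 800, 2500) / 50) * 50
    off <- round(runif(config$n_background_peaks, 0,
                       lay$cell - w - 50) / 50) * 50
    bg <- data.frame(start = cells + off, end = cells + off + w,
                     value = config$baseline_value *
                       exp(rnorm(config$n_background_peaks, 0,
                                 config$noise_sd)))
    # planted constituent peaks (footprint in every sample)
    pk <- do.call(rbind, lapply(seq_len(n_planted), function(i) {
      f <- foot[[i]]
      f$value <- true_density[i, s]
      f
    }))
    peaks <- rbind(bg[c("start", "end")], pk[c("start", "end")])
    peaks <- peaks[order(peaks$start), , drop = FALSE]
    write_bed(data.frame(chrom = lay$chrom, start = peaks$start,
                         end = peaks$end),
              file.path(dir, manifest$peaks_path[s]))
    # coverage = peaks + promoter anchor, all scaled; plus an off-target
    # mass on a decoy contig that distorts total-signal normalization
    cov <- rbind(bg, pk,
                 data.frame(start = prom$start, end = prom$end,
                            value = config$promoter_value))
    cov <- cov[order(cov$start), , drop = FALSE]
    cov <- data.frame(chrom = lay$chrom, cov, stringsAsFactors = FALSE)
    cov <- rbind(cov, data.frame(
      chrom = "chrU", start = 0, end = 1e6,
      value = config$baseline_value * offtarget[s]))
    cov$value <- cov$value * scale_factors[s]
    out <- data.frame(chrom = cov$chrom, start = cov$start, end = cov$end,
                      value = format(cov$value, digits = 10,
                                     scientific = FALSE, trim = TRUE))
    write.table(format(out, scientific = FALSE, trim = TRUE),
                file.path(dir, manifest$signal_path[s]), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  truth <- structure(list(
    planted = cbind(planted,
                    target_gene = sprintf("TG%03d", seq_len(n_planted))),
    carriers = carriers,
    true_density = true_density,
    scale_factors = scale_factors,
    samples = samples), class = "se_truth")

  expression <- plant_expression(truth, config, genes)
  expr_tab <- data.frame(gene_id = rownames(expression), expression,
                         check.names = FALSE)
  write.table(expr_tab, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth(truth, file.path(dir, "truth.json"))

  list(dir = dir,
       manifest = read_manifest(file.path(dir, "manifest.tsv")),
       genes = genes, expression = expression, truth = truth,
       paths = list(manifest = file.path(dir, "manifest.tsv"),
                    genes = file.path(dir, "genes.tsv"),
                    expression = file.path(dir, "expression.tsv"),
                    truth = file.path(dir, "truth.json")))
}

#' Plant expression linear in true SE signal
#'
#' Each planted locus's target gene gets
#' `TPM = 5 + d(s) + Normal(0, sigma)` with `sigma` chosen from the design
#' correlation `rho`: `sigma = sd(d) * sqrt(1/rho^2 - 1)`, so the expected
#' signal-expression correlation equals `rho`. Non-target genes are drawn
#' independently log-normal (median 10 TPM, well above the 2 TPM floor, so
#' they act as genuine decoys). TPM is truncated at 0.
#'
#' @param truth an `se_truth` (supplies per-sample true densities).
#' @param config the `cohort_config`.
#' @param genes the cohort gene table.
#' @return TPM matrix, genes x samples.
#' @export
plant_expression <- function(truth, config, genes) {
  samples <- truth$samples
  expr <- matrix(NA_real_, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  is_target <- genes$gene_id %in% truth$planted$target_gene
  n_dec <- sum(!is_target)
  expr[!is_target, ] <- matrix(
    rlnorm(n_dec * length(samples), meanlog = log(10), sdlog = 0.5),
    n_dec, length(samples))
  for (i in seq_len(nrow(truth$planted))) {
    g <- truth$planted$target_gene[i]
    rho <- truth$planted$target_r[i]
    d <- truth$true_density[truth$planted$locus_id[i], ]
    sigma <- sd(d) * sqrt(1 / rho^2 - 1)
    expr[g, ] <- pmax(0, 5 + d + rnorm(length(d), 0, sigma))
  }
  expr
}

#' Write / read a truth set as JSON
#'
#' @param truth an `se_truth`.
#' @param path JSON path.
#' @return `path` (write) or the reconstructed `se_truth` (read), the
#'   matrices restored with dimnames.
#' @export
write_truth <- function(truth, path) {
  obj <- list(planted = truth$planted,
              carriers = truth$carriers,
              true_density = list(values = unname(truth$true_density),
                                  loci = rownames(truth$true_density),
                                  samples = colnames(truth$true_density)),
              scale_factors = as.list(truth$scale_factors),
              samples = truth$samples)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  td <- as.matrix(obj$true_density$values)
  dimnames(td) <- list(obj$true_density$loci, obj$true_density$samples)
  structure(list(planted = as.data.frame(obj$planted),
                 carriers = lapply(obj$carriers, as.character),
                 true_density = td,
                 scale_factors = unlist(obj$scale_factors),
                 samples = obj$samples), class = "se_truth")
}

#' Score pipeline recovery against a planted truth set
#'
#' @param truth an `se_truth`.
#' @param catalog the consensus `se_catalog` computed on the cohort.
#' @param differentials optional [differential_ses()] table (tumor vs
#'   normal) used to report the mean log2 fold change at tumor-gained loci.
#' @param candidates optional [prioritize_candidates()] result.
#' @param assignments optional [assign_all()] table.
#' @return object of class `recovery_report`: list with `se_recall`,
#'   `se_precision`, `candidate_recovery` (fraction of high-recurrence
#'   tumor-gained loci in the candidate set), `assignment_accuracy`,
#'   `mean_lfc_tumor_gained`, and the per-locus match table.
#' @export
score_recovery <- function(truth, catalog, differentials = NULL,
                           candidates = NULL, assignments = NULL) {
  pl <- truth$planted
  pl_gr <- .gi_to_gr(pl)
  n_cat <- nrow(catalog$loci)
  if (n_cat == 0L) {
    return(structure(list(se_recall = 0, se_precision = NA_real_,
                          candidate_recovery = NA_real_,
                          assignment_accuracy = NA_real_,
                          mean_lfc_tumor_gained = NA_real_,
                          matches = NULL), class = "recovery_report"))
  }
  cat_gr <- .gi_to_gr(catalog$loci)
  hits <- GenomicRanges::findOverlaps(pl_gr, cat_gr)
  match_locus <- rep(NA_character_, nrow(pl))
  qh <- S4Vectors::queryHits(hits)
  match_locus[qh] <- catalog$loci$locus_id[S4Vectors::subjectHits(hits)]
  matches <- data.frame(locus_id = pl$locus_id, class = pl$class,
                        matched = match_locus, stringsAsFactors = FALSE)
  se_recall <- mean(!is.na(match_locus))
  se_precision <-
    length(unique(S4Vectors::subjectHits(hits))) / n_cat

  candidate_recovery <- NA_real_
  if (!is.null(candidates)) {
    min_k <- attr(candidates, "provenance")$min_k
    if (is.null(min_k)) min_k <- 9
    hi <- pl$class == "tumor_gained" & pl$recurrence_k >= min_k
    if (any(hi)) {
      candidate_recovery <-
        mean(!is.na(match_locus[hi]) & match_locus[hi] %in% candidates)
    }
  }

  assignment_accuracy <- NA_real_
  if (!is.null(assignments)) {
    idx <- match(match_locus, assignments$locus_id)
    assigned <- assignments$assigned[idx]
    scored <- !is.na(assigned)
    if (any(scored)) {
      assignment_accuracy <-
        mean(assigned[scored] == pl$target_gene[scored])
    }
  }

  mean_lfc <- NA_real_
  if (!is.null(differentials)) {
    tg <- match_locus[pl$class == "tumor_gained"]
    mean_lfc <- mean(differentials$log2fc[
      match(tg[!is.na(tg)], differentials$locus_id)])
  }

  structure(list(se_recall = se_recall, se_precision = se_precision,
                 candidate_recovery = candidate_recovery,
                 assignment_accuracy = assignment_accuracy,
                 mean_lfc_tumor_gained = mean_lfc, matches = matches),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 4)
  cat("Recovery vs planted truth:\n",
      " SE recall:            ", fmt(x$se_recall), "\n",
      " SE precision:         ", fmt(x$se_precision), "\n",
      " candidate recovery:   ", fmt(x$candidate_recovery), "\n",
      " assignment accuracy:  ", fmt(x$assignment_accuracy), "\n",
      " mean log2FC (gained): ", fmt(x$mean_lfc_tumor_gained), "\n")
  invisible(x)
}
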
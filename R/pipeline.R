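#' Build a pipeline configuration
#'
#' Defaults are the analysis parameters of the matched-cohort design:
#' 12.5 kb stitching, 2.5 kb promoter exclusion, 500 kb target windows,
#' 2 TPM expression floor, P < 0.01 with |log2FC| > 1 for differential
#' selection, top-100 ranking intersected with recurrence >= 9 for
#' candidates, and P < 0.05 target assignment.
#'
#' @param manifest_path,gene_table_path,expression_path input files
#'   (`expression_path` may be `NA`: the assignment stage is then skipped).
#' @param output_dir where stage outputs are written.
#' @param group_a,group_b manifest groups compared by the differential
#'   stage (`group_a` is the fold-change numerator).
#' @param stitch_gap,tss_window,promoter_window,target_window,expr_floor,eps
#'   stage parameters in bp / TPM / density units.
#' @param diff_p,diff_lfc,top_n,min_recurrence,alpha selection parameters.
#' @param seed recorded for reproducibility (no stage is stochastic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path, gene_table_path,
                            expression_path = NA_character_,
                            output_dir = "se_out",
                            group_a = "tumor", group_b = "normal",
                            stitch_gap = 12500, tss_window = 2500,
                            promoter_window = 1000, target_window = 500000,
                            expr_floor = 2.0, eps = 0.1, diff_p = 0.01,
                            diff_lfc = 1.0, top_n = 100,
                            min_recurrence = 9, alpha = 0.05, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Keys mirror [pipeline_config()] arguments; unknown keys are rejected.
#'
#' @param path a `.yaml`/`.yml` (requires the yaml package) or `.json`
#'   file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs; ",
           "use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  base <- dirname(normalizePath(path))
  for (k in c("manifest_path", "gene_table_path", "expression_path")) {
    if (!is.null(vals[[k]]) && !is.na(vals[[k]]) &&
        !grepl("^/", vals[[k]])) {
      vals[[k]] <- file.path(base, vals[[k]])
    }
  }
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Never throws: collects missing files, parameter violations and manifest
#' inconsistencies into a report.
#'
#' @param config a `pipeline_config`.
#' @return `data.frame` with columns `level` (`error`/`warning`) and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  issues <- list()
  note <- function(level, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  for (k in c("manifest_path", "gene_table_path")) {
    if (is.na(config[[k]]) || !file.exists(config[[k]])) {
      note("error", paste0(k, " does not exist: ", config[[k]]))
    }
  }
  if (!is.na(config$expression_path) &&
      !file.exists(config$expression_path)) {
    note("error", paste0("expression_path does not exist: ",
                         config$expression_path))
  }
  for (k in c("stitch_gap", "target_window", "expr_floor", "diff_p",
              "diff_lfc", "top_n", "min_recurrence", "alpha", "eps",
              "promoter_window")) {
    if (!is.numeric(config[[k]]) || config[[k]] <= 0) {
      note("error", paste0("parameter ", k, " must be positive"))
    }
  }
  if (is.numeric(config$tss_window) && config$tss_window < 0) {
    note("error", "tss_window must be >= 0")
  }
  mf <- if (!is.na(config$manifest_path) &&
            file.exists(config$manifest_path)) {
    tryCatch(read_manifest(config$manifest_path), error = function(e) {
      note("error", paste0("manifest invalid: ", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(mf)) {
    for (g in c(config$group_a, config$group_b)) {
      n <- sum(mf$group == g)
      if (n < 2L) note("error", paste0("group '", g, "' has ", n,
                                       " samples; need >= 2"))
    }
    n_a <- sum(mf$group == config$group_a)
    if (config$min_recurrence > n_a) {
      note("warning", paste0("min_recurrence (", config$min_recurrence,
                             ") exceeds group size (", n_a, ")"))
    }
    tum <- mf[mf$group == "tumor" & !is.na(mf$pair_id), ]
    nor <- mf[mf$group == "normal" & !is.na(mf$pair_id), ]
    dangling <- setdiff(tum$pair_id, nor$pair_id)
    if (length(dangling)) {
      note("warning", paste0("pair_id without a matched normal: ",
                             paste(dangling, collapse = ", ")))
    }
    for (i in seq_len(nrow(mf))) {
      for (col in c("peaks_path", "signal_path")) {
        if (!file.exists(mf[[col]][i])) {
          note("error", paste0(col, " missing for sample ",
                               mf$sample_id[i]))
        }
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(format(round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
          "s")
  out
}

#' Run the full super-enhancer landscape pipeline
#'
#' Stages: per-sample SE calling, consensus catalog, signal matrix with
#' promoter normalization, group differential statistics, recurrence and
#' saturation summaries, candidate prioritization, and (when expression is
#' available) target assignment. Every stage's table is written under
#' `config$output_dir` together with a JSON run summary. Reruns on
#' identical inputs are bit-identical; no stage is stochastic.
#'
#' @param config a `pipeline_config` or path to one.
#' @return invisibly, a list with all stage objects (`calls`, `catalog`,
#'   `matrix_raw`, `matrix`, `differential`, `ranked`, `divergent`,
#'   `recurrence`, `saturation`, `candidates`, `assignments`, `summary`).
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  rep <- validate_config(config)
  if (any(rep$level == "error")) {
    stop("invalid configuration:\n  ",
         paste(rep$message[rep$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- read_manifest(config$manifest_path)
  genes <- read_gene_table(config$gene_table_path)
  expression <- if (!is.na(config$expression_path))
    read_expression(config$expression_path)

  tracks <- list()
  calls <- .stage("call", {
    lapply(seq_len(nrow(manifest)), function(i) {
      sid <- manifest$sample_id[i]
      tracks[[sid]] <<- read_signal(manifest$signal_path[i])
      control <- if (!is.na(manifest$control_path[i]))
        read_signal(manifest$control_path[i])
      cl <- call_superenhancers(read_bed(manifest$peaks_path[i]),
                                tracks[[sid]], genes = genes,
                                control = control, sample_id = sid,
                                stitch_gap = config$stitch_gap,
                                tss_window = config$tss_window)
      write_se_call(cl, file.path(out_dir, "calls"))
      cl
    })
  })

  catalog <- .stage("consensus", build_consensus(calls))
  matrix_raw <- .stage("quantify",
                       quantify_matrix(catalog, manifest, tracks = tracks))
  matrix <- .stage("normalize",
                   promoter_normalize(matrix_raw, manifest, genes,
                                      promoter_window =
                                        config$promoter_window,
                                      tracks = tracks))
  write_catalog(catalog, matrix_raw, out_dir)
  write_catalog(catalog, matrix, out_dir)

  group_a_ids <- manifest_samples(manifest, config$group_a)
  group_b_ids <- manifest_samples(manifest, config$group_b)
  differential <- .stage("differential",
                         differential_ses(matrix, group_a_ids, group_b_ids,
                                          eps = config$eps))
  ranked <- rank_by_fold_change(differential)
  divergent <- select_divergent(differential, max_p = config$diff_p,
                                min_abs_lfc = config$diff_lfc,
                                direction = "both")
  write.table(ranked, file.path(out_dir, "differential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  recurrence <- .stage("recurrence",
                       recurrence_counts(catalog, manifest, config$group_a))
  write.table(data.frame(locus_id = names(recurrence),
                         k = as.integer(recurrence),
                         n = attr(recurrence, "n_group")),
              file.path(out_dir, "recurrence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  saturation <- .stage("saturation", {
    lapply(stats::setNames(c(config$group_a, config$group_b),
                           c(config$group_a, config$group_b)),
           function(g) {
             cur <- saturation_curve(catalog, manifest, g)
             write.table(cur, file.path(out_dir,
                                        paste0("saturation_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
             cur
           })
  })

  candidates <- .stage("prioritize",
                       prioritize_candidates(ranked, recurrence,
                                             top_n = config$top_n,
                                             min_k = config$min_recurrence))
  write.table(data.frame(locus_id = candidates),
              file.path(out_dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  zm <- if (nrow(divergent) > 1L) {
    zscore_rows(matrix$values[divergent$locus_id, , drop = FALSE])
  } else matrix(numeric(), 0L, ncol(matrix$values))
  write.table(data.frame(locus_id = rownames(zm), zm, check.names = FALSE),
              file.path(out_dir, "zscore.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  assignments <- NULL
  if (!is.null(expression)) {
    assignments <- .stage("assign",
                          assign_all(catalog, matrix, genes, expression,
                                     alpha = config$alpha,
                                     window = config$target_window,
                                     expr_floor = config$expr_floor))
    write.table(as.data.frame(assignments),
                file.path(out_dir, "assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    warning("no expression matrix; target assignment skipped",
            call. = FALSE)
  }

  summary <- list(
    n_samples = nrow(manifest),
    n_consensus_loci = nrow(catalog$loci),
    n_differential = nrow(divergent),
    n_candidates = length(candidates),
    n_assigned = if (!is.null(assignments))
      sum(!is.na(assignments$assigned)) else NA,
    mean_fraction_signal_in_ses =
      mean(vapply(calls, fraction_signal_in_ses, 0)),
    parameters = unclass(config)[!(names(config) %in%
                                     c("manifest_path", "gene_table_path",
                                       "expression_path", "output_dir"))],
    package_version = as.character(utils::packageVersion("selandscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, manifest = manifest, calls = calls,
                 catalog = catalog, matrix_raw = matrix_raw,
                 matrix = matrix, differential = differential,
                 ranked = ranked, divergent = divergent,
                 recurrence = recurrence, saturation = saturation,
                 candidates = candidates, assignments = assignments,
                 summary = summary))
}
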
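#' Pipeline configuration
#'
#' Collects the paths, contrasts and thresholds for a full run: DE per
#' contrast, top-gene ranking with Venn partitioning, enrichment per
#' contrast with the heatmap matrix, and (optionally) qPCR quantification.
#'
#' @param counts Path to a counts TSV/MTX (as written by [write_counts()]).
#' @param annotation Optional path to an annotation TSV or GAF (`.gaf`).
#' @param ct_table Optional path to a long-format Ct TSV.
#' @param out_dir Output directory (created if missing).
#' @param control Control condition label; default the first factor level of
#'   the counts.
#' @param treatments Treatment labels; default every non-control condition.
#' @param fdr,logcpm,top_n,min_term_size Analysis thresholds (strict FDR cut,
#'   strict logCPM cut, top-set size, minimum term size).
#' @param reference_gene qPCR reference gene id.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotation = NULL, ct_table = NULL,
                            out_dir = "coldtx-out", control = NULL,
                            treatments = NULL, fdr = 0.01, logcpm = 4,
                            top_n = 50, min_term_size = 5,
                            reference_gene = "AtUBQ5", seed = 1L) {
  stopifnot(fdr > 0, logcpm >= 0, top_n > 0, min_term_size > 0)
  structure(list(counts = counts, annotation = annotation,
                 ct_table = ct_table, out_dir = out_dir, control = control,
                 treatments = treatments, fdr = fdr, logcpm = logcpm,
                 top_n = as.integer(top_n),
                 min_term_size = as.integer(min_term_size),
                 reference_gene = reference_gene, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis chain
#'
#' Stages, in order, each writing its outputs under `config$out_dir`:
#' \enumerate{
#'   \item DE: TMM factors, common dispersion and exact NB test per
#'     treatment-vs-control contrast (`de_<treatment>.tsv`).
#'   \item Ranking: per-contrast top induced genes
#'     (`top_<treatment>.tsv`), exclusive Venn counts (`venn_counts.json`)
#'     and region gene lists (`venn_regions.tsv`), and the all-treatments
#'     shared-gene table ordered by the first treatment's logFC
#'     (`shared_genes.tsv`).
#'   \item Enrichment (if an annotation is given): per-contrast enrichment
#'     tables (`enrichment_<treatment>.tsv`) and the BP score matrix
#'     (`enrichment_heatmap_BP.tsv`).
#'   \item qPCR (if a Ct table is given): relative expression with per-gene
#'     ANOVA + Tukey (`qpcr_summary.tsv`, `qpcr_anova.tsv`).
#' }
#' A `manifest.json` records the package version, seed, thresholds and an
#' md5 checksum per output file. A stage failure aborts the run with the
#' stage named.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
  }

  cm <- stage("read_counts", read_counts(config$counts))
  control <- if (is.null(config$control)) levels(cm$conditions)[1]
             else config$control
  treatments <- if (is.null(config$treatments))
    setdiff(levels(cm$conditions), control) else config$treatments

  factors <- stage("normalization", tmm_factors(cm))
  de_tables <- list()
  for (trt in treatments) {
    de_tables[[trt]] <- stage(paste0("de_", trt),
      nb_exact_test(cm, control, trt, factors = factors))
    emit(de_tables[[trt]], paste0("de_", trt, ".tsv"))
  }

  tops <- stage("ranking", lapply(de_tables, top_induced,
                                  n = config$top_n, fdr_max = config$fdr,
                                  logcpm_min = config$logcpm))
  for (trt in treatments)
    emit(tops[[trt]]$table, paste0("top_", trt, ".tsv"))

  venn <- NULL
  if (length(tops) >= 2) {
    venn <- stage("venn", venn_partition(tops))
    venn_path <- file.path(config$out_dir, "venn_counts.json")
    jsonlite::write_json(as.list(venn$counts), venn_path, auto_unbox = TRUE)
    outputs <- c(outputs, venn_path)
    region_df <- data.frame(
      region = rep(names(venn$regions), lengths(venn$regions)),
      gene_id = unlist(venn$regions, use.names = FALSE),
      stringsAsFactors = FALSE)
    emit(region_df, "venn_regions.tsv")
    all_region <- paste(treatments, collapse = "&")
    if (length(venn$regions[[all_region]]))
      emit(stage("shared_genes",
                 shared_gene_table(venn, de_tables, order_by = treatments[1],
                                   region = all_region)),
           "shared_genes.tsv")
  }

  if (!is.null(config$annotation)) {
    ann <- stage("read_annotation",
                 if (grepl("\\.gaf$", config$annotation))
                   read_gaf(config$annotation)
                 else read_annotation(config$annotation))
    enr <- list()
    for (trt in treatments) {
      enr[[trt]] <- stage(paste0("enrichment_", trt),
        enrich_all(de_tables[[trt]], ann,
                   min_term_size = config$min_term_size))
      emit(enr[[trt]], paste0("enrichment_", trt, ".tsv"))
    }
    heat <- stage("heatmap", enrichment_heatmap_matrix(enr, "BP"))
    emit(data.frame(term_id = rownames(heat), heat, check.names = FALSE),
         "enrichment_heatmap_BP.tsv")
  }

  if (!is.null(config$ct_table)) {
    ct <- stage("read_ct", read_ct_table(config$ct_table))
    rel <- stage("qpcr", relative_expression(ct, config$reference_gene,
                                             control_condition = control))
    emit(rel$summary, "qpcr_summary.tsv")
    anova_rows <- lapply(unique(rel$values$gene), function(g) {
      sub <- rel$values[rel$values$gene == g, ]
      res <- anova_tukey(split(sub$rel_expr, sub$condition))
      data.frame(gene = g, F = res$F, p = res$p,
                 degenerate = res$degenerate, stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, anova_rows), "qpcr_anova.tsv")
  }

  manifest <- list(
    package = "coldtx",
    version = as.character(utils::packageVersion("coldtx")),
    seed = config$seed,
    control = control,
    treatments = as.list(treatments),
    thresholds = list(fdr = config$fdr, logcpm = config$logcpm,
                      top_n = config$top_n,
                      min_term_size = config$min_term_size),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
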
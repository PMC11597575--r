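#' Top induced genes for one contrast
#'
#' Filters a DE table to significantly induced, well-expressed genes
#' (strict `FDR < fdr_max`, strict `logCPM > logcpm_min`, `logFC > 0`) and
#' returns the `n` genes with the largest logFC. Ties on logFC are broken by
#' smaller FDR, then lexicographic gene id, so the ordering is total and
#' reproducible.
#'
#' @param de A `de_result` (or data.frame with `gene_id`, `logFC`, `logCPM`,
#'   `FDR`).
#' @param n Maximum number of genes to return (> 0); no padding if fewer
#'   qualify.
#' @param fdr_max Strict FDR threshold (default 0.01).
#' @param logcpm_min Strict logCPM threshold (default 4).
#' @return Object of class `top_gene_set`: list with `gene_ids` (ordered by
#'   selection rank), `table` (the selected rows in rank order),
#'   `n_requested` and `thresholds`.
#' @export
top_induced <- function(de, n = 50, fdr_max = 0.01, logcpm_min = 4) {
  if (n <= 0) stop("n must be positive")
  stopifnot(all(c("gene_id", "logFC", "logCPM", "FDR") %in% names(de)))
  keep <- de$FDR < fdr_max & de$logCPM > logcpm_min & de$logFC > 0
  sub <- de[keep, , drop = FALSE]
  ord <- order(-sub$logFC, sub$FDR, sub$gene_id)
  sub <- sub[ord, , drop = FALSE][seq_len(min(n, nrow(sub))), , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(gene_ids = sub$gene_id,
                 table = sub,
                 n_requested = as.integer(n),
                 thresholds = list(fdr_max = fdr_max, logcpm_min = logcpm_min)),
            class = "top_gene_set")
}

#' @export
print.top_gene_set <- function(x, ...) {
  cat("top_gene_set:", length(x$gene_ids), "of", x$n_requested,
      sprintf("requested (FDR < %g, logCPM > %g)\n",
              x$thresholds$fdr_max, x$thresholds$logcpm_min))
  invisible(x)
}

#' Exclusive Venn partition of gene sets
#'
#' Splits the union of two or more gene sets into exclusive regions: for
#' every non-empty subset S of the set names, the region holds the genes
#' present in all sets of S and in none of the others. Regions are pairwise
#' disjoint and their counts sum to the size of the union.
#'
#' @param sets Named list (>= 2 entries) of character vectors, or of
#'   [top_induced()] results.
#' @return Object of class `venn_partition`: list with `regions` (named list
#'   of gene-id vectors, names like `"A&B"`) and `counts` (named integer
#'   vector over the same regions, including empty ones). Regions are ordered
#'   by subset size, then by position of the member sets.
#' @examples
#' venn_partition(list(A = c("g1", "g2"), B = c("g2", "g3")))$counts
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need a named list of at least two gene sets")
  sets <- lapply(sets, function(s)
    if (inherits(s, "top_gene_set")) s$gene_ids else as.character(s))
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)

  subsets <- .nonempty_subsets(length(sets))
  labels <- vapply(subsets, function(s) paste(nm[s], collapse = "&"), "")
  regions <- stats::setNames(vector("list", length(subsets)), labels)
  for (i in seq_along(subsets)) {
    inside <- rep(TRUE, length(universe))
    for (k in seq_along(sets))
      inside <- inside & (member[, k] == (k %in% subsets[[i]]))
    regions[[i]] <- sort(universe[inside])
  }
  structure(list(regions = regions,
                 counts = stats::setNames(lengths(regions), labels)),
            class = "venn_partition")
}

# all non-empty subsets of 1..n, ordered by size then lexicographic
.nonempty_subsets <- function(n) {
  out <- list()
  for (size in seq_len(n))
    out <- c(out, utils::combn(n, size, simplify = FALSE))
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Table of a Venn region's genes with per-condition logFC
#'
#' Joins the genes of one exclusive region against the per-condition DE
#' tables and orders rows by the logFC of a chosen condition, descending —
#' the layout used to report shared cold-induced genes.
#'
#' @param partition A [venn_partition()].
#' @param de_by_condition Named list, condition -> `de_result`.
#' @param order_by Condition whose logFC orders the rows.
#' @param region Region label (e.g. `"0C&4C"`); default the region shared by
#'   all conditions in `de_by_condition`.
#' @return data.frame with `gene_id` and one `logFC_<condition>` column per
#'   condition of the region, sorted descending by the `order_by` column.
#' @export
shared_gene_table <- function(partition, de_by_condition, order_by,
                              region = NULL) {
  stopifnot(inherits(partition, "venn_partition"))
  if (is.null(region))
    region <- paste(names(de_by_condition), collapse = "&")
  if (!region %in% names(partition$regions))
    stop("unknown region: ", region)
  conds <- strsplit(region, "&", fixed = TRUE)[[1]]
  if (!order_by %in% conds)
    stop("order_by must be one of the region's conditions")
  genes <- partition$regions[[region]]
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cc in conds) {
    de <- de_by_condition[[cc]]
    if (is.null(de)) stop("no DE table for condition ", cc)
    hit <- match(genes, de$gene_id)
    if (anyNA(hit))
      stop("gene(s) missing from DE table of ", cc, ": ",
           paste(genes[is.na(hit)], collapse = ", "))
    out[[paste0("logFC_", cc)]] <- de$logFC[hit]
  }
  out <- out[order(-out[[paste0("logFC_", order_by)]], out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
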
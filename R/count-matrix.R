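#' Gene-level count matrix with condition labels
#'
#' Lightweight container for an RNA-seq experiment: an integer matrix of
#' counts (genes in rows, samples in columns) plus the condition label of
#' each sample. The first level of the condition factor is treated as the
#' control by downstream helpers.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param conditions Condition label per sample: either a character/factor
#'   vector of `ncol(counts)` (recycled in column order) or a named vector
#'   keyed by sample id.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix), `conditions` (factor, one per sample),
#'   `gene_ids` and `sample_ids`.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("ctrl", "ctrl", "cold", "cold"))
#' @export
count_matrix <- function(counts, conditions) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"

  if (!is.null(names(conditions))) {
    missing <- setdiff(colnames(counts), names(conditions))
    if (length(missing))
      stop("no condition given for sample(s): ", paste(missing, collapse = ", "))
    conditions <- conditions[colnames(counts)]
  }
  if (length(conditions) != ncol(counts))
    stop("need one condition label per sample")
  conditions <- if (is.factor(conditions)) droplevels(conditions)
                else factor(conditions, levels = unique(as.character(conditions)))

  structure(list(counts = counts,
                 conditions = conditions,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$conditions)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# samples (column indices) belonging to one condition; errors on unknown label
.samples_of <- function(cm, condition) {
  idx <- which(as.character(cm$conditions) == condition)
  if (!length(idx)) stop("unknown condition label: ", condition)
  idx
}
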
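#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: header row of sample ids, first column gene ids, integer
#' cells. MatrixMarket layout: a `.mtx` file plus `<stem>.rows.txt` (gene
#' ids) and `<stem>.cols.txt` (sample ids) sidecars. Malformed cells are
#' rejected with their row and column named.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param conditions Condition per sample: a named vector, an unnamed vector
#'   in column order, or the path of a two-column TSV (sample, condition). If
#'   `NULL`, a `<stem>.conditions.tsv` sidecar is read.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rows <- readLines(paste0(stem, ".rows.txt"))
    cols <- readLines(paste0(stem, ".cols.txt"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m))
      stop("row/col sidecar lengths do not match the matrix")
    dimnames(m) <- list(rows, cols)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    gene_ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("malformed count at row %d (gene %s), column %s",
                   bad[1] + 1L, gene_ids[bad[1]], colnames(m)[bad[2]]))
    }
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative count at row %d (gene %s), column %s",
                   neg[1, 1] + 1L, gene_ids[neg[1, 1]],
                   colnames(m)[neg[1, 2]]))
    frac <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(frac))
      stop(sprintf("non-integer count at row %d (gene %s), column %s",
                   frac[1, 1] + 1L, gene_ids[frac[1, 1]],
                   colnames(m)[frac[1, 2]]))
    rownames(m) <- gene_ids
  }
  if (is.null(conditions)) {
    stem <- sub("\\.(tsv|mtx)$", "", path)
    conditions <- paste0(stem, ".conditions.tsv")
  }
  if (is.character(conditions) && length(conditions) == 1 &&
      file.exists(conditions)) {
    cd <- utils::read.delim(conditions, stringsAsFactors = FALSE)
    conditions <- stats::setNames(cd[[2]], cd[[1]])
  }
  count_matrix(m, conditions)
}

#' Write a count matrix (TSV plus condition sidecar, optionally MTX)
#'
#' @param cm A [count_matrix()].
#' @param path Output `.tsv` path; `<stem>.conditions.tsv` is written next to
#'   it.
#' @param mtx Also write `<stem>.mtx` with `.rows.txt`/`.cols.txt` sidecars.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, mtx = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stem <- sub("\\.tsv$", "", path)
  utils::write.table(
    data.frame(sample_id = cm$sample_ids,
               condition = as.character(cm$conditions)),
    paste0(stem, ".conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (mtx) {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                    paste0(stem, ".mtx"))
    writeLines(cm$gene_ids, paste0(stem, ".rows.txt"))
    writeLines(cm$sample_ids, paste0(stem, ".cols.txt"))
  }
  invisible(path)
}

#' Read a GO annotation from a two-column TSV
#'
#' Columns: term id, gene id, optional name (3rd) and namespace (4th). No
#' header. Lines starting with `#` are ignored.
#'
#' @param path TSV path.
#' @return A [go_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation needs at least two columns")
  members <- split(df[[2]], df[[1]])
  terms <- NULL
  if (ncol(df) >= 3) {
    first <- !duplicated(df[[1]])
    terms <- data.frame(term_id = df[[1]][first], name = df[[3]][first],
                        namespace = if (ncol(df) >= 4) df[[4]][first] else "BP",
                        stringsAsFactors = FALSE)
  }
  go_annotation(members, terms)
}

#' Write a GO annotation as TSV (term_id, gene_id, name, namespace)
#'
#' @param annotation A [go_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "go_annotation"))
  n <- lengths(annotation$members)
  idx <- match(rep(names(annotation$members), n), annotation$terms$term_id)
  df <- data.frame(term_id = rep(names(annotation$members), n),
                   gene_id = unlist(annotation$members, use.names = FALSE),
                   name = annotation$terms$name[idx],
                   namespace = annotation$terms$namespace[idx],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GO annotation from a GAF 2.x file
#'
#' Uses column 2 (gene/product id) and column 5 (GO id), ignoring
#' qualifiers; the aspect column (9) supplies the namespace (P/F/C mapped to
#' BP/MF/CC). Comment lines starting with `!` are skipped.
#'
#' @param path GAF path (uncompressed).
#' @return A [go_annotation()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(go_annotation(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) stop("GAF records need at least 9 columns")
  gene <- vapply(fields, `[[`, "", 2)
  term <- vapply(fields, `[[`, "", 5)
  aspect <- vapply(fields, `[[`, "", 9)
  ns <- c(P = "BP", F = "MF", C = "CC")[aspect]
  ns[is.na(ns)] <- "BP"
  members <- split(gene, term)
  first <- !duplicated(term)
  terms <- data.frame(term_id = term[first], name = term[first],
                      namespace = ns[first], stringsAsFactors = FALSE)
  go_annotation(members, terms)
}

#' Read a long-format qPCR Ct table (condition, gene, replicate, ct)
#'
#' @param path TSV path with a header naming the four columns.
#' @return A `ct_table` data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a data.frame as TSV (helper shared by the pipeline writers)
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-contrast DE result written by the pipeline
#' @param path TSV path with columns gene_id, logFC, logCPM, PValue, FDR.
#' @return A `de_result` data.frame.
#' @export
read_de_result <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "logFC", "logCPM", "PValue", "FDR")
  if (!all(need %in% names(df)))
    stop("DE result needs columns: ", paste(need, collapse = ", "))
  class(df) <- c("de_result", "data.frame")
  df
}
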
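#' Shared cold-induced Arabidopsis genes reported for the 0/4/10 degC study
#'
#' The 50 genes reported as shared between at least two of the three
#' per-temperature top-50 induced-gene lists (31 shared by all three
#' treatments, 9 exclusive to 0 and 4 degC, 8 to 4 and 10 degC, 2 to 0 and
#' 10 degC), with the printed per-treatment log2 fold changes. Shipped as a
#' plain-text fixture so the Venn partitioning can be exercised on real
#' published gene lists.
#'
#' @return data.frame with columns `gene_id`, `symbol`, `regions`
#'   (semicolon-joined condition labels) and `logFC_0C`, `logFC_4C`,
#'   `logFC_10C` (NA where the treatment is not part of the region).
#' @export
published_shared_induced_genes <- function() {
  path <- system.file("extdata", "arabidopsis_cold_shared_induced_genes.tsv",
                      package = "coldtx", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reconstruct the three per-temperature top-50 sets from the shared lists
#'
#' Only the shared portions of the per-temperature top-50 lists were
#' published gene by gene; each temperature's remaining slots were genes
#' unique to that temperature. This helper rebuilds the three sets by taking
#' each temperature's shared genes and padding to `n` with per-temperature
#' placeholder ids (`only_<condition>_k`), which by construction fall into
#' the single-set Venn regions and leave all shared-region counts intact.
#'
#' @param n Set size to pad to (default 50).
#' @return Named list of three character vectors (`0C`, `4C`, `10C`), each of
#'   length `n`.
#' @export
published_top_induced_sets <- function(n = 50) {
  shared <- published_shared_induced_genes()
  conds <- c("0C", "4C", "10C")
  sets <- lapply(conds, function(cc) {
    members <- shared$gene_id[vapply(strsplit(shared$regions, ";"),
                                     function(r) cc %in% r, logical(1))]
    if (length(members) > n)
      stop("more shared genes than the requested set size")
    pad <- sprintf("only_%s_%02d", cc, seq_len(n - length(members)))
    c(members, pad)
  })
  stats::setNames(sets, conds)
}
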
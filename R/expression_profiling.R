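# TPM-threshold gene selection and per-cluster expressed/total ratios.

#' Read a genes-by-samples TPM table
#'
#' Tab-separated with a header; first column `gene_id`, remaining columns
#' sample labels. Negative values are rejected.
#'
#' @param path Input path.
#' @return A numeric matrix with gene ids as row names.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expression table must start with a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop("non-numeric TPM value in expression table")
  if (any(m < 0)) stop("negative TPM value in expression table")
  m
}

#' Write a TPM matrix as tab-separated text
#'
#' @param tpm Numeric matrix with gene ids as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tpm, path) {
  out <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select highly expressed genes in one sample
#'
#' Inclusive threshold: genes with `TPM >= threshold` in `sample`.
#'
#' @param tpm Numeric genes-by-samples matrix.
#' @param sample Sample column label.
#' @param threshold TPM threshold (inclusive).
#' @return Character vector of selected gene ids.
#' @export
select_highly_expressed <- function(tpm, sample, threshold) {
  if (!(sample %in% colnames(tpm))) stop("unknown sample: ", sample)
  rownames(tpm)[tpm[, sample] >= threshold]
}

#' Per-cluster expressed/total ratios
#'
#' @param selected Gene ids passing the expression threshold.
#' @param clusters A `cluster_set`.
#' @return Data frame: `cluster_id`, `n_selected`, `n_total`, `ratio`.
#' @export
cluster_expression_ratios <- function(selected, clusters) {
  data.frame(
    cluster_id = clusters$cluster_id,
    n_selected = vapply(clusters$members, function(m)
      sum(m %in% selected), 0L),
    n_total = clusters$n_members,
    ratio = vapply(clusters$members, function(m)
      sum(m %in% selected) / length(m), 0),
    stringsAsFactors = FALSE
  )
}

#' Highly expressed clusters
#'
#' A cluster counts as highly expressed when more than `min_ratio` of its
#' members pass the expression threshold (default: more than half).
#'
#' @param ratios Output of [cluster_expression_ratios()].
#' @param min_ratio Exclusive ratio cut-off (default 0.5).
#' @return Integer vector of cluster ids.
#' @export
highly_expressed_clusters <- function(ratios, min_ratio = 0.5) {
  ratios$cluster_id[ratios$ratio > min_ratio]
}
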
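# Gene x fingerprint occurrence profiling.

#' Build the gene-by-fingerprint occurrence matrix
#'
#' Rows are genes (including zero-ZnF genes as all-zero rows, so cluster
#' denominators match the gene census), columns are distinct fingerprint
#' triplets, cells are occurrence counts. Columns are ordered by descending
#' genome-wide total, ties lexicographic.
#'
#' @param annotations A named list of `znf_annotation` objects.
#' @return An integer matrix of class `fingerprint_matrix`.
#' @export
build_fingerprint_matrix <- function(annotations) {
  genes <- vapply(annotations, `[[`, character(1), "gene_id")
  fps_by_gene <- lapply(annotations, function(a) a$znfs$fingerprint)
  all_fps <- sort(unique(unlist(fps_by_gene, use.names = FALSE)))
  m <- matrix(0L, nrow = length(genes), ncol = length(all_fps),
              dimnames = list(genes, all_fps))
  for (i in seq_along(genes)) {
    if (!length(fps_by_gene[[i]])) next
    tab <- table(fps_by_gene[[i]])
    m[i, names(tab)] <- as.integer(tab)
  }
  if (ncol(m)) {
    ord <- order(-colSums(m), colnames(m))
    m <- m[, ord, drop = FALSE]
  }
  class(m) <- c("fingerprint_matrix", class(m))
  m
}

#' Dominant fingerprint species within a gene subset
#'
#' Restricts the matrix to `gene_subset`, ranks fingerprints by their subset
#' total (descending, ties lexicographic), keeps the top `top_k` species
#' whose subset total is at least `min_count`, and reports how many of the
#' subset's ZnFs those species cover.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param gene_subset Non-empty character vector of row names (e.g. the
#'   pooled members of one or more clusters).
#' @param min_count Minimum within-subset occurrence for a species to count.
#' @param top_k Number of top species considered.
#' @return A list: `n_znf` (subset total), `n_covered`, `fraction`, and
#'   `top_species` (data frame of the retained species and counts).
#' @export
top_species_stats <- function(matrix, gene_subset, min_count = 10L, top_k = 5L) {
  if (!length(gene_subset)) stop("empty gene subset")
  missing <- setdiff(gene_subset, rownames(matrix))
  if (length(missing)) {
    stop("gene(s) not in fingerprint matrix: ", paste(missing, collapse = ", "))
  }
  sub <- matrix[gene_subset, , drop = FALSE]
  tot <- colSums(sub)
  n_znf <- sum(tot)
  ord <- order(-tot, names(tot))
  sel <- utils::head(ord[tot[ord] >= min_count], top_k)
  covered <- sum(tot[sel])
  list(
    n_znf = as.integer(n_znf),
    n_covered = as.integer(covered),
    fraction = if (n_znf > 0) covered / n_znf else 0,
    top_species = data.frame(fingerprint = names(tot)[sel],
                             count = as.integer(tot[sel]),
                             stringsAsFactors = FALSE)
  )
}

#' Per-fingerprint cluster exclusivity
#'
#' For every fingerprint and cluster, reports the on-cluster occurrence
#' count, the genome-wide count, and the exclusivity fraction (on-cluster /
#' genome-wide).
#'
#' @param matrix A `fingerprint_matrix`; every clustered gene must be a row.
#' @param clusters A `cluster_set`.
#' @return A long data frame: `fingerprint`, `cluster_id`, `n_on_cluster`,
#'   `n_genome`, `exclusivity`.
#' @export
fingerprint_exclusivity <- function(matrix, clusters) {
  clustered <- unlist(clusters$members, use.names = FALSE)
  missing <- setdiff(clustered, rownames(matrix))
  if (length(missing)) {
    stop("clustered gene(s) missing from fingerprint matrix: ",
         paste(missing, collapse = ", "))
  }
  genome <- colSums(matrix)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    on <- colSums(matrix[clusters$members[[i]], , drop = FALSE])
    data.frame(fingerprint = names(genome),
               cluster_id = clusters$cluster_id[i],
               n_on_cluster = as.integer(on),
               n_genome = as.integer(genome),
               exclusivity = ifelse(genome > 0, on / genome, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(fingerprint = character(), cluster_id = integer(),
                      n_on_cluster = integer(), n_genome = integer(),
                      exclusivity = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Write the fingerprint matrix in wide and long form
#'
#' @param matrix A `fingerprint_matrix`.
#' @param wide_path,long_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_fingerprint_matrix <- function(matrix, wide_path = NULL, long_path = NULL) {
  if (!is.null(wide_path)) {
    wide <- data.frame(gene_id = rownames(matrix),
                       as.data.frame(unclass(matrix)),
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(wide, wide_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(long_path)) {
    idx <- which(unclass(matrix) > 0, arr.ind = TRUE)
    long <- data.frame(gene_id = rownames(matrix)[idx[, 1]],
                       fingerprint = colnames(matrix)[idx[, 2]],
                       count = matrix[idx],
                       stringsAsFactors = FALSE)
    long <- long[order(long$gene_id, long$fingerprint), , drop = FALSE]
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(wide_path, long_path))
}
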
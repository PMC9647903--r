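# Gap-rule cluster calling.
#
# A cluster is a maximal run of same-chromosome genes in which every
# neighbour gap is at most max_gap, with at least min_size members.

#' Cluster-calling parameters
#'
#' Defaults follow the family-wide convention: neighbour gaps of at most
#' 200 kb and at least two genes per cluster. The gap metric between two
#' start-sorted neighbours defaults to `end(prev) -> start(next)` (the
#' strictest interval reading; overlapping or book-ended genes give a gap
#' <= 0 and always co-cluster); `start_start` and `midpoint` are available
#' for sensitivity analysis.
#'
#' @param max_gap Maximum neighbour gap in base pairs (>= 0).
#' @param min_size Minimum genes per cluster (>= 2).
#' @param gap_metric One of `"end_start"`, `"start_start"`, `"midpoint"`.
#' @return A `cluster_params` object.
#' @export
cluster_params <- function(max_gap = 200000L, min_size = 2L,
                           gap_metric = c("end_start", "start_start", "midpoint")) {
  gap_metric <- match.arg(gap_metric)
  max_gap <- as.numeric(max_gap)
  min_size <- as.integer(min_size)
  if (is.na(max_gap) || max_gap < 0) stop("max_gap must be >= 0")
  if (is.na(min_size) || min_size < 2L) stop("min_size must be >= 2")
  structure(list(max_gap = max_gap, min_size = min_size,
                 gap_metric = gap_metric),
            class = "cluster_params")
}

empty_cluster_set <- function() {
  out <- data.frame(cluster_id = integer(), chromosome = character(),
                    span_start = integer(), span_end = integer(),
                    n_members = integer(), stringsAsFactors = FALSE)
  out$members <- list()
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Call gene clusters under the gap rule
#'
#' Per chromosome, genes are sorted by start (ties by end, then gene id); a
#' new run starts whenever the gap to the previous gene exceeds `max_gap`;
#' runs with fewer than `min_size` genes are discarded. Cluster ids are
#' assigned 1..N in (chromosome lexicographic, start) order. Strand is
#' ignored.
#'
#' @param table A `gene_table`.
#' @param params A [cluster_params()].
#' @return A `cluster_set` data frame: `cluster_id`, `chromosome`,
#'   `span_start`, `span_end`, `n_members` and a `members` list column of
#'   gene ids ordered by start.
#' @export
call_clusters <- function(table, params = cluster_params()) {
  stopifnot(inherits(table, "gene_table"))
  if (!nrow(table)) return(empty_cluster_set())
  rows <- list()
  for (chrom in sort(unique(table$chromosome))) {
    sub <- table[table$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$gene_id), , drop = FALSE]
    n <- nrow(sub)
    gaps <- if (n < 2L) numeric() else switch(
      params$gap_metric,
      end_start = sub$start[-1] - sub$end[-n],
      start_start = diff(sub$start),
      midpoint = diff((sub$start + sub$end) / 2)
    )
    breaks <- c(0L, which(gaps > params$max_gap), n)
    for (b in seq_len(length(breaks) - 1L)) {
      idx <- (breaks[b] + 1L):breaks[b + 1L]
      if (length(idx) < params$min_size) next
      rows[[length(rows) + 1L]] <- list(
        chromosome = chrom,
        span_start = min(sub$start[idx]),
        span_end = max(sub$end[idx]),
        n_members = length(idx),
        members = sub$gene_id[idx]
      )
    }
  }
  if (!length(rows)) return(empty_cluster_set())
  out <- data.frame(
    cluster_id = seq_along(rows),
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    span_start = vapply(rows, function(r) as.integer(r$span_start), 0L),
    span_end = vapply(rows, function(r) as.integer(r$span_end), 0L),
    n_members = vapply(rows, `[[`, 0L, "n_members"),
    stringsAsFactors = FALSE
  )
  out$members <- lapply(rows, `[[`, "members")
  attr(out, "params") <- params
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Summarise a cluster call
#'
#' @param clusters A `cluster_set` produced from `table`.
#' @param table The `gene_table` the clusters were called on.
#' @return A list: `n_clusters`, `n_genes`, `n_clustered`, `n_unclustered`,
#'   `genes_per_chromosome` (named vector) and `cluster_sizes`.
#' @export
cluster_census <- function(clusters, table) {
  clustered <- unlist(clusters$members, use.names = FALSE)
  list(
    n_clusters = nrow(clusters),
    n_genes = nrow(table),
    n_clustered = length(clustered),
    n_unclustered = nrow(table) - length(clustered),
    genes_per_chromosome = table(table$chromosome),
    cluster_sizes = setNames(clusters$n_members,
                             paste0("cluster_", clusters$cluster_id))
  )
}

#' Map genes to their cluster
#'
#' @param clusters A `cluster_set`.
#' @param table A `gene_table`.
#' @return Named integer vector over `table$gene_id`; `NA` for unclustered
#'   genes.
#' @export
cluster_membership <- function(clusters, table) {
  mem <- setNames(rep(NA_integer_, nrow(table)), table$gene_id)
  for (i in seq_len(nrow(clusters))) {
    mem[clusters$members[[i]]] <- clusters$cluster_id[i]
  }
  mem
}

#' Write a cluster table as tab-separated text
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- clusters
  out$members <- vapply(clusters$members, paste, character(1), collapse = ",")
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
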
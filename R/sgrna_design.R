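# Multi-target sgRNA design from linker regions.
#
# Candidates are 20-nt protospacers immediately 5' of an NGG whose triplet
# starts inside a linker tile, read on the coding strand from the full CDS
# (so windows may extend into the preceding ZnF tile). Cut-site prediction
# searches both strands; PAM matching is always exact NGG, mismatch
# tolerance applies to the protospacer only.

PROTOSPACER_LEN <- 20L

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

empty_candidates <- function(target_clusters = NULL) {
  out <- data.frame(protospacer = character(), pam = character(),
                    design_frequency = integer(), stringsAsFactors = FALSE)
  attr(out, "target_clusters") <- target_clusters
  attr(out, "n_skipped") <- 0L
  class(out) <- c("sgrna_candidates", "data.frame")
  out
}

#' Enumerate multi-target sgRNA candidates from linker tiles
#'
#' For every NGG motif starting inside a linker tile of a target gene, takes
#' the 20 nt immediately 5' of the N on the coding strand (drawn from the
#' full CDS). Identical protospacers are merged; `design_frequency` is the
#' number of source windows. Candidates are ranked by descending frequency,
#' ties broken lexicographically. PAMs with fewer than 20 nt of upstream CDS
#' are skipped and counted.
#'
#' @param annotations Named list of `znf_annotation` objects.
#' @param target_genes Gene ids to design against (default: all annotated).
#' @param target_clusters Optional cluster id(s) the design targets; carried
#'   on the result for specificity scoring.
#' @return A ranked `sgrna_candidates` data frame (`protospacer`, `pam`,
#'   `design_frequency`) with attributes `target_clusters` and `n_skipped`.
#' @export
enumerate_candidates <- function(annotations, target_genes = NULL,
                                 target_clusters = NULL) {
  if (is.null(target_genes)) target_genes <- names(annotations)
  missing <- setdiff(target_genes, names(annotations))
  if (length(missing)) {
    stop("unannotated target gene(s): ", paste(missing, collapse = ", "))
  }
  protos <- character()
  pams <- character()
  n_skipped <- 0L
  for (g in target_genes) {
    a <- annotations[[g]]
    if (!nrow(a$linkers)) next
    for (j in seq_len(nrow(a$linkers))) {
      base0 <- 3L * (a$linkers$aa_start[j] - 1L)
      for (o in a$linkers$pam_offsets[[j]]) {
        pam0 <- base0 + o             # 0-based PAM start in the CDS
        if (pam0 < PROTOSPACER_LEN) {
          n_skipped <- n_skipped + 1L
          next
        }
        protos <- c(protos, substr(a$cds_seq, pam0 - PROTOSPACER_LEN + 1L, pam0))
        pams <- c(pams, substr(a$cds_seq, pam0 + 1L, pam0 + 3L))
      }
    }
  }
  if (!length(protos)) {
    out <- empty_candidates(target_clusters)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  freq <- table(protos)
  pam_of <- vapply(names(freq), function(p) {
    pp <- sort(table(pams[protos == p]), decreasing = TRUE)
    names(pp)[1]
  }, character(1))
  out <- data.frame(protospacer = names(freq), pam = unname(pam_of),
                    design_frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$design_frequency, out$protospacer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_clusters") <- target_clusters
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("sgrna_candidates", "data.frame")
  out
}

#' Keep the top-k candidates by design frequency
#'
#' Rank is the deterministic order of [enumerate_candidates()] (descending
#' frequency, ties lexicographic). Fewer than `k` candidates are returned
#' with a notice.
#'
#' @param candidates An `sgrna_candidates` data frame.
#' @param k Number of candidates to keep (default 11).
#' @return The first `k` rows (attributes preserved).
#' @export
select_top <- function(candidates, k = 11L) {
  if (nrow(candidates) < k) {
    message("only ", nrow(candidates), " candidate(s) available (k = ", k, ")")
  }
  out <- utils::head(candidates, k)
  attr(out, "target_clusters") <- attr(candidates, "target_clusters")
  attr(out, "n_skipped") <- attr(candidates, "n_skipped")
  class(out) <- class(candidates)
  out
}

# Hits of `proto` in `seq` with <= max_mismatches substitutions in the
# protospacer and an exact NGG immediately 3'. Returns 1-based starts and
# mismatch counts.
protospacer_hits <- function(proto, seq, max_mismatches = 0L) {
  plen <- nchar(proto)
  n <- nchar(seq)
  if (n < plen + 3L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  m <- Biostrings::matchPattern(proto, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatches,
                                with.indels = FALSE)
  st <- BiocGenerics::start(m)
  st <- st[st >= 1L & st + plen + 2L <= n]
  if (!length(st)) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  keep <- substr(rep(seq, length(st)), st + plen + 1L, st + plen + 2L) == "GG"
  st <- st[keep]
  pchars <- strsplit(proto, "")[[1]]
  schars <- strsplit(seq, "")[[1]]
  mm <- vapply(st, function(s) sum(schars[s:(s + plen - 1L)] != pchars), 0L)
  data.frame(start = st, mismatches = mm)
}

#' Predict cut sites of a candidate across a gene set
#'
#' Scans each gene's CDS (both strands by default) for the protospacer
#' followed immediately by an NGG PAM, allowing at most `max_mismatches`
#' substitutions in the protospacer; the PAM must be exact. Positions are
#' 0-based offsets of the protospacer start in the searched sequence (the
#' CDS for `+`, its reverse complement for `-`).
#'
#' @param candidate A protospacer string, or a one-row `sgrna_candidates`
#'   slice.
#' @param table A sequenced `gene_table`.
#' @param max_mismatches Maximum protospacer substitutions (default 0:
#'   exact-match predicted cleavage sites).
#' @param both_strands Search the reverse complement too (default TRUE).
#' @return A `cut_sites` data frame: `gene_id`, `strand`, `position`,
#'   `mismatches`.
#' @export
predict_cut_sites <- function(candidate, table, max_mismatches = 0L,
                              both_strands = TRUE) {
  proto <- if (is.character(candidate)) candidate else candidate$protospacer
  stopifnot(length(proto) == 1L, !is.na(proto))
  rows <- list()
  for (i in which(table$sequenced)) {
    cds <- table$cds_seq[i]
    strands <- c("+" = cds)
    if (both_strands) strands <- c(strands, "-" = revcomp(cds))
    for (s in names(strands)) {
      h <- protospacer_hits(proto, strands[[s]], max_mismatches)
      if (nrow(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = table$gene_id[i], strand = s,
          position = h$start - 1L, mismatches = h$mismatches,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), strand = character(),
               position = integer(), mismatches = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cut_sites", "data.frame")
  out
}

#' Cluster-specificity report for a candidate set
#'
#' Predicts cut sites for every candidate across the full gene table and
#' aggregates them by the cluster membership of the harbouring gene (plus
#' an `unclustered` column). The on-target fraction is the share of sites
#' inside the candidates' target clusters; candidates with zero sites get
#' `NA` (undefined), not 0.
#'
#' @param candidates An `sgrna_candidates` data frame (its
#'   `target_clusters` attribute defines on-target, unless overridden).
#' @param table A sequenced `gene_table` (the full search space).
#' @param clusters A `cluster_set` on the same table.
#' @param target_clusters Optional override of the candidates' target
#'   cluster ids.
#' @param max_mismatches Passed to [predict_cut_sites()].
#' @return A `specificity_report`: list with `counts` (candidate x cluster
#'   matrix), `total_sites`, `on_target_fraction`, `target_clusters`.
#' @export
specificity_report <- function(candidates, table, clusters,
                               target_clusters = NULL, max_mismatches = 0L) {
  if (is.null(target_clusters)) {
    target_clusters <- attr(candidates, "target_clusters")
  }
  membership <- cluster_membership(clusters, table)
  col_ids <- c(as.character(clusters$cluster_id), "unclustered")
  counts <- matrix(0L, nrow = nrow(candidates), ncol = length(col_ids),
                   dimnames = list(candidates$protospacer, col_ids))
  for (i in seq_len(nrow(candidates))) {
    sites <- predict_cut_sites(candidates$protospacer[i], table,
                               max_mismatches = max_mismatches)
    if (!nrow(sites)) next
    cl <- membership[sites$gene_id]
    cl <- ifelse(is.na(cl), "unclustered", as.character(cl))
    tab <- table(cl)
    counts[i, names(tab)] <- as.integer(tab)
  }
  total <- rowSums(counts)
  on_cols <- intersect(as.character(target_clusters), colnames(counts))
  on <- if (length(on_cols)) rowSums(counts[, on_cols, drop = FALSE]) else
    rep(0, nrow(counts))
  frac <- ifelse(total > 0, on / total, NA_real_)
  structure(list(counts = counts, total_sites = total,
                 on_target_fraction = frac,
                 target_clusters = target_clusters),
            class = "specificity_report")
}

#' Write candidate and specificity tables
#'
#' @param report A `specificity_report`.
#' @param candidates The matching `sgrna_candidates`.
#' @param path Output path (tab-separated; one row per candidate with
#'   per-cluster counts, total and on-target fraction).
#' @return `path`, invisibly.
#' @export
write_specificity_table <- function(report, candidates, path) {
  out <- data.frame(protospacer = candidates$protospacer,
                    pam = candidates$pam,
                    design_frequency = candidates$design_frequency,
                    report$counts,
                    total_sites = report$total_sites,
                    on_target_fraction = report$on_target_fraction,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
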
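# Reading/writing gene tables, FASTA binding, BED export.
#
# Coordinate convention: gene tables are 1-based inclusive (genome-browser
# style); BED output is 0-based half-open.

GENE_TABLE_COLUMNS <- c("gene_id", "species", "chromosome", "start", "end", "strand")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a tab-separated gene coordinate table
#'
#' The table must carry a header naming the six required columns
#' `gene_id`, `species`, `chromosome`, `start`, `end`, `strand`.
#' Coordinates are 1-based inclusive. Strand values other than `+` or `-`
#' are normalised to `"*"` (unknown). Row order is preserved.
#'
#' @param path Path to the tab-separated file.
#' @param species_filter Optional character vector; keep only rows whose
#'   `species` is in this set.
#' @return A `gene_table` data frame (one row per gene) with empty sequence
#'   slots; fill them with [bind_sequences()].
#' @export
read_gene_table <- function(path, species_filter = NULL) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  missing_cols <- setdiff(GENE_TABLE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("non-integer coordinate at line ", bad[1] + 1L,
         " (gene ", raw$gene_id[bad[1]], ")")
  }
  bad <- which(start > end)
  if (length(bad)) {
    stop("start > end at line ", bad[1] + 1L,
         " (gene ", raw$gene_id[bad[1]], ")")
  }
  gt <- data.frame(
    gene_id = raw$gene_id,
    species = raw$species,
    chromosome = raw$chromosome,
    start = start,
    end = end,
    strand = ifelse(raw$strand %in% c("+", "-"), raw$strand, "*"),
    protein_seq = NA_character_,
    cds_seq = NA_character_,
    sequenced = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(species_filter)) {
    gt <- gt[gt$species %in% species_filter, , drop = FALSE]
    rownames(gt) <- NULL
  }
  if (anyDuplicated(gt$gene_id)) {
    stop("duplicate gene_id in gene table: ",
         paste(unique(gt$gene_id[duplicated(gt$gene_id)]), collapse = ", "))
  }
  attr(gt, "provenance") <- path
  class(gt) <- c("gene_table", "data.frame")
  gt
}

#' Write a gene table back to tab-separated text
#'
#' Writes the six defined columns; round-trips through [read_gene_table()].
#'
#' @param table A `gene_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  utils::write.table(table[, GENE_TABLE_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene table in code
#'
#' Convenience constructor used by the synthetic generator and by tests.
#'
#' @param gene_id,chromosome,start,end Required vectors (recycled where
#'   length 1).
#' @param species,strand Optional vectors; default `"synthetic"` / `"*"`.
#' @param protein_seq,cds_seq Optional sequence vectors; when both are given
#'   for a gene it is marked as sequenced.
#' @param provenance Provenance label stored as an attribute.
#' @return A `gene_table` data frame.
#' @export
gene_table <- function(gene_id, chromosome, start, end,
                       species = "synthetic", strand = "*",
                       protein_seq = NA_character_, cds_seq = NA_character_,
                       provenance = "in-memory") {
  gt <- data.frame(gene_id = gene_id, species = species,
                   chromosome = chromosome,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, protein_seq = protein_seq,
                   cds_seq = cds_seq, stringsAsFactors = FALSE)
  gt$sequenced <- !is.na(gt$protein_seq) & !is.na(gt$cds_seq)
  if (anyDuplicated(gt$gene_id)) stop("duplicate gene_id")
  if (any(gt$start > gt$end)) stop("start > end")
  attr(gt, "provenance") <- provenance
  class(gt) <- c("gene_table", "data.frame")
  gt
}

fasta_ids <- function(xset, path) {
  ids <- sub("\\s.*$", "", names(xset))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ids
}

#' Bind protein and CDS sequences to a gene table
#'
#' Matches FASTA records to genes by `gene_id` (first whitespace-delimited
#' token of the FASTA header). Terminal `*` on proteins and a terminal stop
#' codon on the CDS are stripped, so that `nchar(cds) == 3 * nchar(protein)`
#' for every bound gene. Genes absent from either FASTA stay in the table
#' flagged unsequenced and are excluded from sequence-dependent stages.
#'
#' @param table A `gene_table`.
#' @param protein_fasta,cds_fasta Paths to the protein and CDS FASTA files.
#' @return The table with `protein_seq`, `cds_seq` and `sequenced` filled in.
#' @export
bind_sequences <- function(table, protein_fasta, cds_fasta) {
  stopifnot(inherits(table, "gene_table"))
  aa <- Biostrings::readAAStringSet(protein_fasta)
  nt <- Biostrings::readDNAStringSet(cds_fasta)
  aa_ids <- fasta_ids(aa, protein_fasta)
  nt_ids <- fasta_ids(nt, cds_fasta)
  prot <- setNames(sub("\\*+$", "", as.character(aa)), aa_ids)
  cds <- setNames(toupper(as.character(nt)), nt_ids)

  errors <- character()
  for (i in seq_len(nrow(table))) {
    id <- table$gene_id[i]
    if (!(id %in% aa_ids) || !(id %in% nt_ids)) next
    p <- prot[[id]]
    cc <- cds[[id]]
    len_aa <- nchar(p)
    last_codon <- substr(cc, nchar(cc) - 2L, nchar(cc))
    if (nchar(cc) == 3L * len_aa + 3L && last_codon %in% STOP_CODONS) {
      cc <- substr(cc, 1L, nchar(cc) - 3L)
    }
    if (nchar(cc) != 3L * len_aa) {
      errors <- c(errors, sprintf(
        "%s: CDS length %d inconsistent with protein length %d",
        id, nchar(cc), len_aa))
      next
    }
    table$protein_seq[i] <- p
    table$cds_seq[i] <- cc
    table$sequenced[i] <- TRUE
  }
  if (length(errors)) {
    stop("sequence binding failed for ", length(errors), " gene(s):\n  ",
         paste(errors, collapse = "\n  "))
  }
  n_missing <- sum(!table$sequenced)
  if (n_missing > 0) {
    message(n_missing, " gene(s) without FASTA entries remain unsequenced")
  }
  table
}

#' Export clusters as BED6
#'
#' Converts the 1-based inclusive cluster spans to 0-based half-open BED
#' intervals. Name is `cluster_<id>`, score is the member count, strand is
#' `"."`. Chromosomes are ordered lexicographically.
#'
#' @param clusters A `cluster_set` from [call_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path) {
  if (!nrow(clusters)) {
    writeLines("# no clusters", path)
    return(invisible(path))
  }
  cl <- clusters[order(clusters$chromosome, clusters$span_start), , drop = FALSE]
  for (chrom in unique(cl$chromosome)) {
    sub <- cl[cl$chromosome == chrom, , drop = FALSE]
    if (nrow(sub) > 1 &&
        any(sub$span_start[-1] <= sub$span_end[-nrow(sub)])) {
      stop("overlapping clusters on ", chrom, "; refusing to write BED")
    }
  }
  lines <- sprintf("%s\t%d\t%d\tcluster_%d\t%d\t.",
                   cl$chromosome, cl$span_start - 1L, cl$span_end,
                   cl$cluster_id, cl$n_members)
  writeLines(lines, path)
  invisible(path)
}

#' Write bound sequences out as FASTA
#'
#' @param table A sequenced `gene_table`.
#' @param protein_fasta,cds_fasta Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_sequences <- function(table, protein_fasta, cds_fasta) {
  keep <- table[table$sequenced, , drop = FALSE]
  aa <- Biostrings::AAStringSet(setNames(keep$protein_seq, keep$gene_id))
  nt <- Biostrings::DNAStringSet(setNames(keep$cds_seq, keep$gene_id))
  Biostrings::writeXStringSet(aa, protein_fasta)
  Biostrings::writeXStringSet(nt, cds_fasta)
  invisible(list(protein = protein_fasta, cds = cds_fasta))
}
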
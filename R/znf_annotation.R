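# C2H2 zinc-finger array decomposition.
#
# Two overlapping tile sets cover an array: "ZnF" tiles run from the first
# zinc-coordinating cysteine pair to the histidine pair (CXXC ... HXXXH), and
# "linker" tiles run from one finger's HXXXH through the next finger's CXXC,
# so consecutive tiles share the coordinating residues.

#' C2H2 pattern configuration
#'
#' Default spacing is C-X2-C-X12-H-X3-H (21 residues). Each spacer can be
#' given as a `c(min, max)` range; matching is greedy leftmost
#' non-overlapping, and within a variable-range match the lexicographically
#' smallest spacer lengths are preferred (deterministic tie-break).
#'
#' @param c_spacer Residues between the two cysteines, `c(min, max)`.
#' @param mid_spacer Residues between second Cys and first His.
#' @param h_spacer Residues between the two histidines.
#' @return A `pattern_config` object.
#' @export
pattern_config <- function(c_spacer = c(2L, 2L), mid_spacer = c(12L, 12L),
                           h_spacer = c(3L, 3L)) {
  chk <- function(r, nm) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || anyNA(r) || r[1] < 0L || r[1] > r[2]) {
      stop("invalid spacer range for ", nm)
    }
    r
  }
  structure(list(c_spacer = chk(c_spacer, "c_spacer"),
                 mid_spacer = chk(mid_spacer, "mid_spacer"),
                 h_spacer = chk(h_spacer, "h_spacer")),
            class = "pattern_config")
}

spacer_re <- function(r) {
  if (r[1] == r[2]) sprintf("(.{%d})", r[1]) else sprintf("(.{%d,%d}?)", r[1], r[2])
}

znf_regex <- function(pattern, anchored = FALSE) {
  re <- paste0("C", spacer_re(pattern$c_spacer),
               "C", spacer_re(pattern$mid_spacer),
               "H", spacer_re(pattern$h_spacer), "H")
  if (anchored) paste0("^", re, "$") else re
}

# Spacer lengths (a, b, c) and the 1-based position of the first
# zinc-coordinating histidine within a matched unit.
decompose_znf <- function(znf_aa, pattern) {
  m <- regexec(znf_regex(pattern, anchored = TRUE), znf_aa, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("sequence does not match the C2H2 pattern: ", znf_aa)
  lens <- attr(m, "match.length")[2:4]
  list(a = lens[1], b = lens[2], c = lens[3],
       h1 = 3L + lens[1] + lens[2])
}

#' Extract the DNA-binding fingerprint triplet of a zinc finger
#'
#' The fingerprint is the amino-acid triplet at recognition-helix positions
#' -1, +3 and +6. Anchored on the first zinc-coordinating histidine H1 (helix
#' position +7), these are the residues at offsets H1-8, H1-4 and H1-1 within
#' the ZnF tile, concatenated N to C.
#'
#' @param znf_aa Amino-acid sequence of one ZnF tile (CXXC ... HXXXH).
#' @param pattern A [pattern_config()].
#' @return A 3-letter character string.
#' @export
extract_fingerprint <- function(znf_aa, pattern = pattern_config()) {
  d <- decompose_znf(znf_aa, pattern)
  paste0(substr(znf_aa, d$h1 - 8L, d$h1 - 8L),
         substr(znf_aa, d$h1 - 4L, d$h1 - 4L),
         substr(znf_aa, d$h1 - 1L, d$h1 - 1L))
}

empty_znf_df <- function() {
  data.frame(ordinal = integer(), aa_start = integer(), aa_end = integer(),
             aa_seq = character(), nt_seq = character(),
             fingerprint = character(), stringsAsFactors = FALSE)
}

empty_linker_df <- function() {
  out <- data.frame(ordinal = integer(), aa_start = integer(),
                    aa_end = integer(), aa_seq = character(),
                    nt_seq = character(), stringsAsFactors = FALSE)
  out$pam_offsets <- list()
  out
}

# 0-based offsets of NGG triplet starts on the given (coding) strand.
ngg_offsets <- function(nt) {
  hits <- gregexpr("(?=.GG)", nt, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}

tile_nt <- function(cds, aa_start, aa_end) {
  substr(cds, 3L * (aa_start - 1L) + 1L, 3L * aa_end)
}

#' Decompose one gene into ZnF and linker tiles
#'
#' Scans the protein with a greedy leftmost non-overlapping C2H2 pattern
#' search. Each match becomes a ZnF tile with its fingerprint; each pair of
#' consecutive matches yields a linker tile running from the first match's
#' HXXXH through the next match's CXXC. Tile nucleotide sequences are read
#' off the CDS by codon position, and NGG motif offsets (coding strand,
#' 0-based) are recorded for every linker.
#'
#' @param gene A single-row `gene_table` slice (or any list) with bound
#'   `protein_seq` and `cds_seq`; `nchar(cds_seq)` must equal
#'   `3 * nchar(protein_seq)`.
#' @param pattern A [pattern_config()].
#' @return A `znf_annotation` object: list with `gene_id`, `znfs` and
#'   `linkers` data frames, `unmatched_tail_aa`, `n_znfs`, and the source
#'   sequences. Genes with zero matches return an empty annotation flagged
#'   `no_znf`.
#' @export
annotate_znf_array <- function(gene, pattern = pattern_config()) {
  prot <- gene$protein_seq
  cds <- gene$cds_seq
  if (is.na(prot) || is.na(cds)) stop("gene has no bound sequences: ", gene$gene_id)
  if (nchar(cds) != 3L * nchar(prot)) {
    stop("CDS/protein mapping out of range for ", gene$gene_id,
         " (", nchar(cds), " nt vs ", nchar(prot), " aa)")
  }
  ann <- list(gene_id = gene$gene_id, protein_seq = prot, cds_seq = cds)

  m <- gregexpr(znf_regex(pattern), prot, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    ann$znfs <- empty_znf_df()
    ann$linkers <- empty_linker_df()
    ann$unmatched_tail_aa <- nchar(prot)
    ann$n_znfs <- 0L
    ann$no_znf <- TRUE
    class(ann) <- "znf_annotation"
    return(ann)
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  k <- length(starts)
  aa_seqs <- substring(prot, starts, starts + lens - 1L)
  dec <- lapply(aa_seqs, decompose_znf, pattern = pattern)
  ann$znfs <- data.frame(
    ordinal = seq_len(k),
    aa_start = starts,
    aa_end = starts + lens - 1L,
    aa_seq = aa_seqs,
    nt_seq = vapply(seq_len(k), function(i)
      tile_nt(cds, starts[i], starts[i] + lens[i] - 1L), character(1)),
    fingerprint = vapply(seq_len(k), function(i) {
      h1 <- dec[[i]]$h1
      paste0(substr(aa_seqs[i], h1 - 8L, h1 - 8L),
             substr(aa_seqs[i], h1 - 4L, h1 - 4L),
             substr(aa_seqs[i], h1 - 1L, h1 - 1L))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (k >= 2L) {
    l_start <- starts[-k] + vapply(dec[-k], function(d) d$h1, 0L) - 1L
    l_end <- starts[-1] + vapply(dec[-1], function(d) d$a, 0L) + 1L
    lk <- data.frame(
      ordinal = seq_len(k - 1L),
      aa_start = l_start,
      aa_end = l_end,
      aa_seq = substring(prot, l_start, l_end),
      nt_seq = vapply(seq_len(k - 1L), function(i)
        tile_nt(cds, l_start[i], l_end[i]), character(1)),
      stringsAsFactors = FALSE
    )
    lk$pam_offsets <- lapply(lk$nt_seq, ngg_offsets)
    ann$linkers <- lk
  } else {
    ann$linkers <- empty_linker_df()
  }
  ann$unmatched_tail_aa <- nchar(prot) - (starts[k] + lens[k] - 1L)
  ann$n_znfs <- k
  ann$no_znf <- FALSE
  class(ann) <- "znf_annotation"
  ann
}

#' Annotate every sequenced gene of a table
#'
#' @param table A `gene_table` with bound sequences.
#' @param pattern A [pattern_config()].
#' @return A named list of `znf_annotation` objects (sequenced genes only;
#'   the number of skipped, unsequenced genes is reported via `message()`).
#' @export
annotate_gene_table <- function(table, pattern = pattern_config()) {
  stopifnot(inherits(table, "gene_table"))
  n_skip <- sum(!table$sequenced)
  if (n_skip > 0) {
    message("skipping ", n_skip, " unsequenced gene(s) in annotation")
  }
  keep <- which(table$sequenced)
  anns <- lapply(keep, function(i) annotate_znf_array(table[i, ], pattern))
  names(anns) <- table$gene_id[keep]
  anns
}

#' Summarise a set of annotations
#'
#' @param annotations A list of `znf_annotation` objects.
#' @return A list: `n_znf` (total ZnF tiles), `n_distinct_fingerprints`, and
#'   `per_gene` (data frame of per-gene ZnF and linker counts).
#' @export
tile_census <- function(annotations) {
  if (!length(annotations)) {
    return(list(n_znf = 0L, n_distinct_fingerprints = 0L,
                per_gene = data.frame(gene_id = character(),
                                      n_znf = integer(),
                                      n_linkers = integer())))
  }
  per_gene <- data.frame(
    gene_id = vapply(annotations, `[[`, character(1), "gene_id"),
    n_znf = vapply(annotations, function(a) nrow(a$znfs), 0L),
    n_linkers = vapply(annotations, function(a) nrow(a$linkers), 0L),
    stringsAsFactors = FALSE
  )
  rownames(per_gene) <- NULL
  fps <- unlist(lapply(annotations, function(a) a$znfs$fingerprint),
                use.names = FALSE)
  list(n_znf = sum(per_gene$n_znf),
       n_distinct_fingerprints = length(unique(fps)),
       per_gene = per_gene)
}

#' Export tile annotations as a tab-separated table
#'
#' One row per tile: `gene_id`, `tile_type` (`ZnF`/`Linker`), `ordinal`,
#' `aa_start`, `aa_end`, `aa_seq`, `nt_seq`, `fingerprint` (empty for
#' linkers), `pam_offsets` (comma-separated, empty for ZnFs).
#'
#' @param annotations A list of `znf_annotation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tile_table <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    z <- a$znfs
    l <- a$linkers
    rbind(
      if (nrow(z)) data.frame(gene_id = a$gene_id, tile_type = "ZnF",
                              ordinal = z$ordinal, aa_start = z$aa_start,
                              aa_end = z$aa_end, aa_seq = z$aa_seq,
                              nt_seq = z$nt_seq, fingerprint = z$fingerprint,
                              pam_offsets = "", stringsAsFactors = FALSE),
      if (nrow(l)) data.frame(gene_id = a$gene_id, tile_type = "Linker",
                              ordinal = l$ordinal, aa_start = l$aa_start,
                              aa_end = l$aa_end, aa_seq = l$aa_seq,
                              nt_seq = l$nt_seq, fingerprint = "",
                              pam_offsets = vapply(l$pam_offsets, paste,
                                                   character(1), collapse = ","),
                              stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), tile_type = character(),
                      ordinal = integer(), aa_start = integer(),
                      aa_end = integer(), aa_seq = character(),
                      nt_seq = character(), fingerprint = character(),
                      pam_offsets = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
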
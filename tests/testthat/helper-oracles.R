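# Independent brute-force oracles. These deliberately avoid the code paths
# of the implementations they check: plain character-vector loops instead of
# regex scans or Biostrings matching.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random protein with Cys/His enriched so C2H2-like motifs actually occur.
random_protein <- function(n, p_ch = 0.22) {
  probs <- setNames(rep((1 - 2 * p_ch) / 18, 20), AA_ALPHABET)
  probs[c("C", "H")] <- p_ch
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = probs), collapse = "")
}

# Random reverse translation (uniform over synonymous codons).
random_cds_for <- function(protein) {
  syn <- split(names(Biostrings::GENETIC_CODE),
               unname(Biostrings::GENETIC_CODE))
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(syn[[a]], 1), character(1)),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force C2H2 scan: test every start position, spacer lengths in
# lexicographic order, greedy leftmost non-overlapping.
oracle_scan_znf <- function(protein, pattern = pattern_config()) {
  pv <- strsplit(protein, "")[[1]]
  n <- length(pv)
  cr <- pattern$c_spacer
  mr <- pattern$mid_spacer
  hr <- pattern$h_spacer
  res <- list()
  s <- 1L
  while (s <= n) {
    found <- NULL
    for (a in cr[1]:cr[2]) {
      for (b in mr[1]:mr[2]) {
        for (cc in hr[1]:hr[2]) {
          e <- s + 3L + a + b + cc
          if (e > n) next
          if (pv[s] == "C" && pv[s + 1L + a] == "C" &&
              pv[s + 2L + a + b] == "H" && pv[e] == "H") {
            found <- c(a, b, cc)
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      s <- s + 1L
    } else {
      len <- 4L + sum(found)
      res[[length(res) + 1L]] <- list(start = s, len = len,
                                      a = found[1], b = found[2], c = found[3])
      s <- s + len
    }
  }
  res
}

oracle_fingerprint <- function(protein, unit) {
  h1 <- unit$start + 2L + unit$a + unit$b   # absolute first-His position
  pv <- strsplit(protein, "")[[1]]
  paste0(pv[h1 - 8L], pv[h1 - 4L], pv[h1 - 1L])
}

# Candidate windows the slow way: every CDS position tested for an NGG
# starting inside a linker tile (linker spans from the oracle scan).
oracle_candidates <- function(protein, cds, pattern = pattern_config()) {
  sc <- oracle_scan_znf(protein, pattern)
  k <- length(sc)
  windows <- character()
  skips <- 0L
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      l_aa_start <- sc[[i]]$start + 2L + sc[[i]]$a + sc[[i]]$b
      l_aa_end <- sc[[i + 1L]]$start + sc[[i + 1L]]$a + 1L
      l0 <- 3L * (l_aa_start - 1L)      # 0-based tile start
      l1 <- 3L * l_aa_end - 1L          # 0-based tile end
      for (p0 in l0:(l1 - 2L)) {
        if (substr(cds, p0 + 2L, p0 + 3L) == "GG") {
          if (p0 >= 20L) {
            windows <- c(windows, substr(cds, p0 - 19L, p0))
          } else {
            skips <- skips + 1L
          }
        }
      }
    }
  }
  list(windows = windows, skips = skips)
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Sliding-window Hamming scan for protospacer + exact NGG, both strands.
oracle_cut_sites <- function(proto, seq, max_mm = 0L) {
  pv <- strsplit(proto, "")[[1]]
  plen <- length(pv)
  scan1 <- function(s, strand) {
    sv <- strsplit(s, "")[[1]]
    n <- length(sv)
    out <- list()
    if (n >= plen + 3L) {
      for (st in seq_len(n - plen - 2L)) {
        d <- sum(sv[st:(st + plen - 1L)] != pv)
        if (d <= max_mm && sv[st + plen + 1L] == "G" && sv[st + plen + 2L] == "G") {
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, position = st - 1L, mismatches = d,
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  }
  hits <- c(scan1(seq, "+"), scan1(oracle_revcomp(seq), "-"))
  if (length(hits)) do.call(rbind, hits) else
    data.frame(strand = character(), position = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
}

# Exhaustive maximal-run cluster oracle: every contiguous window of
# start-sorted genes is a cluster iff all internal gaps pass, it is big
# enough, and it cannot be extended on either side.
oracle_clusters <- function(table, params) {
  res <- list()
  for (chrom in sort(unique(table$chromosome))) {
    sub <- table[table$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$gene_id), , drop = FALSE]
    n <- nrow(sub)
    gap_ok <- function(i) {
      g <- switch(params$gap_metric,
                  end_start = sub$start[i + 1L] - sub$end[i],
                  start_start = sub$start[i + 1L] - sub$start[i],
                  midpoint = (sub$start[i + 1L] + sub$end[i + 1L]) / 2 -
                    (sub$start[i] + sub$end[i]) / 2)
      g <= params$max_gap
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1L < params$min_size) next
        if (!all(vapply(i:(j - 1L), gap_ok, TRUE))) next
        if (i > 1L && gap_ok(i - 1L)) next
        if (j < n && gap_ok(j)) next
        res[[length(res) + 1L]] <- list(chromosome = chrom,
                                        members = sub$gene_id[i:j])
      }
    }
  }
  res
}

# Independent per-position information content (all sequences same length).
oracle_ic <- function(seqs, alphabet_size) {
  chm <- do.call(rbind, strsplit(seqs, ""))
  vapply(seq_len(ncol(chm)), function(p) {
    f <- as.numeric(table(chm[, p])) / nrow(chm)
    log2(alphabet_size) + sum(f * log2(f))
  }, numeric(1))
}

# Minimal hand-made annotation object (for boundary cases the full
# annotator cannot reach, e.g. a linker at the very start of a CDS).
fake_annotation <- function(gene_id, cds, linker_aa_start, linker_nt,
                            pam_offsets) {
  lk <- data.frame(ordinal = 1L, aa_start = linker_aa_start,
                   aa_end = linker_aa_start + nchar(linker_nt) / 3 - 1,
                   aa_seq = strrep("X", nchar(linker_nt) / 3),
                   nt_seq = linker_nt, stringsAsFactors = FALSE)
  lk$pam_offsets <- list(as.integer(pam_offsets))
  structure(list(gene_id = gene_id, protein_seq = NA, cds_seq = cds,
                 znfs = data.frame(), linkers = lk,
                 unmatched_tail_aa = 0L, n_znfs = 2L, no_znf = FALSE),
            class = "znf_annotation")
}

# A small sequenced gene table built directly in memory.
toy_gene_table <- function(ids, chrom, start, end, cds = NA_character_,
                           protein = NA_character_) {
  gene_table(gene_id = ids, chromosome = chrom, start = start, end = end,
             protein_seq = protein, cds_seq = cds)
}
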
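make_gene <- function(protein, seed = 1) {
  set.seed(seed)
  list(gene_id = "g", protein_seq = protein, cds_seq = random_cds_for(protein))
}

ZNF1 <- "CAACQRSTNVWAYDKLHAAAH"   # one C-X2-C-X12-H-X3-H unit

test_that("a single C2H2 unit is annotated with its fingerprint", {
  ann <- annotate_znf_array(make_gene(ZNF1))
  expect_equal(nrow(ann$znfs), 1L)
  expect_equal(ann$znfs$aa_start, 1L)
  expect_equal(ann$znfs$aa_end, 21L)
  expect_equal(nrow(ann$linkers), 0L)
  expect_equal(ann$unmatched_tail_aa, 0L)
  # first His at position 17; fingerprint = residues 9, 13, 16
  expect_identical(ann$znfs$fingerprint, "NYL")
  expect_identical(extract_fingerprint(ZNF1), "NYL")
})

test_that("two units joined by TGEKP give one overlapping linker tile", {
  prot <- paste0(ZNF1, "TGEKP", ZNF1)
  ann <- annotate_znf_array(make_gene(prot))
  expect_equal(nrow(ann$znfs), 2L)
  expect_equal(ann$znfs$aa_start, c(1L, 27L))
  expect_equal(nrow(ann$linkers), 1L)
  # HXXXH of unit 1 (17..21) through CXXC of unit 2 (27..30)
  expect_equal(ann$linkers$aa_start, 17L)
  expect_equal(ann$linkers$aa_end, 30L)
  expect_equal(nchar(ann$linkers$aa_seq), 14L)
  expect_identical(ann$linkers$aa_seq, substr(prot, 17, 30))
  expect_identical(ann$linkers$nt_seq, substr(ann$cds_seq, 3 * 16 + 1, 3 * 30))
  # nucleotide tile maps codon-exactly
  expect_identical(translate_cds(ann$linkers$nt_seq), ann$linkers$aa_seq)
  expect_identical(translate_cds(ann$znfs$nt_seq[2]), ann$znfs$aa_seq[2])
})

test_that("fingerprints follow the His-anchored offsets", {
  # uniform spacer collapses the triplet to one letter
  expect_identical(extract_fingerprint("CAACAAAAAAAAAAAAHAAAH"), "AAA")
  expect_error(extract_fingerprint("NOTAZINCFINGER"), "does not match")
  # variable-spacer pattern anchors on the first His, not a fixed offset
  pat <- pattern_config(c_spacer = c(2, 4), mid_spacer = c(10, 14),
                        h_spacer = c(3, 5))
  znf <- "CAACQRSTNVWAYDKLMNHAAAH"   # mid spacer of 14
  d_h1 <- 19L
  expect_identical(extract_fingerprint(znf, pat),
                   paste0(substr(znf, d_h1 - 8, d_h1 - 8),
                          substr(znf, d_h1 - 4, d_h1 - 4),
                          substr(znf, d_h1 - 1, d_h1 - 1)))
})

test_that("genes without any unit keep an empty flagged annotation", {
  ann <- annotate_znf_array(make_gene("MARSTEELLKKY"))
  expect_true(ann$no_znf)
  expect_equal(ann$n_znfs, 0L)
  expect_equal(nrow(ann$linkers), 0L)
  cen <- tile_census(list(ann))
  expect_equal(cen$n_znf, 0L)
  expect_equal(cen$n_distinct_fingerprints, 0L)
})

test_that("annotation matches the brute-force scan on random proteins", {
  set.seed(101)
  pats <- list(pattern_config(),
               pattern_config(c_spacer = c(2, 4), mid_spacer = c(10, 14),
                              h_spacer = c(3, 5)))
  for (case in seq_len(60)) {
    pat <- pats[[case %% 2 + 1]]
    prot <- random_protein(sample(80:500, 1))
    gene <- list(gene_id = "r", protein_seq = prot,
                 cds_seq = random_cds_for(prot))
    ann <- annotate_znf_array(gene, pat)
    ora <- oracle_scan_znf(prot, pat)
    expect_equal(nrow(ann$znfs), length(ora), info = paste("case", case))
    if (length(ora)) {
      expect_equal(ann$znfs$aa_start,
                   vapply(ora, `[[`, 0L, "start"), info = paste("case", case))
      expect_equal(ann$znfs$aa_end,
                   vapply(ora, function(u) u$start + u$len - 1L, 0L))
      expect_identical(ann$znfs$fingerprint,
                       vapply(ora, oracle_fingerprint, character(1),
                              protein = prot))
    }
  }
})

test_that("tiles reconstruct the array span and back-translate", {
  fam <- generate_family(family_config(seed = 3))
  anns <- annotate_gene_table(fam$genes)
  for (a in anns) {
    expect_equal(nrow(a$linkers), max(0L, nrow(a$znfs) - 1L))
    # ZnF tiles plus inter-tile gaps rebuild the protein span exactly
    k <- nrow(a$znfs)
    pieces <- character()
    for (i in seq_len(k)) {
      pieces <- c(pieces, a$znfs$aa_seq[i])
      if (i < k) {
        pieces <- c(pieces, substr(a$protein_seq, a$znfs$aa_end[i] + 1L,
                                   a$znfs$aa_start[i + 1L] - 1L))
      }
    }
    expect_identical(paste(pieces, collapse = ""),
                     substr(a$protein_seq, a$znfs$aa_start[1], a$znfs$aa_end[k]))
    # every tile's nucleotides translate back to its amino acids
    for (nt in c(a$znfs$nt_seq, a$linkers$nt_seq)) {
      expect_equal(nchar(nt) %% 3, 0)
    }
    expect_identical(vapply(a$znfs$nt_seq, translate_cds, character(1),
                            USE.NAMES = FALSE), a$znfs$aa_seq)
    expect_identical(vapply(a$linkers$nt_seq, translate_cds, character(1),
                            USE.NAMES = FALSE), a$linkers$aa_seq)
    # recorded PAM offsets all point at NGG triplets
    for (j in seq_len(nrow(a$linkers))) {
      for (o in a$linkers$pam_offsets[[j]]) {
        expect_identical(substr(a$linkers$nt_seq[j], o + 2, o + 3), "GG")
      }
    }
  }
})

test_that("tile_census counts totals and distinct fingerprints", {
  anns <- list(
    structure(list(gene_id = "g1",
                   znfs = data.frame(fingerprint = c("UYL", "UYL", "KQV")),
                   linkers = data.frame(x = 1:2)), class = "znf_annotation"),
    structure(list(gene_id = "g2",
                   znfs = data.frame(fingerprint = c("UYL", "RDE")),
                   linkers = data.frame(x = 1)), class = "znf_annotation")
  )
  cen <- tile_census(anns)
  expect_equal(cen$n_znf, 5L)
  expect_equal(cen$n_distinct_fingerprints, 3L)
  expect_equal(cen$per_gene$n_znf, c(3L, 2L))
})

test_that("tile tables export one row per tile", {
  fam <- generate_family(family_config(seed = 8, cluster_sizes = c(2L, 2L),
                                       isolated_genes = 0L))
  anns <- annotate_gene_table(fam$genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tile_table(anns, path)
  tab <- read.delim(path)
  cen <- tile_census(anns)
  expect_equal(sum(tab$tile_type == "ZnF"), cen$n_znf)
  expect_equal(sum(tab$tile_type == "Linker"),
               sum(cen$per_gene$n_linkers))
})
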
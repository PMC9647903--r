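test_that("the protospacer window sits immediately 5' of the PAM", {
  # linker tile at the very start of the CDS: one NGG at tile offset 23
  linker_nt <- paste0("TTT", "ACGTACGTACGTACGTACGT", "AGG")   # 26 nt... padded
  # pad to a codon multiple (27 nt = 9 aa) so the fake annotation is coherent
  linker_nt <- paste0(linker_nt, "A")
  ann <- fake_annotation("g1", cds = linker_nt, linker_aa_start = 1L,
                         linker_nt = linker_nt, pam_offsets = 23L)
  cand <- enumerate_candidates(list(g1 = ann))
  expect_equal(nrow(cand), 1L)
  expect_identical(cand$protospacer, "ACGTACGTACGTACGTACGT")
  expect_identical(cand$pam, "AGG")
  expect_equal(cand$design_frequency, 1L)
  expect_equal(attr(cand, "n_skipped"), 0L)
})

test_that("PAMs with fewer than 20 upstream nucleotides are skipped and logged", {
  cds <- paste0(strrep("A", 10), "TGG", strrep("A", 20))
  ann <- fake_annotation("g1", cds = cds, linker_aa_start = 1L,
                         linker_nt = cds, pam_offsets = 10L)
  cand <- enumerate_candidates(list(g1 = ann))
  expect_equal(nrow(cand), 0L)
  expect_equal(attr(cand, "n_skipped"), 1L)
})

test_that("candidate enumeration equals the naive scan on random arrays", {
  set.seed(606)
  for (case in 1:40) {
    # arrays with real linkers: alternate ZnF units and random inter-linkers
    n_znf <- sample(2:6, 1)
    inter <- vapply(seq_len(n_znf - 1L), function(i)
      random_protein(sample(4:9, 1), p_ch = 0), character(1))
    prot <- paste0(random_protein(sample(8:30, 1), p_ch = 0),
                   paste0(vapply(seq_len(n_znf), function(i)
                     "CAACQRSTNVWAYDKLHAAAH", character(1)),
                     c(inter, ""), collapse = ""),
                   random_protein(5, p_ch = 0))
    cds <- random_cds_for(prot)
    ann <- annotate_znf_array(list(gene_id = "r", protein_seq = prot,
                                   cds_seq = cds))
    got <- enumerate_candidates(list(r = ann))
    ora <- oracle_candidates(prot, cds)
    expect_equal(sum(got$design_frequency), length(ora$windows),
                 info = paste("case", case))
    expect_equal(attr(got, "n_skipped"), ora$skips)
    ora_freq <- sort(table(ora$windows), decreasing = TRUE)
    expect_identical(sort(got$protospacer),
                     sort(as.character(names(ora_freq))))
    expect_equal(got$design_frequency[match(names(ora_freq), got$protospacer)],
                 unname(as.integer(ora_freq)))
  }
})

test_that("ranking is frequency-descending with lexicographic ties", {
  fam <- generate_family(family_config(seed = 42))
  anns <- annotate_gene_table(fam$genes)
  cl <- call_clusters(fam$genes)
  cand <- enumerate_candidates(anns, cl$members[[1]], target_clusters = 1L)
  expect_equal(nrow(cand), 2L)                       # the two planted PAMs
  expect_equal(cand$design_frequency[1], cand$design_frequency[2])
  expect_true(cand$protospacer[1] < cand$protospacer[2])
  top1 <- select_top(cand, 1L)
  expect_identical(top1$protospacer, cand$protospacer[1])
  expect_message(select_top(cand, 11L), "only 2 candidate")
  expect_equal(nrow(select_top(cand, 11L)), 2L)
})

test_that("cut-site prediction sees both strands and exact PAMs only", {
  proto <- "ACGTACGTACGTACGTACGT"
  hit <- paste0(proto, "TGG")
  cds <- paste0("AAAA", hit, "CCCCC", oracle_revcomp(hit), "AA")
  gt <- toy_gene_table("g1", "chr1", 1L, nchar(cds),
                       cds = cds, protein = "M")
  sites <- predict_cut_sites(proto, gt)
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$strand, c("+", "-"))
  expect_equal(sites$position[sites$strand == "+"], 4L)
  expect_true(all(sites$mismatches == 0L))

  # PAM must be NGG: NAG neighbours are not cleavage sites
  gt2 <- toy_gene_table("g1", "chr1", 1L, 100L,
                        cds = paste0("AAAA", proto, "TAG", "AAAA"),
                        protein = "M")
  expect_equal(nrow(predict_cut_sites(proto, gt2)), 0L)

  # coding-strand-only search is available as a flag
  expect_equal(nrow(predict_cut_sites(proto, gt, both_strands = FALSE)), 1L)

  no_ngg <- toy_gene_table("g1", "chr1", 1L, 30L,
                           cds = "ACACACACACACACACACACACACACACAC",
                           protein = "M")
  expect_equal(nrow(predict_cut_sites(proto, no_ngg)), 0L)
})

test_that("cut sites match the sliding-window Hamming oracle", {
  set.seed(707)
  for (case in 1:30) {
    n <- sample(300:1500, 1)
    seq <- random_dna(n)
    proto <- random_dna(20)
    if (case %% 2 == 0) {
      # plant an exact or 1-mismatch occurrence with a valid PAM
      ins <- strsplit(proto, "")[[1]]
      if (case %% 4 == 0) {
        p <- sample(20, 1)
        ins[p] <- sample(setdiff(c("A", "C", "G", "T"), ins[p]), 1)
      }
      at <- sample(n - 60, 1)
      seq <- paste0(substr(seq, 1, at), paste(ins, collapse = ""), "AGG",
                    substr(seq, at + 24, n))
    }
    mm <- sample(0:1, 1)
    gt <- toy_gene_table("g", "chr1", 1L, nchar(seq), cds = seq, protein = "M")
    got <- predict_cut_sites(proto, gt, max_mismatches = mm)
    ora <- oracle_cut_sites(proto, seq, mm)
    got <- got[order(got$strand, got$position), ]
    ora <- ora[order(ora$strand, ora$position), ]
    expect_equal(nrow(got), nrow(ora), info = paste("case", case))
    expect_equal(got$position, ora$position, info = paste("case", case))
    expect_equal(got$strand, ora$strand)
    expect_equal(got$mismatches, ora$mismatches)
  }
})

test_that("specificity aggregates by cluster with conserved row sums", {
  fam <- generate_family(family_config(seed = 42))
  anns <- annotate_gene_table(fam$genes)
  cl <- call_clusters(fam$genes)
  cand <- enumerate_candidates(anns, cl$members[[2]], target_clusters = 2L)
  rep <- specificity_report(cand, fam$genes, cl)
  expect_equal(unname(rowSums(rep$counts)), unname(rep$total_sites))
  expect_equal(unname(rep$on_target_fraction), rep(1, nrow(cand)))
  # design windows are genuine sites
  expect_true(all(rep$total_sites >= cand$design_frequency))
  # the unclustered column exists and is empty for cluster-private guides
  expect_true("unclustered" %in% colnames(rep$counts))
  expect_equal(sum(rep$counts[, "unclustered"]), 0L)

  # a candidate with no sites anywhere reports an undefined fraction
  ghost <- cand[1, ]
  ghost$protospacer <- strrep("ACGTG", 4)
  attr(ghost, "target_clusters") <- 2L
  class(ghost) <- class(cand)
  rep2 <- specificity_report(ghost, fam$genes, cl)
  expect_true(is.na(rep2$on_target_fraction[1]))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_specificity_table(rep, cand, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(tab$total_sites, unname(rep$total_sites))
})
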
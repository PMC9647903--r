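test_that("information content hits the bounds on degenerate columns", {
  prof <- build_profile(rep("ACGTACGT", 10), "nucleotide")
  expect_equal(prof$length, 8L)
  expect_equal(prof$n_sequences, 10L)
  expect_equal(prof$ic, rep(2, 8))            # identical columns: 2 bits

  uniform <- c("ACGT", "CGTA", "GTAC", "TACG") # every column uniform
  prof2 <- build_profile(uniform, "nucleotide")
  expect_equal(prof2$ic, rep(0, 4))

  aa <- build_profile(rep("MKV", 5), "amino_acid")
  expect_equal(aa$ic, rep(log2(20), 3))
})

test_that("profiles keep the modal length and report discards", {
  seqs <- c("AAAA", "AAAA", "CCCC", "GG", "TTTTT")
  prof <- build_profile(seqs, "nucleotide")
  expect_equal(prof$length, 4L)
  expect_equal(prof$n_sequences, 3L)
  expect_equal(prof$n_discarded, 2L)
  # ties in length frequency resolve toward the shorter length
  tie <- build_profile(c("AA", "AA", "CCC", "CCC"), "nucleotide")
  expect_equal(tie$length, 2L)
  expect_error(build_profile(character(), "nucleotide"), "no sequences")
})

test_that("frequencies normalise and ic matches an independent computation", {
  set.seed(55)
  for (case in 1:20) {
    alpha <- sample(c("nucleotide", "amino_acid"), 1)
    letters_ <- if (alpha == "nucleotide") c("A", "C", "G", "T") else AA_ALPHABET
    n <- sample(3:40, 1)
    L <- sample(5:30, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(letters_, L, replace = TRUE), collapse = ""), character(1))
    prof <- build_profile(seqs, alpha)
    expect_equal(unname(rowSums(prof$freqs)), rep(1, L), tolerance = 1e-9)
    expect_true(all(prof$ic >= -1e-12 & prof$ic <= log2(length(letters_)) + 1e-12))
    expect_equal(prof$ic, oracle_ic(seqs, length(letters_)), tolerance = 1e-12)
  }
})

test_that("profile levels pool the requested tiles and record provenance", {
  fam <- generate_family(family_config(seed = 9))
  anns <- annotate_gene_table(fam$genes)
  cl <- call_clusters(fam$genes)

  gene_prof <- profile_levels(anns, "gene", ids = names(anns)[1],
                              tile_type = "linker", alphabet = "nucleotide")
  expect_equal(gene_prof$ic, rep(2, gene_prof$length)) # zero-noise: identical
  expect_equal(attr(gene_prof, "provenance")$level, "gene")

  cl_prof <- profile_levels(anns, "cluster", ids = cl$cluster_id[1],
                            clusters = cl, tile_type = "linker",
                            alphabet = "nucleotide")
  genome_prof <- profile_levels(anns, "genome", tile_type = "linker",
                                alphabet = "nucleotide")
  # pooling more divergent groups never raises conservation
  expect_true(mean(cl_prof$ic) >= mean(genome_prof$ic) - 1e-12)
  expect_equal(cl_prof$length, 42L)

  znf_aa <- profile_levels(anns, "genome", tile_type = "znf",
                           alphabet = "amino_acid")
  expect_equal(znf_aa$length, 21L)

  expect_error(profile_levels(anns, "cluster", ids = 99L, clusters = cl),
               "unknown cluster")
  expect_error(profile_levels(anns, "gene", ids = "nope"), "unknown gene")
})

test_that("conserved PAM discovery reports NGG-compatible offsets", {
  prof <- build_profile(rep("AAAAAGGAAA", 5), "nucleotide")
  rep1 <- find_conserved_pams(prof)
  expect_equal(rep1$pam_offsets, 4L)          # G at positions 6,7 (1-based)
  expect_equal(rep1$g_frequency, 1)

  uniform <- build_profile(c("ACGT", "CGTA", "GTAC", "TACG"), "nucleotide")
  expect_length(find_conserved_pams(uniform)$pam_offsets, 0L)

  # overlapping conserved Gs are all reported
  run <- find_conserved_pams(build_profile(rep("AGGGA", 4), "nucleotide"))
  expect_equal(run$pam_offsets, c(0L, 1L))

  expect_error(find_conserved_pams(build_profile(rep("MKV", 3), "amino_acid")),
               "nucleotide")
})

test_that("planted linker PAMs are recovered at cluster level", {
  fam <- generate_family(family_config(seed = 13))
  anns <- annotate_gene_table(fam$genes)
  cl <- call_clusters(fam$genes)
  for (i in seq_len(nrow(cl))) {
    prof <- profile_levels(anns, "cluster", ids = cl$cluster_id[i],
                           clusters = cl, tile_type = "linker",
                           alphabet = "nucleotide")
    pams <- find_conserved_pams(prof)
    planted <- fam$truth$linkers[[i]]$pam_offsets
    expect_equal(pams$pam_offsets, planted)
  }
})

test_that("profile export writes one row per position", {
  prof <- build_profile(rep("ACGT", 3), "nucleotide")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$ic, prof$ic)
  expect_equal(names(tab), c("position", "A", "C", "G", "T", "ic"))
})
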
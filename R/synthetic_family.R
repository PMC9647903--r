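# Synthetic KRAB-ZFP family generator with planted ground truth.
#
# Genes are built at the protein level as
#   [N-flank] + ZnF + inter-linker + ZnF + ... + ZnF + [C-flank]
# with a shared 21-aa ZnF scaffold (CWSC + 12-aa spacer + HTIRH) whose
# fingerprint slots are filled from cluster-private pools, then laid down
# codon-by-codon. The linker tile (HXXXH + 5-aa inter-linker + CXXC, 42 nt)
# uses hand-chosen codons that place exactly two NGG motifs at nucleotide
# offsets 21 and 33 — both at least 20 nt into the tile, so the protospacer
# windows upstream of each PAM stay inside the linker consensus. Two
# inter-linker residues vary per group (cluster or isolated gene) and are
# encoded by G-free codons, which cannot create or destroy an NGG; they make
# both protospacers cluster-private.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_SAFE <- setdiff(AA20, c("C", "H"))   # avoids spurious C2H2 anchors

PREFERRED_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC")

# G-free codons for the two cluster-variable inter-linker residues: no G
# anywhere, so substituting them can never add or remove a GG dinucleotide.
VARIANT_CODON <- c(N = "AAT", K = "AAA", T = "ACA", S = "TCA", I = "ATT",
                   L = "CTT", Q = "CAA", F = "TTT", Y = "TAT")

# ZnF scaffold: position -> (residue, codon). Fingerprint slots are spacer
# positions 5, 9, 12 (tile positions 9, 13, 16 = H1-8, H1-4, H1-1).
ZNF_HEAD <- list(aa = c("C", "W", "S", "C"),
                 codon = c("TGT", "TGG", "TCA", "TGT"))
ZNF_TAIL <- list(aa = c("H", "T", "I", "R", "H"),
                 codon = c("CAT", "ACA", "ATC", "CGT", "CAT"))
FP_SLOTS <- c(5L, 9L, 12L)  # positions within the 12-aa spacer

# Inter-linker: T v1 W v2 E; the W codon TGG supplies the first planted NGG,
# the W at scaffold position 2 of the following ZnF supplies the second.
INTER_FIXED_AA <- c("T", NA, "W", NA, "E")
INTER_FIXED_CODON <- c("ACT", NA, "TGG", NA, "GAA")

codon_synonyms <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

#' Translate a CDS under the standard genetic code
#'
#' @param cds Nucleotide string; length must be a multiple of 3.
#' @return Amino-acid string (`*` for stop codons).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Configuration for a synthetic KRAB-ZFP family
#'
#' Defaults describe the reference study condition: three clusters of 5, 4
#' and 3 genes plus two isolated genes on three chromosomes, 4-8 ZnFs per
#' gene, five private fingerprint triplets per cluster reused with skewed
#' weights, intra-cluster gaps of 5-150 kb (inside the 200 kb rule), 1 Mb
#' isolation elsewhere, and a noise-free planted model
#' (`linker_mutation_rate = 0`, `synonymous_wobble_rate = 0`). Expression
#' defaults plant each cluster coherently high (TPM 50-200 at penetrance
#' 0.75) in one sample against a 0-5 TPM background.
#'
#' @param seed Integer seed; the generator draws from a single stream.
#' @param n_chromosomes Number of chromosomes to spread genes over.
#' @param cluster_sizes Integer vector of member counts (each >= 2).
#' @param isolated_genes Number of genes placed far from every other gene.
#' @param znf_per_gene `c(min, max)` ZnFs per gene.
#' @param fingerprints_per_cluster Size of each cluster-private pool.
#' @param fingerprint_weights Usage weights within a pool (recycled /
#'   normalised); default a skewed profile so a few triplets dominate.
#' @param intra_gap_range `c(min, max)` bp between cluster neighbours.
#' @param inter_cluster_gap bp separating clusters and isolated genes.
#' @param flank_n,flank_c N-/C-terminal flank lengths (aa).
#' @param linker_mutation_rate Per-nucleotide substitution probability in
#'   linker tiles (stop codons are never introduced).
#' @param synonymous_wobble_rate Probability of a synonymous codon swap per
#'   ZnF spacer-interior residue.
#' @param samples Sample labels for the TPM table.
#' @param expression Data frame (`cluster`, `sample`, `penetrance`)
#'   declaring which clusters are planted high where; default alternates
#'   the first two samples over clusters at penetrance 0.75.
#' @param high_tpm_range,background_tpm_range TPM ranges for planted-high
#'   and background cells.
#' @return A `family_config` object.
#' @export
family_config <- function(seed = 1L,
                          n_chromosomes = 3L,
                          cluster_sizes = c(5L, 4L, 3L),
                          isolated_genes = 2L,
                          znf_per_gene = c(4L, 8L),
                          fingerprints_per_cluster = 5L,
                          fingerprint_weights = NULL,
                          intra_gap_range = c(5000L, 150000L),
                          inter_cluster_gap = 1000000L,
                          flank_n = 10L,
                          flank_c = 8L,
                          linker_mutation_rate = 0,
                          synonymous_wobble_rate = 0,
                          samples = c("mESC", "forebrain", "liver"),
                          expression = NULL,
                          high_tpm_range = c(50, 200),
                          background_tpm_range = c(0, 5)) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (any(cluster_sizes < 2L)) stop("planted clusters need at least 2 members")
  if (linker_mutation_rate < 0 || linker_mutation_rate > 1 ||
      synonymous_wobble_rate < 0 || synonymous_wobble_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (znf_per_gene[1] < 2L) stop("genes need at least 2 ZnFs to carry a linker")
  n_groups <- length(cluster_sizes) + as.integer(isolated_genes)
  if (n_groups > length(VARIANT_CODON)) {
    stop("infeasible config: at most ", length(VARIANT_CODON),
         " groups (clusters + isolated genes) can carry distinct linker variants")
  }
  k <- length(cluster_sizes)
  if (is.null(expression)) {
    expression <- data.frame(
      cluster = seq_len(k),
      sample = rep(samples[seq_len(min(2L, length(samples)))], length.out = k),
      penetrance = 0.75,
      stringsAsFactors = FALSE)
  }
  if (any(expression$penetrance < 0 | expression$penetrance > 1)) {
    stop("penetrance must lie in [0, 1]")
  }
  if (!all(expression$sample %in% samples)) {
    stop("expression samples must be among the configured sample labels")
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 cluster_sizes = cluster_sizes,
                 isolated_genes = as.integer(isolated_genes),
                 znf_per_gene = as.integer(znf_per_gene),
                 fingerprints_per_cluster = as.integer(fingerprints_per_cluster),
                 fingerprint_weights = fingerprint_weights,
                 intra_gap_range = as.numeric(intra_gap_range),
                 inter_cluster_gap = as.numeric(inter_cluster_gap),
                 flank_n = as.integer(flank_n), flank_c = as.integer(flank_c),
                 linker_mutation_rate = linker_mutation_rate,
                 synonymous_wobble_rate = synonymous_wobble_rate,
                 samples = samples, expression = expression,
                 high_tpm_range = as.numeric(high_tpm_range),
                 background_tpm_range = as.numeric(background_tpm_range)),
            class = "family_config")
}

# Consensus linker tile (42 nt) for a group given its two variant residues.
linker_consensus <- function(v1, v2, spacer_template) {
  aa <- c(ZNF_TAIL$aa, "T", v1, "W", v2, "E", ZNF_HEAD$aa)
  codons <- c(ZNF_TAIL$codon, "ACT", VARIANT_CODON[[v1]], "TGG",
              VARIANT_CODON[[v2]], "GAA", ZNF_HEAD$codon)
  list(aa = paste(aa, collapse = ""), nt = paste(codons, collapse = ""))
}

validate_consensus <- function(nt) {
  offs <- ngg_offsets(nt)
  if (length(offs) != 2L || any(offs < PROTOSPACER_LEN)) {
    stop("infeasible config: linker consensus must carry exactly two NGG ",
         "motifs at offsets >= ", PROTOSPACER_LEN, " (found: ",
         paste(offs, collapse = ","), ")")
  }
  offs
}

build_synthetic_gene <- function(n_znf, fingerprints, v1, v2, spacer_template,
                                 flank_n, flank_c, wobble_rate, synonyms) {
  aa <- character()
  codons <- character()
  emit <- function(a, cd) {
    aa <<- c(aa, a)
    codons <<- c(codons, cd)
  }
  flank1 <- sample(AA_SAFE, flank_n, replace = TRUE)
  emit(flank1, PREFERRED_CODON[flank1])
  for (i in seq_len(n_znf)) {
    emit(ZNF_HEAD$aa, ZNF_HEAD$codon)
    sp <- spacer_template
    sp[FP_SLOTS] <- strsplit(fingerprints[i], "")[[1]]
    sp_codons <- PREFERRED_CODON[sp]
    if (wobble_rate > 0) {
      for (j in seq_along(sp_codons)) {
        if (runif(1) < wobble_rate) {
          alt <- setdiff(synonyms[[sp[j]]], sp_codons[j])
          if (length(alt)) sp_codons[j] <- sample(alt, 1)
        }
      }
    }
    emit(sp, sp_codons)
    emit(ZNF_TAIL$aa, ZNF_TAIL$codon)
    if (i < n_znf) {
      inter_aa <- INTER_FIXED_AA
      inter_aa[c(2L, 4L)] <- c(v1, v2)
      inter_codon <- INTER_FIXED_CODON
      inter_codon[c(2L, 4L)] <- VARIANT_CODON[c(v1, v2)]
      emit(inter_aa, inter_codon)
    }
  }
  flank2 <- sample(AA_SAFE, flank_c, replace = TRUE)
  emit(flank2, PREFERRED_CODON[flank2])
  cds <- paste(codons, collapse = "")
  # 0-based CDS offsets of each 42-nt linker tile (H1 of ZnF i).
  linker_nt0 <- if (n_znf >= 2L) {
    h1_aa <- flank_n + (seq_len(n_znf - 1L) - 1L) * 26L + 17L
    3L * (h1_aa - 1L)
  } else integer()
  list(cds = cds, protein = paste(aa, collapse = ""), linker_nt0 = linker_nt0)
}

mutate_linkers <- function(cds, linker_nt0, rate) {
  if (rate == 0 || !length(linker_nt0)) return(cds)
  chars <- strsplit(cds, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (s0 in linker_nt0) {
    for (pos in (s0 + 1L):(s0 + 42L)) {
      if (runif(1) >= rate) next
      cand <- sample(setdiff(bases, chars[pos]))
      for (b in cand) {
        old <- chars[pos]
        chars[pos] <- b
        c0 <- ((pos - 1L) %/% 3L) * 3L + 1L
        codon <- paste(chars[c0:(c0 + 2L)], collapse = "")
        if (codon %in% STOP_CODONS) chars[pos] <- old else break
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic KRAB-ZFP family with planted ground truth
#'
#' Deterministic given `config$seed` (one pseudo-random stream, drawn in a
#' fixed order). Emits a coordinate table, protein/CDS sequences, a TPM
#' table and a `truth` record that states what was planted: cluster
#' membership and spans, per-gene fingerprint sequences, the per-group
#' linker consensus with its two NGG offsets and protospacers, expected and
#' realised protospacer site counts, and the planted highly expressed gene
#' sets.
#'
#' @param config A [family_config()].
#' @return A `synthetic_family`: list with `genes` (a sequenced
#'   `gene_table`), `tpm`, `truth` and `config`.
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  k <- length(config$cluster_sizes)
  n_groups <- k + config$isolated_genes
  synonyms <- codon_synonyms()

  # 1. shared ZnF spacer template (fingerprint slots overwritten per finger)
  spacer_template <- sample(AA_SAFE, 12L, replace = TRUE)

  # 2. distinct linker variants per group
  v1 <- sample(names(VARIANT_CODON), n_groups)
  v2 <- sample(names(VARIANT_CODON), n_groups)
  group_linker <- lapply(seq_len(n_groups), function(g) {
    cons <- linker_consensus(v1[g], v2[g], spacer_template)
    offs <- validate_consensus(cons$nt)
    cons$pam_offsets <- offs
    cons$protospacers <- vapply(offs, function(o)
      substr(cons$nt, o - PROTOSPACER_LEN + 1L, o), character(1))
    cons$pams <- vapply(offs, function(o)
      substr(cons$nt, o + 1L, o + 3L), character(1))
    cons
  })

  # 3. cluster-private fingerprint pools (disjoint across groups)
  n_pools <- k + as.integer(config$isolated_genes > 0L)
  n_fp <- n_pools * config$fingerprints_per_cluster
  fp_space <- replicate(4L * n_fp + 50L,
                        paste(sample(AA_SAFE, 3L, replace = TRUE), collapse = ""))
  fp_all <- unique(fp_space)[seq_len(n_fp)]
  if (length(fp_all) < n_fp || anyNA(fp_all)) {
    stop("could not draw enough distinct fingerprint triplets")
  }
  pools <- split(fp_all, rep(seq_len(n_pools),
                             each = config$fingerprints_per_cluster))
  w <- config$fingerprint_weights
  if (is.null(w)) w <- 0.6^(seq_len(config$fingerprints_per_cluster) - 1L)
  w <- rep_len(w, config$fingerprints_per_cluster)
  w <- w / sum(w)

  # 4. genes: clusters first, then isolated
  gene_group <- c(rep(seq_len(k), config$cluster_sizes),
                  if (config$isolated_genes > 0L)
                    k + seq_len(config$isolated_genes))
  n_genes <- length(gene_group)
  ids <- sprintf("szfp%03d", seq_len(n_genes))
  proteins <- character(n_genes)
  cdss <- character(n_genes)
  planted_fps <- vector("list", n_genes)
  n_znfs <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    g <- gene_group[i]
    pool_idx <- if (g <= k) g else k + 1L
    z <- sample(config$znf_per_gene[1]:config$znf_per_gene[2], 1L)
    fps <- sample(pools[[pool_idx]], z, replace = TRUE, prob = w)
    built <- build_synthetic_gene(z, fps, v1[g], v2[g], spacer_template,
                                  config$flank_n, config$flank_c,
                                  config$synonymous_wobble_rate, synonyms)
    cds <- mutate_linkers(built$cds, built$linker_nt0,
                          config$linker_mutation_rate)
    proteins[i] <- translate_cds(cds)
    cdss[i] <- cds
    planted_fps[[i]] <- fps
    n_znfs[i] <- z
  }
  names(planted_fps) <- ids

  # 5. genomic coordinates
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cursor <- setNames(rep(100000, config$n_chromosomes), chroms)
  chrom_of <- character(n_genes)
  starts <- numeric(n_genes)
  ends <- numeric(n_genes)
  truth_clusters <- vector("list", k)
  for (cl in seq_len(k)) {
    ch <- chroms[(cl - 1L) %% config$n_chromosomes + 1L]
    members <- which(gene_group == cl)
    for (m in members) {
      chrom_of[m] <- ch
      starts[m] <- cursor[ch]
      ends[m] <- starts[m] + nchar(cdss[m]) - 1
      gap <- round(runif(1, config$intra_gap_range[1], config$intra_gap_range[2]))
      cursor[ch] <- ends[m] + gap
    }
    cursor[ch] <- ends[members[length(members)]] + config$inter_cluster_gap
    truth_clusters[[cl]] <- list(cluster = cl, chromosome = ch,
                                 members = ids[members],
                                 span = c(min(starts[members]),
                                          max(ends[members])))
  }
  iso_idx <- which(gene_group > k)
  for (j in seq_along(iso_idx)) {
    m <- iso_idx[j]
    ch <- chroms[(j - 1L) %% config$n_chromosomes + 1L]
    chrom_of[m] <- ch
    starts[m] <- cursor[ch]
    ends[m] <- starts[m] + nchar(cdss[m]) - 1
    cursor[ch] <- ends[m] + config$inter_cluster_gap
  }

  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- gene_table(gene_id = ids, chromosome = chrom_of,
                      start = starts, end = ends,
                      species = "synthetic", strand = strands,
                      protein_seq = proteins, cds_seq = cdss,
                      provenance = "synthetic")
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "provenance") <- "synthetic"
  class(genes) <- c("gene_table", "data.frame")

  # 6. expression
  tpm <- matrix(runif(n_genes * length(config$samples),
                      config$background_tpm_range[1],
                      config$background_tpm_range[2]),
                nrow = n_genes,
                dimnames = list(ids, config$samples))
  truth_expr <- vector("list", nrow(config$expression))
  for (r in seq_len(nrow(config$expression))) {
    cl <- config$expression$cluster[r]
    smp <- config$expression$sample[r]
    members <- ids[gene_group == cl]
    high <- members[runif(length(members)) < config$expression$penetrance[r]]
    if (length(high)) {
      tpm[high, smp] <- runif(length(high), config$high_tpm_range[1],
                              config$high_tpm_range[2])
    }
    truth_expr[[r]] <- list(cluster = cl, sample = smp,
                            penetrance = config$expression$penetrance[r],
                            expressed = high)
  }
  tpm <- tpm[genes$gene_id, , drop = FALSE]

  # 7. planted candidate bookkeeping (realised counts scanned from the
  #    emitted CDS, so they remain exact under linker mutation)
  truth_linker <- lapply(seq_len(n_groups), function(g) {
    members <- ids[gene_group == g]
    expected <- sum(n_znfs[gene_group == g] - 1L)
    realised <- vapply(group_linker[[g]]$protospacers, function(p) {
      sum(vapply(cdss[gene_group == g], function(s)
        count_protospacer_sites(p, s), 0L))
    }, 0L)
    list(group = g,
         is_cluster = g <= k,
         members = members,
         consensus_aa = group_linker[[g]]$aa,
         consensus_nt = group_linker[[g]]$nt,
         pam_offsets = group_linker[[g]]$pam_offsets,
         protospacers = unname(group_linker[[g]]$protospacers),
         expected_design_frequency = expected,
         realised_site_counts = unname(realised))
  })

  truth <- list(
    seed = config$seed,
    clusters = truth_clusters,
    isolated = ids[iso_idx],
    fingerprints = planted_fps,
    n_znfs = setNames(n_znfs, ids),
    linkers = truth_linker,
    expression = truth_expr,
    high_tpm_min = config$high_tpm_range[1],
    background_tpm_max = config$background_tpm_range[2]
  )
  structure(list(genes = genes, tpm = tpm, truth = truth, config = config),
            class = "synthetic_family")
}

# Forward-strand occurrences of protospacer followed immediately by NGG.
count_protospacer_sites <- function(proto, seq) {
  hits <- gregexpr(paste0("(?=", proto, ".GG)"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Verify the internal consistency of a synthetic family
#'
#' Checks that every CDS translates exactly to its protein, that CDS and
#' protein lengths agree, that coordinates are valid and sorted, that
#' planted cluster members obey the gap rule while isolated genes stay far
#' from every neighbour, that the planted protospacers occur at the
#' recorded site counts, and that planted highly expressed genes are
#' separated from the background TPM range.
#'
#' @param family A `synthetic_family`.
#' @return A list with `ok` (logical) and `failures` (character vector of
#'   named failures, empty when consistent).
#' @export
truth_check <- function(family) {
  stopifnot(inherits(family, "synthetic_family"))
  g <- family$genes
  truth <- family$truth
  failures <- character()
  fail <- function(...) failures <<- c(failures, paste0(...))

  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    if (nchar(g$cds_seq[i]) != 3L * nchar(g$protein_seq[i])) {
      fail("length:", id)
    } else if (translate_cds(g$cds_seq[i]) != g$protein_seq[i]) {
      fail("translation:", id)
    }
  }
  if (any(g$start > g$end)) fail("coordinates:start>end")
  for (ch in unique(g$chromosome)) {
    st <- g$start[g$chromosome == ch]
    if (is.unsorted(st)) fail("coordinates:unsorted:", ch)
  }
  max_gap <- family$config$intra_gap_range[2]
  pos <- setNames(seq_len(nrow(g)), g$gene_id)
  for (tc in truth$clusters) {
    idx <- sort(pos[tc$members])
    if (length(unique(g$chromosome[idx])) != 1L) {
      fail("cluster:multichrom:", tc$cluster)
      next
    }
    gaps <- g$start[idx][-1] - g$end[idx][-length(idx)]
    if (any(gaps > max_gap)) fail("cluster:gap:", tc$cluster)
  }
  for (iso in truth$isolated) {
    i <- pos[iso]
    same <- which(g$chromosome == g$chromosome[i])
    others <- setdiff(same, i)
    if (length(others)) {
      d <- pmax(g$start[i] - g$end[others], g$start[others] - g$end[i])
      if (any(d <= max_gap)) fail("isolated:too-close:", iso)
    }
  }
  for (tl in truth$linkers) {
    member_cds <- g$cds_seq[match(tl$members, g$gene_id)]
    for (j in seq_along(tl$protospacers)) {
      n_obs <- sum(vapply(member_cds, function(s)
        count_protospacer_sites(tl$protospacers[j], s), 0L))
      if (n_obs != tl$realised_site_counts[j]) {
        fail("protospacer:count:group", tl$group, ":", j)
      }
    }
  }
  for (ex in truth$expression) {
    if (!length(ex$expressed)) next
    vals <- family$tpm[ex$expressed, ex$sample]
    if (any(vals < truth$high_tpm_min)) fail("expression:low-high:", ex$cluster)
    cl_members <- truth$clusters[[ex$cluster]]$members
    bg <- setdiff(cl_members, ex$expressed)
    if (length(bg) && any(family$tpm[bg, ex$sample] > truth$background_tpm_max)) {
      fail("expression:high-background:", ex$cluster)
    }
  }
  list(ok = !length(failures), failures = failures)
}

#' Write a synthetic family to disk
#'
#' Emits `genes.tsv`, `protein.fa`, `cds.fa`, `tpm.tsv` and `truth.json`
#' under `dir`.
#'
#' @param family A `synthetic_family`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(family$genes, file.path(dir, "genes.tsv"))
  write_sequences(family$genes, file.path(dir, "protein.fa"),
                  file.path(dir, "cds.fa"))
  write_expression_table(family$tpm, file.path(dir, "tpm.tsv"))
  jsonlite::write_json(family$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
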
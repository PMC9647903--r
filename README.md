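# zfplinker

Cluster-level analysis of KRAB zinc-finger protein (KRAB-ZFP) gene families,
and design of multi-target sgRNAs against cluster-specific zinc-finger linker
sequences.

## The problem

KRAB-ZFPs are the largest transcription-factor superfamily in mammals
(~357 genes in mouse, ~380 in human). They repress transposable elements, and
they are organised in genomic clusters whose members share evolutionary
history, zinc-finger usage and expression patterns. Dissecting the function of
a whole cluster is hard with conventional single-locus knockouts. A
cluster-level alternative exploits two sequence properties of the C2H2
zinc-finger arrays:

1. The **linker** segments between consecutive fingers are highly conserved
   within a cluster but carry cluster-specific nucleotide variants.
2. The native linker DNA contains **conserved NGG motifs** usable as SpCas9
   PAM sites, so a single guide RNA designed against a cluster's linker
   consensus has dozens of predicted cleavage sites inside that cluster — and,
   ideally, none outside it.

`zfplinker` implements this analysis for anyone working with a KRAB-ZFP-like
tandem gene family: geneticists planning multi-copy CRISPR screens against
gene clusters, and computational biologists studying zinc-finger array
evolution.

## What it computes

* **Cluster calling.** Genes on a chromosome are sorted by start; a cluster is
  a maximal run in which every neighbour gap `start(i+1) − end(i)` is at most
  `max_gap` (default 200 kb) with at least `min_size` (default 2) members.
* **Tile decomposition.** Each protein is scanned for the C2H2 pattern
  C‑X2‑C‑X12‑H‑X3‑H (spacer ranges configurable). Two overlapping tile sets
  cover the array: *ZnF* tiles (CXXC → HXXXH) and *linker* tiles (HXXXH of one
  finger → CXXC of the next). Each finger's **fingerprint** — the DNA-contacting
  triplet at recognition-helix positions −1, +3, +6 — is read at offsets
  (H1−8, H1−4, H1−1) from the first zinc-coordinating histidine.
* **Fingerprint profiling.** A genes × fingerprints occurrence matrix, the
  dominant-species coverage statistic (share of a cluster's ZnFs carried by
  the top-k fingerprints used at least `min_count` times), and per-fingerprint
  cluster exclusivity (on-cluster / genome-wide occurrences).
* **Conservation profiles.** Per-position letter frequencies and information
  content `ic[p] = log2(|A|) − H(freqs[p])` in bits (sequence-logo data) at
  genome, cluster, or single-gene level, plus discovery of conserved NGG PAM
  positions (both G frequencies ≥ 0.8 by default).
* **sgRNA design.** Every 20-nt window immediately 5′ of an NGG starting
  inside a linker tile is a candidate protospacer; candidates are ranked by
  within-cluster frequency, cut sites are predicted by exact protospacer+NGG
  matching on both strands across the full gene set, and a specificity matrix
  reports per-cluster site counts and the on-target fraction.
* **Expression selection.** Highly expressed genes (`TPM ≥ threshold`,
  inclusive) and per-cluster expressed/total ratios identify the clusters
  worth targeting.
* **Synthetic families.** `generate_family()` builds a family with planted
  clusters, cluster-private fingerprint pools, near-identical linkers carrying
  exactly two NGG motifs, and planted expression structure — with a `truth`
  record, so every stage has a ground-truth recovery test without downloads.

Given the published mouse/human KRAB-ZFP coordinate and sequence tables, the
same calls compute the family-wide statistics reported for those genomes
(cluster census under the 200 kb / 2-gene rule, genome-wide ZnF and
fingerprint counts, dominant-species coverage, per-guide predicted-site
counts and on-target fractions). Those tables are not redistributed here;
the test suite validates every stage against brute-force oracles and planted
synthetic ground truth instead.

## Worked example

```r
library(zfplinker)

fam  <- generate_family(family_config(seed = 42))
anns <- annotate_gene_table(fam$genes)
cl   <- call_clusters(fam$genes, cluster_params(max_gap = 200000, min_size = 2))
cen  <- tile_census(anns)
#> genes: 14   ZnFs: 80   distinct fingerprints: 17
#> cluster_1 cluster_2 cluster_3
#>         5         4         3

prof <- profile_levels(anns, "cluster", ids = 1, clusters = cl,
                       tile_type = "linker", alphabet = "nucleotide")
find_conserved_pams(prof)$pam_offsets
#> [1] 21 33        # the two conserved NGG motifs, mean linker ic = 2 bits

cand <- enumerate_candidates(anns, cl$members[[1]], target_clusters = 1)
cand
#>            protospacer pam design_frequency
#> 1 ATACAATCCGTCATACTTCA TGG               25
#> 2 ATACTTCATGGTATGAATGT TGG               25

specificity_report(cand, fam$genes, cl)$counts
#>                       1 2 3 unclustered
#> ATACAATCCGTCATACTTCA 25 0 0           0
#> ATACTTCATGGTATGAATGT 25 0 0           0
```

Each guide hits all 25 linkers of its cluster and nothing else
(on-target fraction 1.0). Expression selection works the same way:
`select_highly_expressed(fam$tpm, "mESC", 25)` followed by
`cluster_expression_ratios()` gives per-cluster ratios (here 1.0, 0, 1.0 —
clusters 1 and 3 are the planted mESC-active clusters).

The whole analysis, including writing per-stage artefacts and a JSON run
report, is one call:

```r
run_pipeline(pipeline_config(out_dir = "out", simulate = family_config(),
                             seed = 42))
```

or from a shell: `Rscript inst/scripts/run-pipeline.R --simulate --seed 42 --out out/`.

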
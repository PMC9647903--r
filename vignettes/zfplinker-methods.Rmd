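---
title: "Methods: cluster-level KRAB-ZFP analysis and linker-targeted sgRNA design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-level KRAB-ZFP analysis and linker-targeted sgRNA design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfplinker)
```

This vignette documents the models and procedures behind `zfplinker`, the
conventions and tunable parameters that matter, what the synthetic family
generator does and does not emulate, and the numerical and design choices
made where the problem left the design open.

## Biological background

KRAB zinc-finger proteins combine an N-terminal KRAB repressor domain with a
C-terminal tandem array of C2H2 zinc fingers. Each finger chelates zinc
through two cysteines and two histidines and contacts roughly three base
pairs of DNA through the residues at recognition-helix positions −1, +3 and
+6 — the finger's *fingerprint*. The genes sit in genomic clusters whose
members tend to share fingerprint usage and expression context, while the
short *linker* segments between fingers are nearly identical within a
cluster and carry cluster-specific nucleotide variants. Those two facts make
the linkers natural targets for multi-copy CRISPR editing of a whole
cluster with a single guide, provided the linker DNA offers a conserved NGG
PAM. `zfplinker` turns that observation into a reproducible pipeline.

## Cluster calling

Genes are grouped per chromosome after sorting by start coordinate. A
cluster is a maximal run in which every neighbour gap is at most `max_gap`
(default 200,000 bp) and that contains at least `min_size` genes (default 2).

* **Gap metric.** The default gap is `start(next) − end(prev)`, the
  strictest interval reading: overlapping or book-ended genes yield a gap
  ≤ 0 and always co-cluster. Because the metric between sorted neighbours is
  a convention rather than a biological fact, `start_start` and `midpoint`
  metrics are available for sensitivity analysis (`cluster_params()`).
* **Strand is ignored**; clustering is purely positional.
* **Identifiers** are assigned 1..N in (chromosome lexicographic, start)
  order, which is deterministic and matches genomic browsing order.

The implementation is a linear scan; the test suite checks it against an
exhaustive oracle that examines every contiguous window for the two
criteria and both maximality conditions, and against
`GenomicRanges::reduce()` on non-overlapping layouts. Two invariants are
property-tested: growing `max_gap` never removes a gene from the clustered
set, and raising `min_size` never increases the number of clusters.

## Tile decomposition and fingerprints

Each protein is scanned with a greedy, leftmost, non-overlapping search for
the C2H2 pattern. The default is the fixed form **C‑X2‑C‑X12‑H‑X3‑H**
(21 residues). For real data, where finger geometry varies, the spacers can
be widened (e.g. `C-X{2,4}-C-X{10,14}-H-X{3,5}-H`); within a variable-range
match the lexicographically smallest spacer lengths are preferred, which
makes matching deterministic. This preference is implemented with lazy
regular-expression quantifiers and is verified against a brute-force
all-start-positions scan on thousands of random proteins.

Two overlapping tile sets cover the array:

* **ZnF tile**: CXXC through HXXXH of one finger;
* **linker tile**: HXXXH of finger *i* through CXXC of finger *i+1* — so
  consecutive tiles share the zinc-coordinating residues, and a gene with
  *k* fingers has exactly *k − 1* linkers.

Nucleotide tiles are read off the CDS by codon position
(`cds[3(a−1)+1 .. 3b]` for amino-acid span `[a, b]`), which requires the
bound CDS to be exactly three times the protein length; terminal stop
codons and `*` are stripped at load time for this reason.

**Fingerprint convention.** The helix positions −1/+3/+6 are anchored on
the first zinc-coordinating histidine H1 (helix position +7): the triplet is
read at offsets (H1−8, H1−4, H1−1) within the tile. The anchor makes the
convention robust to spacer-length variation. This is the single documented
convention used by both the annotator and the synthetic generator, so all
recovery tests are self-consistent; other fingerprint-numbering conventions
exist in the literature, and a user comparing against an external fingerprint
table should confirm the offsets match.

Genes with zero pattern matches are kept with empty annotations (flagged
`no_znf`) rather than dropped, so cluster-level gene counts are unaffected.

## Fingerprint usage matrices

`build_fingerprint_matrix()` counts fingerprint occurrences per gene; row
sums equal per-gene ZnF counts by construction (asserted against
`tile_census()`), and zero-ZnF genes appear as all-zero rows so expression
and census denominators stay consistent. The dominant-species statistic
(`top_species_stats()`) ranks fingerprints by within-subset total, keeps the
top `top_k` with at least `min_count` occurrences, and reports the covered
fraction of the subset's ZnFs. Because ranking is descending, filtering
before or after taking the top k yields the same set, so the two possible
readings of "top 5 species occurring at least 10 times" coincide.
Cluster-level statistics pool member genes; pooling two neighbouring
clusters is expressed by passing their combined gene set.

## Conservation profiles and PAM discovery

Profiles stack equal-length tiles without alignment: sequences are
restricted to the modal length (ties resolve toward the shorter length) and
the discarded fraction is reported. Per-position information content is

`ic[p] = log2(|A|) − H(freqs[p])`

with Shannon entropy in bits, no small-sample correction, and
zero-frequency letters contributing nothing. Bounds are 2 bits for
nucleotides and log2 20 ≈ 4.32 bits for amino acids. Ungapped stacking was
chosen over multiple alignment because it is exactly reproducible and the
tiles are near-constant length by construction; off-modal tiles are
reported, not silently aligned.

`find_conserved_pams()` reports every 0-based offset whose two following
positions both have G frequency at or above `min_g_freq`. The default 0.8
reflects that PAM conservation is a screening threshold, not a family
constant: at 0.8, a PAM survives in at least ~80% of the stacked linkers,
which keeps a multi-target guide's site count close to the linker count.
The threshold is exposed everywhere it is used. Overlapping sites (e.g.
within a G run) are all reported rather than collapsed.

## sgRNA design and specificity

Candidates are the 20-nt windows immediately 5′ of every NGG whose triplet
starts inside a linker tile. Windows are taken from the gene's full CDS, so
a PAM near a linker's 5′ end yields a window crossing into the preceding
ZnF tile — containment anchors the PAM, not the window. PAMs with fewer
than 20 nt of upstream CDS are skipped and counted. Identical protospacers
merge with `design_frequency` equal to the number of source windows;
ranking is by descending frequency with lexicographic tie-break.

Cut-site prediction scans each CDS **on both strands** for the protospacer
followed immediately by an exact NGG. Discovery is coding-strand only
(linker tiles are defined on the coding frame and the conserved PAMs are
read from coding-strand profiles), while cleavage is strand-agnostic; both
choices are flags. The default mismatch tolerance is 0 — a "predicted
cleavage site" is an exact match — and a tolerance parameter exists for
exploration only. Non-canonical PAMs (NAG etc.) are out of scope. The
search space is the provided gene table, i.e. the gene family itself, not a
whole genome; off-family genomic sites are a separate question this package
does not address.

The specificity report aggregates each candidate's sites by the cluster
membership of the harbouring gene, with an `unclustered` column; row sums
equal total sites exactly, and a candidate with zero sites reports an `NA`
(undefined) on-target fraction rather than 0. Every designed candidate
necessarily rediscovers its own source windows, so `total_sites ≥
design_frequency` is asserted as an invariant.

## The synthetic family generator

`generate_family()` emulates the family structure the analysis targets:
genes laid out in chromosomal clusters under the gap rule; per-cluster
fingerprint pools reused with skewed weights; near-identical cluster-specific
linkers carrying exactly two NGG motifs; CDS consistent with protein by
construction; and a TPM table in which chosen clusters are coherently high
in one sample.

Construction details that matter:

* **ZnF scaffold.** All fingers share a 21-residue scaffold (CWSC + 12-aa
  spacer + HTIRH) whose three fingerprint slots are filled per finger from
  the cluster's pool. Flanks, spacer and fingerprint alphabets exclude C and
  H so no spurious C2H2 anchor can arise; the annotator therefore recovers
  exactly the planted fingers.
* **Linker consensus.** The 14-aa linker tile (HXXXH + T·v1·W·v2·E + CXXC)
  uses fixed codons chosen so the 42-nt tile carries exactly two NGG motifs,
  at offsets 21 and 33 — both ≥ 20, so the two protospacer windows lie
  entirely inside the consensus. The two variable residues v1 and v2 are
  drawn without replacement per group (cluster or isolated gene) from a set
  encoded by G-free codons; substituting a G-free codon can neither create
  nor destroy a GG dinucleotide, so the two-NGG property holds for every
  group, and each group's two protospacers contain a group-private codon —
  which is what makes on-target fractions exactly 1.0 in the planted model.
  At most 9 groups can be distinct (the size of the G-free codon set); more
  is an infeasible-configuration error.
* **Noise model.** `linker_mutation_rate` substitutes linker nucleotides
  uniformly (never creating an in-frame stop); `synonymous_wobble_rate`
  swaps synonymous codons. The stated rule that wobble applies to ZnF tiles
  but not linkers cannot be taken literally because the tiles overlap at
  HXXXH/CXXC; wobble is therefore restricted to the ZnF spacer interior,
  the only region belonging to a ZnF tile and no linker. The final protein
  is always re-translated from the final CDS, so protein/CDS consistency
  holds at any mutation rate.
* **Determinism.** One pseudo-random stream, seeded once, drawn in a fixed
  documented order: scaffold, linker variants, fingerprint pools, genes (in
  cluster order), coordinates, expression. The same seed gives byte-identical
  outputs.
* **Defaults as study conditions.** Three clusters of 5/4/3 genes plus two
  isolated genes on three chromosomes, 4–8 fingers per gene, five
  fingerprints per pool with geometric weights (0.6 decay), intra-cluster
  gaps of 5–150 kb (safely inside the 200 kb rule), 1 Mb isolation, planted
  expression at TPM 50–200 against a 0–5 background with penetrance 0.75,
  and zero noise. Zero noise is the reference condition because the planted
  model's recovery guarantees are exact there; degradation tests raise the
  rates explicitly on a {0, 0.01, 0.05, 0.1} grid.

What the generator does **not** emulate: evolutionary history (duplication,
recombination, pseudogenisation), intron structure (genes are intronless,
with gene span equal to CDS length), inter-cluster fingerprint sharing,
length variation between linkers of one family, and biased codon usage
beyond a fixed preference table. Passing recovery tests therefore
demonstrate algorithmic correctness on the planted structure, not
performance on real genomes — real KRAB-ZFP data have partially shared
fingerprints across clusters, variable finger geometry and linker length
variants, which is exactly why the spacer ranges, gap metric and
conservation thresholds are exposed as parameters.

## Numerical choices and degenerate inputs

* Tie-breaks are lexicographic everywhere a rank can tie (candidate
  ranking, fingerprint column order, modal-length ties toward shorter).
* Frequencies are exact ratios of integer counts; profile rows sum to 1
  within 1e−9 and information content is clamped only by arithmetic, never
  post-processed.
* Empty inputs: an empty gene table yields an empty cluster set; a gene
  with no fingers yields an empty annotation (kept); a profile over an
  empty selection is an error; a candidate with zero predicted sites has an
  undefined, not zero, on-target fraction.
* Coordinates are 1-based inclusive in tables and converted once, at BED
  export, to 0-based half-open.

## Problem sizes used in the test suite

The suite generates all fixtures in code. Oracle-equivalence tests run 200
randomized cases per operation (proteins up to 600 aa, DNA up to ~5 kb,
layouts up to 40 genes); recovery tests use the default 14-gene family and a
two-cluster, 20-members-each family for the expression statistic. These
sizes keep the full suite under a minute while exercising every code path;
all statistical checks run at fixed, pre-chosen seeds so results are exactly
reproducible.

## Known limitations

* Exact-match cut-site prediction understates off-target potential; the
  mismatch tolerance exists for exploration but activity scoring (e.g.
  CFD-style models) is out of scope.
* The fingerprint offset convention is fixed; comparing against an external
  fingerprint table derived under another numbering requires care.
* Profiles ignore off-modal-length tiles instead of aligning them; families
  with common linker-length polymorphism will under-use data.
* The cluster caller treats gene intervals as opaque; nested or overlapping
  gene models are clustered by the start-sorted neighbour rule, which is one
  of several defensible readings (hence the configurable gap metric).
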
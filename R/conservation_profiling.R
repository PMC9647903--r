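# Position-frequency / information-content profiles (sequence-logo data)
# and conserved NGG PAM discovery.

PROFILE_ALPHABETS <- list(
  nucleotide = c("A", "C", "G", "T"),
  amino_acid = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
)

#' Build a positional conservation profile
#'
#' Sequences are restricted to the modal length (no alignment; off-length
#' sequences are counted in `n_discarded`, ties broken toward the shorter
#' length). Per-position letter frequencies are computed over the alphabet,
#' and the information content at position p is
#' `ic[p] = log2(|alphabet|) - H(freqs[p])` with Shannon entropy in bits,
#' no small-sample correction; zero-frequency letters contribute 0.
#'
#' @param seqs Character vector of same-type tile sequences.
#' @param alphabet `"nucleotide"` (4 letters, max 2 bits) or `"amino_acid"`
#'   (20 letters, max log2(20) ~ 4.32 bits).
#' @return A `conservation_profile`: list with `alphabet`, `length`,
#'   `freqs` (length x alphabet matrix, rows summing to 1), `ic`,
#'   `n_sequences`, `n_discarded`.
#' @export
build_profile <- function(seqs, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  letters_ <- PROFILE_ALPHABETS[[alphabet]]
  seqs <- toupper(seqs[!is.na(seqs)])
  if (!length(seqs)) stop("no sequences to profile")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])
  keep <- seqs[lens == modal]
  n_discarded <- sum(lens != modal)
  if (modal == 0L) stop("modal sequence length is zero")
  chm <- do.call(rbind, strsplit(keep, ""))
  counts <- vapply(seq_len(modal), function(p)
    tabulate(factor(chm[, p], levels = letters_), nbins = length(letters_)),
    integer(length(letters_)))
  denom <- colSums(counts)
  if (any(denom == 0L)) {
    stop("position with no letters from the ", alphabet, " alphabet")
  }
  freqs <- t(counts) / denom   # length x alphabet
  colnames(freqs) <- letters_
  rownames(freqs) <- NULL
  ent <- apply(freqs, 1, function(f) -sum(f[f > 0] * log2(f[f > 0])))
  structure(list(alphabet = alphabet, length = modal, freqs = freqs,
                 ic = log2(length(letters_)) - ent,
                 n_sequences = length(keep), n_discarded = n_discarded),
            class = "conservation_profile")
}

gather_tiles <- function(annotations, genes = NULL,
                         tile_type = c("linker", "znf"),
                         what = c("nt", "aa")) {
  tile_type <- match.arg(tile_type)
  what <- match.arg(what)
  if (is.null(genes)) genes <- names(annotations)
  missing <- setdiff(genes, names(annotations))
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  }
  col <- paste0(what, "_seq")
  unlist(lapply(annotations[genes], function(a) {
    df <- if (tile_type == "znf") a$znfs else a$linkers
    df[[col]]
  }), use.names = FALSE)
}

#' Conservation profile at genome, cluster, or single-gene level
#'
#' Gathers the matching tiles and delegates to [build_profile()]. For the
#' cluster level, `ids` may name several clusters whose member genes are
#' pooled (e.g. two neighbouring clusters with shared features).
#'
#' @param annotations Named list of `znf_annotation` objects.
#' @param level `"genome"`, `"cluster"` or `"gene"`.
#' @param ids Cluster ids (integer) or gene ids (character), depending on
#'   `level`; ignored for `"genome"`.
#' @param clusters A `cluster_set`; required for `level = "cluster"`.
#' @param tile_type `"linker"` or `"znf"`.
#' @param alphabet `"nucleotide"` or `"amino_acid"`; selects nt or aa tiles.
#' @return A `conservation_profile` with a `provenance` attribute recording
#'   the selection.
#' @export
profile_levels <- function(annotations, level = c("genome", "cluster", "gene"),
                           ids = NULL, clusters = NULL,
                           tile_type = c("linker", "znf"),
                           alphabet = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  tile_type <- match.arg(tile_type)
  alphabet <- match.arg(alphabet)
  what <- if (alphabet == "nucleotide") "nt" else "aa"
  genes <- switch(
    level,
    genome = names(annotations),
    cluster = {
      if (is.null(clusters)) stop("clusters required for cluster-level profile")
      unknown <- setdiff(ids, clusters$cluster_id)
      if (length(unknown)) {
        stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
      }
      intersect(
        unlist(clusters$members[match(ids, clusters$cluster_id)],
               use.names = FALSE),
        names(annotations))
    },
    gene = {
      unknown <- setdiff(ids, names(annotations))
      if (length(unknown)) {
        stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
      }
      ids
    }
  )
  if (!length(genes)) stop("empty selection for profile")
  tiles <- gather_tiles(annotations, genes, tile_type, what)
  if (!length(tiles)) stop("selection contains no ", tile_type, " tiles")
  prof <- build_profile(tiles, alphabet)
  attr(prof, "provenance") <- list(level = level, ids = ids,
                                   tile_type = tile_type, n_genes = length(genes))
  prof
}

#' Find conserved NGG PAM positions in a nucleotide profile
#'
#' Reports every 0-based offset `o` such that the G frequency at both
#' positions `o+1` and `o+2` of the profile is at least `min_g_freq`
#' (the N position is unconstrained); overlapping sites are all reported.
#'
#' @param profile A nucleotide `conservation_profile`.
#' @param min_g_freq Minimum G frequency at both G positions (default 0.8;
#'   the conservation cut-off is a tunable, not a family constant).
#' @return A `pam_site_report`: list with `pam_offsets` (0-based) and
#'   `g_frequency` (the smaller of the two G frequencies per site).
#' @export
find_conserved_pams <- function(profile, min_g_freq = 0.8) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (profile$alphabet != "nucleotide") {
    stop("PAM discovery requires a nucleotide profile")
  }
  g <- profile$freqs[, "G"]
  L <- profile$length
  offs <- integer()
  gf <- numeric()
  if (L >= 3L) {
    for (o in 0:(L - 3L)) {
      lo <- min(g[o + 2L], g[o + 3L])
      if (lo >= min_g_freq) {
        offs <- c(offs, o)
        gf <- c(gf, lo)
      }
    }
  }
  structure(list(pam_offsets = offs, g_frequency = gf,
                 min_g_freq = min_g_freq),
            class = "pam_site_report")
}

#' Write a profile as a per-position table
#'
#' Columns: `position` (1-based), one frequency column per letter, `ic`.
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(position = seq_len(profile$length),
                    profile$freqs, ic = profile$ic,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
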
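# End-to-end orchestration: load/simulate -> annotate -> cluster ->
# fingerprints -> conservation (+ PAM discovery) -> expression selection ->
# sgRNA design -> specificity. Stages communicate via files in the output
# directory and a machine-readable run report.

#' Pipeline configuration
#'
#' Either point `genes`/`protein_fasta`/`cds_fasta` (and optionally `tpm`)
#' at input files, or supply a `simulate` block ([family_config()]) to run
#' on a generated family.
#'
#' @param out_dir Output directory for stage artefacts and the run report.
#' @param genes,protein_fasta,cds_fasta,tpm Input paths (ignored when
#'   `simulate` is given).
#' @param simulate Optional [family_config()].
#' @param cluster_params A [cluster_params()].
#' @param pattern A [pattern_config()].
#' @param expression_sample,tpm_threshold Sample and inclusive TPM cut-off
#'   for the expression stage.
#' @param cluster_ratio_cutoff Exclusive expressed/total ratio above which a
#'   cluster counts as highly expressed.
#' @param top_k Number of top sgRNA candidates to keep.
#' @param max_mismatches Protospacer mismatch tolerance for cut-site
#'   prediction (0 = exact-match predicted cleavage sites).
#' @param min_g_freq PAM-conservation threshold for [find_conserved_pams()].
#' @param seed Seed for any stochastic stage (simulation).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            genes = NULL, protein_fasta = NULL,
                            cds_fasta = NULL, tpm = NULL,
                            simulate = NULL,
                            cluster_params = zfplinker::cluster_params(),
                            pattern = pattern_config(),
                            expression_sample = "mESC",
                            tpm_threshold = 25,
                            cluster_ratio_cutoff = 0.5,
                            top_k = 11L,
                            max_mismatches = 0L,
                            min_g_freq = 0.8,
                            seed = 1L) {
  if (is.null(simulate) &&
      (is.null(genes) || is.null(protein_fasta) || is.null(cds_fasta))) {
    stop("either a simulate block or genes + protein_fasta + cds_fasta is required")
  }
  structure(list(out_dir = out_dir, genes = genes,
                 protein_fasta = protein_fasta, cds_fasta = cds_fasta,
                 tpm = tpm, simulate = simulate,
                 cluster_params = cluster_params, pattern = pattern,
                 expression_sample = expression_sample,
                 tpm_threshold = tpm_threshold,
                 cluster_ratio_cutoff = cluster_ratio_cutoff,
                 top_k = as.integer(top_k),
                 max_mismatches = as.integer(max_mismatches),
                 min_g_freq = min_g_freq, seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cluster-analysis pipeline
#'
#' Executes load/simulate, annotation, cluster calling, fingerprint
#' profiling, conservation profiling with PAM discovery, expression
#' selection (when a TPM table is available), sgRNA candidate design against
#' the highly expressed clusters (all clusters when no expression data), and
#' specificity scoring against the full gene set. Every stage writes its
#' artefact under `config$out_dir`; a JSON run report (`report.json`)
#' records counts, parameters and the seed. Identical config + seed gives an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    fam <- with_stage("simulate", {
      cfg <- config$simulate
      cfg$seed <- config$seed
      generate_family(cfg)
    })
    with_stage("simulate", write_family(fam, file.path(out, "family")))
    table <- fam$genes
    tpm <- fam$tpm
  } else {
    table <- with_stage("read_gene_table", read_gene_table(config$genes))
    table <- with_stage("bind_sequences",
                        bind_sequences(table, config$protein_fasta,
                                       config$cds_fasta))
    tpm <- if (!is.null(config$tpm)) {
      with_stage("read_expression_table", read_expression_table(config$tpm))
    }
  }

  annotations <- with_stage("annotate",
                            annotate_gene_table(table, config$pattern))
  with_stage("annotate",
             write_tile_table(annotations, file.path(out, "tiles.tsv")))
  census <- tile_census(annotations)

  clusters <- with_stage("clusters", call_clusters(table, config$cluster_params))
  with_stage("clusters", {
    write_cluster_table(clusters, file.path(out, "clusters.tsv"))
    write_bed(clusters, file.path(out, "clusters.bed"))
  })
  ccensus <- cluster_census(clusters, table)

  fpm <- with_stage("fingerprints", build_fingerprint_matrix(annotations))
  with_stage("fingerprints",
             write_fingerprint_matrix(fpm,
                                      file.path(out, "fingerprints_wide.tsv"),
                                      file.path(out, "fingerprints_long.tsv")))

  genome_prof <- with_stage("conservation",
                            profile_levels(annotations, "genome",
                                           tile_type = "linker",
                                           alphabet = "nucleotide"))
  with_stage("conservation",
             write_profile(genome_prof, file.path(out, "linker_profile_genome.tsv")))
  pam_by_cluster <- with_stage("conservation", {
    lapply(seq_len(nrow(clusters)), function(i) {
      prof <- profile_levels(annotations, "cluster",
                             ids = clusters$cluster_id[i], clusters = clusters,
                             tile_type = "linker", alphabet = "nucleotide")
      write_profile(prof, file.path(
        out, sprintf("linker_profile_cluster_%d.tsv", clusters$cluster_id[i])))
      find_conserved_pams(prof, config$min_g_freq)
    })
  })

  if (!is.null(tpm)) {
    selected <- with_stage("expression",
                           select_highly_expressed(tpm, config$expression_sample,
                                                   config$tpm_threshold))
    ratios <- with_stage("expression",
                         cluster_expression_ratios(selected, clusters))
    utils::write.table(ratios, file.path(out, "expression_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    target_clusters <- highly_expressed_clusters(ratios,
                                                 config$cluster_ratio_cutoff)
  } else {
    selected <- character()
    ratios <- NULL
    target_clusters <- clusters$cluster_id
  }
  if (!length(target_clusters)) target_clusters <- clusters$cluster_id

  target_genes <- intersect(
    unlist(clusters$members[match(target_clusters, clusters$cluster_id)],
           use.names = FALSE),
    names(annotations))
  candidates <- with_stage("design",
                           enumerate_candidates(annotations, target_genes,
                                                target_clusters))
  top <- with_stage("design", select_top(candidates, config$top_k))
  report_spec <- with_stage("specificity",
                            specificity_report(top, table, clusters,
                                               max_mismatches = config$max_mismatches))
  with_stage("specificity",
             write_specificity_table(report_spec, top,
                                     file.path(out, "sgrna_specificity.tsv")))

  report <- list(
    seed = config$seed,
    parameters = list(
      max_gap = config$cluster_params$max_gap,
      min_size = config$cluster_params$min_size,
      gap_metric = config$cluster_params$gap_metric,
      expression_sample = config$expression_sample,
      tpm_threshold = config$tpm_threshold,
      cluster_ratio_cutoff = config$cluster_ratio_cutoff,
      top_k = config$top_k,
      max_mismatches = config$max_mismatches,
      min_g_freq = config$min_g_freq
    ),
    n_genes = nrow(table),
    n_sequenced = sum(table$sequenced),
    n_clusters = ccensus$n_clusters,
    n_clustered = ccensus$n_clustered,
    n_znfs = census$n_znf,
    n_distinct_fingerprints = census$n_distinct_fingerprints,
    n_selected_genes = length(selected),
    target_clusters = as.integer(target_clusters),
    pam_offsets_per_cluster = lapply(pam_by_cluster, `[[`, "pam_offsets"),
    n_candidates = nrow(candidates),
    top_candidates = top$protospacer,
    top_design_frequency = top$design_frequency,
    top_total_sites = unname(report_spec$total_sites),
    top_on_target_fraction = unname(report_spec$on_target_fraction)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
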
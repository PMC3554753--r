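#' Run the full synthetic grain-filling analysis pipeline
#'
#' simulate -> annotate -> discover -> targets -> dge -> dynamics, on data
#' generated from `config`.  Every stage consumes the previous stage's
#' in-memory objects; with `out_dir` set, all module outputs are also
#' written (FASTA/GFF3/TSV/JSON) so a run is fully reproducible from its
#' seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if missing).
#' @param k number of expression clusters (capped at the number of
#'   filtered profiles).
#' @param tpm_filter strict TPM threshold for the dynamics filter.
#' @param quiet suppress per-stage messages.
#' @return a report bundle (list) with elements `sim`, `libs`,
#'   `classified`, `partition`, `size_unique`, `size_total`, `tpm`,
#'   `star_ratios`, `novel`, `target_hits`, `dge`, `weights`, `model`,
#'   `clusters`, `cluster_rate_pcc`, `pair_correlation`, `recovery`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         k = 10L, tpm_filter = 10, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  sim <- stage("simulate", simulate_genome(config))
  libs <- stage("libraries", simulate_libraries(sim$genome, sim$truth, config))
  totals <- colSums(count_matrix(libs))

  hits <- stage("map", map_to_genome(libs$sequence, sim$genome))
  classified <- stage("classify", classify_reads(libs, hits, sim$tracks))
  partition <- partition_table(classified)
  size_u <- size_distribution(classified, "unique")
  size_t <- size_distribution(classified, "total")
  tpm <- tpm_normalize(count_matrix(classified), totals)

  pm <- sim$truth$planted_mirnas
  known <- pm[pm$known, , drop = FALSE]
  star_tab <- NULL
  if (nrow(known)) {
    ids <- rownames(tpm)
    pairs <- data.frame(mature_id = known$mature, star_id = known$star)
    pairs <- pairs[pairs$mature_id %in% ids & pairs$star_id %in% ids, ]
    if (nrow(pairs)) star_tab <- star_ratio(tpm, pairs)
  }

  disc <- stage("discover",
                discover_novel_mirnas(classified, hits, sim$genome,
                                      tracks = sim$tracks, totals = totals))

  dge_sim <- stage("dge-simulate", simulate_dge(sim$truth, config))
  mirnas <- setNames(pm$mature, pm$id)
  target_hits <- stage("targets",
                       scan_transcriptome(mirnas, dge_sim$transcripts))
  tags <- filter_tags(dge_sim$tags)
  dge_q <- stage("dge-quantify",
                 quantify_genes(tags, dge_sim$transcripts,
                                stages = names(config$library_depths)))

  lp <- sim$truth$logistic_params
  weights <- stage("weights",
                   simulate_grain_weights(lp, days = seq(5, 45, by = 5),
                                          noise_sd = 0.3,
                                          seed = config$seed + 3L))
  model <- stage("fit", fit_logistic(weights))

  mir_tpm <- tpm[rownames(tpm) %in% pm$mature, , drop = FALSE]
  rownames(mir_tpm) <- pm$id[match(rownames(mir_tpm), pm$mature)]
  filt <- filter_expressed(mir_tpm, tpm_filter)
  clusters <- NULL; cluster_pcc <- NULL
  if (nrow(filt) >= 2) {
    kk <- min(k, nrow(filt))
    clusters <- cluster_profiles(filt, k = kk)
    cluster_pcc <- vapply(seq_len(kk), function(g) {
      correlate_with_rate(clusters$means[g, ], model,
                          stage_days = STAGE_DAYS)
    }, numeric(1))
  }

  gene_tpm <- as.matrix(dge_q$genes[, paste0(names(config$library_depths), "_tpm")])
  rownames(gene_tpm) <- dge_q$genes$gene
  colnames(gene_tpm) <- names(config$library_depths)
  pair_cor <- mirna_target_correlation(mir_tpm, gene_tpm, dge_sim$pairs)

  recovery <- data.frame(
    id = pm$id, known = pm$known,
    mature_detected = pm$mature %in% classified$sequence,
    recovered_novel = !pm$known & pm$mature %in% disc$novel$sequence,
    stringsAsFactors = FALSE)

  bundle <- list(sim = sim, libs = libs, classified = classified,
                 partition = partition, size_unique = size_u,
                 size_total = size_t, tpm = tpm, star_ratios = star_tab,
                 novel = disc$novel, discovery_report = disc$report,
                 target_hits = target_hits, dge = dge_q,
                 dge_inputs = dge_sim, weights = weights, model = model,
                 clusters = clusters, cluster_rate_pcc = cluster_pcc,
                 pair_correlation = pair_cor, recovery = recovery,
                 seed = config$seed)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# write every module output of a pipeline bundle under out_dir
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(bundle$sim$genome, p("genome.fasta"))
  write_gff3(bundle$sim$tracks, p("tracks.gff3"))
  pm <- bundle$sim$truth$planted_mirnas
  known <- pm[pm$known, , drop = FALSE]
  if (nrow(known)) {
    prec <- substring(bundle$sim$genome[["chr1"]], known$prec_start + 1L,
                      known$prec_end)
    write_fasta(setNames(prec, known$id), p("known_mirna_precursors.fasta"))
    mat <- setNames(known$mature,
                    sprintf("%s-5p precursor=%s start=%d end=%d arm=5p",
                            known$id, known$id,
                            known$mature_start - known$prec_start,
                            known$mature_end - known$prec_start))
    write_fasta(mat, p("known_mirna_matures.fasta"))
  }
  for (s in names(attr(bundle$libs, "depths"))) {
    write_collapsed_fasta(bundle$libs, s, p(sprintf("lib_%s.fasta", s)))
  }
  write_tsv(bundle$partition, p("partition.tsv"), digits = NA)
  write_tsv(bundle$size_unique, p("size_distribution_unique.tsv"), digits = 4)
  write_tsv(bundle$size_total, p("size_distribution_total.tsv"), digits = 4)
  tpm_df <- data.frame(sequence = rownames(bundle$tpm),
                       as.data.frame(bundle$tpm), check.names = FALSE)
  write_tsv(tpm_df, p("tpm.tsv"))
  if (!is.null(bundle$star_ratios)) write_tsv(bundle$star_ratios, p("star_ratios.tsv"))
  write_tsv(bundle$novel, p("novel_mirnas.tsv"))
  write_tsv(bundle$target_hits, p("target_hits.tsv"))
  write_tsv(bundle$dge$genes, p("gene_expression.tsv"))
  write_tsv(bundle$weights, p("weights.tsv"), digits = 4)
  jsonlite::write_json(
    list(K = bundle$model$K, a = bundle$model$a, b = bundle$model$b,
         seed = bundle$seed),
    p("logistic_model.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$clusters)) {
    write_tsv(data.frame(id = names(bundle$clusters$assignment),
                         cluster = as.integer(bundle$clusters$assignment)),
              p("clusters.tsv"), digits = NA)
  }
  write_tsv(bundle$pair_correlation, p("pair_correlation.tsv"), digits = 4)
  write_tsv(bundle$recovery, p("recovery.tsv"), digits = NA)
  jsonlite::write_json(
    list(planted_mirnas = pm,
         logistic_params = as.list(bundle$sim$truth$logistic_params)),
    p("truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
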
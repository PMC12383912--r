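.run_all_defaults <- function() {
  list(
    # simulation
    n_genes = 2000L, n_reps_per_group = 3L, phi = 0.1, baseline_mean = 500,
    mean_sdlog = 0.5, effect_log2fc = 2,
    category_fractions = c(Transcription = 0.19, Translation = 0.12,
                           Homodirection = 0.24, Opposite = 0.01,
                           Unchanged = 0.44),
    pi_frame = 0.9, rho_cds = 0.9, psite_offset = 12L,
    uorf_plant_rate = 0.5, translated_uorf_fraction = 0.3,
    uorf_read_fraction = 0.15,
    # analysis
    min_read_len = 20L, max_read_len = 40L,
    lfc_thr = 1, fdr_thr = 0.05,
    fold_backend = "nussinov", fold_max_len = 400L,
    min_uorf_len = 9L,
    uorf_thresholds = list(orfscore = 6, rrs = 2, fickett = 0.74,
                           hexamer = 0, min_fpkm = 1))
}

# per-group mean TE with NA-tolerant means
.group_te <- function(te_tbl, groups) {
  g <- groups[colnames(te_tbl$values)]
  vapply(split(colnames(te_tbl$values), g), function(cs)
    rowMeans(te_tbl$values[, cs, drop = FALSE], na.rm = TRUE),
    numeric(nrow(te_tbl$values)))
}

#' Run the full synthetic study end to end
#'
#' Simulates a two-group study, writes its inputs (FASTA, GTF, count TSVs,
#' footprint table, ground truth), then runs footprint QC, FPKM/TE
#' quantification, the three differential layers with five-category
#' classification, CDS feature analysis across TE bins, and the uORF stage,
#' writing TSV/JSON outputs plus a run manifest (tool version, config
#' snapshot, seed, input checksums, per-stage row counts) into `outdir`.
#' Everything is driven by the single `seed`, which fans out into per-stage
#' substreams, so two runs with the same seed produce byte-identical outputs.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer global seed.
#' @param config named list overriding any default returned by the internal
#'   defaults (unknown keys are an error listing the valid ones).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(outdir, seed = 1L, config = list()) {
  defaults <- .run_all_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "\nvalid keys: ", paste(names(defaults), collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  manifest <- list(tool = "riboscape",
                   version = as.character(packageVersion("riboscape")),
                   seed = as.integer(seed),
                   config = cfg, rows = list(), input_checksums = list())

  ## stage 1: simulate ------------------------------------------------------
  log_msg("stage simulate: ", cfg$n_genes, " genes, 2 x ", cfg$n_reps_per_group,
          " replicates")
  sim_args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  sim_args$seed <- seed
  study <- simulate_study(do.call(sim_config, sim_args))
  write_transcriptome(study$models, pth("transcripts.fa"), pth("annotation.gtf"))
  write_counts(study$rna, pth("rna_counts.tsv"))
  write_counts(study$ribo, pth("ribo_counts.tsv"))
  write_footprints(study$footprints, pth("footprints.tsv"))
  data.table::fwrite(study$truth, pth("truth_genes.tsv"), sep = "\t")
  if (!is.null(study$uorf_truth))
    data.table::fwrite(study$uorf_truth, pth("truth_uorfs.tsv"), sep = "\t")
  manifest$rows$simulate <- list(genes = nrow(study$models),
                                 footprints = nrow(study$footprints))
  manifest$input_checksums <- as.list(tools::md5sum(
    c(pth("transcripts.fa"), pth("annotation.gtf"), pth("rna_counts.tsv"),
      pth("ribo_counts.tsv"), pth("footprints.tsv"))))
  names(manifest$input_checksums) <- basename(names(manifest$input_checksums))

  ## stage 2: quantify (needed by QC's sample panel) ------------------------
  log_msg("stage quantify: FPKM and TE")
  fpkm_rna <- fpkm(study$rna)
  fpkm_ribo <- fpkm(study$ribo)
  te <- translation_efficiency(fpkm_ribo, fpkm_rna)
  te_group <- .group_te(te, study$groups)
  bins <- lapply(colnames(te_group), function(g) te_bins(te_group[, g]))
  names(bins) <- colnames(te_group)
  write_counts(fpkm_rna, pth("fpkm_rna.tsv"))
  write_counts(fpkm_ribo, pth("fpkm_ribo.tsv"))
  write_counts(te, pth("te.tsv"))
  bins_df <- data.frame(gene_id = rownames(te_group),
                        te_g1 = te_group[, 1L], te_g2 = te_group[, 2L],
                        bin_g1 = as.character(bins[[1L]][rownames(te_group)]),
                        bin_g2 = as.character(bins[[2L]][rownames(te_group)]),
                        stringsAsFactors = FALSE)
  data.table::fwrite(bins_df, pth("te_bins.tsv"), sep = "\t")
  manifest$rows$quantify <- list(genes = nrow(te$values))

  ## stage 3: QC -------------------------------------------------------------
  log_msg("stage qc: footprint QC and periodicity")
  qc <- qc_report(study$footprints, study$models, fpkm_table = fpkm_ribo,
                  min_len = cfg$min_read_len, max_len = cfg$max_read_len)
  data.table::fwrite(data.table::as.data.table(qc$length_histogram,
                                               keep.rownames = "read_length"),
                     pth("qc_length_histogram.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(qc$region$fractions,
                                               keep.rownames = "sample_id"),
                     pth("qc_region_fractions.tsv"), sep = "\t")
  data.table::fwrite(data.frame(read_length = names(qc$offsets),
                                offset = as.integer(qc$offsets)),
                     pth("qc_psite_offsets.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(qc$periodicity$by_length,
                                               keep.rownames = "read_length"),
                     pth("qc_periodicity.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(qc$samples$correlation,
                                               keep.rownames = "sample_id"),
                     pth("qc_sample_correlation.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(qc$samples$pca,
                                               keep.rownames = "sample_id"),
                     pth("qc_pca.tsv"), sep = "\t")
  manifest$rows$qc <- list(footprints_after_filter = sum(qc$length_histogram))

  ## stage 4: differential ----------------------------------------------------
  log_msg("stage diff: NB tests at RNA / RIBO / TE layers")
  grp <- factor(study$groups, levels = c("g1", "g2"))
  d_rna <- nb_two_group_test(study$rna, grp)
  d_ribo <- nb_two_group_test(study$ribo, grp)
  d_te <- dteg_test(study$rna, study$ribo, grp)
  cls <- classify_divergence(d_rna, d_ribo, cfg$lfc_thr, cfg$fdr_thr, "Translation")
  cls_te <- classify_divergence(d_rna, d_te, cfg$lfc_thr, cfg$fdr_thr, "TE")
  for (nm in c("d_rna", "d_ribo", "d_te")) {
    data.table::fwrite(get(nm), pth(paste0("diff_", sub("d_", "", nm), ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(merge(cls, cls_te, by = "gene_id",
                           suffixes = c("_rna_vs_ribo", "_rna_vs_te")),
                     pth("divergence.tsv"), sep = "\t")
  data.table::fwrite(divergence_summary(cls), pth("divergence_summary.tsv"), sep = "\t")
  data.table::fwrite(divergence_summary(cls_te), pth("divergence_te_summary.tsv"),
                     sep = "\t")
  manifest$rows$diff <- list(
    dtg = diff_totals(d_ribo, lfc_thr = cfg$lfc_thr, fdr_thr = cfg$fdr_thr),
    dteg = diff_totals(d_te, lfc_thr = cfg$lfc_thr, fdr_thr = cfg$fdr_thr))

  ## stage 5: CDS sequence features by TE bin --------------------------------
  log_msg("stage seqfeat: CDS length / GC / NMFE across TE bins")
  cds_seq <- region_sequence(study$models, "cds")
  fold <- fold_nmfe(cds_seq, backend = cfg$fold_backend, max_len = cfg$fold_max_len)
  feat <- data.frame(gene_id = study$models$gene_id,
                     cds_length = cds_length(study$models),
                     gc = gc_content(cds_seq),
                     nmfe = fold$nmfe, backend = fold$backend,
                     stringsAsFactors = FALSE)
  feat$te_bin <- as.character(bins[["g1"]][feat$gene_id])
  feat_tested <- feat[!is.na(feat$te_bin), ]
  sf_res <- feature_by_te_bin(feat_tested)
  data.table::fwrite(feat, pth("seqfeat.tsv"), sep = "\t")
  letters_df <- do.call(rbind, lapply(names(sf_res), function(f) {
    if (is.null(sf_res[[f]]$letters)) return(NULL)
    data.frame(feature = f, te_bin = names(sf_res[[f]]$letters),
               letters = unname(sf_res[[f]]$letters),
               kruskal_p = sf_res[[f]]$kruskal_p, stringsAsFactors = FALSE)
  }))
  if (!is.null(letters_df))
    data.table::fwrite(letters_df, pth("seqfeat_letters.tsv"), sep = "\t")
  manifest$rows$seqfeat <- list(genes = nrow(feat))

  ## stage 6: uORFs ------------------------------------------------------------
  log_msg("stage uorf: detection, scoring, classification")
  fp_filt <- filter_by_length(study$footprints, cfg$min_read_len, cfg$max_read_len)
  uorfs <- detect_uorfs(study$models, min_len = cfg$min_uorf_len)
  hex_tab <- train_hexamer_table(study$models, seed = stage_seed(seed, "hexamer"))
  scored <- score_uorfs(uorfs, fp_filt, study$models, qc$offsets, study$groups,
                        hex_tab, fold_backend = cfg$fold_backend)
  scored <- classify_translated(scored, cfg$uorf_thresholds)
  data.table::fwrite(scored, pth("uorfs.tsv"), sep = "\t")

  kz <- NULL
  n_tr <- sum(scored$translated)
  n_un <- sum(!scored$translated)
  if (n_tr >= 5L && n_un >= 5L) {
    kz <- kozak_analysis(scored$kozak_context[scored$translated],
                         scored$kozak_context[!scored$translated])
    jsonlite::write_json(list(pwm_translated = kz$pwm_a,
                              pwm_untranslated = kz$pwm_b,
                              chisq_p = as.list(kz$p_values)),
                         pth("uorf_kozak.json"), auto_unbox = TRUE, digits = 8)
  }
  # uORF-vs-mORF start contexts
  m_ctx <- kozak_context(study$models, study$models$transcript_id,
                         study$models$cds_start)
  kz_morf <- if (nrow(scored) >= 5L)
    kozak_analysis(scored$kozak_context, m_ctx) else NULL

  # per-gene relation table: last uORF, its change, the mORF change, TE
  lastu <- last_uorf_per_gene(scored)
  eps <- 0.01
  rel <- data.frame(gene_id = lastu$gene_id,
                    uorf_log2fc = log2((lastu$fpkm_g2 + eps) / (lastu$fpkm_g1 + eps)),
                    uorf_length = lastu$length, uorf_gc = lastu$gc,
                    uorf_nmfe = lastu$nmfe,
                    uorf_class = ifelse(lastu$translated, "translated", "untranslated"),
                    stringsAsFactors = FALSE)
  rel$morf_log2fc <- d_ribo$log2fc[match(rel$gene_id, d_ribo$gene_id)]
  rel$te <- te_group[match(rel$gene_id, rownames(te_group)), 1L]
  keep <- pmax(lastu$fpkm_g1, lastu$fpkm_g2) >= 1   # expressed in >= one group
  no_u <- data.frame(gene_id = setdiff(study$models$gene_id, rel$gene_id),
                     stringsAsFactors = FALSE)
  no_u$uorf_log2fc <- NA_real_; no_u$uorf_length <- NA_real_
  no_u$uorf_gc <- NA_real_; no_u$uorf_nmfe <- NA_real_
  no_u$uorf_class <- "none"
  no_u$morf_log2fc <- d_ribo$log2fc[match(no_u$gene_id, d_ribo$gene_id)]
  no_u$te <- te_group[match(no_u$gene_id, rownames(te_group)), 1L]
  rel_all <- rbind(rel[keep, ], no_u[, names(rel)])
  relation <- uorf_morf_relation(rel_all)
  data.table::fwrite(rel_all, pth("uorf_morf_relation.tsv"), sep = "\t")
  jsonlite::write_json(
    list(correlation = relation$correlation,
         regressions = relation$regressions,
         ks = relation$ks,
         kozak_uorf_vs_morf_p = if (!is.null(kz_morf)) as.list(kz_morf$p_values)),
    pth("uorf_relation.json"), auto_unbox = TRUE, digits = 8)
  manifest$rows$uorf <- list(candidates = nrow(scored), translated = n_tr)

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE, digits = 8)
  invisible(list(study = study, qc = qc, fpkm_rna = fpkm_rna,
                 fpkm_ribo = fpkm_ribo, te = te, te_group = te_group,
                 bins = bins, diff = list(rna = d_rna, ribo = d_ribo, te = d_te),
                 divergence = cls, divergence_te = cls_te, seqfeat = sf_res,
                 features = feat, uorfs = scored, kozak = kz,
                 relation = relation, manifest = manifest))
}
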
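#' Configuration for the synthetic two-group Ribo-seq/RNA-seq study
#'
#' Defaults emulate a two-group (yak-like vs hybrid-like), three-replicate
#' testis study: negative-binomial counts (Var = mu + phi mu^2) around a
#' lognormal baseline, planted divergence categories, footprint lengths
#' peaked at 28 and 30 nt, 90% of CDS footprints in frame 0, a global P-site
#' offset of 12 nt, and AUG uORFs of 51-198 nt planted into half of the
#' 5'UTRs, a configurable fraction of which are actively translated.
#'
#' @param n_genes number of genes (one canonical transcript each).
#' @param n_reps_per_group replicates per group.
#' @param seed global seed; fanned out per stage via [stage_seed()].
#' @param phi NB dispersion.
#' @param baseline_mean median baseline RNA count per gene.
#' @param mean_sdlog lognormal spread of gene baselines.
#' @param effect_log2fc planted |log2 fold change| for affected genes.
#' @param category_fractions named fractions over the five divergence
#'   categories (must sum to 1).
#' @param pi_frame probability that a CDS footprint's P-site is in frame 0.
#' @param rho_cds fraction of a gene's footprints placed in the CDS.
#' @param psite_offset planted global P-site offset (nt).
#' @param footprint_length_probs named probabilities over read lengths 20-40.
#' @param uorf_plant_rate fraction of genes receiving a planted uORF.
#' @param translated_uorf_fraction fraction of planted uORFs that are
#'   translated.
#' @param uorf_read_fraction fraction of a translated-uORF gene's footprints
#'   diverted into the uORF (frame-biased relative to the uORF start).
#' @param utr5_range,cds_range,utr3_range length ranges (nt); CDS forced to a
#'   multiple of 3.
#' @param uorf_len_range planted uORF length range (nt, multiple of 3).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_reps_per_group = 3L, seed = 1L,
                       phi = 0.1, baseline_mean = 500, mean_sdlog = 0.5,
                       effect_log2fc = 2,
                       category_fractions = c(Transcription = 0.19,
                                              Translation = 0.12,
                                              Homodirection = 0.24,
                                              Opposite = 0.01,
                                              Unchanged = 0.44),
                       pi_frame = 0.9, rho_cds = 0.9, psite_offset = 12L,
                       footprint_length_probs = NULL,
                       uorf_plant_rate = 0.5, translated_uorf_fraction = 0.3,
                       uorf_read_fraction = 0.15,
                       utr5_range = c(100L, 500L), cds_range = c(300L, 3000L),
                       utr3_range = c(100L, 500L),
                       uorf_len_range = c(51L, 198L)) {
  if (is.null(footprint_length_probs)) {
    p <- setNames(rep(0.004, 21L), 20:40)
    p[c("26", "27", "28", "29", "30", "31", "32")] <-
      c(0.05, 0.09, 0.28, 0.12, 0.28, 0.05, 0.03)
    footprint_length_probs <- p / sum(p)
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_reps_per_group = as.integer(n_reps_per_group),
              seed = as.integer(seed), phi = phi, baseline_mean = baseline_mean,
              mean_sdlog = mean_sdlog, effect_log2fc = effect_log2fc,
              category_fractions = category_fractions, pi_frame = pi_frame,
              rho_cds = rho_cds, psite_offset = as.integer(psite_offset),
              footprint_length_probs = footprint_length_probs,
              uorf_plant_rate = uorf_plant_rate,
              translated_uorf_fraction = translated_uorf_fraction,
              uorf_read_fraction = uorf_read_fraction,
              utr5_range = utr5_range, cds_range = cds_range,
              utr3_range = utr3_range, uorf_len_range = uorf_len_range)
  if (abs(sum(cfg$category_fractions) - 1) > 1e-8)
    stop("category fractions must sum to 1", call. = FALSE)
  if (!all(names(cfg$category_fractions) ==
           c("Transcription", "Translation", "Homodirection", "Opposite", "Unchanged")))
    stop("category_fractions must be named Transcription, Translation, ",
         "Homodirection, Opposite, Unchanged (in order)", call. = FALSE)
  if (cfg$pi_frame <= 1 / 3 || cfg$pi_frame > 1)
    stop("pi_frame must lie in (1/3, 1]", call. = FALSE)
  if (cfg$phi <= 0) stop("phi must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# positional base profiles of the synthetic coding model: strongly
# asymmetric codon positions so coding sequence carries the positional
# signal real CDS does (drives Fickett/hexamer separability)
.coding_pos_probs <- list(
  c(A = 0.15, C = 0.05, G = 0.60, T = 0.20),  # codon position 1
  c(A = 0.45, C = 0.25, G = 0.05, T = 0.25),  # codon position 2
  c(A = 0.05, C = 0.45, G = 0.35, T = 0.15))  # codon position 3
.utr_base_probs <- c(A = 0.275, C = 0.225, G = 0.225, T = 0.275)
.stop_codons <- c("TAA", "TAG", "TGA")

# n codons from the coding model, none of them stops
.sample_codons <- function(n) {
  draw <- function(k) {
    p1 <- sample(names(.coding_pos_probs[[1L]]), k, TRUE, .coding_pos_probs[[1L]])
    p2 <- sample(names(.coding_pos_probs[[2L]]), k, TRUE, .coding_pos_probs[[2L]])
    p3 <- sample(names(.coding_pos_probs[[3L]]), k, TRUE, .coding_pos_probs[[3L]])
    paste0(p1, p2, p3)
  }
  out <- draw(n)
  repeat {
    bad <- out %in% .stop_codons
    if (!any(bad)) break
    out[bad] <- draw(sum(bad))
  }
  out
}

# n codons of near-uniform composition, none of them stops (noncoding-like)
.sample_codons_flat <- function(n) {
  out <- vapply(seq_len(n), function(i)
    paste0(sample(names(.utr_base_probs), 3L, TRUE, .utr_base_probs), collapse = ""),
    character(1L))
  repeat {
    bad <- out %in% .stop_codons
    if (!any(bad)) break
    out[bad] <- vapply(seq_len(sum(bad)), function(i)
      paste0(sample(names(.utr_base_probs), 3L, TRUE, .utr_base_probs), collapse = ""),
      character(1L))
  }
  out
}

.random_seq <- function(n) paste0(sample(names(.utr_base_probs), n, TRUE,
                                         .utr_base_probs), collapse = "")

#' Simulate a transcriptome with planted uORFs
#'
#' Each gene gets one canonical transcript: a 100-500 nt 5'UTR, an
#' AUG...stop CDS of 300-3000 nt drawn from a positionally asymmetric coding
#' model, and a 100-500 nt 3'UTR. A configured fraction of 5'UTRs receives
#' an embedded AUG uORF of 51-198 nt; translated-planted uORFs use the coding
#' sequence model, untranslated-planted ones a flat composition.
#'
#' @param cfg `sim_config`.
#' @return `transcript_models`; attribute `"uorf_truth"` is a data frame of
#'   planted uORFs (`transcript_id`, `start`, `end`, `translated`).
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "transcriptome"))
  n <- cfg$n_genes
  if (n == 0L)
    return(transcript_models(data.frame(transcript_id = character(),
                                        gene_id = character(), sequence = character(),
                                        cds_start = integer(), cds_end = integer())))
  utr5_len <- sample(cfg$utr5_range[1L]:cfg$utr5_range[2L], n, TRUE)
  n_codons <- sample((cfg$cds_range[1L] %/% 3L):(cfg$cds_range[2L] %/% 3L), n, TRUE)
  utr3_len <- sample(cfg$utr3_range[1L]:cfg$utr3_range[2L], n, TRUE)

  plant <- runif(n) < cfg$uorf_plant_rate
  translated <- plant & runif(n) < cfg$translated_uorf_fraction
  truth <- vector("list", n)

  seqs <- character(n)
  for (i in seq_len(n)) {
    utr5 <- .random_seq(utr5_len[i])
    if (plant[i]) {
      # keep a downstream gap of >= 20 nt so uORF termination is observable;
      # translated uORFs are planted shorter and closer to the CDS
      min_gap <- 20L
      max_len <- min(if (translated[i]) 120L else cfg$uorf_len_range[2L],
                     utr5_len[i] - min_gap)
      max_len <- max_len - max_len %% 3L
      if (max_len >= cfg$uorf_len_range[1L]) {
        ul <- sample(seq(cfg$uorf_len_range[1L], max_len, by = 3L), 1L)
        gap_max <- utr5_len[i] - ul
        if (translated[i]) gap_max <- min(gap_max, 60L)
        gap <- if (gap_max > min_gap) sample(min_gap:gap_max, 1L) else min_gap
        ustart <- utr5_len[i] - ul - gap
        codons <- if (translated[i]) .sample_codons(ul %/% 3L - 2L)
                  else .sample_codons_flat(ul %/% 3L - 2L)
        useq <- paste0("ATG", paste0(codons, collapse = ""),
                       sample(.stop_codons, 1L))
        utr5 <- paste0(substr(utr5, 1L, ustart), useq,
                       substr(utr5, ustart + ul + 1L, utr5_len[i]))
        truth[[i]] <- data.frame(transcript_id = sprintf("tx%05d", i),
                                 start = ustart, end = ustart + ul,
                                 translated = translated[i],
                                 stringsAsFactors = FALSE)
      }
    }
    cds <- paste0("ATG", paste0(.sample_codons(n_codons[i] - 2L), collapse = ""),
                  sample(.stop_codons, 1L))
    seqs[i] <- paste0(utr5, cds, .random_seq(utr3_len[i]))
  }
  models <- transcript_models(data.frame(
    transcript_id = sprintf("tx%05d", seq_len(n)),
    gene_id = sprintf("g%05d", seq_len(n)),
    sequence = seqs,
    cds_start = utr5_len,
    cds_end = utr5_len + 3L * n_codons,
    stringsAsFactors = FALSE))
  attr(models, "uorf_truth") <- do.call(rbind, truth[!vapply(truth, is.null, logical(1L))])
  models
}

#' Simulate RNA and RIBO count tables with planted divergence categories
#'
#' Per gene g and sample s in group k, counts are
#' NegBin(mean = mu_g * 2^beta, Var = mu + phi mu^2) where beta is the
#' planted per-layer log2 shift for group 2 (group 1 is baseline):
#' Transcription genes shift the RNA layer only (translationally buffered);
#' Translation genes shift the RIBO layer only (these are the TE-shifted
#' genes); Homodirection genes shift both layers with the same sign;
#' Opposite genes shift the two layers in opposite directions; Unchanged
#' genes shift neither. Shift signs are random per gene.
#'
#' @param models transcript_models from [simulate_transcriptome()].
#' @param cfg `sim_config`.
#' @return list with `rna` and `ribo` count `expression_table`s (RNA lengths
#'   = transcript length, RIBO lengths = CDS length) and `truth` (per-gene
#'   `category`, `lfc_rna`, `lfc_ribo`).
#' @export
simulate_counts <- function(models, cfg) {
  stopifnot(nrow(models) > 0L)
  set.seed(stage_seed(cfg$seed, "counts"))
  n <- nrow(models)
  nrep <- cfg$n_reps_per_group
  cats <- names(cfg$category_fractions)
  n_per <- floor(cfg$category_fractions * n)
  n_per["Unchanged"] <- n - sum(n_per[names(n_per) != "Unchanged"])
  category <- sample(rep(cats, times = n_per))
  sgn <- sample(c(-1, 1), n, TRUE)
  lfc <- cfg$effect_log2fc
  lfc_rna <- ifelse(category %in% c("Transcription", "Homodirection", "Opposite"),
                    sgn * lfc, 0)
  lfc_ribo <- ifelse(category %in% c("Translation", "Homodirection"), sgn * lfc,
                     ifelse(category == "Opposite", -sgn * lfc, 0))
  mu <- rlnorm(n, meanlog = log(cfg$baseline_mean), sdlog = cfg$mean_sdlog)

  samples <- c(paste0("g1_rep", seq_len(nrep)), paste0("g2_rep", seq_len(nrep)))
  grp2 <- rep(c(FALSE, TRUE), each = nrep)
  draw_layer <- function(lfc_layer) {
    m <- vapply(seq_along(samples), function(s) {
      mus <- mu * 2^(if (grp2[s]) lfc_layer else 0)
      as.numeric(rnbinom(n, mu = mus, size = 1 / cfg$phi))
    }, numeric(n))
    dimnames(m) <- list(models$gene_id, samples)
    storage.mode(m) <- "integer"
    m
  }
  rna <- expression_table(draw_layer(lfc_rna), layer = "RNA", unit = "count",
                          gene_lengths = setNames(models$length, models$gene_id))
  ribo <- expression_table(draw_layer(lfc_ribo), layer = "RIBO", unit = "count",
                           gene_lengths = setNames(cds_length(models), models$gene_id))
  truth <- data.frame(gene_id = models$gene_id, category = category,
                      lfc_rna = lfc_rna, lfc_ribo = lfc_ribo, mu = mu,
                      stringsAsFactors = FALSE)
  list(rna = rna, ribo = ribo, truth = truth)
}

#' Simulate ribosome footprints from RIBO counts
#'
#' For each gene and sample, exactly the RIBO count of footprints is placed
#' (conservation: per-sample footprint totals equal per-sample RIBO totals).
#' A fraction `rho_cds` lands in the CDS with P-site frame-0 probability
#' `pi_frame`; the remainder is uniform over the UTRs. Genes carrying a
#' translated planted uORF divert `uorf_read_fraction` of their footprints
#' into the uORF with the same frame bias relative to the uORF start. Read
#' lengths follow the configured distribution and the aligned 5' end is
#' placed at `psite - psite_offset` (clamped at 0 near the transcript start).
#'
#' @param models transcript_models (with the `"uorf_truth"` attribute when
#'   uORF reads should be planted).
#' @param ribo_counts RIBO count `expression_table` from [simulate_counts()].
#' @param cfg `sim_config`.
#' @return footprints table.
#' @export
simulate_footprints <- function(models, ribo_counts, cfg) {
  set.seed(stage_seed(cfg$seed, "footprints"))
  counts <- ribo_counts$values
  stopifnot(identical(rownames(counts), models$gene_id))
  ut <- attr(models, "uorf_truth")
  tr_uorf <- if (!is.null(ut)) ut[ut$translated, ] else NULL
  has_uorf <- if (!is.null(tr_uorf)) models$transcript_id %in% tr_uorf$transcript_id
              else rep(FALSE, nrow(models))
  u_start <- u_ncod <- rep(NA_integer_, nrow(models))
  if (!is.null(tr_uorf)) {
    m <- match(models$transcript_id, tr_uorf$transcript_id)
    u_start <- tr_uorf$start[m]
    u_ncod <- (tr_uorf$end[m] - tr_uorf$start[m]) %/% 3L
  }
  lens <- as.integer(names(cfg$footprint_length_probs))
  cs <- models$cds_start
  ncod <- cds_length(models) %/% 3L
  u5 <- utr5_length(models)
  u3 <- utr3_length(models)
  ce <- models$cds_end
  txlen <- models$length

  out <- vector("list", ncol(counts))
  for (s in seq_len(ncol(counts))) {
    n_gs <- counts[, s]
    gene <- rep(seq_len(nrow(models)), n_gs)
    N <- length(gene)
    if (!N) next
    # translated-uORF genes divert a fixed fraction of reads into the uORF
    in_uorf <- has_uorf[gene] & runif(N) < cfg$uorf_read_fraction
    in_cds <- !in_uorf & runif(N) < cfg$rho_cds
    frame <- sample(0:2, N, TRUE,
                    prob = c(cfg$pi_frame, (1 - cfg$pi_frame) / 2,
                             (1 - cfg$pi_frame) / 2))
    psite <- integer(N)
    # CDS placement: uniform codon, biased frame
    idx <- which(in_cds)
    codon <- floor(runif(length(idx)) * ncod[gene[idx]])
    psite[idx] <- cs[gene[idx]] + 3L * as.integer(codon) + frame[idx]
    # uORF placement: uniform codon within the uORF, biased frame
    idx <- which(in_uorf)
    codon <- floor(runif(length(idx)) * u_ncod[gene[idx]])
    psite[idx] <- u_start[gene[idx]] + 3L * as.integer(codon) + frame[idx]
    # UTR background: uniform over the UTR nucleotides
    idx <- which(!in_cds & !in_uorf)
    tot <- u5[gene[idx]] + u3[gene[idx]]
    pos <- floor(runif(length(idx)) * tot)
    p5 <- pos < u5[gene[idx]]
    psite[idx] <- ifelse(p5, as.integer(pos),
                         ce[gene[idx]] + as.integer(pos) - u5[gene[idx]])
    rl <- sample(lens, N, TRUE, prob = cfg$footprint_length_probs)
    fp5 <- pmax(psite - cfg$psite_offset, 0L)
    fp5 <- pmin(fp5, txlen[gene] - 1L)
    out[[s]] <- data.table::data.table(
      sample_id = colnames(counts)[s],
      transcript_id = models$transcript_id[gene],
      five_prime_pos = as.integer(fp5),
      read_length = as.integer(rl))
  }
  as_footprints(data.table::rbindlist(out))
}

#' Simulate the full study: transcriptome, counts, footprints, ground truth
#'
#' @param cfg `sim_config`.
#' @return list with `models`, `rna`, `ribo`, `footprints`, `truth`
#'   (per-gene) and `uorf_truth` (planted uORFs), plus the `groups` label
#'   vector (named by sample).
#' @export
simulate_study <- function(cfg = sim_config()) {
  models <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(models, cfg)
  fps <- simulate_footprints(models, cnt$ribo, cfg)
  samples <- colnames(cnt$rna$values)
  groups <- setNames(sub("_rep.*$", "", samples), samples)
  list(models = models, rna = cnt$rna, ribo = cnt$ribo, footprints = fps,
       truth = cnt$truth, uorf_truth = attr(models, "uorf_truth"),
       groups = groups, config = cfg)
}
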
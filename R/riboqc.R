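#' Filter footprints by read length
#'
#' Retains footprints with `min <= read_length <= max` (defaults 20-40 nt,
#' the usual ribosome-protected fragment window).
#'
#' @param footprints footprints table.
#' @param min,max inclusive length bounds (nt).
#' @return filtered footprints; removed-record count in attribute `"removed"`.
#' @export
filter_by_length <- function(footprints, min = 20L, max = 40L) {
  if (min > max) stop("min length exceeds max length", call. = FALSE)
  keep <- footprints$read_length >= min & footprints$read_length <= max
  out <- footprints[keep, ]
  removed <- sum(!keep)
  if (removed) log_msg(removed, " footprint(s) outside ", min, "-", max, " nt removed")
  attr(out, "removed") <- removed
  out
}

#' Per-sample footprint length histogram
#'
#' @param footprints footprints table.
#' @param lengths integer vector of length classes to tabulate (default 20:40).
#' @return matrix lengths x samples of counts.
#' @export
length_histogram <- function(footprints, lengths = 20:40) {
  samples <- sort(unique(footprints$sample_id))
  out <- vapply(samples, function(s) {
    tabulate(factor(footprints$read_length[footprints$sample_id == s],
                    levels = lengths), nbins = length(lengths))
  }, integer(length(lengths)))
  rownames(out) <- lengths
  out
}

# anchor position per record: raw 5' end or P-site (5' end + per-length offset)
.anchor_pos <- function(footprints, mode, offsets) {
  if (mode == "five_prime") return(footprints$five_prime_pos)
  if (is.null(offsets)) stop("psite mode requires offsets", call. = FALSE)
  off <- offsets[as.character(footprints$read_length)]
  off[is.na(off)] <- attr(offsets, "default") %||% 12L
  footprints$five_prime_pos + as.integer(off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign footprints to 5'UTR / CDS / 3'UTR
#'
#' Each footprint is labeled by the transcript span containing its anchor
#' position: the raw aligned 5' end (default, the conventional assignment
#' rule) or the inferred P-site. Half-open spans mean an anchor exactly at
#' `cds_start` is CDS. Anchors shifted past the transcript end are labeled
#' `out_of_bounds` and excluded from the fractions.
#'
#' @param footprints footprints table.
#' @param models transcript_models.
#' @param mode `"five_prime"` or `"psite"`.
#' @param offsets named per-length P-site offsets (required for psite mode).
#' @return list with `labels` (per record) and `fractions`
#'   (samples x c(utr5, cds, utr3) matrix, rows summing to 1).
#' @export
assign_regions <- function(footprints, models, mode = c("five_prime", "psite"),
                           offsets = NULL) {
  mode <- match.arg(mode)
  idx <- match(footprints$transcript_id, models$transcript_id)
  if (anyNA(idx))
    .stop_listing("footprints on unknown transcript(s)",
                  unique(footprints$transcript_id[is.na(idx)]))
  pos <- .anchor_pos(footprints, mode, offsets)
  cs <- models$cds_start[idx]
  ce <- models$cds_end[idx]
  len <- models$length[idx]
  lab <- rep("out_of_bounds", nrow(footprints))
  lab[pos >= 0 & pos < cs] <- "utr5"
  lab[pos >= cs & pos < ce] <- "cds"
  lab[pos >= ce & pos < len] <- "utr3"
  samples <- sort(unique(footprints$sample_id))
  frac <- t(vapply(samples, function(s) {
    l <- lab[footprints$sample_id == s]
    l <- l[l != "out_of_bounds"]
    tab <- table(factor(l, levels = c("utr5", "cds", "utr3")))
    as.numeric(tab) / max(sum(tab), 1L)
  }, numeric(3L)))
  colnames(frac) <- c("utr5", "cds", "utr3")
  rownames(frac) <- samples
  list(labels = lab, fractions = frac)
}

#' Estimate per-read-length P-site offsets
#'
#' For each read-length class, candidate offsets 10-15 nt are scored by the
#' meta-gene count of 5' ends lying exactly at `cds_start - offset` across
#' all transcripts; the argmax wins, with ties broken toward the canonical
#' 12 nt. Length classes with fewer than `min_reads` footprints fall back to
#' the global default and are flagged.
#'
#' @param footprints footprints table.
#' @param models transcript_models.
#' @param candidates integer candidate offsets (nt).
#' @param min_reads minimum reads per length class for estimation.
#' @param default fallback offset (nt).
#' @return named integer vector of offsets (names = read lengths), with
#'   attributes `"flagged"` (lengths that fell back) and `"default"`.
#' @export
estimate_psite_offsets <- function(footprints, models, candidates = 10:15,
                                   min_reads = 200L, default = 12L) {
  idx <- match(footprints$transcript_id, models$transcript_id)
  cs <- models$cds_start[idx]
  implied <- cs - footprints$five_prime_pos    # offset that would put the P-site on the start codon
  lens <- sort(unique(footprints$read_length))
  flagged <- integer(0L)
  off <- vapply(lens, function(L) {
    sel <- footprints$read_length == L
    if (sum(sel) < min_reads) {
      flagged <<- c(flagged, L)
      return(as.integer(default))
    }
    sc <- vapply(candidates, function(o) sum(implied[sel] == o, na.rm = TRUE), integer(1L))
    best <- candidates[sc == max(sc)]
    as.integer(best[order(abs(best - default), best)][1L])
  }, integer(1L))
  names(off) <- lens
  attr(off, "flagged") <- flagged
  attr(off, "default") <- as.integer(default)
  off
}

#' Trinucleotide periodicity: P-site frame fractions per read length
#'
#' P-sites (5' end + per-length offset) falling inside the CDS are binned by
#' reading frame relative to `cds_start` (frame 0 = first codon position).
#' Active translation shows the classic high-low-low pattern with frame 0
#' dominant.
#'
#' @param footprints footprints table.
#' @param models transcript_models.
#' @param offsets named per-length offsets, e.g. from
#'   [estimate_psite_offsets()].
#' @return list with `by_length` (length x f0/f1/f2 fraction matrix, plus n)
#'   and `pooled` (named f0/f1/f2 vector).
#' @export
frame_periodicity <- function(footprints, models, offsets) {
  idx <- match(footprints$transcript_id, models$transcript_id)
  psite <- .anchor_pos(footprints, "psite", offsets)
  cs <- models$cds_start[idx]
  ce <- models$cds_end[idx]
  in_cds <- psite >= cs & psite < ce
  if (!any(in_cds)) {
    warning("no CDS-internal P-sites; periodicity undefined", call. = FALSE)
    return(list(by_length = NULL, pooled = setNames(rep(NA_real_, 3L), paste0("f", 0:2))))
  }
  frame <- (psite[in_cds] - cs[in_cds]) %% 3L
  rl <- footprints$read_length[in_cds]
  lens <- sort(unique(rl))
  by_len <- t(vapply(lens, function(L) {
    f <- frame[rl == L]
    c(as.numeric(table(factor(f, levels = 0:2))) / length(f), length(f))
  }, numeric(4L)))
  dimnames(by_len) <- list(lens, c("f0", "f1", "f2", "n"))
  pooled <- as.numeric(table(factor(frame, levels = 0:2))) / length(frame)
  list(by_length = by_len, pooled = setNames(pooled, c("f0", "f1", "f2")))
}

#' Sample-level QC: correlation matrix and PCA on log10(FPKM + 1)
#'
#' Pearson correlations between samples and principal components of the
#' log10(FPKM + 1) matrix (genes with zero variance dropped; samples are
#' observations). High within-group correlations (> 0.94 in well-replicated
#' testis data) indicate reliable libraries.
#'
#' @param fpkm_table `expression_table` with `unit = "FPKM"`.
#' @return list with `correlation` (samples x samples), `pca` (samples x 2
#'   coordinate matrix) and `var_explained` (length 2).
#' @export
sample_qc <- function(fpkm_table) {
  v <- if (inherits(fpkm_table, "expression_table")) fpkm_table$values else as.matrix(fpkm_table)
  if (ncol(v) < 2L) stop("sample QC needs at least 2 samples", call. = FALSE)
  x <- log10(v + 1)
  keep <- apply(x, 1L, function(r) var(r) > 0)
  if (!any(keep))
    stop("zero variance: all genes constant across samples; PCA undefined", call. = FALSE)
  x <- x[keep, , drop = FALSE]
  cc <- cor(x, method = "pearson")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(correlation = cc, pca = pc$x[, seq_len(k), drop = FALSE], var_explained = ve)
}

#' Assemble a full QC report
#'
#' Runs the length histogram, region assignment, offset estimation, frame
#' periodicity and (when an FPKM table is given) sample-level QC in one call.
#'
#' @param footprints footprints table (already length-filtered or not; the
#'   20-40 nt filter is applied here).
#' @param models transcript_models.
#' @param fpkm_table optional FPKM `expression_table` for correlation/PCA.
#' @param min_len,max_len retained length window (nt).
#' @return list of class `qc_report`.
#' @export
qc_report <- function(footprints, models, fpkm_table = NULL,
                      min_len = 20L, max_len = 40L) {
  fp <- filter_by_length(footprints, min_len, max_len)
  offs <- estimate_psite_offsets(fp, models)
  out <- list(
    length_histogram = length_histogram(fp, min_len:max_len),
    region = assign_regions(fp, models, mode = "five_prime"),
    offsets = offs,
    periodicity = frame_periodicity(fp, models, offs),
    removed_by_length = attr(fp, "removed"))
  if (!is.null(fpkm_table)) out$samples <- sample_qc(fpkm_table)
  class(out) <- "qc_report"
  out
}
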
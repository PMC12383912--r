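#' Transcript models: the coordinate authority for all position math
#'
#' A `transcript_models` object is a data frame with one row per transcript
#' and columns `transcript_id`, `gene_id`, `sequence` (uppercase A/C/G/T/N),
#' `length`, `cds_start`, `cds_end` and `nonstandard_start`. All coordinates
#' are 0-based, half-open, in transcript space; the 5'UTR is
#' `[0, cds_start)`, the CDS (including its stop codon) is
#' `[cds_start, cds_end)` and the 3'UTR is `[cds_end, length)`. The three
#' spans tile the transcript exactly; the 5'UTR and 3'UTR may be empty, the
#' CDS must be a non-empty multiple of 3 of at least 6 nt and must begin with
#' ATG unless `nonstandard_start` is set.
#'
#' @param df data frame with the columns above (`length` and
#'   `nonstandard_start` optional; derived/defaulted).
#' @return a validated `transcript_models` data frame.
#' @export
transcript_models <- function(df) {
  req <- c("transcript_id", "gene_id", "sequence", "cds_start", "cds_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sequence <- toupper(df$sequence)
  df$length <- nchar(df$sequence)
  if (is.null(df$nonstandard_start)) df$nonstandard_start <- rep_len(FALSE, nrow(df))
  if (anyDuplicated(df$transcript_id))
    .stop_listing("duplicate transcript_id", df$transcript_id[duplicated(df$transcript_id)])
  bad_alpha <- grepl("[^ACGTN]", df$sequence)
  if (any(bad_alpha))
    .stop_listing("non-ACGTN characters in sequence", df$transcript_id[bad_alpha])
  validate_transcript_models(df)
  rownames(df) <- df$transcript_id
  class(df) <- c("transcript_models", "data.frame")
  df
}

validate_transcript_models <- function(df) {
  cds_len <- df$cds_end - df$cds_start
  ok <- df$cds_start >= 0 & df$cds_end <= df$length & cds_len >= 6 &
    cds_len %% 3 == 0
  if (any(!ok)) .stop_listing("invalid CDS span", df$transcript_id[!ok])
  starts <- substr(df$sequence, df$cds_start + 1L, df$cds_start + 3L)
  bad_start <- starts != "ATG" & !df$nonstandard_start
  if (any(bad_start))
    .stop_listing("CDS does not begin with ATG (set nonstandard_start to keep)",
                  df$transcript_id[bad_start])
  invisible(df)
}

# span accessors (vectorised over the model table)
utr5_length <- function(models) models$cds_start
cds_length <- function(models) models$cds_end - models$cds_start
utr3_length <- function(models) models$length - models$cds_end

#' Extract subsequences by region
#'
#' @param models transcript_models.
#' @param region one of "utr5", "cds", "utr3".
#' @return named character vector of sequences (empty string for empty spans).
#' @export
region_sequence <- function(models, region = c("utr5", "cds", "utr3")) {
  region <- match.arg(region)
  out <- switch(region,
    utr5 = substr(models$sequence, 1L, models$cds_start),
    cds  = substr(models$sequence, models$cds_start + 1L, models$cds_end),
    utr3 = substr(models$sequence, models$cds_end + 1L, models$length))
  names(out) <- models$transcript_id
  out
}

#' Read transcript models from a transcript FASTA and a transcript-space GTF
#'
#' The GTF is expected in transcript space: `seqname` is the transcript id
#' and each transcript carries one or more `exon` features tiling
#' `1..length` plus `CDS` feature(s) whose extent (stop codon included)
#' defines the coding span. 1-based GTF coordinates are converted to 0-based
#' half-open intervals here and nowhere else. Transcripts whose CDS length is
#' not a multiple of 3, or that lack a CDS feature, are skipped with a
#' warning (an error under `strict = TRUE`); an annotated transcript missing
#' from the FASTA is always a hard error.
#'
#' @param fasta_path path to transcript FASTA (records keyed by transcript id,
#'   first whitespace-delimited token of the header).
#' @param gtf_path path to GTF/GFF with exon and CDS features.
#' @param strict error instead of skipping invariant violations.
#' @return `transcript_models`; attribute `"report"` holds skip counts.
#' @export
read_transcriptome <- function(fasta_path, gtf_path, strict = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gtf_path)
  meta <- S4Vectors::mcols(gr)
  tx_id <- if (!is.null(meta$transcript_id)) as.character(meta$transcript_id)
           else as.character(GenomicRanges::seqnames(gr))
  gene_id <- if (!is.null(meta$gene_id)) as.character(meta$gene_id) else tx_id
  type <- as.character(meta$type)
  keep <- type %in% c("exon", "CDS")
  dt <- data.table::data.table(
    tx = tx_id[keep], gene = gene_id[keep], type = type[keep],
    start0 = GenomicRanges::start(gr)[keep] - 1L,  # GTF 1-based -> 0-based
    end = GenomicRanges::end(gr)[keep])            # GTF closed -> half-open end

  all_tx <- unique(dt$tx)
  ex <- dt[dt$type == "exon", list(exon_start = min(start0), exon_end = max(end)), by = "tx"]
  cds <- dt[dt$type == "CDS", list(cds_start = min(start0), cds_end = max(end)), by = "tx"]
  gene_map <- dt[, list(gene = gene[1L]), by = "tx"]

  report <- list(n_annotated = length(all_tx), skipped_no_cds = 0L,
                 skipped_bad_frame = 0L, skipped_invalid = 0L)
  no_cds <- setdiff(all_tx, cds$tx)
  if (length(no_cds)) {
    report$skipped_no_cds <- length(no_cds)
    msg <- paste0("skipping ", length(no_cds), " transcript(s) without a CDS feature")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  tab <- merge(merge(ex, cds, by = "tx"), gene_map, by = "tx")

  missing_seq <- setdiff(tab$tx, names(seqs))
  if (length(missing_seq))
    .stop_listing("annotated transcript(s) missing from FASTA", missing_seq)

  tab$sequence <- as.character(seqs[tab$tx])
  tab$len <- nchar(tab$sequence)

  bad_frame <- (tab$cds_end - tab$cds_start) %% 3 != 0
  if (any(bad_frame)) {
    report$skipped_bad_frame <- sum(bad_frame)
    msg <- paste0(sum(bad_frame), " transcript(s) skipped: CDS length not a multiple of 3 (",
                  paste(head(tab$tx[bad_frame], 5L), collapse = ", "), ")")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    tab <- tab[!bad_frame, ]
  }
  bad_span <- tab$cds_start < 0 | tab$cds_end > tab$len |
    (tab$cds_end - tab$cds_start) < 6 | tab$exon_start != 0L | tab$exon_end != tab$len
  if (any(bad_span)) {
    report$skipped_invalid <- sum(bad_span)
    msg <- paste0(sum(bad_span), " transcript(s) skipped: CDS/exon extent inconsistent with sequence")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    tab <- tab[!bad_span, ]
  }
  starts <- substr(tab$sequence, tab$cds_start + 1L, tab$cds_start + 3L)
  models <- transcript_models(data.frame(
    transcript_id = tab$tx, gene_id = tab$gene, sequence = tab$sequence,
    cds_start = tab$cds_start, cds_end = tab$cds_end,
    nonstandard_start = starts != "ATG", stringsAsFactors = FALSE))
  attr(models, "report") <- report
  models
}

#' Write transcript models as FASTA + transcript-space GTF
#'
#' @param models transcript_models.
#' @param fasta_path,gtf_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcriptome <- function(models, fasta_path, gtf_path) {
  seqs <- Biostrings::DNAStringSet(models$sequence)
  names(seqs) <- models$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  n <- nrow(models)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(models$transcript_id, 2L),
    ranges = IRanges::IRanges(
      start = c(rep(1L, n), models$cds_start + 1L),        # back to 1-based
      end = c(models$length, models$cds_end)),
    strand = "+",
    type = rep(c("exon", "CDS"), each = n),
    phase = c(rep(NA_integer_, n), rep(0L, n)),
    source = "riboscape",
    transcript_id = rep(models$transcript_id, 2L),
    gene_id = rep(models$gene_id, 2L))
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(c(fasta_path, gtf_path))
}
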
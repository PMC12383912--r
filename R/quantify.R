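#' FPKM normalization
#'
#' FPKM\[g, s\] = count\[g, s\] * 1e9 / (library_size\[s\] * length\[g\]),
#' i.e. fragments per kilobase of feature per million mapped reads. Effective
#' lengths default to the table's `gene_lengths` (the CDS length of the
#' canonical transcript for the RIBO layer, the mature transcript length for
#' RNA, in the simulator's convention).
#'
#' @param counts `expression_table` with `unit = "count"`.
#' @param gene_lengths optional named lengths overriding the table's.
#' @param library_sizes optional named per-sample totals overriding the table's.
#' @return `expression_table` with `unit = "FPKM"`.
#' @export
fpkm <- function(counts, gene_lengths = NULL, library_sizes = NULL) {
  stopifnot(inherits(counts, "expression_table"), counts$unit == "count")
  len <- if (!is.null(gene_lengths)) gene_lengths[rownames(counts$values)] else counts$gene_lengths
  lib <- if (!is.null(library_sizes)) library_sizes[colnames(counts$values)] else counts$library_sizes
  if (is.null(len) || anyNA(len)) stop("gene lengths required for FPKM", call. = FALSE)
  if (any(len <= 0)) stop("zero or negative gene length", call. = FALSE)
  if (is.null(lib) || any(!is.finite(lib)) || any(lib <= 0))
    stop("library sizes must be positive for FPKM", call. = FALSE)
  v <- sweep(counts$values, 2L, lib, "/")
  v <- sweep(v, 1L, as.numeric(len), "/") * 1e9
  expression_table(v, layer = counts$layer, unit = "FPKM",
                   gene_lengths = len, library_sizes = lib)
}

#' Translation efficiency: TE = FPKM(Ribo-seq) / FPKM(RNA-seq)
#'
#' Computed per sample by default (sample names must match between layers;
#' a group-mean mode divides group-mean FPKMs instead). TE is `NA` where the
#' RNA FPKM does not exceed `rna_floor` (default 0: only an exact zero
#' denominator is undefined); a zero numerator over a positive denominator
#' is a TE of 0.
#'
#' @param fpkm_ribo,fpkm_rna FPKM `expression_table`s on the same genes.
#' @param groups optional named group labels; when given, TE is the ratio of
#'   group-mean FPKMs (one column per group).
#' @param rna_floor RNA FPKM at or below which TE is undefined.
#' @return `expression_table` with `layer = "TE"`, `unit = "ratio"`.
#' @export
translation_efficiency <- function(fpkm_ribo, fpkm_rna, groups = NULL, rna_floor = 0) {
  stopifnot(fpkm_ribo$unit == "FPKM", fpkm_rna$unit == "FPKM")
  if (!identical(rownames(fpkm_ribo$values), rownames(fpkm_rna$values)))
    stop("gene sets differ between RIBO and RNA FPKM tables", call. = FALSE)
  if (is.null(groups)) {
    un <- union(colnames(fpkm_ribo$values), colnames(fpkm_rna$values))
    inb <- intersect(colnames(fpkm_ribo$values), colnames(fpkm_rna$values))
    if (length(inb) < length(un))
      .stop_listing("unmatched sample id(s) between layers", setdiff(un, inb))
    num <- fpkm_ribo$values[, inb, drop = FALSE]
    den <- fpkm_rna$values[, inb, drop = FALSE]
  } else {
    gm <- function(m) {
      g <- groups[colnames(m)]
      vapply(split(colnames(m), g), function(cs) rowMeans(m[, cs, drop = FALSE]),
             numeric(nrow(m)))
    }
    num <- gm(fpkm_ribo$values)
    den <- gm(fpkm_rna$values)
  }
  te <- num / den
  te[den <= rna_floor] <- NA_real_
  out <- expression_table(te, layer = "TE", unit = "ratio")
  out
}

#' Assign genes to the four log2(TE) bins
#'
#' Bins (upper edges inclusive): log2(TE) <= -1, (-1, 0], (0, 1], > 1.
#' Zero or missing TE values are excluded and counted in the `"excluded"`
#' attribute.
#'
#' @param te numeric vector of (typically group-mean) TE values, named by gene.
#' @return factor of bin labels, named by gene, with attribute `"excluded"`.
#' @export
te_bins <- function(te) {
  usable <- is.finite(te) & te > 0
  l2 <- log2(te[usable])
  bins <- cut(l2, breaks = c(-Inf, -1, 0, 1, Inf),
              labels = c("<=-1", "(-1,0]", "(0,1]", ">1"), right = TRUE)
  names(bins) <- names(te)[usable]
  attr(bins, "excluded") <- sum(!usable)
  bins
}

#' Per-group mean of an expression table
#'
#' @param tbl expression_table.
#' @param groups named group labels (names = sample ids).
#' @return matrix genes x groups of row means.
#' @export
group_means <- function(tbl, groups) {
  g <- groups[colnames(tbl$values)]
  vapply(split(colnames(tbl$values), g),
         function(cs) rowMeans(tbl$values[, cs, drop = FALSE]),
         numeric(nrow(tbl$values)))
}
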
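#' Expression tables: one layer of genes x samples values
#'
#' Container for one quantification layer. `values` is a genes x samples
#' matrix with dimnames; `layer` is `"RNA"`, `"RIBO"` or `"TE"`; `unit` is
#' `"count"`, `"FPKM"` or `"ratio"`. Counts must be non-negative integers;
#' FPKM and TE are non-negative reals (TE may be `NA` where the RNA
#' denominator is zero). `gene_lengths` (nt) and `library_sizes` (total
#' mapped reads per sample) travel with the table for FPKM math.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param layer one of "RNA", "RIBO", "TE".
#' @param unit one of "count", "FPKM", "ratio".
#' @param gene_lengths named numeric, effective length per gene (nt), or NULL.
#' @param library_sizes named numeric, per-sample totals; defaults to
#'   `colSums(values)` for count tables.
#' @return an `expression_table`.
#' @export
expression_table <- function(values, layer = c("RNA", "RIBO", "TE"),
                             unit = c("count", "FPKM", "ratio"),
                             gene_lengths = NULL, library_sizes = NULL) {
  layer <- match.arg(layer)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  if (unit == "count") {
    if (any(values < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
    if (any(values != round(values), na.rm = TRUE))
      stop("counts must be integers (round fractional estimates upstream)", call. = FALSE)
    if (is.null(library_sizes)) library_sizes <- colSums(values)
  } else if (any(values < 0, na.rm = TRUE)) {
    stop(unit, " values must be non-negative", call. = FALSE)
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(values)]
    names(gene_lengths) <- rownames(values)
  }
  if (!is.null(library_sizes)) library_sizes <- setNames(as.numeric(library_sizes), colnames(values))
  structure(list(layer = layer, unit = unit, values = values,
                 gene_lengths = gene_lengths, library_sizes = library_sizes),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: layer=%s unit=%s  %d genes x %d samples\n",
              x$layer, x$unit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a count matrix TSV into an expression table
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene ids and non-numeric or fractional cells are errors (values
#' like `12.0` are accepted as the integer 12; `12.5` is rejected because the
#' negative-binomial tests require integer counts).
#'
#' @param path counts TSV.
#' @param layer "RNA" or "RIBO".
#' @param gene_lengths optional named effective lengths (nt).
#' @return `expression_table` with `unit = "count"`.
#' @export
read_counts <- function(path, layer = c("RNA", "RIBO"), gene_lengths = NULL) {
  layer <- match.arg(layer)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE,
                          colClasses = list(character = 1L))
  gene_ids <- dt[[1L]]
  if (anyDuplicated(gene_ids))
    .stop_listing(paste0("duplicate gene id(s) in ", path),
                  unique(gene_ids[duplicated(gene_ids)]))
  m <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    where <- if (nrow(bad)) paste0(" (first at gene ", gene_ids[bad[1L, 1L]],
                                   ", sample ", colnames(m)[bad[1L, 2L]], ")") else ""
    stop("non-numeric count cell(s) in ", path, where, call. = FALSE)
  }
  frac <- which(m != round(m), arr.ind = TRUE)
  if (nrow(frac))
    stop("fractional count at gene ", gene_ids[frac[1L, 1L]], ", sample ",
         colnames(m)[frac[1L, 2L]], " in ", path,
         "; counts must be integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  expression_table(m, layer = layer, unit = "count", gene_lengths = gene_lengths)
}

#' Write an expression table as TSV (layer and unit recorded in the header)
#'
#' @param tbl expression_table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(tbl, path) {
  dt <- data.table::data.table(gene_id = rownames(tbl$values))
  for (s in colnames(tbl$values)) dt[[paste0(s)]] <- tbl$values[, s]
  data.table::setnames(dt, "gene_id", paste0("gene_id.", tbl$layer, ".", tbl$unit))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
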
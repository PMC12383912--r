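#' Read ribosome footprints from a BED-like transcript-space table
#'
#' The canonical dialect is a tab-separated file with header
#' `transcript_id  five_prime_pos  read_length  sample_id` and one row per
#' mapped footprint; `five_prime_pos` is the 0-based transcript coordinate of
#' the aligned 5' end. An optional fifth `count` column collapses identical
#' rows and is expanded to logical records on read. Rows whose position falls
#' outside the transcript (when `models` is supplied) or that are otherwise
#' malformed are rejected and counted in the `"report"` attribute.
#'
#' @param path footprint TSV path.
#' @param models optional `transcript_models` used to validate positions.
#' @return data.table with class `footprints` and columns `sample_id`,
#'   `transcript_id`, `five_prime_pos`, `read_length`.
#' @export
read_footprints <- function(path, models = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  req <- c("transcript_id", "five_prime_pos", "read_length", "sample_id")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("footprint table ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(dt)
  bad <- !is.finite(dt$five_prime_pos) | dt$five_prime_pos < 0 |
    !is.finite(dt$read_length) | dt$read_length <= 0
  if ("count" %in% names(dt)) bad <- bad | !is.finite(dt$count) | dt$count < 1
  rejected_malformed <- sum(bad)
  if (rejected_malformed) {
    warning(rejected_malformed, " malformed footprint row(s) rejected in ", path,
            " (first at data line ", which(bad)[1L], ")", call. = FALSE)
    dt <- dt[!bad]
  }
  rejected_oob <- 0L
  if (!is.null(models)) {
    txlen <- setNames(models$length, models$transcript_id)
    lim <- txlen[dt$transcript_id]
    oob <- is.na(lim) | dt$five_prime_pos >= lim
    rejected_oob <- sum(oob)
    if (rejected_oob) {
      warning(rejected_oob, " footprint row(s) rejected in ", path,
              ": position beyond transcript end or unknown transcript (first at data line ",
              which(oob)[1L], ")", call. = FALSE)
      dt <- dt[!oob]
    }
  }
  if ("count" %in% names(dt)) {
    dt <- dt[rep(seq_len(nrow(dt)), dt$count)]
    dt[, "count" := NULL]
  }
  out <- dt[, req[c(4L, 1L, 2L, 3L)], with = FALSE]
  out$five_prime_pos <- as.integer(out$five_prime_pos)
  out$read_length <- as.integer(out$read_length)
  data.table::setattr(out, "class", c("footprints", class(out)))
  attr(out, "report") <- list(n_input = n_in, rejected_malformed = rejected_malformed,
                              rejected_out_of_bounds = rejected_oob)
  out
}

#' Write footprints in the canonical 4-column dialect
#'
#' `write_footprints(read_footprints(f), f2)` is byte-identical to `f` when
#' `f` is already in canonical column order.
#'
#' @param footprints footprints table.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_footprints <- function(footprints, path) {
  cols <- c("transcript_id", "five_prime_pos", "read_length", "sample_id")
  data.table::fwrite(data.table::as.data.table(footprints)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

as_footprints <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("sample_id", "transcript_id", "five_prime_pos", "read_length")
  stopifnot(all(req %in% names(dt)))
  dt <- dt[, req, with = FALSE]
  data.table::setattr(dt, "class", c("footprints", class(dt)))
  dt
}
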
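# Internal helpers: logging and seed fan-out.

log_msg <- function(..., verbose = getOption("riboscape.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[riboscape] ", ...)
}

#' Derive a reproducible per-stage seed from one global seed
#'
#' A single run seed fans out to independent sub-seeds so that each pipeline
#' stage is individually reproducible. Kept strictly below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # small deterministic hash of the stage label
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435.0 + h * 97.0) %% 2147483629)
}

# half-open interval membership in transcript coordinates
.in_span <- function(pos, start, end) pos >= start & pos < end

# stop with a compact message listing offending ids
.stop_listing <- function(msg, ids, max_show = 10L) {
  ids <- as.character(ids)
  shown <- paste(head(ids, max_show), collapse = ", ")
  if (length(ids) > max_show) shown <- paste0(shown, ", ... (", length(ids), " total)")
  stop(msg, ": ", shown, call. = FALSE)
}
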
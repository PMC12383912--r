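#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from the
#' denominator. Vectorised over sequences.
#'
#' @param sequence character vector of A/C/G/T/N sequences.
#' @return numeric fraction(s) in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  sequence <- toupper(sequence)
  count <- function(pat) nchar(sequence) - nchar(gsub(pat, "", sequence, fixed = FALSE))
  gc <- count("[GC]")
  acgt <- count("[ACGT]")
  if (any(acgt == 0))
    stop("GC content undefined for empty or all-N sequence", call. = FALSE)
  gc / acgt
}

#' Fold a sequence and report (normalized) minimum free energy
#'
#' The default `"nussinov"` backend is an internal base-pair-maximization
#' fold (canonical AU/GC/GU pairs, minimum hairpin loop of 3 unpaired bases)
#' scored at -1 kcal/mol per pair; it is a structure-capacity proxy, not a
#' thermodynamic model, and the backend tag is carried in the result. The
#' `"rnafold"` backend shells out to ViennaRNA's RNAfold when it is on the
#' PATH. NMFE = MFE / length (kcal/mol per nt). Sequences longer than
#' `max_len` are truncated from the 5' end with a message.
#'
#' @param sequence character vector of sequences (>= 8 nt each).
#' @param backend `"nussinov"` or `"rnafold"`.
#' @param max_len folding-length guard (nt).
#' @return data frame `length`, `mfe`, `nmfe`, `backend` (lengths are the
#'   original, pre-truncation lengths; `nmfe = mfe / folded length`).
#' @export
fold_nmfe <- function(sequence, backend = c("nussinov", "rnafold"), max_len = 3000L) {
  backend <- match.arg(backend)
  sequence <- toupper(sequence)
  orig_len <- nchar(sequence)
  if (any(orig_len < 8L)) stop("fold_nmfe requires sequences of >= 8 nt", call. = FALSE)
  trunc <- orig_len > max_len
  if (any(trunc)) {
    log_msg(sum(trunc), " sequence(s) truncated to ", max_len, " nt for folding")
    sequence[trunc] <- substr(sequence[trunc], 1L, max_len)
  }
  fold_len <- nchar(sequence)
  mfe <- switch(backend,
    nussinov = -vapply(sequence, .nussinov_pairs, integer(1L), USE.NAMES = FALSE),
    rnafold = .rnafold_mfe(sequence))
  data.frame(length = orig_len, mfe = mfe, nmfe = mfe / fold_len,
             backend = paste0(if (backend == "nussinov") "internal-nussinov"
                              else "external-folder"),
             stringsAsFactors = FALSE)
}

.rnafold_mfe <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("RNAfold not found on PATH; use backend = \"nussinov\"", call. = FALSE)
  out <- system2(exe, args = "--noPS", input = paste(sequence, collapse = "\n"),
                 stdout = TRUE)
  en <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
}

#' Compare CDS features across TE bins
#'
#' For each requested feature (CDS length, GC content, NMFE of the CDS),
#' summarises the per-bin distribution, runs a Kruskal-Wallis omnibus test,
#' then BH-corrected pairwise Mann-Whitney tests, and condenses the pairwise
#' pattern into a compact letter display at `alpha`: bins sharing a letter are
#' not significantly different. Bins with fewer than 3 genes are excluded
#' from testing and reported.
#'
#' @param features data frame with columns `gene_id`, `te_bin`, and one
#'   column per feature (e.g. `cds_length`, `gc`, `nmfe`).
#' @param feature_cols which feature columns to analyse.
#' @param alpha letter-display significance level.
#' @return named list per feature: `summary` (per-bin n/median/mean),
#'   `kruskal_p`, `pairwise_p` (matrix), `letters` (named character).
#' @export
feature_by_te_bin <- function(features,
                              feature_cols = c("cds_length", "gc", "nmfe"),
                              alpha = 0.05) {
  stopifnot(all(c("te_bin", feature_cols) %in% names(features)))
  features$te_bin <- droplevels(factor(features$te_bin))
  sizes <- table(features$te_bin)
  testable <- names(sizes)[sizes >= 3L]
  excluded <- setdiff(names(sizes), testable)
  out <- lapply(feature_cols, function(fc) {
    x <- features[[fc]]
    smry <- do.call(rbind, lapply(levels(features$te_bin), function(b) {
      xi <- x[features$te_bin == b]
      data.frame(te_bin = b, n = length(xi), median = median(xi, na.rm = TRUE),
                 mean = mean(xi, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
    res <- list(summary = smry, kruskal_p = NA_real_, pairwise_p = NULL,
                letters = NULL, excluded_bins = excluded)
    if (length(testable) >= 2L) {
      sub <- features$te_bin %in% testable
      g <- droplevels(factor(features$te_bin[sub], levels = testable))
      xi <- x[sub]
      res$kruskal_p <- kruskal.test(xi, g)$p.value
      pw <- .pairwise_wilcox_bh(xi, g)
      res$pairwise_p <- pw
      res$letters <- compact_letters(pw < alpha)
    }
    res
  })
  names(out) <- feature_cols
  out
}

# pairwise Mann-Whitney with BH correction; returns symmetric p matrix
.pairwise_wilcox_bh <- function(x, g) {
  lv <- levels(g)
  k <- length(lv)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  p <- apply(pairs, 1L, function(ij) {
    suppressWarnings(wilcox.test(x[g == lv[ij[1L]]], x[g == lv[ij[2L]]],
                                 exact = FALSE)$p.value)
  })
  p <- p.adjust(p, method = "BH")
  m <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  m[cbind(pairs[, 1L], pairs[, 2L])] <- p
  m[cbind(pairs[, 2L], pairs[, 1L])] <- p
  diag(m) <- 1
  m
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: starting from one letter containing all
#' groups, each significantly different pair splits every letter containing
#' both; letters that are subsets of others are absorbed. Groups that are not
#' significantly different share at least one letter.
#'
#' @param sig logical matrix (TRUE = pair significantly different), symmetric,
#'   with group dimnames.
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(sig) {
  groups <- rownames(sig)
  cols <- list(groups)
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      gi <- groups[pairs[r, 1L]]
      gj <- groups[pairs[r, 2L]]
      newcols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          newcols <- c(newcols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else newcols <- c(newcols, list(col))
      }
      # absorb subsets
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            !(all(newcols[[b]] %in% newcols[[a]]) && a < b)) keep[a] <- FALSE
      }
      cols <- newcols[keep]
    }
  }
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
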
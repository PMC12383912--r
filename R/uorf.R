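#' Detect AUG-initiated uORFs in 5'UTRs
#'
#' Scans each 5'UTR for ATG codons with an in-frame stop codon entirely
#' within the UTR; the uORF runs from the A of the AUG to the end of the stop
#' codon (half-open, 0-based transcript coordinates; because the 5'UTR starts
#' at position 0, UTR and transcript coordinates coincide). An AUG whose
#' frame has no in-frame stop before the CDS start is not a uORF under the
#' default policy. Nested AUGs sharing a stop in the same frame are collapsed
#' to the most 5' AUG unless `keep_nested`.
#'
#' @param models transcript_models.
#' @param min_len minimum uORF length in nt, stop codon included (default 9).
#' @param keep_nested keep in-frame nested AUGs sharing a stop.
#' @return data frame `uorf_id`, `transcript_id`, `gene_id`, `start`, `end`,
#'   `length`, `gc`.
#' @export
detect_uorfs <- function(models, min_len = 9L, keep_nested = FALSE) {
  utrs <- region_sequence(models, "utr5")
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    utr <- utrs[[i]]
    n <- nchar(utr)
    if (n < min_len) next
    atg <- gregexpr("ATG", utr, fixed = TRUE)[[1L]]
    if (atg[1L] == -1L) next
    starts0 <- as.integer(atg) - 1L
    stops <- gregexpr("(?=TAA|TAG|TGA)", utr, perl = TRUE)[[1L]]
    if (stops[1L] == -1L) next
    stops0 <- as.integer(stops) - 1L
    # first in-frame stop at or after start+3 whose codon fits in the UTR
    ends <- vapply(starts0, function(s) {
      cand <- stops0[stops0 >= s + 3L & (stops0 - s) %% 3L == 0L & stops0 + 3L <= n]
      if (length(cand)) cand[1L] + 3L else NA_integer_
    }, integer(1L))
    ok <- !is.na(ends) & (ends - starts0) >= min_len
    if (!any(ok)) next
    df <- data.frame(start = starts0[ok], end = ends[ok])
    if (!keep_nested) {
      df <- df[order(df$start), ]
      df <- df[!duplicated(df$end), ]  # most 5' AUG per shared stop
    }
    rows[[i]] <- data.frame(
      transcript_id = models$transcript_id[i], gene_id = models$gene_id[i],
      start = df$start, end = df$end, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    return(data.frame(uorf_id = character(), transcript_id = character(),
                      gene_id = character(), start = integer(), end = integer(),
                      length = integer(), gc = numeric(), stringsAsFactors = FALSE))
  out$length <- out$end - out$start
  out$uorf_id <- sprintf("%s:%d-%d", out$transcript_id, out$start, out$end)
  seqs <- substr(models[out$transcript_id, "sequence"], out$start + 1L, out$end)
  out$gc <- gc_content(seqs)
  rownames(out) <- NULL
  out[, c("uorf_id", "transcript_id", "gene_id", "start", "end", "length", "gc")]
}

#' ORFscore: frame bias of P-site counts within an ORF
#'
#' With per-frame P-site counts (F0, F1, F2) relative to the ORF start and
#' their mean Fbar, the score is `log2(1 + sum((Fi - Fbar)^2 / Fbar))`,
#' negated when frame 0 is not the strict maximum. Positive values indicate
#' the frame-0-dominant periodicity of active translation. Zero total counts
#' give `NA`.
#'
#' @param f0,f1,f2 numeric vectors of per-frame counts.
#' @return numeric score vector.
#' @export
orfscore <- function(f0, f1, f2) {
  total <- f0 + f1 + f2
  fbar <- total / 3
  chi <- ((f0 - fbar)^2 + (f1 - fbar)^2 + (f2 - fbar)^2) / fbar
  s <- log2(1 + chi)
  neg <- !(f0 > f1 & f0 > f2)
  s[neg] <- -s[neg]
  s[total == 0] <- NA_real_
  s
}

#' Ribosome release score for uORFs
#'
#' Ratio of P-site density inside the uORF to density in the downstream
#' 5'UTR gap between the uORF stop and the CDS start; the gap count carries a
#' pseudocount of 1. Translation that terminates at the uORF stop gives high
#' values. Gaps shorter than `min_gap` leave the denominator undefined and
#' return `NA`.
#'
#' @param n_inside P-site count within the uORF.
#' @param uorf_len uORF length (nt).
#' @param n_gap P-site count in the gap region.
#' @param gap_len gap length (nt): `cds_start - uorf_end`.
#' @param min_gap minimum gap (nt) for a defined denominator.
#' @return numeric RRS vector.
#' @export
rrs <- function(n_inside, uorf_len, n_gap, gap_len, min_gap = 15L) {
  out <- (n_inside / uorf_len) / ((n_gap + 1) / gap_len)
  out[gap_len < min_gap] <- NA_real_
  out
}

# --- Fickett TESTCODE -------------------------------------------------------
# Published lookup tables: probability that a window with the observed
# position-asymmetry / composition value is coding, with per-base weights.
.fickett_pos_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickett_pos_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_pos_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_cont_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickett_cont_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_cont_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

.fickett_lookup <- function(value, breaks, probs) probs[which(value >= breaks)[1L]]

#' Fickett TESTCODE coding-potential score
#'
#' The classic statistic: for each base, the position asymmetry
#' `max(n1, n2, n3) / (min(n1, n2, n3) + 1)` over the three codon positions
#' and the overall composition fraction are mapped through the published
#' lookup tables to coding probabilities, which are combined with the
#' published per-base weights. Typical values span roughly 0.16-1.30; 0.74 is
#' the conventional coding threshold. Sequences with more than 10% non-ACGT
#' content are flagged via the `"flagged"` attribute.
#'
#' @param sequence character vector of sequences (>= 6 nt each).
#' @return numeric score vector (attribute `"flagged"`: logical vector).
#' @export
fickett_score <- function(sequence) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 6L)) stop("fickett_score requires >= 6 nt", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  scores <- numeric(length(sequence))
  flagged <- logical(length(sequence))
  for (k in seq_along(sequence)) {
    ch <- strsplit(sequence[k], "", fixed = TRUE)[[1L]]
    pos <- (seq_along(ch) - 1L) %% 3L + 1L
    keep <- ch %in% bases
    flagged[k] <- mean(!keep) > 0.10
    ch <- ch[keep]; pos <- pos[keep]
    s <- 0
    for (b in bases) {
      npos <- vapply(1:3, function(p) sum(ch == b & pos == p), numeric(1L))
      asym <- max(npos) / (min(npos) + 1)
      comp <- sum(npos) / length(ch)
      s <- s +
        .fickett_lookup(asym, .fickett_pos_breaks, .fickett_pos_prob[[b]]) *
          .fickett_pos_weight[[b]] +
        .fickett_lookup(comp, .fickett_cont_breaks, .fickett_cont_prob[[b]]) *
          .fickett_cont_weight[[b]]
    }
    scores[k] <- s
  }
  attr(scores, "flagged") <- flagged
  scores
}

# --- hexamer usage ----------------------------------------------------------

.all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  apply(g, 1L, paste0, collapse = "")
}

# in-frame hexamers (step 3) of one sequence; N-containing dropped
.inframe_hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(character(0L))
  st <- seq.int(1L, n - 5L, by = 3L)
  h <- substring(seq, st, st + 5L)
  h[!grepl("N", h, fixed = TRUE)]
}

# Altschul-Erikson dinucleotide-preserving shuffle
dinuc_shuffle <- function(seq, max_tries = 200L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(seq)
  from <- ch[-n]; to <- ch[-1L]
  edges <- split(to, from)
  s1 <- ch[1L]; sn <- ch[n]
  need_last <- setdiff(names(edges), sn)
  for (try in seq_len(max_tries)) {
    last <- vapply(need_last, function(v) sample(edges[[v]], 1L), character(1L))
    # last-exit edges must form a tree into the final vertex
    ok <- all(vapply(need_last, function(v) {
      seen <- character(0L)
      while (v != sn) {
        if (v %in% seen || !(v %in% need_last)) return(FALSE)
        seen <- c(seen, v)
        v <- last[[v]]
      }
      TRUE
    }, logical(1L)))
    if (!ok) next
    ordered <- edges
    for (v in names(edges)) {
      pool <- edges[[v]]
      if (v %in% need_last) {
        pool <- pool[-match(last[[v]], pool)]
        ordered[[v]] <- c(sample(pool), last[[v]])
      } else ordered[[v]] <- sample(pool)
    }
    ptr <- setNames(rep(1L, length(ordered)), names(ordered))
    res <- character(n)
    res[1L] <- s1
    cur <- s1
    for (i in 2:n) {
      nxt <- ordered[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    return(paste0(res, collapse = ""))
  }
  seq
}

#' Train a hexamer usage table from coding sequences
#'
#' Coding frequencies come from in-frame (step-3) hexamers of the CDS
#' sequences; the noncoding background from in-frame hexamers of a
#' dinucleotide-preserving shuffle of each CDS (seeded). Both frequency sets
#' get additive smoothing of 1e-6 per hexamer and sum to 1.
#'
#' @param models transcript_models (>= 50 CDS sequences) or a character
#'   vector of CDS sequences.
#' @param seed RNG seed for the shuffle.
#' @return list of class `hexamer_table` with `coding` and `noncoding`
#'   named frequency vectors (4096 hexamers each).
#' @export
train_hexamer_table <- function(models, seed = 1L) {
  cds <- if (inherits(models, "transcript_models")) region_sequence(models, "cds") else models
  if (length(cds) < 50L)
    stop("hexamer training needs >= 50 CDS sequences", call. = FALSE)
  hx <- .all_hexamers()
  count_freq <- function(seqs) {
    h <- unlist(lapply(seqs, .inframe_hexamers), use.names = FALSE)
    cnt <- tabulate(factor(h, levels = hx), nbins = length(hx))
    f <- cnt + 1e-6
    setNames(f / sum(f), hx)
  }
  coding <- count_freq(cds)
  set.seed(seed)
  noncoding <- count_freq(vapply(cds, dinuc_shuffle, character(1L), USE.NAMES = FALSE))
  structure(list(coding = coding, noncoding = noncoding), class = "hexamer_table")
}

#' Hexamer log-likelihood-ratio score
#'
#' Mean natural-log ratio of coding to noncoding frequency over the in-frame
#' hexamers of `sequence`. Positive values indicate coding-like hexamer
#' usage. Sequences shorter than 6 nt return `NA`.
#'
#' @param sequence character vector.
#' @param table `hexamer_table` from [train_hexamer_table()].
#' @return numeric score vector.
#' @export
hexamer_score <- function(sequence, table) {
  stopifnot(inherits(table, "hexamer_table"))
  vapply(toupper(sequence), function(s) {
    h <- .inframe_hexamers(s)
    if (!length(h)) return(NA_real_)
    mean(log(table$coding[h] / table$noncoding[h]))
  }, numeric(1L), USE.NAMES = FALSE)
}

# --- Kozak ------------------------------------------------------------------

#' Extract the -6..+4 Kozak context around a start codon
#'
#' Ten positions: -6..-1 upstream of the AUG, the AUG itself at +1..+3, and
#' +4. Windows clipped at the transcript 5' end are padded with N.
#'
#' @param models transcript_models.
#' @param transcript_id,start parallel vectors locating each AUG (0-based
#'   transcript coordinate of the A).
#' @return character vector of 10-nt contexts.
#' @export
kozak_context <- function(models, transcript_id, start) {
  seqs <- models[transcript_id, "sequence"]
  lo <- start - 6L
  ctx <- substr(seqs, pmax(lo, 0L) + 1L, start + 4L)
  pad <- pmax(-lo, 0L)
  ifelse(pad > 0L, paste0(strrep("N", pad), ctx), ctx)
}

#' Position probability matrix of Kozak contexts
#'
#' @param contexts character vector of 10-nt contexts (N allowed; N excluded
#'   position-wise).
#' @return 4 x 10 probability matrix (rows A/C/G/T, columns -6..-1, +1..+4);
#'   attribute `"n"` = number of sequences.
#' @export
kozak_pwm <- function(contexts) {
  stopifnot(all(nchar(contexts) == 10L))
  m <- do.call(rbind, strsplit(toupper(contexts), "", fixed = TRUE))
  pwm <- vapply(seq_len(10L), function(j) {
    cnt <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(cnt) / max(sum(cnt), 1L)
  }, numeric(4L))
  dimnames(pwm) <- list(c("A", "C", "G", "T"),
                        c(paste0("-", 6:1), paste0("+", 1:4)))
  attr(pwm, "n") <- length(contexts)
  pwm
}

#' Compare Kozak contexts of two start-codon sets
#'
#' Builds a position probability matrix per set and, for every non-AUG
#' position, runs a 4-category chi-square test of base composition between
#' the sets (no continuity correction; zero-count bases dropped pairwise).
#' Used for translated-vs-untranslated uORF starts and for uORF-vs-mORF
#' starts.
#'
#' @param contexts_a,contexts_b character vectors of 10-nt contexts
#'   (>= 5 each).
#' @return list with `pwm_a`, `pwm_b`, and `p_values` named by position
#'   (-6..-1, +4; AUG positions omitted).
#' @export
kozak_analysis <- function(contexts_a, contexts_b) {
  if (length(contexts_a) < 5L || length(contexts_b) < 5L)
    stop("each context set needs >= 5 sequences", call. = FALSE)
  pos_all <- c(paste0("-", 6:1), paste0("+", 1:4))
  test_pos <- setdiff(pos_all, c("+1", "+2", "+3"))
  ma <- do.call(rbind, strsplit(toupper(contexts_a), "", fixed = TRUE))
  mb <- do.call(rbind, strsplit(toupper(contexts_b), "", fixed = TRUE))
  p <- vapply(test_pos, function(lab) {
    j <- match(lab, pos_all)
    ca <- table(factor(ma[, j], levels = c("A", "C", "G", "T")))
    cb <- table(factor(mb[, j], levels = c("A", "C", "G", "T")))
    tab <- rbind(as.numeric(ca), as.numeric(cb))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L) return(1)
    st <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (!is.finite(st$statistic) || st$statistic == 0) 1 else st$p.value
  }, numeric(1L))
  list(pwm_a = kozak_pwm(contexts_a), pwm_b = kozak_pwm(contexts_b), p_values = p)
}

# --- distances and classification ------------------------------------------

#' Distance from a uORF to the main ORF start
#'
#' `dist_to_cds = cds_start - uorf_end` (nt, >= 0) and
#' `norm_dist = dist_to_cds / 5'UTR length`.
#'
#' @param uorfs uORF data frame with `transcript_id`, `end`.
#' @param models transcript_models.
#' @return `uorfs` with `dist_to_cds` and `norm_dist` columns added.
#' @export
uorf_distance <- function(uorfs, models) {
  idx <- match(uorfs$transcript_id, models$transcript_id)
  uorfs$dist_to_cds <- models$cds_start[idx] - uorfs$end
  uorfs$norm_dist <- uorfs$dist_to_cds / models$cds_start[idx]
  uorfs
}

#' Keep only the most 3' ("last") uORF of each gene
#'
#' The distance comparison between translated and untranslated uORFs is made
#' on the last uORF per gene.
#'
#' @param uorfs uORF data frame with `gene_id`, `start`.
#' @return subset of `uorfs`.
#' @export
last_uorf_per_gene <- function(uorfs) {
  o <- order(uorfs$gene_id, -uorfs$start)
  u <- uorfs[o, ]
  u[!duplicated(u$gene_id), ]
}

#' Score uORF candidates with footprint evidence and sequence features
#'
#' Computes, per uORF: per-frame P-site counts and the ORFscore; the
#' ribosome release score against the downstream 5'UTR gap; Fickett and
#' hexamer scores of the uORF sequence; per-sample footprint FPKM (uORF
#' P-site count over uORF length, normalized by the sample's total mapped
#' footprints) with per-group and overall means; NMFE of the uORF sequence;
#' the Kozak context; and distances to the CDS start.
#'
#' @param uorfs from [detect_uorfs()].
#' @param footprints footprints table (length-filtered).
#' @param models transcript_models.
#' @param offsets per-length P-site offsets.
#' @param groups named group labels per sample.
#' @param hexamer_table from [train_hexamer_table()].
#' @param min_gap minimum RRS gap (nt).
#' @param fold_backend folding backend for NMFE.
#' @return `uorfs` with score columns appended.
#' @export
score_uorfs <- function(uorfs, footprints, models, offsets, groups,
                        hexamer_table, min_gap = 15L,
                        fold_backend = "nussinov") {
  if (!nrow(uorfs)) return(uorfs)
  idx <- match(uorfs$transcript_id, models$transcript_id)
  cds_start <- models$cds_start[idx]
  fp <- data.table::as.data.table(footprints)
  fp <- fp[fp$transcript_id %in% unique(uorfs$transcript_id)]
  fp$psite <- .anchor_pos(fp, "psite", offsets)
  ud <- data.table::data.table(uorf_id = uorfs$uorf_id,
                               transcript_id = uorfs$transcript_id,
                               start = uorfs$start, end = uorfs$end,
                               cds_start = cds_start)
  j <- merge(fp, ud, by = "transcript_id", allow.cartesian = TRUE)
  inside <- j[j$psite >= j$start & j$psite < j$end]
  ingap <- j[j$psite >= j$end & j$psite < j$cds_start]
  inside$frame <- (inside$psite - inside$start) %% 3L

  fr <- inside[, list(n = .N), by = c("uorf_id", "frame")]
  fmat <- matrix(0, nrow(uorfs), 3L, dimnames = list(uorfs$uorf_id, paste0("F", 0:2)))
  fmat[cbind(match(fr$uorf_id, uorfs$uorf_id), fr$frame + 1L)] <- fr$n
  gapn <- ingap[, list(n = .N), by = "uorf_id"]
  n_gap <- setNames(rep(0, nrow(uorfs)), uorfs$uorf_id)
  n_gap[gapn$uorf_id] <- gapn$n

  uorfs$f0 <- fmat[, 1L]; uorfs$f1 <- fmat[, 2L]; uorfs$f2 <- fmat[, 3L]
  uorfs$orfscore <- orfscore(uorfs$f0, uorfs$f1, uorfs$f2)
  gap_len <- cds_start - uorfs$end
  uorfs$rrs <- rrs(uorfs$f0 + uorfs$f1 + uorfs$f2, uorfs$length,
                   n_gap, gap_len, min_gap = min_gap)
  # zero footprints inside the uORF: no evidence of occupancy at all
  uorfs$rrs[(uorfs$f0 + uorfs$f1 + uorfs$f2) == 0 & gap_len >= min_gap] <- 0

  seqs <- substr(models[uorfs$transcript_id, "sequence"], uorfs$start + 1L, uorfs$end)
  uorfs$fickett <- as.numeric(fickett_score(seqs))
  uorfs$hexamer <- hexamer_score(seqs, hexamer_table)
  uorfs$nmfe <- fold_nmfe(seqs, backend = fold_backend)$nmfe

  # footprint FPKM per sample, then group and overall means
  lib <- table(factor(footprints$sample_id, levels = unique(footprints$sample_id)))
  samples <- names(lib)
  cnt <- inside[, list(n = .N), by = c("uorf_id", "sample_id")]
  cmat <- matrix(0, nrow(uorfs), length(samples),
                 dimnames = list(uorfs$uorf_id, samples))
  cmat[cbind(match(cnt$uorf_id, uorfs$uorf_id), match(cnt$sample_id, samples))] <- cnt$n
  fpkm_mat <- sweep(cmat, 2L, as.numeric(lib), "/") / uorfs$length * 1e9
  uorfs$mean_fpkm <- rowMeans(fpkm_mat)
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    cols <- intersect(cols, samples)
    uorfs[[paste0("fpkm_", g)]] <- if (length(cols))
      rowMeans(fpkm_mat[, cols, drop = FALSE]) else NA_real_
  }
  uorfs$kozak_context <- kozak_context(models, uorfs$transcript_id, uorfs$start)
  uorf_distance(uorfs, models)
}

#' Classify uORFs as potentially translated
#'
#' A uORF is potentially translated when all four scores clear their
#' thresholds -- ORFscore >= `orfscore`, RRS >= `rrs`, Fickett >= `fickett`,
#' hexamer > `hexamer` -- and its mean footprint FPKM is at least
#' `min_fpkm`. Any missing score fails the test (no evidence is treated as
#' untranslated).
#'
#' @param scored output of [score_uorfs()].
#' @param thresholds named list overriding any of `orfscore` (6), `rrs` (2),
#'   `fickett` (0.74), `hexamer` (0), `min_fpkm` (1).
#' @return `scored` with a logical `translated` column.
#' @export
classify_translated <- function(scored, thresholds = list()) {
  th <- utils::modifyList(
    list(orfscore = 6, rrs = 2, fickett = 0.74, hexamer = 0, min_fpkm = 1),
    thresholds)
  pass <- function(x, cut, strict = FALSE) {
    ok <- if (strict) x > cut else x >= cut
    ok & !is.na(x)
  }
  scored$translated <- pass(scored$orfscore, th$orfscore) &
    pass(scored$rrs, th$rrs) &
    pass(scored$fickett, th$fickett) &
    pass(scored$hexamer, th$hexamer, strict = TRUE) &
    pass(scored$mean_fpkm, th$min_fpkm)
  scored
}

#' uORF-mORF relationships
#'
#' Given one row per gene with the uORF and mORF translational log2 fold
#' changes, the gene's TE and uORF features, computes: the Pearson
#' correlation between uORF and mORF changes; simple linear regressions of
#' TE on uORF length, GC and NMFE; and two-sample Kolmogorov-Smirnov
#' comparisons of TE between uORF classes (none / untranslated / translated).
#' With fewer than `min_n` paired observations the correlation is suppressed
#' with a warning.
#'
#' @param genes data frame; recognised columns: `uorf_log2fc`, `morf_log2fc`,
#'   `te`, `uorf_length`, `uorf_gc`, `uorf_nmfe`, `uorf_class`.
#' @param min_n minimum pairs for the correlation.
#' @return list with `correlation`, `regressions`, `ks`.
#' @export
uorf_morf_relation <- function(genes, min_n = 10L) {
  out <- list(correlation = NULL, regressions = NULL, ks = NULL)
  if (all(c("uorf_log2fc", "morf_log2fc") %in% names(genes))) {
    ok <- complete.cases(genes[, c("uorf_log2fc", "morf_log2fc")])
    if (sum(ok) < min_n) {
      warning("fewer than ", min_n, " uORF-mORF pairs; correlation suppressed",
              call. = FALSE)
    } else {
      ct <- stats::cor.test(genes$uorf_log2fc[ok], genes$morf_log2fc[ok],
                            method = "pearson")
      out$correlation <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }
  }
  if ("te" %in% names(genes)) {
    preds <- intersect(c("uorf_length", "uorf_gc", "uorf_nmfe"), names(genes))
    out$regressions <- lapply(setNames(preds, preds), function(p) {
      d <- genes[is.finite(genes$te) & is.finite(genes[[p]]), ]
      if (nrow(d) < min_n) return(NULL)
      fit <- lm(log2(d$te + 1e-9) ~ d[[p]])
      sm <- summary(fit)
      list(slope = unname(coef(fit)[2L]), p = sm$coefficients[2L, 4L],
           r_squared = sm$r.squared, n = nrow(d))
    })
    if ("uorf_class" %in% names(genes)) {
      cl <- factor(genes$uorf_class)
      lv <- levels(cl)
      if (length(lv) >= 2L) {
        prs <- utils::combn(lv, 2L, simplify = FALSE)
        out$ks <- lapply(setNames(prs, vapply(prs, paste, "", collapse = "_vs_")),
          function(pr) {
            a <- genes$te[cl == pr[1L] & is.finite(genes$te)]
            b <- genes$te[cl == pr[2L] & is.finite(genes$te)]
            if (length(a) < 3L || length(b) < 3L) return(NULL)
            kt <- suppressWarnings(ks.test(a, b))
            list(D = unname(kt$statistic), p = kt$p.value,
                 n = c(length(a), length(b)))
          })
      }
    }
  }
  out
}
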
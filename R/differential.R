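#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per gene, the geometric mean across samples of
#' genes observed in every sample is the reference; each sample's factor is
#' the median ratio to that reference. When fewer than `min_genes` genes are
#' positive in all samples, the method degrades gracefully to library-size
#' factors scaled to geometric mean 1.
#'
#' @param counts genes x samples integer matrix.
#' @param min_genes minimum all-positive genes for the median-of-ratios path.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts, min_genes = 10L) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= min_genes) {
    lg <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2L, function(col) exp(median(col - ref)))
  } else {
    lib <- colSums(counts)
    if (any(lib == 0)) stop("cannot normalize: a sample has zero total counts", call. = FALSE)
    sf <- lib / exp(mean(log(lib)))
  }
  setNames(as.numeric(sf), colnames(counts))
}

# Method-of-moments NB dispersion per gene (Var = mu + phi mu^2 on the
# normalized scale), shrunk toward a gamma-family trend phi ~ a/mu + b fitted
# by least squares across genes. The shrinkage weight is empirical-Bayes
# adaptive: each gene's MoM estimate is weighted by the ratio of its sampling
# variance (large at 2 x 3 replicates) to the between-gene spread of true
# dispersions around the trend, so homogeneous dispersion collapses to the
# trend while genuine dispersion outliers keep their own estimate.
estimate_dispersions <- function(counts, groups, sf = NULL, phi_min = 1e-8) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  z <- sweep(counts, 2L, sf, "/")
  gl <- split(seq_len(ncol(z)), groups)
  k <- length(gl)
  df_resid <- max(ncol(z) - k, 1L)
  mu <- rowMeans(z)
  # pooled within-group variance
  ssq <- Reduce(`+`, lapply(gl, function(idx) {
    zi <- z[, idx, drop = FALSE]
    rowSums((zi - rowMeans(zi))^2)
  }))
  s2 <- ssq / df_resid
  phi_mom <- pmax((s2 - mu) / mu^2, 0)
  phi_mom[!is.finite(phi_mom)] <- 0
  use <- mu > 0 & phi_mom > 0
  if (sum(use) >= 10L) {
    fit <- lm(phi_mom[use] ~ I(1 / mu[use]))
    b <- coef(fit)
    phi_trend <- pmax(b[1L] + b[2L] / pmax(mu, 1e-8), phi_min)
  } else {
    m0 <- mean(phi_mom[use])
    phi_trend <- rep(max(if (is.finite(m0)) m0 else phi_min, phi_min), length(mu))
  }
  # delta-method sampling variance of the MoM estimator around the trend,
  # using NB cumulants (k4 term matters at these replicate numbers)
  mu_s <- pmax(mu, 1e-8)
  k2 <- mu_s + phi_trend * mu_s^2
  k4 <- mu_s + 7 * phi_trend * mu_s^2 + 12 * phi_trend^2 * mu_s^3 +
    6 * phi_trend^3 * mu_s^4
  n_g <- lengths(gl)
  var_s2 <- Reduce(`+`, lapply(n_g, function(ng)
    (ng - 1)^2 * (k4 / ng + 2 * k2^2 / max(ng - 1, 1L)))) / df_resid^2
  samp_var <- var_s2 / mu_s^4
  resid_var <- var(phi_mom[use] - phi_trend[use])
  between_var <- max(ifelse(is.finite(resid_var), resid_var, 0) -
                       mean(samp_var[use]), 0)
  if (!is.finite(between_var)) between_var <- 0
  w_trend <- samp_var / (samp_var + between_var)   # 1 when dispersions are homogeneous
  phi <- pmax(w_trend * phi_trend + (1 - w_trend) * phi_mom, phi_min)
  list(phi = phi, phi_mom = phi_mom, phi_trend = phi_trend,
       w_trend = w_trend, mu = mu, sf = sf)
}

# Exact conditional two-group NB test (Robinson-Smyth): conditional on the
# total of the size-factor-adjusted pseudo-counts, the group-1 total follows
# a distribution free of the mean; the two-sided p-value sums all outcome
# probabilities not exceeding that of the observed split.
.nb_exact_p <- function(y1_sum, y2_sum, n1, n2, phi) {
  s <- y1_sum + y2_sum
  if (s == 0) return(1)
  size1 <- n1 / max(phi, 1e-8)
  size2 <- n2 / max(phi, 1e-8)
  m <- s / (size1 + size2)
  y <- 0:s
  pr <- dnbinom(y, size = size1, mu = size1 * m) *
    dnbinom(s - y, size = size2, mu = size2 * m)
  pr <- pr / sum(pr)
  min(sum(pr[pr <= pr[y1_sum + 1L] * (1 + 1e-12)]), 1)
}

# Wald test on one coefficient of an NB GLM with fixed dispersion.
# The formula must carry the offset as offset(.off).
# Returns c(estimate, se, p) in natural-log units; NA on failure.
.nb_wald <- function(y, X_df, formula, offset_log, phi, coef_name) {
  theta <- 1 / max(phi, 1e-8)
  dat <- cbind(X_df, .y = y, .off = offset_log)
  fit <- tryCatch(
    suppressWarnings(glm(formula, data = dat,
                         family = MASS::negative.binomial(theta = theta))),
    error = function(e) NULL)
  if (is.null(fit) || !coef_name %in% names(coef(fit)))
    return(c(NA_real_, NA_real_, NA_real_))
  sm <- summary(fit, dispersion = 1)$coefficients
  est <- sm[coef_name, "Estimate"]
  se <- sm[coef_name, "Std. Error"]
  if (!is.finite(est) || !is.finite(se) || se <= 0 || abs(est) > 50)
    return(c(NA_real_, NA_real_, NA_real_))
  z <- est / se
  c(est, se, 2 * pnorm(-abs(z)))
}

#' Negative-binomial two-group test per gene
#'
#' Fits, per gene, the NB log-linear model `count ~ group` with
#' `offset = log(size factor)` and a fixed dispersion (method-of-moments
#' estimate shrunk adaptively toward the fitted mean-dispersion trend); the
#' log2 fold change (`group2 / group1`, second factor level over first) is
#' the fitted group coefficient. P-values come, by default, from the exact
#' conditional NB test on size-factor-adjusted pseudo-counts, which stays
#' calibrated at 3 replicates per group where the asymptotic Wald z reference
#' is anti-conservative; `method = "wald"` gives the plain Wald test. All-zero
#' genes get `log2fc = 0`, `p = 1` and status `"all_zero"`; genes where the
#' GLM cannot be fit stably are refit with a 0.5 pseudocount and flagged
#' `"pseudocount"`.
#'
#' @param counts `expression_table` (unit "count") or genes x samples matrix.
#' @param groups factor/character of group labels, one per sample (the first
#'   level is the reference, e.g. yak; the second the contrast, e.g.
#'   cattle-yak).
#' @param norm_factors optional size factors; median-of-ratios by default.
#' @param method `"exact"` (default) or `"wald"`.
#' @return data frame `gene_id`, `log2fc`, `p_value`, `fdr`, `status` with
#'   attribute `"contrast"`.
#' @export
nb_two_group_test <- function(counts, groups, norm_factors = NULL,
                              method = c("exact", "wald")) {
  method <- match.arg(method)
  m <- if (inherits(counts, "expression_table")) counts$values else as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group", call. = FALSE)
  sf <- if (is.null(norm_factors)) size_factors(m) else norm_factors
  disp <- estimate_dispersions(m, groups, sf = sf)
  off <- log(sf)
  gfac <- data.frame(g = groups)
  g1 <- groups == levels(groups)[1L]
  pseudo <- round(sweep(m, 2L, sf, "/"))
  res <- matrix(NA_real_, nrow(m), 3L)
  status <- rep("ok", nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    if (all(y == 0)) {
      res[i, ] <- c(0, NA, 1)
      status[i] <- "all_zero"
      next
    }
    w <- .nb_wald(y, gfac, .y ~ g + offset(.off), off, disp$phi[i],
                  paste0("g", levels(groups)[2L]))
    if (anyNA(w)) {
      w <- .nb_wald(y + 0.5, gfac, .y ~ g + offset(.off), off, disp$phi[i],
                    paste0("g", levels(groups)[2L]))
      status[i] <- if (anyNA(w)) "non_converged" else "pseudocount"
      if (anyNA(w)) w <- c(0, NA, 1)
    }
    if (method == "exact")
      w[3L] <- .nb_exact_p(sum(pseudo[i, g1]), sum(pseudo[i, !g1]),
                           sum(g1), sum(!g1), disp$phi[i])
    res[i, ] <- w
  }
  out <- data.frame(gene_id = rownames(m),
                    log2fc = res[, 1L] / log(2),
                    p_value = res[, 3L],
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$status <- status
  attr(out, "contrast") <- paste(levels(groups)[2L], "vs", levels(groups)[1L])
  attr(out, "dispersion") <- disp$phi
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard BH: order the m non-missing p-values increasingly, compute
#' p(i) * m / i and enforce monotonicity by a cumulative minimum from the
#' largest rank down, capped at 1. `NA` p-values propagate as `NA` and are
#' excluded from m and from the ranking.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of FDR values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)          # largest first
  q <- pv[o] * m / (m:1)                     # ranks m..1
  q <- pmin(cummin(q), 1)
  out[ok[o]] <- q
  out
}

#' Differential translation efficiency (DTEG) interaction test
#'
#' Joint NB model per gene over both layers:
#' `count ~ layer + group + layer:group`, with per-layer median-of-ratios
#' size factors as offsets and a fixed dispersion (mean of the two per-layer
#' shrunk estimates). The Wald test on the interaction coefficient asks
#' whether the Ribo-seq fold change differs from the RNA-seq fold change,
#' i.e. whether TE changed; `log2fc` is the interaction estimate in log2
#' units. A gene all-zero in either layer is flagged and given `p = 1`.
#'
#' @param rna_counts,ribo_counts count `expression_table`s or matrices on the
#'   same genes and samples.
#' @param groups group labels per sample (shared by both layers).
#' @return data frame as in [nb_two_group_test()].
#' @export
dteg_test <- function(rna_counts, ribo_counts, groups) {
  mr <- if (inherits(rna_counts, "expression_table")) rna_counts$values else as.matrix(rna_counts)
  mb <- if (inherits(ribo_counts, "expression_table")) ribo_counts$values else as.matrix(ribo_counts)
  if (!identical(rownames(mr), rownames(mb)))
    stop("RNA and RIBO tables must cover the same genes in the same order", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  sfr <- size_factors(mr)
  sfb <- size_factors(mb)
  dr <- estimate_dispersions(mr, groups, sf = sfr)
  db <- estimate_dispersions(mb, groups, sf = sfb)
  phi <- (dr$phi + db$phi) / 2
  n <- ncol(mr)
  dat <- data.frame(layer = factor(rep(c("RNA", "RIBO"), each = n), levels = c("RNA", "RIBO")),
                    g = factor(rep(groups, 2L), levels = levels(groups)))
  off <- log(c(sfr, sfb))
  cname <- paste0("layerRIBO:g", levels(groups)[2L])
  res <- matrix(NA_real_, nrow(mr), 3L)
  status <- rep("ok", nrow(mr))
  for (i in seq_len(nrow(mr))) {
    if (all(mr[i, ] == 0) || all(mb[i, ] == 0)) {
      res[i, ] <- c(0, NA, 1)
      status[i] <- "all_zero_layer"
      next
    }
    y <- c(mr[i, ], mb[i, ])
    w <- .nb_wald(y, dat, .y ~ layer * g + offset(.off), off, phi[i], cname)
    if (anyNA(w)) {
      w <- .nb_wald(y + 0.5, dat, .y ~ layer * g + offset(.off), off, phi[i], cname)
      status[i] <- if (anyNA(w)) "non_converged" else "pseudocount"
      if (anyNA(w)) w <- c(0, NA, 1)
    }
    res[i, ] <- w
  }
  out <- data.frame(gene_id = rownames(mr),
                    log2fc = res[, 1L] / log(2),
                    p_value = res[, 3L],
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$status <- status
  attr(out, "contrast") <- paste0("TE: ", levels(groups)[2L], " vs ", levels(groups)[1L])
  out
}

#' Five-category divergence classification
#'
#' With sigX := |log2FC_X| >= `lfc_thr` and FDR_X < `fdr_thr` for each of two
#' contrasts A (transcription) and B (translation, or TE), genes are
#' partitioned into: Homodirection (both significant, same sign), Opposite
#' (both significant, opposite signs), Transcription (A only), the B-only
#' label (`label_b`, "Translation" or "TE"), and Unchanged (neither). Genes
#' present in only one contrast are excluded and counted in the
#' `"excluded"` attribute.
#'
#' @param diff_a,diff_b data frames from the differential tests
#'   (`gene_id`, `log2fc`, `fdr`).
#' @param lfc_thr,fdr_thr significance thresholds (defaults 1 and 0.05).
#' @param label_b label for B-only genes.
#' @return data frame `gene_id`, `category` (factor with the five levels).
#' @export
classify_divergence <- function(diff_a, diff_b, lfc_thr = 1, fdr_thr = 0.05,
                                label_b = c("Translation", "TE")) {
  label_b <- match.arg(label_b)
  shared <- intersect(diff_a$gene_id, diff_b$gene_id)
  excluded <- length(union(diff_a$gene_id, diff_b$gene_id)) - length(shared)
  a <- diff_a[match(shared, diff_a$gene_id), ]
  b <- diff_b[match(shared, diff_b$gene_id), ]
  sig_a <- abs(a$log2fc) >= lfc_thr & !is.na(a$fdr) & a$fdr < fdr_thr
  sig_b <- abs(b$log2fc) >= lfc_thr & !is.na(b$fdr) & b$fdr < fdr_thr
  lv <- c("Transcription", label_b, "Homodirection", "Opposite", "Unchanged")
  cat <- rep("Unchanged", length(shared))
  cat[sig_a & !sig_b] <- "Transcription"
  cat[!sig_a & sig_b] <- label_b
  same <- sign(a$log2fc) == sign(b$log2fc)
  cat[sig_a & sig_b & same] <- "Homodirection"
  cat[sig_a & sig_b & !same] <- "Opposite"
  out <- data.frame(gene_id = shared, category = factor(cat, levels = lv),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Category counts and percentages for a divergence classification
#'
#' Reports each category's gene count and its percentage of the classified
#' universe, rounded to two decimals, in the conventional
#' "Category (xx.xx%, n)" display form.
#'
#' @param x either the output of [classify_divergence()] or a named integer
#'   vector of category counts.
#' @return data frame `category`, `n`, `pct`, `label`.
#' @export
divergence_summary <- function(x) {
  counts <- if (is.data.frame(x)) table(x$category) else x
  n <- as.numeric(counts)
  pct <- round(100 * n / sum(n), 2L)
  data.frame(category = names(counts), n = n, pct = pct,
             label = sprintf("%s (%.2f%%, %d)", names(counts), pct, n),
             stringsAsFactors = FALSE)
}

#' Up/down/total summary of one differential contrast
#'
#' Given a differential result, counts significant up- and down-regulated
#' genes at the thresholds; given explicit up/down counts, just totals them.
#'
#' @param x differential result data frame, or the number of up-regulated
#'   genes when `down` is supplied.
#' @param down number of down-regulated genes (with scalar `x`).
#' @param lfc_thr,fdr_thr thresholds used with a result data frame.
#' @return list with `up`, `down`, `total`.
#' @export
diff_totals <- function(x, down = NULL, lfc_thr = 1, fdr_thr = 0.05) {
  if (is.data.frame(x)) {
    sig <- abs(x$log2fc) >= lfc_thr & !is.na(x$fdr) & x$fdr < fdr_thr
    up <- sum(sig & x$log2fc > 0)
    dn <- sum(sig & x$log2fc < 0)
  } else {
    stopifnot(!is.null(down))
    up <- x
    dn <- down
  }
  list(up = up, down = dn, total = up + dn)
}
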
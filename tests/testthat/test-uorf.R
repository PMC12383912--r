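test_that("uORF detection finds AUG...stop ORFs within the 5'UTR", {
  # hand scan: UTR "AAATGGCTTAAGG" -> ATG GCT TAA at [2, 11)
  utr <- "AAATGGCTTAAGG"
  cds <- paste0("ATG", strrep("GCA", 10L), "TGA")
  m <- transcript_models(data.frame(
    transcript_id = "t", gene_id = "g",
    sequence = paste0(utr, cds, "AAAA"),
    cds_start = nchar(utr), cds_end = nchar(utr) + nchar(cds),
    stringsAsFactors = FALSE))
  u <- detect_uorfs(m, min_len = 9L)
  expect_identical(nrow(u), 1L)
  expect_identical(u$start, 2L)
  expect_identical(u$end, 11L)
  expect_identical(u$length, 9L)

  # no ATG in the UTR -> no candidates
  m2 <- m; m2$sequence <- paste0(strrep("C", 13L), cds, "AAAA")
  expect_identical(nrow(detect_uorfs(m2)), 0L)

  # ATG without an in-frame stop before the CDS -> excluded
  m3 <- m; m3$sequence <- paste0("AAATGGCTGCTGG", cds, "AAAA")
  expect_identical(nrow(detect_uorfs(m3)), 0L)

  # nested in-frame AUGs sharing a stop collapse to the most 5' one
  utr4 <- paste0("ATGGCAATGGCATAA", strrep("C", 10L))
  m4 <- m; m4$sequence <- paste0(utr4, cds, "AAAA")
  m4$cds_start <- nchar(utr4); m4$cds_end <- nchar(utr4) + nchar(cds)
  m4 <- transcript_models(as.data.frame(m4))
  u4 <- detect_uorfs(m4)
  expect_identical(nrow(u4), 1L)
  expect_identical(u4$start, 0L)
  u4k <- detect_uorfs(m4, keep_nested = TRUE)
  expect_identical(nrow(u4k), 2L)
})

test_that("detected uORFs on simulated transcripts satisfy the type invariants", {
  st <- small_study(n_genes = 300L, seed = 42L)
  u <- detect_uorfs(st$models)
  expect_gt(nrow(u), 0L)
  seqs <- substr(st$models[u$transcript_id, "sequence"], u$start + 1L, u$end)
  expect_true(all(substr(seqs, 1L, 3L) == "ATG"))
  expect_true(all(substr(seqs, nchar(seqs) - 2L, nchar(seqs)) %in% c("TAA", "TAG", "TGA")))
  expect_true(all(u$length %% 3L == 0L & u$length >= 9L))
  expect_true(all(u$end <= st$models[u$transcript_id, "cds_start"]))
  expect_true(all(u$end - u$start == u$length))
})

test_that("ORFscore matches closed forms and its frame-permutation sign rule", {
  expect_equal(orfscore(10, 10, 10), 0)
  expect_equal(orfscore(30, 0, 0), log2(61))
  expect_equal(orfscore(0, 30, 0), -log2(61))
  expect_equal(orfscore(0, 0, 30), -log2(61))
  expect_true(is.na(orfscore(0, 0, 0)))
  # brute force over all permutations of (30, 0, 0): magnitude preserved,
  # sign positive only when frame 0 holds the strict maximum
  perms <- rbind(c(30, 0, 0), c(0, 30, 0), c(0, 0, 30),
                 c(30, 30, 0), c(30, 0, 30), c(0, 30, 30))
  s <- orfscore(perms[, 1L], perms[, 2L], perms[, 3L])
  expect_equal(abs(s[1:3]), rep(log2(61), 3L))
  expect_true(s[1L] > 0 && all(s[2:3] < 0))
  expect_true(all(s[4:6] < 0))   # ties are not a strict maximum
})

test_that("RRS follows the density-ratio definition with its gap policy", {
  expect_equal(rrs(10, 30, 1, 30), 5)        # (10/30)/((1+1)/30)
  expect_equal(rrs(0, 30, 5, 30), 0)
  expect_true(is.na(rrs(10, 30, 1, 10)))     # gap below 15 nt
})

# independent transcription of the TESTCODE tables (oracle)
fickett_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  codpos <- rep_len(1:3, length(ch))
  pos_tab <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  cont_tab <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.61, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  s <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- sapply(1:3, function(p) sum(ch == b & codpos == p))
    a <- max(cnt) / (min(cnt) + 1)
    f <- sum(cnt) / length(ch)
    # bucket = first boundary at or below the value (boundaries inclusive)
    ia <- 11L - sum(a >= c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0))
    ic <- 11L - sum(f >= c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0))
    s <- s + pos_tab[[b]][ia] * c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)[[b]] +
      cont_tab[[b]][ic] * c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)[[b]]
  }
  s
}

test_that("Fickett score agrees with an independent table lookup and stays in range", {
  a60 <- strrep("A", 60L)
  expect_equal(as.numeric(fickett_score(a60)), fickett_oracle(a60))
  set.seed(8)
  for (i in 1:40) {
    s <- paste0(sample(c("A", "C", "G", "T"), 300L, TRUE), collapse = "")
    got <- as.numeric(fickett_score(s))
    expect_equal(got, fickett_oracle(s))
    expect_gte(got, 0.16); expect_lte(got, 1.30)
    # in-frame self-concatenation preserves composition exactly; the position
    # statistic max/(min + 1) shifts only through its +1 regularizer
    expect_lt(abs(as.numeric(fickett_score(paste0(s, s))) - got), 0.13)
  }
  flagged <- attr(fickett_score("ATGNNNNNNGGG"), "flagged")
  expect_true(flagged)
})

test_that("hexamer score is the mean in-frame log-likelihood ratio", {
  tab <- structure(list(coding = setNames(rep(1 / 4096, 4096), riboscape:::.all_hexamers()),
                        noncoding = setNames(rep(1 / 4096, 4096), riboscape:::.all_hexamers())),
                   class = "hexamer_table")
  expect_equal(hexamer_score("ATGGCATGA", tab), 0)    # identical tables
  tab$coding["ATGGCA"] <- 0.02
  tab$noncoding["ATGGCA"] <- 0.01
  expect_equal(hexamer_score("ATGGCA", tab), log(2))
  expect_true(is.na(hexamer_score("ATG", tab)))

  st <- small_study(n_genes = 60L, seed = 2L)
  t1 <- train_hexamer_table(st$models, seed = 5L)
  t2 <- train_hexamer_table(st$models, seed = 5L)
  expect_identical(t1, t2)                            # seeded determinism
  expect_equal(sum(t1$coding), 1, tolerance = 1e-9)
  expect_equal(sum(t1$noncoding), 1, tolerance = 1e-9)
  expect_true(all(t1$coding > 0) && all(t1$noncoding > 0))
})

test_that("dinucleotide shuffle preserves dinucleotide counts and endpoints", {
  set.seed(3)
  dinuc_counts <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    table(paste0(ch[-length(ch)], ch[-1L]))
  }
  for (i in 1:20) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(20:80, 1L), TRUE), collapse = "")
    sh <- riboscape:::dinuc_shuffle(s)
    expect_identical(nchar(sh), nchar(s))
    expect_identical(substr(sh, 1L, 1L), substr(s, 1L, 1L))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
  }
})

test_that("Kozak PWM and chi-square comparison behave at the extremes", {
  ctx <- function(minus5) paste0("A", minus5, "ACCA", "ATG", "G")
  a <- rep(ctx("C"), 50L)
  b <- rep(ctx("G"), 50L)
  same <- kozak_analysis(a, a)
  expect_true(all(same$p_values == 1))
  diffr <- kozak_analysis(a, b)
  expect_lt(diffr$p_values[["-5"]], 1e-10)
  expect_equal(unname(diffr$pwm_a["C", "-5"]), 1)     # one-hot column
  expect_equal(colSums(diffr$pwm_a), rep(1, 10L), ignore_attr = TRUE)
  expect_error(kozak_analysis(a[1:3], b), ">= 5")
})

test_that("Kozak windows are clipped and padded at the transcript start", {
  m <- tiny_model()
  ctx <- kozak_context(m, "tx1", 3L)   # only 3 nt upstream available
  expect_identical(nchar(ctx), 10L)
  expect_identical(substr(ctx, 1L, 3L), "NNN")
  ctx2 <- kozak_context(m, "tx1", 20L)
  expect_identical(substr(ctx2, 7L, 9L), "ATG")
})

test_that("uORF distances and last-uORF selection follow their definitions", {
  m <- transcript_models(data.frame(
    transcript_id = "t", gene_id = "g",
    sequence = paste0(strrep("C", 100L), "ATG", strrep("GCA", 20L), "TAA",
                      strrep("A", 30L)),
    cds_start = 100L, cds_end = 166L, stringsAsFactors = FALSE))
  u <- data.frame(uorf_id = c("u1", "u2"), transcript_id = "t", gene_id = "g",
                  start = c(10L, 40L), end = c(40L, 80L), stringsAsFactors = FALSE)
  d <- uorf_distance(u, m)
  expect_equal(d$dist_to_cds, c(60L, 20L))
  expect_equal(d$norm_dist, c(0.6, 0.2))
  expect_identical(last_uorf_per_gene(d)$uorf_id, "u2")
  # uORF abutting the CDS
  u0 <- uorf_distance(data.frame(uorf_id = "u3", transcript_id = "t",
                                 gene_id = "g", start = 70L, end = 100L), m)
  expect_equal(u0$dist_to_cds, 0L)
  expect_equal(u0$norm_dist, 0)
})

test_that("classifier requires all four scores plus expression; missing scores fail", {
  sc <- data.frame(orfscore = c(7, 10, 7, 7, 7),
                   rrs = c(3, NA, 3, 3, 3),
                   fickett = c(0.8, 0.9, 0.5, 0.8, 0.8),
                   hexamer = c(0.5, 0.5, 0.5, 0, 0.5),
                   mean_fpkm = c(2, 2, 2, 2, 0.5))
  out <- classify_translated(sc)
  expect_equal(out$translated, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("uORF-mORF relation reports correlation, regressions and KS comparisons", {
  set.seed(9)
  lfc <- rnorm(500)
  g <- data.frame(uorf_log2fc = lfc, morf_log2fc = lfc,
                  te = exp(rnorm(500)), uorf_length = runif(500, 51, 198),
                  uorf_gc = runif(500, 0.3, 0.7), uorf_nmfe = -runif(500, 0, 0.5),
                  uorf_class = sample(c("none", "untranslated", "translated"),
                                      500, TRUE))
  rel <- uorf_morf_relation(g)
  expect_equal(rel$correlation$r, 1)
  # independent vectors: near-zero correlation
  g2 <- g; g2$uorf_log2fc <- rnorm(500)
  expect_lt(abs(uorf_morf_relation(g2)$correlation$r), 0.1)
  expect_named(rel$regressions, c("uorf_length", "uorf_gc", "uorf_nmfe"))
  expect_true(all(c("none_vs_translated", "none_vs_untranslated",
                    "translated_vs_untranslated") %in% names(rel$ks)))
  # planted TE suppression in uORF-bearing genes is detected by KS
  g3 <- g
  g3$te[g3$uorf_class == "translated"] <- g3$te[g3$uorf_class == "translated"] * 0.3
  expect_lt(uorf_morf_relation(g3)$ks$translated_vs_untranslated$p, 0.01)
  expect_warning(uorf_morf_relation(g[1:5, ]), "suppressed")
})
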
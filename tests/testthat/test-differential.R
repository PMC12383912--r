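test_that("BH adjustment equals an independent reference on random p-vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5L)), rep(1, 5L))
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))

  set.seed(101)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1L))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("size factors match the median-of-ratios construction", {
  set.seed(7)
  m <- matrix(rnbinom(400, mu = 100, size = 10), 100L, 4L,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  m[, 2L] <- m[, 2L] * 3L
  sf <- size_factors(m)
  # brute-force reference: median log-ratio to the all-positive geometric mean
  pos <- m[rowSums(m > 0) == 4L, ]
  expected <- apply(log(pos), 2L, function(lc) exp(median(lc - rowMeans(log(pos)))))
  expect_equal(unname(sf), unname(expected))
  expect_equal(unname(sf[2L] / sf[1L]), 3, tolerance = 0.1)
})

test_that("two-group NB test handles degenerate genes and equal groups", {
  m <- rbind(flat = rep(50L, 6L), zero = rep(0L, 6L))
  colnames(m) <- paste0("s", 1:6)
  grp <- rep(c("g1", "g2"), each = 3L)
  res <- nb_two_group_test(m, grp, norm_factors = setNames(rep(1, 6L), colnames(m)))
  expect_equal(res$log2fc[1L], 0, tolerance = 1e-6)
  expect_equal(res$p_value[1L], 1)
  expect_identical(res$status[2L], "all_zero")
  expect_equal(res$p_value[2L], 1)
  expect_equal(res$log2fc[2L], 0)
})

test_that("NB test is calibrated under the null and powered under planted shifts", {
  set.seed(2024)
  n <- 1200L
  grp <- rep(c("g1", "g2"), each = 3L)
  null_m <- matrix(rnbinom(n * 6L, mu = 200, size = 10), n, 6L,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  res <- nb_two_group_test(null_m, grp)
  rej <- mean(res$p_value < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rej - 0.05), 0.05 + 3 * se)   # anti-conservative blowups caught

  set.seed(2025)
  na <- 200L
  mu2 <- rep(500, na)
  alt <- cbind(matrix(rnbinom(na * 3L, mu = mu2, size = 10), na, 3L),
               matrix(rnbinom(na * 3L, mu = mu2 * 4, size = 10), na, 3L))
  dimnames(alt) <- list(paste0("a", 1:na), paste0("s", 1:6))
  res2 <- nb_two_group_test(alt, grp, norm_factors = setNames(rep(1, 6L), paste0("s", 1:6)))
  expect_gte(mean(sign(res2$log2fc) == 1), 0.99)
  power <- mean(res2$fdr < 0.05 & abs(res2$log2fc) >= 1)
  expect_gte(power, 0.9)
})

test_that("DTEG interaction test cancels equal shifts and flags all-zero layers", {
  set.seed(31)
  n <- 300L
  grp <- rep(c("g1", "g2"), each = 3L)
  base <- matrix(rnbinom(n * 6L, mu = 300, size = 10), n, 6L,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  shift <- cbind(base[, 1:3], matrix(rnbinom(n * 3L, mu = 300 * 4, size = 10), n, 3L))
  dimnames(shift) <- dimnames(base)
  # same shift in both layers: interaction ~ 0, near-uniform p
  res <- dteg_test(shift, shift, grp)
  expect_lt(mean(abs(res$log2fc) >= 1 & res$fdr < 0.05), 0.02)

  z <- base; z[1L, ] <- 0L
  res2 <- dteg_test(z, base, grp)
  expect_identical(res2$status[1L], "all_zero_layer")
  expect_equal(res2$p_value[1L], 1)
})

test_that("DTEG test recovers planted TE shifts among unshifted genes", {
  set.seed(77)
  n <- 600L
  shifted <- seq_len(180L)          # RIBO-only |log2FC| = 2 in group 2, balanced signs
  grp <- rep(c("g1", "g2"), each = 3L)
  rna <- matrix(rnbinom(n * 6L, mu = 500, size = 10), n, 6L,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
  mu_ribo <- matrix(500, n, 6L)
  mu_ribo[shifted, 4:6] <- rep(c(2000, 125), each = 90L)
  ribo <- matrix(rnbinom(n * 6L, mu = mu_ribo, size = 10), n, 6L,
                 dimnames = dimnames(rna))
  res <- dteg_test(rna, ribo, grp)
  hit <- res$fdr < 0.05 & abs(res$log2fc) >= 1
  expect_gte(mean(hit[shifted], na.rm = TRUE), 0.85)
  expect_lte(mean(hit[-shifted], na.rm = TRUE), 0.05)
})

test_that("five-category classifier applies the sign and significance rules", {
  mk <- function(lfc, fdr) data.frame(gene_id = paste0("g", seq_along(lfc)),
                                      log2fc = lfc, fdr = fdr,
                                      stringsAsFactors = FALSE)
  a <- mk(c(2, -1.2, 2, 0, 0.2), c(0.01, 0.01, 0.01, 1, 0.2))
  b <- mk(c(1.5, 1.3, 0.2, 0, 1.4), c(0.01, 0.02, 0.6, 1, 0.01))
  cls <- classify_divergence(a, b)
  expect_equal(as.character(cls$category),
               c("Homodirection", "Opposite", "Transcription", "Unchanged", "Translation"))
  # categories partition the shared universe
  expect_equal(sum(table(cls$category)), 5)

  # gene present in only one contrast is excluded and counted
  b2 <- b[-1L, ]
  cls2 <- classify_divergence(a, b2)
  expect_identical(attr(cls2, "excluded"), 1L)
  expect_false("g1" %in% cls2$gene_id)
})

test_that("summary ops reproduce percentages and totals from counts", {
  s <- divergence_summary(c(Transcription = 3949, Translation = 2441,
                            Homodirection = 4992, Opposite = 63, Unchanged = 9520))
  expect_equal(s$pct, c(18.84, 11.64, 23.81, 0.30, 45.41))
  expect_equal(sum(s$n), 20965)
  tot <- diff_totals(1263, 2973)
  expect_identical(tot$total, 4236)
})
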
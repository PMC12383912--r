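test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 40L, seed = 123L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$models$sequence, b$models$sequence)
  expect_identical(a$rna$values, b$rna$values)
  expect_identical(a$ribo$values, b$ribo$values)
  expect_identical(as.data.frame(a$footprints), as.data.frame(b$footprints))

  # different seed changes the data
  c2 <- simulate_study(sim_config(n_genes = 40L, seed = 124L))
  expect_false(identical(a$rna$values, c2$rna$values))
})

test_that("simulated transcripts satisfy the model invariants", {
  st <- small_study(n_genes = 100L, seed = 6L)
  m <- st$models
  expect_true(all(substr(m$sequence, m$cds_start + 1L, m$cds_start + 3L) == "ATG"))
  expect_true(all((m$cds_end - m$cds_start) %% 3L == 0L))
  stops <- substr(m$sequence, m$cds_end - 2L, m$cds_end)
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_true(all(m$cds_start >= 100L & m$cds_start <= 500L))

  # planted uORFs start with ATG and end with a stop inside the 5'UTR
  ut <- st$uorf_truth
  useq <- substr(m[ut$transcript_id, "sequence"], ut$start + 1L, ut$end)
  expect_true(all(substr(useq, 1L, 3L) == "ATG"))
  expect_true(all(substr(useq, nchar(useq) - 2L, nchar(useq)) %in% c("TAA", "TAG", "TGA")))
  expect_true(all(ut$end <= m[ut$transcript_id, "cds_start"]))
})

test_that("uORF plant rate 0 leaves no compatible AUG...stop in any 5'UTR frame by construction", {
  st0 <- simulate_study(sim_config(n_genes = 30L, seed = 8L, uorf_plant_rate = 0))
  expect_null(st0$uorf_truth)
})

test_that("empty simulation returns an empty model set", {
  m <- simulate_transcriptome(sim_config(n_genes = 0L, seed = 1L))
  expect_identical(nrow(m), 0L)
})

test_that("planted fold changes are recovered in group-mean ratios (law of large numbers)", {
  cfg <- sim_config(n_genes = 600L, seed = 55L, phi = 0.001, baseline_mean = 1000,
                    mean_sdlog = 0, effect_log2fc = 1,
                    category_fractions = c(Transcription = 0, Translation = 1,
                                           Homodirection = 0, Opposite = 0,
                                           Unchanged = 0))
  st <- simulate_study(cfg)
  g2 <- grepl("^g2", colnames(st$ribo$values))
  ratio <- rowMeans(st$ribo$values[, g2]) / rowMeans(st$ribo$values[, !g2])
  up <- st$truth$lfc_ribo > 0
  expect_gt(sum(up), 200L)
  expect_lt(abs(mean(ratio[up]) - 2), 0.1)           # 2^1, within 5%
  expect_lt(abs(mean(1 / ratio[!up]) - 2), 0.1)
  # RNA layer untouched for Translation-planted genes
  r_rna <- rowMeans(st$rna$values[, g2]) / rowMeans(st$rna$values[, !g2])
  expect_lt(abs(mean(r_rna) - 1), 0.05)
})

test_that("unchanged genes yield nominal type-I error in the NB test", {
  cfg <- sim_config(n_genes = 2000L, seed = 77L, phi = 0.1, baseline_mean = 200,
                    mean_sdlog = 0,
                    category_fractions = c(Transcription = 0, Translation = 0,
                                           Homodirection = 0, Opposite = 0,
                                           Unchanged = 1))
  st <- simulate_study(cfg)
  res <- nb_two_group_test(st$rna, factor(st$groups, levels = c("g1", "g2")))
  rej <- mean(res$p_value < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), 0.05)   # generous envelope; exact band in acceptance suite
  expect_gt(rej, 0.001)
})

test_that("footprints respect conservation, frame construction, and length modes", {
  st <- small_study(n_genes = 120L, seed = 3L, uorf_plant_rate = 0)
  fp <- st$footprints
  # conservation: per-sample totals equal per-sample RIBO totals
  tot <- table(fp$sample_id)[colnames(st$ribo$values)]
  expect_equal(unname(as.integer(tot)), unname(colSums(st$ribo$values)))

  # perfect frame bias: every CDS footprint lands P-site in frame 0
  cfg1 <- sim_config(n_genes = 30L, seed = 4L, pi_frame = 1, uorf_plant_rate = 0)
  st1 <- simulate_study(cfg1)
  idx <- match(st1$footprints$transcript_id, st1$models$transcript_id)
  psite <- st1$footprints$five_prime_pos + 12L
  cs <- st1$models$cds_start[idx]
  in_cds <- psite >= cs & psite < st1$models$cds_end[idx]
  expect_true(all((psite[in_cds] - cs[in_cds]) %% 3L == 0L))

  # CDS fraction of P-sites ~ rho_cds at large read counts
  frac <- mean(in_cds)
  n <- length(in_cds)
  expect_lt(abs(frac - 0.9), 0.01)

  # configured length distribution: modes at 28 and 30
  h <- table(fp$read_length)
  expect_true(all(names(sort(h, decreasing = TRUE))[1:2] %in% c("28", "30")))
})
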
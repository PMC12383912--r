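test_that("GTF/FASTA reader derives UTR/CDS spans and skips invalid transcripts", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "tx.fa")
  gtf <- file.path(dir, "tx.gtf")
  m <- tiny_model()
  # add a transcript with no CDS and one with a CDS of length 61
  seq2 <- strrep("ACGT", 25L)
  seq3 <- paste0(strrep("C", 10L), "ATG", strrep("GCT", 19L), "T", strrep("A", 10L))
  writeLines(c(">tx1", m$sequence, ">tx2", seq2, ">tx3", seq3), fa)
  gtf_line <- function(tx, type, s, e)
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t+\t.\tgene_id \"g_%s\"; transcript_id \"%s\";",
            tx, type, s, e, tx, tx)
  writeLines(c(
    gtf_line("tx1", "exon", 1L, 100L), gtf_line("tx1", "CDS", 21L, 80L),
    gtf_line("tx2", "exon", 1L, 100L),                     # no CDS
    gtf_line("tx3", "exon", 1L, nchar(seq3)), gtf_line("tx3", "CDS", 11L, 71L)), gtf)

  expect_warning(expect_warning(models <- read_transcriptome(fa, gtf),
                                "without a CDS"), "multiple of 3")
  expect_identical(models$transcript_id, "tx1")
  expect_identical(models$cds_start, 20L)   # 1-based 21 -> 0-based 20
  expect_identical(models$cds_end, 80L)
  rep <- attr(models, "report")
  expect_identical(rep$skipped_no_cds, 1L)
  expect_identical(rep$skipped_bad_frame, 1L)
  # spans tile the transcript
  expect_equal(riboscape:::utr5_length(models) + riboscape:::cds_length(models) +
                 riboscape:::utr3_length(models), models$length)
})

test_that("missing FASTA sequence for an annotated transcript is a hard error", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "tx.fa")
  gtf <- file.path(dir, "tx.gtf")
  writeLines(c(">other", "ACGTACGT"), fa)
  writeLines(paste0("tx1\tt\texon\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"tx1\";\n",
                    "tx1\tt\tCDS\t21\t80\t.\t+\t.\tgene_id \"g\"; transcript_id \"tx1\";"), gtf)
  expect_error(read_transcriptome(fa, gtf), "missing from FASTA")
})

test_that("transcriptome write/read round-trips spans and sequences", {
  st <- small_study(n_genes = 20L, seed = 5L)
  dir <- withr::local_tempdir()
  write_transcriptome(st$models, file.path(dir, "t.fa"), file.path(dir, "t.gtf"))
  back <- read_transcriptome(file.path(dir, "t.fa"), file.path(dir, "t.gtf"))
  back <- back[st$models$transcript_id, ]
  expect_equal(back$sequence, st$models$sequence)
  expect_equal(back$cds_start, st$models$cds_start)
  expect_equal(back$cds_end, st$models$cds_end)
  # tiling invariant for every accepted transcript
  expect_true(all(riboscape:::utr5_length(back) + riboscape:::cds_length(back) +
                    riboscape:::utr3_length(back) == back$length))
})

test_that("footprint reader validates rows, expands counts, and round-trips", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fp.tsv")
  writeLines(c("transcript_id\tfive_prime_pos\tread_length\tsample_id",
               "tx1\t37\t28\ts1",
               "tx1\t1000000\t28\ts1",     # beyond 100-nt transcript
               "tx1\t5\t30\ts2"), f)
  expect_warning(fp <- read_footprints(f, tiny_model()), "beyond transcript end")
  expect_identical(nrow(fp), 2L)
  expect_identical(fp$five_prime_pos[1L], 37L)
  expect_identical(attr(fp, "report")$rejected_out_of_bounds, 1L)

  # collapsed dialect expands to logical records
  f2 <- file.path(dir, "fp2.tsv")
  writeLines(c("transcript_id\tfive_prime_pos\tread_length\tsample_id\tcount",
               "tx1\t10\t28\ts1\t3"), f2)
  fp2 <- read_footprints(f2)
  expect_identical(nrow(fp2), 3L)
  expect_true(all(fp2$five_prime_pos == 10L))

  # canonical round-trip is byte-identical
  g <- file.path(dir, "out.tsv")
  write_footprints(fp, g)
  fp_rt <- read_footprints(g)
  g2 <- file.path(dir, "out2.tsv")
  write_footprints(fp_rt, g2)
  expect_identical(readBin(g, "raw", file.size(g)), readBin(g2, "raw", file.size(g2)))
})

test_that("count reader enforces integer counts and unique gene ids", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "c.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t0\t0", "g2\t0\t0"), f)
  tbl <- read_counts(f, "RNA")
  expect_equal(unname(tbl$library_sizes), c(0, 0))

  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), f)
  expect_error(read_counts(f, "RNA"), "duplicate gene id")

  writeLines(c("gene_id\ts1", "g1\t12.0", "g2\t3"), f)
  expect_equal(unname(read_counts(f, "RNA")$values[1L, 1L]), 12L)

  writeLines(c("gene_id\ts1", "g1\t12.5"), f)
  expect_error(read_counts(f, "RNA"), "fractional count")
})

test_that("transcript model invariants are enforced", {
  base <- data.frame(transcript_id = "t", gene_id = "g",
                     sequence = paste0("CCCC", "ATG", "AAA", "TAA", "GG"),
                     cds_start = 4L, cds_end = 13L, stringsAsFactors = FALSE)
  expect_silent(transcript_models(base))
  bad_frame <- base; bad_frame$cds_end <- 12L
  expect_error(transcript_models(bad_frame), "invalid CDS span")
  bad_start <- base; bad_start$sequence <- sub("ATG", "CTG", bad_start$sequence)
  expect_error(transcript_models(bad_start), "ATG")
  bad_start$nonstandard_start <- TRUE
  expect_silent(transcript_models(bad_start))
})
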
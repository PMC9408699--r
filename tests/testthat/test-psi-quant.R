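# 10-read fixture over the 3-exon toy gene: exons [1,100], [201,300],
# [401,500] 1-based; four reads skip exon 2, two reads splice into it,
# two body reads sit in it, one read each in exons 1 and 3.
fixture_reads <- function() {
  data.frame(
    pos = c(81, 81, 81, 81, 81, 81, 220, 230, 10, 420),
    cigar = c(rep("20M300N30M", 4), rep("20M100N30M", 2),
              "50M", "50M", "50M", "50M"),
    mapq = 60L, flag = 0L, stringsAsFactors = FALSE)
}

test_that("hand-counted SAM fixture: exon-2 skipping reads are exclusions", {
  m <- toy_model(3)
  sam <- withr::local_tempfile(fileext = ".sam")
  r <- fixture_reads()
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr\tLN:1000",
               sprintf("r%d\t%d\tchr\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       seq_len(nrow(r)), r$flag, r$pos, r$mapq, r$cigar)),
             sam)
  counts <- count_bin_evidence(sam, m, "s1", norm = "raw")
  expect_equal(counts$exclusion_reads[counts$bin_id == "2"], 4L)
  expect_equal(counts$inclusion_reads[counts$bin_id == "2"], 4L)  # 2 junction + 2 body
  expect_equal(counts$inclusion_reads[counts$bin_id == "1"], 7L)
  expect_equal(counts$exclusion_reads[counts$bin_id == "1"], 0L)
  expect_equal(counts$inclusion_reads[counts$bin_id == "3"], 5L)
  # the data.frame path agrees with the SAM path
  counts_df <- count_bin_evidence(r, m, "s1", norm = "raw")
  expect_equal(counts_df$inclusion_reads, counts$inclusion_reads)
  expect_equal(counts_df$exclusion_reads, counts$exclusion_reads)
})

test_that("MAPQ raised above all reads zeroes every count", {
  m <- toy_model(3)
  counts <- count_bin_evidence(fixture_reads(), m, "s1", mapq_min = 100)
  expect_true(all(counts$inclusion_reads == 0L))
  expect_true(all(counts$exclusion_reads == 0L))
})

test_that("bin-inclusive junction reads never count as exclusions", {
  m <- toy_model(3)
  # only reads splicing exon1 -> exon2 (annotated junction)
  r <- data.frame(pos = 81, cigar = "20M100N30M", mapq = 60L, flag = 0L)
  counts <- count_bin_evidence(r, m, "s1")
  expect_equal(counts$exclusion_reads, rep(0L, 3))
})

test_that("secondary, supplementary and duplicate reads are skipped", {
  m <- toy_model(3)
  r <- fixture_reads()
  r$flag <- c(256L, 2048L, 1024L, rep(0L, 7))
  counts <- count_bin_evidence(r, m, "s1")
  expect_equal(counts$exclusion_reads[counts$bin_id == "2"], 1L)
})

test_that("classifier agrees with the brute-force per-read oracle", {
  set.seed(101)
  for (rep in 1:15) {
    m <- toy_model(sample(2:5, 1), exon_len = sample(50:150, 1),
                   gap = sample(50:150, 1))
    if (rep %% 2 == 0) {
      span <- max(m$exons$end0)
      j <- data.frame(start = sample.int(span - 100L, 2))
      j$end <- j$start + sample(30:90, 2)
      m <- suppressWarnings(flatten_to_bins(m, j))
    }
    reads <- random_reads(m, sample(30:120, 1))
    got <- count_bin_evidence(reads, m, "s", norm = "raw")
    want <- oracle_bin_counts(reads, m)
    expect_equal(got$inclusion_reads, want$inclusion_reads)
    expect_equal(got$exclusion_reads, want$exclusion_reads)
  }
})

test_that("PSI formula: boundary values and hand arithmetic", {
  base <- data.frame(sample_id = "s", bin_id = "b",
                     inclusion_positions = 1, exclusion_positions = 1)
  p1 <- compute_psi(cbind(base, inclusion_reads = 50, exclusion_reads = 0))
  expect_equal(p1$psi, 1)
  p0 <- compute_psi(cbind(base, inclusion_reads = 0, exclusion_reads = 50))
  expect_equal(p0$psi, 0)
  ph <- compute_psi(data.frame(sample_id = "s", bin_id = "b",
                               inclusion_reads = 30, exclusion_reads = 10,
                               inclusion_positions = 60,
                               exclusion_positions = 20))
  expect_equal(ph$psi, 0.5)
  expect_equal(ph$total_support, 40L)
})

test_that("PSI is missing below min_support and bounded when defined", {
  low <- compute_psi(data.frame(sample_id = "s", bin_id = "b",
                                inclusion_reads = 4, exclusion_reads = 3,
                                inclusion_positions = 1,
                                exclusion_positions = 1),
                     min_support = 10)
  expect_true(is.na(low$psi))
  set.seed(5)
  rnd <- data.frame(sample_id = "s", bin_id = letters[1:50],
                    inclusion_reads = rpois(50, 40),
                    exclusion_reads = rpois(50, 40),
                    inclusion_positions = sample(1:200, 50),
                    exclusion_positions = sample(1:200, 50))
  psi <- compute_psi(rnd, min_support = 10)$psi
  expect_true(all(psi >= 0 & psi <= 1, na.rm = TRUE))
  # psi = 1 iff no exclusion reads, 0 iff no inclusion reads
  def <- !is.na(psi)
  expect_equal(psi[def] == 1, rnd$exclusion_reads[def] == 0)
  expect_equal(psi[def] == 0, rnd$inclusion_reads[def] == 0)
})

test_that("PSI is invariant under joint count/position scaling", {
  set.seed(6)
  base <- data.frame(sample_id = "s", bin_id = letters[1:20],
                     inclusion_reads = rpois(20, 30),
                     exclusion_reads = rpois(20, 30),
                     inclusion_positions = sample(1:50, 20),
                     exclusion_positions = sample(1:50, 20))
  for (k in c(2L, 7L)) {
    scaled <- base
    scaled[, 3:6] <- scaled[, 3:6] * k
    expect_equal(compute_psi(scaled, min_support = 1)$psi,
                 compute_psi(base, min_support = 1)$psi)
  }
})

test_that("psi_table assembly is complete, ordered, and order-invariant", {
  m <- toy_model(3)
  meta <- data.frame(sample_id = c("a", "b"), genotype = c("WT", "mdm"),
                     muscle = "EDL")
  counts <- rbind(
    count_bin_evidence(fixture_reads(), m, "a", norm = "raw"),
    count_bin_evidence(fixture_reads()[1:6, ], m, "b", norm = "raw"))
  tab <- build_psi_table(counts, m, meta, min_support = 4)
  expect_equal(nrow(tab$psi), 6L)  # 2 samples x 3 bins
  # sample b has only junction reads: exon 3 has 4 inclusions (support ok),
  # exon 1 has 6; exon 2 has 2+4: all >= 4 -- lower the bar to force one NA
  tab2 <- build_psi_table(counts, m, meta, min_support = 5)
  expect_equal(sum(is.na(tab2$psi$psi)), 1L)
  shuffled <- counts[sample(nrow(counts)), ]
  tab3 <- build_psi_table(shuffled, m, meta, min_support = 4)
  expect_identical(tab3$psi, tab$psi)
  expect_error(build_psi_table(counts, m, meta[1, , drop = FALSE],
                               min_support = 4),
               "metadata missing")
})

test_that("counts TSV round-trips into the table builder", {
  m <- toy_model(3)
  counts <- count_bin_evidence(fixture_reads(), m, "a", norm = "raw")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(counts, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts_tsv(tsv)
  expect_equal(back$inclusion_reads, counts$inclusion_reads)
  filtered <- count_bin_evidence(back, m, "a")
  expect_equal(filtered$exclusion_reads, counts$exclusion_reads)
})
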
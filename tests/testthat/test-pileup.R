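test_that("counts match manual enumeration on a hand-built SAM", {
  # 10 fragments with 'C' over the SMN1 position, 5 with 'T' over the SMN2
  # position, all MAPQ 0 (no mapping-quality filter may be applied).
  recs <- do.call(rbind, c(
    lapply(1:10, function(i) sam_read(sprintf("c%02d", i), 100L, "C")),
    lapply(1:5, function(i) sam_read(sprintf("t%02d", i), 300L, "T"))))
  sam <- write_sam_fixture(recs)
  pc <- count_c840_reads(sam, fixture_sam_config())
  expect_equal(pc$n_c, 10L)
  expect_equal(pc$n_t, 5L)
  expect_equal(pc$n_other, 0L)
  expect_equal(pc$n_total, 15L)
  expect_equal(pc$per_locus$smn1$n_total, 10L)
  expect_equal(pc$per_locus$smn2$n_total, 5L)
  # per-locus counters sum to the combined counters
  for (f in c("n_total", "n_c", "n_t", "n_other"))
    expect_equal(pc$per_locus$smn1[[f]] + pc$per_locus$smn2[[f]], pc[[f]])
})

test_that("a file with no reads near either position yields all-zero counters", {
  recs <- sam_read("far", 500L, "G")
  sam <- write_sam_fixture(recs)
  pc <- count_c840_reads(sam, fixture_sam_config())
  expect_equal(pc$n_total, 0L)
  expect_equal(pc$n_c + pc$n_t + pc$n_other, 0L)
})

test_that("overlapping mates contribute one observation, from the higher-quality mate", {
  # both mates of fragment 'fragA' span the SMN1 position: 'C'@Q30, 'C'@Q20
  recs <- rbind(
    sam_read("fragA", 100L, "C", flag = 99L, qual_char = "?"),   # Q30
    sam_read("fragA", 100L, "C", flag = 147L, qual_char = "5",   # Q20
             start_offset = 10L))
  pc <- count_c840_reads(write_sam_fixture(recs), fixture_sam_config())
  expect_equal(pc$n_c, 1L)
  expect_equal(pc$n_total, 1L)

  # disagreeing mates: the higher-quality base wins
  recs2 <- rbind(
    sam_read("fragB", 100L, "T", flag = 99L, qual_char = "?"),   # Q30, T
    sam_read("fragB", 100L, "C", flag = 147L, qual_char = "5",   # Q20, C
             start_offset = 10L))
  pc2 <- count_c840_reads(write_sam_fixture(recs2), fixture_sam_config())
  expect_equal(pc2$n_t, 1L)
  expect_equal(pc2$n_c, 0L)
  expect_equal(pc2$n_total, 1L)
})

test_that("a CIGAR deletion spanning the position contributes no observation", {
  # alignment starts at 80; 10M10D31M places ref 90-99 in the deletion...
  # use start such that position 100 falls inside the D operation
  del <- data.frame(qname = "del1", flag = 0L, rname = "ctg", pos = 95L,
                    mapq = 0L, cigar = "3M10D38M",
                    seq = strrep("A", 41L), qual = strrep("?", 41L),
                    stringsAsFactors = FALSE)
  keep <- sam_read("ok1", 100L, "C")
  pc <- count_c840_reads(write_sam_fixture(rbind(del, keep)),
                         fixture_sam_config())
  expect_equal(pc$n_total, 1L)
  expect_equal(pc$n_c, 1L)
})

test_that("insertions and soft clips shift the query position correctly", {
  # 5S10M2I24M starting at ref 95: ref 95..104 from query 6..15, then 2I,
  # ref 105.. from query 18. Position 100 -> query index 11.
  seq <- strrep("A", 41L)
  substr(seq, 11L, 11L) <- "C"
  rec <- data.frame(qname = "ins1", flag = 0L, rname = "ctg", pos = 95L,
                    mapq = 0L, cigar = "5S10M2I24M", seq = seq,
                    qual = strrep("?", 41L), stringsAsFactors = FALSE)
  pc <- count_c840_reads(write_sam_fixture(rec), fixture_sam_config())
  expect_equal(pc$n_c, 1L)
  expect_equal(pc$n_total, 1L)
})

test_that("duplicate, secondary, supplementary, and QC-fail reads never count", {
  base <- sam_read("good", 100L, "C")
  flagged <- rbind(
    sam_read("dup", 100L, "C", flag = 1024L),
    sam_read("sec", 100L, "C", flag = 256L),
    sam_read("supp", 100L, "C", flag = 2048L),
    sam_read("qcfail", 100L, "C", flag = 512L))
  pc <- count_c840_reads(write_sam_fixture(rbind(base, flagged)),
                         fixture_sam_config())
  expect_equal(pc$n_total, 1L)
  expect_equal(pc$n_c, 1L)
})

test_that("base-quality filtering is applied at the pileup position only", {
  # read with Q12 at the position is excluded at the default threshold (13),
  # included when the threshold is lowered
  recs <- rbind(sam_read("hi", 100L, "C", qual_char = "?"),    # Q30
                sam_read("lo", 100L, "C", qual_char = "-"))    # Q12
  sam <- write_sam_fixture(recs)
  cfg <- fixture_sam_config()
  expect_equal(count_c840_reads(sam, cfg)$n_total, 1L)
  expect_equal(count_c840_reads(sam, cfg, min_base_quality = 0L)$n_total, 2L)
})

test_that("lowering the base-quality threshold never decreases n_total", {
  set.seed(42)
  quals <- c("?", "5", "-", ".", "I")  # Q30, Q20, Q12, Q13, Q40
  recs <- do.call(rbind, lapply(1:20, function(i)
    sam_read(sprintf("r%02d", i), sample(c(100L, 300L), 1),
             sample(c("C", "T", "G"), 1), qual_char = sample(quals, 1))))
  sam <- write_sam_fixture(recs)
  cfg <- fixture_sam_config()
  totals <- vapply(c(40L, 30L, 20L, 13L, 0L), function(q)
    count_c840_reads(sam, cfg, min_base_quality = q)$n_total, integer(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("counts are deterministic and invariant to record order", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:12, function(i)
    sam_read(sprintf("r%02d", i), sample(c(100L, 300L), 1),
             sample(c("C", "T", "A", "N"), 1))))
  sam1 <- write_sam_fixture(recs)
  sam2 <- write_sam_fixture(recs[sample(nrow(recs)), ])
  cfg <- fixture_sam_config()
  pc1 <- count_c840_reads(sam1, cfg)
  pc1_again <- count_c840_reads(sam1, cfg)
  pc2 <- count_c840_reads(sam2, cfg)
  for (f in c("n_total", "n_c", "n_t", "n_other")) {
    expect_equal(pc1[[f]], pc1_again[[f]])
    expect_equal(pc1[[f]], pc2[[f]])
  }
})

test_that("'N' base calls count toward n_other and n_total", {
  recs <- rbind(sam_read("n1", 100L, "N"), sam_read("c1", 100L, "C"))
  pc <- count_c840_reads(write_sam_fixture(recs), fixture_sam_config())
  expect_equal(pc$n_other, 1L)
  expect_equal(pc$n_total, 2L)
})

test_that("missing contigs and unreadable files raise informative errors", {
  recs <- sam_read("a", 100L, "C")
  sam <- write_sam_fixture(recs)
  badcfg <- locus_config("x", "chrX", 100L, 300L)
  expect_error(count_c840_reads(sam, badcfg), "not present")
  expect_error(count_c840_reads(tempfile(fileext = ".bam"),
                                fixture_sam_config()), "not found")
  corrupt <- tempfile(fileext = ".bam")
  writeLines("this is not a bam", corrupt)
  expect_error(count_c840_reads(corrupt, fixture_sam_config()))
})

test_that("sample_id falls back from read group to file name", {
  recs <- sam_read("a", 100L, "C")
  sam <- write_sam_fixture(recs)
  pc <- count_c840_reads(sam, fixture_sam_config())
  expect_equal(pc$sample_id, sub("\\.sam$", "", basename(sam)))
  pc2 <- count_c840_reads(sam, fixture_sam_config(), sample_id = "explicit")
  expect_equal(pc2$sample_id, "explicit")
})
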
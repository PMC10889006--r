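scan_reads <- function(bam) {
  param <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "seq",
                                            "mapq", "flag"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  list(qname = res$qname, rname = as.character(res$rname), pos = res$pos,
       seq = as.character(res$seq), mapq = res$mapq, flag = res$flag)
}

test_that("the mini-reference has two equal-length contigs differing at few sites", {
  ref <- fixture_mini_reference()
  contigs <- Biostrings::readDNAStringSet(ref$fasta)
  expect_equal(length(contigs), 2L)
  expect_equal(Biostrings::width(contigs)[[1L]], Biostrings::width(contigs)[[2L]])
  p1 <- strsplit(as.character(contigs[[1L]]), "")[[1L]]
  p2 <- strsplit(as.character(contigs[[2L]]), "")[[1L]]
  diffs <- which(p1 != p2)
  expect_lte(length(diffs), 4L)
  expect_true(ref$key_pos %in% diffs)
  # exactly one difference within a read length of the key site
  near <- diffs[abs(diffs - ref$key_pos) <= ref$read_length]
  expect_equal(near, ref$key_pos)
  expect_equal(p1[ref$key_pos], "C")
  expect_equal(p2[ref$key_pos], "T")
  # emitted config validates against the emitted FASTA by construction
  expect_true(validate_reference_bases(ref$config, ref$fasta)$pass)
  # and the on-disk config file round-trips to the same coordinates
  cfg <- load_locus_config("mini", source = ref$config_path)
  expect_equal(cfg$smn1_c840_pos, ref$config$smn1_c840_pos)
})

test_that("identical specs reproduce identical reads; the caller RNG is untouched", {
  ref <- fixture_mini_reference()
  spec <- sim_spec(1, 2, seed = 11)
  set.seed(999)
  before <- get(".Random.seed", envir = globalenv())
  a <- simulate_sample(spec, ref, tempfile())
  expect_identical(get(".Random.seed", envir = globalenv()), before)  # RNG restored
  b <- simulate_sample(spec, ref, tempfile())
  ra <- scan_reads(a$bam)
  rb <- scan_reads(b$bam)
  expect_identical(ra, rb)
  # a different seed gives different reads
  c <- simulate_sample(sim_spec(1, 2, seed = 12), ref, tempfile())
  expect_false(identical(scan_reads(c$bam)$pos, ra$pos))
})

test_that("key-site reads are MAPQ 0 and each fragment is counted exactly once", {
  ref <- fixture_mini_reference()
  out <- simulate_sample(sim_spec(2, 2, mean_depth_per_copy = 20, seed = 3),
                         ref, tempfile())
  reads <- scan_reads(out$bam)
  covers_key <- reads$pos <= ref$key_pos &
    reads$pos + ref$read_length - 1L >= ref$key_pos
  expect_true(any(covers_key))
  expect_true(all(reads$mapq[covers_key] == 0L))
  # conservation: qualifying pileup observations == distinct key fragments
  pc <- count_c840_reads(out$bam, ref$config, min_base_quality = 0L)
  expect_equal(pc$n_total, length(unique(reads$qname[covers_key])))
})

test_that("mate-overlap mode exercises the pileup deduplication path", {
  ref <- fixture_mini_reference()
  spec <- sim_spec(1, 1, mean_depth_per_copy = 10, seed = 5,
                   force_mate_overlap = TRUE)
  out <- simulate_sample(spec, ref, tempfile())
  reads <- scan_reads(out$bam)
  covers_key <- reads$pos <= ref$key_pos &
    reads$pos + ref$read_length - 1L >= ref$key_pos
  # every fragment has both mates over the key site...
  expect_equal(sum(covers_key), 2L * length(unique(reads$qname)))
  # ...yet contributes a single observation
  pc <- count_c840_reads(out$bam, ref$config)
  expect_equal(pc$n_total, length(unique(reads$qname)))
})

test_that("zero total copies yields a valid, empty alignment file", {
  ref <- fixture_mini_reference()
  out <- simulate_sample(sim_spec(0, 0, seed = 1), ref, tempfile())
  expect_true(file.exists(out$bam))
  pc <- count_c840_reads(out$bam, ref$config)
  expect_equal(pc$n_total, 0L)
  expect_equal(classify(pc)$status, "not_enough_reads")
})

test_that("the observed 'C' fraction tracks the copy-number ratio", {
  ref <- fixture_mini_reference()
  dir <- tempfile()
  # balanced configuration: pooled n_c/n_total over replicates near 1/2
  tot_c <- 0L; tot_n <- 0L
  for (s in 1:60) {
    out <- simulate_sample(sim_spec(2, 2, seed = s,
                                    sample_id = sprintf("bal%03d", s)),
                           ref, dir)
    pc <- count_c840_reads(out$bam, ref$config)
    tot_c <- tot_c + pc$n_c; tot_n <- tot_n + pc$n_total
  }
  # ~3 binomial SEs at the realized N (SE ~ 0.5/sqrt(N))
  expect_lt(abs(tot_c / tot_n - 0.5), 3 * 0.5 / sqrt(tot_n) + 0.005)

  # SMN1-deleted configuration: every 'C' is an injected miscall, so the
  # pooled fraction stays at error-rate scale
  tot_c <- 0L; tot_n <- 0L
  for (s in 1:60) {
    out <- simulate_sample(sim_spec(0, 2, seed = s,
                                    sample_id = sprintf("del%03d", s)),
                           ref, dir)
    pc <- count_c840_reads(out$bam, ref$config)
    tot_c <- tot_c + pc$n_c; tot_n <- tot_n + pc$n_total
  }
  expect_lt(tot_c / tot_n, 0.005)
})

test_that("parameter recovery holds across copy-number configurations", {
  ref <- fixture_mini_reference()
  dir <- tempfile()
  grid <- list(c(1, 1), c(1, 3), c(3, 1), c(2, 2))
  for (g in grid) {
    tot_c <- 0L; tot_n <- 0L
    for (s in 1:40) {
      out <- simulate_sample(
        sim_spec(g[1], g[2], seed = s,
                 sample_id = sprintf("g%d%d_%03d", g[1], g[2], s)),
        ref, dir)
      pc <- count_c840_reads(out$bam, ref$config)
      tot_c <- tot_c + pc$n_c; tot_n <- tot_n + pc$n_total
    }
    expected <- g[1] / sum(g)   # error adjustment is sub-SE at this scale
    se <- sqrt(expected * (1 - expected) / tot_n)
    expect_lt(abs(tot_c / tot_n - expected), 3 * se + 0.01)
  }
})

test_that("simulate_cohort writes one indexed BAM and one truth row per spec", {
  specs <- list(sim_spec(0, 2, seed = 1, sample_id = "s1"),
                sim_spec(2, 2, seed = 2, sample_id = "s2"),
                sim_spec(1, 1, mean_depth_per_copy = 2, seed = 3,
                         sample_id = "s3"))
  dir <- tempfile()
  cohort <- simulate_cohort(specs, dir)
  expect_equal(nrow(cohort$manifest), 3L)
  expect_equal(nrow(cohort$truth), 3L)
  expect_true(all(file.exists(cohort$manifest$bam)))
  expect_true(all(file.exists(paste0(cohort$manifest$bam, ".bai"))))
  truth_file <- utils::read.delim(cohort$truth_path, stringsAsFactors = FALSE)
  expect_equal(names(truth_file),
               c("sample_id", "smn1_copies", "smn2_copies", "expected_status"))
  expect_equal(truth_file$expected_status, c("positive", "negative", "negative"))

  # end-to-end: calls reproduce the truth labels wherever coverage allows
  for (i in seq_len(nrow(cohort$manifest))) {
    call <- call_sample(cohort$manifest$bam[[i]], cohort$reference$config)
    if (call$n >= 14L)
      expect_equal(call$status, cohort$truth$expected_status[[i]])
  }
})

test_that("duplicate sample ids are a manifest error", {
  specs <- list(sim_spec(0, 2, seed = 1, sample_id = "dup"),
                sim_spec(2, 2, seed = 2, sample_id = "dup"))
  expect_error(simulate_cohort(specs, tempfile()), "duplicate sample_id")
})

test_that("sim_spec validates its invariants", {
  expect_error(sim_spec(6, 2), "smn1_copies")
  expect_error(sim_spec(-1, 2))
  expect_error(sim_spec(2, 2, read_length = 30), "read_length")
  expect_error(sim_spec(2, 2, base_error_rate = 0.2), "base_error_rate")
})
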
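#' Build the simulator's mini-reference
#'
#' Writes a small FASTA emulating the SMN segmental duplication: two
#' equal-length (~2 kb) contigs, `paralog1` and `paralog2`, identical
#' except at one aligned key site ('C' in paralog1, 'T' in paralog2 —
#' the c.840 analogue) plus a few scattered paralog-distinguishing bases
#' placed outside the read window of the key site. Reads covering the
#' key site therefore carry no other distinguishing base, reproducing
#' the MAPQ-0 ambiguity seen at the real locus. A matching
#' [locus_config] is written alongside and is guaranteed to pass
#' [validate_reference_bases()].
#'
#' @param dir Output directory (created if needed).
#' @param contig_length Length of each contig (default 2000 bp).
#' @param key_pos Position of the discriminating site on both contigs
#'   (default 1000).
#' @param read_length Read length the reference must accommodate; the
#'   extra distinguishing bases are placed at least this far from
#'   `key_pos` (default 150).
#' @param n_extra_diffs Number of additional paralog-distinguishing
#'   bases (default 2; at most 3).
#' @param seed Seed for the random background sequence (default 101);
#'   the same seed always yields the same reference.
#' @return A list with elements `fasta`, `config`, `config_path`,
#'   `contig_length`, `key_pos`, `read_length`, and
#'   `extra_diff_positions`.
#' @export
build_mini_reference <- function(dir, contig_length = 2000L, key_pos = 1000L,
                                 read_length = 150L, n_extra_diffs = 2L,
                                 seed = 101L) {
  stopifnot(n_extra_diffs >= 0L, n_extra_diffs <= 3L,
            key_pos > read_length, key_pos + 2L * read_length < contig_length)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L)
    stop(sprintf("output directory '%s' is not writable", dir), call. = FALSE)

  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    background <- sample(bases, contig_length, replace = TRUE)
    p1 <- background
    p1[key_pos] <- "C"
    p2 <- p1
    p2[key_pos] <- "T"
    # distinguishing bases well clear of any read window touching key_pos
    lo <- key_pos + read_length + 10L
    hi <- contig_length - 10L
    extra <- if (n_extra_diffs > 0L)
      sort(sample(seq(lo, hi), n_extra_diffs)) else integer(0)
    for (p in extra)
      p2[p] <- sample(setdiff(bases, p1[p]), 1L)

    fasta <- file.path(dir, "mini_reference.fa")
    seqs <- Biostrings::DNAStringSet(c(paralog1 = paste(p1, collapse = ""),
                                       paralog2 = paste(p2, collapse = "")))
    Biostrings::writeXStringSet(seqs, fasta)
    Rsamtools::indexFa(fasta)

    config <- locus_config("mini", chromosome = "paralog1",
                           smn2_chromosome = "paralog2",
                           smn1_c840_pos = key_pos, smn2_c840_pos = key_pos)
    config_path <- file.path(dir, "mini_locus_config.txt")
    write_locus_config(config, config_path)

    list(fasta = fasta, config = config, config_path = config_path,
         contig_length = as.integer(contig_length),
         key_pos = as.integer(key_pos),
         read_length = as.integer(read_length),
         extra_diff_positions = extra)
  })
}

#' Specify one simulated sample
#'
#' Describes a sample by its (SMN1, SMN2) copy-number configuration and
#' sequencing parameters. Copy numbers 0-5 per paralog match the range
#' observed in human genomes. The expected truth status follows
#' deterministically: positive (SMA) iff `smn1_copies == 0`.
#'
#' @param smn1_copies Integer 0-5, copies of the 'C'-carrying paralog.
#' @param smn2_copies Integer 0-5, copies of the 'T'-carrying paralog.
#' @param mean_depth_per_copy Expected read observations at the key site
#'   per gene copy; total key-site fragment count is
#'   Poisson(`mean_depth_per_copy * (smn1_copies + smn2_copies)`).
#' @param read_length Read length in bases (default 150, Illumina-style).
#' @param base_error_rate Independent per-base miscall probability
#'   (default 0.005).
#' @param fragment_size_mean,fragment_size_sd Insert-size model for mate
#'   placement (defaults 400 / 50).
#' @param seed Random seed; identical specs reproduce identical reads.
#' @param sample_id Sample identifier; defaults to a name encoding the
#'   copy numbers and seed.
#' @param force_mate_overlap When `TRUE`, both mates of every fragment
#'   cover the key site (exercises the pileup's mate-overlap
#'   deduplication); by default at most one mate covers it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(smn1_copies, smn2_copies, mean_depth_per_copy = 15,
                     read_length = 150L, base_error_rate = 0.005,
                     fragment_size_mean = 400, fragment_size_sd = 50,
                     seed = 1L, sample_id = NULL,
                     force_mate_overlap = FALSE) {
  smn1_copies <- as.integer(smn1_copies)
  smn2_copies <- as.integer(smn2_copies)
  stopifnot(smn1_copies >= 0L, smn1_copies <= 5L,
            smn2_copies >= 0L, smn2_copies <= 5L,
            read_length >= 50L,
            base_error_rate >= 0, base_error_rate < 0.1,
            mean_depth_per_copy >= 0)
  if (is.null(sample_id))
    sample_id <- sprintf("sim_smn1.%d_smn2.%d_seed.%d",
                         smn1_copies, smn2_copies, as.integer(seed))
  structure(list(smn1_copies = smn1_copies, smn2_copies = smn2_copies,
                 mean_depth_per_copy = mean_depth_per_copy,
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 fragment_size_mean = fragment_size_mean,
                 fragment_size_sd = fragment_size_sd,
                 seed = as.integer(seed), sample_id = sample_id,
                 force_mate_overlap = isTRUE(force_mate_overlap)),
            class = "sim_spec")
}

#' Simulate one sample's aligned reads
#'
#' Draws paired-end fragments whose paralog of origin is categorical
#' with probabilities proportional to the copy numbers, injects
#' independent per-base miscalls, and writes a coordinate-sorted,
#' indexed BAM. Each read is assigned to the contig that best matches
#' its (post-error) sequence; reads whose window contains no
#' distinguishing base besides the key site get MAPQ 0, mirroring the
#' ambiguous mapping the real locus produces. Zero total copies yields
#' a valid BAM with no reads (whole-locus deletion), not an error.
#'
#' @param spec A [sim_spec].
#' @param reference The list returned by [build_mini_reference()].
#' @param dir Output directory for the BAM.
#' @return A list with `bam` (path) and `truth` (one-row data frame:
#'   `sample_id`, `smn1_copies`, `smn2_copies`, `expected_status`).
#' @export
simulate_sample <- function(spec, reference, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  contigs <- Biostrings::readDNAStringSet(reference$fasta)
  stopifnot(all(c("paralog1", "paralog2") %in% names(contigs)))
  p1 <- strsplit(as.character(contigs[["paralog1"]]), "")[[1L]]
  p2 <- strsplit(as.character(contigs[["paralog2"]]), "")[[1L]]
  diff_pos <- which(p1 != p2)
  key_pos <- reference$key_pos
  extra_diffs <- setdiff(diff_pos, key_pos)
  L <- length(p1)
  rl <- spec$read_length

  records <- .with_seed(spec$seed, {
    total <- spec$smn1_copies + spec$smn2_copies
    n_frag <- if (total == 0L) 0L
              else stats::rpois(1L, spec$mean_depth_per_copy * total)
    if (n_frag == 0L) character(0) else {
      origin <- sample(1:2, n_frag, replace = TRUE,
                       prob = c(spec$smn1_copies, spec$smn2_copies) / total)
      r1_start <- sample(seq(key_pos - rl + 1L, key_pos), n_frag, replace = TRUE)
      if (spec$force_mate_overlap) {
        r2_start <- r1_start
      } else {
        isize <- round(stats::rnorm(n_frag, spec$fragment_size_mean,
                                    spec$fragment_size_sd))
        r2_start <- r1_start + pmax(isize, 2L * rl) - rl
        r2_start <- pmin(pmax(r2_start, key_pos + 1L), L - rl + 1L)
      }
      out <- character(2L * n_frag)
      for (i in seq_len(n_frag)) {
        qname <- sprintf("%s_frag%06d", spec$sample_id, i)
        mates <- list(list(start = r1_start[[i]], flag = 99L),
                      list(start = r2_start[[i]], flag = 147L))
        fields <- lapply(mates, function(m) {
          src <- if (origin[[i]] == 1L) p1 else p2
          win <- seq(m$start, m$start + rl - 1L)
          seq_chars <- src[win]
          err <- which(stats::runif(rl) < spec$base_error_rate)
          for (e in err)
            seq_chars[e] <- sample(setdiff(c("A", "C", "G", "T"),
                                           seq_chars[e]), 1L)
          # assign to the contig the read sequence matches best
          in_win <- diff_pos[diff_pos >= m$start & diff_pos <= m$start + rl - 1L]
          d1 <- sum(seq_chars[in_win - m$start + 1L] != p1[in_win])
          d2 <- sum(seq_chars[in_win - m$start + 1L] != p2[in_win])
          contig <- if (d1 < d2) "paralog1"
                    else if (d2 < d1) "paralog2"
                    else c("paralog1", "paralog2")[origin[[i]]]
          has_informative <- any(extra_diffs >= m$start &
                                 extra_diffs <= m$start + rl - 1L)
          list(contig = contig, start = m$start,
               mapq = if (has_informative) 60L else 0L,
               seq = paste(seq_chars, collapse = ""))
        })
        for (j in 1:2) {
          f <- fields[[j]]
          o <- fields[[3L - j]]
          rnext <- if (identical(o$contig, f$contig)) "=" else o$contig
          tlen <- if (!identical(o$contig, f$contig)) 0L
                  else if (j == 1L) (o$start + rl - 1L) - f$start + 1L
                  else -((f$start + rl - 1L) - o$start + 1L)
          out[2L * (i - 1L) + j] <- paste(
            qname, mates[[j]]$flag, f$contig, f$start, f$mapq,
            paste0(rl, "M"), rnext, o$start, tlen, f$seq,
            strrep("?", rl), "RG:Z:sim", sep = "\t")
        }
      }
      out
    }
  })

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      Biostrings::width(contigs)),
              sprintf("@RG\tID:sim\tSM:%s", spec$sample_id))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, records), sam)
  dest <- file.path(dir, spec$sample_id)
  tmp <- Rsamtools::asBam(sam, destination = paste0(dest, "_unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp, destination = dest)
  unlink(c(sam, tmp))
  bam <- paste0(dest, ".bam")
  Rsamtools::indexBam(bam)

  truth <- data.frame(
    sample_id = spec$sample_id,
    smn1_copies = spec$smn1_copies,
    smn2_copies = spec$smn2_copies,
    expected_status = if (spec$smn1_copies == 0L) "positive" else "negative",
    stringsAsFactors = FALSE)
  list(bam = bam, truth = truth)
}

#' Simulate a cohort of samples
#'
#' Runs [simulate_sample()] for each spec and writes a tab-separated
#' truth table (`truth.tsv`: sample_id, smn1_copies, smn2_copies,
#' expected_status) alongside the BAMs.
#'
#' @param specs Non-empty list of [sim_spec] objects with unique
#'   `sample_id`s.
#' @param dir Output directory.
#' @param reference Optional pre-built mini-reference; built in `dir`
#'   when omitted.
#' @return A list with `manifest` (data frame: sample_id, bam),
#'   `truth` (data frame), `truth_path`, and `reference`.
#' @export
simulate_cohort <- function(specs, dir, reference = NULL) {
  stopifnot(length(specs) > 0L)
  ids <- vapply(specs, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample_id in cohort specs: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(reference))
    reference <- build_mini_reference(file.path(dir, "reference"))
  out <- lapply(specs, simulate_sample, reference = reference, dir = dir)
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- data.frame(sample_id = ids,
                         bam = vapply(out, `[[`, character(1), "bam"),
                         stringsAsFactors = FALSE)
  list(manifest = manifest, truth = truth, truth_path = truth_path,
       reference = reference)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
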
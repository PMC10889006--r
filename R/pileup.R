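#' Count c.840 base observations in one alignment file
#'
#' Extracts the reads overlapping the configured *SMN1* and *SMN2*
#' c.840 positions and tallies the base each read carries there. The
#' combined totals are the method's two statistics: `n_total` (N), the
#' number of qualifying base observations over both positions, and
#' `n_c` (r), the subset of those observations that read 'C' — the
#' *SMN1*-defining base.
#'
#' Filtering rules:
#' \itemize{
#'   \item Duplicate-flagged, secondary, supplementary, unmapped and
#'     QC-fail records are excluded.
#'   \item No mapping-quality filter is applied: reads in this segmental
#'     duplication map ambiguously and typically carry MAPQ 0, so any
#'     MAPQ cutoff would discard essentially all of the signal.
#'   \item The base call at the pileup position must have base quality
#'     \eqn{\ge} `min_base_quality` (default 13, ~5\% error ceiling).
#'   \item When both mates of a fragment cover the same position, the
#'     fragment contributes one observation, taken from the mate with
#'     the higher base quality there (ties: first encountered).
#'     Overlapping mates are one molecule, not independent evidence.
#'   \item Reads whose CIGAR places a deletion or reference skip across
#'     the position contribute nothing — there is no base observation.
#'   \item 'N' and other non-C/T base calls count in `n_other` and hence
#'     in `n_total`.
#' }
#'
#' @param alignments Path to a coordinate-sorted BAM (indexed; an index
#'   is created if missing), SAM (converted on the fly), or CRAM
#'   (requires `reference`; converted via samtools).
#' @param config A [locus_config] for the build the file is aligned to.
#' @param min_base_quality Minimum base quality at the pileup position
#'   (default 13).
#' @param reference Reference FASTA path; required for CRAM input.
#' @param sample_id Optional override; defaults to the read-group `SM`
#'   tag, or the file name when no read group is present.
#' @return An object of class `smn_pileup` with the combined counters
#'   (`n_total`, `n_c`, `n_t`, `n_other`) and a `per_locus` breakdown.
#' @export
count_c840_reads <- function(alignments, config, min_base_quality = 13L,
                             reference = NULL, sample_id = NULL) {
  stopifnot(inherits(config, "locus_config"))
  bam <- .as_indexed_bam(alignments, reference)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  targets <- hdr$targets

  .warn_if_alt_contigs(names(targets), alignments)

  loci <- list(
    smn1 = list(chrom = config$chromosome, pos = config$smn1_c840_pos),
    smn2 = list(chrom = config$smn2_chromosome, pos = config$smn2_c840_pos))

  per_locus <- lapply(loci, function(locus) {
    contig <- .resolve_contig(locus$chrom, names(targets))
    if (is.na(contig))
      stop(sprintf("contig '%s' (or 'chr%s') not present in alignment header of '%s'",
                   locus$chrom, locus$chrom, alignments), call. = FALSE)
    obs <- .pileup_observations(bam, contig, locus$pos)
    obs <- obs[obs$qual >= min_base_quality, , drop = FALSE]
    obs <- .dedup_mate_overlap(obs)
    .count_bases(obs)
  })

  combined <- list(
    n_total = per_locus$smn1$n_total + per_locus$smn2$n_total,
    n_c = per_locus$smn1$n_c + per_locus$smn2$n_c,
    n_t = per_locus$smn1$n_t + per_locus$smn2$n_t,
    n_other = per_locus$smn1$n_other + per_locus$smn2$n_other)

  if (is.null(sample_id))
    sample_id <- .sample_id_from_header(hdr, alignments)

  structure(c(list(sample_id = sample_id), combined,
              list(per_locus = per_locus,
                   min_base_quality = as.integer(min_base_quality))),
            class = "smn_pileup")
}

#' @export
print.smn_pileup <- function(x, ...) {
  cat(sprintf("c.840 pileup for sample '%s'\n", x$sample_id))
  cat(sprintf("  N (total) = %d, r (base C) = %d, T = %d, other = %d\n",
              x$n_total, x$n_c, x$n_t, x$n_other))
  cat(sprintf("  SMN1 locus: N = %d (C=%d T=%d other=%d)\n",
              x$per_locus$smn1$n_total, x$per_locus$smn1$n_c,
              x$per_locus$smn1$n_t, x$per_locus$smn1$n_other))
  cat(sprintf("  SMN2 locus: N = %d (C=%d T=%d other=%d)\n",
              x$per_locus$smn2$n_total, x$per_locus$smn2$n_c,
              x$per_locus$smn2$n_t, x$per_locus$smn2$n_other))
  invisible(x)
}

# Normalize SAM/BAM/CRAM input to an indexed BAM path. SAM is converted in
# the session temp dir (cached per input path); CRAM goes through samtools
# with the supplied reference.
.as_indexed_bam <- function(alignments, reference = NULL) {
  if (!file.exists(alignments))
    stop(sprintf("alignment file not found: '%s'", alignments), call. = FALSE)
  ext <- tolower(tools::file_ext(alignments))
  if (ext == "sam") {
    dest <- file.path(tempdir(), paste0(
      "smacaller_", substr(.digest_path(alignments), 1, 12)))
    bam <- paste0(dest, ".bam")
    if (!file.exists(bam) ||
        file.mtime(bam) < file.mtime(alignments)) {
      tmp <- Rsamtools::asBam(alignments, destination = paste0(dest, "_u"),
                              overwrite = TRUE, indexDestination = FALSE)
      Rsamtools::sortBam(tmp, destination = dest)
      unlink(tmp)
      Rsamtools::indexBam(bam)
    }
    return(bam)
  }
  if (ext == "cram") {
    if (is.null(reference))
      stop("CRAM input requires a reference FASTA (reference = ...)", call. = FALSE)
    samtools <- Sys.which("samtools")
    if (!nzchar(samtools))
      stop("CRAM input requires the 'samtools' executable on PATH", call. = FALSE)
    bam <- file.path(tempdir(), paste0(
      "smacaller_", substr(.digest_path(alignments), 1, 12), ".bam"))
    if (!file.exists(bam)) {
      status <- system2(samtools, c("view", "-b", "-T", shQuote(reference),
                                    "-o", shQuote(bam), shQuote(alignments)))
      if (status != 0L || !file.exists(bam))
        stop(sprintf("failed to convert CRAM '%s' to BAM", alignments), call. = FALSE)
      Rsamtools::indexBam(bam)
    }
    return(bam)
  }
  if (!file.exists(paste0(alignments, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", alignments)))
    Rsamtools::indexBam(alignments)
  alignments
}

.digest_path <- function(path) {
  # cheap stable key for temp-file caching; not cryptographic
  gsub("[^A-Za-z0-9]", "_",
       paste0(basename(path), "_", format(file.size(path))))
}

.warn_if_alt_contigs <- function(contigs, file) {
  alt <- grepl("^(chr)?5_.*_alt$", contigs, ignore.case = TRUE)
  if (any(alt))
    warning(sprintf(paste0(
      "'%s' header contains chromosome 5 ALT contigs (%s); these may carry ",
      "extra SMN1/SMN2 copies. Only primary-assembly positions are counted; ",
      "ensure the aligner was ALT-aware so primary alignments stay on chr5."),
      basename(file), paste(contigs[alt], collapse = ", ")),
      call. = FALSE)
  invisible(NULL)
}

.sample_id_from_header <- function(hdr, file) {
  rg <- hdr$text[names(hdr$text) == "@RG"]
  for (fields in rg) {
    sm <- fields[startsWith(fields, "SM:")]
    if (length(sm) > 0L) return(sub("^SM:", "", sm[[1L]]))
  }
  sub("\\.(bam|sam|cram)$", "", basename(file), ignore.case = TRUE)
}

# One row per primary, non-duplicate, QC-pass read whose alignment places a
# base (not a deletion/skip) on `pos`: qname, base, qual.
.pileup_observations <- function(bam, contig, pos) {
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE,
      isNotPassingQualityControls = FALSE))
  res <- tryCatch(
    Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)[[1L]],
    error = function(e) stop(sprintf("failed to read '%s': %s",
                                     bam, conditionMessage(e)), call. = FALSE))
  n <- length(res$qname)
  if (n == 0L)
    return(data.frame(qname = character(0), base = character(0),
                      qual = integer(0), stringsAsFactors = FALSE))
  seqs <- as.character(res$seq)
  quals <- as(res$qual, "IntegerList")
  qpos <- vapply(seq_len(n), function(i)
    .query_position(res$cigar[[i]], res$pos[[i]], pos), integer(1))
  keep <- !is.na(qpos)
  data.frame(
    qname = res$qname[keep],
    base = toupper(substr(seqs[keep], qpos[keep], qpos[keep])),
    qual = vapply(which(keep), function(i) quals[[i]][qpos[[i]]], integer(1)),
    stringsAsFactors = FALSE)
}

# Map a 1-based reference coordinate onto the read's query coordinates by
# walking the CIGAR. Returns NA when the position falls in a deletion or
# reference skip, or outside the aligned span.
.query_position <- function(cigar, aln_start, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  ref_at <- aln_start   # next reference base to be consumed
  query_at <- 1L        # next query base to be consumed
  for (op in ops) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", op))
    code <- substr(op, nchar(op), nchar(op))
    if (code %in% c("M", "=", "X")) {
      if (target < ref_at + len)
        return(if (target >= ref_at) query_at + (target - ref_at) else NA_integer_)
      ref_at <- ref_at + len
      query_at <- query_at + len
    } else if (code %in% c("I", "S")) {
      query_at <- query_at + len
    } else if (code %in% c("D", "N")) {
      if (target >= ref_at && target < ref_at + len) return(NA_integer_)
      ref_at <- ref_at + len
    }
    # H and P consume neither
  }
  NA_integer_
}

# Collapse overlapping mates: one observation per fragment (qname), keeping
# the base seen with the higher base quality; ties keep the first record.
.dedup_mate_overlap <- function(obs) {
  if (nrow(obs) <= 1L) return(obs)
  ord <- order(match(obs$qname, obs$qname), -obs$qual)
  obs <- obs[ord, , drop = FALSE]
  obs[!duplicated(obs$qname), , drop = FALSE]
}

.count_bases <- function(obs) {
  list(n_total = nrow(obs),
       n_c = sum(obs$base == "C"),
       n_t = sum(obs$base == "T"),
       n_other = sum(!obs$base %in% c("C", "T")))
}
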
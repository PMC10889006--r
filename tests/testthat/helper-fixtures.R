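# Shared fixtures, built in code at test time.

# One mini-reference per test run, cached in the testthat process.
.fixture_env <- new.env(parent = emptyenv())

fixture_mini_reference <- function() {
  if (is.null(.fixture_env$ref)) {
    dir <- file.path(tempdir(), "smacaller-miniref")
    .fixture_env$ref <- build_mini_reference(dir)
  }
  .fixture_env$ref
}

# Hand-built SAM fixtures for the pileup tests. `records` is a data frame
# with columns qname, flag, rname, pos, mapq, cigar, seq, qual (qual as a
# phred string). Contigs default to one 600 bp contig "ctg".
write_sam_fixture <- function(records,
                              contigs = c(ctg = 600L),
                              path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
          "*", 0, 0, r$seq, r$qual, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A read record whose aligned span covers `cover_pos` with base `base`.
# Alignment starts 20 bp before the covered position; read length 41.
sam_read <- function(qname, cover_pos, base, flag = 0L, mapq = 0L,
                     qual_char = "?", cigar = NULL, start_offset = 20L) {
  pos <- cover_pos - start_offset
  len <- 41L
  seq <- strrep("A", len)
  substr(seq, start_offset + 1L, start_offset + 1L) <- base
  data.frame(qname = qname, flag = flag, rname = "ctg", pos = pos,
             mapq = mapq,
             cigar = if (is.null(cigar)) paste0(len, "M") else cigar,
             seq = seq, qual = strrep(qual_char, len),
             stringsAsFactors = FALSE)
}

# Config matching the single-contig SAM fixtures: "SMN1" position at 100,
# "SMN2" position at 300 on the same contig.
fixture_sam_config <- function() {
  locus_config("samfix", chromosome = "ctg",
               smn1_c840_pos = 100L, smn2_c840_pos = 300L)
}

# Independent Fisher oracle: exhaustive enumeration of the hypergeometric
# support with plain choose() arithmetic (no dhyper, no log space).
fisher_bruteforce <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0L, c1 - r2):min(c1, r1)
  probs <- vapply(support, function(k)
    choose(r1, k) * choose(r2, c1 - k), numeric(1)) / choose(r1 + r2, c1)
  pobs <- probs[support == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Independent log-likelihood-ratio oracle via binomial densities.
llr10_oracle <- function(r, n, eps = 0.005, theta = 0.25) {
  log10(dbinom(r, n, eps)) - log10(dbinom(r, n, theta))
}
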
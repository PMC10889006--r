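#' Locus configuration for the SMN1/SMN2 c.840 position
#'
#' A `locus_config` records, for one reference build, where the c.840
#' position of *SMN1* and *SMN2* sits and which base each paralog is
#' expected to carry there. The two paralogs are ~99.9% identical; the
#' c.840 site is the discriminating base: 'C' in *SMN1* (proper exon 7
#' splicing) and 'T' in *SMN2* (exon 7 skipping). All downstream read
#' counting keys off these two coordinates.
#'
#' Coordinates are 1-based, consistent with VCF/HGVS convention.
#' Chromosome names are stored without a dialect prefix (i.e. `"5"`, not
#' `"chr5"`); the `"chr"` prefix is resolved against each alignment file
#' or FASTA at run time, in either direction.
#'
#' @param build_name Identifier for the reference build (e.g. `"GRCh38"`,
#'   or a user-defined name such as the simulator's mini-reference).
#' @param chromosome Contig holding the *SMN1* c.840 position, dialect-free.
#' @param smn1_c840_pos 1-based coordinate of c.840 in *SMN1*.
#' @param smn2_c840_pos 1-based coordinate of c.840 in *SMN2*.
#' @param smn1_base Expected reference base at the *SMN1* position; must
#'   be `"C"`.
#' @param smn2_base Expected reference base at the *SMN2* position; must
#'   be `"T"`.
#' @param smn2_chromosome Contig holding the *SMN2* position. Defaults to
#'   `chromosome`; the human builds keep both paralogs on chromosome 5,
#'   but the simulator's mini-reference places them on separate contigs.
#' @return An object of class `locus_config`.
#' @examples
#' locus_config("GRCh38", "5", 70951946, 70076526)
#' @export
locus_config <- function(build_name, chromosome, smn1_c840_pos, smn2_c840_pos,
                         smn1_base = "C", smn2_base = "T",
                         smn2_chromosome = chromosome) {
  stopifnot(is.character(build_name), length(build_name) == 1L, nzchar(build_name))
  stopifnot(is.character(chromosome), length(chromosome) == 1L, nzchar(chromosome))
  stopifnot(is.character(smn2_chromosome), length(smn2_chromosome) == 1L)
  smn1_c840_pos <- as.integer(smn1_c840_pos)
  smn2_c840_pos <- as.integer(smn2_c840_pos)
  if (is.na(smn1_c840_pos) || smn1_c840_pos < 1L)
    stop("smn1_c840_pos must be a positive integer", call. = FALSE)
  if (is.na(smn2_c840_pos) || smn2_c840_pos < 1L)
    stop("smn2_c840_pos must be a positive integer", call. = FALSE)
  smn1_base <- toupper(smn1_base)
  smn2_base <- toupper(smn2_base)
  if (!identical(smn1_base, "C"))
    stop("smn1_base must be 'C' (the SMN1-defining base at c.840)", call. = FALSE)
  if (!identical(smn2_base, "T"))
    stop("smn2_base must be 'T' (the SMN2-defining base at c.840)", call. = FALSE)
  if (identical(chromosome, smn2_chromosome) &&
      smn1_c840_pos == smn2_c840_pos)
    stop("the SMN1 and SMN2 positions must differ when on the same chromosome",
         call. = FALSE)
  structure(
    list(build_name = build_name,
         chromosome = chromosome,
         smn2_chromosome = smn2_chromosome,
         smn1_c840_pos = smn1_c840_pos,
         smn2_c840_pos = smn2_c840_pos,
         smn1_base = smn1_base,
         smn2_base = smn2_base),
    class = "locus_config")
}

#' @export
print.locus_config <- function(x, ...) {
  cat("SMN c.840 locus configuration [", x$build_name, "]\n", sep = "")
  cat(sprintf("  SMN1: %s:%d  expected base %s\n",
              x$chromosome, x$smn1_c840_pos, x$smn1_base))
  cat(sprintf("  SMN2: %s:%d  expected base %s\n",
              x$smn2_chromosome, x$smn2_c840_pos, x$smn2_base))
  invisible(x)
}

# Built-in c.840 coordinates. Both are 1-based primary-assembly chromosome 5
# positions and are expected to read 'C' (SMN1) / 'T' (SMN2); run
# validate_reference_bases() against your FASTA to confirm before production
# use. T2T-CHM13 is supported through derive_locus_config(), which locates
# the site by exact flank matching and validates the bases, so no unverified
# coordinate is shipped for that build.
.builtin_locus_registry <- function() {
  list(
    GRCh37 = locus_config("GRCh37", "5", 70247773L, 69372353L),
    GRCh38 = locus_config("GRCh38", "5", 70951946L, 70076526L)
  )
}

#' Load a locus configuration by build name
#'
#' Resolves `build_name` either against the built-in registry (GRCh37,
#' GRCh38) or against a user-supplied configuration file. T2T-CHM13 and
#' other builds without bundled coordinates can be derived once from a
#' known build with [derive_locus_config()] and saved with
#' [write_locus_config()].
#'
#' @param build_name Build identifier to look up.
#' @param source Optional path to a configuration file written in the
#'   block key-value format produced by [write_locus_config()]. When
#'   `NULL`, the built-in registry is used.
#' @return A [locus_config] object.
#' @export
load_locus_config <- function(build_name, source = NULL) {
  if (is.null(source)) {
    registry <- .builtin_locus_registry()
    if (!build_name %in% names(registry)) {
      extra <- if (identical(build_name, "T2T-CHM13"))
        " T2T-CHM13 coordinates are not bundled; derive them once with derive_locus_config() using a GRCh38 and a T2T-CHM13 FASTA."
      else ""
      stop(sprintf("unknown build '%s'; available built-in builds: %s.%s",
                   build_name, paste(names(registry), collapse = ", "), extra),
           call. = FALSE)
    }
    return(registry[[build_name]])
  }
  configs <- read_locus_config_file(source)
  if (!build_name %in% names(configs))
    stop(sprintf("build '%s' not found in '%s'; available: %s",
                 build_name, source, paste(names(configs), collapse = ", ")),
         call. = FALSE)
  configs[[build_name]]
}

#' Read a locus-configuration file
#'
#' The file format is flat key-value text, one build per block:
#' \preformatted{
#' [GRCh38]
#' chromosome = 5
#' smn1_c840_pos = 70951946
#' smn2_c840_pos = 70076526
#' smn1_base = C
#' smn2_base = T
#' }
#' `smn2_chromosome` may be given when the paralogs sit on different
#' contigs (the simulator's mini-reference does this). Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the configuration file.
#' @return Named list of [locus_config] objects, one per block.
#' @export
read_locus_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("locus config file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  block <- NULL
  fields <- list()
  flush_block <- function(block, fields, lineno) {
    required <- c("chromosome", "smn1_c840_pos", "smn2_c840_pos")
    missing <- setdiff(required, names(fields))
    if (length(missing) > 0L)
      stop(sprintf("config parse error near line %d: block [%s] is missing field(s): %s",
                   lineno, block, paste(missing, collapse = ", ")), call. = FALSE)
    locus_config(
      build_name = block,
      chromosome = fields$chromosome,
      smn2_chromosome = if (is.null(fields$smn2_chromosome)) fields$chromosome
                        else fields$smn2_chromosome,
      smn1_c840_pos = suppressWarnings(as.integer(fields$smn1_c840_pos)),
      smn2_c840_pos = suppressWarnings(as.integer(fields$smn2_c840_pos)),
      smn1_base = if (is.null(fields$smn1_base)) "C" else fields$smn1_base,
      smn2_base = if (is.null(fields$smn2_base)) "T" else fields$smn2_base)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^\\[.+\\]$", line)) {
      if (!is.null(block)) configs[[block]] <- flush_block(block, fields, i)
      block <- sub("^\\[(.+)\\]$", "\\1", line)
      fields <- list()
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(block))
        stop(sprintf("config parse error at line %d: key-value pair before any [build] header", i),
             call. = FALSE)
      key <- trimws(sub("=.*$", "", line))
      value <- trimws(sub("^[^=]*=", "", line))
      fields[[key]] <- value
    } else {
      stop(sprintf("config parse error at line %d: expected '[build]' or 'key = value', got '%s'",
                   i, line), call. = FALSE)
    }
  }
  if (!is.null(block)) configs[[block]] <- flush_block(block, fields, length(lines))
  if (length(configs) == 0L)
    stop(sprintf("config parse error: no [build] blocks found in '%s'", path),
         call. = FALSE)
  configs
}

#' Write locus configurations to a file
#'
#' @param config A [locus_config] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(config, path) {
  if (inherits(config, "locus_config")) config <- list(config)
  lines <- character(0)
  for (cfg in config) {
    lines <- c(lines,
               sprintf("[%s]", cfg$build_name),
               sprintf("chromosome = %s", cfg$chromosome))
    if (!identical(cfg$smn2_chromosome, cfg$chromosome))
      lines <- c(lines, sprintf("smn2_chromosome = %s", cfg$smn2_chromosome))
    lines <- c(lines,
               sprintf("smn1_c840_pos = %d", cfg$smn1_c840_pos),
               sprintf("smn2_c840_pos = %d", cfg$smn2_c840_pos),
               sprintf("smn1_base = %s", cfg$smn1_base),
               sprintf("smn2_base = %s", cfg$smn2_base),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

# Resolve a dialect-free contig name against the names present in a file
# header: "5" matches "5" or "chr5" and vice versa. Returns NA when absent.
.resolve_contig <- function(name, available) {
  candidates <- unique(c(name,
                         paste0("chr", name),
                         sub("^chr", "", name)))
  hit <- candidates[candidates %in% available]
  if (length(hit) == 0L) NA_character_ else hit[[1L]]
}

.open_fa <- function(reference) {
  if (inherits(reference, "FaFile")) return(reference)
  if (!file.exists(reference))
    stop(sprintf("reference FASTA not found: '%s'", reference), call. = FALSE)
  if (!file.exists(paste0(reference, ".fai")))
    Rsamtools::indexFa(reference)
  Rsamtools::FaFile(reference)
}

#' Validate configured c.840 bases against a reference FASTA
#'
#' Reads the single base at each configured coordinate and checks that
#' the *SMN1* position carries 'C' and the *SMN2* position carries 'T'
#' (case-insensitive). This is the ground-truth check for any
#' coordinate set — bundled, user-supplied, or flank-derived — and should
#' be run once per reference FASTA before calling samples aligned to it.
#'
#' @param config A [locus_config].
#' @param reference Path to an indexed FASTA (a `.fai` index is created
#'   if missing) or an open `Rsamtools::FaFile`.
#' @return An object of class `smn_reference_validation` with elements
#'   `pass` (logical), and a `loci` data frame listing each position with
#'   its expected and observed base.
#' @export
validate_reference_bases <- function(config, reference) {
  stopifnot(inherits(config, "locus_config"))
  fa <- .open_fa(reference)
  info <- Rsamtools::scanFaIndex(fa)
  available <- as.character(GenomicRanges::seqnames(info))
  lens <- stats::setNames(GenomicRanges::width(info), available)

  fetch_base <- function(chrom, pos, label) {
    contig <- .resolve_contig(chrom, available)
    if (is.na(contig))
      stop(sprintf("contig '%s' (or 'chr%s') not found in reference; available contigs include: %s",
                   chrom, chrom,
                   paste(utils::head(available, 5), collapse = ", ")),
           call. = FALSE)
    if (pos > lens[[contig]])
      stop(sprintf("%s position %d exceeds length of contig '%s' (%d bp)",
                   label, pos, contig, lens[[contig]]), call. = FALSE)
    rng <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
    toupper(as.character(Rsamtools::scanFa(fa, rng)[[1L]]))
  }

  smn1_obs <- fetch_base(config$chromosome, config$smn1_c840_pos, "SMN1")
  smn2_obs <- fetch_base(config$smn2_chromosome, config$smn2_c840_pos, "SMN2")
  loci <- data.frame(
    locus = c("SMN1", "SMN2"),
    chromosome = c(config$chromosome, config$smn2_chromosome),
    position = c(config$smn1_c840_pos, config$smn2_c840_pos),
    expected = c(config$smn1_base, config$smn2_base),
    observed = c(smn1_obs, smn2_obs),
    stringsAsFactors = FALSE)
  loci$ok <- loci$expected == loci$observed
  structure(list(build_name = config$build_name,
                 pass = all(loci$ok),
                 loci = loci),
            class = "smn_reference_validation")
}

#' @export
print.smn_reference_validation <- function(x, ...) {
  cat(sprintf("Reference-base validation [%s]: %s\n",
              x$build_name, if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$loci))) {
    row <- x$loci[i, ]
    cat(sprintf("  %s %s:%d expected %s observed %s %s\n",
                row$locus, row$chromosome, row$position,
                row$expected, row$observed,
                if (row$ok) "" else "<-- mismatch"))
  }
  invisible(x)
}

#' Derive c.840 coordinates for a new build by flank matching
#'
#' Lifts the two c.840 coordinates from a known build onto another
#' reference (typically T2T-CHM13) without any liftover chain: a
#' `2*flank + 1` bp window centred on each configured position is
#' extracted from the source FASTA and located as a unique exact match
#' in the target FASTA. The derived configuration is then confirmed with
#' [validate_reference_bases()], which catches any off-by-one.
#'
#' @param build_name Name for the derived build (e.g. `"T2T-CHM13"`).
#' @param source_config [locus_config] for the known build.
#' @param source_fasta Indexed FASTA matching `source_config`.
#' @param target_fasta Indexed FASTA for the new build.
#' @param flank Flank length either side of the site (default 30 bp).
#' @return A validated [locus_config] for the target build.
#' @export
derive_locus_config <- function(build_name, source_config, source_fasta,
                                target_fasta, flank = 30L) {
  stopifnot(inherits(source_config, "locus_config"), flank >= 10L)
  src <- .open_fa(source_fasta)
  tgt <- .open_fa(target_fasta)
  src_info <- Rsamtools::scanFaIndex(src)
  src_names <- as.character(GenomicRanges::seqnames(src_info))
  tgt_seqs <- Rsamtools::scanFa(tgt)

  locate <- function(chrom, pos, label) {
    contig <- .resolve_contig(chrom, src_names)
    if (is.na(contig))
      stop(sprintf("contig '%s' not found in source reference", chrom), call. = FALSE)
    rng <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(pos - flank, pos + flank))
    probe <- Rsamtools::scanFa(src, rng)[[1L]]
    # prefer the corresponding target contig; fall back to a genome-wide scan
    tgt_contig <- .resolve_contig(chrom, names(tgt_seqs))
    search_set <- if (!is.na(tgt_contig)) tgt_seqs[tgt_contig] else tgt_seqs
    hits <- Biostrings::vmatchPattern(probe, search_set)
    n_hits <- sum(S4Vectors::elementNROWS(hits))
    if (n_hits != 1L)
      stop(sprintf("%s flank (%d bp around %s:%d) has %d exact matches in target; need exactly 1",
                   label, 2L * flank + 1L, chrom, pos, n_hits), call. = FALSE)
    idx <- which(S4Vectors::elementNROWS(hits) == 1L)
    list(chromosome = sub("^chr", "", names(search_set)[idx]),
         position = BiocGenerics::start(hits[[idx]]) + flank)
  }

  smn1 <- locate(source_config$chromosome, source_config$smn1_c840_pos, "SMN1")
  smn2 <- locate(source_config$smn2_chromosome, source_config$smn2_c840_pos, "SMN2")
  derived <- locus_config(build_name,
                          chromosome = smn1$chromosome,
                          smn2_chromosome = smn2$chromosome,
                          smn1_c840_pos = smn1$position,
                          smn2_c840_pos = smn2$position)
  check <- validate_reference_bases(derived, tgt)
  if (!check$pass)
    stop(paste0("derived coordinates failed the C/T base check:\n",
                paste(utils::capture.output(print(check)), collapse = "\n")),
         call. = FALSE)
  derived
}
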
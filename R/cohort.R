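#' Run the caller over a cohort of alignment files
#'
#' Calls each input file in order and writes a tab-separated results
#' table with one row per input. Per-sample failures never abort the
#' batch: a failing sample gets `sma_status` `"error"` with the reason
#' in the `error` column, so cohort-scale runs are fault-tolerant.
#'
#' Output columns (exactly, tab-delimited):
#' `sample_id`, `file`, `genome_version`, `sma_status`,
#' `confidence_score`, `c840_reads_with_smn1_base_C`,
#' `c840_total_reads`, `error`. Status values are self-documenting:
#' `"has_sma"`, `"does_not_have_sma"`, `"not_enough_reads"`, `"error"`.
#'
#' @param inputs Character vector of alignment file paths (>= 1).
#' @param config A [locus_config]; its `build_name` is reported in the
#'   `genome_version` column.
#' @param params A [caller_params].
#' @param output Path for the results TSV, or `NULL` to skip writing.
#' @param reference Reference FASTA (required for CRAM inputs).
#' @param min_base_quality Passed to [count_c840_reads()].
#' @param verbose Log per-sample progress to stderr.
#' @return An object of class `sma_cohort`: the results data frame plus
#'   summary counts (`n_positive`, `n_negative`, `n_nocall`, `n_error`).
#'   `success` is `TRUE` iff no sample errored.
#' @export
run_cohort <- function(inputs, config, params = caller_params(),
                       output = NULL, reference = NULL,
                       min_base_quality = 13L, verbose = FALSE) {
  if (length(inputs) < 1L)
    stop("run_cohort needs at least one input alignment file", call. = FALSE)
  stopifnot(inherits(config, "locus_config"))

  status_label <- c(positive = "has_sma",
                    negative = "does_not_have_sma",
                    not_enough_reads = "not_enough_reads")

  rows <- lapply(seq_along(inputs), function(i) {
    path <- inputs[[i]]
    if (verbose)
      message(sprintf("[%d/%d] %s", i, length(inputs), path))
    tryCatch({
      call <- call_sample(path, config, params,
                          min_base_quality = min_base_quality,
                          reference = reference)
      data.frame(sample_id = call$sample_id,
                 file = path,
                 genome_version = config$build_name,
                 sma_status = unname(status_label[[call$status]]),
                 confidence_score = sprintf("%.1f", call$confidence),
                 c840_reads_with_smn1_base_C = call$r,
                 c840_total_reads = call$n,
                 error = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      if (verbose)
        message(sprintf("  sample failed: %s", conditionMessage(e)))
      data.frame(sample_id = sub("\\.(bam|sam|cram)$", "", basename(path),
                                 ignore.case = TRUE),
                 file = path,
                 genome_version = config$build_name,
                 sma_status = "error",
                 confidence_score = "",
                 c840_reads_with_smn1_base_C = NA_integer_,
                 c840_total_reads = NA_integer_,
                 error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  results <- do.call(rbind, rows)

  if (!is.null(output)) {
    out <- results
    out$c840_reads_with_smn1_base_C <-
      ifelse(is.na(out$c840_reads_with_smn1_base_C), "",
             out$c840_reads_with_smn1_base_C)
    out$c840_total_reads <-
      ifelse(is.na(out$c840_total_reads), "", out$c840_total_reads)
    utils::write.table(out, output, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  structure(list(
    results = results,
    n_positive = sum(results$sma_status == "has_sma"),
    n_negative = sum(results$sma_status == "does_not_have_sma"),
    n_nocall = sum(results$sma_status == "not_enough_reads"),
    n_error = sum(results$sma_status == "error"),
    success = !any(results$sma_status == "error"),
    params = params,
    output = output),
    class = "sma_cohort")
}

#' @export
print.sma_cohort <- function(x, ...) {
  cat(sprintf("SMA cohort run: %d sample(s)\n", nrow(x$results)))
  cat(sprintf("  positive: %d  negative: %d  no-call: %d  error: %d\n",
              x$n_positive, x$n_negative, x$n_nocall, x$n_error))
  if (!is.null(x$output)) cat(sprintf("  results written to %s\n", x$output))
  invisible(x)
}

#' @export
summary.sma_cohort <- function(object, ...) {
  print(object)
  pos <- object$results[object$results$sma_status == "has_sma", , drop = FALSE]
  if (nrow(pos) > 0L) {
    cat("  positive samples:\n")
    for (i in seq_len(nrow(pos)))
      cat(sprintf("    %s (r=%s, N=%s, confidence=%s)\n",
                  pos$sample_id[i], pos$c840_reads_with_smn1_base_C[i],
                  pos$c840_total_reads[i], pos$confidence_score[i]))
  }
  invisible(object)
}

#' @export
plot.sma_cohort <- function(x, output = NULL, ...) {
  plot_r_vs_n(x$results, params = x$params, output = output, ...)
}
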
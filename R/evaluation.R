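#' Positive predictive value
#'
#' PPV = TP / (TP + FP) among positive calls. Use [percent_label()]
#' with `digits = 0` for the conventional whole-percent rendering.
#'
#' @param tp True-positive count.
#' @param fp False-positive count.
#' @return The PPV as a fraction in `[0, 1]`.
#' @examples
#' compute_ppv(28, 1)            # 0.9655...
#' percent_label(compute_ppv(28, 1))  # "97%"
#' @export
compute_ppv <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0)
    stop("PPV is undefined when there are no positive calls (tp + fp == 0)",
         call. = FALSE)
  tp / (tp + fp)
}

#' Render a fraction as a percentage label
#'
#' @param x Fraction in `[0, 1]`.
#' @param digits Decimal places (default 0).
#' @return Character label such as `"97%"`.
#' @export
percent_label <- function(x, digits = 0L) {
  sprintf(paste0("%.", digits, "f%%"), round(100 * x, digits))
}

#' No-call rate with report-style rendering
#'
#' Returns the fraction of samples with insufficient coverage and a
#' percent label rendered the way cohort summaries report it: rates of
#' at least 0.1\% are rounded to one decimal; smaller rates keep three
#' decimals, truncated rather than rounded so a vanishing rate is never
#' inflated. The rendering depends only on the ratio, so scaling both
#' counts leaves the label unchanged.
#'
#' @param n_nocall Number of no-call samples.
#' @param n_total Total samples (> 0).
#' @return A list with `fraction` and `label`.
#' @examples
#' nocall_rate(112, 16626)$label   # "0.7%"
#' nocall_rate(85, 198868)$label   # "0.042%"
#' @export
nocall_rate <- function(n_nocall, n_total) {
  stopifnot(n_nocall >= 0)
  if (n_total <= 0)
    stop("no-call rate is undefined for an empty cohort (n_total == 0)",
         call. = FALSE)
  if (n_nocall > n_total)
    stop("n_nocall cannot exceed n_total", call. = FALSE)
  frac <- n_nocall / n_total
  pct <- 100 * frac
  label <- if (pct >= 0.1 || pct == 0) {
    sprintf("%.1f%%", round(pct, 1L))
  } else {
    sprintf("%.3f%%", floor(pct * 1000) / 1000)
  }
  list(fraction = frac, label = label)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell `a` follows a
#' hypergeometric distribution. The two-sided p-value is the
#' point-probability definition: the sum, over the whole hypergeometric
#' support, of the probabilities of tables whose point probability does
#' not exceed that of the observed table. Probabilities are computed in
#' log space (`dhyper(log = TRUE)`), so tables with margins in the
#' hundreds of thousands — e.g. cohort-scale no-call contrasts — are
#' handled without overflow; the support itself stays small.
#'
#' @param a,b,c,d Cell counts; rows are the two groups (e.g. assay
#'   types), columns the two outcomes (e.g. no-call vs called).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(85, 198783, 14, 198854)  # ~1.4e-13
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0)
    stop("degenerate 2x2 table: all cells are zero", call. = FALSE)
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  support <- max(0, col1 - row2):min(col1, row1)
  logp <- stats::dhyper(support, row1, row2, col1, log = TRUE)
  logp_obs <- stats::dhyper(a, row1, row2, col1, log = TRUE)
  # relative tolerance guards against ties lost to floating-point noise
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  min(1, p)
}

#' Compare two call sets for concordance
#'
#' Concordance is computed over samples that received a definite call
#' (positive or negative — not no-call, not error) in both sets;
#' samples excluded by that rule are reported separately rather than
#' counted as discordant, since a coverage failure is not a
#' disagreement about the genotype.
#'
#' @param calls_a,calls_b Data frames with columns `sample_id` and a
#'   status column (`status` or `sma_status`; cohort-TSV labels like
#'   `"has_sma"` are understood).
#' @return An object of class `call_set_comparison` with `concordance`,
#'   `n_compared`, `discordant` (data frame of sample_id, status_a,
#'   status_b), and `excluded` (same shape, samples without a definite
#'   call in one of the sets).
#' @export
compare_call_sets <- function(calls_a, calls_b) {
  norm <- function(df) {
    stopifnot("sample_id" %in% names(df))
    col <- intersect(c("status", "sma_status"), names(df))
    if (length(col) == 0L)
      stop("call set needs a 'status' or 'sma_status' column", call. = FALSE)
    status <- as.character(df[[col[[1L]]]])
    map <- c(has_sma = "positive", does_not_have_sma = "negative")
    status <- ifelse(status %in% names(map), map[status], status)
    data.frame(sample_id = as.character(df$sample_id), status = status,
               stringsAsFactors = FALSE)
  }
  a <- norm(calls_a)
  b <- norm(calls_b)
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) == 0L)
    stop("the two call sets share no sample_ids", call. = FALSE)
  sa <- a$status[match(shared, a$sample_id)]
  sb <- b$status[match(shared, b$sample_id)]
  definite <- c("positive", "negative")
  callable <- sa %in% definite & sb %in% definite
  concordant <- sa[callable] == sb[callable]
  structure(list(
    concordance = if (any(callable)) mean(concordant) else NA_real_,
    n_compared = sum(callable),
    discordant = data.frame(sample_id = shared[callable][!concordant],
                            status_a = sa[callable][!concordant],
                            status_b = sb[callable][!concordant],
                            stringsAsFactors = FALSE),
    excluded = data.frame(sample_id = shared[!callable],
                          status_a = sa[!callable],
                          status_b = sb[!callable],
                          stringsAsFactors = FALSE)),
    class = "call_set_comparison")
}

#' @export
print.call_set_comparison <- function(x, ...) {
  cat(sprintf("Call-set concordance: %s over %d samples called in both sets\n",
              ifelse(is.na(x$concordance), "NA",
                     sprintf("%.4f", x$concordance)), x$n_compared))
  if (nrow(x$discordant) > 0L) {
    cat("  discordant:\n")
    for (i in seq_len(nrow(x$discordant)))
      cat(sprintf("    %s: %s vs %s\n", x$discordant$sample_id[i],
                  x$discordant$status_a[i], x$discordant$status_b[i]))
  }
  if (nrow(x$excluded) > 0L)
    cat(sprintf("  excluded (no definite call in one set): %d\n",
                nrow(x$excluded)))
  invisible(x)
}

#' Evaluate calls against a truth table
#'
#' Builds the confusion matrix of definite calls versus truth labels;
#' no-calls and errors are tallied separately and excluded from the
#' matrix.
#'
#' @param calls Data frame with `sample_id` and `status`/`sma_status`.
#' @param truth Data frame with `sample_id` and `expected_status`
#'   (`"positive"`/`"negative"`).
#' @return An object of class `cohort_eval` with `tp`, `fp`, `tn`,
#'   `fn`, `n_nocall`, `n_error`, and `ppv` (NA when no positive
#'   calls).
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(all(c("sample_id", "expected_status") %in% names(truth)))
  col <- intersect(c("status", "sma_status"), names(calls))[[1L]]
  status <- as.character(calls[[col]])
  map <- c(has_sma = "positive", does_not_have_sma = "negative")
  status <- ifelse(status %in% names(map), map[status], status)
  expected <- truth$expected_status[match(as.character(calls$sample_id),
                                          as.character(truth$sample_id))]
  if (anyNA(expected))
    stop("truth table is missing sample(s): ",
         paste(utils::head(calls$sample_id[is.na(expected)], 5), collapse = ", "),
         call. = FALSE)
  tp <- sum(status == "positive" & expected == "positive")
  fp <- sum(status == "positive" & expected == "negative")
  tn <- sum(status == "negative" & expected == "negative")
  fn <- sum(status == "negative" & expected == "positive")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_nocall = sum(status == "not_enough_reads"),
                 n_error = sum(status == "error"),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
            class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  cat("Cohort evaluation vs truth\n")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d  no-call=%d error=%d\n",
              x$tp, x$fp, x$tn, x$fn, x$n_nocall, x$n_error))
  if (!is.na(x$ppv))
    cat(sprintf("  PPV = %.4f (%s)\n", x$ppv, percent_label(x$ppv)))
  invisible(x)
}
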
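#' Parameters for the SMA likelihood-ratio caller
#'
#' The caller compares two binomial hypotheses for the number of 'C'
#' observations r among the N reads overlapping c.840:
#' \itemize{
#'   \item H0 (SMA): zero functional *SMN1* copies; any 'C' is a
#'     sequencing miscall, so r ~ Binomial(N, `base_error_rate`).
#'   \item H1 (not SMA): at least one *SMN1* copy; the smallest
#'     plausible 'C' fraction is one *SMN1* copy among four total SMN
#'     copies, so r ~ Binomial(N, `carrier_c_fraction`).
#' }
#' The decision statistic is the base-10 log-likelihood ratio
#' \deqn{llr_{10} = r \log_{10}(\epsilon/\theta) +
#'       (N - r) \log_{10}((1-\epsilon)/(1-\theta))}
#' whose zero contour is the straight line \eqn{r = cN} with slope
#' `decision_boundary_slope()`. With the defaults
#' (\eqn{\epsilon = 0.005}, \eqn{\theta = 0.25}) the slope is ~0.0674,
#' i.e. a positive call requires the 'C' fraction to fall below ~6.7\%.
#'
#' @param min_coverage Minimum N to make any call; below this the sample
#'   is reported as `not_enough_reads`. Inclusive: N = 14 is callable
#'   under the default.
#' @param base_error_rate \eqn{\epsilon}, the probability that a
#'   sequenced base is miscalled as 'C' when no *SMN1* copy exists
#'   (post base-quality-filter Illumina error; default 0.005).
#' @param carrier_c_fraction \eqn{\theta}, the expected 'C' fraction
#'   under the minimal *SMN1*-present configuration (1 copy of 4 total;
#'   default 0.25). Must exceed `base_error_rate`.
#' @param max_confidence Cap on the reported phred-scaled confidence
#'   (default 1000); cosmetic, keeps output finite at very high N.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 14L, base_error_rate = 0.005,
                          carrier_c_fraction = 0.25, max_confidence = 1000) {
  min_coverage <- as.integer(min_coverage)
  if (is.na(min_coverage) || min_coverage < 1L)
    stop("min_coverage must be an integer >= 1", call. = FALSE)
  if (!(base_error_rate > 0 && carrier_c_fraction < 1 &&
        base_error_rate < carrier_c_fraction))
    stop("need 0 < base_error_rate < carrier_c_fraction < 1", call. = FALSE)
  if (!(max_confidence > 0))
    stop("max_confidence must be positive", call. = FALSE)
  structure(list(min_coverage = min_coverage,
                 base_error_rate = base_error_rate,
                 carrier_c_fraction = carrier_c_fraction,
                 max_confidence = max_confidence),
            class = "caller_params")
}

#' Slope of the linear decision boundary
#'
#' Returns the constant c such that the zero contour of the
#' log-likelihood ratio is the line r = c N; samples with r below the
#' line (fewer 'C' reads than the boundary allows) are called positive.
#'
#' @param params A [caller_params].
#' @return The boundary slope (a fraction in (0, 1)).
#' @export
decision_boundary_slope <- function(params = caller_params()) {
  l0 <- log10(params$base_error_rate / params$carrier_c_fraction)
  l1 <- log10((1 - params$base_error_rate) / (1 - params$carrier_c_fraction))
  l1 / (l1 - l0)
}

.llr10 <- function(r, n, params) {
  r * log10(params$base_error_rate / params$carrier_c_fraction) +
    (n - r) * log10((1 - params$base_error_rate) /
                    (1 - params$carrier_c_fraction))
}

.check_counts_invariants <- function(counts) {
  with(counts, {
    if (any(c(n_c, n_t, n_other, n_total) < 0))
      stop("pileup counters must be non-negative", call. = FALSE)
    if (n_c + n_t + n_other != n_total)
      stop(sprintf("pileup counters are inconsistent: C=%d + T=%d + other=%d != N=%d",
                   n_c, n_t, n_other, n_total), call. = FALSE)
  })
  invisible(counts)
}

#' Classify a sample from its c.840 pileup counts
#'
#' Applies the coverage gate and the binomial likelihood-ratio rule to
#' the (r, N) counts. With N below `min_coverage` the sample is a
#' no-call (`not_enough_reads`, confidence 0). Otherwise the call is
#' `positive` (SMA) when the log-likelihood ratio favours the
#' zero-*SMN1* hypothesis (llr10 > 0) and `negative` otherwise; an
#' exact tie is called negative, since a positive SMA report should
#' require positive evidence. The confidence is the phred-scaled
#' magnitude `min(10 * |llr10|, max_confidence)` and always supports
#' the reported status.
#'
#' @param counts An `smn_pileup` from [count_c840_reads()], or any list
#'   with fields `n_c`, `n_t`, `n_other`, `n_total` (and optionally
#'   `sample_id`).
#' @param params A [caller_params].
#' @param sample_id Optional override for the sample identifier.
#' @return An object of class `sma_call` with fields `sample_id`,
#'   `status` (one of `"positive"`, `"negative"`, `"not_enough_reads"`),
#'   `confidence`, `r`, `n`, and `llr10`.
#' @examples
#' classify(list(n_c = 0, n_t = 40, n_other = 0, n_total = 40))
#' @export
classify <- function(counts, params = caller_params(), sample_id = NULL) {
  stopifnot(inherits(params, "caller_params"))
  .check_counts_invariants(counts)
  r <- counts$n_c
  n <- counts$n_total
  if (is.null(sample_id))
    sample_id <- if (!is.null(counts$sample_id)) counts$sample_id else NA_character_
  if (n < params$min_coverage) {
    status <- "not_enough_reads"
    llr10 <- NA_real_
    confidence <- 0
  } else {
    llr10 <- .llr10(r, n, params)
    status <- if (llr10 > 0) "positive" else "negative"
    confidence <- min(10 * abs(llr10), params$max_confidence)
  }
  structure(list(sample_id = sample_id, status = status,
                 confidence = confidence, r = r, n = n,
                 llr10 = llr10, params = params),
            class = "sma_call")
}

#' @export
print.sma_call <- function(x, ...) {
  label <- switch(x$status,
                  positive = "SMA POSITIVE (zero functional SMN1 copies)",
                  negative = "SMA negative",
                  not_enough_reads = "no call (insufficient read coverage)")
  cat(sprintf("Sample '%s': %s\n", x$sample_id, label))
  cat(sprintf("  r = %d reads with 'C', N = %d reads total at c.840\n",
              x$r, x$n))
  cat(sprintf("  confidence = %.1f phred\n", x$confidence))
  invisible(x)
}

#' Call one sample from an alignment file
#'
#' Convenience composition of [count_c840_reads()] and [classify()].
#'
#' @inheritParams count_c840_reads
#' @param params A [caller_params].
#' @return An `sma_call`.
#' @export
call_sample <- function(alignments, config, params = caller_params(),
                        min_base_quality = 13L, reference = NULL,
                        sample_id = NULL) {
  counts <- count_c840_reads(alignments, config,
                             min_base_quality = min_base_quality,
                             reference = reference, sample_id = sample_id)
  classify(counts, params)
}
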
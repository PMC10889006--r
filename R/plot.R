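#' Diagnostic scatter of r versus N
#'
#' Plots each sample's c.840 read counts — reads with the *SMN1* 'C'
#' base on the x axis, total reads on the y axis — with the caller's
#' linear decision boundary in red and the no-call region (N below the
#' coverage gate) shaded gray. Both axes use a symmetric log scale that
#' is linear up to the coverage gate (14 by default) and logarithmic
#' beyond, so low-count positives and deep negatives are visible on one
#' panel; on that scale part of the (Cartesian-linear) boundary appears
#' curved. Marginal histograms show the distribution of r (top) and N
#' (right). Positive, negative, and no-call samples are distinguished
#' by colour.
#'
#' @param rows Data frame of results — the `results` component of an
#'   [run_cohort()] object, or any frame with columns
#'   `c840_reads_with_smn1_base_C`, `c840_total_reads`, and
#'   `sma_status` (or `r`, `n`, `status`).
#' @param params A [caller_params] (boundary and gate to draw).
#' @param output Image path ending in `.png`, `.svg`, or `.pdf`; `NULL`
#'   draws on the active device.
#' @param width,height Device size in inches (default 7 x 7).
#' @param main Plot title.
#' @return `output` (or `NULL`), invisibly.
#' @export
plot_r_vs_n <- function(rows, params = caller_params(), output = NULL,
                        width = 7, height = 7, main = "SMA caller read counts") {
  r <- if ("r" %in% names(rows)) rows$r else rows$c840_reads_with_smn1_base_C
  n <- if ("n" %in% names(rows)) rows$n else rows$c840_total_reads
  status <- if ("status" %in% names(rows)) rows$status else rows$sma_status
  keep <- !is.na(r) & !is.na(n)
  r <- as.numeric(r[keep]); n <- as.numeric(n[keep])
  status <- as.character(status[keep])
  if (length(r) == 0L)
    stop("no plottable rows (all samples errored?)", call. = FALSE)
  map <- c(has_sma = "positive", does_not_have_sma = "negative")
  status <- ifelse(status %in% names(map), map[status], status)

  L <- params$min_coverage
  symlog <- function(x) ifelse(x <= L, x, L * (1 + log(x / L)))

  if (!is.null(output)) {
    ext <- tolower(tools::file_ext(output))
    ok <- tryCatch({
      switch(ext,
             png = grDevices::png(output, width = width, height = height,
                                  units = "in", res = 150),
             svg = grDevices::svg(output, width = width, height = height),
             pdf = grDevices::pdf(output, width = width, height = height),
             stop(sprintf("unsupported image format '.%s' (use png/svg/pdf)", ext),
                  call. = FALSE))
      TRUE
    }, error = function(e) {
      if (grepl("unsupported image format", conditionMessage(e))) stop(e)
      # headless fallback when no bitmap device is available
      grDevices::pdf(sub("\\.[A-Za-z]+$", ".pdf", output),
                     width = width, height = height)
      FALSE
    })
    on.exit(grDevices::dev.off())
    if (!ok) output <- sub("\\.[A-Za-z]+$", ".pdf", output)
  }

  cols <- c(positive = "#d62728", negative = "#7f7f7f",
            not_enough_reads = "#1f77b4")
  pt_col <- cols[status]
  pt_col[is.na(pt_col)] <- "black"

  xmax <- max(r, L * 2, na.rm = TRUE)
  ymax <- max(n, L * 2, na.rm = TRUE)
  xlim <- c(0, symlog(xmax) * 1.05)
  ylim <- c(0, symlog(ymax) * 1.05)

  ticks_for <- function(maxval) {
    cand <- c(0, 5, 10, L, 50, 100, 500, 1000, 5000, 10000)
    cand[cand <= maxval * 1.2]
  }

  old_par <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old_par), add = TRUE)
  layout_m <- matrix(c(2, 4, 1, 3), nrow = 2, byrow = TRUE)
  graphics::layout(layout_m, widths = c(4, 1), heights = c(1, 4))

  # main panel
  graphics::par(mar = c(4.5, 4.5, 0.5, 0.5))
  graphics::plot(NA, xlim = xlim, ylim = ylim, axes = FALSE,
                 xlab = "reads with 'C' at c.840 (r)",
                 ylab = "total reads at c.840 (N)")
  graphics::rect(xlim[1], 0, xlim[2], symlog(L), col = "#dddddd", border = NA)
  xt <- ticks_for(xmax); yt <- ticks_for(ymax)
  graphics::axis(1, at = symlog(xt), labels = xt)
  graphics::axis(2, at = symlog(yt), labels = yt)
  graphics::box()
  # decision boundary r = c * N, drawn over N >= gate
  slope <- decision_boundary_slope(params)
  nn <- exp(seq(log(L), log(max(ymax, L + 1)), length.out = 200))
  graphics::lines(symlog(slope * nn), symlog(nn), col = "red", lwd = 2)
  graphics::points(symlog(r), symlog(n), pch = 19, cex = 0.7, col = pt_col)
  graphics::legend("bottomright", bty = "n", pch = 19, cex = 0.8,
                   col = cols,
                   legend = c("positive", "negative", "no-call"))

  hist_counts <- function(v, breaks) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h
  }
  brks <- function(v, lim) {
    b <- pretty(symlog(v), n = 20)
    unique(sort(c(b[b >= 0], lim[2])))
  }

  # top marginal: r
  graphics::par(mar = c(0.2, 4.5, 0.5, 0.5))
  hx <- hist_counts(symlog(r), brks(r, xlim))
  graphics::barplot(hx$counts, space = 0, axes = FALSE, col = "#bbbbbb",
                    border = "white")
  # right marginal: N
  graphics::par(mar = c(4.5, 0.2, 0.5, 0.5))
  hy <- hist_counts(symlog(n), brks(n, ylim))
  graphics::barplot(hy$counts, space = 0, horiz = TRUE, axes = FALSE,
                    col = "#bbbbbb", border = "white")
  # corner: title
  graphics::par(mar = c(0.2, 0.2, 0.5, 0.5))
  graphics::plot.new()
  graphics::text(0.5, 0.5, main, cex = 0.7, srt = 0)

  invisible(output)
}
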
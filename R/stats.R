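# Occupancy-correlation statistics and publication-style cavity tables.

#' Time-binned paired occupancy
#'
#' Averages two equally-timed series within aligned, non-overlapping time
#' bins, for occupancy-correlation analysis (e.g. lipid atoms vs ligand
#' molecules in the same cavity at a given time).
#'
#' @param x,y numeric series on the same time base.
#' @param times time stamps (ns) shared by both series.
#' @param bin_width bin width in frames (default 10); 1 returns the series
#'   unchanged.
#' @return object of class `chan_paired`: data.frame with `t` (bin mid-time),
#'   `x`, `y`.
#' @export
bin_paired_occupancy <- function(x, y, times = seq_along(x), bin_width = 10) {
  if (length(x) != length(y) || length(x) != length(times))
    stop("alignment error: x, y and times must have equal length")
  g <- (seq_along(x) - 1) %/% bin_width
  out <- data.frame(t = tapply(times, g, mean),
                    x = tapply(x, g, mean),
                    y = tapply(y, g, mean))
  out <- out[stats::complete.cases(out), ]
  rownames(out) <- NULL
  class(out) <- c("chan_paired", "data.frame")
  out
}

#' Ordinary least-squares linear fit with R^2
#'
#' @param paired a `chan_paired` (or any data.frame with columns `x`, `y`).
#' @return object of class `chan_linear_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `se_slope`, `se_intercept`, `n`.
#' @export
linear_fit <- function(paired) {
  x <- paired$x; y <- paired$y
  if (length(x) < 3) stop("fit error: need at least 3 points")
  if (var(x) == 0) stop("fit error: zero variance in x")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # exact lines are legitimate input
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 se_slope = s$coefficients[2, 2],
                 se_intercept = s$coefficients[1, 2],
                 n = length(x)),
            class = "chan_linear_fit")
}

#' @export
print.chan_linear_fit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   (R^2 = %.4f, n = %d)\n", x$slope,
              x$intercept, x$r_squared, x$n))
  invisible(x)
}

fmt_pm <- function(m, s, digits = 1) {
  if (is.na(m)) "missing" else
    sprintf(paste0("%.", digits, "f±%.", digits, "f"), m, s)
}

#' Publication-style per-cavity summary table
#'
#' Rows are quantities, columns the five cavities plus an Average column;
#' cells are "mean+/-SD" over the stated window.  The Average column is the
#' mean of the per-cavity means, with the SD of the subunit-averaged time
#' series.
#'
#' @param quantities named list of frames x cavities numeric matrices (e.g.
#'   `volume`, `lipid`, `water`, `ligand`).
#' @param window_frames integer frame indices the statistics are computed
#'   over (e.g. the second half).
#' @param digits decimal places in the formatted cells.
#' @return data.frame of formatted cells with attribute `numeric` holding
#'   `mean` and `sd` matrices.
#' @export
cavity_table <- function(quantities, window_frames = NULL, digits = 1) {
  qn <- names(quantities)
  ncav <- ncol(quantities[[1]])
  if (is.null(window_frames)) window_frames <- seq_len(nrow(quantities[[1]]))
  mean_m <- matrix(NA_real_, length(qn), ncav + 1,
                   dimnames = list(qn, c(paste0("cavity", seq_len(ncav)),
                                         "Average")))
  sd_m <- mean_m
  cells <- matrix("missing", length(qn), ncav + 1, dimnames = dimnames(mean_m))
  for (qi in seq_along(qn)) {
    m <- quantities[[qi]][window_frames, , drop = FALSE]
    mu <- colMeans(m); s <- apply(m, 2, sd)
    avg_series <- rowMeans(m)
    mean_m[qi, ] <- c(mu, mean(mu))
    sd_m[qi, ] <- c(s, sd(avg_series))
    cells[qi, ] <- vapply(seq_len(ncav + 1), function(j)
      fmt_pm(mean_m[qi, j], sd_m[qi, j], digits), "")
  }
  out <- as.data.frame(cells, stringsAsFactors = FALSE)
  attr(out, "numeric") <- list(mean = mean_m, sd = sd_m)
  out
}
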
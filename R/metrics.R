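# Plot-level map validation: RMSE, bias, R^2, their relative forms,
# and bias by reference-value bin.
#
#   RMSE  = sqrt( sum_i (y_i - yhat_i)^2 / n )
#   Bias  = sum_i (y_i - yhat_i) / n          (reference minus prediction)
#   R^2   = 1 - sum_i (y_i - yhat_i)^2 / sum_i (y_i - ybar)^2
#
# Relative forms divide by the validation-set reference mean and are
# expressed in percent (RMSE%, Bias%).  Because "overestimation of
# small values" reads naturally as prediction minus reference, the
# binned report carries both sign conventions, clearly labelled.

#' Validation metrics for one variable
#'
#' @param y reference values.
#' @param y_hat predicted values.
#' @param variable optional label.
#' @param units optional unit string.
#' @return An object of class `metrics_report`: `n`, `mean_ref`,
#'   `rmse`, `bias` (reference minus prediction), `bias_pred`
#'   (prediction minus reference), `rmse_pct`, `bias_pct`,
#'   `bias_pred_pct`, `r2`.  Relative metrics are `NA` when the
#'   reference mean is zero.
#' @export
compute_metrics <- function(y, y_hat, variable = "", units = "") {
  stopifnot(length(y) == length(y_hat))
  ok <- is.finite(y) & is.finite(y_hat)
  y <- y[ok]; y_hat <- y_hat[ok]
  n <- length(y)
  if (n < 1L) stop("no finite validation pairs")
  ybar <- mean(y)
  res <- y - y_hat
  rmse <- sqrt(mean(res^2))
  bias <- mean(res)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (n >= 2L && ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  rel <- function(v) if (ybar == 0) NA_real_ else v / ybar * 100
  structure(list(variable = variable, units = units, n = n,
                 mean_ref = ybar, rmse = rmse, bias = bias,
                 bias_pred = -bias, rmse_pct = rel(rmse),
                 bias_pct = rel(bias), bias_pred_pct = rel(-bias),
                 r2 = r2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Validation metrics%s (n = %d, mean ref = %.1f %s)\n",
              if (nzchar(x$variable)) paste0(" for ", x$variable) else "",
              x$n, x$mean_ref, x$units))
  cat(sprintf("  RMSE  %8.2f %s  (%.1f %%)\n", x$rmse, x$units,
              x$rmse_pct))
  cat(sprintf("  Bias  %8.2f %s  (%.1f %%)   [reference - prediction]\n",
              x$bias, x$units, x$bias_pct))
  cat(sprintf("  R2    %8.3f\n", x$r2))
  invisible(x)
}

#' Default above-ground-biomass bin edges (t/ha)
#'
#' Integer-labelled bins 0-124, 125-249, 250-374, 375-499 and 500 and
#' above, implemented on continuous values as half-open intervals
#' \[0, 125), \[125, 250), \[250, 375), \[375, 500), \[500, Inf).
#' @export
AGB_BIN_EDGES <- c(0, 125, 250, 375, 500, Inf)

#' Bias by reference-value bin
#'
#' Bins validation pairs by their reference value and reports per-bin
#' bias in both sign conventions, relative to the bin's reference mean.
#'
#' @inheritParams compute_metrics
#' @param edges strictly increasing bin edges; the last may be `Inf`.
#' @return A `data.frame` with one row per bin: `bin` label, `n`,
#'   `mean_ref`, `bias` (reference minus prediction), `bias_pct`,
#'   `bias_pred` (prediction minus reference), `bias_pred_pct`.
#'   Empty bins carry `n = 0` and `NA` metrics.
#' @export
binned_bias <- function(y, y_hat, edges = AGB_BIN_EDGES) {
  stopifnot(length(y) == length(y_hat), all(diff(edges) > 0),
            length(edges) >= 2L)
  nb <- length(edges) - 1L
  lab <- vapply(seq_len(nb), function(i) {
    if (is.infinite(edges[i + 1])) sprintf("%d->", as.integer(edges[i]))
    else sprintf("%d-%d", as.integer(edges[i]),
                 as.integer(edges[i + 1]) - 1L)
  }, character(1))
  bin <- findInterval(y, edges, rightmost.closed = FALSE)
  bin[bin == nb + 1L & is.infinite(edges[nb + 1L])] <- nb
  out <- data.frame(bin = lab, n = 0L, mean_ref = NA_real_,
                    bias = NA_real_, bias_pct = NA_real_,
                    bias_pred = NA_real_, bias_pred_pct = NA_real_)
  for (i in seq_len(nb)) {
    sel <- which(bin == i)
    out$n[i] <- length(sel)
    if (!length(sel)) next
    m <- mean(y[sel])
    b <- mean(y[sel] - y_hat[sel])
    out$mean_ref[i] <- m
    out$bias[i] <- b
    out$bias_pred[i] <- -b
    if (m != 0) {
      out$bias_pct[i] <- b / m * 100
      out$bias_pred_pct[i] <- -b / m * 100
    }
  }
  out
}

#' Full metrics report for the three mapped variables
#'
#' @param reference data frame with columns `vol`, `agb`, `dcp`.
#' @param predicted data frame with the same columns.
#' @param agb_edges bin edges for the binned-bias report.
#' @return List of three `metrics_report`s (`vol`, `agb`, `dcp`) plus
#'   `agb_binned_bias`.
#' @export
validation_report <- function(reference, predicted,
                              agb_edges = AGB_BIN_EDGES) {
  units <- c(vol = "m3/ha", agb = "t/ha", dcp = "%")
  out <- lapply(c("vol", "agb", "dcp"), function(v)
    compute_metrics(reference[[v]], predicted[[v]], variable = v,
                    units = units[[v]]))
  names(out) <- c("vol", "agb", "dcp")
  out$agb_binned_bias <- binned_bias(reference$agb, predicted$agb,
                                     edges = agb_edges)
  out
}
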
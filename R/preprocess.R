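#' Average rate time-series over the delay window
#'
#' Bins each trial's rate time-series by taking the arithmetic mean of
#' all samples whose go-cue-relative time falls in the half-open window
#' `(window[1], window[2]]` (default the 200 ms before the go cue). The
#' half-open convention avoids double-counting the go-cue sample.
#'
#' @param series a [simulate_timecourse()] result.
#' @param window numeric length-2, ms relative to the go cue.
#' @return a [trial_table()] whose rate columns are the window means.
#' @export
select_delay_window <- function(series, window = c(-200, 0)) {
  stopifnot(inherits(series, "rate_timeseries"), length(window) == 2,
            window[2] > window[1])
  rel <- series$time_ms - series$go_cue_ms
  keep <- rel > window[1] & rel <= window[2]
  if (!any(keep))
    stop("delay window (", window[1], ", ", window[2],
         "] ms contains no samples for trial_id ", series$trials$trial_id[1])
  R <- apply(series$rates[, , keep, drop = FALSE], c(1, 2), mean)
  colnames(R) <- sprintf("rate_%03d", seq_len(ncol(R)) - 1)
  trial_table(cbind(series$trials, as.data.frame(R)))
}

#' Subtract per-session baseline rates
#'
#' Centers every channel within each recording session (mean rate 0 per
#' session per channel), removing day-to-day drifts in baseline firing.
#' Idempotent; all metadata columns are untouched.
#'
#' @param table a [trial_table()].
#' @return the centered [trial_table()] (rates may be negative).
#' @export
subtract_session_baseline <- function(table) {
  validate_trial_table(table)
  rc <- rate_cols(table)
  for (s in unique(table$session_id)) {
    i <- table$session_id == s
    m <- colMeans(table[i, rc, drop = FALSE])
    table[i, rc] <- sweep(table[i, rc, drop = FALSE], 2, m)
  }
  table
}

#' Screen channels for task relevance
#'
#' Fits, for each channel separately, a linear regression of its rate on
#' the target's (x, y) location and keeps the channel when the overall
#' F-test p-value clears a Bonferroni-corrected level
#' `alpha / n_channels`. Screened-out channels are flagged, not deleted:
#' downstream stages accept the `kept` vector as an optional mask.
#'
#' @param table a [trial_table()].
#' @param alpha familywise significance level (default 0.05).
#' @return an object of class `channel_screen`: data.frame with one row
#'   per channel (`channel`, `p_value`, `kept`) and attributes `alpha`,
#'   `n_channels`. Constant channels get `p_value = 1`, `kept = FALSE`.
#' @export
screen_channels <- function(table, alpha = 0.05) {
  validate_trial_table(table)
  pos <- unique(cbind(table$target_x, table$target_y))
  if (nrow(pos) < 3) stop("need >= 3 distinct target positions")
  R <- rate_matrix(table)
  X <- cbind(1, table$target_x, table$target_y)
  n <- nrow(R); p <- ncol(X)
  qr_X <- qr(X)
  fitted <- qr.fitted(qr_X, R)
  rss <- colSums((R - fitted)^2)
  tss <- colSums(sweep(R, 2, colMeans(R))^2)
  pval <- rep(1, ncol(R))
  ok <- tss > 0 & rss < tss
  f <- ((tss[ok] - rss[ok]) / (p - 1)) / (rss[ok] / (n - p))
  pval[ok] <- stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  out <- data.frame(channel = seq_len(ncol(R)) - 1L, p_value = pval,
                    kept = pval < alpha / ncol(R))
  structure(out, alpha = alpha, n_channels = ncol(R),
            class = c("channel_screen", "data.frame"))
}

#' @export
print.channel_screen <- function(x, ...) {
  cat(sprintf(
    "<channel_screen: %d / %d channels task-correlated at p < %g / %d (Bonferroni)>\n",
    sum(x$kept), attr(x, "n_channels"), attr(x, "alpha"),
    attr(x, "n_channels")))
  invisible(x)
}
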
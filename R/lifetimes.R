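#' Mean lifetime by time integration of a survival correlator
#'
#' The mean lifetime is the time integral of the survival probability; on
#' the computed window it is evaluated by the trapezoidal rule on the
#' uniform lag grid.  Truncation is explicit: if the terminal value exceeds
#' `tail_threshold`, a single-exponential tail fitted to the last decade of
#' the decay is integrated analytically and added, with the tail's share of
#' the total recorded in `tail_fraction`.  A terminal value above
#' `terminal_max` (or a non-decaying tail that still needs extrapolation)
#' makes the integral unreliable and is an error.
#'
#' @param corr an `hb_corr` object, or a list with numeric `lag` (fs,
#'   uniform) and `value`.
#' @param tail_threshold terminal value above which the tail correction is
#'   applied (default 0.01).
#' @param terminal_max terminal value above which the window is rejected
#'   (default 0.5).
#' @return list of class `lifetime_estimate`: `mean` (fs), `method`,
#'   `tail_fraction`, `terminal_value`.
#' @export
mean_lifetime <- function(corr, tail_threshold = 0.01, terminal_max = 0.5) {
  lag <- corr$lag
  val <- corr$value
  stopifnot(length(lag) == length(val), length(lag) >= 2,
            all(is.finite(val)))
  if (diff(range(diff(lag))) > 1e-9 * max(diff(lag)))
    stop("lag grid must be uniform")
  v_end <- val[length(val)]
  base <- pracma::trapz(lag, val)
  tail_int <- 0
  method <- "trapezoid"
  if (v_end > terminal_max)
    stop(sprintf(
      "window too short: terminal correlator value %.3f exceeds %.2f; integral unreliable",
      v_end, terminal_max))
  if (v_end > tail_threshold) {
    sel <- which(val > 0 & val <= min(1, 10 * v_end))
    sel <- sel[sel > length(val) / 2]  # fit the terminal decade only
    if (length(sel) < 5)
      stop("window too short: too few points in the terminal decade for a tail fit")
    fit <- lm(log(val[sel]) ~ lag[sel])
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= -1e-12)
      stop("window too short: terminal decay is flat, tail cannot be extrapolated")
    tau_tail <- -1 / slope
    tail_int <- v_end * tau_tail
    method <- "trapezoid+tail"
  }
  total <- base + tail_int
  structure(list(mean = total, method = method,
                 tail_fraction = tail_int / total, terminal_value = v_end),
            class = "lifetime_estimate")
}

#' Aggregate block lifetimes into a mean with uncertainty
#'
#' The reported value is the sample mean of the block means.  In `"ci"`
#' mode the half-width is the Student-t confidence interval at `ci_level`
#' with `N - 1` degrees of freedom; in `"sd"` mode (used for monomer
#' lifetimes) the half-width is the sample standard deviation.
#'
#' @param means numeric vector of block mean lifetimes (fs).
#' @param ci_level confidence level (default 0.95).
#' @param method `"ci"` or `"sd"`.
#' @return list of class `lifetime_estimate`: `mean`, `ci_half_width`,
#'   `ci_level`, `n_functions`, `method`.
#' @export
aggregate_lifetimes <- function(means, ci_level = 0.95,
                                method = c("ci", "sd")) {
  method <- match.arg(method)
  n <- length(means)
  stopifnot(n >= 1, all(is.finite(means)))
  if (n == 1 && method == "ci")
    stop("a confidence interval needs at least two block means")
  half <- if (n == 1) 0 else switch(method,
    ci = qt(1 - (1 - ci_level) / 2, df = n - 1) * sd(means) / sqrt(n),
    sd = sd(means))
  structure(list(mean = mean(means), ci_half_width = half,
                 ci_level = if (method == "ci") ci_level else NA_real_,
                 n_functions = n, method = method),
            class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  if (!is.null(x$ci_half_width))
    cat(sprintf("<lifetime_estimate> %.4g +/- %.3g fs (N = %d, %s)\n",
                x$mean, x$ci_half_width, x$n_functions, x$method))
  else
    cat(sprintf("<lifetime_estimate> %.4g fs (%s, tail %.1f%%)\n",
                x$mean, x$method, 100 * x$tail_fraction))
  invisible(x)
}

#' Block lifetimes from a time series
#'
#' Partitions the frames into `n_segments` equal non-overlapping blocks,
#' computes one correlation function per block (its origins sampled inside
#' the block), and integrates each - the construction behind averaging
#' several independent correlation functions.
#'
#' @param series a `bond_state_series`, `bond_series` or logical matrix.
#' @param mode `"continuous"`, `"intermittent"` or `"monomer"`.
#' @param n_segments number of blocks.
#' @param n_origins origins per block.
#' @param max_lag maximum lag in frames.
#' @param seed base seed; block b uses `seed + b`.
#' @param ... passed to [mean_lifetime()].
#' @return numeric vector of `n_segments` block mean lifetimes (fs).
#' @export
segment_lifetimes <- function(series, mode = c("continuous", "intermittent",
                                               "monomer"),
                              n_segments = 5, n_origins = 20, max_lag,
                              seed = 1, ...) {
  mode <- match.arg(mode)
  sm <- .as_state_matrix(series, mode)
  n_frames <- ncol(sm$states)
  block_len <- n_frames %/% n_segments
  if (block_len < 2 * max_lag)
    stop(sprintf(
      "series too short: %d segments of >= %d frames need %d frames, have %d",
      n_segments, 2 * max_lag, n_segments * 2 * max_lag, n_frames))
  vapply(seq_len(n_segments), function(b) {
    cols <- ((b - 1) * block_len + 1):(b * block_len)
    sub <- sm$states[, cols, drop = FALSE]
    attr(sub, "dt") <- sm$dt
    origins <- sample_origins(block_len, max_lag, n_origins, seed = seed + b)
    corr <- if (mode == "intermittent")
      intermittent_correlation(sub, origins, max_lag)
    else if (mode == "monomer")
      monomer_correlation(sub, origins, max_lag)
    else continuous_correlation(sub, origins, max_lag)
    mean_lifetime(corr, ...)$mean
  }, numeric(1))
}
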
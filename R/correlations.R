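#' Sample time origins for correlation averaging
#'
#' Draws `n_origins` distinct frame indices uniformly without replacement
#' from the frames that leave every lag up to `max_lag_frames` observable
#' (no right-censoring inside the window).
#'
#' @param n_frames total stored frames.
#' @param max_lag_frames maximum lag in frames.
#' @param n_origins number of origins.
#' @param seed integer seed.
#' @return sorted integer vector of 1-based frame indices.
#' @export
sample_origins <- function(n_frames, max_lag_frames, n_origins, seed = 1) {
  stopifnot(n_origins >= 1, max_lag_frames >= 0)
  if (n_frames <= max_lag_frames)
    stop("n_frames must exceed max_lag_frames")
  eligible <- n_frames - max_lag_frames
  if (eligible < n_origins)
    stop(sprintf(
      "only %d eligible origin frames for %d origins; reduce max_lag or n_origins",
      eligible, n_origins))
  sort(with_seed(seed, sample.int(eligible, n_origins)))
}

.as_state_matrix <- function(series, mode) {
  if (inherits(series, "bond_state_series")) {
    states <- series$states
    if (mode == "monomer") states <- !states  # inverted semantics on request
    list(states = states, dt = series$dt)
  } else if (inherits(series, "bond_series")) {
    states <- switch(mode,
      monomer = series$monomer_states,
      series$pair_states)
    list(states = states, dt = series$dt)
  } else if (is.matrix(series) && is.logical(series)) {
    list(states = series, dt = attr(series, "dt") %||% 1)
  } else stop("series must be a bond_state_series, bond_series or logical matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.make_corr <- function(kernel, series, origins, max_lag, mode) {
  sm <- .as_state_matrix(series, mode)
  states <- sm$states
  if (nrow(states) == 0) stop("undefined correlation: no entities in the series")
  stopifnot(all(origins >= 1), all(origins + max_lag <= ncol(states)))
  res <- kernel(states, as.integer(origins) - 1L, as.integer(max_lag))
  if (res$den == 0)
    stop("undefined correlation: no active entities at any origin")
  structure(list(mode = mode, lag = (0:max_lag) * sm$dt,
                 value = res$num / res$den, n_origins = length(origins),
                 origins = origins, denominator = res$den, dt = sm$dt),
            class = "hb_corr")
}

#' Continuous bond survival correlator H_c(t)
#'
#' Fraction of (pair, origin) events bonded at the origin that remain
#' bonded at every stored frame up to lag t (zero tolerance for gaps at the
#' stored resolution).  Normalization is the ratio of pooled sums over all
#' origins: the denominator counts bonded pairs at the origins.
#'
#' @param series a `bond_state_series`, `bond_series`, or logical
#'   entities-by-frames matrix.
#' @param origins origin frame indices from [sample_origins()].
#' @param max_lag maximum lag in frames.
#' @return object of class `hb_corr` with fields `lag` (fs), `value`,
#'   `n_origins`, `denominator`.
#' @export
continuous_correlation <- function(series, origins, max_lag) {
  .make_corr(corr_continuous_cpp, series, origins, max_lag, "continuous")
}

#' Intermittent (presence-at-endpoints) bond correlator H_int(t)
#'
#' Counts pairs bonded at the origin AND at lag t regardless of intermediate
#' states: a pair present at both endpoints either never broke or restored
#' its broken bond within the interval.
#'
#' @inheritParams continuous_correlation
#' @return `hb_corr` object.
#' @export
intermittent_correlation <- function(series, origins, max_lag) {
  .make_corr(corr_intermittent_cpp, series, origins, max_lag, "intermittent")
}

#' Monomer persistence correlator M(t)
#'
#' Continuous survival of the non-bonded state: fraction of monomers at the
#' origin that remain non-bonded at every stored frame up to lag t.  For a
#' `bond_series` the molecule-level monomer series is used; for a
#' `bond_state_series` the stored states are interpreted as "non-bonded"
#' (inverted Markov semantics).  Dense cold states may legitimately have no
#' monomers at any origin, which raises an undefined-correlation error.
#'
#' @inheritParams continuous_correlation
#' @return `hb_corr` object.
#' @export
monomer_correlation <- function(series, origins, max_lag) {
  sm <- .as_state_matrix(series, "monomer")
  states <- sm$states
  stopifnot(all(origins >= 1), all(origins + max_lag <= ncol(states)))
  res <- corr_continuous_cpp(states, as.integer(origins) - 1L,
                             as.integer(max_lag))
  if (res$den == 0)
    stop("undefined correlation: no monomers at any origin")
  structure(list(mode = "monomer", lag = (0:max_lag) * sm$dt,
                 value = res$num / res$den, n_origins = length(origins),
                 origins = origins, denominator = res$den, dt = sm$dt),
            class = "hb_corr")
}

#' @export
print.hb_corr <- function(x, ...) {
  cat(sprintf("<hb_corr> %s, %d lags (0..%g fs), %d origins, denominator %g\n",
              x$mode, length(x$lag), max(x$lag), x$n_origins, x$denominator))
  invisible(x)
}

#' Theoretical correlators of the two-state Markov bond process
#'
#' Continuous survival `exp(-k_break t)`; intermittent (no escape)
#' `pi + (1 - pi) exp(-(k_break + k_reform) t)` with stationary probability
#' `pi = k_reform / (k_break + k_reform)`.
#'
#' @param t times (fs).
#' @param k_break,k_reform rates (1/fs).
#' @param mode `"continuous"` or `"intermittent"`.
#' @return numeric vector of theoretical correlator values.
#' @export
markov_correlation_theory <- function(t, k_break, k_reform = 0,
                                      mode = c("continuous", "intermittent")) {
  mode <- match.arg(mode)
  if (mode == "continuous") return(exp(-k_break * t))
  if (k_break + k_reform == 0) return(rep(1, length(t)))
  p <- k_reform / (k_break + k_reform)
  p + (1 - p) * exp(-(k_break + k_reform) * t)
}
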
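.gas_R <- 8.314  # J mol^-1 K^-1

.adj_r2 <- function(y, fitted, n_par) {
  n <- length(y)
  ss <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  1 - (1 - (1 - ss / sst)) * (n - 1) / (n - n_par - 1)
}

.fit_result <- function(model, parameters, y, fitted, n_par, extra = list()) {
  structure(c(list(model = model, parameters = parameters,
                   adj_r_squared = .adj_r2(y, fitted, n_par),
                   residuals = y - fitted, fitted = fitted), extra),
            class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat(sprintf("<hb_fit> %s: %s; adj R^2 = %.4f\n", x$model,
              paste(names(x$parameters), signif(unlist(x$parameters), 4),
                    sep = " = ", collapse = ", "),
              x$adj_r_squared))
  invisible(x)
}

#' Two-exponential decay fit of a survival correlator
#'
#' Least-squares fit of `a exp(-t/tau1) + (1 - a) exp(-t/tau2)` with
#' `a` constrained to `[0, 1]`, multi-started over a decade-spaced grid of
#' initial `(tau1, tau2)` pairs with the best fit reported; deterministic
#' given the grid.  The components are ordered `tau1 <= tau2`.  A fit where
#' the two components collapse (nearly equal time constants or a weight at
#' the boundary) is flagged `degenerate`, not an error - it is the expected
#' outcome on single-exponential data.
#'
#' @param corr an `hb_corr`, or a list with `lag` (fs) and `value`.
#' @return `hb_fit` with parameters `a`, `tau1`, `tau2` (fs) and a
#'   `degenerate` flag.
#' @export
fit_two_exponential <- function(corr) {
  t <- corr$lag
  y <- corr$value
  stopifnot(length(t) >= 6, all(y > 0), all(y <= 1))
  grid <- 10^(0:4)
  starts <- expand.grid(tau1 = grid, tau2 = grid)
  starts <- starts[starts$tau1 <= starts$tau2, ]
  model <- function(p) p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3])
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(0.5, starts$tau1[k], starts$tau2[k]),
        lower = c(0, 1e-6, 1e-6), upper = c(1, 1e12, 1e12),
        fn = function(p) y - model(p),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("two-exponential fit failed to converge from every start; ",
         "check that the correlator decays")
  p <- list(a = best$par[1], tau1 = best$par[2], tau2 = best$par[3])
  if (p$tau1 > p$tau2) p <- list(a = 1 - p$a, tau1 = p$tau2, tau2 = p$tau1)
  degenerate <- (p$tau2 - p$tau1) / p$tau2 < 0.05 || p$a < 0.01 || p$a > 0.99
  fitted <- p$a * exp(-t / p$tau1) + (1 - p$a) * exp(-t / p$tau2)
  .fit_result("two_exponential", p, y, fitted, 3,
              list(degenerate = degenerate))
}

#' Transition-state-theory fit of reciprocal intermittent lifetime
#'
#' Nonlinear least squares of `1/tau = A' T exp(-E / (R T))` on reciprocal
#' lifetimes in 1/ps as a function of temperature, unweighted, initialized
#' from the linearized `ln((1/tau)/T)` vs `1/T` regression.  `A'` is
#' reported in 1/ps and the activation energy `E` in kJ/mol
#' (R = 8.314 J/(mol K)).
#'
#' @param temps temperatures (K), at least 3.
#' @param tau_int intermittent lifetimes (fs), all positive.
#' @return `hb_fit` with parameters `A_prime` (1/ps) and `E_act` (kJ/mol).
#' @export
fit_tst <- function(temps, tau_int) {
  stopifnot(length(temps) == length(tau_int), length(temps) >= 3)
  if (any(tau_int <= 0)) stop("lifetimes must be positive")
  y <- 1000 / tau_int  # 1/ps
  lin <- lm(log(y / temps) ~ I(1 / temps))
  A0 <- unname(exp(coef(lin)[1]))
  E0 <- unname(-coef(lin)[2] * .gas_R / 1000)
  model <- function(p) p[1] * temps * exp(-p[2] * 1000 / (.gas_R * temps))
  fit <- minpack.lm::nls.lm(par = c(A0, E0), lower = c(1e-12, 0),
                            upper = c(Inf, Inf),
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  .fit_result("tst", list(A_prime = p[1], E_act = p[2]), y, model(p), 2)
}

#' Linear temperature law of the monomer lifetime
#'
#' Ordinary least squares of the monomer lifetime (fs) on temperature (K).
#' The linear regime holds only up to `max_temp` (default 573 K, where the
#' continuous network is lost); points above are excluded from the fit.
#'
#' @param temps temperatures (K).
#' @param tau_nb monomer lifetimes (fs).
#' @param max_temp upper temperature bound of the fitted regime (K); use
#'   `Inf` to fit all points.
#' @return `hb_fit` with parameters `slope` (fs/K) and `intercept` (fs).
#' @export
fit_linear_monomer <- function(temps, tau_nb, max_temp = 573) {
  stopifnot(length(temps) == length(tau_nb))
  keep <- temps <= max_temp
  temps <- temps[keep]
  tau_nb <- tau_nb[keep]
  if (length(temps) < 3)
    stop("need at least 3 points at or below max_temp")
  fit <- lm(tau_nb ~ temps)
  .fit_result("linear",
              list(slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1])),
              tau_nb, unname(predict(fit)), 1)
}

#' Ratio of a lifetime column between two state points
#'
#' @param table data.frame with a temperature column `T_K` and lifetime
#'   columns (e.g. from [hb_lifetimes()]).
#' @param state_a,state_b temperatures (K) identifying the two states.
#' @param column lifetime column name (e.g. `"tau_nb_fs"`).
#' @return dimensionless ratio `column[state_a] / column[state_b]`.
#' @export
lifetime_ratio <- function(table, state_a, state_b, column) {
  ia <- match(state_a, table$T_K)
  ib <- match(state_b, table$T_K)
  if (is.na(ia) || is.na(ib))
    stop("state not present in the table: ",
         paste(c(state_a, state_b)[is.na(c(ia, ib))], collapse = ", "), " K")
  if (!column %in% names(table)) stop("no column '", column, "' in the table")
  table[[column]][ia] / table[[column]][ib]
}
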
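#' Parameters of the two-step photodissociation kinetic scheme
#'
#' Linear scheme: cis <-> trans (effective photoisomerization `k_iso`,
#' proportional to incident power times isomerization quantum efficiency,
#' and thermal reversion `k_rev`), followed by light-independent strand
#' loss from trans (`k_diss`), spontaneous loss from cis in the dark
#' (`k_dark`), and pseudo-first-order binding of the excess labelled strand
#' (`k_bind`) producing the exchanged (color-shifted) species.
#'
#' @param k_iso,k_rev,k_diss,k_dark,k_bind rates (1/min), all >= 0.
#' @return object of class `two_step_params`.
#' @export
two_step_params <- function(k_iso, k_rev, k_diss, k_dark = 0, k_bind) {
  p <- c(k_iso = k_iso, k_rev = k_rev, k_diss = k_diss, k_dark = k_dark,
         k_bind = k_bind)
  if (any(p < 0)) stop("negative rate constant")
  structure(as.list(p), class = "two_step_params")
}

two_step_matrix <- function(p) {
  # states: cis, trans, empty, exchanged
  matrix(c(
    -(p$k_iso + p$k_dark), p$k_rev,                 0,        0,
    p$k_iso,              -(p$k_rev + p$k_diss),    0,        0,
    p$k_dark,              p$k_diss,               -p$k_bind, 0,
    0,                     0,                       p$k_bind, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("cis", "trans", "empty", "exchanged"), NULL))
}

#' Simulate the two-step photodissociation scheme
#'
#' Numerically integrates the linear kinetic scheme
#' cis <-> trans -> empty -> exchanged (with spontaneous cis -> empty in
#' the dark) with a stiff-capable implicit integrator.
#'
#' @param params a [two_step_params()].
#' @param t_grid increasing times (min) starting at 0.
#' @return data.frame with columns `time`, `cis`, `trans`, `empty`,
#'   `exchanged`; fractions sum to 1 at all times.
#' @export
simulate_two_step <- function(params, t_grid) {
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid, strictly = TRUE))
  A <- two_step_matrix(params)
  deriv <- function(t, y, parms) list(as.vector(A %*% y))
  out <- deSolve::ode(y = c(cis = 1, trans = 0, empty = 0, exchanged = 0),
                      times = t_grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  out
}

#' Effective pseudo-first-order exchange rate of the scheme
#'
#' Steady-state closed form for the observed exchange rate when binding is
#' fast and isomerization is rate-limiting:
#' `k_obs = k_iso * k_diss / (k_rev + k_diss)`.
#'
#' @param params a [two_step_params()].
#' @return rate (1/min).
#' @export
steady_state_rate <- function(params) {
  params$k_iso * params$k_diss / (params$k_rev + params$k_diss)
}

#' Fit a pseudo-first-order exchange trace
#'
#' Nonlinear least squares of `signal = offset + amplitude * (1 - exp(-k
#' t))`, the single-exponential form of the strand-exchange readout, with
#' starting values from log-linearization. A constant trace returns
#' `k_obs = 0` flagged with infinite standard error.
#'
#' @param trace an `exchange_trace` or data.frame with columns `t_min` and
#'   `signal` (at least 4 points).
#' @return an `exchange_fit` with elements `k_obs`, `amplitude`, `offset`,
#'   `stderr` (of `k_obs`), `sigma` (residual sd), `flat`, and the fitted
#'   model; supports `coef`, `print`, `summary`, `predict`, `residuals`
#'   and `plot`.
#' @export
fit_exchange <- function(trace) {
  t <- trace$t_min
  y <- trace$signal
  if (length(t) < 4) stop("need at least 4 points to fit")
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    fit <- structure(list(k_obs = 0, amplitude = 0, offset = mean(y),
                          stderr = Inf, sigma = 0, flat = TRUE,
                          trace = trace, model = NULL),
                     class = "exchange_fit")
    return(fit)
  }
  off0 <- min(y)
  amp0 <- max(y) - min(y)
  frac <- 1 - (y - off0) / (amp0 * 1.05)
  frac[frac < 1e-6] <- 1e-6
  k0 <- max(1e-6, -stats::coef(stats::lm(log(frac) ~ t))[["t"]])
  m <- minpack.lm::nlsLM(
    y ~ offset + amplitude * (1 - exp(-k * t)),
    start = list(offset = off0, amplitude = amp0, k = k0),
    lower = c(-Inf, 0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!m$convInfo$isConv)
    stop("exchange fit did not converge: ", m$convInfo$stopMessage)
  est <- stats::coef(m)
  se <- summary(m)$coefficients[, "Std. Error"]
  structure(list(k_obs = unname(est["k"]),
                 amplitude = unname(est["amplitude"]),
                 offset = unname(est["offset"]),
                 stderr = unname(se["k"]),
                 sigma = summary(m)$sigma,
                 flat = FALSE, trace = trace, model = m),
            class = "exchange_fit")
}

#' @export
coef.exchange_fit <- function(object, ...) {
  c(k_obs = object$k_obs, amplitude = object$amplitude,
    offset = object$offset)
}

#' @export
print.exchange_fit <- function(x, ...) {
  if (x$flat) {
    cat("exchange_fit: constant signal, k_obs = 0 (stderr Inf)\n")
  } else {
    cat(sprintf(
      "exchange_fit: k_obs = %.4g min^-1 (se %.2g), amplitude %.3g, offset %.3g\n",
      x$k_obs, x$stderr, x$amplitude, x$offset))
  }
  invisible(x)
}

#' @export
summary.exchange_fit <- function(object, ...) {
  cat(sprintf("Pseudo-first-order exchange fit on %d points\n",
              nrow(object$trace)))
  print(object)
  if (!object$flat)
    cat(sprintf("  residual sd %.3g, t_half = %.3g min\n", object$sigma,
                log(2) / object$k_obs))
  invisible(object)
}

#' @export
predict.exchange_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$t_min else newdata$t_min
  object$offset + object$amplitude * (1 - exp(-object$k_obs * t))
}

#' @export
residuals.exchange_fit <- function(object, ...) {
  object$trace$signal - predict(object)
}

#' @export
plot.exchange_fit <- function(x, ...) {
  graphics::plot(x$trace$t_min, x$trace$signal, xlab = "time (min)",
                 ylab = "signal (a.u.)", ...)
  tt <- seq(min(x$trace$t_min), max(x$trace$t_min), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(t_min = tt)), col = 2)
  invisible(x)
}

#' Ratio of two fitted exchange rates
#'
#' First-order uncertainty propagation of `k_a / k_b`, the form in which
#' mutant accelerations (e.g. a 20-fold faster triple mutant) and
#' light/dark contrasts (e.g. an 85-fold slower dark exchange) are
#' reported.
#'
#' @param fit_a,fit_b `exchange_fit` objects (or lists with `k_obs`,
#'   `stderr`).
#' @return the ratio, with its propagated standard error in attribute
#'   `"stderr"`.
#' @export
rate_ratio <- function(fit_a, fit_b) {
  if (fit_b$k_obs <= 0) stop("denominator rate is zero")
  r <- fit_a$k_obs / fit_b$k_obs
  se <- r * sqrt((fit_a$stderr / fit_a$k_obs)^2 +
                   (fit_b$stderr / fit_b$k_obs)^2)
  structure(r, stderr = se)
}

#' Fit a directory (or list) of exchange traces into a rate table
#'
#' @param traces named list of `exchange_trace` objects.
#' @return data.frame with one row per trace: `variant`, `light_on`,
#'   `k_obs`, `stderr`.
#' @export
exchange_rate_table <- function(traces) {
  rows <- lapply(names(traces), function(nm) {
    f <- fit_exchange(traces[[nm]])
    data.frame(variant = nm,
               light_on = isTRUE(attr(traces[[nm]], "light_on")),
               k_obs = f$k_obs, stderr = f$stderr)
  })
  do.call(rbind, rows)
}
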
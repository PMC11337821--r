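#' No-lag primary growth model curves
#'
#' Predicted log10 bacterial concentration at storage time `t` under the two
#' no-lag primary growth models commonly used for refrigerated produce:
#' a smooth saturating form (Baranyi without lag) and a piecewise
#' log-linear/plateau form (Buchanan without lag, also called the three-phase
#' linear model with the lag phase removed).
#'
#' The Baranyi no-lag curve on the log10 scale is
#' \deqn{\log_{10} N(t) = N_{max} - \log_{10}\!\left(1 + (10^{N_{max}-N_0} - 1)\, e^{-\mu_{max} t}\right)}
#' which equals \eqn{N_0} at \eqn{t = 0} and approaches \eqn{N_{max}} as
#' \eqn{t \to \infty}. The Buchanan no-lag curve is
#' \deqn{\log_{10} N(t) = \min\!\left(N_0 + \mu_{max} t / \ln 10,\; N_{max}\right)}
#' with breakpoint \eqn{t^* = \ln(10)(N_{max}-N_0)/\mu_{max}}.
#'
#' @param t Time since packaging, in days (vectorised).
#' @param N0 Initial concentration at day 0, log10 CFU/g.
#' @param mumax Maximum specific growth rate, ln(CFU/g) per day (must be > 0).
#' @param Nmax Stationary-phase concentration, log10 CFU/g (must be >= `N0`).
#'
#' @return Numeric vector of log10 CFU/g, same length as `t`.
#' @seealso [fit_growth()], [time_to_threshold()]
#' @examples
#' baranyi_nolag_log10(7, N0 = 5, mumax = 0.5, Nmax = 8)
#' buchanan_nolag_log10(7, N0 = 5, mumax = 0.5, Nmax = 8)
#' @export
baranyi_nolag_log10 <- function(t, N0, mumax, Nmax) {
  check_growth_params(N0, mumax, Nmax)
  stopifnot(is.numeric(t), all(is.finite(t)))
  # log1p form is stable for large mumax * t where exp(mumax * t) overflows
  Nmax - log1p((10^(Nmax - N0) - 1) * exp(-mumax * t)) / log(10)
}

#' @rdname baranyi_nolag_log10
#' @export
buchanan_nolag_log10 <- function(t, N0, mumax, Nmax) {
  check_growth_params(N0, mumax, Nmax)
  stopifnot(is.numeric(t), all(is.finite(t)))
  pmin(N0 + mumax * t / log(10), Nmax)
}

check_growth_params <- function(N0, mumax, Nmax) {
  if (!all(is.finite(N0), is.finite(mumax), is.finite(Nmax))) {
    abort("Growth parameters must be finite.")
  }
  if (mumax <= 0) abort("`mumax` must be positive.")
  if (Nmax < N0) abort("`Nmax` must be >= `N0`.")
  invisible(TRUE)
}

growth_model_fun <- function(model) {
  switch(match.arg(model, c("baranyi_nolag", "buchanan_nolag")),
    baranyi_nolag = baranyi_nolag_log10,
    buchanan_nolag = buchanan_nolag_log10
  )
}

#' Time for a fitted growth curve to reach a threshold concentration
#'
#' Analytic inversion of the no-lag growth curves for the storage time at
#' which log10 concentration reaches a threshold `X` (e.g. the 7 log10 CFU/g
#' quality threshold for packaged spinach). Optionally the initial
#' concentration is overridden (the "what if all lots started at
#' 5 log10 CFU/g" counterfactual) while the fitted growth rate and plateau are
#' retained.
#'
#' Closed forms: for the Buchanan no-lag model
#' \eqn{t = \ln(10)(X - N_0)/\mu_{max}}; for the Baranyi no-lag model
#' \eqn{t = \ln\{D(E-1)/(1-D)\}/\mu_{max}} with \eqn{D = 10^{X - N_{max}}} and
#' \eqn{E = 10^{N_{max} - N_0}}. Both round-trip through the model function to
#' `X` within 1e-9.
#'
#' @param fit A [growth_fit][fit_growth] object, or a list with elements
#'   `model`, `N0`, `mumax`, `Nmax`.
#' @param threshold Target concentration `X`, log10 CFU/g.
#' @param N0_override Optional replacement initial concentration,
#'   log10 CFU/g.
#' @return Time in days (length 1 numeric). Errors when the threshold is not
#'   strictly between the (effective) initial concentration and the plateau,
#'   the situation in which a time to threshold is undefined; a threshold
#'   exactly equal to the initial concentration returns 0.
#' @examples
#' fit <- list(model = "buchanan_nolag", N0 = 5.31, mumax = 0.37, Nmax = 9.03)
#' time_to_threshold(fit, 7) # 10.5 days to one decimal
#' @export
time_to_threshold <- function(fit, threshold = 7, N0_override = NULL) {
  N0 <- if (is.null(N0_override)) fit$N0 else N0_override
  mumax <- fit$mumax
  Nmax <- fit$Nmax
  check_growth_params(N0, mumax, Nmax)
  if (threshold == N0) return(0)
  if (threshold < N0 || threshold >= Nmax) {
    abort(sprintf(
      "Threshold %.2f is outside (N0 = %.2f, Nmax = %.2f); time to threshold is undefined.",
      threshold, N0, Nmax
    ))
  }
  model <- match.arg(fit$model, c("baranyi_nolag", "buchanan_nolag"))
  if (model == "buchanan_nolag") {
    log(10) * (threshold - N0) / mumax
  } else {
    D <- 10^(threshold - Nmax)
    E <- 10^(Nmax - N0)
    log(D * (E - 1) / (1 - D)) / mumax
  }
}

#' Stationary-phase check from observed shelf-life counts
#'
#' A sample is taken to have reached stationary phase when the difference in
#' (mean) log10 concentration between the last and the second-to-last test day
#' is below 0.50 log10 CFU/g.
#'
#' @param data Data frame of observations with columns `day` and
#'   `log10_conc`; replicate rows per day are averaged first.
#' @param delta Stationary cutoff on the last-step increase, log10 CFU/g.
#' @return A one-row tibble with `diff_last` (last minus second-to-last day
#'   mean) and logical `reached_stationary`.
#' @export
stationary_check <- function(data, delta = 0.50) {
  means <- day_means(data)
  if (nrow(means) < 2) abort("Need observations on at least 2 distinct days.")
  k <- nrow(means)
  d <- means$log10_conc[k] - means$log10_conc[k - 1]
  tibble(diff_last = d, reached_stationary = d < delta)
}

#' Net growth over shelf life
#'
#' Mean log10 concentration on the last test day minus the mean on the first
#' test day.
#'
#' @inheritParams stationary_check
#' @return Net growth in log10 CFU/g (length 1 numeric).
#' @export
net_growth <- function(data) {
  means <- day_means(data)
  if (nrow(means) < 2) abort("Need observations on at least 2 distinct days.")
  means$log10_conc[nrow(means)] - means$log10_conc[1]
}

day_means <- function(data) {
  stopifnot(all(c("day", "log10_conc") %in% names(data)))
  data %>%
    group_by(day = .data$day) %>%
    summarise(log10_conc = mean(.data$log10_conc), .groups = "drop") %>%
    arrange(.data$day)
}
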
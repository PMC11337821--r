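#' Fit a no-lag primary growth model to shelf-life counts
#'
#' Nonlinear least squares on the log10 scale via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]), with data-driven start values and bounded
#' parameters. Start values: `N0` from the first observation, `Nmax` from the
#' maximum observation, `mumax` from the steepest adjacent log-linear slope
#' (converted to ln units, floored at 0.1). Up to `restarts` jittered restarts
#' are attempted before the fit is flagged as non-converged.
#'
#' @param data Data frame with columns `day` (days since packaging) and
#'   `log10_conc` (log10 CFU/g). At least 4 observations spanning at least 2
#'   distinct days are required.
#' @param model `"baranyi_nolag"` or `"buchanan_nolag"`.
#' @param restarts Maximum number of jittered restarts after a failed fit.
#' @return A `growth_fit` object: list with `model`, `N0`, `mumax`, `Nmax`,
#'   `rss`, `n_obs`, `aic`, `converged`, `degenerate` and the observed data.
#'   The AIC convention is \eqn{n \log(RSS/n) + 2k} with \eqn{k = 4} (three
#'   kinetic parameters plus the residual variance). Fits with
#'   `Nmax - N0 < 0.1` are flagged `degenerate`.
#' @seealso [select_model()], [time_to_threshold()], [fit_growth_curves()]
#' @examples
#' obs <- tibble::tibble(
#'   day = c(0, 7, 12, 17, 22),
#'   log10_conc = baranyi_nolag_log10(c(0, 7, 12, 17, 22), 5, 0.5, 8)
#' )
#' fit <- fit_growth(obs, "baranyi_nolag")
#' tidy(fit)
#' @export
fit_growth <- function(data, model = c("baranyi_nolag", "buchanan_nolag"),
                       restarts = 5) {
  model <- match.arg(model)
  stopifnot(all(c("day", "log10_conc") %in% names(data)))
  data <- as_tibble(data)[c("day", "log10_conc")]
  if (nrow(data) < 4 || dplyr::n_distinct(data$day) < 2) {
    abort("Growth fitting needs >= 4 observations spanning >= 2 distinct days.")
  }
  if (any(data$day < 0)) abort("`day` must be non-negative.")

  ord <- order(data$day)
  dd <- data[ord, ]
  start <- growth_start_values(dd)
  lower <- c(N0 = 0, mumax = 1e-6, Nmax = 0)
  upper <- c(N0 = 12, mumax = 10, Nmax = 12)
  fun <- growth_model_fun(model)

  best <- NULL
  for (i in seq_len(restarts + 1)) {
    st <- start
    if (i > 1) { # jitter restarts around the heuristic start
      st$N0 <- min(max(start$N0 + rnorm(1, 0, 0.3), 0.01), 11.9)
      st$Nmax <- min(max(start$Nmax + rnorm(1, 0, 0.3), st$N0 + 0.05), 12)
      st$mumax <- min(max(start$mumax * exp(rnorm(1, 0, 0.4)), 1e-3), 9.9)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        log10_conc ~ fun(day, N0, mumax, Nmax),
        data = dd, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10, ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      cf <- coef(fit)
      if (cf[["Nmax"]] >= cf[["N0"]]) {
        rss <- sum(resid(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12) {
          best <- list(fit = fit, rss = rss)
        }
      }
    }
    if (!is.null(best) && i == 1) break # first attempt succeeded
  }

  n <- nrow(dd)
  if (is.null(best)) {
    res <- list(
      model = model, N0 = NA_real_, mumax = NA_real_, Nmax = NA_real_,
      rss = NA_real_, n_obs = n, aic = Inf, converged = FALSE,
      degenerate = NA, data = dd
    )
    return(structure(res, class = "growth_fit"))
  }
  cf <- coef(best$fit)
  rss <- best$rss
  aic <- n * log(max(rss, 1e-300) / n) + 2 * 4
  res <- list(
    model = model, N0 = unname(cf["N0"]), mumax = unname(cf["mumax"]),
    Nmax = unname(cf["Nmax"]), rss = rss, n_obs = n, aic = aic,
    converged = TRUE, degenerate = unname(cf["Nmax"] - cf["N0"]) < 0.1,
    data = dd
  )
  structure(res, class = "growth_fit")
}

growth_start_values <- function(dd) {
  means <- day_means(dd)
  slopes <- diff(means$log10_conc) / diff(means$day)
  mu0 <- log(10) * max(slopes, 0.05)
  list(
    N0 = max(means$log10_conc[1], 0.01),
    mumax = min(max(mu0, 0.1), 9.9),
    Nmax = min(max(max(means$log10_conc), means$log10_conc[1] + 0.2), 12)
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit: %s>\n  N0 = %.3f log10 CFU/g, mumax = %.3f /day, Nmax = %.3f log10 CFU/g\n  n = %d, RSS = %.4g, AIC = %.2f, converged = %s\n",
    x$model, x$N0, x$mumax, x$Nmax, x$n_obs, x$rss, x$aic, x$converged
  ))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("N0", "mumax", "Nmax"),
    estimate = c(x$N0, x$mumax, x$Nmax),
    unit = c("log10 CFU/g", "ln(CFU/g)/day", "log10 CFU/g")
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    model = x$model, rss = x$rss, n_obs = x$n_obs, aic = x$aic,
    converged = x$converged, degenerate = x$degenerate
  )
}

#' Select the better of several candidate growth fits by AIC
#'
#' Returns the converged fit with the lowest AIC; exact ties are broken in
#' favour of the Baranyi no-lag model.
#'
#' @param ... `growth_fit` objects, or a single list of them.
#' @return The selected `growth_fit`.
#' @export
select_model <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "growth_fit")) fits <- fits[[1]]
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) abort("No converged growth fits to select from.")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  best <- which(aic == min(aic))
  if (length(best) > 1) {
    is_bar <- vapply(fits[best], function(f) f$model == "baranyi_nolag", logical(1))
    best <- if (any(is_bar)) best[which(is_bar)[1]] else best[1]
  }
  fits[[best]]
}

#' Per-sample growth-curve fitting, model selection and threshold inversion
#'
#' Fits both no-lag growth models to each sample's (aggregated) shelf-life
#' counts, selects per sample by AIC, and computes the time to reach a
#' spoilage threshold, plus the counterfactual time under a common initial
#' concentration.
#'
#' @param data Data frame with columns `sample_id`, `day`, `log10_conc`
#'   (one row per sample x day, e.g. the output of [aggregate_replicates()]
#'   filtered to one test type and renamed).
#' @param model `"auto"` (fit both, select by AIC) or one of the model names.
#' @param threshold Threshold concentration, log10 CFU/g.
#' @param N0_override Optional common initial concentration for the
#'   counterfactual inversion; `NULL` skips it.
#' @return A tibble with one row per sample: fitted parameters, AIC, the
#'   selected model, `days_to_threshold` and (when requested)
#'   `days_to_threshold_n0fix`. Samples whose fitted curve cannot reach the
#'   threshold (plateau below it, or initial concentration above it) get `NA`
#'   with a reason in `threshold_note`.
#' @export
fit_growth_curves <- function(data, model = c("auto", "baranyi_nolag", "buchanan_nolag"),
                              threshold = 7, N0_override = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("sample_id", "day", "log10_conc") %in% names(data)))
  data %>%
    group_by(sample_id = .data$sample_id) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(row = purrr::map(.data$data, function(d) {
      fits <- if (model == "auto") {
        list(
          fit_growth(d, "baranyi_nolag"),
          fit_growth(d, "buchanan_nolag")
        )
      } else {
        list(fit_growth(d, model))
      }
      conv <- Filter(function(f) isTRUE(f$converged), fits)
      if (length(conv) == 0) {
        return(tibble(
          model = NA_character_, N0 = NA_real_, mumax = NA_real_,
          Nmax = NA_real_, rss = NA_real_, aic = NA_real_, converged = FALSE,
          days_to_threshold = NA_real_, threshold_note = "no converged fit"
        ))
      }
      sel <- select_model(conv)
      tt <- tryCatch(time_to_threshold(sel, threshold), error = function(e) NA_real_)
      note <- if (is.na(tt)) "threshold outside (N0, Nmax)" else NA_character_
      out <- tibble(
        model = sel$model, N0 = sel$N0, mumax = sel$mumax, Nmax = sel$Nmax,
        rss = sel$rss, aic = sel$aic, converged = TRUE,
        days_to_threshold = tt, threshold_note = note
      )
      if (!is.null(N0_override)) {
        out$days_to_threshold_n0fix <- tryCatch(
          time_to_threshold(sel, threshold, N0_override = N0_override),
          error = function(e) NA_real_
        )
      }
      out
    })) %>%
    select("sample_id", "row") %>%
    tidyr::unnest("row")
}

#' Plot observed counts with the fitted growth curve
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  grid <- tibble(day = seq(0, max(object$data$day), length.out = 200))
  fun <- growth_model_fun(object$model)
  grid$log10_conc <- fun(grid$day, object$N0, object$mumax, object$Nmax)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$day, .data$log10_conc)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Day of shelf life",
      y = expression(log[10] ~ CFU / g),
      title = sprintf("%s fit", object$model)
    ) +
    ggplot2::theme_minimal()
}
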
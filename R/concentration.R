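#' Aggregate replicate plate counts to geometric means
#'
#' The geometric mean concentration of a sample is the arithmetic mean of the
#' log10-transformed replicate concentrations; all downstream modelling runs
#' on these per-sample x test x day means.
#'
#' @param records Data frame of replicate records with columns `sample_id`,
#'   `test`, `shelf_day`, `log10_cfu_g`; extra grouping columns (`region`,
#'   `sample_type`, ...) are carried through.
#' @return Tibble with one row per sample x test x day and column
#'   `geo_mean_log10`.
#' @export
aggregate_replicates <- function(records) {
  needed <- c("sample_id", "test", "shelf_day", "log10_cfu_g")
  stopifnot(all(needed %in% names(records)))
  carry <- intersect(c("region", "sample_type"), names(records))
  records %>%
    group_by(across(dplyr::all_of(c("sample_id", carry, "test", "shelf_day")))) %>%
    summarise(
      geo_mean_log10 = mean(.data$log10_cfu_g),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Type-7 sample quantiles
#'
#' Linear-interpolation quantiles with plotting position
#' \eqn{h = (n-1)p + 1} — R's default `type = 7`, used for all medians and
#' interquartile ranges in this package.
#'
#' @param x Numeric vector (non-empty; `NA` removed).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, named by probability.
#' @export
quantile_type7 <- function(x, probs = c(0.25, 0.5, 0.75)) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("Cannot take quantiles of an empty vector.")
  if (any(probs < 0 | probs > 1)) abort("`probs` must lie in [0, 1].")
  quantile(x, probs = probs, type = 7, names = TRUE)
}

#' Orthogonal polynomial design columns for shelf day
#'
#' Degree-`degree` orthogonal polynomial contrasts of the day variable:
#' columns are mutually orthogonal, unit norm, and orthogonal to the
#' constant, so linear and quadratic shelf-life trends are estimated on
#' uncorrelated axes.
#'
#' @param days Numeric vector of day values.
#' @param degree Polynomial degree (default 2).
#' @return Matrix with `degree` columns named `poly1`, `poly2`, ...
#' @export
orthogonal_poly <- function(days, degree = 2) {
  if (dplyr::n_distinct(days) < degree + 1) {
    abort(sprintf("Need at least %d distinct day values for degree %d.", degree + 1, degree))
  }
  m <- unclass(poly(days, degree = degree))
  colnames(m) <- paste0("poly", seq_len(degree))
  attr(m, "coefs") <- NULL
  m
}

#' Screen for a test-by-region interaction
#'
#' Fits a combined mixed model of geometric-mean log10 concentration on test
#' type, growing region and their interaction (random intercept per
#' sample x test for packaged data with a shelf-day polynomial, random
#' intercept per sample for harvest data) and asks whether the effect of
#' region differs among the plate-count tests. A significant interaction
#' routes the analysis to separate per-test models; otherwise a single model
#' is fit to APC only.
#'
#' @param data Aggregated counts (one row per sample x test x day) with
#'   columns `sample_id`, `test`, `region`, `geo_mean_log10` and, for
#'   packaged data, `shelf_day`.
#' @param alpha Significance level for the interaction.
#' @param packaged Logical: include the shelf-day polynomial and use the
#'   sample x test random intercept.
#' @return List: `p_value` of the interaction, `decision` (`"separate_tests"`
#'   or `"apc_only"`), and the fitted screen model.
#' @export
interaction_screen <- function(data, alpha = 0.05, packaged = TRUE) {
  stopifnot(all(c("sample_id", "test", "region", "geo_mean_log10") %in% names(data)))
  if (dplyr::n_distinct(data$test) < 2) abort("Need at least 2 test types.")
  if (dplyr::n_distinct(data$region) < 2) abort("Need at least 2 regions.")
  data <- mutate(data, unit = interaction(.data$sample_id, .data$test))
  if (packaged) {
    pd <- orthogonal_poly(data$shelf_day, 2)
    data$day_lin <- pd[, 1]
    data$day_quad <- pd[, 2]
    f <- geo_mean_log10 ~ test * region + day_lin + day_quad + (1 | unit)
  } else {
    f <- geo_mean_log10 ~ test * region + (1 | sample_id)
  }
  fit <- lmerTest::lmer(f, data = data, REML = FALSE)
  an <- anova(fit, type = 2)
  p <- an["test:region", "Pr(>F)"]
  list(
    p_value = p,
    decision = if (p < alpha) "separate_tests" else "apc_only",
    model = fit
  )
}

#' Fit a fixed- or mixed-effects concentration model
#'
#' The workhorse for the harvest-sample (fixed effects) and packaged-sample
#' (random intercept per lot) concentration models: geometric-mean log10
#' concentration regressed on arbitrary fixed terms, with shelf day entered
#' as an orthogonal second-degree polynomial when `"poly_day"` appears in
#' `fixed_terms`.
#'
#' @param data Aggregated counts plus any covariates named in `fixed_terms`.
#' @param fixed_terms Character vector of fixed-effect terms; `"poly_day"`
#'   expands to the orthogonal linear + quadratic day columns.
#' @param random_intercept Optional name of the grouping column for a random
#'   intercept (`NULL` fits an ordinary linear model).
#' @param objective `"REML"` (final estimates) or `"ML"` (model selection);
#'   ignored for fixed-effects fits.
#' @param response Name of the response column.
#' @return A `region_fit` object wrapping the `lm`/`lmerModLmerTest` fit;
#'   inspect with [tidy()] and [glance()].
#' @export
fit_region_model <- function(data, fixed_terms,
                             random_intercept = NULL,
                             objective = c("REML", "ML"),
                             response = "geo_mean_log10") {
  objective <- match.arg(objective)
  data <- as_tibble(data)
  terms_expanded <- expand_poly_day(fixed_terms, data)
  data <- terms_expanded$data
  rhs <- paste(terms_expanded$terms, collapse = " + ")
  if (length(terms_expanded$terms) == 0) rhs <- "1"
  if (is.null(random_intercept)) {
    f <- as.formula(paste(response, "~", rhs))
    fit <- lm(f, data = data)
    check_full_rank(fit)
  } else {
    f <- as.formula(paste(response, "~", rhs, "+ (1 |", random_intercept, ")"))
    fit <- lmerTest::lmer(f, data = data, REML = objective == "REML")
  }
  structure(
    list(fit = fit, fixed_terms = terms_expanded$terms,
         random_intercept = random_intercept, objective = objective,
         response = response, data = data),
    class = "region_fit"
  )
}

expand_poly_day <- function(fixed_terms, data) {
  if ("poly_day" %in% fixed_terms) {
    if (!"shelf_day" %in% names(data)) abort("`poly_day` needs a `shelf_day` column.")
    pd <- orthogonal_poly(data$shelf_day, 2)
    data$day_lin <- pd[, 1]
    data$day_quad <- pd[, 2]
    fixed_terms <- unique(unlist(lapply(fixed_terms, function(t) {
      if (t == "poly_day") c("day_lin", "day_quad") else t
    })))
  }
  list(terms = fixed_terms, data = data)
}

check_full_rank <- function(fit) {
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Design is rank deficient; aliased terms: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(fit)
}

#' @export
print.region_fit <- function(x, ...) {
  kind <- if (is.null(x$random_intercept)) "fixed-effects" else
    sprintf("mixed-effects (random intercept: %s, %s)", x$random_intercept, x$objective)
  cat(sprintf("<region_fit: %s>\n", kind))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.region_fit <- function(x, ...) {
  if (is.null(x$random_intercept)) {
    s <- summary(x$fit)$coefficients
    tibble(
      term = rownames(s), estimate = unname(s[, 1]),
      std_error = unname(s[, 2]), df = x$fit$df.residual,
      statistic = unname(s[, 3]), p_value = unname(s[, 4])
    )
  } else {
    s <- summary(x$fit)$coefficients # lmerTest: Satterthwaite df
    tibble(
      term = rownames(s), estimate = unname(s[, "Estimate"]),
      std_error = unname(s[, "Std. Error"]), df = unname(s[, "df"]),
      statistic = unname(s[, "t value"]), p_value = unname(s[, "Pr(>|t|)"])
    )
  }
}

#' @export
glance.region_fit <- function(x, ...) {
  out <- tibble(
    loglik = as.numeric(logLik(x$fit)),
    aic = AIC(x$fit),
    objective = if (is.null(x$random_intercept)) "OLS" else x$objective,
    n_obs = nrow(x$data)
  )
  if (!is.null(x$random_intercept)) {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    out$random_intercept_variance <- vc$vcov[vc$grp == x$random_intercept][1]
    out$residual_variance <- vc$vcov[vc$grp == "Residual"][1]
    out$singular <- lme4::isSingular(x$fit)
  } else {
    out$residual_variance <- summary(x$fit)$sigma^2
  }
  out
}

#' Protected backward elimination of fixed effects
#'
#' Starting from the full term list, repeatedly refits the model (with the
#' ML objective for mixed models) and drops the single least-significant
#' eligible term whose p-value exceeds `alpha`, respecting marginality
#' (interaction terms are dropped before their main effects) and never
#' touching `keep` terms. Mixed models are refit with REML at the end.
#'
#' Likelihoods and AICs along the trace use the ML objective; the marginal
#' F-test p-values that drive each drop are computed on a REML refit of the
#' same terms, where the Satterthwaite denominator-df approximation is
#' calibrated (on ML fits it is anti-conservative).
#'
#' @inheritParams fit_region_model
#' @param keep Character vector of protected terms (default `"region"`).
#' @param alpha Retention threshold: terms with p > alpha are candidates for
#'   removal.
#' @return List: `fit` (final `region_fit`, REML for mixed models) and
#'   `trace` tibble (step, term dropped, its p-value, AIC after the drop).
#' @export
backward_eliminate <- function(data, fixed_terms, keep = "region",
                               random_intercept = NULL, alpha = 0.10,
                               response = "geo_mean_log10") {
  current <- fixed_terms
  trace <- tibble(step = integer(), dropped = character(),
                  p_value = numeric(), aic = numeric())
  step_i <- 0L
  repeat {
    fit <- fit_region_model(data, current, random_intercept,
                            objective = "REML", response = response)
    pv <- term_p_values(fit)
    # marginality: a main effect is ineligible while an interaction contains it
    eligible <- setdiff(names(pv), expand_keep(keep, names(pv)))
    eligible <- Filter(function(t) !is_marginal_to(t, names(pv)), eligible)
    pv <- pv[eligible]
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0 || max(pv) <= alpha) break
    worst <- names(pv)[which.max(pv)]
    current <- drop_term(current, worst)
    step_i <- step_i + 1L
    refit_ml <- fit_region_model(data, current, random_intercept,
                                 objective = "ML", response = response)
    trace <- bind_rows(trace, tibble(
      step = step_i, dropped = worst, p_value = unname(max(pv)),
      aic = glance(refit_ml)$aic
    ))
  }
  final <- fit_region_model(data, current, random_intercept,
                            objective = "REML", response = response)
  list(fit = final, trace = trace)
}

expand_keep <- function(keep, terms) {
  # protect the orthogonal day pair together when "poly_day" is protected
  out <- keep
  if ("poly_day" %in% keep) out <- c(out, "day_lin", "day_quad")
  intersect(out, terms)
}

is_marginal_to <- function(term, terms) {
  inters <- grep(":", terms, value = TRUE)
  any(vapply(inters, function(it) term %in% strsplit(it, ":")[[1]], logical(1)))
}

drop_term <- function(terms, victim) {
  setdiff(terms, victim)
}

term_p_values <- function(rf) {
  fit <- rf$fit
  d1 <- suppressMessages(suppressWarnings(drop1(fit, test = "F")))
  rows <- rownames(d1)
  pcol <- grep("^Pr\\(", colnames(d1), value = TRUE)[1]
  pv <- d1[[pcol]]
  names(pv) <- rows
  pv <- pv[!rows %in% c("<none>", "(Intercept)")]
  pv[!is.na(pv)]
}

#' Normalize a harvest count to a reference harvest-to-testing time
#'
#' Adjusts a harvest-sample concentration to what it would have been at the
#' reference time between harvest and testing (default the 36.75 h study
#' median), assuming each additional hour adds `slope` log10 CFU/g.
#'
#' @param value Observed concentration, log10 CFU/g.
#' @param hours Actual harvest-to-testing time, hours (>= 0).
#' @param ref_hours Reference time, hours.
#' @param slope Adjustment slope, log10 CFU/g per hour.
#' @return Adjusted concentration, log10 CFU/g.
#' @export
normalize_harvest_apc <- function(value, hours, ref_hours = 36.75, slope = 0.01) {
  if (any(hours < 0)) abort("`hours` must be non-negative.")
  value - slope * (hours - ref_hours)
}

#' Rank-based association and group-comparison statistics
#'
#' Convenience wrappers for the nonparametric toolkit used throughout:
#' Spearman correlation, two-sided Mann-Whitney U, and Holm step-down
#' adjustment for a family of m comparisons.
#'
#' @param x,y Numeric vectors: paired for `spearman_cor()`, the two groups
#'   for `mann_whitney()`.
#' @return One-row tibbles with the statistic and p-value.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("Spearman correlation needs >= 3 paired observations.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, constant_input = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, constant_input = FALSE)
}

#' @rdname spearman_cor
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Need >= 2 observations per group.")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' @rdname spearman_cor
#' @param p Vector of raw p-values.
#' @param m Family size (defaults to `length(p)`).
#' @export
holm_adjust <- function(p, m = length(p)) {
  p.adjust(p, method = "holm", n = m)
}
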
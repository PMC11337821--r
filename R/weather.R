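#' Summarize preharvest hourly weather into window features
#'
#' For each sample, summarizes the week of hourly weather preceding harvest
#' over four windows — 0-24, 25-48, 49-72 and 73-168 hours before harvest —
#' into mean/min/max temperature, mean dew point, mean windspeed and mean
#' solar radiation per window, plus total precipitation over 0-72 and
#' 73-168 hours. Windows are half-open toward the past: an hourly stamp `t`
#' belongs to window k1-k2 when `k1 < (harvest - t) <= k2` hours, so the four
#' windows partition the 168 preharvest stamps and the harvest hour itself is
#' excluded.
#'
#' Samples with unknown time of harvest (column `harvest_time_known` equal to
#' `FALSE`, when present) have their harvest clock time replaced by
#' `harvest_time_fallback` — the study convention of imputing the median
#' harvest time — and are flagged in the output.
#'
#' @param metadata Tibble with `sample_id`, `harvest_time` (POSIXct) and
#'   optionally `harvest_time_known`.
#' @param weather Tibble with `sample_id`, `timestamp` and the five weather
#'   metrics (`temp_c`, `dew_c`, `windspeed_kmh`, `solar_wm2`, `precip_mm`).
#' @param harvest_time_fallback Clock time (`"HH:MM"`) substituted when the
#'   harvest time is unknown.
#' @return Wide tibble: one row per sample, 26 feature columns named
#'   `<metric>_<stat>_<k1>_<k2>`, plus `harvest_time_imputed`.
#' @export
build_feature_table <- function(metadata, weather, harvest_time_fallback = "03:00") {
  stopifnot(all(c("sample_id", "harvest_time") %in% names(metadata)),
            all(c("sample_id", "timestamp", "temp_c", "dew_c", "windspeed_kmh",
                  "solar_wm2", "precip_mm") %in% names(weather)))
  purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    harvest <- m$harvest_time
    imputed <- FALSE
    if ("harvest_time_known" %in% names(metadata) && !isTRUE(m$harvest_time_known)) {
      day <- format(harvest, "%Y-%m-%d", tz = "UTC")
      harvest <- as.POSIXct(paste(day, harvest_time_fallback), tz = "UTC")
      imputed <- TRUE
    }
    w <- weather[weather$sample_id == m$sample_id, ]
    hrs_before <- as.numeric(difftime(harvest, w$timestamp, units = "hours"))
    w <- w[hrs_before > 0 & hrs_before <= 168, ]
    hrs_before <- hrs_before[hrs_before > 0 & hrs_before <= 168]
    if (nrow(w) < 168) {
      abort(sprintf("Sample '%s' has only %d of the 168 required preharvest hours.",
                    m$sample_id, nrow(w)))
    }
    win <- cut(hrs_before, breaks = c(0, 24, 48, 72, 168),
               labels = c("0_24", "25_48", "49_72", "73_168"), right = TRUE)
    feats <- w %>%
      mutate(window = win) %>%
      group_by(.data$window) %>%
      summarise(
        temp_mean = mean(.data$temp_c), temp_min = min(.data$temp_c),
        temp_max = max(.data$temp_c), dew_mean = mean(.data$dew_c),
        wind_mean = mean(.data$windspeed_kmh), solar_mean = mean(.data$solar_wm2),
        .groups = "drop"
      ) %>%
      tidyr::pivot_longer(-"window") %>%
      mutate(feature = paste0(.data$name, "_", .data$window)) %>%
      select("feature", "value") %>%
      tidyr::pivot_wider(names_from = "feature", values_from = "value")
    precip <- tibble(
      precip_total_0_72 = sum(w$precip_mm[hrs_before <= 72]),
      precip_total_73_168 = sum(w$precip_mm[hrs_before > 72])
    )
    bind_cols(tibble(sample_id = m$sample_id, harvest_time_imputed = imputed),
              feats, precip)
  })
}

#' Cluster weather features by rank correlation
#'
#' Groups the feature columns by agglomerative clustering on the distance
#' `1 - |Spearman rho|` (average linkage), choosing the number of clusters in
#' `1..max_clusters` by mean silhouette width (a single cluster is returned
#' only when every candidate partition has non-positive mean silhouette).
#' Constant columns cannot be correlated and are isolated as their own
#' flagged singleton clusters.
#'
#' The clustering backend is deterministic, so `runs` (kept for interface
#' compatibility with stochastic subspace methods) does not alter the result.
#'
#' @param features Feature table from [build_feature_table()] (non-numeric
#'   and flag columns ignored).
#' @param max_clusters Maximum number of clusters considered.
#' @param runs Unused by the deterministic backend.
#' @param seed Seed (the backend is deterministic; accepted for interface
#'   stability).
#' @return Tibble with `feature`, `cluster` (integer) and `constant` flag.
#' @export
cluster_variables <- function(features, max_clusters = 7, runs = 20, seed = 1) {
  x <- features[vapply(features, is.numeric, logical(1))]
  x <- x[setdiff(names(x), "sample_id")]
  if (ncol(x) < 2) abort("Need at least 2 numeric feature columns.")
  if (nrow(x) < 3) abort("Need at least 3 samples.")
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  xv <- x[!const]
  out_const <- tibble(feature = names(x)[const], cluster = NA_integer_,
                      constant = TRUE)
  if (ncol(xv) < 2) {
    assign <- tibble(feature = names(xv),
                     cluster = if (ncol(xv)) 1L else integer(0),
                     constant = FALSE)
  } else {
    rho <- suppressWarnings(stats::cor(xv, method = "spearman"))
    d <- stats::as.dist(1 - abs(rho))
    if (max(d) < 1e-12) { # all features effectively identical
      return(bind_rows(
        tibble(feature = names(xv), cluster = 1L, constant = FALSE),
        mutate(out_const, cluster = 1L + dplyr::row_number())
      ))
    }
    hc <- stats::hclust(d, method = "average")
    kmax <- min(max_clusters, ncol(xv) - 1)
    ks <- if (kmax >= 2) seq(2L, kmax) else integer(0)
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k = k)
      if (dplyr::n_distinct(cl) < 2) return(-Inf)
      s <- cluster::silhouette(cl, d)
      if (is.matrix(s)) mean(s[, "sil_width"]) else -Inf
    }, numeric(1))
    best_k <- if (length(ks) == 0 || all(sil <= 0)) 1L else ks[which.max(sil)]
    cl <- if (best_k == 1) rep(1L, ncol(xv)) else stats::cutree(hc, k = best_k)
    assign <- tibble(feature = names(xv), cluster = as.integer(cl),
                     constant = FALSE)
  }
  # constant columns numbered after the real clusters
  if (nrow(out_const)) {
    base <- max(c(assign$cluster, 0L))
    out_const$cluster <- base + seq_len(nrow(out_const))
  }
  bind_rows(assign, out_const)
}

model_aic_with <- function(base, feature, data) {
  rf <- fit_region_model(
    data, c(base$fixed_terms, feature), base$random_intercept,
    objective = "ML", response = base$response
  )
  glance(rf)$aic
}

#' Preselect weather covariates per cluster by single-addition AIC
#'
#' For every cluster, each member variable is added alone to the base model
#' (ML objective) and the `per_cluster` variables with the lowest resulting
#' AIC are kept as forward-selection candidates; variables in singleton
#' (including constant-flagged) clusters are carried along automatically.
#' When two selected variables have `|Spearman rho| > rho_max`, the one whose
#' single addition improved AIC less is replaced by the next-best unselected
#' member of its cluster; replacements iterate until no pair violates the
#' correlation ceiling or alternatives run out.
#'
#' @param base A `region_fit` to which candidates would be added (its data
#'   must already contain the feature columns).
#' @param features Feature table (columns matched by name against
#'   `clusters$feature`).
#' @param clusters Output of [cluster_variables()].
#' @param per_cluster Variables kept per cluster.
#' @param rho_max Spearman-correlation ceiling between selected candidates.
#' @return List: `candidates` (character vector, ordered by AIC), `aic`
#'   (named numeric of single-addition AICs) and `trace` of replacements.
#' @export
preselect_candidates <- function(base, features, clusters, per_cluster = 2,
                                 rho_max = 0.70) {
  feat_names <- clusters$feature[!clusters$constant]
  aics <- vapply(feat_names, function(f) model_aic_with(base, f, base$data),
                 numeric(1))
  picked <- character(0)
  for (k in sort(unique(clusters$cluster[!clusters$constant]))) {
    members <- clusters$feature[clusters$cluster == k & !clusters$constant]
    if (length(members) <= per_cluster) {
      picked <- c(picked, members)
    } else {
      picked <- c(picked, members[order(aics[members])][seq_len(per_cluster)])
    }
  }
  trace <- tibble(dropped = character(), replacement = character(),
                  rho = numeric())
  repeat {
    viol <- NULL
    if (length(picked) >= 2) {
      prs <- utils::combn(picked, 2)
      for (j in seq_len(ncol(prs))) {
        r <- suppressWarnings(stats::cor(features[[prs[1, j]]],
                                         features[[prs[2, j]]],
                                         method = "spearman"))
        if (is.finite(r) && abs(r) > rho_max) { viol <- c(prs[, j], r); break }
      }
    }
    if (is.null(viol)) break
    pair <- viol[1:2]
    loser <- pair[which.max(aics[pair])] # lesser AIC improvement = higher AIC
    cl <- clusters$cluster[clusters$feature == loser]
    alts <- setdiff(clusters$feature[clusters$cluster == cl & !clusters$constant],
                    c(picked, trace$dropped))
    picked <- setdiff(picked, loser)
    repl <- NA_character_
    if (length(alts)) {
      repl <- alts[which.min(aics[alts])]
      picked <- c(picked, repl)
    }
    trace <- bind_rows(trace, tibble(dropped = loser, replacement = repl,
                                     rho = as.numeric(viol[3])))
  }
  picked <- picked[order(aics[picked])]
  list(candidates = picked, aic = aics[picked], trace = trace)
}

#' Stepwise forward selection of weather covariates
#'
#' Candidates are tried in ascending order of their single-addition AIC
#' (computed under the ML objective, the objective under which AICs of
#' models with different fixed effects are comparable); each is added to the
#' working model and retained when its coefficient is significant at `alpha`
#' on the REML fit, where the Satterthwaite df approximation is calibrated.
#' The final model is a REML fit.
#'
#' @inheritParams preselect_candidates
#' @param candidates Character vector of candidate feature columns present in
#'   the base model's data.
#' @param alpha Retention threshold (retain when p < alpha).
#' @return List: `fit` (final `region_fit`), `trace` tibble of tried
#'   candidates with p-values and decisions.
#' @export
forward_select <- function(base, candidates, alpha = 0.10) {
  if (length(candidates) == 0) {
    return(list(fit = base, trace = tibble(
      candidate = character(), p_value = numeric(), aic = numeric(),
      retained = logical()
    )))
  }
  aics <- vapply(candidates, function(f) model_aic_with(base, f, base$data),
                 numeric(1))
  order_try <- candidates[order(aics)]
  current <- base$fixed_terms
  trace <- tibble(candidate = character(), p_value = numeric(),
                  aic = numeric(), retained = logical())
  for (cand in order_try) {
    rf <- fit_region_model(base$data, c(current, cand), base$random_intercept,
                           objective = "REML", response = base$response)
    td <- tidy(rf)
    p <- td$p_value[td$term == cand]
    keep <- length(p) == 1 && is.finite(p) && p < alpha
    aic_ml <- glance(fit_region_model(base$data, c(current, cand),
                                      base$random_intercept, objective = "ML",
                                      response = base$response))$aic
    if (keep) current <- c(current, cand)
    trace <- bind_rows(trace, tibble(candidate = cand,
                                     p_value = if (length(p)) p else NA_real_,
                                     aic = aic_ml, retained = keep))
  }
  final <- fit_region_model(base$data, current, base$random_intercept,
                            objective = "REML", response = base$response)
  list(fit = final, trace = trace)
}
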
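#' Enumerate the post hoc power-analysis design grid
#'
#' All combinations of per-region packaged-sample counts from `min_each` up
#' to region-specific maxima; the study grid of 4-8 region-A by 4-12
#' region-B samples yields 45 designs.
#'
#' @param min_each Minimum samples per region.
#' @param max_A,max_B Maximum samples for regions A and B.
#' @return Tibble with columns `n_A`, `n_B`, one row per design.
#' @export
enumerate_grid <- function(min_each = 4, max_A = 8, max_B = 12) {
  if (max_A < min_each || max_B < min_each) {
    abort("Each maximum must be at least `min_each`.")
  }
  tidyr::crossing(n_A = seq.int(min_each, max_A), n_B = seq.int(min_each, max_B))
}

#' Simulation-based power for one design
#'
#' Repeatedly draws, without replacement, `n_A` and `n_B` packaged samples
#' from the two regions of a dataset, refits the packaged-sample mixed model
#' (region + orthogonal day polynomial + harvest-to-arrival time, random
#' intercept per sample) on each draw, and counts rejections of the
#' no-region-difference null at `alpha` using the Satterthwaite p-value of
#' the region coefficient from the REML fit (the objective under which the
#' Satterthwaite approximation is calibrated; on ML fits it is
#' anti-conservative and the simulated type-I error overshoots `alpha`).
#' Singular or failed fits count as non-rejections and are tallied
#' separately.
#'
#' @param data Aggregated packaged counts (one test type) with columns
#'   `sample_id`, `region`, `shelf_day`, `geo_mean_log10`,
#'   `harvest_to_arrival_days`.
#' @param n_A,n_B Samples to draw from the first and second region level
#'   (alphabetical order of the region labels).
#' @param n_sims Number of simulated draws.
#' @param alpha Test size.
#' @param seed Seed; results are deterministic given it.
#' @return One-row tibble: `n_A`, `n_B`, `power`, `n_sims`, `n_rejected`,
#'   `n_singular`, `n_failed`, `alpha`, `seed`.
#' @export
estimate_power <- function(data, n_A, n_B, n_sims = 100, alpha = 0.05, seed = 1) {
  stopifnot(all(c("sample_id", "region", "shelf_day", "geo_mean_log10",
                  "harvest_to_arrival_days") %in% names(data)))
  regions <- sort(unique(data$region))
  if (length(regions) != 2) abort("Power simulation expects exactly 2 regions.")
  ids_A <- unique(data$sample_id[data$region == regions[1]])
  ids_B <- unique(data$sample_id[data$region == regions[2]])
  if (length(ids_A) < n_A || length(ids_B) < n_B) {
    abort(sprintf("Pool too small: have %d/%d samples, need %d/%d.",
                  length(ids_A), length(ids_B), n_A, n_B))
  }
  withr::with_seed(as.integer(seed), {
    rejected <- 0L; singular <- 0L; failed <- 0L
    for (s in seq_len(n_sims)) {
      draw <- c(sample(ids_A, n_A), sample(ids_B, n_B))
      dd <- data[data$sample_id %in% draw, ]
      res <- tryCatch(suppressWarnings({
        rf <- fit_region_model(
          dd, c("region", "poly_day", "harvest_to_arrival_days"),
          random_intercept = "sample_id", objective = "REML"
        )
        td <- tidy(rf)
        p <- td$p_value[grepl("^region", td$term)][1]
        list(p = p, singular = lme4::isSingular(rf$fit))
      }), error = function(e) NULL)
      if (is.null(res) || !is.finite(res$p)) {
        failed <- failed + 1L
      } else {
        if (res$singular) singular <- singular + 1L
        if (res$p < alpha) rejected <- rejected + 1L
      }
    }
    tibble(
      n_A = n_A, n_B = n_B, power = rejected / n_sims, n_sims = n_sims,
      n_rejected = rejected, n_singular = singular, n_failed = failed,
      alpha = alpha, seed = as.integer(seed)
    )
  })
}

#' Power over the whole design grid
#'
#' Runs [estimate_power()] for every design in the grid. The per-design seed
#' is `seed` so the full grid is reproducible from one integer.
#'
#' @inheritParams estimate_power
#' @param grid Design tibble from [enumerate_grid()].
#' @return `power_grid` tibble: the grid with power columns appended.
#' @export
power_grid <- function(data, grid = enumerate_grid(), n_sims = 100,
                       alpha = 0.05, seed = 1) {
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    estimate_power(data, grid$n_A[i], grid$n_B[i], n_sims = n_sims,
                   alpha = alpha, seed = seed)
  })
  structure(out, class = c("power_grid", class(out)))
}

#' Pareto-minimal designs reaching a power target
#'
#' Among designs with power at or above `target`, returns those not
#' dominated by another qualifying design with both sample counts less than
#' or equal (and at least one strictly smaller).
#'
#' @param grid A tibble with `n_A`, `n_B`, `power` (e.g. from
#'   [power_grid()]).
#' @param target Power target (default 0.80).
#' @return Tibble of Pareto-minimal qualifying designs (possibly empty).
#' @export
minimum_design <- function(grid, target = 0.80) {
  if (nrow(grid) == 0) abort("Empty power grid.")
  ok <- grid[grid$power >= target, , drop = FALSE]
  if (nrow(ok) == 0) return(as_tibble(ok))
  keep <- vapply(seq_len(nrow(ok)), function(i) {
    dominated <- ok$n_A <= ok$n_A[i] & ok$n_B <= ok$n_B[i] &
      (ok$n_A < ok$n_A[i] | ok$n_B < ok$n_B[i])
    !any(dominated)
  }, logical(1))
  as_tibble(ok[keep, ])
}

#' Heatmap of simulated power over the design grid
#'
#' @param object A `power_grid`.
#' @param target Contour level to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_grid <- function(object, target = 0.80, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_A, .data$n_B, fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$power)),
                       size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Samples, region A", y = "Samples, region B",
                  fill = "Power") +
    ggplot2::theme_minimal()
}
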
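#' Pipeline configuration
#'
#' Assembles the parameters of every stage of the end-to-end analysis with
#' defaults matching the study conventions: spoilage threshold 7 log10
#' CFU/g, counterfactual initial concentration 5 log10 CFU/g, backward /
#' forward selection alpha 0.10, interaction-screen alpha 0.05, 999
#' PERMANOVA permutations, power grid 4-8 x 4-12 with 100 simulations,
#' rare-genus cutoff 1 percent, 0.50-percentage-point escalation margin,
#' 99 percent alignment-length filter, reference harvest-to-testing time
#' 36.75 h with slope 0.01 log10 CFU/g per hour, and seed 1.
#'
#' @param ... Overrides for any default element.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sim = list(), # overrides for sim_config()
    stages = c("simulate", "aggregate", "growth", "models", "weather",
               "power", "taxonomy"),
    threshold = 7,
    n0_counterfactual = 5,
    screen_alpha = 0.05,
    keep_alpha = 0.10,
    forward_alpha = 0.10,
    ref_hours = 36.75,
    harvest_slope = 0.01,
    power_min = 4, power_max_a = 8, power_max_b = 12,
    power_n_sims = 100, power_alpha = 0.05,
    n_perm = 999,
    min_len_frac = 0.99, delta_pp = 0.50, rare_threshold = 0.01,
    drop_visits = "Dend"
  )
  cfg <- modifyList(defaults, list(...))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors [pipeline_config()] field for field; missing fields
#' take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulates a study dataset, aggregates replicates, fits per-sample growth
#' curves with threshold inversion, runs the interaction screen and the
#' packaged-sample mixed model with protected backward elimination, builds
#' weather features and runs the covariate-selection harness, estimates the
#' power grid, and post-processes the isolates through composition,
#' Bray-Curtis, PCoA and PERMANOVA. Every stage writes CSV artifacts into
#' `out_dir` plus a JSON manifest of seeds and parameters; a failing stage
#' aborts with a stage-named error, preserving earlier outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    res$dataset <- on_stage("simulate", {
      ds <- simulate_study(do.call(sim_config, c(config$sim, list(seed = config$seed))))
      write_sim_dataset(ds, file.path(out_dir, "data"))
      ds
    })
  }
  ds <- res$dataset

  if ("aggregate" %in% stages) {
    res$aggregated <- on_stage("aggregate", {
      agg <- aggregate_replicates(ds$counts)
      readr::write_csv(agg, file.path(out_dir, "aggregated_counts.csv"))
      agg
    })
  }

  if ("growth" %in% stages) {
    res$growth <- on_stage("growth", {
      apc <- res$aggregated %>%
        filter(.data$sample_type == "packaged", .data$test == "APC") %>%
        rename(day = "shelf_day", log10_conc = "geo_mean_log10")
      fits <- fit_growth_curves(apc, model = "auto",
                                threshold = config$threshold,
                                N0_override = config$n0_counterfactual)
      fits <- left_join(fits, distinct(ds$truth, .data$sample_id, .data$region),
                        by = "sample_id")
      readr::write_csv(fits, file.path(out_dir, "growth_fits.csv"))
      fits
    })
  }

  if ("models" %in% stages) {
    res$models <- on_stage("models", {
      pk <- res$aggregated %>%
        filter(.data$sample_type == "packaged") %>%
        left_join(select(ds$metadata, "sample_id", "harvest_to_arrival_days",
                         "arrival_to_packaging_days"),
                  by = "sample_id")
      screen <- interaction_screen(pk, alpha = config$screen_alpha)
      tests_used <- if (screen$decision == "separate_tests") unique(pk$test) else "APC"
      per_test <- purrr::map(setNames(tests_used, tests_used), function(tt) {
        backward_eliminate(
          filter(pk, .data$test == tt),
          fixed_terms = c("region", "poly_day", "harvest_to_arrival_days",
                          "arrival_to_packaging_days"),
          keep = "region", random_intercept = "sample_id",
          alpha = config$keep_alpha
        )
      })
      coefs <- purrr::imap_dfr(per_test, function(m, tt) {
        mutate(tidy(m$fit), test = tt, .before = 1)
      })
      readr::write_csv(coefs, file.path(out_dir, "model_coefficients.csv"))
      readr::write_csv(
        purrr::imap_dfr(per_test, function(m, tt) mutate(m$trace, test = tt, .before = 1)),
        file.path(out_dir, "elimination_trace.csv")
      )
      list(screen = screen, per_test = per_test, coefficients = coefs)
    })
  }

  if ("weather" %in% stages) {
    res$weather <- on_stage("weather", {
      ft <- build_feature_table(ds$metadata, ds$weather)
      readr::write_csv(ft, file.path(out_dir, "weather_features.csv"))
      cl <- cluster_variables(ft, seed = config$seed)
      apc_model <- res$models$per_test[["APC"]]$fit
      dat <- left_join(apc_model$data, ft, by = "sample_id")
      base <- fit_region_model(dat, apc_model$fixed_terms,
                               random_intercept = "sample_id",
                               objective = "ML")
      pre <- preselect_candidates(base, ft, cl)
      sel <- forward_select(base, pre$candidates, alpha = config$forward_alpha)
      readr::write_csv(sel$trace, file.path(out_dir, "weather_selection_trace.csv"))
      readr::write_csv(tidy(sel$fit), file.path(out_dir, "weather_model_coefficients.csv"))
      list(features = ft, clusters = cl, candidates = pre, selection = sel)
    })
  }

  if ("power" %in% stages) {
    res$power <- on_stage("power", {
      apc <- res$aggregated %>%
        filter(.data$sample_type == "packaged", .data$test == "APC") %>%
        left_join(select(ds$metadata, "sample_id", "harvest_to_arrival_days"),
                  by = "sample_id")
      grid <- enumerate_grid(config$power_min, config$power_max_a, config$power_max_b)
      # stay within the simulated pool
      pool <- count(distinct(apc, .data$sample_id, .data$region), .data$region)
      grid <- grid[grid$n_A <= min(pool$n) & grid$n_B <= min(pool$n), ]
      pg <- power_grid(apc, grid, n_sims = config$power_n_sims,
                       alpha = config$power_alpha, seed = config$seed)
      readr::write_csv(pg, file.path(out_dir, "power_grid.csv"))
      pg
    })
  }

  if ("taxonomy" %in% stages) {
    res$taxonomy <- on_stage("taxonomy", {
      iso <- ds$isolates
      asg <- process_isolates(iso$hits, iso$qlen, iso$taxonomy, iso$isolate_map,
                              min_len_frac = config$min_len_frac,
                              delta_pp = config$delta_pp,
                              rare_threshold = config$rare_threshold)
      readr::write_csv(asg, file.path(out_dir, "isolate_assignments.csv"))
      comp <- build_composition(asg, drop_visits = config$drop_visits)
      comp <- left_join(comp, distinct(ds$metadata, .data$sample_id, .data$region),
                        by = "sample_id")
      readr::write_csv(comp, file.path(out_dir, "composition.csv"))
      d <- bray_curtis(comp)
      utils::write.csv(d, file.path(out_dir, "bray_curtis.csv"))
      ord <- pcoa(d)
      readr::write_csv(ord$points, file.path(out_dir, "pcoa_coordinates.csv"))
      pmv <- permanova(d, comp, rhs = c("visit", "region", "visit:region"),
                       n_perm = config$n_perm, seed = config$seed)
      readr::write_csv(pmv, file.path(out_dir, "permanova.csv"))
      list(assignments = asg, composition = comp, dissimilarity = d,
           pcoa = ord, permanova = pmv)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spinachshelf")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "stages"))],
    stages_run = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Render a plain-text summary report from pipeline artifacts
#'
#' Reads the stage CSVs in an artifact directory and writes `report.md`:
#' median (IQR) growth parameters and times to threshold by region (type-7
#' quantiles), concentration-model coefficient tables, the retained weather
#' covariates, the power grid, and the PERMANOVA table. Stages whose outputs
#' are missing are listed as absent rather than failing.
#'
#' @param dir Artifact directory from [run_pipeline()].
#' @return Invisibly, the path of the report file.
#' @export
render_report <- function(dir) {
  lines <- c("# Synthetic study analysis report", "")
  absent <- character(0)
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|")
      }, character(1)), "")
  }

  gf_path <- file.path(dir, "growth_fits.csv")
  if (file.exists(gf_path)) {
    gf <- readr::read_csv(gf_path, show_col_types = FALSE)
    summ <- gf %>%
      filter(.data$converged) %>%
      group_by(.data$region) %>%
      summarise(across(c("N0", "mumax", "Nmax", "days_to_threshold"),
                       function(x) {
                         q <- quantile_type7(x, c(0.25, 0.5, 0.75))
                         sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
                       }), .groups = "drop")
    lines <- c(lines, "## Growth kinetics: median (IQR) by region", "",
               md_table(summ))
  } else absent <- c(absent, "growth")

  mc_path <- file.path(dir, "model_coefficients.csv")
  if (file.exists(mc_path)) {
    lines <- c(lines, "## Concentration model coefficients", "",
               md_table(readr::read_csv(mc_path, show_col_types = FALSE)))
  } else absent <- c(absent, "models")

  ws_path <- file.path(dir, "weather_selection_trace.csv")
  if (file.exists(ws_path)) {
    lines <- c(lines, "## Weather covariate forward selection", "",
               md_table(readr::read_csv(ws_path, show_col_types = FALSE)))
  } else absent <- c(absent, "weather")

  pg_path <- file.path(dir, "power_grid.csv")
  if (file.exists(pg_path)) {
    pg <- readr::read_csv(pg_path, show_col_types = FALSE)
    lines <- c(lines, "## Power grid", "", md_table(pg))
    md <- minimum_design(pg)
    if (nrow(md)) {
      lines <- c(lines, "Pareto-minimal designs reaching 80% power:", "",
                 md_table(select(md, "n_A", "n_B", "power")))
    }
  } else absent <- c(absent, "power")

  pm_path <- file.path(dir, "permanova.csv")
  if (file.exists(pm_path)) {
    lines <- c(lines, "## PERMANOVA", "",
               md_table(readr::read_csv(pm_path, show_col_types = FALSE)))
  } else absent <- c(absent, "taxonomy")

  if (length(absent)) {
    lines <- c(lines, "## Absent stages", "",
               paste("-", absent), "")
  }
  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
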
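#' Configuration for the synthetic two-region study generator
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. Defaults emulate a two-region (desert southwest vs. coastal
#' central-coast) baby-spinach sampling design: paired harvest and packaged
#' samples per lot, triplicate testing with three plate-count tests (APC, PC,
#' GN), quintuple shelf-day schedules, a week of preharvest hourly weather
#' with a region-dependent temperature climate, and 36-colony isolate draws
#' per sample visit from region- and visit-dependent genus mixtures.
#'
#' Default kinetic parameters follow the reported medians for packaged
#' spinach: reference-region (region A) initial concentration 4.8
#' log10 CFU/g, growth rate 0.53 ln(CFU/g)/day, plateau 7.9 log10 CFU/g, with
#' region B shifted upward by `region_effect_N0` = 0.75 and
#' `region_effect_Nmax` = 0.9 log10 CFU/g. Per-test offsets default to APC 0,
#' PC +0.3, GN -0.5 log10 CFU/g, mimicking the typical ordering PC > APC > GN
#' on packaged samples. Part of each region gap in initial concentration is
#' mediated by preharvest temperature through `temp_to_N0_slope`
#' (log10 CFU/g per degree C of mean temperature in the 24 h before harvest).
#'
#' @param n_samples_per_region Packaged samples per region (each with a
#'   paired harvest sample from the same lot).
#' @param regions Character vector of two region labels; the first is the
#'   model reference level.
#' @param growth_model Generating kinetic form, `"baranyi_nolag"` or
#'   `"buchanan_nolag"`.
#' @param true_params Named list of reference-region means and between-sample
#'   standard deviations: `N0`, `mumax`, `Nmax`, `sd_N0`, `sd_mumax`,
#'   `sd_Nmax`.
#' @param region_effect_N0,region_effect_Nmax Region-B shifts in initial and
#'   stationary concentration, log10 CFU/g.
#' @param noise_sd Replicate-level Gaussian noise on the log10 scale.
#' @param shelf_day_schedules List of candidate shelf-day schedules; the
#'   first element of each is replaced by the sample's simulated "day
#'   initial" (packaging-to-arrival lag).
#' @param day_initial_range Packaging-to-arrival lag range in days (the first
#'   shelf-life test day).
#' @param tests Character vector of test types with `test_offsets` the
#'   per-test log10 shifts.
#' @param test_offsets Named numeric of per-test offsets (log10 CFU/g).
#' @param sample_sd Between-sample (lot) random-intercept standard deviation
#'   shared across tests and days, log10 CFU/g.
#' @param harvest_to_testing_hours_range,harvest_to_arrival_days_range,arrival_to_packaging_days_range
#'   Uniform ranges for logistics lags.
#' @param harvest_to_arrival_slope Increase in packaged-sample concentration
#'   per day between harvest and arrival at the processing facility
#'   (log10 CFU/g per day).
#' @param harvest_testing_slope Increase in harvest-sample concentration per
#'   hour between harvest and testing (log10 CFU/g per hour).
#' @param weather_baseline Per-region list of climate parameters: `temp_mean`
#'   (degrees C), `temp_amplitude` (diurnal half-range), `dew_offset`,
#'   `wind_mean`, `solar_peak`, `precip_prob`, `precip_mean`.
#' @param temp_to_N0_slope Coupling from mean temperature in the 24 h before
#'   harvest to initial concentration, log10 CFU/g per degree C.
#' @param genus_mixture Named list `region -> visit -> named probability
#'   vector over genera`; `NULL` for the built-in default (see
#'   [default_genus_mixture()]).
#' @param taxonomy Data frame mapping `genus` to `family` and `order`;
#'   `NULL` for the built-in default.
#' @param colonies_per_film,films_per_test,replicates Isolate-selection
#'   arithmetic: colonies picked per film, films per test, replicate tests
#'   per sample; with three tests the default yields 2 x 2 x 3 x 3 = 36
#'   isolates per sample visit.
#' @param isolate_visits Visits at which colonies are picked (harvest, day 7,
#'   end of shelf life).
#' @param identity_margin_range Range (percentage points) of the identity gap
#'   between the true-genus top BLAST hit and decoy hits from other genera;
#'   set below 0.5 to exercise the rank-escalation rule.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples_per_region = 13,
                       regions = c("yuma_az_area", "salinas_ca_area"),
                       growth_model = c("baranyi_nolag", "buchanan_nolag"),
                       true_params = list(
                         N0 = 4.8, mumax = 0.53, Nmax = 7.9,
                         sd_N0 = 0.30, sd_mumax = 0.08, sd_Nmax = 0.25
                       ),
                       region_effect_N0 = 0.75,
                       region_effect_Nmax = 0.90,
                       noise_sd = 0.20,
                       shelf_day_schedules = list(c(0, 7, 12, 17, 22), c(0, 7, 14, 21, 28)),
                       day_initial_range = c(2, 4),
                       tests = c("APC", "PC", "GN"),
                       test_offsets = c(APC = 0, PC = 0.3, GN = -0.5),
                       sample_sd = 0.15,
                       harvest_to_testing_hours_range = c(24, 50),
                       harvest_to_arrival_days_range = c(0.5, 3),
                       arrival_to_packaging_days_range = c(0.5, 2),
                       harvest_to_arrival_slope = 0.0,
                       harvest_testing_slope = 0.01,
                       weather_baseline = list(
                         yuma_az_area = list(
                           temp_mean = 12, temp_amplitude = 8, dew_offset = 8,
                           wind_mean = 12, solar_peak = 650, precip_prob = 0.01,
                           precip_mean = 0.5
                         ),
                         salinas_ca_area = list(
                           temp_mean = 14, temp_amplitude = 5, dew_offset = 3,
                           wind_mean = 15, solar_peak = 550, precip_prob = 0.04,
                           precip_mean = 1.0
                         )
                       ),
                       temp_to_N0_slope = 0.12,
                       genus_mixture = NULL,
                       taxonomy = NULL,
                       colonies_per_film = 2,
                       films_per_test = 2,
                       replicates = 3,
                       isolate_visits = c("H", "D7", "Dend"),
                       identity_margin_range = c(0.6, 3.0),
                       seed = 1L) {
  growth_model <- match.arg(growth_model)
  if (is.null(genus_mixture)) genus_mixture <- default_genus_mixture(regions)
  if (is.null(taxonomy)) taxonomy <- default_taxonomy()
  cfg <- structure(list(
    n_samples_per_region = as.integer(n_samples_per_region),
    regions = regions, growth_model = growth_model,
    true_params = true_params,
    region_effect_N0 = region_effect_N0, region_effect_Nmax = region_effect_Nmax,
    noise_sd = noise_sd, shelf_day_schedules = shelf_day_schedules,
    day_initial_range = day_initial_range,
    tests = tests, test_offsets = test_offsets, sample_sd = sample_sd,
    harvest_to_testing_hours_range = harvest_to_testing_hours_range,
    harvest_to_arrival_days_range = harvest_to_arrival_days_range,
    arrival_to_packaging_days_range = arrival_to_packaging_days_range,
    harvest_to_arrival_slope = harvest_to_arrival_slope,
    harvest_testing_slope = harvest_testing_slope,
    weather_baseline = weather_baseline, temp_to_N0_slope = temp_to_N0_slope,
    genus_mixture = genus_mixture, taxonomy = taxonomy,
    colonies_per_film = as.integer(colonies_per_film),
    films_per_test = as.integer(films_per_test),
    replicates = as.integer(replicates),
    isolate_visits = isolate_visits,
    identity_margin_range = identity_margin_range,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  tp <- cfg$true_params
  if (cfg$n_samples_per_region < 1) abort("`n_samples_per_region` must be >= 1.")
  if (length(cfg$regions) < 1) abort("Need at least one region label.")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  for (s in cfg$shelf_day_schedules) {
    if (any(diff(s) <= 0) || any(s < 0)) {
      abort("Shelf-day schedules must be strictly increasing and non-negative.")
    }
  }
  if (tp$Nmax <= tp$N0) abort("Mean `Nmax` must exceed mean `N0`.")
  if (tp$Nmax + cfg$region_effect_Nmax <= tp$N0 + cfg$region_effect_N0) {
    abort("Region-shifted mean `Nmax` must exceed shifted mean `N0`.")
  }
  if (!all(cfg$tests %in% names(cfg$test_offsets))) {
    abort("Every test needs an entry in `test_offsets`.")
  }
  for (r in cfg$regions) {
    mix <- cfg$genus_mixture[[r]]
    if (is.null(mix)) abort(sprintf("No genus mixture for region '%s'.", r))
    for (v in cfg$isolate_visits) {
      p <- mix[[v]]
      if (is.null(p)) abort(sprintf("No genus mixture for region '%s', visit '%s'.", r, v))
      if (abs(sum(p) - 1) > 1e-9) {
        abort(sprintf("Genus mixture for '%s'/'%s' must sum to 1.", r, v))
      }
      if (!all(names(p) %in% cfg$taxonomy$genus)) {
        abort("Every mixture genus needs a taxonomy row.")
      }
    }
    if (is.null(cfg$weather_baseline[[r]])) {
      abort(sprintf("No weather baseline for region '%s'.", r))
    }
  }
  cfg
}

#' Built-in genus mixtures and taxonomy for the isolate generator
#'
#' The default mixtures put Pseudomonas, Pantoea and Erwinia in the lead with
#' a regional tilt (more Pseudomonas in region A, more Exiguobacterium and
#' minor genera in region B) and shift composition over shelf life toward
#' Pseudomonas and Shewanella, echoing the community patterns typical of
#' refrigerated leafy greens.
#'
#' @param regions Region labels (two expected).
#' @return `default_genus_mixture()`: named list region -> visit -> named
#'   probability vector. `default_taxonomy()`: tibble with columns `genus`,
#'   `family`, `order`.
#' @export
default_genus_mixture <- function(regions = c("yuma_az_area", "salinas_ca_area")) {
  gA <- list(
    H    = c(Pseudomonas = 0.35, Pantoea = 0.30, Bacillus = 0.15, Erwinia = 0.10,
             Shewanella = 0.02, Exiguobacterium = 0.01, Curtobacterium = 0.04,
             Flavobacterium = 0.03),
    D7   = c(Pseudomonas = 0.60, Pantoea = 0.20, Bacillus = 0.03, Erwinia = 0.12,
             Shewanella = 0.02, Exiguobacterium = 0.01, Curtobacterium = 0.01,
             Flavobacterium = 0.01),
    Dend = c(Pseudomonas = 0.50, Pantoea = 0.15, Bacillus = 0.03, Erwinia = 0.15,
             Shewanella = 0.12, Exiguobacterium = 0.01, Curtobacterium = 0.02,
             Flavobacterium = 0.02)
  )
  gB <- list(
    H    = c(Pseudomonas = 0.25, Pantoea = 0.28, Bacillus = 0.15, Erwinia = 0.12,
             Shewanella = 0.02, Exiguobacterium = 0.08, Curtobacterium = 0.05,
             Flavobacterium = 0.05),
    D7   = c(Pseudomonas = 0.40, Pantoea = 0.25, Bacillus = 0.05, Erwinia = 0.18,
             Shewanella = 0.03, Exiguobacterium = 0.05, Curtobacterium = 0.02,
             Flavobacterium = 0.02),
    Dend = c(Pseudomonas = 0.35, Pantoea = 0.15, Bacillus = 0.04, Erwinia = 0.18,
             Shewanella = 0.15, Exiguobacterium = 0.06, Curtobacterium = 0.03,
             Flavobacterium = 0.04)
  )
  out <- list(gA, gB)[seq_along(regions)]
  names(out) <- regions
  out
}

#' @rdname default_genus_mixture
#' @export
default_taxonomy <- function() {
  tibble::tribble(
    ~genus, ~family, ~order,
    "Pseudomonas", "Pseudomonadaceae", "Pseudomonadales",
    "Pantoea", "Erwiniaceae", "Enterobacterales",
    "Erwinia", "Erwiniaceae", "Enterobacterales",
    "Bacillus", "Bacillaceae", "Bacillales",
    "Shewanella", "Shewanellaceae", "Alteromonadales",
    "Exiguobacterium", "Bacillaceae", "Bacillales",
    "Curtobacterium", "Microbacteriaceae", "Micrococcales",
    "Flavobacterium", "Flavobacteriaceae", "Flavobacteriales",
    "Rahnella", "Yersiniaceae", "Enterobacterales",
    "Serratia", "Yersiniaceae", "Enterobacterales"
  )
}

#' Simulate sample metadata and preharvest weather
#'
#' Generates one paired harvest + packaged sample per lot and region, with
#' harvest timestamps, logistics lags (harvest to testing, harvest to arrival
#' at the processing facility, arrival to packaging, packaging to first
#' shelf-life test) and at least 168 hours of hourly preharvest weather per
#' sample: temperature with a diurnal cycle and AR(1) noise around the
#' region's climate mean, dew point, windspeed, solar radiation and
#' occasional precipitation.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `metadata` (one row per packaged sample/lot) and
#'   `weather` (one row per sample x hour, 192 hours before harvest).
#' @export
simulate_metadata_weather <- function(config) {
  cfg <- validate_sim_config(config)
  withr::with_seed(cfg$seed + 1000L, sim_metadata_weather_impl(cfg))
}

sim_metadata_weather_impl <- function(cfg) {
  meta <- purrr::map_dfr(seq_along(cfg$regions), function(ri) {
    region <- cfg$regions[ri]
    purrr::map_dfr(seq_len(cfg$n_samples_per_region), function(i) {
      sched_id <- sample.int(length(cfg$shelf_day_schedules), 1)
      harvest <- as.POSIXct("2022-03-01 03:00:00", tz = "UTC") +
        round(runif(1, 0, 270)) * 86400 + round(runif(1, -2, 4)) * 3600
      tibble(
        sample_id = sprintf("%s_%02d", toupper(substr(region, 1, 2)), i),
        region = region,
        harvest_time = harvest,
        harvest_time_known = runif(1) > 0.15,
        harvest_to_testing_hours = runif(1, cfg$harvest_to_testing_hours_range[1],
                                         cfg$harvest_to_testing_hours_range[2]),
        harvest_to_arrival_days = runif(1, cfg$harvest_to_arrival_days_range[1],
                                        cfg$harvest_to_arrival_days_range[2]),
        arrival_to_packaging_days = runif(1, cfg$arrival_to_packaging_days_range[1],
                                          cfg$arrival_to_packaging_days_range[2]),
        day_initial = round(runif(1, cfg$day_initial_range[1], cfg$day_initial_range[2])),
        schedule_id = sched_id
      )
    })
  })

  weather <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    wb <- cfg$weather_baseline[[m$region]]
    # clock-hour stamps covering the harvest day plus the preceding 9 days,
    # so any within-day harvest anchor (true or imputed) has >= 168 h of history
    day0 <- as.POSIXct(format(m$harvest_time, "%Y-%m-%d 00:00:00"), tz = "UTC")
    stamps <- seq(day0 - 9 * 86400, day0 + 23 * 3600, by = 3600)
    n_hours <- length(stamps)
    hod <- as.numeric(format(stamps, "%H"))
    diurnal <- wb$temp_amplitude * sin(2 * pi * (hod - 9) / 24)
    ar <- as.numeric(stats::filter(rnorm(n_hours, 0, 1.2), 0.8, method = "recursive"))
    temp <- wb$temp_mean + diurnal + ar
    solar <- pmax(0, wb$solar_peak * sin(pi * (hod - 6) / 12)) * (hod >= 6 & hod <= 18) +
      rnorm(n_hours, 0, 10)
    tibble(
      sample_id = m$sample_id,
      timestamp = stamps,
      temp_c = temp,
      dew_c = temp - wb$dew_offset + rnorm(n_hours, 0, 0.8),
      windspeed_kmh = pmax(0, wb$wind_mean + rnorm(n_hours, 0, 4)),
      solar_wm2 = pmax(0, solar),
      precip_mm = ifelse(runif(n_hours) < wb$precip_prob,
                         rexp(n_hours, 1 / wb$precip_mean), 0)
    )
  })

  list(metadata = meta, weather = weather)
}

#' Simulate plate-count records with known kinetic truth
#'
#' Draws per-sample true growth parameters (region-shifted means, Gaussian
#' between-sample variation, a weather-mediated component of the initial
#' concentration), evaluates the configured no-lag growth model on each
#' sample's shelf-day schedule, and adds per-test offsets, a shared lot
#' random intercept and replicate-level Gaussian noise on the log10 scale.
#' Paired harvest-sample counts are generated around the sample's true
#' initial concentration with the harvest-to-testing time effect.
#'
#' Samples whose drawn plateau does not exceed the drawn initial
#' concentration by at least 0.2 log10 are redrawn (at most 100 attempts).
#'
#' @param config A [sim_config()].
#' @param metadata,weather Optional pre-generated tibbles from
#'   [simulate_metadata_weather()]; generated internally when `NULL`.
#' @return List with tibbles `counts` (sample x type x test x day x
#'   replicate) and `truth` (per-sample true parameters), plus the metadata
#'   and weather used.
#' @export
simulate_counts <- function(config, metadata = NULL, weather = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(metadata) || is.null(weather)) {
    mw <- simulate_metadata_weather(cfg)
    metadata <- mw$metadata
    weather <- mw$weather
  }
  withr::with_seed(cfg$seed + 2000L, sim_counts_impl(cfg, metadata, weather))
}

sim_counts_impl <- function(cfg, metadata, weather) {
  tp <- cfg$true_params
  ref_temp <- cfg$weather_baseline[[cfg$regions[1]]]$temp_mean

  # mean temperature in the 24 h before harvest drives part of N0
  t24 <- weather %>%
    left_join(select(metadata, "sample_id", "harvest_time"), by = "sample_id") %>%
    filter(.data$harvest_time - .data$timestamp <= 24 * 3600,
           .data$harvest_time - .data$timestamp > 0) %>%
    group_by(.data$sample_id) %>%
    summarise(temp24 = mean(.data$temp_c), .groups = "drop")

  md <- left_join(metadata, t24, by = "sample_id")
  truth <- purrr::map_dfr(seq_len(nrow(md)), function(i) {
    region_b <- md$region[i] != cfg$regions[1]
    mu_N0 <- tp$N0 + region_b * cfg$region_effect_N0 +
      cfg$temp_to_N0_slope * (md$temp24[i] - ref_temp) +
      cfg$harvest_to_arrival_slope * md$harvest_to_arrival_days[i]
    mu_Nmax <- tp$Nmax + region_b * cfg$region_effect_Nmax
    for (attempt in seq_len(100)) {
      N0 <- rnorm(1, mu_N0, tp$sd_N0)
      Nmax <- rnorm(1, mu_Nmax, tp$sd_Nmax)
      mumax <- abs(rnorm(1, tp$mumax, tp$sd_mumax))
      if (Nmax - N0 >= 0.2 && mumax > 0.05) break
      if (attempt == 100) abort("Could not draw Nmax > N0 within 100 attempts.")
    }
    lot <- rnorm(1, 0, cfg$sample_sd)
    # N0_curve/Nmax_curve are the realized trajectory levels: the lot-level
    # intercept shifts the whole curve, so it belongs to the kinetic truth
    tibble(sample_id = md$sample_id[i], region = md$region[i],
           N0 = N0, mumax = mumax, Nmax = Nmax, lot_intercept = lot,
           N0_curve = N0 + lot, Nmax_curve = Nmax + lot)
  })

  fun <- growth_model_fun(cfg$growth_model)

  packaged <- purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    tr <- truth[truth$sample_id == m$sample_id, ]
    days <- cfg$shelf_day_schedules[[m$schedule_id]]
    days[1] <- m$day_initial
    grid <- tidyr::expand_grid(
      shelf_day = days, test = cfg$tests, replicate = seq_len(cfg$replicates)
    )
    grid$log10_cfu_g <- fun(grid$shelf_day, tr$N0, tr$mumax, tr$Nmax) +
      unname(cfg$test_offsets[grid$test]) + tr$lot_intercept +
      rnorm(nrow(grid), 0, cfg$noise_sd)
    tibble(
      sample_id = m$sample_id, region = m$region, sample_type = "packaged",
      test = grid$test, shelf_day = grid$shelf_day,
      replicate = grid$replicate, log10_cfu_g = grid$log10_cfu_g
    )
  })

  harvest <- purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    tr <- truth[truth$sample_id == m$sample_id, ]
    grid <- tidyr::expand_grid(test = cfg$tests, replicate = seq_len(cfg$replicates))
    base <- tr$N0 - 0.3 + # field concentration sits slightly below packaged day 0
      cfg$harvest_testing_slope * (m$harvest_to_testing_hours - 36.75)
    grid$log10_cfu_g <- base + unname(cfg$test_offsets[grid$test]) +
      rnorm(nrow(grid), 0, cfg$noise_sd)
    tibble(
      sample_id = paste0(m$sample_id, "_H"), region = m$region,
      sample_type = "harvest", test = grid$test, shelf_day = NA_real_,
      replicate = grid$replicate, log10_cfu_g = grid$log10_cfu_g
    )
  })

  list(
    counts = bind_rows(packaged, harvest),
    truth = truth,
    metadata = metadata,
    weather = weather
  )
}

#' Simulate culture isolates as BLAST-style hit tables
#'
#' For each packaged sample and visit, draws `colonies_per_film x
#' films_per_test x n_tests x replicates` isolates (36 under the default 2 x
#' 2 x 3 x 3 scheme) multinomially from the region x visit genus mixture, and
#' emits each isolate as a small set of 12-column BLAST tabular hits: a
#' full-length top hit carrying the true genus plus 2-4 decoy hits from other
#' genera at a configurable identity margin below the top (set the margin
#' under 0.5 percentage points to trigger downstream rank escalation).
#'
#' @param config A [sim_config()].
#' @param metadata Optional metadata tibble (generated when `NULL`).
#' @return List of tibbles: `hits` (BLAST outfmt-6 columns plus nothing
#'   else), `qlen` (`qseqid`, `qlen`), `taxonomy` (`sseqid`, `genus`,
#'   `family`, `order`), `isolate_map` (`isolate_id`, `sample_id`, `visit`,
#'   `true_genus`).
#' @export
simulate_isolates <- function(config, metadata = NULL) {
  cfg <- validate_sim_config(config)
  if (is.null(metadata)) metadata <- simulate_metadata_weather(cfg)$metadata
  withr::with_seed(cfg$seed + 3000L, sim_isolates_impl(cfg, metadata))
}

sim_isolates_impl <- function(cfg, metadata) {
  n_per_visit <- cfg$colonies_per_film * cfg$films_per_test *
    length(cfg$tests) * cfg$replicates
  tax <- cfg$taxonomy
  # one reference subject per genus, plus a second accession for realism
  subjects <- tibble(
    sseqid = paste0("RDP|", tax$genus, "_", rep(1, nrow(tax))),
    genus = tax$genus, family = tax$family, order = tax$order
  )

  rows <- purrr::map_dfr(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    mix <- cfg$genus_mixture[[m$region]]
    purrr::map_dfr(cfg$isolate_visits, function(v) {
      p <- mix[[v]]
      draw <- as.integer(rmultinom(1, n_per_visit, p))
      tibble(
        sample_id = m$sample_id, visit = v,
        true_genus = rep(names(p), draw)
      )
    })
  })
  rows$isolate_id <- sprintf("ISO%05d", seq_len(nrow(rows)))

  qlen <- tibble(qseqid = rows$isolate_id,
                 qlen = as.integer(round(runif(nrow(rows), 650, 900))))

  hits <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    iso <- rows[i, ]
    ql <- qlen$qlen[i]
    top_ident <- round(runif(1, 98.2, 99.9), 2)
    n_decoy <- sample(2:4, 1)
    others <- setdiff(subjects$genus, iso$true_genus)
    decoy_gen <- sample(others, n_decoy)
    margins <- runif(n_decoy, cfg$identity_margin_range[1], cfg$identity_margin_range[2])
    gen <- c(iso$true_genus, decoy_gen)
    ident <- round(c(top_ident, pmax(top_ident - margins, 80)), 2)
    alen <- as.integer(round(c(ql, ifelse(runif(n_decoy) < 0.15, ql * 0.97, ql))))
    tibble(
      qseqid = iso$isolate_id,
      sseqid = subjects$sseqid[match(gen, subjects$genus)],
      pident = ident,
      length = alen,
      mismatch = as.integer(round(alen * (100 - ident) / 100)),
      gapopen = 0L,
      qstart = 1L, qend = alen,
      sstart = 1L, send = alen,
      evalue = 0, bitscore = round(2 * alen * ident / 100)
    )
  })

  list(
    hits = hits,
    qlen = qlen,
    taxonomy = select(subjects, "sseqid", "genus", "family", "order"),
    isolate_map = select(rows, "isolate_id", "sample_id", "visit", "true_genus")
  )
}

#' Simulate a complete synthetic study dataset
#'
#' Orchestrates [simulate_metadata_weather()], [simulate_counts()] and
#' [simulate_isolates()] under one seed, so the weather that drives part of
#' the initial concentration is the same weather exposed to the covariate
#' harness.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `counts`, `truth`, `metadata`, `weather`,
#'   `isolates` (itself a list of hit/qlen/taxonomy/map tibbles) and the
#'   `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  mw <- simulate_metadata_weather(cfg)
  cts <- simulate_counts(cfg, mw$metadata, mw$weather)
  iso <- simulate_isolates(cfg, mw$metadata)
  structure(list(
    counts = cts$counts, truth = cts$truth, metadata = mw$metadata,
    weather = mw$weather, isolates = iso, config = cfg
  ), class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Counts, metadata and weather as CSV; isolate hits as 12-column BLAST
#' tabular TSV without header; taxonomy, query lengths and the isolate map as
#' CSV sidecars.
#'
#' @param dataset A `sim_dataset` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.csv"),
    metadata = file.path(dir, "metadata.csv"),
    weather = file.path(dir, "weather.csv"),
    hits = file.path(dir, "isolate_hits.tsv"),
    qlen = file.path(dir, "isolate_qlen.csv"),
    taxonomy = file.path(dir, "isolate_taxonomy.csv"),
    isolate_map = file.path(dir, "isolate_map.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(dataset$counts, paths["counts"])
  readr::write_csv(dataset$metadata, paths["metadata"])
  readr::write_csv(dataset$weather, paths["weather"])
  readr::write_tsv(dataset$isolates$hits, paths["hits"], col_names = FALSE)
  readr::write_csv(dataset$isolates$qlen, paths["qlen"])
  readr::write_csv(dataset$isolates$taxonomy, paths["taxonomy"])
  readr::write_csv(dataset$isolates$isolate_map, paths["isolate_map"])
  readr::write_csv(dataset$truth, paths["truth"])
  invisible(paths)
}
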
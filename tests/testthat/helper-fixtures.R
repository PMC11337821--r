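# Small builders shared across test files; everything is generated in code.

tiny_config <- function(..., seed = 101) {
  sim_config(n_samples_per_region = 4, seed = seed, ...)
}

# exact no-noise observations from a Baranyi curve on the study day grid
exact_baranyi_obs <- function(N0 = 5, mumax = 0.5, Nmax = 8,
                              days = c(0, 7, 12, 17, 22)) {
  tibble::tibble(day = days,
                 log10_conc = baranyi_nolag_log10(days, N0, mumax, Nmax))
}

# aggregated packaged APC counts with arrival covariate, ready for the P model
packaged_apc_pool <- function(cfg) {
  sim <- simulate_counts(cfg)
  agg <- aggregate_replicates(sim$counts)
  agg <- dplyr::filter(agg, sample_type == "packaged", test == "APC")
  dplyr::left_join(
    agg,
    dplyr::select(sim$metadata, sample_id, harvest_to_arrival_days),
    by = "sample_id"
  )
}

# a dataset drawn from the packaged-model class itself: region shift, quadratic
# day trend, lot intercept, iid noise, plus an optional sample-level covariate
pmodel_class_data <- function(seed, n_per = 10, region_effect = 0.5,
                              lot_sd = 0.3, noise_sd = 0.25,
                              null_cov = TRUE,
                              days = c(3, 7, 12, 17, 22)) {
  withr::with_seed(seed, {
    md <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(2 * n_per)),
      region = rep(c("A", "B"), each = n_per)
    )
    if (null_cov) md$null_cov <- rnorm(2 * n_per)
    md$lot <- rnorm(2 * n_per, 0, lot_sd)
    d <- tidyr::crossing(sample_id = md$sample_id, shelf_day = days)
    d <- dplyr::left_join(d, md, by = "sample_id")
    d$geo_mean_log10 <- 5 + region_effect * (d$region == "B") +
      0.35 * d$shelf_day - 0.009 * d$shelf_day^2 + d$lot +
      rnorm(nrow(d), 0, noise_sd)
    d
  })
}

# hand-built BLAST hit tables for the assignment rules
hit_row <- function(q, s, pident, len = 700, qlen = 700) {
  tibble::tibble(
    qseqid = q, sseqid = s, pident = pident, length = len,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
    sstart = 1L, send = len, evalue = 0, bitscore = 2 * len,
    qlen = qlen
  )
}

with_tax <- function(hits, tax) {
  dplyr::left_join(hits, tax, by = "sseqid")
}

toy_taxonomy <- tibble::tribble(
  ~sseqid, ~genus, ~family, ~order,
  "sA", "GenusA", "FamF", "OrdO",
  "sB", "GenusB", "FamF", "OrdO",
  "sC", "GenusC", "FamG", "OrdO",
  "sD", "GenusD", "FamH", "OrdP"
)
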
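#' Read a 12-column BLAST tabular hit file with taxonomy sidecars
#'
#' Parses outfmt-6-style output (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore), joins per-query
#' sequence lengths and per-subject taxonomy (genus, family, order). Subject
#' ids missing from the taxonomy table are an error.
#'
#' @param hits Path to a headerless TSV, or a data frame already holding the
#'   12 columns.
#' @param qlen Data frame (or CSV path) with columns `qseqid`, `qlen`.
#' @param taxonomy Data frame (or CSV path) with columns `sseqid`, `genus`,
#'   `family`, `order`.
#' @return Tibble of hits with `qlen`, `genus`, `family`, `order` joined.
#' @export
parse_blast_table <- function(hits, qlen, taxonomy) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (is.character(hits)) {
    hits <- readr::read_tsv(hits, col_names = cols, show_col_types = FALSE)
  } else {
    hits <- as_tibble(hits)
    if (!all(cols %in% names(hits))) names(hits)[seq_along(cols)] <- cols
  }
  if (is.character(qlen)) qlen <- readr::read_csv(qlen, show_col_types = FALSE)
  if (is.character(taxonomy)) taxonomy <- readr::read_csv(taxonomy, show_col_types = FALSE)
  if (nrow(hits) == 0) {
    return(mutate(hits, qlen = integer(0), genus = character(0),
                  family = character(0), order = character(0)))
  }
  missing <- setdiff(unique(hits$sseqid), taxonomy$sseqid)
  if (length(missing)) {
    abort(paste0("Subject ids missing from taxonomy table: ",
                 paste(missing, collapse = ", ")))
  }
  hits %>%
    left_join(select(qlen, "qseqid", "qlen"), by = "qseqid") %>%
    left_join(select(taxonomy, "sseqid", "genus", "family", "order"),
              by = "sseqid")
}

#' Filter hits by alignment-length fraction
#'
#' Removes hits whose alignment length is less than `min_len_frac` of the
#' query length (the "alignment shorter than 99 percent of the query" rule);
#' a hit exactly at the fraction is kept.
#'
#' @param hits Parsed hit tibble with columns `length` and `qlen`.
#' @param min_len_frac Minimum alignment length as a fraction of query
#'   length.
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_len_frac = 0.99) {
  stopifnot(all(c("length", "qlen") %in% names(hits)))
  hits[hits$length >= min_len_frac * hits$qlen, , drop = FALSE]
}

#' Genus assignment with rank escalation for near-ties
#'
#' Each query's top hit by percent identity nominates its genus. If any hit
#' from a *different* genus lies within `delta_pp` percentage points of the
#' top identity (inclusive; exact ties at the top count), the call is
#' escalated to the lowest taxonomic rank shared by the top hit and all such
#' contenders — family if they agree on family, else order, else the isolate
#' is left unclassified (and is excluded from genus-level analyses).
#'
#' @param hits Filtered hit tibble (from [filter_hits()]) for any number of
#'   queries.
#' @param delta_pp Identity margin (percentage points) within which a
#'   different-genus hit forces escalation.
#' @return Tibble with one row per query: `isolate_id`, `rank`
#'   (`"genus"`, `"family"`, `"order"` or `"unclassified"`), `taxon`, and
#'   `top_pident`. Queries with no hits are absent (callers may reinstate
#'   them as unclassified via the isolate map).
#' @export
assign_taxa <- function(hits, delta_pp = 0.50) {
  if (nrow(hits) == 0) {
    return(tibble(isolate_id = character(), rank = character(),
                  taxon = character(), top_pident = numeric()))
  }
  hits %>%
    group_by(isolate_id = .data$qseqid) %>%
    dplyr::group_modify(function(h, key) assign_one(h, delta_pp)) %>%
    ungroup()
}

assign_one <- function(h, delta_pp) {
  top_ident <- max(h$pident)
  top <- h[h$pident == top_ident, , drop = FALSE]
  top_genus <- top$genus[1]
  contenders <- h[top_ident - h$pident <= delta_pp & h$genus != top_genus, ,
                  drop = FALSE]
  if (nrow(contenders) == 0) {
    return(tibble(rank = "genus", taxon = top_genus, top_pident = top_ident))
  }
  grp <- bind_rows(top[1, ], contenders)
  if (dplyr::n_distinct(grp$family) == 1) {
    tibble(rank = "family", taxon = grp$family[1], top_pident = top_ident)
  } else if (dplyr::n_distinct(grp$order) == 1) {
    tibble(rank = "order", taxon = grp$order[1], top_pident = top_ident)
  } else {
    tibble(rank = "unclassified", taxon = NA_character_, top_pident = top_ident)
  }
}

#' Pool rare genera
#'
#' Genus-rank calls whose genus accounts for less than `threshold` of all
#' genus-rank calls (the analysis set) are relabelled `"rare"`; a genus at
#' exactly the threshold is kept. Non-genus calls are untouched.
#'
#' @param assignments Assignment tibble from [assign_taxa()].
#' @param threshold Prevalence cutoff (fraction of analyzed isolates).
#' @return The assignments with a logical `rare` column and pooled `taxon`
#'   labels.
#' @export
pool_rare <- function(assignments, threshold = 0.01) {
  genus_rows <- assignments$rank == "genus"
  n_analyzed <- sum(genus_rows)
  prev <- table(assignments$taxon[genus_rows]) / max(n_analyzed, 1)
  rare_genera <- names(prev)[prev < threshold]
  assignments %>%
    mutate(
      rare = .data$rank == "genus" & .data$taxon %in% rare_genera,
      taxon = ifelse(.data$rare, "rare", .data$taxon)
    )
}

#' Per-sample-visit genus composition matrix
#'
#' Counts genus-rank isolates (after rare pooling) per sample x visit unit.
#' Non-genus (escalated or unclassified) isolates are excluded; chosen visits
#' (e.g. the unbalanced end-of-shelf-life day) can be dropped before
#' ordination or PERMANOVA.
#'
#' @param assignments Assignment tibble carrying `sample_id` and `visit`
#'   columns (join the isolate map first).
#' @param drop_visits Character vector of visits to exclude (`NULL` keeps
#'   all).
#' @return A `composition` tibble: `sample_id`, `visit`, `unit` and one
#'   integer count column per taxon; taxa columns sum row-wise to the number
#'   of analyzed isolates of that unit.
#' @export
build_composition <- function(assignments, drop_visits = NULL) {
  stopifnot(all(c("sample_id", "visit", "rank", "taxon") %in% names(assignments)))
  d <- assignments %>%
    filter(.data$rank == "genus") %>%
    filter(is.null(drop_visits) | !.data$visit %in% drop_visits)
  if (nrow(d) == 0) abort("No genus-rank isolates left after exclusions.")
  wide <- d %>%
    count(.data$sample_id, .data$visit, .data$taxon) %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "n",
                       values_fill = 0L) %>%
    mutate(unit = paste(.data$sample_id, .data$visit, sep = "."),
           .after = "visit")
  structure(wide, class = c("composition", class(wide)))
}

composition_matrix <- function(comp) {
  taxa <- setdiff(names(comp), c("sample_id", "visit", "unit", "region"))
  m <- as.matrix(comp[taxa])
  rownames(m) <- comp$unit
  storage.mode(m) <- "double"
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between
#' non-negative abundance vectors: 0 for identical rows, 1 for disjoint
#' supports.
#'
#' @param x A `composition` tibble or a numeric matrix (rows = units).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "composition")) composition_matrix(x) else as.matrix(x)
  if (nrow(m) < 2) abort("Need at least 2 rows.")
  if (any(m < 0)) abort("Abundances must be non-negative.")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("All-zero rows have undefined Bray-Curtis distances.")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / (rs[i] + rs[j])
    }
  }
  d
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); cm <- colMeans(a); gm <- mean(a)
  a - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double-centering
#' of \eqn{-d^2/2}, eigendecomposition, coordinates from the positive
#' eigenvalues scaled by their square roots. Variance explained is reported
#' relative to the sum of positive eigenvalues; negative eigenvalues (from
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported but not
#' embedded.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @return A `pcoa_result`: list with `points` tibble (`unit`, `axis1`,
#'   `axis2`, ...), `eigenvalues`, `variance_explained` and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    abort("`d` must be square and symmetric.")
  }
  g <- gower_center(d)
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  pos <- which(eg$values > tol)
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                    length(pos))
  colnames(coords) <- paste0("axis", seq_along(pos))
  pts <- as_tibble(coords)
  pts$unit <- rownames(d) %||% as.character(seq_len(nrow(d)))
  structure(list(
    points = select(pts, "unit", dplyr::everything()),
    eigenvalues = eg$values,
    variance_explained = eg$values[pos] / sum(eg$values[pos]),
    negative_eigenvalues = eg$values[eg$values < -tol]
  ), class = "pcoa_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result: %d units, %d positive axes>\n",
              nrow(x$points), length(x$variance_explained)))
  cat(sprintf("  axis 1: %.1f%%, axis 2: %.1f%% of positive-eigenvalue variance\n",
              100 * x$variance_explained[1],
              100 * (x$variance_explained[2] %||% NA)))
  invisible(x)
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param groups Optional vector (aligned with units) used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) pts$group <- groups
  ve <- 100 * object$variance_explained
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", ve[1]),
                  y = sprintf("PCo2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Permutational multivariate analysis of variance
#'
#' Two-factor PERMANOVA with sequential (Type-I) sums of squares computed
#' from the Gower-centered dissimilarity matrix, pseudo-F statistics per
#' term, and p-values from `n_perm` permutations of the observation labels:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm} + 1)}.
#'
#' @param d Dissimilarity matrix whose rows match `data`.
#' @param data Data frame of factors for the rows of `d`.
#' @param rhs Character vector of model terms in sequential order, e.g.
#'   `c("visit", "region", "visit:region")`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return A `permanova` tibble: term, df, sum of squares, R2, pseudo-F and
#'   permutation p-value, plus residual and total rows.
#' @export
permanova <- function(d, data, rhs = c("visit", "region", "visit:region"),
                      n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(nrow(data) == n)
  for (v in all.vars(as.formula(paste("~", paste(rhs, collapse = "+"))))) {
    if (dplyr::n_distinct(data[[v]]) < 2) {
      abort(sprintf("Factor '%s' needs at least 2 levels.", v))
    }
  }
  g <- gower_center(d)
  ss_total <- sum(diag(g))

  # cumulative hat matrices for sequential SS
  hats <- vector("list", length(rhs))
  prev_terms <- character(0)
  dfs <- numeric(length(rhs))
  prev_rank <- 1 # intercept
  for (k in seq_along(rhs)) {
    terms_k <- c(prev_terms, rhs[k])
    X <- model.matrix(as.formula(paste("~", paste(terms_k, collapse = "+"))),
                      data = data)
    qr_x <- qr(X)
    if (qr_x$rank == prev_rank) {
      abort(sprintf("Term '%s' is confounded with earlier terms.", rhs[k]))
    }
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[k]] <- Q %*% t(Q)
    dfs[k] <- qr_x$rank - prev_rank
    prev_rank <- qr_x$rank
    prev_terms <- terms_k
  }
  df_res <- n - prev_rank

  stat_fun <- function(gp) {
    tr <- vapply(hats, function(h) sum(h * gp), numeric(1)) # tr(H G H) = sum(H * G) for idempotent symmetric H
    ss <- diff(c(0, tr))
    # clamp: a saturated design leaves exactly zero residual SS, but floating
    # point can make it tiny-negative, flipping the pseudo-F sign
    ss_res <- max(sum(diag(gp)) - tr[length(tr)], 0)
    list(ss = ss, ss_res = ss_res,
         f = (ss / dfs) / (ss_res / df_res))
  }
  obs <- stat_fun(g)

  withr::with_seed(as.integer(seed), {
    exceed <- rep(1L, length(rhs)) # the observed ordering counts once
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fp <- stat_fun(g[p, p])$f
      exceed <- exceed + (fp >= obs$f - 1e-12)
    }
    pvals <- exceed / (n_perm + 1)
  })

  out <- tibble(
    term = c(rhs, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA)
  )
  structure(out, class = c("permanova", class(out)), n_perm = n_perm)
}

#' Monte-Carlo Fisher exact test for r x c contingency tables
#'
#' Tests independence of rows and columns by simulating `B` random tables
#' with the observed margins ([stats::r2dtable()]) and comparing their null
#' probabilities to the observed table's: the two-sided p-value is
#' \eqn{(1 + \#\{P_{sim} \le P_{obs}\})/(B + 1)}, the usual
#' table-probability ordering for exact tests.
#'
#' @param tab Non-negative integer matrix with positive row and column sums.
#' @param B Number of simulated tables.
#' @param seed Optional seed.
#' @return One-row tibble with `p_value`, `B` and the observed
#'   log-probability.
#' @export
fisher_exact_mc <- function(tab, B = 2000, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain non-negative integers.")
  }
  r <- rowSums(tab); cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) abort("All margins must be positive.")
  logp <- function(m) {
    sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(m) + 1) -
      sum(lgamma(m + 1))
  }
  obs <- logp(tab)
  run <- function() {
    sims <- r2dtable(B, r, cs)
    hits <- vapply(sims, function(m) logp(m) <= obs + 1e-7, logical(1))
    tibble(p_value = (1 + sum(hits)) / (B + 1), B = B, log_prob_obs = obs)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Full isolate post-processing chain
#'
#' Parse, length-filter, assign with rank escalation, join the isolate map,
#' and pool rare genera — the path from raw BLAST tabular output to
#' analysis-ready assignments.
#'
#' @inheritParams parse_blast_table
#' @param isolate_map Data frame (or CSV path) with `isolate_id`,
#'   `sample_id`, `visit` (isolates absent from the hit table are reinstated
#'   as unclassified).
#' @param min_len_frac,delta_pp,rare_threshold Stage parameters (see
#'   [filter_hits()], [assign_taxa()], [pool_rare()]).
#' @return Assignment tibble with sample/visit columns, rank, taxon and rare
#'   flag.
#' @export
process_isolates <- function(hits, qlen, taxonomy, isolate_map,
                             min_len_frac = 0.99, delta_pp = 0.50,
                             rare_threshold = 0.01) {
  if (is.character(isolate_map)) {
    isolate_map <- readr::read_csv(isolate_map, show_col_types = FALSE)
  }
  parsed <- parse_blast_table(hits, qlen, taxonomy)
  kept <- filter_hits(parsed, min_len_frac)
  asg <- assign_taxa(kept, delta_pp)
  full <- isolate_map %>%
    left_join(asg, by = "isolate_id") %>%
    mutate(
      rank = ifelse(is.na(.data$rank), "unclassified", .data$rank)
    )
  pool_rare(full, rare_threshold)
}
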
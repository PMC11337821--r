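test_that("BLAST tables parse with taxonomy joins and strict subject checking", {
  hits <- dplyr::bind_rows(
    hit_row("q1", "sA", 99.5), hit_row("q1", "sB", 99.2), hit_row("q2", "sC", 98.0)
  )[, 1:12]
  qlen <- tibble::tibble(qseqid = c("q1", "q2"), qlen = c(700L, 700L))
  parsed <- parse_blast_table(hits, qlen, toy_taxonomy)
  expect_equal(nrow(parsed), 3)
  expect_equal(parsed$genus, c("GenusA", "GenusB", "GenusC"))
  bad <- dplyr::mutate(hits, sseqid = c("sA", "sZ", "sC"))
  expect_error(parse_blast_table(bad, qlen, toy_taxonomy), "sZ")
  empty <- hits[0, ]
  expect_equal(nrow(parse_blast_table(empty, qlen, toy_taxonomy)), 0)
  # round-trips through a headerless TSV on disk
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(hits, tsv, col_names = FALSE)
  expect_equal(nrow(parse_blast_table(tsv, qlen, toy_taxonomy)), 3)
})

test_that("alignment-length filter keeps hits at exactly the 99% boundary", {
  h <- dplyr::bind_rows(
    hit_row("q1", "sA", 99, len = 593, qlen = 600), # 593 < 594: removed
    hit_row("q2", "sA", 99, len = 594, qlen = 600), # exactly 99%: kept
    hit_row("q3", "sA", 99, len = 600, qlen = 600)
  )
  kept <- filter_hits(h)
  expect_setequal(kept$qseqid, c("q2", "q3"))
})

test_that("genus assignment escalates on near-ties by shared rank", {
  tax <- toy_taxonomy
  # different genus, same family, within 0.5 pp: family call
  h1 <- with_tax(dplyr::bind_rows(hit_row("q1", "sA", 99.5),
                                  hit_row("q1", "sB", 99.2)), tax)
  a1 <- assign_taxa(h1)
  expect_equal(a1$rank, "family")
  expect_equal(a1$taxon, "FamF")
  # margin above 0.5 pp: genus of the top hit
  h2 <- with_tax(dplyr::bind_rows(hit_row("q2", "sA", 99.5),
                                  hit_row("q2", "sB", 98.9)), tax)
  a2 <- assign_taxa(h2)
  expect_equal(a2$rank, "genus")
  expect_equal(a2$taxon, "GenusA")
  # single hit: its genus, regardless of identity
  a3 <- assign_taxa(with_tax(hit_row("q3", "sC", 97.0), tax))
  expect_equal(a3$taxon, "GenusC")
  # margin exactly 0.5 pp is within the rule
  h4 <- with_tax(dplyr::bind_rows(hit_row("q4", "sA", 99.5),
                                  hit_row("q4", "sB", 99.0)), tax)
  expect_equal(assign_taxa(h4)$rank, "family")
  # contenders spanning families but one order escalate to order
  h5 <- with_tax(dplyr::bind_rows(hit_row("q5", "sA", 99.5),
                                  hit_row("q5", "sC", 99.3)), tax)
  a5 <- assign_taxa(h5)
  expect_equal(a5$rank, "order")
  expect_equal(a5$taxon, "OrdO")
  # no shared named rank at all: unclassified
  h6 <- with_tax(dplyr::bind_rows(hit_row("q6", "sA", 99.5),
                                  hit_row("q6", "sD", 99.4)), tax)
  expect_equal(assign_taxa(h6)$rank, "unclassified")
  # an exact tie at the top across genera triggers the rule at 0 pp
  h7 <- with_tax(dplyr::bind_rows(hit_row("q7", "sA", 99.5),
                                  hit_row("q7", "sB", 99.5)), tax)
  expect_equal(assign_taxa(h7)$rank, "family")
})

test_that("assignment is order-independent across hit rows", {
  tax <- toy_taxonomy
  h <- with_tax(dplyr::bind_rows(hit_row("q1", "sA", 99.5),
                                 hit_row("q1", "sB", 99.2),
                                 hit_row("q1", "sC", 97.0)), tax)
  expect_equal(assign_taxa(h), assign_taxa(h[c(3, 1, 2), ]))
})

test_that("rare pooling applies the strict 1% rule to the analysis set", {
  asg <- tibble::tibble(
    isolate_id = sprintf("i%04d", 1:1000),
    rank = "genus",
    taxon = c(rep("Big", 700), rep("Mid", 281), rep("Rare9", 9),
              rep("Edge10", 10))
  )
  pooled <- pool_rare(asg)
  expect_true(all(pooled$taxon[asg$taxon == "Rare9"] == "rare")) # 0.9% < 1%
  expect_true(all(pooled$taxon[asg$taxon == "Edge10"] == "Edge10")) # exactly 1%
  expect_equal(sum(pooled$rare), 9)
  # single-genus data pool nothing
  one <- tibble::tibble(isolate_id = "a", rank = "genus", taxon = "Only")
  expect_false(pool_rare(one)$rare)
})

test_that("composition counts genus-rank isolates per sample visit", {
  asg <- tibble::tibble(
    isolate_id = sprintf("i%02d", 1:40),
    sample_id = "s1",
    visit = c(rep("H", 36), rep("D28", 4)),
    rank = c(rep("genus", 30), rep("genus", 6), rep("family", 2), rep("genus", 2)),
    taxon = c(rep("Pseudomonas", 30), rep("Pantoea", 6), rep("FamX", 2),
              rep("Pseudomonas", 2))
  )
  comp <- build_composition(asg)
  h <- comp[comp$visit == "H", ]
  expect_equal(h$Pseudomonas, 30)
  expect_equal(h$Pantoea, 6)
  # family-rank rows never enter the genus matrix
  expect_false("FamX" %in% names(comp))
  # visit exclusion removes whole units
  comp2 <- build_composition(asg, drop_visits = "D28")
  expect_false("D28" %in% comp2$visit)
  expect_error(build_composition(asg[asg$rank == "family", ]), "No genus-rank")
})

test_that("Bray-Curtis matches its formula and stays in [0, 1]", {
  m <- rbind(c(2, 1), c(1, 2))
  d <- bray_curtis(m)
  expect_equal(d[1, 2], 1 / 3)
  expect_equal(diag(d), c(0, 0))
  expect_equal(bray_curtis(rbind(c(5, 0), c(0, 7)))[1, 2], 1) # disjoint
  expect_equal(bray_curtis(rbind(c(3, 3), c(3, 3)))[1, 2], 0) # identical
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "All-zero")
  withr::with_seed(10, {
    for (i in 1:10) {
      m <- matrix(rpois(24, 5) + 1, 6, 4)
      d <- bray_curtis(m)
      expect_equal(d, t(d))
      expect_true(all(d >= 0 & d <= 1))
    }
  })
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(12, m <- matrix(rpois(40, 6), 8, 5) + 1)
  expect_equal(unname(bray_curtis(m)[lower.tri(diag(8))]),
               as.vector(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  withr::with_seed(13, pts <- matrix(rnorm(20), 10, 2))
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  emb <- as.matrix(res$points[paste0("axis", 1:2)])
  expect_equal(unname(as.matrix(dist(emb))), unname(d), tolerance = 1e-8)
  expect_true(all(diff(res$variance_explained) <= 1e-12)) # sorted axes
  # coincident points get coincident coordinates
  d2 <- as.matrix(dist(rbind(pts[1, ], pts[1, ], pts[2, ])))
  res2 <- pcoa(d2)
  expect_equal(unlist(res2$points[1, -1]), unlist(res2$points[2, -1]),
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA matches classical cmdscale axes up to sign", {
  withr::with_seed(14, m <- matrix(rpois(30, 5) + 1, 6, 5))
  d <- bray_curtis(m)
  res <- pcoa(d)
  ref <- cmdscale(as.dist(d), k = 2)
  for (k in 1:2) {
    a <- res$points[[paste0("axis", k)]]
    expect_equal(min(sum((a - ref[, k])^2), sum((a + ref[, k])^2)), 0,
                 tolerance = 1e-8)
  }
})

test_that("PERMANOVA decomposes variance and matches vegan's statistics", {
  skip_if_not_installed("vegan")
  withr::with_seed(15, {
    m <- matrix(rpois(60, 8), 12, 5) + 1
    meta <- tibble::tibble(
      visit = rep(c("H", "D7"), 6),
      region = rep(c("A", "B"), each = 6)
    )
    m[meta$region == "B", 1] <- m[meta$region == "B", 1] + 12
  })
  d <- bray_curtis(m)
  res <- permanova(d, meta, rhs = c("visit", "region", "visit:region"),
                   n_perm = 499, seed = 1)
  expect_equal(sum(res$r_squared[1:4]), 1, tolerance = 1e-10)
  ref <- vegan::adonis2(as.dist(d) ~ visit * region, data = meta,
                        permutations = 499, by = "terms")
  expect_equal(res$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(res$sum_sq[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(res$p_value[res$term == "region"],
               ref$`Pr(>F)`[2], tolerance = 0.05)
})

test_that("PERMANOVA p-values approach the permutation floor for separated groups", {
  # zero within-group distance, large between: only permutations recreating
  # the exact 5/5 split (probability 2/choose(10,5) each) match the observed
  # pseudo-F, so p concentrates near (1 + n_perm * 2/252) / (n_perm + 1)
  m <- rbind(matrix(rep(c(10, 0, 0, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 0, 10), 5), 5, byrow = TRUE))
  d <- bray_curtis(m)
  meta <- tibble::tibble(group = rep(c("a", "b"), each = 5))
  res <- permanova(d, meta, rhs = "group", n_perm = 9999, seed = 1)
  expect_lte(res$p_value[1], 0.01)
  expect_gte(res$p_value[1], 1 / 10000) # bounded below by 1/(n_perm+1)
  # deterministic given the seed
  res2 <- permanova(d, meta, rhs = "group", n_perm = 999, seed = 1)
  res3 <- permanova(d, meta, rhs = "group", n_perm = 999, seed = 1)
  expect_equal(res2$p_value[1], res3$p_value[1])
  # confounded factors are refused
  meta$dup <- meta$group
  expect_error(permanova(d, meta, rhs = c("group", "dup")), "confounded")
})

test_that("Monte-Carlo Fisher approximates the exact diagonal-table p-value", {
  tab <- rbind(c(5, 0), c(0, 5))
  exact <- 2 / choose(10, 5) # the two extreme tables of the hypergeometric
  res <- fisher_exact_mc(tab, B = 4000, seed = 17)
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$p_value - exact), 3 * mc_se + 1 / 4001)
  expect_error(fisher_exact_mc(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(fisher_exact_mc(rbind(c(0.5, 1), c(1, 2))), "integers")
  # agrees with the reference Monte-Carlo implementation on an r x c table
  withr::with_seed(18, tab2 <- matrix(rpois(12, 6) + 1, 3, 4))
  p_ours <- fisher_exact_mc(tab2, B = 5000, seed = 19)$p_value
  p_ref <- stats::fisher.test(tab2, simulate.p.value = TRUE, B = 5000)$p.value
  expect_lt(abs(p_ours - p_ref), 0.04)
})

test_that("the isolate chain recovers generated truth and exercises escalation", {
  cfg <- tiny_config()
  ds <- simulate_study(cfg)
  iso <- ds$isolates
  asg <- process_isolates(iso$hits, iso$qlen, iso$taxonomy, iso$isolate_map)
  expect_equal(nrow(asg), nrow(iso$isolate_map))
  genus_rows <- asg[asg$rank == "genus" & !asg$rare, ]
  truth <- iso$isolate_map$true_genus[match(genus_rows$isolate_id,
                                            iso$isolate_map$isolate_id)]
  expect_true(all(genus_rows$taxon == truth))
  # with identity margins inside the 0.5-pp rule every isolate escalates
  cfg2 <- tiny_config(identity_margin_range = c(0.1, 0.3))
  iso2 <- simulate_isolates(cfg2)
  asg2 <- process_isolates(iso2$hits, iso2$qlen, iso2$taxonomy, iso2$isolate_map)
  # a few isolates lose all their decoy hits to the length filter and stay
  # at genus rank; the overwhelming majority must escalate
  expect_gt(mean(asg2$rank != "genus"), 0.9)
})
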
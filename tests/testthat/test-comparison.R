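test_that("the packaged Apulian class grid reproduces the published divergences", {
  classes <- read_eqs_classes(bg_example("apulia_eqs_classes.tsv"))
  dv <- class_divergence(classes)
  expect_equal(dv$n_comparisons, 30)
  expect_equal(dv$n_divergent, 8)
  expect_equal(dv$percent_divergent, 100 * 8 / 30, tolerance = 1e-12)
  expect_equal(dv$percent_divergent_rounded, 27)
  expect_equal(dv$n_reduced_better, 1)
  better <- dv$per_cell[dv$per_cell$signed_distance > 0, ]
  expect_equal(better$site_id, "9")
  expect_equal(better$season, "fall")
  expect_equal(better$class_morph, "Poor")
  expect_equal(better$class_reduced, "Moderate")
  # one two-class jump is present in the grid and must be surfaced
  expect_equal(dv$max_class_distance, 2)
})

test_that("divergence bookkeeping is antisymmetric and identity-safe", {
  classes <- read_eqs_classes(bg_example("apulia_eqs_classes.tsv"))
  dv <- class_divergence(classes)
  expect_equal(dv$n_divergent, dv$n_reduced_better + dv$n_reduced_worse)

  swapped <- classes
  swapped$database <- ifelse(classes$database == "reduced",
                             "morphological", "reduced")
  dv2 <- class_divergence(swapped)
  expect_equal(dv2$n_reduced_better, dv$n_reduced_worse)
  expect_equal(dv2$n_reduced_worse, dv$n_reduced_better)
  expect_equal(sort(dv2$per_cell$signed_distance),
               sort(-dv$per_cell$signed_distance))

  same <- classes
  same$eqs_class[same$database == "reduced"] <-
    same$eqs_class[same$database == "morphological"][
      match(paste(same$site_id, same$season)[same$database == "reduced"],
            paste(same$site_id, same$season)[same$database == "morphological"])]
  same$ordinal <- eqs_ordinal(same$eqs_class)
  expect_equal(class_divergence(same)$n_divergent, 0)

  expect_error(class_divergence(classes[-1, ]), "unpaired")
})

test_that("pearson matches the product-moment formula and cor.test", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:3, 3:1)$r, -1)
  r <- pearson(c(1, 2, 4), c(1, 3, 5))
  expect_equal(r$r, 6 / sqrt(4.666666666666667 * 8), tolerance = 1e-12)
  expect_equal(round(r$r, 4), 0.982)
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  # r is invariant to Shannon log-base change (a positive rescale)
  x <- c(1.2, 2.3, 0.8, 3.1); y <- c(1.1, 2.0, 1.0, 2.8)
  expect_equal(pearson(x / log(2), y / log(2))$r, pearson(x, y)$r,
               tolerance = 1e-12)
})

test_that("paired extraction aligns keys and errors on mismatch", {
  cat <- tiny_catalog()
  com <- tiny_community()
  red <- reduce_community(com, reduce_catalog(cat))
  mm <- compute_metrics(com, cat, "morphological")
  mr <- compute_metrics(red, cat, "reduced")
  pm <- paired_metrics(mm, mr, "S")
  expect_equal(length(pm$x), nrow(mm))
  expect_true(all(pm$y <= pm$x))
  expect_error(paired_metrics(mm[-1, ], mr, "S"), "unmatched")
  expect_error(paired_metrics(mm[mm$season == "fall", ],
                              mr[mr$season == "spring", ], "S"),
               "unmatched|no overlapping")
})

test_that("the pipeline is deterministic and validates its inputs", {
  cfg <- synth_config(seed = 5)
  cat <- simulate_catalog(cfg)
  com <- simulate_communities(cfg, cat)
  r1 <- run_pipeline(cat, com)
  r2 <- run_pipeline(cat, com)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$correlations, r2$correlations)

  bad_com <- suppressWarnings(community_table("s1", "fall", "Ghost sp", 3))
  expect_error(run_pipeline(cat, bad_com), "absent from the catalog")

  # union of sources can only add species, never remove them, per site
  r_bold <- run_pipeline(cat, com, sources = "bold")
  s_union <- r1$metrics[r1$metrics$database == "reduced", ]
  s_bold <- r_bold$metrics[r_bold$metrics$database == "reduced", ]
  expect_true(all(s_union$S >= s_bold$S))

  # output bundle round trip
  out <- withr::local_tempdir()
  run_pipeline(cat, com, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("metrics.tsv", "mambi.tsv", "eqs_classes.tsv",
           "divergence_cells.tsv", "correlations.tsv", "run_log.txt")))))
  back <- read_eqs_classes(file.path(out, "eqs_classes.tsv"))
  expect_equal(nrow(back), nrow(as.data.frame(r1$classes)))
})
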
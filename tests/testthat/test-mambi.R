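# metrics table builder for direct score tests
fake_metrics <- function(ambi, h, s, database = "morphological") {
  n <- length(ambi)
  structure(data.frame(
    site_id = sprintf("s%02d", seq_len(n)), season = "fall",
    database = database, S = s, H = h, ambi = ambi,
    na_fraction = 0, ambi_valid = TRUE, azoic = FALSE, log_base = 2,
    stringsAsFactors = FALSE), class = c("metrics_table", "data.frame"))
}

test_that("default references inflate observed maxima and validate ordering", {
  m <- fake_metrics(ambi = c(1, 2), h = c(3.0, 2.0), s = c(20, 10))
  refs <- default_references(m)
  expect_equal(unname(refs$high), c(0, 3.45, 23))
  expect_equal(unname(refs$bad), c(6, 0, 0))
  refs1 <- default_references(m, inflation = 1)
  expect_equal(unname(refs1$high), c(0, 3, 20))
  expect_error(default_references(m[0, ]), "empty")
  expect_error(default_references(m, high = c(ambi = 7, h = 1, s = 1)),
               "invalid references")
})

test_that("references score exactly 1 and 0; the midpoint scores 0.5", {
  m <- fake_metrics(ambi = c(1.2, 4.1, 3, 2.6), h = c(3.1, 0.7, 1.8, 2.2),
                    s = c(18, 4, 9, 12))
  refs <- default_references(m)
  # append the reference triplets themselves as pseudo-samples
  mid <- (refs$high + refs$bad) / 2
  m2 <- rbind(m, fake_metrics(
    ambi = c(refs$high[["ambi"]], refs$bad[["ambi"]], mid[["ambi"]]),
    h = c(refs$high[["h"]], refs$bad[["h"]], mid[["h"]]),
    s = c(refs$high[["s"]], refs$bad[["s"]], mid[["s"]])))
  sc <- mambi_scores(m2, refs)
  n <- nrow(sc)
  expect_equal(sc$raw_score[n - 2], 1, tolerance = 1e-9)
  expect_equal(sc$raw_score[n - 1], 0, tolerance = 1e-9)
  expect_equal(sc$raw_score[n], 0.5, tolerance = 1e-9)
})

test_that("scores are invariant to positive rescaling of any input column", {
  m <- fake_metrics(ambi = c(1.2, 4.1, 3), h = c(3.1, 0.7, 1.8),
                    s = c(18, 4, 9))
  refs <- default_references(m)
  base <- mambi_scores(m, refs)$raw_score
  for (col in c("ambi", "H", "S")) {
    k <- 3.7
    m2 <- m; m2[[col]] <- m2[[col]] * k
    refs2 <- refs
    rc <- tolower(ifelse(col == "ambi", "ambi", col))
    refs2$high[[rc]] <- refs2$high[[rc]] * k
    refs2$bad[[rc]] <- refs2$bad[[rc]] * k
    expect_equal(mambi_scores(m2, refs2)$raw_score, base, tolerance = 1e-9)
  }
})

test_that("full-rank projection equals the direct standardized-space oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8
    m <- fake_metrics(ambi = runif(n, 0, 6), h = runif(n, 0, 4),
                      s = sample(3:25, n, replace = TRUE))
    refs <- default_references(m)
    got <- mambi_scores(m, refs, n_factors = 3)$raw_score
    # oracle: standardize, then project straight onto the bad->high axis
    x <- rbind(as.matrix(m[, c("ambi", "H", "S")]),
               refs$high, refs$bad)
    z <- scale(x)
    hi <- z[n + 1, ]; lo <- z[n + 2, ]
    oracle <- as.numeric((sweep(z[1:n, , drop = FALSE], 2, lo) %*%
                            (hi - lo)) / sum((hi - lo)^2))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("points along the bad-to-high segment score monotonically", {
  m <- fake_metrics(ambi = c(1, 3, 5), h = c(3, 2, 1), s = c(20, 10, 5))
  refs <- default_references(m)
  ts <- seq(0.1, 0.9, by = 0.2)
  seg <- fake_metrics(
    ambi = refs$bad[["ambi"]] + ts * (refs$high[["ambi"]] - refs$bad[["ambi"]]),
    h = refs$bad[["h"]] + ts * (refs$high[["h"]] - refs$bad[["h"]]),
    s = refs$bad[["s"]] + ts * (refs$high[["s"]] - refs$bad[["s"]]))
  sc <- mambi_scores(rbind(m, seg), refs)$raw_score
  seg_scores <- tail(sc, length(ts))
  expect_true(all(diff(seg_scores) > 0))
  expect_equal(seg_scores, ts, tolerance = 1e-9)
})

test_that("azoic samples score zero and degenerate columns error", {
  m <- fake_metrics(ambi = c(2, 3), h = c(1, 2), s = c(5, 9))
  m$azoic[1] <- TRUE
  sc <- mambi_scores(m, default_references(m))
  expect_equal(sc$score[1], 0)
  expect_equal(sc$eqs_class[1], "Bad")

  # all samples and both references share one AMBI value: no variance left
  m2 <- fake_metrics(ambi = c(3, 3), h = c(1, 2), s = c(5, 9))
  degenerate_refs <- structure(list(
    high = c(ambi = 3, h = 4, s = 20),
    bad = c(ambi = 3, h = 0, s = 0)), class = "reference_conditions")
  expect_error(mambi_scores(m2, degenerate_refs), "zero variance")
})

test_that("EQS classification uses >= boundary semantics", {
  expect_equal(classify_eqs(0.90), "High")
  expect_equal(classify_eqs(0.53), "Good")
  expect_equal(classify_eqs(0.39), "Moderate")
  expect_equal(classify_eqs(0.20), "Poor")
  expect_equal(classify_eqs(0.10), "Bad")
  expect_equal(classify_eqs(c(0.77, 0.769999)), c("High", "Good"))
  expect_error(classify_eqs(1.2), "outside")
  expect_error(classify_eqs(0.5, c(0.9, 0.9, 0.3, 0.1)), "descending")
})
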
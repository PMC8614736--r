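#' Quality-class divergence between morphological and reduced databases
#'
#' Pairs every (site, season) cell of an EQS class table across the two
#' databases and counts divergences. The signed class distance is
#' `ordinal(reduced) - ordinal(morphological)` on the fixed encoding
#' Bad = 0 ... High = 4; a cell is divergent iff the distance is nonzero,
#' "reduced better" iff positive. `max_class_distance` reports the largest
#' absolute distance so multi-class jumps are surfaced, not hidden.
#'
#' @param classes an `eqs_class_table` (see [read_eqs_classes()]) holding
#'   both databases for every sampled cell.
#' @return a `divergence_summary` list: `n_comparisons`, `n_divergent`,
#'   `percent_divergent` (unrounded), `percent_divergent_rounded`
#'   (half-up), `n_reduced_better`, `n_reduced_worse`,
#'   `max_class_distance`, and `per_cell` (data frame with the per-cell
#'   classes and signed distances).
#' @export
class_divergence <- function(classes) {
  morph <- classes[classes$database == "morphological", , drop = FALSE]
  red <- classes[classes$database == "reduced", , drop = FALSE]
  key_m <- paste(morph$site_id, morph$season, sep = "\r")
  key_r <- paste(red$site_id, red$season, sep = "\r")
  missing <- c(setdiff(key_m, key_r), setdiff(key_r, key_m))
  if (length(missing)) {
    stop("unpaired (site, season) cell(s): ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  }
  ord <- order(morph$site_id, morph$season)
  morph <- morph[ord, ]
  red <- red[match(paste(morph$site_id, morph$season, sep = "\r"), key_r), ]
  per_cell <- data.frame(
    site_id = morph$site_id,
    season = morph$season,
    class_morph = morph$eqs_class,
    class_reduced = red$eqs_class,
    signed_distance = red$ordinal - morph$ordinal,
    stringsAsFactors = FALSE
  )
  n <- nrow(per_cell)
  n_div <- sum(per_cell$signed_distance != 0)
  structure(list(
    n_comparisons = n,
    n_divergent = n_div,
    percent_divergent = 100 * n_div / n,
    percent_divergent_rounded = .round_half_up(100 * n_div / n),
    n_reduced_better = sum(per_cell$signed_distance > 0),
    n_reduced_worse = sum(per_cell$signed_distance < 0),
    max_class_distance = if (n) max(abs(per_cell$signed_distance)) else 0L,
    per_cell = per_cell
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "EQS class divergence: %d / %d cells (%.1f%%, rounded %d%%)\n",
    "  reduced better: %d, reduced worse: %d, max class distance: %d\n"),
    x$n_divergent, x$n_comparisons, x$percent_divergent,
    as.integer(x$percent_divergent_rounded),
    x$n_reduced_better, x$n_reduced_worse, x$max_class_distance))
  div <- x$per_cell[x$per_cell$signed_distance != 0, , drop = FALSE]
  if (nrow(div)) {
    for (i in seq_len(nrow(div))) {
      cat(sprintf("  %s/%s: %s -> %s (%+d)\n", div$site_id[i],
                  div$season[i], div$class_morph[i], div$class_reduced[i],
                  div$signed_distance[i]))
    }
  }
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between paired index values, with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return a `correlation_result` list with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs for a correlation test")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in input")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance in ",
         if (sd(x) == 0) "x" else "y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)), class = "correlation_result")
}

#' Extract paired metric vectors for the two databases
#'
#' Aligns the morphological and reduced metrics tables on (site, season)
#' in deterministic sort order and returns the paired values of one metric,
#' optionally restricted to a season (the standard presentation is one
#' correlation per season).
#'
#' @param morph,reduced `metrics_table` or `mambi_table` objects for the
#'   two databases.
#' @param metric one of `"S"`, `"H"`, `"AMBI"`, `"MAMBI"`.
#' @param season optional season filter.
#' @return list with numeric vectors `x` (morphological), `y` (reduced)
#'   and the data frame `keys`.
#' @export
paired_metrics <- function(morph, reduced,
                           metric = c("S", "H", "AMBI", "MAMBI"),
                           season = NULL) {
  metric <- match.arg(metric)
  col <- switch(metric, S = "S", H = "H", AMBI = "ambi", MAMBI = "score")
  if (!col %in% names(morph) || !col %in% names(reduced)) {
    stop("metric '", metric, "' not present in the supplied tables")
  }
  if (!is.null(season)) {
    morph <- morph[morph$season == season, , drop = FALSE]
    reduced <- reduced[reduced$season == season, , drop = FALSE]
  }
  key_m <- paste(morph$site_id, morph$season, sep = "\r")
  key_r <- paste(reduced$site_id, reduced$season, sep = "\r")
  missing <- c(setdiff(key_m, key_r), setdiff(key_r, key_m))
  if (length(missing)) {
    stop("unmatched (site, season) key(s): ",
         paste(gsub("\r", "/", missing), collapse = ", "))
  }
  if (!length(key_m)) stop("no overlapping (site, season) keys")
  ord <- order(morph$site_id, morph$season)
  morph <- morph[ord, ]
  reduced <- reduced[match(paste(morph$site_id, morph$season, sep = "\r"),
                           key_r), ]
  list(x = morph[[col]], y = reduced[[col]],
       keys = morph[, c("site_id", "season")])
}

#' Run the full library-gap comparison pipeline
#'
#' Validates the inputs, builds the reduced database, computes per-sample
#' metrics and M-AMBI scores for both databases (with reference conditions
#' shared across databases by default, so the comparison isolates the
#' library-gap effect), classifies every sample, and summarizes class
#' divergence and per-season correlations of S, H, AMBI and M-AMBI.
#'
#' @param catalog a [species_catalog()].
#' @param community a [community_table()] validated against `catalog`.
#' @param sources barcode sources defining the reduced database.
#' @param log_base Shannon log base.
#' @param na_threshold,azoic_value see [ambi()].
#' @param refs optional explicit [default_references()] object; by default
#'   references are derived from the morphological metrics and shared.
#' @param shared_refs if `FALSE`, references are derived separately per
#'   database instead of shared.
#' @param thresholds EQS class boundaries.
#' @param correlations_pooled also compute season-pooled correlations.
#' @param out_dir optional directory; when given, all tables plus a run log
#'   (config hash, package version) are written as TSV files.
#' @return a list with `reduced_catalog`, `coverage`, `metrics`
#'   (both databases, stacked), `mambi` (stacked), `classes`
#'   (an `eqs_class_table`), `divergence`, and `correlations` (data frame
#'   with one row per metric and season).
#' @export
run_pipeline <- function(catalog, community,
                         sources = c("bold", "genbank"),
                         log_base = 2, na_threshold = 0.20, azoic_value = 7,
                         refs = NULL, shared_refs = TRUE,
                         thresholds = default_eqs_thresholds(),
                         correlations_pooled = FALSE,
                         out_dir = NULL) {
  validate_community(community, catalog)
  reduced_cat <- reduce_catalog(catalog, sources)
  reduced_com <- reduce_community(community, reduced_cat)
  coverage <- coverage_stats(catalog, sources)

  m_morph <- compute_metrics(community, catalog, "morphological",
                             log_base, na_threshold, azoic_value)
  m_red <- compute_metrics(reduced_com, catalog, "reduced",
                           log_base, na_threshold, azoic_value)

  if (is.null(refs)) {
    refs_morph <- default_references(m_morph)
    refs_red <- if (shared_refs) refs_morph else default_references(m_red)
  } else {
    refs_morph <- refs_red <- refs
  }
  mb_morph <- mambi_scores(m_morph, refs_morph, thresholds = thresholds)
  mb_red <- mambi_scores(m_red, refs_red, thresholds = thresholds)

  classes <- eqs_class_table(
    site_id = c(mb_morph$site_id, mb_red$site_id),
    season = c(mb_morph$season, mb_red$season),
    database = c(mb_morph$database, mb_red$database),
    eqs_class = c(mb_morph$eqs_class, mb_red$eqs_class)
  )
  divergence <- class_divergence(classes)

  seasons <- unique(community$season)
  scopes <- lapply(seasons, function(s) list(label = s, season = s))
  if (correlations_pooled) {
    scopes <- c(scopes, list(list(label = "pooled", season = NULL)))
  }
  correlations <- do.call(rbind, lapply(scopes, function(sc) {
    do.call(rbind, lapply(c("S", "H", "AMBI", "MAMBI"), function(m) {
      pm <- if (m == "MAMBI") paired_metrics(mb_morph, mb_red, m, sc$season)
        else paired_metrics(m_morph, m_red, m, sc$season)
      res <- tryCatch(pearson(pm$x, pm$y), error = function(e) NULL)
      data.frame(metric = m, season = sc$label,
                 r = if (is.null(res)) NA_real_ else res$r,
                 p_value = if (is.null(res)) NA_real_ else res$p_value,
                 n = length(pm$x), stringsAsFactors = FALSE)
    }))
  }))

  result <- list(
    reduced_catalog = reduced_cat,
    reduced_community = reduced_com,
    coverage = coverage,
    metrics = rbind(m_morph, m_red),
    mambi = rbind(mb_morph, mb_red),
    classes = classes,
    divergence = divergence,
    correlations = correlations
  )
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir,
                                                 sources, log_base)
  result
}

.write_pipeline_outputs <- function(result, out_dir, sources, log_base) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(result$metrics, "metrics.tsv")
  w(result$mambi, "mambi.tsv")
  w(as.data.frame(result$classes), "eqs_classes.tsv")
  w(result$divergence$per_cell, "divergence_cells.tsv")
  w(result$correlations, "correlations.tsv")
  cfg <- paste0("sources=", paste(sources, collapse = ","),
                ";log_base=", log_base)
  log_lines <- c(
    paste0("barcodegap version: ",
           as.character(utils::packageVersion("barcodegap"))),
    paste0("config: ", cfg),
    paste0("config_hash: ",
           sum(utf8ToInt(cfg) * seq_along(utf8ToInt(cfg))) %% 1e9),
    paste0("n_comparisons: ", result$divergence$n_comparisons),
    paste0("n_divergent: ", result$divergence$n_divergent)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
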
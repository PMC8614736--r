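#' Reference conditions for M-AMBI
#'
#' M-AMBI scales a sample between two hypothetical reference states: "bad"
#' (azoic: AMBI 6, H 0, S 0) and "high" (pristine). When high reference
#' values are not supplied by the assessor, the common practice is to take
#' the observed maxima of H and S inflated by 15% with AMBI 0; that is the
#' default here.
#'
#' @param metrics a `metrics_table` from [compute_metrics()] (or any data
#'   frame with columns `H`, `S`, and optionally `azoic`).
#' @param inflation multiplier applied to the observed maxima (default 1.15).
#' @param high,bad optional explicit overrides, each a numeric vector with
#'   elements `ambi`, `h`, `s`.
#' @return a `reference_conditions` list with `high` and `bad` triplets.
#' @export
default_references <- function(metrics, inflation = 1.15,
                               high = NULL, bad = NULL) {
  if (is.null(bad)) bad <- c(ambi = 6, h = 0, s = 0)
  if (is.null(high)) {
    if (!nrow(metrics)) stop("cannot derive references from empty metrics")
    usable <- if ("azoic" %in% names(metrics)) !metrics$azoic
      else rep(TRUE, nrow(metrics))
    if (!any(usable)) stop("all samples azoic: cannot derive high reference")
    high <- c(ambi = 0,
              h = inflation * max(metrics$H[usable]),
              s = inflation * max(metrics$S[usable]))
  }
  high <- high[c("ambi", "h", "s")]
  bad <- bad[c("ambi", "h", "s")]
  if (!(high[["ambi"]] < bad[["ambi"]] && high[["h"]] > bad[["h"]] &&
        high[["s"]] > bad[["s"]])) {
    stop("invalid references: high must have lower AMBI and higher H, S than bad")
  }
  structure(list(high = high, bad = bad), class = "reference_conditions")
}

#' Default WFD class boundaries on the M-AMBI scale
#'
#' High/Good 0.77, Good/Moderate 0.53, Moderate/Poor 0.39, Poor/Bad 0.20 —
#' boundary values widely used for transitional waters in WFD
#' intercalibration. A boundary value belongs to the upper class.
#'
#' @return named numeric vector of four descending boundaries.
#' @export
default_eqs_thresholds <- function() {
  c(high_good = 0.77, good_moderate = 0.53,
    moderate_poor = 0.39, poor_bad = 0.20)
}

#' M-AMBI scores by factor-analysis projection
#'
#' Implements the multivariate AMBI construction: the (AMBI, H, S) triplets
#' of all samples are pooled with the two reference triplets, each column
#' is standardized to zero mean and unit variance over the pooled rows, the
#' rows are projected onto the leading principal components of the
#' correlation matrix (default all 3, i.e. an isometry of the standardized
#' space), and each sample is scored by its position along the bad-to-high
#' reference axis in that space:
#'
#'   t = ((x - bad) . (high - bad)) / |high - bad|^2
#'
#' so the bad reference maps to 0 and the high reference to 1 by
#' construction. Scores are clamped to \[0, 1\]; the raw value is kept for
#' diagnostics. Azoic samples are scored 0 directly.
#'
#' @param metrics a `metrics_table` from [compute_metrics()].
#' @param refs a `reference_conditions` object; default derived from
#'   `metrics` via [default_references()].
#' @param n_factors number of leading components to retain (default 3 = all;
#'   values below 3 project onto a subspace).
#' @param thresholds class boundaries for [classify_eqs()].
#' @return a `mambi_table` data frame with columns `site_id`, `season`,
#'   `database`, `score`, `raw_score`, `eqs_class`.
#' @export
mambi_scores <- function(metrics, refs = default_references(metrics),
                         n_factors = 3,
                         thresholds = default_eqs_thresholds()) {
  if (!nrow(metrics)) stop("empty metrics table")
  azoic <- if ("azoic" %in% names(metrics)) metrics$azoic
    else rep(FALSE, nrow(metrics))
  live <- metrics[!azoic, , drop = FALSE]

  raw <- rep(0, nrow(metrics))
  if (nrow(live)) {
    x <- rbind(
      as.matrix(live[, c("ambi", "H", "S")]),
      refs$high[c("ambi", "h", "s")],
      refs$bad[c("ambi", "h", "s")]
    )
    colnames(x) <- c("ambi", "h", "s")
    mu <- colMeans(x)
    sdev <- apply(x, 2, sd)
    if (any(sdev == 0)) {
      stop("degenerate input: column(s) ",
           paste(colnames(x)[sdev == 0], collapse = ", "),
           " have zero variance across samples and references")
    }
    z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
    k <- min(n_factors, ncol(z))
    ev <- eigen(cor(x), symmetric = TRUE)
    v <- ev$vectors[, seq_len(k), drop = FALSE]
    proj <- z %*% v
    nr <- nrow(proj)
    hi <- proj[nr - 1L, ]
    lo <- proj[nr, ]
    axis <- hi - lo
    denom <- sum(axis^2)
    if (denom <= 0) stop("degenerate references: high and bad coincide after projection")
    t <- as.numeric((sweep(proj[seq_len(nr - 2L), , drop = FALSE], 2, lo, "-") %*% axis) / denom)
    raw[!azoic] <- t
  }
  score <- pmin(1, pmax(0, raw))
  out <- data.frame(
    site_id = metrics$site_id,
    season = metrics$season,
    database = metrics$database,
    score = score,
    raw_score = raw,
    eqs_class = classify_eqs(score, thresholds),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mambi_table", "data.frame")
  out
}

#' Classify an M-AMBI score into the five EQS classes
#'
#' Interval lookup against four descending boundaries; a score equal to a
#' boundary belongs to the upper class (>= semantics).
#'
#' @param score numeric vector of scores in \[0, 1\].
#' @param thresholds four strictly descending boundaries in (0, 1), as from
#'   [default_eqs_thresholds()].
#' @return character vector of class labels.
#' @export
#' @examples
#' classify_eqs(c(0.9, 0.53, 0.1))
classify_eqs <- function(score, thresholds = default_eqs_thresholds()) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4 || any(diff(thresholds) >= 0) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must be four strictly descending values in (0, 1)")
  }
  if (any(score < 0 | score > 1)) {
    stop("score outside [0, 1]; clamp before classification")
  }
  vapply(score, function(s) {
    if (s >= thresholds[1]) "High"
    else if (s >= thresholds[2]) "Good"
    else if (s >= thresholds[3]) "Moderate"
    else if (s >= thresholds[4]) "Poor"
    else "Bad"
  }, character(1))
}
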
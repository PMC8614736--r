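#' Build the reduced (barcoded-only) catalog
#'
#' The reduced database is the subset of the checklist with at least one
#' barcode record in any of the requested reference libraries. Row order is
#' preserved. An all-unbarcoded catalog reduces to an empty (but valid)
#' catalog, with a message.
#'
#' @param catalog a [species_catalog()].
#' @param sources character subset of `c("bold", "genbank")`; a species is
#'   kept if its flag is `TRUE` for at least one requested source (union
#'   semantics, matching the pooling of BOLD and GenBank records).
#' @return a [species_catalog()] restricted to barcoded species.
#' @export
reduce_catalog <- function(catalog, sources = c("bold", "genbank")) {
  if (!length(sources)) stop("'sources' must be a non-empty subset of bold/genbank")
  sources <- match.arg(sources, c("bold", "genbank"), several.ok = TRUE)
  keep <- rep(FALSE, nrow(catalog))
  if ("bold" %in% sources) keep <- keep | catalog$barcoded_bold
  if ("genbank" %in% sources) keep <- keep | catalog$barcoded_genbank
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) message("reduced catalog is empty: no species barcoded in ",
                          paste(sources, collapse = "/"))
  class(out) <- c("species_catalog", "data.frame")
  out
}

#' Restrict a community table to a reduced catalog
#'
#' Drops every community entry whose taxon is absent from `reduced`. The
#' sampled (site, season) units are preserved in the `"keys"` attribute even
#' when all their species are dropped, so such units are carried forward as
#' azoic samples rather than silently disappearing; they are also listed in
#' the `"azoic_keys"` attribute.
#'
#' @param community a [community_table()].
#' @param reduced a reduced [species_catalog()] (subset of the catalog the
#'   community was validated against).
#' @return a [community_table()] containing only barcoded taxa.
#' @export
reduce_community <- function(community, reduced) {
  keep <- community$taxon_name %in% reduced$taxon_name
  out <- community[keep, , drop = FALSE]
  rownames(out) <- NULL
  keys <- attr(community, "keys")
  attr(out, "keys") <- keys
  attr(out, "n_zero_rows") <- sum(out$abundance == 0)
  # units whose every individual belongs to a non-barcoded species
  occupied <- unique(out[out$abundance > 0, c("site_id", "season")])
  azoic <- keys[!paste(keys$site_id, keys$season) %in%
                  paste(occupied$site_id, occupied$season), , drop = FALSE]
  rownames(azoic) <- NULL
  attr(out, "azoic_keys") <- azoic
  class(out) <- c("community_table", "data.frame")
  out
}

.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Barcode-coverage statistics for a catalog
#'
#' Summarizes how much of the checklist has at least one barcode record:
#' overall and per phylum, plus each phylum's share of the *missing*
#' (non-barcoded) species. Percentages are carried unrounded; display
#' rounding is half-up to the integer (`percent_barcoded_rounded`).
#'
#' Two per-phylum statistics are reported because both readings of a
#' "phylum gap" are useful: `percent_missing_within` (share of that
#' phylum's species lacking a barcode) and `missing_share` (that phylum's
#' share of all missing species, summing to 100 over phyla when anything
#' is missing).
#'
#' @param catalog a [species_catalog()]; must be non-empty.
#' @param sources as in [reduce_catalog()].
#' @return a `coverage_summary` list with elements `n_total`, `n_barcoded`,
#'   `percent_barcoded`, `percent_barcoded_rounded`, `per_source`,
#'   `per_phylum` (data frame), `missing_share_per_phylum`.
#' @export
coverage_stats <- function(catalog, sources = c("bold", "genbank")) {
  if (!nrow(catalog)) stop("cannot compute coverage of an empty catalog")
  sources <- match.arg(sources, c("bold", "genbank"), several.ok = TRUE)
  barcoded <- rep(FALSE, nrow(catalog))
  if ("bold" %in% sources) barcoded <- barcoded | catalog$barcoded_bold
  if ("genbank" %in% sources) barcoded <- barcoded | catalog$barcoded_genbank

  n_total <- nrow(catalog)
  n_barcoded <- sum(barcoded)
  per_source <- c(
    bold = 100 * sum(catalog$barcoded_bold) / n_total,
    genbank = 100 * sum(catalog$barcoded_genbank) / n_total
  )

  phyla <- unique(catalog$phylum)
  per_phylum <- do.call(rbind, lapply(phyla, function(p) {
    in_p <- catalog$phylum == p
    nt <- sum(in_p)
    nb <- sum(barcoded & in_p)
    data.frame(phylum = p, n_total = nt, n_barcoded = nb,
               percent_barcoded = 100 * nb / nt,
               percent_missing_within = 100 * (nt - nb) / nt,
               stringsAsFactors = FALSE)
  }))
  n_missing <- n_total - n_barcoded
  missing_share <- if (n_missing > 0) {
    setNames(100 * (per_phylum$n_total - per_phylum$n_barcoded) / n_missing,
             per_phylum$phylum)
  } else {
    setNames(numeric(0), character(0))
  }
  structure(list(
    n_total = n_total,
    n_barcoded = n_barcoded,
    percent_barcoded = 100 * n_barcoded / n_total,
    percent_barcoded_rounded = .round_half_up(100 * n_barcoded / n_total),
    per_source = per_source,
    per_phylum = per_phylum,
    missing_share_per_phylum = missing_share
  ), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Barcode coverage: %d / %d species (%.1f%%, rounded %d%%)\n",
              x$n_barcoded, x$n_total, x$percent_barcoded,
              as.integer(x$percent_barcoded_rounded)))
  cat(sprintf("  by source: BOLD %.1f%%, GenBank %.1f%%\n",
              x$per_source[["bold"]], x$per_source[["genbank"]]))
  for (i in seq_len(nrow(x$per_phylum))) {
    r <- x$per_phylum[i, ]
    share <- if (length(x$missing_share_per_phylum))
      sprintf(", %.1f%% of all missing species",
              x$missing_share_per_phylum[[r$phylum]]) else ""
    cat(sprintf("  %s: %d/%d barcoded (%.1f%%)%s\n",
                r$phylum, r$n_barcoded, r$n_total, r$percent_barcoded, share))
  }
  invisible(x)
}
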
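#' Species richness
#'
#' Number of taxa with strictly positive abundance.
#'
#' @param abundances numeric vector (optionally named by taxon) of
#'   non-negative abundances.
#' @return integer richness.
#' @export
richness <- function(abundances) {
  abundances <- as.numeric(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative")
  sum(abundances > 0)
}

#' Shannon diversity index
#'
#' H = -sum p_i log(p_i) over taxa with positive abundance, with p_i the
#' abundance share. The default log base is 2 (the convention of the
#' AZTI assessment software this package parallels); the base used should
#' be recorded alongside results since H scales with 1/log(base).
#'
#' @inheritParams richness
#' @param log_base base of the logarithm (default 2).
#' @return H in the requested base; 0 for a single-species sample.
#' @export
shannon <- function(abundances, log_base = 2) {
  abundances <- as.numeric(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative")
  pos <- abundances[abundances > 0]
  if (!length(pos)) stop("all abundances are zero (azoic sample); Shannon undefined")
  p <- pos / sum(pos)
  -sum(p * log(p, base = log_base))
}

# AMBI weights for ecological groups I..V; the coefficient is the
# abundance-weighted mean of these over individuals with an assigned group.
.AMBI_WEIGHTS <- c(I = 0, II = 1.5, III = 3, IV = 4.5, V = 6)

#' AMBI benthic biotic coefficient
#'
#' The AZTI Marine Biotic Index scores a sample on a 0–6 pollution scale
#' from the proportions of individuals in five ecological groups, from
#' sensitive (I) to first-order opportunist (V):
#'
#'   AMBI = 0 f_I + 1.5 f_II + 3 f_III + 4.5 f_IV + 6 f_V
#'
#' where the fractions f are renormalized over *assigned* individuals only.
#' Individuals belonging to species with no assigned group (`"NA"`) count
#' toward `na_fraction` but not the weighted mean; when `na_fraction`
#' exceeds `na_threshold` (default 20%) the value is flagged unreliable
#' (`ambi_valid = FALSE`) following standard AMBI practice. An azoic sample
#' (total abundance 0) gets the sentinel value `azoic_value` (default 7)
#' with `azoic = TRUE`; downstream it is classified Bad.
#'
#' @param abundances named numeric vector, names are normalized taxon names.
#' @param catalog a [species_catalog()] supplying `ecological_group` per
#'   taxon; every abundance name must be present.
#' @param na_threshold maximum tolerated not-assigned fraction.
#' @param azoic_value sentinel reported for azoic samples.
#' @return list with `ambi`, `na_fraction`, `ambi_valid`, `azoic`.
#' @export
#' @examples
#' cat <- species_catalog(c("A sp", "B sp", "C sp"), "Annelida",
#'                        c("I", "III", "V"), TRUE, TRUE)
#' ambi(c("A sp" = 50, "B sp" = 30, "C sp" = 20), cat)  # 2.1
ambi <- function(abundances, catalog, na_threshold = 0.20, azoic_value = 7) {
  abundances <- abundances[abundances > 0]
  if (!length(abundances)) {
    return(list(ambi = azoic_value, na_fraction = NA_real_,
                ambi_valid = FALSE, azoic = TRUE))
  }
  taxa <- names(abundances)
  if (is.null(taxa)) stop("abundances must be named by taxon")
  idx <- match(taxa, catalog$taxon_name)
  if (anyNA(idx)) {
    stop("taxon not in catalog: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  eg <- catalog$ecological_group[idx]
  total <- sum(abundances)
  assigned <- eg != "NA"
  na_fraction <- sum(abundances[!assigned]) / total
  if (!any(assigned)) {
    return(list(ambi = NA_real_, na_fraction = 1, ambi_valid = FALSE,
                azoic = FALSE))
  }
  f <- tapply(abundances[assigned], factor(eg[assigned], levels = names(.AMBI_WEIGHTS)),
              sum)
  f[is.na(f)] <- 0
  f <- f / sum(f)
  list(
    ambi = sum(.AMBI_WEIGHTS * f),
    na_fraction = na_fraction,
    ambi_valid = na_fraction <= na_threshold,
    azoic = FALSE
  )
}

#' Per-sample metrics table for a community
#'
#' Computes species richness, Shannon diversity and AMBI for every sampled
#' (site, season) unit of a community table, including units rendered azoic
#' by database reduction (richness and H reported as 0, AMBI as the azoic
#' sentinel).
#'
#' @param community a [community_table()].
#' @param catalog the [species_catalog()] covering all community taxa (for
#'   a reduced community, the reduced catalog or the full one — ecological
#'   groups are identical).
#' @param database label stored with each row, `"morphological"` or
#'   `"reduced"`.
#' @param log_base Shannon log base (recorded in the output).
#' @inheritParams ambi
#' @return a `metrics_table` data frame with columns `site_id`, `season`,
#'   `database`, `S`, `H`, `ambi`, `na_fraction`, `ambi_valid`, `azoic`,
#'   `log_base`.
#' @export
compute_metrics <- function(community, catalog,
                            database = c("morphological", "reduced"),
                            log_base = 2, na_threshold = 0.20,
                            azoic_value = 7) {
  database <- match.arg(database)
  validate_community(community, catalog)
  keys <- attr(community, "keys")
  if (is.null(keys)) keys <- unique(community[, c("site_id", "season")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- community$site_id == keys$site_id[i] &
      community$season == keys$season[i]
    ab <- setNames(community$abundance[sel], community$taxon_name[sel])
    ab <- ab[ab > 0]
    a <- ambi(ab, catalog, na_threshold = na_threshold,
              azoic_value = azoic_value)
    data.frame(
      site_id = keys$site_id[i], season = keys$season[i],
      database = database,
      S = richness(ab),
      H = if (length(ab)) shannon(ab, log_base) else 0,
      ambi = a$ambi, na_fraction = a$na_fraction,
      ambi_valid = a$ambi_valid, azoic = a$azoic,
      log_base = log_base,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$season), ]
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}
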
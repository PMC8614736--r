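#' Normalize taxon names for exact joining
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds to the conventional binomial capitalization
#' (first letter upper-case, rest lower-case). Joining between catalogs and
#' community tables is exact string matching on the normalized form; no fuzzy
#' or synonym matching is attempted.
#'
#' The transformation is idempotent: `normalize_taxon(normalize_taxon(x))`
#' equals `normalize_taxon(x)`.
#'
#' @param x character vector of raw taxon names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_taxon(c("  Nereis   falsa ", "HEDISTE DIVERSICOLOR"))
normalize_taxon <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  x <- tolower(x)
  first <- toupper(substring(x, 1L, 1L))
  paste0(first, substring(x, 2L))
}

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.as_flag <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  if (anyNA(out)) {
    stop("column '", column, "' contains non-boolean value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Construct a validated species catalog
#'
#' A species catalog lists every taxon of a regional checklist together with
#' its phylum, its AMBI ecological group (sensitivity class I–V, or `"NA"`
#' for species with no assigned group), and per-source barcode-availability
#' flags (BOLD, GenBank). Taxon names are normalized with
#' [normalize_taxon()] and must be unique afterwards.
#'
#' @param taxon_name,phylum character vectors.
#' @param ecological_group character vector with values in
#'   `I, II, III, IV, V, NA`.
#' @param barcoded_bold,barcoded_genbank logical vectors.
#' @param primer_reported optional character vector naming the primer pair
#'   reported for the species' barcode records (`NA` if none).
#' @return a `species_catalog`, a data frame with one row per species.
#' @export
species_catalog <- function(taxon_name, phylum, ecological_group,
                            barcoded_bold, barcoded_genbank,
                            primer_reported = NA_character_) {
  taxon_raw <- as.character(taxon_name)
  taxon <- normalize_taxon(taxon_raw)
  dup <- duplicated(taxon)
  if (any(dup)) {
    clash <- taxon[dup][1L]
    raw <- taxon_raw[taxon == clash]
    stop("duplicate taxon after normalization: '", clash, "' (raw names: ",
         paste(sQuote(raw), collapse = ", "), ")")
  }
  eg <- trimws(as.character(ecological_group))
  eg[is.na(eg) | eg == ""] <- "NA"
  bad <- which(!eg %in% .EG_LEVELS)
  if (length(bad)) {
    stop("illegal ecological-group label '", eg[bad[1L]], "' at row ",
         bad[1L], " (allowed: ", paste(.EG_LEVELS, collapse = ", "), ")")
  }
  out <- data.frame(
    taxon_name = taxon,
    phylum = trimws(as.character(phylum)),
    ecological_group = eg,
    barcoded_bold = as.logical(barcoded_bold),
    barcoded_genbank = as.logical(barcoded_genbank),
    primer_reported = as.character(primer_reported),
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_catalog", "data.frame")
  out
}

#' Read a species catalog from delimited text
#'
#' Expects a header with columns `taxon_name`, `phylum`, `ecological_group`,
#' `barcoded_bold`, `barcoded_genbank` and optionally `primer_reported`.
#' The field separator is auto-detected (tab if the header contains one,
#' comma otherwise) unless forced with `sep`.
#'
#' @param path path to the file.
#' @param sep optional field separator (`","` or `"\t"`).
#' @return a [species_catalog()].
#' @export
read_catalog <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  required <- c("taxon_name", "phylum", "ecological_group",
                "barcoded_bold", "barcoded_genbank")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("catalog file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  species_catalog(
    taxon_name = raw$taxon_name,
    phylum = raw$phylum,
    ecological_group = raw$ecological_group,
    barcoded_bold = .as_flag(raw$barcoded_bold, "barcoded_bold"),
    barcoded_genbank = .as_flag(raw$barcoded_genbank, "barcoded_genbank"),
    primer_reported = if ("primer_reported" %in% names(raw))
      raw$primer_reported else NA_character_
  )
}

#' Construct a validated community table
#'
#' A community table records abundances in long (tidy) form: one row per
#' (site, season, taxon) triple. The (site, season) grid may be ragged (a
#' site sampled in one season only), but each triple must be unique and all
#' abundances non-negative. Zero-abundance rows are retained (they document
#' sampling effort) and counted in the `n_zero_rows` attribute. The set of
#' sampled (site, season) units is stored in the `"keys"` attribute so that
#' sites that lose all species under database reduction remain visible as
#' azoic samples.
#'
#' If every abundance is 0 or 1 the data are presence/absence; they are
#' accepted, but a warning notes that Shannon diversity and AMBI then
#' degrade to richness-driven values.
#'
#' @param site_id,season,taxon_name character vectors (recycled rules not
#'   applied; all must have the same length).
#' @param abundance numeric vector of non-negative abundances.
#' @param seasons closed season vocabulary; defaults to fall/spring.
#' @return a `community_table` data frame.
#' @export
community_table <- function(site_id, season, taxon_name, abundance,
                            seasons = .SEASONS) {
  season <- tolower(trimws(as.character(season)))
  bad <- which(!season %in% seasons)
  if (length(bad)) {
    stop("season '", season[bad[1L]], "' at row ", bad[1L],
         " not in the allowed vocabulary {",
         paste(seasons, collapse = ", "), "}")
  }
  abundance <- as.numeric(abundance)
  if (anyNA(abundance)) stop("non-numeric abundance value(s)")
  neg <- which(abundance < 0)
  if (length(neg)) {
    stop("negative abundance (", abundance[neg[1L]], ") at row ", neg[1L])
  }
  out <- data.frame(
    site_id = as.character(site_id),
    season = season,
    taxon_name = normalize_taxon(taxon_name),
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  key <- paste(out$site_id, out$season, out$taxon_name, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (site, season, taxon) triple: (",
         out$site_id[dup[1L]], ", ", out$season[dup[1L]], ", ",
         out$taxon_name[dup[1L]], ")")
  }
  keys <- unique(out[, c("site_id", "season")])
  rownames(keys) <- NULL
  attr(out, "keys") <- keys
  attr(out, "n_zero_rows") <- sum(abundance == 0)
  pos <- abundance[abundance > 0]
  if (length(pos) && all(pos == 1)) {
    warning("all abundances are 0/1 (presence/absence data): Shannon ",
            "diversity and AMBI degrade to richness-driven values",
            call. = FALSE)
  }
  class(out) <- c("community_table", "data.frame")
  out
}

#' Read a long-format community table
#'
#' Expects columns `site_id`, `season`, `taxon_name`, `abundance`.
#'
#' @inheritParams read_catalog
#' @param seasons closed season vocabulary; defaults to fall/spring.
#' @return a [community_table()].
#' @export
read_community <- function(path, sep = NULL, seasons = .SEASONS) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("site_id", "season", "taxon_name", "abundance")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("community file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  community_table(raw$site_id, raw$season, raw$taxon_name, raw$abundance,
                  seasons = seasons)
}

#' Read a wide site-by-species matrix as a community table
#'
#' Convenience reader for the common wide layout: first two columns
#' `site_id` and `season`, remaining columns one per taxon. Converted to
#' the canonical long form; zero cells are kept as explicit zero rows.
#'
#' @inheritParams read_community
#' @return a [community_table()].
#' @export
read_community_wide <- function(path, sep = NULL, seasons = .SEASONS) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("site_id", "season") %in% names(raw)[1:2])) {
    stop("wide community file must start with columns site_id, season")
  }
  taxa <- setdiff(names(raw), c("site_id", "season"))
  if (!length(taxa)) stop("wide community file has no taxon columns")
  long <- data.frame(
    site_id = rep(raw$site_id, times = length(taxa)),
    season = rep(raw$season, times = length(taxa)),
    taxon_name = rep(taxa, each = nrow(raw)),
    abundance = unlist(raw[taxa], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  community_table(long$site_id, long$season, long$taxon_name,
                  long$abundance, seasons = seasons)
}

#' Check that every community taxon appears in a catalog
#'
#' @param community a [community_table()].
#' @param catalog a [species_catalog()].
#' @return invisibly `TRUE`; errors listing unknown taxa otherwise.
#' @export
validate_community <- function(community, catalog) {
  unknown <- setdiff(unique(community$taxon_name), catalog$taxon_name)
  if (length(unknown)) {
    stop("community references taxa absent from the catalog: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a table of EQS classes per site, season and database
#'
#' Expects columns `site_id`, `season`, `database`
#' (`morphological`/`reduced`) and `eqs_class` (one of Bad, Poor, Moderate,
#' Good, High). Used both for externally published class grids and for the
#' package's own output.
#'
#' @inheritParams read_catalog
#' @return an `eqs_class_table` data frame with an added `ordinal` column.
#' @export
read_eqs_classes <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path, sep)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("site_id", "season", "database", "eqs_class")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("class file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  eqs_class_table(raw$site_id, raw$season, raw$database, raw$eqs_class)
}

#' Construct a validated EQS class table
#'
#' @param site_id,season character vectors.
#' @param database character vector, each `morphological` or `reduced`.
#' @param eqs_class character vector of class labels.
#' @return an `eqs_class_table` data frame.
#' @export
eqs_class_table <- function(site_id, season, database, eqs_class) {
  database <- tolower(trimws(as.character(database)))
  bad <- which(!database %in% c("morphological", "reduced"))
  if (length(bad)) {
    stop("database label '", database[bad[1L]], "' at row ", bad[1L],
         " must be 'morphological' or 'reduced'")
  }
  out <- data.frame(
    site_id = as.character(site_id),
    season = tolower(trimws(as.character(season))),
    database = database,
    eqs_class = trimws(as.character(eqs_class)),
    stringsAsFactors = FALSE
  )
  out$ordinal <- eqs_ordinal(out$eqs_class)
  key <- paste(out$site_id, out$season, out$database, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (site, season, database) cell: ",
         gsub("\r", ", ", d))
  }
  class(out) <- c("eqs_class_table", "data.frame")
  out
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
#' @examples
#' bg_example()
#' read_eqs_classes(bg_example("apulia_eqs_classes.tsv"))
bg_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "barcodegap")))
  }
  path <- system.file("extdata", file, package = "barcodegap")
  if (path == "") stop("no packaged file named '", file, "'")
  path
}
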
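#' Majority-rule consensus sequence with IUPAC ambiguity fallback
#'
#' Collapses the aligned accessions of one species into a single consensus
#' sequence. Per column: the most frequent non-gap symbol wins if its
#' frequency among non-gap symbols exceeds `majority_threshold`; otherwise
#' the minimal IUPAC ambiguity code covering all symbols tied at the
#' maximum frequency is emitted. All-gap columns are dropped; a single
#' input sequence is returned unchanged (minus its gap columns).
#'
#' Ambiguity codes in the input are counted as atomic symbols; when they
#' participate in a tie the covering code is computed over the union of
#' their base sets.
#'
#' @param alignment character matrix (rows = accessions) as from
#'   [read_alignment()], or a character vector of equal-length strings.
#' @param majority_threshold frequency a symbol must exceed to win a
#'   column outright (default 0.5).
#' @return a single lower-case consensus string.
#' @export
#' @examples
#' consensus_sequence(c("ACGT", "ACGA"))  # "acgw"
consensus_sequence <- function(alignment, majority_threshold = 0.5) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (!length(alignment)) stop("empty sequence set")
    chars <- lapply(alignment, .seq_to_chars)
    if (length(unique(lengths(chars))) != 1L) {
      stop("sequences differ in length; consensus requires an alignment")
    }
    alignment <- do.call(rbind, chars)
  }
  if (!nrow(alignment)) stop("empty sequence set")
  alignment <- tolower(alignment)
  .check_iupac(as.vector(alignment), "alignment")
  cols <- vapply(seq_len(ncol(alignment)), function(j) {
    col <- alignment[, j]
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)  # all-gap column: drop
    tab <- table(col)
    freq <- as.numeric(tab) / length(col)
    top <- max(freq)
    if (top > majority_threshold && sum(freq == top) == 1L) {
      return(names(tab)[which.max(freq)])
    }
    tied <- names(tab)[freq == top]
    bases <- sort(unique(unlist(.IUPAC_SETS[tied])))
    code <- .SET_TO_CODE[[paste(bases, collapse = "")]]
    code
  }, character(1))
  paste(cols[!is.na(cols)], collapse = "")
}

#' Per-species consensus sequences from a labelled alignment
#'
#' Groups the rows of an alignment by a species map and builds one
#' consensus per species.
#'
#' @inheritParams consensus_sequence
#' @param species named character vector mapping each row label
#'   (accession) to a species label.
#' @return named character vector of consensus sequences, one per species.
#' @export
consensus_by_species <- function(alignment, species,
                                 majority_threshold = 0.5) {
  labs <- rownames(alignment)
  if (is.null(labs)) stop("alignment rows must be labelled by accession")
  missing <- setdiff(labs, names(species))
  if (length(missing)) {
    stop("accession(s) missing from the species map: ",
         paste(missing, collapse = ", "))
  }
  sp <- species[labs]
  out <- vapply(unique(sp), function(s) {
    consensus_sequence(alignment[sp == s, , drop = FALSE],
                       majority_threshold)
  }, character(1))
  setNames(out, unique(sp))
}
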
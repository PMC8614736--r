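#' Packaged universal COI primer pairs
#'
#' Returns the standard Folmer barcoding primers LCO1490/HCO2198 together
#' with a commonly used degenerate variant, read from the packaged primer
#' file (`inst/extdata/folmer_primers.tsv`). Users can supply their own
#' pairs in the same three-column format (`name`, `forward`, `reverse`).
#'
#' @param path optional user primer file overriding the packaged one.
#' @return data frame with columns `name`, `forward`, `reverse`.
#' @export
folmer_primers <- function(path = NULL) {
  if (is.null(path)) path <- bg_example("folmer_primers.tsv")
  p <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("name", "forward", "reverse")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop("primer file missing column(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(p))) {
    .check_iupac(.seq_to_chars(p$forward[i]), paste0("primer ", p$name[i]))
    .check_iupac(.seq_to_chars(p$reverse[i]), paste0("primer ", p$name[i]))
  }
  p
}

# positions where two IUPAC codes are incompatible (base sets disjoint)
.iupac_mismatches <- function(primer_chars, window_chars) {
  sum(!mapply(function(p, t) {
    if (p == "-" || t == "-") return(FALSE)
    length(intersect(.IUPAC_SETS[[p]], .IUPAC_SETS[[t]])) > 0
  }, primer_chars, window_chars))
}

.scan_primer <- function(primer, target, max_mismatch) {
  p <- .seq_to_chars(primer)
  t <- .seq_to_chars(target)
  t <- t[t != "-"]
  np <- length(p); nt <- length(t)
  if (np > nt) {
    return(list(found = FALSE, positions = integer(0),
                mismatches = NA_integer_, note = "primer longer than target"))
  }
  mm <- vapply(seq_len(nt - np + 1L), function(off) {
    .iupac_mismatches(p, t[off:(off + np - 1L)])
  }, numeric(1))
  best <- min(mm)
  list(found = best <= max_mismatch,
       positions = which(mm == best),
       mismatches = as.integer(best),
       note = NULL)
}

#' Degenerate primer matching against a target sequence
#'
#' Scans the forward primer along the target and the reverse primer along
#' the reverse complement of the target, using IUPAC-aware base
#' compatibility: two codes match iff their base sets intersect (so `N`
#' matches anything, `W` matches `A` or `T`, ...). Gaps in the target are
#' ignored. A primer "matches" when its best alignment has at most
#' `max_mismatch` incompatible positions; both primers must match for the
#' pair to be reported as found.
#'
#' @param target nucleotide string (consensus or accession sequence).
#' @param forward,reverse primer strings (IUPAC codes allowed); the
#'   reverse primer is given 5'->3' as synthesized, i.e. it is matched
#'   against the reverse-complement strand.
#' @param max_mismatch maximum tolerated mismatches per primer (default 3).
#' @return list with `found` (both primers), and per-primer sublists
#'   `forward`/`reverse` holding `found`, best `positions` (1-based
#'   offsets on the scanned strand) and `mismatches`.
#' @export
#' @examples
#' primer_match("ccggtcaacaaatcataaagatattggaac",
#'               forward = "GGTCAACAAATCATAAAGATATTGG",
#'               reverse = "GTTCCAATATC")
primer_match <- function(target, forward, reverse, max_mismatch = 3) {
  if (!nzchar(target)) stop("empty target sequence")
  .check_iupac(.seq_to_chars(target), "target")
  .check_iupac(.seq_to_chars(forward), "forward primer")
  .check_iupac(.seq_to_chars(reverse), "reverse primer")
  fwd <- .scan_primer(forward, target, max_mismatch)
  rev <- .scan_primer(reverse, reverse_complement(target), max_mismatch)
  list(found = fwd$found && rev$found, forward = fwd, reverse = rev)
}

#' Match a set of primer pairs against consensus sequences
#'
#' Applies [primer_match()] to every (sequence, primer pair) combination
#' and reports, per sequence, whether any pair amplifies it.
#'
#' @param sequences named character vector of target sequences.
#' @param primers data frame as from [folmer_primers()].
#' @inheritParams primer_match
#' @return data frame with one row per sequence x pair: `taxon`, `primer`,
#'   `found`, `forward_mismatches`, `reverse_mismatches`; plus an
#'   `any_match` attribute (named logical per sequence).
#' @export
primer_screen <- function(sequences, primers = folmer_primers(),
                          max_mismatch = 3) {
  rows <- list()
  for (s in names(sequences)) {
    for (i in seq_len(nrow(primers))) {
      m <- primer_match(sequences[[s]], primers$forward[i],
                        primers$reverse[i], max_mismatch)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = s, primer = primers$name[i], found = m$found,
        forward_mismatches = m$forward$mismatches,
        reverse_mismatches = m$reverse$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  any_match <- tapply(out$found, out$taxon, any)
  attr(out, "any_match") <- any_match[names(sequences)]
  out
}
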
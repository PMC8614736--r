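# IUPAC nucleotide machinery shared by the consensus, distance and primer
# code. Base sets are the defining property: two codes are compatible iff
# their sets intersect; the consensus code for a set of bases is the code
# whose set equals it.

.IUPAC_SETS <- list(
  a = "a", c = "c", g = "g", t = "t",
  r = c("a", "g"), y = c("c", "t"), s = c("c", "g"), w = c("a", "t"),
  k = c("g", "t"), m = c("a", "c"),
  b = c("c", "g", "t"), d = c("a", "g", "t"), h = c("a", "c", "t"),
  v = c("a", "c", "g"), n = c("a", "c", "g", "t")
)

.IUPAC_CODES <- names(.IUPAC_SETS)

# code for an exact base set, keyed by sorted concatenation ("ag" -> "r")
.SET_TO_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""),
                 character(1))
  setNames(names(.IUPAC_SETS), keys)
})

.IUPAC_COMPLEMENT <- c(
  a = "t", c = "g", g = "c", t = "a",
  r = "y", y = "r", s = "s", w = "w", k = "m", m = "k",
  b = "v", d = "h", h = "d", v = "b", n = "n", `-` = "-"
)

.check_iupac <- function(chars, what = "sequence") {
  bad <- setdiff(unique(chars), c(.IUPAC_CODES, "-"))
  if (length(bad)) {
    stop(what, " contains non-IUPAC character(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

.seq_to_chars <- function(x) strsplit(tolower(x), "")[[1]]

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param x a single nucleotide string (IUPAC codes and `-` allowed).
#' @return the reverse complement, same case convention (lower-case).
#' @export
reverse_complement <- function(x) {
  chars <- .seq_to_chars(x)
  .check_iupac(chars)
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file of pre-aligned nucleotide sequences into a character
#' matrix (rows = sequences, columns = alignment positions, lower-case
#' IUPAC codes, `-` for gaps). All sequences must have the same length;
#' a ragged file is an error.
#'
#' @param path path to the FASTA file.
#' @return a character matrix with sequence labels as row names and an
#'   `alignment_length` attribute.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- ape::read.FASTA(path)
  if (!length(seqs)) stop("FASTA file contains no sequences: ", path)
  len <- lengths(seqs)
  if (length(unique(len)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(len), collapse = ", "), " differ")
  }
  m <- do.call(rbind, lapply(as.character(seqs), identity))
  rownames(m) <- names(seqs)
  .check_iupac(as.vector(m), "alignment")
  attr(m, "alignment_length") <- ncol(m)
  m
}

#' Write an alignment (character matrix) to FASTA
#'
#' @param alignment character matrix as returned by [read_alignment()], or
#'   a named character vector of equal-length strings.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_alignment <- function(alignment, path) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    chars <- lapply(alignment, .seq_to_chars)
    if (length(unique(lengths(chars))) != 1L) {
      stop("ragged alignment: sequences differ in length")
    }
    alignment <- do.call(rbind, chars)
  }
  labels <- rownames(alignment)
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(alignment)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(c(paste0(">", labels[i]),
                 paste(alignment[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read / write trees in Newick format
#'
#' Thin wrappers around the standard Newick reader/writer, kept as the
#' package's single tree I/O surface. Round trips preserve topology, labels
#' and branch lengths to better than 1e-9.
#'
#' @param path file path.
#' @param tree an object of class `phylo`.
#' @return `read_newick` returns a `phylo`; `write_newick` invisibly
#'   returns the path.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}
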
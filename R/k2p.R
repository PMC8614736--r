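# transition pairs under the two-parameter model: purine<->purine,
# pyrimidine<->pyrimidine; everything else between unambiguous bases is a
# transversion.
.is_purine <- c(a = TRUE, g = TRUE, c = FALSE, t = FALSE)

#' Kimura 2-parameter distance between two aligned sequences
#'
#' K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)), with P and Q the transition and
#' transversion proportions over comparable sites. Sites where either
#' sequence has a gap or an ambiguity code are excluded pairwise
#' (conservative handling; ambiguities are not resolved probabilistically).
#' When the estimator saturates (any log argument non-positive) the result
#' is `NA` with attribute `saturated = TRUE`.
#'
#' @param seq1,seq2 equal-length nucleotide strings (or character vectors
#'   of single characters).
#' @return the K2P distance, or `NA` (attr `saturated`) on saturation.
#' @export
#' @examples
#' k2p("acgtacgt", "acgtacgt")  # 0
k2p <- function(seq1, seq2) {
  s1 <- if (length(seq1) == 1L) .seq_to_chars(seq1) else tolower(seq1)
  s2 <- if (length(seq2) == 1L) .seq_to_chars(seq2) else tolower(seq2)
  if (length(s1) != length(s2)) stop("sequences must be aligned (equal length)")
  plain <- c("a", "c", "g", "t")
  ok <- s1 %in% plain & s2 %in% plain
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  a <- s1[ok]; b <- s2[ok]
  diff <- a != b
  ts <- sum(diff & (.is_purine[a] == .is_purine[b]))
  tv <- sum(diff) - ts
  .k2p_from_pq(ts / n, tv / n)
}

# closed form from transition proportion P and transversion proportion Q
.k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(structure(NA_real_, saturated = TRUE))
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param alignment character matrix as from [read_alignment()].
#' @return a `dist_k2p` list: `labels`, symmetric matrix `d` (with `NA`
#'   where saturated), and `undefined_pairs` (two-column matrix of
#'   saturated label pairs, possibly empty).
#' @export
k2p_matrix <- function(alignment) {
  n <- nrow(alignment)
  labels <- rownames(alignment)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  undef <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- k2p(alignment[i, ], alignment[j, ])
        if (is.na(v)) {
          undef[[length(undef) + 1L]] <- c(labels[i], labels[j])
          d[i, j] <- d[j, i] <- NA_real_
        } else {
          d[i, j] <- d[j, i] <- v
        }
      }
    }
  }
  undefined <- if (length(undef)) do.call(rbind, undef)
    else matrix(character(0), ncol = 2)
  structure(list(labels = labels, d = d, undefined_pairs = undefined),
            class = "dist_k2p")
}
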
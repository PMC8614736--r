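#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration with the standard Q-criterion
#' Q(i,j) = (n-2) d(i,j) - R_i - R_j. At every step the minimal-Q pair is
#' joined, with ties broken deterministically by the lowest (i, j) index
#' pair in the current matrix ordering, so the output is fully
#' reproducible. Negative branch-length estimates are clamped to zero with
#' the deficit transferred to the sibling branch (so the path length
#' between the joined taxa is preserved). The result is unrooted, ending
#' in a trifurcating root node (two taxa yield a single edge split evenly
#' across the root).
#'
#' On an additive (tree-like) matrix the algorithm reconstructs the
#' generating tree exactly — topology and branch lengths.
#'
#' @param dm a `dist_k2p` object from [k2p_matrix()], a `dist`, or a
#'   symmetric numeric matrix with dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist_k2p")) {
    if (nrow(dm$undefined_pairs) > 0) {
      stop("distance matrix has saturated (undefined) pairs: ",
           paste(apply(dm$undefined_pairs, 1, paste, collapse = "/"),
                 collapse = ", "))
    }
    d <- dm$d
  } else if (inherits(dm, "dist")) {
    d <- as.matrix(dm)
  } else {
    d <- as.matrix(dm)
  }
  if (anyNA(d)) stop("distance matrix contains NA entries")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  fmt <- function(x) sprintf("%.15g", max(x, 0))
  # each active cluster carries its newick subtree string (no terminal ';')
  node <- labels
  while (n > 3) {
    R <- rowSums(d)
    q <- (n - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    # lowest (i, j) pair among minima: column-major which() on the upper
    # triangle scanned in row order gives i ascending, then j
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (q[i, j] < best - 1e-12) { best <- q[i, j]; bi <- i; bj <- j }
      }
    }
    i <- bi; j <- bj
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    # clamp negatives, moving the deficit onto the sibling branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- paste0("(", node[i], ":", fmt(li), ",",
                     node[j], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                   c(du[keep], 0))
    node <- c(node[keep], merged)
    rownames(d_new) <- colnames(d_new) <- NULL
    d <- d_new
    n <- n - 1L
  }
  if (n == 2) {
    half <- d[1, 2] / 2
    nwk <- paste0("(", node[1], ":", fmt(half), ",",
                  node[2], ":", fmt(half), ");")
  } else {
    # final three clusters around the trifurcating root
    l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- paste0("(", node[1], ":", fmt(l1), ",", node[2], ":", fmt(l2),
                  ",", node[3], ":", fmt(l3), ");")
  }
  ape::read.tree(text = nwk)
}
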
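# Shared fixtures and independent brute-force oracles used across tests.

tiny_catalog <- function() {
  species_catalog(
    taxon_name = c("Alpha one", "Beta two", "Gamma three", "Delta four",
                   "Epsilon five", "Zeta six"),
    phylum = c("Mollusca", "Mollusca", "Annelida", "Annelida",
               "Arthropoda", "Arthropoda"),
    ecological_group = c("I", "II", "III", "IV", "V", "NA"),
    barcoded_bold = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    barcoded_genbank = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

tiny_community <- function() {
  suppressWarnings(community_table(
    site_id = rep(c("s1", "s2"), each = 6),
    season = rep(c("fall", "spring", "fall", "spring"), each = 3),
    taxon_name = rep(c("Alpha one", "Gamma three", "Epsilon five"), 4),
    abundance = c(10, 5, 2, 8, 3, 1, 4, 4, 4, 0, 6, 2)
  ))
}

# random named abundance vector over a catalog's taxa
random_abundances <- function(catalog, p_zero = 0.3) {
  ab <- stats::rpois(nrow(catalog), lambda = 8)
  ab[stats::runif(nrow(catalog)) < p_zero] <- 0
  stats::setNames(ab, catalog$taxon_name)
}

# per-individual brute-force AMBI: expand every individual, average weights
ambi_brute <- function(abundances, catalog) {
  w <- c(I = 0, II = 1.5, III = 3, IV = 4.5, V = 6)
  eg <- catalog$ecological_group[match(names(abundances),
                                       catalog$taxon_name)]
  keep <- abundances > 0 & eg != "NA"
  if (!any(keep)) return(NA_real_)
  individuals <- rep(w[eg[keep]], times = abundances[keep])
  mean(individuals)
}

# a random rooted binary tree with exponential branch lengths
random_blen_tree <- function(n, scale = 1) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / scale)
  tr
}

# --- brute-force PTP oracle -------------------------------------------------
# Enumerates every valid delimitation (antichain of nodes covering all
# leaves) of a rooted binary tree, computes the maximized two-class
# log-likelihood for each directly from first principles, and returns the
# best. Independent of the package's dynamic-programming search.

ptp_enumerate <- function(tree, min_branch = 1e-4) {
  stopifnot(ape::is.rooted(tree), ape::is.binary(tree))
  tree$edge.length <- pmax(tree$edge.length, min_branch)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length

  below_edges <- function(v) {
    if (v <= ntip) return(integer(0))
    ch <- kids[[as.character(v)]]
    c(ch, unlist(lapply(ch, below_edges)))
  }
  # all delimitations rooted at v: each a vector of chosen species roots
  delims <- function(v) {
    if (v <= ntip) return(list(v))
    ch <- kids[[as.character(v)]]
    out <- list(v)
    for (a in delims(ch[1])) for (b in delims(ch[2])) {
      out[[length(out) + 1L]] <- c(a, b)
    }
    out
  }
  S_total <- sum(tree$edge.length)
  E_total <- nrow(tree$edge)
  llp <- function(k, S) if (k > 0) k * log(k / S) - k else 0
  best <- NULL; best_ll <- -Inf
  for (d in delims(root)) {
    within <- unlist(lapply(d, below_edges))
    kw <- length(within); Sw <- sum(elen[within])
    ll <- llp(kw, Sw) + llp(E_total - kw, S_total - Sw)
    if (ll > best_ll + 1e-10) { best_ll <- ll; best <- d }
  }
  leaves_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[as.character(v)]], leaves_below))
  }
  assignment <- integer(ntip)
  for (i in seq_along(best)) assignment[leaves_below(best[i])] <- i
  list(log_likelihood = best_ll,
       assignment = stats::setNames(assignment, tree$tip.label))
}

# TRUE iff two cluster assignments induce the same partition of the leaves
same_partition <- function(a, b) {
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
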
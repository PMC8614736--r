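#' Maximum-likelihood Poisson Tree Processes species delimitation
#'
#' Models the branch lengths of a rooted phylogeny as draws from two
#' exponential classes — between-species (speciation) branches and
#' within-species (coalescent) branches. A delimitation assigns each leaf
#' to a putative species whose leaves form a subtree; the branches strictly
#' inside those subtrees are within-species, all others between-species.
#' The maximized two-class log-likelihood (rates at their MLEs, k/S for k
#' branches of total length S) is compared against the one-rate null by
#' AIC; if the null wins, a single-cluster partition is returned.
#'
#' For trees of moderate size the optimum is found *exactly* by dynamic
#' programming over subtree partitions: each node accumulates the set of
#' attainable (within-branch count, within-branch length) pairs, which is
#' the sufficient statistic of the likelihood. When the candidate-set size
#' exceeds `exact_limit`, a deterministic greedy split/merge hill-climb is
#' used instead. Ties are broken toward fewer species, then by leaf order,
#' so results are reproducible.
#'
#' Unrooted input is midpoint-rooted (with a message); this matters because
#' delimitation depends on the root position.
#'
#' @param tree a `phylo`. Branch lengths must be non-negative with positive
#'   total length; at least 3 leaves.
#' @param exact_limit maximum candidate-set size per node for the exact
#'   search (default 5e5).
#' @param min_branch floor applied to branch lengths before fitting
#'   (default 1e-4 substitutions/site). Distance trees routinely contain
#'   exactly-zero branches (identical sequences); without a floor the
#'   exponential likelihood of a class made of zero-length branches
#'   diverges and the optimizer degenerately "shaves off" those branches
#'   as a pseudo-class. The floor corresponds to well under one
#'   substitution on a barcode-length fragment.
#' @param seed unused by the exact search; accepted for interface
#'   stability with stochastic searchers.
#' @return a `species_partition` list: `assignment` (named integer vector,
#'   cluster ids contiguous from 1 in leaf order), `n_clusters`,
#'   `log_likelihood` (two-class, at the optimum), `null_log_likelihood`,
#'   `aic`, `null_aic`, `model` (`"two-rate"` or `"one-rate"`),
#'   `method` (`"exact"` or `"greedy"`).
#' @export
ptp_delimit <- function(tree, exact_limit = 5e5, min_branch = 1e-4,
                        seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("degenerate tree: zero total branch length")
  if (length(tree$tip.label) < 3) stop("need at least 3 leaves")
  if (!ape::is.rooted(tree)) {
    message("unrooted input: applying midpoint rooting")
    tree <- phangorn::midpoint(tree)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  eps <- 1e-12
  tree$edge.length <- pmax(tree$edge.length, min_branch)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- numeric(max(tree$edge))         # length of edge above node
  edge_len[tree$edge[, 2]] <- tree$edge.length
  S_total <- sum(tree$edge.length)
  E_total <- nrow(tree$edge)

  # per-node totals of the subtree below (edges strictly below the node)
  k_below <- integer(max(tree$edge)); s_below <- numeric(max(tree$edge))
  postorder <- unique(tree$edge[ape::postorder(tree), 1])  # parents, tipward first
  for (v in postorder) {
    ch <- children[[as.character(v)]]
    k_below[v] <- sum(k_below[ch]) + length(ch)
    s_below[v] <- sum(s_below[ch] + edge_len[ch])
  }

  ll_part <- function(k, S) if (k > 0) k * log(k / max(S, eps)) - k else 0
  ll_two <- function(kw, Sw) {
    ll_part(kw, Sw) + ll_part(E_total - kw, S_total - Sw)
  }
  ll_null <- ll_part(E_total, S_total)

  res <- .ptp_exact(tree, children, edge_len, k_below, s_below,
                    ll_two, exact_limit)
  if (is.null(res)) {
    res <- .ptp_greedy(tree, children, edge_len, k_below, s_below, ll_two)
  }

  assignment_ml <- .ptp_assignment(tree, children, res$chosen)
  n_clusters_ml <- max(assignment_ml)
  # Parameter count of the fitted delimitation follows the accounting used
  # by multi-rate PTP implementations: the species boundaries are estimated
  # structure, so k = 2 rates + (n_clusters - 1) boundary choices. A flat
  # k = 2 would let the partition search overfit its way past the null on
  # any tree with heterogeneous branch lengths.
  aic_two <- 2 * (n_clusters_ml + 1) - 2 * res$ll
  aic_null <- 2 * 1 - 2 * ll_null
  if (aic_null <= aic_two) {
    assignment <- setNames(rep(1L, ntip), tree$tip.label)
    chosen_model <- "one-rate"
    n_clusters <- 1L
  } else {
    assignment <- assignment_ml
    chosen_model <- "two-rate"
    n_clusters <- n_clusters_ml
  }
  structure(list(
    assignment = assignment,
    n_clusters = n_clusters,
    log_likelihood = res$ll,
    null_log_likelihood = ll_null,
    aic = aic_two, null_aic = aic_null,
    model = chosen_model,
    method = res$method,
    tree = tree
  ), class = "species_partition")
}

# Exact DP. g(v) = attainable (k_within, S_within) pairs for the leaves
# below v: either v is a species root (all below within) or the children
# are delimited independently. Returns NULL if any candidate set would
# exceed the cap.
.ptp_exact <- function(tree, children, edge_len, k_below, s_below,
                       ll_two, exact_limit) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  g <- vector("list", max(tree$edge))
  order_nodes <- c(seq_len(ntip), unique(tree$edge[ape::postorder(tree), 1]))
  for (v in order_nodes) {
    if (v <= ntip) {
      g[[v]] <- list(k = 0L, S = 0)
      next
    }
    ch <- children[[as.character(v)]]
    a <- g[[ch[1]]]; b <- g[[ch[2]]]
    k <- as.vector(outer(a$k, b$k, "+"))
    S <- as.vector(outer(a$S, b$S, "+"))
    # option: v itself is a species root
    k <- c(k_below[v], k)
    S <- c(s_below[v], S)
    dup <- duplicated(paste(k, signif(S, 12)))
    k <- k[!dup]; S <- S[!dup]
    if (length(k) > exact_limit) return(NULL)
    g[[v]] <- list(k = k, S = S)
  }
  cand <- g[[root]]
  ll <- mapply(ll_two, cand$k, cand$S)
  # ties: prefer the larger within set (fewer species), deterministic
  ord <- order(-ll, -cand$k, -cand$S)
  best <- ord[1]
  chosen <- .ptp_backtrack(root, cand$k[best], cand$S[best], g, tree,
                           children, k_below, s_below, ntip)
  list(ll = ll[best], chosen = chosen, method = "exact")
}

# recover the set of species-root nodes giving the target (k, S) at `v`
.ptp_backtrack <- function(v, k_target, S_target, g, tree, children,
                           k_below, s_below, ntip) {
  if (v <= ntip) return(v)  # leaf as its own species root
  tol <- 1e-8 * max(1, abs(S_target))
  if (k_target == k_below[v] && abs(S_target - s_below[v]) <= tol) {
    return(v)  # v chosen: whole subtree is one species
  }
  ch <- children[[as.character(v)]]
  a <- g[[ch[1]]]; b <- g[[ch[2]]]
  for (ia in seq_along(a$k)) {
    kb <- k_target - a$k[ia]
    ib <- which(b$k == kb & abs(b$S - (S_target - a$S[ia])) <= tol)
    if (length(ib)) {
      return(c(
        .ptp_backtrack(ch[1], a$k[ia], a$S[ia], g, tree, children,
                       k_below, s_below, ntip),
        .ptp_backtrack(ch[2], b$k[ib[1]], b$S[ib[1]], g, tree, children,
                       k_below, s_below, ntip)
      ))
    }
  }
  stop("internal error: backtracking failed in PTP search")
}

# deterministic split/merge hill-climb over species-root sets, used for
# trees too large for the exact enumeration
.ptp_greedy <- function(tree, children, edge_len, k_below, s_below,
                        ll_two) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  state <- root  # start: everything one species
  stat <- function(nodes) {
    c(sum(k_below[nodes]), sum(s_below[nodes]))
  }
  current <- stat(state)
  ll_cur <- ll_two(current[1], current[2])
  repeat {
    best_ll <- ll_cur; best_state <- NULL
    for (i in seq_along(state)) {
      v <- state[i]
      if (v > ntip) {  # split v into its children
        cand <- sort(c(state[-i], children[[as.character(v)]]))
        s <- stat(cand); ll <- ll_two(s[1], s[2])
        if (ll > best_ll + 1e-10) { best_ll <- ll; best_state <- cand }
      }
    }
    # merges: any node whose two children are both current species roots
    parents <- unique(tree$edge[, 1])
    for (v in parents) {
      ch <- children[[as.character(v)]]
      if (all(ch %in% state)) {
        cand <- sort(c(setdiff(state, ch), v))
        s <- stat(cand); ll <- ll_two(s[1], s[2])
        if (ll > best_ll + 1e-10) { best_ll <- ll; best_state <- cand }
      }
    }
    if (is.null(best_state)) break
    state <- best_state
    ll_cur <- best_ll
  }
  list(ll = ll_cur, chosen = state, method = "greedy")
}

# leaves below each chosen species root -> contiguous cluster ids in leaf
# order
.ptp_assignment <- function(tree, children, chosen) {
  ntip <- length(tree$tip.label)
  leaves_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(children[[as.character(v)]], leaves_below))
  }
  assignment <- integer(ntip)
  for (v in chosen) assignment[leaves_below(v)] <- v
  ids <- unique(assignment[order(seq_len(ntip))])
  assignment <- match(assignment, ids)
  setNames(assignment, tree$tip.label)
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("PTP delimitation: %d cluster(s) over %d leaves (%s model, %s search)\n",
              x$n_clusters, length(x$assignment), x$model, x$method))
  cat(sprintf("  two-rate logLik %.3f (AIC %.3f) vs one-rate logLik %.3f (AIC %.3f)\n",
              x$log_likelihood, x$aic, x$null_log_likelihood, x$null_aic))
  invisible(x)
}

#' Delimit putative species directly from an alignment
#'
#' The package's canonical distance-based delimitation workflow: identical
#' sequences are collapsed to one haplotype (standard practice before
#' PTP-type analyses — duplicate tips only create zero-length branches
#' that carry no delimitation signal), pairwise K2P distances are computed,
#' a neighbor-joining tree is built and midpoint-rooted, and the ML-PTP
#' delimitation is run. Collapsed duplicates are assigned the cluster of
#' their representative.
#'
#' @param alignment character matrix as from [read_alignment()] or
#'   [simulate_sequences()]; rows must be labelled.
#' @inheritParams ptp_delimit
#' @return a `species_partition` covering every input row; the underlying
#'   tree (on unique haplotypes) is attached as `$tree`.
#' @export
delimit_alignment <- function(alignment, exact_limit = 5e5,
                              min_branch = 1e-4) {
  labs <- rownames(alignment)
  if (is.null(labs)) stop("alignment rows must be labelled")
  seqs <- apply(alignment, 1, paste, collapse = "")
  rep_of <- labs[match(seqs, seqs)]  # first identical row represents all
  uniq <- !duplicated(seqs)
  if (sum(uniq) < 3) stop("fewer than 3 unique haplotypes; nothing to delimit")
  dm <- k2p_matrix(alignment[uniq, , drop = FALSE])
  tree <- nj_tree(dm)
  part <- suppressMessages(
    ptp_delimit(tree, exact_limit = exact_limit, min_branch = min_branch))
  full <- part$assignment[rep_of]
  names(full) <- labs
  part$assignment <- full
  part$n_duplicates_collapsed <- sum(!uniq)
  part
}

#' Compare a delimitation against known species
#'
#' A true species counts as *separated* iff its leaves form exactly one
#' cluster and that cluster contains no other species' leaves. Species
#' sharing a cluster are *merged*; species spread over several clusters
#' are *split* (a species can be both).
#'
#' @param partition a `species_partition` from [ptp_delimit()], or a named
#'   vector of cluster ids.
#' @param truth named character vector mapping every leaf to its true
#'   species label.
#' @return list with `percent_separated`, `n_species`, `n_separated`,
#'   `merges` (list of character vectors of co-clustered species) and
#'   `splits` (character vector of split species).
#' @export
partition_summary <- function(partition, truth) {
  assignment <- if (inherits(partition, "species_partition"))
    partition$assignment else partition
  missing <- setdiff(names(assignment), names(truth))
  if (length(missing)) {
    stop("leaf (leaves) missing from truth: ", paste(missing, collapse = ", "))
  }
  truth <- truth[names(assignment)]
  species <- unique(truth)
  cl_of <- function(sp) unique(assignment[truth == sp])
  separated <- vapply(species, function(sp) {
    cl <- cl_of(sp)
    length(cl) == 1L && all(truth[assignment == cl] == sp)
  }, logical(1))
  splits <- species[vapply(species, function(sp) length(cl_of(sp)) > 1L,
                           logical(1))]
  merges <- lapply(unique(assignment), function(cl) {
    sp <- unique(truth[assignment == cl])
    if (length(sp) > 1L) sort(sp) else NULL
  })
  merges <- Filter(Negate(is.null), merges)
  list(
    percent_separated = 100 * sum(separated) / length(species),
    n_species = length(species),
    n_separated = sum(separated),
    merges = merges,
    splits = splits
  )
}
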
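# Tolerance anchor per ecological group: position on the 0-1 disturbance
# axis where the group's occupancy peaks (sensitive species at pristine
# sites, first-order opportunists at the most disturbed).
.EG_TOLERANCE <- c(I = 0.0, II = 0.25, III = 0.5, IV = 0.75, V = 1.0)

.child_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Configuration for the survey simulator
#'
#' Bundles and validates the knobs of [simulate_catalog()] and
#' [simulate_communities()]. The default is the `"apulia-like"` preset: a
#' checklist of 82 species over six phyla with the three dominant phyla
#' (Mollusca, Annelida, Arthropoda) making up ~93% of species and carrying
#' barcode probabilities 0.58, 0.65 and 0.73 respectively — the coverage
#' regime of a southeast-Mediterranean transitional-water checklist against
#' the 2021 state of BOLD/GenBank — sampled at 15 sites in two seasons
#' across a disturbance gradient wide enough to span all five EQS classes.
#'
#' @param seed integer master seed; per-stage child seeds are derived by
#'   fixed offsets so stages can be regenerated independently.
#' @param n_species checklist size.
#' @param phylum_proportions named fractions summing to 1.
#' @param barcode_prob_per_phylum named per-phylum probability that a
#'   species has at least one barcode record (applied independently per
#'   source, see [simulate_catalog()]).
#' @param n_sites number of sampling sites.
#' @param seasons season labels.
#' @param disturbance_per_site numeric in \[0, 1\] per site; default an
#'   even spread over the gradient.
#' @param eg_probs named probabilities over groups I–V and `"NA"` used to
#'   assign ecological groups to species.
#' @param occupancy_base peak occupancy probability of a species at a site
#'   whose disturbance equals the species' tolerance.
#' @param occupancy_bw Gaussian bandwidth of the occupancy kernel on the
#'   disturbance axis.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance
#'   parameters for occupied cells (counts, rounded up to >= 1).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_species = 82,
                         phylum_proportions = c(
                           Mollusca = 0.38, Annelida = 0.33,
                           Arthropoda = 0.22, Cnidaria = 0.03,
                           Echinodermata = 0.02, Chordata = 0.02),
                         barcode_prob_per_phylum = c(
                           Mollusca = 0.58, Annelida = 0.65,
                           Arthropoda = 0.73, Cnidaria = 0.64,
                           Echinodermata = 0.64, Chordata = 0.64),
                         n_sites = 15,
                         seasons = .SEASONS,
                         disturbance_per_site = NULL,
                         eg_probs = c(I = 0.22, II = 0.18, III = 0.25,
                                      IV = 0.15, V = 0.12, "NA" = 0.08),
                         occupancy_base = 0.55,
                         occupancy_bw = 0.35,
                         abundance_meanlog = 2, abundance_sdlog = 1) {
  if (abs(sum(phylum_proportions) - 1) > 1e-9) {
    stop("phylum_proportions must sum to 1")
  }
  if (any(barcode_prob_per_phylum < 0 | barcode_prob_per_phylum > 1)) {
    stop("barcode probabilities must lie in [0, 1]")
  }
  missing_p <- setdiff(names(phylum_proportions),
                       names(barcode_prob_per_phylum))
  if (length(missing_p)) {
    stop("no barcode probability for phylum(s): ",
         paste(missing_p, collapse = ", "))
  }
  if (n_species < 1) stop("n_species must be >= 1")
  if (abs(sum(eg_probs) - 1) > 1e-9) stop("eg_probs must sum to 1")
  if (!all(names(eg_probs) %in% .EG_LEVELS)) {
    stop("eg_probs names must be among ", paste(.EG_LEVELS, collapse = ", "))
  }
  if (is.null(disturbance_per_site)) {
    disturbance_per_site <- setNames(
      seq(0.03, 0.97, length.out = n_sites),
      paste0("site", sprintf("%02d", seq_len(n_sites))))
  }
  if (any(disturbance_per_site < 0 | disturbance_per_site > 1)) {
    stop("disturbance values must lie in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    phylum_proportions = phylum_proportions,
    barcode_prob_per_phylum = barcode_prob_per_phylum,
    n_sites = as.integer(n_sites), seasons = seasons,
    disturbance_per_site = disturbance_per_site,
    eg_probs = eg_probs,
    occupancy_base = occupancy_base, occupancy_bw = occupancy_bw,
    abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog
  ), class = "synth_config")
}

#' Simulate a species catalog with barcode-availability flags
#'
#' Species are assigned phyla by the configured proportion vector,
#' ecological groups by the configured mixture, and independent Bernoulli
#' barcode flags per source (BOLD, GenBank) such that the probability of
#' having *at least one* record equals the per-phylum probability: each
#' source flag is drawn with p_source = 1 - sqrt(1 - p_union). Fully
#' reproducible from the config seed.
#'
#' @param config a [synth_config()].
#' @return a [species_catalog()].
#' @export
simulate_catalog <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.child_seed(config$seed, 101L))
  n <- config$n_species
  phyla <- sample(names(config$phylum_proportions), n, replace = TRUE,
                  prob = config$phylum_proportions)
  eg <- sample(names(config$eg_probs), n, replace = TRUE,
               prob = config$eg_probs)
  p_union <- config$barcode_prob_per_phylum[phyla]
  p_source <- 1 - sqrt(1 - pmin(p_union, 1 - 1e-12))
  bold <- runif(n) < p_source
  genbank <- runif(n) < p_source
  species_catalog(
    taxon_name = sprintf("Taxon sp%03d", seq_len(n)),
    phylum = phyla,
    ecological_group = eg,
    barcoded_bold = bold,
    barcoded_genbank = genbank
  )
}

#' Simulate community tables along a disturbance gradient
#'
#' Per site and season, each species' occupancy probability follows a
#' Gaussian kernel on the distance between the site's disturbance level
#' and the species' tolerance (derived from its ecological group by the
#' fixed anchors I -> 0, II -> 0.25, III -> 0.5, IV -> 0.75, V -> 1;
#' not-assigned species get tolerance 0.5). Low-disturbance sites are
#' therefore enriched in groups I–II and high-disturbance sites in IV–V,
#' so expected AMBI increases along the gradient. Abundances of occupied
#' cells are log-normal counts (rounded up to at least one individual).
#'
#' @param config a [synth_config()].
#' @param catalog catalog to populate sites from; default simulated from
#'   the same config.
#' @return a [community_table()] (with explicit zero rows omitted).
#' @export
simulate_communities <- function(config = synth_config(),
                                 catalog = simulate_catalog(config)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.child_seed(config$seed, 202L))
  tol <- .EG_TOLERANCE[catalog$ecological_group]
  tol[is.na(tol)] <- 0.5  # not-assigned species: indifferent
  sites <- names(config$disturbance_per_site)
  rows <- list()
  for (si in seq_along(sites)) {
    d <- config$disturbance_per_site[si]
    p_occ <- config$occupancy_base *
      exp(-((d - tol) / config$occupancy_bw)^2)
    for (season in config$seasons) {
      occ <- runif(nrow(catalog)) < p_occ
      if (!any(occ)) next
      ab <- ceiling(rlnorm(sum(occ), config$abundance_meanlog,
                           config$abundance_sdlog))
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sites[si], season = season,
        taxon_name = catalog$taxon_name[occ], abundance = ab,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    stop("simulation produced an all-azoic survey; increase occupancy_base")
  }
  long <- do.call(rbind, rows)
  out <- community_table(long$site_id, long$season, long$taxon_name,
                         long$abundance, seasons = config$seasons)
  # register units that drew no species at all as sampled-but-azoic
  all_keys <- expand.grid(site_id = sites, season = config$seasons,
                          stringsAsFactors = FALSE)
  all_keys <- all_keys[order(all_keys$site_id, all_keys$season), ]
  rownames(all_keys) <- NULL
  attr(out, "keys") <- all_keys
  out
}

#' Configuration for the COI accession simulator
#'
#' @param seed integer seed.
#' @param n_species number of species in the tree.
#' @param accessions_per_species integer count, or length-2 range sampled
#'   uniformly per species.
#' @param between_species_rate mean length (substitutions/site) of
#'   species-tree branches; speciation branches are drawn iid exponential
#'   at this scale, the generative assumption of the PTP model itself.
#'   The default 0.05 puts sister-species divergence around 10%, a typical
#'   congeneric COI figure.
#' @param within_species_rate mean length of branches inside each
#'   species' accession subtree (intraspecific scale; the default 0.002
#'   gives ~0.4% pairwise intraspecific divergence, the usual COI value).
#'   The between/within ratio controls how cleanly species separate —
#'   the defaults give the classic ten-fold-plus "barcoding gap".
#' @param kappa transition/transversion rate ratio of the K80 substitution
#'   model used to evolve sequences.
#' @param seq_length alignment length (>= 50), default the ~658 bp COI
#'   barcode fragment.
#' @return a validated `seqsim_config` list.
#' @export
seqsim_config <- function(seed = 1, n_species = 10,
                          accessions_per_species = 3,
                          between_species_rate = 0.05,
                          within_species_rate = 0.002,
                          kappa = 4, seq_length = 658) {
  if (between_species_rate <= 0 || within_species_rate <= 0) {
    stop("branch-length scales must be positive")
  }
  if (seq_length < 50) stop("seq_length must be >= 50")
  if (n_species < 2) stop("need at least 2 species")
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    accessions_per_species = as.integer(accessions_per_species),
    between_species_rate = between_species_rate,
    within_species_rate = within_species_rate,
    kappa = kappa, seq_length = as.integer(seq_length)
  ), class = "seqsim_config")
}

#' Simulate aligned COI-like accession sets with known species membership
#'
#' Draws a pure-birth species-tree topology whose branch lengths are
#' redrawn iid exponential at the between-species scale, grafts a
#' coalescent-topology subtree of accessions with branches iid exponential
#' at the within-species scale onto each species tip, and evolves
#' sequences along the combined tree under the K80 model. Drawing both
#' branch classes from their exponential scales mirrors the generative
#' assumption of the PTP delimitation model, making this the natural
#' harness for recovery experiments. Returns the gap-free alignment, the
#' accession-to-species truth map, and the generating tree.
#'
#' @param config a [seqsim_config()].
#' @return list with `alignment` (character matrix, accessions x sites),
#'   `truth` (named character vector accession -> species), and `tree`
#'   (the generating `phylo`).
#' @export
simulate_sequences <- function(config = seqsim_config()) {
  stopifnot(inherits(config, "seqsim_config"))
  set.seed(.child_seed(config$seed, 303L))
  nsp <- config$n_species
  sp_tree <- ape::rphylo(nsp, birth = 1, death = 0)
  sp_tree$edge.length <- stats::rexp(nrow(sp_tree$edge),
                                     rate = 1 / config$between_species_rate)
  sp_tree$tip.label <- sprintf("SP%02d", seq_len(nsp))

  acc_range <- config$accessions_per_species
  n_acc <- if (length(acc_range) == 2L)
    sample(acc_range[1]:acc_range[2], nsp, replace = TRUE)
  else rep(acc_range, nsp)

  tree <- sp_tree
  truth <- character(0)
  for (i in seq_len(nsp)) {
    sp <- sprintf("SP%02d", i)
    accs <- sprintf("%s_a%d", sp, seq_len(n_acc[i]))
    truth[accs] <- sp
    if (n_acc[i] == 1L) {
      tree$tip.label[tree$tip.label == sp] <- accs
      next
    }
    sub <- ape::rcoal(n_acc[i])
    sub$edge.length <- stats::rexp(nrow(sub$edge),
                                   rate = 1 / config$within_species_rate)
    sub$tip.label <- accs
    tree <- ape::bind.tree(tree, sub,
                           where = which(tree$tip.label == sp))
  }

  q <- c(1, config$kappa, 1, 1, config$kappa, 1)  # transitions: a-g, c-t
  sim <- phangorn::simSeq(tree, l = config$seq_length, Q = q,
                          bf = rep(0.25, 4))
  alignment <- as.character(sim)
  alignment <- alignment[order(rownames(alignment)), , drop = FALSE]
  attr(alignment, "alignment_length") <- ncol(alignment)
  list(alignment = alignment, truth = truth[rownames(alignment)],
       tree = tree)
}
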
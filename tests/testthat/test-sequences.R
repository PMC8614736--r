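test_that("consensus applies the majority and ambiguity-tie rules", {
  expect_equal(consensus_sequence("ACGT"), "acgt")
  expect_equal(consensus_sequence(c("ACGT", "ACGA")), "acgw")
  expect_equal(consensus_sequence(c("AC-T", "AC-T")), "act")
  # 2/3 majority beats the tie rule at the default threshold
  expect_equal(consensus_sequence(c("ACGT", "ACGT", "ACGA")), "acgt")
  # three-way tie covers three bases
  expect_equal(consensus_sequence(c("A", "C", "G")), "v")
  expect_error(consensus_sequence(character(0)), "empty")
  expect_error(consensus_sequence(c("ACG", "AC")), "differ in length")

  # idempotence
  set.seed(3)
  seqs <- replicate(5, paste(sample(c("a", "c", "g", "t", "-"), 30,
                                    replace = TRUE), collapse = ""))
  cons <- consensus_sequence(seqs)
  expect_equal(consensus_sequence(cons), cons)
})

test_that("per-species consensus groups accessions by the truth map", {
  aln <- rbind(x1 = strsplit("acgt", "")[[1]],
               x2 = strsplit("acga", "")[[1]],
               y1 = strsplit("ttgg", "")[[1]])
  cons <- consensus_by_species(aln, c(x1 = "X", x2 = "X", y1 = "Y"))
  expect_equal(unname(cons["X"]), "acgw")
  expect_equal(unname(cons["Y"]), "ttgg")
  expect_error(consensus_by_species(aln, c(x1 = "X", x2 = "X")), "missing")
})

test_that("K2P matches the closed form, symmetry, and saturates correctly", {
  expect_equal(k2p("acgtacgt", "acgtacgt"), 0)
  # P = 0.1, Q = 0.1 by construction over 10 sites: one transition (a->g),
  # one transversion (a->c)
  s1 <- "aaaaaaaaaa"
  s2 <- "gcaaaaaaaa"
  expect_equal(k2p(s1, s2), -0.5 * log((1 - 0.3) * sqrt(0.8)),
               tolerance = 1e-12)
  expect_equal(round(k2p(s1, s2), 4), 0.2341)
  expect_equal(k2p(s2, s1), k2p(s1, s2))
  # P = 0.5, Q = 0: log argument hits zero
  sat <- k2p("aaaagggg", "ggggaaaa")
  expect_true(is.na(sat) && isTRUE(attr(sat, "saturated")))
  # gap and ambiguity sites are excluded pairwise
  expect_equal(k2p("ac-tn", "acgta"), 0)
  expect_error(k2p("nnn", "acg"), "no comparable sites")

  # cross-check against the phylogenetics standard implementation
  set.seed(9)
  sim <- simulate_sequences(seqsim_config(seed = 9, n_species = 4,
                                          accessions_per_species = 2,
                                          seq_length = 300))
  ours <- k2p_matrix(sim$alignment)$d
  bin <- ape::as.DNAbin(sim$alignment)
  theirs <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-9)
})

test_that("reverse complement honours IUPAC codes", {
  expect_equal(reverse_complement("acgt"), "acgt")
  expect_equal(reverse_complement("ARYN"), "nryt")
  expect_error(reverse_complement("acxz"), "non-IUPAC")
})

test_that("primer matching is IUPAC-aware on both strands", {
  target <- "ccggtcaacaaatcataaagatattggaacactatacgaggatt"
  folmer <- folmer_primers()
  fwd <- folmer$forward[folmer$name == "LCO1490/HCO2198"]
  rev <- reverse_complement(substr(target, 30, 44))
  hit <- primer_match(target, fwd, reverse = rev, max_mismatch = 0)
  expect_true(hit$found)
  expect_equal(hit$forward$positions, 3L)
  expect_equal(hit$forward$mismatches, 0L)

  # N matches anything
  m <- primer_match("catgca", "atgn", "tgcatg", max_mismatch = 0)
  expect_true(m$forward$found)
  expect_equal(m$forward$positions, 2L)

  # degenerate W matches A and T but not G
  expect_true(primer_match("aaataaa", "awa", "ttt", 0)$forward$found)

  # primer longer than target: a no-match result, not an error
  long <- primer_match("acg", "acgtacgt", "acgtacgt", 3)
  expect_false(long$found)
  expect_equal(long$forward$note, "primer longer than target")
})

test_that("mismatch counting matches a brute-force scan", {
  set.seed(21)
  bases <- c("a", "c", "g", "t")
  for (i in 1:25) {
    target <- paste(sample(bases, 40, replace = TRUE), collapse = "")
    start <- sample(1:20, 1)
    primer <- substr(target, start, start + 11)
    # corrupt k positions of the primer
    k <- sample(0:5, 1)
    pc <- strsplit(primer, "")[[1]]
    if (k > 0) {
      pos <- sample(seq_along(pc), k)
      pc[pos] <- vapply(pc[pos], function(b) sample(setdiff(bases, b), 1), "")
    }
    primer_mut <- paste(pc, collapse = "")
    got <- primer_match(target, primer_mut, reverse = "aaa",
                        max_mismatch = 3)$forward
    # brute force best mismatch count over all offsets
    tc <- strsplit(target, "")[[1]]
    best <- min(vapply(1:(40 - 12 + 1), function(off) {
      sum(tc[off:(off + 11)] != pc)
    }, numeric(1)))
    expect_equal(got$mismatches, best)
    expect_equal(got$found, best <= 3)
  }
})

test_that("the packaged primer file holds a valid Folmer pair", {
  p <- folmer_primers()
  expect_true("LCO1490/HCO2198" %in% p$name)
  expect_equal(nchar(p$forward[p$name == "LCO1490/HCO2198"]), 25)
  expect_equal(nchar(p$reverse[p$name == "LCO1490/HCO2198"]), 26)
})
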
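test_that("taxon normalization trims, squishes, case-folds and is idempotent", {
  raw <- c("  Nereis   falsa ", "HEDISTE DIVERSICOLOR", "abra\talba")
  norm <- normalize_taxon(raw)
  expect_equal(norm, c("Nereis falsa", "Hediste diversicolor", "Abra alba"))
  expect_equal(normalize_taxon(norm), norm)
})

test_that("catalog reading validates schema, duplicates and group labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon_name,phylum,ecological_group,barcoded_bold,barcoded_genbank",
               "Abra alba,Mollusca,I,true,false",
               "Nereis falsa,Annelida,III,false,true",
               "Gammarus sp,Arthropoda,V,true,true"), path)
  cat <- read_catalog(path)
  expect_s3_class(cat, "species_catalog")
  expect_equal(nrow(cat), 3)
  expect_equal(cat$ecological_group, c("I", "III", "V"))

  writeLines(c("taxon_name,phylum,ecological_group,barcoded_bold,barcoded_genbank",
               "Nereis falsa,Annelida,I,true,true",
               "nereis  falsa,Annelida,II,true,true"), path)
  expect_error(read_catalog(path), "duplicate taxon")

  writeLines(c("taxon_name,phylum,ecological_group,barcoded_bold,barcoded_genbank",
               "Abra alba,Mollusca,VI,true,false"), path)
  expect_error(read_catalog(path), "illegal ecological-group")

  writeLines(c("taxon_name,phylum,barcoded_bold,barcoded_genbank",
               "Abra alba,Mollusca,true,false"), path)
  expect_error(read_catalog(path), "ecological_group")
})

test_that("community reading validates seasons, abundances and duplicates", {
  make <- function(...) {
    community_table(...)
  }
  com <- make(site_id = rep(c("s1", "s2"), each = 6),
              season = rep(rep(c("fall", "spring"), each = 3), 2),
              taxon_name = rep(c("A a", "B b", "C c"), 4),
              abundance = rep(c(5, 3, 2), 4))
  expect_equal(nrow(com), 12)
  expect_equal(nrow(attr(com, "keys")), 4)

  expect_error(make("s1", "fall", "A a", -1), "negative abundance")
  expect_error(make("s1", "winter", "A a", 1), "vocabulary")
  expect_error(make(c("s1", "s1"), c("fall", "fall"),
                    c("A a", "a  A"), c(1, 2)),
               "duplicate \\(site, season, taxon\\)")
  expect_warning(make(c("s1", "s1"), "fall", c("A a", "B b"), c(1, 1)),
                 "presence/absence")
})

test_that("wide community reader matches the long reader content", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site_id\tseason\tAbra alba\tNereis falsa",
               "s1\tfall\t5\t0",
               "s1\tspring\t2\t3"), wide)
  com <- read_community_wide(wide)
  expect_equal(nrow(com), 4)
  expect_equal(sum(com$abundance), 10)
  expect_setequal(unique(com$taxon_name), c("Abra alba", "Nereis falsa"))
})

test_that("catalog and community survive a write/read round trip", {
  cat <- tiny_catalog()
  com <- tiny_community()
  catf <- withr::local_tempfile(fileext = ".tsv")
  comf <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(cat), catf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(com), comf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat2 <- read_catalog(catf)
  com2 <- suppressWarnings(read_community(comf))
  expect_equal(as.data.frame(cat2), as.data.frame(cat))
  expect_equal(com2$abundance, com$abundance)
  expect_equal(com2$taxon_name, com$taxon_name)
})

test_that("alignment reader enforces rectangular IUPAC input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTRYSWKM", ">b", "acgtacgtnn"), f)
  aln <- read_alignment(f)
  expect_equal(attr(aln, "alignment_length"), 10)
  expect_equal(rownames(aln), c("a", "b"))

  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f)
  expect_error(read_alignment(f), "ragged")
})

test_that("alignment and newick round trips are stable", {
  aln <- rbind(a = strsplit("acgt-ryn", "")[[1]],
               b = strsplit("acgtacgt", "")[[1]])
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(unname(back[, ]), unname(aln))

  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  nf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nf)
  tr2 <- read_newick(nf)
  expect_equal(ape::write.tree(tr2), ape::write.tree(tr))
  expect_error(read_newick(withr::local_tempfile(fileext = ".nwk")),
               "not found")
})

test_that("EQS class tables validate labels and pair uniqueness", {
  expect_error(eqs_class_table("s1", "fall", "sequence", "Good"),
               "morphological")
  expect_error(eqs_class_table("s1", "fall", "reduced", "Fine"),
               "unknown EQS class")
  expect_error(eqs_class_table(c("s1", "s1"), "fall", "reduced",
                               c("Good", "Bad")),
               "duplicate")
  tab <- eqs_class_table("s1", "fall", "reduced", "High")
  expect_equal(tab$ordinal, 4L)
})
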
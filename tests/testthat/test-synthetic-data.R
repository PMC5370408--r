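# Generator behaviour: determinism, constrained-position protection,
# planted motifs, shared trees, contig/GFF consistency.

test_that("generateTrna is deterministic and validates its spec", {
  a <- generateTrna("Tyr", pair = "C-G", n73 = "A", vArmLen = 13,
                    mutationRate = 0.2, seed = 11)
  b <- generateTrna("Tyr", pair = "C-G", n73 = "A", vArmLen = 13,
                    mutationRate = 0.2, seed = 11)
  expect_identical(a$sequence, b$sequence)
  c <- generateTrna("Tyr", pair = "C-G", n73 = "A", vArmLen = 13,
                    mutationRate = 0.2, seed = 12)
  expect_false(identical(a$sequence, c$sequence))

  expect_error(generateTrna("Tyr", vArmLen = 5), "vArmLen")
  expect_error(generateTrna("Tyr", mutationRate = 0.5), "mutationRate")
  expect_error(generateTrna("Tyr", n73 = "Q"), "n73")
  expect_error(generateTrna("Tyr", anticodon = "GT"), "anticodon")
})

test_that("constrained tRNA positions are never mutated at high rates", {
  for (i in 1:1000) {
    g <- generateTrna("Trp", pair = "G-C", n73 = "A", vArmLen = 0,
                      mutationRate = 0.2, seed = i)
    ch <- strsplit(g$sequence, "")[[1]]
    V <- length(ch) - 71L
    expect_identical(ch[1], "G")
    expect_identical(ch[67 + V], "C")
    expect_identical(ch[68 + V], "A")
    expect_identical(paste(ch[34:36], collapse = ""), "CCA")
  }
})

test_that("zero-rate protein families are identical copies of the root", {
  fam <- generateProteinFamily(8, rootLength = 150, subsPerSite = 0,
                               seed = 4)
  seqs <- as.character(fam$sequences)
  expect_length(seqs, 8)
  expect_length(unique(seqs), 1)
})

test_that("planted motifs are intact in every leaf", {
  fam <- generateProteinFamily(10, rootLength = 250, subsPerSite = 0.25,
                               motifs = c(HIGH = 40, KMSKS = 180),
                               seed = 21)
  for (s in as.character(fam$sequences)) {
    expect_true(40 %in% oracleGreedy(oracleScanStarts(s, ORACLE_HIGH), 4))
    expect_true(180 %in% oracleGreedy(oracleScanStarts(s, ORACLE_KMSKS), 5))
  }
})

test_that("families sharing a tree have identical true topologies", {
  skip_if_not_installed("phangorn")
  famA <- generateProteinFamily(9, subsPerSite = 0.1, seed = 31)
  famB <- generateProteinFamily(9, tree = famA$tree, subsPerSite = 0.1,
                                seed = 32)
  expect_equal(phangorn::RF.dist(ape::unroot(famA$tree),
                                 ape::unroot(famB$tree)), 0)
  expect_false(identical(as.character(famA$sequences),
                         as.character(famB$sequences)))
})

test_that("a fixed tree with the wrong leaf count is rejected", {
  tr <- ape::rtree(5)
  expect_error(generateProteinFamily(8, tree = tr, seed = 1), "leaves")
})

test_that("contig specs are validated", {
  expect_error(contigSpec(character(0)), "layout")
  expect_error(contigSpec("filler", intergenicGap = -1), "intergenicGap")
  expect_error(contigSpec("no_such_template"), "unknown feature template")
})

test_that("contig generation is byte-deterministic across re-runs", {
  specs <- lapply(1:10, function(i) {
    set.seed(i)
    contigSpec(sample(c("trna_trp_A73", "orf1", "trprs_a1", "filler"),
                      3, replace = TRUE),
               seed = i, contig = sprintf("c%02d", i))
  })
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeContigSet(generateContigs(specs), d1)
  p2 <- writeContigSet(generateContigs(specs), d2)
  for (k in c("fasta", "gff3")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("GFF3 coordinates are 1-based, in range and in layout order", {
  for (str in c("+", "-")) {
    sc <- generateContigs(contigSpec(
      c("trna_trp_A73", "orf1", "trprs_a1"), strand = str, seed = 77,
      contig = "ctg"))
    tr <- sc$truth$features
    L <- nchar(as.character(sc$contigs[["ctg"]]))
    expect_true(all(tr$start >= 1 & tr$end <= L & tr$start <= tr$end))
    # transcription order along the strand follows the layout order
    ord <- if (str == "+") order(tr$start) else order(-tr$start)
    expect_identical(tr$template[ord], c("trna_trp_A73", "orf1",
                                         "trprs_a1"))
    # strand-aware extraction recovers the planted tRNA exactly
    feats <- loadFeatures(sc$features, sc$contigs)
    planted <- generateTrna("Trp", pair = "G-C", n73 = "A", vArmLen = 0,
                            seed = 77 * 1000L + 1L, id = "x")$sequence
    i <- which(S4Vectors::mcols(feats)$label == "trna_trp_A73")
    expect_identical(S4Vectors::mcols(feats)$sequence[i], planted)
  }
})

test_that("layout truth marks operons only when gaps are compatible", {
  tight <- generateContigs(contigSpec(c("trna_trp_A73", "orf1",
                                        "trprs_a1"),
                                      intergenicGap = 30, seed = 2))
  wide <- generateContigs(contigSpec(c("trna_trp_A73", "orf1",
                                       "trprs_a1"),
                                     intergenicGap = 200, seed = 2))
  expect_identical(tight$truth$operons$pattern, "tRNA_ORF1_TrpRSA1")
  expect_identical(nrow(wide$truth$operons), 0L)
})
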